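# Dataset I/O, Bemis-Murcko scaffold splitting, evaluation metrics, and the
# deterministic fixture-molecule generator that makes the whole pipeline
# testable without external data.

#' Read a labelled property dataset from CSV
#'
#' The CSV must contain a `smiles` column; every other column (or the ones
#' named in `labelCols`) becomes a task. Empty cells are missing labels.
#' Classification columns must contain only 0, 1 or empty cells.
#'
#' @param path CSV file.
#' @param taskType "classification" or "regression", recycled per column.
#' @param labelCols optional character vector naming the label columns.
#' @return a [LabeledSet-class].
#' @export
readLabeledCsv <- function(path, taskType = "classification", labelCols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!"smiles" %in% names(df))
    stop("missing 'smiles' column in ", path, call. = FALSE)
  if (is.null(labelCols)) labelCols <- setdiff(names(df), "smiles")
  if (length(labelCols) == 0L) stop("no label columns found", call. = FALSE)
  taskType <- rep_len(taskType, length(labelCols))
  labels <- matrix(NA_real_, nrow(df), length(labelCols),
                   dimnames = list(NULL, labelCols))
  for (j in seq_along(labelCols)) {
    raw <- trimws(df[[labelCols[j]]])
    filled <- which(nzchar(raw) & !is.na(raw))
    v <- suppressWarnings(as.numeric(raw[filled]))
    if (any(is.na(v)))
      stop("unparsable label in column '", labelCols[j], "' at row ",
           filled[which(is.na(v))[1L]], call. = FALSE)
    if (taskType[j] == "classification" && !all(v %in% c(0, 1)))
      stop("non-binary label in classification column '", labelCols[j],
           "' at row ", filled[which(!v %in% c(0, 1))[1L]], call. = FALSE)
    labels[filled, j] <- v
  }
  new("LabeledSet", smiles = as.character(df$smiles), labels = labels,
      taskType = taskType)
}

#' Write a labelled set to CSV (round-trips with [readLabeledCsv()])
#' @param ds a [LabeledSet-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeLabeledCsv <- function(ds, path) {
  df <- data.frame(smiles = ds@smiles, check.names = FALSE)
  lab <- ds@labels
  if (is.null(colnames(lab))) colnames(lab) <- paste0("task", seq_len(ncol(lab)))
  for (j in seq_len(ncol(lab))) df[[colnames(lab)[j]]] <- lab[, j]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The ring-and-linker framework: terminal (degree-1) atoms are pruned
#' iteratively until none remain, leaving ring systems and the acyclic
#' linkers between them; the result is returned as canonical SMILES.
#' Acyclic molecules have an empty framework and return `""`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of scaffold SMILES (same length).
#' @export
murckoScaffold <- function(smiles) {
  vapply(smiles, function(s) {
    g <- parseSmiles(s)
    if (!any(g@bondInRing)) return("")
    keep <- rep(TRUE, nAtoms(g))
    bonds <- g@bonds
    repeat {
      deg <- integer(nAtoms(g))
      for (b in seq_len(nrow(bonds))) {
        if (keep[bonds[b, 1L]] && keep[bonds[b, 2L]]) {
          deg[bonds[b, 1L]] <- deg[bonds[b, 1L]] + 1L
          deg[bonds[b, 2L]] <- deg[bonds[b, 2L]] + 1L
        }
      }
      leaves <- which(keep & deg <= 1L)
      if (length(leaves) == 0L) break
      keep[leaves] <- FALSE
    }
    if (!any(keep)) return("")
    idx <- which(keep)
    remap <- integer(nAtoms(g)); remap[idx] <- seq_along(idx)
    bkeep <- keep[bonds[, 1L]] & keep[bonds[, 2L]]
    canonicalFromParts(g@elements[idx], g@charges[idx],
                       matrix(remap[bonds[bkeep, , drop = FALSE]], ncol = 2L),
                       g@bondOrders[bkeep])
  }, character(1), USE.NAMES = FALSE)
}

#' Scaffold-based train/valid/test split
#'
#' Molecules are grouped by Bemis-Murcko scaffold (acyclic molecules form
#' singleton groups keyed by their canonical SMILES, avoiding one giant
#' empty-scaffold group). Groups are ordered by size descending with ties
#' broken by the scaffold string, then assigned whole: train is filled to at
#' least `ratios[1]`, then valid to at least `ratios[2]`, the remainder is
#' test. No scaffold ever spans two splits.
#'
#' @param ds a [LabeledSet-class] or character vector of SMILES.
#' @param ratios length-3 ratios summing to 1 (default 8:1:1).
#' @param seed stored with the assignment (the greedy fill itself is
#'   deterministic and invariant to input row order).
#' @return a [SplitAssignment-class].
#' @export
scaffoldSplit <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  smiles <- if (is(ds, "LabeledSet")) ds@smiles else as.character(ds)
  stopIfNot(abs(sum(ratios) - 1) < 1e-8, "ratios must sum to 1")
  sc <- murckoScaffold(smiles)
  acyclic <- !nzchar(sc)
  if (any(acyclic)) {
    can <- vapply(smiles[acyclic],
                  function(s) parseSmiles(s)@smiles, character(1))
    sc[acyclic] <- paste0("acyclic:", can)
  }
  groups <- split(seq_along(smiles), sc)
  if (length(groups) < 3L)
    stop("fewer scaffold groups (", length(groups),
         ") than splits; scaffold splitting impossible", call. = FALSE)
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups), method = "radix")  # locale-independent
  groups <- groups[ord]
  n <- length(smiles)
  train <- integer(0); valid <- integer(0); test <- integer(0)
  gi <- 1L
  while (length(train) < ratios[1] * n && gi <= length(groups) - 2L) {
    train <- c(train, groups[[gi]]); gi <- gi + 1L
  }
  while (length(valid) < ratios[2] * n && gi <= length(groups) - 1L) {
    valid <- c(valid, groups[[gi]]); gi <- gi + 1L
  }
  while (gi <= length(groups)) { test <- c(test, groups[[gi]]); gi <- gi + 1L }
  if (length(valid) == 0L || length(test) == 0L)
    stop("scaffold groups too coarse to fill all three splits", call. = FALSE)
  new("SplitAssignment", train = sort(train), valid = sort(valid),
      test = sort(test), ratios = ratios, scaffolds = sc,
      seed = as.integer(seed))
}

#' Serialize / restore a split as JSON index lists
#' @param split a [SplitAssignment-class].
#' @param path JSON file.
#' @return `splitToJson` returns `path` invisibly; `splitFromJson` the object.
#' @export
splitToJson <- function(split, path) {
  jsonlite::write_json(list(train = split@train, valid = split@valid,
                            test = split@test, ratios = split@ratios,
                            scaffolds = split@scaffolds, seed = split@seed),
                       path, digits = NA)
  invisible(path)
}

#' @rdname splitToJson
#' @export
splitFromJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SplitAssignment", train = as.integer(o$train),
      valid = as.integer(o$valid), test = as.integer(o$test),
      ratios = as.numeric(o$ratios), scaffolds = as.character(o$scaffolds),
      seed = as.integer(o$seed))
}

.aurocRank <- function(y, s) {
  pos <- y == 1; neg <- y == 0
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(s)               # average ranks give ties 0.5 credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.auprc <- function(y, s) {
  if (sum(y == 1) == 0L || sum(y == 0) == 0L) return(NA_real_)
  ord <- order(-s, seq_along(s))
  yo <- y[ord]
  prec <- cumsum(yo) / seq_along(yo)
  mean(prec[yo == 1])        # average precision
}

#' Evaluation metrics
#'
#' Classification: AUROC (exact rank formula, ties credited 0.5) and AUPRC
#' (average precision). Regression: RMSE, MAE, Spearman's and Pearson's r.
#' Missing labels are excluded pairwise; multi-task inputs are scored per
#' task and averaged over the tasks where the metric is defined (an AUROC on
#' single-class truth is undefined and reported as NA).
#'
#' @param yTrue numeric vector or matrix of labels (NA = missing).
#' @param yScore numeric vector or matrix of scores, same shape.
#' @param taskType "classification" or "regression".
#' @return named list of metric means plus a `perTask` matrix.
#' @export
computeMetrics <- function(yTrue, yScore, taskType = "classification") {
  if (is.null(dim(yTrue))) yTrue <- matrix(yTrue, ncol = 1L)
  if (is.null(dim(yScore))) yScore <- matrix(yScore, ncol = 1L)
  stopifnot(all(dim(yTrue) == dim(yScore)))
  metricNames <- if (taskType == "classification") c("auroc", "auprc")
  else c("rmse", "mae", "spearman", "pearson")
  perTask <- matrix(NA_real_, ncol(yTrue), length(metricNames),
                    dimnames = list(colnames(yTrue), metricNames))
  for (j in seq_len(ncol(yTrue))) {
    obs <- which(!is.na(yTrue[, j]) & is.finite(yScore[, j]))
    if (length(obs) == 0L) next
    y <- yTrue[obs, j]; s <- yScore[obs, j]
    if (taskType == "classification") {
      perTask[j, "auroc"] <- .aurocRank(y, s)
      perTask[j, "auprc"] <- .auprc(y, s)
    } else {
      perTask[j, "rmse"] <- sqrt(mean((s - y)^2))
      perTask[j, "mae"] <- mean(abs(s - y))
      perTask[j, "spearman"] <- suppressWarnings(
        stats::cor(y, s, method = "spearman"))
      perTask[j, "pearson"] <- suppressWarnings(stats::cor(y, s))
    }
  }
  out <- lapply(metricNames, function(m) {
    v <- perTask[, m]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(out) <- metricNames
  out$perTask <- perTask
  out
}

# Ring cores and attachable fragments of the fixture grammar. Every core
# SMILES starts with a ring atom, so prefixing an attachable fragment always
# yields a valid molecule. Terminal groups may appear only leftmost.
.fixtureCores <- c(
  "c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1", "c1cc[nH]c1", "c1cncnc1",
  "c1cnccn1", "c1cc[nH]n1", "c1cscn1", "c1ccc2ccccc2c1", "c1ccc2ncccc2c1",
  "c1ccc2[nH]ccc2c1", "c1ccc2occc2c1", "C1CCCCC1", "C1CCCC1", "C1CC1",
  "C1CCC1", "C1CCOC1", "C1CCNCC1", "C1CNCCN1", "C1COCCN1", "C1CCOCC1",
  "C1CCSCC1", "c1ccc(-c2ccccc2)cc1", "c1ccc(Oc2ccccc2)cc1",
  "c1ccc(Cc2ccccc2)cc1", "c1ccc(-c2ccncc2)cc1", "C1CCC2(CC1)CCCCC2")

.fixtureLinkers <- c("C", "CC", "CCC", "CC(C)", "C(=O)", "CC(=O)", "OC(=O)",
                     "NC(=O)", "CO", "CN", "CS", "OCC", "CN(C)", "OC", "NC")

# terminal groups saturate their leftmost atom and may only open the string
.fixtureTerminals <- c("", "F", "Cl", "Br", "O", "N", "OC", "NC",
                       "FC(F)(F)", "N#C")

#' Generate deterministic drug-like fixture molecules
#'
#' Composes valid SMILES from a closed grammar: a ring core (28 distinct
#' aromatic/saturated mono-, bi- and spiro-cyclic systems) prefixed by up to
#' `complexity` chain fragments (alkyl, carbonyl, ether, amine, nitrile,
#' trifluoromethyl, ...) and an optional terminal substituent. Every
#' generated string parses; at `n >= 100` the set covers at least 20
#' distinct Bemis-Murcko scaffolds with overwhelming probability.
#'
#' @param n number of molecules.
#' @param seed RNG seed (same seed, same list).
#' @param complexity maximum number of chained prefix fragments (>= 0).
#' @return character vector of `n` SMILES.
#' @export
generateFixtureMolecules <- function(n, seed = 1L, complexity = 2L) {
  stopIfNot(n >= 1L, "n must be >= 1")
  withSeed(seed, {
    vapply(seq_len(n), function(i) {
      core <- sample(.fixtureCores, 1L)
      k <- sample(0:max(0L, complexity), 1L)
      chain <- if (k > 0L)
        paste(sample(.fixtureLinkers, k, replace = TRUE), collapse = "") else ""
      term <- if (k > 0L) sample(.fixtureTerminals, 1L) else ""
      paste0(term, chain, core)
    }, character(1))
  })
}

#' Fixture molecules with synthetic labels
#'
#' Labels are a stated function of a computed descriptor, so tasks are
#' learnable by construction: classification is lipophilicity (logP) above
#' the set median; regression is the logP value itself.
#'
#' @param n,seed,complexity passed to [generateFixtureMolecules()].
#' @param taskType "classification" or "regression".
#' @return a [LabeledSet-class].
#' @export
fixtureLabeledSet <- function(n, seed = 1L, complexity = 2L,
                              taskType = "classification") {
  smiles <- generateFixtureMolecules(n, seed, complexity)
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("m", seq_len(n)))))
  logP <- as.numeric(ChemmineR::propOB(sdf)$logP)
  y <- if (taskType == "classification")
    as.numeric(logP > stats::median(logP)) else logP
  new("LabeledSet", smiles = smiles,
      labels = matrix(y, ncol = 1L, dimnames = list(NULL, "y")),
      taskType = taskType)
}
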