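# Additional knowledge attached to the K node: 200 molecular descriptors and
# a 512-bit path-based topological fingerprint, plus the robust descriptor
# normalizer used to put heterogeneous descriptor scales on a common footing.

.atomMass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
               P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
               B = 10.81, Si = 28.085, Se = 78.971, As = 74.922)
.atomEN <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98, P = 2.19,
             S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66, B = 2.04, Si = 1.90,
             Se = 2.55, As = 2.18)
.valenceElectrons <- c(C = 4, N = 5, O = 6, F = 7, S = 6, P = 5, Cl = 7,
                       Br = 7, I = 7, B = 3, Si = 4, Se = 6, As = 5)

.lookup <- function(tab, keys, default) {
  v <- tab[keys]
  v[is.na(v)] <- default
  unname(v)
}

#' Names of the 200-descriptor registry
#'
#' The registry combines OpenBabel physicochemical properties with
#' deterministic 2D graph-topological descriptors (counts, connectivity and
#' shape indices, distance histogram, spectral terms, and Moreau-Broto /
#' centered / Moran autocorrelations over atomic mass, electronegativity,
#' degree, charge, aromaticity and hydrogen count). The order is fixed and
#' the length is exactly 200.
#'
#' @return character vector of length 200.
#' @export
descriptorNames <- function() {
  props <- c("mass", "en", "deg", "chg", "arom", "nH")
  c(
    c("OB_MW", "OB_logP", "OB_TPSA", "OB_MR", "OB_HBA1", "OB_HBA2", "OB_HBD", "OB_nF"),
    c("nAtoms", "nBonds", "nRings", "nAromaticRings", "nAromaticAtoms",
      "nHeteroatoms", "nHalogens", "nRotatableBonds", "nImplicitH", "fracCsp3",
      "netCharge", "nPosCharged", "nNegCharged", "meanDegree", "maxDegree"),
    paste0("count_", c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")),
    paste0("ringSize", 3:8),
    paste0("degCount", 1:4),
    c("nSingleBonds", "nDoubleBonds", "nTripleBonds", "nAromaticBonds", "nRingBonds"),
    c("wiener", "zagreb1", "zagreb2", "randic", "balabanJ", "radius", "diameter",
      "petitjean", "eccConn", "chi0", "chi1", "chi0v", "chi1v",
      "kappa1", "kappa2", "kappa3", "density"),
    paste0("distCount", 1:10),
    c("adjEigMax", "adjEigMin", "graphEnergy", "laplFiedler", "laplEigMax",
      "bcutMassHigh", "bcutMassLow"),
    paste0("walk", 2:5),
    paste0("ATS_", rep(props, each = 7), "_", 1:7),
    paste0("ATSC_", rep(props, each = 7), "_", 1:7),
    paste0("Moran_", rep(props, each = 5), "_", 1:5)
  )
}

# Deterministic shortest-cycle enumeration used for ring-size counts: for
# every ring bond, the smallest cycle through it (BFS with the bond removed).
.ringCycles <- function(g) {
  nb <- nBonds(g)
  if (nb == 0L || !any(g@bondInRing)) return(list())
  n <- nAtoms(g)
  adj <- vector("list", n)
  for (b in seq_len(nb)) {
    i <- g@bonds[b, 1L]; j <- g@bonds[b, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, sort)
  cycles <- list(); seen <- character(0)
  for (b in which(g@bondInRing)) {
    s <- g@bonds[b, 1L]; t <- g@bonds[b, 2L]
    # BFS s -> t avoiding the direct edge
    d <- rep(-1L, n); parent <- rep(NA_integer_, n)
    d[s] <- 0L; queue <- s; head <- 1L
    while (head <= length(queue) && d[t] < 0L) {
      u <- queue[head]; head <- head + 1L
      for (v in adj[[u]]) {
        if ((u == s && v == t) || (u == t && v == s)) next
        if (d[v] < 0L) { d[v] <- d[u] + 1L; parent[v] <- u; queue <- c(queue, v) }
      }
    }
    if (d[t] < 0L) next
    p <- t
    while (p[1L] != s) p <- c(parent[p[1L]], p)
    key <- paste(sort(p), collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); cycles[[length(cycles) + 1L]] <- p }
  }
  cycles
}

#' Compute the raw 200-descriptor vector of a molecule
#'
#' Deterministic for a fixed molecule. Descriptors that are undefined for a
#' given structure (e.g. connectivity indices of a single-atom molecule)
#' yield non-finite entries rather than errors; the
#' [DescriptorNormalizer-class] maps those to 0 downstream.
#'
#' @param g a [MolecularGraph-class].
#' @return named numeric vector of length 200 (see [descriptorNames()]).
#' @export
computeDescriptors <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  n <- nAtoms(g); m <- nBonds(g)
  el <- g@elements; deg <- integer(n)
  if (m > 0L) for (b in seq_len(m)) for (a in g@bonds[b, ]) deg[a] <- deg[a] + 1L

  # OpenBabel properties; failures become NA, never errors
  ob <- rep(NA_real_, 8)
  names(ob) <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
  pb <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(g@smiles, "m")))
    if (ChemmineR::validSDF(sdf)[1L]) ChemmineR::propOB(sdf) else NULL
  }, error = function(e) NULL)
  if (!is.null(pb)) {
    for (k in names(ob)) if (k %in% names(pb)) ob[k] <- as.numeric(pb[[k]][1L])
  }
  if (!is.finite(ob["MW"]))
    ob["MW"] <- sum(.lookup(.atomMass, el, 40)) + 1.008 * sum(g@nH)

  cycles <- .ringCycles(g)
  cycleSizes <- vapply(cycles, length, integer(1))
  aromCycles <- vapply(cycles, function(p) all(g@aromatic[p]), logical(1))

  rotatable <- if (m > 0L)
    sum(g@bondOrders == 1 & !g@bondInRing &
          deg[g@bonds[, 1L]] >= 2L & deg[g@bonds[, 2L]] >= 2L)
  else 0L

  basic <- c(
    nAtoms = n, nBonds = m,
    nRings = if (m > 0L) m - n + 1L else 0L,   # cyclomatic (connected graph)
    nAromaticRings = sum(aromCycles),
    nAromaticAtoms = sum(g@aromatic),
    nHeteroatoms = sum(!el %in% c("C", "H")),
    nHalogens = sum(el %in% c("F", "Cl", "Br", "I")),
    nRotatableBonds = rotatable,
    nImplicitH = sum(g@nH),
    fracCsp3 = if (sum(el == "C") > 0) sum(el == "C" & g@hybrid == "sp3") / sum(el == "C") else NA_real_,
    netCharge = sum(g@charges),
    nPosCharged = sum(g@charges > 0L),
    nNegCharged = sum(g@charges < 0L),
    meanDegree = mean(deg),
    maxDegree = max(deg))

  elCount <- vapply(c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
                    function(e) sum(el == e), numeric(1))
  elCount <- c(elCount, other = n - sum(elCount))
  ringSize <- vapply(3:8, function(s) sum(cycleSizes == s), numeric(1))
  degCount <- vapply(1:4, function(d) sum(deg == d), numeric(1))
  bondCounts <- c(
    nSingleBonds = sum(g@bondOrders == 1 & !g@bondAromatic),
    nDoubleBonds = sum(g@bondOrders == 2 & !g@bondAromatic),
    nTripleBonds = sum(g@bondOrders == 3),
    nAromaticBonds = sum(g@bondAromatic),
    nRingBonds = sum(g@bondInRing))

  # topological distance matrix on the atom graph (connected by construction)
  if (n > 1L) {
    ig <- igraph::graph_from_edgelist(g@bonds, directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    D <- igraph::distances(ig)
  } else D <- matrix(0, 1L, 1L)
  up <- upper.tri(D)

  bi <- g@bonds[, 1L]; bj <- g@bonds[, 2L]
  dv <- .lookup(.valenceElectrons, el, 4) - g@nH
  topo <- local({
    wiener <- sum(D[up])
    zagreb1 <- sum(deg^2)
    zagreb2 <- if (m > 0L) sum(deg[bi] * deg[bj]) else 0
    randic <- if (m > 0L) sum(1 / sqrt(deg[bi] * deg[bj])) else NA_real_
    mu <- m - n + 1L
    srow <- rowSums(D)
    balabanJ <- if (m > 0L && all(srow[c(bi, bj)] > 0))
      m / (mu + 1) * sum(1 / sqrt(srow[bi] * srow[bj])) else NA_real_
    ecc <- apply(D, 1L, max)
    radius <- min(ecc); diameter <- max(ecc)
    petitjean <- if (radius > 0) (diameter - radius) / radius else NA_real_
    eccConn <- sum(ecc * deg)
    chi0 <- if (all(deg > 0)) sum(1 / sqrt(deg)) else NA_real_
    chi0v <- if (all(dv > 0)) sum(1 / sqrt(dv)) else NA_real_
    chi1v <- if (m > 0L && all(dv > 0)) sum(1 / sqrt(dv[bi] * dv[bj])) else NA_real_
    p2 <- sum(choose(deg, 2))
    p3 <- 0
    if (m > 0L) {
      adj <- vector("list", n)
      for (b in seq_len(m)) {
        adj[[bi[b]]] <- c(adj[[bi[b]]], bj[b]); adj[[bj[b]]] <- c(adj[[bj[b]]], bi[b])
      }
      for (b in seq_len(m)) {
        u <- bi[b]; v <- bj[b]
        for (a in setdiff(adj[[u]], v)) for (w in setdiff(adj[[v]], u))
          if (a != w) p3 <- p3 + 1
      }
      p3 <- p3 / 2
    }
    kappa1 <- if (m > 0L) n * (n - 1)^2 / m^2 else NA_real_
    kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else NA_real_
    kappa3 <- if (p3 > 0) {
      if (n %% 2L == 1L) (n - 1) * (n - 3)^2 / p3^2 else (n - 3) * (n - 2)^2 / p3^2
    } else NA_real_
    density <- if (n > 1L) 2 * m / (n * (n - 1)) else NA_real_
    c(wiener = wiener, zagreb1 = zagreb1, zagreb2 = zagreb2, randic = randic,
      balabanJ = balabanJ, radius = radius, diameter = diameter,
      petitjean = petitjean, eccConn = eccConn, chi0 = chi0, chi1 = randic,
      chi0v = chi0v, chi1v = chi1v, kappa1 = kappa1, kappa2 = kappa2,
      kappa3 = kappa3, density = density)
  })

  distCount <- vapply(1:10, function(d) sum(D[up] == d), numeric(1))

  spectral <- local({
    A <- matrix(0, n, n)
    if (m > 0L) { A[cbind(bi, bj)] <- 1; A[cbind(bj, bi)] <- 1 }
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    L <- diag(deg, n) - A
    lev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    Bm <- A * 0.1; Bm[A == 0] <- 0.001; diag(Bm) <- .lookup(.atomMass, el, 40) / 12
    bev <- eigen(Bm, symmetric = TRUE, only.values = TRUE)$values
    c(adjEigMax = max(ev), adjEigMin = min(ev), graphEnergy = sum(abs(ev)),
      laplFiedler = if (n >= 2L) sort(lev)[2L] else NA_real_,
      laplEigMax = max(lev), bcutMassHigh = max(bev), bcutMassLow = min(bev))
  })

  walks <- local({
    A <- matrix(0, n, n)
    if (m > 0L) { A[cbind(bi, bj)] <- 1; A[cbind(bj, bi)] <- 1 }
    Ak <- A
    out <- numeric(4)
    for (k in 1:4) { Ak <- Ak %*% A; out[k] <- sum(Ak) }
    names(out) <- paste0("walk", 2:5)
    out
  })

  P <- cbind(mass = .lookup(.atomMass, el, 40),
             en = .lookup(.atomEN, el, 2.5),
             deg = deg, chg = as.numeric(g@charges),
             arom = as.numeric(g@aromatic), nH = as.numeric(g@nH))
  ats <- numeric(0); atsc <- numeric(0); moran <- numeric(0)
  for (p in colnames(P)) {
    x <- P[, p]; xc <- x - mean(x)
    for (lag in 1:7) {
      sel <- up & D == lag
      ats <- c(ats, sum(x[row(D)[sel]] * x[col(D)[sel]]))
      atsc <- c(atsc, sum(xc[row(D)[sel]] * xc[col(D)[sel]]))
    }
  }
  for (p in colnames(P)) {
    x <- P[, p]; xc <- x - mean(x); ss <- sum(xc^2)
    for (lag in 1:5) {
      sel <- up & D == lag
      W <- sum(sel)
      moran <- c(moran, if (W > 0 && ss > 0)
        (n / (2 * W)) * (2 * sum(xc[row(D)[sel]] * xc[col(D)[sel]])) / ss
        else NA_real_)
    }
  }

  out <- c(ob, basic, elCount, ringSize, degCount, bondCounts, topo,
           distCount, spectral, walks, ats, atsc, moran)
  out <- as.numeric(out)
  names(out) <- descriptorNames()
  stopifnot(length(out) == 200L)
  out
}

#' Hashed path-based topological fingerprint
#'
#' OpenBabel's FP2 fingerprint (hashed linear fragments of up to seven atoms,
#' 1024 bits) folded by OR-ing equal-sized blocks down to `nBits` bits.
#' Bond-less molecules have no paths to hash and return the all-zero vector.
#'
#' @param g a [MolecularGraph-class].
#' @param nBits output length; must divide 1024. Default 512.
#' @return numeric 0/1 vector of length `nBits`.
#' @export
computeFingerprint <- function(g, nBits = 512L) {
  stopifnot(is(g, "MolecularGraph"))
  if (1024L %% as.integer(nBits) != 0L)
    stop("nBits must divide 1024", call. = FALSE)
  if (nBonds(g) == 0L) return(numeric(nBits))
  bits <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(g@smiles, "m")))
    fp <- ChemmineR::fingerprintOB(sdf, "FP2")
    as.numeric(as.matrix(fp)[1L, ])
  }, error = function(e) numeric(1024L))
  if (length(bits) != 1024L) bits <- numeric(1024L)
  folds <- matrix(bits, nrow = as.integer(nBits))
  as.numeric(rowSums(folds) > 0)
}

#' Fit a robust descriptor normalizer on a corpus
#'
#' Per-descriptor location is the median over finite entries; scale is a
#' normal-consistent IQR estimate (IQR / 1.349). Descriptors that are
#' constant (or all non-finite) in the corpus get scale 1 so the transform
#' stays defined.
#'
#' @param corpus numeric matrix (molecules x 200) of raw descriptors, or a
#'   list of raw descriptor vectors.
#' @param clipBound clip bound for normalized values, in z-score units.
#' @return a [DescriptorNormalizer-class].
#' @export
fitNormalizer <- function(corpus, clipBound = 10) {
  if (is.list(corpus)) corpus <- do.call(rbind, corpus)
  if (is.null(corpus) || nrow(corpus) == 0L)
    stop("cannot fit a normalizer on an empty corpus", call. = FALSE)
  loc <- apply(corpus, 2L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) 0 else stats::median(x)
  })
  sc <- apply(corpus, 2L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(1)
    s <- stats::IQR(x) / 1.349
    if (!is.finite(s) || s <= 0) 1 else s
  })
  new("DescriptorNormalizer",
      location = unname(loc), scale = unname(sc),
      clipBound = clipBound, nFitted = nrow(corpus),
      descriptorNames = descriptorNames())
}

#' Apply a fitted normalizer to a raw descriptor vector
#'
#' `z = clip((raw - location) / scale, +/- clipBound)`, with non-finite raw
#' entries imputed to 0 after centering.
#'
#' @param nz a [DescriptorNormalizer-class].
#' @param raw numeric vector matching the normalizer's length.
#' @return numeric normalized vector (finite everywhere).
#' @export
applyNormalizer <- function(nz, raw) {
  stopifnot(is(nz, "DescriptorNormalizer"))
  if (length(raw) != length(nz@location))
    stop("descriptor length mismatch: expected ", length(nz@location), call. = FALSE)
  z <- (raw - nz@location) / nz@scale
  z[!is.finite(z)] <- 0
  clipValue(z, nz@clipBound)
}

#' Assemble the knowledge vector of a molecule
#'
#' Concatenation order is fixed: normalized descriptors (200) then
#' fingerprint bits (512), for a total K-node input dimension of 712.
#'
#' @param g a [MolecularGraph-class].
#' @param nz a fitted [DescriptorNormalizer-class].
#' @return a [KnowledgeVector-class].
#' @export
buildKnowledgeVector <- function(g, nz) {
  raw <- computeDescriptors(g)
  new("KnowledgeVector",
      descriptors = unname(applyNormalizer(nz, raw)),
      fingerprint = computeFingerprint(g),
      rawDescriptors = unname(raw))
}

#' Persist / restore a normalizer as JSON
#' @param nz a [DescriptorNormalizer-class].
#' @param path JSON file path.
#' @return `normalizerToJson` returns `path` invisibly; `normalizerFromJson`
#'   the restored object.
#' @export
normalizerToJson <- function(nz, path) {
  jsonlite::write_json(list(location = nz@location, scale = nz@scale,
                            clipBound = nz@clipBound, nFitted = nz@nFitted,
                            descriptorNames = nz@descriptorNames),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname normalizerToJson
#' @export
normalizerFromJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DescriptorNormalizer", location = o$location, scale = o$scale,
      clipBound = o$clipBound, nFitted = as.integer(o$nFitted),
      descriptorNames = o$descriptorNames)
}
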