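# LiGhT — knowledge-guided line-graph transformer for molecules

Molecular property prediction (ADMET endpoints, target bio-activity,
physicochemical properties) is chronically label-poor: assays are expensive,
datasets are small, and scaffold-split generalization is hard. This package
implements a self-supervised remedy for R users: a **line-graph
transformer** pre-trained with a **knowledge-guided masked-graph
objective**, whose frozen or finetuned representations transfer to
downstream property tasks. It is aimed at cheminformaticians who want a
fully inspectable, dependency-light implementation of this model family —
every forward and backward pass is plain R matrix algebra, verified against
finite differences.

## The model

A molecule parsed from SMILES becomes a heavy-atom graph
G = (V, E), then its *line graph*: one node per bond, nodes adjacent iff
their bonds share an atom, so bond features enter on equal terms with atom
features. Node `v̂_ij` is embedded as

    h = concat(Wv·x_i + Wv·x_j, We·x_e)

and encoded by L transformer layers whose attention is biased by molecular
structure:

    A = softmax(Q·Kᵀ/√Dh + Aᵖ + Aᵈ)

where `Aᵖ` encodes each pair's shortest path (a per-position projection
bank averaged over the path's initial node embeddings) and `Aᵈ` a GELU MLP
of the clipped hop distance. Each graph is augmented with a **knowledge
node** connected to every node and initialized from 712 numbers — 200
molecular descriptors plus a 512-bit hashed path fingerprint.

Pre-training corrupts each graph (nodes selected at rate 0.5; replaced by a
learned mask token / random node / kept at 8:1:1; knowledge entries masked
at the same rate) and minimizes

    L = CE(node types) + RMSE(masked descriptors) + BCE(masked fingerprint bits)

Transfer runs either as finetuning — with layer-wise learning-rate decay,
top-layer re-initialization, FLAG adversarial feature augmentation, and
L2-SP regularization, all independently switchable — or as feature
extraction, where pooled embeddings serve as *neural fingerprints* for
kNN probing.

## Worked example

```r
library(LiGhT)

## deterministic drug-like fixture molecules with learnable labels
ds    <- fixtureLabeledSet(60, seed = 303)          # logP-above-median classes
split <- scaffoldSplit(ds, ratios = c(.8, .1, .1))  # Bemis-Murcko groups
split
#> SplitAssignment: 48 train / 6 valid / 6 test; 26 scaffold groups

## desk-scale pre-training (2 layers, 32 hidden)
cfg <- lightConfig(nLayers = 2, hidden = 32, nHeads = 2, pathDim = 8,
                   distDim = 8, maxPathNodes = 4, dropout = 0)
pre <- pretrainRun(ds@smiles[split@train], cfg, nSteps = 100,
                   batchSize = 16, lr = 3e-3, lrSchedule = "warmup_cosine",
                   seed = 7)
round(range(pre$history$total), 2)
#> [1] 2.62 4.98                                    # three-term loss falls

## finetune with layer-wise lr decay, then probe frozen embeddings
ft <- finetuneRun(pre$model, ds, split,
                  finetuneConfig(baseLr = 2e-3, llrdGamma = 0.95,
                                 epochs = 3, batchSize = 16, seed = 7))
ft$testMetrics$auroc
#> [1] 1                                            # 6 scaffold-held-out mols

fp  <- extractNeuralFingerprints(pre$model, ds@smiles)   # n x 32 matrix
knn <- knnPredict(fp[split@train, ], ds@labels[split@train, 1],
                  fp[split@test, ], k = 5)
computeMetrics(ds@labels[split@test, 1], knn$prob)$auroc
#> [1] 1
```

The numbers above are what this exact script prints: the three-term
pre-training loss falls from 4.98 to 2.62 over 100 steps, the finetuned
head separates the six scaffold-held-out molecules perfectly on this tiny
task, and the frozen-embedding kNN probe also reaches AUROC 1 — the
embeddings carry label-relevant structure before any supervised training.
(Every run is bit-reproducible under its seeds; the end-to-end suite
asserts identical metrics across repeated runs of this pipeline.)

A reference-scale model is one call away (and is only counted, not
trained, anywhere in the tests):

```r
countParameters(initLightModel(lightConfig()))   # 12 layers, 768 hidden
#> [1] 79328836                                     # order 1e8
```

A thin CLI over the same functions lives in `inst/cli/light.R`
(`fixtures`, `split`, `pretrain`, `finetune`, `extract` subcommands).

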