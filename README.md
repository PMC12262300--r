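# rcnet

Predicting whether an enzyme catalyzes a reaction, with reaction-center-aware
graph encoders.

Most enzymes carry uncharacterized secondary activities, and testing
candidate enzyme-reaction pairs in the laboratory is slow. `rcnet` scores
the hypothesis that an amino-acid sequence significantly catalyzes a given
reaction (its full set of reactants and products), so that *de novo*
enzyme-reaction pairs can be pre-screened in silico. It is aimed at
metabolic engineers mapping computed reactions onto candidate sequences and
at evolutionary biologists reasoning about underground metabolism.

## The model

Both inputs are mapped into one vector space and scored by a two-tower head:

```
p(catalysis) = sigmoid( < z_rxn , W_p e_prot > )
```

where `e_prot` is a precomputed 1280-dimensional protein-language-model
embedding (consumed as input), `W_p` a learned projection, and `z_rxn` the
output of one of five reaction encoders built on directed-edge message
passing over the reactants-and-products graph:

| encoder | aggregation | uses the reaction center (RC) |
|---|---|---|
| `rc_aggregated` | virtual-node embedding | virtual node wired to all RC atoms |
| `rc_connected` | mean of atom embeddings | virtual node wired to all RC atoms |
| `bag_of_molecules` | mean of atom embeddings | no |
| `cgr` | mean of condensed-node embeddings | via the atom map |
| `morgan` | projected count-fingerprint difference | no |

The RC — the atoms whose bonding environment changes — is derived from a
total atom map or by applying minimal reaction operators. With `M` message
passings, the `rc_aggregated` embedding depends on features within `M - 1`
bonds of the RC and on nothing else; `M = 4` (a three-bond window) is the
default. Training minimizes the weighted binary cross-entropy
`-[ m p y log s(x) + (1-y) log(1-s(x)) ]` with `m = p = 3`.

Generalization is measured with two alignment-based similarity metrics —
RCMCS (atoms in the RC-containing maximum common subgraph over the larger
reaction's atom count) and GSI (identities in a local alignment over the
longer sequence) — which drive a stratified similarity split: whole
single-linkage clusters are sampled into the test fold under ascending
similarity bounds, so test items fall into declared bands of maximum
similarity to the training pool, verified by measurement. Negatives are
sampled globally from unobserved pairs (3:1 in training folds, 1:1
elsewhere); at 0.03% observed density and at least 10% assumed coverage of
true promiscuity, a sampled negative is mislabelled with probability below
0.3%.

## A worked example

```r
library(rcnet)

# an ester hydrolysis, atom-mapped; derive its reaction center
r <- parseReaction(
  "[CH3:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]>>[CH3:1][C:2](=[O:3])[OH:6].[CH3:5][OH:4]",
  id = "hydrolysis")
r <- deriveRcFromMap(r)
sideAtoms(r, "reactant")$map[rcAtoms(r)]
#> [1] 2 4 6        # carbonyl carbon, ester oxygen, water oxygen

# similarity to the ethyl ester of the same reaction
r2 <- deriveRcFromMap(parseReaction(
  "[CH3:7][CH2:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]>>[CH3:7][CH2:1][C:2](=[O:3])[OH:6].[CH3:5][OH:4]",
  id = "ethyl"))
rcmcs(r, r2)
#> [1] 0.8571429    # 12 shared atoms / 14 atoms in the larger reaction

gsi("ACDEFGHIKL", "ACDEFGWIKL")
#> [1] 0.9          # 9 identities over the longer sequence

# an end-to-end run on generated data
cfg <- readRunConfig(system.file("extdata", "config-example.yaml",
                                 package = "rcnet"))
runPipeline(cfg, seed = 4, outDir = "demo")
ev <- jsonlite::read_json("demo/evaluation.json", simplifyVector = TRUE)
ev$global$accuracy
#> [1] 0.7321429    # held-out accuracy on the small demo dataset
```

The 0.857 RCMCS score says the two hydrolyses share their entire smaller
reaction graph around a common ester RC; the pipeline's `evaluation.json`
also reports per-bin metrics against each test reaction's measured maximum
similarity to the training pool, which is where encoder differences show up.

A shell entry point wrapping the same functions ships in `inst/cli/rcnet`
(`rcnet synth|standardize|similarity|split|train|evaluate|embed|all`).

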