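# stCrosstalk

Cell-type deconvolution and spatially resolved cell–cell communication
inference for spatial transcriptomics (ST), in R.

## The problem

Spot-based ST platforms (10x Visium and similar) measure mixtures: each
capture spot holds up to a few dozen cells. Bead platforms approach
single-cell resolution but still need cell-type identities. And once
cells and types are placed in space, the interesting biology is often
*between* them — which ligand–receptor interactions (LRIs) connect which
sender and receiver cell types, where, and with what downstream effect.

`stCrosstalk` is for analysts with (1) a gene × spot (or gene × cell) ST
count matrix with 2-D coordinates and (2) a labeled scRNA-seq reference.
It provides:

* **Deconvolution** — per unit, a non-negative linear model
  `Y = Xβ + ε` fit under the mean relative-entropy (KL) loss by
  multiplicative updates (`fitNNLM`), where `X` holds the per-type mean
  reference profiles. Single cells get the argmax label (with an
  explicit `"unsure"` class); spots get proportions.
* **Atlas reconstruction** — integer per-type cell counts per spot by
  half-up rounding of `Mβ` with a capacity cap
  (`spotCellCombination`), best-fitting reference cells per spot by
  randomized least squares (`selectSpotCells`), and coordinates sampled
  from a neighborhood-informed law: sector `q` around the spot center is
  chosen with probability `(R_q+1)/Σ(R_i+1)` (`R_q` = same-type ratio of
  the sector's nearest neighbor spot), then the cell is placed at
  `α·d_min/2` from the center (`reconstructAtlas`).
* **Communication scoring** — a directed K-nearest-neighbor cell graph
  in space; for each (sender type A, receiver type B, ligand i,
  receptor j) the co-expressed pair count `C⁰` over graph edges; a
  label-shuffling permutation test `P = #{C^z ≥ C⁰}/Z` giving the
  inter-cellular score `S_inter = 1 − P` for `P < 0.05`; and an
  intracellular score from bounded random walks on a
  co-expression-weighted ligand–receptor–TF knowledge graph,
  `S_intra = logistic(Σ_k θ_k p_k / η_k)` over activated TFs (hit
  probability `p`, step count `η`, expressed targets `θ`). The final
  score is the geometric mean `S = √(S_inter · S_intra)`
  (`scoreCommunications`).
* **Benchmark procedures** — simulated spots from single-cell data with
  exact ground truth (`simulateSpots`), per-spot Pearson/RMSE recovery
  metrics (`evaluateComposition`), a one-sided Wilcoxon spatial
  proximity test, co-expression percentages, and Fisher-exact pathway
  enrichment (`fisherPathwayEnrichment`).
* **A synthetic data generator** (`syntheticScenario`,
  `generateReference`, `generateSpatial`, `generatePrior`) producing
  zoned tissues with a planted, spatially proximal LRI and its
  receptor→TF→target chain, plus decoys — every stage of the package is
  testable offline.

## Worked example

Generate the default synthetic tissue (4 striped cell types, 800 cells,
200 genes, one planted interaction `LIG1→REC1` from type T1 to the
adjacent type T2 with a downstream `TF1 → TGT1/TGT2` chain), score all
communications, and benchmark deconvolution on simulated spots:

```r
library(stCrosstalk)
set.seed(1)
scenario <- syntheticScenario()          # 4 types, 200 genes, 800 cells
tissue   <- generateSpatial(scenario)    # single-cell ST with planted LRI
prior    <- generatePrior(scenario)      # LR pairs, pathway edges, TFs

atlas <- tissue$atlas
atlas
#> CellAtlas: 800 placed cells from 800 spots

tab <- scoreCommunications(atlas, prior, runConfig())
top <- significantCommunications(tab)
print(top[, c("sender", "receiver", "ligand", "receptor",
              "C0", "P", "S_inter", "S_intra", "score")], digits = 3)
#>   sender receiver ligand receptor C0 P S_inter S_intra score
#> 5     T1       T2   LIG1     REC1 89 0   0.999   0.881 0.938

# spot-level benchmark: bin the atlas, deconvolve, score the recovery
ref  <- generateReference(scenario)
sim  <- simulateSpots(atlas, binSize = 0.1)
prof <- buildReferenceProfile(ref$expr, ref$labels,
                              stGenes = geneNames(sim$spots))
comp <- fitNNLM(linearLayer(sim$spots)[rownames(referenceProfile(prof)), ],
                prof, runConfig(minGenes = 1))
met  <- evaluateComposition(comp, sim$truth)
cat(sprintf("mean per-spot Pearson r = %.3f, mean RMSE = %.3f over %d spots\n",
            met$meanPearson, met$meanRMSE, nrow(met$perSpot)))
#> mean per-spot Pearson r = 0.998, mean RMSE = 0.012 over 100 spots
```

Reading the output: the planted interaction is the only ranked
communication — 89 co-expressing sender→receiver edges in the spatial
graph, none of 1000 label shuffles reached that count (`P = 0`, so
`S_inter` is capped at `1 − 1/1001 ≈ 0.999`), and the receiver-side walk
activates `TF1` with both targets expressed
(`S_intra = logistic(2) ≈ 0.881`), giving a combined score of `0.938`.
Decoy pairs either fail the permutation test or, when tissue zoning
makes them spatially "significant", are zeroed by the intracellular
stage because no TF chain is activated. The spot benchmark shows the
composition of ~100 simulated spots recovered almost exactly.

## Command line

A thin CLI wraps the same functions
(`inst/scripts/stcrosstalk`; after installation locate it with
`system.file("scripts", "stcrosstalk", package = "stCrosstalk")`):

```sh
stcrosstalk simulate    --out sim/ --seed 1
stcrosstalk decompose   --st sim/st.tsv --coords sim/coords.tsv \
                        --ref sim/reference.tsv --ref-labels sim/reference_labels.tsv \
                        --mode cell --out dec/ --seed 1
stcrosstalk communicate --atlas dec/atlas.tsv --expr sim/st.tsv \
                        --lri sim/lri.tsv --pathways sim/pathways.tsv \
                        --tfs sim/tfs.txt --out comm/ --seed 1
stcrosstalk benchmark   --mode pathway --targets targets.txt \
                        --gmt sim/pathways.gmt --universe genes.txt --out bench/
```

All subcommands honor `--seed`; repeated runs are byte-identical.

## Documentation

The methods vignette
(`vignettes/spatial-crosstalk-methods.Rmd`) gives the full model
description, parameter meanings and defaults, the generator's design and
its limits, and the package's numerical conventions.
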