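# fragweb

Quantitative plant–leafhopper food webs in fragmented calcareous grasslands.

Habitat fragmentation filters herbivore communities: habitat-specialist
leafhoppers (Auchenorrhyncha) and habitat generalists respond differently to
fragment size, patch isolation and the arable matrix, and that filtering is
visible in the structure of the plant–herbivore food web. `fragweb`
implements the complete analysis chain for a paired small/large fragment
design along connectivity and landscape-composition gradients:

1. **Community data** — transect vegetation surveys (percent cover per
   1 × 5 m plot, plus bare ground and litter) and sweep-net leafhopper counts
   pooled over 6 transects × 3 occasions per fragment. Relative cover of a
   plant species is its cover divided by total plant + bare ground + litter
   cover, averaged over transects.
2. **Web assembly** — a literature diet database (species- or genus-rank food
   plants, monophagy flags) is matched against each fragment's flora. Three
   exclusion rules apply: taxa not identified to species, taxa with unknown
   diets, and — per fragment — taxa none of whose food plants were recorded
   there. Each retained species' pooled abundance `n_j` is then allocated
   over its available food plants proportionally to their mean relative
   covers `c_i` (renormalised over the matched plants):
   `b_ij = n_j · c_i / Σ_k c_k`, giving a quantitative bipartite matrix
   `b` with total `B = Σ b_ij`.
3. **Network indices** — with `p_ij = b_ij / B`, interaction diversity
   `H = −Σ p_ij ln p_ij`; weighted generality
   `G = Σ_j (b_·j/B) exp(H_j)` (effective food plants per leafhopper);
   weighted vulnerability `V = Σ_i (b_i·/B) exp(H_i)`; weighted linkage
   density `LD = (G + V)/2`.
4. **Landscape** — the incidence-function connectivity index
   `S_i = Σ_{j≠i, d_ij ≤ r} exp(−α d_ij) A_j^β` over neighbouring grassland
   patches (defaults α = 0.001 m⁻¹, β = 0.5, r = 2000 m), and a Spearman
   independence check of the three design variables.
5. **Inference** — for each response (specialist/generalist richness ratio
   as a binomial GLM; LD, G and H as Gaussian models) every submodel of the
   global model {arable L, size class S, log10 connectivity C, their two-way
   interactions, richness covariate R} respecting marginality is fitted
   (36 models), ranked by AICc, and coefficients are averaged conditionally
   over the candidate models within 6 AICc units of the best, with
   importance counts, 95% CIs and VIF diagnostics.

Because raw field data of this kind are typically not deposited alongside
the papers that use them, the package ships a **synthetic-study generator**
(`generate_study()`) that emulates the design — 28 fragments, connectivity
20–849, 27–77% arable, 167-species flora, 67 retainable leafhopper species
(29 specialists), 66%/24% monophagy among specialists/generalists, ~5%
excluded specimens — with a known ground-truth effect structure on the logit
of specialist prevalence, so every stage is testable and power-checkable.

## Worked example

The numbered scripts under `analysis/` run the whole chain on the synthetic
study and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # design + surveys + diet (CSV)
Rscript analysis/02_assemble_webs.R   # 28 quantitative webs + exclusion log
Rscript analysis/03_network_metrics.R # H, G, V, LD per fragment
Rscript analysis/04_model_selection.R # AICc averaging, Table-style output
```

Stage 2 prints the specimen bookkeeping (output of the run above):

```
Assembled 28 webs: 1689 links, 127 plant and 67 leafhopper taxa
Specimens: 6604 pooled = 6199 retained + 405 excluded (6.1%)
Exclusions by rule:
      diet_unknown no_food_plant_here       unidentified
                33                 23                  6
```

Pooled specimens always equal retained (`B` summed over webs) plus excluded
specimens, exactly — the pipeline refuses to continue otherwise. Stage 4
prints the model-averaged coefficient table; for the specialist/generalist
ratio of this run:

```
Specialist/Generalist : 36 models, 14 candidates, R2(full) = 0.63, max VIF = 1.31
  L     imp= 9     0.214 +/- 0.653
  S     imp=14    -0.899 +/- 0.666 **
  C     imp=12     0.481 +/- 0.786
  S:C   imp= 6     0.935 +/- 1.069
  ...
```

`imp` is the number of candidate models containing the term; estimates are
conditional averages with 95% CI half-widths; the planted positive
size-by-connectivity interaction (truth 1.13 on the standardized logit
scale) is recovered at 0.935 ± 1.069 here.

In R the same chain is one call:

```r
library(fragweb)
study <- generate_study(seed = 1)
pipeline <- run_pipeline(study)
model_table(pipeline)
```

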