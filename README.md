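# npqcell

Single-cell decomposition of nonphotochemical quenching (NPQ) from
chlorophyll-fluorescence time series.

## The problem

In pulse-amplitude-modulated (PAM) fluorescence microscopy, a saturating
pulse (SP) transiently saturates photochemistry so that the emitted
fluorescence — the maximal yield Fm (dark) or Fm′ (light) — reports only the
non-photochemical de-excitation of photosystem II. Imaging a field of
immobilized microalgae through a high-light/dark protocol with an SP every
20 s yields, for every cell, a 91-point Fm′ trace shaped by three
overlapping quenching processes: fast, reversible energetic quenching
(**qE**), minutes-scale state transitions that transiently *raise* Fm′
(**qT**), and slow, poorly reversible photoinhibition (**qI**).

`npqcell` is for photosynthesis researchers who want per-cell, per-component
quenching phenotypes from such movies (or from pre-extracted trace tables):
how much qE, qT and qI each cell expresses, how variable these traits are
across an isogenic population, and how they co-vary.

## The method

Traces are treated under the working hypothesis that a mixed trace is a
linear combination of elementary component traces. The pipeline:

1. **Filter** — drop cells with area < 5 px; sum-normalize each trace
   (`y ← y / Σy`); drop traces whose nearest neighbour is further than
   `D = 0.01`.
2. **Sparse dictionary learning** — on a balanced subsample of
   `n_samples = 300` traces, learn `N_D = 10` unit-norm atoms and sparse
   codes by minimizing

   ```
   min_{D,X}  ½ ‖Y − XD‖²_F + λ ‖X‖₁ ,   λ = 10⁻⁶
   ```

   (alternating lasso coding / atom updates); every trace becomes a
   10-dimensional code.
3. **LDA** — a 4-class linear discriminant analysis (between- vs pooled
   within-class scatter) projects codes to a 3D space (`c − 1 = 3`).
4. **Axis alignment** — the principal directions of the qT-, qE- and
   qI-expressing training clouds form an oblique transfer matrix `R`;
   coordinates become `R⁻¹·(Tᵗx)`, and each axis origin is anchored by the
   populations known to lack that component. The result: named per-cell
   scores (qT, qE, qI).
5. **Heterogeneity statistics** — same-cell vs cell-to-population distance
   distributions across protocol repeats (`D_ij` matrix, Levene test),
   coefficients of variation, 8×8 grid-trace maps, and affine (total
   least squares) trend fits in the score planes.

A fully parameterized synthetic-data generator (elementary first-order
kinetics, log-normal amplitude dispersion, multiplicative noise, rendered
movies with ground truth) provides the test bed; a watershed segmentation
path extracts traces from movies.

## Worked example

```r
library(npqcell)
library(dplyr)

protocol <- reference_protocol()          # 15 min HL + 15 min dark, SP / 20 s
length(pulse_times(protocol))             # 91

# four single-component training populations (150 cells each here)
specs    <- reference_population_specs(seed = 1, n_cells = 150)
training <- lapply(specs, simulate_population, protocol = protocol)
model    <- train_npq_model(training, seed = 1)
glance(model)
#> # A tibble: 1 × 7
#>   n_training n_atoms lambda dict_objective fisher_separability R_condition  seed
#> 1        600      10   1e-6       0.000600                32.7        1.07     1

# score a wild-type-like mixture (qE + qT) and inspect the trait space
wt     <- simulate_population(population_spec("wt", n_cells = 200, seed = 42),
                              protocol)
scores <- score_traces(wt, model)
head(scores, 3)
#>   cell_id qT_score qE_score qI_score population repeat
#> 1 wt_0001    0.383    0.314  -0.0386 wt              1
#> 2 wt_0002    0.491    0.120  -0.0225 wt              1
#> 3 wt_0003    0.592    0.165  -0.0308 wt              1

# noise vs biology: two consecutive repeats on the same cells
pair <- simulate_repeat_pair(population_spec("pop_qt", n_cells = 176, seed = 7),
                             protocol)
rd <- repeat_distance_matrix(score_traces(pair[[1]], model),
                             score_traces(pair[[2]], model))
rd
#> <npq_repeat_distance> 176 cells; sd(D_ii) = 0.0163 sd(D_ij) = 0.0559 ;
#>   levene p = < 2.22e-16
```

The wild-type cells land at positive qT (~0.50) and qE (~0.17) scores and
near-zero qI, i.e. both components are detected per cell. The same-cell
repeat distances (`D_ii`, SD 0.016) are ~3.4× narrower than cell-to-
population distances (`D_ij`, SD 0.056): the observed cell-to-cell spread
is biological heterogeneity, not measurement noise — here by construction
(amplitudes are redrawn per cell, noise per repeat), on real data the same
contrast carries the inference. `plot_scores()`, `autoplot()` methods and
`plot_traces()` render the standard figures; `tidy()`/`glance()` give
broom-style summaries.

A thin command-line front end wraps the same functions
(`inst/cli/npqcell.R`, subcommands `simulate`, `segment`, `extract`,
`train`, `score`, `analyze`).

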