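# ctcdyn

Fluctuation-based analysis of molecular dynamics trajectories: pairwise
stiffness, dynamic cross-correlation maps, distance distributions,
time-delayed correlations, and **conditional time-delayed correlation (CTC)
causality** — which member of a correlated residue pair *drives* and which
*follows*.

## Who this is for

Structural biophysicists analysing MD trajectories of allosteric proteins
(the motivating system is nucleotide-dependent switching in Ras-family
GTPases). An equal-time correlation map is symmetric and cannot orient
information flow; comparing the forward and backward *lagged* correlations
of a pair can. ctcdyn packages that pipeline with synthetic
Ornstein–Uhlenbeck ground truth so every estimator is validated without MD
data.

## The quantities

For mean-centered fluctuations ΔR_i(t) (after rigid-body superposition):

* **Stiffness** — each pair is a harmonic spring (Gaussian-network picture):

  `k_ij = kB·T / ⟨|ΔR_i − ΔR_j|²⟩`   [kcal/mol·Å²; 1 kcal/mol·Å² = 694.769 pN/nm]

  with per-site means over the N−1 partners and an overall constant
  (pair-mean default). Joint low-RMSF + high-stiffness classifies per-site
  *stability* between two states.
* **Correlation map** — `C_ij = ⟨ΔR_i·ΔR_j⟩ / √(⟨ΔR_i²⟩⟨ΔR_j²⟩) ∈ [−1, 1]`,
  with display thresholds (defaults +0.6 / −0.45) kept out of the math.
* **Time-delayed correlation** — `C_ij(τ) = ⟨ΔR_i(t)·ΔR_j(t+τ)⟩` (truncated
  overlap), normalized by C(0); 1/e decay times by interpolated first
  crossing. A binned conditional-expectation estimator is provided as a
  fidelity check on the direct one.
* **Causality** — at a scan lag, the direction with the larger
  Pearson-normalized lagged correlation is the driver; edges require
  strength ≥ 0.2 and forward−backward asymmetry ≥ 0.1 (both tunable), and
  sub-threshold asymmetry yields *no* edge rather than an arbitrary one.

## Worked example

A 3-site driver chain (site 1 → 2 → 3, unidirectional OU coupling,
coupling/relax = 0.5, 10⁵ steps of 0.05 ps) with known ground truth:

```r
library(ctcdyn)

ch <- make_driver_follower_chain(n_sites = 3, coupling = 0.5, relax = 1,
                                 dt = 0.05, n_steps = 1e5, seed = 11)

K <- pairwise_spring_constants(ch$fluct, temperature = 310)
round(K$k[1, 2], 4)
#> [1] 0.2428                        # kcal/mol.A^2
ko <- as.numeric(overall_spring_constant(K))
c(round(ko, 4), round(convert_stiffness_units(ko), 2))
#> [1]   0.2262 157.15               # kcal/mol.A^2 and pN/nm, side by side

C <- cross_correlation_map(ch$fluct)
round(c(C$C[1, 2], C$C[1, 3]), 3)
#> [1] 0.227 0.043                   # neighbours correlate, 1-3 barely

v  <- connectivity_fluctuation(ch$fluct, 1, 2)   # dR_1 - dR_2
cu <- delayed_autocorrelation(v, max_lag = 5, lag_stride = 0.05)
round(as.numeric(decay_time(cu)), 3)
#> [1] 0.777                         # ps; 1/e decay of the pair's relative motion

causality_scan(ch$fluct, lag = 1)[, c("driver", "follower",
                                      "c_forward", "c_backward", "asymmetry")]
#>   driver follower c_forward c_backward asymmetry
#> 1      2        3     0.281     0.1101     0.171
#> 2      1        2     0.257     0.0899     0.167
```

The scan recovers exactly the ground-truth edges 1→2 and 2→3 — the indirect
1→3 correlation (Pearson-normalized 0.107 analytically) stays below the
strength threshold, and no reversed edge appears.

The interpretation mirrors the biological use case: a stiffer complex has
larger k values and smaller pair fluctuations; long decay times mark
persistent coupled motions; and the driver→follower edges orient the
information flow between switch regions.

## Command line

Every step is also a subcommand (deterministic CSV/JSON artifacts plus a
provenance sidecar; exit codes 0/1/2 = ok/data error/usage error):

```sh
ctcdyn="$(Rscript -e 'cat(system.file("cli", "ctcdyn", package = "ctcdyn"))')"
printf 'kind: chain\nn_sites: 3\nn_steps: 100000\nseed: 11\n' > chain.cfg
Rscript "$ctcdyn" simulate  --spec chain.cfg --out sim/
Rscript "$ctcdyn" stiffness --fluct sim/fluct --out stiff/
Rscript "$ctcdyn" causality --fluct sim/fluct --lag 1 --out caus/
Rscript "$ctcdyn" report    --dir .
```

Other subcommands: `fluct` (PDB/DCD → superposed fluctuation container),
`rmsf`, `xcorr`, `dist`, `ctc`. Lags are ps, temperature K, stiffness
reported in both unit systems.

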