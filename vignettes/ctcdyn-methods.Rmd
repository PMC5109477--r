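---
title: "Fluctuation stiffness, delayed correlations and causality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation stiffness, delayed correlations and causality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcdyn)
```

# The problem

Correlated residue motions carry allosteric information through a protein,
but an equal-time correlation map is symmetric by construction and says
nothing about *direction*: it cannot distinguish the residue whose
fluctuations drive a coupled motion from the residue that follows. ctcdyn
implements a pipeline that quantifies, from an MD trajectory (or a synthetic
stand-in), (i) how stiffly each residue pair is coupled, (ii) which pairs
move together, and (iii) which member of a correlated pair *leads* — the
conditional time-delayed correlation (CTC) approach to causality in residue
dynamics, with Ras-family GTPase switch dynamics as the motivating use case.

# Models and estimators

## Fluctuations

All estimators consume mean-centered fluctuation series
$\Delta R_i(t_k) = R_i(t_k) - \langle R_i \rangle$ computed after rigid-body
superposition of every frame onto a reference frame (least-squares
Kabsch fit, uniform weights, reference = first frame). Site selection
defaults to one C$\alpha$ per protein residue plus the heavy atoms of
non-water, non-ion hetero groups, so a bound nucleotide enters the analysis
the same way the protein does. Residue numbering is kept verbatim from the
source file.

## Pairwise stiffness

Each pair $(i, j)$ is modelled as a harmonic spring in the Gaussian-network
sense. Equipartition for the scalar separation fluctuation gives

$$ k_{ij} \;=\; \frac{k_B T}{\langle (\Delta R_i)^2 \rangle
   - 2 \langle \Delta R_i \cdot \Delta R_j \rangle
   + \langle (\Delta R_j)^2 \rangle }
   \;=\; \frac{k_B T}{\langle | \Delta R_i - \Delta R_j |^2 \rangle}, $$

with 3-D squared norms and dot products, $k_B =
1.98720425864 \times 10^{-3}$ kcal/(mol K), default $T = 310$ K
(physiological). Small separation fluctuations mean stiff coupling. The
denominator is non-negative by construction; a rigidly co-moving pair has
denominator 0 and is flagged as infinite stiffness rather than poisoning
aggregates. Per-site means average over the $N-1$ partners; the *overall*
stiffness is exposed under two aggregations (mean over distinct pairs,
default; mean of per-site means) because the source's defining expression
for the overall constant is ambiguous and both are consistent readings —
they coincide for uniform matrices. Stiffness is reported in
kcal/mol/Å$^2$ and pN/nm side by side
(1 kcal/mol/Å$^2$ = 694.769 pN/nm from the thermochemical calorie and the
Avogadro constant).

Stability is classified jointly: a site is *more stable* in state A when its
RMSF is lower **and** its mean spring constant higher in A; agreement of both
quantities within a relative tolerance (default 2%) is "unchanged", and
discordant combinations — including one-sided ties — are "mixed", since a
tie in one quantity provides no evidence for either state.

## Equal-time correlations and distances

The cross-correlation map is
$C_{ij} = \langle \Delta R_i \cdot \Delta R_j \rangle /
\sqrt{\langle \Delta R_i^2 \rangle \langle \Delta R_j^2 \rangle} \in [-1, 1]$.
Display thresholding (defaults $C \ge 0.6$ positive, $C \le -0.45$ negative,
boundaries inclusive) lives in `threshold_map()` and the report layer, never
in the computation. Pair distance distributions are histograms over the
observed [min, max] range (default 100 bins) normalized to unit integral —
a density per Å, not a unit-sum mass, because distance has continuous
support; a constant series degenerates to one narrow bin carrying all mass.

## Time-delayed correlations

For an ordered pair, $C_{ij}(\tau) = \langle \Delta R_i(t) \cdot
\Delta R_j(t + \tau) \rangle$, estimated with truncated overlap: only frame
pairs with both endpoints inside the trajectory contribute and the
denominator is the count of valid pairs (no padding). At $\tau = 0$ the
ordering is immaterial and $C_{ij}(0) = C_{ji}(0)$ holds exactly, which the
tests assert to $10^{-12}$. Curves are normalized by their value at zero
lag, so autocorrelations start at exactly 1 and the 1/e decay time is read
off as the first downward crossing of $e^{-1}$, linearly interpolated
between lag samples; a curve that never crosses within its lag range
returns a flagged "not reached" value rather than a number.

The *conditional* reading — average $\Delta R_j(t+\tau)$ given
$\Delta R_i(t)$, weighted by the conditioning distribution — equals the
plain lagged expectation by the law of total expectation. Both estimators
are exposed: the direct lagged-product estimator (default) and a
binned-conditional estimator that partitions each component of
$\Delta R_i(t)$ into equal-count bins (default 20), averages
$\Delta R_j(t+\tau)$ within each bin and recombines
$\sum_b p_b \langle \Delta R_i \rangle_b \langle \Delta R_j \rangle_b$
summed over the three components. The binned estimator discards within-bin
covariance, a $\sim 1$–2% bias for Gaussian data at 20 bins; the test suite
requires agreement within 0.05 on normalized curves. Fewer than 10 samples
per bin raises a binning error suggesting fewer bins.

## Causality scan

If fluctuations of $i$ drive those of $j$, the forward correlation
$C_{ij}(\tau)$ exceeds the backward $C_{ji}(\tau)$ at positive lag. The scan
computes both directions for every pair at one scan lag, calls the larger
direction the driver, and emits an edge when
$\max(|c_f|, |c_b|) \ge$ `min_strength` (default 0.2) **and**
$c_f - c_b \ge$ `min_asymmetry` (default 0.1). Below the asymmetry
threshold no edge is emitted — never an arbitrary direction. Edges are
sorted by asymmetry and the output is deterministic.

**Normalization choice (design decision).** Curves follow the
normalize-by-$C(0)$ convention. For the *scan*, however, dividing both
directions by their common $C_{ij}(0)$ is ill-behaved: a weakly
equal-time-correlated pair has a small $C_{ij}(0)$, so the ratio is
unbounded and fixed thresholds in $[0,1]$ lose meaning. Concretely, in the
3-site driver chain used for validation, the *indirect* pair 1→3 has an
analytic $C(0)$-normalized forward value of 1.84 — above any sensible
strength threshold — while its Pearson-normalized value
($C_{ij}(\tau)/\sqrt{C_{ii}(0) C_{jj}(0)}$) is 0.107, well below the
direct-edge values of 0.26–0.29. The scan therefore defaults to Pearson
normalization, which keeps values on a fixed scale, makes the default
thresholds separate direct from indirect influence, and lets the chain
recovery criterion be met *exactly*; `normalization = "c0"` remains
available. This was derived from the analytic lagged-covariance oracle
before the validation tests were written.

The default thresholds are a stated-world choice: white-noise inputs at the
tested frame counts have Pearson-normalized lagged correlations of order
$1/\sqrt{3N} \lesssim 0.01$, two orders below `min_strength`, so null inputs
yield no edges; both thresholds are exposed as tunables at the API and CLI.

# Synthetic ground truth

The generators state a world in which every estimator has a closed-form
answer; they are first-class, tested code.

* **Gaussian ensembles** draw frames i.i.d. with a prescribed per-component
  site covariance $S$, each spatial component independent (isotropy), so
  $\langle \Delta R_i \cdot \Delta R_j \rangle = 3 S_{ij}$ and the stiffness
  denominator is $3(S_{ii} - 2 S_{ij} + S_{jj})$ exactly.
* **OU networks** integrate $dX = -A X\,dt + B\,dW$ per component by
  Euler–Maruyama with an enforced step bound
  $dt \le 0.1/\max|\mathrm{eig}(A)|$ (at that bound the discrete
  autocorrelation $(1 - \lambda dt)^{\tau/dt}$ deviates from
  $e^{-\lambda\tau}$ by under 3% at $\tau = 1/\lambda$ — inside every
  stochastic tolerance used) and a fixed burn-in of 10 relaxation times.
  The stationary covariance solves the Lyapunov equation
  $A S + S A^\top = B B^\top$ (Kronecker solve) and the lagged covariance is
  $e^{-A \tau} S$ (`Matrix::expm`), giving an oracle exact to solver
  tolerance.
* **Driver chains** set $A = \mathrm{relax}\cdot I$ with $-\mathrm{coupling}$
  on the first subdiagonal — site $k$ unidirectionally drives $k+1$ — and
  return the ground-truth edge list. Defaults: relax = 1/ps (picosecond-scale
  fluctuation relaxation, the natural scale for residue-level motions),
  coupling/relax = 0.5, dt = 0.05 ps, $10^5$ steps, scan lag = 1 ps
  (the follower's relaxation time). These values were fixed from the
  analytic oracle before any validation was run.

What the generators *do not* emulate: anharmonicity, multi-state kinetics,
solvent memory, force-field physics, and the slow collective modes of real
proteins. A green recovery test establishes that the estimators detect
asymmetric lagged coupling when it exists and stay silent on null data — it
does not establish that a real 300 ns trajectory has converged sampling, nor
that detected asymmetry in real data implies mechanistic causation.

# Numerical choices

* Exact symmetry of $k$ and $C$ matrices is enforced by mirroring the upper
  triangle, so downstream equality tests are exact rather than
  round-off-limited.
* Zero-variance (frozen) sites yield flagged `NA` entries plus a warning,
  never exceptions, so full-molecule maps survive fixed atoms; rigidly
  co-moving pairs are flagged infinite stiffness and skipped by all
  aggregations.
* Superposition requires ≥ 3 non-collinear sites (second singular value of
  the centered reference > $10^{-8}$ of the first); reflections are
  excluded by the usual determinant correction; the operation is idempotent
  to $10^{-10}$ Å.
* Lags must be multiples of the frame spacing; fractional lags are an
  argument error, not silently rounded.
* Fluctuation containers store full double precision (`%.17g` text), so a
  write/read round trip is bit-exact and CLI artifacts are byte-identical
  across reruns with equal seeds (PNG/HTML excluded).
* All randomness flows through explicit mandatory seeds (`withr::with_seed`
  semantics: the global RNG state is untouched).

# Known limitations

* XTC input is not supported (no reader available in the target
  environment); convert to DCD or multi-model PDB. DCD support covers the
  common CHARMM/NAMD single-precision layout, not X-PLOR double-delta
  headers.
* The causality scan tests a single lag per invocation; scanning a lag grid
  is the caller's loop. Transfer-entropy or regression-based causality is
  out of scope by design.
* Estimates from short trajectories inherit the usual
  $O(1/\sqrt{\text{frames}})$ sampling error; the effective sample count of
  correlated series is smaller by the ratio of the correlation time to the
  frame spacing — decay times of order the trajectory length are not
  measurable.
* The binned-conditional estimator is a fidelity check, not a variance
  improvement; its bin count trades bias against noise and is not
  auto-tuned.
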