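---
title: "Methods: phylogenetic analysis of sexual size dimorphism and Rensch's rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic analysis of sexual size dimorphism and Rensch's rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylorensch)
```

## The scientific problem

Sexual size dimorphism (SSD) — a systematic size difference between the
sexes — is shaped by fecundity selection on females and sexual selection on
males.  Rensch's rule is the macroevolutionary pattern in which male size
diverges faster than female size, so that on a log-log plot of male size
against female size across related species the allometric slope exceeds 1.
Highly eusocial bees add a third morph: sterile female workers, which are
shielded from direct reproductive selection and therefore act as a natural
control when comparing the divergence of queens and males.

`phylorensch` implements the comparative workflow for caste-structured taxa:

1. an SSD index per species from queen and male body size;
2. phylogenetic independent contrasts (PIC) to remove phylogenetic
   non-independence;
3. major-axis (MA) regression of contrasts for each caste pair, with a test
   of the isometry null slope = 1;
4. maximum-likelihood ancestral reconstruction of the SSD index under
   Brownian motion, with along-branch interpolation for painted-tree figures;
5. a synthetic-data module (Yule trees, correlated Brownian caste traits,
   clade-level dimorphism reversals) so that every stage has a verifiable
   ground truth.

Body size is measured as intertegular (thorax) width in millimetres, the
standard age-invariant size proxy in bees.  A transcription of a published
compilation of intertegular widths for 44 corbiculate bee taxa (queens,
males and, where available, workers) ships with the package:

```{r fixture}
traits <- read_trait_table(system.file("extdata", "meliponini_traits.csv",
                                       package = "phylorensch"))
nrow(traits)
head(ssdi_table(traits)[, 1:4], 3)
```

## The SSD index and its conventions

The Lovich–Gibbons index expresses dimorphism as
(larger sex / smaller sex) − 1, signed negative when males are larger.
`compute_ssdi()` implements two conventions:

* **`queen_over_male`** (default): queen/male − 1.  Recomputing the bundled
  table shows this is the formula behind its printed index column — for
  male-biased species the printed values equal queen/male − 1 (e.g.
  queen 2.158 mm, male 2.556 mm gives −0.156), not the sign-flipped
  larger/smaller ratio (which would give −0.184).
* **`ratio_signed`**: the index as originally defined, antisymmetric under
  swapping the sexes.

Both are exposed and tested; the discrepancy between them for male-biased
species is documented rather than silently resolved.  For comparison against
the printed column the package truncates toward zero at three decimals
(fp-safe), because truncation reproduces the majority of the printed values
(0.4258 → 0.425, 0.7775 → 0.777); the bundled column itself mixes truncation
and rounding row by row, and three of its 44 printed values are not
reproducible from their own printed sizes at ±0.002 — the test suite records
these as data defects rather than loosening its tolerance.

`classify_ssd()` calls a species female-biased, male-biased or monomorphic
using a symmetric threshold on the index.  The default threshold is 0.06,
chosen once to cover the six species the source compilation describes as
similar-sized (their largest |index| is 0.058); no threshold reproduces that
compilation's own printed category counts exactly, which is why the counts
are not used as a reference anywhere in the package.

## Independent contrasts

`compute_contrasts()` implements Felsenstein's pruning recursion.  At an
internal node with child values \(x_i, x_j\) on variance-adjusted branches
\(v_i, v_j\):

* standardized contrast \((x_i - x_j) / \sqrt{v_i + v_j}\),
* nodal value \((x_i/v_i + x_j/v_j) / (1/v_i + 1/v_j)\),
* the node's own parent branch is lengthened by \(v_i v_j / (v_i + v_j)\).

Under Brownian motion with rate \(\sigma^2\) the \(n-1\) standardized
contrasts are iid \(N(0, \sigma^2)\); `estimate_bm_rate()` returns the ML
estimator (mean squared contrast).  Numerical choices:

* the recursion requires a rooted, fully bifurcating tree; polytomies must
  be broken first with `resolve_polytomies()`, which inserts zero-length
  branches (the standard soft-polytomy treatment, order driven by a seed);
* a single zero-length child branch is legal — the nodal value collapses to
  that child and the branch-length adjustment vanishes; two zero-length
  branches meeting at one node leave the contrast undefined and raise an
  error;
* child order is fixed by the tree's edge ordering, so contrasts of two
  traits computed on the same tree form correctly co-signed pairs;
* sizes are log10-transformed before contrasts (the scale on which
  allometric slopes are defined); natural logs are deliberately not offered,
  to avoid silent slope-unit mismatches.

The recursion's nodal and root values are tested against the closed-form GLS
estimates computed independently from the Brownian covariance matrix
(`V[i, j]` = shared path length), and against a second PIC implementation
from the `ape` package.

## Major-axis regression and the isometry test

Because both caste sizes are measured on the same scale and both carry
error, the allometric line is fit by major-axis regression — the line
minimizing summed squared *perpendicular* distances.  With (un)centered sums
\(S_{xx}, S_{yy}, S_{xy}\):

\[
\hat\beta \;=\; \frac{S_{yy} - S_{xx} +
  \sqrt{(S_{yy}-S_{xx})^2 + 4S_{xy}^2}}{2S_{xy}},
\qquad r^2 = \frac{S_{xy}^2}{S_{xx}S_{yy}} .
\]

Contrast regressions are fit **through the origin** (uncentered sums,
df = n − 1): contrasts have no meaningful intercept, and the degrees of
freedom printed by the analyses this package reproduces (42 for 44 taxa,
39 for 41 taxa) are only consistent with through-origin fitting.  The
`through_origin = FALSE` variant (df = n − 2) is available for ordinary
bivariate data.

`ma_slope_test()` is the classical MA slope test: residual scores
\(u_i = y_i - b_0 x_i\) and axis scores \(w_i = x_i + b_0 y_i\) are
uncorrelated under \(H_0\!: \beta = b_0\), so
\(F = r_{uw}^2\,\mathrm{df} / (1 - r_{uw}^2) \sim F_{1,\mathrm{df}}\).
With \(b_0 = 1\) this is the isometry test: a significant slope above 1 is
Rensch's rule, below 1 its converse.  Degenerate cases are handled
explicitly: a perfect fit at \(b_0\) returns \(F = 0, p = 1\); a perfect
correlation away from \(b_0\) returns \(p = 0\); an isotropic cloud (no
major axis) and an axis-orthogonal \(b_0\) are errors.  Sign
"positivization" of contrast pairs is applied in plots only — through-origin
MA is invariant to joint sign flips, which the tests assert.

`rensch()` wires these together per caste pair: taxa missing a trait are
dropped per pair (not globally), the tree is pruned per pair, both traits'
contrasts are computed on the identical pruned tree, and studentized
perpendicular residuals beyond |3| are reported, never removed.  In the
bundled table the three taxa without worker measurements (the two solitary
Euglossini and *Trichotrigona extranea*) therefore participate in
male~queen but drop out of the worker pairs, giving 43 and 40 contrasts
respectively.

## Ancestral reconstruction

`ml_ancestral_states()` estimates each internal node's state by re-rooting
the pruning recursion at that node: conditional (value, variance) pairs are
propagated inward from every direction and pooled by inverse variance.
This local estimate equals the GLS/ML estimate under the Brownian
covariance, which the tests verify against the explicit matrix computation
to 1e−8.  Properties asserted in the suite: linearity in the data
(anc(ax + b) = a·anc(x) + b), a root estimate inside the tip range,
unbiasedness under simulated Brownian motion, and invariance of the point
estimates to the (scale-free) rate \(\hat\sigma^2\), which is recorded for
reference only.  No confidence intervals are reported.

Along each branch the state is interpolated linearly between the endpoint
estimates (`interpolate_branch()`).  For interior points under Brownian
motion the ML state given the two endpoints is their length-weighted
average, which is exactly the linear interpolant, so linearity is adopted as
the deterministic, testable rule.  `paint_tree()` renders the map with a
diverging ramp centered at index 0, so male-biased lineages and female-biased
lineages fall on opposite sides of the ramp.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be checked
against a known truth.  `sim_yule_tree()` grows a pure-birth tree forward in
time: with \(k\) lineages the next split waits \(\mathrm{Exp}(k\lambda)\),
and after the \(n\)-th tip appears one final \(\mathrm{Exp}(n\lambda)\)
epoch is added, so the tree is ultrametric by construction and its expected
root height is \(\sum_{k=2}^{n} 1/(k\lambda)\) — a closed form the tests
verify.  A birth–death extension was deliberately left out: pure-birth trees
are sufficient for validating Brownian-motion machinery.

`sim_caste_dataset()` implements the minimal generative model under which
the contrast MA slope has a known target: log10 worker size evolves by
Brownian motion; queen and male log-sizes track the worker deviation through
evolutionary allometric slopes plus independent Brownian noise; and a
positive queen−male intercept offset makes the average species
female-biased.  With `clade_shift = TRUE` the internal clade whose size is
closest to `clade_size` has that offset difference negated — at zero noise
exactly that clade becomes male-biased, emulating the *Melipona*-like
reversal.

Defaults were chosen once to mirror the empirical dataset's structure, and
are stated here with their reasoning:

| parameter | default | rationale |
|---|---|---|
| `n_tips` | 44 | size of the bundled table |
| `lambda` | 1 | expected tree height ≈ 3.3 time units at 44 tips |
| `sigma2_worker` | 0.01 | log10 size spread across tips comparable to the bundled table (≈ 1–8 mm) |
| `slope_queen`, `slope_male` | 1.1, 1.0 | queen size slightly hyperallometric to worker size, males isometric — the qualitative empirical pattern |
| `offset_queen`, `offset_male` | 0.07, 0 | log10(queen/male) ≈ 0.07, i.e. a mean index ≈ +0.18, the non-male-biased average |
| `sigma2_noise` | 5e−4 | per-caste deviation noise giving a log-ratio scatter comparable to the observed index spread |
| `clade_size` | 12 | size of the male-biased clade in the bundled table |

Seeds are mandatory; each generator is a pure function of (arguments, seed)
and restores the caller's RNG stream, and determinism is asserted
byte-for-byte in the tests.

What the generator does **not** emulate: within-species measurement
variance, non-ultrametric sampling, non-Brownian processes (selection,
Ornstein–Uhlenbeck pull, rate shifts), and missing-data patterns.  Passing
simulation-based tests therefore demonstrates the correctness of the
estimators under their stated model, not the adequacy of that model for any
particular empirical dataset.

For type-I-error checks of the isometry test the suite uses data that
satisfy the null *exactly*: either symmetric error on both coordinates of a
bivariate cloud, or the male~queen pair with equal unit slopes (queen and
male then being exchangeable).  The queen~worker pair with noise only on the
queen side has a slightly steeper major axis than the generating slope (a
property of MA with asymmetric error, of order noise/signal ≈ 0.025 at the
defaults), which is why it is used for slope-*recovery* checks at a 0.05
band rather than for size calibration.

## Trees, tolerances, and matching

Chronograms are consumed, never inferred.  `read_phylo_tree()` accepts
Newick and minimal NEXUS (TREES block with optional TRANSLATE; everything
else ignored).  Ultrametricity is checked as a *relative* tip-depth
deviation with default tolerance 1e−6, absorbing the rounding noise dating
software leaves; `rensch()` refuses non-ultrametric trees beyond tolerance
unless `force = TRUE`.  Species matching between tree and table is
case-insensitive with underscores and spaces equivalent, and unmatched
tips/rows are dropped with a warning rather than an error — pruning, not
failing, is the convention of this analysis style.  Pruning preserves path
lengths among retained tips exactly, which the tests assert to 1e−12.

## Interfaces and scope

The package's interface is its functions — `rensch()` as the central fit
returning a classed object with `print`/`summary`/`coef`/`plot` methods,
`ssd_reconstruction()` for the ancestral map, and `rensch_pipeline()` to run
the whole analysis (full run plus a clade-exclusion rerun) from a YAML/JSON
configuration with reproducible CSV/JSON outputs.  A shell entry point was
deliberately not shipped: an analysis package of this kind is driven from R
scripts and configs, and a thin CLI would duplicate `rensch_pipeline()`.

The test suite runs its Monte-Carlo checks at sizes chosen to keep the
routine suite fast while the dedicated acceptance tests use the full study
conditions (e.g. 200-tip trees with 100–200 replicates, 1000 replicates for
test size); these sizes are stated in the test files themselves.

Known limitations: no within-species variance or measurement-error model
(one value per species); no SMA/OLS line fits (MA only, by design); no
lambda/OU transformations of the tree; no confidence intervals on ancestral
states; discrete characters out of scope.
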