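---
title: "Models and methods behind t1revo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind t1revo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

t1revo analyses heterologous-expression assays of the T1R1–T1R3 taste
receptor and maps the resulting response phenotypes onto a phylogeny. This
vignette explains each model, the tunable parameters and their defaults,
the design choices made where the methodology was genuinely open, and what
the synthetic-data generators do and do not emulate.

## Agonist calling

Each well reports a luminescence response of cells transfected with a
receptor pair (or untransfected controls carrying only the signalling
machinery) to a ligand mix. `summarize_responses()` collapses wells to
group means and standard errors (sample SD/√n); groups with one replicate
are kept but flagged untestable. `test_agonists()` runs Welch's
unequal-variance *t*-test, one-tailed (transfected > untransfected for the
same mix), computed from the summary statistics with Satterthwaite degrees
of freedom — algebraically identical to `t.test()` on the raw wells, which
the unit tests verify. P-values are Holm-adjusted within the family of all
mixes tested for one receptor in one experiment; the family choice is a
package decision, since "multiple hypothesis testing" alone does not fix
one, and per-receptor families match how a single receptor's ligand panel
is screened. The default family-wise level is α = 0.05, configurable.
Simulations in the test suite confirm the family-wise false-positive rate
stays at or below α under a global null (2,000 panels of 20 mixes at
n = 6).

## Normalization

Receptors expressed in different experiments differ in transfection
efficiency, which scales all of a receptor's responses multiplicatively.
`normalize_profile()` divides each ligand's background-subtracted mean by
the background-subtracted sucralose mean, pinning sucralose at exactly 1.
Background is the untransfected mean for the same ligand when untransfected
wells for that ligand exist, else the untransfected no-ligand control mean.
Negative normalized values are preserved at this stage. Note the exact
cancellation property: a multiplicative factor applied to the
*receptor-driven* signal cancels in the ratio, but a factor applied to raw
wells only cancels exactly when the subtracted background is itself scaled
or zero; the generator's batch effect therefore multiplies transfected
wells (signal plus receptor baseline), which the normalization cancels
exactly in the noise-free limit.

## Hill fits

`fit_hill()` fits `B + E_max·c^h/(EC50^h + c^h)` by bounded least squares
(`optim`, L-BFGS-B), multi-started from the concentration quartiles for
EC50 and Hill slopes 1 and 2, keeping the best optimum. Bounds:
`h ∈ [0.5, 10]` (slopes outside this range are not biologically
interpretable for these receptors and destabilize the fit), `E_max, B ≥ 0`,
EC50 within a 100-fold band around the observed concentrations. At least 4
distinct concentrations are required; flat series converge honestly to
`E_max ≈ 0` with `B` at the series level. Validation: noiseless curves are
recovered to better than 1e-3 relative; with Gaussian noise (sd 2 response
units, 6 replicates at each of 8 concentrations) the median EC50 error
over 50 simulations is well under 25%.

## Synergy against the additive proxy

A true additive expectation for a two-ligand mix is unavailable from raw
luminescence, so the proxy is the sum of the two single-ligand responses
minus one no-ligand untransfected background (`additive_estimate()`), which
puts the estimate on the scale of a single observed well. To attach
replicate-level variance, `test_synergy()` builds an additive pseudo-sample
by pairing replicates within batch and then by sorted replicate index:
`a_i + s_i − bg_i`, with the background wells paired the same way. The
per-replicate background term matters: subtracting the *mean* background
from every pseudo-replicate would give all of them a shared noise
component, which a two-sample test cannot see, and simulation shows the
type-I rate then inflates to ≈ 0.07 at α = 0.05; with paired backgrounds
the empirical size is ≈ 0.045 and power at an interaction of 4× the well
noise (n = 6) is ≈ 0.94. When fewer background wells than paired singles
exist, the mean-background form is the fallback. The test is Welch's
two-tailed, per the convention for these assays, but the `synergistic` flag
additionally requires positive excess, since a two-tailed p cannot
distinguish enhancement from suppression; significant sub-additive mixes
are reported unflagged. Default α: 0.01 for panel screens, 0.05 for dose
ladders, both configurable.

`synergy_dose_profile()` walks an ascending amino-acid concentration
ladder at fixed sugar concentration and reports, per level, both the
synergy call and whether the amino acid alone is an agonist (Welch
one-tailed versus no-ligand untransfected controls, Holm across levels).
"Synergy without solo activation" — the signature of potentiation at
sub-activating concentrations — is thus directly queryable, and the test
suite reproduces it in simulation with a weak solo agonist carrying a
strong interaction term.

## Response index and Brownian-motion reconstruction

The relative response index is `I = (S − A)/(S + A)` with `S` and `A` the
sums of normalized responses over a sugar set and an amino-acid set.
Package decisions, both configurable: the inputs are sucralose-normalized,
background-subtracted means with negatives clipped to 0 before summation
(keeping `I` inside [−1, 1] and receptors comparable), and the sugar set
contains carbohydrates only — sucralose, being the normalization reference
and an artificial sweetener, enters neither sum.

Ancestral states are maximum-likelihood estimates under Brownian motion.
`bm_ancestral_states()` solves the sparse normal equations of the
edge-wise quadratic form `Σ_e (x_child − x_parent)²/b_e` for all internal
states at once; these estimates coincide with the re-rooting construction
(each node's state is the GLS mean `(1ᵀC_k⁻¹1)⁻¹1ᵀC_k⁻¹x` with the tree
re-rooted at that node), which the test suite verifies against an explicit
matrix-solve oracle on random trees to 1e-8 and against
`phytools::fastAnc`. The rate is the ML estimator
`σ̂² = (x − â1)ᵀC⁻¹(x − â1)/n` (biased low by factor (n−1)/n, as ML is).
Zero-length branches are perturbed to 1e-9 before any solve; branch
lengths are taken as given (dS units in the intended workflow — computing
dS itself is out of scope). The estimator is invariant to tip order and to
uniform branch rescaling (σ² rescales inversely), and a 64-tip simulation
confirms the root estimate is unbiased within Monte-Carlo error.
`edge_trait_interpolation()` paints the trait by linear interpolation
between parent and child states — the simplest rule consistent with BM,
whose conditional mean along an edge is linear in position.

## Phylogenetic PCA

`phylo_pca()` centers traits on the GLS phylogenetic mean
`a = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹X` and eigendecomposes the evolutionary covariance
`R = (X − 1aᵀ)ᵀC⁻¹(X − 1aᵀ)/(n − 1)`; correlation mode rescales `R` to
unit diagonal and refuses constant traits by name. Scores are the centered
traits projected on the loadings, so `scores · loadingsᵀ` reconstructs the
centered data exactly. Sign convention: the largest-magnitude entry of
each loading column is positive, making outputs deterministic. On a star
tree with unit branch lengths `C ∝ I` and the procedure reduces to
ordinary PCA, which the tests verify against an independent oracle; on
arbitrary trees the implementation matches `phytools::phyl.pca`
(covariance mode) to machine precision.

## Chimera-residue screen

Columns where the two ancestral sequences differ are evaluated against
three criteria: (a) *radical* change — the residues fall in different
classes of the partition hydrophobic AVLIMFWY / polar STNQ / positive KRH /
negative DE / special GCP; (b) BLOSUM62 score ≤ 0 (standard matrix, via
Biostrings); (c) conservation — every extant sequence carries the second
ancestor's residue, gaps counting as mismatches. "Radical" has no single
standard definition, so the class map is an argument and alternative
partitions (or Grantham-distance rules) can be swapped in. Columns where
either ancestor has a gap are skipped and counted: an indel column cannot
be nominated as a point mutation. Domain assignment (VFT/CRD/TMD) comes
from user-supplied 1-based inclusive ranges, since domain boundaries are a
property of the particular alignment. The `require` argument restricts
`passes_all` to any subset of the criteria.

## Bout analysis

Bout durations are `(end_frame − start_frame)/fps` with each visit one
sample. The two-sample Kolmogorov–Smirnov machinery is implemented from
its definition so the pipeline is self-contained: `D` is the sup-distance
between ECDFs evaluated at pooled unique values (tie-safe); the exact
p-value enumerates all `C(n+m, n)` assignments of the pooled sample when
`n·m ≤ 100` (a valid permutation p-value with or without ties), and the
asymptotic two-sample Kolmogorov series is used otherwise. Frame
quantization makes ties common; an optional jitter (intended well below
one frame interval, e.g. `1/(10·fps)`) supports sensitivity analysis.
`stats::ks.test` serves as an independent oracle in the tests, which also
confirm `D = 1` fully-separated samples give `p = 2/C(n+m, n)` and that
the exact test is conservative on discrete nulls. Pooling across
species/sexes/seasons is always the caller's decision.

## Synthetic-data generators

The generators exist to give every stage inputs with known truth:

- `simulate_plate_data()`: transfected wells follow
  `batch_scale × (B + Σ E_max·c^h/(EC50^h + c^h) + γ·min(occ_a, occ_s)) +
  noise`. The interaction form `γ·min(occupancy)` was chosen because no
  generative synergy model is standard for these assays: it makes the
  excess scale with the lesser-occupied site, so a low amino-acid
  concentration can potentiate a saturating sugar response, which is the
  qualitative behavior the dose-ladder analysis must detect. The batch
  effect is one multiplicative lognormal factor per transfection batch on
  transfected wells, exactly the structure sucralose normalization
  cancels. Untransfected wells are background (default 20 response units)
  plus noise, with an artifact bump of 10% of the panel's largest `E_max`
  only for histidine and for mixes totalling over 175 mM — the two known
  receptor-independent responses in this assay system. Defaults:
  `batch_scale_sd` 0.25, `noise_sd` 10, 6 replicates from 2 batches,
  matching the 4–6 replicates from 2–3 transfections typical of these
  experiments.
- `simulate_tree()`: pure-birth topology with per-branch lognormal rate
  multipliers (mean 1), giving non-ultrametric, substitution-rate-like
  branch lengths; `rate_sd = 0` recovers a clock.
- `simulate_alignment_fixture()`: plants candidate columns with specified
  ancestral and extant residues and computes the criteria truth table
  inline (class map + BLOSUM62 lookup), independent of the screening code
  it validates.
- `simulate_bouts()`: two-component lognormal mixture — sampling bouts
  with a ~0.2 s mode and appetitive bouts with a ~1.5 s mode — quantized
  to the frame interval, emulating the short-visits-with-occasional-long-
  draughts structure of feeder arrays.

What the generators do *not* emulate: plate-position and edge-well
effects, heteroscedastic or non-Gaussian well noise, receptor
desensitization within a recording, drift between field seasons, observer
scoring error, and individual birds contributing correlated bouts. Passing
tests therefore establish correctness of the statistics under the stated
generative model, not robustness to every artefact of real plates or field
video.

## Numerical choices and problem sizes

Zero-length branches: ε = 1e-9. KS exact/asymptotic switch: `n·m ≤ 100`.
Hill multi-start: 6 starts, 500 L-BFGS-B iterations each. Validation
problem sizes, chosen to give stable Monte-Carlo estimates at desk scale:
2,000 panels for family-wise error, 1,000 replicates for synergy size,
200 for synergy power and BM root bias (64-tip tree), 100 random trees for
the GLS oracle, 50 fits for EC50 recovery, 10,000 random profiles for the
index bounds.

## Known limitations

The additive proxy assumes the receptor's no-ligand baseline matches the
untransfected background; a systematic offset between them biases the
excess estimate by that offset. Holm families are per receptor — analyses
pooling calls across receptors should correct accordingly. The BM model
treats dS branch lengths as the trait's expected-variance scale; rate
shifts (OU-type adaptive models) are outside this package's scope. The
exact KS p is a permutation p-value: under heavy ties it is valid but
conservative.
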