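# t1revo

Functional and phylogenetic analysis of T1R taste-receptor assays.

Hummingbirds sense sugars through T1R1–T1R3, the receptor pair that in most
birds and mammals detects amino acids (umami). Studying how that switch
evolved requires a chain of analyses that this package implements end to
end:

- **Agonist calling** from cell-based luminescence plates: Welch's
  one-tailed *t*-tests of receptor-transfected wells against untransfected
  controls presented with the same ligand, with Holm step-down correction
  across the ligand family per receptor (family-wise α = 0.05).
- **Normalized response profiles**: each ligand's background-subtracted
  mean divided by the receptor's background-subtracted sucralose response,
  cancelling transfection-efficiency differences between experiments, plus
  grand means across receptors and four-parameter Hill dose–response fits
  (`B + E_max·c^h/(EC50^h + c^h)`).
- **Synergy testing** of sugar + amino-acid mixes against an
  additive-response proxy (sum of the single-ligand responses minus one
  no-ligand background), Welch two-tailed, with a dose-ladder profile that
  exposes synergy at amino-acid concentrations too low to activate the
  receptor alone.
- **Relative response index** `I = (S − A)/(S + A)` in [−1, 1], where `S`
  and `A` sum the normalized sugar and amino-acid responses; maximum-
  likelihood **ancestral states under Brownian motion** on a dS-scaled
  phylogeny (re-rooted GLS estimates, `σ̂² = (x − â1)ᵀC⁻¹(x − â1)/n`),
  with linear within-edge interpolation for trait painting.
- **Phylogenetic PCA**: GLS phylogenetic mean
  `a = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹X`, evolutionary covariance
  `R = (X − 1aᵀ)ᵀC⁻¹(X − 1aᵀ)/(n − 1)`, eigendecomposition with a
  deterministic sign convention.
- **Chimera-residue screen**: columns differing between two ancestral
  receptor sequences are nominated when the substitution is (a) a radical
  physicochemical change, (b) BLOSUM62 ≤ 0, and (c) the younger ancestor's
  residue is conserved across all extant sequences.
- **Drinking-bout analysis**: bout durations from 60-fps frame scoring and
  two-sample Kolmogorov–Smirnov comparisons, with the exact permutation
  p-value (complete enumeration) for small samples.

A synthetic-data module (`simulate_plate_data()`, `simulate_tree()`,
`simulate_alignment_fixture()`, `simulate_bouts()`) generates every input
with known ground truth, so the full pipeline runs and is validated
without any external data.

## Worked example

```r
library(t1revo)

dir <- tempfile()
cfg <- write_demo_inputs(dir, seed = 42)   # four synthetic input files
manifest <- run_pipeline(cfg)              # eight outputs + log + manifest

idx <- jsonlite::read_json(file.path(cfg$out_dir, "response_index.json"))
unlist(idx$index)
#>        t1        t2        t5        t4        t3        t6
#> 0.3812074 0.4673406 0.8513256 0.7088182 0.5724482 1.0000000
unlist(idx$node_states)
#>         7         8         9        10        11
#> 0.6711383 0.6074291 0.7142752 0.7348882 0.7404254
```

The demo plants a gradient of amino-acid responsiveness across the six
receptors: the response index runs from 0.38 (receptor retaining strong
amino-acid responses, like the hermit lineage) to 1.00 (purely
sugar-biased); the reconstructed ancestral states (internal nodes 7–11)
sit between their descendants, with the root near 0.67.

```r
read.delim(file.path(cfg$out_dir, "synergy_report.tsv"))[1:2, c(1, 6:10)]
#>   receptor_id observed_mean additive_estimate   excess            p synergistic
#> 1          t1      521.8407          467.8209 54.01976 0.0005107941        TRUE
#> 2          t2      393.0815          346.7526 46.32890 0.1045757374       FALSE
```

Receptor t1 carries planted sucrose × alanine synergy (γ = 150) and its
mix response exceeds the additive proxy by 54 units at p = 5.1e-4; the
rest of the panel is consistent with additivity at α = 0.01.

```r
read.delim(file.path(cfg$out_dir, "behavior_report.tsv"))[1, ]
#>   stimulus_1 stimulus_2    D            p     method   n   m  median_1 median_2
#> 1    sucrose      water 0.46 3.284907e-14 asymptotic 150 150 0.5166667      0.2
```

Sucrose feeders elicit longer drinking bouts than water (median 0.52 s vs
0.20 s, KS D = 0.46).

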