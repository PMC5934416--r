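---
title: "Methods: hit calling for RT-qPCR-based shRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hit calling for RT-qPCR-based shRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctscreen)
```

## The problem

Loss-of-function screens that read out an *endogenous*, stimulus-inducible
transcript by RT-qPCR sit between classical reporter-based RNAi screens and
modern sequencing readouts. The design this package analyzes knocks down a
roster of nuclear cofactors with several shRNA constructs per gene, arrayed
on 48-well plates, and measures the cycle-threshold (ct) of an inducible
chemokine readout (e.g. *Cxcl2*) and a housekeeping reference (e.g.
*Ube2l3*) in untreated and cytokine-stimulated (IL-1) cells. Each plate
carries three control transfections: the empty knockdown vector (the
quantification reference), a scrambled hairpin, and a GFP vector used only
to monitor transfection.

Two screen formats are supported and meant to be combined:

* **individual** mode: every hairpin in its own untreated/stimulated well
  pair (4–5 hairpins for up to 4 targets per plate);
* **pooled** mode: all hairpins against a target combined into a single
  well pair (20 targets per plate).

The interesting biology is a *change* in the readout caused by a knockdown,
in any of three senses, and the pipeline quantifies all three.

## The model

All quantification is ddct-based with PCR efficiency fixed at perfect
doubling (no standard-curve correction — the screens used validated
single-product assays). For each well,

$$\Delta ct = ct_\text{readout} - ct_\text{housekeeping},$$

computed within the well so that per-well material differences cancel. In
individual mode the Δct values of a target's hairpins (and replicate
wells) are averaged arithmetically into one value per (target, condition);
pooled wells pass through. Relative to the *same-plate* empty-vector
control, three comparisons are formed:

* **basal**: $\Delta\Delta ct = \Delta ct_{kd,unt} - \Delta ct_{vec,unt}$,
* **stimulated**: the same in stimulated cells,
* **regulation**: the change in the extent of stimulus-mediated induction,
  $fold_{reg} = fold_{stim} / fold_{basal}$, i.e.
  $\Delta\Delta ct_{reg} = \Delta\Delta ct_{stim} - \Delta\Delta ct_{basal}$.

Fold change is $2^{-\Delta\Delta ct}$ throughout, so the conservation law
$fold_{reg} \times fold_{basal} = fold_{stim}$ holds identically — a useful
internal consistency check that the tests enforce to floating tolerance.
The regulation comparison exists because a knockdown that shifts basal and
stimulated levels *alike* leaves the induction ratio untouched and would be
invisible to a regulation-only analysis; conversely, effects confined to
one condition distort the ratio. Scoring all three comparisons avoids both
blind spots.

### Z-ranking and dual-screen concordance

Within each (screen, comparison) stratum the ΔΔct values of all targets are
converted to z-scores, $z = (x - \bar x)/s$, using the sample (n−1)
standard deviation; with screen-sized strata (170 targets) the n vs n−1
distinction is far below measurement noise, and the convention is
configurable. Z-scores are computed on ΔΔct — the log2 scale of the ratio —
rather than on the linear fold, because the log scale symmetrizes up- and
down-effects; this too is configurable by transforming the inputs.

A target is called a **hit** for a comparison when |z| ≥ 1 in *every*
screen (ties included) and, by default, the ΔΔct signs agree across
screens. Sign concordance is what makes a 1-SD threshold usable: under a
null model two independent screens each put ≈31.7% of targets beyond 1 SD,
but requiring the same tail in both drops the expected concordant fraction
to $2\,P(z>1)^2 \approx 5\%$. Direction follows the sign: ΔΔct > 0 means
the knockdown *raised* the ct (suppressed the readout), so the target is a
**coactivator**; ΔΔct < 0 marks a **corepressor**.

### Housekeeping diagnostics

Before normalization, `housekeeping_stability()` compares the median ct of
each candidate reference gene between hairpin wells and empty-vector wells
per condition. A candidate whose median shifts by more than 0.5 cycles
(default) in either condition is flagged to omit — the fate that befalls
*ActB*-like readouts depressed by hairpin transfection, which would
otherwise masquerade as a global expression change in every knockdown.

## The synthetic-data generator

No raw screen ct values are published for this design, so the package
ships a generator whose defaults *are* the study conditions, and all
calibration and recovery claims are made against it:

| parameter | default | meaning |
|---|---|---|
| `baseline_ct` | Cxcl2 30, Ube2l3 20 | low-abundance inducible readout, abundant housekeeping |
| `stimulation_shift` | Cxcl2 −6, Ube2l3 0 | ≈64-fold induction; untouched reference |
| `plate_effect_sd` | 0.5 ct | additive per-plate offset on all measurements |
| `well_noise_sd` | 0.25 ct | independent Gaussian noise per measurement |
| `gfp_shift` | +1.5 ct | GFP suppresses mRNA levels (raises ct) on all readouts |
| `efficiency_mean`, `efficiency_sd` | 1.0, 0.2 | per-construct knockdown efficiency, truncated to [0, 1.5], drawn once per hairpin so replicate wells share it |
| `off_target_prob` | 0.02 | probability a hairpin's effect sign flips |
| `max_cycles` | 40 | instrument cap; above it a measurement is "undetermined" |

Magnitudes are the package's own choices: the baselines and induction
reproduce the qualitative facts the screen design rests on (the inducible
readout is rare basally and strongly induced; the housekeeping gene is
condition-invariant), 0.25 ct well noise is typical of replicate Taqman
measurements, and the efficiency distribution centers hairpins on their
target's nominal effect with realistic spread. The off-target rate is kept
low because flipped-sign hairpins were the exception in the original
screens (one construct was singled out among 791). These are study
conditions, not tuning knobs: the calibration and recovery results below
are reported under exactly these defaults.

Knockdown effects are implanted as ct shifts on the non-housekeeping
readouts, per condition (`basal_shift`, `stim_shift`), scaled per hairpin
by its efficiency; pooled wells receive the mean of the constituent
hairpins' scaled effects — the simplest model consistent with pooling the
plasmids before transfection. The generator returns the implanted ground
truth alongside the table.

What the generator does **not** emulate: per-well input-material scale
factors distinct from Gaussian ct noise (the miniaturized no-purification
protocol likely adds such a term; it is absorbed into `well_noise_sd`
here), amplification-efficiency differences between assays, positional
plate effects (well coordinates are opaque labels), and cross-hairpin
seed-sequence correlations. Passing recovery tests therefore demonstrate
the *procedure's* statistical behavior under the stated noise model, not
performance on any particular laboratory's data.

### Plate capacity and replicates

A 48-well plate holding 4 targets × 5 hairpins in both conditions plus the
six control wells uses 46 wells; the screening duplicates are therefore
modeled as the untreated/stimulated well pair itself (half of each plate is
stimulated), and `replicates` counts additional well pairs per construct.
Requesting more than the plate holds raises a capacity error stating the
overflow. With 170 targets this yields 43 individual-mode and 9 pooled-mode
plates.

## Calibration and recovery, as computed here

Problem sizes are chosen so the whole suite runs in a few minutes on one
core. Under the defaults:

* **Null calibration**: on 50 pure-noise dual screens of 170 targets the
  mean concordant hit fraction per comparison is asserted to lie in
  [0.02, 0.09] around the analytic ≈0.05.
* **Recovery**: 10 of 170 targets implanted with ±1.5-ct effects in both
  conditions (5 coactivators, 5 corepressors); across 20 seed pairs at
  least 90% of the implanted (target × affected comparison) cells must be
  called with the correct direction.
* **Oracle equivalence**: on ≤10-target fixtures the pipeline's ΔΔct, fold,
  z and hit decisions are compared against a deliberately naive
  straight-line recomputation (plain loops, no shared code).

## Validation-stage analysis

Hit validation uses conventional RT-qPCR with controlled RNA input.
`relative_expression()` rescales linear expression ($2^{-\Delta ct}$) so
the maximal stimulated vector-control value is 1 per readout; independent
experiment series are normalized separately (anchors per series) and never
pooled, preserving their biological variation. `validation_folds()` takes
means over replicates on the linear scale (matching bar-graph convention;
log-scale averaging is available) and forms the same three comparisons.
`classify_effects()` applies the 1.5-fold rule — fold ≥ 1.5 is a
corepressor (derepression), fold ≤ 1/1.5 a coactivator — which is exactly
symmetric under fold ↔ 1/fold. Overlaps across the three comparisons are
summarized as three-set Venn region counts, and two-group comparisons use
the exact two-sided Wilcoxon rank-sum test (`stats::wilcox.test`), flagged
at p < 0.05.

## ChIP-qPCR quantification

`percent_of_input()` implements $2^{-(ct_{IP} - ct_{input})}$ relative to
the input aliquot (1% by convention). The raw formula value is the default
output, preserving the printed convention bit-exactly; converting to
percent of *total* input multiplies by `input_fraction * 100` (the identity
at 1%), and an optional `dilution_cycles` offset corrects an input ct
recorded on undiluted material. `enrichment_table()` adds per-(region,
antibody, condition) ratios to IgG and to a gene-free negative-control
region when present.

## Network enrichment

Whether a hit list is more interconnected than chance is tested against a
user-supplied protein-interaction edge list (either the 0–1 or the 0–1000
combined-score dialect, auto-detected) filtered at medium confidence
(score ≥ 0.4 by default). The null model resamples node sets of the same
size uniformly from a user-supplied background universe;
$p = (1 + \#\{perm \ge obs\}) / (1 + n_{perm})$. Uniform resampling is the
closest offline analog of a whole-genome expectation; a degree-preserving
null would additionally condition on the hit genes' hubness and is a
deliberate non-goal here — interpret small p-values accordingly when hit
sets are enriched for well-studied (high-degree) proteins. Database-version
drift is also why the package takes edge lists as input rather than
querying a live resource.

## Numerical and design notes

* Undetermined ct values (token or >40 cycles) are flagged, never imputed;
  they drop out of averaging with a logged count.
* A plate whose vector control is missing falls back to the screen-wide
  mean control with a warning rather than silently losing its targets.
* Ties at the z threshold are included; ranking sorts are stable, so tied
  keys keep input order.
* z-scores on a zero-spread stratum are a hard error, not NaN.
* Every output file of `run_pipeline()` carries a provenance header
  (config fingerprint, seed, package version); identical configs produce
  byte-identical outputs.
* The package's interface is its functions and this document;
  `run_pipeline()` plus a YAML config covers scripted end-to-end use, so
  no shell executable is shipped.

## Worked example

```{r example}
designs <- demo_designs(n_targets = 12, shrnas_per_target = 5)
params <- default_sim_params(knockdown_effects = tibble::tibble(
  target = c("TGT01", "TGT02"), basal_shift = c(2, -2), stim_shift = c(2, -2)
))
s1 <- simulate_screen(designs$individual, params, seed = 1)
s2 <- simulate_screen(designs$pooled, params, seed = 2)
hits <- call_hits(list(
  analyze_screen(s1$ct, designs$individual, "I"),
  analyze_screen(s2$ct, designs$pooled, "II")
))
hits[, c("target", "comparison", "direction", "min_abs_z")]
```

## Limitations

The z threshold of 1 SD is a ranking heuristic, not an error-rate
guarantee; the concordance requirement supplies the specificity. No FDR
machinery or per-hairpin scoring (RSA-style) is implemented — targets enter
the statistics only after hairpin averaging. PCR efficiency is fixed at 2;
assays with poor efficiency need external correction before import.
Absolute hit lists from any particular wet-lab screen depend on unpublished
raw values and live database versions and are outside what this package
can, or tries to, reproduce.
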