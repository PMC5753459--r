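---
title: "Somatic SNV calling strategies on flow-based amplicon data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic SNV calling strategies on flow-based amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsomatic)
```

## The problem

Deep targeted amplicon sequencing on flow-based platforms reads homopolymer
runs by measuring incorporation signal per nucleotide flow, so the length of
a run beyond a few bases is estimated, not observed. Misestimated lengths
cause alignment slippage, which in turn produces cascades of spurious SNV
calls near runs — most conspicuously at amplicon boundaries. On top of that,
the widely used somatic callers are tuned for other chemistries: run
out-of-the-box, one produces an order of magnitude too few calls on this
kind of data and another an order of magnitude too many. `ionsomatic`
implements a pipeline for extracting high-confidence somatic SNVs under
these conditions and for measuring what each calling strategy buys and
costs.

The pipeline's unit of analysis is the *locus*: a distinct
(chromosome, position, ref, alt) SNV allele, pooled across samples and
patients. Indels, MNVs and symbolic alleles are rejected at ingestion (the
platform's indel calling is unreliable enough that modelling it would imply
precision the data cannot support); multi-allelic VCF records are split
into one candidate per alternate allele first. Chromosome names are compared
with the `chr` prefix stripped so mixed-dialect inputs match.

## Caller channels

Four channels produce candidate somatic calls:

* **IR** — tumor–normal calls from the platform vendor's pipeline, ingested
  from VCF (FILTER must be PASS or `.`).
* **PM** — tumor-minus-normal subtraction of the raw per-sample Torrent
  Variant Caller output. Matching is by *exact allele*, not locus: a
  different alternate allele at the same position in the normal is not
  evidence that the tumor allele is germline. (A locus-level mode exists
  behind a flag for sensitivity analysis.) Subtraction deliberately uses
  emitted calls only and never re-examines normal pileups; when the caller
  misses a germline variant in the normal, the leak must be caught by the
  classifier's matched-normal rule, mirroring how this failure mode arises
  in practice.
* **MG** — MuTect with rejection rescue. MuTect's per-candidate call-stats
  table is scanned and a REJECT is restored iff its failure reasons are a
  non-empty subset of the rescue set (default: `nearby_gap_events` only —
  amplicon sequencing has gaps by construction, so that rejection is a
  platform mismatch rather than evidence against the variant). Subset
  semantics make multiple rescue flags compose predictably: a REJECT
  carrying any non-rescued reason stays rejected. `clustered_read_position`
  is accepted as a configurable flag but is off by default; rescuing it
  produced poorly overlapping, poorly validating calls.
* **VS** — VarScan2 somatic calls kept iff somatic p-value ≤ 10⁻⁶.
  "Greater than the threshold" is the rejection condition, so the boundary
  value is retained. Calls without a p-value are an error, not silently
  kept.

Annotation filters then drop calls flagged in either of two population
databases (presence/absence only — no frequency threshold, because the
filter models "seen in a population catalogue" rather than "common"), and
calls outside the retained functional classes (exonic, UTR3, UTR5, stopgain,
splicing, ncRNA). ncRNA is treated as a single retained class without an
exonic/intronic split. Unannotated calls error by default; a lenient mode
retains them with a warning. Both filters are idempotent and commute.

## The inspection-rule classifier

Human review of candidate variants in a genome browser follows recognizable
visual patterns. The classifier encodes them as explicit rules over
per-variant read evidence (strand-split alt counts, depths, a poor-mapping
fraction, matched-normal counts) and reference context. Each (variant,
sample) pair receives exactly one label — `valid`, `bad`, or `homopolymer` —
with reason codes.

Precedence: a candidate is **homopolymer** when a run of at least `min_run`
bases lies within the context window AND the call shows either

* the *slippage signature* (`HP_SLIPPAGE`): a run of the alternate base, at
  least `exception_run_min` long, within `slippage_proximity_bp` of the
  variant — the quantitative proxy for "the called variant base is visible
  on the reference nearby", or
* *coupled calls* (`HP_COUPLED`): at least one other called locus within
  `coupled_window_bp` in the same sample, with both calls lacking
  bidirectional support — the cascade pattern near amplicon boundaries;

unless the *exception* applies: every run in the window is 5–6 bases long,
the flanking window sequence is heterogeneous (≥ 3 distinct bases outside
the runs), support is bidirectional and the allele fraction is adequate —
short runs in complex context still map well, so such calls are let through
to the ordinary rules. Otherwise the candidate is **bad** if any of the
following trigger (all triggered reasons are recorded): missing support on
either strand (`NO_BIDIR`), tumor allele fraction below `af_min` (`LOW_AF`),
poor-mapping fraction above `poor_map_max` (`POOR_MAP`), or normal-sample
allele fraction above `normal_af_max` (`IN_NORMAL`). Otherwise **valid**.

Parameters, defaults, and why:

| parameter | default | meaning / rationale |
|---|---|---|
| `window_bp` | 10 | context half-width; "within approximately 10 bp" read as a window centered on the variant (one-sided reading rejected as arbitrary) |
| `min_run` | 6 | run length that makes a locus a homopolymer suspect |
| `exception_run_min` | 5 | 5–6 base runs are the exception-eligible range; also the minimum run for the slippage proxy |
| `slippage_proximity_bp` | 2 | "close proximity" proxy; decisions tabulated over offsets 0–10 fixed the boundary at 2 bp (adjacent or one base removed) |
| `heterogeneity_min_distinct` | 3 | distinct bases outside the run(s) for "sufficiently heterogeneous" flanks |
| `min_alt_per_strand` | 1 | bidirectional support requirement |
| `af_min` | 0.05 | minimum tumor allele fraction |
| `af_precision_depth` | 200 | depth below which the 5% rule loses precision; a `LOW_DEPTH_NOTE` is attached but the rule still applies — suppressing it would silently pass unverifiable calls |
| `poor_map_max` | 0.5 | "predominantly poorly mapped" proxy: more than half the supporting reads |
| `normal_af_max` | 0.05 | matched-normal contamination threshold |
| `coupled_window_bp` | 15 | neighborhood for coupled-call detection |

The visual cues are inherently qualitative; these proxies are design
decisions, each exposed as a named parameter, and no claim is made that they
reproduce any particular human reviewer's verdicts. `N` bases break runs and
never count toward flank heterogeneity. "High coverage" is not enforced as a
separate validity rule (no defensible number exists); it surfaces only
through `LOW_DEPTH_NOTE`.

A variant carried by several samples is classified per sample and collapsed
per locus; the default collapse (`any_valid`) marks the locus valid if valid
in at least one sample, matching the practice of loading all carrying
samples into one browser view and issuing one verdict. The collapse rule is
configurable. External hand labels can replace the classifier entirely,
since human inspection remains the reference standard.

## Concordance, strategies, and metrics

The concordance matrix records which channels called each locus; the
*caller signature* (the subset of channels) is the unit of combination
analysis. Strategies are set expressions over channels — `&`, `|`,
parentheses, and `any(k)` for "at least k of all channels" — evaluated per
locus against the signatures. The inspection set is every multi-caller locus
plus at most `max_singletons` (default 50) randomly sampled single-channel
loci per channel; the multi-caller component is deterministic and only the
singleton sampling consumes randomness, drawn from a named substream of the
run seed.

For a strategy calling `C` loci of which `v` are valid, `PPV = v/C` and
`Sensitivity = v/V`, where `V` counts all valid loci discovered by any
channel. Because variants missed by every channel are invisible, `V` is a
proxy and the sensitivity an upper bound. Valid counts are extrapolated from
inspected to uninspected loci within each caller-signature stratum — the
finest partition on which "observed rates hold in the uninspected" can be
asserted — as `round(rate × n_uninspected)`, rounded per stratum so the
reported `v` columns stay integers. Under the standard design uninspected
loci exist only in singleton strata; if a user-supplied inspection set
leaves a stratum without inspected loci, the pooled inspected singleton rate
of that channel (or the overall inspected rate for a multi-caller stratum)
is used with a warning.

Standard errors use the binomial form `sqrt(p(1−p)/n)` with `n` the number
of *inspected* loci in the relevant universe — the strategy's inspected
count for PPV, the total inspected count for sensitivity — never the called
count, since extrapolated tallies carry no sampling precision. An SE is
reported only when `n · min(p, 1−p) ≥ 5` (the usual normal-approximation
validity rule); otherwise the table shows the literal string `NA`. Display
rounding is 2 decimals for proportions and 3 for SEs, with R's default
round-half-even; a consequence worth knowing is that a proportion landing
exactly on a half (e.g. 39/40 = 0.975) is at the mercy of binary floating
point and may round either way in other software.

All analysis is locus-level. A per-variant universe (counting the same
allele once per carrying sample) is a meaningful alternative for
per-sample questions, but every combination metric here is defined on
distinct loci, so a per-variant mode is not offered.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes, not
reads. It emits a reference panel whose background is kept free of runs ≥ 4
(so planted runs are the only homopolymer structure), with runs planted at
`homopolymer_density` per kb (default 4) and lengths 4 + Poisson(1.2),
giving a realistic share of runs ≥ 6. Truth records are then placed:

* **somatic** variants uniformly over "clean" positions (≥ 12 bp from any
  run ≥ 5, keeping mechanisms separable), with allele fractions from
  Beta(2, 5) truncated below at 0.08. The Beta shape mimics purity and
  intra-tumoral dilution; the floor reflects that this pipeline *defines*
  sub-5% calls as unverifiable, so the generator simulates detectable
  somatic variants safely above that decision boundary rather than planting
  truth the rules are designed to reject.
* **homopolymer-slippage artifacts** within 2 bp of a run ≥ 6, with the
  alternate allele equal to the run base and unidirectional support — the
  canonical slippage signature.
* **strand-bias artifacts** (all alt reads on one strand, AF 0.10–0.25) and
  **low-AF noise** (true AF 0.008–0.035, bidirectional) on clean positions;
  a configurable fraction of these additionally get a high poor-mapping
  fraction.
* **germline het variants** (AF 0.5 in tumor *and* normal) that each channel
  "leaks" into its somatic calls with a per-channel probability; a
  configured fraction are flagged in the population databases so that filter
  has work to do.

Depths are negative binomial with mean 1400 (typical for this class of
panel; configurable down for fast tests), alt counts binomial in
(depth, true AF) split binomially across strands, and the normal shows the
variant at its germline fraction or at a background error rate of 0.002.
Artifact pool sizes are Poisson draws around each caller profile's expected
count (`fp_per_mb` × panel size); a `tvc_shared_frac` share (default 0.4)
of the TVC-linked channels' common budget is drawn *once* and called by
every linked channel, reproducing the elevated IR/PM concordance that shared
calling machinery produces. Somatic calls are independent Bernoulli
(sensitivity) per channel. The MuTect stream writes a configurable fraction
of true MG calls as rescuable REJECTs plus non-rescuable decoy REJECTs; the
VarScan stream attaches p-values straddling the 10⁻⁶ threshold. Every stage
draws from a named substream of the single seed, so stages regenerate
independently and fixtures are byte-identical under a fixed configuration.

What the generator does **not** emulate: read-level errors and mapping (no
FASTQ/BAM), PCR/FFPE damage chemistry, caller-specific biases beyond the
sensitivity/artifact/leak profiles, and correlation between channels on
*true* calls (only artifact draws are shared). Passing the end-to-end tests
therefore shows that the pipeline's logic and estimators are correct under
the stated error model — not that the classifier's thresholds are optimal
for any particular real dataset, whose artifact morphology must be reviewed
against the proxies above.

## Parameter recovery and test design

The recovery experiment (`parameter_recovery_config()`) fixes the study
conditions: 4 patients × 75 somatic loci (300 total) on a 240 kb panel,
channel sensitivities 0.85/0.55/0.90/0.95 (IR/MG/PM/VS) and artifact budgets
chosen so the configured PPVs are 0.50/0.40/0.36/0.10, with annotation
nuisance switched off so the configured operating points are exactly what
the estimator targets. The pipeline runs with an *uncapped* inspection set:
with the 50-per-channel cap, a single lucky valid singleton in a ~2500-locus
stratum extrapolates to ~50 phantom valid calls, so the estimator's variance
would be dominated by inspection sampling rather than by the quantities
being recovered; full inspection isolates profile recovery, and the capped
design is exercised by its own unit tests. The acceptance test checks all
eight recovered estimates (4 channels × PPV and sensitivity) against their
configured values jointly at the 5% level: with eight simultaneous
binomial-scale estimates, per-estimate 95% intervals would fail about a
third of correct runs by construction, so the per-estimate quantile is
Bonferroni-adjusted to hold the family at 95%.

Test problem sizes are deliberately small where distributional shape is not
under test: the shared unit-test fixture uses an 8 × 1.5 kb panel with 24
somatic and 10 germline records, the reference-structure checks use 10 kb at
5 runs/kb (Poisson 99% band), and the strategy-engine oracle comparison runs
1,000 random matrices of up to 4 callers × 200 loci against an independent
per-locus evaluator.

## Known limitations

* The classifier's proxies are calibrated to the synthetic error model;
  thresholds for real cohorts should be reviewed against a hand-labelled
  sample (the pipeline accepts external labels for exactly this purpose).
* Sensitivity is relative to the union of channels; true sensitivity is
  lower by the (unobservable) fraction of variants all channels miss.
* Extrapolated strata contribute no SE, so strategies dominated by
  uninspected singletons have optimistic-looking precision fields (`NA`
  rather than a wide interval).
* SNVs only; indels and structural variants are out of scope by design.
* The IGV batch generator emits the control script but does not drive a
  browser.
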