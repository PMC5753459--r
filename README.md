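# ionsomatic

Identifying somatic single-nucleotide variants (SNVs) from deep targeted
amplicon sequencing on flow-based platforms (Ion Torrent style) is hard:
homopolymer length misestimation causes alignment slippage and cascades of
artifact calls, and the popular somatic callers are tuned for other
chemistries. `ionsomatic` implements a complete, testable pipeline for
deriving *high-confidence* somatic SNVs from such data by combining four
caller channels, rule-based artifact triage, and combination-strategy
evaluation. It is aimed at bioinformaticians running tumor–normal panels
(e.g. a 409-gene comprehensive cancer panel at ~1400× depth) who need to
choose a calling strategy with known positive predictive value (PPV) and
sensitivity trade-offs.

## What it does

**Caller channels.** Four call-set constructions over per-sample VCFs:

* **IR** — Ion Reporter tumor–normal calls, ingested as-is;
* **PM** — a "Poor Man's" somatic detector: exact-allele subtraction of the
  matched normal's Torrent Variant Caller (TVC) calls from the tumor's;
* **MG** — MuTect with *rejection rescue*: candidates REJECTed **only** for
  `nearby_gap_events` (an exclusion inappropriate for amplicon data, where
  gaps are implicit) are restored from the call-stats file;
* **VS** — VarScan2 somatic calls filtered to somatic p-value ≤ 10⁻⁶.

**Filters.** Variants present in 1000 Genomes or the Exome Variant Server
are excluded, as are intronic/intergenic calls (retained classes: exonic,
UTR3, UTR5, stopgain, splicing, ncRNA).

**Automated inspection.** A classifier reproduces the manual IGV-review
procedure as explicit rules, labelling each candidate
`valid | bad | homopolymer`: homopolymer slippage (alt-base run of ≥ 6 bases
within ±10 bp, with a good-mapping exception for 5–6 base runs in
heterogeneous context), coupled unidirectional calls, strand support, allele
fraction ≥ 5%, mapping quality, and presence > 5% in the matched normal. An
IGV batch-script generator is included for human review, with caller-blind
ordering and naming.

**Strategy evaluation.** A caller×locus concordance matrix supports a small
strategy language (`IR & PM`, `(IR | PM) & (MG | VS)`, `any(k)`, …). For a
strategy with `C` called loci and `v` valid ones,

    PPV = v / C        Sensitivity = v / V

where `V` is the valid total over all channels, extrapolated from inspected
to uninspected loci stratum-by-stratum (caller signature). Standard errors
are `sqrt(p(1−p)/n)` with `n` the number of *inspected* loci, reported only
when `n · min(p, 1−p) ≥ 5`.

**Synthetic cohorts.** A generator produces fully labelled fixtures —
reference panel with controlled homopolymer structure, per-channel VCFs,
MuTect call-stats, annotations, read evidence — with per-caller sensitivity
and artifact profiles (TVC-linked channels share artifact draws), so the
whole pipeline is validated end to end against known truth.

## Worked example

```r
library(ionsomatic)

cfg <- simulation_config(seed = 42)        # 4 patients, 25 somatic SNVs each
write_fixture(cfg, "fixture")
run <- run_pipeline(pipeline_config("fixture", "run", seed = 7))
cat(summarize_run(run), sep = "\n")
```

The summary reports stage counts, the caller-signature Venn breakdown, the
classifier reason histogram and the strategy table. On this seed the single
channels come out as:

```
IR                       C=142   v=85   PPV=0.60 (SE 0.041, n=142) Sens=0.86 (SE 0.020)
MG                       C=117   v=46   PPV=0.39 (SE 0.050, n=96) Sens=0.46 (SE 0.029)
PM                       C=203   v=91   PPV=0.45 (SE 0.038, n=168) Sens=0.92 (SE 0.016)
VS                       C=507   v=95   PPV=0.19 (SE 0.032, n=145) Sens=0.96 (SE 0.011)
```

i.e. the subtraction and VarScan channels buy sensitivity at a steep PPV
cost, intersections push PPV toward 1 while sacrificing sensitivity — the
trade-off surface the package exists to quantify. `v` is the extrapolated
valid count, `PPV = v/C`, and `Sens = v/V̂` with `V̂` the valid total across
all channels (here 99, the planted somatic variants discovered by at least
one channel and confirmed by the classifier).

A command-line wrapper for the main steps is installed under
`inst/cli/ionsomatic` (subcommands `simulate`, `run-all`, `call-pm`,
`rescue-mg`, `filter-vs`).

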