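# Independent scan used as the oracle for run structure in generated
# references: maximal runs of identical bases of length >= min_len.
scan_runs <- function(seq_chr, min_len) {
  r <- rle(strsplit(seq_chr, "")[[1]])
  sum(r$lengths >= min_len)
}

test_that("reference generation controls homopolymer structure", {
  # degenerate density: no run of length >= 4 anywhere
  cfg0 <- simulation_config(seed = 21L, n_regions = 4L,
                            region_length = 2000L, homopolymer_density = 0)
  ref0 <- generate_reference(cfg0)
  counts <- vapply(as.character(ref0$sequences), scan_runs, 0L, min_len = 4L)
  expect_true(all(counts == 0L))

  # 5 runs/kb over 10 kb: planted count within the Poisson 99% band of 50
  cfg5 <- simulation_config(seed = 22L, n_regions = 5L,
                            region_length = 2000L, homopolymer_density = 5)
  ref5 <- generate_reference(cfg5)
  n_runs <- sum(vapply(as.character(ref5$sequences), scan_runs, 0L,
                       min_len = 4L))
  band <- qpois(c(0.005, 0.995), 5 * 10)
  expect_gte(n_runs, band[1])
  expect_lte(n_runs, band[2])
  # runs of length >= 6 occur at this density
  expect_gt(sum(vapply(as.character(ref5$sequences), scan_runs, 0L,
                       min_len = 6L)), 0L)

  # panel intervals tile the sequences
  expect_equal(ref5$panel$end - ref5$panel$start0,
               rep(2000L, 5L))

  expect_error(generate_reference(
    simulation_config(seed = 1L, region_length = 0L)))
})

test_that("reference generation is a pure function of the seed", {
  cfg <- simulation_config(seed = 33L, n_regions = 3L, region_length = 1000L)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(generate_reference(cfg)$sequences, f1)
  Biostrings::writeXStringSet(generate_reference(cfg)$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted truth respects placement and distribution contracts", {
  cfg <- small_sim_config(seed = 44L, n_somatic = 40L)
  ref <- generate_reference(cfg)
  truth <- plant_truth(ref, cfg)

  # no somatic truth -> only artifact and germline records
  cfg0 <- small_sim_config(seed = 45L, n_somatic = 0L)
  truth0 <- plant_truth(generate_reference(cfg0), cfg0)
  expect_setequal(unique(truth0$status), c("artifact", "germline"))

  # slippage artifacts sit within 10 bp of an independently-scanned run of
  # length >= 5 whose base equals the alternate allele
  seqs <- as.character(ref$sequences)
  hp <- truth[truth$mechanism == "homopolymer_slippage", ]
  expect_gt(nrow(hp), 0L)
  for (i in seq_len(nrow(hp))) {
    r <- rle(strsplit(seqs[[hp$chrom[i]]], "")[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    near <- r$lengths >= 5L & r$values == hp$alt[i] &
      (pmax(starts - hp$pos[i], hp$pos[i] - ends, 0L) <= 10L)
    expect_true(any(near), info = hp$id[i])
  }

  # truth alleles match the reference base at their positions
  refbase <- vapply(seq_len(nrow(truth)), function(i) {
    substr(seqs[[truth$chrom[i]]], truth$pos[i], truth$pos[i])
  }, "")
  expect_equal(refbase, truth$ref)
  expect_true(all(truth$ref != truth$alt))
})

test_that("somatic allele fractions follow the truncated Beta", {
  cfg <- simulation_config(seed = 46L, n_regions = 10L,
                           region_length = 2000L, n_patients = 4L,
                           n_somatic = 150L, n_germline = 0L,
                           af_floor = 0, af_shape1 = 2, af_shape2 = 5)
  truth <- plant_truth(generate_reference(cfg), cfg)
  af <- truth$true_af[truth$status == "somatic"]
  mu <- 2 / 7                       # Beta(2,5) mean
  sd <- sqrt(2 * 5 / (49 * 8))      # Beta(2,5) sd
  expect_lt(abs(mean(af) - mu), 3 * sd / sqrt(length(af)))
  expect_true(all(af > 0 & af <= 1))
})

test_that("read evidence encodes the artifact mechanisms", {
  cfg <- small_sim_config(seed = 47L)
  truth <- plant_truth(generate_reference(cfg), cfg)
  ev <- simulate_evidence(truth, cfg)
  ev$status <- truth$status[match(ev$id, truth$id)]
  ev$mech <- truth$mechanism[match(ev$id, truth$id)]

  sb <- ev[ev$mech == "strand_bias", ]
  expect_gt(nrow(sb), 0L)
  expect_true(all(sb$alt_fwd == 0L | sb$alt_rev == 0L))

  germ <- ev[ev$status == "germline", ]
  expect_gt(nrow(germ), 0L)
  expect_true(all(germ$alt_normal / germ$depth_normal > 0.05))

  low <- ev[ev$mech == "low_af_noise", ]
  expect_true(all(low$tumor_af_obs < 0.05))

  expect_true(all(ev$alt_fwd + ev$alt_rev <= ev$depth_tumor))
  expect_true(all(ev$alt_normal <= ev$depth_normal))
})

test_that("alt counts are binomial in depth and allele fraction", {
  cfg <- small_sim_config(seed = 48L)
  hand_truth <- tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "G", id = "1:100:A>G",
    patient = "P1", status = "somatic", mechanism = "none", true_af = 0.2,
    func_class = "exonic", in_1kg = FALSE, in_evs = FALSE,
    artifact_channel = ""
  )
  ev <- simulate_evidence(hand_truth[rep(1, 200), ], cfg)
  alt <- ev$alt_fwd + ev$alt_rev
  # each draw within the 0.9999 binomial envelope of its own depth
  lo <- qbinom(5e-5, ev$depth_tumor, 0.2)
  hi <- qbinom(1 - 5e-5, ev$depth_tumor, 0.2)
  expect_true(all(alt >= lo & alt <= hi))
  expect_lt(abs(mean(alt / ev$depth_tumor) - 0.2), 0.01)
})

test_that("caller profiles shape the emitted call sets", {
  # perfect sensitivity and zero artifact rates: every channel's locus set
  # equals the somatic truth
  zero_fp <- stats::setNames(rep(0, 3),
                             c("homopolymer_slippage", "strand_bias",
                               "low_af_noise"))
  profiles <- list(IR = caller_profile("IR", 1, zero_fp, TRUE),
                   MG = caller_profile("MG", 1, zero_fp),
                   PM = caller_profile("PM", 1, zero_fp, TRUE),
                   VS = caller_profile("VS", 1, zero_fp))
  cfg <- simulation_config(seed = 49L, n_regions = 4L, region_length = 1500L,
                           n_patients = 2L, n_somatic = 10L,
                           n_germline = 0L, profiles = profiles)
  truth <- plant_truth(generate_reference(cfg), cfg)
  ev <- simulate_evidence(truth, cfg)
  sim <- simulate_caller_calls(truth, ev, cfg)
  som_ids <- sort(truth$id[truth$status == "somatic"])
  for (ch in names(sim$calls)) {
    expect_equal(sort(unique(sim$calls[[ch]]$id)), som_ids, info = ch)
  }
  # with no artifacts and no germline there is nothing to subtract
  pm <- dplyr::bind_rows(lapply(c("P1", "P2"), function(p) {
    pm_subtract(sim$tvc_tumor[sim$tvc_tumor$patient == p, ],
                sim$tvc_normal[sim$tvc_normal$patient == p, ])
  }))
  expect_equal(sort(unique(pm$id)), som_ids)
})

test_that("shared TVC draws raise IR/PM artifact overlap above IR/VS", {
  overlaps <- vapply(1:6, function(s) {
    cfg <- small_sim_config(seed = 100L + s, n_somatic = 5L, n_germline = 0L)
    truth <- plant_truth(generate_reference(cfg), cfg)
    ev <- simulate_evidence(truth, cfg)
    sim <- simulate_caller_calls(truth, ev, cfg)
    art <- truth$id[truth$status == "artifact"]
    ir <- intersect(unique(sim$calls$IR$id), art)
    pm <- intersect(unique(sim$calls$PM$id), art)
    vs <- intersect(unique(sim$calls$VS$id), art)
    c(ir_pm = length(intersect(ir, pm)), ir_vs = length(intersect(ir, vs)))
  }, c(ir_pm = 0, ir_vs = 0))
  expect_gt(mean(overlaps["ir_pm", ]), mean(overlaps["ir_vs", ]))
})

test_that("the MuTect call-stats stream encodes rescuable rejections", {
  cfg <- small_sim_config(seed = 50L)
  truth <- plant_truth(generate_reference(cfg), cfg)
  ev <- simulate_evidence(truth, cfg)
  sim <- simulate_caller_calls(truth, ev, cfg)
  cs <- sim$callstats
  expect_true(all(cs$judgement %in% c("KEEP", "REJECT")))
  keeps <- cs$judgement == "KEEP"
  expect_true(all(lengths(cs$failure_reasons[keeps]) == 0L))
  # rescue restores exactly the intended MG channel
  rescued <- mutect_rescue(cs)
  expect_setequal(unique(rescued$id), unique(sim$calls$MG$id))
  # the VS stream straddles the p-value threshold
  expect_true(any(sim$vs_records$p_value <= 1e-6))
  expect_true(any(sim$vs_records$p_value > 1e-6))
  expect_setequal(
    unique(varscan_somatic_filter(sim$vs_records)$id),
    unique(sim$calls$VS$id))
})

test_that("fixtures are written completely and reproducibly", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 51L)
  m1 <- write_fixture(cfg, dir1)
  m2 <- write_fixture(cfg, dir2)
  expect_gte(length(unique(m1$kind)), 6L)
  expect_identical(m1$md5, m2$md5)   # byte-identical regeneration
  expect_true(all(file.exists(file.path(dir1, m1$path))))

  # annotation rows cover every truth record
  ann <- read_annotations(file.path(dir1, "annotations.tsv"))
  truth <- utils::read.table(file.path(dir1, "truth.tsv"), header = TRUE,
                             sep = "\t")
  expect_equal(nrow(ann), nrow(truth))
})
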