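test_that("homopolymer runs are found with exact length thresholds", {
  runs <- find_homopolymer_runs("ACGTAAAAAAGT", 6)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$base, "A")
  expect_equal(runs$length, 6L)
  expect_equal(runs$start, 5L)

  expect_equal(nrow(find_homopolymer_runs("ACGTACGTACG", 6)), 0L)

  # "at least 6" boundary: a 5-run only appears when the threshold drops
  expect_equal(nrow(find_homopolymer_runs("AAAAA", 6)), 0L)
  expect_equal(find_homopolymer_runs("AAAAA", 5)$length, 5L)

  # N breaks runs and never forms one
  expect_equal(nrow(find_homopolymer_runs("AAANNNNNNAAA", 4)), 0L)
  expect_error(find_homopolymer_runs("ACGX", 2),
               class = "ionsomatic_bad_sequence")
})

test_that("slippage signature requires the alt base run in close proximity", {
  p <- classifier_params()
  # run of 6 Gs one base away from the call, alt = G -> slippage
  ctx <- mk_context("ACGTACGTACAGGGGGGACTA", pos = 50, window_start = 40)
  expect_true(is_slippage_signature("G", ctx, p))
  # same context, alt = T (base mismatch) -> no slippage
  expect_false(is_slippage_signature("T", ctx, p))
})

test_that("slippage proximity boundary sits at 2 bp", {
  # tabulate decisions over gaps 1..5 between run end and the variant
  for (gap in 1:5) {
    chars <- strsplit("ACTTACTTACTTACTTACTTA", "")[[1]] # 21 G-free bases
    run_end <- 11 - gap  # variant at offset 11 (pos 50, window 40..60)
    chars[(run_end - 5):run_end] <- "G"
    ctx <- mk_context(paste(chars, collapse = ""), pos = 50,
                      window_start = 40)
    expect_equal(is_slippage_signature("G", ctx), gap <= 2,
                 info = paste("gap", gap))
  }
})

test_that("coupled unidirectional neighbors are detected", {
  p <- classifier_params()
  uni <- mk_evidence(alt_fwd = 30L, alt_rev = 0L)
  bidi <- mk_evidence()
  nb_uni <- tibble::as_tibble(uni)
  nb_bidi <- tibble::as_tibble(bidi)
  expect_true(has_coupled_calls(uni, nb_uni, p))
  expect_false(has_coupled_calls(uni, NULL, p))             # isolated call
  expect_false(has_coupled_calls(bidi, nb_uni, p))          # self bidirectional
  expect_false(has_coupled_calls(uni, nb_bidi, p))          # neighbor clean
})

test_that("classification reproduces the inspection criteria", {
  p <- classifier_params()
  # typical valid: bidirectional, AF 0.20, deep, absent from normal
  res <- classify_variant(mk_evidence(depth_tumor = 500L, alt_fwd = 50L,
                                      alt_rev = 50L),
                          clean_ctx(), NULL, p)
  expect_equal(res$label, "valid")
  expect_length(res$reasons, 0L)

  # (iii) no reads on both strands
  res <- classify_variant(mk_evidence(alt_fwd = 100L, alt_rev = 0L),
                          clean_ctx(), NULL, p)
  expect_equal(res$label, "bad")
  expect_true("NO_BIDIR" %in% res$reasons)

  # (iv) allele fraction below 5%
  res <- classify_variant(mk_evidence(depth_tumor = 400L, alt_fwd = 6L,
                                      alt_rev = 6L),
                          clean_ctx(), NULL, p)
  expect_equal(res$label, "bad")
  expect_true("LOW_AF" %in% res$reasons)

  # (v) predominantly poorly mapped support
  res <- classify_variant(mk_evidence(poor_map_frac = 0.8), clean_ctx(),
                          NULL, p)
  expect_equal(res$label, "bad")
  expect_true("POOR_MAP" %in% res$reasons)

  # (vi) present at more than 5% in the normal
  res <- classify_variant(mk_evidence(alt_normal = 50L, depth_normal = 500L),
                          clean_ctx(), NULL, p)
  expect_equal(res$label, "bad")
  expect_true("IN_NORMAL" %in% res$reasons)

  # (i) alt base adjacent to a long run, unidirectional -> homopolymer
  hp_ctx <- mk_context("ACGTACGTACAGGGGGGGACT", pos = 50, window_start = 40)
  res <- classify_variant(mk_evidence(alt = "G", alt_fwd = 60L,
                                      alt_rev = 0L),
                          hp_ctx, NULL, p)
  expect_equal(res$label, "homopolymer")
  expect_equal(res$reasons[1], "HP_SLIPPAGE")

  # homopolymer precedence over the bad rules
  res <- classify_variant(mk_evidence(alt = "G", alt_fwd = 10L, alt_rev = 0L,
                                      depth_tumor = 400L),
                          hp_ctx, NULL, p)
  expect_equal(res$label, "homopolymer")
})

test_that("a 6-base run with good mappings triggers the exception", {
  p <- classifier_params()
  # run of exactly 6, heterogeneous flanks, bidirectional support, AF 0.3
  ctx <- mk_context("ACGTACGTACAGGGGGGACTA", pos = 50, window_start = 40)
  ev <- mk_evidence(alt = "G", depth_tumor = 500L, alt_fwd = 75L,
                    alt_rev = 75L)
  res <- classify_variant(ev, ctx, NULL, p)
  expect_equal(res$label, "valid")

  # a 7-base run is beyond the exception range -> homopolymer stands
  ctx7 <- mk_context("ACGTACGTACAGGGGGGGACT", pos = 50, window_start = 40)
  expect_equal(classify_variant(ev, ctx7, NULL, p)$label, "homopolymer")

  # homogeneous flanks defeat the exception
  ctx_flat <- mk_context("ACACACACACAGGGGGGACAC", pos = 50,
                         window_start = 40)
  expect_equal(classify_variant(ev, ctx_flat, NULL, p)$label, "homopolymer")
})

test_that("a low-depth note annotates but never suppresses the AF rule", {
  p <- classifier_params()
  res <- classify_variant(mk_evidence(depth_tumor = 150L, alt_fwd = 3L,
                                      alt_rev = 3L),
                          clean_ctx(), NULL, p)
  expect_equal(res$label, "bad")
  expect_true(all(c("LOW_AF", "LOW_DEPTH_NOTE") %in% res$reasons))

  res <- classify_variant(mk_evidence(depth_tumor = 150L, alt_fwd = 15L,
                                      alt_rev = 15L),
                          clean_ctx(), NULL, p)
  expect_equal(res$label, "valid")
  expect_equal(res$reasons, "LOW_DEPTH_NOTE")
})

test_that("labelling is exhaustive and exclusive on randomized evidence", {
  set.seed(501)
  p <- classifier_params()
  for (i in 1:300) {
    depth <- sample(50:2000, 1)
    alt <- rbinom(1, depth, runif(1, 0, 0.6))
    fwd <- rbinom(1, alt, runif(1))
    ev <- mk_evidence(alt = sample(c("A", "C", "G", "T"), 1),
                      depth_tumor = depth, alt_fwd = fwd,
                      alt_rev = alt - fwd,
                      poor_map_frac = runif(1),
                      depth_normal = sample(50:2000, 1),
                      alt_normal = rbinom(1, 100, runif(1, 0, 0.2)))
    ctx <- mk_context(random_window(), pos = 50, window_start = 40)
    res <- classify_variant(ev, ctx, NULL, p)
    expect_true(res$label %in% c("valid", "bad", "homopolymer"))
    if (res$label == "valid") {
      expect_true(length(res$reasons) == 0 ||
                    identical(res$reasons, "LOW_DEPTH_NOTE"))
    }
    if (res$label == "homopolymer") {
      expect_true(res$reasons[1] %in% c("HP_SLIPPAGE", "HP_COUPLED"))
    }
    if (res$label == "bad") {
      expect_true(length(setdiff(res$reasons, "LOW_DEPTH_NOTE")) > 0)
    }
  }
})

test_that("threshold changes act monotonically on the labels", {
  set.seed(502)
  p_strict <- classifier_params()
  p_loose_af <- classifier_params(af_min = 0.02)
  p_loose_norm <- classifier_params(normal_af_max = 0.10)
  for (i in 1:100) {
    depth <- sample(100:1000, 1)
    alt <- rbinom(1, depth, runif(1, 0, 0.2))
    fwd <- rbinom(1, alt, 0.5)
    ev <- mk_evidence(depth_tumor = depth, alt_fwd = fwd, alt_rev = alt - fwd,
                      poor_map_frac = runif(1, 0, 0.6),
                      alt_normal = rbinom(1, 500, runif(1, 0, 0.12)))
    ctx <- clean_ctx()
    strict <- classify_variant(ev, ctx, NULL, p_strict)
    # lowering af_min never flips a valid call to bad
    if (strict$label == "valid") {
      expect_equal(classify_variant(ev, ctx, NULL, p_loose_af)$label, "valid")
    }
    # raising normal_af_max never creates a new IN_NORMAL reason
    loose <- classify_variant(ev, ctx, NULL, p_loose_norm)
    if (!"IN_NORMAL" %in% strict$reasons) {
      expect_false("IN_NORMAL" %in% loose$reasons)
    }
  }
})

test_that("classify_all is deterministic, complete, and demands evidence", {
  reference <- Biostrings::DNAStringSet(c(
    chr1 = strrep("ACGTACGTGT", 20)
  ))
  calls <- mk_calls(c("chr1:50:A>G", "chr1:120:G>A"))
  evidence <- tibble::tibble(
    chrom = "chr1", pos = c(50L, 120L), ref = calls$ref, alt = calls$alt,
    id = calls$id, sample = "P1_T1",
    depth_tumor = 600L, alt_fwd = c(60L, 0L), alt_rev = c(60L, 40L),
    poor_map_frac = 0.05, depth_normal = 500L, alt_normal = 1L
  )
  lab1 <- classify_all(calls, evidence, reference)
  lab2 <- classify_all(calls, evidence, reference)
  expect_identical(lab1$label, lab2$label)
  expect_equal(nrow(lab1), 2L)
  expect_setequal(lab1$label, c("valid", "bad"))

  empty <- classify_all(mk_calls(character()), evidence, reference)
  expect_equal(nrow(empty), 0L)

  expect_error(
    classify_all(mk_calls("chr1:77:A>G"), evidence, reference),
    class = "ionsomatic_missing_evidence")
})

test_that("per-sample labels collapse per locus under both rules", {
  labels <- tibble::tibble(
    id = c("1:10:A>G", "1:10:A>G", "1:20:C>T", "1:20:C>T"),
    sample = c("S1", "S2", "S1", "S2"),
    label = c("valid", "bad", "bad", "homopolymer")
  )
  any_rule <- collapse_labels(labels)
  expect_true(any_rule$valid[any_rule$id == "1:10:A>G"])
  expect_false(any_rule$valid[any_rule$id == "1:20:C>T"])
  all_rule <- collapse_labels(labels, rule = "all_valid")
  expect_false(any(all_rule$valid))
})
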