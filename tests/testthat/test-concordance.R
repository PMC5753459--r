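toy_matrix <- function() {
  mk_matrix(list(
    IR = c("chr1:10:A>G", "chr1:20:A>G", "chr1:30:A>G"),  # a, b, c
    PM = c("chr1:20:A>G", "chr1:30:A>G", "chr1:40:A>G")   # b, c, d
  ))
}

test_that("the incidence matrix and signatures are built correctly", {
  m <- toy_matrix()
  expect_equal(nrow(m$loci), 4L)
  expect_equal(m$signature[m$loci$pos == 20], "IR+PM")
  expect_equal(m$signature[m$loci$pos == 10], "IR")
  expect_equal(sum(m$incidence["IR", ]), 3)

  single <- mk_matrix(list(IR = key_seq(5)))
  expect_true(all(single$signature == "IR"))

  expect_error(build_concordance(list(mk_calls(key_seq(2), caller = "IR")),
                                 callers = c("IR", "IR")),
               class = "ionsomatic_bad_channels")
})

test_that("Venn cells partition the loci and recover the marginals", {
  m <- toy_matrix()
  vc <- venn_counts(m)
  expect_equal(sum(vc$n), nrow(m$loci))
  expect_equal(vc$n[vc$signature == "IR"], 1L)
  expect_equal(vc$n[vc$signature == "PM"], 1L)
  expect_equal(vc$n[vc$signature == "IR+PM"], 2L)

  # marginal recovery on random matrices against direct counting
  set.seed(31)
  for (rep in 1:10) {
    sets <- list(IR = sample(key_seq(40), 12), MG = sample(key_seq(40), 9),
                 PM = sample(key_seq(40), 15))
    m <- mk_matrix(sets)
    vc <- venn_counts(m)
    expect_equal(sum(vc$n), nrow(m$loci))
    for (ch in names(sets)) {
      cells <- vapply(strsplit(vc$signature, "+", fixed = TRUE),
                      function(s) ch %in% s, logical(1))
      expect_equal(sum(vc$n[cells]), length(unique(sets[[ch]])))
    }
  }

  empty <- build_concordance(list(new_calls(caller = character())),
                             callers = c("IR", "PM"))
  expect_true(all(venn_counts(empty)$n == 0L))
})

test_that("strategy expressions evaluate with set semantics", {
  m <- toy_matrix()
  expect_setequal(evaluate_strategy(m, "any(1)"),
                  m$loci$id)                       # union by definition
  expect_setequal(evaluate_strategy(m, "any(2)"),
                  m$loci$id[m$loci$pos %in% c(20, 30)])
  expect_setequal(evaluate_strategy(m, "IR & PM"),
                  m$loci$id[m$loci$pos %in% c(20, 30)])
  expect_setequal(evaluate_strategy(m, "IR | PM"), m$loci$id)

  four <- mk_matrix(list(IR = key_seq(3), MG = key_seq(4), PM = key_seq(5),
                         VS = key_seq(2)))
  expect_setequal(evaluate_strategy(four, "any(4)"),
                  evaluate_strategy(four, "IR & MG & PM & VS"))
})

test_that("malformed strategy expressions fail with positions", {
  m <- toy_matrix()
  expect_error(evaluate_strategy(m, "IR &"),
               class = "ionsomatic_strategy_parse_error")
  expect_error(evaluate_strategy(m, "IR & XX"),
               class = "ionsomatic_strategy_parse_error")
  expect_error(evaluate_strategy(m, "any(9)"),
               class = "ionsomatic_strategy_parse_error")
  expect_error(evaluate_strategy(m, "(IR | PM"),
               class = "ionsomatic_strategy_parse_error")
  err <- tryCatch(parse_strategy("IR & ???", c("IR")), error = identity)
  expect_match(conditionMessage(err), "parse error")
})

test_that("engine agrees with the brute-force signature oracle", {
  set.seed(91)
  exprs <- c("IR & PM", "IR | PM", "(IR | PM) & (MG | VS)", "any(2)",
             "any(3)", "IR & MG & PM", "(IR & PM) | (MG & VS)", "any(1)")
  for (rep in 1:40) {
    k <- sample(2:4, 1)
    callers <- c("IR", "MG", "PM", "VS")[seq_len(k)]
    pool <- key_seq(sample(20:200, 1))
    sets <- lapply(callers, function(ch)
      sample(pool, sample.int(length(pool), 1)))
    names(sets) <- callers
    m <- mk_matrix(sets)
    for (e in exprs) {
      uses <- regmatches(e, gregexpr("[A-Z]{2}", e))[[1]]
      ks <- suppressWarnings(
        as.integer(sub("any\\((\\d)\\)", "\\1",
                       regmatches(e, gregexpr("any\\(\\d\\)", e))[[1]])))
      if (!all(uses %in% callers) || any(ks > k, na.rm = TRUE)) next
      expect_setequal(evaluate_strategy(m, e), brute_force_strategy(m, e))
    }
    # nesting: any(k+1) is contained in any(k)
    for (kk in seq_len(k - 1)) {
      expect_true(all(evaluate_strategy(m, sprintf("any(%d)", kk + 1)) %in%
                        evaluate_strategy(m, sprintf("any(%d)", kk))))
    }
  }
})

test_that("inspection set keeps all multi-caller loci and caps singletons", {
  pool <- sprintf("chr1:%d:A>G", seq(100, by = 3, length.out = 400))
  shared <- pool[1:40]
  m <- mk_matrix(list(
    IR = c(shared, pool[41:63]),    # 23 singletons: all selected
    VS = c(shared, pool[64:372])    # 309 singletons: capped at 50
  ))
  sel <- select_inspection_set(m, max_singletons = 50, seed = 5)
  expect_setequal(sel$multi_ids, m$loci$id[m$signature == "IR+VS"])
  log <- sel$sampling_log
  expect_equal(log$n_sampled[log$caller == "IR"], 23L)
  expect_equal(log$n_singletons[log$caller == "VS"], 309L)
  expect_equal(log$n_sampled[log$caller == "VS"], 50L)
  expect_equal(length(sel$ids), 40L + 23L + 50L)

  # reproducible under the same seed; multi-caller part seed-independent
  sel2 <- select_inspection_set(m, max_singletons = 50, seed = 5)
  expect_identical(sel$ids, sel2$ids)
  sel3 <- select_inspection_set(m, max_singletons = 50, seed = 99)
  expect_identical(sel$multi_ids, sel3$multi_ids)
  expect_true(all(sel3$multi_ids %in% sel3$ids))

  expect_error(select_inspection_set(m, 50), class = "ionsomatic_bad_params")
})

test_that("pairwise sharing reports both directions", {
  m <- toy_matrix()
  sh <- pairwise_share(m, "IR", "PM")
  expect_equal(sh$n_both, 2L)
  expect_equal(sh$pct_of_a, round(100 * 2 / 3))
  expect_equal(sh$pct_of_b, round(100 * 2 / 3))
})
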