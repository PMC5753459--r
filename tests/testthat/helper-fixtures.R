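# Shared fixture builders: everything is constructed in code at test time.

# Compact calls-table constructor: keys as "chrom:pos:ref>alt" strings.
mk_calls <- function(keys, caller = "IR", patient = "P1", sample = "P1_T1",
                     tumor_af = NA_real_, p_value = NA_real_) {
  if (!length(keys)) return(new_calls(caller = character()))
  parts <- regmatches(keys, regexec("^([^:]+):(\\d+):([ACGT])>([ACGT])$",
                                    keys))
  stopifnot(all(lengths(parts) == 5L))
  m <- do.call(rbind, parts)
  new_calls(chrom = m[, 2], pos = as.integer(m[, 3]), ref = m[, 4],
            alt = m[, 5], caller = caller, patient = patient,
            sample = sample, tumor_af = tumor_af, p_value = p_value)
}

# Concordance matrix from named list of key-string vectors.
mk_matrix <- function(sets, patient = "P1") {
  calls <- lapply(names(sets), function(ch) {
    mk_calls(sets[[ch]], caller = ch, patient = patient)
  })
  build_concordance(calls, callers = names(sets))
}

# Arbitrary distinct key strings on one chromosome.
key_seq <- function(n, chrom = "chr1", start = 100L) {
  sprintf("%s:%d:A>G", chrom, seq.int(start, by = 7L, length.out = n))
}

# One-row read evidence for classifier tests.
mk_evidence <- function(alt = "G", depth_tumor = 500L, alt_fwd = 50L,
                        alt_rev = 50L, poor_map_frac = 0.05,
                        depth_normal = 500L, alt_normal = 0L) {
  list(alt = alt, depth_tumor = depth_tumor, alt_fwd = alt_fwd,
       alt_rev = alt_rev, poor_map_frac = poor_map_frac,
       depth_normal = depth_normal, alt_normal = alt_normal)
}

# Reference context straight from a window string centered on `pos`.
mk_context <- function(window, pos, window_start = pos -
                         (nchar(window) - 1L) %/% 2L) {
  runs <- find_homopolymer_runs(window, min_length = 2L)
  runs$start <- runs$start + window_start - 1L
  structure(list(chrom = "chr1", pos = as.integer(pos), window = window,
                 window_start = as.integer(window_start), runs = runs),
            class = "reference_context")
}

# A homopolymer-free context window centered on `pos`.
clean_ctx <- function(pos = 50) {
  mk_context("ACGTACGTACGTACGTACGTA", pos = pos, window_start = pos - 10)
}

# Random 21-base window, sometimes with a planted run of 4-8 bases.
random_window <- function() {
  chars <- sample(c("A", "C", "G", "T"), 21, replace = TRUE)
  if (runif(1) < 0.4) {
    len <- sample(4:8, 1)
    start <- sample(1:(21 - len), 1)
    chars[start:(start + len - 1)] <- sample(c("A", "C", "G", "T"), 1)
  }
  paste(chars, collapse = "")
}

# Small, fast simulation configuration for IO / pipeline tests.
small_sim_config <- function(seed = 11L, n_somatic = 12L, n_germline = 5L,
                             ...) {
  mk <- function(total) {
    stats::setNames(total * c(0.15, 0.35, 0.5),
                    c("homopolymer_slippage", "strand_bias", "low_af_noise"))
  }
  profiles <- list(
    IR = caller_profile("IR", 0.9, mk(1200), tvc_linked = TRUE),
    MG = caller_profile("MG", 0.6, mk(1200)),
    PM = caller_profile("PM", 0.9, mk(2000), tvc_linked = TRUE),
    VS = caller_profile("VS", 0.95, mk(5000))
  )
  simulation_config(seed = seed, n_regions = 8L, region_length = 1500L,
                    homopolymer_density = 5, n_patients = 2L,
                    n_somatic = n_somatic, n_germline = n_germline,
                    profiles = profiles, ...)
}

# Memoised small fixture on disk, shared across test files.
small_fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "ionsomatic-small-fixture")
      if (!file.exists(file.path(dir, "manifest.tsv"))) {
        write_fixture(small_sim_config(), dir)
      }
    }
    dir
  }
})

# Independent per-locus strategy oracle: substitutes each locus's signature
# into the expression and lets R's own evaluator decide membership.
brute_force_strategy <- function(matrix, expr) {
  k <- length(matrix$callers)
  sel <- vapply(seq_len(nrow(matrix$loci)), function(j) {
    called <- matrix$incidence[, j]
    e <- expr
    e <- gsub("any\\((\\d+)\\)", sprintf("(%d >= \\1)", sum(called)), e)
    for (ch in matrix$callers) {
      e <- gsub(paste0("\\b", ch, "\\b"),
                if (called[[ch]]) "TRUE" else "FALSE", e)
    }
    isTRUE(eval(parse(text = e)))
  }, logical(1))
  matrix$loci$id[sel]
}
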