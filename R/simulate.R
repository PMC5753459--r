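# Synthetic-data generator: reference panel with homopolymer structure,
# ground-truth somatic/artifact/germline records, per-variant read evidence,
# and four caller channels' files (VCFs, MuTect call-stats, annotations),
# all deterministic functions of (config, seed).

MECHANISMS <- c("homopolymer_slippage", "strand_bias", "low_af_noise")

#' Per-caller error profile
#'
#' @param caller Channel identifier.
#' @param sensitivity Probability a true somatic variant is called.
#' @param fp_per_mb Named numeric vector of expected artifact calls per Mb of
#'   panel, one entry per mechanism in
#'   `homopolymer_slippage`, `strand_bias`, `low_af_noise`.
#' @param tvc_linked Does the channel share the Torrent Variant Caller's
#'   artifact draws? (IR and PM both sit on top of TVC, so their artifacts
#'   are correlated.)
#' @return A list of class `caller_profile`.
#' @export
caller_profile <- function(caller, sensitivity, fp_per_mb,
                           tvc_linked = FALSE) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, all(fp_per_mb >= 0),
            setequal(names(fp_per_mb), MECHANISMS))
  structure(list(caller = caller, sensitivity = sensitivity,
                 fp_per_mb = fp_per_mb[MECHANISMS], tvc_linked = tvc_linked),
            class = "caller_profile")
}

#' Default caller profiles
#'
#' Calibration knobs emulating the observed ordering of the four channels on
#' deep amplicon data: the subtraction caller (PM) and VarScan (VS) are the
#' most sensitive, the rescued MuTect channel (MG) the least; VS pays for its
#' sensitivity with by far the highest artifact rate, and the two TVC-backed
#' channels (IR, PM) share artifact draws.
#'
#' @return Named list of [caller_profile()]s for IR, MG, PM, VS.
#' @export
default_caller_profiles <- function() {
  mk <- function(total, mix = c(0.15, 0.35, 0.5)) {
    stats::setNames(total * mix, MECHANISMS)
  }
  list(
    IR = caller_profile("IR", 0.85, mk(1700), tvc_linked = TRUE),
    MG = caller_profile("MG", 0.55, mk(1650)),
    PM = caller_profile("PM", 0.90, mk(3200), tvc_linked = TRUE),
    VS = caller_profile("VS", 0.95, mk(10700))
  )
}

#' Simulation configuration
#'
#' Defaults emulate a deep targeted amplicon study: a multi-region panel with
#' homopolymer runs at realistic density, a handful of patients each with one
#' matched normal, tumor allele fractions diluted by purity/heterogeneity
#' (truncated Beta), negative-binomial depth around 1400x, and the four
#' caller channels of [default_caller_profiles()].
#'
#' @param seed Integer seed (mandatory; every stage draws from a named
#'   substream of it).
#' @param n_regions,region_length Panel geometry (regions x bases).
#' @param homopolymer_density Planted runs per kb of reference.
#' @param run_length_lambda Planted run length is `4 + rpois(lambda)`.
#' @param n_patients Number of patients.
#' @param samples_per_patient Tumor samples per patient.
#' @param sample_carrier_prob With multiple tumor samples, probability each
#'   carries a given somatic variant (intra-tumoral heterogeneity).
#' @param n_somatic True somatic variants per patient.
#' @param n_germline Germline het variants per patient that TVC sees in both
#'   tissues (leak candidates for the subtraction channel).
#' @param af_shape1,af_shape2,af_floor Somatic allele-fraction distribution:
#'   Beta(shape1, shape2) truncated below at `af_floor`.
#' @param depth_mean,depth_size Negative-binomial tumor depth.
#' @param normal_depth_mean Normal-sample mean depth.
#' @param error_rate Background alt-read rate in the normal.
#' @param poor_map_frac_artifact Fraction of strand-bias / low-AF artifacts
#'   whose supporting reads are additionally poorly mapped.
#' @param profiles Named list of [caller_profile()]s.
#' @param tvc_shared_frac Fraction of the TVC-linked channels' common
#'   artifact budget drawn once and shared by all linked channels.
#' @param germline_leak_prob Named per-caller probability that a germline
#'   variant leaks into the tumor call set.
#' @param mg_reject_rescuable_frac Fraction of true MG calls written as
#'   REJECT with only the `nearby_gap_events` reason (rescuable) rather than
#'   KEEP.
#' @param frac_artifact_intronic Fraction of artifact loci annotated
#'   intronic/intergenic (removed by the functional filter).
#' @param frac_germline_in_pop Fraction of germline loci flagged in the
#'   population databases (removed by the population filter).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_regions = 25L, region_length = 2000L,
                              homopolymer_density = 4,
                              run_length_lambda = 1.2,
                              n_patients = 4L, samples_per_patient = 1L,
                              sample_carrier_prob = 0.8,
                              n_somatic = 25L, n_germline = 8L,
                              af_shape1 = 2, af_shape2 = 5, af_floor = 0.08,
                              depth_mean = 1400, depth_size = 8,
                              normal_depth_mean = 1400,
                              error_rate = 0.002,
                              poor_map_frac_artifact = 0.15,
                              profiles = default_caller_profiles(),
                              tvc_shared_frac = 0.4,
                              germline_leak_prob = c(IR = 0.05, MG = 0.02,
                                                     PM = 0.12, VS = 0.05),
                              mg_reject_rescuable_frac = 0.3,
                              frac_artifact_intronic = 0.25,
                              frac_germline_in_pop = 0.7) {
  if (missing(seed) || !is.numeric(seed)) {
    abort_typed("simulation_config requires an integer `seed`",
                "ionsomatic_bad_config")
  }
  cfg <- as.list(environment())
  stopifnot(cfg$n_regions >= 1, cfg$region_length >= 1, cfg$n_patients >= 1,
            cfg$n_somatic >= 0, cfg$n_germline >= 0,
            cfg$homopolymer_density >= 0)
  structure(cfg, class = "simulation_config")
}

panel_mb <- function(config) {
  config$n_regions * config$region_length / 1e6
}

#' Study conditions for end-to-end parameter recovery
#'
#' A fixed configuration used to check that the pipeline recovers known
#' per-caller operating points: 4 patients x 75 somatic variants (300 true
#' somatic loci), a 240 kb panel, and caller profiles with sensitivities
#' 0.85/0.55/0.90/0.95 (IR/MG/PM/VS) and artifact budgets chosen so the
#' configured PPVs are 0.50/0.40/0.36/0.10. Annotation nuisance is switched
#' off (no germline records, no intronic artifacts) so the configured
#' operating points are exactly the quantities the estimator targets; see
#' [expected_operating_points()].
#'
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
parameter_recovery_config <- function(seed) {
  n_som_total <- 4L * 75L
  mb <- 60L * 4000L / 1e6
  sens <- c(IR = 0.85, MG = 0.55, PM = 0.90, VS = 0.95)
  ppv_target <- c(IR = 0.50, MG = 0.40, PM = 0.36, VS = 0.10)
  mix <- c(0.15, 0.35, 0.5)
  profiles <- lapply(names(sens), function(ch) {
    fp_total <- sens[[ch]] * n_som_total * (1 - ppv_target[[ch]]) /
      ppv_target[[ch]]
    caller_profile(ch, sens[[ch]],
                   stats::setNames(fp_total / mb * mix, MECHANISMS),
                   tvc_linked = ch %in% c("IR", "PM"))
  })
  simulation_config(
    seed = seed, n_regions = 60L, region_length = 4000L,
    n_patients = 4L, n_somatic = 75L, n_germline = 0L,
    profiles = stats::setNames(profiles, names(sens)),
    frac_artifact_intronic = 0
  )
}

#' Expected channel operating points implied by a configuration
#'
#' The configured "true" per-caller PPV and sensitivity that an end-to-end
#' run should recover: sensitivity is the profile's own, PPV is
#' `E[somatic calls] / (E[somatic calls] + E[artifact calls])` over the whole
#' cohort (annotation-filter attrition not included — use configurations with
#' `frac_artifact_intronic = 0` when checking recovery against these values).
#'
#' @param config A [simulation_config()].
#' @return A tibble: caller, sensitivity, expected_fp, expected_ppv.
#' @export
expected_operating_points <- function(config) {
  mb <- panel_mb(config)
  n_som <- config$n_patients * config$n_somatic
  rows <- lapply(config$profiles, function(pr) {
    fp <- sum(pr$fp_per_mb) * mb
    s <- pr$sensitivity * n_som
    tibble::tibble(caller = pr$caller, sensitivity = pr$sensitivity,
                   expected_fp = fp, expected_ppv = s / (s + fp))
  })
  dplyr::bind_rows(rows)
}

# Replace any run of >= 4 identical bases in `chars` so the background never
# forms homopolymers; planted runs are then the only runs of length >= 4.
break_background_runs <- function(chars) {
  repeat {
    r <- rle(chars)
    long <- which(r$lengths >= 4L)
    if (!length(long)) break
    ends <- cumsum(r$lengths)
    for (j in long) {
      pos <- ends[j] - r$lengths[j] + 4L # 4th base of the run
      chars[pos] <- sample(setdiff(BASES, r$values[j]), 1L)
    }
  }
  chars
}

#' Generate the synthetic reference panel
#'
#' Builds `n_regions` sequences of `region_length` bases whose background is
#' free of homopolymer runs of length >= 4, then plants runs (length
#' `4 + rpois(run_length_lambda)`, so lengths of 6+ occur) at
#' `homopolymer_density` per kb. Panel intervals tile the sequences.
#'
#' @param config A [simulation_config()].
#' @return A list: `sequences` ([Biostrings::DNAStringSet], regions named
#'   chr1..chrN), `panel` (tibble chrom/start0/end, BED-style 0-based
#'   half-open), `runs` (tibble of planted runs: chrom, start, length, base).
#' @export
generate_reference <- function(config) {
  if (config$region_length < 1L) {
    abort_typed("zero-length regions are not allowed", "ionsomatic_bad_config")
  }
  with_substream(config$seed, "reference", {
    seqs <- character(config$n_regions)
    run_rows <- list()
    for (r in seq_len(config$n_regions)) {
      chars <- sample(BASES, config$region_length, replace = TRUE)
      chars <- break_background_runs(chars)
      n_runs <- stats::rpois(1L, config$homopolymer_density *
                               config$region_length / 1000)
      placed <- integer()
      lens <- integer()
      bases <- character()
      if (n_runs > 0L) {
        cand <- sort(sample.int(max(config$region_length - 30L, 1L), n_runs))
        for (s in cand) {
          len <- 4L + stats::rpois(1L, config$run_length_lambda)
          if (length(placed) &&
              s <= max(placed + lens) + 2L) next # keep runs separated
          if (s + len + 1L > config$region_length) next
          base <- sample(BASES, 1L)
          chars[s:(s + len - 1L)] <- base
          # make both flanks differ from the run base so the run is maximal
          for (fl in c(s - 1L, s + len)) {
            if (fl >= 1L && fl <= config$region_length &&
                chars[fl] == base) {
              chars[fl] <- sample(setdiff(BASES, base), 1L)
            }
          }
          placed <- c(placed, s)
          lens <- c(lens, len)
          bases <- c(bases, base)
        }
      }
      seqs[r] <- paste(chars, collapse = "")
      if (length(placed)) {
        run_rows[[r]] <- tibble::tibble(chrom = paste0("chr", r),
                                        start = placed, length = lens,
                                        base = bases)
      }
    }
    names(seqs) <- paste0("chr", seq_len(config$n_regions))
    list(
      sequences = Biostrings::DNAStringSet(seqs),
      panel = tibble::tibble(chrom = names(seqs), start0 = 0L,
                             end = config$region_length),
      runs = dplyr::bind_rows(run_rows)
    )
  })
}

# Positions eligible for "clean" truth placement: further than `margin` bp
# from any planted run of length >= 5 (so variant mechanisms stay separable).
clean_positions <- function(reference, margin = 12L) {
  len <- config_region_length(reference)
  out <- list()
  for (chrom in names(reference$sequences)) {
    ok <- rep(TRUE, len)
    ok[1:min(2L, len)] <- FALSE
    ok[max(1L, len - 1L):len] <- FALSE
    runs <- reference$runs[reference$runs$chrom == chrom &
                             reference$runs$length >= 5L, , drop = FALSE]
    if (nrow(runs)) {
      for (i in seq_len(nrow(runs))) {
        lo <- max(1L, runs$start[i] - margin)
        hi <- min(len, runs$start[i] + runs$length[i] - 1L + margin)
        ok[lo:hi] <- FALSE
      }
    }
    out[[chrom]] <- which(ok)
  }
  out
}

config_region_length <- function(reference) {
  unique(Biostrings::width(reference$sequences))[1]
}

# Slots adjacent (within 2 bp) to runs of length >= 6 where ref != run base;
# planting the run base as alt there creates a canonical slippage artifact.
slippage_slots <- function(reference) {
  rows <- list()
  seqs <- as.character(reference$sequences)
  runs6 <- reference$runs[reference$runs$length >= 6L, , drop = FALSE]
  if (nrow(runs6) == 0L) return(tibble::tibble())
  for (i in seq_len(nrow(runs6))) {
    chrom <- runs6$chrom[i]
    len <- nchar(seqs[[chrom]])
    s <- runs6$start[i]
    e <- s + runs6$length[i] - 1L
    for (pos in c(s - 2L, s - 1L, e + 1L, e + 2L)) {
      if (pos < 1L || pos > len) next
      refb <- substr(seqs[[chrom]], pos, pos)
      if (refb != runs6$base[i] && refb %in% BASES) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = chrom, pos = pos, ref = refb, alt = runs6$base[i]
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
}

rtrunc_beta <- function(n, shape1, shape2, floor) {
  lo <- stats::pbeta(floor, shape1, shape2)
  stats::qbeta(stats::runif(n, lo, 1), shape1, shape2)
}

draw_alt_allele <- function(ref) {
  vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
}

#' Plant ground-truth variant records
#'
#' Places, per patient, the configured somatic variants (uniform over clean
#' panel positions, truncated-Beta allele fractions), germline het variants,
#' and the artifact loci each caller channel will emit: homopolymer-slippage
#' artifacts sit within 2 bp of a planted run of length >= 6 with the
#' alternate allele equal to the run base; strand-bias and low-AF artifacts
#' sit on clean positions. Artifact pool sizes are Poisson draws around each
#' profile's expected count; a `tvc_shared_frac` share of the TVC-linked
#' channels' common budget is drawn once and stamped `artifact_channel =
#' "TVC_SHARED"`, the rest are channel-private.
#'
#' @param reference Output of [generate_reference()].
#' @param config A [simulation_config()].
#' @return A truth tibble: key columns, `id`, `patient`, `status`
#'   (somatic/artifact/germline), `mechanism`, `true_af`, `in_1kg`, `in_evs`,
#'   `func_class`, `artifact_channel` (generator bookkeeping: "" for
#'   non-artifacts, a channel name, or "TVC_SHARED").
#' @export
plant_truth <- function(reference, config) {
  with_substream(config$seed, "truth", {
    clean <- clean_positions(reference)
    clean_tbl <- dplyr::bind_rows(lapply(names(clean), function(ch) {
      tibble::tibble(chrom = ch, pos = clean[[ch]])
    }))
    slots <- slippage_slots(reference)
    seqs <- as.character(reference$sequences)
    mb <- panel_mb(config)
    patients <- paste0("P", seq_len(config$n_patients))

    take_clean <- function(n) {
      if (n > nrow(clean_tbl)) {
        abort_typed("more variants requested than available clean positions",
                    "ionsomatic_bad_config")
      }
      idx <- sample.int(nrow(clean_tbl), n)
      out <- clean_tbl[idx, , drop = FALSE]
      if (length(idx)) clean_tbl <<- clean_tbl[-idx, , drop = FALSE]
      out$ref <- vapply(seq_len(nrow(out)), function(i) {
        substr(seqs[[out$chrom[i]]], out$pos[i], out$pos[i])
      }, "")
      out$alt <- draw_alt_allele(out$ref)
      out
    }
    take_slots <- function(n) {
      if (n > nrow(slots)) {
        abort_typed(sprintf(
          "requested %d homopolymer artifacts but only %d slippage slots exist",
          n, nrow(slots)), "ionsomatic_bad_config")
      }
      idx <- sample.int(nrow(slots), n)
      out <- slots[idx, , drop = FALSE]
      if (length(idx)) slots <<- slots[-idx, , drop = FALSE]
      out
    }

    rows <- list()
    add <- function(df, patient, status, mechanism, true_af, channel = "") {
      if (!nrow(df)) return(invisible())
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
        patient = patient, status = status, mechanism = mechanism,
        true_af = true_af, artifact_channel = channel
      )
    }

    for (p in patients) {
      som <- take_clean(config$n_somatic)
      add(som, p, "somatic", "none",
          rtrunc_beta(config$n_somatic, config$af_shape1, config$af_shape2,
                      config$af_floor))
      ger <- take_clean(config$n_germline)
      add(ger, p, "germline", "germline_leak", rep(0.5, config$n_germline))
    }

    # artifact pools: shared TVC budget once, channel-private remainder,
    # spread uniformly over patients
    linked <- names(Filter(function(pr) pr$tvc_linked, config$profiles))
    af_for <- function(mech, n) {
      switch(mech,
        homopolymer_slippage = stats::runif(n, 0.08, 0.30),
        strand_bias = stats::runif(n, 0.10, 0.25),
        low_af_noise = stats::runif(n, 0.008, 0.035)
      )
    }
    plant_artifacts <- function(n, mech, channel) {
      if (n == 0L) return(invisible())
      df <- if (mech == "homopolymer_slippage") take_slots(n) else
        take_clean(n)
      pat <- sample(patients, n, replace = TRUE)
      for (p in unique(pat)) {
        sel <- pat == p
        add(df[sel, , drop = FALSE], p, "artifact", mech,
            af_for(mech, sum(sel)), channel)
      }
    }
    for (mech in MECHANISMS) {
      shared_mean <- if (length(linked) >= 2L) {
        config$tvc_shared_frac *
          min(vapply(config$profiles[linked],
                     function(pr) pr$fp_per_mb[[mech]], 0)) * mb
      } else 0
      plant_artifacts(stats::rpois(1L, shared_mean), mech, "TVC_SHARED")
      for (pr in config$profiles) {
        mean_c <- pr$fp_per_mb[[mech]] * mb -
          (if (pr$tvc_linked) shared_mean else 0)
        plant_artifacts(stats::rpois(1L, max(mean_c, 0)), mech, pr$caller)
      }
    }

    truth <- dplyr::bind_rows(rows)
    truth$id <- variant_id(truth$chrom, truth$pos, truth$ref, truth$alt)
    truth <- truth[!duplicated(truth$id), , drop = FALSE]

    # annotations drawn here so the truth table is self-contained
    n <- nrow(truth)
    keep_classes_p <- c(exonic = 0.70, UTR3 = 0.08, UTR5 = 0.06,
                        stopgain = 0.04, splicing = 0.04, ncRNA = 0.08)
    truth$func_class <- sample(names(keep_classes_p), n, replace = TRUE,
                               prob = keep_classes_p)
    is_art <- truth$status == "artifact"
    intronic <- is_art &
      stats::runif(n) < config$frac_artifact_intronic
    truth$func_class[intronic] <- sample(c("intronic", "intergenic"),
                                         sum(intronic), replace = TRUE,
                                         prob = c(0.85, 0.15))
    is_ger <- truth$status == "germline"
    in_pop <- is_ger & stats::runif(n) < config$frac_germline_in_pop
    truth$in_1kg <- in_pop & stats::runif(n) < 0.9
    truth$in_evs <- in_pop & stats::runif(n) < 0.6
    # "in population" germline must be in at least one database
    fixup <- in_pop & !truth$in_1kg & !truth$in_evs
    truth$in_1kg[fixup] <- TRUE
    ord <- order_variant_keys(truth$chrom, truth$pos, truth$alt)
    truth[ord, c("chrom", "pos", "ref", "alt", "id", "patient", "status",
                 "mechanism", "true_af", "func_class", "in_1kg", "in_evs",
                 "artifact_channel")]
  })
}

tumor_samples_of <- function(patient, config) {
  paste0(patient, "_T", seq_len(config$samples_per_patient))
}

normal_sample_of <- function(patient) paste0(patient, "_N")

#' Simulate per-variant read evidence
#'
#' For every truth record and every tumor sample of its patient, draws tumor
#' depth (negative binomial), alt reads (binomial at the true allele
#' fraction) split across strands (strand-bias artifacts put all alt reads on
#' one strand), a poor-mapping fraction (elevated for a configured subset of
#' artifacts), and matched-normal depth/alt counts (germline records show the
#' variant at ~50% in the normal; everything else at the background error
#' rate).
#'
#' @param truth Output of [plant_truth()].
#' @param config A [simulation_config()].
#' @return An evidence tibble (one row per record x tumor sample) with the
#'   columns of [read_evidence()], plus `patient`, `carrier` (whether the
#'   sample truly carries a somatic variant) and `tumor_af_obs`.
#' @export
simulate_evidence <- function(truth, config) {
  with_substream(config$seed, "evidence", {
    n_s <- config$samples_per_patient
    n_rec <- nrow(truth)
    idx <- rep(seq_len(n_rec), each = n_s)
    s_idx <- rep(seq_len(n_s), times = n_rec)
    n <- length(idx)

    carrier <- rep(TRUE, n)
    if (n_s > 1L) {
      som <- truth$status[idx] == "somatic"
      carrier[som] <- stats::runif(sum(som)) < config$sample_carrier_prob
      # every somatic record keeps at least one carrying sample
      any_carrier <- tapply(carrier, idx, any)
      rescue <- which(!any_carrier)
      if (length(rescue)) {
        pick <- (rescue - 1L) * n_s + sample.int(n_s, length(rescue),
                                                 replace = TRUE)
        carrier[pick] <- TRUE
      }
    }

    depth_t <- pmax(50L, stats::rnbinom(n, size = config$depth_size,
                                        mu = config$depth_mean))
    af <- ifelse(carrier, truth$true_af[idx], 0)
    alt <- stats::rbinom(n, depth_t, af)
    unidir <- truth$mechanism[idx] %in% c("strand_bias",
                                          "homopolymer_slippage")
    side <- stats::rbinom(n, 1L, 0.5)
    alt_fwd <- ifelse(unidir, side * alt,
                      stats::rbinom(n, alt, 0.5))
    alt_rev <- alt - alt_fwd
    depth_n <- pmax(50L, stats::rnbinom(n, size = config$depth_size,
                                        mu = config$normal_depth_mean))
    p_normal <- ifelse(truth$status[idx] == "germline", truth$true_af[idx],
                       config$error_rate)
    alt_n <- stats::rbinom(n, depth_n, p_normal)
    poor_rec <- truth$mechanism %in% c("strand_bias", "low_af_noise") &
      stats::runif(n_rec) < config$poor_map_frac_artifact
    poor <- ifelse(poor_rec[idx], stats::runif(n, 0.6, 0.95),
                   stats::runif(n, 0, 0.2))

    tibble::tibble(
      chrom = truth$chrom[idx], pos = truth$pos[idx], ref = truth$ref[idx],
      alt = truth$alt[idx], id = truth$id[idx], patient = truth$patient[idx],
      sample = paste0(truth$patient[idx], "_T", s_idx),
      carrier = carrier,
      depth_tumor = depth_t, alt_fwd = as.integer(alt_fwd),
      alt_rev = as.integer(alt_rev),
      tumor_af_obs = round((alt_fwd + alt_rev) / depth_t, 6),
      poor_map_frac = round(poor, 4),
      depth_normal = depth_n, alt_normal = alt_n
    )
  })
}

#' Simulate the four caller channels' call sets
#'
#' Applies each profile to the truth and evidence: somatic variants are
#' called per channel with probability `sensitivity` (per carrying sample);
#' artifact loci are called by their private channel, or by every TVC-linked
#' channel when the locus came from the shared TVC pool; germline variants
#' leak into each channel with its configured leak probability. VS calls get
#' somatic p-values at or below 1e-6 and its file also carries decoy records
#' with p-values above threshold; MG calls are represented as call-stats rows
#' — a configured fraction REJECTed with only `nearby_gap_events` (rescuable),
#' plus non-rescuable REJECT rows for candidates the channel does not call.
#'
#' @param truth Output of [plant_truth()].
#' @param evidence Output of [simulate_evidence()].
#' @param config A [simulation_config()].
#' @return A list: `calls` (named list of calls tibbles per channel IR, MG,
#'   PM, VS), `tvc_tumor`, `tvc_normal` (TVC per-sample calls feeding the
#'   subtraction channel), `vs_records` (VS calls + decoys with p-values),
#'   `callstats` (MuTect call-stats tibble).
#' @export
simulate_caller_calls <- function(truth, evidence, config) {
  with_substream(config$seed, "calls", {
    channels <- names(config$profiles)

    ev_carrier <- evidence[evidence$carrier, , drop = FALSE]
    ev_carrier <- ev_carrier[!duplicated(paste(ev_carrier$id,
                                               ev_carrier$sample)), ,
                             drop = FALSE]

    # one Bernoulli draw per (record, channel); the draws are organised
    # record-major so the stream is stable under channel reordering
    n_rec <- nrow(truth)
    u <- matrix(stats::runif(n_rec * length(channels)), nrow = n_rec,
                dimnames = list(NULL, channels))
    finalize <- function(ch) {
      pr <- config$profiles[[ch]]
      called <- (truth$status == "somatic" & u[, ch] < pr$sensitivity) |
        (truth$status == "artifact" &
           (truth$artifact_channel == ch |
              (pr$tvc_linked & truth$artifact_channel == "TVC_SHARED"))) |
        (truth$status == "germline" &
           u[, ch] < config$germline_leak_prob[[ch]])
      rows <- ev_carrier[ev_carrier$id %in% truth$id[called], , drop = FALSE]
      ord <- order_variant_keys(rows$chrom, rows$pos, rows$alt)
      rows <- rows[ord, , drop = FALSE]
      new_calls(rows$chrom, rows$pos, rows$ref, rows$alt,
                caller = if (nrow(rows)) ch else character(),
                patient = rows$patient, sample = rows$sample,
                tumor_af = rows$tumor_af_obs)
    }
    call_sets <- stats::setNames(lapply(channels, finalize), channels)

    # --- PM channel realized as TVC tumor / normal call pairs -------------
    # tumor TVC = PM calls plus non-leaked germline (also called in normal);
    # normal TVC = the non-leaked germline. Subtraction then returns exactly
    # the PM set, while leaked germline survives (the documented failure
    # mode).
    germ <- truth[truth$status == "germline", , drop = FALSE]
    pm_ids <- unique(call_sets$PM$id)
    germ_unleaked <- germ[!germ$id %in% pm_ids, , drop = FALSE]
    extra <- ev_carrier[ev_carrier$id %in% germ_unleaked$id, , drop = FALSE]
    pm_as_tvc <- call_sets$PM
    if (nrow(pm_as_tvc)) pm_as_tvc$caller <- "TVC"
    tvc_tumor <- validate_calls(dplyr::bind_rows(
      pm_as_tvc,
      new_calls(extra$chrom, extra$pos, extra$ref, extra$alt,
                caller = if (nrow(extra)) "TVC" else character(),
                patient = extra$patient, sample = extra$sample,
                tumor_af = extra$tumor_af_obs)
    ))
    tvc_normal <- if (nrow(germ_unleaked)) {
      new_calls(germ_unleaked$chrom, germ_unleaked$pos, germ_unleaked$ref,
                germ_unleaked$alt, caller = "TVC",
                patient = germ_unleaked$patient,
                sample = normal_sample_of(germ_unleaked$patient),
                tumor_af = 0.5)
    } else {
      new_calls(caller = character())
    }

    # --- VS records: true calls with p <= 1e-6, decoys above ---------------
    vs <- call_sets$VS
    if (nrow(vs)) {
      vs$p_value <- 10^-stats::runif(nrow(vs), 6, 12)
      vs$p_value[1L] <- 1e-6 # exercise the boundary
    }
    uncalled <- truth[!truth$id %in% vs$id, , drop = FALSE]
    n_decoy <- min(nrow(uncalled), max(5L, nrow(vs) %/% 10L))
    decoys <- NULL
    if (n_decoy > 0L) {
      dec <- uncalled[sample.int(nrow(uncalled), n_decoy), , drop = FALSE]
      dec_ev <- ev_carrier[ev_carrier$id %in% dec$id, , drop = FALSE]
      dec_ev <- dec_ev[!duplicated(dec_ev$id), , drop = FALSE]
      if (nrow(dec_ev)) {
        decoys <- new_calls(dec_ev$chrom, dec_ev$pos, dec_ev$ref, dec_ev$alt,
                            caller = "VS", patient = dec_ev$patient,
                            sample = dec_ev$sample,
                            tumor_af = dec_ev$tumor_af_obs)
        decoys$p_value <- 10^-stats::runif(nrow(decoys), 2, 5.9)
      }
    }
    vs_records <- validate_calls(dplyr::bind_rows(vs, decoys))

    # --- MG call-stats ------------------------------------------------------
    mg <- call_sets$MG
    mg_loci <- mg[!duplicated(paste(mg$id, mg$sample)), , drop = FALSE]
    rescuable <- stats::runif(nrow(mg_loci)) < config$mg_reject_rescuable_frac
    keep_stats <- tibble::tibble(
      chrom = mg_loci$chrom, pos = mg_loci$pos, ref = mg_loci$ref,
      alt = mg_loci$alt, patient = mg_loci$patient, sample = mg_loci$sample,
      judgement = ifelse(rescuable, "REJECT", "KEEP"),
      failure_reasons = ifelse(rescuable, "nearby_gap_events", "")
    )
    un_mg <- truth[!truth$id %in% mg$id, , drop = FALSE]
    n_rej <- min(nrow(un_mg), max(5L, nrow(mg_loci) %/% 5L))
    rej_stats <- NULL
    if (n_rej > 0L) {
      rej <- un_mg[sample.int(nrow(un_mg), n_rej), , drop = FALSE]
      other <- c("clustered_read_position", "fstar_tumor_lod",
                 "possible_contamination")
      reason <- vapply(seq_len(n_rej), function(i) {
        r <- sample(other, sample(1:2, 1L))
        if (stats::runif(1L) < 0.4) r <- c("nearby_gap_events", r)
        paste(sort(unique(r)), collapse = ",")
      }, "")
      rej_stats <- tibble::tibble(
        chrom = rej$chrom, pos = rej$pos, ref = rej$ref, alt = rej$alt,
        patient = rej$patient,
        sample = vapply(rej$patient, function(p)
          tumor_samples_of(p, config)[1L], ""),
        judgement = "REJECT", failure_reasons = reason
      )
    }
    callstats <- dplyr::bind_rows(keep_stats, rej_stats)
    callstats$failure_reasons <- strsplit(callstats$failure_reasons, ",",
                                          fixed = TRUE)
    callstats$failure_reasons <- lapply(callstats$failure_reasons,
                                        function(x) x[nzchar(x)])
    callstats$id <- variant_id(callstats$chrom, callstats$pos, callstats$ref,
                               callstats$alt)
    ord <- order_variant_keys(callstats$chrom, callstats$pos, callstats$alt)
    callstats <- callstats[ord, ]

    list(calls = call_sets, tvc_tumor = tvc_tumor, tvc_normal = tvc_normal,
         vs_records = vs_records, callstats = callstats)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Runs the full generator ([generate_reference()], [plant_truth()],
#' [simulate_evidence()], [simulate_caller_calls()]) and emits: reference
#' FASTA (indexed when Rsamtools is available), panel BED (0-based
#' half-open), per-sample VCFs for the IR channel, TVC tumor/normal VCF pairs
#' (the subtraction channel's input), VS VCFs with `SPV` p-values, per-sample
#' MuTect call-stats TSVs, the annotation, evidence and truth TSVs, and a
#' manifest listing every file with its MD5 checksum. Everything is a pure
#' function of the configuration (and its seed): re-running with the same
#' config reproduces identical bytes.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (`kind`, `patient`, `sample`, `path`, `md5`),
#'   invisibly; paths are relative to `dir`.
#' @export
write_fixture <- function(config, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort_typed(paste("cannot create fixture directory", dir),
                "ionsomatic_io_error")
  }
  reference <- generate_reference(config)
  truth <- plant_truth(reference, config)
  evidence <- simulate_evidence(truth, config)
  sim <- simulate_caller_calls(truth, evidence, config)

  manifest <- list()
  register <- function(kind, path, patient = NA, sample = NA) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      kind = kind, patient = as.character(patient),
      sample = as.character(sample), path = path
    )
  }
  fp <- function(rel) file.path(dir, rel)

  Biostrings::writeXStringSet(reference$sequences, fp("reference.fa"),
                              width = 70L)
  register("reference", "reference.fa")
  if (requireNamespace("Rsamtools", quietly = TRUE)) {
    Rsamtools::indexFa(fp("reference.fa"))
    register("reference_index", "reference.fa.fai")
  }
  utils::write.table(as.data.frame(reference$panel), fp("panel.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  register("panel_bed", "panel.bed")

  contigs <- stats::setNames(Biostrings::width(reference$sequences),
                             names(reference$sequences))
  patients <- paste0("P", seq_len(config$n_patients))
  dir.create(fp("vcf"), showWarnings = FALSE)
  for (p in patients) {
    for (s in tumor_samples_of(p, config)) {
      ir <- sim$calls$IR[sim$calls$IR$sample == s, , drop = FALSE]
      rel <- file.path("vcf", paste0(s, ".ir.vcf"))
      write_simple_vcf(ir, fp(rel), s, contigs)
      register("ir_vcf", rel, p, s)

      tvc <- sim$tvc_tumor[sim$tvc_tumor$sample == s, , drop = FALSE]
      rel <- file.path("vcf", paste0(s, ".tvc.vcf"))
      write_simple_vcf(tvc, fp(rel), s, contigs)
      register("tvc_tumor_vcf", rel, p, s)

      vs <- sim$vs_records[sim$vs_records$sample == s, , drop = FALSE]
      rel <- file.path("vcf", paste0(s, ".vs.vcf"))
      write_simple_vcf(vs, fp(rel), s, contigs, with_spv = TRUE)
      register("vs_vcf", rel, p, s)

      cs <- sim$callstats[sim$callstats$sample == s, , drop = FALSE]
      rel <- file.path("vcf", paste0(s, ".mg_callstats.tsv"))
      write_callstats(cs, fp(rel))
      register("mg_callstats", rel, p, s)
    }
    ns <- normal_sample_of(p)
    tvc_n <- sim$tvc_normal[sim$tvc_normal$sample == ns, , drop = FALSE]
    rel <- file.path("vcf", paste0(ns, ".tvc.vcf"))
    write_simple_vcf(tvc_n, fp(rel), ns, contigs)
    register("tvc_normal_vcf", rel, p, ns)
  }

  ann <- truth[, c("chrom", "pos", "ref", "alt", "func_class", "in_1kg",
                   "in_evs")]
  write_tsv_stable(ann, fp("annotations.tsv"))
  register("annotations", "annotations.tsv")

  ev_cols <- c("chrom", "pos", "ref", "alt", "sample", "depth_tumor",
               "alt_fwd", "alt_rev", "poor_map_frac", "depth_normal",
               "alt_normal")
  write_tsv_stable(evidence[, ev_cols], fp("evidence.tsv"))
  register("evidence", "evidence.tsv")

  write_tsv_stable(
    truth[, c("chrom", "pos", "ref", "alt", "patient", "status", "mechanism",
              "true_af", "artifact_channel")],
    fp("truth.tsv"))
  register("truth", "truth.tsv")

  manifest <- dplyr::bind_rows(manifest)
  manifest$md5 <- unname(tools::md5sum(file.path(dir, manifest$path)))
  write_tsv_stable(manifest, fp("manifest.tsv"))
  invisible(manifest)
}
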