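# Rule-based classifier automating the visual-inspection procedure: each
# candidate is labelled valid, bad, or homopolymer, with reason codes
# mirroring the six inspection criteria. The human visual cues are replaced
# by quantitative proxies (documented per parameter below).

#' Classifier thresholds
#'
#' Named parameters behind every inspection rule, with defaults:
#' \describe{
#'   \item{window_bp}{half-width of the reference window scanned for
#'     homopolymer runs, centered on the variant (10 bp).}
#'   \item{min_run}{run length that makes a locus a homopolymer suspect (6).}
#'   \item{exception_run_min}{shortest run that can trigger the slippage
#'     signature, and the lower bound of the run lengths eligible for the
#'     good-mapping exception (5).}
#'   \item{heterogeneity_min_distinct}{distinct bases required outside the
#'     run(s) for the exception's "sufficiently heterogeneous" flank test (3).}
#'   \item{slippage_proximity_bp}{maximum distance between the variant and a
#'     run of its alternate base for the alignment-slippage proxy (2).}
#'   \item{min_alt_per_strand}{bidirectional support means at least this many
#'     alt reads on each strand (1).}
#'   \item{af_min}{minimum tumor allele fraction (0.05).}
#'   \item{af_precision_depth}{tumor depth below which a low-depth note is
#'     attached, since the 5% AF rule loses precision (200).}
#'   \item{poor_map_max}{maximum tolerated fraction of variant-supporting
#'     reads with poor mapping (0.5).}
#'   \item{normal_af_max}{maximum normal-sample allele fraction (0.05).}
#'   \item{coupled_window_bp}{window within which co-occurring unidirectional
#'     calls count as conspicuously coupled (15).}
#' }
#'
#' @param ... Overrides for any of the above.
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(...) {
  p <- list(
    window_bp = 10L, min_run = 6L, exception_run_min = 5L,
    heterogeneity_min_distinct = 3L, slippage_proximity_bp = 2L,
    min_alt_per_strand = 1L, af_min = 0.05, af_precision_depth = 200L,
    poor_map_max = 0.5, normal_af_max = 0.05, coupled_window_bp = 15L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    abort_typed(paste("unknown classifier parameter(s):",
                      paste(unknown, collapse = ", ")),
                "ionsomatic_bad_params")
  }
  p[names(dots)] <- dots
  structure(p, class = "classifier_params")
}

#' Find maximal homopolymer runs in a sequence
#'
#' Scans a reference window for maximal stretches of identical bases of at
#' least `min_length`. N bases break runs and never form one.
#'
#' @param sequence A character scalar over A/C/G/T/N.
#' @param min_length Minimum run length to report.
#' @return A tibble with columns `base`, `start` (1-based offset within
#'   `sequence`), `length`.
#' @export
find_homopolymer_runs <- function(sequence, min_length = 6L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  empty <- tibble::tibble(base = character(), start = integer(),
                          length = integer())
  if (!nzchar(sequence)) return(empty)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (any(!chars %in% c(BASES, "N"))) {
    abort_typed("sequence contains characters outside A/C/G/T/N",
                "ionsomatic_bad_sequence")
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_length & r$values != "N"
  tibble::tibble(base = r$values[keep], start = starts[keep],
                 length = r$lengths[keep])
}

#' Extract reference context around a variant
#'
#' Pulls the +/- `window_bp` reference window around a position and the
#' maximal homopolymer runs (length >= 2) overlapping it, in genomic
#' coordinates.
#'
#' @param reference A [Biostrings::DNAStringSet] (or named character vector)
#'   of reference sequences.
#' @param chrom,pos Variant coordinates (1-based). Chromosome names are
#'   matched canonically.
#' @param window_bp Window half-width.
#' @return A list of class `reference_context`: `chrom`, `pos`, `window`
#'   (string), `window_start` (genomic coordinate of the window's first
#'   base), `runs` (tibble with genomic `start`, `length`, `base`).
#' @export
reference_context <- function(reference, chrom, pos, window_bp = 10L) {
  seqs <- if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else {
    reference
  }
  hit <- match(canonical_chrom(chrom), canonical_chrom(names(seqs)))
  if (is.na(hit)) {
    abort_typed(paste("chromosome not in reference:", chrom),
                "ionsomatic_missing_context")
  }
  seq <- seqs[[hit]]
  len <- nchar(seq)
  if (pos < 1L || pos > len) {
    abort_typed(sprintf("position %d outside %s (length %d)", pos, chrom, len),
                "ionsomatic_missing_context")
  }
  from <- max(1L, pos - window_bp)
  to <- min(len, pos + window_bp)
  window <- substr(seq, from, to)
  runs <- find_homopolymer_runs(window, min_length = 2L)
  runs$start <- runs$start + from - 1L
  structure(list(chrom = chrom, pos = as.integer(pos), window = window,
                 window_start = from, runs = runs),
            class = "reference_context")
}

# Distance (bp) from a position to each run; 0 when pos falls inside a run.
run_distance <- function(pos, runs) {
  ends <- runs$start + runs$length - 1L
  pmax(0L, pmax(runs$start - pos, pos - ends))
}

#' Alignment-slippage signature
#'
#' Quantitative proxy for the visual slippage cue: the called alternate base
#' is "present on reference sequence in close proximity", i.e. a homopolymer
#' run of the alt base, at least `exception_run_min` long, lies within
#' `slippage_proximity_bp` of the variant.
#'
#' @param alt Alternate base of the call.
#' @param context A [reference_context()].
#' @param params A [classifier_params()].
#' @return TRUE/FALSE.
#' @export
is_slippage_signature <- function(alt, context, params = classifier_params()) {
  runs <- context$runs
  if (!nrow(runs)) return(FALSE)
  near <- run_distance(context$pos, runs) <= params$slippage_proximity_bp
  any(near & runs$base == alt & runs$length >= params$exception_run_min)
}

evidence_af <- function(ev) {
  if (ev$depth_tumor <= 0) return(0)
  (ev$alt_fwd + ev$alt_rev) / ev$depth_tumor
}

bidirectional <- function(ev, params) {
  ev$alt_fwd >= params$min_alt_per_strand &&
    ev$alt_rev >= params$min_alt_per_strand
}

#' Conspicuously coupled unidirectional calls
#'
#' TRUE iff at least one other call in the same sample lies within
#' `coupled_window_bp`, and both this call and at least one such neighbor
#' lack bidirectional support — the cascade pattern of slippage at amplicon
#' boundaries.
#'
#' @param evidence One-row evidence (list or single-row tibble) for the call.
#' @param neighbor_evidence Evidence rows for other called loci in the same
#'   sample within the window (may have zero rows).
#' @param params A [classifier_params()].
#' @return TRUE/FALSE.
#' @export
has_coupled_calls <- function(evidence, neighbor_evidence,
                              params = classifier_params()) {
  if (is.null(neighbor_evidence) || nrow(neighbor_evidence) == 0L) {
    return(FALSE)
  }
  if (bidirectional(evidence, params)) return(FALSE)
  any(neighbor_evidence$alt_fwd < params$min_alt_per_strand |
        neighbor_evidence$alt_rev < params$min_alt_per_strand)
}

# Exception to the homopolymer rule: a run of 5-6 bases with heterogeneous
# flanks, bidirectional support and adequate AF still yields plausible calls.
hp_exception_applies <- function(ev, context, params) {
  runs5 <- context$runs[context$runs$length >= params$exception_run_min, ,
                        drop = FALSE]
  if (!nrow(runs5)) return(FALSE)
  if (any(runs5$length > params$min_run)) return(FALSE)
  # flank heterogeneity: distinct non-N bases in the window outside the runs
  chars <- strsplit(context$window, "", fixed = TRUE)[[1]]
  gpos <- seq.int(context$window_start, length.out = length(chars))
  in_run <- rep(FALSE, length(chars))
  for (i in seq_len(nrow(runs5))) {
    in_run <- in_run | (gpos >= runs5$start[i] &
                          gpos <= runs5$start[i] + runs5$length[i] - 1L)
  }
  flank <- setdiff(unique(chars[!in_run]), "N")
  length(flank) >= params$heterogeneity_min_distinct &&
    bidirectional(ev, params) &&
    evidence_af(ev) >= params$af_min
}

#' Classify one candidate variant from read evidence and reference context
#'
#' Applies the inspection criteria in fixed precedence:
#' \enumerate{
#'   \item *homopolymer* — a run of at least `min_run` bases lies within the
#'     window AND the call shows the alignment-slippage signature
#'     (`HP_SLIPPAGE`) or conspicuously coupled unidirectional calls
#'     (`HP_COUPLED`), unless the good-mapping exception applies (all runs in
#'     the window of length 5–6, heterogeneous flanks, bidirectional support,
#'     adequate AF);
#'   \item *bad* — any of: no supporting reads on both strands (`NO_BIDIR`),
#'     tumor allele fraction below `af_min` (`LOW_AF`), predominantly poorly
#'     mapped supporting reads (`POOR_MAP`), or allele fraction above
#'     `normal_af_max` in the matched normal (`IN_NORMAL`); all triggered
#'     reasons are recorded;
#'   \item *valid* otherwise.
#' }
#' A `LOW_DEPTH_NOTE` is appended (to any label) when tumor depth is below
#' `af_precision_depth`; the AF rule still applies at low depth rather than
#' silently passing unverifiable calls.
#'
#' @param evidence One-row evidence (list or single-row tibble) with fields
#'   `alt`, `depth_tumor`, `alt_fwd`, `alt_rev`, `poor_map_frac`,
#'   `depth_normal`, `alt_normal`.
#' @param context A [reference_context()] covering the variant.
#' @param neighbor_evidence Evidence rows for other called loci within
#'   `coupled_window_bp` in the same sample (or NULL).
#' @param params A [classifier_params()].
#' @return A list with `label` ("valid", "bad" or "homopolymer") and
#'   `reasons` (character vector, possibly empty).
#' @export
classify_variant <- function(evidence, context, neighbor_evidence = NULL,
                             params = classifier_params()) {
  if (is.null(context)) {
    abort_typed("missing reference context", "ionsomatic_missing_context")
  }
  ev <- as.list(evidence)
  reasons <- character()
  label <- NULL

  hp_run_present <- any(context$runs$length >= params$min_run)
  if (hp_run_present) {
    slip <- is_slippage_signature(ev$alt, context, params)
    coupled <- has_coupled_calls(ev, neighbor_evidence, params)
    if ((slip || coupled) && !hp_exception_applies(ev, context, params)) {
      label <- "homopolymer"
      if (slip) reasons <- c(reasons, "HP_SLIPPAGE")
      if (coupled) reasons <- c(reasons, "HP_COUPLED")
    }
  }

  if (is.null(label)) {
    if (!bidirectional(ev, params)) reasons <- c(reasons, "NO_BIDIR")
    if (evidence_af(ev) < params$af_min) reasons <- c(reasons, "LOW_AF")
    if (ev$poor_map_frac > params$poor_map_max) {
      reasons <- c(reasons, "POOR_MAP")
    }
    normal_af <- if (ev$depth_normal > 0) {
      ev$alt_normal / ev$depth_normal
    } else 0
    if (normal_af > params$normal_af_max) reasons <- c(reasons, "IN_NORMAL")
    label <- if (length(reasons)) "bad" else "valid"
  }

  if (ev$depth_tumor < params$af_precision_depth) {
    reasons <- c(reasons, "LOW_DEPTH_NOTE")
  }
  list(label = label, reasons = reasons)
}

#' Classify all candidate variants
#'
#' Runs [classify_variant()] over every (variant key, sample) pair in
#' `calls`, deriving reference context from `reference` and coupled-call
#' neighborhoods from the co-called loci in each sample.
#'
#' @param calls Calls tibble (the candidates to label; callers are ignored —
#'   one verdict per key/sample pair).
#' @param evidence Evidence tibble (see [read_evidence()]).
#' @param reference Reference sequences ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param params A [classifier_params()].
#' @return A tibble with one row per (id, sample): key columns, `label`,
#'   `reasons` (comma-joined codes). Attribute `summary` holds per-label and
#'   per-reason counts.
#' @export
classify_all <- function(calls, evidence, reference,
                         params = classifier_params()) {
  units <- unique(calls[, c("chrom", "pos", "ref", "alt", "id", "sample")])
  out <- tibble::tibble(
    chrom = units$chrom, pos = units$pos, ref = units$ref, alt = units$alt,
    id = units$id, sample = units$sample,
    label = character(nrow(units)), reasons = character(nrow(units))
  )
  if (!nrow(units)) {
    attr(out, "summary") <- list(labels = table(character()),
                                 reasons = table(character()))
    return(out)
  }
  ev_key <- paste(evidence$id, evidence$sample)
  ev_hit <- match(paste(units$id, units$sample), ev_key)
  if (anyNA(ev_hit)) {
    miss <- which(is.na(ev_hit))[1]
    abort_typed(sprintf("no read evidence for %s in sample %s",
                        units$id[miss], units$sample[miss]),
                "ionsomatic_missing_evidence")
  }
  ev_df <- as.data.frame(evidence[ev_hit, c("alt", "depth_tumor", "alt_fwd",
                                            "alt_rev", "poor_map_frac",
                                            "depth_normal", "alt_normal")])
  u_sample <- units$sample
  u_chrom <- canonical_chrom(units$chrom)
  u_pos <- units$pos
  u_id <- units$id
  # cache contexts per key (samples share the reference window)
  ctx_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(units))) {
    ctx <- if (!is.null(ctx_cache[[u_id[i]]])) {
      ctx_cache[[u_id[i]]]
    } else {
      ctx_cache[[u_id[i]]] <- reference_context(reference, units$chrom[i],
                                                u_pos[i], params$window_bp)
    }
    neighbors <- which(u_sample == u_sample[i] & u_chrom == u_chrom[i] &
                         abs(u_pos - u_pos[i]) <= params$coupled_window_bp &
                         u_id != u_id[i])
    nb <- if (length(neighbors)) ev_df[neighbors, , drop = FALSE] else NULL
    res <- classify_variant(ev_df[i, ], ctx, nb, params)
    out$label[i] <- res$label
    out$reasons[i] <- paste(res$reasons, collapse = ",")
  }
  reason_codes <- unlist(strsplit(out$reasons[nzchar(out$reasons)], ","))
  attr(out, "summary") <- list(labels = table(out$label),
                               reasons = table(reason_codes))
  out
}

#' Collapse per-sample labels to one verdict per locus
#'
#' A locus observed in several samples (or patients) gets a single verdict:
#' with `rule = "any_valid"` (default) it is valid if valid in at least one
#' sample; with `rule = "all_valid"` it must be valid in every carrying
#' sample. Non-valid collapsed loci take the most frequent non-valid label.
#'
#' @param labels Output of [classify_all()].
#' @param rule Collapse rule.
#' @return A tibble with one row per `id`: `label` and `valid` (logical).
#' @export
collapse_labels <- function(labels, rule = c("any_valid", "all_valid")) {
  rule <- match.arg(rule)
  if (!nrow(labels)) {
    return(tibble::tibble(id = character(), label = character(),
                          valid = logical()))
  }
  split_lab <- split(labels$label, labels$id)
  collapsed <- vapply(split_lab, function(ls) {
    ok <- if (rule == "any_valid") any(ls == "valid") else all(ls == "valid")
    if (ok) return("valid")
    nv <- ls[ls != "valid"]
    if (!length(nv)) nv <- ls
    names(sort(table(nv), decreasing = TRUE))[1]
  }, character(1))
  tibble::tibble(id = names(collapsed), label = unname(collapsed),
                 valid = collapsed == "valid")
}
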