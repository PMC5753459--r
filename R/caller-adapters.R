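# The three bespoke channel constructions: tumor-normal subtraction (PM),
# MuTect rejection rescue (MG), and VarScan somatic p-value filtering (VS).

#' "Poor Man's" tumor-normal subtraction
#'
#' Somatic candidates are the tumor sample's TVC calls whose exact variant key
#' (chromosome, position, ref, alt) is absent from the matched normal's TVC
#' call set. Subtraction deliberately operates on *emitted calls only* — it
#' never consults normal pileups — which preserves the channel's documented
#' failure mode: a variant present in both tissues but not called in the
#' normal leaks through, and must be caught downstream by the
#' normal-allele-fraction inspection criterion.
#'
#' @param tumor Calls tibble from the TVC channel for one tumor sample.
#' @param normal Calls tibble from the TVC channel for the matched normal.
#' @param by Matching unit: `"allele"` (default; exact key) or `"locus"`
#'   (chromosome+position only, for sensitivity analysis — a different alt in
#'   the normal then also suppresses the tumor allele).
#' @return The tumor calls not seen in the normal, relabelled caller `"PM"`.
#' @export
pm_subtract <- function(tumor, normal, by = c("allele", "locus")) {
  by <- match.arg(by)
  tumor <- validate_calls(tumor)
  normal <- validate_calls(normal)
  pats <- unique(stats::na.omit(c(tumor$patient, normal$patient)))
  if (length(pats) > 1L) {
    abort_typed(paste("pm_subtract: tumor and normal belong to different",
                      "patients:", paste(pats, collapse = ", ")),
                "ionsomatic_patient_mismatch")
  }
  key_of <- function(x) {
    if (by == "allele") x$id
    else paste0(canonical_chrom(x$chrom), ":", x$pos)
  }
  keep <- !(key_of(tumor) %in% key_of(normal))
  out <- tumor[keep, , drop = FALSE]
  out$caller <- rep("PM", nrow(out))
  validate_calls(out)
}

#' Rescue MuTect rejections by failure reason
#'
#' Builds the MG channel from a MuTect call-stats table: a candidate is
#' retained iff its judgement is KEEP, or it was REJECTed *only* for reasons
#' contained in `rescue_flags`. The default rescues candidates rejected
#' solely as `nearby_gap_events` — gaps are implicit in amplicon sequencing,
#' so this rejection is inappropriate for the platform. A REJECT carrying any
#' non-rescuable reason stays rejected. `clustered_read_position` may be
#' added to `rescue_flags`, but is off by default (it performed poorly and
#' was discarded).
#'
#' @param callstats Tibble from [read_callstats()].
#' @param rescue_flags Character vector of rescuable failure reasons.
#' @param sample,patient Identifiers stamped onto the resulting calls.
#' @return A calls tibble labelled caller `"MG"`.
#' @export
mutect_rescue <- function(callstats,
                          rescue_flags = "nearby_gap_events",
                          sample = NA_character_, patient = NA_character_) {
  bad <- setdiff(unique(callstats$judgement), c("KEEP", "REJECT"))
  if (length(bad)) {
    abort_typed(paste("unknown call-stats judgement token:",
                      paste(bad, collapse = ", ")),
                "ionsomatic_bad_callstats")
  }
  rescued <- vapply(callstats$failure_reasons, function(r) {
    length(r) > 0L && all(r %in% rescue_flags)
  }, logical(1))
  keep <- callstats$judgement == "KEEP" |
    (callstats$judgement == "REJECT" & rescued)
  kept <- callstats[keep, , drop = FALSE]
  new_calls(kept$chrom, kept$pos, kept$ref, kept$alt,
            caller = if (nrow(kept)) "MG" else character(),
            patient = patient, sample = sample)
}

#' Filter VarScan somatic calls on the somatic p-value
#'
#' Retains calls with somatic p-value `<= p_max`; a call annotated with a
#' p-value *greater than* the threshold is rejected, so the boundary value
#' itself is kept. The default threshold of 1e-6 brings VarScan's call volume
#' on flow-based deep amplicon data in line with the other channels.
#'
#' @param calls Calls tibble; every row must carry `p_value`.
#' @param p_max Rejection threshold (reject iff p > p_max).
#' @return The retained calls.
#' @export
varscan_somatic_filter <- function(calls, p_max = 1e-6) {
  calls <- validate_calls(calls)
  if (nrow(calls) && anyNA(calls$p_value)) {
    first <- calls$id[which(is.na(calls$p_value))[1]]
    abort_typed(sprintf("call %s lacks a somatic p-value", first),
                "ionsomatic_missing_pvalue")
  }
  calls[!nrow(calls) | calls$p_value <= p_max, , drop = FALSE]
}
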