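# Population-database and functional-class exclusion filters.

#' Functional classes retained by default
#'
#' Exonic and exon-adjacent classes; intronic, intergenic and everything else
#' is excluded from the analysis universe.
#'
#' @export
KEEP_FUNC_CLASSES <- c("exonic", "UTR3", "UTR5", "stopgain", "splicing",
                       "ncRNA")

lookup_annotations <- function(calls, annotations, lenient, stage) {
  hit <- match(calls$id, annotations$id)
  if (anyNA(hit)) {
    n_missing <- sum(is.na(hit))
    msg <- sprintf("%s: %d calls lack annotations", stage, n_missing)
    if (!lenient) {
      abort_typed(paste0(msg, " (strict mode)"), "ionsomatic_unannotated")
    }
    warning(paste0(msg, "; retained (lenient mode)"), call. = FALSE)
  }
  hit
}

#' Exclude population-database variants
#'
#' Drops calls whose variant key is flagged as present in either the 1000
#' Genomes Project or the Exome Variant Server — presence in either database
#' marks a candidate as likely germline polymorphism. Membership is
#' presence/absence only; no frequency threshold is applied. Lookup is by
#' exact allele (population membership is allele-specific).
#'
#' @param calls Calls tibble.
#' @param annotations Annotation tibble from [read_annotations()].
#' @param lenient If TRUE, unannotated calls are retained with a warning;
#'   default (strict) errors on any unannotated call.
#' @return The retained calls, with attribute `n_excluded`.
#' @export
apply_population_filter <- function(calls, annotations, lenient = FALSE) {
  calls <- validate_calls(calls)
  hit <- lookup_annotations(calls, annotations, lenient, "population filter")
  in_pop <- !is.na(hit) &
    (annotations$in_1kg[hit] | annotations$in_evs[hit])
  out <- calls[!in_pop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(in_pop)
  out
}

#' Exclude variants outside the retained functional classes
#'
#' Keeps calls annotated with one of `keep_classes`; intronic and intergenic
#' calls (and by default any other class such as upstream/downstream) are
#' excluded, restricting the analysis to the coding-adjacent target space.
#'
#' @inheritParams apply_population_filter
#' @param keep_classes Functional classes to retain.
#' @return The retained calls, with attribute `n_excluded`.
#' @export
apply_functional_filter <- function(calls, annotations,
                                    keep_classes = KEEP_FUNC_CLASSES,
                                    lenient = FALSE) {
  calls <- validate_calls(calls)
  hit <- lookup_annotations(calls, annotations, lenient, "functional filter")
  keep <- is.na(hit) | annotations$func_class[hit] %in% keep_classes
  out <- calls[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}
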