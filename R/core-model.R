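#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

BASES <- c("A", "C", "G", "T")

#' Caller channels known to the pipeline
#'
#' IR = Ion Reporter tumor-normal calls; MG = MuTect with rejection rescue;
#' PM = "Poor Man's" tumor-normal subtraction of per-sample TVC calls;
#' VS = VarScan2 somatic calls filtered on the somatic p-value; TVC = raw
#' Torrent Variant Caller per-sample calls (the input to PM, not itself a
#' somatic channel).
#'
#' @export
CALLER_CHANNELS <- c("IR", "MG", "PM", "VS", "TVC")

#' Construct a single-nucleotide variant key
#'
#' A variant key identifies one alternate allele at one 1-based reference
#' position. Only true SNVs are representable: `ref` and `alt` must each be a
#' single A/C/G/T base and must differ. Anything else (indels, MNVs, symbolic
#' alleles, `*`) is rejected with a condition of class
#' `ionsomatic_not_snv`, because indel calling on flow-based platforms is out
#' of scope for this pipeline.
#'
#' Chromosome names keep their original spelling but compare canonically:
#' "chr1" and "1" denote the same chromosome.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param pos 1-based position (integer >= 1).
#' @param ref Reference base, one of A/C/G/T.
#' @param alt Alternate base, one of A/C/G/T, different from `ref`.
#' @return An object of class `variant_key`: a list with fields `chrom`,
#'   `pos`, `ref`, `alt` and the canonical string `id`.
#' @examples
#' make_variant_key("chr1", 100, "A", "G")
#' @export
make_variant_key <- function(chrom, pos, ref, alt) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom)) {
    abort_typed("`chrom` must be a non-empty string", "ionsomatic_bad_key")
  }
  pos <- suppressWarnings(as.integer(pos))
  if (is.na(pos) || pos < 1L) {
    abort_typed("`pos` must be an integer >= 1", "ionsomatic_bad_key")
  }
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  for (allele in list(c("ref", ref), c("alt", alt))) {
    a <- allele[2]
    if (is.na(a) || nchar(a) != 1L || !a %in% BASES) {
      abort_typed(
        sprintf("`%s` allele %s is not a single A/C/G/T base: not an SNV",
                allele[1], dQuote(a, q = FALSE)),
        "ionsomatic_not_snv"
      )
    }
  }
  if (ref == alt) {
    abort_typed("`ref` and `alt` must differ", "ionsomatic_bad_key")
  }
  structure(
    list(chrom = chrom, pos = pos, ref = ref, alt = alt,
         id = variant_id(chrom, pos, ref, alt)),
    class = "variant_key"
  )
}

#' @export
print.variant_key <- function(x, ...) {
  cat("<variant_key>", x$id, "\n")
  invisible(x)
}

#' @export
format.variant_key <- function(x, ...) x$id

#' Order variant keys
#'
#' Total order: canonical chromosome (lexical), then position, then alternate
#' base. Used wherever deterministic output ordering matters.
#'
#' @param chrom,pos,alt Parallel vectors of key fields.
#' @return An integer permutation, as [base::order()].
#' @export
order_variant_keys <- function(chrom, pos, alt) {
  order(canonical_chrom(chrom), as.integer(pos), as.character(alt),
        method = "radix")
}

# Columns every calls table carries. `tumor_af`, `p_value` may be NA.
CALL_COLUMNS <- c("chrom", "pos", "ref", "alt", "id", "caller", "patient",
                  "sample", "tumor_af", "p_value")

#' Assemble a calls table
#'
#' The package represents collections of variant calls as plain tibbles with
#' a fixed column set; `new_calls()` builds and validates one. Most users get
#' calls tables from [load_vcf_calls()] or the synthetic-data generator and
#' never call this directly.
#'
#' @param chrom,pos,ref,alt Variant key fields (vectors, recycled by tibble).
#' @param caller Channel identifier, one of [CALLER_CHANNELS].
#' @param patient,sample Patient and sample identifiers.
#' @param tumor_af Tumor allele fraction in \[0,1\], or NA.
#' @param p_value Somatic p-value in (0,1\], or NA (VS channel only).
#' @return A tibble with columns `r paste(CALL_COLUMNS, collapse=", ")`.
#' @export
new_calls <- function(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), caller = character(),
                      patient = NA_character_, sample = NA_character_,
                      tumor_af = NA_real_, p_value = NA_real_) {
  calls <- tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    caller = as.character(caller),
    patient = as.character(patient), sample = as.character(sample),
    tumor_af = as.numeric(tumor_af), p_value = as.numeric(p_value)
  )
  calls$id <- variant_id(calls$chrom, calls$pos, calls$ref, calls$alt)
  validate_calls(calls[, CALL_COLUMNS])
}

#' Validate a calls table
#'
#' Checks the column contract and the type invariants (SNV alleles, positions
#' >= 1, declared caller channels, allele fractions in \[0,1\]).
#'
#' @param calls A calls tibble.
#' @param channels Allowed channel identifiers.
#' @return `calls`, invisibly usable, with columns in canonical order.
#' @export
validate_calls <- function(calls, channels = CALLER_CHANNELS) {
  missing_cols <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing_cols)) {
    abort_typed(paste("calls table lacks columns:",
                      paste(missing_cols, collapse = ", ")),
                "ionsomatic_bad_calls")
  }
  if (nrow(calls)) {
    if (any(calls$pos < 1L, na.rm = TRUE)) {
      abort_typed("positions must be >= 1", "ionsomatic_bad_calls")
    }
    bad_allele <- !(calls$ref %in% BASES) | !(calls$alt %in% BASES) |
      calls$ref == calls$alt
    if (any(bad_allele)) {
      abort_typed(sprintf("%d records are not simple SNVs", sum(bad_allele)),
                  "ionsomatic_not_snv")
    }
    if (!all(calls$caller %in% channels)) {
      abort_typed("undeclared caller channel in calls table",
                  "ionsomatic_bad_calls")
    }
    af <- calls$tumor_af
    if (any(!is.na(af) & (af < 0 | af > 1))) {
      abort_typed("tumor_af outside [0,1]", "ionsomatic_bad_calls")
    }
  }
  tibble::as_tibble(calls[, CALL_COLUMNS])
}

#' Collapse calls to their distinct loci
#'
#' Projects a collection of calls (possibly spanning samples, patients and
#' callers) onto the set of distinct variant keys. A locus counts once no
#' matter how many samples carry it; this is the "637 loci from 813 called
#' variants" style of collapse used throughout concordance analysis.
#'
#' @param calls A calls tibble (see [new_calls()]).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `id`, one row
#'   per distinct key, sorted in key order.
#' @export
locus_projection <- function(calls) {
  if (!nrow(calls)) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          id = character()))
  }
  loci <- calls[!duplicated(calls$id), c("chrom", "pos", "ref", "alt", "id")]
  loci <- loci[order_variant_keys(loci$chrom, loci$pos, loci$alt), ]
  tibble::as_tibble(loci)
}

#' Describe a patient's sample layout
#'
#' @param patient Patient identifier.
#' @param tumor_samples Character vector of tumor sample identifiers (>= 1).
#' @param normal_sample The single matched-normal sample identifier.
#' @return A list of class `patient_context`.
#' @export
patient_context <- function(patient, tumor_samples, normal_sample) {
  if (length(normal_sample) != 1L) {
    abort_typed("exactly one normal sample per patient",
                "ionsomatic_bad_patient")
  }
  if (length(tumor_samples) < 1L) {
    abort_typed("at least one tumor sample per patient",
                "ionsomatic_bad_patient")
  }
  structure(list(patient = patient,
                 tumor_samples = as.character(tumor_samples),
                 normal_sample = as.character(normal_sample)),
            class = "patient_context")
}
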