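# File-format boundary: VCF ingestion (via vcfR), the small bespoke VCF
# emitter used by the synthetic-data generator, and the TSV dialects for
# MuTect call-stats, annotations, read evidence and truth records.

#' Load SNV calls from a VCF file
#'
#' Reads one caller channel's VCF and returns a normalized calls table.
#' Multi-allelic records are split into one candidate per alternate allele
#' *before* SNV filtering; non-SNV alleles are dropped (not errors) and
#' counted in the `skipped_non_snv` attribute. Only records whose FILTER is
#' `PASS` or `.` are kept. The tumor allele fraction is taken from the `AF`
#' FORMAT field when present, and the VarScan somatic p-value from the `SPV`
#' INFO field when present.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param caller Channel identifier for the resulting calls.
#' @param sample Sample identifier.
#' @param patient Patient identifier.
#' @return A calls tibble (see [new_calls()]) with attributes
#'   `skipped_non_snv` (count) and `skipped_filtered` (count).
#' @export
load_vcf_calls <- function(path, caller, sample, patient) {
  if (!file.exists(path)) {
    abort_typed(paste("VCF not found:", path), "ionsomatic_io_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !startsWith(first, "##fileformat=VCF")) {
    abort_typed(sprintf("malformed VCF %s: line 1 lacks ##fileformat header",
                        path), "ionsomatic_vcf_parse_error")
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) {
      abort_typed(sprintf("malformed VCF %s: %s", path, conditionMessage(e)),
                  "ionsomatic_vcf_parse_error")
    }
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(as.matrix(fix)) == 0L) {
    out <- new_calls(caller = character())
    attr(out, "skipped_non_snv") <- 0L
    attr(out, "skipped_filtered") <- 0L
    return(out)
  }
  fix <- as.data.frame(as.matrix(fix), stringsAsFactors = FALSE)
  if (nrow(fix) == 1L && ncol(fix) == 1L) { # vcfR collapses 1-row matrices
    fix <- as.data.frame(t(vcfR::getFIX(vcf)), stringsAsFactors = FALSE)
  }

  af <- rep(NA_real_, nrow(fix))
  if (!is.null(vcf@gt) && ncol(vcf@gt) >= 2L) {
    af_chr <- tryCatch(vcfR::extract.gt(vcf, element = "AF")[, 1L],
                       error = function(e) rep(NA_character_, nrow(fix)))
    af <- suppressWarnings(as.numeric(af_chr))
  }
  spv <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = "SPV"))
  )
  if (!length(spv)) spv <- rep(NA_real_, nrow(fix))

  pass <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  skipped_filtered <- sum(!pass)
  fix <- fix[pass, , drop = FALSE]
  af <- af[pass]
  spv <- spv[pass]

  # split multi-allelic ALT fields
  alt_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  cand <- data.frame(
    chrom = fix$CHROM[idx], pos = as.integer(fix$POS[idx]),
    ref = toupper(fix$REF[idx]), alt = toupper(unlist(alt_list)),
    tumor_af = af[idx], p_value = spv[idx],
    stringsAsFactors = FALSE
  )
  is_snv <- nchar(cand$ref) == 1L & nchar(cand$alt) == 1L &
    cand$ref %in% BASES & cand$alt %in% BASES & cand$ref != cand$alt
  skipped <- sum(!is_snv)
  cand <- cand[is_snv, , drop = FALSE]
  out <- new_calls(cand$chrom, cand$pos, cand$ref, cand$alt,
                   caller = if (nrow(cand)) caller else character(),
                   patient = patient, sample = sample,
                   tumor_af = cand$tumor_af, p_value = cand$p_value)
  attr(out, "skipped_non_snv") <- as.integer(skipped)
  attr(out, "skipped_filtered") <- as.integer(skipped_filtered)
  out
}

# Minimal deterministic VCF v4.2 emitter for simulator output. `records` must
# have chrom,pos,ref,alt plus optional tumor_af (FORMAT AF) and p_value
# (INFO SPV). Records are written in key order.
write_simple_vcf <- function(records, path, sample_name,
                             contigs = NULL, with_spv = FALSE) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ionsomatic-simulator"
  )
  if (!is.null(contigs)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contigs), as.integer(contigs)))
  }
  if (with_spv) {
    header <- c(header,
      "##INFO=<ID=SPV,Number=1,Type=Float,Description=\"Somatic p-value\">")
  }
  header <- c(header,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  lines <- header
  if (nrow(records)) {
    ord <- order_variant_keys(records$chrom, records$pos, records$alt)
    records <- records[ord, , drop = FALSE]
    af <- records$tumor_af %||% rep(NA_real_, nrow(records))
    info <- if (with_spv) {
      ifelse(is.na(records$p_value), ".",
             sprintf("SPV=%s", formatC(records$p_value, format = "e",
                                       digits = 4)))
    } else {
      rep(".", nrow(records))
    }
    gt <- ifelse(is.na(af), "0/1:.", sprintf("0/1:%.4f", af))
    lines <- c(lines, paste(records$chrom, records$pos, ".", records$ref,
                            records$alt, ".", "PASS", info, "GT:AF", gt,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MuTect call-stats table
#'
#' Parses the tab-separated per-candidate annotation file MuTect writes
#' alongside its VCF. Expected columns: `contig`, `position`, `ref_allele`,
#' `alt_allele`, `judgement` (KEEP|REJECT), `failure_reasons`
#' (comma-separated tokens, empty for KEEP).
#'
#' @param path Path to the call-stats TSV.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `id`,
#'   `judgement`, `failure_reasons` (list column of character vectors).
#' @export
read_callstats <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = character())
  need <- c("contig", "position", "ref_allele", "alt_allele", "judgement",
            "failure_reasons")
  if (!all(need %in% names(raw))) {
    abort_typed(paste("call-stats file lacks columns:",
                      paste(setdiff(need, names(raw)), collapse = ", ")),
                "ionsomatic_io_error")
  }
  reasons <- strsplit(ifelse(is.na(raw$failure_reasons), "",
                             raw$failure_reasons), ",", fixed = TRUE)
  reasons <- lapply(reasons, function(x) x[nzchar(x)])
  tibble::tibble(
    chrom = as.character(raw$contig), pos = as.integer(raw$position),
    ref = toupper(raw$ref_allele), alt = toupper(raw$alt_allele),
    id = variant_id(raw$contig, raw$position, raw$ref_allele, raw$alt_allele),
    judgement = as.character(raw$judgement),
    failure_reasons = reasons
  )
}

write_callstats <- function(stats, path) {
  df <- data.frame(
    contig = stats$chrom, position = stats$pos, ref_allele = stats$ref,
    alt_allele = stats$alt, judgement = stats$judgement,
    failure_reasons = vapply(stats$failure_reasons, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a variant annotation table
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `func_class`, `in_1kg`, `in_evs`.
#' Annotations are consumed as input (computing them is the job of external
#' annotators); exactly one row per variant key is expected.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble keyed by `id`.
#' @export
read_annotations <- function(path) {
  ann <- read_tsv_stable(path)
  need <- c("chrom", "pos", "ref", "alt", "func_class", "in_1kg", "in_evs")
  if (!all(need %in% names(ann))) {
    abort_typed("annotation table lacks required columns",
                "ionsomatic_io_error")
  }
  ann$id <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann$id)) {
    abort_typed("annotation table has duplicate variant keys",
                "ionsomatic_io_error")
  }
  ann$in_1kg <- as.logical(ann$in_1kg)
  ann$in_evs <- as.logical(ann$in_evs)
  ann
}

#' Read a per-variant read-evidence table
#'
#' One row per (variant key, tumor sample): tumor depth, forward/reverse
#' alt-read counts, fraction of variant-supporting reads with poor mapping,
#' and matched-normal depth and alt count. These are the quantities the
#' inspection-criteria classifier consumes.
#'
#' @param path Path to the evidence TSV.
#' @return A tibble keyed by (`id`, `sample`).
#' @export
read_evidence <- function(path) {
  ev <- read_tsv_stable(path)
  need <- c("chrom", "pos", "ref", "alt", "sample", "depth_tumor", "alt_fwd",
            "alt_rev", "poor_map_frac", "depth_normal", "alt_normal")
  if (!all(need %in% names(ev))) {
    abort_typed("evidence table lacks required columns", "ionsomatic_io_error")
  }
  ev$id <- variant_id(ev$chrom, ev$pos, ev$ref, ev$alt)
  ev
}
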