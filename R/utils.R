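# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical chromosome name
#'
#' Strips a leading "chr" prefix (case-insensitively) so that mixed-dialect
#' inputs ("1" vs "chr1") compare equal. The original spelling is preserved
#' wherever names are echoed back to the user; only comparisons use the
#' canonical form.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of canonical names.
#' @export
canonical_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

# Stable string identifier for a variant allele; the unit of all set algebra.
variant_id <- function(chrom, pos, ref, alt) {
  paste0(canonical_chrom(chrom), ":", as.integer(pos), ":", ref, ">", alt)
}

# Derive a reproducible sub-seed (< 2^31) for a named stage from a base seed,
# so independent stages draw from independent-looking streams.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_substream <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stage))
  expr
}

abort_typed <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ionsomatic_error"), ...)
}

# write.table with a fixed dialect so repeated runs are byte-identical.
write_tsv_stable <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) {
    out <- sprintf("%.10g", v)
    out[is.na(v)] <- "NA"
    out
  })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_stable <- function(path, ...) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      colClasses = NA, ...))
}
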