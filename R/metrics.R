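# Performance surface: PPV, sensitivity with extrapolated valid counts,
# binomial standard errors with the reportability rule.

#' Positive predictive value
#'
#' `v / C`: the fraction of a strategy's called loci that are valid.
#'
#' @param v Valid count (0 <= v <= C).
#' @param C Called count (> 0).
#' @return v/C.
#' @export
ppv <- function(v, C) {
  if (any(C <= 0)) {
    abort_typed("PPV undefined for C = 0", "ionsomatic_undefined_metric")
  }
  if (any(v < 0 | v > C)) {
    abort_typed("need 0 <= v <= C", "ionsomatic_undefined_metric")
  }
  v / C
}

#' Sensitivity against the discovered-valid proxy
#'
#' `v / V`, where `V` is the proxy for the true number of valid variants
#' (all valid variants discovered by any channel, inspected plus
#' extrapolated). Because variants missed by every channel are invisible,
#' this is an upper bound on true sensitivity.
#'
#' @param v Valid count captured by the strategy.
#' @param V Total valid count (> 0).
#' @return v/V.
#' @export
sensitivity <- function(v, V) {
  if (any(V <= 0)) {
    abort_typed("sensitivity undefined for V = 0", "ionsomatic_undefined_metric")
  }
  if (any(v < 0 | v > V)) {
    abort_typed("need 0 <= v <= V", "ionsomatic_undefined_metric")
  }
  v / V
}

#' Binomial standard error with reportability rule
#'
#' `sqrt(p(1-p)/n)` when `n * min(p, 1-p) >= 5`, else NA. `n` is the number
#' of variants *examined* (not called): extrapolated counts do not contribute
#' estimated precision, so strata known only by extrapolation never tighten
#' the SE.
#'
#' @param p Estimated proportion in \[0,1\].
#' @param n Number of inspected variants (>= 1).
#' @return The SE, or NA when the rule fails.
#' @export
binomial_se <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 1))
  se <- sqrt(p * (1 - p) / n)
  se[n * pmin(p, 1 - p) < 5] <- NA_real_
  se
}

#' Extrapolate valid counts to uninspected loci
#'
#' Partitions loci by caller signature (the finest stratification consistent
#' with "observed rates in the inspected variants hold in the uninspected"),
#' computes the inspected valid rate per stratum, and adds
#' `round(rate * n_uninspected)` extrapolated valid calls per stratum. Under
#' the standard inspection design every multi-caller locus is inspected, so
#' uninspected loci exist only in singleton strata. A stratum with
#' uninspected loci but no inspected ones (possible only with user-supplied
#' inspection sets) falls back to the pooled inspected singleton rate of the
#' stratum's channel — or the overall inspected rate for multi-caller strata
#' — with a warning.
#'
#' @param matrix A [build_concordance()] result.
#' @param labels Collapsed per-locus labels for the inspected loci
#'   ([collapse_labels()] output, or any tibble with `id` and logical
#'   `valid`).
#' @param inspected_ids Locus ids that were inspected.
#' @return A list of class `extrapolation_report`: `strata` (tibble per
#'   signature: n, n_inspected, v_inspected, rate, n_uninspected, addition),
#'   `v_inspected_total`, `additions_total`, `V_hat`.
#' @export
extrapolate_valid <- function(matrix, labels, inspected_ids) {
  if (!all(inspected_ids %in% matrix$loci$id)) {
    abort_typed("inspected set contains loci absent from the matrix",
                "ionsomatic_bad_inspection")
  }
  lab_valid <- labels$valid[match(inspected_ids, labels$id)]
  if (anyNA(lab_valid)) {
    abort_typed("every inspected locus must be labelled",
                "ionsomatic_bad_inspection")
  }
  ids <- matrix$loci$id
  inspected <- ids %in% inspected_ids
  valid <- rep(NA, length(ids))
  valid[match(inspected_ids, ids)] <- lab_valid
  sig <- matrix$signature

  strata <- lapply(unique(sig), function(s) {
    in_s <- sig == s
    n <- sum(in_s)
    n_ins <- sum(in_s & inspected)
    v_ins <- sum(valid[in_s & inspected], na.rm = TRUE)
    n_unins <- n - n_ins
    if (n_ins > 0L) {
      rate <- v_ins / n_ins
    } else if (n_unins > 0L) {
      # fallback: pooled singleton rate of the channel, or overall rate
      if (!grepl("+", s, fixed = TRUE)) {
        ch <- s
        pool <- !grepl("+", sig, fixed = TRUE) & inspected &
          matrix$incidence[ch, ]
      } else {
        pool <- inspected
      }
      rate <- if (any(pool)) mean(valid[pool]) else 0
      warning(sprintf(
        "stratum %s has %d uninspected loci and none inspected; using pooled rate %.3f",
        s, n_unins, rate), call. = FALSE)
    } else {
      rate <- 0
    }
    tibble::tibble(signature = s, n = n, n_inspected = n_ins,
                   v_inspected = v_ins, rate = rate,
                   n_uninspected = n_unins,
                   addition = as.integer(round(rate * n_unins)))
  })
  strata <- dplyr::bind_rows(strata)
  v_ins_total <- sum(strata$v_inspected)
  additions <- sum(strata$addition)
  structure(list(strata = strata, v_inspected_total = v_ins_total,
                 additions_total = additions,
                 V_hat = v_ins_total + additions),
            class = "extrapolation_report")
}

#' @export
print.extrapolation_report <- function(x, ...) {
  cat(sprintf("<extrapolation_report> V_hat = %d (%d inspected valid + %d extrapolated)\n",
              x$V_hat, x$v_inspected_total, x$additions_total))
  invisible(x)
}

#' The default strategy battery
#'
#' Single channels, all pairwise/3-way intersections, at-least-k rules, the
#' IR/PM union and the (IR|PM)&(MG|VS) composite.
#'
#' @param callers Channel names (default the four somatic channels).
#' @return Named character vector of strategy expressions.
#' @export
default_strategies <- function(callers = c("IR", "MG", "PM", "VS")) {
  singles <- stats::setNames(callers, callers)
  pairs <- utils::combn(callers, 2, paste, collapse = " & ")
  triples <- utils::combn(callers, 3, paste, collapse = " & ")
  isect <- " \u2229 " # set-intersection glyph for display names
  union_g <- " \u222a "
  out <- c(
    singles,
    stats::setNames("any(1)", "Any one"),
    stats::setNames(pairs, gsub(" & ", isect, pairs)),
    stats::setNames("any(2)", "Any two"),
    stats::setNames(triples, gsub(" & ", isect, triples)),
    stats::setNames("any(3)", "Any three"),
    stats::setNames(paste(callers, collapse = " & "),
                    paste(callers, collapse = isect)),
    stats::setNames("IR | PM", paste0("IR", union_g, "PM")),
    stats::setNames("(IR | PM) & (MG | VS)",
                    paste0("(IR", union_g, "PM)", isect, "(MG", union_g,
                           "VS)"))
  )
  out
}

#' Evaluate combination strategies
#'
#' Builds the full performance table: for each strategy, the called loci `C`,
#' inspected and inspected-valid counts, the extrapolated valid count
#' `v_hat` (inspected valid within the strategy plus the extrapolated
#' additions of every signature stratum the strategy covers), PPV and
#' sensitivity with their standard errors. The sensitivity denominator
#' `V_hat` is the extrapolated valid count of the union of all channels; its
#' SE uses the total number of inspected loci, matching the convention that
#' only examined variants contribute precision.
#'
#' @param matrix A [build_concordance()] result.
#' @param labels Collapsed labels for inspected loci (see
#'   [extrapolate_valid()]).
#' @param inspected_ids Inspected locus ids.
#' @param strategies Named character vector of strategy expressions.
#' @return A tibble with one row per strategy: `name`, `expr`, `C`,
#'   `n_inspected`, `v_inspected`, `v_hat`, `extrapolated`, `ppv`, `ppv_se`,
#'   `sens`, `sens_se`. Attributes: `V_hat`, `n_total_inspected`,
#'   `extrapolation` (the [extrapolate_valid()] report).
#' @export
evaluate_strategies <- function(matrix, labels, inspected_ids,
                                strategies = default_strategies(matrix$callers)) {
  report <- extrapolate_valid(matrix, labels, inspected_ids)
  V_hat <- report$V_hat
  n_total <- length(inspected_ids)
  ids <- matrix$loci$id
  inspected <- ids %in% inspected_ids
  valid <- rep(FALSE, length(ids))
  valid[match(labels$id[labels$valid], ids)] <- TRUE
  sig_add <- stats::setNames(report$strata$addition, report$strata$signature)

  rows <- lapply(seq_along(strategies), function(i) {
    expr <- strategies[[i]]
    sel_ids <- evaluate_strategy(matrix, expr)
    sel <- ids %in% sel_ids
    C <- sum(sel)
    n_ins <- sum(sel & inspected)
    v_ins <- sum(sel & inspected & valid)
    covered <- unique(matrix$signature[sel])
    additions <- sum(sig_add[covered])
    v_hat <- v_ins + additions
    p_hat <- if (C > 0) ppv(v_hat, C) else NA_real_
    s_hat <- sensitivity(v_hat, V_hat)
    tibble::tibble(
      name = names(strategies)[i] %||% expr, expr = expr,
      C = C, n_inspected = n_ins, v_inspected = v_ins,
      v_hat = as.integer(v_hat), extrapolated = additions > 0L,
      ppv = p_hat,
      ppv_se = if (C > 0 && n_ins >= 1) binomial_se(p_hat, n_ins) else NA_real_,
      sens = s_hat,
      sens_se = if (n_total >= 1) binomial_se(s_hat, n_total) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "V_hat") <- V_hat
  attr(out, "n_total_inspected") <- n_total
  attr(out, "extrapolation") <- report
  out
}

#' Strategy arithmetic from fixed counts
#'
#' Computes the performance row(s) — PPV, sensitivity, SEs and reportability
#' verdicts — directly from supplied counts, without a concordance matrix.
#' Useful for re-deriving a published performance table from its printed
#' `C`, `v` and inspected-`n` columns.
#'
#' @param name Strategy names.
#' @param C Called counts.
#' @param v Valid counts (extrapolated where the source says so).
#' @param n_inspected Inspected counts per strategy (PPV SE denominator).
#' @param V Total valid denominator for sensitivity.
#' @param n_total_inspected Inspected-total for the sensitivity SE.
#' @return A tibble: `name`, `C`, `v`, `ppv`, `ppv_se`, `sens`, `sens_se`.
#' @export
strategy_table_from_counts <- function(name, C, v, n_inspected, V,
                                       n_total_inspected) {
  p <- ppv(v, C)
  s <- sensitivity(v, V)
  tibble::tibble(
    name = name, C = C, v = v,
    ppv = p, ppv_se = binomial_se(p, n_inspected),
    sens = s, sens_se = binomial_se(s, n_total_inspected)
  )
}

#' Round a performance table for display
#'
#' PPV and sensitivity to 2 decimals, SEs to 3; NA rendered as the literal
#' string "NA".
#'
#' @param tbl Output of [evaluate_strategies()] or
#'   [strategy_table_from_counts()].
#' @return A character-formatted data frame.
#' @export
format_strategy_table <- function(tbl) {
  fmt <- function(x, d) ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"),
                                                       round(x, d)))
  out <- as.data.frame(tbl)
  for (col in intersect(c("ppv", "sens"), names(out))) {
    out[[col]] <- fmt(out[[col]], 2)
  }
  for (col in intersect(c("ppv_se", "sens_se"), names(out))) {
    out[[col]] <- fmt(out[[col]], 3)
  }
  out
}
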