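# Caller x locus incidence structure, combination-strategy evaluation
# (a small set-expression language), Venn counts and inspection-set
# selection.

#' Build the caller-by-locus concordance matrix
#'
#' Pools calls across samples and patients to the locus level: a locus is
#' attributed to a channel iff any of that channel's calls covers it. The
#' resulting incidence structure (and each locus's *caller signature*, the
#' subset of channels that called it) is the unit of all combination
#' analysis.
#'
#' @param calls Either one calls tibble (with its `caller` column) or a list
#'   of calls tibbles, one per channel.
#' @param callers Optional explicit channel ordering; defaults to the callers
#'   observed, in first-appearance order.
#' @return An object of class `concordance_matrix`: list with `callers`,
#'   `loci` (tibble of keys in key order), `incidence` (logical matrix,
#'   callers x loci) and `signature` (character vector per locus, e.g.
#'   `"IR+PM"`).
#' @export
build_concordance <- function(calls, callers = NULL) {
  if (is.data.frame(calls)) calls <- list(calls)
  combined <- dplyr::bind_rows(lapply(calls, validate_calls))
  if (is.null(callers)) callers <- unique(combined$caller)
  if (anyDuplicated(callers)) {
    abort_typed("duplicate channel names", "ionsomatic_bad_channels")
  }
  extra <- setdiff(unique(combined$caller), callers)
  if (length(extra)) {
    abort_typed(paste("calls from undeclared channels:",
                      paste(extra, collapse = ", ")),
                "ionsomatic_bad_channels")
  }
  loci <- locus_projection(combined)
  incidence <- matrix(FALSE, nrow = length(callers), ncol = nrow(loci),
                      dimnames = list(callers, loci$id))
  for (ch in callers) {
    ids <- unique(combined$id[combined$caller == ch])
    incidence[ch, loci$id %in% ids] <- TRUE
  }
  signature <- apply(incidence, 2L, function(col) {
    paste(callers[col], collapse = "+")
  })
  if (nrow(loci) == 0L) signature <- character()
  structure(list(callers = callers, loci = loci, incidence = incidence,
                 signature = unname(signature)),
            class = "concordance_matrix")
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("<concordance_matrix> %d callers x %d loci\n",
              length(x$callers), nrow(x$loci)))
  print(rowSums(x$incidence))
  invisible(x)
}

# ---- strategy expression mini-language ------------------------------------
# grammar:  expr   := term ('|' term)*
#           term   := factor ('&' factor)*
#           factor := '(' expr ')' | 'any' '(' int ')' | channel-identifier
# '&' is intersection, '|' union, any(k) = loci called by at least k of all
# declared channels. Whitespace-insensitive.

tokenize_strategy <- function(expr) {
  pat <- "[A-Za-z_][A-Za-z0-9_]*|[0-9]+|[&|()]"
  m <- gregexpr(pat, expr)[[1]]
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  consumed <- gsub("\\s+", "", gsub(pat, "", expr))
  if (nzchar(consumed)) {
    abort_typed(sprintf("strategy parse error near \"%s\" in \"%s\"",
                        substr(consumed, 1, 8), expr),
                "ionsomatic_strategy_parse_error")
  }
  list(tokens = toks, pos = as.integer(m))
}

#' Parse a strategy expression
#'
#' @param expr Expression string, e.g. `"IR & PM"`, `"(IR|PM)&(MG|VS)"`,
#'   `"any(2)"`.
#' @param callers Declared channel names the expression may reference.
#' @return A parse tree (nested lists) consumed by [evaluate_strategy()].
#' @export
parse_strategy <- function(expr, callers) {
  tk <- tokenize_strategy(expr)
  toks <- tk$tokens
  i <- 0L
  peek <- function() if (i < length(toks)) toks[i + 1L] else NA_character_
  take <- function() {
    i <<- i + 1L
    toks[i]
  }
  fail <- function(what) {
    at <- if (i < length(toks)) tk$pos[i + 1L] else nchar(expr) + 1L
    abort_typed(sprintf("strategy parse error at position %d of \"%s\": %s",
                        at, expr, what),
                "ionsomatic_strategy_parse_error")
  }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && peek() == "|") {
      take()
      node <- list(op = "union", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && peek() == "&") {
      take()
      node <- list(op = "intersect", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    if (t == "(") {
      take()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail("expected )")
      take()
      return(node)
    }
    if (t == "any") {
      take()
      if (is.na(peek()) || peek() != "(") fail("expected ( after any")
      take()
      k <- suppressWarnings(as.integer(peek()))
      if (is.na(k)) fail("any() needs an integer")
      take()
      if (is.na(peek()) || peek() != ")") fail("expected ) after any(k")
      take()
      if (k < 1L || k > length(callers)) {
        fail(sprintf("any(%d) out of range for %d channels", k,
                     length(callers)))
      }
      return(list(op = "any", k = k))
    }
    if (t %in% callers) {
      take()
      return(list(op = "channel", name = t))
    }
    fail(sprintf("unknown token \"%s\"", t))
  }
  node <- parse_expr()
  if (!is.na(peek())) fail(sprintf("trailing token \"%s\"", peek()))
  node
}

eval_strategy_node <- function(node, matrix) {
  switch(node$op,
    channel = matrix$incidence[node$name, ],
    any = colSums(matrix$incidence) >= node$k,
    union = eval_strategy_node(node$lhs, matrix) |
      eval_strategy_node(node$rhs, matrix),
    intersect = eval_strategy_node(node$lhs, matrix) &
      eval_strategy_node(node$rhs, matrix),
    abort_typed("unknown strategy node", "ionsomatic_strategy_parse_error")
  )
}

#' Evaluate a combination strategy over the concordance matrix
#'
#' @param matrix A [build_concordance()] result.
#' @param expr Strategy expression string or a [parse_strategy()] tree.
#' @return Character vector of locus ids selected by the strategy.
#' @export
evaluate_strategy <- function(matrix, expr) {
  node <- if (is.character(expr)) parse_strategy(expr, matrix$callers) else expr
  if (!nrow(matrix$loci)) return(character())
  sel <- eval_strategy_node(node, matrix)
  matrix$loci$id[sel]
}

#' Venn cell counts over caller signatures
#'
#' Counts loci for every nonempty subset of channels (2^k - 1 cells, zeros
#' included). Per-channel marginal totals are recoverable by summing the
#' cells containing that channel.
#'
#' @param matrix A [build_concordance()] result.
#' @return A tibble with `signature` (e.g. `"IR+PM"`) and `n`.
#' @export
venn_counts <- function(matrix) {
  k <- length(matrix$callers)
  subsets <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(matrix$callers, m, paste, collapse = "+", simplify = FALSE)
  }))
  observed <- table(matrix$signature)
  tibble::tibble(
    signature = subsets,
    n = as.integer(ifelse(subsets %in% names(observed),
                          observed[subsets], 0L))
  )
}

#' Pairwise sharing between two channels
#'
#' Reports how much of channel `a`'s locus set is shared with channel `b`
#' (and vice versa) — the "74% of IR's and 47% of PM's variants" style of
#' summary.
#'
#' @param matrix A [build_concordance()] result.
#' @param a,b Channel names.
#' @return A list: `n_a`, `n_b`, `n_both`, `pct_of_a`, `pct_of_b`
#'   (percentages rounded to whole numbers).
#' @export
pairwise_share <- function(matrix, a, b) {
  stopifnot(a %in% matrix$callers, b %in% matrix$callers)
  n_a <- sum(matrix$incidence[a, ])
  n_b <- sum(matrix$incidence[b, ])
  n_both <- sum(matrix$incidence[a, ] & matrix$incidence[b, ])
  list(n_a = n_a, n_b = n_b, n_both = n_both,
       pct_of_a = round(100 * n_both / n_a),
       pct_of_b = round(100 * n_both / n_b))
}

#' Select the inspection set
#'
#' Every locus called by two or more channels is inspected; in addition, at
#' most `max_singletons` single-channel loci per channel are sampled
#' uniformly at random. The multi-caller component is deterministic; only the
#' singleton sampling consumes randomness (from a named substream of `seed`,
#' so it is independent of simulation randomness).
#'
#' @param matrix A [build_concordance()] result.
#' @param max_singletons Per-channel cap on sampled singletons.
#' @param seed Integer seed.
#' @return A list: `ids` (locus ids, key order), `multi_ids`,
#'   `sampling_log` (tibble: caller, n_singletons, n_sampled).
#' @export
select_inspection_set <- function(matrix, max_singletons = 50L, seed) {
  if (missing(seed)) {
    abort_typed("inspection-set selection requires a seed",
                "ionsomatic_bad_params")
  }
  n_callers <- colSums(matrix$incidence)
  multi_ids <- matrix$loci$id[n_callers >= 2L]
  sampled <- character()
  log_rows <- list()
  for (ch in matrix$callers) {
    singles <- matrix$loci$id[matrix$incidence[ch, ] & n_callers == 1L]
    take <- min(max_singletons, length(singles))
    picked <- with_substream(seed, paste0("inspection_", ch), {
      if (length(singles) == 1L) {
        singles[sample.int(1L, take)]
      } else {
        sample(singles, take)
      }
    })
    sampled <- c(sampled, picked)
    log_rows[[ch]] <- tibble::tibble(caller = ch,
                                     n_singletons = length(singles),
                                     n_sampled = take)
  }
  ids <- union(multi_ids, sampled)
  ids <- matrix$loci$id[matrix$loci$id %in% ids] # restore key order
  list(ids = ids, multi_ids = multi_ids,
       sampling_log = dplyr::bind_rows(log_rows))
}
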