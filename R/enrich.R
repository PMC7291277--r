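#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` where `X` counts study hits when `n` proteins are drawn
#' without replacement from a background of `N` proteins of which `K` are
#' annotated to the term. This is the one-sided enrichment p-value
#' (equivalently Fisher's exact test, alternative "greater"), the field
#' default for over-representation screens. Computed via [stats::phyper()],
#' which works on log-binomial coefficients for numerical stability.
#'
#' @param k Study hits (vectorized).
#' @param n Study size.
#' @param K Background hits (annotated proteins in the background).
#' @param N Background size.
#' @return Numeric vector of tail probabilities in `[0, 1]`.
#' @examples
#' hypergeom_tail(3, 5, 5, 20) # 1126/15504
#' @export
hypergeom_tail <- function(k, n, K, N) {
  lens <- c(length(k), length(n), length(K), length(N))
  sz <- max(lens)
  if (any(lens != 1 & lens != sz)) {
    mhl_stop("arguments must share length or be scalar", "mhl_param_error")
  }
  k <- rep_len(as.numeric(k), sz)
  n <- rep_len(as.numeric(n), sz)
  K <- rep_len(as.numeric(K), sz)
  N <- rep_len(as.numeric(N), sz)
  ok <- !is.na(k) & !is.na(n) & !is.na(K) & !is.na(N) &
    k >= 0 & k <= n & n <= N & K >= 0 & K <= N & k <= K
  if (!all(ok)) {
    mhl_stop(
      "inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N",
      "mhl_param_error"
    )
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' clipped at 1, returned in input order (wraps [stats::p.adjust()] with
#' input validation).
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) {
    return(numeric(0))
  }
  if (any(is.na(pvalues) | pvalues < 0 | pvalues > 1)) {
    mhl_stop("p-values must lie in [0, 1]", "mhl_param_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Term over-representation analysis
#'
#' One-sided hypergeometric enrichment of a study protein set against a
#' background, per annotation term. Term annotations are intersected with
#' the background before counting; terms with no study hit are omitted
#' (they cannot be enriched and are not tested). Multiple testing is
#' corrected with Benjamini-Hochberg across the tested terms.
#'
#' @param study Character vector of study protein ids; must be a subset of
#'   `background`.
#' @param background Character vector of background protein ids.
#' @param terms Term annotation table (see [read_term_annotations()]).
#' @param q_max Significance threshold on the adjusted value; default 0.05.
#' @return A data frame sorted by (`q`, `p`, `term_id`) with columns
#'   `term_id`, `term_name`, `k` (study hits), `n` (study size), `K`
#'   (background hits), `N` (background size), `p`, `q` and `significant`
#'   (`q <= q_max`).
#' @export
enrich <- function(study, background, terms, q_max = 0.05) {
  study <- unique(study)
  background <- unique(background)
  offenders <- setdiff(study, background)
  if (length(offenders) > 0) {
    mhl_stop(
      sprintf(
        "study proteins absent from background: %s",
        paste(sort(offenders), collapse = ", ")
      ),
      "mhl_param_error"
    )
  }
  N <- length(background)
  n <- length(study)
  rows <- list()
  for (i in seq_len(nrow(terms))) {
    ann <- intersect(terms$proteins[[i]], background)
    K <- length(ann)
    k <- length(intersect(study, ann))
    if (k == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = terms$term_id[i], term_name = terms$term_name[i],
      k = k, n = n, K = K, N = N, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(
      term_id = character(0), term_name = character(0), k = integer(0),
      n = integer(0), K = integer(0), N = integer(0), p = numeric(0),
      q = numeric(0), significant = logical(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out$p <- hypergeom_tail(out$k, out$n, out$K, out$N)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= q_max
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
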