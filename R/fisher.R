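#' One-sided Fisher exact enrichment p-value
#'
#' Exact upper-tail probability P(X >= a) of the hypergeometric distribution
#' with the margins of the 2x2 table
#'
#' \preformatted{
#'                 inside interval   outside interval
#'   focal genes         a                 b
#'   other genes         c                 d
#' }
#'
#' i.e. the classical one-sided (over-representation) Fisher exact test.
#' Computed exactly from the hypergeometric distribution, not by a normal
#' approximation. All arguments are vectorised.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return numeric vector of raw one-sided p-values.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("contingency counts must be non-negative and finite")
  if (any(counts != round(counts)))
    stop("contingency counts must be integers")
  # P(X >= a), X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c)
  phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param raw_p raw p-value(s).
#' @param m number of simultaneous hypotheses (>= 1).
#' @return `min(1, raw_p * m)`, vectorised over `raw_p`.
#' @export
bonferroni <- function(raw_p, m) {
  m <- check_count(m, "m", min = 1L)
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE))
    stop("raw p-values must lie in [0, 1]")
  pmin(1, raw_p * m)
}
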