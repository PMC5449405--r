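# term-by-quantile count matrix: rows = terms, cols = quantiles 1..q;
# entry = number of the term's genes falling in that quantile of the partition
term_quantile_counts <- function(sets, partition) {
  qof <- setNames(partition$quantile, partition$gene_id)
  t(vapply(sets, function(g) {
    tabulate(qof[g[g %in% names(qof)]], nbins = partition$q)
  }, integer(partition$q)))
}

#' Step 1: per-interval gene-set enrichment against a background universe
#'
#' For every fold-change interval (all 21 for q = 6, full list included) and
#' every gene set with at least `min_genes` members inside the interval, a
#' 2x2 table of (interval genes vs rest of the background) by (in set vs not)
#' is tested with the one-sided Fisher exact test. P-values are Bonferroni
#' adjusted by (number of terms actually tested) x (number of intervals);
#' terms with `adj_p < alpha1` in at least one interval are the candidates
#' passed to [step2_specificity()].
#'
#' @param partition a [quantile_partition()] of one directional DEG list.
#' @param ann a [gene_sets()] annotation.
#' @param background character vector: the gene universe. Genes of the
#'   partition missing from it are added with a warning.
#' @param alpha1 significance threshold on adjusted p (default 0.001).
#' @param min_genes minimum set members inside an interval for the pair to
#'   be tested (default 2).
#' @param include_full test the full interval too (default `TRUE`).
#' @return data frame (class `fcs_step1`) with one row per tested
#'   term x interval: `term_id`, `direction`, `lo`, `hi`, `interval_label`,
#'   `a`, `b`, `c`, `d`, `raw_p`, `adj_p`, `significant`. Attributes
#'   `multiplier`, `n_terms_tested`, `n_intervals`, `alpha1`.
#' @export
step1_enrichment <- function(partition, ann, background,
                             alpha1 = 0.001, min_genes = 2L,
                             include_full = TRUE) {
  stopifnot(inherits(partition, "quantile_partition"),
            inherits(ann, "gene_sets"))
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background universe")
  missing <- setdiff(partition$gene_id, background)
  if (length(missing)) {
    warning(length(missing),
            " DEG(s) missing from the background were added to it")
    background <- c(background, missing)
  }
  N <- length(background)
  sets <- lapply(ann$sets, function(g) g[g %in% background])
  term_total <- lengths(sets)
  cnt <- term_quantile_counts(sets, partition)
  ivs <- enumerate_intervals(partition$q, include_full = include_full)
  int_sizes <- vapply(seq_len(nrow(ivs)), function(i)
    sum(partition$sizes[ivs$lo[i]:ivs$hi[i]]), integer(1))

  rows <- vector("list", nrow(ivs))
  tested_terms <- logical(length(sets))
  for (i in seq_len(nrow(ivs))) {
    a <- as.integer(rowSums(cnt[, ivs$lo[i]:ivs$hi[i], drop = FALSE]))
    keep <- a >= min_genes
    tested_terms <- tested_terms | keep
    if (!any(keep)) next
    b <- term_total[keep] - a[keep]
    cc <- int_sizes[i] - a[keep]
    d <- (N - int_sizes[i]) - b
    rows[[i]] <- data.frame(
      term_id = names(sets)[keep], direction = partition$direction,
      lo = ivs$lo[i], hi = ivs$hi[i], interval_label = ivs$label[i],
      a = a[keep], b = unname(b), c = cc, d = unname(d),
      raw_p = fisher_one_sided(a[keep], b, cc, d),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(term_id = character(0), direction = character(0),
                      lo = integer(0), hi = integer(0),
                      interval_label = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      raw_p = numeric(0))
  multiplier <- max(1L, sum(tested_terms)) * nrow(ivs)
  res$adj_p <- bonferroni(res$raw_p, multiplier)
  res$significant <- res$adj_p < alpha1
  res <- res[order(res$term_id, res$hi - res$lo, res$lo), ]
  rownames(res) <- NULL
  structure(res, class = c("fcs_step1", "data.frame"),
            multiplier = multiplier, n_terms_tested = sum(tested_terms),
            n_intervals = nrow(ivs), alpha1 = alpha1)
}

#' Terms selected by step 1
#' @param step1 result of [step1_enrichment()].
#' @return character vector of term ids significant in >= 1 interval.
#' @export
selected_terms <- function(step1) {
  unique(step1$term_id[step1$significant])
}

#' Step 2: fold-change specificity of selected terms
#'
#' For each step-1 candidate term, its members inside versus outside each of
#' the 20 component fold-change intervals are compared against the remaining
#' genes of the directional DEG list (the universe for this step is the
#' directional list itself, not the genome):
#'
#' \preformatted{
#'                         in interval   outside interval   total
#'   DEGs in the term           a              b             a+b
#'   the rest of the DEGs       c              d             c+d
#' }
#'
#' One-sided Fisher p-values are Bonferroni adjusted by (number of testable
#' candidate terms) x (number of component intervals). A term is
#' fold-change-specific iff its minimal adjusted p is below `alpha2`; it is
#' then assigned to the best interval (minimal adjusted p, ties broken by
#' shorter interval then lower bound). The full interval is excluded: every
#' term gene lies inside it, so its one-sided p is identically 1.
#'
#' @param terms character vector of term ids (normally
#'   `selected_terms(step1)`); terms without members in the directional list
#'   are skipped with a warning.
#' @param partition a [quantile_partition()].
#' @param ann a [gene_sets()] annotation.
#' @param alpha2 specificity threshold on adjusted p (default 0.05).
#' @return object of class `specificity_result`: list with `per_interval`
#'   (data frame: term x component interval tests), `summary` (one row per
#'   term: `term_id`, `direction`, `n_genes`, `min_adj_p`,
#'   `fold_change_specific`, `best_lo`, `best_hi`, `best_interval` label),
#'   `multiplier`, `alpha2`, `direction`, `q`.
#' @export
step2_specificity <- function(terms, partition, ann, alpha2 = 0.05) {
  stopifnot(inherits(partition, "quantile_partition"),
            inherits(ann, "gene_sets"))
  terms <- unique(as.character(terms))
  unknown <- setdiff(terms, names(ann$sets))
  if (length(unknown))
    stop("terms absent from the annotation: ",
         paste(head(unknown, 3), collapse = ", "))
  n <- partition$n
  sets <- lapply(ann$sets[terms],
                 function(g) g[g %in% partition$gene_id])
  testable <- lengths(sets) > 0L
  if (any(!testable))
    warning(sum(!testable), " term(s) with no genes in the ",
            partition$direction, "-regulated list skipped")
  sets <- sets[testable]
  ivs <- enumerate_intervals(partition$q, include_full = FALSE)
  multiplier <- max(1L, length(sets)) * nrow(ivs)

  if (length(sets) == 0L) {
    per <- data.frame(term_id = character(0), direction = character(0),
                      lo = integer(0), hi = integer(0),
                      interval_label = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      raw_p = numeric(0), adj_p = numeric(0))
    summ <- data.frame(term_id = character(0), direction = character(0),
                       n_genes = integer(0), min_adj_p = numeric(0),
                       fold_change_specific = logical(0),
                       best_lo = integer(0), best_hi = integer(0),
                       best_interval = character(0))
    return(structure(list(per_interval = per, summary = summ,
                          multiplier = multiplier, alpha2 = alpha2,
                          direction = partition$direction, q = partition$q),
                     class = "specificity_result"))
  }
  cnt <- term_quantile_counts(sets, partition)
  focal_total <- lengths(sets)
  int_sizes <- vapply(seq_len(nrow(ivs)), function(i)
    sum(partition$sizes[ivs$lo[i]:ivs$hi[i]]), integer(1))

  rows <- vector("list", nrow(ivs))
  for (i in seq_len(nrow(ivs))) {
    a <- as.integer(rowSums(cnt[, ivs$lo[i]:ivs$hi[i], drop = FALSE]))
    b <- focal_total - a
    cc <- int_sizes[i] - a
    d <- (n - int_sizes[i]) - b
    rows[[i]] <- data.frame(
      term_id = names(sets), direction = partition$direction,
      lo = ivs$lo[i], hi = ivs$hi[i], interval_label = ivs$label[i],
      a = a, b = unname(b), c = cc, d = unname(d),
      raw_p = fisher_one_sided(a, b, cc, d),
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  per$adj_p <- bonferroni(per$raw_p, multiplier)
  per <- per[order(per$term_id, per$hi - per$lo, per$lo), ]
  rownames(per) <- NULL

  summ <- do.call(rbind, lapply(names(sets), function(t) {
    sub <- per[per$term_id == t, ]
    best <- assign_best_interval(sub)
    specific <- min(sub$adj_p) < alpha2
    data.frame(term_id = t, direction = partition$direction,
               n_genes = focal_total[[t]], min_adj_p = min(sub$adj_p),
               fold_change_specific = specific,
               best_lo = if (specific) best$lo else NA_integer_,
               best_hi = if (specific) best$hi else NA_integer_,
               best_interval = if (specific)
                 interval_label(best$lo, best$hi, partition$q)
               else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_interval = per, summary = summ,
                 multiplier = multiplier, alpha2 = alpha2,
                 direction = partition$direction, q = partition$q),
            class = "specificity_result")
}

#' Assign the best (most significantly enriched) interval
#'
#' Minimal adjusted p-value; ties broken by shorter interval first, then by
#' lower quantile bound, so the assignment is deterministic and prefers the
#' tightest fold-change-specificity claim.
#'
#' @param per_interval data frame with columns `lo`, `hi`, `adj_p` (one
#'   term's per-interval tests).
#' @return list with elements `lo`, `hi`, `adj_p` of the winning interval.
#' @export
assign_best_interval <- function(per_interval) {
  stopifnot(nrow(per_interval) >= 1L,
            all(c("lo", "hi", "adj_p") %in% names(per_interval)))
  o <- order(per_interval$adj_p,
             per_interval$hi - per_interval$lo,
             per_interval$lo)[1]
  list(lo = per_interval$lo[o], hi = per_interval$hi[o],
       adj_p = per_interval$adj_p[o])
}

#' @export
print.specificity_result <- function(x, ...) {
  cat("Fold-change specificity (", x$direction, "-regulated, q = ", x$q,
      ")\n", sep = "")
  cat("  ", nrow(x$summary), " candidate term(s); Bonferroni multiplier ",
      x$multiplier, "\n", sep = "")
  cat("  ", sum(x$summary$fold_change_specific),
      " fold-change-specific at adjusted p < ", x$alpha2, "\n", sep = "")
  invisible(x)
}
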