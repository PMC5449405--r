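#' Quantile labels for a partition
#'
#' For q = 6 the conventional response-strength labels are used
#' (vw, w, m, i, s, vs = very weak .. very strong); for other q the quantiles
#' are labelled q1..qq.
#'
#' @param q number of quantiles.
#' @return character vector of length `q`, weakest response first.
#' @export
quantile_labels <- function(q) {
  q <- check_count(q, "q", min = 2L)
  if (q == 6L) c("vw", "w", "m", "i", "s", "vs") else paste0("q", seq_len(q))
}

#' Label a fold-change interval
#'
#' Single quantiles keep their own label; unions of neighbouring quantiles are
#' labelled "lo-hi" (e.g. "vw-w" for quantiles 1..2 at q = 6).
#'
#' @param lo,hi quantile bounds, 1 <= lo <= hi <= q (vectorised).
#' @param q number of quantiles.
#' @return character vector of labels.
#' @export
interval_label <- function(lo, hi, q) {
  labs <- quantile_labels(q)
  ifelse(lo == hi, labs[lo], paste(labs[lo], labs[hi], sep = "-"))
}

#' Rank a directional gene list and partition it into fold-change quantiles
#'
#' Genes of one direction are sorted by ascending linear fold change (ties
#' broken by gene id, so the partition is deterministic and independent of
#' input order) and split into `q` quantiles of equal size. When n is not a
#' multiple of q, quantile k spans ranks (ceil((k-1)n/q), ceil(kn/q)], so
#' sizes differ by at most one, extra genes sit in the lower half of the
#' scale, and the cumulative count after k quantiles is always ceil(kn/q)
#' (e.g. 789 genes at q = 6 put 263 genes in quantiles 1-2).
#'
#' @param genes data frame with columns `gene_id`, `direction` (all one of
#'   "up"/"down") and `fold_change` (positive linear magnitude).
#' @param q number of quantiles (default 6).
#' @return an object of class `quantile_partition`: a list with elements
#'   `direction`, `q`, `n`, `gene_id` (ordered by ascending fold change),
#'   `fold_change`, `quantile` (index 1..q per ordered gene, 1 = weakest
#'   response), `sizes`, `boundaries` (largest fold change in each quantile)
#'   and `labels`.
#' @export
quantile_partition <- function(genes, q = 6L) {
  q <- check_count(q, "q", min = 2L)
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "direction", "fold_change") %in% names(genes)))
  dirs <- unique(as.character(genes$direction))
  if (length(dirs) != 1L)
    stop("all genes must share one direction; got: ",
         paste(dirs, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids within direction '", dirs, "'")
  fc <- as.numeric(genes$fold_change)
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop("fold changes must be finite and > 0")
  n <- nrow(genes)
  if (n < q) stop("need at least q = ", q, " genes, got ", n)

  ord <- order(fc, as.character(genes$gene_id), method = "radix")
  gid <- as.character(genes$gene_id)[ord]
  fc <- fc[ord]
  bounds <- (seq_len(q) * n + q - 1L) %/% q   # ceil(k n / q), exact
  sizes <- diff(c(0L, bounds))
  qidx <- rep.int(seq_len(q), sizes)
  structure(list(direction = dirs, q = q, n = n,
                 gene_id = gid, fold_change = fc, quantile = qidx,
                 sizes = sizes,
                 boundaries = fc[cumsum(sizes)],
                 labels = quantile_labels(q)),
            class = "quantile_partition")
}

#' @export
print.quantile_partition <- function(x, ...) {
  cat("Fold-change quantile partition (", x$direction, "-regulated, q = ",
      x$q, ")\n", sep = "")
  cat("  n =", x$n, "genes; quantile sizes:",
      paste(x$sizes, collapse = " "), "\n")
  cat("  fold-change range:",
      format(min(x$fold_change), digits = 3), "-",
      format(max(x$fold_change), digits = 3), "\n")
  cat("  upper quantile boundaries:",
      paste(x$labels, format(x$boundaries, digits = 3), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' @method as.data.frame quantile_partition
#' @export
as.data.frame.quantile_partition <- function(x, ...) {
  data.frame(gene_id = x$gene_id, direction = x$direction,
             fold_change = x$fold_change, quantile = x$quantile,
             quantile_label = x$labels[x$quantile],
             stringsAsFactors = FALSE)
}

#' Enumerate contiguous quantile-union intervals
#'
#' All fold-change intervals (lo, hi) with 1 <= lo <= hi <= q, sorted by
#' length (hi - lo) then lower bound. Including the full interval (1, q)
#' there are q(q+1)/2 intervals (21 for q = 6); excluding it there are
#' q(q+1)/2 - 1 "component" intervals (20 for q = 6).
#'
#' @param q number of quantiles.
#' @param include_full keep the full interval (1, q)? Default `TRUE`.
#' @return data frame with columns `lo`, `hi`, `label`.
#' @export
enumerate_intervals <- function(q, include_full = TRUE) {
  q <- check_count(q, "q", min = 2L)
  lo <- unlist(lapply(seq_len(q), function(len) seq_len(q - len + 1L)))
  len <- rep.int(seq_len(q), q:1)
  hi <- lo + len - 1L
  keep <- if (include_full) rep(TRUE, length(lo)) else !(lo == 1L & hi == q)
  data.frame(lo = lo[keep], hi = hi[keep],
             label = interval_label(lo[keep], hi[keep], q),
             stringsAsFactors = FALSE)
}

#' Genes of a fold-change interval
#'
#' @param partition a [quantile_partition()].
#' @param lo,hi quantile bounds of the interval.
#' @return character vector of gene ids in quantiles lo..hi.
#' @export
interval_genes <- function(partition, lo, hi) {
  stopifnot(inherits(partition, "quantile_partition"))
  lo <- check_count(lo, "lo", min = 1L)
  hi <- check_count(hi, "hi", min = lo)
  if (hi > partition$q) stop("hi exceeds q = ", partition$q)
  partition$gene_id[partition$quantile >= lo & partition$quantile <= hi]
}

#' Write a partition dump TSV
#'
#' Columns: gene_id, direction, fold_change, quantile, quantile_label.
#'
#' @param partition a [quantile_partition()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  write_tsv(as.data.frame(partition), path)
}

# shared argument check: positive integer scalar
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stop("'", name, "' must be a single integer >= ", min)
  as.integer(x)
}
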