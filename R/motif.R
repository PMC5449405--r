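#' Reverse complement of DNA strings
#'
#' @param x character vector over A/C/G/T/N (case-insensitive; upper-cased
#'   on input).
#' @return reverse-complemented upper-case strings; an involution.
#' @export
revcomp <- function(x) {
  x <- toupper(as.character(x))
  if (any(grepl("[^ACGTN]", x)))
    stop("revcomp: sequences may contain only A, C, G, T, N")
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), "")
}

#' Canonical representative of a hexamer (or any k-mer)
#'
#' A k-mer and its reverse complement are one variant; the canonical
#' representative is the lexicographically smaller of the pair (A < C < G <
#' T). Palindromic k-mers (equal to their reverse complement) represent
#' themselves. Idempotent, and `canonical_kmer(h) == canonical_kmer(revcomp(h))`.
#'
#' @param x character vector of A/C/G/T k-mers.
#' @return canonical representatives.
#' @export
canonical_kmer <- function(x) {
  x <- toupper(as.character(x))
  rc <- revcomp(x)
  # compare in a locale-independent collation: A<C<G<T maps to digits
  ifelse(chartr("ACGT", "0123", x) <= chartr("ACGT", "0123", rc), x, rc)
}

#' Enumerate all canonical hexamers
#'
#' From the 4^6 = 4096 raw hexamers, collapsing each complementary pair to
#' one variant leaves (4096 - 64)/2 + 64 = 2080 canonical hexamers, 64 of
#' which are palindromic (self-complementary).
#'
#' @return character vector of the 2080 canonical hexamers in lexicographic
#'   order, with a logical attribute `palindromic`.
#' @export
enumerate_canonical_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  all6 <- do.call(paste0, rev(expand.grid(b, b, b, b, b, b,
                                          stringsAsFactors = FALSE)))
  canon <- sort(unique(canonical_kmer(all6)), method = "radix")
  structure(canon, palindromic = canon == revcomp(canon))
}

#' Scan promoters for canonical hexamer presence
#'
#' Slides a 6-bp window over each promoter sequence, canonicalises each
#' all-ACGT window (windows containing N match nothing) and records, per
#' gene, which of the 2080 canonical hexamers occur at least once. Scanning
#' one strand with canonicalisation covers both strands. Counting is done
#' with `Biostrings::oligonucleotideFrequency`.
#'
#' @param promoters a [promoter_set()], `DNAStringSet`, or named character
#'   vector of sequences.
#' @param counts return occurrence counts instead of presence? Default
#'   `FALSE` (presence/absence is what feeds the enrichment tables).
#' @return genes x 2080 logical presence matrix (or integer count matrix),
#'   rows named by gene id, columns by canonical hexamer.
#' @export
scan_hexamer_presence <- function(promoters, counts = FALSE) {
  if (inherits(promoters, "promoter_set")) promoters <- promoters$seq
  if (is.character(promoters)) {
    if (is.null(names(promoters)))
      stop("promoter sequences must be named by gene id")
    promoters <- Biostrings::DNAStringSet(toupper(promoters))
  }
  short <- sum(Biostrings::width(promoters) < 6L)
  if (short > 0L)
    message(short, " promoter(s) shorter than 6 bp have empty presence sets")
  cnt <- Biostrings::oligonucleotideFrequency(promoters, width = 6L,
                                              step = 1L)
  canon <- enumerate_canonical_hexamers()
  pal <- attr(canon, "palindromic")
  rc <- revcomp(canon)
  m <- cnt[, canon, drop = FALSE]
  m[, !pal] <- m[, !pal] + cnt[, rc[!pal], drop = FALSE]
  dimnames(m) <- list(names(promoters), as.character(canon))
  if (counts) m else m > 0L
}

#' Two-step hexamer enrichment
#'
#' Mirrors the gene-set procedure for promoter hexamers. Step 1: for each
#' fold-change interval (21 per direction, full list included) and each of
#' the 2080 canonical hexamers, the 2x2 table of (genes in interval vs rest
#' of the genome) by (promoter has the hexamer vs not) is tested one-sided;
#' Bonferroni multiplier 2080 x number of intervals. Step 2: hexamers with
#' step-1 adjusted p < `alpha1` in some interval are re-tested on the 20
#' component intervals against the directional DEG list only; Bonferroni
#' multiplier = surviving hexamers x 20. A hexamer is fold-change-specific
#' iff its minimal step-2 adjusted p is below `alpha2`, and is assigned the
#' best interval as in [assign_best_interval()].
#'
#' @param presence logical genes x hexamers matrix from
#'   [scan_hexamer_presence()] covering the genome universe (all partition
#'   genes must be among its rows).
#' @param partition a [quantile_partition()] of one directional DEG list.
#' @param alpha1,alpha2 step-1 / step-2 thresholds (defaults 0.001, 0.05).
#' @param include_full test the full interval in step 1 (default `TRUE`).
#' @return object of class `hexamer_two_step`: list with `step1` (data
#'   frame: hexamer x interval tests, flagged `significant`), `survivors`
#'   (character), `per_interval` (step-2 tests), `summary` (one row per
#'   surviving hexamer: `hexamer`, `pair`, `direction`, `min_adj_p`,
#'   `fold_change_specific`, `best_lo`, `best_hi`, `best_interval`),
#'   `multiplier1`, `multiplier2`, `alpha1`, `alpha2`.
#' @export
hexamer_two_step <- function(presence, partition,
                             alpha1 = 0.001, alpha2 = 0.05,
                             include_full = TRUE) {
  stopifnot(inherits(partition, "quantile_partition"),
            is.logical(presence), is.matrix(presence))
  genome <- rownames(presence)
  if (is.null(genome)) stop("presence matrix must have gene-id rownames")
  missing <- setdiff(partition$gene_id, genome)
  if (length(missing))
    stop(length(missing), " partition gene(s) lack promoters; drop them ",
         "before partitioning (e.g. via fcs_motif)")
  hex <- colnames(presence)
  n_hex <- length(hex)
  N <- nrow(presence)
  genome_tot <- colSums(presence)

  ivs1 <- enumerate_intervals(partition$q, include_full = include_full)
  multiplier1 <- n_hex * nrow(ivs1)
  rows <- vector("list", nrow(ivs1))
  for (i in seq_len(nrow(ivs1))) {
    ig <- interval_genes(partition, ivs1$lo[i], ivs1$hi[i])
    n_i <- length(ig)
    a <- colSums(presence[ig, , drop = FALSE])
    b <- genome_tot - a
    cc <- n_i - a
    d <- (N - n_i) - b
    rows[[i]] <- data.frame(
      hexamer = hex, direction = partition$direction,
      lo = ivs1$lo[i], hi = ivs1$hi[i], interval_label = ivs1$label[i],
      a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
      raw_p = unname(fisher_one_sided(a, b, cc, d)),
      stringsAsFactors = FALSE)
  }
  step1 <- do.call(rbind, rows)
  step1$adj_p <- bonferroni(step1$raw_p, multiplier1)
  step1$significant <- step1$adj_p < alpha1
  survivors <- unique(step1$hexamer[step1$significant])

  ivs2 <- enumerate_intervals(partition$q, include_full = FALSE)
  multiplier2 <- max(1L, length(survivors)) * nrow(ivs2)
  deg <- partition$gene_id
  if (length(survivors)) {
    sub <- presence[deg, survivors, drop = FALSE]
    deg_tot <- colSums(sub)
    rows <- vector("list", nrow(ivs2))
    for (i in seq_len(nrow(ivs2))) {
      ig <- interval_genes(partition, ivs2$lo[i], ivs2$hi[i])
      n_i <- length(ig)
      a <- colSums(sub[ig, , drop = FALSE])
      b <- deg_tot - a
      cc <- n_i - a
      d <- (partition$n - n_i) - b
      rows[[i]] <- data.frame(
        hexamer = survivors, direction = partition$direction,
        lo = ivs2$lo[i], hi = ivs2$hi[i], interval_label = ivs2$label[i],
        a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
        raw_p = unname(fisher_one_sided(a, b, cc, d)),
        stringsAsFactors = FALSE)
    }
    per <- do.call(rbind, rows)
    per$adj_p <- bonferroni(per$raw_p, multiplier2)
    summ <- do.call(rbind, lapply(survivors, function(h) {
      s <- per[per$hexamer == h, ]
      best <- assign_best_interval(s)
      specific <- min(s$adj_p) < alpha2
      data.frame(hexamer = h, pair = paste(h, revcomp(h), sep = "/"),
                 direction = partition$direction,
                 min_adj_p = min(s$adj_p),
                 fold_change_specific = specific,
                 best_lo = if (specific) best$lo else NA_integer_,
                 best_hi = if (specific) best$hi else NA_integer_,
                 best_interval = if (specific)
                   interval_label(best$lo, best$hi, partition$q)
                 else NA_character_,
                 stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
  } else {
    per <- step1[0, setdiff(names(step1), "significant")]
    names(per)[names(per) == "hexamer"] <- "hexamer"
    summ <- data.frame(hexamer = character(0), pair = character(0),
                       direction = character(0), min_adj_p = numeric(0),
                       fold_change_specific = logical(0),
                       best_lo = integer(0), best_hi = integer(0),
                       best_interval = character(0))
  }
  structure(list(step1 = step1, survivors = survivors, per_interval = per,
                 summary = summ, multiplier1 = multiplier1,
                 multiplier2 = multiplier2, alpha1 = alpha1,
                 alpha2 = alpha2, direction = partition$direction,
                 q = partition$q, n_hexamers = n_hex),
            class = "hexamer_two_step")
}

#' @export
print.hexamer_two_step <- function(x, ...) {
  cat("Two-step hexamer enrichment (", x$direction, "-regulated, q = ",
      x$q, ")\n", sep = "")
  cat("  hexamers tested:", x$n_hexamers,
      "| step-1 Bonferroni multiplier:", x$multiplier1, "\n")
  cat("  step-1 survivors:", length(x$survivors),
      "| step-2 Bonferroni multiplier:", x$multiplier2, "\n")
  cat("  fold-change-specific hexamers:",
      sum(x$summary$fold_change_specific), "\n")
  invisible(x)
}
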