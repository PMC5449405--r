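#' Construct a promoter set
#'
#' @param seq named character vector or `DNAStringSet` of promoter sequences
#'   (names = gene ids); sequences are upper-cased.
#' @param provenance optional data frame with one row per gene:
#'   `gene_id`, `chrom`, `strand`, `start0`, `end0` (0-based half-open
#'   genomic interval extracted), `clipped`.
#' @return object of class `promoter_set`.
#' @export
promoter_set <- function(seq, provenance = NULL) {
  if (inherits(seq, "DNAStringSet")) seq <- as.character(seq)
  stopifnot(is.character(seq), !is.null(names(seq)))
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("non-ACGTN characters in promoter sequence of ",
         names(seq)[bad][1])
  if (is.null(provenance))
    provenance <- data.frame(gene_id = names(seq), chrom = NA_character_,
                             strand = NA_character_, start0 = NA_integer_,
                             end0 = NA_integer_, clipped = NA,
                             stringsAsFactors = FALSE)
  structure(list(seq = seq, provenance = provenance), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("Promoter set:", length(x$seq), "sequences, lengths",
      paste(range(nchar(x$seq)), collapse = "-"), "\n")
  invisible(x)
}

#' @export
length.promoter_set <- function(x) length(x$seq)

#' Extract promoter regions from a genome FASTA and a GFF3 annotation
#'
#' For each gene the region from `upstream_len` bases upstream of the
#' transcription start of the representative transcript through the end of
#' its annotated 5' UTR is extracted, strand-aware (minus-strand regions are
#' reverse-complemented so every sequence reads 5'->3' towards the coding
#' start). The representative transcript is the mRNA with the
#' lowest-sorting ID. Genes without an annotated 5' UTR fall back to the
#' pure upstream window ending at the TSS. Regions are clipped at contig
#' edges (with a warning); genes on contigs absent from the FASTA raise an
#' error, and gene features without usable coordinates are skipped with a
#' warning. Promoters are not truncated when they overlap a neighbouring
#' gene.
#'
#' @param genome path to a genome FASTA, or a `DNAStringSet`.
#' @param features path to a GFF3 file, or a `GRanges` as returned by
#'   `rtracklayer::import`.
#' @param upstream_len bases upstream of the TSS (default 1500).
#' @return a [promoter_set()] with per-gene provenance (chromosome, strand,
#'   0-based half-open interval, clipping flag).
#' @export
extract_promoters <- function(genome, features, upstream_len = 1500L) {
  upstream_len <- check_count(upstream_len, "upstream_len", min = 1L)
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(features))
    features <- rtracklayer::import(features, format = "gff3")

  type <- as.character(features$type)
  genes <- features[type == "gene"]
  mrnas <- features[type %in% c("mRNA", "transcript")]
  utrs <- features[type == "five_prime_UTR"]
  if (length(genes) == 0L) stop("no gene features in GFF3")
  mrna_parent <- vapply(as.list(mrnas$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  utr_parent <- vapply(as.list(utrs$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")

  seqs <- character(0)
  prov <- list()
  n_clipped <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    gid <- g$ID %||% g$Name
    if (is.null(gid) || is.na(gid)) {
      warning("gene feature without ID skipped (row ", i, ")")
      next
    }
    chrom <- as.character(GenomicRanges::seqnames(g))
    if (!chrom %in% names(genome))
      stop("contig '", chrom, "' absent from genome FASTA")
    strand <- as.character(GenomicRanges::strand(g))
    if (!strand %in% c("+", "-")) {
      warning("gene ", gid, " without stranded coordinates skipped")
      next
    }
    # representative transcript: lowest-sorting mRNA ID; gene coords if none
    kids <- which(mrna_parent == gid)
    if (length(kids)) {
      ids <- mrnas$ID[kids]
      rep_i <- kids[order(ids, method = "radix")[1]]
      tx <- mrnas[rep_i]
      tx_id <- mrnas$ID[rep_i]
    } else {
      tx <- g
      tx_id <- gid
    }
    u <- utrs[utr_parent == tx_id]
    clen <- length(genome[[chrom]])
    if (strand == "+") {
      tss0 <- GenomicRanges::start(tx) - 1L          # 0-based TSS position
      end0 <- if (length(u)) max(GenomicRanges::end(u)) else tss0
      start0 <- tss0 - upstream_len
    } else {
      tss0 <- GenomicRanges::end(tx) - 1L
      start0 <- if (length(u)) min(GenomicRanges::start(u)) - 1L
                else tss0 + 1L
      end0 <- tss0 + 1L + upstream_len
    }
    clipped <- start0 < 0L || end0 > clen
    if (clipped) n_clipped <- n_clipped + 1L
    start0 <- max(start0, 0L)
    end0 <- min(end0, clen)
    if (end0 <= start0) {
      warning("gene ", gid, " yields an empty promoter region; skipped")
      next
    }
    s <- Biostrings::subseq(genome[[chrom]], start0 + 1L, end0)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    seqs[gid] <- as.character(s)
    prov[[gid]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                              start0 = start0, end0 = end0,
                              clipped = clipped, stringsAsFactors = FALSE)
  }
  if (n_clipped > 0L)
    warning(n_clipped, " promoter region(s) clipped at contig edges")
  promoter_set(seqs, do.call(rbind, c(prov, list(make.row.names = FALSE))))
}

#' Read promoters from FASTA
#'
#' Headers (up to the first whitespace) become gene ids.
#'
#' @param path promoter FASTA.
#' @return a [promoter_set()] (provenance unknown).
#' @export
read_promoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  promoter_set(x)
}

#' Write promoters to FASTA
#'
#' @param promoters a [promoter_set()].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  stopifnot(inherits(promoters, "promoter_set"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(promoters$seq), path)
  invisible(path)
}
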