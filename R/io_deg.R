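#' Read a differential-expression table
#'
#' Reads a tab-separated DEG table with a header row and returns one record
#' per gene with a direction and a linear fold-change magnitude (>= 1).
#' Two input layouts are supported:
#'
#' * a signed table with a log2 fold-change column: direction is derived from
#'   the sign and the magnitude is `2^|log2FC|`;
#' * a two-list style table with a `direction` column (`up`/`down`) and a
#'   linear fold-change column (a separate up- or down-regulated file can be
#'   read by passing `direction = "up"` / `"down"` instead).
#'
#' If an adjusted-p column is mapped, rows failing `padj_threshold` are
#' excluded.
#'
#' @param path tab-separated file with a header.
#' @param columns named list mapping the table's column names; recognised
#'   entries: `gene`, `log2fc`, `fc`, `direction`, `padj`. Defaults:
#'   `list(gene = "gene_id", log2fc = "log2FC", padj = "padj")`.
#' @param direction fixed direction ("up"/"down") for single-direction files;
#'   overrides any direction/sign in the table.
#' @param padj_threshold adjusted-p cutoff (default 0.05); set to `NULL` (or
#'   map no `padj` column) to keep all rows.
#' @return data frame of gene records: `gene_id`, `direction`,
#'   `fold_change`, `adj_p` (NA when absent).
#' @export
read_deg_table <- function(path,
                           columns = list(gene = "gene_id",
                                          log2fc = "log2FC",
                                          padj = "padj"),
                           direction = NULL,
                           padj_threshold = 0.05) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  get_col <- function(role, required = FALSE) {
    nm <- columns[[role]]
    if (is.null(nm)) {
      if (required) stop("no column mapped for required role '", role, "'")
      return(NULL)
    }
    if (!nm %in% names(tab))
      stop("DEG table ", path, " lacks mapped column '", nm,
           "' (role: ", role, ")")
    tab[[nm]]
  }
  gene <- as.character(get_col("gene", required = TRUE))

  num_col <- function(role) {
    x <- get_col(role)
    if (is.null(x)) return(NULL)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
    if (length(bad))
      stop("non-numeric ", role, " value in ", path,
           " at line ", bad[1] + 1L, ": '", x[bad[1]], "'")
    v
  }
  log2fc <- num_col("log2fc")
  fc <- num_col("fc")
  padj <- num_col("padj")

  if (!is.null(direction)) {
    direction <- match.arg(direction, c("up", "down"))
    dir <- rep(direction, nrow(tab))
    if (is.null(fc) && is.null(log2fc))
      stop("no fold-change column mapped (role 'fc' or 'log2fc')")
    mag <- if (!is.null(fc)) fc else 2^abs(log2fc)
  } else if (!is.null(log2fc)) {
    dir <- ifelse(log2fc >= 0, "up", "down")
    mag <- 2^abs(log2fc)
  } else {
    dcol <- get_col("direction", required = TRUE)
    dir <- tolower(as.character(dcol))
    if (!all(dir %in% c("up", "down")))
      stop("direction column must contain only 'up'/'down'")
    if (is.null(fc)) stop("no column mapped for required role 'fc'")
    mag <- fc
  }
  if (any(!is.finite(mag) | mag <= 0))
    stop("fold-change magnitudes must be finite and positive in ", path)

  out <- data.frame(gene_id = gene, direction = dir, fold_change = mag,
                    adj_p = if (is.null(padj)) NA_real_ else padj,
                    stringsAsFactors = FALSE)
  if (!is.null(padj) && !is.null(padj_threshold))
    out <- out[!is.na(out$adj_p) & out$adj_p < padj_threshold, , drop = FALSE]
  for (d in unique(out$direction))
    if (anyDuplicated(out$gene_id[out$direction == d]))
      stop("duplicate gene ids within direction '", d, "'")
  rownames(out) <- NULL
  out
}

#' Write a DEG table in the package's canonical schema
#'
#' Tab-separated with header `gene_id, direction, fold_change, padj`;
#' readable back by [read_deg_table()] with
#' `columns = list(gene = "gene_id", direction = "direction",
#' fc = "fold_change", padj = "padj")`.
#'
#' @param deg data frame of gene records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  out <- data.frame(gene_id = deg$gene_id, direction = deg$direction,
                    fold_change = deg$fold_change,
                    padj = if ("adj_p" %in% names(deg)) deg$adj_p else NA,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

# column mapping for tables produced by write_deg_table()
canonical_deg_columns <- function() {
  list(gene = "gene_id", direction = "direction", fc = "fold_change",
       padj = "padj")
}

# TSV writer that round-trips doubles exactly (R's default as.character
# keeps only 15 significant digits)
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
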