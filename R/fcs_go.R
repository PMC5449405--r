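#' Fold-change-specific gene-set enrichment analysis
#'
#' The package's main gene-set interface. Each direction of the DEG table is
#' ranked by fold change, partitioned into `q` quantiles, and analysed by the
#' two-step procedure: [step1_enrichment()] of every term in every
#' fold-change interval against the background universe, then
#' [step2_specificity()] of the step-1 candidates against the directional
#' list itself.
#'
#' @param deg data frame of gene records (`gene_id`, `direction`,
#'   `fold_change`), e.g. from [read_deg_table()] or [gen_deg_table()].
#' @param annotation a [gene_sets()] object (propagate with
#'   [propagate_annotations()] beforehand if an ontology is available).
#' @param background gene universe for step 1. Default `NULL` = all genes in
#'   the annotation plus the DEGs ("annotation" background mode); pass an
#'   explicit character vector (e.g. all expressed genes) to override.
#' @param q number of fold-change quantiles (default 6; 3, 4 and 8 mirror
#'   the robustness settings).
#' @param alpha1 step-1 threshold on Bonferroni-adjusted p (default 0.001).
#' @param alpha2 step-2 threshold on Bonferroni-adjusted p (default 0.05).
#' @param min_genes minimum in-interval set size tested in step 1
#'   (default 2).
#' @return object of class `fcs_go`: per direction, the
#'   `quantile_partition`, the `fcs_step1` table and the
#'   `specificity_result`; plus the parameters used.
#' @examples
#' cfg <- synthetic_config(
#'   n_up = 300, n_down = 200, seed = 7,
#'   planted_terms = list(list(term_id = "PLT:0001", size = 60,
#'                             direction = "up", interval = c(1, 2),
#'                             concentration = 0.85)),
#'   n_background_terms = 20)
#' sim <- gen_deg_table(cfg)
#' ann <- gen_annotation(cfg, sim$deg, genome_size = 2000)
#' fit <- fcs_go(sim$deg, ann$annotation, background = ann$universe)
#' fit
#' summary(fit)
#' @export
fcs_go <- function(deg, annotation, background = NULL, q = 6L,
                   alpha1 = 0.001, alpha2 = 0.05, min_genes = 2L) {
  stopifnot(is.data.frame(deg), inherits(annotation, "gene_sets"))
  if (is.null(background))
    background <- union(annotation_genes(annotation), deg$gene_id)
  if (length(intersect(deg$gene_id, annotation_genes(annotation))) == 0L)
    stop("no DEG is annotated to any term: ",
         "the DEG table and the annotation share no gene ids")
  dirs <- intersect(c("up", "down"), unique(deg$direction))
  fits <- lapply(setNames(dirs, dirs), function(d) {
    part <- quantile_partition(deg[deg$direction == d, , drop = FALSE], q)
    s1 <- step1_enrichment(part, annotation, background,
                           alpha1 = alpha1, min_genes = min_genes)
    sel <- selected_terms(s1)
    s2 <- step2_specificity(sel, part, annotation, alpha2 = alpha2)
    list(partition = part, step1 = s1, step2 = s2)
  })
  structure(list(directions = fits, annotation_info = annotation$info,
                 params = list(q = q, alpha1 = alpha1, alpha2 = alpha2,
                               min_genes = min_genes,
                               background_size = length(unique(background))),
                 call = match.call()),
            class = "fcs_go")
}

#' @export
print.fcs_go <- function(x, ...) {
  cat("Fold-change-specific gene-set enrichment (q = ", x$params$q,
      ", background = ", x$params$background_size, " genes)\n", sep = "")
  for (d in names(x$directions)) {
    f <- x$directions[[d]]
    cat(sprintf(
      "  %4s: n = %d; %d term(s) enriched in >= 1 interval (adj p < %g); %d fold-change-specific (adj p < %g)\n",
      d, f$partition$n, length(selected_terms(f$step1)), x$params$alpha1,
      sum(f$step2$summary$fold_change_specific), x$params$alpha2))
  }
  invisible(x)
}

#' Summarise a fold-change-specific enrichment fit
#'
#' @param object an `fcs_go` fit.
#' @param specific_only keep only fold-change-specific terms? Default
#'   `FALSE`.
#' @param ... unused.
#' @return data frame, one row per candidate term and direction: term id,
#'   name, namespace, number of member DEGs, minimal adjusted step-2 p,
#'   specificity flag and best interval.
#' @method summary fcs_go
#' @export
summary.fcs_go <- function(object, specific_only = FALSE, ...) {
  out <- do.call(rbind, lapply(object$directions,
                               function(f) f$step2$summary))
  rownames(out) <- NULL
  info <- object$annotation_info
  out$name <- info$name[match(out$term_id, info$term_id)]
  out$namespace <- info$namespace[match(out$term_id, info$term_id)]
  if (specific_only) out <- out[out$fold_change_specific, , drop = FALSE]
  out[order(out$direction, out$min_adj_p), ]
}

#' @method as.data.frame fcs_go
#' @export
as.data.frame.fcs_go <- function(x, ...) summary.fcs_go(x, ...)

#' Plot the per-interval significance profile of candidate terms
#'
#' One line per candidate term: -log10 adjusted step-2 p across the
#' component fold-change intervals (ordered as enumerated: single quantiles
#' first, then longer unions). Fold-change-specific terms are drawn in
#' colour.
#'
#' @param x an `fcs_go` fit.
#' @param direction which directional list to plot (default "up").
#' @param ... passed to `matplot`.
#' @return `x`, invisibly.
#' @method plot fcs_go
#' @export
plot.fcs_go <- function(x, direction = "up", ...) {
  f <- x$directions[[direction]]
  if (is.null(f) || nrow(f$step2$per_interval) == 0L) {
    warning("nothing to plot for direction '", direction, "'")
    return(invisible(x))
  }
  per <- f$step2$per_interval
  ivs <- enumerate_intervals(x$params$q, include_full = FALSE)
  terms <- unique(per$term_id)
  m <- vapply(terms, function(t) {
    s <- per[per$term_id == t, ]
    -log10(pmax(s$adj_p[match(paste(ivs$lo, ivs$hi),
                              paste(s$lo, s$hi))], 1e-300))
  }, numeric(nrow(ivs)))
  spec <- f$step2$summary$fold_change_specific[
    match(terms, f$step2$summary$term_id)]
  graphics::matplot(m, type = "l", lty = 1,
                    col = ifelse(spec, "firebrick", "grey60"),
                    xaxt = "n", xlab = "fold-change interval",
                    ylab = expression(-log[10] ~ "adjusted p"),
                    main = paste0("Step-2 specificity profile (",
                                  direction, ")"), ...)
  graphics::axis(1, at = seq_len(nrow(ivs)), labels = ivs$label,
                 las = 2, cex.axis = 0.7)
  graphics::abline(h = -log10(f$step2$alpha2), lty = 2)
  invisible(x)
}

#' Fold-change-specific promoter hexamer analysis
#'
#' Companion of [fcs_go()] for cis-regulatory motifs: scans promoters for
#' the 2080 canonical hexamers and runs the two-step enrichment
#' ([hexamer_two_step()]) per direction — step 1 against the whole-genome
#' promoter set, step 2 against the directional DEG promoters. DEGs without
#' a promoter are dropped (with a warning) before partitioning.
#'
#' @param deg data frame of gene records.
#' @param promoters a [promoter_set()] (or named sequences) covering the
#'   genome universe, or a precomputed logical presence matrix from
#'   [scan_hexamer_presence()].
#' @param q,alpha1,alpha2 as in [fcs_go()].
#' @return object of class `fcs_motif`: per direction the
#'   `quantile_partition` and the `hexamer_two_step` result, plus
#'   parameters.
#' @export
fcs_motif <- function(deg, promoters, q = 6L,
                      alpha1 = 0.001, alpha2 = 0.05) {
  stopifnot(is.data.frame(deg))
  presence <- if (is.logical(promoters) && is.matrix(promoters)) promoters
              else scan_hexamer_presence(promoters)
  missing <- setdiff(deg$gene_id, rownames(presence))
  if (length(missing)) {
    warning(length(missing), " DEG(s) without a promoter excluded")
    deg <- deg[!deg$gene_id %in% missing, , drop = FALSE]
  }
  dirs <- intersect(c("up", "down"), unique(deg$direction))
  fits <- lapply(setNames(dirs, dirs), function(d) {
    part <- quantile_partition(deg[deg$direction == d, , drop = FALSE], q)
    list(partition = part,
         two_step = hexamer_two_step(presence, part, alpha1 = alpha1,
                                     alpha2 = alpha2))
  })
  structure(list(directions = fits,
                 params = list(q = q, alpha1 = alpha1, alpha2 = alpha2,
                               genome_size = nrow(presence),
                               n_hexamers = ncol(presence)),
                 call = match.call()),
            class = "fcs_motif")
}

#' @export
print.fcs_motif <- function(x, ...) {
  cat("Fold-change-specific hexamer enrichment (q = ", x$params$q,
      ", genome promoters = ", x$params$genome_size, ")\n", sep = "")
  for (d in names(x$directions)) {
    ts <- x$directions[[d]]$two_step
    cat(sprintf(
      "  %4s: %d hexamer(s) enriched step 1; %d fold-change-specific\n",
      d, length(ts$survivors), sum(ts$summary$fold_change_specific)))
  }
  invisible(x)
}

#' @method summary fcs_motif
#' @export
summary.fcs_motif <- function(object, specific_only = FALSE, ...) {
  out <- do.call(rbind, lapply(object$directions,
                               function(f) f$two_step$summary))
  rownames(out) <- NULL
  if (specific_only) out <- out[out$fold_change_specific, , drop = FALSE]
  out[order(out$direction, out$min_adj_p), ]
}
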