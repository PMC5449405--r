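# minimal run logger: appends stage-tagged lines to a file and emits them
# as messages so interactive runs see them too
make_logger <- function(path) {
  if (!is.null(path)) file.create(path)
  function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    if (!is.null(path)) cat(line, "\n", file = path, append = TRUE,
                            sep = "")
    message(line)
  }
}

#' Run the gene-set pipeline end to end and write result files
#'
#' rank -> partition -> interval enumeration -> step-1 enrichment ->
#' candidate selection -> step-2 specificity -> best-interval assignment,
#' with all stages logged (including every Bonferroni multiplier applied).
#' Outputs written to `out_dir`: `partition_<dir>.tsv`, `step1_<dir>.tsv`,
#' `step2_<dir>.tsv`, `summary.tsv`, `config.yaml` (the fully serialized run
#' configuration) and `run.log`.
#'
#' @param deg DEG table: a path (read via [read_deg_table()] with
#'   `deg_columns`) or a data frame of gene records.
#' @param annotation a path (two-column TSV or GAF; see `annotation_format`)
#'   or a [gene_sets()] object.
#' @param out_dir output directory (created if needed).
#' @param obo optional OBO path or `obo_ontology` for ancestor propagation.
#' @param background optional explicit background universe (character
#'   vector or a one-column file of gene ids); default: annotation genes +
#'   DEGs.
#' @param q,alpha1,alpha2,min_genes passed to [fcs_go()].
#' @param annotation_format `"two_column_tsv"` or `"gaf"`.
#' @param deg_columns column mapping for [read_deg_table()].
#' @return the `fcs_go` fit, invisibly.
#' @export
run_go_pipeline <- function(deg, annotation, out_dir, obo = NULL,
                            background = NULL, q = 6L, alpha1 = 0.001,
                            alpha2 = 0.05, min_genes = 2L,
                            annotation_format = "two_column_tsv",
                            deg_columns = canonical_deg_columns()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- make_logger(file.path(out_dir, "run.log"))
  t0 <- proc.time()[["elapsed"]]
  if (is.character(deg)) deg <- read_deg_table(deg, columns = deg_columns)
  if (is.character(annotation))
    annotation <- read_gene_sets(annotation, format = annotation_format)
  if (!is.null(obo)) {
    if (is.character(obo)) obo <- read_obo(obo)
    annotation <- propagate_annotations(annotation, obo)
    log("annotate", "ontology propagation: ", length(annotation),
        " terms after closure")
  }
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- readLines(background)
  log("input", nrow(deg), " gene records (",
      sum(deg$direction == "up"), " up, ",
      sum(deg$direction == "down"), " down); ",
      length(annotation), " terms")

  fit <- fcs_go(deg, annotation, background = background, q = q,
                alpha1 = alpha1, alpha2 = alpha2, min_genes = min_genes)
  for (d in names(fit$directions)) {
    f <- fit$directions[[d]]
    write_partition(f$partition, file.path(out_dir,
                                           paste0("partition_", d, ".tsv")))
    write_tsv(as.data.frame(f$step1),
              file.path(out_dir, paste0("step1_", d, ".tsv")))
    write_tsv(f$step2$per_interval,
              file.path(out_dir, paste0("step2_", d, ".tsv")))
    log("step1", d, ": ", attr(f$step1, "n_intervals"), " intervals x ",
        attr(f$step1, "n_terms_tested"),
        " terms tested; Bonferroni multiplier ",
        attr(f$step1, "multiplier"), "; selected ",
        length(selected_terms(f$step1)), " terms at adj p < ", alpha1)
    log("step2", d, ": ", nrow(enumerate_intervals(q, FALSE)),
        " component intervals; Bonferroni multiplier ",
        f$step2$multiplier, "; ",
        sum(f$step2$summary$fold_change_specific),
        " fold-change-specific terms at adj p < ", alpha2)
  }
  summ <- summary(fit)
  write_tsv(summ, file.path(out_dir, "summary.tsv"))
  yaml::write_yaml(list(pipeline = "go", q = q, alpha1 = alpha1,
                        alpha2 = alpha2, min_genes = min_genes,
                        background_size = fit$params$background_size),
                   file.path(out_dir, "config.yaml"))
  log("done", "elapsed ", round(proc.time()[["elapsed"]] - t0, 1), " s")
  invisible(fit)
}

#' Run the hexamer pipeline end to end and write result files
#'
#' Promoters are taken from a FASTA (`promoters`) or extracted from a
#' genome FASTA + GFF3 (`genome` + `gff`). Outputs: `hexamers_step1_<dir>.tsv`,
#' `hexamers_step2_<dir>.tsv`, `hexamer_summary.tsv`, `config.yaml`,
#' `run.log`.
#'
#' @param deg DEG table path or data frame.
#' @param out_dir output directory.
#' @param promoters promoter FASTA path or [promoter_set()].
#' @param genome,gff genome FASTA and GFF3 paths (used when `promoters` is
#'   `NULL`).
#' @param upstream_len upstream window for extraction (default 1500).
#' @param q,alpha1,alpha2 passed to [fcs_motif()].
#' @param deg_columns column mapping for [read_deg_table()].
#' @return the `fcs_motif` fit, invisibly.
#' @export
run_motif_pipeline <- function(deg, out_dir, promoters = NULL,
                               genome = NULL, gff = NULL,
                               upstream_len = 1500L, q = 6L,
                               alpha1 = 0.001, alpha2 = 0.05,
                               deg_columns = canonical_deg_columns()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- make_logger(file.path(out_dir, "run.log"))
  t0 <- proc.time()[["elapsed"]]
  if (is.character(deg)) deg <- read_deg_table(deg, columns = deg_columns)
  if (is.null(promoters)) {
    if (is.null(genome) || is.null(gff))
      stop("provide either a promoter FASTA or genome + GFF3")
    promoters <- extract_promoters(genome, gff, upstream_len = upstream_len)
    log("promoters", "extracted ", length(promoters),
        " promoter regions (upstream ", upstream_len, " bp + 5'UTR)")
  } else if (is.character(promoters)) {
    promoters <- read_promoters(promoters)
  }
  n_missing <- sum(!deg$gene_id %in% names(promoters$seq))
  if (n_missing > 0L)
    log("promoters", n_missing, " DEG(s) without a promoter excluded")
  presence <- scan_hexamer_presence(promoters)
  log("scan", "hexamers tested: ", ncol(presence), " over ",
      nrow(presence), " promoters")
  fit <- suppressWarnings(
    fcs_motif(deg, presence, q = q, alpha1 = alpha1, alpha2 = alpha2))
  for (d in names(fit$directions)) {
    ts <- fit$directions[[d]]$two_step
    write_tsv(ts$step1,
              file.path(out_dir, paste0("hexamers_step1_", d, ".tsv")))
    write_tsv(ts$per_interval,
              file.path(out_dir, paste0("hexamers_step2_", d, ".tsv")))
    log("step1", d, ": Bonferroni multiplier ", ts$multiplier1,
        "; survivors ", length(ts$survivors))
    log("step2", d, ": Bonferroni multiplier ", ts$multiplier2, "; ",
        sum(ts$summary$fold_change_specific),
        " fold-change-specific hexamers")
  }
  write_tsv(summary(fit), file.path(out_dir, "hexamer_summary.tsv"))
  yaml::write_yaml(list(pipeline = "motif", q = q, alpha1 = alpha1,
                        alpha2 = alpha2, upstream_len = upstream_len,
                        n_hexamers = ncol(presence),
                        genome_size = nrow(presence)),
                   file.path(out_dir, "config.yaml"))
  log("done", "elapsed ", round(proc.time()[["elapsed"]] - t0, 1), " s")
  invisible(fit)
}

#' Generate a complete synthetic study and write it to disk
#'
#' Writes the DEG table, the two-column annotation, the promoter FASTA and
#' a `ground_truth.yaml` recording every planted term/motif, sufficient to
#' score recovery without re-deriving anything.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory.
#' @param genome_size gene-universe size (default 5000).
#' @param promoters also generate promoters? Default `TRUE` when
#'   `cfg$motif_plants` is non-empty.
#' @return list of written file paths, invisibly.
#' @export
run_simulate <- function(cfg, out_dir, genome_size = 5000L,
                         promoters = length(cfg$motif_plants) > 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- gen_deg_table(cfg)
  ann <- gen_annotation(cfg, sim$deg, genome_size)
  paths <- list(deg = file.path(out_dir, "deg.tsv"),
                annotation = file.path(out_dir, "annotation.tsv"),
                universe = file.path(out_dir, "universe.txt"),
                ground_truth = file.path(out_dir, "ground_truth.yaml"))
  write_deg_table(sim$deg, paths$deg)
  write_gene_sets(ann$annotation, paths$annotation)
  writeLines(ann$universe, paths$universe)
  gt <- list(seed = cfg$seed, q = cfg$q,
             planted_terms = lapply(cfg$planted_terms, function(p)
               lapply(p, function(v) if (length(v) > 1) as.list(v) else v)),
             motif_plants = lapply(cfg$motif_plants, function(p)
               lapply(p, function(v) if (length(v) > 1) as.list(v) else v)))
  if (promoters) {
    prom <- gen_promoters(cfg, sim$deg, ann$universe)
    paths$promoters <- file.path(out_dir, "promoters.fa")
    write_promoters(prom$promoters, paths$promoters)
  }
  yaml::write_yaml(gt, paths$ground_truth)
  invisible(paths)
}

#' Type-I (family-wise) error of the gene-set pipeline under the null
#'
#' Simulates annotations with no planted structure (term members drawn
#' uniformly from the gene universe) and runs the full two-step procedure on
#' each; returns whether any term was flagged fold-change-specific per
#' simulation. Under Bonferroni control the fraction of flagged simulations
#' bounds the family-wise error rate.
#'
#' @param n_sims number of simulated annotations.
#' @param n_up directional list size (default 400).
#' @param q quantiles (default 6).
#' @param n_terms background terms per simulated annotation (default 50).
#' @param genome_size gene-universe size (default 2000).
#' @param alpha1,alpha2,min_genes thresholds as in [fcs_go()].
#' @param seed RNG seed.
#' @return logical vector of length `n_sims`: `TRUE` where >= 1 term was
#'   (falsely) flagged fold-change-specific.
#' @export
sim_null_fwer <- function(n_sims, n_up = 400L, q = 6L, n_terms = 50L,
                          genome_size = 2000L, alpha1 = 0.001,
                          alpha2 = 0.05, min_genes = 2L, seed = 1L) {
  vapply(seq_len(n_sims), function(i) {
    cfg <- synthetic_config(n_up = n_up, n_down = q, q = q,
                            n_background_terms = n_terms,
                            seed = seed + i)
    sim <- gen_deg_table(cfg)
    deg <- sim$deg[sim$deg$direction == "up", ]
    ann <- gen_annotation(cfg, deg, genome_size)
    part <- quantile_partition(deg, q)
    s1 <- step1_enrichment(part, ann$annotation, ann$universe,
                           alpha1 = alpha1, min_genes = min_genes)
    sel <- selected_terms(s1)
    if (length(sel) == 0L) return(FALSE)
    s2 <- step2_specificity(sel, part, ann$annotation, alpha2 = alpha2)
    any(s2$summary$fold_change_specific)
  }, logical(1))
}

#' Family-wise error of the hexamer step under a uniform-presence null
#'
#' Presence of each hexamer in each promoter is an independent Bernoulli
#' draw with the same probability everywhere (no association with fold
#' change), the null the two-step motif test should control.
#'
#' @param n_sims number of simulations.
#' @param n_up directional list size (default 300).
#' @param genome_size promoter universe size (default 1500).
#' @param n_hexamers hexamers simulated (default 2080).
#' @param presence_p uniform presence probability (default 0.1).
#' @param q,alpha1,alpha2 as in [fcs_motif()].
#' @param seed RNG seed.
#' @return logical vector: `TRUE` where any hexamer was flagged
#'   fold-change-specific.
#' @export
sim_motif_null_fwer <- function(n_sims, n_up = 300L, genome_size = 1500L,
                                n_hexamers = 2080L, presence_p = 0.1,
                                q = 6L, alpha1 = 0.001, alpha2 = 0.05,
                                seed = 1L) {
  hex <- as.character(enumerate_canonical_hexamers())[seq_len(n_hexamers)]
  vapply(seq_len(n_sims), function(i) {
    cfg <- synthetic_config(n_up = n_up, n_down = q, q = q, seed = seed + i)
    sim <- gen_deg_table(cfg)
    deg <- sim$deg[sim$deg$direction == "up", ]
    universe <- c(deg$gene_id,
                  sprintf("GBG%05d", seq_len(genome_size - nrow(deg))))
    set.seed(cfg$seed + 3L)
    presence <- matrix(runif(genome_size * n_hexamers) < presence_p,
                       nrow = genome_size,
                       dimnames = list(universe, hex))
    part <- quantile_partition(deg, q)
    ts <- hexamer_two_step(presence, part, alpha1 = alpha1,
                           alpha2 = alpha2)
    any(ts$summary$fold_change_specific)
  }, logical(1))
}

#' Planted-term recovery of the gene-set pipeline
#'
#' For each seed, generates a DEG list with one planted term (size,
#' concentration and target interval configurable) among background terms,
#' runs the full two-step procedure, and scores the run as recovered when
#' the planted term is flagged fold-change-specific with a best interval
#' overlapping the planted one.
#'
#' @param n_seeds number of independent replicates.
#' @param q quantiles (default 6).
#' @param size planted term size (default 100).
#' @param concentration planted in-interval fraction pi (default 0.85).
#' @param interval planted target interval (default c(1, 2)).
#' @param n_up directional list size (default 1200).
#' @param n_background_terms background terms (default 50).
#' @param genome_size gene-universe size (default 5000).
#' @param seed base seed; replicate i uses `seed + i`.
#' @return logical vector of length `n_seeds` (recovered or not).
#' @export
sim_go_recovery <- function(n_seeds, q = 6L, size = 100L,
                            concentration = 0.85, interval = c(1L, 2L),
                            n_up = 1200L, n_background_terms = 50L,
                            genome_size = 5000L, seed = 100L) {
  vapply(seq_len(n_seeds), function(i) {
    cfg <- synthetic_config(
      n_up = n_up, n_down = q, q = q,
      planted_terms = list(list(term_id = "PLT:0001", size = size,
                                direction = "up", interval = interval,
                                concentration = concentration)),
      n_background_terms = n_background_terms, seed = seed + i)
    sim <- gen_deg_table(cfg)
    deg <- sim$deg[sim$deg$direction == "up", ]
    ann <- gen_annotation(cfg, deg, genome_size)
    fit <- fcs_go(deg, ann$annotation, background = ann$universe, q = q)
    summ <- fit$directions$up$step2$summary
    row <- summ[summ$term_id == "PLT:0001", ]
    nrow(row) == 1L && row$fold_change_specific &&
      row$best_lo <= interval[2] && row$best_hi >= interval[1]
  }, logical(1))
}

#' Planted-hexamer recovery of the motif pipeline
#'
#' For each seed, plants one hexamer into synthetic promoters with
#' `presence_in` insertion probability for genes of the target interval and
#' `presence_out` elsewhere, scans real sequence, runs the two-step motif
#' test, and scores recovery of the planted canonical hexamer with an
#' overlapping best interval.
#'
#' @param n_seeds replicates.
#' @param q quantiles (default 6).
#' @param hexamer planted hexamer (default "TTAGGG").
#' @param interval target interval (default c(1, 1)).
#' @param presence_in,presence_out insertion probabilities (defaults 0.6 /
#'   0.1).
#' @param n_up directional list size (default 600).
#' @param genome_size promoter universe size (default 3000).
#' @param promoter_length synthetic promoter length (default 300; short
#'   promoters keep the chance-occurrence floor of any specific hexamer low
#'   so the planted signal dominates at these gene counts).
#' @param seed base seed.
#' @return list with `recovered` (logical per seed) and `false_flags`
#'   (count of non-planted hexamers flagged per seed).
#' @export
sim_motif_recovery <- function(n_seeds, q = 6L, hexamer = "TTAGGG",
                               interval = c(1L, 1L), presence_in = 0.6,
                               presence_out = 0.1, n_up = 600L,
                               genome_size = 3000L, promoter_length = 300L,
                               seed = 200L) {
  target <- canonical_kmer(hexamer)
  rec <- logical(n_seeds)
  fp <- integer(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- synthetic_config(
      n_up = n_up, n_down = q, q = q,
      promoter_length = promoter_length,
      motif_plants = list(list(hexamer = hexamer, direction = "up",
                               interval = interval,
                               presence_in = presence_in,
                               presence_out = presence_out)),
      seed = seed + i)
    sim <- gen_deg_table(cfg)
    deg <- sim$deg[sim$deg$direction == "up", ]
    universe <- c(deg$gene_id,
                  sprintf("GBG%05d", seq_len(genome_size - nrow(deg))))
    prom <- gen_promoters(cfg, deg, universe)
    fit <- fcs_motif(deg, prom$promoters, q = q)
    summ <- fit$directions$up$two_step$summary
    row <- summ[summ$hexamer == target, ]
    rec[i] <- nrow(row) == 1L && row$fold_change_specific &&
      row$best_lo <= interval[2] && row$best_hi >= interval[1]
    fp[i] <- sum(summ$fold_change_specific & summ$hexamer != target)
  }
  list(recovered = rec, false_flags = fp)
}

#' Benchmark recovery and error control across quantile schemes
#'
#' For each q in `qs`, measures (i) planted-term recovery
#' ([sim_go_recovery()] with the planted interval scaled to a single
#' weakest quantile, pi = 0.9), (ii) planted-hexamer recovery
#' ([sim_motif_recovery()]), and (iii) the null family-wise error
#' ([sim_null_fwer()]); writes a TSV report when `out_dir` is given.
#'
#' @param qs quantile schemes (default c(3, 4, 6, 8), the robustness grid).
#' @param n_seeds recovery replicates per q (default 10).
#' @param n_null null simulations per q (default 50).
#' @param out_dir optional output directory for `benchmark.tsv`.
#' @param seed base seed.
#' @param motifs include the motif recovery arm? Default `TRUE`.
#' @return data frame: per q, recovery rates and null FWER.
#' @export
run_benchmark <- function(qs = c(3L, 4L, 6L, 8L), n_seeds = 10L,
                          n_null = 50L, out_dir = NULL, seed = 1L,
                          motifs = TRUE) {
  base <- as.integer(seed %% 1000000L)   # keep derived seeds in int range
  rows <- lapply(qs, function(q) {
    go_rec <- sim_go_recovery(n_seeds, q = q, concentration = 0.9,
                              interval = c(1L, 1L),
                              seed = base + 100000L + q * 1000L)
    mot_rec <- if (motifs)
      sim_motif_recovery(n_seeds, q = q,
                         seed = base + 200000L + q * 1000L)$recovered
      else NA
    null_flag <- sim_null_fwer(n_null, q = q,
                               seed = base + 300000L + q * 1000L)
    data.frame(q = q, n_seeds = n_seeds,
               go_recovery = mean(go_rec),
               motif_recovery = if (motifs) mean(mot_rec) else NA_real_,
               n_null = n_null, null_fwer = mean(null_flag))
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(report, file.path(out_dir, "benchmark.tsv"))
  }
  report
}
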