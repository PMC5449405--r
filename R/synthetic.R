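#' Configuration for the synthetic-data generator
#'
#' Defines a synthetic auxin-response-like study: two directional DEG lists
#' with heavy-tailed linear fold changes, gene-set annotations with planted
#' fold-change-specific terms, and random promoters with planted hexamers.
#' Defaults mirror the study conditions the generator emulates: 789
#' up-regulated and 659 down-regulated genes, fold-change magnitudes in
#' 1.5-88 (up) and 1.4-143 (down), q = 6 quantiles. Fold-change magnitudes
#' are drawn from a log-normal truncated to the direction's range (heavy
#' tail, no boundary mass).
#'
#' @param n_up,n_down directional list sizes (defaults 789 and 659).
#' @param q quantiles used to define planted target intervals (default 6).
#' @param fc_log_mean,fc_log_sd meanlog/sdlog of the log-normal fold-change
#'   draw (defaults log(3) and 1.2).
#' @param fc_range_up,fc_range_down (min, max) truncation per direction
#'   (defaults c(1.5, 88) and c(1.4, 143)).
#' @param planted_terms list of planted gene sets; each element a list with
#'   `term_id`, `size`, `direction`, `interval` = c(lo, hi), `concentration`
#'   (the fraction pi of members placed inside the target interval).
#' @param n_background_terms number of unplanted terms (default 50).
#' @param background_term_size_range (min, max) background set size
#'   (default c(10, 100)).
#' @param promoter_length synthetic promoter length in bp (default 1500).
#' @param gc background GC content of promoters (default 0.36, a plant
#'   promoter-like composition).
#' @param motif_plants list of planted hexamers; each element a list with
#'   `hexamer`, `direction`, `interval` = c(lo, hi), `presence_in`,
#'   `presence_out` (insertion probabilities inside / outside the target
#'   interval).
#' @param seed integer seed; fully determines every generated output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_up = 789L, n_down = 659L, q = 6L,
                             fc_log_mean = log(3), fc_log_sd = 1.2,
                             fc_range_up = c(1.5, 88),
                             fc_range_down = c(1.4, 143),
                             planted_terms = list(),
                             n_background_terms = 50L,
                             background_term_size_range = c(10L, 100L),
                             promoter_length = 1500L,
                             gc = 0.36,
                             motif_plants = list(),
                             seed = 1L) {
  q <- check_count(q, "q", min = 2L)
  n_up <- check_count(n_up, "n_up", min = q)
  n_down <- check_count(n_down, "n_down", min = q)
  for (rng in list(fc_range_up, fc_range_down))
    if (length(rng) != 2L || rng[1] >= rng[2] || rng[1] <= 0)
      stop("fold-change ranges must be (min, max) with 0 < min < max")
  for (pt in planted_terms) {
    stopifnot(all(c("term_id", "size", "direction", "interval",
                    "concentration") %in% names(pt)))
    if (pt$concentration < 0 || pt$concentration > 1)
      stop("concentration must lie in [0, 1]")
    if (pt$concentration * q < (pt$interval[2] - pt$interval[1] + 1L))
      warning("planted concentration for ", pt$term_id,
              " is below the interval's null share; this plants depletion")
  }
  for (mp in motif_plants) {
    stopifnot(all(c("hexamer", "direction", "interval", "presence_in",
                    "presence_out") %in% names(mp)))
    if (nchar(mp$hexamer) != 6L)
      stop("planted motifs must be hexamers")
  }
  structure(list(n_up = n_up, n_down = n_down, q = q,
                 fc_log_mean = fc_log_mean, fc_log_sd = fc_log_sd,
                 fc_range_up = fc_range_up, fc_range_down = fc_range_down,
                 planted_terms = planted_terms,
                 n_background_terms = check_count(n_background_terms,
                                                  "n_background_terms",
                                                  min = 0L),
                 background_term_size_range = background_term_size_range,
                 promoter_length = check_count(promoter_length,
                                               "promoter_length", min = 6L),
                 gc = gc, motif_plants = motif_plants,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# truncated log-normal draw (no mass at the clip boundaries)
rlnorm_trunc <- function(n, meanlog, sdlog, range) {
  pr <- plnorm(range, meanlog, sdlog)
  qlnorm(runif(n, pr[1], pr[2]), meanlog, sdlog)
}

#' Generate a synthetic DEG table
#'
#' Draws `n_up` up- and `n_down` down-regulated gene records with truncated
#' log-normal fold-change magnitudes and adjusted p-values below 0.05.
#' Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `deg` (data frame of gene records in the canonical DEG
#'   schema) and `ground_truth` (list with the per-direction quantile
#'   membership implied by the generated fold changes at `cfg$q`).
#' @export
gen_deg_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  up <- data.frame(
    gene_id = sprintf("GUP%05d", seq_len(cfg$n_up)), direction = "up",
    fold_change = rlnorm_trunc(cfg$n_up, cfg$fc_log_mean, cfg$fc_log_sd,
                               cfg$fc_range_up),
    adj_p = runif(cfg$n_up) * 0.05, stringsAsFactors = FALSE)
  down <- data.frame(
    gene_id = sprintf("GDN%05d", seq_len(cfg$n_down)), direction = "down",
    fold_change = rlnorm_trunc(cfg$n_down, cfg$fc_log_mean, cfg$fc_log_sd,
                               cfg$fc_range_down),
    adj_p = runif(cfg$n_down) * 0.05, stringsAsFactors = FALSE)
  deg <- rbind(up, down)
  gt <- lapply(c(up = "up", down = "down"), function(d) {
    p <- quantile_partition(deg[deg$direction == d, ], cfg$q)
    setNames(p$quantile, p$gene_id)
  })
  list(deg = deg, ground_truth = list(quantile_of = gt, q = cfg$q))
}

#' Generate a synthetic gene-set annotation with planted structure
#'
#' Background terms draw members uniformly from the whole gene universe
#' (DEGs plus `genome_size - n_DEG` non-DEG genes, so genome-wide
#' backgrounds are realistic). Each planted term of size s places
#' `round(concentration * s)` members among the genes of its direction
#' whose fold-change ranks fall in the target interval, and the remaining
#' members uniformly among the same direction's DEGs outside the interval
#' (this is what reproduces the worked contingency-table layout where all
#' term genes are DEGs).
#'
#' @param cfg a [synthetic_config()].
#' @param degs DEG data frame from [gen_deg_table()].
#' @param genome_size total gene-universe size (>= number of DEGs).
#' @return list with `annotation` (a [gene_sets()]), `universe` (character
#'   vector of all genome genes) and `ground_truth` (data frame: one row per
#'   planted term with its direction, target interval and concentration).
#' @export
gen_annotation <- function(cfg, degs, genome_size) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genome_size <- check_count(genome_size, "genome_size", min = nrow(degs))
  set.seed(cfg$seed + 1L)
  n_bg_genes <- genome_size - nrow(degs)
  universe <- c(degs$gene_id,
                if (n_bg_genes > 0) sprintf("GBG%05d", seq_len(n_bg_genes)))
  sets <- list()
  if (cfg$n_background_terms > 0L) {
    szr <- cfg$background_term_size_range
    sizes <- sample(seq.int(szr[1], szr[2]), cfg$n_background_terms,
                    replace = TRUE)
    for (i in seq_len(cfg$n_background_terms))
      sets[[sprintf("BGT:%04d", i)]] <- sample(universe, sizes[i])
  }
  gt <- list()
  for (pt in cfg$planted_terms) {
    part <- quantile_partition(degs[degs$direction == pt$direction, ],
                               cfg$q)
    inside_pool <- interval_genes(part, pt$interval[1], pt$interval[2])
    outside_pool <- setdiff(part$gene_id, inside_pool)
    n_in <- round(pt$concentration * pt$size)
    if (n_in > length(inside_pool))
      stop("planted term ", pt$term_id, ": ", n_in,
           " members exceed the target interval's ", length(inside_pool),
           " genes")
    if (pt$size - n_in > length(outside_pool))
      stop("planted term ", pt$term_id,
           ": outside members exceed the genes outside the interval")
    sets[[pt$term_id]] <- c(sample(inside_pool, n_in),
                            sample(outside_pool, pt$size - n_in))
    gt[[pt$term_id]] <- data.frame(
      term_id = pt$term_id, direction = pt$direction,
      lo = pt$interval[1], hi = pt$interval[2],
      concentration = pt$concentration, size = pt$size,
      n_inside = n_in, stringsAsFactors = FALSE)
  }
  list(annotation = gene_sets(sets), universe = universe,
       ground_truth = do.call(rbind, c(gt, list(make.row.names = FALSE))))
}

#' Generate synthetic promoters with planted hexamers
#'
#' Promoters are i.i.d. random DNA of length `cfg$promoter_length` with GC
#' content `cfg$gc`. For each motif plant, the hexamer is written at a
#' uniform random position of a gene's promoter with probability
#' `presence_in` for genes of the target interval and `presence_out` for
#' every other gene (including non-DEG genome genes). The hexamer can also
#' occur by chance in the random background, as in real sequence.
#'
#' @param cfg a [synthetic_config()].
#' @param degs DEG data frame from [gen_deg_table()].
#' @param genome_genes character vector: the full gene universe (e.g.
#'   `gen_annotation(...)$universe`).
#' @return list with `promoters` (a [promoter_set()]) and `ground_truth`
#'   (data frame: per planted motif, its canonical form, direction, target
#'   interval and insertion probabilities).
#' @export
gen_promoters <- function(cfg, degs, genome_genes) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!all(degs$gene_id %in% genome_genes))
    stop("all DEGs must be part of the gene universe")
  set.seed(cfg$seed + 2L)
  L <- cfg$promoter_length
  bases <- c("A", "C", "G", "T")
  pr <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  seqs <- vapply(seq_along(genome_genes), function(i)
    paste(sample(bases, L, replace = TRUE, prob = pr), collapse = ""), "")
  names(seqs) <- genome_genes
  gt <- list()
  for (mp in cfg$motif_plants) {
    hex <- toupper(mp$hexamer)
    part <- quantile_partition(degs[degs$direction == mp$direction, ],
                               cfg$q)
    inside <- interval_genes(part, mp$interval[1], mp$interval[2])
    p_ins <- ifelse(genome_genes %in% inside, mp$presence_in,
                    mp$presence_out)
    hit <- runif(length(genome_genes)) < p_ins
    pos <- sample.int(L - 5L, length(genome_genes), replace = TRUE)
    for (i in which(hit))
      substr(seqs[i], pos[i], pos[i] + 5L) <- hex
    gt[[hex]] <- data.frame(
      hexamer = hex, canonical = canonical_kmer(hex),
      direction = mp$direction, lo = mp$interval[1], hi = mp$interval[2],
      presence_in = mp$presence_in, presence_out = mp$presence_out,
      stringsAsFactors = FALSE)
  }
  list(promoters = promoter_set(seqs),
       ground_truth = do.call(rbind, c(gt, list(make.row.names = FALSE))))
}
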