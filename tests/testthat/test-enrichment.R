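test_that("fisher_one_sided matches closed-form corner cases", {
  # single most extreme table: p = 1/C(4,2)
  expect_equal(fisher_one_sided(2, 0, 0, 2), 1 / 6)
  # focal genes are the entire universe: degenerate margins give p = 1
  expect_equal(fisher_one_sided(10, 0, 0, 0), 1)
  # P(X >= 0) = 1 for any margins
  expect_equal(fisher_one_sided(0, 5, 7, 11), 1)
  expect_error(fisher_one_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_one_sided(1.5, 2, 3, 4), "integer")
})

test_that("fisher_one_sided agrees with the brute-force oracle", {
  set.seed(2024)
  for (i in 1:300) {
    N <- sample(4:200, 1)
    row1 <- sample.int(N, 1)
    col1 <- sample.int(N, 1)
    rng <- max(0, row1 + col1 - N):min(row1, col1)
    a <- rng[sample.int(length(rng), 1)]
    tab <- c(a, row1 - a, col1 - a, N - row1 - col1 + a)
    expect_equal(fisher_one_sided(tab[1], tab[2], tab[3], tab[4]),
                 oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("enlarging the focal-in-interval cell never increases p", {
  set.seed(7)
  for (i in 1:50) {
    row1 <- sample(2:30, 1); col1 <- sample(2:30, 1)
    N <- row1 + col1 + sample(0:40, 1)
    amax <- min(row1, col1)
    p <- vapply(0:amax, function(a)
      fisher_one_sided(a, row1 - a, col1 - a, N - row1 - col1 + a),
      numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("bonferroni multiplies and caps at 1", {
  expect_equal(bonferroni(0.001, 1), 0.001)
  expect_equal(bonferroni(0.01, 200), 1.0)
  expect_equal(bonferroni(1e-6, 420), 4.2e-4)
  expect_error(bonferroni(0.1, 0), "m")
  p <- runif(50)
  expect_true(all(bonferroni(p, 13) >= p))  # adjusted never below raw
})

test_that("step 1 flags maximal enrichment and ignores proportional terms", {
  # 40-gene universe, 20 DEGs; term A = exactly the 5 weakest-FC genes,
  # term B spread proportionally to the background
  deg <- make_genes(20, fc = seq(1.1, 5, length.out = 20))
  part <- quantile_partition(deg, q = 4)
  universe <- c(deg$gene_id, sprintf("BG%03d", 1:20))
  inA <- interval_genes(part, 1, 1)
  ann <- gene_sets(list(
    A = inA,
    B = universe[seq(1, 40, by = 5)]))
  s1 <- step1_enrichment(part, ann, universe, alpha1 = 0.001)
  expect_equal(attr(s1, "n_intervals"), 10L)  # q(q+1)/2 for q = 4
  expect_equal(attr(s1, "multiplier"), 2L * 10L)
  rowA <- s1[s1$term_id == "A" & s1$lo == 1 & s1$hi == 1, ]
  # all 5 term genes inside the 5-gene interval: smallest achievable p
  expect_equal(rowA$a, 5L)
  expect_equal(rowA$raw_p, oracle_fisher(5, 0, 0, 35), tolerance = 1e-12)
  expect_true(rowA$significant)
  # the proportional term is never enriched anywhere
  rowsB <- s1[s1$term_id == "B", ]
  expect_true(all(rowsB$raw_p >= 0.5))
  expect_false(any(rowsB$significant))
  expect_identical(selected_terms(s1), "A")
})

test_that("step 1 adds missing DEGs to the background with a warning", {
  deg <- make_genes(12)
  part <- quantile_partition(deg, q = 3)
  ann <- gene_sets(list(T1 = deg$gene_id[1:4]))
  expect_warning(
    s1 <- step1_enrichment(part, ann, sprintf("BG%02d", 1:30)),
    "missing from the background")
  # universe = 30 + 12: margins must stay consistent
  expect_true(all(s1$a + s1$b + s1$c + s1$d == 42L))
  expect_error(step1_enrichment(part, ann, character(0)), "empty")
})

test_that("step 2 reproduces the worked contingency-table layout", {
  # 108-gene term among 789 up-regulated genes, 96 members inside the
  # 263-gene weakest interval (quantiles 1-2 at q = 6)
  study <- synthetic_config(
    n_up = 789, n_down = 659, seed = 5,
    planted_terms = list(list(term_id = "GO:TRANS", size = 108,
                              direction = "up", interval = c(1, 2),
                              concentration = 96 / 108)),
    n_background_terms = 0)
  sim <- gen_deg_table(study)
  deg <- sim$deg[sim$deg$direction == "up", ]
  ann <- gen_annotation(study, deg, genome_size = 789)
  part <- quantile_partition(deg, q = 6)
  s2 <- step2_specificity("GO:TRANS", part, ann$annotation)
  row <- s2$per_interval[s2$per_interval$lo == 1 &
                           s2$per_interval$hi == 2, ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(96, 12, 167, 514))
  # fractions as printed for this layout (implementation keeps them raw)
  expect_equal(100 * row$a / (row$a + row$b), 88.9, tolerance = 1e-3)
  expect_equal(100 * (row$a + row$c) / part$n, 33.3, tolerance = 2e-3)
  expect_equal(row$raw_p, oracle_fisher(96, 12, 167, 514),
               tolerance = 1e-12)
  summ <- s2$summary
  expect_true(summ$fold_change_specific)
  expect_equal(c(summ$best_lo, summ$best_hi), c(1, 2))
  expect_equal(summ$best_interval, "vw-w")
})

test_that("step 2 is null for uniformly spread terms and excludes the full interval", {
  deg <- make_genes(60)
  part <- quantile_partition(deg, q = 6)
  # term = every 3rd gene along the ranking: uniform across quantiles
  ann <- gene_sets(list(U = part$gene_id[seq(1, 60, by = 3)]))
  s2 <- step2_specificity("U", part, ann)
  expect_false(s2$summary$fold_change_specific)
  expect_true(is.na(s2$summary$best_interval))
  # only the 20 component intervals are tested
  expect_equal(nrow(s2$per_interval), 20L)
  expect_false(any(s2$per_interval$lo == 1 & s2$per_interval$hi == 6))
  # rationale for the exclusion: on the full interval every term gene is
  # inside, so the one-sided p would be exactly 1 for any term
  expect_equal(fisher_one_sided(20, 0, 40, 0), 1)
  # skipped terms: no member in the directional list
  ann2 <- gene_sets(list(U = part$gene_id[1:5], Z = "absent_gene"))
  expect_warning(s2b <- step2_specificity(c("U", "Z"), part, ann2),
                 "skipped")
  expect_equal(nrow(s2b$summary), 1L)
})

test_that("best-interval assignment prefers the tightest claim on ties", {
  df <- data.frame(lo = c(1L, 1L), hi = c(1L, 2L), adj_p = c(1e-8, 1e-5))
  expect_equal(assign_best_interval(df)[c("lo", "hi")],
               list(lo = 1L, hi = 1L))
  tie <- data.frame(lo = c(1L, 1L), hi = c(2L, 1L), adj_p = c(1e-6, 1e-6))
  expect_equal(assign_best_interval(tie)[c("lo", "hi")],
               list(lo = 1L, hi = 1L))   # shorter wins
  tie2 <- data.frame(lo = c(2L, 1L), hi = c(2L, 1L), adj_p = c(0.5, 0.5))
  expect_equal(assign_best_interval(tie2)$lo, 1L)  # then weaker lo
})

test_that("significance decisions are invariant under input permutation", {
  study <- make_planted_study(seed = 21)
  part <- quantile_partition(study$deg, q = 6)
  s1 <- step1_enrichment(part, study$ann$annotation, study$ann$universe)
  perm <- study$deg[rev(seq_len(nrow(study$deg))), ]
  s1p <- step1_enrichment(quantile_partition(perm, 6),
                          study$ann$annotation, study$ann$universe)
  expect_identical(selected_terms(s1), selected_terms(s1p))
  expect_equal(s1$adj_p, s1p$adj_p)
})
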