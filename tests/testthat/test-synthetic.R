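test_that("generated DEG tables have the configured counts and ranges", {
  cfg <- synthetic_config(seed = 1)   # defaults: 789 up, 659 down
  sim <- gen_deg_table(cfg)
  expect_equal(sum(sim$deg$direction == "up"), 789L)
  expect_equal(sum(sim$deg$direction == "down"), 659L)
  up <- sim$deg$fold_change[sim$deg$direction == "up"]
  dn <- sim$deg$fold_change[sim$deg$direction == "down"]
  expect_true(all(up >= 1.5 & up <= 88))
  expect_true(all(dn >= 1.4 & dn <= 143))
  expect_true(all(sim$deg$adj_p < 0.05))
  expect_error(synthetic_config(fc_range_up = c(5, 2)), "min < max")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_up = 50, n_down = 40, seed = 77,
                          promoter_length = 60,
                          motif_plants = list(list(
                            hexamer = "TTAGGG", direction = "up",
                            interval = c(1, 2), presence_in = 0.5,
                            presence_out = 0.1)))
  f1 <- tempfile(); f2 <- tempfile()
  write_deg_table(gen_deg_table(cfg)$deg, f1)
  write_deg_table(gen_deg_table(cfg)$deg, f2)
  expect_identical(readLines(f1), readLines(f2))
  sim <- gen_deg_table(cfg)
  p1 <- gen_promoters(cfg, sim$deg, sim$deg$gene_id)
  p2 <- gen_promoters(cfg, sim$deg, sim$deg$gene_id)
  expect_identical(p1$promoters$seq, p2$promoters$seq)
})

test_that("generated tables pass the package's own readers", {
  cfg <- synthetic_config(n_up = 60, n_down = 50, seed = 9)
  sim <- gen_deg_table(cfg)
  ann <- gen_annotation(cfg, sim$deg, genome_size = 400)
  dtab <- tempfile(); atab <- tempfile()
  write_deg_table(sim$deg, dtab)
  write_gene_sets(ann$annotation, atab)
  back_deg <- read_deg_table(dtab,
                             columns = foldspec:::canonical_deg_columns())
  expect_equal(nrow(back_deg), nrow(sim$deg))
  back_ann <- read_gene_sets(atab)
  expect_equal(length(back_ann), length(ann$annotation))
  expect_identical(back_ann$sets, ann$annotation$sets)
})

test_that("planted terms are placed with the requested concentration", {
  study <- synthetic_config(
    n_up = 789, n_down = 6, seed = 2,
    planted_terms = list(list(term_id = "P1", size = 108, direction = "up",
                              interval = c(1, 2),
                              concentration = 0.889)),
    n_background_terms = 5)
  sim <- gen_deg_table(study)
  deg <- sim$deg[sim$deg$direction == "up", ]
  ann <- gen_annotation(study, deg, genome_size = 2000)
  part <- quantile_partition(deg, q = 6)
  inside <- interval_genes(part, 1, 2)
  members <- ann$annotation$sets$P1
  expect_length(members, 108L)
  expect_equal(sum(members %in% inside), round(0.889 * 108))   # = 96
  expect_equal(sum(members %in% inside), 96L)
  expect_true(all(members %in% deg$gene_id))  # outside members stay DEGs
  expect_equal(ann$ground_truth$n_inside, 96L)
  # planting beyond the interval capacity is refused
  over <- synthetic_config(
    n_up = 30, n_down = 6, seed = 2,
    planted_terms = list(list(term_id = "P1", size = 20, direction = "up",
                              interval = c(1, 1), concentration = 1.0)))
  simo <- gen_deg_table(over)
  expect_error(gen_annotation(over, simo$deg[simo$deg$direction == "up", ],
                              100),
               "exceed")
})

test_that("null planting (concentration = interval share) is not flagged", {
  cfg <- suppressWarnings(synthetic_config(
    n_up = 600, n_down = 6, seed = 15,
    planted_terms = list(list(term_id = "NULLT", size = 90,
                              direction = "up", interval = c(1, 2),
                              concentration = 2 / 6)),
    n_background_terms = 10))
  sim <- gen_deg_table(cfg)
  deg <- sim$deg[sim$deg$direction == "up", ]
  ann <- gen_annotation(cfg, deg, genome_size = 3000)
  part <- quantile_partition(deg, q = 6)
  s2 <- step2_specificity("NULLT", part, ann$annotation)
  expect_false(any(s2$summary$fold_change_specific))
})

test_that("background promoter presence matches the closed form", {
  # uniform-composition promoters: P(hexamer class present) is
  # 1 - (1 - 2/4096)^(L-5) for a non-palindromic hexamer
  n <- 3000; L <- 400
  cfg <- synthetic_config(n_up = 6, n_down = 6, seed = 23,
                          promoter_length = L, gc = 0.5)
  sim <- gen_deg_table(cfg)
  prom <- gen_promoters(cfg, sim$deg,
                        c(sim$deg$gene_id,
                          sprintf("R%05d", seq_len(n - nrow(sim$deg)))))
  pres <- scan_hexamer_presence(prom$promoters)
  expected <- 1 - (1 - 2 / 4096)^(L - 5)
  observed <- mean(pres[, "AAGCTC"])   # non-palindromic, non-overlapping
  mc_sd <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 4 * mc_sd + 0.005)
})

test_that("recovery is monotone in the planted concentration", {
  rates <- vapply(c(0.35, 0.60, 0.90), function(conc)
    mean(sim_go_recovery(10, size = 60, concentration = conc,
                         interval = c(1, 2), n_up = 300,
                         n_background_terms = 20, genome_size = 2000,
                         seed = 400)),
    numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gte(rates[3], 0.9)
})
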