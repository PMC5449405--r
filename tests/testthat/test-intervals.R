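test_that("quantile sizes follow the ceil(kn/q) boundary rule", {
  p12 <- quantile_partition(make_genes(12), q = 6)
  expect_equal(p12$sizes, rep(2L, 6))
  p13 <- quantile_partition(make_genes(13), q = 6)
  expect_equal(p13$sizes, c(3L, 2L, 2L, 2L, 2L, 2L))  # extra gene lowest
  # cumulative counts always hit ceil(k * n / q)
  expect_equal(cumsum(p13$sizes), as.integer(ceiling(1:6 * 13 / 6)))
  # the directional list size of the motivating study: quantiles 1-2 of
  # 789 genes at q = 6 hold 263 genes
  p789 <- quantile_partition(make_genes(789), q = 6)
  expect_equal(sum(p789$sizes[1:2]), 263L)
  expect_equal(length(interval_genes(p789, 1, 2)), 263L)
  expect_equal(length(interval_genes(p789, 1, 6)), 789L)
})

test_that("partition rejects bad inputs", {
  expect_error(quantile_partition(make_genes(5), q = 6), "at least q")
  mixed <- rbind(make_genes(6, "up"), make_genes(6, "down", prefix = "H"))
  expect_error(quantile_partition(mixed, q = 3), "one direction")
  dup <- make_genes(6)
  dup$gene_id[2] <- dup$gene_id[1]
  expect_error(quantile_partition(dup, q = 3), "duplicate")
})

test_that("partition is deterministic and monotone in fold change", {
  set.seed(1)
  g <- make_genes(101, fc = round(runif(101, 1, 50), 1)) # has ties
  p <- quantile_partition(g, q = 6)
  # permuting the input rows never changes the partition
  for (i in 1:5) {
    gp <- g[sample.int(nrow(g)), ]
    pp <- quantile_partition(gp, q = 6)
    expect_identical(pp$gene_id, p$gene_id)
    expect_identical(pp$quantile, p$quantile)
  }
  # every gene in quantile k has fold change <= every gene in k+1
  for (k in 1:5)
    expect_lte(max(p$fold_change[p$quantile == k]),
               min(p$fold_change[p$quantile == k + 1]))
  # quantiles are disjoint and exhaustive
  expect_equal(sum(p$sizes), 101L)
  expect_setequal(p$gene_id, g$gene_id)
})

test_that("interval enumeration counts and ordering match q(q+1)/2", {
  for (q in c(3L, 4L, 6L, 8L)) {
    full <- enumerate_intervals(q, include_full = TRUE)
    expect_equal(nrow(full), q * (q + 1L) / 2L)
    comp <- enumerate_intervals(q, include_full = FALSE)
    expect_equal(nrow(comp), q * (q + 1L) / 2L - 1L)
    expect_false(any(comp$lo == 1L & comp$hi == q))
  }
  expect_equal(nrow(enumerate_intervals(6)), 21L)
  expect_equal(nrow(enumerate_intervals(6, include_full = FALSE)), 20L)
  # exhaustive listing for q = 3, sorted by (length, lo)
  e3 <- enumerate_intervals(3)
  expect_equal(e3$lo, c(1L, 2L, 3L, 1L, 2L, 1L))
  expect_equal(e3$hi, c(1L, 2L, 3L, 2L, 3L, 3L))
  expect_error(enumerate_intervals(1), "q")
})

test_that("interval gene sets are unions of quantiles with exact sizes", {
  p <- quantile_partition(make_genes(12), q = 6)
  expect_equal(interval_genes(p, 1, 1), p$gene_id[1:2]) # 2 weakest genes
  expect_equal(length(interval_genes(p, 1, 6)), 12L)
  singles <- lapply(1:6, function(k) interval_genes(p, k, k))
  expect_equal(length(unique(unlist(singles))), 12L)    # disjoint singles
  ivs <- enumerate_intervals(6)
  for (i in seq_len(nrow(ivs)))
    expect_equal(length(interval_genes(p, ivs$lo[i], ivs$hi[i])),
                 sum(p$sizes[ivs$lo[i]:ivs$hi[i]]))
  expect_error(interval_genes(p, 2, 7), "exceeds q")
})

test_that("interval labels follow the vw..vs scheme at q = 6", {
  expect_equal(quantile_labels(6), c("vw", "w", "m", "i", "s", "vs"))
  expect_equal(interval_label(1, 1, 6), "vw")
  expect_equal(interval_label(1, 2, 6), "vw-w")
  expect_equal(interval_label(1, 6, 6), "vw-vs")
  expect_equal(interval_label(2, 2, 8), "q2")
})

test_that("partition dump TSV round-trips", {
  p <- quantile_partition(make_genes(17, fc = runif(17, 1.1, 90)), q = 6)
  path <- tempfile(fileext = ".tsv")
  write_partition(p, path)
  back <- read.delim(path)
  expect_equal(back$gene_id, p$gene_id)
  expect_identical(back$fold_change, p$fold_change)
  expect_equal(back$quantile, p$quantile)
  expect_equal(back$quantile_label, p$labels[p$quantile])
})
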