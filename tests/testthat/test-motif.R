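test_that("revcomp complements known pairs and is an involution", {
  expect_equal(revcomp("AAACCC"), "GGGTTT")
  expect_equal(revcomp("AAATTT"), "AAATTT")   # self-complementary
  expect_equal(revcomp("TTAGGG"), "CCCTAA")
  expect_equal(revcomp("acgtn"), "NACGT")     # case-folded, N kept
  set.seed(5)
  r <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 8, TRUE), collapse = ""), "")
  expect_identical(revcomp(revcomp(r)), r)
  expect_error(revcomp("ACGU"), "only A, C, G, T, N")
})

test_that("canonicalisation is idempotent and strand-symmetric", {
  set.seed(6)
  h <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""), "")
  expect_identical(canonical_kmer(canonical_kmer(h)), canonical_kmer(h))
  expect_identical(canonical_kmer(h), canonical_kmer(revcomp(h)))
})

test_that("2080 canonical hexamers arise from the 4096 raw ones", {
  canon <- enumerate_canonical_hexamers()
  expect_length(canon, 2080L)
  pal <- attr(canon, "palindromic")
  expect_equal(sum(pal), 64L)   # 4^3 self-complementary hexamers
  # class sizes (2 per non-palindromic pair, 1 per palindrome) tile 4096
  expect_equal(sum(ifelse(pal, 1L, 2L)), 4096L)
  expect_equal((4096 - 64) / 2 + 64, 2080)
  expect_identical(as.character(canon),
                   sort(as.character(canon), method = "radix"))
  expect_false(any(duplicated(canon)))
})

test_that("presence scanning enumerates windows and honours N", {
  pres <- scan_hexamer_presence(c(g1 = "AAACCCAA"))
  hits <- colnames(pres)[pres[1, ]]
  expect_setequal(hits, canonical_kmer(c("AAACCC", "AACCCA", "ACCCAA")))
  # all-N promoter and too-short promoter: empty presence sets
  suppressMessages(
    pres2 <- scan_hexamer_presence(c(gN = strrep("N", 50), tiny = "ACG")))
  expect_equal(sum(pres2), 0L)
  # window containing an N contributes nothing
  pres3 <- scan_hexamer_presence(c(g = "AAANCCCTAA"))
  expect_true(pres3[1, "CCCTAA"])
  expect_equal(sum(pres3), 1L)  # the 4 N-containing windows match nothing
  # occurrence counts behind the flag
  cnt <- scan_hexamer_presence(c(g = "AAATTTAAATTT"), counts = TRUE)
  expect_equal(cnt[1, "AAATTT"], 2L)
})

test_that("scanning is double-strand symmetric", {
  set.seed(8)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), "")
  names(seqs) <- sprintf("g%02d", 1:20)
  fwd <- scan_hexamer_presence(seqs)
  rev <- scan_hexamer_presence(setNames(revcomp(seqs), names(seqs)))
  expect_identical(fwd, rev)
})

test_that("a planted hexamer is present in at least the planted genes", {
  cfg <- synthetic_config(
    n_up = 100, n_down = 6, promoter_length = 120, seed = 13,
    motif_plants = list(list(hexamer = "TTAGGG", direction = "up",
                             interval = c(1, 6), presence_in = 1.0,
                             presence_out = 0.0)))
  sim <- gen_deg_table(cfg)
  deg <- sim$deg[sim$deg$direction == "up", ]
  prom <- gen_promoters(cfg, deg, deg$gene_id)
  pres <- scan_hexamer_presence(prom$promoters)
  # presence_in = 1: every one of the 100 promoters carries the motif
  expect_gte(sum(pres[, "CCCTAA"]), 100L)
})

test_that("two-step hexamer testing flags planted, not saturated, motifs", {
  set.seed(31)
  n_up <- 240; n_bg <- 1000
  deg <- make_genes(n_up, fc = sort(runif(n_up, 1.2, 90)))
  part <- quantile_partition(deg, q = 6)
  universe <- c(deg$gene_id, sprintf("BG%04d", seq_len(n_bg)))
  canon <- as.character(enumerate_canonical_hexamers())
  n_hex <- 300L   # reduced vocabulary keeps this fixture cheap
  hex <- canon[seq_len(n_hex)]
  presence <- matrix(runif(length(universe) * n_hex) < 0.10,
                     nrow = length(universe),
                     dimnames = list(universe, hex))
  presence[, "AAAAAC"] <- TRUE                     # saturated everywhere
  target <- interval_genes(part, 1, 1)
  presence[, "AAAAAG"] <- runif(length(universe)) < 0.10
  presence[target, "AAAAAG"] <- runif(length(target)) < 0.65  # planted
  ts <- hexamer_two_step(presence, part)
  expect_equal(ts$multiplier1, n_hex * 21L)
  # a motif present in every promoter discriminates nothing: p = 1
  sat <- ts$step1[ts$step1$hexamer == "AAAAAC", ]
  expect_true(all(sat$raw_p == 1))
  expect_false("AAAAAC" %in% ts$survivors)
  # the planted motif survives step 1 and is fold-change-specific at (1,1)
  expect_true("AAAAAG" %in% ts$survivors)
  row <- ts$summary[ts$summary$hexamer == "AAAAAG", ]
  expect_true(row$fold_change_specific)
  expect_true(row$best_lo <= 1 && row$best_hi >= 1)
  expect_equal(ts$multiplier2, length(ts$survivors) * 20L)
  # genes missing a promoter are refused at this level
  expect_error(hexamer_two_step(presence[-1, ], part), "lack promoters")
})

test_that("uniform-presence null keeps the hexamer family-wise error below 5%", {
  flagged <- sim_motif_null_fwer(500, seed = 314)
  expect_lte(mean(flagged), 0.05)
})
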