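# Shared fixtures built in code.

# independent brute-force oracle for the one-sided Fisher test:
# sums choose() products over every table with the same margins whose
# first cell is at least `a` (no phyper, no dhyper)
oracle_fisher <- function(a, b, c, d) {
  row1 <- a + b
  col1 <- a + c
  N <- a + b + c + d
  xs <- max(0L, row1 + col1 - N):min(row1, col1)
  mass <- choose(col1, xs) * choose(N - col1, row1 - xs)
  sum(mass[xs >= a]) / choose(N, row1)
}

# minimal directional gene-record data frame
make_genes <- function(n, direction = "up", fc = seq_len(n) + 0.5,
                       prefix = "G") {
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
             direction = direction, fold_change = fc,
             stringsAsFactors = FALSE)
}

# write a tiny genome FASTA + GFF3 promoter fixture; returns the two paths.
# geneA: plus strand, TSS at 1-based 2001, 100 bp 5'UTR -> region [500, 2100)
# geneB: minus strand with a 50 bp UTR
# geneC: plus strand close to the contig start (clipped)
write_promoter_fixture <- function(dir = tempfile("promfix")) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(99)
  contig <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1 test contig", contig), fa)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t2001\t4000\t.\t+\t.\tID=geneA",
    "chr1\ttest\tmRNA\t2001\t4000\t.\t+\t.\tID=geneA.1;Parent=geneA",
    "chr1\ttest\tfive_prime_UTR\t2001\t2100\t.\t+\t.\tID=geneA.1.utr;Parent=geneA.1",
    "chr1\ttest\tCDS\t2101\t4000\t.\t+\t.\tID=geneA.1.cds;Parent=geneA.1",
    "chr1\ttest\tgene\t5001\t7000\t.\t-\t.\tID=geneB",
    "chr1\ttest\tmRNA\t5001\t7000\t.\t-\t.\tID=geneB.1;Parent=geneB",
    "chr1\ttest\tfive_prime_UTR\t6951\t7000\t.\t-\t.\tID=geneB.1.utr;Parent=geneB.1",
    "chr1\ttest\tgene\t801\t1500\t.\t+\t.\tID=geneC",
    "chr1\ttest\tmRNA\t801\t1500\t.\t+\t.\tID=geneC.1;Parent=geneC"),
    gff)
  list(fasta = fa, gff = gff, contig = contig)
}

# small planted-term study shared by enrichment tests
make_planted_study <- function(seed = 11, n_up = 300, size = 60,
                               concentration = 0.85, interval = c(1, 2),
                               n_background_terms = 20,
                               genome_size = 2000) {
  cfg <- synthetic_config(
    n_up = n_up, n_down = 6, seed = seed,
    planted_terms = list(list(term_id = "PLT:0001", size = size,
                              direction = "up", interval = interval,
                              concentration = concentration)),
    n_background_terms = n_background_terms)
  sim <- gen_deg_table(cfg)
  deg <- sim$deg[sim$deg$direction == "up", ]
  ann <- gen_annotation(cfg, deg, genome_size)
  list(cfg = cfg, deg = deg, ann = ann)
}
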