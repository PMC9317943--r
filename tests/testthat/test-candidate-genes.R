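test_that("interval extension pads and clips", {
  expect_equal(unname(extend_interval(1e6, 1.05e6, 2e5)), c(8e5, 1.25e6))
  expect_equal(unname(extend_interval(1e5, 1.5e5, 2e5)), c(1, 3.5e5))
  expect_equal(unname(extend_interval(500, 900, 0)), c(500, 900))
  expect_equal(unname(extend_interval(1e6, 1.2e6, 2e5, chrom_length = 1.3e6)),
               c(8e5, 1.3e6))
})

test_that("gene retrieval uses 1-bp overlap semantics", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      chrom = c("c1", "c1", "c1", "c2"),
                      start = c(100L, 900L, 5000L, 100L),
                      end = c(300L, 1100L, 5200L, 300L),
                      stringsAsFactors = FALSE)
  # fully inside, straddling the edge, outside, other chromosome
  hit <- genes_in_interval(genes, "c1", 50, 1000)
  expect_setequal(hit$gene_id, c("g1", "g2"))
  # single-bp overlap at the boundary still counts
  expect_equal(genes_in_interval(genes, "c1", 300, 310)$gene_id, "g1")
  expect_equal(nrow(genes_in_interval(genes, "c1", 301, 400)), 0L)
  expect_equal(nrow(genes_in_interval(genes[0, ], "c1", 1, 10)), 0L)
  expect_equal(nrow(genes_in_interval(genes, "c9", 1, 1e6)), 0L)
})

test_that("GFF3 written by the generator round-trips through the reader", {
  cfg <- sim_config(n_accessions = 20, n_chromosomes = 2,
                    n_blocks_per_chrom = 2, n_qtls = 1, genes_per_chrom = 5,
                    rng_seed = 2)
  st <- generate_population(cfg)
  d <- tempfile("study")
  write_study(st, d)
  genes <- read_gene_annotation(file.path(d, "genes.gff3"))
  expect_equal(nrow(genes), 10L)
  expect_setequal(genes$gene_id, st$genes$gene_id)
  expect_equal(genes$start[order(genes$gene_id)],
               st$genes$start[order(st$genes$gene_id)])
})

test_that("chi-square independence test matches hand computation and pools", {
  # [[30,10],[10,30]]: expected counts all 20, X2 = 4 * 100/20 = 20, df 1
  q <- rep(rep(1:2, each = 40), 1)
  g <- c(rep(1, 30), rep(2, 10), rep(1, 10), rep(2, 30))
  tt <- test_independence(q, g)
  expect_equal(tt$statistic, 20)
  expect_equal(tt$df, 1L)
  expect_equal(tt$p, stats::pchisq(20, 1, lower.tail = FALSE))

  # perfect association -> tiny p
  q2 <- rep(1:3, each = 30)
  expect_lt(test_independence(q2, q2)$p, 1e-10)

  # invariance to class relabelling
  tt2 <- test_independence(3 - q, g)
  expect_equal(tt2$statistic, tt$statistic)

  # rare class pooled into "other" before testing
  q3 <- c(rep(1, 48), rep(2, 48), rep(3, 4))   # class 3 expected < 5
  g3 <- rep(1:2, 50)
  t3 <- test_independence(q3, g3)
  expect_equal(nrow(t3$table), 2L)

  # degenerate margins are refused
  expect_error(test_independence(rep(1, 50), g[1:50]), "fewer than 2 classes")
})

test_that("permutation null keeps type-I error near 5%", {
  set.seed(42)
  n <- 200
  q <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.35, 0.25))
  g <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  nrep <- 1000
  rej <- logical(nrep)
  for (i in seq_len(nrep))
    rej[i] <- test_independence(q, sample(g))$p <= 0.05
  rate <- mean(rej)
  band <- 2.58 * sqrt(0.05 * 0.95 / nrep)     # 99% binomial band
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})

test_that("candidate screening ties genes to loci and tallies categories", {
  cfg <- sim_config(n_accessions = 150, n_chromosomes = 2,
                    n_blocks_per_chrom = 6, n_qtls = 3, target_h2 = 0.8,
                    genes_per_chrom = 30, rng_seed = 31)
  st <- generate_population(cfg)
  geno <- impute_missing(filter_snps(st$geno))
  set <- assemble_snpldb(geno)
  fit <- rtm_gwas(st$phenotypes, set, h2_cap = 0.85)
  expect_gte(nrow(fit$loci), 1L)
  cg <- candidate_gene_scan(fit, geno, st$genes, pad_bp = 2e5)
  # every tested gene overlaps its locus's extended interval
  if (nrow(cg) > 0) for (i in seq_len(nrow(cg))) {
    li <- fit$loci[fit$loci$id == cg$qtl[i], ]
    span <- extend_interval(li$start_bp, li$end_bp, 2e5)
    expect_true(cg$chrom[i] == li$chrom)
    expect_true(cg$start[i] <= span[["end"]] && cg$end[i] >= span[["start"]])
  }
  # category tallies count candidate genes exactly once each
  tall <- categorize_genes(cg, st$go_table)
  expect_equal(sum(tall), length(unique(cg$gene_id[cg$candidate])))
  # hand tally on a constructed fixture
  fake <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     candidate = c(TRUE, TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  go <- data.frame(gene_id = c("g1", "g2"),
                   category = c("translation", "translation"),
                   stringsAsFactors = FALSE)
  tf <- categorize_genes(fake, go)
  expect_equal(unname(tf["translation"]), 2L)
  expect_equal(unname(tf["unannotated"]), 1L)
  # empty candidate list -> all-zero tallies
  expect_true(all(categorize_genes(fake[fake$candidate == FALSE, ][0, ], go) == 0L))
})
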