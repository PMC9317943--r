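test_that("GSC equals the fraction of shared marker alleles", {
  # 4 markers, 3 accessions: a and b share alleles at exactly 2 markers
  codes <- rbind(c(1, 1, 2), c(2, 2, 1), c(1, 2, 1), c(2, 1, 1))
  set <- make_snpldb(codes)
  sc <- compute_gsc(set, n_eigenvectors = 2)
  expect_equal(unname(diag(sc$gsc)), rep(1, 3))
  expect_equal(sc$gsc["a001", "a002"], 2 / 4)   # markers 1 and 4 shared
  expect_true(isSymmetric(sc$gsc))
  expect_true(all(diff(sc$eigenvalues) <= 1e-12))

  # identical accessions -> similarity 1; nowhere-equal accessions -> 0
  codes2 <- rbind(c(1, 1, 2), c(1, 1, 2), c(2, 2, 1))
  sc2 <- compute_gsc(make_snpldb(codes2), n_eigenvectors = 1)
  expect_equal(sc2$gsc["a001", "a002"], 1)
  expect_equal(sc2$gsc["a001", "a003"], 0)
})

test_that("stage-1 preselection holds its size under the null", {
  set.seed(101)
  n <- 150; m <- 400
  codes <- matrix(sample.int(3, n * m, replace = TRUE), m, n)
  set <- make_snpldb(codes)
  cov <- compute_gsc(set, 10)
  vals <- matrix(rnorm(2 * n), n, 2,
                 dimnames = list(set$accessions, c("E1", "E2")))
  s1 <- stage1_scan(make_means(vals), set, cov, alpha = 0.05)
  rate <- mean(s1$preselected)
  se <- sqrt(0.05 * 0.95 / m)
  expect_gt(rate, 0.05 - 3 * se)
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("stage-1 detects a marker explaining 30% of the variance", {
  set.seed(102)
  n <- 300
  codes <- matrix(sample.int(3, 50 * n, replace = TRUE), 50, n)
  set <- make_snpldb(codes)
  cov <- compute_gsc(set, 10)
  eff <- c(-1, 0, 1)[codes[25, ]]           # marker 25 carries the signal
  resid_sd <- sqrt(var(eff) * 0.7 / 0.3)
  vals <- matrix(eff + rnorm(2 * n, 0, resid_sd), n, 2,
                 dimnames = list(set$accessions, c("E1", "E2")))
  s1 <- stage1_scan(make_means(vals), set, cov, alpha = 0.05)
  expect_true(s1$preselected[25])
  expect_lt(s1$p[25], 1e-10)
})

test_that("stepwise selection recovers a single planted QTL with correct sign", {
  cfg <- sim_config(n_accessions = 300, n_chromosomes = 2,
                    n_blocks_per_chrom = 8, n_qtls = 1, qtl_effect_sd = 0.5,
                    target_h2 = 0.8, target_h2_gei = 0.05, rng_seed = 404)
  st <- generate_population(cfg)
  set <- assemble_snpldb(filter_snps(st$geno))
  fit <- rtm_gwas(st$phenotypes, set, h2_cap = 0.85)
  expect_gte(nrow(fit$loci), 1L)
  # the top locus sits inside the planted block
  top <- fit$loci[which.max(fit$loci$r2_main_pct), ]
  expect_equal(top$chrom, st$truth$chrom[1])
  expect_true(top$start_bp >= st$truth$start_bp[1] - 1 &&
                top$end_bp <= st$truth$end_bp[1] + 1)
  # effect ordering: with a single planted QTL the true genotypic value is
  # entirely this locus's contribution, so carrier groups of the detected
  # alleles must rank the same way under estimated and true effects
  eff <- fit$effects[[top$id]]
  carrier_codes <- fit$codes[top$id, ]
  true_by_code <- tapply(st$g[colnames(fit$codes)], carrier_codes, mean)
  est_by_code <- eff$effect[as.integer(names(true_by_code))]
  expect_equal(unname(which.max(est_by_code)), unname(which.max(true_by_code)))
  expect_equal(unname(which.min(est_by_code)), unname(which.min(true_by_code)))
  expect_gt(cor(est_by_code, as.numeric(true_by_code)), 0.9)
  # per-locus effects have frequency-weighted zero mean
  for (id in names(fit$effects)) {
    e <- fit$effects[[id]]
    expect_equal(sum(e$freq * e$effect), 0, tolerance = 1e-10)
  }
})

test_that("the heritability cap restricts total QTL contribution", {
  cfg <- sim_config(n_accessions = 200, n_chromosomes = 2,
                    n_blocks_per_chrom = 8, n_qtls = 5, target_h2 = 0.8,
                    rng_seed = 77)
  st <- generate_population(cfg)
  set <- assemble_snpldb(filter_snps(st$geno))
  for (cap in c(0.05, 0.15, 0.60)) {
    fit <- rtm_gwas(st$phenotypes, set, h2_cap = cap)
    expect_lte(fit$r2_qtl_total, cap)
    expect_lte(sum(fit$loci$r2_main_pct, fit$loci$r2_qei_pct, na.rm = TRUE),
               100 * cap + 1e-8)
  }
  # a vanishingly small cap admits no terms
  fit0 <- rtm_gwas(st$phenotypes, set, h2_cap = 1e-9)
  expect_equal(nrow(fit0$loci), 0L)
  expect_error(rtm_gwas(st$phenotypes, set, h2_cap = 0))
})

test_that("permuting phenotype labels destroys detections", {
  cfg <- sim_config(n_accessions = 200, n_chromosomes = 2,
                    n_blocks_per_chrom = 8, n_qtls = 3, target_h2 = 0.7,
                    rng_seed = 55)
  st <- generate_population(cfg)
  set <- assemble_snpldb(filter_snps(st$geno))
  n_loci <- integer(3)
  for (s in 1:3) {
    set.seed(500 + s)
    perm <- sample(st$geno$accessions)
    ph <- st$phenotypes
    ph$accession <- perm[match(ph$accession, st$geno$accessions)]
    fitp <- rtm_gwas(ph, set, h2_cap = 0.8)
    n_loci[s] <- nrow(fitp$loci)
  }
  expect_lte(stats::median(n_loci), 1)
})

test_that("classification, allele matrix and prediction are mutually consistent", {
  cfg <- sim_config(n_accessions = 250, n_chromosomes = 2,
                    n_blocks_per_chrom = 8, n_qtls = 4, qtl_effect_sd = 0.5,
                    target_h2 = 0.8, rng_seed = 99)
  st <- generate_population(cfg)
  set <- assemble_snpldb(filter_snps(st$geno))
  fit <- rtm_gwas(st$phenotypes, set, h2_cap = 0.85)
  expect_gte(nrow(fit$loci), 1L)

  cls <- classify_contribution(fit, threshold_pct = 1)
  expect_true(all(cls$loci$class[cls$loci$r2_main_pct >= 1] == "LC"))
  expect_true(all(cls$loci$class[cls$loci$r2_main_pct < 1] == "SC"))
  expect_equal(sum(cls$classes$n), nrow(fit$loci))
  # empty model -> zero counts
  cls0 <- classify_contribution(
    rtm_gwas(st$phenotypes, set, h2_cap = 1e-9), 1)
  expect_equal(sum(cls0$classes$n), 0L)

  qm <- qtl_allele_matrix(fit)
  expect_equal(dim(qm), c(nrow(fit$loci), length(set$accessions)))
  # every entry is one of that locus's allele effects
  for (i in seq_len(nrow(qm)))
    expect_true(all(qm[i, ] %in% fit$effects[[rownames(qm)[i]]]$effect))
  # column sum + intercept equals the genotypic prediction
  pred <- predict(fit)
  expect_equal(unname(pred), unname(fit$intercept + colSums(qm)))
  # predictions correlate with true genotypic values
  expect_gt(cor(pred, st$g[names(pred)]), 0.7)
})
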