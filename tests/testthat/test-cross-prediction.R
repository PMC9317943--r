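test_that("cross enumeration counts n(n-1)/2 and labels scopes", {
  expect_equal(nrow(enumerate_crosses(sprintf("x%03d", 1:361))), 64980L)
  expect_equal(nrow(enumerate_crosses(c("a", "b"))), 1L)
  for (n in c(5, 17, 40))
    expect_equal(nrow(enumerate_crosses(sprintf("x%02d", 1:n))), n * (n - 1) / 2)

  acc <- sprintf("x%03d", 1:300)
  grp <- setNames(rep(c("old", "new"), c(143, 157)), acc)
  cr <- enumerate_crosses(acc, grp)
  expect_equal(sum(cr$within & cr$scope == "old"), 143 * 142 / 2)
  expect_equal(sum(cr$within & cr$scope == "new"), 157 * 156 / 2)
  expect_equal(sum(!cr$within), 143 * 157)
  # unordered pairs appear once
  expect_false(any(duplicated(paste(pmin(cr$p1, cr$p2), pmax(cr$p1, cr$p2)))))
  expect_error(enumerate_crosses("a"), "two accessions")
})

test_that("progeny simulation respects parental identity and tight linkage", {
  loci <- data.frame(chrom = c("c1", "c1", "c2"), pos_cM = c(10, 10, 50))
  cfg <- progeny_sim_config(n_progeny = 300, model = "linkage", seed = 1)
  # identical parents -> all progeny identical
  set.seed(1)
  pr <- simulate_progeny(c(1L, 2L, 1L), c(1L, 2L, 1L), loci, cfg)
  expect_true(all(pr == rep(c(1L, 2L, 1L), each = 300)))
  # loci at the same cM position co-segregate always
  set.seed(2)
  pr2 <- simulate_progeny(c(1L, 1L, 1L), c(2L, 2L, 2L), loci, cfg)
  expect_true(all(pr2[, 1] == pr2[, 2]))
  # segregating locus allele frequency ~ 1/2 (3-SE binomial band)
  cfg2 <- progeny_sim_config(n_progeny = 2000, model = "linkage", seed = 3)
  set.seed(3)
  pr3 <- simulate_progeny(c(1L, 1L, 1L), c(2L, 2L, 2L), loci, cfg2)
  for (j in 1:3) {
    f <- mean(pr3[, j] == 2L)
    expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 2000))
  }
})

test_that("linkage simulator reproduces Haldane recombination at 20 cM", {
  loci <- data.frame(chrom = c("c1", "c1"), pos_cM = c(10, 30))
  cfg <- progeny_sim_config(n_progeny = 50000, model = "linkage", seed = 5)
  set.seed(5)
  pr <- simulate_progeny(c(1L, 1L), c(2L, 2L), loci, cfg,
                         chrom_len = c(c1 = 60))
  rf <- mean(pr[, 1] != pr[, 2])
  r_hald <- (1 - exp(-2 * 20 / 100)) / 2       # 0.16484
  expect_lt(abs(rf - r_hald), 3 * sqrt(r_hald * (1 - r_hald) / 50000))
  # RIL model inflates effective recombination to 2r/(1+2r)
  cfg_ril <- progeny_sim_config(n_progeny = 50000, model = "linkage",
                                progeny_model = "ril", seed = 6)
  set.seed(6)
  pr_ril <- simulate_progeny(c(1L, 1L), c(2L, 2L), loci, cfg_ril,
                             chrom_len = c(c1 = 60))
  R <- 2 * r_hald / (1 + 2 * r_hald)
  rf_ril <- mean(pr_ril[, 1] != pr_ril[, 2])
  expect_lt(abs(rf_ril - R), 3 * sqrt(R * (1 - R) / 50000))
})

test_that("progeny values follow the additive model and its enumeration", {
  effects <- list(ldbA = c(-1, 1), ldbB = c(1, -1))
  codes <- rbind(c(1L, 2L), c(1L, 2L))
  colnames(codes) <- c("P1", "P2")
  mod <- make_fake_model(effects, codes, intercept = 40,
                         chrom = c("c1", "c2"))
  # 2-locus toy: the four possible homozygous progeny values by hand
  prog <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  expect_equal(predict_value(prog, mod),
               c(40 - 1 + 1, 40 - 1 - 1, 40 + 1 + 1, 40 + 1 - 1))
  # progeny equal to parent P1 -> P1's genotypic prediction
  expect_equal(predict_value(matrix(codes[, "P1"], 1), mod), 40)
  # all-zero effects -> always the intercept
  mod0 <- make_fake_model(list(ldbA = c(0, 0), ldbB = c(0, 0)), codes,
                          intercept = 40)
  expect_equal(predict_value(prog, mod0), rep(40, 4))
  expect_error(predict_value(rbind(c(3L, 1L)), mod), "unknown allele")
})

test_that("percentile rule is linear interpolation of order statistics", {
  effects <- list(ldbA = c(0, 0))
  codes <- rbind(c(1L, 1L)); colnames(codes) <- c("P1", "P2")
  mod <- make_fake_model(effects, codes)
  # values 1..100 -> P95 at position 1 + 99 * 0.95 = 95.05
  expect_equal(unname(stats::quantile(1:100, 0.95, type = 7)), 95.05)
  # selfing-like identical parents -> SD 0, all percentiles at parent value
  cfg <- progeny_sim_config(n_progeny = 100, model = "independent", seed = 2)
  cp <- cross_potential("P1", "P2", mod, cfg,
                        observed = c(P1 = 40, P2 = 40))
  expect_equal(cp$sd, 0)
  expect_equal(cp$p95, mod$intercept)
  expect_equal(cp$min, cp$max)
})

test_that("independent-model P95 matches brute-force enumeration", {
  # two unlinked loci, effects +/-1, parents fully complementary:
  # progeny values {-2, 0, 0, 2} each with probability 1/4; the population
  # 95th percentile is 2 because the top outcome holds probability 0.25 >> 0.05
  effects <- list(ldbA = c(-1, 1), ldbB = c(-1, 1))
  codes <- rbind(c(1L, 2L), c(2L, 1L))
  colnames(codes) <- c("P1", "P2")
  mod <- make_fake_model(effects, codes, intercept = 0,
                         chrom = c("c1", "c2"))
  enum_vals <- c(-2, 0, 0, 2)                     # enumeration oracle
  q_enum <- unname(stats::quantile(rep(enum_vals, 500), 0.95, type = 7))
  cfg <- progeny_sim_config(n_progeny = 2000, model = "independent", seed = 4)
  cp <- cross_potential("P1", "P2", mod, cfg)
  expect_equal(cp$p95, q_enum, tolerance = 1e-8)
  expect_equal(cp$max, 2)
  expect_lt(abs(cp$mean - 0), 3 * sqrt(2 / 2000))  # var = 2 per progeny
  # linkage and independent models agree for loci on distinct chromosomes
  cfgL <- progeny_sim_config(n_progeny = 2000, model = "linkage", seed = 4)
  cpL <- cross_potential("P1", "P2", mod, cfgL, chrom_len = c(c1 = 100, c2 = 100))
  expect_equal(cpL$p95, cp$p95, tolerance = 1e-8)
  expect_lt(abs(cpL$mean - cp$mean), 4 * sqrt(2 / 1000))
})

test_that("cross scoring is order-invariant, capped and rankable", {
  set.seed(10)
  n_par <- 8
  codes <- rbind(sample(1:2, n_par, TRUE), sample(1:3, n_par, TRUE),
                 sample(1:2, n_par, TRUE))
  colnames(codes) <- sprintf("P%02d", 1:n_par)
  effects <- list(ldbA = c(-0.8, 0.8), ldbB = c(-0.5, 0, 0.5),
                  ldbC = c(0.3, -0.3))
  mod <- make_fake_model(effects, codes, intercept = 40,
                         chrom = c("c1", "c1", "c2"), pos_cM = c(10, 40, 20))
  obs <- setNames(40 + rnorm(n_par, 0, 0.5), colnames(codes))
  grp <- setNames(rep(c("A", "B"), each = 4), colnames(codes))
  cfg <- progeny_sim_config(n_progeny = 400, model = "linkage", seed = 7)
  recs <- cross_potential_all(mod, cfg, observed = obs, groups = grp,
                              chrom_len = c(c1 = 100, c2 = 100))
  expect_equal(nrow(recs), n_par * (n_par - 1) / 2)
  # per-cross seeding: scoring a single cross reproduces the batch row
  one <- cross_potential(recs$p1[5], recs$p2[5], mod, cfg, observed = obs,
                         chrom_len = c(c1 = 100, c2 = 100))
  expect_equal(one$p95, recs$p95[5])
  # percentile monotonicity within each record
  expect_true(all(recs$min <= recs$p90 & recs$p90 <= recs$p95 &
                    recs$p95 <= recs$p99 & recs$p99 <= recs$max))
  # P95 bounded by the best-possible progeny (per-locus max parental effect)
  for (i in seq_len(nrow(recs))) {
    ub <- mod$intercept + sum(vapply(seq_len(3), function(l)
      max(effects[[l]][codes[l, c(recs$p1[i], recs$p2[i])]]), numeric(1)))
    expect_lte(recs$p95[i], ub + 1e-9)
  }
  # ranking: descending percentile, deterministic under permutation
  rk <- rank_optimal(recs, "entire", top_k = 3)
  expect_equal(rk$p95, sort(recs$p95, decreasing = TRUE)[1:3])
  recs_perm <- recs[sample(nrow(recs)), ]
  rk2 <- rank_optimal(recs_perm, "entire", top_k = 3)
  expect_equal(rk2$p1, rk$p1)
  expect_equal(rk2$p2, rk$p2)
  # top_k beyond the available crosses returns everything
  expect_equal(nrow(rank_optimal(recs, "A", top_k = 99)), sum(recs$scope == "A"))

  # scope summaries: arithmetic of potentials
  gmax <- tapply(obs, grp, max)
  pot <- summarize_potentials(recs, mean(obs), gmax)
  ent <- pot[pot$scope == "entire", ]
  expect_equal(ent$n_crosses, nrow(recs))
  expect_equal(ent$recomb_potential, mean(recs$p95) - mean(obs))
  expect_equal(ent$max_recomb_potential, max(recs$p95) - mean(obs))
  expect_equal(ent$transgressive_potential, max(recs$p95) - max(obs))
  expect_equal(ent$n_superior, sum(recs$p95 > max(obs)))
})
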