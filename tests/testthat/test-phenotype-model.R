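# brute-force balanced two-environment randomized-block sums of squares,
# written directly from the textbook decomposition (independent of aov)
brute_ss <- function(d) {
  gm <- mean(d$value)
  envs <- unique(d$environment); accs <- unique(d$accession)
  reps <- unique(d$replication)
  n_t <- length(envs); n_r <- length(reps); n_g <- length(accs)
  m_env <- as.numeric(tapply(d$value, d$environment, mean))
  m_acc <- as.numeric(tapply(d$value, d$accession, mean))
  m_cell <- tapply(d$value, list(d$accession, d$environment), mean)
  m_rep <- tapply(d$value, list(d$environment, d$replication), mean)
  ss_env <- n_r * n_g * sum((m_env - gm)^2)
  ss_rep <- n_g * sum((m_rep - rep(m_env, n_r))^2)
  ss_gen <- n_t * n_r * sum((m_acc - gm)^2)
  ss_ge <- n_r * sum((t(t(m_cell) - m_env) - (m_acc - gm))^2)
  ss_tot <- sum((d$value - gm)^2)
  c(environment = ss_env, rep_in_env = ss_rep, genotype = ss_gen,
    gxe = ss_ge, error = ss_tot - ss_env - ss_rep - ss_gen - ss_ge,
    total = ss_tot)
}

make_balanced <- function(n_g, n_t = 2, n_r = 2, sg = 1, sgt = 0, se = 1,
                          mu = 10, seed = 1) {
  set.seed(seed)
  g <- rnorm(n_g, 0, sg)
  t_ <- rnorm(n_t, 0, 0.5)
  gt <- matrix(rnorm(n_g * n_t, 0, sgt), n_g, n_t)
  d <- expand.grid(accession = sprintf("g%02d", 1:n_g),
                   environment = sprintf("e%d", 1:n_t),
                   replication = sprintf("r%d", 1:n_r),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(d$environment, sprintf("e%d", 1:n_t))
  k <- match(d$accession, sprintf("g%02d", 1:n_g))
  d$value <- mu + t_[i] + g[k] + gt[cbind(k, i)] + rnorm(nrow(d), 0, se)
  d
}

test_that("joint ANOVA reproduces the hand-computed decomposition", {
  d <- make_balanced(n_g = 2, n_t = 2, n_r = 2, seed = 4)
  an <- fit_joint_anova(d)
  bs <- brute_ss(d)
  for (term in c("environment", "rep_in_env", "genotype", "gxe", "error"))
    expect_equal(an$ss[an$term == term], unname(bs[term]), tolerance = 1e-10)
  # component SS add to the total (balanced orthogonality)
  expect_equal(sum(an$ss), unname(bs["total"]), tolerance = 1e-8)
  expect_equal(an$df, c(1L, 2L, 1L, 1L, 2L))

  # zero genotype spread -> genotype effect not significant
  d0 <- make_balanced(n_g = 12, n_t = 2, n_r = 3, sg = 0, se = 1, seed = 8)
  an0 <- fit_joint_anova(d0)
  expect_gt(an0$p[an0$term == "genotype"], 0.05)

  # strong heritability -> genotype effect significant at 0.01
  cfgh <- sim_config(n_accessions = 80, n_chromosomes = 2,
                     n_blocks_per_chrom = 6, n_qtls = 4,
                     target_h2 = 0.83, rng_seed = 2)
  sth <- generate_population(cfgh)
  anh <- fit_joint_anova(sth$phenotypes)
  expect_lt(anh$p[anh$term == "genotype"], 0.01)
})

test_that("ANOVA variance components equal the closed-form EMS solution", {
  d <- make_balanced(n_g = 20, n_t = 2, n_r = 4, sg = 1.5, sgt = 0.8,
                     se = 2, seed = 21)
  vc <- estimate_variance_components(d, method = "anova")
  bs <- brute_ss(d)
  n_t <- 2; n_r <- 4; n_g <- 20
  ms_g <- bs[["genotype"]] / (n_g - 1)
  ms_gt <- bs[["gxe"]] / ((n_g - 1) * (n_t - 1))
  ms_e <- bs[["error"]] / (n_t * n_g * (n_r - 1) - n_t * (n_r - 1))
  expect_equal(vc$sigma_e2, ms_e, tolerance = 1e-8)
  expect_equal(vc$sigma_gt2, max(0, (ms_gt - ms_e) / n_r), tolerance = 1e-8)
  expect_equal(vc$sigma_g2, max(0, (ms_g - ms_gt) / (n_t * n_r)), tolerance = 1e-8)
})

test_that("REML recovers planted variance components within 20% at n = 300", {
  d <- make_balanced(n_g = 300, n_t = 2, n_r = 4, sg = sqrt(2), sgt = 1,
                     se = 2, seed = 31)
  vc <- estimate_variance_components(d, method = "reml")
  expect_lt(abs(vc$sigma_g2 - 2) / 2, 0.20)
  expect_lt(abs(vc$sigma_gt2 - 1) / 1, 0.20)
  expect_lt(abs(vc$sigma_e2 - 4) / 4, 0.20)
  # pure noise -> genotypic variance near zero
  dn <- make_balanced(n_g = 100, n_t = 2, n_r = 4, sg = 0, se = 1, seed = 32)
  vcn <- estimate_variance_components(dn)
  expect_lt(vcn$sigma_g2, 0.05)
})

test_that("heritability and GCV follow their plug-in formulas", {
  vc <- structure(list(sigma_g2 = 2, sigma_gt2 = 1, sigma_e2 = 4,
                       n_t = 2, n_r = 4, mu = 40, method = "anova"),
                  class = "variance_components")
  expect_equal(heritability(vc, "multi"), 2 / (2 + 0.5 + 0.5))
  expect_equal(heritability(vc, "single"), 2 / (2 + 1))
  expect_equal(heritability(vc, "gei"), 0.5 / 3)
  vc1 <- vc; vc1$sigma_g2 <- 1; vc1$sigma_e2 <- 0; vc1$sigma_gt2 <- 0
  expect_equal(heritability(vc1, "multi"), 1)
  # monotone in sigma_g2
  h <- vapply(c(0.5, 1, 2, 4), function(s) {
    v <- vc; v$sigma_g2 <- s; heritability(v, "multi")
  }, numeric(1))
  expect_true(all(diff(h) > 0))
  # GCV: 100 * sqrt(1.96) / 40.77 = 3.434
  vg <- vc; vg$sigma_g2 <- 1.96; vg$mu <- 40.77
  expect_equal(gcv(vg), 100 * 1.4 / 40.77, tolerance = 1e-12)
  vg2 <- vg; vg2$mu <- 2 * 40.77
  expect_equal(gcv(vg2), gcv(vg) / 2)
  vg$sigma_g2 <- 0
  expect_equal(gcv(vg), 0)
  vz <- vc; vz$sigma_g2 <- vz$sigma_gt2 <- vz$sigma_e2 <- 0
  expect_error(heritability(vz), "undefined")
  vm <- vc; vm$mu <- 0
  expect_error(gcv(vm), "positive")
})

test_that("maturity-group summaries bin, count and letter correctly", {
  # single group -> letter "a"
  d1 <- make_balanced(n_g = 10, seed = 5)
  mg1 <- setNames(rep("I", 10), sprintf("g%02d", 1:10))
  s1 <- summarize_by_mg(d1, mg1)
  expect_equal(nrow(s1$summary), 1L)
  expect_equal(s1$summary$letter, "a")
  expect_equal(sum(s1$summary$n), 10L)

  # groups with identical values share a letter
  d2 <- expand.grid(accession = sprintf("g%02d", 1:20),
                    environment = c("e1", "e2"), replication = c("r1", "r2"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(6)
  base <- rep(rnorm(10), 2)   # the two groups carry identical value sets
  d2$value <- 10 + base[match(d2$accession, sprintf("g%02d", 1:20))]
  mg2 <- setNames(rep(c("A", "B"), each = 10), sprintf("g%02d", 1:20))
  s2 <- summarize_by_mg(d2, mg2)
  expect_equal(s2$summary$letter[1], s2$summary$letter[2])

  # 1-SD mean offset at n = 50 per group -> distinct letters
  set.seed(7)
  vals <- c(rnorm(50, 10, 1), rnorm(50, 11, 1))
  d3 <- expand.grid(accession = sprintf("g%03d", 1:100),
                    environment = c("e1", "e2"), replication = c("r1", "r2"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d3$value <- vals[match(d3$accession, sprintf("g%03d", 1:100))]
  mg3 <- setNames(rep(c("old", "new"), each = 50), sprintf("g%03d", 1:100))
  s3 <- summarize_by_mg(d3, mg3)
  expect_false(s3$summary$letter[1] == s3$summary$letter[2])
  # group sizes sum to the panel, bins count every accession
  expect_equal(sum(s3$summary$n), 100L)
  expect_equal(sum(s3$bins), 100L)

  expect_error(summarize_by_mg(d1, mg1[-1]), "maturity-group label")
})
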