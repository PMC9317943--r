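#' Validate plot-level phenotype records
#'
#' A phenotype table has one row per plot: columns `accession`, `environment`,
#' `replication`, `value`, following the randomized-block model
#' y_ijk = mu + t_i + r_j(i) + g_k + (gt)_ik + e_ijk with environments,
#' replications-within-environment, genotype-by-environment interaction and
#' error random and the accession effect fixed.
#'
#' @param records data frame with the four columns above.
#' @return The records, with factors coerced, invisibly checked for balance;
#'   attribute `balanced` is TRUE when every accession x environment cell has
#'   the same replication count.
#' @export
phenotype_records <- function(records) {
  need <- c("accession", "environment", "replication", "value")
  if (!all(need %in% names(records))) stop("columns required: ", paste(need, collapse = ", "))
  if (!all(is.finite(records$value))) stop("phenotype values must be finite")
  records$accession <- factor(records$accession)
  records$environment <- factor(records$environment)
  records$replication <- factor(records$replication)
  cells <- table(records$accession, records$environment)
  attr(records, "balanced") <- length(unique(as.vector(cells))) == 1L
  records
}

#' Joint randomized-block analysis of variance over environments
#'
#' Fits the fixed-effects decomposition of the joint model by least squares
#' and returns the ANOVA table for environment, replication within
#' environment, genotype, genotype-by-environment and error. Sums of squares
#' are sequential, which in the balanced case equals the orthogonal
#' decomposition. F tests use expected mean squares for a model with genotype
#' fixed and the remaining effects random: genotype and environment are tested
#' against the genotype-by-environment mean square, the rest against error.
#'
#' @param records a phenotype table (see [phenotype_records()]).
#' @return Data frame with rows environment, rep_in_env, genotype, gxe,
#'   error and columns df, ss, ms, f, p.
#' @export
fit_joint_anova <- function(records) {
  records <- phenotype_records(records)
  if (nlevels(records$environment) < 2L) stop("need >= 2 environments")
  if (nlevels(records$replication) < 2L) stop("need >= 2 replications")
  if (!attr(records, "balanced"))
    warning("unbalanced design: sequential sums of squares are approximate")
  fit <- stats::aov(value ~ environment + environment:replication +
                      accession + accession:environment, data = records)
  an <- stats::anova(fit)
  rn <- rownames(an)
  pick <- function(nm) which(rn == nm)
  out <- data.frame(
    term = c("environment", "rep_in_env", "genotype", "gxe", "error"),
    df = c(an$Df[pick("environment")], an$Df[pick("environment:replication")],
           an$Df[pick("accession")], an$Df[pick("environment:accession")],
           an$Df[pick("Residuals")]),
    ss = c(an$`Sum Sq`[pick("environment")], an$`Sum Sq`[pick("environment:replication")],
           an$`Sum Sq`[pick("accession")], an$`Sum Sq`[pick("environment:accession")],
           an$`Sum Sq`[pick("Residuals")]))
  out$ms <- out$ss / out$df
  ms_e <- out$ms[out$term == "error"]
  ms_ge <- out$ms[out$term == "gxe"]
  denom <- c(ms_ge, ms_e, ms_ge, ms_e, NA)
  denom_df <- c(out$df[out$term == "gxe"], out$df[out$term == "error"],
                out$df[out$term == "gxe"], out$df[out$term == "error"], NA)
  out$f <- out$ms / denom
  out$p <- stats::pf(out$f, out$df, denom_df, lower.tail = FALSE)
  out$f[out$term == "error"] <- NA
  out$p[out$term == "error"] <- NA
  out
}

#' Estimate variance components of the joint model
#'
#' Estimates the genotypic variance, genotype-by-environment variance and
#' error variance of the randomized-block model over environments, treating
#' accession, accession-by-environment, environment and
#' replication-within-environment as random.
#'
#' `method = "reml"` fits the mixed model by REML (via \pkg{lme4});
#' `method = "anova"` solves the balanced expected-mean-square equations in
#' closed form (MS_G = s2 + n_r s2_gt + n_t n_r s2_g; MS_GT = s2 + n_r s2_gt;
#' MS_E = s2). Negative solutions are truncated at zero. If REML fails the
#' ANOVA solution is returned with a warning.
#'
#' @param records a phenotype table (see [phenotype_records()]).
#' @param method `"reml"` (default) or `"anova"`.
#' @return An object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_gt2`, `sigma_e2`, `n_t` (environments), `n_r` (replications per
#'   environment; harmonic mean if unbalanced), `mu` (grand mean), `method`.
#' @export
estimate_variance_components <- function(records, method = c("reml", "anova")) {
  method <- match.arg(method)
  records <- phenotype_records(records)
  n_t <- nlevels(records$environment)
  cells <- table(records$accession, records$environment)
  n_r <- if (attr(records, "balanced")) as.vector(cells)[1L] else
    1 / mean(1 / as.vector(cells)[as.vector(cells) > 0])
  mu <- mean(records$value)
  vc_anova <- function() {
    an <- suppressWarnings(fit_joint_anova(records))
    ms <- stats::setNames(an$ms, an$term)
    s2 <- ms[["error"]]
    s2_gt <- max(0, (ms[["gxe"]] - s2) / n_r)
    s2_g <- max(0, (ms[["genotype"]] - ms[["gxe"]]) / (n_t * n_r))
    c(s2_g, s2_gt, s2)
  }
  est <- if (method == "anova") vc_anova() else {
    fit <- tryCatch(
      lme4::lmer(value ~ 1 + (1 | environment) + (1 | environment:replication) +
                   (1 | accession) + (1 | accession:environment),
                 data = records,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("REML fit failed; falling back to ANOVA estimators")
      method <- "anova"
      vc_anova()
    } else {
      vc <- as.data.frame(lme4::VarCorr(fit))
      get1 <- function(g) {
        v <- vc$vcov[vc$grp == g]
        if (length(v) == 0L) 0 else v
      }
      c(get1("accession"), get1("accession:environment"), get1("Residual"))
    }
  }
  structure(list(sigma_g2 = est[1L], sigma_gt2 = est[2L], sigma_e2 = est[3L],
                 n_t = n_t, n_r = n_r, mu = mu, method = method),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components (%s): sigma_g2 = %.4g, sigma_gt2 = %.4g, sigma_e2 = %.4g\n",
              x$method, x$sigma_g2, x$sigma_gt2, x$sigma_e2))
  cat(sprintf("  n_t = %d environments, n_r = %.3g replications, mean = %.4g\n",
              x$n_t, x$n_r, x$mu))
  invisible(x)
}

#' Entry-mean heritability from variance components
#'
#' Plug-in heritability on an entry-mean basis. `scope = "single"` gives the
#' single-environment form s2_g / (s2_g + s2_e / n_r); `scope = "multi"` the
#' multi-environment form s2_g / (s2_g + s2_gt / n_t + s2_e / (n_t n_r));
#' `scope = "gei"` the genotype-by-environment share of the same entry-mean
#' denominator, (s2_gt / n_t) / (s2_g + s2_gt / n_t + s2_e / (n_t n_r)).
#'
#' @param vc a [estimate_variance_components()] result.
#' @param scope `"multi"` (default), `"single"` or `"gei"`.
#' @return A fraction in \[0, 1\].
#' @export
heritability <- function(vc, scope = c("multi", "single", "gei")) {
  scope <- match.arg(scope)
  stopifnot(inherits(vc, "variance_components"))
  with(vc, {
    if (sigma_g2 == 0 && sigma_gt2 == 0 && sigma_e2 == 0)
      stop("heritability undefined: all variance components are zero")
    switch(scope,
      single = sigma_g2 / (sigma_g2 + sigma_e2 / n_r),
      multi = sigma_g2 / (sigma_g2 + sigma_gt2 / n_t + sigma_e2 / (n_t * n_r)),
      gei = (sigma_gt2 / n_t) /
        (sigma_g2 + sigma_gt2 / n_t + sigma_e2 / (n_t * n_r)))
  })
}

#' Genetic coefficient of variation
#'
#' GCV = 100 * sigma_g / mu, in percent of the population mean.
#'
#' @param vc a [estimate_variance_components()] result.
#' @return Percentage.
#' @export
gcv <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$mu <= 0) stop("GCV requires a positive population mean")
  100 * sqrt(vc$sigma_g2) / vc$mu
}

#' Descriptive statistics of accession means by maturity group
#'
#' Summarizes accession means (over environments and replications) per
#' maturity group: group size, mean, range, a frequency distribution over
#' 1-unit bins centered on integers, and mean-comparison letters from
#' Fisher's LSD at `alpha` on the one-way ANOVA of accession means by group
#' (groups sharing a letter do not differ significantly).
#'
#' @param records a phenotype table (see [phenotype_records()]).
#' @param mg named character/factor vector: maturity group per accession.
#' @param alpha significance level for the LSD letters (default 0.05).
#' @return List with `summary` (data frame: group, n, mean, min, max,
#'   letter) and `bins` (group x bin-midpoint count matrix).
#' @export
summarize_by_mg <- function(records, mg, alpha = 0.05) {
  records <- phenotype_records(records)
  acc_means <- tapply(records$value, records$accession, mean)
  accs <- names(acc_means)
  if (!all(accs %in% names(mg))) stop("every accession needs a maturity-group label")
  grp <- factor(mg[accs], levels = unique(mg[accs]))
  means <- tapply(acc_means, grp, mean)
  ns <- as.vector(table(grp))
  mids <- seq(floor(min(acc_means) + 0.5), ceiling(max(acc_means) - 0.5))
  if (length(mids) == 0L) mids <- round(mean(acc_means))
  bins <- t(vapply(levels(grp), function(g) {
    v <- acc_means[grp == g]
    vapply(mids, function(m) sum(v >= m - 0.5 & v < m + 0.5), integer(1))
  }, integer(length(mids))))
  colnames(bins) <- mids
  letters_ <- if (nlevels(grp) == 1L) "a" else
    lsd_letters(acc_means, grp, alpha = alpha)
  out <- data.frame(group = levels(grp), n = ns,
                    mean = as.vector(means),
                    min = as.vector(tapply(acc_means, grp, min)),
                    max = as.vector(tapply(acc_means, grp, max)),
                    letter = letters_, stringsAsFactors = FALSE)
  list(summary = out, bins = bins)
}

# Fisher's LSD grouping letters: pairwise t tests on group means with the
# pooled one-way-ANOVA error, no multiplicity adjustment; letters mark
# maximal runs (in decreasing-mean order) with no significant pair inside.
lsd_letters <- function(values, grp, alpha = 0.05) {
  fit <- stats::aov(values ~ grp)
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  dfe <- stats::df.residual(fit)
  means <- tapply(values, grp, mean)
  ns <- as.vector(table(grp))
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- ord[i]; b <- ord[j]
    se <- sqrt(mse * (1 / ns[a] + 1 / ns[b]))
    tt <- abs(means[a] - means[b]) / se
    sig[i, j] <- sig[j, i] <- 2 * stats::pt(tt, dfe, lower.tail = FALSE) <= alpha
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1L), i:(j + 1L)])) j <- j + 1L
    runs[[length(runs) + 1L]] <- i:j
  }
  runs <- runs[!vapply(seq_along(runs), function(r) any(vapply(runs[-r], function(s)
    all(runs[[r]] %in% s), logical(1))), logical(1))]
  lab <- character(k)
  for (r in seq_along(runs)) {
    lab[runs[[r]]] <- paste0(lab[runs[[r]]], letters[r])
  }
  out <- character(k)
  out[ord] <- lab
  stats::setNames(out, names(means))[levels(grp)]
}
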