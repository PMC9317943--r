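#' Genetic similarity coefficients and structure covariates
#'
#' The genetic similarity coefficient (GSC) between two accessions is the
#' fraction of SNPLDB markers at which they carry the same allele. The
#' eigen-decomposition of the GSC matrix supplies population-structure
#' covariates: the top eigenvectors play the role principal components play
#' in SNP-based GWAS, but computed from multi-allelic marker identity.
#'
#' @param snpldb an `snpldb_set` (see [assemble_snpldb()]).
#' @param n_eigenvectors how many leading eigenvectors to expose as
#'   covariates (default 10).
#' @return List of class `structure_covariates`: `gsc` (n x n similarity
#'   matrix, unit diagonal), `eigenvalues` (decreasing), `vectors` (n x
#'   `n_eigenvectors` matrix, rownames = accessions).
#' @export
compute_gsc <- function(snpldb, n_eigenvectors = 10) {
  stopifnot(inherits(snpldb, "snpldb_set"))
  codes <- snpldb$codes
  if (anyNA(codes)) stop("accessions with missing allele codes")
  n <- ncol(codes)
  m <- nrow(codes)
  if (n < 2L || m < 1L) stop("need >= 2 accessions and >= 1 marker")
  G <- matrix(0, n, n)
  chunk <- 400L
  for (st in seq(1L, m, by = chunk)) {
    rows <- st:min(st + chunk - 1L, m)
    kk <- snpldb$markers$n_alleles[rows]
    X <- matrix(0, n, sum(kk))
    off <- 0L
    for (i in seq_along(rows)) {
      cc <- codes[rows[i], ]
      X[cbind(seq_len(n), off + cc)] <- 1
      off <- off + kk[i]
    }
    G <- G + tcrossprod(X)
  }
  G <- G / m
  dimnames(G) <- list(colnames(codes), colnames(codes))
  ed <- eigen(G, symmetric = TRUE)
  k <- min(n_eigenvectors, n)
  vec <- ed$vectors[, seq_len(k), drop = FALSE]
  rownames(vec) <- colnames(codes)
  structure(list(gsc = G, eigenvalues = ed$values, vectors = vec),
            class = "structure_covariates")
}

#' Accession-by-environment phenotype means
#'
#' Averages plot values over replications, giving one row per accession and
#' environment — the phenotype input to the association scan.
#'
#' @param records a phenotype table (see [phenotype_records()]).
#' @return Data frame with columns `accession`, `environment`, `value`.
#' @export
accession_env_means <- function(records) {
  records <- phenotype_records(records)
  ag <- stats::aggregate(value ~ accession + environment, data = records, FUN = mean)
  ag$accession <- as.character(ag$accession)
  ag$environment <- as.character(ag$environment)
  ag[order(ag$accession, ag$environment), ]
}

# Internal: shared design-matrix context for the two GWAS stages.
# Rows are accession x environment means; base columns are intercept,
# environment factor and structure eigenvectors.
gwas_context <- function(pheno_means, snpldb, covariates) {
  accs <- snpldb$accessions
  pm <- pheno_means[pheno_means$accession %in% accs, ]
  if (length(unique(pm$accession)) != length(accs))
    stop("phenotype means must cover every genotyped accession")
  acc <- factor(pm$accession, levels = accs)
  env <- factor(pm$environment)
  y <- pm$value
  ev <- covariates$vectors[as.integer(acc), , drop = FALSE]
  Xbase <- cbind(`(Intercept)` = 1,
                 if (nlevels(env) > 1L) stats::model.matrix(~env)[, -1L, drop = FALSE],
                 ev)
  list(y = y, acc = acc, env = env, n_t = nlevels(env), Xbase = Xbase,
       acc_idx = as.integer(acc))
}

# Internal: main-effect columns for one marker (alleles 2..k treatment-coded,
# allele 1 = most frequent = reference) and QEI columns (allele indicator x
# environment sum-contrast, alleles 2..k).
marker_columns <- function(ctx, codes_row, n_alleles) {
  k <- n_alleles
  ind <- matrix(0, length(ctx$y), max(k - 1L, 0L))
  if (k >= 2L) for (a in 2L:k)
    ind[, a - 1L] <- as.numeric(codes_row[ctx$acc_idx] == a)
  main <- ind
  qei <- NULL
  if (ctx$n_t > 1L && k >= 2L) {
    cf <- stats::contr.sum(ctx$n_t)[as.integer(ctx$env), , drop = FALSE]
    qei <- do.call(cbind, lapply(seq_len(k - 1L), function(j) ind[, j] * cf))
  }
  list(main = main, qei = qei)
}

# Internal: residual sum of squares and rank of a least-squares fit.
rss_rank <- function(X, y) {
  f <- stats::lm.fit(X, y)
  list(rss = sum(f$residuals^2), rank = f$rank)
}

#' Stage-1 single-locus preselection scan
#'
#' Tests each SNPLDB marker with a joint F test of its allele main effect and
#' allele-by-environment interaction against the covariate-only model
#' (intercept + environment + structure eigenvectors). Markers with
#' p <= `alpha` are preselected for the multi-locus stage. Markers whose
#' columns add no rank beyond the covariates are skipped with a warning.
#'
#' @param pheno_means accession-by-environment means
#'   (see [accession_env_means()]).
#' @param snpldb an `snpldb_set`.
#' @param covariates a [compute_gsc()] result.
#' @param alpha preselection threshold (default 0.05).
#' @param include_qei include allele-by-environment columns in the stage-1
#'   test (default TRUE, so interaction-only loci can survive).
#' @return Data frame (`marker`, `p`, `preselected`) for all markers, with
#'   preselected markers flagged.
#' @export
stage1_scan <- function(pheno_means, snpldb, covariates, alpha = 0.05,
                        include_qei = TRUE) {
  ctx <- gwas_context(pheno_means, snpldb, covariates)
  base <- rss_rank(ctx$Xbase, ctx$y)
  n <- length(ctx$y)
  m <- nrow(snpldb$markers)
  pvals <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    mc <- marker_columns(ctx, snpldb$codes[i, ], snpldb$markers$n_alleles[i])
    Xm <- cbind(ctx$Xbase, mc$main, if (include_qei) mc$qei)
    full <- rss_rank(Xm, ctx$y)
    df1 <- full$rank - base$rank
    df2 <- n - full$rank
    if (df1 < 1L || df2 < 1L) {
      warning("marker ", snpldb$markers$id[i], " collinear with covariates; skipped")
      next
    }
    Fv <- ((base$rss - full$rss) / df1) / (full$rss / df2)
    pvals[i] <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  data.frame(marker = snpldb$markers$id, p = pvals,
             preselected = !is.na(pvals) & pvals <= alpha,
             stringsAsFactors = FALSE)
}

#' Fit the restricted two-stage multi-locus association model
#'
#' The central fitting function. Stage 1 preselects SNPLDB markers by a
#' single-locus joint F test at `alpha1`; stage 2 runs forward-backward
#' stepwise selection over the preselected markers' allele main-effect and
#' allele-by-environment (QEI) terms at `alpha2`, with the trait heritability
#' `h2_cap` as the upper bound on the total phenotypic variance the selected
#' QTL terms may explain — a term whose entry would push the QTL contribution
#' past the cap is not admitted. Forward ties are broken by the larger
#' partial F, then the smaller genomic coordinate. The final joint fit gives
#' allele effects (reported as frequency-weighted zero-mean deviations per
#' locus, so the intercept is the population mean), per-term R2 (sequential
#' in selection order, which telescopes exactly to the joint QTL R2) and
#' drop-one (Type-III style) p values.
#'
#' @param records plot-level phenotype table, or precomputed
#'   accession-by-environment means (data frame with columns `accession`,
#'   `environment`, `value`).
#' @param snpldb an `snpldb_set`.
#' @param h2_cap heritability cap on total QTL contribution, in (0, 1\];
#'   typically the entry-mean [heritability()] of the trait.
#' @param alpha1,alpha2 stage thresholds (defaults 0.05, 0.01).
#' @param n_eigenvectors structure eigenvectors used as covariates
#'   (default 10).
#' @param include_qei admit QEI candidate terms (default TRUE).
#' @param covariates optionally a precomputed [compute_gsc()] result.
#' @param max_steps safety bound on forward steps (default 200).
#' @return An object of class `rtm_gwas`; see [summary.rtm_gwas()]. Key
#'   elements: `loci` (per-locus table: id, chrom, position, allele count,
#'   -log10 p for model/main/QEI, R2 main/QEI in percent), `effects` (per
#'   locus, data frame of allele codes, frequencies and centered main
#'   effects), `qei_effects`, `intercept` (population mean), `r2_qtl_total`,
#'   `h2_cap`, `stage1`.
#' @export
rtm_gwas <- function(records, snpldb, h2_cap, alpha1 = 0.05, alpha2 = 0.01,
                     n_eigenvectors = 10, include_qei = TRUE,
                     covariates = NULL, max_steps = 200L) {
  stopifnot(inherits(snpldb, "snpldb_set"), h2_cap > 0, h2_cap <= 1)
  pheno_means <- if (all(c("replication", "value") %in% names(records)))
    accession_env_means(records) else records
  if (is.null(covariates)) covariates <- compute_gsc(snpldb, n_eigenvectors)
  ctx <- gwas_context(pheno_means, snpldb, covariates)
  y <- ctx$y
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  s1 <- stage1_scan(pheno_means, snpldb, covariates, alpha = alpha1,
                    include_qei = include_qei)
  pre <- which(s1$preselected)

  # candidate terms: one main + (optionally) one QEI term per preselected marker
  cand <- list()
  for (i in pre) {
    mc <- marker_columns(ctx, snpldb$codes[i, ], snpldb$markers$n_alleles[i])
    ord_key <- snpldb$markers$start_bp[i]
    chrom <- snpldb$markers$chrom[i]
    if (ncol(mc$main) > 0L)
      cand[[length(cand) + 1L]] <- list(marker = i, kind = "main",
                                        cols = mc$main, chrom = chrom, pos = ord_key)
    if (include_qei && !is.null(mc$qei))
      cand[[length(cand) + 1L]] <- list(marker = i, kind = "qei",
                                        cols = mc$qei, chrom = chrom, pos = ord_key)
  }
  base <- rss_rank(ctx$Xbase, y)
  selected <- integer(0)           # indices into cand, in selection order
  cur_X <- ctx$Xbase
  cur <- base
  partial_f <- function(X0, fit0, cols) {
    fit1 <- rss_rank(cbind(X0, cols), y)
    df1 <- fit1$rank - fit0$rank
    df2 <- n - fit1$rank
    if (df1 < 1L || df2 < 1L) return(list(f = -Inf, p = 1, fit = fit1, df1 = df1))
    Fv <- ((fit0$rss - fit1$rss) / df1) / (fit1$rss / df2)
    list(f = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE), fit = fit1, df1 = df1)
  }
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    avail <- setdiff(seq_along(cand), selected)
    if (length(avail) == 0L) break
    tests <- lapply(avail, function(j) partial_f(cur_X, cur, cand[[j]]$cols))
    ps <- vapply(tests, `[[`, numeric(1), "p")
    fs <- vapply(tests, `[[`, numeric(1), "f")
    pos <- vapply(avail, function(j) cand[[j]]$pos, numeric(1))
    best <- order(ps, -fs, pos)[1L]
    if (ps[best] > alpha2) break
    # heritability cap: admit only if total QTL R2 stays within h2_cap
    new_r2 <- (base$rss - tests[[best]]$fit$rss) / tss
    if (new_r2 > h2_cap) break
    selected <- c(selected, avail[best])
    cur_X <- cbind(cur_X, cand[[avail[best]]]$cols)
    cur <- tests[[best]]
    cur <- list(rss = cur$fit$rss, rank = cur$fit$rank)
    # backward elimination at the stay threshold
    repeat {
      if (length(selected) == 0L) break
      drop_p <- vapply(seq_along(selected), function(s) {
        keep <- selected[-s]
        X0 <- ctx$Xbase
        for (j in keep) X0 <- cbind(X0, cand[[j]]$cols)
        f0 <- rss_rank(X0, y)
        pf <- partial_f(X0, f0, cand[[selected[s]]]$cols)
        pf$p
      }, numeric(1))
      worst <- which.max(drop_p)
      if (drop_p[worst] <= alpha2) break
      selected <- selected[-worst]
      cur_X <- ctx$Xbase
      for (j in selected) cur_X <- cbind(cur_X, cand[[j]]$cols)
      cur <- rss_rank(cur_X, y)
    }
  }

  finalize_rtm_gwas(ctx, snpldb, cand, selected, base, tss, h2_cap, s1,
                    include_qei, match.call())
}

# Internal: joint refit of the selected terms; effects, R2 partition, tests.
finalize_rtm_gwas <- function(ctx, snpldb, cand, selected, base, tss, h2_cap,
                              s1, include_qei, call) {
  y <- ctx$y
  n <- length(y)
  mu <- mean(y)
  # sequential R2 in selection order (telescopes to the joint QTL R2)
  seq_r2 <- numeric(length(selected))
  X <- ctx$Xbase
  prev <- base
  for (s in seq_along(selected)) {
    X <- cbind(X, cand[[selected[s]]]$cols)
    f <- rss_rank(X, y)
    seq_r2[s] <- (prev$rss - f$rss) / tss
    prev <- f
  }
  full <- prev
  r2_qtl <- if (length(selected)) (base$rss - full$rss) / tss else 0
  # joint coefficient fit for allele effects
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  col_owner <- rep(0L, ncol(ctx$Xbase))
  for (s in seq_along(selected))
    col_owner <- c(col_owner, rep(selected[s], ncol(cand[[selected[s]]]$cols)))

  loci_idx <- unique(vapply(selected, function(j) cand[[j]]$marker, integer(1)))
  loci_idx <- loci_idx[order(match(snpldb$markers$chrom[loci_idx],
                                   unique(snpldb$markers$chrom)),
                             snpldb$markers$start_bp[loci_idx])]
  drop_test <- function(terms_drop) {
    if (length(selected) == 0L) return(c(NA, NA))
    keep <- setdiff(selected, terms_drop)
    X0 <- ctx$Xbase
    for (j in keep) X0 <- cbind(X0, cand[[j]]$cols)
    f0 <- rss_rank(X0, y)
    df1 <- full$rank - f0$rank
    df2 <- n - full$rank
    if (df1 < 1L || df2 < 1L) return(c(NA, NA))
    Fv <- ((f0$rss - full$rss) / df1) / (full$rss / df2)
    c(Fv, stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }
  effects <- list(); qei_effects <- list()
  tab <- NULL
  for (li in loci_idx) {
    terms_here <- selected[vapply(selected, function(j) cand[[j]]$marker == li, logical(1))]
    kinds <- vapply(terms_here, function(j) cand[[j]]$kind, character(1))
    k <- snpldb$markers$n_alleles[li]
    freq <- snpldb$alleles[[li]]$freq
    eff <- rep(0, k)
    main_term <- terms_here[kinds == "main"]
    if (length(main_term) == 1L) {
      cols <- which(col_owner == main_term)
      cf <- coefs[cols]
      cf[is.na(cf)] <- 0
      eff[2:k] <- cf
    }
    eff <- eff - sum(freq * eff)          # frequency-weighted zero mean
    effects[[snpldb$markers$id[li]]] <-
      data.frame(code = seq_len(k), haplotype = snpldb$alleles[[li]]$haplotype,
                 freq = freq, effect = eff, stringsAsFactors = FALSE)
    qei_term <- terms_here[kinds == "qei"]
    if (length(qei_term) == 1L) {
      cols <- which(col_owner == qei_term)
      cf <- coefs[cols]
      cf[is.na(cf)] <- 0
      qei_effects[[snpldb$markers$id[li]]] <-
        matrix(cf, nrow = k - 1L, byrow = TRUE,
               dimnames = list(paste0("allele", 2:k),
                               paste0("env_contrast", seq_len(ctx$n_t - 1L))))
    }
    mt <- if (length(main_term)) drop_test(main_term) else c(NA, NA)
    qt <- if (length(qei_term)) drop_test(qei_term) else c(NA, NA)
    at <- drop_test(terms_here)
    r2_main <- if (length(main_term)) seq_r2[match(main_term, selected)] else 0
    r2_qei <- if (length(qei_term)) seq_r2[match(qei_term, selected)] else 0
    tab <- rbind(tab, data.frame(
      id = snpldb$markers$id[li], chrom = snpldb$markers$chrom[li],
      start_bp = snpldb$markers$start_bp[li], end_bp = snpldb$markers$end_bp[li],
      pos_cM = snpldb$markers$pos_cM[li], n_alleles = k,
      has_main = length(main_term) == 1L, has_qei = length(qei_term) == 1L,
      neglog10_p_model = -log10(at[2L]),
      neglog10_p_main = -log10(mt[2L]), neglog10_p_qei = -log10(qt[2L]),
      r2_main_pct = 100 * r2_main, r2_qei_pct = 100 * r2_qei,
      stringsAsFactors = FALSE))
  }
  if (is.null(tab))
    tab <- data.frame(id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      pos_cM = numeric(0), n_alleles = integer(0),
                      has_main = logical(0), has_qei = logical(0),
                      neglog10_p_model = numeric(0),
                      neglog10_p_main = numeric(0),
                      neglog10_p_qei = numeric(0),
                      r2_main_pct = numeric(0), r2_qei_pct = numeric(0),
                      stringsAsFactors = FALSE)
  structure(list(
    loci = tab, effects = effects, qei_effects = qei_effects,
    intercept = mu, r2_qtl_total = r2_qtl, h2_cap = h2_cap,
    tss = tss, n_obs = n, stage1 = s1, include_qei = include_qei,
    accessions = snpldb$accessions,
    codes = if (length(loci_idx)) snpldb$codes[loci_idx, , drop = FALSE] else
      matrix(integer(0), 0, length(snpldb$accessions),
             dimnames = list(NULL, snpldb$accessions)),
    call = call), class = "rtm_gwas")
}

#' @export
print.rtm_gwas <- function(x, ...) {
  nl <- if (is.null(x$loci)) 0L else nrow(x$loci)
  cat("rtm_gwas model:", nl, "QTL detected;",
      sprintf("QTL R2 = %.2f%% (cap %.2f%%)\n", 100 * x$r2_qtl_total, 100 * x$h2_cap))
  cat(sprintf("  stage 1 preselected %d / %d markers\n",
              sum(x$stage1$preselected), nrow(x$stage1)))
  invisible(x)
}

#' Summarize a fitted multi-locus association model
#'
#' @param object an `rtm_gwas` fit.
#' @param lc_threshold_pct large-contribution threshold on the main-effect R2
#'   in percent (default 1).
#' @param ... unused.
#' @return List with the per-locus table (with LC/SC class), counts by
#'   main/QEI configuration, and class totals.
#' @export
summary.rtm_gwas <- function(object, lc_threshold_pct = 1, ...) {
  cls <- classify_contribution(object, lc_threshold_pct)
  tab <- object$loci
  cfg <- if (is.null(tab)) c(main_only = 0L, qei_only = 0L, both = 0L) else c(
    main_only = sum(tab$has_main & !tab$has_qei),
    qei_only = sum(!tab$has_main & tab$has_qei),
    both = sum(tab$has_main & tab$has_qei))
  out <- list(loci = cls$loci, configuration = cfg, classes = cls$classes,
              r2_qtl_total = object$r2_qtl_total, h2_cap = object$h2_cap)
  class(out) <- "summary.rtm_gwas"
  out
}

#' @export
print.summary.rtm_gwas <- function(x, ...) {
  cat(sprintf("QTL total R2: %.2f%% (cap %.2f%%)\n",
              100 * x$r2_qtl_total, 100 * x$h2_cap))
  cat("configuration:", paste(names(x$configuration), x$configuration,
                              sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$classes)) print(x$classes)
  invisible(x)
}

#' Classify detected loci by phenotypic contribution
#'
#' Loci whose main-effect R2 is at least `threshold_pct` percent are labelled
#' LC (large contribution), the rest SC (small contribution).
#'
#' @param model an `rtm_gwas` fit.
#' @param threshold_pct percent phenotypic variance (default 1).
#' @return List with `loci` (per-locus table plus `class` column) and
#'   `classes` (counts and summed main R2 per class).
#' @export
classify_contribution <- function(model, threshold_pct = 1) {
  stopifnot(inherits(model, "rtm_gwas"))
  tab <- model$loci
  if (is.null(tab) || nrow(tab) == 0L) {
    return(list(loci = tab,
                classes = data.frame(class = c("LC", "SC"), n = c(0L, 0L),
                                     r2_main_pct = c(0, 0))))
  }
  tab$class <- ifelse(tab$r2_main_pct >= threshold_pct, "LC", "SC")
  classes <- data.frame(
    class = c("LC", "SC"),
    n = c(sum(tab$class == "LC"), sum(tab$class == "SC")),
    r2_main_pct = c(sum(tab$r2_main_pct[tab$class == "LC"]),
                    sum(tab$r2_main_pct[tab$class == "SC"])))
  list(loci = tab, classes = classes)
}

#' Allele main effects of a fitted model
#'
#' @param object an `rtm_gwas` fit.
#' @param ... unused.
#' @return Data frame of locus, allele code, haplotype, frequency and
#'   centered main effect.
#' @export
coef.rtm_gwas <- function(object, ...) {
  if (length(object$effects) == 0L)
    return(data.frame(locus = character(0), code = integer(0),
                      haplotype = character(0), freq = numeric(0),
                      effect = numeric(0)))
  do.call(rbind, lapply(names(object$effects), function(id)
    cbind(locus = id, object$effects[[id]], row.names = NULL)))
}

#' Build the QTL-allele matrix
#'
#' The QTL-allele matrix is the compact form of the population's genetic
#' constitution: rows are detected loci, columns accessions, entries the
#' centered main effect of the allele each accession carries. The companion
#' allele-code matrix is attached as attribute `codes`.
#'
#' @param model an `rtm_gwas` fit.
#' @param codes optional allele-code matrix (loci x accessions) to use
#'   instead of the one captured at fit time (e.g. a subpopulation's
#'   columns).
#' @return Numeric matrix loci x accessions with attribute `codes`.
#' @export
qtl_allele_matrix <- function(model, codes = NULL) {
  stopifnot(inherits(model, "rtm_gwas"))
  if (is.null(codes)) codes <- model$codes
  ids <- rownames(codes)
  if (!all(ids %in% names(model$effects) | ids %in% model$loci$id))
    stop("allele-code rows must match detected loci")
  out <- matrix(NA_real_, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  for (i in seq_len(nrow(codes))) {
    eff <- model$effects[[ids[i]]]
    cc <- codes[i, ]
    if (anyNA(cc) || any(cc > nrow(eff)))
      stop("accession missing allele code at locus ", ids[i])
    out[i, ] <- eff$effect[cc]
  }
  attr(out, "codes") <- codes
  attr(out, "intercept") <- model$intercept
  out
}

#' Predict genotypic values from allele codes
#'
#' Genotypic value of an accession = model intercept (population mean) plus
#' the sum over detected loci of the main effect of the allele carried. QEI
#' effects are not used.
#'
#' @param object an `rtm_gwas` fit.
#' @param codes allele-code matrix (loci x accessions); default the matrix
#'   captured at fit time.
#' @param ... unused.
#' @return Named numeric vector of predicted values.
#' @export
predict.rtm_gwas <- function(object, codes = NULL, ...) {
  qm <- qtl_allele_matrix(object, codes)
  object$intercept + colSums(qm)
}
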