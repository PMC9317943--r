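#' Enumerate all unordered pairwise crosses
#'
#' All n(n-1)/2 unordered parent pairs, labelled within- or between-group
#' when a grouping is supplied (e.g. maturity groups, possibly merged into
#' supergroups).
#'
#' @param accessions character vector of parent ids.
#' @param groups optional named vector: group label per accession.
#' @return Data frame with columns `p1`, `p2` and, when grouped, `g1`, `g2`
#'   and `scope` (the group name for within-group crosses, `"g1 vs g2"` for
#'   between-group crosses).
#' @export
enumerate_crosses <- function(accessions, groups = NULL) {
  accessions <- as.character(accessions)
  n <- length(accessions)
  if (n < 2L) stop("need at least two accessions")
  if (anyDuplicated(accessions)) stop("accession ids must be unique")
  idx <- utils::combn(n, 2L)
  out <- data.frame(p1 = accessions[idx[1L, ]], p2 = accessions[idx[2L, ]],
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    if (!all(accessions %in% names(groups)))
      stop("every accession needs a group label")
    g1 <- as.character(groups[out$p1])
    g2 <- as.character(groups[out$p2])
    out$g1 <- g1
    out$g2 <- g2
    out$scope <- ifelse(g1 == g2, g1,
                        paste(pmin(g1, g2), pmax(g1, g2), sep = " vs "))
    out$within <- g1 == g2
  }
  out
}

#' Progeny simulation configuration
#'
#' @param n_progeny homozygous progeny per cross (default 2000).
#' @param model `"linkage"` (Poisson crossovers along the genetic map) or
#'   `"independent"` (free assortment of all loci).
#' @param progeny_model `"doubled_gamete"` (progeny = one recombinant F1
#'   gamete doubled, as in a doubled-haploid population) or `"ril"`
#'   (recombinant inbred line by repeated selfing, with effective
#'   recombination R = 2r/(1+2r) between adjacent loci).
#' @param percentiles progeny-value percentiles to report (default 90/95/99).
#' @param seed global seed; each cross derives its own stream from the seed
#'   and the parent-pair ids, so results do not depend on enumeration order.
#' @return List of class `progeny_sim_config`.
#' @export
progeny_sim_config <- function(n_progeny = 2000, model = c("linkage", "independent"),
                               progeny_model = c("doubled_gamete", "ril"),
                               percentiles = c(90, 95, 99), seed = 1L) {
  stopifnot(n_progeny >= 1)
  structure(list(n_progeny = as.integer(n_progeny), model = match.arg(model),
                 progeny_model = match.arg(progeny_model),
                 percentiles = percentiles, seed = as.integer(seed)),
            class = "progeny_sim_config")
}

# Deterministic per-cross RNG seed from the global seed and the unordered
# parent pair (enumeration-order invariant).
cross_seed <- function(seed, p1, p2) {
  key <- paste(sort(c(p1, p2)), collapse = "|")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(seed) * 69621 + h) %% 2147483629)
}

#' Simulate homozygous progeny genotypes of one cross
#'
#' Both parents must be fully homozygous, each carrying one allele per locus.
#' Under the linkage model a single F1 gamete is formed per progeny and
#' chromosome: the crossover count is Poisson with the chromosome map length
#' in Morgans as its mean, crossover positions are uniform on the map, and
#' parental segments alternate from a fair-coin starting phase; the progeny
#' is that gamete doubled. With `progeny_model = "ril"` the effective
#' recombination fraction between adjacent loci is inflated to
#' R = 2r/(1+2r) (r from Haldane's map function) to mimic repeated selfing
#' from the F2. Under the independent model every locus takes either
#' parental allele with probability 1/2, independently.
#'
#' The caller controls the RNG state (`set.seed` before calling).
#'
#' @param parentA,parentB integer allele codes at the loci (named or in row
#'   order of `loci`).
#' @param loci data frame with columns `chrom` and `pos_cM` (required for
#'   the linkage model).
#' @param config a [progeny_sim_config()].
#' @param chrom_len optional named vector of chromosome map lengths (cM);
#'   defaults to the furthest locus position + 25 cM per chromosome.
#' @return Integer matrix `n_progeny` x n loci of progeny allele codes.
#' @export
simulate_progeny <- function(parentA, parentB, loci, config, chrom_len = NULL) {
  n_loci <- length(parentA)
  stopifnot(length(parentB) == n_loci, nrow(loci) == n_loci)
  n <- config$n_progeny
  out <- matrix(rep(parentA, each = n), n, n_loci)
  het <- which(parentA != parentB)
  if (length(het) == 0L) return(out)
  if (config$model == "independent") {
    pick <- matrix(stats::runif(n * length(het)) < 0.5, n, length(het))
    for (j in seq_along(het)) {
      l <- het[j]
      out[pick[, j], l] <- parentB[l]
    }
    return(out)
  }
  # linkage model
  if (anyNA(loci$pos_cM)) stop("linkage model requires a map position for every locus")
  for (ch in unique(loci$chrom[het])) {
    l_ch <- het[loci$chrom[het] == ch]
    pos <- loci$pos_cM[l_ch]
    ord <- order(pos)
    l_ch <- l_ch[ord]; pos <- pos[ord]
    L <- if (!is.null(chrom_len) && !is.na(chrom_len[as.character(ch)]))
      chrom_len[[as.character(ch)]] else max(pos) + 25
    if (config$progeny_model == "doubled_gamete") {
      m <- stats::rpois(n, L / 100)
      xo <- stats::runif(sum(m), 0, L)
      pid <- rep.int(seq_len(n), m)
      phase <- stats::runif(n) < 0.5
      for (j in seq_along(l_ch)) {
        nxo <- tabulate(pid[xo < pos[j]], nbins = n)
        fromB <- xor(phase, nxo %% 2L == 1L)
        out[fromB, l_ch[j]] <- parentB[l_ch[j]]
      }
    } else { # ril: Markov chain with inflated effective recombination
      fromB <- stats::runif(n) < 0.5
      out[fromB, l_ch[1L]] <- parentB[l_ch[1L]]
      if (length(l_ch) > 1L) for (j in 2L:length(l_ch)) {
        r <- (1 - exp(-2 * (pos[j] - pos[j - 1L]) / 100)) / 2
        R <- 2 * r / (1 + 2 * r)
        fromB <- xor(fromB, stats::runif(n) < R)
        out[fromB, l_ch[j]] <- parentB[l_ch[j]]
      }
    }
  }
  out
}

#' Predict genotypic trait values of simulated progeny
#'
#' Value = model intercept + sum over loci of the carried allele's main
#' effect (QEI effects are excluded from prediction).
#'
#' @param progeny integer matrix (progeny x loci) of allele codes.
#' @param model an `rtm_gwas` fit whose detected loci match the columns.
#' @param loci_ids locus ids for the columns (default: all detected loci in
#'   model order).
#' @return Numeric vector of predicted values.
#' @export
predict_value <- function(progeny, model, loci_ids = rownames(model$codes)) {
  stopifnot(inherits(model, "rtm_gwas"), ncol(progeny) == length(loci_ids))
  v <- rep(model$intercept, nrow(progeny))
  for (j in seq_along(loci_ids)) {
    eff <- model$effects[[loci_ids[j]]]
    if (is.null(eff)) stop("no effects for locus ", loci_ids[j])
    cc <- progeny[, j]
    if (any(cc > nrow(eff))) stop("unknown allele code at locus ", loci_ids[j])
    v <- v + eff$effect[cc]
  }
  v
}

#' Simulate one cross and summarize its progeny-value distribution
#'
#' Simulates `config$n_progeny` homozygous progenies of the cross, predicts
#' their genotypic values from the QTL-allele model, and returns distribution
#' summaries. Percentiles use linear interpolation of order statistics
#' (position 1 + (n-1)p).
#'
#' @param p1,p2 parent accession ids (must be columns of the model's
#'   allele-code matrix).
#' @param model an `rtm_gwas` fit.
#' @param config a [progeny_sim_config()].
#' @param observed optional named vector of observed parental trait values
#'   (reported as `y1`, `y2`).
#' @param chrom_len optional chromosome map lengths (cM), see
#'   [simulate_progeny()].
#' @return One-row data frame: p1, p2, y1, y2, mean, sd, min, max and one
#'   column per requested percentile (`p90`, `p95`, ...).
#' @export
cross_potential <- function(p1, p2, model, config, observed = NULL,
                            chrom_len = NULL) {
  if (config$n_progeny < 20L)
    warning("fewer than 20 progenies: percentile estimates are unreliable")
  codes <- model$codes
  loci <- model$loci[match(rownames(codes), model$loci$id),
                     c("chrom", "pos_cM")]
  set.seed(cross_seed(config$seed, p1, p2))
  prog <- simulate_progeny(codes[, p1], codes[, p2], loci, config, chrom_len)
  vals <- predict_value(prog, model)
  qs <- stats::quantile(vals, config$percentiles / 100, type = 7, names = FALSE)
  out <- data.frame(p1 = p1, p2 = p2,
                    y1 = if (is.null(observed)) NA_real_ else unname(observed[p1]),
                    y2 = if (is.null(observed)) NA_real_ else unname(observed[p2]),
                    mean = mean(vals), sd = stats::sd(vals),
                    min = min(vals), max = max(vals), stringsAsFactors = FALSE)
  for (i in seq_along(config$percentiles))
    out[[paste0("p", config$percentiles[i])]] <- qs[i]
  out
}

#' Score every pairwise cross of a population
#'
#' Enumerates all unordered crosses ([enumerate_crosses()]) and scores each
#' with [cross_potential()]. Per-cross RNG streams derive from the global
#' seed and the parent pair, so the result is independent of enumeration
#' order.
#'
#' @param model an `rtm_gwas` fit.
#' @param config a [progeny_sim_config()].
#' @param observed named vector of observed accession trait values.
#' @param groups optional named group labels (see [enumerate_crosses()]).
#' @param chrom_len optional chromosome map lengths (cM).
#' @return Data frame of cross records (one row per cross).
#' @export
cross_potential_all <- function(model, config, observed = NULL, groups = NULL,
                                chrom_len = NULL) {
  plan <- enumerate_crosses(colnames(model$codes), groups)
  recs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    recs[[i]] <- cross_potential(plan$p1[i], plan$p2[i], model, config,
                                 observed, chrom_len)
  }
  out <- cbind(plan[setdiff(names(plan), c("p1", "p2"))], do.call(rbind, recs))
  out[, c("p1", "p2", setdiff(names(out), c("p1", "p2")))]
}

#' Summarize cross potentials by scope
#'
#' For each scope — every within-group and between-group-pair scope, the
#' pooled "within" and "between" scopes and the entire population —
#' summarizes the chosen percentile column: cross count, mean/min/max of the
#' percentile, the number of superior crosses (percentile above the scope's
#' maximum observed value), the recombination potential (mean percentile
#' minus the population mean), the maximum recombination potential (max
#' percentile minus the population mean) and the transgressive potential
#' (max percentile minus the scope's maximum observed value).
#'
#' @param records output of [cross_potential_all()] (with group columns).
#' @param population_mean observed population mean trait value.
#' @param group_max_observed named vector: maximum observed value per group;
#'   a between-pair scope uses the larger of its two groups' maxima, the
#'   pooled scopes use the overall maximum.
#' @param percentile which percentile column to use (default 95).
#' @return Data frame, one row per scope.
#' @export
summarize_potentials <- function(records, population_mean, group_max_observed,
                                 percentile = 95) {
  pc <- paste0("p", percentile)
  if (!pc %in% names(records)) stop("records lack column ", pc)
  if (!"scope" %in% names(records)) stop("records lack group scopes")
  scope_max <- function(rows) {
    gs <- unique(c(records$g1[rows], records$g2[rows]))
    if (!all(gs %in% names(group_max_observed))) stop("missing group maxima")
    max(group_max_observed[gs])
  }
  one <- function(label, rows, maxobs) {
    v <- records[[pc]][rows]
    data.frame(scope = label, max_observed = maxobs, n_crosses = length(v),
               mean = mean(v), min = min(v), max = max(v),
               n_superior = sum(v > maxobs),
               recomb_potential = mean(v) - population_mean,
               max_recomb_potential = max(v) - population_mean,
               transgressive_potential = max(v) - maxobs,
               stringsAsFactors = FALSE)
  }
  out <- NULL
  for (sc in unique(records$scope[records$within]))
    out <- rbind(out, one(sc, which(records$scope == sc),
                          scope_max(which(records$scope == sc))))
  for (sc in unique(records$scope[!records$within]))
    out <- rbind(out, one(sc, which(records$scope == sc),
                          scope_max(which(records$scope == sc))))
  overall_max <- max(group_max_observed)
  if (any(records$within))
    out <- rbind(out, one("within", which(records$within), overall_max))
  if (any(!records$within))
    out <- rbind(out, one("between", which(!records$within), overall_max))
  rbind(out, one("entire", seq_len(nrow(records)), overall_max))
}

#' Rank the optimal crosses of a scope
#'
#' Sorts crosses by the chosen percentile descending, breaking ties by the
#' next higher percentile (99th when ranking on the 95th) and then by
#' lexical parent ids, and returns the top `top_k`.
#'
#' @param records output of [cross_potential_all()].
#' @param scope optional scope label to filter on (`"entire"` or absent =
#'   all crosses; a group label or `"within"`/`"between"` otherwise).
#' @param top_k how many crosses (default 5); all if fewer available.
#' @param percentile ranking percentile (default 95).
#' @return The top rows of `records` with a `rank` column.
#' @export
rank_optimal <- function(records, scope = "entire", top_k = 5, percentile = 95) {
  pc <- paste0("p", percentile)
  rows <- if (is.null(scope) || identical(scope, "entire")) seq_len(nrow(records))
    else if (identical(scope, "within")) which(records$within)
    else if (identical(scope, "between")) which(!records$within)
    else which(records$scope == scope)
  if (length(rows) == 0L) stop("no crosses in scope ", scope)
  r <- records[rows, , drop = FALSE]
  tie <- setdiff(grep("^p[0-9]+$", names(r), value = TRUE), pc)
  tie_col <- if (length(tie)) r[[tie[length(tie)]]] else 0
  ord <- order(-r[[pc]], -tie_col, r$p1, r$p2)
  r <- r[ord[seq_len(min(top_k, nrow(r)))], , drop = FALSE]
  r$rank <- seq_len(nrow(r))
  rownames(r) <- NULL
  r
}
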