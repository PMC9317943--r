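#' Alleles present in a subpopulation, tagged by effect sign
#'
#' For each detected locus, lists the alleles carried by at least
#' `min_count` accessions of the group, each tagged positive or negative by
#' its estimated main effect (an effect of exactly zero counts as positive;
#' the tie rule is deterministic and documented).
#'
#' @param model an `rtm_gwas` fit.
#' @param accessions character vector naming the group's accessions.
#' @param min_count minimum carrier count for presence (default 1).
#' @return List of class `allele_presence`, one element per locus: data
#'   frame with `code`, `effect`, `sign` ("+" or "-").
#' @export
allele_presence <- function(model, accessions, min_count = 1L) {
  stopifnot(inherits(model, "rtm_gwas"))
  if (length(accessions) == 0L) stop("empty accession group")
  if (!all(accessions %in% colnames(model$codes)))
    stop("unknown accession(s) in group")
  codes <- model$codes[, accessions, drop = FALSE]
  out <- lapply(seq_len(nrow(codes)), function(i) {
    id <- rownames(codes)[i]
    tab <- table(codes[i, ])
    present <- as.integer(names(tab)[tab >= min_count])
    eff <- model$effects[[id]]$effect[present]
    data.frame(code = present, effect = eff,
               sign = ifelse(eff >= 0, "+", "-"), stringsAsFactors = FALSE)
  })
  names(out) <- rownames(codes)
  structure(out, class = "allele_presence")
}

#' Allele inheritance, emergence and exclusion between two groups
#'
#' Compares the allele sets of an "old" and a "new" subpopulation locus by
#' locus. Inherited alleles are present in both (old intersect new); emerged
#' alleles are in the new group only (new minus old); excluded alleles are in
#' the old group only (old minus new). Counts are split by effect sign, and
#' per category the number of loci with at least one such allele is
#' reported. Fractions use the population-genetics denominators: inherited
#' and emerged over the new group's total, excluded over the old group's
#' total.
#'
#' @param old_presence,new_presence [allele_presence()] results over the
#'   same loci.
#' @return List of class `allele_change_summary`: per-category counts
#'   (`total`, `neg`, `pos`, `n_qtl`), fractions, and the per-locus detail.
#' @export
compare_groups <- function(old_presence, new_presence) {
  if (!identical(names(old_presence), names(new_presence)))
    stop("old and new presence must cover the same loci")
  cat_count <- function(f) {
    per <- lapply(names(old_presence), function(id) {
      o <- old_presence[[id]]; nw <- new_presence[[id]]
      f(o, nw)
    })
    names(per) <- names(old_presence)
    per
  }
  inherited <- cat_count(function(o, nw) o[o$code %in% nw$code, , drop = FALSE])
  emerged <- cat_count(function(o, nw) nw[!(nw$code %in% o$code), , drop = FALSE])
  excluded <- cat_count(function(o, nw) o[!(o$code %in% nw$code), , drop = FALSE])
  tally <- function(per) {
    n <- vapply(per, nrow, integer(1))
    neg <- vapply(per, function(d) sum(d$sign == "-"), integer(1))
    c(total = sum(n), neg = sum(neg), pos = sum(n) - sum(neg),
      n_qtl = sum(n > 0L))
  }
  old_t <- tally(old_presence)
  new_t <- tally(new_presence)
  inh <- tally(inherited); eme <- tally(emerged); exc <- tally(excluded)
  stopifnot(inh[["total"]] + eme[["total"]] == new_t[["total"]],
            inh[["total"]] + exc[["total"]] == old_t[["total"]])
  structure(list(
    old = old_t, new = new_t, inherited = inh, emerged = eme, excluded = exc,
    fractions = c(inherited = inh[["total"]] / new_t[["total"]],
                  emerged = eme[["total"]] / new_t[["total"]],
                  excluded = exc[["total"]] / old_t[["total"]]),
    detail = list(inherited = inherited, emerged = emerged, excluded = excluded)),
    class = "allele_change_summary")
}

#' @export
print.allele_change_summary <- function(x, ...) {
  fmt <- function(v) sprintf("%d (%d,%d) on %d QTL", v[["total"]], v[["neg"]],
                             v[["pos"]], v[["n_qtl"]])
  cat("alleles old:      ", fmt(x$old), "\n")
  cat("alleles new:      ", fmt(x$new), "\n")
  cat("inherited:        ", fmt(x$inherited),
      sprintf(" [%.2f%% of new]", 100 * x$fractions[["inherited"]]), "\n")
  cat("emerged:          ", fmt(x$emerged),
      sprintf(" [%.2f%% of new]", 100 * x$fractions[["emerged"]]), "\n")
  cat("excluded:         ", fmt(x$excluded),
      sprintf(" [%.2f%% of old]", 100 * x$fractions[["excluded"]]), "\n")
  invisible(x)
}

#' Tabulate an allele-change summary for reporting
#'
#' @param x an `allele_change_summary`.
#' @return One-row data frame with the category counts, sign splits and
#'   fractions (percent).
#' @export
allele_change_table <- function(x) {
  stopifnot(inherits(x, "allele_change_summary"))
  data.frame(
    old_total = x$old[["total"]], old_neg = x$old[["neg"]], old_pos = x$old[["pos"]],
    new_total = x$new[["total"]], new_neg = x$new[["neg"]], new_pos = x$new[["pos"]],
    inherited = x$inherited[["total"]], inherited_neg = x$inherited[["neg"]],
    inherited_pos = x$inherited[["pos"]],
    emerged = x$emerged[["total"]], emerged_neg = x$emerged[["neg"]],
    emerged_pos = x$emerged[["pos"]],
    excluded = x$excluded[["total"]], excluded_neg = x$excluded[["neg"]],
    excluded_pos = x$excluded[["pos"]],
    inherited_pct = 100 * x$fractions[["inherited"]],
    emerged_pct = 100 * x$fractions[["emerged"]],
    excluded_pct = 100 * x$fractions[["excluded"]])
}
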