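#' Read gene records from a GFF3 annotation
#'
#' Imports a GFF3 file and returns its `gene` features as a data frame.
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) gr$ID else S4Vectors::mcols(gr)$Name
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Extend a QTL interval by a flanking pad
#'
#' Pads both ends by `pad_bp` (reflecting the LD decay distance of the
#' population), clipping at position 1 and, when known, the chromosome
#' length.
#'
#' @param start,end 1-based inclusive interval.
#' @param pad_bp pad in bp (default 200 kb).
#' @param chrom_length optional chromosome length for right clipping.
#' @return Length-2 numeric vector `c(start, end)`.
#' @export
extend_interval <- function(start, end, pad_bp = 2e5, chrom_length = NULL) {
  stopifnot(pad_bp >= 0, start <= end)
  s <- max(1, start - pad_bp)
  e <- end + pad_bp
  if (!is.null(chrom_length)) e <- min(e, chrom_length)
  c(start = s, end = e)
}

#' Genes overlapping an interval
#'
#' Returns the genes overlapping the query span by at least 1 bp (any
#' overlap counts, including genes straddling an edge).
#'
#' @param genes gene table from [read_gene_annotation()].
#' @param chrom chromosome name.
#' @param start,end query span (1-based inclusive).
#' @return Subset of `genes`.
#' @export
genes_in_interval <- function(genes, chrom, start, end) {
  if (nrow(genes) == 0L || !chrom %in% genes$chrom)
    return(genes[0L, , drop = FALSE])
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(gr, q)
  genes[S4Vectors::queryHits(hits), , drop = FALSE]
}

#' Gene-local haplotype classes
#'
#' Builds accession classes from the SNPs inside the gene span extended by
#' `flank_bp` on each side, with haplotype strings as classes and classes
#' rarer than `rare_freq` pooled into the nearest common class by Hamming
#' distance.
#'
#' @param geno a [genotype_matrix()] (imputed, homozygous).
#' @param chrom,start,end gene span.
#' @param flank_bp flank around the gene capturing regulatory SNPs
#'   (default 5 kb).
#' @param rare_freq pooling floor (default 0.01).
#' @return Integer class codes per accession (1 = most frequent), or `NULL`
#'   when no SNP falls in the span.
#' @export
gene_haplotype_codes <- function(geno, chrom, start, end, flank_bp = 5e3,
                                 rare_freq = 0.01) {
  info <- geno$snp_info
  sel <- which(info$chrom == chrom & info$pos_bp >= start - flank_bp &
                 info$pos_bp <= end + flank_bp)
  if (length(sel) == 0L) return(NULL)
  base <- ifelse(geno$calls[sel, , drop = FALSE] == 0L, info$ref[sel], info$alt[sel])
  hap <- apply(matrix(base, nrow = length(sel)), 2L, paste, collapse = "")
  pooled <- pool_rare_haplotypes(hap, rare_freq)
  tab <- sort(table(pooled$hap), decreasing = TRUE)
  unname(stats::setNames(seq_along(tab), names(tab))[pooled$hap])
}

#' Chi-square independence test between QTL alleles and gene classes
#'
#' Pearson chi-square (no continuity correction) on the contingency table of
#' accession counts, QTL allele classes x gene-local classes. Before
#' testing, classes whose margin would produce an expected cell count below
#' `min_expected` are pooled into an "other" class on that margin
#' (iteratively, smallest margin first). A significant test (p <= alpha in
#' the caller's screening) marks the gene as a candidate.
#'
#' @param qtl_codes,gene_codes integer class codes over the same accessions.
#' @param min_expected expected-count pooling threshold (default 5).
#' @return List of class `gene_qtl_test`: `table` (post-pooling), `statistic`,
#'   `df`, `p`.
#' @export
test_independence <- function(qtl_codes, gene_codes, min_expected = 5) {
  stopifnot(length(qtl_codes) == length(gene_codes))
  tab <- table(qtl = qtl_codes, gene = gene_codes)
  pool_margin <- function(tab, margin) {
    while (TRUE) {
      if (dim(tab)[margin] <= 2L) break
      exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      bad <- if (margin == 1L) apply(exp_tab, 1L, min) else apply(exp_tab, 2L, min)
      if (all(bad >= min_expected)) break
      sums <- if (margin == 1L) rowSums(tab) else colSums(tab)
      ord <- order(sums)[1:2]   # merge the two smallest classes
      if (margin == 1L) {
        merged <- tab[ord[1L], ] + tab[ord[2L], ]
        tab <- tab[-ord, , drop = FALSE]
        tab <- rbind(tab, other = merged)
      } else {
        merged <- tab[, ord[1L]] + tab[, ord[2L]]
        tab <- tab[, -ord, drop = FALSE]
        tab <- cbind(tab, other = merged)
      }
    }
    tab
  }
  tab <- pool_margin(tab, 1L)
  tab <- pool_margin(tab, 2L)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("fewer than 2 classes on a margin after pooling: test undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "gene_qtl_test")
}

#' @export
print.gene_qtl_test <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g\n", x$statistic, x$df, x$p))
  invisible(x)
}

#' Screen candidate genes for the detected QTLs
#'
#' For each detected locus: extends its span by `pad_bp`, collects the
#' overlapping genes, builds gene-local classes (haplotype strings by
#' default, or single-SNP genotype classes with `mode = "per_snp"`, where a
#' gene's p value is the smallest single-SNP p) and tests independence
#' against the locus's allele codes. Genes with p <= `alpha` are candidates.
#' No multiplicity correction is applied to the decision; a
#' Benjamini-Hochberg adjusted p is reported informationally.
#'
#' @param model an `rtm_gwas` fit.
#' @param geno the imputed [genotype_matrix()] used for marker assembly.
#' @param genes gene table from [read_gene_annotation()].
#' @param pad_bp interval extension (default 200 kb).
#' @param flank_bp gene flank for local classes (default 5 kb).
#' @param alpha significance level (default 0.05).
#' @param mode `"haplotype"` (default) or `"per_snp"`.
#' @return Data frame: qtl, gene_id, chrom, start, end, statistic, df, p,
#'   p_adj, candidate.
#' @export
candidate_gene_scan <- function(model, geno, genes, pad_bp = 2e5,
                                flank_bp = 5e3, alpha = 0.05,
                                mode = c("haplotype", "per_snp")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "rtm_gwas"))
  loci <- model$loci
  out <- NULL
  if (!is.null(loci) && nrow(loci) > 0L) for (i in seq_len(nrow(loci))) {
    span <- extend_interval(loci$start_bp[i], loci$end_bp[i], pad_bp)
    gi <- genes_in_interval(genes, loci$chrom[i], span[["start"]], span[["end"]])
    if (nrow(gi) == 0L) next
    qtl_codes <- model$codes[loci$id[i], geno$accessions]
    for (g in seq_len(nrow(gi))) {
      res <- tryCatch({
        if (mode == "haplotype") {
          gc <- gene_haplotype_codes(geno, gi$chrom[g], gi$start[g], gi$end[g],
                                     flank_bp)
          if (is.null(gc)) NULL else test_independence(qtl_codes, gc)
        } else {
          info <- geno$snp_info
          sel <- which(info$chrom == gi$chrom[g] &
                         info$pos_bp >= gi$start[g] - flank_bp &
                         info$pos_bp <= gi$end[g] + flank_bp)
          if (length(sel) == 0L) NULL else {
            tests <- lapply(sel, function(s)
              tryCatch(test_independence(qtl_codes, geno$calls[s, ]),
                       error = function(e) NULL))
            tests <- tests[!vapply(tests, is.null, logical(1))]
            if (length(tests) == 0L) NULL else
              tests[[which.min(vapply(tests, `[[`, numeric(1), "p"))]]
          }
        }
      }, error = function(e) NULL)
      if (is.null(res)) next
      out <- rbind(out, data.frame(
        qtl = loci$id[i], gene_id = gi$gene_id[g], chrom = gi$chrom[g],
        start = gi$start[g], end = gi$end[g],
        statistic = res$statistic, df = res$df, p = res$p,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(qtl = character(0), gene_id = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      statistic = numeric(0), df = integer(0), p = numeric(0),
                      p_adj = numeric(0), candidate = logical(0)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$candidate <- out$p <= alpha
  out
}

#' Tally candidate genes by functional category
#'
#' @param candidates result of [candidate_gene_scan()] (rows with
#'   `candidate = TRUE` are tallied).
#' @param go_table data frame mapping `gene_id` to `category` (e.g. a
#'   13-way biological-process classification plus "other").
#' @return Named integer vector of per-category candidate-gene counts;
#'   unmapped genes are counted as `"unannotated"`.
#' @export
categorize_genes <- function(candidates, go_table) {
  cats <- sort(unique(go_table$category))
  counts <- stats::setNames(integer(length(cats) + 1L), c(cats, "unannotated"))
  genes <- unique(candidates$gene_id[candidates$candidate])
  for (g in genes) {
    cat_g <- go_table$category[go_table$gene_id == g]
    if (length(cat_g) == 0L) counts[["unannotated"]] <- counts[["unannotated"]] + 1L
    else for (cc in unique(cat_g)) counts[[cc]] <- counts[[cc]] + 1L
  }
  counts
}
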