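#' Genotype matrix for inbred accession panels
#'
#' Container for SNP calls of a panel of (nominally homozygous) inbred
#' accessions. Calls are coded `0` = homozygous reference, `2` = homozygous
#' alternate, `1` = heterozygous, `NA` = missing. SNPs are rows, accessions
#' columns, mirroring VCF orientation.
#'
#' @param calls integer matrix, SNPs x accessions, values in \{0, 1, 2, NA\}.
#' @param snp_info data frame with one row per SNP and columns `id`, `chrom`,
#'   `pos_bp` (1-based physical position), `pos_cM` (genetic position), `ref`,
#'   `alt`. Positions must be strictly increasing within each chromosome.
#' @param accessions character vector of unique accession ids (column names).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp_info, accessions) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(snp_info), ncol(calls) == length(accessions))
  if (anyDuplicated(accessions)) stop("accession ids must be unique")
  if (anyDuplicated(snp_info$id)) stop("SNP ids must be unique")
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("calls must be coded 0/1/2/NA")
  for (ch in unique(snp_info$chrom)) {
    p <- snp_info$pos_bp[snp_info$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  dimnames(calls) <- list(snp_info$id, accessions)
  structure(list(calls = calls, snp_info = as.data.frame(snp_info),
                 accessions = as.character(accessions)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "SNPs x", length(x$accessions),
      "accessions on", length(unique(x$snp_info$chrom)), "chromosome(s)\n")
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm, 100 * nm / length(x$calls)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Quality-filter SNPs by missing rate, heterozygosity and MAF
#'
#' Removes SNPs whose missing rate exceeds `max_missing`, whose
#' heterozygosity rate exceeds `max_het`, or whose minor allele frequency is
#' below `min_maf`. Boundaries follow the usual germplasm-panel convention:
#' rates strictly above the cap are removed, MAF strictly below the floor is
#' removed (a SNP at exactly the MAF floor is kept). Allele frequencies are
#' computed from non-missing calls counting each homozygote as two allele
#' copies and each heterozygote as one of each.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing,max_het,min_maf fractions; defaults 0.20, 0.20, 0.01.
#' @return A filtered `genotype_matrix` with attribute `filter_report`, a
#'   named integer vector of SNPs removed per criterion (a SNP failing
#'   several criteria is counted under each).
#' @export
filter_snps <- function(geno, max_missing = 0.20, max_het = 0.20, min_maf = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  g <- geno$calls
  n <- ncol(g)
  n_miss <- rowSums(is.na(g))
  n_obs <- n - n_miss
  miss_rate <- n_miss / n
  het_rate <- ifelse(n_obs > 0, rowSums(g == 1L, na.rm = TRUE) / n_obs, 1)
  alt_freq <- ifelse(n_obs > 0, rowSums(g, na.rm = TRUE) / (2 * n_obs), 0)
  maf <- pmin(alt_freq, 1 - alt_freq)
  fail_miss <- miss_rate > max_missing
  fail_het <- het_rate > max_het
  fail_maf <- maf < min_maf
  keep <- !(fail_miss | fail_het | fail_maf)
  report <- c(missing = sum(fail_miss), heterozygosity = sum(fail_het),
              maf = sum(fail_maf), removed = sum(!keep), retained = sum(keep))
  if (!any(keep)) {
    warning("all SNPs removed by filtering")
  }
  out <- genotype_matrix(g[keep, , drop = FALSE],
                         geno$snp_info[keep, , drop = FALSE],
                         geno$accessions)
  attr(out, "filter_report") <- report
  out
}

#' Impute missing calls by k-nearest-haplotype majority vote
#'
#' Residual heterozygous calls in inbred lines are treated as noise: they are
#' set missing first. Each missing call is then imputed from the `k`
#' accessions whose haplotypes are most similar over a local window of
#' flanking SNPs (same chromosome), by majority vote among their non-missing
#' calls at the target SNP; ties and the no-informative-neighbour case fall
#' back to the SNP-wise major allele.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of nearest neighbours (default 5).
#' @param window number of SNPs in the local comparison window (default 20).
#' @return A `genotype_matrix` with no missing and no heterozygous calls
#'   (all calls in \{0, 2\}).
#' @export
impute_missing <- function(geno, k = 5, window = 20) {
  stopifnot(inherits(geno, "genotype_matrix"))
  g <- geno$calls
  g[g == 1L] <- NA_integer_
  if (any(rowSums(!is.na(g)) == 0L))
    stop("SNP(s) with all calls missing cannot be imputed")
  chrom <- geno$snp_info$chrom
  half <- max(1L, window %/% 2L)
  miss_idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(miss_idx) > 0) {
    # SNP-wise major allele as fallback
    major <- ifelse(rowMeans(g == 2L, na.rm = TRUE) > 0.5, 2L, 0L)
    for (s in unique(miss_idx[, 1L])) {
      on_chrom <- which(chrom == chrom[s])
      lo <- max(min(on_chrom), s - half)
      hi <- min(max(on_chrom), s + half)
      win <- g[lo:hi, , drop = FALSE]
      accs <- miss_idx[miss_idx[, 1L] == s, 2L]
      for (a in accs) {
        ref <- win[, a]
        cmp <- win != ref            # NA where either side missing
        n_cmp <- colSums(!is.na(cmp))
        d <- ifelse(n_cmp > 0, colSums(cmp, na.rm = TRUE) / n_cmp, Inf)
        d[a] <- Inf
        d[is.na(g[s, ])] <- Inf      # neighbour must carry a call at s
        nb <- order(d)[seq_len(min(k, sum(is.finite(d))))]
        nb <- nb[is.finite(d[nb])]
        if (length(nb) == 0L) {
          g[s, a] <- major[s]
        } else {
          votes <- g[s, nb]
          n2 <- sum(votes == 2L)
          n0 <- sum(votes == 0L)
          g[s, a] <- if (n2 > n0) 2L else if (n0 > n2) 0L else major[s]
        }
      }
    }
  }
  genotype_matrix(g, geno$snp_info, geno$accessions)
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF v4.2 file of biallelic SNPs into a [genotype_matrix()]. Only
#' the GT field is used; phased and unphased separators are accepted.
#' Genetic positions are taken from `map` when supplied, otherwise set to
#' `pos_bp / bp_per_cM`.
#'
#' @param path VCF file path.
#' @param map optional data frame (`chrom`, `pos_bp`, `pos_cM`) giving
#'   genetic positions; matched on chromosome and physical position.
#' @param bp_per_cM fallback physical-to-genetic scaling (default 4e5).
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path, map = NULL, bp_per_cM = 4e5) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  code1 <- function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(is.na(x) | x == "./.", NA_integer_,
           ifelse(x == "0/0", 0L, ifelse(x == "1/1", 2L, 1L)))
  }
  calls <- matrix(code1(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  info <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos_bp = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  if (!is.null(map)) {
    key <- paste(info$chrom, info$pos_bp)
    mkey <- paste(map$chrom, map$pos_bp)
    info$pos_cM <- map$pos_cM[match(key, mkey)]
    if (anyNA(info$pos_cM)) stop("map does not cover all VCF positions")
  } else {
    info$pos_cM <- info$pos_bp / bp_per_cM
  }
  info <- info[, c("id", "chrom", "pos_bp", "pos_cM", "ref", "alt")]
  genotype_matrix(calls, info, colnames(calls))
}

#' Write genotypes as a VCF file
#'
#' Writes a [genotype_matrix()] as an uncompressed VCF v4.2 text file with a
#' GT FORMAT field (`0/0`, `1/1`, `0/1`, `./.`).
#'
#' @param geno a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  info <- geno$snp_info
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- matrix("./.", nrow(geno$calls), ncol(geno$calls))
  ok <- !is.na(geno$calls)
  body[ok] <- gtmap[as.character(geno$calls[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=qtlallele",
    paste0("##contig=<ID=", unique(info$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$accessions), collapse = "\t"))
  lines <- paste(info$chrom, info$pos_bp, info$id, info$ref, info$alt,
                 ".", "PASS", ".", "GT",
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}
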