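#' Pairwise normalized linkage disequilibrium D'
#'
#' Computes |D'| between two biallelic SNPs from homozygous calls of inbred
#' accessions, each non-missing homozygote contributing one haplotype.
#' Heterozygous or missing calls are excluded pairwise. D = p_AB - p_A p_B is
#' normalized by its bound given the marginal frequencies:
#' D_max = min(p_A q_B, q_A p_B) for D >= 0 and min(p_A p_B, q_A q_B) for
#' D < 0, so the result lies in \[0, 1\].
#'
#' @param a,b integer vectors of calls in \{0, 2\} (NA and 1 dropped pairwise).
#' @return |D'| in \[0, 1\].
#' @export
d_prime <- function(a, b) {
  use <- !is.na(a) & !is.na(b) & a != 1L & b != 1L
  a <- a[use]; b <- b[use]
  if (length(a) == 0L) stop("no complete homozygous pairs")
  pA <- mean(a == 2L)
  pB <- mean(b == 2L)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("D' undefined for a monomorphic SNP")
  pAB <- mean(a == 2L & b == 2L)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  abs(D) / dmax
}

#' Assemble multi-allelic SNPLDB markers from LD blocks
#'
#' Partitions the retained SNPs of each chromosome into
#' linkage-disequilibrium block markers: adjacent SNPs are merged greedily
#' left to right into a block for as long as every pairwise |D'| within the
#' candidate block exceeds `d_threshold` and the block's physical span stays
#' within `max_span_bp`. SNPs that join no block become single-SNP markers.
#' The haplotypes observed across accessions (strings of ref/alt bases over
#' member SNPs) are the marker's alleles; haplotypes rarer than `rare_freq`
#' are pooled into the closest common haplotype by Hamming distance (ties to
#' the more frequent one). Alleles are coded by decreasing frequency.
#'
#' Input must be filtered and imputed: all calls in \{0, 2\}.
#'
#' @param geno a [genotype_matrix()] with no missing/heterozygous calls.
#' @param d_threshold |D'| threshold for block membership (default 0.7).
#' @param max_span_bp cap on a block's physical span (default 200 kb).
#' @param rare_freq haplotype-frequency floor below which alleles are pooled
#'   (default 0.01).
#' @return An object of class `snpldb_set` with elements `markers` (data
#'   frame: id, chrom, start_bp, end_bp, pos_cM, n_snps, n_alleles, type),
#'   `snp_ids` (list), `alleles` (list of data frames: code, haplotype, freq),
#'   and `codes` (integer matrix, markers x accessions).
#' @export
assemble_snpldb <- function(geno, d_threshold = 0.7, max_span_bp = 2e5,
                            rare_freq = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (anyNA(geno$calls) || any(geno$calls == 1L))
    stop("assemble_snpldb requires imputed homozygous calls (0/2 only)")
  info <- geno$snp_info
  if (anyNA(info$chrom)) stop("all SNPs must be mapped to a chromosome")
  n_acc <- length(geno$accessions)
  blocks <- list()
  for (ch in unique(info$chrom)) {
    idx <- which(info$chrom == ch)
    i <- 1L
    while (i <= length(idx)) {
      members <- idx[i]
      j <- i + 1L
      while (j <= length(idx)) {
        cand <- idx[j]
        if (info$pos_bp[cand] - info$pos_bp[members[1L]] > max_span_bp) break
        ok <- all(vapply(members, function(m) {
          dp <- tryCatch(d_prime(geno$calls[m, ], geno$calls[cand, ]),
                         error = function(e) 0)
          dp > d_threshold
        }, logical(1)))
        if (!ok) break
        members <- c(members, cand)
        j <- j + 1L
      }
      blocks[[length(blocks) + 1L]] <- members
      i <- i + length(members)
    }
  }
  # haplotype alleles per block
  markers <- vector("list", length(blocks))
  allele_tabs <- vector("list", length(blocks))
  snp_ids <- vector("list", length(blocks))
  codes <- matrix(NA_integer_, length(blocks), n_acc,
                  dimnames = list(NULL, geno$accessions))
  for (b in seq_along(blocks)) {
    m <- blocks[[b]]
    base <- ifelse(geno$calls[m, , drop = FALSE] == 0L, info$ref[m], info$alt[m])
    hap <- apply(matrix(base, nrow = length(m)), 2L, paste, collapse = "")
    pooled <- pool_rare_haplotypes(hap, rare_freq)
    tab <- sort(table(pooled$hap), decreasing = TRUE)
    code_of <- stats::setNames(seq_along(tab), names(tab))
    codes[b, ] <- unname(code_of[pooled$hap])
    allele_tabs[[b]] <- data.frame(code = unname(code_of[names(tab)]),
                                   haplotype = names(tab),
                                   freq = as.numeric(tab) / n_acc,
                                   stringsAsFactors = FALSE)
    snp_ids[[b]] <- info$id[m]
    markers[[b]] <- data.frame(
      chrom = info$chrom[m[1L]], start_bp = info$pos_bp[m[1L]],
      end_bp = info$pos_bp[m[length(m)]], pos_cM = mean(info$pos_cM[m]),
      n_snps = length(m), n_alleles = length(tab),
      stringsAsFactors = FALSE)
  }
  mk <- do.call(rbind, markers)
  mk$type <- ifelse(mk$n_snps > 1L, "M", "S")
  mk$id <- sprintf("ldb_%s_%d", mk$chrom, stats::ave(seq_len(nrow(mk)), mk$chrom, FUN = seq_along))
  mk <- mk[, c("id", "chrom", "start_bp", "end_bp", "pos_cM", "n_snps", "n_alleles", "type")]
  rownames(codes) <- mk$id
  structure(list(markers = mk, snp_ids = snp_ids, alleles = allele_tabs,
                 codes = codes, accessions = geno$accessions),
            class = "snpldb_set")
}

# Pool haplotypes with frequency < floor into the nearest common haplotype
# (minimum Hamming distance; ties resolved toward the more frequent, then
# lexicographically). If every haplotype is rare the most frequent one is kept
# as the single common anchor.
pool_rare_haplotypes <- function(hap, floor_freq) {
  n <- length(hap)
  tab <- sort(table(hap), decreasing = TRUE)
  freq <- as.numeric(tab) / n
  common <- names(tab)[freq >= floor_freq]
  if (length(common) == 0L) common <- names(tab)[1L]
  rare <- setdiff(names(tab), common)
  if (length(rare) > 0L) {
    reassign <- vapply(rare, function(h) {
      d <- vapply(common, function(cc) hamming_str(h, cc), numeric(1))
      common[order(d, -as.numeric(tab[common]), common)][1L]
    }, character(1))
    hap[hap %in% rare] <- reassign[hap[hap %in% rare]]
  }
  list(hap = hap, n_pooled = length(rare))
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' @export
print.snpldb_set <- function(x, ...) {
  cat("snpldb_set:", nrow(x$markers), "markers (",
      sum(x$markers$type == "S"), "single-SNP,",
      sum(x$markers$type == "M"), "multi-SNP ) x",
      length(x$accessions), "accessions\n")
  cat("  alleles per marker:", paste(range(x$markers$n_alleles), collapse = "-"),
      " mean", round(mean(x$markers$n_alleles), 2), "\n")
  invisible(x)
}

#' Write / read an SNPLDB marker set as TSV files
#'
#' `write_snpldb()` writes two tab-separated files under `prefix`:
#' `<prefix>_markers.tsv` (marker definitions, member SNP ids and allele
#' haplotypes with frequencies) and `<prefix>_codes.tsv` (markers x
#' accessions allele-code matrix). `read_snpldb()` restores the set.
#'
#' @param x an `snpldb_set`.
#' @param prefix file path prefix.
#' @return `write_snpldb()` returns the two paths invisibly; `read_snpldb()`
#'   returns an `snpldb_set`.
#' @export
write_snpldb <- function(x, prefix) {
  stopifnot(inherits(x, "snpldb_set"))
  def <- x$markers
  def$snp_ids <- vapply(x$snp_ids, paste, character(1), collapse = ",")
  def$allele_haplotypes <- vapply(x$alleles, function(a)
    paste(a$haplotype, collapse = ","), character(1))
  def$allele_freqs <- vapply(x$alleles, function(a)
    paste(format(a$freq, digits = 12, scientific = FALSE, trim = TRUE), collapse = ","), character(1))
  p1 <- paste0(prefix, "_markers.tsv")
  p2 <- paste0(prefix, "_codes.tsv")
  utils::write.table(def, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  codes <- data.frame(marker = rownames(x$codes), x$codes, check.names = FALSE)
  utils::write.table(codes, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_snpldb
#' @export
read_snpldb <- function(prefix) {
  def <- utils::read.delim(paste0(prefix, "_markers.tsv"), stringsAsFactors = FALSE)
  codes_df <- utils::read.delim(paste0(prefix, "_codes.tsv"), check.names = FALSE,
                                stringsAsFactors = FALSE)
  codes <- as.matrix(codes_df[, -1L, drop = FALSE])
  storage.mode(codes) <- "integer"
  rownames(codes) <- codes_df$marker
  alleles <- lapply(seq_len(nrow(def)), function(i) {
    hp <- strsplit(def$allele_haplotypes[i], ",")[[1L]]
    fr <- as.numeric(strsplit(def$allele_freqs[i], ",")[[1L]])
    data.frame(code = seq_along(hp), haplotype = hp, freq = fr,
               stringsAsFactors = FALSE)
  })
  structure(list(
    markers = def[, c("id", "chrom", "start_bp", "end_bp", "pos_cM",
                      "n_snps", "n_alleles", "type")],
    snp_ids = strsplit(def$snp_ids, ","),
    alleles = alleles, codes = codes,
    accessions = colnames(codes)), class = "snpldb_set")
}
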