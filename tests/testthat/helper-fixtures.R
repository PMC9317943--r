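# Shared fixture builders. Everything is generated in code; no stored data.

# genotype_matrix from a plain call matrix (one chromosome unless given)
make_geno <- function(calls, chrom = NULL, pos_bp = NULL, pos_cM = NULL) {
  calls <- as.matrix(calls)
  n_snp <- nrow(calls)
  if (is.null(chrom)) chrom <- rep("chr01", n_snp)
  if (is.null(pos_bp)) pos_bp <- stats::ave(seq_len(n_snp), chrom, FUN = seq_along) * 100L
  if (is.null(pos_cM)) pos_cM <- pos_bp / 4e5
  info <- data.frame(id = sprintf("s%03d", seq_len(n_snp)), chrom = chrom,
                     pos_bp = pos_bp, pos_cM = pos_cM, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, info, sprintf("a%03d", seq_len(ncol(calls))))
}

# snpldb_set from an allele-code matrix (markers x accessions)
make_snpldb <- function(codes, chrom = NULL, start_bp = NULL, pos_cM = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  m <- nrow(codes); n <- ncol(codes)
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("a%03d", seq_len(n))
  if (is.null(chrom)) chrom <- rep("chr01", m)
  if (is.null(start_bp)) start_bp <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1e6
  if (is.null(pos_cM)) pos_cM <- start_bp / 4e5
  ids <- sprintf("ldb_%02d", seq_len(m))
  rownames(codes) <- ids
  n_all <- apply(codes, 1L, max)
  alleles <- lapply(seq_len(m), function(i) {
    k <- n_all[i]
    cnt <- tabulate(codes[i, ], nbins = k)
    data.frame(code = seq_len(k), haplotype = strrep("A", seq_len(k)),
               freq = cnt / n, stringsAsFactors = FALSE)
  })
  structure(list(
    markers = data.frame(id = ids, chrom = chrom, start_bp = start_bp,
                         end_bp = start_bp + 500, pos_cM = pos_cM,
                         n_snps = 1L, n_alleles = n_all, type = "S",
                         stringsAsFactors = FALSE),
    snp_ids = as.list(ids), alleles = alleles, codes = codes,
    accessions = colnames(codes)), class = "snpldb_set")
}

# minimal rtm_gwas-classed object for downstream modules (evolution, crosses)
make_fake_model <- function(effects, codes, intercept = 0,
                            chrom = NULL, pos_cM = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  ids <- names(effects)
  rownames(codes) <- ids
  m <- length(effects)
  if (is.null(chrom)) chrom <- rep("chr01", m)
  if (is.null(pos_cM)) pos_cM <- seq_len(m) * 10
  eff_tabs <- lapply(seq_along(effects), function(i) {
    e <- effects[[i]]
    cnt <- tabulate(codes[i, ], nbins = length(e))
    data.frame(code = seq_along(e), haplotype = strrep("A", seq_along(e)),
               freq = cnt / ncol(codes), effect = e, stringsAsFactors = FALSE)
  })
  names(eff_tabs) <- ids
  loci <- data.frame(id = ids, chrom = chrom, start_bp = seq_len(m) * 1e6,
                     end_bp = seq_len(m) * 1e6 + 500, pos_cM = pos_cM,
                     n_alleles = vapply(effects, length, integer(1)),
                     has_main = TRUE, has_qei = FALSE,
                     neglog10_p_model = NA_real_, neglog10_p_main = NA_real_,
                     neglog10_p_qei = NA_real_,
                     r2_main_pct = NA_real_, r2_qei_pct = NA_real_,
                     stringsAsFactors = FALSE)
  structure(list(loci = loci, effects = eff_tabs, qei_effects = list(),
                 intercept = intercept, r2_qtl_total = NA_real_, h2_cap = 1,
                 stage1 = data.frame(), include_qei = FALSE,
                 accessions = colnames(codes), codes = codes),
            class = "rtm_gwas")
}

# accession x environment phenotype means table
make_means <- function(values_by_acc_env) {
  # values: matrix accessions x environments, dimnames required
  df <- expand.grid(accession = rownames(values_by_acc_env),
                    environment = colnames(values_by_acc_env),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- values_by_acc_env[cbind(df$accession, df$environment)]
  df
}

# direct (textbook) |D'| from a 2x2 gametic count table, independent of d_prime()
dprime_oracle <- function(nAB, nAb, naB, nab) {
  n <- nAB + nAb + naB + nab
  pA <- (nAB + nAb) / n; pB <- (nAB + naB) / n
  D <- nAB / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  abs(D) / dmax
}
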