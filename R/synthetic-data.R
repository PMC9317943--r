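#' Configuration for the synthetic-study generator
#'
#' Defines a synthetic multi-environment trial on a panel of inbred
#' accessions whose genome is organized in founder-haplotype LD blocks:
#' within a block the founder haplotypes descend from a mutation tree
#' (mutations on nested carrier sets), so every within-block SNP pair is in
#' complete LD (|D'| = 1) while blocks assort freely. Tens of blocks carry
#' multi-allelic QTL effects of both signs. Phenotypes follow the joint
#' randomized-block model y_ijk = mu + t_i + r_j(i) + g_k + (gt)_ik + e_ijk
#' with the interaction and error variances solved so the realized
#' entry-mean heritability and its genotype-by-environment counterpart hit
#' the targets.
#'
#' @param n_accessions panel size (default 361).
#' @param n_chromosomes chromosomes (default 20).
#' @param chrom_cM_length genetic length per chromosome in cM (recycled;
#'   default 120).
#' @param chrom_bp_length physical length per chromosome in bp (recycled;
#'   default 5e7).
#' @param n_blocks_per_chrom LD blocks per chromosome (default 25).
#' @param snps_per_block SNPs per block (default 4; a block with S SNPs can
#'   carry at most S + 1 distinct haplotype alleles).
#' @param n_qtls number of QTL blocks (default 40).
#' @param alleles_per_qtl admissible range of distinct haplotype alleles at
#'   a QTL block (default c(2, 10)).
#' @param qtl_effect_sd SD of raw per-haplotype effects, trait units
#'   (default 0.4).
#' @param trait_mean population mean, trait units (default 40.8).
#' @param n_environments,n_replications trial design (defaults 2 and 4).
#' @param target_h2 target entry-mean heritability (default 0.83).
#' @param target_h2_gei target genotype-by-environment share of entry-mean
#'   variance (default 0.12); `target_h2 + target_h2_gei` must be <= 1.
#' @param env_var,rep_var variances of the random environment and
#'   replication-within-environment effects (defaults 0.25, 0.05).
#' @param mg_labels ordered maturity-group labels.
#' @param mg_props group proportions (default mirrors a 361-accession panel
#'   split 21/43/79/157/45/16).
#' @param founder_pool founder haplotypes per block (default 12).
#' @param founder_decay geometric decay ratio of founder frequencies
#'   (default 0.65), giving a handful of common haplotypes per block.
#' @param dirichlet_conc concentration of the per-group Dirichlet
#'   perturbation of founder frequencies (default 50; larger = milder
#'   subpopulation structure).
#' @param equalize_qtl_variance rescale each QTL's centered effects so every
#'   locus contributes the same realized genotypic variance
#'   (`qtl_effect_sd^2`); used for designed recovery experiments where the
#'   planted loci should be equally detectable (default FALSE).
#' @param genes_per_chrom annotated genes per chromosome (default 40).
#' @param rng_seed integer seed (default 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 361, n_chromosomes = 20,
                       chrom_cM_length = 120, chrom_bp_length = 5e7,
                       n_blocks_per_chrom = 25, snps_per_block = 4,
                       n_qtls = 40, alleles_per_qtl = c(2, 10),
                       qtl_effect_sd = 0.4, trait_mean = 40.8,
                       n_environments = 2, n_replications = 4,
                       target_h2 = 0.83, target_h2_gei = 0.12,
                       env_var = 0.25, rep_var = 0.05,
                       mg_labels = c("III", "II", "I", "0", "00", "000"),
                       mg_props = c(21, 43, 79, 157, 45, 16) / 361,
                       founder_pool = 12, founder_decay = 0.65,
                       dirichlet_conc = 50, genes_per_chrom = 40,
                       equalize_qtl_variance = FALSE, rng_seed = 1L) {
  cfg <- list(n_accessions = n_accessions, n_chromosomes = n_chromosomes,
              chrom_cM_length = rep_len(chrom_cM_length, n_chromosomes),
              chrom_bp_length = rep_len(chrom_bp_length, n_chromosomes),
              n_blocks_per_chrom = n_blocks_per_chrom,
              snps_per_block = snps_per_block, n_qtls = n_qtls,
              alleles_per_qtl = alleles_per_qtl,
              qtl_effect_sd = qtl_effect_sd, trait_mean = trait_mean,
              n_environments = n_environments, n_replications = n_replications,
              target_h2 = target_h2, target_h2_gei = target_h2_gei,
              env_var = env_var, rep_var = rep_var,
              mg_labels = mg_labels, mg_props = mg_props / sum(mg_props),
              founder_pool = founder_pool, founder_decay = founder_decay,
              dirichlet_conc = dirichlet_conc,
              genes_per_chrom = genes_per_chrom,
              equalize_qtl_variance = isTRUE(equalize_qtl_variance),
              rng_seed = as.integer(rng_seed))
  counts <- c(n_accessions, n_chromosomes, n_blocks_per_chrom, snps_per_block,
              n_environments, n_replications)
  if (any(counts < 1)) stop("all design counts must be >= 1")
  if (n_qtls < 0) stop("n_qtls must be >= 0")
  if (n_qtls > n_chromosomes * n_blocks_per_chrom)
    stop("more QTLs than blocks")
  if (target_h2 <= 0 || target_h2 > 1 || target_h2_gei < 0 || target_h2_gei >= 1)
    stop("heritability targets out of range")
  if (target_h2 + target_h2_gei > 1)
    stop("infeasible variance targets: target_h2 + target_h2_gei > 1")
  if (length(mg_labels) != length(cfg$mg_props))
    stop("mg_labels and mg_props lengths differ")
  if (alleles_per_qtl[1] < 2 || alleles_per_qtl[2] > 10 ||
      alleles_per_qtl[1] > alleles_per_qtl[2])
    stop("alleles_per_qtl must be a range within [2, 10]")
  structure(cfg, class = "sim_config")
}

# Random laminar (nested-or-disjoint) proper subsets of 1..p, built by
# recursive binary splitting. Mutations on such subsets make every SNP pair
# within a block pass the four-gamete test, i.e. |D'| = 1.
laminar_subsets <- function(p) {
  subs <- list()
  split1 <- function(idx) {
    if (length(idx) < 2L) return(invisible())
    cut <- sample(seq_len(length(idx) - 1L), 1L)
    sh <- sample(idx)
    a <- sort(sh[seq_len(cut)]); b <- sort(sh[-seq_len(cut)])
    subs[[length(subs) + 1L]] <<- a
    subs[[length(subs) + 1L]] <<- b
    split1(a); split1(b)
  }
  split1(seq_len(p))
  unique(subs)
}

# Founder haplotype pool for one block: binary matrix founders x SNPs from
# mutations on laminar carrier sets, plus geometric base frequencies.
founder_block <- function(p, s, decay, allele_range = NULL, max_tries = 20L) {
  for (try in seq_len(max_tries)) {
    subs <- laminar_subsets(p)
    pick <- subs[sample(length(subs), min(s, length(subs)))]
    if (length(pick) < s)
      pick <- c(pick, subs[sample(length(subs), s - length(pick), replace = TRUE)])
    H <- matrix(0L, p, s)
    for (j in seq_len(s)) H[pick[[j]], j] <- 1L
    n_distinct <- nrow(unique(H))
    if (is.null(allele_range) ||
        (n_distinct >= allele_range[1] && n_distinct <= allele_range[2])) break
  }
  freq <- decay^(seq_len(p) - 1L)
  list(hap = H, freq = freq / sum(freq))
}

#' Generate a synthetic multi-environment study
#'
#' Builds the full synthetic study defined by a [sim_config()]: fully
#' homozygous accession genotypes sampled block-wise from founder haplotype
#' pools (maturity groups differ by a mild Dirichlet perturbation of the
#' founder frequencies), QTL effects per distinct block haplotype (drawn
#' symmetric around zero, then centered to a frequency-weighted zero mean),
#' and plot-level phenotypes with interaction and error variances solved
#' from the realized genotypic variance so the entry-mean heritability and
#' its genotype-by-environment share hit the configured targets:
#' with D = Vg / h2, sigma_gt2 = n_t h2_gei D and
#' sigma_e2 = n_t n_r (1 - h2 - h2_gei) D.
#'
#' @param config a [sim_config()].
#' @return List of class `synthetic_study`: `geno` (a [genotype_matrix()]),
#'   `phenotypes` (plot-level records), `mg` (named maturity-group vector),
#'   `map` (per-SNP chrom/bp/cM), `genes` + `go_table` (annotation),
#'   `truth` (per-QTL haplotype effects and frequencies), `g` (true
#'   genotypic values), `variances` (solved component values), `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  C <- config$n_chromosomes; B <- config$n_blocks_per_chrom
  S <- config$snps_per_block; P <- config$founder_pool
  n <- config$n_accessions
  chrom_names <- sprintf("chr%02d", seq_len(C))

  # maturity groups: fixed counts from proportions (largest-remainder rounding)
  raw <- config$mg_props * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1L
  }
  mg <- rep(config$mg_labels, cnt)
  acc_ids <- sprintf("L%03d", seq_len(n))
  names(mg) <- acc_ids
  n_mg <- length(config$mg_labels)

  qtl_blocks <- if (config$n_qtls > 0)
    sort(sample(C * B, config$n_qtls)) else integer(0)

  n_snps <- C * B * S
  calls <- matrix(0L, n_snps, n)
  snp_chrom <- character(n_snps); snp_bp <- integer(n_snps)
  snp_cM <- numeric(n_snps)
  g <- numeric(n)
  truth <- NULL
  qtl_hap <- matrix(NA_character_, length(qtl_blocks), n,
                    dimnames = list(NULL, acc_ids))
  block_no <- 0L
  for (ci in seq_len(C)) {
    bp_step <- config$chrom_bp_length[ci] / B
    cm_step <- config$chrom_cM_length[ci] / B
    for (bi in seq_len(B)) {
      block_no <- block_no + 1L
      is_qtl <- block_no %in% qtl_blocks
      fb <- founder_block(P, S, config$founder_decay,
                          if (is_qtl) config$alleles_per_qtl else NULL)
      # per-group Dirichlet-perturbed founder frequencies
      pick <- integer(n)
      for (m in seq_len(n_mg)) {
        idx <- which(mg == config$mg_labels[m])
        w <- stats::rgamma(P, shape = config$dirichlet_conc * fb$freq)
        if (sum(w) == 0) w <- fb$freq
        pick[idx] <- sample.int(P, length(idx), replace = TRUE, prob = w / sum(w))
      }
      rows <- (block_no - 1L) * S + seq_len(S)
      calls[rows, ] <- t(fb$hap[pick, , drop = FALSE]) * 2L
      snp_chrom[rows] <- chrom_names[ci]
      snp_bp[rows] <- as.integer(round((bi - 0.5) * bp_step)) + (seq_len(S) - 1L) * 200L
      snp_cM[rows] <- (bi - 0.5) * cm_step + (seq_len(S) - 1L) * 1e-4
      if (is_qtl) {
        hap_str <- apply(fb$hap, 1L, paste, collapse = "")
        acc_hap <- hap_str[pick]
        distinct <- unique(hap_str)
        eff <- stats::rnorm(length(distinct), 0, config$qtl_effect_sd)
        names(eff) <- distinct
        f_real <- table(factor(acc_hap, levels = distinct)) / n
        eff <- eff - sum(f_real * eff)           # frequency-weighted zero mean
        if (config$equalize_qtl_variance) {
          v <- sum(f_real * eff^2)
          if (v > 0) eff <- eff * config$qtl_effect_sd / sqrt(v)
        }
        g <- g + eff[acc_hap]
        qtl_hap[match(block_no, qtl_blocks), ] <- acc_hap
        truth <- rbind(truth, data.frame(
          qtl_id = sprintf("qtl_%02d", match(block_no, qtl_blocks)),
          block_id = sprintf("block_%s_%d", chrom_names[ci], bi),
          chrom = chrom_names[ci], block_index = block_no,
          start_bp = snp_bp[rows[1L]], end_bp = snp_bp[rows[S]],
          haplotype = distinct, effect = as.numeric(eff[distinct]),
          freq = as.numeric(f_real[distinct]),
          stringsAsFactors = FALSE))
      }
    }
  }
  g <- as.numeric(g)
  names(g) <- acc_ids

  # variance components solved against the realized genotypic variance
  Vg <- stats::var(g) * (n - 1) / n
  nt <- config$n_environments; nr <- config$n_replications
  if (Vg > 0) {
    D <- Vg / config$target_h2
    s_gt2 <- nt * config$target_h2_gei * D
    s_e2 <- nt * nr * (1 - config$target_h2 - config$target_h2_gei) * D
  } else {
    s_gt2 <- 0; s_e2 <- 1
  }
  t_i <- stats::rnorm(nt, 0, sqrt(config$env_var))
  r_ji <- matrix(stats::rnorm(nt * nr, 0, sqrt(config$rep_var)), nt, nr)
  gt_ik <- matrix(stats::rnorm(nt * n, 0, sqrt(s_gt2)), nt, n)
  env_ids <- sprintf("E%d", seq_len(nt))
  ph <- expand.grid(accession = acc_ids, environment = env_ids,
                    replication = sprintf("R%d", seq_len(nr)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ii <- match(ph$environment, env_ids)
  jj <- as.integer(sub("R", "", ph$replication))
  kk <- match(ph$accession, acc_ids)
  ph$value <- config$trait_mean + t_i[ii] + r_ji[cbind(ii, jj)] + g[kk] +
    gt_ik[cbind(ii, kk)] + stats::rnorm(nrow(ph), 0, sqrt(s_e2))

  map <- data.frame(chrom = snp_chrom, pos_bp = snp_bp, pos_cM = snp_cM,
                    stringsAsFactors = FALSE)
  snp_info <- data.frame(id = sprintf("snp_%05d", seq_len(n_snps)),
                         chrom = snp_chrom, pos_bp = snp_bp, pos_cM = snp_cM,
                         ref = "A", alt = "T", stringsAsFactors = FALSE)
  geno <- genotype_matrix(calls, snp_info, acc_ids)

  # gene annotation + functional categories
  cats <- c("transporter activity", "translation",
            "regulation of biological process", "metabolic process",
            "transcription", "phosphorylation", "catabolic process",
            "cellular process", "response to stimulus", "signaling",
            "biosynthetic process", "reproductive process", "other")
  genes <- NULL
  for (ci in seq_len(C)) {
    ng <- config$genes_per_chrom
    st <- sort(sample.int(config$chrom_bp_length[ci] - 6000L, ng))
    len <- sample(2000:5000, ng, replace = TRUE)
    genes <- rbind(genes, data.frame(
      gene_id = sprintf("gene_%s_%03d", chrom_names[ci], seq_len(ng)),
      chrom = chrom_names[ci], start = st, end = st + len,
      stringsAsFactors = FALSE))
  }
  annotated <- stats::runif(nrow(genes)) < 0.9
  go_table <- data.frame(
    gene_id = genes$gene_id[annotated],
    category = sample(cats, sum(annotated), replace = TRUE),
    stringsAsFactors = FALSE)

  if (length(qtl_blocks))
    rownames(qtl_hap) <- sprintf("qtl_%02d", seq_along(qtl_blocks))
  structure(list(geno = geno, phenotypes = ph, mg = mg, map = map,
                 genes = genes, go_table = go_table, truth = truth, g = g,
                 qtl_haplotypes = qtl_hap,
                 variances = list(sigma_g2 = Vg, sigma_gt2 = s_gt2,
                                  sigma_e2 = s_e2),
                 chrom_len_cM = stats::setNames(config$chrom_cM_length, chrom_names),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", length(x$geno$accessions), "accessions,",
      nrow(x$geno$calls), "SNPs,",
      if (is.null(x$truth)) 0 else length(unique(x$truth$qtl_id)), "QTL\n")
  cat(sprintf("  targets: h2 = %.2f, h2_gei = %.2f; realized Vg = %.4g\n",
              x$config$target_h2, x$config$target_h2_gei, x$variances$sigma_g2))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `genotypes.vcf` (VCF v4.2), `phenotypes.tsv`, `mg.tsv`,
#' `map.tsv`, `genes.gff3`, `go.tsv` and `truth.tsv` under `dir`. The file
#' set round-trips losslessly through [read_study()].
#'
#' @param study a [generate_population()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  p <- function(f) file.path(dir, f)
  write_vcf_genotypes(study$geno, p("genotypes.vcf"))
  wt <- function(d, f) utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(study$phenotypes, "phenotypes.tsv")
  wt(data.frame(accession = names(study$mg), mg = unname(study$mg)), "mg.tsv")
  wt(study$map, "map.tsv")
  wt(study$go_table, "go.tsv")
  if (!is.null(study$truth)) wt(study$truth, "truth.tsv")
  gff <- c("##gff-version 3",
           paste(study$genes$chrom, "qtlallele", "gene", study$genes$start,
                 study$genes$end, ".", "+", ".",
                 paste0("ID=", study$genes$gene_id), sep = "\t"))
  writeLines(gff, p("genes.gff3"))
  invisible(c(vcf = p("genotypes.vcf"), phenotypes = p("phenotypes.tsv"),
              mg = p("mg.tsv"), map = p("map.tsv"), genes = p("genes.gff3"),
              go = p("go.tsv"), truth = p("truth.tsv")))
}

#' Read a study back from files written by [write_study()]
#'
#' @param dir the study directory.
#' @return List with `geno`, `phenotypes`, `mg`, `map`, `genes`, `go_table`
#'   and (when present) `truth`.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  map <- utils::read.delim(p("map.tsv"), stringsAsFactors = FALSE)
  geno <- read_vcf_genotypes(p("genotypes.vcf"), map = map)
  ph <- utils::read.delim(p("phenotypes.tsv"), stringsAsFactors = FALSE,
                          colClasses = c(accession = "character",
                                         environment = "character",
                                         replication = "character"))
  mgt <- utils::read.delim(p("mg.tsv"), stringsAsFactors = FALSE,
                           colClasses = "character")
  mg <- stats::setNames(mgt$mg, mgt$accession)
  genes <- read_gene_annotation(p("genes.gff3"))
  go <- utils::read.delim(p("go.tsv"), stringsAsFactors = FALSE)
  truth <- if (file.exists(p("truth.tsv")))
    utils::read.delim(p("truth.tsv"), stringsAsFactors = FALSE,
                      colClasses = c(haplotype = "character")) else NULL
  list(geno = geno, phenotypes = ph, mg = mg, map = map, genes = genes,
       go_table = go, truth = truth)
}
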