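#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with defaults
#' matching the package's reference settings: QC thresholds 20% missing, 20%
#' heterozygosity, 1% MAF; |D'| > 0.7 block threshold; association
#' thresholds 0.05 (preselection) and 0.01 (stepwise) with 10 structure
#' eigenvectors; 200 kb candidate-gene pad; 2000 progenies per cross with
#' percentiles 90/95/99.
#'
#' @param input either a [sim_config()] (the study is simulated) or a
#'   directory containing the file set of [write_study()].
#' @param out_dir run directory for stage outputs.
#' @param seed global seed; stages derive independent streams from it.
#' @param max_missing,max_het,min_maf SNP QC thresholds.
#' @param d_threshold LD block threshold on |D'|.
#' @param alpha1,alpha2 association-stage thresholds.
#' @param n_eigenvectors structure covariates.
#' @param lc_threshold_pct large-contribution threshold (percent PV).
#' @param old_groups,new_groups maturity-group labels forming the "old" and
#'   "new" subpopulations for allele-evolution tracking.
#' @param cross_supergroups named vector collapsing maturity groups into the
#'   crossing scopes (default merges the old groups into one).
#' @param n_progeny,model,progeny_model,percentiles cross-simulation
#'   settings (see [progeny_sim_config()]).
#' @param pad_bp,flank_bp,gene_alpha candidate-gene settings.
#' @param stages which stages to run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, seed = 1L,
                            max_missing = 0.20, max_het = 0.20, min_maf = 0.01,
                            d_threshold = 0.7, alpha1 = 0.05, alpha2 = 0.01,
                            n_eigenvectors = 10, lc_threshold_pct = 1,
                            old_groups = c("III", "II", "I"),
                            new_groups = c("0", "00", "000"),
                            cross_supergroups = NULL,
                            n_progeny = 2000, model = "linkage",
                            progeny_model = "doubled_gamete",
                            percentiles = c(90, 95, 99),
                            pad_bp = 2e5, flank_bp = 5e3, gene_alpha = 0.05,
                            stages = c("simulate", "qc", "snpldb", "anova",
                                       "gwas", "evolution", "cross", "genes",
                                       "report")) {
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 max_missing = max_missing, max_het = max_het,
                 min_maf = min_maf, d_threshold = d_threshold,
                 alpha1 = alpha1, alpha2 = alpha2,
                 n_eigenvectors = n_eigenvectors,
                 lc_threshold_pct = lc_threshold_pct,
                 old_groups = old_groups, new_groups = new_groups,
                 cross_supergroups = cross_supergroups,
                 n_progeny = n_progeny, model = model,
                 progeny_model = progeny_model, percentiles = percentiles,
                 pad_bp = pad_bp, flank_bp = flank_bp, gene_alpha = gene_alpha,
                 stages = stages), class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order, writing each stage's
#' outputs as TSV files under the run directory together with a provenance
#' manifest (`manifest.tsv`: file, md5) and the serialized configuration
#' (`config.json`). Reruns with the same configuration are reproducible:
#' deterministic stages byte-identically, stochastic stages through seeds
#' derived from the global seed. A stage whose upstream outputs are missing
#' stops with a missing-dependency error.
#'
#' @param config a [pipeline_config()].
#' @return The run directory path, invisibly; the fitted objects are
#'   returned as attribute `objects`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  wt <- function(d, f) utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  need <- function(stage, files) {
    miss <- files[!file.exists(p(files))]
    if (length(miss))
      stop("stage '", stage, "' missing dependency file(s): ",
           paste(miss, collapse = ", "))
  }
  st <- config$stages
  obj <- list()

  if ("simulate" %in% st) {
    if (inherits(config$input, "sim_config")) {
      sim <- config$input
      sim$rng_seed <- config$seed
      class(sim) <- "sim_config"
      study <- generate_population(sim)
      write_study(study, p("study"))
    } else {
      if (!dir.exists(config$input)) stop("input directory not found")
      dir.create(p("study"), showWarnings = FALSE)
      file.copy(list.files(config$input, full.names = TRUE), p("study"),
                overwrite = TRUE)
    }
  }
  study <- NULL
  load_study <- function() {
    if (is.null(study)) {
      need("load", "study/phenotypes.tsv")
      study <<- read_study(p("study"))
    }
    study
  }

  if ("qc" %in% st) {
    s <- load_study()
    filtered <- filter_snps(s$geno, config$max_missing, config$max_het,
                            config$min_maf)
    imputed <- impute_missing(filtered)
    obj$geno <- imputed
    wt(data.frame(criterion = names(attr(filtered, "filter_report")),
                  n = as.integer(attr(filtered, "filter_report"))),
       "qc_report.tsv")
    write_vcf_genotypes(imputed, p("genotypes_qc.vcf"))
  }

  if ("snpldb" %in% st) {
    need("snpldb", "genotypes_qc.vcf")
    s <- load_study()
    geno <- obj$geno
    if (is.null(geno))
      geno <- read_vcf_genotypes(p("genotypes_qc.vcf"), map = s$map)
    ldb <- assemble_snpldb(geno, d_threshold = config$d_threshold)
    obj$snpldb <- ldb
    write_snpldb(ldb, p("snpldb"))
  }

  if ("anova" %in% st) {
    s <- load_study()
    an <- fit_joint_anova(s$phenotypes)
    vc <- estimate_variance_components(s$phenotypes)
    h2 <- heritability(vc, "multi")
    mgsum <- summarize_by_mg(s$phenotypes, s$mg)
    obj$vc <- vc
    wt(an, "anova.tsv")
    wt(data.frame(quantity = c("sigma_g2", "sigma_gt2", "sigma_e2", "mu",
                               "h2_multi", "h2_single", "h2_gei", "gcv_pct"),
                  value = c(vc$sigma_g2, vc$sigma_gt2, vc$sigma_e2, vc$mu,
                            h2, heritability(vc, "single"),
                            heritability(vc, "gei"), gcv(vc))),
       "variance_components.tsv")
    wt(mgsum$summary, "mg_summary.tsv")
    wt(data.frame(group = rownames(mgsum$bins), mgsum$bins,
                  check.names = FALSE), "mg_bins.tsv")
  }

  if ("gwas" %in% st) {
    need("gwas", c("snpldb_markers.tsv", "variance_components.tsv"))
    s <- load_study()
    ldb <- if (is.null(obj$snpldb)) read_snpldb(p("snpldb")) else obj$snpldb
    vct <- utils::read.delim(p("variance_components.tsv"))
    h2 <- vct$value[vct$quantity == "h2_multi"]
    fit <- rtm_gwas(s$phenotypes, ldb, h2_cap = h2, alpha1 = config$alpha1,
                    alpha2 = config$alpha2,
                    n_eigenvectors = config$n_eigenvectors)
    obj$gwas <- fit
    sm <- summary(fit, lc_threshold_pct = config$lc_threshold_pct)
    wt(sm$loci, "qtl_table.tsv")
    wt(coef(fit), "allele_effects.tsv")
    qm <- qtl_allele_matrix(fit)
    wt(data.frame(locus = rownames(qm), qm, check.names = FALSE),
       "qtl_allele_matrix.tsv")
    wt(fit$stage1, "stage1_scan.tsv")
  }

  if ("evolution" %in% st) {
    need("evolution", "qtl_table.tsv")
    s <- load_study()
    fit <- obj$gwas
    if (is.null(fit)) stop("stage 'evolution' requires the gwas fit in-session")
    old_acc <- names(s$mg)[s$mg %in% config$old_groups]
    new_acc <- names(s$mg)[s$mg %in% config$new_groups]
    if (length(old_acc) && length(new_acc) && nrow(fit$loci) > 0) {
      chg <- compare_groups(allele_presence(fit, old_acc),
                            allele_presence(fit, new_acc))
      obj$evolution <- chg
      wt(allele_change_table(chg), "allele_changes.tsv")
    } else {
      wt(data.frame(note = "no loci or empty group"), "allele_changes.tsv")
    }
  }

  if ("cross" %in% st) {
    need("cross", "qtl_table.tsv")
    s <- load_study()
    fit <- obj$gwas
    if (is.null(fit)) stop("stage 'cross' requires the gwas fit in-session")
    sg <- config$cross_supergroups
    if (is.null(sg)) {
      labs <- unique(s$mg)
      sg <- stats::setNames(labs, labs)
      sg[labs %in% config$old_groups] <- paste(config$old_groups, collapse = "+")
    }
    groups <- stats::setNames(unname(sg[s$mg]), names(s$mg))
    observed <- tapply(s$phenotypes$value, s$phenotypes$accession, mean)
    cfg <- progeny_sim_config(n_progeny = config$n_progeny,
                              model = config$model,
                              progeny_model = config$progeny_model,
                              percentiles = config$percentiles,
                              seed = config$seed + 1L)
    chrom_len <- if (!is.null(s$map)) tapply(s$map$pos_cM, s$map$chrom, max) + 5
      else NULL
    recs <- cross_potential_all(fit, cfg, observed = observed,
                                groups = groups, chrom_len = chrom_len)
    obj$crosses <- recs
    wt(recs, "cross_records.tsv")
    if (nrow(fit$loci) > 0) {
      gmax <- tapply(observed[names(groups)], groups, max)
      pot <- summarize_potentials(recs, mean(observed), gmax)
      wt(pot, "cross_potentials.tsv")
      top <- NULL
      for (sc in c(unique(recs$scope[recs$within]), "entire"))
        top <- rbind(top, cbind(scope_ranked = sc, rank_optimal(recs, sc)))
      wt(top, "optimal_crosses.tsv")
    }
  }

  if ("genes" %in% st) {
    need("genes", "qtl_table.tsv")
    s <- load_study()
    fit <- obj$gwas
    if (is.null(fit)) stop("stage 'genes' requires the gwas fit in-session")
    geno <- obj$geno
    if (is.null(geno)) geno <- read_vcf_genotypes(p("genotypes_qc.vcf"), map = s$map)
    cg <- candidate_gene_scan(fit, geno, s$genes, pad_bp = config$pad_bp,
                              flank_bp = config$flank_bp,
                              alpha = config$gene_alpha)
    obj$genes <- cg
    wt(cg, "candidate_genes.tsv")
    tall <- categorize_genes(cg, s$go_table)
    wt(data.frame(category = names(tall), n = as.integer(tall)),
       "gene_categories.tsv")
  }

  # provenance manifest + serialized config
  cfg_out <- config
  cfg_out$out_dir <- NULL          # path is where the file lives; keep the
                                   # serialized config location-independent
  cfg_out$input <- if (inherits(config$input, "sim_config"))
    unclass(config$input) else config$input
  jsonlite::write_json(unclass(cfg_out), p("config.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   c("manifest.tsv", "report.md"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(p(files))),
                         stringsAsFactors = FALSE)
  wt(manifest, "manifest.tsv")

  if ("report" %in% st) make_report(config$out_dir)
  out <- config$out_dir
  attr(out, "objects") <- obj
  invisible(out)
}

#' Render a human-readable run report
#'
#' Assembles `report.md` from the stage output files of a completed run —
#' maturity-group summary, QTL table, allele-change summary, cross-potential
#' summary and optimal crosses. Every number is read from a stage file; the
#' reporter recomputes nothing.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return Path of `report.md`, invisibly.
#' @export
make_report <- function(run_dir) {
  p <- function(f) file.path(run_dir, f)
  rd <- function(f) if (file.exists(p(f)))
    utils::read.delim(p(f), check.names = FALSE) else NULL
  md_table <- function(d) {
    if (is.null(d)) return("_stage output missing_")
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) formatC(x, digits = 4, format = "fg"))
    c(paste("|", paste(names(d), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|"),
      vapply(seq_len(nrow(d)), function(i)
        paste("|", paste(unlist(d[i, ]), collapse = " | "), "|"), character(1)))
  }
  qtl <- rd("qtl_table.tsv")
  lines <- c(
    "# Pipeline run report", "",
    "## Trait summary by maturity group", "", md_table(rd("mg_summary.tsv")), "",
    "## Variance components and heritability", "",
    md_table(rd("variance_components.tsv")), "",
    "## Detected QTL",
    "",
    if (is.null(qtl) || nrow(qtl) == 0L) "Zero loci detected." else md_table(qtl),
    "",
    "## Allele changes between subpopulations", "",
    md_table(rd("allele_changes.tsv")), "",
    "## Cross potentials by scope", "", md_table(rd("cross_potentials.tsv")), "",
    "## Optimal crosses", "", md_table(rd("optimal_crosses.tsv")), "",
    "## Candidate-gene categories", "", md_table(rd("gene_categories.tsv")))
  writeLines(lines, p("report.md"))
  invisible(p("report.md"))
}
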