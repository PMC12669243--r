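# End-to-end orchestration: QC -> population structure -> ROH calling ->
# F_ROH trait correlation -> regional autozygosity LMM association ->
# clumping -> additive/recessive genotype validation, from one declarative
# config, with per-stage count logging and TSV outputs.

#' Pipeline configuration
#'
#' Collects every stage's parameters in one declarative object so the
#' analysis dialect is a single readable artifact. Input is either a file
#' prefix (bed/bim/fam + phenotype TSV) or an in-memory cohort.
#'
#' @param bed_prefix path prefix of the PLINK fileset (alternative to
#'   \code{genotypes}).
#' @param pheno_path phenotype TSV path (alternative to \code{pheno}).
#' @param genotypes,pheno in-memory \code{genotype_matrix} and phenotype
#'   data.frame.
#' @param qc a \code{\link{qc_thresholds}} object.
#' @param roh a \code{\link{roh_params}} object; \code{genome_length_bp = NA}
#'   means "use the span covered by the SNP map".
#' @param n_pcs principal components to compute (the first two enter the
#'   association model).
#' @param prune_window,prune_step,prune_r2 LD-pruning parameters for the PCA.
#' @param traits trait columns for the F_ROH correlation scan.
#' @param assoc_trait trait for the regional association.
#' @param regional_freq_min regional-frequency filter (default 0.01).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param nominal_p nominal significance line for the Manhattan table.
#' @param clump_p1,clump_p2,clump_r2,clump_kb clumping parameters.
#' @param out_dir output directory (NULL = no files written).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(bed_prefix = NULL, pheno_path = NULL,
                            genotypes = NULL, pheno = NULL,
                            qc = qc_thresholds(), roh = roh_params(),
                            n_pcs = 10, prune_window = 50, prune_step = 5,
                            prune_r2 = 0.2,
                            traits = "trait", assoc_trait = traits[1],
                            regional_freq_min = 0.01, alpha = 0.05,
                            nominal_p = 1e-5,
                            clump_p1 = 1e-4, clump_p2 = 0.01,
                            clump_r2 = 0.5, clump_kb = 250,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full autozygosity-association pipeline
#'
#' Stages, in order: quality control; LD pruning + PCA and GRM; ROH calling
#' with inclusion matrix, F_ROH and summaries; Spearman/BH F_ROH-trait scan;
#' regional autozygosity LMM association (top two PCs, sex, age fixed, GRM
#' random) with Bonferroni threshold and LD clumping; additive and recessive
#' genotype-model validation at the clump index SNPs; Manhattan-ready table.
#' Every stage logs entering/leaving counts. Deterministic given its inputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return result bundle (named list of every stage's tables), invisibly
#'   also written as TSV/JSON under \code{config$out_dir} when set.
#' @export
run_pipeline <- function(config) {
  log_msg <- function(...) message("[rohscan] ", ...)
  g <- config$genotypes
  if (is.null(g)) {
    if (is.null(config$bed_prefix)) stop("no genotype input configured")
    g <- read_bed(paste0(config$bed_prefix, ".bed"), orient_minor = TRUE)
  }
  pheno <- config$pheno
  if (is.null(pheno)) {
    if (is.null(config$pheno_path)) stop("no phenotype input configured")
    pheno <- read_pheno(config$pheno_path)
  }
  log_msg("input: ", n_samples(g), " samples x ", n_variants(g), " variants")

  qc_res <- apply_qc(g, config$qc)
  g <- qc_res$genotypes
  log_msg("qc: ", n_samples(g), " samples x ", n_variants(g),
          " variants retained")
  pheno <- pheno[match(g$samples, pheno$sample_id), , drop = FALSE]
  if (anyNA(pheno$sample_id)) stop("phenotype table misses QC'd samples")

  kept <- ld_prune(g, config$prune_window, config$prune_step,
                   config$prune_r2)
  log_msg("ld_prune: ", length(kept), " of ", n_variants(g),
          " variants retained")
  pcs <- pca_genotypes(subset_genotypes(g, variants = kept),
                       k = min(config$n_pcs, length(kept), n_samples(g)))
  kin <- grm(g)

  params <- config$roh
  if (is.na(params$genome_length_bp)) {
    params$genome_length_bp <- sum(tapply(g$variants$pos, g$variants$chrom,
                                          function(p) max(p) - min(p) + 1))
    log_msg("froh denominator from SNP map span: ",
            format(params$genome_length_bp, big.mark = ","), " bp")
  }
  segments <- call_roh(g, params)
  log_msg("roh: ", nrow(segments), " segments called")
  incl <- inclusion_matrix(segments, g$variants, g$samples)
  summary_roh <- summarize_roh(segments, g$samples, params)
  freq_regions <- region_frequency(incl, g$variants)
  pheno$froh <- froh(segments, g$samples, params)

  corr <- froh_trait_scan(pheno, config$traits)

  status <- filter_for_association(incl, config$regional_freq_min)
  rep_f <- attr(status, "report")
  log_msg("regional filter: removed ", rep_f$samples_removed,
          " zero-ROH samples and ", rep_f$snps_removed,
          " low-frequency SNPs; testing ", rep_f$n_snps, " SNPs on ",
          rep_f$n_samples, " samples")
  idx_s <- match(rownames(status), g$samples)
  covars <- cbind(pcs$components[idx_s, 1:2, drop = FALSE],
                  sex = as.numeric(pheno$sex[idx_s] == "male"),
                  age = pheno$age[idx_s])
  y <- pheno[[config$assoc_trait]][idx_s]
  cc <- stats::complete.cases(covars, y)
  if (any(!cc)) log_msg("regional assoc: dropped ", sum(!cc),
                        " incomplete cases")
  fit <- fit_null_lmm(y[cc], covars[cc, , drop = FALSE],
                      kin[idx_s[cc], idx_s[cc]])
  log_msg("null LMM: var_g = ", signif(fit$var_g, 4), ", var_e = ",
          signif(fit$var_e, 4))
  assoc <- test_regional(status[cc, , drop = FALSE], fit, g$variants)
  n_tests <- sum(!is.na(assoc$p))
  threshold <- bonferroni_threshold(config$alpha, n_tests)
  log_msg("bonferroni: alpha ", config$alpha, " / ", n_tests,
          " tests = ", signif(threshold, 4))
  clumped <- clump_assoc(assoc, g, config$clump_p1, config$clump_p2,
                         config$clump_r2, config$clump_kb)

  index_ids <- unique(clumped$clump[!is.na(clumped$clump) &
                                      clumped$clump == clumped$id])
  validation <- NULL
  for (vid in index_ids) {
    j <- match(vid, g$variants$id)
    for (mod in c("additive", "recessive")) {
      res <- test_genotype(encode_genotype(g$calls[idx_s[cc], j], mod),
                           y[cc], covars[cc, , drop = FALSE], model = mod)
      validation <- rbind(validation,
                          cbind(data.frame(id = vid,
                                           chrom = g$variants$chrom[j],
                                           pos = g$variants$pos[j]), res))
    }
  }

  manhattan <- make_manhattan_table(clumped, genome_wide = threshold,
                                    nominal = config$nominal_p)

  bundle <- list(qc_report = qc_res$report, pcs = pcs, grm = kin,
                 roh_params = params, segments = segments,
                 inclusion = incl, roh_summary = summary_roh,
                 roh_frequency = freq_regions$frequency,
                 roh_regions = freq_regions$regions,
                 pheno = pheno, froh_correlations = corr,
                 null_fit = fit, regional_assoc = clumped,
                 bonferroni = threshold, n_tests = n_tests,
                 genotype_validation = validation, manhattan = manhattan)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$qc_report,
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pcs <- data.frame(sample_id = rownames(bundle$pcs$components),
                    bundle$pcs$components)
  tsv(pcs, "pcs.tsv")
  tsv(data.frame(sample_id = rownames(bundle$grm), bundle$grm,
                 check.names = FALSE), "grm.tsv")
  write_hom(bundle$segments, file.path(out_dir, "roh.hom"))
  tsv(bundle$roh_summary$per_sample, "roh_summary.tsv")
  tsv(bundle$roh_frequency, "roh_frequency.tsv")
  tsv(bundle$roh_regions, "roh_regions.tsv")
  tsv(bundle$froh_correlations, "froh_assoc.tsv")
  tsv(bundle$regional_assoc, "regional_assoc.tsv")
  if (!is.null(bundle$genotype_validation))
    tsv(bundle$genotype_validation, "genotype_validation.tsv")
  tsv(bundle$manhattan, "manhattan.tsv")
  invisible(out_dir)
}

#' Manhattan-ready association table
#'
#' Adds a cumulative genome coordinate (chromosomes laid end to end in map
#' order) and a significance tier: \code{"genome_wide"} when
#' p < \code{genome_wide}, else \code{"nominal"} when p < \code{nominal},
#' else \code{"none"}.
#'
#' @param assoc association data.frame with chrom, pos, p.
#' @param genome_wide,nominal the two significance lines.
#' @return the table with \code{cum_pos} and \code{tier} columns, sorted by
#'   chrom and pos.
#' @export
make_manhattan_table <- function(assoc, genome_wide = 1.21e-8,
                                 nominal = 1e-5) {
  if (nrow(assoc) == 0) {
    assoc$cum_pos <- numeric(0)
    assoc$tier <- character(0)
    return(assoc)
  }
  chroms <- unique(assoc$chrom)
  spans <- vapply(chroms, function(ch) max(assoc$pos[assoc$chrom == ch]),
                  numeric(1))
  offset <- stats::setNames(cumsum(c(0, spans[-length(spans)])), chroms)
  out <- assoc[order(match(assoc$chrom, chroms), assoc$pos), , drop = FALSE]
  out$cum_pos <- out$pos + offset[as.character(out$chrom)]
  out$tier <- ifelse(is.na(out$p), NA_character_,
                     ifelse(out$p < genome_wide, "genome_wide",
                            ifelse(out$p < nominal, "nominal", "none")))
  rownames(out) <- NULL
  out
}
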