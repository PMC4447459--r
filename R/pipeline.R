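#' Pipeline configuration
#'
#' Collects stage parameters, stage toggles and a single global seed for an
#' end-to-end run.  Input data can come from files (`paths`) or from the
#' synthetic generator (`sim`).  The global seed fans out to per-stage seeds
#' via a deterministic counter, so stages can be re-run in isolation.
#'
#' @param sim a [sim_config()] to simulate the inputs, or `NULL`.
#' @param paths named list of input files (`expr`, `detect`, `meta`,
#'   `anno`, and optionally `geno`, `geno_annot`, `geno_validation`,
#'   `meta_validation`) when `sim` is `NULL`.
#' @param B directional-test permutations.
#' @param alpha directional-test significance level.
#' @param R,T_trees,split repeated-forest parameters.
#' @param top_frac HI importance fraction.
#' @param half_window cis window half-width in bp.
#' @param alpha_eqtl,alpha_assoc eQTL and association significance levels.
#' @param k flat cluster count.
#' @param linkage clustering linkage.
#' @param anova_alpha,lrl_target comparator parameters.
#' @param stages character vector of stages to run, a subset of the default.
#' @param seed global integer seed.
#' @param out_dir optional directory for stage output tables.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            B = 5000, alpha = 0.01,
                            R = 2000, T_trees = 2500, split = 0.75,
                            top_frac = 0.1, half_window = 5e5,
                            alpha_eqtl = 0.01, alpha_assoc = 0.05,
                            k = 3, linkage = "complete",
                            anova_alpha = 0.001, lrl_target = 15,
                            stages = c("preprocess", "gmwt", "rf",
                                       "cluster", "eqtl", "comparators"),
                            seed = 1L, out_dir = NULL) {
  cfg <- mget(names(formals()))
  if (is.null(sim) && is.null(paths))
    stop("either a simulation config or input paths are required")
  if (is.null(sim)) {
    absent <- setdiff(c("expr", "detect", "meta"), names(paths))
    if (length(absent))
      stop("missing input paths (data_model): ",
           paste(absent, collapse = ", "))
    bad <- !vapply(unlist(paths), file.exists, logical(1))
    if (any(bad))
      stop("input files not found (data_model): ",
           paste(unlist(paths)[bad], collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full two-stage screening pipeline
#'
#' Stage order: load or simulate, detection filter and quantile
#' normalization, directional testing, repeated random forest, HI-probe
#' selection, Kendall-distance clustering with ARI, cis-eQTL and Fisher
#' association with validation, and the ANOVA / LRL comparators.  Stages
#' not listed in the config are skipped (their report fields stay `NULL`).
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"pipeline_report"`: list of stage results
#'   plus a `counts` summary.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_seed <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      config$seed + counter
    }
  })
  rep <- list(config = config)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$sim)) {
    cfg <- config$sim
    cfg$seed <- stage_seed()
    cohort <- generate_cohort(cfg)
    geno <- generate_genotypes(cfg, cohort)
    expr <- geno$expr
    meta <- cohort$meta
    anno <- cohort$anno
    rep$truth <- geno$truth
  } else {
    expr <- load_expression(config$paths$expr, config$paths$detect)
    meta <- load_metadata(config$paths$meta)
    anno <- if (!is.null(config$paths$anno))
      load_probe_annotation(config$paths$anno) else NULL
    geno <- NULL
    if (!is.null(config$paths$geno)) {
      geno <- list(discovery = load_genotypes(config$paths$geno,
                                              config$paths$geno_annot))
      if (!is.null(config$paths$geno_validation)) {
        geno$validation <- load_genotypes(config$paths$geno_validation,
                                          config$paths$geno_annot)
        geno$meta_validation <- load_metadata(config$paths$meta_validation)
      }
    }
  }
  counts <- list(n_samples = ncol(expr$values),
                 n_probes_input = nrow(expr$values))

  # --- preprocess ---------------------------------------------------------
  if ("preprocess" %in% config$stages) {
    expr <- filter_probes(expr, meta)
    expr <- quantile_normalize(expr)
    counts$n_probes_retained <- nrow(expr$values)
  }
  rep$expr <- expr

  # --- directional testing ------------------------------------------------
  if ("gmwt" %in% config$stages) {
    rep$gmwt <- directional_test(expr, meta, B = config$B,
                                 seed = stage_seed())
    for (ord in unique(rep$gmwt$ordering)) {
      sub <- rep$gmwt[rep$gmwt$ordering == ord, ]
      counts[[paste0("n_significant_", gsub("<", "", ord))]] <-
        sum(sub$p_value < config$alpha)
    }
    by_probe <- tapply(rep$gmwt$p_value, rep$gmwt$probe_id, min)
    counts$n_significant_probes <- sum(by_probe < config$alpha)
    rep$rejection_curve <- bh_rejection_curve(
      rep$gmwt$p_value[rep$gmwt$ordering == rep$gmwt$ordering[1]])
  }

  # --- random forest + HI selection ---------------------------------------
  if ("rf" %in% config$stages) {
    rep$rf <- run_repeated_rf(expr, meta, classes = "3way", R = config$R,
                              T_trees = config$T_trees,
                              split = config$split, seed = stage_seed())
    rep$severeness <- severeness_profile(rep$rf)
    counts$auc_prca_vs_h <- pooled_roc_auc(rep$rf, meta, "PrCa_vs_H")
    counts$auc_a_vs_rest <- pooled_roc_auc(rep$rf, meta, "A_vs_rest")
    if (!is.null(rep$gmwt)) {
      rep$hi <- select_hi_probes(rep$gmwt, aggregate_importance(rep$rf),
                                 alpha = config$alpha,
                                 top_frac = config$top_frac)
      counts$n_hi_probes <- nrow(rep$hi)
    }
  }

  # --- clustering ---------------------------------------------------------
  if ("cluster" %in% config$stages && !is.null(rep$hi) &&
      nrow(rep$hi) >= 2) {
    sub <- expression_matrix(expr$values[rep$hi$probe_id, , drop = FALSE],
                             expr$detected[rep$hi$probe_id, , drop = FALSE])
    D <- kendall_distance_matrix(sub)
    rep$clustering <- hierarchical_cluster(D, k = config$k,
                                           linkage = config$linkage)
    truth <- as.integer(meta$health[match(colnames(expr$values),
                                          meta$sample_id)])
    counts$ari_hi <- adjusted_rand_index(
      rep$clustering$labels[colnames(expr$values)], truth)
  }

  # --- eQTL + association -------------------------------------------------
  if ("eqtl" %in% config$stages && !is.null(geno) && !is.null(anno) &&
      !is.null(rep$hi) && nrow(rep$hi) > 0) {
    hi_anno <- anno[anno$probe_id %in% rep$hi$probe_id, , drop = FALSE]
    links <- link_cis_snps(hi_anno, geno$discovery,
                           half_window = config$half_window)
    rep$eqtl <- eqtl_test(links, expr, geno$discovery, B = config$B,
                          seed = stage_seed())
    counts$n_cis_pairs_tested <- nrow(rep$eqtl)
    counts$n_cis_significant <- sum(rep$eqtl$p_value <= config$alpha_eqtl)
    sig_snps <- unique(rep$eqtl$snp_id[rep$eqtl$p_value <=
                                         config$alpha_eqtl])
    if (length(sig_snps)) {
      disc_meta <- meta[meta$sample_id %in% colnames(geno$discovery$codes), ]
      rep$association <- association_test(geno$discovery, disc_meta,
                                          snp_ids = sig_snps)
      counts$n_assoc_significant <-
        sum(rep$association$fisher_p <= config$alpha_assoc, na.rm = TRUE)
      if (!is.null(geno$validation)) {
        rep$association <- validate_associations(rep$association,
                                                 geno$validation,
                                                 geno$meta_validation)
        counts$n_assoc_validated <-
          sum(rep$association$validation_p <= config$alpha_assoc,
              na.rm = TRUE)
      }
    }
  }

  # --- comparators --------------------------------------------------------
  if ("comparators" %in% config$stages && !is.null(rep$hi)) {
    rep$anova <- anova_screen(expr, meta, alpha = config$anova_alpha)
    rep$lrl <- lrl_two_stage(expr, meta, target_count = config$lrl_target,
                             seed = stage_seed())
    rep$comparison <- compare_selections(
      list(HI = rep$hi, ANOVA = rep$anova, LRL = rep$lrl), expr, meta,
      k = config$k, linkage = config$linkage)
    counts$n_anova_selected <- length(rep$anova$selected)
    counts$n_lrl_selected <- length(rep$lrl$selected)
    counts$ari_anova <- rep$comparison$summary$ari[
      rep$comparison$summary$method == "ANOVA"]
    counts$ari_lrl <- rep$comparison$summary$ari[
      rep$comparison$summary$method == "LRL"]
  }

  rep$counts <- counts
  if (!is.null(config$out_dir)) write_pipeline_outputs(rep, config$out_dir)
  structure(rep, class = "pipeline_report")
}

# Write the report's tabular artefacts as TSV plus a JSON count summary.
write_pipeline_outputs <- function(rep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rep$gmwt)) wt(rep$gmwt, "directional_test.tsv")
  if (!is.null(rep$severeness)) wt(rep$severeness, "severeness.tsv")
  if (!is.null(rep$hi)) wt(rep$hi, "hi_probes.tsv")
  if (!is.null(rep$eqtl)) wt(rep$eqtl, "eqtl.tsv")
  if (!is.null(rep$association)) wt(rep$association, "association.tsv")
  if (!is.null(rep$comparison)) wt(rep$comparison$summary, "comparison.tsv")
  jsonlite::write_json(rep$counts, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Two-stage screening pipeline report\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.numeric(v) && v %% 1 != 0) sprintf("%.4f", v)
                else format(v)))
  }
  invisible(x)
}

#' @export
summary.pipeline_report <- function(object, ...) {
  print(object)
  invisible(object$counts)
}
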