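#' Simulation configuration for synthetic cohorts
#'
#' Defaults mirror the structure of a family-based three-group LCL miRNA
#' study: 78 healthy, 79 non-aggressive and 36 aggressive samples, 547
#' probes of which 20 are planted with a stochastic ordering across the
#' groups (log-scale group shift of `delta` per step, direction randomized
#' per probe), family random effects, a detection mask thresholded at the
#' configured detection rate, and a genotyped discovery subset of 54
#' samples plus an expression-free validation cohort of 83.
#'
#' @param n_H,n_M,n_A group sizes.
#' @param n_probes number of probes.
#' @param n_planted number of probes with a planted ordered group shift.
#' @param delta planted shift per group step, in units of within-group SD
#'   on the log2 scale.
#' @param family_count number of families samples are drawn from.
#' @param family_effect_sd SD of the per-family, per-probe random effect.
#' @param detection_rate overall fraction of entries flagged detected.
#' @param n_snps_per_probe cis SNPs scattered per probe (plus one distant
#'   negative-control SNP per probe).
#' @param maf_range minor-allele-frequency range for simulated SNPs.
#' @param n_planted_eqtl probes receiving a planted cis-eQTL SNP.
#' @param eqtl_beta additive log2-scale expression shift per allele copy of
#'   a planted eQTL, in units of within-group SD.
#' @param n_planted_assoc SNPs with a planted case-control frequency shift.
#' @param case_control_or allelic odds ratio of planted associated SNPs.
#' @param n_discovery,n_validation genotyped cohort sizes.
#' @param seed integer seed; the full output is reproducible from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_H = 78, n_M = 79, n_A = 36,
                       n_probes = 547, n_planted = 20, delta = 1.0,
                       family_count = 100, family_effect_sd = 0.5,
                       detection_rate = 0.9,
                       n_snps_per_probe = 15, maf_range = c(0.05, 0.5),
                       n_planted_eqtl = 5, eqtl_beta = 1.0,
                       n_planted_assoc = 5, case_control_or = 2.5,
                       n_discovery = 54, n_validation = 83,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_H > 0, n_M > 0, n_A > 0, n_probes > 0,
              n_planted >= 0, n_planted <= n_probes, delta >= 0,
              family_count > 0, family_effect_sd >= 0,
              detection_rate > 0, detection_rate <= 1,
              n_snps_per_probe >= 0,
              maf_range[1] > 0, maf_range[2] <= 0.5,
              eqtl_beta >= 0, case_control_or > 0,
              n_discovery > 0, n_validation > 0)
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic expression cohort with planted ordered probes
#'
#' Log2-scale model per probe and sample:
#' baseline + family random effect + planted group shift (0, delta,
#' 2*delta along the planted direction) + N(0, 1) noise, exponentiated to
#' intensity scale.  The detection mask thresholds the intensities at the
#' quantile giving the configured detection rate.  Probes are annotated on
#' synthetic chromosomes with 2 Mb spacing.
#'
#' @param config a [sim_config()].
#' @return List of class `"sim_cohort"`: `expr` (`ExpressionMatrix`),
#'   `meta` (`SampleMetadata`), `anno` (`ProbeAnnotation`), `truth` (list
#'   with `planted` data frame: `probe_id`, `direction`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- c(H = config$n_H, M = config$n_M, A = config$n_A)
  N <- sum(n)
  P <- config$n_probes
  sample_ids <- sprintf("S%03d", seq_len(N))
  probe_ids <- sprintf("P%04d", seq_len(P))
  health <- rep(names(n), n)
  family <- sprintf("F%03d", sample.int(config$family_count, N,
                                        replace = TRUE))
  meta <- sample_metadata(sample_ids, health, family)

  planted <- sort(sample.int(P, config$n_planted))
  direction <- sample(c("H<M<A", "A<M<H"), config$n_planted, replace = TRUE)
  baseline <- stats::rnorm(P, mean = 5, sd = 1)
  fam_ids <- unique(family)
  fam_eff <- matrix(stats::rnorm(P * length(fam_ids), 0,
                                 config$family_effect_sd),
                    P, length(fam_ids), dimnames = list(NULL, fam_ids))
  step <- match(health, c("H", "M", "A")) - 1L  # 0, 1, 2
  logx <- matrix(baseline, P, N) + fam_eff[, family, drop = FALSE] +
    matrix(stats::rnorm(P * N), P, N)
  for (i in seq_along(planted)) {
    p <- planted[i]
    shift <- if (direction[i] == "H<M<A") step else 2L - step
    logx[p, ] <- logx[p, ] + config$delta * shift
  }
  values <- 2^logx
  thr <- stats::quantile(values, 1 - config$detection_rate)
  detected <- values > thr
  dimnames(values) <- dimnames(detected) <- list(probe_ids, sample_ids)

  per_chrom <- 20L
  chrom <- paste0("chr", (seq_len(P) - 1L) %/% per_chrom + 1L)
  center <- (((seq_len(P) - 1L) %% per_chrom) + 1L) * 2e6
  anno <- probe_annotation(probe_ids, paste0("rna-", probe_ids), chrom,
                           center - 10, center + 9)
  structure(list(expr = expression_matrix(values, detected),
                 meta = meta, anno = anno,
                 truth = list(planted = data.frame(
                   probe_id = probe_ids[planted],
                   direction = direction, stringsAsFactors = FALSE)),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d probes x %d samples (%s planted)\n",
              nrow(x$expr$values), ncol(x$expr$values),
              nrow(x$truth$planted)))
  invisible(x)
}

# Hardy-Weinberg genotype draw for one SNP
hw_genotypes <- function(n, q) {
  stats::rbinom(n, 2L, q)
}

#' Generate discovery and validation genotype cohorts
#'
#' Scatters `n_snps_per_probe` SNPs uniformly within +-0.5 Mb of each probe
#' center plus one distant negative-control SNP per probe, draws
#' Hardy-Weinberg genotypes at a MAF uniform in `maf_range`, plants cis-eQTL
#' SNPs (adding `eqtl_beta * genotype` to the linked probe's log2
#' expression of genotyped discovery samples) and case-control associated
#' SNPs (case allele frequency shifted to the configured allelic odds
#' ratio, in both cohorts).  The discovery cohort is a genotyped subset of
#' the expression samples; the validation cohort has genotypes and health
#' labels only.
#'
#' @param config the [sim_config()] used for the cohort.
#' @param cohort a `sim_cohort` from [generate_cohort()].
#' @return List of class `"sim_genotypes"`: `discovery`, `validation`
#'   (`GenotypeData`), `expr` (the cohort expression with eQTL effects
#'   applied), `meta_validation`, and `truth` (planted eQTL and associated
#'   SNP tables).
#' @export
generate_genotypes <- function(config, cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  set.seed(config$seed + 1000L)
  anno <- cohort$anno
  P <- nrow(anno)
  ctr <- probe_center(anno)
  half <- 5e5

  snp_list <- vector("list", P)
  for (i in seq_len(P)) {
    k <- config$n_snps_per_probe
    pos_cis <- round(stats::runif(k, max(1, ctr[i] - half), ctr[i] + half))
    pos_far <- ctr[i] + half + round(stats::runif(1, 2e5, 4e5))
    pos <- c(pos_cis, pos_far)
    snp_list[[i]] <- data.frame(
      snp_id = sprintf("rs%s_%02d", sub("^P", "", anno$probe_id[i]),
                       seq_along(pos)),
      chrom = anno$chrom[i], pos = pos,
      allele1 = "A", allele2 = "G",
      probe_id = anno$probe_id[i], cis = c(rep(TRUE, k), FALSE),
      stringsAsFactors = FALSE)
  }
  snp <- do.call(rbind, snp_list)
  M <- nrow(snp)
  maf <- stats::runif(M, config$maf_range[1], config$maf_range[2])

  # discovery subset of the expression cohort (~28% controls, as in a
  # case-enriched genotyping subset), validation samples are new
  meta <- cohort$meta
  n_ctrl_avail <- sum(meta$health == "H")
  n_case_avail <- sum(meta$health != "H")
  if (config$n_discovery > n_ctrl_avail + n_case_avail)
    stop("n_discovery exceeds the cohort size")
  n_ctrl <- min(n_ctrl_avail, round(0.28 * config$n_discovery))
  n_case <- min(n_case_avail, config$n_discovery - n_ctrl)
  n_ctrl <- config$n_discovery - n_case
  ctrl <- sample(meta$sample_id[meta$health == "H"], n_ctrl)
  case <- sample(meta$sample_id[meta$health != "H"], n_case)
  disc_ids <- c(ctrl, case)
  val_ids <- sprintf("V%03d", seq_len(config$n_validation))
  val_health <- sample(c("H", "M", "A"), config$n_validation,
                       replace = TRUE, prob = c(0.4, 0.4, 0.2))
  meta_val <- sample_metadata(val_ids, val_health,
                              sprintf("VF%03d",
                                      sample.int(config$family_count,
                                                 config$n_validation,
                                                 replace = TRUE)))

  # planted associated SNPs: shift case allele frequency to the target OR
  cis_idx <- which(snp$cis)
  assoc_idx <- sort(sample(cis_idx, min(config$n_planted_assoc,
                                        length(cis_idx))))
  or <- config$case_control_or
  draw_cohort <- function(ids, is_case) {
    codes <- matrix(NA_integer_, M, length(ids),
                    dimnames = list(snp$snp_id, ids))
    for (j in seq_len(M)) {
      q <- maf[j]
      if (j %in% assoc_idx) {
        qc <- or * q / (1 - q + or * q)
        codes[j, ] <- ifelse(is_case, hw_genotypes(length(ids), qc),
                             hw_genotypes(length(ids), q))
      } else {
        codes[j, ] <- hw_genotypes(length(ids), q)
      }
    }
    codes
  }
  disc_case <- meta$health[match(disc_ids, meta$sample_id)] != "H"
  disc_codes <- draw_cohort(disc_ids, disc_case)
  val_codes <- draw_cohort(val_ids, meta_val$health != "H")

  # planted cis-eQTLs: additive allele effect on the linked probe's log2
  # expression of the genotyped discovery samples
  eqtl_probes <- sample(unique(snp$probe_id),
                        min(config$n_planted_eqtl, P))
  eqtl_rows <- integer(0)
  expr <- cohort$expr
  for (pid in eqtl_probes) {
    cand <- which(snp$probe_id == pid & snp$cis)
    row <- sample(cand, 1)
    eqtl_rows <- c(eqtl_rows, row)
    g <- disc_codes[row, ]
    logx <- log2(expr$values[pid, disc_ids]) + config$eqtl_beta * g
    expr$values[pid, disc_ids] <- 2^logx
  }

  ann_cols <- c("snp_id", "chrom", "pos", "allele1", "allele2")
  truth <- cohort$truth
  truth$eqtl <- data.frame(snp_id = snp$snp_id[eqtl_rows],
                           probe_id = snp$probe_id[eqtl_rows],
                           beta = config$eqtl_beta,
                           stringsAsFactors = FALSE)
  truth$assoc <- data.frame(snp_id = snp$snp_id[assoc_idx],
                            odds_ratio = or, stringsAsFactors = FALSE)
  structure(list(discovery = genotype_data(disc_codes, snp[, ann_cols]),
                 validation = genotype_data(val_codes, snp[, ann_cols]),
                 expr = expr, meta_validation = meta_val, truth = truth),
            class = "sim_genotypes")
}

#' Write a simulated cohort as a plain-text fixture set
#'
#' Writes the expression/detection/metadata/annotation tables (and, when
#' present, the genotype cohorts) in the tab-separated formats the loaders
#' read, plus a JSON manifest recording the configuration and seed so the
#' set can be regenerated.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @param genotypes optional `sim_genotypes` for the same cohort.
#' @return Named character vector of the written paths.
#' @export
write_fixture_set <- function(cohort, dir, genotypes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             detect = file.path(dir, "detection.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             anno = file.path(dir, "probe_annotation.tsv"),
             truth = file.path(dir, "ground_truth.tsv"),
             manifest = file.path(dir, "manifest.json"))
  expr <- if (is.null(genotypes)) cohort$expr else genotypes$expr
  write_expression(expr, paths["expr"], paths["detect"])
  write_metadata(cohort$meta, paths["meta"])
  utils::write.table(as.data.frame(cohort$anno), paths["anno"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$planted, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(genotypes)) {
    gp <- c(geno_discovery = file.path(dir, "genotypes_discovery.tsv"),
            geno_validation = file.path(dir, "genotypes_validation.tsv"),
            geno_annot = file.path(dir, "snp_annotation.tsv"),
            meta_validation = file.path(dir, "metadata_validation.tsv"))
    write_id_table(genotypes$discovery$codes, gp["geno_discovery"],
                   id_name = "snp_id")
    write_id_table(genotypes$validation$codes, gp["geno_validation"],
                   id_name = "snp_id")
    utils::write.table(genotypes$discovery$annotation, gp["geno_annot"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_metadata(genotypes$meta_validation, gp["meta_validation"])
    paths <- c(paths, gp)
  }
  manifest <- c(cohort$config, list(written = unname(paths)))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
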