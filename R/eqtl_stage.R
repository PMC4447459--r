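#' Link cis SNPs to probes
#'
#' Pairs every probe with all same-chromosome SNPs within `half_window` base
#' pairs of the probe center (a 1 Mb window by default: 0.5 Mb up- and
#' downstream).
#'
#' @param anno a `ProbeAnnotation`.
#' @param geno a `GenotypeData`.
#' @param half_window window half-width in bp (default 500,000).
#' @return Data frame of cis links: `snp_id`, `probe_id`, `chrom`,
#'   `snp_pos`, `probe_center`, `distance`.
#' @export
link_cis_snps <- function(anno, geno, half_window = 5e5) {
  if (half_window <= 0) stop("half_window must be positive")
  ctr <- probe_center(anno)
  snp <- geno$annotation
  out <- vector("list", nrow(anno))
  for (i in seq_len(nrow(anno))) {
    hit <- snp$chrom == anno$chrom[i] & abs(snp$pos - ctr[i]) <= half_window
    if (!any(hit)) next
    out[[i]] <- data.frame(snp_id = snp$snp_id[hit],
                           probe_id = anno$probe_id[i],
                           chrom = anno$chrom[i],
                           snp_pos = snp$pos[hit],
                           probe_center = unname(ctr[i]),
                           distance = abs(snp$pos[hit] - ctr[i]),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(snp_id = character(), probe_id = character(),
                      chrom = character(), snp_pos = numeric(),
                      probe_center = numeric(), distance = numeric())
  rownames(out) <- NULL
  out
}

#' Genotype-group expression tests for cis links
#'
#' For every SNP-probe link, partitions the shared samples by genotype code
#' (missing genotypes dropped pairwise).  Monomorphic SNPs are excluded.
#' With two genotype groups a two-sided Mann-Whitney test is applied; with
#' three groups the directional generalized Mann-Whitney test is run for
#' both alternatives (expression increasing with allele count, `0<1<2`, and
#' decreasing, `2<1<0`) and the smaller p-value is reported with its
#' direction (both are returned).
#'
#' @param links cis-link data frame from [link_cis_snps()].
#' @param expr an `ExpressionMatrix`.
#' @param geno a `GenotypeData`.
#' @param B permutations for the three-group directional test.
#' @param seed optional integer seed for the permutation stream.
#' @param exhaustive_limit see [directional_test()].
#' @return Data frame with one row per testable link: `snp_id`, `probe_id`,
#'   `n_groups`, `test` (`two_sided_MW`, `directional_012` or
#'   `directional_210`), `p_value`, `p_012`, `p_210`, `n0`, `n1`, `n2`.
#' @export
eqtl_test <- function(links, expr, geno, B = 5000, seed = NULL,
                      exhaustive_limit = 10000) {
  shared <- intersect(colnames(expr$values), colnames(geno$codes))
  if (length(shared) < 6)
    stop("expression and genotype data share fewer than 6 samples")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", nrow(links))
  for (i in seq_len(nrow(links))) {
    gcode <- geno$codes[links$snp_id[i], shared]
    x <- expr$values[links$probe_id[i], shared]
    ok <- !is.na(gcode)
    gcode <- gcode[ok]; x <- x[ok]
    sizes <- tabulate(gcode + 1L, 3L)
    present <- sum(sizes > 0)
    if (present < 2) next  # monomorphic (or empty): excluded
    if (present == 2) {
      lev <- which(sizes > 0) - 1L
      if (max(sizes) < 2) next  # only singleton groups remain
      p <- two_group_mw(x[gcode == lev[1]], x[gcode == lev[2]])
      rows[[i]] <- data.frame(snp_id = links$snp_id[i],
                              probe_id = links$probe_id[i],
                              n_groups = 2L, test = "two_sided_MW",
                              p_value = p, p_012 = NA_real_,
                              p_210 = NA_real_, n0 = sizes[1],
                              n1 = sizes[2], n2 = sizes[3],
                              stringsAsFactors = FALSE)
    } else {
      if (max(sizes) < 2) next  # only singleton groups remain
      N <- length(gcode)
      n_assign <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
      g_up <- gcode + 1L            # 0<1<2
      g_dn <- 3L - gcode            # 2<1<0
      lab_up <- lab_dn <- NULL
      if (n_assign > exhaustive_limit) {
        perms <- t(replicate(B, sample.int(N)))
        lab_up <- matrix(g_up[perms], nrow = B)
        lab_dn <- matrix(g_dn[perms], nrow = B)
      }
      up <- gmw_engine(x, g_up, lab_up, exhaustive_limit)
      dn <- gmw_engine(x, g_dn, lab_dn, exhaustive_limit)
      best <- if (up$p_value <= dn$p_value) "directional_012" else
        "directional_210"
      rows[[i]] <- data.frame(snp_id = links$snp_id[i],
                              probe_id = links$probe_id[i],
                              n_groups = 3L, test = best,
                              p_value = min(up$p_value, dn$p_value),
                              p_012 = up$p_value, p_210 = dn$p_value,
                              n0 = sizes[1], n1 = sizes[2], n2 = sizes[3],
                              stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(snp_id = character(), probe_id = character(),
                      n_groups = integer(), test = character(),
                      p_value = numeric(), p_012 = numeric(),
                      p_210 = numeric(), n0 = integer(), n1 = integer(),
                      n2 = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fisher exact test on a 2 x 3 genotype-by-status table
#'
#' Exact conditional (Freeman-Halton) test: the p-value sums the
#' probabilities of all tables with the observed margins whose
#' hypergeometric probability does not exceed that of the observed table.
#' All-zero genotype columns are dropped first, so the test reduces exactly
#' to the 2 x 2 Fisher test when one genotype class is absent.
#'
#' @param cases,controls length-3 non-negative integer vectors of genotype
#'   counts (hom-allele1, het, hom-allele2) for cases and controls.
#' @return The exact p-value.
#' @export
fisher_2x3 <- function(cases, controls) {
  if (length(cases) != 3 || length(controls) != 3)
    stop("cases and controls must be length-3 genotype count vectors")
  if (any(cases < 0) || any(controls < 0)) stop("counts must be non-negative")
  if (sum(cases) == 0 || sum(controls) == 0)
    stop("each row must have a positive total")
  tab <- rbind(cases, controls)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) == 1) return(1)
  stats::fisher.test(tab)$p.value
}

#' Case-control association for a set of SNPs
#'
#' Builds the 2 x 3 genotype table (cases = M and A pooled vs healthy
#' controls) for every SNP and applies [fisher_2x3()].  Monomorphic SNPs
#' return `p = 1` via the column-dropping rule and can be filtered by the
#' caller.
#'
#' @param snp_ids SNPs to test (default: all in `geno`).
#' @param geno a `GenotypeData`.
#' @param meta a `SampleMetadata` covering the genotyped samples.
#' @return Data frame of class `"association_result"`: `snp_id`, case and
#'   control genotype counts `c0..c2`, `h0..h2`, `fisher_p`.
#' @export
association_test <- function(geno, meta, snp_ids = rownames(geno$codes)) {
  idx <- match(colnames(geno$codes), meta$sample_id)
  if (anyNA(idx)) stop("genotyped samples without metadata")
  is_case <- meta$health[idx] != "H"
  rows <- lapply(snp_ids, function(s) {
    if (!s %in% rownames(geno$codes))
      return(data.frame(snp_id = s, c0 = NA, c1 = NA, c2 = NA,
                        h0 = NA, h1 = NA, h2 = NA, fisher_p = NA_real_,
                        stringsAsFactors = FALSE))
    gcode <- geno$codes[s, ]
    cc <- tabulate(gcode[is_case & !is.na(gcode)] + 1L, 3L)
    hh <- tabulate(gcode[!is_case & !is.na(gcode)] + 1L, 3L)
    p <- if (sum(cc) == 0 || sum(hh) == 0) NA_real_ else fisher_2x3(cc, hh)
    data.frame(snp_id = s, c0 = cc[1], c1 = cc[2], c2 = cc[3],
               h0 = hh[1], h1 = hh[2], h2 = hh[3], fisher_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("association_result", "data.frame"))
}

#' Replicate associations in a validation genotype cohort
#'
#' Recomputes the Fisher 2 x 3 association for the same SNPs on an
#' independent validation cohort and reports discovery and validation
#' p-values side by side.  SNPs absent from the validation panel get a
#' missing validation p-value.
#'
#' @param assoc an `association_result` from the discovery cohort.
#' @param validation_geno a `GenotypeData` for the validation samples.
#' @param meta a `SampleMetadata` covering the validation samples.
#' @return Data frame: discovery columns plus `validation_p`.
#' @export
validate_associations <- function(assoc, validation_geno, meta) {
  val <- association_test(validation_geno, meta,
                          snp_ids = assoc$snp_id)
  out <- as.data.frame(assoc)
  out$validation_p <- val$fisher_p[match(assoc$snp_id, val$snp_id)]
  out
}
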