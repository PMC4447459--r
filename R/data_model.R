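#' Construct an expression matrix with a detection mask
#'
#' The container for probe-level, background-subtracted median intensities
#' together with the array software's boolean "detected" flag.  Values must be
#' finite and non-missing; analysis is always at the probe level (target RNA
#' identity is annotation only).
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param detected logical (or 0/1) matrix of the same dimensions; defaults to
#'   all-detected.
#' @param probe_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `values` and `detected`, both dimension-named matrices.
#' @export
expression_matrix <- function(values, detected = NULL,
                              probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(probe_ids) && nrow(values) == 0) probe_ids <- character(0)
  if (is.null(sample_ids) && ncol(values) == 0) sample_ids <- character(0)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe_ids and sample_ids are required (or set dimnames on values)")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(probe_ids)) stop("duplicated probe IDs")
  if (anyDuplicated(sample_ids)) stop("duplicated sample IDs")
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids))
    stop("values dimensions do not match probe_ids x sample_ids")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values))
  } else {
    detected <- as.matrix(detected)
    if (!all(dim(detected) == dim(values)))
      stop("detection mask dimensions do not match expression values")
    if (is.numeric(detected)) {
      if (!all(detected %in% c(0, 1)))
        stop("detection mask entries must be 0/1")
      detected <- detected == 1
    }
    if (anyNA(detected)) stop("detection mask must not contain missing values")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  dimnames(detected) <- list(probe_ids, sample_ids)
  structure(list(values = values, detected = detected),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples\n")
  cat("  detection rate:",
      sprintf("%.3f", mean(x$detected)), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression table and its detection mask
#'
#' Both files are tab-separated with a header row of sample IDs and the probe
#' ID in the first column; the detection file holds 0/1 entries and must have
#' exactly the same probes and samples in the same order.
#'
#' @param path expression table file.
#' @param detection_path detection mask file.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, detection_path) {
  vals <- read_id_table(path)
  det <- read_id_table(detection_path)
  if (!identical(dim(vals), dim(det)) ||
      !identical(rownames(vals), rownames(det)) ||
      !identical(colnames(vals), colnames(det)))
    stop("expression and detection tables do not match")
  expression_matrix(vals, det)
}

#' Write an expression matrix (and mask) to tab-separated files
#' @param expr an `ExpressionMatrix`.
#' @param path,detection_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(expr, path, detection_path) {
  write_id_table(expr$values, path)
  write_id_table(expr$detected * 1L, detection_path)
  invisible(c(path, detection_path))
}

# shared TSV helpers: first column = row ID, header = column IDs
read_id_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated row IDs in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  rownames(m) <- ids
  m
}

write_id_table <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata (health status and family)
#'
#' Expects a tab-separated file with columns `sample_id`, `health`
#' (one of `H`, `M`, `A`: healthy, non-aggressive, aggressive) and
#' `family_id`.
#'
#' @param path metadata file.
#' @return A `SampleMetadata` data frame.
#' @export
load_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_metadata(df$sample_id, df$health, df$family_id)
}

#' Construct sample metadata
#' @param sample_id,health,family_id vectors of equal length; `health` must
#'   be in `c("H","M","A")`.
#' @return A data frame of class `"SampleMetadata"`.
#' @export
sample_metadata <- function(sample_id, health, family_id) {
  sample_id <- as.character(sample_id)
  health <- as.character(health)
  family_id <- as.character(family_id)
  if (anyDuplicated(sample_id)) stop("duplicated sample IDs in metadata")
  bad <- setdiff(unique(health), c("H", "M", "A"))
  if (length(bad))
    stop("invalid health labels: ", paste(bad, collapse = ", "))
  structure(data.frame(sample_id = sample_id,
                       health = factor(health, levels = c("H", "M", "A")),
                       family_id = family_id,
                       stringsAsFactors = FALSE),
            class = c("SampleMetadata", "data.frame"))
}

#' Group sizes N_H, N_M, N_A
#' @param meta a `SampleMetadata`.
#' @return Named integer vector of the three group sizes.
#' @export
group_sizes <- function(meta) {
  table(meta$health)[c("H", "M", "A")]
}

#' Write sample metadata to a tab-separated file
#' @param meta a `SampleMetadata`.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Probe annotation table
#'
#' Probe genomic locations; `start`/`end` are 1-based and may be printed in
#' descending order (antisense probes) — the probe center is defined either
#' way.
#'
#' @param probe_id,target_id,chrom,start,end equal-length vectors.
#' @return A data frame of class `"ProbeAnnotation"`.
#' @export
probe_annotation <- function(probe_id, target_id, chrom, start, end) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) stop("duplicated probe IDs in annotation")
  start <- as.numeric(start); end <- as.numeric(end)
  if (anyNA(start) || anyNA(end) || any(start < 0) || any(end < 0))
    stop("probe coordinates must be non-negative")
  structure(data.frame(probe_id = probe_id,
                       target_id = as.character(target_id),
                       chrom = as.character(chrom),
                       start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("ProbeAnnotation", "data.frame"))
}

#' @rdname probe_annotation
#' @param path tab-separated file with the five annotation columns.
#' @export
load_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_annotation(df$probe_id, df$target_id, df$chrom, df$start, df$end)
}

#' Probe center position
#'
#' `floor((start + end) / 2)`, robust to coordinates printed in descending
#' order.
#' @param anno a `ProbeAnnotation` (or anything with `start`/`end` columns).
#' @return Numeric vector of center positions, named by probe ID.
#' @export
probe_center <- function(anno) {
  ctr <- floor((anno$start + anno$end) / 2)
  names(ctr) <- anno$probe_id
  ctr
}

#' Genotype data container
#'
#' @param codes integer matrix, SNPs in rows and samples in columns, coded
#'   0/1/2 copies of allele 2, `NA` for missing.
#' @param annotation data frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele1`, `allele2`, one row per SNP, matching `codes` row order.
#' @return An object of class `"GenotypeData"`.
#' @export
genotype_data <- function(codes, annotation) {
  codes <- as.matrix(codes)
  if (!all(codes %in% c(0L, 1L, 2L) | is.na(codes)))
    stop("genotype codes must be 0, 1, 2 or missing")
  snp_ids <- as.character(annotation$snp_id)
  if (anyDuplicated(snp_ids)) stop("duplicated SNP IDs")
  if (nrow(codes) != length(snp_ids))
    stop("genotype matrix does not match annotation")
  if (is.null(colnames(codes))) stop("genotype matrix needs sample IDs")
  if (anyNA(annotation$pos) || any(annotation$pos < 0))
    stop("SNP positions must be non-negative")
  rownames(codes) <- snp_ids
  structure(list(codes = codes,
                 annotation = data.frame(annotation,
                                         stringsAsFactors = FALSE)),
            class = "GenotypeData")
}

#' @export
print.GenotypeData <- function(x, ...) {
  cat("GenotypeData:", nrow(x$codes), "SNPs x", ncol(x$codes), "samples\n")
  invisible(x)
}

#' Read genotype codes and SNP annotation
#' @param path SNP x sample tab-separated table of 0/1/2/NA codes, first
#'   column the SNP ID.
#' @param annotation_path tab-separated table with columns `snp_id`, `chrom`,
#'   `pos`, `allele1`, `allele2`.
#' @return A [genotype_data()].
#' @export
load_genotypes <- function(path, annotation_path) {
  m <- read_id_table(path)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  ann <- ann[match(rownames(m), ann$snp_id), , drop = FALSE]
  if (anyNA(ann$snp_id)) stop("annotation missing for some SNPs")
  genotype_data(m, ann)
}

#' Detection filter: keep probes detected in at least half of one group
#'
#' A probe is retained when its detection fraction is at least `min_frac`
#' within at least one of the health-status groups H, M, A.  Probe order is
#' preserved; an empty result is returned with a warning, not an error.
#'
#' @param expr an `ExpressionMatrix`.
#' @param meta a `SampleMetadata` covering every expression sample.
#' @param min_frac minimum within-group detection fraction (default 0.5).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_probes <- function(expr, meta, min_frac = 0.5) {
  idx <- match(colnames(expr$values), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata: ",
                       paste(colnames(expr$values)[is.na(idx)], collapse = ", "))
  health <- meta$health[idx]
  keep <- rep(FALSE, nrow(expr$values))
  for (g in levels(health)) {
    cols <- health == g
    if (!any(cols)) next
    keep <- keep | rowMeans(expr$detected[, cols, drop = FALSE]) >= min_frac
  }
  if (!any(keep)) warning("no probes pass the detection filter")
  expression_matrix(expr$values[keep, , drop = FALSE],
                    expr$detected[keep, , drop = FALSE])
}

#' Quantile normalization across samples
#'
#' Forces every sample to share the empirical distribution given by the
#' cross-sample means of order statistics.  Tied values within a sample
#' receive the mean of the reference values of their occupied ranks.
#'
#' @param expr an `ExpressionMatrix` (no missing values).
#' @return The normalized `ExpressionMatrix` (detection mask unchanged).
#' @export
quantile_normalize <- function(expr) {
  norm <- limma::normalizeQuantiles(expr$values, ties = TRUE)
  dimnames(norm) <- dimnames(expr$values)
  expression_matrix(norm, expr$detected)
}
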