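#' Repeated random-forest classification with importance tracking
#'
#' Repeatedly splits the cohort into stratified training (default 75%) and
#' test (25%) sets, grows a forest of `T` trees per run, and records the
#' class likelihoods (vote fractions) of the test samples together with the
#' per-run Gini importance of every probe.  The study defaults are `R = 2000`
#' runs of `T = 2500` trees; desk-scale analyses use far smaller values.
#'
#' @param expr an `ExpressionMatrix` (probes x samples).
#' @param meta a `SampleMetadata`.
#' @param classes `"3way"` (H / M / A) or `"2way"` (H vs pooled PrCa `P`).
#' @param R number of split repetitions.
#' @param T_trees trees per forest.
#' @param split training fraction in (0, 1).
#' @param seed optional integer seed.
#' @param mtry features per split; defaults to `sqrt(#probes)`.
#' @return An object of class `"rf_ensemble"`: list with `likelihoods`
#'   (data frame: `run`, `sample_id`, one `L_*` column per class, `truth`),
#'   `importance` (probes x R matrix of Gini importances), `classes`,
#'   `R`, `T_trees`, `split`.
#' @export
run_repeated_rf <- function(expr, meta, classes = c("3way", "2way"),
                            R = 2000, T_trees = 2500, split = 0.75,
                            seed = NULL, mtry = NULL) {
  classes <- match.arg(classes)
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)")
  idx <- match(colnames(expr$values), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata")
  y <- as.character(meta$health[idx])
  if (classes == "2way") y <- ifelse(y == "H", "H", "P")
  lev <- if (classes == "3way") c("H", "M", "A") else c("H", "P")
  y <- factor(y, levels = lev)
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  X <- t(expr$values)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  if (!is.null(seed)) set.seed(seed)
  imp <- matrix(NA_real_, ncol(X), R, dimnames = list(colnames(X), NULL))
  lik <- vector("list", R)
  for (r in seq_len(R)) {
    train <- stratified_split(y, split)
    fit <- randomForest::randomForest(X[train, , drop = FALSE], y[train],
                                      ntree = T_trees, mtry = mtry,
                                      importance = FALSE)
    test <- setdiff(seq_along(y), train)
    pr <- stats::predict(fit, X[test, , drop = FALSE], type = "prob")
    imp[, r] <- fit$importance[, "MeanDecreaseGini"]
    lik[[r]] <- data.frame(run = r, sample_id = rownames(X)[test],
                           pr[, lev, drop = FALSE],
                           truth = as.character(y[test]),
                           stringsAsFactors = FALSE, check.names = FALSE)
  }
  lik <- do.call(rbind, lik)
  names(lik)[match(lev, names(lik))] <- paste0("L_", lev)
  rownames(lik) <- NULL
  structure(list(likelihoods = lik, importance = imp, classes = classes,
                 R = R, T_trees = T_trees, split = split),
            class = "rf_ensemble")
}

# Stratified index sample guaranteeing every class in training; resamples
# (up to 100 times) in the degenerate case of an empty training class.
stratified_split <- function(y, split) {
  for (attempt in 1:100) {
    train <- unlist(lapply(levels(y), function(l) {
      i <- which(y == l)
      sample(i, max(1L, round(split * length(i))))
    }), use.names = FALSE)
    if (all(levels(y) %in% y[train]) && length(train) < length(y))
      return(sort(train))
  }
  stop("could not produce a split with all classes in training")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("rf_ensemble: %s, %d runs x %d trees, split %.2f\n",
              x$classes, x$R, x$T_trees, x$split))
  invisible(x)
}

#' Severeness value from three-class likelihoods
#'
#' `S = L_M / 2 + L_A`, so `S = 0` for a certain healthy call, `0.5` for a
#' certain non-aggressive call and `1` for a certain aggressive call.
#'
#' @param L_H,L_M,L_A non-negative likelihoods summing to 1 (vectorized).
#' @return Severeness values in \[0, 1\].
#' @export
severeness <- function(L_H, L_M, L_A) {
  if (any(L_H < 0 | L_M < 0 | L_A < 0))
    stop("likelihoods must be non-negative")
  if (any(abs(L_H + L_M + L_A - 1) > 1e-9))
    stop("likelihoods must sum to 1")
  L_M / 2 + L_A
}

#' Per-sample severeness profile over all test-set appearances
#'
#' Averages the per-run severeness of each sample over the runs in which it
#' was in the test set, and assigns the reporting category: positive
#' (`S > 0.6`), negative (`S < 0.4`) or undecided (the band in between).
#'
#' @param result a 3-way `rf_ensemble`.
#' @return Data frame: `sample_id`, `mean_severeness`, `n_runs`, `category`.
#' @export
severeness_profile <- function(result) {
  if (result$classes != "3way")
    stop("severeness is defined for the 3-way classifier")
  lik <- result$likelihoods
  s <- severeness(lik$L_H, lik$L_M, lik$L_A)
  agg <- stats::aggregate(s, list(sample_id = lik$sample_id), mean)
  n <- as.data.frame(table(lik$sample_id), stringsAsFactors = FALSE)
  out <- data.frame(sample_id = agg$sample_id,
                    mean_severeness = agg$x,
                    n_runs = n$Freq[match(agg$sample_id, n$Var1)],
                    stringsAsFactors = FALSE)
  out$category <- ifelse(out$mean_severeness > 0.6, "positive",
                         ifelse(out$mean_severeness < 0.4, "negative",
                                "undecided"))
  out
}

# Rank-based AUC (equivalent to the trapezoidal area under the ROC swept by
# a continuous cut-off, with tied scores handled by mid-ranks).
auc_rank <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (!np || !nn) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Pooled ROC AUC of the repeated forest
#'
#' Pools likelihoods into a single score per the requested contrast:
#' `L_M + L_A` against healthy (`PrCa_vs_H`), or `L_A` against the combined
#' healthy and non-aggressive groups (`A_vs_rest`).  By default the score is
#' averaged per sample over all its test-set appearances before the ROC is
#' swept; `per_run = TRUE` instead pools every (run, sample) prediction.
#'
#' @param result an `rf_ensemble`.
#' @param meta a `SampleMetadata`.
#' @param contrast `"PrCa_vs_H"` or `"A_vs_rest"` (3-way only for the latter).
#' @param per_run pool per-run predictions instead of per-sample averages.
#' @return The AUC.
#' @export
pooled_roc_auc <- function(result, meta,
                           contrast = c("PrCa_vs_H", "A_vs_rest"),
                           per_run = FALSE) {
  contrast <- match.arg(contrast)
  lik <- result$likelihoods
  if (result$classes == "2way") {
    if (contrast != "PrCa_vs_H")
      stop("2-way ensembles support only the PrCa_vs_H contrast")
    score <- lik$L_P
    positive <- lik$truth == "P"
  } else if (contrast == "PrCa_vs_H") {
    score <- lik$L_M + lik$L_A
    positive <- lik$truth != "H"
  } else {
    score <- lik$L_A
    positive <- lik$truth == "A"
  }
  if (!per_run) {
    score <- tapply(score, lik$sample_id, mean)
    positive <- tapply(positive, lik$sample_id, function(z) z[1])
    score <- as.numeric(score); positive <- as.logical(positive)
  }
  auc_rank(score, positive)
}

#' Mean Gini importance per probe over all runs
#' @param result an `rf_ensemble`.
#' @return Named numeric vector (probe order preserved).
#' @export
aggregate_importance <- function(result) {
  rowMeans(result$importance)
}

#' Select high-interest (HI) probes
#'
#' A probe is HI when its smallest directional-test p-value over the tested
#' orderings is below `alpha` and its mean Gini importance ranks within the
#' top `top_frac` of all probes (rank at most `ceiling(top_frac * P)`, ties
#' broken deterministically by probe ID).
#'
#' @param test_results a `gmw_test` data frame (both orderings).
#' @param importance named vector of mean importances over the same probes.
#' @param alpha directional-test threshold (default 0.01).
#' @param top_frac importance-rank fraction (default 0.1).
#' @return An object of class `"hi_probes"`: data frame `probe_id`,
#'   `min_p_value`, `best_ordering`, `mean_importance`, `importance_rank`,
#'   with the thresholds in attributes `alpha` and `top_frac`.
#' @export
select_hi_probes <- function(test_results, importance, alpha = 0.01,
                             top_frac = 0.1) {
  probes <- names(importance)
  if (!setequal(probes, unique(test_results$probe_id)))
    stop("test results and importance cover different probe sets")
  min_p <- numeric(length(probes))
  best_ord <- character(length(probes))
  for (i in seq_along(probes)) {
    sub <- test_results[test_results$probe_id == probes[i], ]
    j <- which.min(sub$p_value)
    min_p[i] <- sub$p_value[j]
    best_ord[i] <- sub$ordering[j]
  }
  ord <- order(-importance, probes)
  rk <- integer(length(probes)); rk[ord] <- seq_along(probes)
  keep <- min_p < alpha & rk <= ceiling(top_frac * length(probes))
  out <- data.frame(probe_id = probes[keep], min_p_value = min_p[keep],
                    best_ordering = best_ord[keep],
                    mean_importance = unname(importance[keep]),
                    importance_rank = rk[keep], stringsAsFactors = FALSE)
  out <- out[order(out$importance_rank), ]
  rownames(out) <- NULL
  structure(out, class = c("hi_probes", "data.frame"),
            alpha = alpha, top_frac = top_frac)
}

#' @export
print.hi_probes <- function(x, ...) {
  cat(sprintf("%d HI probes (p < %g and importance rank in top %g%%)\n",
              nrow(x), attr(x, "alpha"), 100 * attr(x, "top_frac")))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}
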