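#' Per-probe one-way ANOVA screen with Bonferroni correction
#'
#' Fixed-effects one-way ANOVA of expression on the three health groups for
#' every probe, selecting probes whose Bonferroni-adjusted p-value falls
#' below `alpha` (the default 0.001 is the conventional screen level; set
#' `adjusted = FALSE` to interpret `alpha` as the per-test level instead).
#' Probes with zero within-group variance in every group get p = 0 when the
#' group means differ and p = 1 when they are all equal.
#'
#' @param expr an `ExpressionMatrix`.
#' @param meta a `SampleMetadata`.
#' @param alpha selection threshold (default 0.001).
#' @param adjusted compare the Bonferroni-adjusted p-value to `alpha`
#'   (default) rather than the raw p-value.
#' @return A `comparator_result`: list with `method = "ANOVA"`, `selected`
#'   probe IDs, `p_values` (raw), `p_adjusted`, `alpha`.
#' @export
anova_screen <- function(expr, meta, alpha = 0.001, adjusted = TRUE) {
  idx <- match(colnames(expr$values), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata")
  health <- meta$health[idx]
  if (any(table(health) < 2)) stop("need >= 2 samples per group")
  pv <- apply(expr$values, 1, function(x) {
    if (all(tapply(x, health, stats::var) == 0)) {
      mns <- tapply(x, health, mean)
      return(if (max(mns) - min(mns) > 0) 0 else 1)
    }
    stats::oneway.test(x ~ health, var.equal = TRUE)$p.value
  })
  p_adj <- stats::p.adjust(pv, method = "bonferroni")
  crit <- if (adjusted) p_adj else pv
  structure(list(method = "ANOVA",
                 selected = rownames(expr$values)[crit < alpha],
                 p_values = pv, p_adjusted = p_adj, alpha = alpha),
            class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("%s comparator: %d probes selected\n", x$method,
              length(x$selected)))
  invisible(x)
}

#' Two-stage lasso logistic regression (LRL) selector
#'
#' Stage 1 fits an L1-penalized logistic regression of healthy versus
#' diseased (M and A pooled) on all samples; stage 2 fits non-aggressive
#' versus aggressive on the cases only.  Probes are standardized to unit
#' variance before penalization.  The penalty is chosen per stage on a grid
#' of 50 log-spaced values so that the combined count of probes with
#' nonzero coefficients is closest to `target_count`; with `cv = TRUE` each
#' stage instead uses the cross-validated-deviance `lambda.min`.  The
#' selection is the union of the two stages.
#'
#' @param expr an `ExpressionMatrix`.
#' @param meta a `SampleMetadata`.
#' @param target_count desired combined selection size.
#' @param cv choose the penalty by cross-validation instead.
#' @param seed optional seed (used for the CV folds).
#' @return A `comparator_result` with `method = "LRL"`, `selected`,
#'   per-stage selections and the chosen penalties.
#' @export
lrl_two_stage <- function(expr, meta, target_count = NULL, cv = FALSE,
                          seed = NULL) {
  if (is.null(target_count) && !cv)
    stop("give target_count or set cv = TRUE")
  idx <- match(colnames(expr$values), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata")
  health <- as.character(meta$health[idx])
  X <- t(expr$values)
  if (!is.null(seed)) set.seed(seed)
  y1 <- factor(ifelse(health == "H", "H", "D"), levels = c("H", "D"))
  cases <- health != "H"
  y2 <- factor(health[cases], levels = c("M", "A"))
  if (length(unique(y1)) < 2 || length(unique(y2)) < 2)
    stop("both stages need both classes present")
  stage_paths <- function(X, y) {
    fit <- glmnet::glmnet(X, y, family = "binomial", nlambda = 50,
                          lambda.min.ratio = 1e-3, standardize = TRUE)
    sel <- lapply(seq_along(fit$lambda), function(j) {
      rownames(fit$beta)[as.vector(fit$beta[, j]) != 0]
    })
    list(fit = fit, sel = sel)
  }
  if (cv) {
    pick_cv <- function(X, y) {
      cvfit <- glmnet::cv.glmnet(X, y, family = "binomial",
                                 lambda.min.ratio = 1e-3, standardize = TRUE)
      b <- stats::coef(cvfit, s = "lambda.min")[-1, , drop = FALSE]
      list(sel = rownames(b)[as.vector(b) != 0], lambda = cvfit$lambda.min)
    }
    s1 <- pick_cv(X, y1)
    s2 <- pick_cv(X[cases, , drop = FALSE], y2)
    sel1 <- s1$sel; sel2 <- s2$sel
    lambdas <- c(stage1 = s1$lambda, stage2 = s2$lambda)
  } else {
    if (target_count == 0) {
      warning("target_count = 0: empty selection")
      sel1 <- sel2 <- character(0)
      lambdas <- c(stage1 = NA_real_, stage2 = NA_real_)
    } else {
      p1 <- stage_paths(X, y1)
      p2 <- stage_paths(X[cases, , drop = FALSE], y2)
      # stage 1 aims for half the budget (larger penalty wins ties), stage 2
      # brings the combined count closest to the target
      gap1 <- abs(lengths(p1$sel) - ceiling(target_count / 2))
      j1 <- which.min(gap1)
      sel1 <- p1$sel[[j1]]
      gap2 <- vapply(p2$sel, function(s)
        abs(length(union(sel1, s)) - target_count), numeric(1))
      j2 <- which.min(gap2)
      sel2 <- p2$sel[[j2]]
      best <- c(j1, j2)
      if (!length(union(sel1, sel2)) && target_count > 0) {
        warning("penalty grid exhausted without selections; using smallest")
        sel1 <- p1$sel[[length(p1$sel)]]
        sel2 <- p2$sel[[length(p2$sel)]]
      }
      lambdas <- c(stage1 = p1$fit$lambda[best[1]],
                   stage2 = p2$fit$lambda[best[2]])
    }
  }
  structure(list(method = "LRL", selected = union(sel1, sel2),
                 stage1 = sel1, stage2 = sel2, lambda = lambdas,
                 target_count = target_count, cv = cv),
            class = "comparator_result")
}

#' Compare probe selections by overlap and clustering quality
#'
#' For each selector, restricts the expression matrix to the selected
#' probes, clusters the samples by Kendall-tau distance (cut at `k`), and
#' scores the agreement of the flat clusters with the true health status by
#' adjusted Rand index.  Also reports all pairwise selection intersections.
#'
#' @param results named list of `comparator_result` or `hi_probes` objects
#'   (at least 2).
#' @param expr an `ExpressionMatrix` covering all selected probes.
#' @param meta a `SampleMetadata`.
#' @param k flat cluster count for the ARI (default 3).
#' @param linkage linkage passed to [hierarchical_cluster()].
#' @return List with `summary` (method, n_selected, ARI), `intersections`
#'   (matrix of pairwise overlap sizes) and `selections`.
#' @export
compare_selections <- function(results, expr, meta, k = 3,
                               linkage = "complete") {
  if (length(results) < 2) stop("need at least two selections to compare")
  sels <- lapply(results, function(r) {
    if (inherits(r, "hi_probes")) r$probe_id else r$selected
  })
  if (is.null(names(sels)))
    names(sels) <- vapply(results, function(r) {
      if (inherits(r, "hi_probes")) "HI" else r$method
    }, character(1))
  idx <- match(colnames(expr$values), meta$sample_id)
  truth <- as.integer(meta$health[idx])
  ari <- vapply(sels, function(s) {
    if (length(s) < 2) return(NA_real_)
    sub <- expression_matrix(expr$values[s, , drop = FALSE],
                             expr$detected[s, , drop = FALSE])
    D <- kendall_distance_matrix(sub)
    cl <- hierarchical_cluster(D, k = k, linkage = linkage)
    adjusted_rand_index(cl$labels[colnames(expr$values)], truth)
  }, numeric(1))
  m <- length(sels)
  inter <- matrix(0L, m, m, dimnames = list(names(sels), names(sels)))
  for (i in seq_len(m)) for (j in seq_len(m))
    inter[i, j] <- length(intersect(sels[[i]], sels[[j]]))
  list(summary = data.frame(method = names(sels),
                            n_selected = lengths(sels),
                            ari = ari, row.names = NULL,
                            stringsAsFactors = FALSE),
       intersections = inter, selections = sels)
}
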