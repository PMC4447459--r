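#' Probabilistic index for an ordered triple of groups
#'
#' Estimates the probability that a randomly drawn triple, one value per
#' group, is strictly increasing in the stated group order:
#' \deqn{\hat P = \frac{1}{n_1 n_2 n_3} \sum_i \sum_j \sum_k
#'   I(x_{1i} < x_{2j} < x_{3k}),}
#' with strict inequalities, so tied triples contribute zero.  Computed by a
#' sort-and-count sweep that is exactly equal to the naive triple loop.
#'
#' @param x_first,x_second,x_third non-empty numeric vectors, one per group,
#'   in the hypothesised increasing order.
#' @return The index, a value in \[0, 1\].
#' @examples
#' probabilistic_index(c(1, 2), c(3, 4), c(5, 6))  # 1: complete separation
#' probabilistic_index(c(1, 3), c(2, 4), c(0, 5))  # 3 of 8 triples
#' @export
probabilistic_index <- function(x_first, x_second, x_third) {
  if (!length(x_first) || !length(x_second) || !length(x_third))
    stop("all three groups must be non-empty")
  x <- c(x_first, x_second, x_third)
  if (anyNA(x)) stop("missing values not allowed")
  g <- rep.int(1:3, c(length(x_first), length(x_second), length(x_third)))
  o <- order(x)
  triple_count_cpp(x[o], g[o]) /
    (length(x_first) * length(x_second) * length(x_third))
}

# Core permutation engine for one value vector and a 3-level grouping.
# Returns p_hat, p_value, n_permutations, exhaustive flag.  `labperm` is a
# B x N matrix of permuted labels (original sample order), so one stream can
# be shared across probes; when the number of distinct label assignments is
# <= exhaustive_limit the full enumeration is used instead and the p-value is
# the exact proportion of assignments with an index at least as large as
# observed.
gmw_engine <- function(x, g, labperm = NULL, exhaustive_limit = 10000) {
  n <- table(factor(g, levels = 1:3))
  if (any(n == 0)) stop("a group has size 0")
  denom <- prod(n)
  o <- order(x)
  xs <- x[o]
  obs <- triple_count_cpp(xs, g[o]) / denom
  n_assign <- exp(lgamma(length(x) + 1) - sum(lgamma(n + 1)))
  if (n_assign <= exhaustive_limit) {
    labs <- enumerate_assignments(length(x), n)
    counts <- triple_count_perms_cpp(xs, labs[, o, drop = FALSE])
    p <- mean(counts / denom >= obs - 1e-12)
    return(list(p_hat = obs, p_value = p, n_permutations = nrow(labs),
                exhaustive = TRUE))
  }
  if (is.null(labperm)) stop("permutation matrix required for sampled p-values")
  counts <- triple_count_perms_cpp(xs, labperm[, o, drop = FALSE])
  B <- nrow(labperm)
  p <- (1 + sum(counts / denom >= obs - 1e-12)) / (B + 1)
  list(p_hat = obs, p_value = p, n_permutations = B, exhaustive = FALSE)
}

# All distinct assignments of labels 1/2/3 with group sizes n to N slots.
enumerate_assignments <- function(N, n) {
  first <- utils::combn(N, n[1])
  out <- vector("list", ncol(first))
  for (i in seq_len(ncol(first))) {
    rest <- setdiff(seq_len(N), first[, i])
    second <- utils::combn(length(rest), n[2])
    block <- matrix(3L, ncol(second), N)
    block[, first[, i]] <- 1L
    for (j in seq_len(ncol(second)))
      block[j, rest[second[, j]]] <- 2L
    out[[i]] <- block
  }
  do.call(rbind, out)
}

#' Directional generalized Mann-Whitney test per probe
#'
#' For every probe and every requested group ordering, computes the
#' probabilistic index on the observed health labels and a one-sided
#' permutation p-value obtained by permuting the labels across all samples
#' (group sizes preserved).  The sampled p-value uses the add-one rule
#' `p = (1 + #\{b: P-hat_b >= P-hat_obs\}) / (B + 1)`; when the number of
#' distinct label assignments is at most `exhaustive_limit`, the exact
#' enumeration p-value is returned instead.  One permutation stream is shared
#' by all probes, so runs are reproducible from the seed.
#'
#' @param expr an `ExpressionMatrix`.
#' @param meta a `SampleMetadata` labelling every sample.
#' @param orderings list of length-3 character vectors giving the group
#'   order in the indicator; defaults to `H<M<A` and `A<M<H`.
#' @param B number of label permutations (the study default is 5000).
#' @param seed optional integer seed for the permutation stream.
#' @param exhaustive_limit enumerate all assignments when their number is at
#'   most this (default 10000).
#' @return A data frame of class `"gmw_test"` with columns `probe_id`,
#'   `ordering` (e.g. `"H<M<A"`), `p_hat`, `p_value`, `n_permutations`,
#'   `exhaustive`.
#' @export
directional_test <- function(expr, meta,
                             orderings = list(c("H", "M", "A"),
                                              c("A", "M", "H")),
                             B = 5000, seed = NULL,
                             exhaustive_limit = 10000) {
  if (B < 1) stop("B must be >= 1")
  idx <- match(colnames(expr$values), meta$sample_id)
  if (anyNA(idx)) stop("samples without metadata")
  health <- as.character(meta$health[idx])
  n <- table(factor(health, levels = c("H", "M", "A")))
  if (any(n == 0)) stop("a health group has size 0")
  N <- length(health)
  n_assign <- exp(lgamma(N + 1) - sum(lgamma(n + 1)))
  perms <- NULL
  if (n_assign > exhaustive_limit) {
    if (!is.null(seed)) set.seed(seed)
    perms <- t(replicate(B, sample.int(N)))
  }
  res <- vector("list", length(orderings) * nrow(expr$values))
  k <- 0L
  for (ord in orderings) {
    if (!setequal(ord, c("H", "M", "A")) || length(ord) != 3)
      stop("orderings must be permutations of H, M, A")
    g <- match(health, ord)
    labperm <- if (is.null(perms)) NULL else matrix(g[perms], nrow = B)
    for (p in seq_len(nrow(expr$values))) {
      fit <- gmw_engine(expr$values[p, ], g, labperm, exhaustive_limit)
      k <- k + 1L
      res[[k]] <- data.frame(probe_id = rownames(expr$values)[p],
                             ordering = paste(ord, collapse = "<"),
                             p_hat = fit$p_hat, p_value = fit$p_value,
                             n_permutations = fit$n_permutations,
                             exhaustive = fit$exhaustive,
                             stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, res), class = c("gmw_test", "data.frame"))
}

#' @export
print.gmw_test <- function(x, alpha = 0.01, ...) {
  cat("Directional generalized Mann-Whitney test\n")
  for (ord in unique(x$ordering)) {
    sub <- x[x$ordering == ord, ]
    cat(sprintf("  %s: %d probes, %d with p < %g\n", ord, nrow(sub),
                sum(sub$p_value < alpha), alpha))
  }
  invisible(x)
}

#' Two-sided two-group Mann-Whitney test
#'
#' Exact enumeration over all label assignments when `n1 + n2 <= 12`
#' (tie-aware, using the half-weighted U statistic); otherwise the normal
#' approximation with tie correction.
#'
#' @param x1,x2 non-empty numeric vectors.
#' @return The two-sided p-value.
#' @export
two_group_mw <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (!n1 || !n2) stop("both groups must be non-empty")
  x <- c(x1, x2)
  u_stat <- function(take1) {
    r <- rank(x)
    sum(r[take1]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_stat(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 12) {
    combs <- utils::combn(n1 + n2, n1)
    dev <- abs(apply(combs, 2, u_stat) - mu)
    return(mean(dev >= abs(u_obs - mu) - 1e-12))
  }
  n <- n1 + n2
  ties <- table(x)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u_obs - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg rejection curve
#'
#' The observed rejection ratio (fraction of p-values at or below each test
#' size) against the expected ratio under the global null (the diagonal),
#' plus the number of BH step-up rejections at the stated FDR: the largest
#' `k` with `p_(k) <= k * fdr / m`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param fdr target false discovery rate for the BH count (default 0.05).
#' @param grid test sizes at which the curve is evaluated.
#' @return An object of class `"rejection_curve"`: list with `grid`,
#'   `expected`, `observed`, `bh_rejections`, `fdr`, `m`.
#' @export
bh_rejection_curve <- function(p_values, fdr = 0.05,
                               grid = seq(0, 1, by = 0.001)) {
  if (!length(p_values)) stop("empty p-value vector")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ps <- sort(p_values)
  observed <- vapply(grid, function(a) mean(ps <= a), numeric(1))
  ok <- which(ps <= seq_len(m) * fdr / m)
  structure(list(grid = grid, expected = grid, observed = observed,
                 bh_rejections = if (length(ok)) max(ok) else 0L,
                 fdr = fdr, m = m),
            class = "rejection_curve")
}

#' @export
print.rejection_curve <- function(x, ...) {
  cat(sprintf("Rejection curve over %d tests: %d BH rejections at FDR %g\n",
              x$m, x$bh_rejections, x$fdr))
  invisible(x)
}

#' @export
plot.rejection_curve <- function(x, ...) {
  graphics::plot(x$expected, x$observed, type = "l",
                 xlab = "expected rejection ratio under the null",
                 ylab = "observed rejection ratio", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
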