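test_that("severeness maps the degenerate likelihoods to 0, 0.5 and 1", {
  expect_equal(severeness(1, 0, 0), 0)
  expect_equal(severeness(0, 1, 0), 0.5)
  expect_equal(severeness(0, 0, 1), 1)
  expect_equal(severeness(0.2, 0.4, 0.4), 0.6)
  expect_error(severeness(0.5, 0.4, 0.2), "sum to 1")
  expect_error(severeness(-0.1, 0.6, 0.5), "non-negative")
  # vectorized and always in [0, 1]
  set.seed(1)
  L <- matrix(rexp(300), 100, 3); L <- L / rowSums(L)
  s <- severeness(L[, 1], L[, 2], L[, 3])
  expect_true(all(s >= 0 & s <= 1))
})

test_that("repeated forest records normalized likelihoods for test samples", {
  set.seed(2)
  e <- make_expr(matrix(rnorm(5 * 12), 5, 12))
  m <- make_meta(4, 4, 4)
  r <- run_repeated_rf(e, m, R = 1, T_trees = 1, seed = 9)
  lik <- r$likelihoods
  expect_true(nrow(lik) >= 3)  # one row per test sample
  expect_equal(lik$L_H + lik$L_M + lik$L_A, rep(1, nrow(lik)))
  expect_true(all(r$importance >= 0))
  expect_identical(rownames(r$importance), rownames(e$values))
})

test_that("a separable fixture is classified nearly perfectly", {
  set.seed(3)
  n <- 12
  vals <- rbind(sep = c(rnorm(n, 0, 0.2), rnorm(2 * n, 10, 0.2)),
                noise = rnorm(3 * n))
  e <- make_expr(vals)
  m <- make_meta(n, n, n)
  r <- run_repeated_rf(e, m, classes = "2way", R = 50, T_trees = 50,
                       seed = 10)
  lik <- r$likelihoods
  acc <- mean(ifelse(lik$L_P > 0.5, "P", "H") == lik$truth)
  expect_gte(acc, 0.95)
  expect_equal(pooled_roc_auc(r, m, "PrCa_vs_H"), 1)
})

test_that("pooled AUC has the tie convention and negation symmetry", {
  fake <- structure(list(
    likelihoods = data.frame(run = 1, sample_id = sprintf("s%02d", 1:20),
                             L_H = rep(0.5, 20), L_M = rep(0.25, 20),
                             L_A = rep(0.25, 20),
                             truth = rep(c("H", "A"), 10),
                             stringsAsFactors = FALSE),
    classes = "3way", R = 1, T_trees = 1, split = 0.75),
    class = "rf_ensemble")
  m <- sample_metadata(sprintf("s%02d", 1:20), rep(c("H", "A"), 10),
                       rep("f", 20))
  expect_equal(pooled_roc_auc(fake, m, "PrCa_vs_H"), 0.5)  # all scores tied

  set.seed(4)
  sc <- runif(20)
  fake$likelihoods$L_A <- sc
  fake$likelihoods$L_M <- 0
  fake$likelihoods$L_H <- 1 - sc
  a1 <- pooled_roc_auc(fake, m, "A_vs_rest")
  fake$likelihoods$L_A <- 1 - sc
  fake$likelihoods$L_H <- sc
  a2 <- pooled_roc_auc(fake, m, "A_vs_rest")
  expect_equal(a1, 1 - a2)
  # agrees with the independent ROC reference
  truth <- fake$likelihoods$truth == "A"
  ref <- as.numeric(pROC::auc(pROC::roc(truth, 1 - sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a2, ref)
})

test_that("importance aggregation and HI selection follow the two-filter rule", {
  r <- structure(list(importance = cbind(c(1, 0), c(0, 1)),
                      classes = "3way"), class = "rf_ensemble")
  rownames(r$importance) <- c("pa", "pb")
  expect_equal(unname(aggregate_importance(r)), c(0.5, 0.5))

  probes <- sprintf("p%02d", 1:10)
  tst <- data.frame(probe_id = rep(probes, 2),
                    ordering = rep(c("H<M<A", "A<M<H"), each = 10),
                    p_hat = 0.5, p_value = 1, n_permutations = 100,
                    exhaustive = FALSE, stringsAsFactors = FALSE)
  imp <- stats::setNames(seq(0.1, 1, by = 0.1), probes)

  # all p-values 1: empty set
  hi0 <- select_hi_probes(tst, imp)
  expect_identical(nrow(hi0), 0L)

  # one significant probe with top importance: selected alone
  tst$p_value[tst$probe_id == "p10" & tst$ordering == "H<M<A"] <- 0.001
  hi1 <- select_hi_probes(tst, imp, alpha = 0.01, top_frac = 0.1)
  expect_identical(hi1$probe_id, "p10")
  expect_identical(hi1$best_ordering, "H<M<A")

  # significant but importance rank 2 of 10 with top_frac 0.1: excluded
  tst$p_value[tst$probe_id == "p09"] <- 0.001
  tst$p_value[tst$probe_id == "p10"] <- 1
  hi2 <- select_hi_probes(tst, imp, alpha = 0.01, top_frac = 0.1)
  expect_identical(nrow(hi2), 0L)
})

test_that("severeness profile averages over test appearances and bands", {
  set.seed(6)
  e <- make_expr(matrix(rnorm(4 * 15), 4, 15))
  m <- make_meta(5, 5, 5)
  r <- run_repeated_rf(e, m, R = 10, T_trees = 20, seed = 12)
  prof <- severeness_profile(r)
  expect_true(all(prof$mean_severeness >= 0 & prof$mean_severeness <= 1))
  expect_true(all(prof$category %in% c("positive", "negative", "undecided")))
  expect_true(all(prof$n_runs >= 1))
  band <- prof$mean_severeness > 0.6
  expect_identical(prof$category[band], rep("positive", sum(band)))
})
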