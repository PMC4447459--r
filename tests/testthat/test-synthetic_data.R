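test_that("cohort generation is deterministic and respects its config", {
  cfg <- sim_config(n_H = 8, n_M = 9, n_A = 6, n_probes = 30, n_planted = 4,
                    delta = 1.5, n_snps_per_probe = 3, n_discovery = 12,
                    n_validation = 10, seed = 51)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$expr$values, c2$expr$values)
  expect_identical(c1$truth$planted, c2$truth$planted)
  g1 <- generate_genotypes(cfg, c1)
  g2 <- generate_genotypes(cfg, c2)
  expect_identical(g1$discovery$codes, g2$discovery$codes)
  expect_identical(g1$expr$values, g2$expr$values)

  expect_identical(dim(c1$expr$values), c(30L, 23L))
  expect_identical(nrow(c1$truth$planted), 4L)
  expect_true(all(c1$truth$planted$probe_id %in% c1$anno$probe_id))
  expect_equal(mean(c1$expr$detected), 0.9, tolerance = 0.02)
  expect_identical(ncol(g1$discovery$codes), 12L)
  expect_identical(ncol(g1$validation$codes), 10L)
  expect_error(sim_config(n_probes = 0), "n_probes")
})

test_that("planted ordered probes carry the planted direction", {
  cfg <- sim_config(n_H = 15, n_M = 15, n_A = 15, n_probes = 40,
                    n_planted = 8, delta = 3, family_effect_sd = 0,
                    seed = 52)
  coh <- generate_cohort(cfg)
  h <- coh$meta$health
  for (i in seq_len(nrow(coh$truth$planted))) {
    pid <- coh$truth$planted$probe_id[i]
    x <- coh$expr$values[pid, ]
    ord <- if (coh$truth$planted$direction[i] == "H<M<A")
      list(x[h == "H"], x[h == "M"], x[h == "A"])
    else
      list(x[h == "A"], x[h == "M"], x[h == "H"])
    expect_gt(probabilistic_index(ord[[1]], ord[[2]], ord[[3]]), 0.5)
  }
})

test_that("null cohorts carry no ordering signal", {
  cfg <- sim_config(n_H = 20, n_M = 20, n_A = 20, n_probes = 400,
                    n_planted = 0, delta = 0, family_effect_sd = 0,
                    seed = 53)
  coh <- generate_cohort(cfg)
  h <- coh$meta$health
  phat <- apply(coh$expr$values, 1, function(x)
    probabilistic_index(x[h == "H"], x[h == "M"], x[h == "A"]))
  # E[P-hat] = 1/6 under exchangeability; 3 MC SDs around the mean
  mc_sd <- stats::sd(phat) / sqrt(length(phat))
  expect_lt(abs(mean(phat) - 1 / 6), 3 * mc_sd + 1e-3)
})

test_that("family effects induce within-family rank correlation", {
  cfg <- sim_config(n_H = 20, n_M = 20, n_A = 20, n_probes = 60,
                    n_planted = 0, delta = 0, family_count = 12,
                    family_effect_sd = 1.5, seed = 54)
  coh <- generate_cohort(cfg)
  S <- stats::cor(coh$expr$values, method = "kendall")
  fam <- coh$meta$family_id[match(colnames(coh$expr$values),
                                  coh$meta$sample_id)]
  same <- outer(fam, fam, "==") & upper.tri(S)
  diff_fam <- !outer(fam, fam, "==") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff_fam]))
})

test_that("directional-test power increases with the planted shift", {
  hits <- matrix(NA, 20, 2)
  for (s in 1:20) {
    for (j in 1:2) {
      cfg <- sim_config(n_H = 12, n_M = 12, n_A = 12, n_probes = 5,
                        n_planted = 1, delta = j, family_effect_sd = 0,
                        seed = 500 + s)
      coh <- generate_cohort(cfg)
      r <- directional_test(coh$expr, coh$meta, B = 200, seed = 600 + s)
      pid <- coh$truth$planted$probe_id
      hits[s, j] <- min(r$p_value[r$probe_id == pid]) < 0.05
    }
  }
  expect_lte(mean(hits[, 1]), mean(hits[, 2]))
  expect_gt(mean(hits[, 2]), 0.8)
})

test_that("fixture sets round-trip through the plain-text formats", {
  cfg <- sim_config(n_H = 6, n_M = 6, n_A = 5, n_probes = 12, n_planted = 3,
                    n_snps_per_probe = 2, n_discovery = 8, n_validation = 6,
                    seed = 55)
  coh <- generate_cohort(cfg)
  gen <- generate_genotypes(cfg, coh)
  dir <- file.path(tempdir(), "fixture_set")
  paths <- write_fixture_set(coh, dir, gen)
  expect_true(all(file.exists(paths)))

  back <- load_expression(paths["expr"], paths["detect"])
  expect_equal(back$values, gen$expr$values, tolerance = 1e-10)
  expect_identical(back$detected, gen$expr$detected)
  meta_back <- load_metadata(paths["meta"])
  expect_identical(meta_back$sample_id, coh$meta$sample_id)
  expect_identical(as.character(meta_back$health),
                   as.character(coh$meta$health))
  geno_back <- load_genotypes(paths["geno_discovery"], paths["geno_annot"])
  expect_identical(geno_back$codes, gen$discovery$codes)

  manifest <- jsonlite::read_json(paths["manifest"])
  expect_equal(manifest$seed, 55)
  truth_back <- utils::read.delim(paths["truth"])
  expect_identical(nrow(truth_back), 3L)
})

test_that("monomorphic simulated SNPs are excluded downstream", {
  ids <- sprintf("s%d", 1:8)
  snps <- data.frame(snp_id = "rsM", chrom = "chr1", pos = 100,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  geno <- genotype_data(matrix(0L, 1, 8, dimnames = list("rsM", ids)), snps)
  e <- expression_matrix(matrix(rnorm(8), 1, dimnames = list("pr1", ids)))
  links <- data.frame(snp_id = "rsM", probe_id = "pr1", chrom = "chr1",
                      snp_pos = 100, probe_center = 120, distance = 20,
                      stringsAsFactors = FALSE)
  expect_identical(nrow(eqtl_test(links, e, geno)), 0L)
})
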