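test_that("cis linking uses the probe center and the 0.5 Mb half-window", {
  # probe with descending printed coordinates: center chr11:2,155,423
  anno <- probe_annotation("probe1", "mir-483-3p-like", "chr11",
                          2155431, 2155415)
  snps <- data.frame(snp_id = c("snpA", "snpB", "snpC", "snpD"),
                     chrom = c("chr11", "chr11", "chr7", "chr11"),
                     pos = c(2310605, 1679711, 2310605, 2655500),
                     allele1 = "A", allele2 = "G",
                     stringsAsFactors = FALSE)
  codes <- matrix(0L, 4, 2, dimnames = list(snps$snp_id, c("s1", "s2")))
  geno <- genotype_data(codes, snps)
  links <- link_cis_snps(anno, geno)
  expect_setequal(links$snp_id, c("snpA", "snpB"))
  expect_equal(links$distance[links$snp_id == "snpA"], 155182)
  expect_equal(links$distance[links$snp_id == "snpB"], 475712)
  # snpC: wrong chromosome; snpD: 500,077 bp away, just outside
  expect_false("snpD" %in% links$snp_id)
  expect_error(link_cis_snps(anno, geno, half_window = 0), "positive")
})

make_eqtl_fixture <- function(codes_row, expr_row) {
  ids <- sprintf("s%d", seq_along(codes_row))
  snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 150,
                     allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)
  geno <- genotype_data(matrix(codes_row, 1, dimnames = list("rs1", ids)),
                        snps)
  e <- expression_matrix(matrix(expr_row, 1,
                                dimnames = list("pr1", ids)))
  links <- data.frame(snp_id = "rs1", probe_id = "pr1", chrom = "chr1",
                      snp_pos = 150, probe_center = 100, distance = 50,
                      stringsAsFactors = FALSE)
  list(links = links, expr = e, geno = geno)
}

test_that("genotype-group tests dispatch on the number of groups", {
  # three ordered groups, complete separation: index 1, smallest exact p
  f <- make_eqtl_fixture(c(0, 0, 1, 1, 2, 2), 1:6)
  r <- eqtl_test(f$links, f$expr, f$geno)
  expect_equal(r$test, "directional_012")
  expect_equal(r$n_groups, 3L)
  expect_equal(r$p_012, 1 / 90)  # 1 of 6!/(2!2!2!) = 90 assignments
  expect_equal(r$p_value, 1 / 90)

  # monomorphic: excluded
  f2 <- make_eqtl_fixture(rep(0, 6), 1:6)
  expect_identical(nrow(eqtl_test(f2$links, f2$expr, f2$geno)), 0L)

  # two groups: exact two-sided Mann-Whitney
  f3 <- make_eqtl_fixture(c(0, 0, 0, 1, 1, 1), 1:6)
  r3 <- eqtl_test(f3$links, f3$expr, f3$geno)
  expect_equal(r3$test, "two_sided_MW")
  expect_equal(r3$p_value, 0.1)

  # missing genotypes are dropped pairwise
  f4 <- make_eqtl_fixture(c(0, 0, 0, 1, 1, 1, NA), c(1:6, 100))
  r4 <- eqtl_test(f4$links, f4$expr, f4$geno)
  expect_equal(r4$p_value, 0.1)
  expect_equal(r4$n0 + r4$n1 + r4$n2, 6L)
})

test_that("directional eQTL p-values cover both alternatives", {
  set.seed(13)
  f <- make_eqtl_fixture(rep(0:2, each = 4), rnorm(12))
  r <- eqtl_test(f$links, f$expr, f$geno)
  expect_true(all(c("p_012", "p_210") %in% names(r)))
  expect_equal(r$p_value, min(r$p_012, r$p_210))
  expect_true(r$test %in% c("directional_012", "directional_210"))
})

test_that("Fisher 2x3 is exact, symmetric and reduces to 2x2", {
  for (nm in names(published_tables)) {
    tb <- published_tables[[nm]]
    expect_equal(round(fisher_2x3(tb$cases, tb$controls), 4), tb$p,
                 info = nm)
  }
  expect_equal(fisher_2x3(c(10, 0, 0), c(10, 0, 0)), 1)
  expect_error(fisher_2x3(c(0, 0, 0), c(1, 2, 3)), "positive")
  expect_error(fisher_2x3(c(-1, 1, 1), c(1, 2, 3)), "non-negative")

  # row swap and column permutation invariance
  expect_equal(fisher_2x3(c(3, 24, 12), c(5, 3, 7)),
               fisher_2x3(c(5, 3, 7), c(3, 24, 12)))
  expect_equal(fisher_2x3(c(3, 24, 12), c(5, 3, 7)),
               fisher_2x3(c(12, 3, 24), c(7, 5, 3)))

  # empty genotype column: exactly the 2x2 Fisher exact test
  expect_equal(fisher_2x3(c(8, 2, 0), c(3, 7, 0)),
               stats::fisher.test(rbind(c(8, 2), c(3, 7)))$p.value)
})

test_that("association tables are built from pooled cases vs controls", {
  ids <- sprintf("s%d", 1:12)
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "chr1",
                     pos = c(100, 200), allele1 = "A", allele2 = "G",
                     stringsAsFactors = FALSE)
  codes <- rbind(rs1 = c(0, 0, 0, 0, 1, 1, 2, 2, 2, 2, 1, 2),
                 rs2 = rep(0L, 12))
  colnames(codes) <- ids
  geno <- genotype_data(codes, snps)
  meta <- sample_metadata(ids, rep(c("H", "M", "A"), each = 4),
                          rep("f", 12))
  a <- association_test(geno, meta)
  expect_equal(unname(unlist(a[a$snp_id == "rs1", c("c0", "c1", "c2")])),
               c(0, 3, 5))
  expect_equal(unname(unlist(a[a$snp_id == "rs1", c("h0", "h1", "h2")])),
               c(4, 0, 0))
  expect_equal(a$fisher_p[a$snp_id == "rs1"],
               fisher_2x3(c(0, 3, 5), c(4, 0, 0)))
  expect_equal(a$fisher_p[a$snp_id == "rs2"], 1)  # monomorphic

  # validation: absent SNP gives a missing validation p
  val_geno <- genotype_data(codes["rs1", , drop = FALSE], snps[1, ])
  out <- validate_associations(a, val_geno, meta)
  expect_equal(out$validation_p[out$snp_id == "rs1"],
               a$fisher_p[a$snp_id == "rs1"])
  expect_true(is.na(out$validation_p[out$snp_id == "rs2"]))
})
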