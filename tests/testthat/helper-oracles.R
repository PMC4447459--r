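# Independent brute-force oracle for the probabilistic index: the naive
# O(n1*n2*n3) triple loop over all ordered triples.
brute_pindex <- function(x1, x2, x3) {
  s <- 0L
  for (a in x1) for (b in x2) for (cc in x3)
    s <- s + (a < b && b < cc)
  s / (length(x1) * length(x2) * length(x3))
}

# Small expression fixture: values matrix plus optional detection mask.
# Probe/sample IDs are always p01..pNN / s01..sNN.
make_expr <- function(values, detected = NULL) {
  rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, detected)
}

# Metadata with the given per-group sizes, samples named to match make_expr.
make_meta <- function(n_H, n_M, n_A, family = NULL) {
  n <- n_H + n_M + n_A
  if (is.null(family)) family <- rep("f1", n)
  sample_metadata(sprintf("s%02d", seq_len(n)),
                  rep(c("H", "M", "A"), c(n_H, n_M, n_A)), family)
}

# The ten published 2x3 genotype count tables (cases; controls) and their
# exact Fisher p-values, used by the association tests.
published_tables <- list(
  RS547311    = list(cases = c(32, 4, 3),   controls = c(8, 6, 1),  p = 0.0410),
  RS17173843  = list(cases = c(30, 9, 0),   controls = c(8, 5, 2),  p = 0.0433),
  RS11849923  = list(cases = c(18, 16, 5),  controls = c(2, 12, 1), p = 0.0309),
  RS11629195  = list(cases = c(3, 24, 12),  controls = c(5, 3, 7),  p = 0.0084),
  RS7079873   = list(cases = c(62, 1, 0),   controls = c(16, 4, 0), p = 0.0110),
  RS7913785   = list(cases = c(62, 1, 0),   controls = c(17, 3, 0), p = 0.0417),
  RS4752755   = list(cases = c(18, 30, 15), controls = c(9, 11, 0), p = 0.0270),
  RS1317356   = list(cases = c(17, 30, 16), controls = c(9, 11, 0), p = 0.0149),
  RS756919    = list(cases = c(52, 11, 0),  controls = c(11, 7, 2), p = 0.0115),
  RS1501466   = list(cases = c(41, 21, 1),  controls = c(14, 3, 3), p = 0.0226))
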