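test_that("counts files parse, drop incomplete SNPs, and survive gzip", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A B", "2,0 1,1"), tmp)
  panel <- read_counts(tmp)
  expect_equal(panel$populations, c("A", "B"))
  expect_equal(nrow(panel$countA), 1)
  expect_equal(unname(panel$countA[1, ]), c(2L, 1L))
  expect_equal(unname(panel$countB[1, ]), c(0L, 1L))

  writeLines(c("A B", "2,0 1,1", "0,0 1,1"), tmp)
  expect_equal(nrow(read_counts(tmp)$countA), 1)                  # dropped
  expect_equal(nrow(read_counts(tmp, drop_incomplete = FALSE)$countA), 2)

  gz <- withr::local_tempfile(fileext = ".gz")
  con <- gzfile(gz, "wt")
  writeLines(c("A B", "2,0 1,1", "0,0 1,1"), con)
  close(con)
  expect_equal(read_counts(gz), read_counts(tmp))
})

test_that("malformed input is rejected with the offending line", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A B", "2,0"), tmp)
  expect_error(read_counts(tmp), "line 2")
  writeLines(c("A B", "2,0 1"), tmp)
  expect_error(read_counts(tmp), "malformed")
  writeLines(c("A A", "2,0 1,1"), tmp)
  expect_error(read_counts(tmp), "duplicate")
  writeLines(c("A B", "2,x 1,1"), tmp)
  expect_error(read_counts(tmp), "line 2")
})

test_that("write_counts round-trips through both transports", {
  set.seed(1)
  g <- serial_divergence_graph(4, 0.01)
  panel <- simulate_panel(g, 50, 10, seed = 3)
  plain <- withr::local_tempfile(fileext = ".txt")
  gz <- withr::local_tempfile(fileext = ".gz")
  write_counts(panel, plain)
  write_counts(panel, gz)
  p1 <- read_counts(plain)
  p2 <- read_counts(gz)
  expect_equal(p1$countA, panel$countA)
  expect_equal(p1, p2)
})

test_that("allele frequencies and unbiased heterozygosity follow the count arithmetic", {
  panel <- allele_panel(c("A", "B", "C"),
                        countA = cbind(2L, 1L, 3L),
                        countB = cbind(0L, 1L, 1L))
  fr <- allele_frequencies(panel)
  expect_equal(unname(fr$freqs[, 1]), c(1.0, 0.5, 0.75))
  expect_equal(unname(fr$sizes[, 1]), c(2, 2, 4))
  # (1,1): h = 2 * 0.25 * 2/1 = 1.0
  expect_equal(unname(fr$het["B"]), 1.0)
  expect_equal(unname(fr$het["A"]), 0.0)
  empty <- allele_panel("A", matrix(integer(), 0, 1), matrix(integer(), 0, 1))
  expect_error(allele_frequencies(empty), "empty")
})

test_that("block covariance matches a scalar-loop oracle on a hand input", {
  set.seed(7)
  P <- 3; L <- 6
  p <- matrix(runif(P * L, 0.2, 0.8), P, L,
              dimnames = list(c("A", "B", "C"), NULL))
  n <- matrix(20, P, L, dimnames = dimnames(p))
  fr <- structure(list(freqs = p, sizes = n, het = rep(0.3, P),
                       populations = rownames(p)),
                  class = "freq_matrix")
  cov <- estimate_covariance(fr, block_size_k = 3, bias_correct = FALSE)
  W1 <- oracle_centered_cov(p[, 1:3])
  W2 <- oracle_centered_cov(p[, 4:6])
  expect_equal(cov$blocks[[1]], W1, tolerance = 1e-12)
  expect_equal(cov$W_hat, (W1 + W2) / 2, tolerance = 1e-12)
  # with correction: subtract centered mean sampling variances per block
  covc <- estimate_covariance(fr, block_size_k = 3)
  C <- diag(P) - matrix(1 / P, P, P)
  v <- p * (1 - p) / (n - 1)
  corr1 <- C %*% diag(rowMeans(v[, 1:3])) %*% t(C)
  expect_equal(unname(covc$blocks[[1]]), unname(W1 - corr1), tolerance = 1e-12)
})

test_that("block covariances are exactly centered before bias correction", {
  set.seed(8)
  g <- rand_tree(5)
  panel <- simulate_panel(g, 400, 15, seed = 9)
  cov <- estimate_covariance(allele_frequencies(panel), 100,
                             bias_correct = FALSE)
  for (B in cov$blocks) {
    expect_lt(max(abs(rowSums(B))), 1e-12)
  }
})

test_that("population permutation permutes the covariance consistently", {
  set.seed(10)
  g <- rand_tree(5)
  panel <- simulate_panel(g, 600, 15, seed = 11)
  fr <- allele_frequencies(panel)
  cov <- estimate_covariance(fr, 200)
  perm <- c(3, 1, 5, 2, 4)
  fr2 <- structure(list(freqs = fr$freqs[perm, ], sizes = fr$sizes[perm, ],
                        het = fr$het[perm], populations = fr$populations[perm]),
                   class = "freq_matrix")
  cov2 <- estimate_covariance(fr2, 200)
  expect_equal(cov2$W_hat, cov$W_hat[perm, perm], tolerance = 1e-12)
  expect_equal(cov2$se, cov$se[perm, perm], tolerance = 1e-12)
})

test_that("identical blocks give zero standard errors", {
  p <- matrix(runif(12, 0.3, 0.7), 3, 4,
              dimnames = list(c("A", "B", "C"), NULL))
  p <- cbind(p, p)  # second block is an exact copy
  fr <- structure(list(freqs = p, sizes = matrix(20, 3, 8),
                       het = rep(0.3, 3), populations = rownames(p)),
                  class = "freq_matrix")
  cov <- estimate_covariance(fr, 4, bias_correct = FALSE)
  expect_equal(cov$K, 2)
  expect_true(all(cov$se == 0))
})

test_that("no variation means a zero covariance estimate", {
  p <- matrix(rep(runif(10, 0.2, 0.8), each = 3), 3, 10,
              dimnames = list(c("A", "B", "C"), NULL))
  fr <- structure(list(freqs = p, sizes = matrix(1e9, 3, 10),
                       het = rep(0, 3), populations = rownames(p)),
                  class = "freq_matrix")
  cov <- estimate_covariance(fr, 5, het_override = c(A = 0, B = 0, C = 0))
  expect_lt(max(abs(cov$W_hat)), 1e-12)
  expect_lt(max(cov$se), 1e-12)
})

test_that("bias correction removes the sampling inflation of the diagonal", {
  # star of 3 populations with known drift, small samples: the corrected
  # diagonal should track the true centered drift covariance, while the
  # uncorrected one is inflated by roughly the centered p(1-p)/n term
  set.seed(12)
  nodes <- data.frame(id = 1:4, label = c("A", "B", "C", NA),
                      tip = c(TRUE, TRUE, TRUE, FALSE))
  edges <- data.frame(from = 4, to = 1:3, length = 0.02,
                      weight = NA_real_, type = "tree")
  g <- popgraph(nodes, edges)
  panel <- simulate_panel(g, 40000, 10, seed = 13, ancestral = c(0.2, 0.8))
  fr <- allele_frequencies(panel)
  corrected <- estimate_covariance(fr, 2000)
  raw <- estimate_covariance(fr, 2000, bias_correct = FALSE)
  Ebar <- 0.25 - 0.6^2 / 12   # E[p(1-p)] for Uniform(0.2, 0.8)
  truth <- predicted_covariance(g, corrected$populations)$W * Ebar
  expect_lt(max(abs(diag(corrected$W_hat) - diag(truth))),
            3 * max(diag(corrected$se)) + 1e-4)
  # inflation is about (1 - 1/P) * mean p-hat (1 - p-hat)/n on the diagonal
  infl <- diag(raw$W_hat) - diag(corrected$W_hat)
  expect_gt(min(infl), 0.5 * (1 - 1 / 3) * Ebar / 10)
})

test_that("estimated covariance converges to the centered model covariance", {
  # master generative/estimative consistency check
  set.seed(14)
  g <- example_admixed_graph(w = 0.3, scale = 0.25)
  panel <- simulate_panel(g, 100000, 30, seed = 15, ancestral = c(0.2, 0.8))
  expect_lt(attr(panel, "truncated"), 0.01)
  cov <- estimate_covariance(allele_frequencies(panel), 1000)
  Ebar <- 0.25 - 0.6^2 / 12
  truth <- predicted_covariance(g, cov$populations)$W * Ebar
  expect_true(all(abs(cov$W_hat - truth) <= 3 * cov$se + 1e-5))
})

test_that("single-chromosome populations require a heterozygosity override", {
  set.seed(16)
  g <- rand_tree(4)
  fr0 <- simulate_frequencies(g, 300, seed = 17)
  panel <- sample_counts(fr0, c(p1 = 1, p2 = 20, p3 = 20, p4 = 20))
  fr <- allele_frequencies(panel)
  expect_error(estimate_covariance(fr, 100), "het_override")
  cov <- estimate_covariance(fr, 100, het_override = c(p1 = 0.13))
  expect_true(is.finite(cov$W_hat["p1", "p1"]))
})

test_that("covariance matrix files round-trip", {
  set.seed(18)
  W <- matrix(rnorm(9), 3, 3, dimnames = list(c("A", "B", "C"),
                                              c("A", "B", "C")))
  tmp <- withr::local_tempfile(fileext = ".cov")
  write_cov_matrix(W, tmp)
  expect_equal(read_cov_matrix(tmp), W, tolerance = 1e-15)
})
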