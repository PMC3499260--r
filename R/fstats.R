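## shared jackknife machinery over blocks of k consecutive SNPs (the final
## partial block is kept, so blocks can differ in size)
block_jackknife_mean <- function(term, block_size_k) {
  L <- length(term)
  block <- ceiling(seq_len(L) / block_size_k)
  K <- max(block)
  if (K < 2) stop("need at least 2 blocks; lower block_size_k or add SNPs")
  est <- mean(term)
  tot <- sum(term)
  bs <- tapply(term, block, sum)
  bn <- tabulate(block)
  loo <- (tot - bs) / (L - bn)
  se <- sqrt((K - 1) / K * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, K = K)
}

fstat_freqs <- function(panel, pops) {
  miss <- setdiff(pops, panel$populations)
  if (length(miss) > 0) {
    stop("unknown population(s): ", paste(miss, collapse = ","),
         "; available: ", paste(panel$populations, collapse = ","))
  }
  if (anyDuplicated(pops)) stop("populations must be distinct")
  a <- panel$countA[, pops, drop = FALSE]
  n <- a + panel$countB[, pops, drop = FALSE]
  keep <- rowSums(n < 1) == 0   # drop SNPs missing in any involved population
  list(p = a[keep, , drop = FALSE] / n[keep, , drop = FALSE],
       n = n[keep, , drop = FALSE])
}

#' Three-population test of treeness
#'
#' Estimates \eqn{f_3(\mathrm{target}; A, B) = E[(p_T - p_A)(p_T - p_B)]}
#' with the sampling-bias correction \eqn{\hat p_T(1-\hat p_T)/(n_T-1)}
#' subtracted for the target population, and a delete-one-block jackknife
#' standard error over blocks of `block_size_k` consecutive SNPs. A
#' significantly negative value is evidence that the target is admixed
#' between populations related to A and B; the reported Z is one-sided in
#' that direction.
#'
#' SNPs with missing data in any of the three populations are dropped for
#' this statistic only, as are SNPs where the target has a single
#' chromosome (the bias correction needs \eqn{n_T \ge 2}).
#'
#' @param panel an `allele_panel`.
#' @param target,A,B population names.
#' @param block_size_k SNPs per jackknife block.
#' @param bias_correct subtract the target sampling-bias term (default
#'   TRUE; FALSE treats the sample frequencies as exact).
#' @return An `fstat_result`: list with `kind`, `populations`, `estimate`,
#'   `se`, `z`, `p`, `n_blocks`, `n_snps`.
#' @export
f3 <- function(panel, target, A, B, block_size_k = 500, bias_correct = TRUE) {
  fr <- fstat_freqs(panel, c(target, A, B))
  ok <- if (bias_correct) fr$n[, 1] >= 2 else rep(TRUE, nrow(fr$n))
  if (!any(ok)) {
    stop("target population has a single chromosome at every SNP; ",
         "the f3 bias correction is impossible")
  }
  p <- fr$p[ok, , drop = FALSE]
  nT <- fr$n[ok, 1]
  term <- (p[, 1] - p[, 2]) * (p[, 1] - p[, 3])
  if (bias_correct) term <- term - p[, 1] * (1 - p[, 1]) / (nT - 1)
  jk <- block_jackknife_mean(term, block_size_k)
  z <- jk$estimate / jk$se
  structure(list(kind = "f3",
                 populations = c(target = target, A = A, B = B),
                 estimate = jk$estimate, se = jk$se, z = z,
                 p = stats::pnorm(z),   # one-sided: admixture is negative
                 n_blocks = jk$K, n_snps = length(term)),
            class = "fstat_result")
}

#' Four-population test of treeness
#'
#' Estimates \eqn{f_4(A, B; C, D) = E[(p_A - p_B)(p_C - p_D)]} with a
#' delete-one-block jackknife standard error. Under the unrooted tree
#' pairing (A,B) against (C,D) the expectation is zero; the reported Z is
#' two-sided. SNPs missing in any of the four populations are dropped for
#' this statistic only.
#'
#' @param panel an `allele_panel`.
#' @param A,B,C,D population names.
#' @param block_size_k SNPs per jackknife block.
#' @return an `fstat_result` (see [f3()]).
#' @export
f4 <- function(panel, A, B, C, D, block_size_k = 500) {
  fr <- fstat_freqs(panel, c(A, B, C, D))
  p <- fr$p
  term <- (p[, 1] - p[, 2]) * (p[, 3] - p[, 4])
  jk <- block_jackknife_mean(term, block_size_k)
  z <- jk$estimate / jk$se
  structure(list(kind = "f4",
                 populations = c(A = A, B = B, C = C, D = D),
                 estimate = jk$estimate, se = jk$se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 n_blocks = jk$K, n_snps = length(term)),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  lab <- if (x$kind == "f3") {
    sprintf("f3(%s; %s, %s)", x$populations[1], x$populations[2],
            x$populations[3])
  } else {
    sprintf("f4(%s, %s; %s, %s)", x$populations[1], x$populations[2],
            x$populations[3], x$populations[4])
  }
  cat(sprintf("%s = %.6g (se %.3g), Z = %.3f, p = %.3g [%d blocks, %d SNPs]\n",
              lab, x$estimate, x$se, x$z, x$p, x$n_blocks, x$n_snps))
  invisible(x)
}
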