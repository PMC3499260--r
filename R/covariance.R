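#' Estimate the centered, bias-corrected sample covariance of allele
#' frequencies
#'
#' For each block of `block_size_k` consecutive SNPs, computes the centered
#' sample covariance
#' \deqn{\hat W^{(k)}_{ij} = \mathrm{mean}_l (\hat p_{il} - \bar p_l)
#'       (\hat p_{jl} - \bar p_l),}
#' where \eqn{\bar p_l} is the across-population mean at SNP \eqn{l}, and
#' subtracts the sampling-bias term \eqn{C \bar S C'}: finite samples act as
#' extra "drift", inflating the diagonal (with smaller effects on
#' off-diagonal terms, handled automatically by the centering matrix
#' \eqn{C}). \eqn{\bar S} is diagonal with entries
#' \eqn{\bar v_i = \mathrm{mean}_l\, \hat h_{il}/(2 n_{il})}, an unbiased
#' estimate of \eqn{p(1-p)/n}. The overall estimate is the mean over
#' blocks; per-entry standard errors are standard errors of that mean over
#' the K blocks, which keeps them honest under linkage disequilibrium when
#' blocks exceed the LD scale. Trailing SNPs not filling a block are
#' discarded.
#'
#' @param freqs a `freq_matrix` from [allele_frequencies()].
#' @param block_size_k SNPs per block (>= 2).
#' @param het_override optional named numeric vector of per-population
#'   heterozygosity values, replacing the sample estimate (needed for
#'   populations with a single sampled chromosome, e.g. ancient samples).
#' @param bias_correct subtract the sampling-bias term (default TRUE).
#' @return A `cov_estimate`: list with `W_hat`, `se` (P x P), `blocks`
#'   (list of K per-block matrices), `K`, `block_size`, `populations`.
#' @export
estimate_covariance <- function(freqs, block_size_k = 500,
                                het_override = NULL, bias_correct = TRUE) {
  p <- freqs$freqs
  n <- freqs$sizes
  P <- nrow(p)
  L <- ncol(p)
  if (block_size_k < 2) stop("block_size_k must be >= 2")
  if (L < block_size_k) stop("fewer SNPs than one block")
  K <- L %/% block_size_k
  if (K < 2) stop("fewer than 2 complete blocks: cannot compute standard errors")
  pops <- freqs$populations
  # per-SNP sampling variance estimate h/(2n) = p(1-p)/(n-1); SNPs with a
  # single chromosome fall back to the population-mean heterozygosity
  if (bias_correct) {
    hl <- 2 * p * (1 - p) * n / (n - 1)
    hl[n < 2] <- NA
    hbar <- rowMeans(hl, na.rm = TRUE)
    v <- hl / (2 * n)
    fill <- which(is.na(v), arr.ind = TRUE)
    if (nrow(fill) > 0) {
      v[fill] <- hbar[fill[, 1]] / (2 * n[fill])
    }
    if (!is.null(het_override)) {
      for (nm in names(het_override)) {
        i <- match(nm, pops)
        if (is.na(i)) stop("het override for unknown population: ", nm)
        v[i, ] <- het_override[[nm]] / (2 * n[i, ])
      }
    }
    if (any(!is.finite(rowMeans(v)))) {
      bad <- pops[!is.finite(rowMeans(v))]
      stop("population(s) with a single chromosome at every SNP: ",
           paste(bad, collapse = ","),
           "; supply het_override for these populations")
    }
  }
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- ((k - 1) * block_size_k + 1):(k * block_size_k)
    X <- p[, idx, drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    Wk <- tcrossprod(Xc) / length(idx)
    if (bias_correct) {
      vb <- rowMeans(v[, idx, drop = FALSE])
      Wk <- Wk - center_matrix(diag(vb, nrow = P))
    }
    dimnames(Wk) <- list(pops, pops)
    blocks[[k]] <- Wk
  }
  cov_from_blocks(blocks, pops, block_size_k)
}

cov_from_blocks <- function(blocks, pops, block_size) {
  K <- length(blocks)
  arr <- simplify2array(blocks)
  W_hat <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(K)
  dimnames(W_hat) <- dimnames(se) <- list(pops, pops)
  structure(list(W_hat = W_hat, se = se, blocks = blocks, K = K,
                 block_size = block_size, populations = pops),
            class = "cov_estimate")
}

#' @export
print.cov_estimate <- function(x, ...) {
  cat(sprintf("cov_estimate: %d populations, %d blocks of %d SNPs\n",
              length(x$populations), x$K, x$block_size))
  invisible(x)
}

#' Restrict a covariance estimate to a subset of populations
#'
#' Re-centers each block submatrix on the subset mean (double-centering the
#' submatrix of a centered matrix yields exactly the estimate that would
#' have been computed from the subset alone) and recomputes the mean and
#' standard errors.
#'
#' @param cov a `cov_estimate`.
#' @param pops population names to keep (order retained).
#' @return a `cov_estimate` over `pops`.
#' @export
subset_covariance <- function(cov, pops) {
  stopifnot(all(pops %in% cov$populations))
  blocks <- lapply(cov$blocks, function(B) center_matrix(B[pops, pops]))
  cov_from_blocks(blocks, pops, cov$block_size)
}

#' Leave-one-block-out covariance estimate
#'
#' @param cov a `cov_estimate`.
#' @param k block index to leave out.
#' @return a `cov_estimate` computed from the remaining K - 1 blocks.
#' @export
drop_block <- function(cov, k) {
  stopifnot(k >= 1, k <= cov$K, cov$K >= 3)
  cov_from_blocks(cov$blocks[-k], cov$populations, cov$block_size)
}

#' Write or read a labeled covariance-style matrix
#'
#' Tab-delimited, first row and first column the population names, entries
#' in full precision. Used for the "cov", "covse", "modelcov" and residual
#' files.
#'
#' @param M a labeled P x P matrix.
#' @param path file path.
#' @return `path` invisibly; `read_cov_matrix()` returns the matrix.
#' @export
write_cov_matrix <- function(M, path) {
  df <- data.frame(pop = rownames(M),
                   format(M, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cov_matrix
#' @export
read_cov_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}
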