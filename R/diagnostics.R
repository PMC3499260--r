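#' Residual covariance matrix
#'
#' The observed minus model covariance, \eqn{R = \hat W - W}. Positive
#' residuals mark population pairs whose covariance the model
#' underestimates (candidates for additional migration edges); negative
#' residuals are the necessary flip side. The scaled version divides by the
#' average standard error across all pairs, the scale used for residual
#' heat maps.
#'
#' @param fit an `admix_fit`.
#' @param cov a `cov_estimate` (defaults to the one stored in `fit`).
#' @return list with `residuals` and `scaled_residuals` (P x P matrices).
#' @export
residual_matrix <- function(fit, cov = fit$cov) {
  if (!identical(rownames(fit$model$W), cov$populations)) {
    stop("population order of fit and covariance estimate differ")
  }
  R <- cov$W_hat - fit$model$W
  list(residuals = R,
       scaled_residuals = R / mean(cov$se[ut_index(nrow(R))]))
}

#' Fraction of covariance variance explained by the model
#'
#' \deqn{f = 1 - \frac{\sum_{i \le j} (\hat W_{ij} - W_{ij})^2}
#'                    {\sum_{i \le j} (\hat W_{ij} - \bar W)^2},}
#' summing over unordered population pairs including the diagonal, with
#' \eqn{\bar W} the mean of the observed entries over the same domain. This
#' approximates the fraction of the variance in relatedness between
#' populations accounted for by the model.
#'
#' @param fit an `admix_fit`.
#' @param cov a `cov_estimate` (defaults to the one stored in `fit`).
#' @return scalar in \eqn{(-\infty, 1]}.
#' @export
variance_explained <- function(fit, cov = fit$cov) {
  if (!identical(rownames(fit$model$W), cov$populations)) {
    stop("population order of fit and covariance estimate differ")
  }
  variance_explained_matrix(cov$W_hat, fit$model$W)
}

variance_explained_matrix <- function(W_hat, W_model) {
  ut <- ut_index(nrow(W_hat))
  denom <- sum((W_hat[ut] - mean(W_hat[ut]))^2)
  if (denom == 0) stop("observed covariance is constant; variance explained undefined")
  1 - sum((W_hat[ut] - W_model[ut])^2) / denom
}

#' Residual heat map
#'
#' Minimal display of the scaled residual matrix (observed minus model
#' covariance in units of the average standard error).
#'
#' @param fit an `admix_fit`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the scaled residual matrix.
#' @export
plot_residuals <- function(fit, ...) {
  R <- fit$scaled_residuals
  P <- nrow(R)
  graphics::image(seq_len(P), seq_len(P), t(R[P:1, ]), axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(P), labels = colnames(R), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(P), labels = rev(rownames(R)), las = 1,
                 cex.axis = 0.7)
  invisible(R)
}
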