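#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimate of the between-study variance, used as the
#' starting value for the REML iteration.
#'
#' @param yi effect sizes.
#' @param vi sampling variances (positive).
#' @return non-negative tau-squared estimate.
#' @export
dl_tau2 <- function(yi, vi) {
  stopifnot(length(yi) == length(vi), length(yi) >= 2L, all(vi > 0))
  w <- 1 / vi
  mu <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - mu)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (q - (length(yi) - 1)) / denom)
}

#' REML estimate of the between-study variance
#'
#' Maximizes the restricted log-likelihood of the random-effects model
#' \deqn{\ell(\tau^2) = -\tfrac12\Big[\sum_i \log(v_i+\tau^2)
#'   + \log \sum_i (v_i+\tau^2)^{-1}
#'   + \sum_i \frac{(y_i-\hat\mu(\tau^2))^2}{v_i+\tau^2}\Big]}
#' with \eqn{\hat\mu(\tau^2)} the inverse-variance weighted mean, by Fisher
#' scoring: the estimate starts at the DerSimonian-Laird value, is clamped to
#' be non-negative after every step, and iterates until the change in
#' tau-squared falls below `tol`.
#'
#' @inheritParams dl_tau2
#' @param tol convergence tolerance on the change in tau-squared.
#' @param maxit maximum number of Fisher-scoring iterations.
#' @return non-negative tau-squared, with attributes `iterations` and
#'   `converged`. Non-convergence is an error whose condition carries the
#'   last iterate in field `tau2_last`.
#' @examples
#' reml_tau2(c(0, 1), c(0.1, 0.1))
#' @export
reml_tau2 <- function(yi, vi, tol = 1e-10, maxit = 100L) {
  k <- length(yi)
  if (k < 2L) stop("REML needs at least two effects", call. = FALSE)
  stopifnot(length(vi) == k, all(vi > 0), all(is.finite(yi)))
  tau2 <- dl_tau2(yi, vi)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    w <- 1 / (vi + tau2)
    sw <- sum(w)
    mu <- sum(w * yi) / sw
    # restricted score and expected information in tau^2
    score <- 0.5 * (sum(w^2 * (yi - mu)^2) - sw + sum(w^2) / sw)
    info <- 0.5 * (sum(w^2) - 2 * sum(w^3) / sw + (sum(w^2) / sw)^2)
    if (info <= 0) break
    new <- max(0, tau2 + score / info)
    if (abs(new - tau2) < tol) {
      tau2 <- new
      converged <- TRUE
      break
    }
    tau2 <- new
  }
  if (!converged) {
    stop(errorCondition(
      sprintf("REML did not converge within %d iterations (last tau2 = %.6g)",
              maxit, tau2),
      tau2_last = tau2, class = "mcidmeta_reml_nonconvergence"))
  }
  structure(tau2, iterations = it, converged = TRUE)
}

# restricted log-likelihood; also the test oracle's target function
restricted_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}
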