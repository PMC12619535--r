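# S3 methods for mcid_meta objects

#' @export
print.mcid_meta <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects meta-analysis of MCID-unit mean differences (%s)\n",
              x$method))
  cat(sprintf("k = %d studies\n\n", x$k))
  cat(sprintf("Pooled MD: %.*f MCID units, %d%% CI [%.*f, %.*f]%s\n",
              digits, x$mu, round(100 * x$level), digits, x$ci_low,
              digits, x$ci_high,
              if (x$knapp_hartung) " (Knapp-Hartung)" else ""))
  cat(sprintf("tau^2 = %.*f, ", digits, x$tau2))
  if (!is.na(x$q)) {
    cat(sprintf("Q = %.*f (df = %d), I^2 = %.1f%% (%s heterogeneity)\n",
                digits, x$q, x$df, x$i2, x$band))
  } else {
    cat("heterogeneity not estimable (k < 2)\n")
  }
  invisible(x)
}

#' @export
summary.mcid_meta <- function(object, ...) {
  rows <- forest_data(object)
  out <- list(fit = object, table = rows)
  class(out) <- "summary.mcid_meta"
  out
}

#' @export
print.summary.mcid_meta <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits, ...)
  cat("\nPer-study effects (MCID units):\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mcid_meta <- function(object, ...) {
  c(mu = object$mu)
}

#' @export
confint.mcid_meta <- function(object, parm = "mu", level = NULL, ...) {
  if (is.null(level) || isTRUE(all.equal(level, object$level))) {
    ci <- c(object$ci_low, object$ci_high)
    lv <- object$level
  } else {
    p <- pool_random_effects(
      data.frame(md = object$yi, variance = object$vi),
      tau2 = object$tau2, level = level,
      knapp_hartung = object$knapp_hartung)
    ci <- c(p$ci_low, p$ci_high)
    lv <- level
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("mu", sprintf("%.1f %%",
                                              c((1 - lv) / 2, 1 - (1 - lv) / 2) * 100)))
  out
}

#' @export
weights.mcid_meta <- function(object, normalized = TRUE, ...) {
  w <- if (normalized) object$weights else 1 / (object$vi + object$tau2)
  stats::setNames(as.numeric(w), object$slab)
}

#' @export
residuals.mcid_meta <- function(object, ...) {
  stats::setNames(object$yi - object$mu, object$slab)
}

#' Predicted pooled effect and prediction interval
#'
#' Returns the pooled estimate with its confidence interval and, for
#' random-effects fits with k >= 2, the prediction interval for the true
#' effect in a new study, which widens the CI by the between-study variance:
#' `mu +/- crit * sqrt(se_mu^2 + tau2)`.
#'
#' @param object an `mcid_meta` fit.
#' @param ... unused.
#' @return one-row data frame with `pred`, `se`, `ci_low`, `ci_high`,
#'   `pi_low`, `pi_high`.
#' @export
predict.mcid_meta <- function(object, ...) {
  pi_se <- sqrt(object$se_mu^2 + object$tau2)
  data.frame(pred = object$mu, se = object$se_mu,
             ci_low = object$ci_low, ci_high = object$ci_high,
             pi_low = object$mu - object$crit * pi_se,
             pi_high = object$mu + object$crit * pi_se)
}
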