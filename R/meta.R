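#' Random-effects meta-analysis of MCID-unit effects
#'
#' The package's central model fit: an inverse-variance random-effects
#' meta-analysis of per-study mean differences expressed in MCID units. The
#' between-study variance is estimated by restricted maximum likelihood
#' ([reml_tau2()]) unless another method is requested; studies are weighted
#' by `1/(v_i + tau2)`; the 95% confidence interval is Wald-type by default,
#' with the Knapp-Hartung small-sample adjustment available. Heterogeneity is
#' summarized by Cochran's Q (computed with fixed-effect weights) and
#' Higgins' I², banded as low (< 25%), moderate (25%–75%) or high (> 75%);
#' both boundaries fall in the moderate band.
#'
#' @param yi effect sizes (mean differences in MCID units), or a data frame
#'   of effects such as [unified_effects()] output (columns `md`, `variance`,
#'   and optionally `study_id`), in which case `vi`/`slab` are taken from it.
#' @param vi sampling variances (positive), required when `yi` is numeric.
#' @param slab optional study labels.
#' @param method `"REML"` (default), `"DL"`, or `"FE"` (fixed-effect,
#'   tau2 = 0).
#' @param level confidence level, default 0.95.
#' @param knapp_hartung logical; use the Knapp-Hartung variance adjustment
#'   and a t reference distribution for the pooled CI.
#' @param control list with `tol` and `maxit` for the REML iteration.
#' @return object of class `mcid_meta`: pooled estimate `mu`, its standard
#'   error `se_mu`, confidence bounds `ci_low`/`ci_high`, `tau2`, `q`, `df`,
#'   `i2`, `band`, normalized `weights`, plus the inputs. Methods:
#'   [print()], [summary()], [coef()], [confint()], [weights()],
#'   [residuals()], [predict()] (prediction interval), [plot()] (forest).
#' @examples
#' fit <- mcid_meta(c(0.1, 0.56, 0.3), c(0.146, 0.033, 0.041),
#'                  slab = paste("Study", 1:3))
#' fit
#' coef(fit)
#' @export
mcid_meta <- function(yi, vi = NULL, slab = NULL,
                      method = c("REML", "DL", "FE"), level = 0.95,
                      knapp_hartung = FALSE, control = list()) {
  method <- match.arg(method)
  if (is.data.frame(yi)) {
    require_columns(yi, c("md", "variance"), "effects table")
    if (is.null(slab) && "study_id" %in% names(yi)) slab <- yi$study_id
    vi <- yi$variance
    yi <- yi$md
  }
  k <- length(yi)
  stopifnot(k >= 1L, length(vi) == k, all(vi > 0), all(is.finite(yi)),
            level > 0, level < 1)
  if (is.null(slab)) slab <- paste("Study", seq_len(k))
  ctl <- utils::modifyList(list(tol = 1e-10, maxit = 100L), control)

  tau2 <- switch(method,
    FE = 0,
    DL = if (k >= 2L) dl_tau2(yi, vi) else 0,
    REML = if (k >= 2L) as.numeric(reml_tau2(yi, vi, tol = ctl$tol,
                                             maxit = ctl$maxit)) else 0)

  pooled <- pool_random_effects(
    data.frame(study_id = slab, md = yi, variance = vi, se = sqrt(vi),
               stringsAsFactors = FALSE),
    tau2 = tau2, level = level, knapp_hartung = knapp_hartung)
  het <- if (k >= 2L) heterogeneity_stats(
    data.frame(md = yi, variance = vi)) else
    list(q = NA_real_, df = NA_integer_, i2 = NA_real_, band = NA_character_)

  out <- list(yi = yi, vi = vi, slab = as.character(slab), k = k,
              method = method, level = level, knapp_hartung = knapp_hartung,
              tau2 = tau2, mu = pooled$mu, se_mu = pooled$se_mu,
              ci_low = pooled$ci_low, ci_high = pooled$ci_high,
              crit = pooled$crit, zval = pooled$mu / pooled$se_mu,
              pval = pooled$pval, q = het$q, df = het$df, i2 = het$i2,
              band = het$band, weights = pooled$weights)
  class(out) <- "mcid_meta"
  out
}

#' Inverse-variance random-effects pooling at a given tau-squared
#'
#' Pools effects with weights `1/(v_i + tau2)`. With `tau2 = 0` this is
#' exactly the fixed-effect inverse-variance pool.
#'
#' @param effects data frame with columns `md` and `variance` (optionally
#'   `study_id`).
#' @param tau2 non-negative between-study variance.
#' @param level confidence level.
#' @param knapp_hartung logical, see [mcid_meta()].
#' @return list with `mu`, `se_mu`, `ci_low`, `ci_high`, `pval`, `crit` (the
#'   critical value used) and normalized `weights` (summing to one).
#' @export
pool_random_effects <- function(effects, tau2, level = 0.95,
                                knapp_hartung = FALSE) {
  require_columns(effects, c("md", "variance"), "effects table")
  stopifnot(tau2 >= 0, nrow(effects) >= 1L)
  yi <- effects$md
  vi <- effects$variance
  k <- length(yi)
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  if (knapp_hartung && k >= 2L) {
    s2 <- sum(w * (yi - mu)^2) / ((k - 1) * sum(w))
    se_mu <- sqrt(s2)
    crit <- stats::qt(1 - (1 - level) / 2, df = k - 1)
    pval <- 2 * stats::pt(abs(mu / se_mu), df = k - 1, lower.tail = FALSE)
  } else {
    crit <- stats::qnorm(1 - (1 - level) / 2)
    pval <- 2 * stats::pnorm(abs(mu / se_mu), lower.tail = FALSE)
  }
  wn <- w / sum(w)
  if (!is.null(effects$study_id)) names(wn) <- effects$study_id
  list(mu = mu, se_mu = se_mu, ci_low = mu - crit * se_mu,
       ci_high = mu + crit * se_mu, pval = pval, crit = crit, weights = wn)
}

#' Cochran's Q and Higgins' I-squared
#'
#' Q is computed with fixed-effect weights `1/v_i` around the fixed-effect
#' pooled mean; `I2 = max(0, (Q - df) / Q) * 100`, clamped at zero when Q
#' falls below its degrees of freedom. The band follows the conventional
#' cut-offs: low below 25%, high above 75%, moderate in between (both
#' boundaries inclusive).
#'
#' @param effects data frame with columns `md` and `variance`.
#' @return list with `q`, `df`, `i2` (percent) and `band`.
#' @examples
#' heterogeneity_stats(data.frame(md = c(0, 2), variance = c(0.1, 0.1)))
#' @export
heterogeneity_stats <- function(effects) {
  require_columns(effects, c("md", "variance"), "effects table")
  yi <- effects$md
  vi <- effects$variance
  k <- length(yi)
  if (k < 2L) stop("heterogeneity statistics need at least two effects",
                   call. = FALSE)
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - mu_fe)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  band <- if (i2 < 25) "low" else if (i2 > 75) "high" else "moderate"
  list(q = q, df = df, i2 = i2, band = band)
}
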