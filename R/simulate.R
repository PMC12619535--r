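#' Simulate multi-study two-arm PROM datasets with known ground truth
#'
#' Generates study-level summary data emulating a hip arthroscopy comparison
#' of two techniques across `k` independent two-arm studies, for validating
#' the whole normalization/prioritization/pooling pipeline. Each study i has
#' a true effect `theta_i = delta + tau * z_i` (z_i standard normal) on the
#' MCID-unit scale; it reports between `proms_per_study[1]` and
#' `proms_per_study[2]` instruments drawn from `prom_pool`, and for every
#' reported instrument the two arms' true raw-scale means differ by
#' `theta_i * MCID`. Observed summaries are drawn from their sampling
#' distributions (mean from a normal with variance `sd^2/n`, SD from a
#' scaled chi distribution), so arms are summarized analytically rather than
#' via patient-level scores — which is all the pipeline consumes. With
#' `missing_sd_prob > 0` an arm's SD is occasionally withheld and a
#' `mean +/- 2 SD` range reported instead, exercising the range rule.
#'
#' True raw means falling outside an instrument's scale are truncated to the
#' boundary and flagged; a configuration whose truncation rate exceeds 1% of
#' arms fails outright, since silent truncation would bias recovery
#' experiments. One global seed drives a separate deterministic stream per
#' study, so enlarging `k` leaves earlier studies' records unchanged.
#'
#' The defaults mirror the seven-study two-arm demonstration design:
#' `k = 7` studies, per-arm sizes between 20 and 180, raw-scale SDs between
#' 9 and 19 points, one to three instruments per study drawn with
#' probability proportional to the reporting-frequency survey, and a true
#' pooled effect of half an MCID with between-study SD 0.2.
#'
#' @param k number of studies (>= 1).
#' @param delta true pooled effect, arm 1 minus arm 2, in MCID units.
#' @param tau between-study SD of true effects, in MCID units (>= 0).
#' @param n_range length-2 integer bounds for per-arm sample sizes.
#' @param prom_pool named numeric vector of instrument sampling weights;
#'   default: the six MCID-bearing instruments of the shipped registry,
#'   weighted by their mention counts in the default ranking.
#' @param proms_per_study length-2 bounds on instruments per study.
#' @param sd_points_range length-2 bounds for true raw-scale SDs, points.
#' @param missing_sd_prob probability an arm-instrument SD is withheld and
#'   replaced by a range.
#' @param mean_band where arm-2 true means sit inside the scale, as fractions
#'   of scale width; default `c(0.55, 0.85)`.
#' @param seed integer seed controlling all randomness.
#' @param registry a `prom_registry`; every pool instrument must carry an
#'   MCID.
#' @param ranking a `prom_ranking` used for the answer key.
#' @param max_truncated maximum tolerated fraction of truncated arms.
#' @return list with `measurements` (a data frame consumable by
#'   [normalize_measurements()]) and `truth`: `delta`, `tau`, per-study
#'   `theta`, the `retained` answer key (instrument prioritization must
#'   pick per study), and `truncated` flags.
#' @examples
#' sim <- simulate_mcid_studies(k = 3, seed = 42)
#' head(sim$measurements)
#' sim$truth$theta
#' @export
simulate_mcid_studies <- function(k = 7, delta = 0.5, tau = 0.2,
                                  n_range = c(20L, 180L),
                                  prom_pool = NULL,
                                  proms_per_study = c(1L, 3L),
                                  sd_points_range = c(9, 19),
                                  missing_sd_prob = 0,
                                  mean_band = c(0.55, 0.85),
                                  seed = 1L,
                                  registry = mcid_registry(),
                                  ranking = default_prom_ranking(),
                                  max_truncated = 0.01) {
  stopifnot(k >= 1L, tau >= 0, n_range[1] >= 2L, n_range[1] <= n_range[2],
            proms_per_study[1] >= 1L,
            proms_per_study[1] <= proms_per_study[2],
            sd_points_range[1] > 0, sd_points_range[1] <= sd_points_range[2],
            missing_sd_prob >= 0, missing_sd_prob <= 1,
            mean_band[1] < mean_band[2], mean_band[1] >= 0, mean_band[2] <= 1)
  if (is.null(prom_pool)) {
    usable <- registry$name[registry$normalizable]
    cnt <- ranking$count[match(canon_prom(usable), canon_prom(ranking$prom))]
    cnt[is.na(cnt)] <- 1
    prom_pool <- stats::setNames(cnt / sum(cnt), usable)
  }
  pool_idx <- match_prom(registry, names(prom_pool))
  if (any(is.na(pool_idx)) || !all(registry$normalizable[pool_idx])) {
    stop("every instrument in prom_pool must be in the registry with an MCID",
         call. = FALSE)
  }
  if (proms_per_study[2] > length(prom_pool)) {
    stop("proms_per_study exceeds the size of prom_pool", call. = FALSE)
  }
  # feasibility: the systematic arm separation must fit inside every scale
  width <- registry$scale_max[pool_idx] - registry$scale_min[pool_idx]
  shift <- max(abs(delta + c(-3, 3) * tau))  # typical extremes of theta_i
  if (any(shift * registry$mcid[pool_idx] > width)) {
    stop("configuration infeasible: arm means cannot fit the instrument scales",
         call. = FALSE)
  }

  rows <- list()
  theta <- numeric(k)
  retained <- character(k)
  truncated <- logical(k)
  n_arms <- 0L
  n_trunc_arms <- 0L
  for (i in seq_len(k)) {
    # named per-study stream: stable as k changes
    set.seed((seed + i * 9973L) %% .Machine$integer.max)
    theta[i] <- delta + tau * stats::rnorm(1)
    n1 <- sample(seq(n_range[1], n_range[2]), 1L)
    n2 <- sample(seq(n_range[1], n_range[2]), 1L)
    m <- sample(seq(proms_per_study[1], proms_per_study[2]), 1L)
    proms <- sample(names(prom_pool), m, prob = prom_pool)
    rk <- prom_rank(ranking, proms, registry)
    retained[i] <- proms[which.min(rk)]
    sid <- sprintf("Sim study %d", i)
    for (p in proms) {
      def <- prom_lookup(registry, p)
      w <- def$scale_max - def$scale_min
      mu2 <- def$scale_min + stats::runif(1, mean_band[1], mean_band[2]) * w
      sgn <- if (def$orientation == "higher_worse") -1 else 1
      mu1 <- mu2 + sgn * theta[i] * def$mcid
      for (arm in 1:2) {
        mu_true <- c(mu1, mu2)[arm]
        if (mu_true < def$scale_min || mu_true > def$scale_max) {
          mu_true <- min(max(mu_true, def$scale_min), def$scale_max)
          truncated[i] <- TRUE
          n_trunc_arms <- n_trunc_arms + 1L
        }
        n_arm <- c(n1, n2)[arm]
        sd_true <- stats::runif(1, sd_points_range[1], sd_points_range[2])
        mean_obs <- stats::rnorm(1, mu_true, sd_true / sqrt(n_arm))
        sd_obs <- sd_true * sqrt(stats::rchisq(1, n_arm - 1) / (n_arm - 1))
        drop_sd <- stats::runif(1) < missing_sd_prob
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = sid, arm_id = as.character(arm), prom = p,
          timepoint = "post", n = n_arm, mean = mean_obs,
          sd = if (drop_sd) NA_real_ else sd_obs,
          range_min = if (drop_sd) mean_obs - 2 * sd_obs else NA_real_,
          range_max = if (drop_sd) mean_obs + 2 * sd_obs else NA_real_,
          stringsAsFactors = FALSE)
        n_arms <- n_arms + 1L
      }
    }
  }
  if (n_trunc_arms / n_arms > max_truncated) {
    stop(sprintf(
      "simulation config truncates %.1f%% of arms (> %.1f%% allowed); widen the scales or shrink the effect",
      100 * n_trunc_arms / n_arms, 100 * max_truncated), call. = FALSE)
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  list(measurements = measurements,
       truth = list(delta = delta, tau = tau, theta = theta,
                    retained = stats::setNames(retained,
                                               sprintf("Sim study %d", seq_len(k))),
                    truncated = truncated, seed = seed))
}

#' Seven-study two-arm demonstration dataset
#'
#' The packaged simulated demonstration dataset: seven two-arm studies
#' comparing two hip arthroscopy techniques, reporting one to three
#' instruments each (postoperative summaries only), in the measurement-record
#' format consumed by [normalize_measurements()]. This is synthetic
#' illustration data, not clinical data.
#'
#' @return data frame with columns `study_id`, `arm_id`, `prom`, `timepoint`,
#'   `n`, `mean`, `sd`, `range_min`, `range_max` (7 studies, 14 arms, 22
#'   records).
#' @export
demo_hip_studies <- function() {
  df <- utils::read.csv(mcidmeta_extdata("demo_hip_studies.csv"),
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  df$arm_id <- as.character(df$arm_id)
  df
}
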