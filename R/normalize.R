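#' Estimate a standard deviation from a reported range
#'
#' When a study reports only the observed range of a score, the SD is
#' approximated by the range rule `(max - min) / 4`, the conventional
#' estimate for roughly normal outcomes at moderate sample sizes.
#'
#' @param range_min,range_max observed minimum and maximum, in scale points.
#' @return estimated SD in scale points.
#' @examples
#' sd_from_range(0, 4)  # 1
#' @export
sd_from_range <- function(range_min, range_max) {
  stopifnot(is.numeric(range_min), is.numeric(range_max))
  if (any(range_min > range_max)) {
    stop("range_min must not exceed range_max", call. = FALSE)
  }
  (range_max - range_min) / 4
}

#' Impute a missing standard deviation from donor records
#'
#' When neither an SD nor a range is available, the SD is borrowed from other
#' arms reporting the same instrument at the same timepoint. The default rule
#' takes the largest eligible donor SD — a conservative choice that inflates
#' rather than shrinks the imputed uncertainty — with the mean of donors as a
#' configurable alternative.
#'
#' @param target a list or one-row data frame with at least `prom` and
#'   `timepoint`.
#' @param donors data frame of measurement records (columns `prom`,
#'   `timepoint`, `sd`) from which to borrow.
#' @param rule `"max"` (default) or `"mean"`.
#' @return imputed SD in scale points.
#' @export
impute_missing_sd <- function(target, donors, rule = c("max", "mean")) {
  rule <- match.arg(rule)
  require_columns(donors, c("prom", "timepoint", "sd"), "donor records")
  eligible <- donors[canon_prom(donors$prom) == canon_prom(target$prom) &
                     donors$timepoint == target$timepoint &
                     !is.na(donors$sd), , drop = FALSE]
  if (nrow(eligible) == 0L) {
    stop(sprintf("cannot impute SD for %s at timepoint '%s': no donor reports an SD",
                 target$prom, target$timepoint), call. = FALSE)
  }
  switch(rule, max = max(eligible$sd), mean = mean(eligible$sd))
}

#' Convert a mean score to MCID units
#'
#' Divides an observed mean by the instrument's MCID, so that the result
#' counts how many minimal clinically important differences the score
#' represents. Orientation does not enter level normalization (it matters for
#' change scores, see [change_mcid()]).
#'
#' @param mean observed mean, in scale points.
#' @param prom a `prom_definition` from [prom_lookup()].
#' @return mean in MCID units.
#' @examples
#' reg <- mcid_registry()
#' normalize_mean(84.7, prom_lookup(reg, "mHHS"))
#' @export
normalize_mean <- function(mean, prom) {
  check_normalizable(prom)
  mean / prom$mcid
}

#' Convert a standard deviation to MCID units
#'
#' @param sd observed SD, in scale points (non-negative).
#' @inheritParams normalize_mean
#' @return SD in MCID units.
#' @export
normalize_sd <- function(sd, prom) {
  check_normalizable(prom)
  stopifnot(all(sd >= 0))
  sd / prom$mcid
}

check_normalizable <- function(prom) {
  stopifnot(inherits(prom, "prom_definition"))
  if (!isTRUE(prom$normalizable)) {
    stop(sprintf("'%s' has no adopted MCID and cannot be normalized",
                 prom$name), call. = FALSE)
  }
  invisible(prom)
}

#' Pre/post change in MCID units
#'
#' Computes the change score divided by the MCID, with the sign convention
#' that positive always means improvement: for inversely scaled instruments
#' (higher = worse, e.g. WOMAC) the difference is flipped.
#'
#' @param pre_mean,post_mean means before and after treatment, scale points.
#' @inheritParams normalize_mean
#' @return improvement in MCID units.
#' @export
change_mcid <- function(pre_mean, post_mean, prom) {
  check_normalizable(prom)
  raw <- if (prom$orientation == "higher_worse") pre_mean - post_mean
         else post_mean - pre_mean
  raw / prom$mcid
}

#' Standard deviation of a paired change score
#'
#' Change scores are paired data, so their SD depends on the correlation `r`
#' between pre- and post-treatment measurements:
#' `sqrt(sd_pre^2 + sd_post^2 - 2 * r * sd_pre * sd_post)`. The result is in
#' scale points; divide by the MCID (via [normalize_sd()]) for MCID units.
#' When `r` is unreported, 0.5 is the conventional midpoint; a sensitivity
#' sweep over, say, `r = c(0.2, 0.5, 0.8)` is recommended (see
#' [change_outcomes()]).
#'
#' @param sd_pre,sd_post SDs of the pre and post measurements (non-negative).
#' @param r pre/post correlation in `[-1, 1]`.
#' @return SD of the change score, in scale points.
#' @examples
#' sd_change(3, 4, 0)    # 5
#' sd_change(12, 10, 0.5)
#' @export
sd_change <- function(sd_pre, sd_post, r) {
  stopifnot(all(sd_pre >= 0), all(sd_post >= 0))
  if (any(r < -1 | r > 1)) stop("r must lie in [-1, 1]", call. = FALSE)
  # pmax guards the tiny negative values floating point can give at r = 1
  sqrt(pmax(0, sd_pre^2 + sd_post^2 - 2 * r * sd_pre * sd_post))
}

#' Normalize a table of measurement records to MCID units
#'
#' The table-level workhorse. For every record it resolves an SD (reported
#' value, else the range rule of [sd_from_range()], else conservative donor
#' imputation via [impute_missing_sd()]), then converts mean and SD to MCID
#' units. Records whose instrument carries no MCID cannot be normalized and
#' are excluded with an audit entry; records whose SD cannot be resolved are
#' likewise excluded with a warning. Means outside the instrument's scale
#' bounds raise a warning (likely source typo) but are kept.
#'
#' @param measurements data frame with columns `study_id`, `arm_id`, `prom`,
#'   `timepoint`, `n`, `mean`, and optionally `sd`, `range_min`, `range_max`
#'   (empty/NA = missing).
#' @param registry a `prom_registry`.
#' @param impute_rule donor-borrowing rule passed to [impute_missing_sd()].
#' @return data frame with columns `study_id`, `arm_id`, `prom` (canonical
#'   name), `timepoint`, `n`, `mean_mcid`, `sd_mcid`, `sd_provenance`
#'   (`"reported"`, `"from_range"` or `"imputed"`); attribute `"audit"` holds
#'   every exclusion, imputation and out-of-scale flag.
#' @examples
#' norm <- normalize_measurements(demo_hip_studies(), mcid_registry())
#' head(norm)
#' @export
normalize_measurements <- function(measurements, registry,
                                   impute_rule = c("max", "mean")) {
  impute_rule <- match.arg(impute_rule)
  require_columns(measurements, c("study_id", "arm_id", "prom", "timepoint",
                                  "n", "mean"), "measurements table")
  m <- measurements
  for (col in c("sd", "range_min", "range_max")) {
    if (!col %in% names(m)) m[[col]] <- NA_real_
    m[[col]] <- suppressWarnings(as.numeric(m[[col]]))
  }
  m$n <- as.integer(m$n)
  m$mean <- as.numeric(m$mean)
  if (any(is.na(m$n) | m$n < 1)) {
    stop("measurements: n must be a positive integer in every row", call. = FALSE)
  }
  if (any(!is.na(m$sd) & m$sd < 0)) {
    stop("measurements: sd must be non-negative", call. = FALSE)
  }

  audit <- list()
  idx <- match_prom(registry, m$prom)
  if (any(is.na(idx))) {
    bad <- which(is.na(idx))
    stop(sprintf("unknown PROM '%s' in measurements row %d; known instruments: %s",
                 m$prom[bad[1]], bad[1],
                 paste(registry$name, collapse = ", ")), call. = FALSE)
  }
  m$prom <- registry$name[idx]

  # rows whose instrument has no MCID cannot enter the MCID-unit pipeline
  no_mcid <- !registry$normalizable[idx]
  if (any(no_mcid)) {
    for (i in which(no_mcid)) {
      audit[[length(audit) + 1L]] <- audit_record(
        "normalize", "excluded_no_mcid", m$study_id[i], m$arm_id[i], m$prom[i],
        "instrument has no adopted MCID")
    }
    idx <- idx[!no_mcid]
    m <- m[!no_mcid, , drop = FALSE]
  }

  keep <- rep(TRUE, nrow(m))
  sd_points <- m$sd
  provenance <- rep("reported", nrow(m))
  # first pass: the range rule
  for (i in seq_len(nrow(m))) {
    if (!is.na(sd_points[i])) next
    if (!is.na(m$range_min[i]) && !is.na(m$range_max[i])) {
      sd_points[i] <- sd_from_range(m$range_min[i], m$range_max[i])
      provenance[i] <- "from_range"
      audit[[length(audit) + 1L]] <- audit_record(
        "normalize", "sd_from_range", m$study_id[i], m$arm_id[i], m$prom[i],
        sprintf("SD %.4g from range [%g, %g]", sd_points[i],
                m$range_min[i], m$range_max[i]))
    }
  }
  # second pass: donor imputation; reported and range-derived SDs are donors
  for (i in seq_len(nrow(m))) {
    if (!is.na(sd_points[i])) next
    donors <- data.frame(prom = m$prom, timepoint = m$timepoint,
                         sd = sd_points, stringsAsFactors = FALSE)[-i, ]
    imp <- tryCatch(impute_missing_sd(m[i, ], donors, rule = impute_rule),
                    error = function(e) NULL)
    if (is.null(imp)) {
      keep[i] <- FALSE
      warning(sprintf("dropping %s / arm %s / %s: SD missing and no donor available",
                      m$study_id[i], m$arm_id[i], m$prom[i]), call. = FALSE)
      audit[[length(audit) + 1L]] <- audit_record(
        "normalize", "excluded_no_sd", m$study_id[i], m$arm_id[i], m$prom[i],
        "SD missing, no range, no eligible donor")
    } else {
      sd_points[i] <- imp
      provenance[i] <- "imputed"
      audit[[length(audit) + 1L]] <- audit_record(
        "normalize", "sd_imputed", m$study_id[i], m$arm_id[i], m$prom[i],
        sprintf("SD %.4g imputed (%s of donors)", imp, impute_rule))
    }
  }

  out_of_scale <- which(m$mean < registry$scale_min[idx] |
                        m$mean > registry$scale_max[idx])
  for (i in out_of_scale) {
    warning(sprintf("%s / arm %s / %s: mean %g outside scale [%g, %g]",
                    m$study_id[i], m$arm_id[i], m$prom[i], m$mean[i],
                    registry$scale_min[idx[i]], registry$scale_max[idx[i]]),
            call. = FALSE)
    audit[[length(audit) + 1L]] <- audit_record(
      "normalize", "out_of_scale", m$study_id[i], m$arm_id[i], m$prom[i],
      sprintf("mean %g outside [%g, %g]", m$mean[i],
              registry$scale_min[idx[i]], registry$scale_max[idx[i]]))
  }

  mcid <- registry$mcid[idx]
  out <- data.frame(study_id = m$study_id, arm_id = m$arm_id, prom = m$prom,
                    timepoint = m$timepoint, n = m$n,
                    mean_mcid = m$mean / mcid, sd_mcid = sd_points / mcid,
                    sd_provenance = provenance, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- do.call(rbind, c(list(empty_audit()), audit))
  out
}

#' Pre/post change outcomes in MCID units
#'
#' Pairs each arm's pre- and post-treatment records for the same instrument
#' and produces correlation-adjusted change scores in MCID units:
#' improvement via [change_mcid()] and its SD via [sd_change()] divided by
#' the MCID. Supplying several `r` values yields one block per value — the
#' recommended sensitivity sweep when the pre/post correlation is unreported.
#'
#' @inheritParams normalize_measurements
#' @param r pre/post correlation(s) in `[-1, 1]`; default 0.5.
#' @return data frame with columns `study_id`, `arm_id`, `prom`, `n`,
#'   `delta_mcid`, `sd_delta_mcid`, `r_used`.
#' @export
change_outcomes <- function(measurements, registry, r = 0.5,
                            impute_rule = c("max", "mean")) {
  impute_rule <- match.arg(impute_rule)
  if (any(r < -1 | r > 1)) stop("r must lie in [-1, 1]", call. = FALSE)
  norm <- normalize_measurements(measurements, registry,
                                 impute_rule = impute_rule)
  pre <- norm[norm$timepoint == "pre", , drop = FALSE]
  post <- norm[norm$timepoint == "post", , drop = FALSE]
  key <- function(d) paste(d$study_id, d$arm_id, d$prom, sep = "\r")
  idx <- match(key(post), key(pre))
  paired <- which(!is.na(idx))
  if (length(paired) == 0L) {
    stop("no (study, arm, prom) pair has both pre and post records", call. = FALSE)
  }
  post <- post[paired, , drop = FALSE]
  pre <- pre[idx[paired], , drop = FALSE]
  # orientation-aware sign: mean_mcid values are already on the MCID scale
  reg_idx <- match_prom(registry, post$prom)
  flip <- registry$orientation[reg_idx] == "higher_worse"
  delta <- ifelse(flip, pre$mean_mcid - post$mean_mcid,
                  post$mean_mcid - pre$mean_mcid)
  out <- do.call(rbind, lapply(r, function(ri) {
    data.frame(study_id = post$study_id, arm_id = post$arm_id,
               prom = post$prom, n = post$n, delta_mcid = delta,
               sd_delta_mcid = sd_change(pre$sd_mcid, post$sd_mcid, ri),
               r_used = ri, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
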