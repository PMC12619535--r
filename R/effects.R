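#' Mean-difference effect size from two arms
#'
#' Builds the per-study effect: the difference of the two arms' means in MCID
#' units, with sampling variance from the independent two-group summary
#' formula `sd1^2/n1 + sd2^2/n2`.
#'
#' @param arm1,arm2 lists or one-row data frames with fields `n`, `mean_mcid`,
#'   `sd_mcid` (unified outcomes of one study).
#' @return list of class `effect_size` with fields `study_id`, `md`
#'   (arm1 − arm2), `variance`, `se`.
#' @export
md_effect <- function(arm1, arm2) {
  if (!is.null(arm1$study_id) && !is.null(arm2$study_id) &&
      !identical(as.character(arm1$study_id), as.character(arm2$study_id))) {
    stop("md_effect: arms belong to different studies", call. = FALSE)
  }
  stopifnot(arm1$n >= 2, arm2$n >= 2)
  if (arm1$sd_mcid <= 0 && arm2$sd_mcid <= 0) {
    stop("degenerate effect: both arms have zero SD", call. = FALSE)
  }
  v <- arm1$sd_mcid^2 / arm1$n + arm2$sd_mcid^2 / arm2$n
  out <- list(study_id = if (is.null(arm1$study_id)) NA_character_
                         else as.character(arm1$study_id),
              md = arm1$mean_mcid - arm2$mean_mcid,
              variance = v, se = sqrt(v))
  class(out) <- "effect_size"
  out
}

#' Per-study effect sizes from unified outcomes
#'
#' Pairs the two arms of each study and computes mean-difference effects via
#' [md_effect()]. The direction is `md = arm1 - arm2` where "arm 1" is the
#' non-reference arm: by default the arm whose label sorts first is arm 1, and
#' `reference_arm` names the arm to subtract (so positive `md` favours the
#' other arm). The direction is recorded in attribute `"direction"` so it is
#' never inferred downstream.
#'
#' @param unified output of [prioritize_outcomes()]: two rows per study.
#' @param reference_arm optional arm label to use as the subtrahend.
#' @return data frame with columns `study_id`, `source_prom`, `md`,
#'   `variance`, `se`; attribute `"direction"`.
#' @export
unified_effects <- function(unified, reference_arm = NULL) {
  require_columns(unified, c("study_id", "arm_id", "n", "source_prom",
                             "mean_mcid", "sd_mcid"), "unified outcomes")
  pieces <- lapply(split(unified, unified$study_id), function(s) {
    if (nrow(s) != 2L) {
      stop(sprintf("study '%s' has %d arms; exactly two are required",
                   s$study_id[1], nrow(s)), call. = FALSE)
    }
    s <- s[order(s$arm_id), , drop = FALSE]
    if (!is.null(reference_arm)) {
      if (!reference_arm %in% s$arm_id) {
        stop(sprintf("study '%s': reference arm '%s' not present",
                     s$study_id[1], reference_arm), call. = FALSE)
      }
      s <- s[order(s$arm_id == reference_arm), , drop = FALSE]
    }
    e <- md_effect(s[1, ], s[2, ])
    data.frame(study_id = s$study_id[1], source_prom = s$source_prom[1],
               md = e$md, variance = e$variance, se = e$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "direction") <- if (is.null(reference_arm))
    "first arm (sorted by arm_id) minus second"
  else sprintf("other arm minus reference arm '%s'", reference_arm)
  out
}
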