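#' Collapse one study's normalized PROMs to a single unified outcome
#'
#' When a study reports several PROMs, retaining all of them would let one
#' cohort contribute several statistically dependent effect sizes. Instead the
#' instrument with the best (lowest) rank in the frequency ranking is retained
#' for both arms, and all other instruments are recorded as discarded.
#' Retention is decided on the intersection of the two arms' instrument sets,
#' since an effect size needs the same instrument in both arms; instruments
#' reported by only one arm are discarded with an audit note.
#'
#' @param outcomes normalized outcomes for a single study (rows of
#'   [normalize_measurements()] output sharing one `study_id`).
#' @param ranking a `prom_ranking` (e.g. [default_prom_ranking()]).
#' @param registry optional `prom_registry` used to resolve synonym spellings
#'   against the ranking.
#' @return a data frame with one row per arm: `study_id`, `arm_id`, `n`,
#'   `source_prom`, `mean_mcid`, `sd_mcid`, `discarded` (comma-separated);
#'   attribute `"audit"` records the decision.
#' @examples
#' norm <- normalize_measurements(demo_hip_studies(), mcid_registry())
#' s5 <- norm[norm$study_id == "Primary study 5", ]
#' prioritize_study(s5, default_prom_ranking())
#' @export
prioritize_study <- function(outcomes, ranking, registry = NULL) {
  stopifnot(nrow(outcomes) >= 1L)
  if (length(unique(outcomes$study_id)) != 1L) {
    stop("prioritize_study expects outcomes from a single study", call. = FALSE)
  }
  study <- outcomes$study_id[1]
  arms <- sort(unique(outcomes$arm_id))
  prom_sets <- lapply(arms, function(a)
    unique(outcomes$prom[outcomes$arm_id == a]))
  common <- Reduce(intersect, prom_sets)
  all_proms <- unique(outcomes$prom)
  if (length(common) == 0L) {
    stop(sprintf("study '%s': arms report disjoint PROM sets (%s); no common instrument",
                 study, paste(all_proms, collapse = ", ")), call. = FALSE)
  }
  rk <- prom_rank(ranking, common, registry)
  if (any(is.na(rk))) {
    stop(sprintf("study '%s': PROM '%s' is absent from the ranking",
                 study, common[which(is.na(rk))[1]]), call. = FALSE)
  }
  retained <- common[which.min(rk)]
  discarded <- setdiff(all_proms, retained)

  audit <- audit_record(
    "prioritize", "retained", study, NA, retained,
    sprintf("rank %d among {%s}; discarded: %s", min(rk),
            paste(common, collapse = ", "),
            if (length(discarded)) paste(discarded, collapse = ", ") else "none"))
  one_arm_only <- setdiff(all_proms, common)
  if (length(one_arm_only)) {
    audit <- rbind(audit, audit_record(
      "prioritize", "not_in_both_arms", study, NA,
      paste(one_arm_only, collapse = ", "),
      "reported by a single arm; ineligible for retention"))
  }

  rows <- outcomes[outcomes$prom == retained, , drop = FALSE]
  rows <- rows[order(rows$arm_id), , drop = FALSE]
  out <- data.frame(study_id = rows$study_id, arm_id = rows$arm_id,
                    n = rows$n, source_prom = rows$prom,
                    mean_mcid = rows$mean_mcid, sd_mcid = rows$sd_mcid,
                    discarded = if (length(discarded))
                      paste(discarded, collapse = ",") else "",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Prioritize every study in a normalized table
#'
#' Applies [prioritize_study()] per study, producing one unified functional
#' MCID outcome per (study, arm). Studies left without any normalizable
#' instrument upstream are absent from the input and therefore from the
#' output; their exclusion is audited by [normalize_measurements()].
#'
#' @param normalized output of [normalize_measurements()].
#' @inheritParams prioritize_study
#' @return data frame of unified outcomes (see [prioritize_study()]);
#'   attribute `"audit"` concatenates all per-study decisions.
#' @export
prioritize_outcomes <- function(normalized, ranking, registry = NULL) {
  require_columns(normalized, c("study_id", "arm_id", "prom", "n",
                                "mean_mcid", "sd_mcid"), "normalized table")
  if (nrow(normalized) == 0L) stop("no normalized outcomes to prioritize",
                                   call. = FALSE)
  pieces <- lapply(split(normalized, normalized$study_id),
                   prioritize_study, ranking = ranking, registry = registry)
  out <- do.call(rbind, pieces)
  audit <- do.call(rbind, c(list(empty_audit()),
                            lapply(pieces, attr, "audit")))
  rownames(out) <- rownames(audit) <- NULL
  attr(out, "audit") <- audit
  out
}
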