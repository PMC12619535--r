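# shared internal helpers

# Canonical form of an instrument name: unicode hyphen/dash variants unified,
# case folded, everything but letters and digits stripped. Idempotent.
canon_prom <- function(x) {
  x <- as.character(x)
  x <- gsub("[\u2010\u2011\u2012\u2013\u2014\u2015\u2212]", "-", x)
  x <- tolower(trimws(x))
  gsub("[^a-z0-9]+", "", x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (`0.25 -> 0.3` at one
#' decimal), the convention used in clinical summary tables, as opposed to the
#' round-half-even rule of base [round()]. Used only when reporting; all
#' internal arithmetic keeps full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (non-negative integer).
#' @return `x` rounded to `digits` decimals, half-up.
#' @examples
#' round_half_up(c(1.25, 1.35, -1.25), 1)
#' round_half_up(84.7 / 9.5, 1)  # 8.9 MCID units
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  # small guard against binary representation error in decimal inputs
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# single audit record; all stages append rows of this shape
audit_record <- function(stage, action, study_id = NA, arm_id = NA,
                         prom = NA, detail = "") {
  data.frame(stage = stage, action = action,
             study_id = as.character(study_id), arm_id = as.character(arm_id),
             prom = as.character(prom), detail = detail,
             stringsAsFactors = FALSE)
}

empty_audit <- function() {
  audit_record(character(0), character(0), character(0), character(0),
               character(0), character(0))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# path to a shipped example data file
mcidmeta_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mcidmeta")
  if (!nzchar(path)) stop("shipped data file not found: ", file, call. = FALSE)
  path
}
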