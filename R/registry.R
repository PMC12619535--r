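#' Load a PROM instrument registry
#'
#' Reads a comma-separated registry of patient-reported outcome measures
#' (PROMs). Each row describes one instrument: its score bounds, whether
#' higher scores mean better or worse outcome, and its published minimal
#' clinically important difference (MCID) in scale points — the divisor used
#' by every normalization in this package. An empty `mcid` cell marks an
#' instrument with no adopted MCID; such instruments are kept in the registry
#' (so they can be recognised and audited) but are not normalizable, and
#' attempting to normalize them is an error rather than a silent skip.
#'
#' @param path path to a CSV file with columns `name`, `scale_min`,
#'   `scale_max`, `orientation` (`"higher_better"` or `"higher_worse"`),
#'   `mcid` (points; may be empty) and `mcid_source`. An optional `synonyms`
#'   column carries pipe-separated alternative spellings used by
#'   [prom_lookup()].
#' @return an object of class `prom_registry`: a data frame with one row per
#'   instrument and a `normalizable` logical column.
#' @seealso [mcid_registry()] for the registry shipped with the package,
#'   [prom_lookup()] for name resolution.
#' @examples
#' reg <- mcid_registry()
#' prom_lookup(reg, "mHHS")$mcid
#' @export
load_prom_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  require_columns(raw, c("name", "scale_min", "scale_max", "orientation",
                         "mcid", "mcid_source"), "registry file")
  n <- nrow(raw)
  reg <- data.frame(
    name        = trimws(raw$name),
    scale_min   = as.numeric(raw$scale_min),
    scale_max   = as.numeric(raw$scale_max),
    orientation = trimws(raw$orientation),
    mcid        = suppressWarnings(as.numeric(raw$mcid)),
    mcid_source = raw$mcid_source,
    synonyms    = if ("synonyms" %in% names(raw)) raw$synonyms else
                    rep("", n),
    stringsAsFactors = FALSE
  )
  reg$mcid[!nzchar(trimws(raw$mcid))] <- NA_real_
  reg$normalizable <- !is.na(reg$mcid)

  bad_mcid <- which(!is.na(reg$mcid) & reg$mcid <= 0)
  if (length(bad_mcid)) {
    stop(sprintf("registry row %d ('%s'): mcid must be a positive number",
                 bad_mcid[1], reg$name[bad_mcid[1]]), call. = FALSE)
  }
  unparsed <- which(nzchar(trimws(raw$mcid)) & is.na(reg$mcid))
  if (length(unparsed)) {
    stop(sprintf("registry row %d ('%s'): mcid '%s' is not a number",
                 unparsed[1], reg$name[unparsed[1]], raw$mcid[unparsed[1]]),
         call. = FALSE)
  }
  if (any(is.na(reg$scale_min)) || any(is.na(reg$scale_max)) ||
      any(reg$scale_min >= reg$scale_max)) {
    stop("registry: every row needs numeric scale bounds with scale_min < scale_max",
         call. = FALSE)
  }
  if (!all(reg$orientation %in% c("higher_better", "higher_worse"))) {
    stop("registry: orientation must be 'higher_better' or 'higher_worse'",
         call. = FALSE)
  }
  if (anyDuplicated(canon_prom(reg$name))) {
    dup <- reg$name[duplicated(canon_prom(reg$name))][1]
    stop("registry: duplicate instrument name '", dup, "'", call. = FALSE)
  }
  class(reg) <- c("prom_registry", "data.frame")
  reg
}

#' Registry of hip-specific PROMs shipped with the package
#'
#' The packaged instrument registry for hip arthroscopy research. It covers
#' the ten most frequently reported hip-specific PROMs; the six leading
#' instruments carry their most frequently reported MCIDs from the validation
#' literature (mHHS 9.5, iHOT-12 13.0, HOS-SSS 12.1, NAHS 8.5, HOS-ADL 9.8,
#' iHOT-33 10.7 points), while HOOS, WOMAC, HAGOS and HHS are registered
#' without an MCID and therefore flagged non-normalizable. WOMAC is the one
#' inversely scaled instrument (higher = worse).
#'
#' @return a `prom_registry` object; see [load_prom_registry()].
#' @export
mcid_registry <- function() {
  load_prom_registry(mcidmeta_extdata("hip_prom_registry.csv"))
}

#' Look up an instrument in a registry
#'
#' Resolves an instrument name against a registry, tolerant of case,
#' punctuation and unicode hyphen variants (`"mhhs"`, `"iHOT-12"` with any
#' dash). Pipe-separated synonyms from the registry file (for example
#' `"HOS-Sport"` for `"HOS-SSS"`) resolve to their canonical instrument.
#'
#' @param registry a `prom_registry` from [load_prom_registry()].
#' @param name instrument identifier (length one).
#' @return a list of class `prom_definition` with fields `name`, `scale_min`,
#'   `scale_max`, `orientation`, `mcid`, `mcid_source`, `normalizable`.
#' @examples
#' prom_lookup(mcid_registry(), "ihot-33")$mcid
#' @export
prom_lookup <- function(registry, name) {
  stopifnot(inherits(registry, "prom_registry"), length(name) == 1L)
  idx <- match_prom(registry, name)
  if (is.na(idx)) {
    stop(sprintf("unknown PROM '%s'; known instruments: %s",
                 name, paste(registry$name, collapse = ", ")), call. = FALSE)
  }
  def <- as.list(registry[idx, setdiff(names(registry), "synonyms")])
  class(def) <- "prom_definition"
  def
}

# vectorised canonical match: registry row index per name, NA when unknown
match_prom <- function(registry, names) {
  key <- canon_prom(names)
  canon_names <- canon_prom(registry$name)
  idx <- match(key, canon_names)
  if (any(is.na(idx)) && any(nzchar(registry$synonyms))) {
    syn_tab <- synonym_table(registry)
    miss <- which(is.na(idx))
    idx[miss] <- syn_tab[key[miss]]
  }
  unname(idx)
}

synonym_table <- function(registry) {
  out <- integer(0)
  for (i in seq_len(nrow(registry))) {
    syn <- registry$synonyms[i]
    if (!nzchar(syn)) next
    keys <- canon_prom(strsplit(syn, "|", fixed = TRUE)[[1]])
    add <- stats::setNames(rep(i, length(keys)), keys)
    out <- c(out, add)
  }
  out
}

#' @export
print.prom_definition <- function(x, ...) {
  cat(sprintf("<PROM> %s [%g-%g, %s]\n", x$name, x$scale_min, x$scale_max,
              x$orientation))
  if (x$normalizable) {
    cat(sprintf("  MCID: %g points (%s)\n", x$mcid, x$mcid_source))
  } else {
    cat("  MCID: none adopted (not normalizable)\n")
  }
  invisible(x)
}

#' @export
print.prom_registry <- function(x, ...) {
  cat(sprintf("<prom_registry> %d instruments (%d with MCID)\n",
              nrow(x), sum(x$normalizable)))
  print.data.frame(x[, c("name", "scale_min", "scale_max", "orientation",
                         "mcid")], row.names = FALSE)
  invisible(x)
}
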