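#' Component record table
#'
#' Validates and normalizes a table of chemical components. Each record has an
#' id (never uppercased; component ids live in their own namespace), a name, a
#' set of herb codes (`;`-separated in the `herbs` column), the four ADME
#' properties used for screening -- molecular weight MW (Da), oral
#' bioavailability OB (percent), Caco-2 permeability and drug-likeness DL --
#' and an `include_listed` flag marking components admitted from the
#' literature regardless of their ADME profile.
#'
#' @param x data.frame with columns `id`, `name`, `herbs`, `mw`, `ob`,
#'   `caco2`, `dl` and optionally `include_listed`.
#' @return the validated data.frame with class `component_records` prepended.
#' @export
component_records <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  cols <- c("id", "name", "herbs", "mw", "ob", "caco2", "dl")
  if (nrow(x) == 0L) {
    x <- data.frame(id = character(), name = character(), herbs = character(),
                    mw = numeric(), ob = numeric(), caco2 = numeric(),
                    dl = numeric(), include_listed = logical(),
                    stringsAsFactors = FALSE)
  }
  missing <- setdiff(cols, names(x))
  if (length(missing)) stop("component table lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(x$include_listed)) x$include_listed <- FALSE
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) stop("duplicate component id: ", x$id[duplicated(x$id)][1])
  if (any(!nzchar(trimws(x$herbs)))) stop("every component needs at least one herb code")
  ok_mw <- is.na(x$mw) | x$mw > 0
  if (!all(ok_mw)) stop("MW must be positive")
  ok_ob <- is.na(x$ob) | (x$ob >= 0 & x$ob <= 100)
  if (!all(ok_ob)) stop("OB must lie in [0, 100]")
  class(x) <- c("component_records", class(x))
  x
}

#' Herb sets of component records
#' @param records a [component_records()] table
#' @return named list of character vectors (sorted herb codes per component).
#' @export
component_herbs <- function(records) {
  out <- lapply(strsplit(records$herbs, ";", fixed = TRUE),
                function(h) sort(unique(trimws(h[nzchar(trimws(h))]))))
  names(out) <- records$id
  out
}

#' ADME screening thresholds
#'
#' Defaults are the standard screening criteria for orally active herbal
#' components: OB > 30 percent, MW < 500 Da, Caco-2 > 0.4, DL > 0.14. All
#' four comparisons are strict.
#'
#' @param ob,mw,caco2,dl numeric thresholds.
#' @return named list of class `adme_thresholds`.
#' @export
adme_thresholds <- function(ob = 30, mw = 500, caco2 = 0.4, dl = 0.14) {
  th <- list(ob = ob, mw = mw, caco2 = caco2, dl = dl)
  if (!all(vapply(th, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE))) {
    stop("all thresholds must be single finite numbers")
  }
  structure(th, class = "adme_thresholds")
}

#' Select potential active components
#'
#' Keeps records satisfying all four strict ADME inequalities
#' (OB > `ob`, MW < `mw`, Caco-2 > `caco2`, DL > `dl`), unioned with records
#' flagged `include_listed` (high-concentration components admitted from the
#' literature, which bypass ADME screening entirely). Input order is
#' preserved. Records with a missing ADME property fail closed unless
#' include-listed; their ids and reasons are attached as attribute
#' `"rejected"`.
#'
#' @param records a [component_records()] table.
#' @param thresholds an [adme_thresholds()] list.
#' @return the kept subset of `records` (still a `component_records` table),
#'   with attribute `rejected`: data.frame of dropped ids and reasons.
#' @export
filter_active_components <- function(records, thresholds = adme_thresholds()) {
  stopifnot(inherits(records, "component_records"))
  th <- thresholds
  has_all <- !(is.na(records$ob) | is.na(records$mw) |
                 is.na(records$caco2) | is.na(records$dl))
  pass_adme <- has_all &
    records$ob > th$ob & records$mw < th$mw &
    records$caco2 > th$caco2 & records$dl > th$dl
  keep <- pass_adme | records$include_listed
  reason <- ifelse(!has_all, "missing ADME property", "failed ADME thresholds")
  rejected <- data.frame(id = records$id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Count components by exact herb subset
#'
#' UpSet-style partition: each component is counted once under its exact herb
#' set, so the counts over all subsets sum to the number of components.
#'
#' @param records a [component_records()] table.
#' @return data.frame with columns `herbs` (sorted codes joined by `;`),
#'   `n_herbs` and `count`, ordered by decreasing subset size then count.
#' @export
herb_overlap_counts <- function(records) {
  hs <- component_herbs(records)
  key <- vapply(hs, paste, "", collapse = ";")
  tab <- table(key)
  out <- data.frame(herbs = names(tab),
                    n_herbs = lengths(strsplit(names(tab), ";", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$n_herbs, -out$count, out$herbs), , drop = FALSE]
  rownames(out) <- NULL
  out
}
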