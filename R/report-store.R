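#' Construct a report store
#'
#' The in-memory container for a collection of spontaneous safety reports.
#' One row per (case_id, version); list columns hold the multi-valued fields
#' (drug names and roles, reaction PTs, outcome codes).
#'
#' @param reports tibble with columns `case_id` (chr), `version` (int),
#'   `year` (int), `quarter` (int 1-4), `sex`, `age_group`, `country`,
#'   `indication` (chr, `"unknown"` sentinel allowed), and list columns
#'   `drug_names`, `drug_roles`, `reactions`, `outcomes` (character vectors;
#'   `reactions` nonempty, `outcomes` possibly empty).
#' @param provenance one-line description of where the reports came from.
#' @return object of class `report_store`.
#' @export
report_store <- function(reports, provenance = "in-memory") {
  reports <- tibble::as_tibble(reports)
  needed <- c(
    "case_id", "version", "year", "quarter", "sex", "age_group",
    "country", "indication", "drug_names", "drug_roles", "reactions", "outcomes"
  )
  missing <- setdiff(needed, names(reports))
  if (length(missing)) {
    stop("report_store missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(reports$case_id, reports$version)
  if (anyDuplicated(key)) {
    stop("report_store: case_id + version must be unique", call. = FALSE)
  }
  if (any(lengths(reports$reactions) == 0)) {
    stop("report_store: every report must carry at least one reaction PT", call. = FALSE)
  }
  structure(list(reports = reports[, needed], provenance = provenance),
    class = "report_store"
  )
}

#' @export
print.report_store <- function(x, ...) {
  cat(
    "<report_store> ", nrow(x$reports), " reports (",
    length(unique(x$reports$case_id)), " cases) from ", x$provenance, "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of report rows in a store
#' @param store a [report_store()].
#' @return integer count.
#' @export
n_reports <- function(store) nrow(store$reports)

store_slice <- function(store, keep, provenance = store$provenance) {
  report_store(store$reports[keep, , drop = FALSE], provenance)
}

# empty stores are legal intermediates (filters may drop everything), so the
# internal slicer bypasses the nonempty-reaction check only for 0 rows
store_slice0 <- function(store, keep, provenance = store$provenance) {
  out <- store
  out$reports <- store$reports[keep, , drop = FALSE]
  out$provenance <- provenance
  out
}

#' Does any drug entry on each report carry the PS role for `drug`?
#' @param store a [report_store()].
#' @param drug canonical drug name.
#' @return logical vector, one element per report row.
#' @export
is_primary_suspect <- function(store, drug) {
  purrr::map2_lgl(
    store$reports$drug_names, store$reports$drug_roles,
    function(nm, role) any(nm == drug & role == "PS")
  )
}

# first PS drug on each report (NA if none); used for all-pairs GPS cells
ps_drug_of <- function(store) {
  purrr::map2_chr(
    store$reports$drug_names, store$reports$drug_roles,
    function(nm, role) {
      i <- which(role == "PS")
      if (length(i)) nm[i[1]] else NA_character_
    }
  )
}
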