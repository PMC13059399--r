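#' Normalize a raw drug name
#'
#' Case-folds, trims and collapses whitespace, then maps through a synonym
#' table (e.g. trade name -> active substance). Names absent from the map are
#' returned case-folded, so normalization is idempotent.
#'
#' @param raw character vector of drug names as reported.
#' @param synonyms named character vector or list, lowercase keys, e.g.
#'   `c(crysvita = "burosumab")`; `NULL` for fold-only normalization.
#' @return character vector of canonical names.
#' @examples
#' normalize_drug_name("CRYSVITA ", c(crysvita = "burosumab")) # "burosumab"
#' @export
normalize_drug_name <- function(raw, synonyms = NULL) {
  folded <- gsub("\\s+", " ", trimws(tolower(raw)))
  if (length(synonyms)) {
    syn <- unlist(synonyms)
    hit <- folded %in% names(syn)
    folded[hit] <- unname(syn[folded[hit]])
  }
  folded
}

#' Read a drug-synonym map from TSV
#' @param path TSV with header columns `raw`, `canonical`.
#' @return named character vector keyed by lowercase raw name.
#' @export
read_synonyms <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("raw", "canonical") %in% names(tab))) {
    stop("synonym file must have columns raw, canonical", call. = FALSE)
  }
  stats::setNames(tolower(tab$canonical), tolower(tab$raw))
}

#' Collapse duplicate case versions
#'
#' FAERS cases accumulate follow-up versions; analyses keep one row per case.
#' The highest version wins; ties on version are broken by latest receipt
#' quarter, then by input order (last occurrence wins).
#'
#' @param store a [report_store()].
#' @return a [report_store()] with exactly one report per `case_id`.
#' @export
deduplicate <- function(store) {
  r <- store$reports
  if (nrow(r) == 0) {
    return(store)
  }
  ord <- order(r$case_id, r$version, quarter_index(r$year, r$quarter),
    seq_len(nrow(r)),
    method = "radix"
  )
  keep_last <- !duplicated(r$case_id[ord], fromLast = TRUE)
  store_slice0(store, sort(ord[keep_last]),
    provenance = paste0(store$provenance, " | deduplicated")
  )
}

#' Keep reports naming a drug as primary suspect
#'
#' Retains exactly the reports where some drug entry has the canonical name
#' `drug` with role `PS`; all other reports are excluded. The result is always
#' a subset of the input.
#'
#' @param store a [report_store()].
#' @param drug canonical drug name (normalize first; see
#'   [normalize_drug_name()]).
#' @return filtered [report_store()].
#' @export
filter_primary_suspect <- function(store, drug) {
  store_slice0(store, which(is_primary_suspect(store, drug)),
    provenance = paste0(store$provenance, " | PS=", drug)
  )
}

#' Keep reports received within an inclusive quarter window
#'
#' @param store a [report_store()].
#' @param start,end `c(year, quarter)`; both ends inclusive.
#' @return filtered [report_store()].
#' @export
filter_period <- function(store, start, end) {
  start <- check_quarter(start, "start")
  end <- check_quarter(end, "end")
  lo <- quarter_index(start[1], start[2])
  hi <- quarter_index(end[1], end[2])
  if (lo > hi) stop("argument error: start quarter after end quarter", call. = FALSE)
  qi <- quarter_index(store$reports$year, store$reports$quarter)
  store_slice0(store, which(qi >= lo & qi <= hi),
    provenance = sprintf(
      "%s | %dQ%d-%dQ%d", store$provenance,
      start[1], start[2], end[1], end[2]
    )
  )
}
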