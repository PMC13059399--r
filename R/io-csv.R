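# Simple one-row-per-report CSV dialect (RFC 4180; list-valued cells joined
# with ";"). Human-writable counterpart of the FAERS table set; drug entries
# pair up positionally between the drug_names and drug_roles cells.

CSV_COLS <- c(
  "case_id", "version", "year", "quarter", "sex", "age_group", "country",
  "indication", "drug_names", "drug_roles", "reactions", "outcomes"
)

#' Write a report store as one-row-per-report CSV
#'
#' Multi-valued cells (`drug_names`, `drug_roles`, `reactions`, `outcomes`)
#' are `";"`-joined; an empty outcome set becomes an empty cell. Field values
#' must not themselves contain `";"`.
#'
#' @param store a [report_store()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_reports_csv <- function(store, path) {
  r <- store$reports
  join <- function(col) vapply(col, paste, character(1), collapse = ";")
  flat <- data.frame(
    case_id = r$case_id, version = r$version, year = r$year, quarter = r$quarter,
    sex = r$sex, age_group = r$age_group, country = r$country,
    indication = r$indication,
    drug_names = join(r$drug_names), drug_roles = join(r$drug_roles),
    reactions = join(r$reactions), outcomes = join(r$outcomes)
  )
  utils::write.csv(flat, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the one-row-per-report CSV dialect
#'
#' @param path CSV produced by [write_reports_csv()] (or hand-written to the
#'   same schema).
#' @param synonyms optional drug-synonym map applied via
#'   [normalize_drug_name()].
#' @return a [report_store()].
#' @export
read_reports_csv <- function(path, synonyms = NULL) {
  flat <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(CSV_COLS, names(flat))
  if (length(missing)) {
    stop("CSV lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  split_cell <- function(x) strsplit(x, ";", fixed = TRUE)
  drug_names <- lapply(split_cell(flat$drug_names), function(d) normalize_drug_name(d, synonyms))
  drug_roles <- split_cell(flat$drug_roles)
  drug_roles <- lapply(drug_roles, function(role) {
    role[!role %in% ROLE_LEVELS] <- "C"
    role
  })
  reports <- tibble::tibble(
    case_id = flat$case_id, version = as.integer(flat$version),
    year = as.integer(flat$year), quarter = as.integer(flat$quarter),
    sex = flat$sex, age_group = flat$age_group, country = flat$country,
    indication = flat$indication,
    drug_names = drug_names, drug_roles = drug_roles,
    reactions = split_cell(flat$reactions),
    outcomes = split_cell(flat$outcomes)
  )
  keep <- lengths(reports$reactions) > 0
  if (any(!keep)) warning(sum(!keep), " report(s) without reactions dropped")
  report_store(reports[keep, ], provenance = paste("csv:", path))
}
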