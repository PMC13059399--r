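#' Frequency summary of one report characteristic
#'
#' Produces the clinical-characteristics style table for a deduplicated,
#' drug-filtered store: category, report count, percentage of all reports in
#' the store (half-up, 2 decimals). Years sort ascending; every other field
#' sorts by count descending. The `"unknown"` sentinel is always tabulated
#' (even at zero). For `country` and `indication` the categories beyond
#' `top_n` (unknown excluded from the cut) pool into `"Other"`. Outcomes are
#' not mutually exclusive: each outcome category counts the reports carrying
#' that code, and `"unknown"` counts reports with no outcome code at all, so
#' outcome percentages need not sum to 100.
#'
#' @param store a [report_store()], deduplicated and filtered to the drug of
#'   interest.
#' @param field one of `"year"`, `"sex"`, `"age_group"`, `"country"`,
#'   `"outcome"`, `"indication"`.
#' @param top_n optional pooling cut for `country` / `indication`.
#' @return tibble with columns `category`, `count`, `percent` (character,
#'   2 decimals); attributes `field` and `total`.
#' @export
summarize_reports <- function(store, field, top_n = NULL) {
  fields <- c("year", "sex", "age_group", "country", "outcome", "indication")
  if (!is.character(field) || length(field) != 1 || !field %in% fields) {
    stop(
      "argument error: field must be one of ",
      paste(fields, collapse = ", "),
      call. = FALSE
    )
  }
  r <- store$reports
  total <- nrow(r)
  if (total == 0) {
    out <- tibble::tibble(category = character(), count = integer(), percent = character())
    attr(out, "field") <- field
    attr(out, "total") <- 0L
    return(out)
  }

  if (field == "outcome") {
    counts <- vapply(
      OUTCOME_LEVELS,
      function(oc) sum(vapply(r$outcomes, function(x) oc %in% x, logical(1))),
      integer(1)
    )
    counts <- c(counts, unknown = sum(lengths(r$outcomes) == 0))
    tab <- tibble::tibble(category = names(counts), count = as.integer(counts))
    tab <- tab[order(-tab$count, tab$category), ]
  } else {
    values <- if (field == "year") as.character(r$year) else r[[field]]
    tt <- table(values)
    tab <- tibble::tibble(category = names(tt), count = as.integer(tt))
    if (field %in% c("sex", "age_group", "country") && !UNKNOWN %in% tab$category) {
      tab <- dplyr::bind_rows(tab, tibble::tibble(category = UNKNOWN, count = 0L))
    }
    if (field == "year") {
      tab <- tab[order(tab$category), ]
    } else {
      tab <- tab[order(-tab$count, tab$category), ]
    }
    if (!is.null(top_n) && field %in% c("country", "indication")) {
      named <- tab[tab$category != UNKNOWN, ]
      unk <- tab[tab$category == UNKNOWN, ]
      if (nrow(named) > top_n) {
        pooled <- tibble::tibble(
          category = "Other",
          count = sum(named$count[-seq_len(top_n)])
        )
        named <- dplyr::bind_rows(named[seq_len(top_n), ], pooled)
      }
      tab <- dplyr::bind_rows(named, unk)
    }
  }
  tab$percent <- percent(tab$count, total)
  attr(tab, "field") <- field
  attr(tab, "total") <- total
  tab
}

#' Render a frequency table as TSV lines (category, count, percent)
#' @param tab output of [summarize_reports()].
#' @param path file to write.
#' @return invisibly, `path`.
#' @export
write_frequency_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
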