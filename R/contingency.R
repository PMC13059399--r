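#' Construct a 2x2 contingency table
#'
#' Cell roles for one (drug, event-label) pair against the whole background:
#' `a` = reports that are primary-suspect (PS) for the drug and carry the
#' label, `b` = PS reports without the label, `c` = non-PS reports with the
#' label, `d` = the remainder. `a + b + c + d = N`, the deduplicated report
#' count in the analysis window.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return object of class `contingency_table` (named numeric length 4).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be nonnegative integers", call. = FALSE)
  }
  structure(as.numeric(cells), names = c("a", "b", "c", "d"), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(x, 2, 2,
    byrow = TRUE,
    dimnames = list(c("drug", "other drugs"), c("event", "other events"))
  )
  print(m)
  invisible(x)
}

as_cells <- function(t) {
  if (inherits(t, "contingency_table")) {
    as.list(stats::setNames(as.numeric(t), c("a", "b", "c", "d")))
  } else if (is.numeric(t) && length(t) == 4) {
    as.list(stats::setNames(as.numeric(t), c("a", "b", "c", "d")))
  } else {
    stop("expected a contingency_table or numeric vector of 4 cells", call. = FALSE)
  }
}

#' Build the 2x2 table for one (drug, label) pair
#'
#' @param all_reports a [report_store()] that is deduplicated and
#'   period-filtered but NOT PS-filtered (the background is needed).
#' @param drug canonical drug name.
#' @param label event label at `level`.
#' @param level `"PT"`, `"SOC"` or `"SMQ"`.
#' @param h a [meddra_hierarchy()].
#' @return a [contingency_table()].
#' @export
build_table <- function(all_reports, drug, label, level, h) {
  level <- match.arg(level, c("PT", "SOC", "SMQ"))
  long <- labels_long(all_reports, h, level)
  if (!label %in% long$label) {
    stop("lookup error: label '", label, "' unknown at level ", level, call. = FALSE)
  }
  ps <- is_primary_suspect(all_reports, drug)
  n_total <- n_reports(all_reports)
  with_label <- unique(long$row[long$label == label])
  a <- sum(ps[with_label])
  b <- sum(ps) - a
  c_ <- length(with_label) - a
  contingency_table(a, b, c_, n_total - a - b - c_)
}

#' Build 2x2 tables for every label at a level
#'
#' One table per label whose target-drug count `a` reaches `min_count`;
#' reserved aggregation buckets (`"unmapped"` at SOC level, `"NA"` at SMQ
#' level) are excluded from signal tables. Ordering is by label; ranking is a
#' downstream concern.
#'
#' @inheritParams build_table
#' @param min_count smallest `a` to emit (0 keeps every label with a PS
#'   report... including `a = 0` labels only if `min_count = 0` and the label
#'   occurs in the background).
#' @return tibble with columns `label`, `a`, `b`, `c`, `d`.
#' @export
build_all_tables <- function(all_reports, drug, level, h, min_count = 0) {
  level <- match.arg(level, c("PT", "SOC", "SMQ"))
  long <- labels_long(all_reports, h, level)
  long <- long[!long$label %in% reserved_labels(level), , drop = FALSE]
  ps <- is_primary_suspect(all_reports, drug)
  n_total <- n_reports(all_reports)
  n_ps <- sum(ps)
  if (nrow(long) == 0) {
    return(tibble::tibble(
      label = character(), a = numeric(), b = numeric(),
      c = numeric(), d = numeric()
    ))
  }
  counts <- long |>
    dplyr::mutate(ps = ps[.data$row]) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      a = sum(.data$ps), with_label = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      b = n_ps - .data$a,
      c = .data$with_label - .data$a,
      d = n_total - n_ps - .data$c
    ) |>
    dplyr::filter(.data$a >= min_count) |>
    dplyr::arrange(.data$label) |>
    dplyr::select("label", "a", "b", "c", "d")
  counts
}

# (drug, label) cells across ALL PS drugs at a level: observed count a and
# expected count E = rowtotal * coltotal / N for every pair with positive
# margins (zero-observation cells included). Feeds the GPS prior fit, which
# shrinks against the overall reporting rate across all drugs.
all_pair_cells <- function(all_reports, level, h) {
  long <- labels_long(all_reports, h, level)
  long <- long[!long$label %in% reserved_labels(level), , drop = FALSE]
  ps_drug <- ps_drug_of(all_reports)
  n_total <- n_reports(all_reports)
  drugs <- sort(unique(ps_drug[!is.na(ps_drug)]))
  labels <- sort(unique(long$label))
  if (!length(drugs) || !length(labels)) {
    return(tibble::tibble(drug = character(), label = character(), a = numeric(), E = numeric()))
  }
  long$drug <- ps_drug[long$row]
  obs <- long |>
    dplyr::filter(!is.na(.data$drug)) |>
    dplyr::count(.data$drug, .data$label, name = "a")
  n_drug <- as.numeric(table(factor(ps_drug, drugs)))
  n_label <- as.numeric(table(factor(long$label, labels)))
  grid <- tibble::tibble(
    drug = rep(drugs, each = length(labels)),
    label = rep(labels, length(drugs)),
    E = rep(n_drug, each = length(labels)) * rep(n_label, length(drugs)) / n_total
  )
  out <- dplyr::left_join(grid, obs, by = c("drug", "label"))
  out$a[is.na(out$a)] <- 0
  out[, c("drug", "label", "a", "E")]
}
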