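#' Full disproportionality screen for one drug at one aggregation level
#'
#' Builds the 2x2 table of every event label with at least `th$min_a` target
#' cases, computes all four statistics, fits the MGPS prior once on the
#' (drug, label) cells of ALL primary-suspect drugs at the level (so the
#' shrinkage reflects the overall reporting rate across drugs), and applies
#' the combined four-threshold gate.
#'
#' @param all_reports deduplicated, period-filtered (NOT PS-filtered)
#'   [report_store()].
#' @param drug canonical target drug name.
#' @param level `"PT"`, `"SOC"` or `"SMQ"`.
#' @param h a [meddra_hierarchy()].
#' @param th a [da_thresholds()].
#' @param ic_method `"closed"` or `"bate"` (see [bcpnn_ic()]).
#' @param yates continuity-correct the chi-square.
#' @param prior optional pre-fitted [gps_prior()]; fitted from the data when
#'   `NULL`.
#' @param count_unit `"report"` (default; each report counts once per label)
#'   or `"event"` (each reaction PT occurrence counts; N is then the total
#'   number of report-PT pairs).
#' @return tibble with one row per label: `label`, `level`, `a`, `ror`,
#'   `ror_lo95`, `ror_hi95`, `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05`,
#'   `signal`.
#' @export
compute_all <- function(all_reports, drug, level, h, th = da_thresholds(),
                        ic_method = c("closed", "bate"), yates = FALSE,
                        prior = NULL, count_unit = c("report", "event")) {
  ic_method <- match.arg(ic_method)
  count_unit <- match.arg(count_unit)
  level <- match.arg(level, c("PT", "SOC", "SMQ"))

  tables <- if (count_unit == "report") {
    build_all_tables(all_reports, drug, level, h, min_count = th$min_a)
  } else {
    build_all_tables_events(all_reports, drug, level, h, min_count = th$min_a)
  }
  if (nrow(tables) == 0) {
    return(empty_da_results(level))
  }

  if (is.null(prior)) {
    cells <- all_pair_cells(all_reports, level, h)
    prior <- fit_gps_prior(cells)
  }

  a <- tables$a
  b <- tables$b
  c_ <- tables$c
  d <- tables$d
  n <- a + b + c_ + d
  e <- (a + b) * (a + c_) / n
  ror_r <- suppressMessages(ror_stats(a, b, c_, d, correction = TRUE))
  prr_r <- prr_stats(a, b, c_, d, yates = yates)
  ic_r <- ic_stats(a, b, c_, d, method = ic_method)
  eb_r <- ebgm_stats(a, e, prior)

  out <- tibble::tibble(
    label = tables$label, level = level, a = a,
    ror = ror_r$ror, ror_lo95 = ror_r$lo95, ror_hi95 = ror_r$hi95,
    prr = prr_r$prr, chi2 = prr_r$chi2,
    ic = ic_r$ic, ic025 = ic_r$ic025,
    ebgm = eb_r$ebgm, ebgm05 = eb_r$ebgm05
  )
  out$signal <- evaluate_signal(out, th)
  attr(out, "prior") <- prior
  attr(out, "N") <- n_reports(all_reports)
  out
}

empty_da_results <- function(level) {
  tibble::tibble(
    label = character(), level = character(), a = numeric(),
    ror = numeric(), ror_lo95 = numeric(), ror_hi95 = numeric(),
    prr = numeric(), chi2 = numeric(), ic = numeric(), ic025 = numeric(),
    ebgm = numeric(), ebgm05 = numeric(), signal = logical()
  )
}

# event-occurrence counting mode: the unit is a (report, reaction PT) pair
# rather than a distinct report; provided because published tabulations are
# ambiguous at SOC level
build_all_tables_events <- function(all_reports, drug, level, h, min_count = 0) {
  reac <- all_reports$reports$reactions
  if (length(reac) == 0) {
    return(tibble::tibble(
      label = character(), a = numeric(), b = numeric(),
      c = numeric(), d = numeric()
    ))
  }
  long <- tibble::tibble(
    row = rep.int(seq_along(reac), lengths(reac)),
    pt = unlist(reac, use.names = FALSE)
  )
  long$label <- switch(level,
    PT = long$pt,
    SOC = {
      soc <- h$pt_to_soc[long$pt]
      soc[is.na(soc)] <- "unmapped"
      unname(soc)
    },
    SMQ = stop("event counting unit is not defined at SMQ level (a PT may hit several SMQs)",
      call. = FALSE
    )
  )
  long <- long[!long$label %in% reserved_labels(level), , drop = FALSE]
  ps <- is_primary_suspect(all_reports, drug)
  n_total <- nrow(long)
  n_ps <- sum(ps[long$row])
  long |>
    dplyr::mutate(ps = ps[.data$row]) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(a = sum(.data$ps), tot = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      b = n_ps - .data$a, c = .data$tot - .data$a,
      d = n_total - n_ps - .data$c
    ) |>
    dplyr::filter(.data$a >= min_count) |>
    dplyr::arrange(.data$label) |>
    dplyr::select("label", "a", "b", "c", "d")
}
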