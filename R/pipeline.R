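#' Configuration for an end-to-end signal-detection run
#'
#' @param input either a [report_store()] already in memory, or a path: a
#'   directory of FAERS-style tables (`format = "faers"`) or a CSV file
#'   (`format = "csv"`).
#' @param format `"faers"` or `"csv"`; ignored when `input` is a store.
#' @param drug target drug (normalized against `synonyms` before use).
#' @param synonyms named synonym map or path to a TSV for [read_synonyms()].
#' @param hierarchy a [meddra_hierarchy()], or `c(pt_soc =, smq =)` file paths.
#' @param quarter_start,quarter_end inclusive analysis window.
#' @param thresholds a [da_thresholds()].
#' @param levels subset of `c("PT", "SOC", "SMQ")`, nonempty.
#' @param top_n rows kept in each ranked top table.
#' @param out_dir output directory (created if needed).
#' @param ic_method,yates,count_unit passed to [compute_all()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, format = c("faers", "csv"), drug,
                            synonyms = NULL, hierarchy,
                            quarter_start = c(2018, 1), quarter_end = c(2024, 3),
                            thresholds = da_thresholds(),
                            levels = c("PT", "SOC", "SMQ"), top_n = 30,
                            out_dir = ".", ic_method = "closed", yates = FALSE,
                            count_unit = "report") {
  format <- match.arg(format)
  levels <- match.arg(levels, c("PT", "SOC", "SMQ"), several.ok = TRUE)
  if (length(levels) == 0) stop("level set must be nonempty", call. = FALSE)
  structure(
    list(
      input = input, format = format, drug = drug, synonyms = synonyms,
      hierarchy = hierarchy,
      quarter_start = check_quarter(quarter_start, "quarter_start"),
      quarter_end = check_quarter(quarter_end, "quarter_end"),
      thresholds = thresholds, levels = levels, top_n = top_n,
      out_dir = out_dir, ic_method = ic_method, yates = yates,
      count_unit = count_unit
    ),
    class = "pipeline_config"
  )
}

#' Run the full signal-detection pipeline
#'
#' Ingest -> deduplicate -> quarter window -> descriptives on the
#' primary-suspect-filtered store, disproportionality on the full background
#' store at each requested level, ranked by IC025 descending. Writes, under
#' `out_dir`: `descriptives/<field>.tsv`, `results_<level>.tsv` (full),
#' `top_<level>.tsv` (first `top_n` rows), and `provenance.yaml` with the
#' report funnel and configuration hash. Deterministic for fixed inputs and
#' configuration.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a run summary list: `N` (background reports in window),
#'   `drug_total` (PS reports for the drug), `results` (named list of result
#'   tibbles by level), `descriptives`, `outputs` (paths written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  synonyms <- cfg$synonyms
  if (is.character(synonyms) && length(synonyms) == 1 && file.exists(synonyms)) {
    synonyms <- read_synonyms(synonyms)
  }
  store <- if (inherits(cfg$input, "report_store")) {
    cfg$input
  } else if (cfg$format == "faers") {
    read_faers_tables(cfg$input, synonyms = synonyms)
  } else {
    read_reports_csv(cfg$input, synonyms = synonyms)
  }
  n_ingested <- n_reports(store)

  h <- cfg$hierarchy
  if (!inherits(h, "meddra_hierarchy")) {
    h <- load_hierarchy(h[["pt_soc"]], h[["smq"]])
  }
  drug <- normalize_drug_name(cfg$drug, synonyms)

  store <- deduplicate(store)
  n_dedup <- n_reports(store)
  store <- filter_period(store, cfg$quarter_start, cfg$quarter_end)
  n_window <- n_reports(store)

  ps_store <- filter_primary_suspect(store, drug)
  drug_total <- n_reports(ps_store)
  message(sprintf(
    "funnel: %d ingested -> %d deduplicated -> %d in window -> %d PS for %s",
    n_ingested, n_dedup, n_window, drug_total, drug
  ))

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  desc_dir <- file.path(cfg$out_dir, "descriptives")
  if (!dir.exists(desc_dir)) dir.create(desc_dir)
  outputs <- character()
  descriptives <- list()
  for (field in c("year", "sex", "age_group", "country", "outcome", "indication")) {
    top_cut <- if (field %in% c("country", "indication")) cfg$top_n else NULL
    tab <- summarize_reports(ps_store, field, top_n = top_cut)
    descriptives[[field]] <- tab
    p <- file.path(desc_dir, paste0(field, ".tsv"))
    write_frequency_table(tab, p)
    outputs <- c(outputs, p)
  }

  results <- list()
  smq_na <- NA_integer_
  for (level in cfg$levels) {
    res <- compute_all(store, drug, level, h,
      th = cfg$thresholds,
      ic_method = cfg$ic_method, yates = cfg$yates,
      count_unit = cfg$count_unit
    )
    res <- rank_results(res, key = "ic025", descending = TRUE)
    results[[level]] <- res
    full_path <- file.path(cfg$out_dir, paste0("results_", level, ".tsv"))
    top_path <- file.path(cfg$out_dir, paste0("top_", level, ".tsv"))
    write_results_tsv(res, full_path)
    write_results_tsv(top_n_results(res, cfg$top_n), top_path)
    outputs <- c(outputs, full_path, top_path)
    if (level == "SMQ") {
      long <- labels_long(ps_store, h, "SMQ")
      smq_na <- length(unique(long$row[long$label == "NA"]))
    }
  }

  prov <- list(
    N = n_window, drug = drug, drug_total = drug_total,
    funnel = list(
      ingested = n_ingested, deduplicated = n_dedup,
      in_window = n_window, primary_suspect = drug_total
    ),
    smq_unclassified_reports = if (is.na(smq_na)) NULL else smq_na,
    window = sprintf(
      "%dQ%d-%dQ%d", cfg$quarter_start[1], cfg$quarter_start[2],
      cfg$quarter_end[1], cfg$quarter_end[2]
    ),
    package_version = as.character(utils::packageVersion("pvsignal")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), c("input", "out_dir"))])
  )
  prov_path <- file.path(cfg$out_dir, "provenance.yaml")
  yaml::write_yaml(prov, prov_path)
  outputs <- c(outputs, prov_path)

  invisible(list(
    N = n_window, drug_total = drug_total, results = results,
    descriptives = descriptives, outputs = outputs, provenance = prov
  ))
}

#' Rank disproportionality results
#'
#' Stable sort on one statistic; ties broken by case count descending, then
#' label lexicographic.
#'
#' @param results tibble from [compute_all()].
#' @param key `"ic025"`, `"a"` or `"ebgm05"`.
#' @param descending sort direction for `key`.
#' @return the reordered tibble.
#' @export
rank_results <- function(results, key = c("ic025", "a", "ebgm05"), descending = TRUE) {
  key <- match.arg(key)
  if (nrow(results) == 0) {
    return(results)
  }
  k <- results[[key]]
  if (descending) k <- -k
  results[order(k, -results$a, results$label, method = "radix"), ]
}

#' First n rows of a ranked result list
#' @param ordered ranked tibble (see [rank_results()]).
#' @param n positive integer.
#' @return the first `min(n, nrow)` rows.
#' @export
top_n_results <- function(ordered, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  utils::head(ordered, n)
}

#' Write results with the standard signal-table column set
#'
#' Columns: label, case_reports, ROR, ROR_lo95, ROR_hi95, PRR, chi2, EBGM,
#' EBGM05, IC, IC025, signal; statistics printed half-up to 2 decimals as in
#' published signal tables.
#'
#' @param results tibble from [compute_all()] / [rank_results()].
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_results_tsv <- function(results, path) {
  fmt <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  flat <- data.frame(
    label = results$label, case_reports = results$a,
    ROR = fmt(results$ror), ROR_lo95 = fmt(results$ror_lo95),
    ROR_hi95 = fmt(results$ror_hi95), PRR = fmt(results$prr),
    chi2 = fmt(results$chi2), EBGM = fmt(results$ebgm),
    EBGM05 = fmt(results$ebgm05), IC = fmt(results$ic),
    IC025 = fmt(results$ic025), signal = results$signal
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
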