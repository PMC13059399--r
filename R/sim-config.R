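#' Specify an injected drug--event signal
#'
#' A signal multiplies the conditional reporting probability of one preferred
#' term (PT) given that a drug is the primary suspect (PS) of the report, by a
#' relative reporting ratio `rr`; the per-report event distribution is then
#' renormalized. `rr = 1` leaves the pair at its background rate; `rr = 0`
#' suppresses the event for that drug.
#'
#' @param drug_id integer index of the drug in the simulated vocabulary.
#' @param event_id integer index of the PT in the simulated vocabulary.
#' @param rr nonnegative relative reporting ratio.
#' @return a `signal_spec` list.
#' @export
signal_spec <- function(drug_id, event_id, rr) {
  stopifnot(length(drug_id) == 1, length(event_id) == 1, length(rr) == 1)
  if (!is.finite(rr) || rr < 0) stop("rr must be a nonnegative number", call. = FALSE)
  structure(
    list(drug_id = as.integer(drug_id), event_id = as.integer(event_id), rr = as.numeric(rr)),
    class = "signal_spec"
  )
}

#' Configuration for the spontaneous-report simulator
#'
#' Describes a FAERS-like reporting system at desk scale: a drug vocabulary
#' with popularity weights, a PT vocabulary with background reporting rates, a
#' per-report event-count distribution, optional injected drug--event signals,
#' demographic missingness, duplicate case versions, and a quarter window.
#'
#' Defaults emulate the clinical-characteristics profile typical of a rare-
#' disease biologic in FAERS: near-total sex/age missingness, a single
#' dominant reporting country, a dominant indication, and mostly-unknown
#' serious outcomes. Drug and event popularity are Zipf-distributed unless
#' rates are supplied.
#'
#' @param n_reports number of distinct cases to generate (before duplication).
#' @param n_drugs,n_events vocabulary sizes.
#' @param background_drug_rates probability vector over drugs (PS-drug choice);
#'   default Zipf(1).
#' @param background_event_rates probability vector over PTs; default Zipf(1).
#' @param events_per_report_mean mean of the 1 + Geometric event-count
#'   distribution (>= 1).
#' @param signals list of [signal_spec()].
#' @param missingness named vector with probabilities of the `"unknown"`
#'   sentinel for `sex`, `age`, `country`.
#' @param duplicate_rate fraction of cases emitted with a second version.
#' @param quarter_start,quarter_end inclusive window, each `c(year, quarter)`.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param extra_drugs_mean Poisson mean for non-PS co-reported drugs.
#' @param country_levels,indication_levels named probability vectors for the
#'   non-missing categorical fields.
#' @param outcome_probs named per-outcome independent probabilities; a report
#'   with no outcome drawn is tabulated as outcome `"unknown"`.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_reports = 50000,
                       n_drugs = 25,
                       n_events = 100,
                       background_drug_rates = NULL,
                       background_event_rates = NULL,
                       events_per_report_mean = 1.8,
                       signals = list(),
                       missingness = c(sex = 0.9954, age = 0.997, country = 0.01),
                       duplicate_rate = 0.05,
                       quarter_start = c(2018, 1),
                       quarter_end = c(2024, 3),
                       seed = 1L,
                       extra_drugs_mean = 0.8,
                       country_levels = c(
                         "United States" = 0.935, "United Kingdom" = 0.022,
                         "Germany" = 0.010, "France" = 0.008, "Japan" = 0.025
                       ),
                       indication_levels = c(
                         "hereditary hypophosphataemic rickets" = 0.7835,
                         "product used for unknown indication" = 0.1466,
                         "hypophosphataemic osteomalacia" = 0.0190,
                         "hypophosphataemia" = 0.0184,
                         "phosphorus metabolism disorder" = 0.0172,
                         "osteomalacia" = 0.0077,
                         "rickets" = 0.0076
                       ),
                       outcome_probs = c(
                         death = 0.006, life_threatening = 0.0014,
                         hospitalization = 0.063, disability = 0.002, other = 0.12
                       )) {
  zipf <- function(n) {
    w <- 1 / seq_len(n)
    w / sum(w)
  }
  if (is.null(background_drug_rates)) background_drug_rates <- zipf(n_drugs)
  if (is.null(background_event_rates)) background_event_rates <- zipf(n_events)

  cfg <- structure(
    list(
      n_reports = as.integer(n_reports), n_drugs = as.integer(n_drugs),
      n_events = as.integer(n_events),
      background_drug_rates = as.numeric(background_drug_rates),
      background_event_rates = as.numeric(background_event_rates),
      events_per_report_mean = as.numeric(events_per_report_mean),
      signals = signals, missingness = missingness,
      duplicate_rate = as.numeric(duplicate_rate),
      quarter_start = check_quarter(quarter_start, "quarter_start"),
      quarter_end = check_quarter(quarter_end, "quarter_end"),
      seed = as.integer(seed), extra_drugs_mean = as.numeric(extra_drugs_mean),
      country_levels = country_levels / sum(country_levels),
      indication_levels = indication_levels / sum(indication_levels),
      outcome_probs = outcome_probs
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_reports) || cfg$n_reports < 1) {
    stop("configuration error: n_reports must be >= 1", call. = FALSE)
  }
  if (cfg$n_drugs < 1 || cfg$n_events < 1) {
    stop("configuration error: vocabulary sizes must be positive", call. = FALSE)
  }
  for (nm in c("background_drug_rates", "background_event_rates")) {
    p <- cfg[[nm]]
    n_expect <- if (nm == "background_drug_rates") cfg$n_drugs else cfg$n_events
    if (length(p) != n_expect) {
      stop("configuration error: ", nm, " must have length ", n_expect, call. = FALSE)
    }
    if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("configuration error: ", nm, " must be a probability vector summing to 1",
        call. = FALSE
      )
    }
  }
  if (cfg$events_per_report_mean < 1) {
    stop("configuration error: events_per_report_mean must be >= 1", call. = FALSE)
  }
  rates <- c(cfg$missingness, cfg$duplicate_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("configuration error: missingness and duplicate_rate must lie in [0, 1]",
      call. = FALSE
    )
  }
  if (!all(c("sex", "age", "country") %in% names(cfg$missingness))) {
    stop("configuration error: missingness needs sex, age, country entries", call. = FALSE)
  }
  for (s in cfg$signals) {
    if (!inherits(s, "signal_spec")) {
      stop("configuration error: signals must be signal_spec objects", call. = FALSE)
    }
    if (s$drug_id < 1 || s$drug_id > cfg$n_drugs ||
      s$event_id < 1 || s$event_id > cfg$n_events) {
      stop("configuration error: signal references unknown drug or event id", call. = FALSE)
    }
  }
  if (quarter_index(cfg$quarter_start[1], cfg$quarter_start[2]) >
    quarter_index(cfg$quarter_end[1], cfg$quarter_end[2])) {
    stop("configuration error: quarter_start must not exceed quarter_end", call. = FALSE)
  }
  cfg
}

drug_name <- function(i) sprintf("drug_%03d", as.integer(i))
pt_name <- function(i) sprintf("pt_%03d", as.integer(i))
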