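#' Generate a FAERS-like collection of spontaneous reports
#'
#' Samples reports under a fully specified scheme so that every downstream
#' statistic has a closed-form oracle (see [expected_counts()]):
#' each report draws one primary-suspect (PS) drug from the drug popularity
#' vector, an event count `k ~ 1 + Geometric(1/mean)`, and `k` i.i.d. PTs from
#' the event distribution conditional on the PS drug (background rates, with
#' any injected signal's PT multiplied by its `rr` and the vector
#' renormalized); the report's reaction set is the distinct PTs drawn.
#' Non-PS co-reported drugs, demographics with an explicit `"unknown"`
#' sentinel, serious-outcome codes, receipt quarter, and duplicate case
#' versions are then attached.
#'
#' @param config a [sim_config()].
#' @return a [report_store()]; `n_reports` distinct case ids, plus duplicate
#'   second versions for a `duplicate_rate` fraction of cases. Byte-identical
#'   across runs for a fixed `config$seed`.
#' @export
generate_reports <- function(config) {
  config <- validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_reports
  ps <- sample.int(config$n_drugs, n, replace = TRUE, prob = config$background_drug_rates)
  pr_geom <- 1 / config$events_per_report_mean
  k <- 1L + stats::rgeom(n, prob = pr_geom)

  # reaction sets: group reports by conditional event distribution (drugs with
  # signals each get their own tilted vector; all others share the background)
  signal_drugs <- unique(vapply(config$signals, `[[`, integer(1), "drug_id"))
  reactions <- vector("list", n)
  groups <- split(seq_len(n), ifelse(ps %in% signal_drugs, ps, 0L))
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    g <- as.integer(gname)
    p <- event_dist_given_drug(config, g) # g = 0 -> background
    draws <- sample.int(config$n_events, sum(k[idx]), replace = TRUE, prob = p)
    per_report <- split(draws, rep.int(seq_along(idx), k[idx]))
    reactions[idx] <- lapply(per_report, function(e) pt_name(sort(unique(e))))
  }

  # non-PS co-medications (roles SS/C/I); duplicates of the PS drug dropped
  m_extra <- stats::rpois(n, config$extra_drugs_mean)
  extra <- sample.int(config$n_drugs, sum(m_extra),
    replace = TRUE,
    prob = config$background_drug_rates
  )
  extra_roles <- sample(c("SS", "C", "I"), sum(m_extra),
    replace = TRUE,
    prob = c(0.3, 0.6, 0.1)
  )
  split_idx <- rep.int(seq_len(n), m_extra)
  extra_by_report <- split(data.frame(d = extra, r = extra_roles), factor(split_idx, seq_len(n)))
  drug_names <- vector("list", n)
  drug_roles <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- extra_by_report[[i]]
    keep <- ex$d != ps[i]
    drug_names[[i]] <- c(drug_name(ps[i]), drug_name(ex$d[keep]))
    drug_roles[[i]] <- c("PS", ex$r[keep])
  }

  q_lo <- quarter_index(config$quarter_start[1], config$quarter_start[2])
  q_hi <- quarter_index(config$quarter_end[1], config$quarter_end[2])
  qidx <- sample(q_lo:q_hi, n, replace = TRUE)
  yq <- index_to_quarter(qidx)

  sex <- draw_categorical(n, c(female = 14, male = 9), config$missingness["sex"])
  age <- draw_categorical(n, c(under18 = 8, "18plus" = 7), config$missingness["age"])
  country <- draw_categorical(n, config$country_levels, config$missingness["country"])
  indication <- draw_categorical(n, config$indication_levels, 0)

  oc <- matrix(stats::runif(n * length(config$outcome_probs)), nrow = n)
  oc <- sweep(oc, 2, config$outcome_probs, "<")
  colnames(oc) <- names(config$outcome_probs)
  outcomes <- apply(oc, 1, function(row) sort(colnames(oc)[row]), simplify = FALSE)

  reports <- tibble::tibble(
    case_id = sprintf("C%07d", seq_len(n)), version = 1L,
    year = yq[, "year"], quarter = yq[, "q"],
    sex = sex, age_group = age, country = country, indication = indication,
    drug_names = drug_names, drug_roles = drug_roles,
    reactions = reactions, outcomes = outcomes
  )

  n_dup <- as.integer(round(config$duplicate_rate * n))
  if (n_dup > 0) {
    dup_idx <- sort(sample.int(n, n_dup))
    dups <- reports[dup_idx, ]
    dups$version <- 2L
    # follow-up versions may revise demographics; resample sex under the same
    # missingness so deduplication is exercised on genuinely differing rows
    dups$sex <- draw_categorical(n_dup, c(female = 14, male = 9), config$missingness["sex"])
    reports <- dplyr::bind_rows(reports, dups)
  }

  report_store(reports, provenance = sprintf("simulated (seed %d)", config$seed))
}

# event distribution conditional on PS drug g; g = 0 means no-signal background
event_dist_given_drug <- function(config, g) {
  p <- config$background_event_rates
  if (g > 0) {
    for (s in config$signals) {
      if (s$drug_id == g) p[s$event_id] <- p[s$event_id] * s$rr
    }
  }
  p / sum(p)
}

# P(PT e appears in a report | PS drug g) under the generator's scheme:
# 1 - E[(1-p)^k] with k ~ 1 + Geom(pr), closed form pr(1-p) / (1-(1-pr)(1-p))
prob_event_in_report <- function(config, g, e) {
  p <- event_dist_given_drug(config, g)[e]
  pr <- 1 / config$events_per_report_mean
  1 - pr * (1 - p) / (1 - (1 - pr) * (1 - p))
}

#' Expected 2x2 contingency table under the simulator
#'
#' Closed-form expectation of the (a, b, c, d) cells for one (drug, event)
#' pair under the sampling scheme of [generate_reports()], before duplication.
#' Serves as the analytic oracle for convergence tests of the empirical
#' tables.
#'
#' @param config a [sim_config()].
#' @param pair integer vector `c(drug_id, event_id)`.
#' @return named numeric vector `c(a, b, c, d)`; sums to `config$n_reports`.
#' @export
expected_counts <- function(config, pair) {
  config <- validate_sim_config(config)
  if (length(pair) != 2 || pair[1] < 1 || pair[1] > config$n_drugs ||
    pair[2] < 1 || pair[2] > config$n_events) {
    stop("lookup error: unknown (drug_id, event_id) pair", call. = FALSE)
  }
  g <- as.integer(pair[1])
  e <- as.integer(pair[2])
  n <- config$n_reports
  p_drug <- config$background_drug_rates
  signal_drugs <- unique(vapply(config$signals, `[[`, integer(1), "drug_id"))
  p_event_given <- vapply(seq_len(config$n_drugs), function(gg) {
    prob_event_in_report(config, if (gg %in% signal_drugs) gg else 0L, e)
  }, numeric(1))

  a <- n * p_drug[g] * p_event_given[g]
  b <- n * p_drug[g] - a
  c_ <- n * sum(p_drug[-g] * p_event_given[-g])
  d <- n - a - b - c_
  c(a = a, b = b, c = c_, d = d)
}

#' Build a synthetic MedDRA-style hierarchy for a simulated vocabulary
#'
#' Every simulated PT is assigned to exactly one system organ class (SOC) by
#' cycling PT indices through the `n_socs` classes; standardized query (SMQ)
#' subsets are taken verbatim from `smq_specs`.
#'
#' @param config a [sim_config()] (supplies the PT vocabulary size).
#' @param n_socs number of SOCs; must not exceed `config$n_events`.
#' @param smq_specs named list: SMQ name -> integer PT ids (or PT names).
#' @return a [meddra_hierarchy()].
#' @export
make_meddra <- function(config, n_socs = 10, smq_specs = list()) {
  config <- validate_sim_config(config)
  if (n_socs < 1 || n_socs > config$n_events) {
    stop("configuration error: need 1 <= n_socs <= n_events", call. = FALSE)
  }
  pts <- pt_name(seq_len(config$n_events))
  socs <- sprintf("soc_%02d", (seq_len(config$n_events) - 1L) %% as.integer(n_socs) + 1L)
  pt_to_soc <- stats::setNames(socs, pts)
  smq_members <- lapply(smq_specs, function(members) {
    if (is.numeric(members)) members <- pt_name(members)
    if (length(members) == 0) {
      stop("configuration error: SMQ must have at least one member PT", call. = FALSE)
    }
    sort(unique(members))
  })
  meddra_hierarchy(pt_to_soc, smq_members)
}

draw_categorical <- function(n, weights, p_unknown) {
  out <- rep(UNKNOWN, n)
  known <- stats::runif(n) >= p_unknown
  if (any(known)) {
    out[known] <- sample(names(weights), sum(known),
      replace = TRUE,
      prob = weights / sum(weights)
    )
  }
  out
}
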