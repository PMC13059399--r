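# shared fixture builders -- everything is constructed in code

# compact hand-built store: each report described as
# list(id, v = version, yq = c(year, quarter), drugs = c(name = role),
#      pts = character, sex/age/country/indication/outcomes optional)
make_store <- function(...) {
  specs <- list(...)
  rows <- lapply(specs, function(s) {
    tibble::tibble(
      case_id = s$id,
      version = as.integer(s$v %||% 1L),
      year = as.integer((s$yq %||% c(2020, 1))[1]),
      quarter = as.integer((s$yq %||% c(2020, 1))[2]),
      sex = s$sex %||% "unknown",
      age_group = s$age %||% "unknown",
      country = s$country %||% "unknown",
      indication = s$indication %||% "unknown",
      drug_names = list(names(s$drugs %||% c(burosumab = "PS"))),
      drug_roles = list(unname(s$drugs %||% c(burosumab = "PS"))),
      reactions = list(sort(s$pts %||% "pt_001")),
      outcomes = list(s$outcomes %||% character())
    )
  })
  report_store(dplyr::bind_rows(rows), provenance = "test fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hierarchy over pt_001..pt_010: two SOCs (odd ids -> soc_01, even -> soc_02),
# one SMQ covering pt_003/pt_005/pt_007
tiny_hierarchy <- function() {
  pts <- sprintf("pt_%03d", 1:10)
  meddra_hierarchy(
    stats::setNames(ifelse(1:10 %% 2 == 1, "soc_01", "soc_02"), pts),
    list(smq_tox = sprintf("pt_%03d", c(3, 5, 7)))
  )
}

# small but nontrivial simulated dataset reused across tests
tiny_sim_config <- function(seed = 11, signals = list(), n_reports = 2000) {
  sim_config(
    n_reports = n_reports, n_drugs = 6, n_events = 20,
    events_per_report_mean = 1.5, duplicate_rate = 0.05,
    signals = signals, seed = seed
  )
}

# brute-force contingency counts: double loop over reports x labels
brute_force_tables <- function(store, drug, level, h) {
  r <- store$reports
  n <- nrow(r)
  ps <- vapply(
    seq_len(n),
    function(i) any(r$drug_names[[i]] == drug & r$drug_roles[[i]] == "PS"),
    logical(1)
  )
  label_sets <- lapply(r$reactions, event_labels, h = h, level = level)
  labels <- setdiff(
    sort(unique(unlist(label_sets))),
    switch(level, SOC = "unmapped", SMQ = "NA", character())
  )
  out <- lapply(labels, function(lab) {
    has <- vapply(label_sets, function(s) lab %in% s, logical(1))
    data.frame(
      label = lab, a = sum(ps & has), b = sum(ps & !has),
      c = sum(!ps & has), d = sum(!ps & !has)
    )
  })
  do.call(rbind, out)
}
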