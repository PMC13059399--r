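# FAERS-style dollar-delimited table set.
#
# Five tables keyed by primaryid (caseid concatenated with version via "."):
#   DEMO  primaryid$caseid$caseversion$fda_dt$sex$age_grp$occr_country
#   DRUG  primaryid$drugname$role_cod
#   REAC  primaryid$pt
#   OUTC  primaryid$outc_cod
#   INDI  primaryid$indi_pt
# fda_dt is YYYYMMDD; the receipt quarter is derived from it by calendar
# quarter. Sex/age/country use FAERS-flavoured codes (F/M/UNK, LT18/GE18/UNK)
# and outcomes the standard OUTC codes (DE, LT, HO, DS, OT). A report with an
# unknown outcome simply has no OUTC rows; likewise INDI for an unknown
# indication.

SEX_TO_FAERS <- c(female = "F", male = "M", unknown = "UNK")
AGE_TO_FAERS <- c(under18 = "LT18", "18plus" = "GE18", unknown = "UNK")
OUTC_TO_FAERS <- c(
  death = "DE", life_threatening = "LT", hospitalization = "HO",
  disability = "DS", other = "OT"
)

#' Write a report store as a FAERS-style dollar-delimited table set
#'
#' @param store a [report_store()].
#' @param dir output directory; files `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`, `INDI.txt` are (over)written there.
#' @return invisibly, a named vector of the five paths.
#' @export
write_faers_tables <- function(store, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  r <- store$reports
  pid <- paste(r$case_id, r$version, sep = ".")
  mo <- sprintf("%02d", (r$quarter - 1L) * 3L + 1L)
  demo <- data.frame(
    primaryid = pid, caseid = r$case_id, caseversion = r$version,
    fda_dt = paste0(r$year, mo, "01"),
    sex = unname(SEX_TO_FAERS[r$sex]),
    age_grp = unname(AGE_TO_FAERS[r$age_group]),
    occr_country = ifelse(r$country == UNKNOWN, "UNK", r$country)
  )
  drug <- data.frame(
    primaryid = rep(pid, lengths(r$drug_names)),
    drugname = unlist(r$drug_names, use.names = FALSE),
    role_cod = unlist(r$drug_roles, use.names = FALSE)
  )
  reac <- data.frame(
    primaryid = rep(pid, lengths(r$reactions)),
    pt = unlist(r$reactions, use.names = FALSE)
  )
  outc <- data.frame(
    primaryid = rep(pid, lengths(r$outcomes)),
    outc_cod = unname(OUTC_TO_FAERS[unlist(r$outcomes, use.names = FALSE)])
  )
  if (!nrow(outc)) outc <- data.frame(primaryid = character(), outc_cod = character())
  has_indi <- r$indication != UNKNOWN
  indi <- data.frame(primaryid = pid[has_indi], indi_pt = r$indication[has_indi])

  paths <- c(
    DEMO = file.path(dir, "DEMO.txt"), DRUG = file.path(dir, "DRUG.txt"),
    REAC = file.path(dir, "REAC.txt"), OUTC = file.path(dir, "OUTC.txt"),
    INDI = file.path(dir, "INDI.txt")
  )
  tabs <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc, INDI = indi)
  for (nm in names(paths)) {
    utils::write.table(tabs[[nm]], paths[nm],
      sep = "$", quote = FALSE,
      row.names = FALSE, fileEncoding = "UTF-8"
    )
  }
  invisible(paths)
}

read_dollar_table <- function(path, required_cols) {
  tab <- utils::read.table(path,
    sep = "$", header = TRUE, colClasses = "character",
    quote = "", comment.char = "", fileEncoding = "UTF-8"
  )
  missing <- setdiff(required_cols, names(tab))
  if (length(missing)) {
    stop("table ", basename(path), " lacks column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tab
}

#' Read a FAERS-style dollar-delimited table set into a report store
#'
#' DEMO, DRUG and REAC are mandatory; OUTC and INDI optional. Reports with no
#' reaction rows are dropped with a warning (spontaneous-report extracts are
#' dirty by nature). Malformed DEMO rows (bad date or caseversion) are skipped
#' with a warning, but more than 10% malformed rows is an error.
#'
#' @param paths named list/vector with entries `DEMO`, `DRUG`, `REAC` and
#'   optionally `OUTC`, `INDI`; alternatively a directory produced by
#'   [write_faers_tables()].
#' @param synonyms optional drug-synonym map passed to
#'   [normalize_drug_name()]; applied to every drug name.
#' @return a [report_store()].
#' @export
read_faers_tables <- function(paths, synonyms = NULL) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    paths <- stats::setNames(
      file.path(paths, paste0(c("DEMO", "DRUG", "REAC", "OUTC", "INDI"), ".txt")),
      c("DEMO", "DRUG", "REAC", "OUTC", "INDI")
    )
    paths <- paths[file.exists(paths)]
  }
  for (nm in c("DEMO", "DRUG", "REAC")) {
    if (!nm %in% names(paths) || !file.exists(paths[[nm]])) {
      stop("I/O error: mandatory table ", nm, " missing", call. = FALSE)
    }
  }
  demo <- read_dollar_table(paths[["DEMO"]], c(
    "primaryid", "caseid", "caseversion",
    "fda_dt", "sex", "age_grp", "occr_country"
  ))
  drug <- read_dollar_table(paths[["DRUG"]], c("primaryid", "drugname", "role_cod"))
  reac <- read_dollar_table(paths[["REAC"]], c("primaryid", "pt"))
  outc <- if ("OUTC" %in% names(paths) && file.exists(paths[["OUTC"]])) {
    read_dollar_table(paths[["OUTC"]], c("primaryid", "outc_cod"))
  } else {
    data.frame(primaryid = character(), outc_cod = character())
  }
  indi <- if ("INDI" %in% names(paths) && file.exists(paths[["INDI"]])) {
    read_dollar_table(paths[["INDI"]], c("primaryid", "indi_pt"))
  } else {
    data.frame(primaryid = character(), indi_pt = character())
  }

  version <- suppressWarnings(as.integer(demo$caseversion))
  dt_ok <- grepl("^[0-9]{8}$", demo$fda_dt)
  bad <- is.na(version) | version < 0 | !dt_ok
  if (any(bad)) {
    if (mean(bad) > 0.10) {
      stop("I/O error: >10% of DEMO rows malformed", call. = FALSE)
    }
    warning(sum(bad), " malformed DEMO row(s) skipped")
    demo <- demo[!bad, , drop = FALSE]
    version <- version[!bad]
  }
  year <- as.integer(substr(demo$fda_dt, 1, 4))
  month <- as.integer(substr(demo$fda_dt, 5, 6))
  quarter <- (month - 1L) %/% 3L + 1L

  drug$drugname <- normalize_drug_name(drug$drugname, synonyms)
  role <- drug$role_cod
  if (any(!role %in% ROLE_LEVELS)) {
    warning("unrecognized role code(s) treated as concomitant (C)")
    role[!role %in% ROLE_LEVELS] <- "C"
  }
  drug$role_cod <- role

  sex_back <- stats::setNames(names(SEX_TO_FAERS), SEX_TO_FAERS)
  age_back <- stats::setNames(names(AGE_TO_FAERS), AGE_TO_FAERS)
  outc_back <- stats::setNames(names(OUTC_TO_FAERS), OUTC_TO_FAERS)

  pid <- demo$primaryid
  reac_by <- split(reac$pt, factor(reac$primaryid, pid))
  drug_by_name <- split(drug$drugname, factor(drug$primaryid, pid))
  drug_by_role <- split(drug$role_cod, factor(drug$primaryid, pid))
  outc_by <- split(unname(outc_back[outc$outc_cod]), factor(outc$primaryid, pid))
  indi_by <- split(indi$indi_pt, factor(indi$primaryid, pid))

  reactions <- lapply(reac_by, function(x) sort(unique(x)))
  has_reac <- lengths(reactions) > 0
  if (any(!has_reac)) {
    warning(sum(!has_reac), " report(s) without reaction rows dropped")
  }
  indication <- vapply(indi_by, function(x) if (length(x)) x[1] else UNKNOWN, character(1))

  reports <- tibble::tibble(
    case_id = demo$caseid, version = version, year = year, quarter = quarter,
    sex = unname(sex_back[demo$sex]),
    age_group = unname(age_back[demo$age_grp]),
    country = ifelse(demo$occr_country == "UNK", UNKNOWN, demo$occr_country),
    indication = unname(indication),
    drug_names = unname(drug_by_name), drug_roles = unname(drug_by_role),
    reactions = unname(reactions),
    outcomes = unname(lapply(outc_by, function(x) sort(unique(x))))
  )[has_reac, ]
  reports$sex[is.na(reports$sex)] <- UNKNOWN
  reports$age_group[is.na(reports$age_group)] <- UNKNOWN
  report_store(reports, provenance = paste("faers tables:", dirname(paths[["DEMO"]])))
}
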