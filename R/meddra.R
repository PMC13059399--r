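#' Construct an event hierarchy
#'
#' Holds the two MedDRA-style mappings the pipeline aggregates over: a total
#' PT -> SOC map (every preferred term belongs to exactly one system organ
#' class) and named SMQ membership sets (a standardized query is an arbitrary
#' PT subset, possibly crossing SOCs; a PT may belong to several SMQs or to
#' none).
#'
#' @param pt_to_soc named character vector, names = PTs, values = SOCs.
#' @param smq_members named list of character vectors of member PTs.
#' @return object of class `meddra_hierarchy`.
#' @export
meddra_hierarchy <- function(pt_to_soc, smq_members = list()) {
  if (is.null(names(pt_to_soc)) || anyDuplicated(names(pt_to_soc))) {
    stop("pt_to_soc must be a named vector with unique PT names", call. = FALSE)
  }
  smq_members <- lapply(smq_members, function(m) sort(unique(as.character(m))))
  unknown <- setdiff(unique(unlist(smq_members)), names(pt_to_soc))
  if (length(unknown)) {
    stop(
      "validation error: SMQ member PTs absent from PT->SOC map: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(lengths(smq_members) == 0)) {
    stop("validation error: every SMQ must be a nonempty PT set", call. = FALSE)
  }
  structure(list(pt_to_soc = pt_to_soc, smq_members = smq_members),
    class = "meddra_hierarchy"
  )
}

#' @export
print.meddra_hierarchy <- function(x, ...) {
  cat(
    "<meddra_hierarchy> ", length(x$pt_to_soc), " PTs, ",
    length(unique(x$pt_to_soc)), " SOCs, ", length(x$smq_members), " SMQs\n",
    sep = ""
  )
  invisible(x)
}

#' Load a hierarchy from TSV files
#'
#' @param pt_soc_path TSV with header columns `pt`, `soc` (one row per pair;
#'   duplicate rows are collapsed, conflicting SOCs for one PT are an error).
#' @param smq_path optional TSV with header columns `smq`, `pt`; may contain
#'   zero data rows. PTs named here must appear in the PT file.
#' @return a [meddra_hierarchy()].
#' @export
load_hierarchy <- function(pt_soc_path, smq_path = NULL) {
  pt_tab <- utils::read.delim(pt_soc_path, colClasses = "character")
  if (!all(c("pt", "soc") %in% names(pt_tab))) {
    stop("PT->SOC file must have columns pt, soc", call. = FALSE)
  }
  pt_tab <- unique(pt_tab[, c("pt", "soc")])
  dup <- unique(pt_tab$pt[duplicated(pt_tab$pt)])
  if (length(dup)) {
    stop(
      "validation error: conflicting SOC assignments for PT(s): ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  pt_to_soc <- stats::setNames(pt_tab$soc, pt_tab$pt)

  smq_members <- list()
  if (!is.null(smq_path)) {
    smq_tab <- utils::read.delim(smq_path, colClasses = "character")
    if (!all(c("smq", "pt") %in% names(smq_tab))) {
      stop("SMQ file must have columns smq, pt", call. = FALSE)
    }
    if (nrow(smq_tab)) {
      smq_members <- lapply(split(smq_tab$pt, smq_tab$smq), unique)
    }
  }
  meddra_hierarchy(pt_to_soc, smq_members)
}

#' Write a hierarchy to TSV files (inverse of [load_hierarchy()])
#' @param h a [meddra_hierarchy()].
#' @param pt_soc_path,smq_path output paths.
#' @return invisibly, the paths written.
#' @export
write_hierarchy <- function(h, pt_soc_path, smq_path) {
  utils::write.table(
    data.frame(pt = names(h$pt_to_soc), soc = unname(h$pt_to_soc)),
    pt_soc_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  smq_tab <- data.frame(
    smq = rep(names(h$smq_members), lengths(h$smq_members)),
    pt = unlist(h$smq_members, use.names = FALSE)
  )
  if (!nrow(smq_tab)) smq_tab <- data.frame(smq = character(), pt = character())
  utils::write.table(smq_tab, smq_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pt_soc_path, smq_path))
}

#' Event labels of a reaction set at a given aggregation level
#'
#' PT level returns the (sorted, distinct) reaction set itself; SOC level its
#' image under the PT -> SOC map; SMQ level every SMQ whose member set
#' intersects the reactions (possibly none -- such reports are later pooled
#' under the reserved `"NA"` row). A report contributes each label at most
#' once.
#'
#' @param reactions character vector of reaction PTs (or a single report row's
#'   `reactions` element).
#' @param h a [meddra_hierarchy()].
#' @param level one of `"PT"`, `"SOC"`, `"SMQ"`.
#' @return sorted character vector of labels (possibly empty at SMQ level).
#' @export
event_labels <- function(reactions, h, level = c("PT", "SOC", "SMQ")) {
  level <- match.arg(level)
  pts <- sort(unique(as.character(reactions)))
  switch(level,
    PT = pts,
    SOC = {
      socs <- h$pt_to_soc[pts]
      if (anyNA(socs)) {
        warning(
          "PT(s) not in hierarchy mapped to 'unmapped': ",
          paste(pts[is.na(socs)], collapse = ", ")
        )
        socs[is.na(socs)] <- "unmapped"
      }
      sort(unique(unname(socs)))
    },
    SMQ = {
      hit <- vapply(h$smq_members, function(m) any(pts %in% m), logical(1))
      sort(names(h$smq_members)[hit])
    }
  )
}

# long (row, label) pairs for a whole store, one row per distinct
# report x label; SMQ-less reports appear with the reserved "NA" label and
# unmapped PTs at SOC level with "unmapped" (both excluded from signal tables)
labels_long <- function(store, h, level) {
  reac <- store$reports$reactions
  nrep <- length(reac)
  if (nrep == 0) {
    return(tibble::tibble(row = integer(), label = character()))
  }
  long <- tibble::tibble(
    row = rep.int(seq_len(nrep), lengths(reac)),
    pt = unlist(reac, use.names = FALSE)
  )
  if (level == "PT") {
    out <- dplyr::distinct(long, .data$row, label = .data$pt)
  } else if (level == "SOC") {
    soc <- h$pt_to_soc[long$pt]
    soc[is.na(soc)] <- "unmapped"
    out <- dplyr::distinct(tibble::tibble(row = long$row, label = unname(soc)))
  } else if (level == "SMQ") {
    smq_tab <- tibble::tibble(
      pt = as.character(unlist(h$smq_members, use.names = FALSE)),
      label = as.character(rep(names(h$smq_members), lengths(h$smq_members)))
    )
    hits <- dplyr::distinct(dplyr::inner_join(long, smq_tab,
      by = "pt",
      relationship = "many-to-many"
    ), .data$row, .data$label)
    no_hit <- setdiff(seq_len(nrep), unique(hits$row))
    out <- dplyr::bind_rows(hits, tibble::tibble(row = no_hit, label = "NA"))
  } else {
    stop("level must be PT, SOC or SMQ", call. = FALSE)
  }
  out
}

reserved_labels <- function(level) {
  switch(level, SOC = "unmapped", SMQ = "NA", character())
}
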