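# CSV layout (canonical dialect)
#   individuals.csv: id, death_day, clutch_day, clutch_size[, estimated]
#     one row per clutch; an animal with no clutches gets one row with the
#     clutch fields empty; an empty death_day marks a censored animal.
#   cohort.csv: event ("death"|"clutch"), day, size (empty for deaths),
#     with a sidecar JSON file {"n0": ..., "label": ...}.

.canonical_cols <- c("id", "death_day", "clutch_day", "clutch_size")

resolve_dialect <- function(header, dialect = NULL) {
  map <- stats::setNames(.canonical_cols, .canonical_cols)
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || !all(names(dialect) %in% .canonical_cols))
      stop("`dialect` must be a named vector mapping canonical column names",
           call. = FALSE)
    map[names(dialect)] <- dialect
  }
  missing <- map[!(map %in% header)]
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  map
}

parse_int_col <- function(x, col, rows) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA
  out <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & (is.na(out) | x != as.character(out))
  if (any(bad))
    stop(sprintf("column %s: non-integer value '%s' at file row %d",
                 col, x[which(bad)[1]], rows[which(bad)[1]]), call. = FALSE)
  out
}

#' Read per-individual reproduction records from CSV
#'
#' @param path path to a CSV file with columns `id`, `death_day`,
#'   `clutch_day`, `clutch_size` (one row per clutch; empty clutch fields
#'   for animals that never reproduced; empty `death_day` for censored
#'   animals). An optional `estimated` column flags back-dated layings.
#' @param dialect optional named character vector mapping canonical column
#'   names to the headers actually used in the file, e.g.
#'   `c(clutch_day = "day_laid")`.
#' @return a list of [individual_record()] objects, clutches sorted by day,
#'   in order of first appearance of each id.
#' @export
read_individual_records <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, comment.char = "#")
  map <- resolve_dialect(names(raw), dialect)
  if (nrow(raw) == 0) return(list())
  rows <- seq_len(nrow(raw)) + 1L   # header is file row 1
  id <- trimws(raw[[map[["id"]]]])
  death <- parse_int_col(raw[[map[["death_day"]]]], map[["death_day"]], rows)
  cday <- parse_int_col(raw[[map[["clutch_day"]]]], map[["clutch_day"]], rows)
  csize <- parse_int_col(raw[[map[["clutch_size"]]]], map[["clutch_size"]], rows)
  est <- if ("estimated" %in% names(raw))
    trimws(raw$estimated) %in% c("TRUE", "true", "1") else rep(FALSE, nrow(raw))
  if (any(is.na(cday) != is.na(csize)))
    stop("clutch_day and clutch_size must be both present or both empty",
         call. = FALSE)
  out <- list()
  for (i in unique(id)) {
    sel <- id == i
    keep <- sel & !is.na(cday)
    dd <- unique(death[sel])
    if (length(dd) > 1)
      stop(sprintf("conflicting death_day values for id %s", i), call. = FALSE)
    out[[i]] <- individual_record(
      i, clutch_events(cday[keep], csize[keep], est[keep]), death_day = dd)
  }
  out
}

#' Write individual records to canonical CSV
#'
#' Inverse of [read_individual_records()]; `read` then `write` reproduces a
#' canonical file byte for byte.
#'
#' @param records list of [individual_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_individual_records <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (nrow(r$clutches) == 0)
      data.frame(id = r$id, death_day = r$death_day,
                 clutch_day = NA_integer_, clutch_size = NA_integer_,
                 estimated = FALSE)
    else
      data.frame(id = r$id, death_day = r$death_day,
                 clutch_day = r$clutches$day, clutch_size = r$clutches$size,
                 estimated = r$clutches$estimated)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(id = character(), death_day = integer(),
                                    clutch_day = integer(),
                                    clutch_size = integer(),
                                    estimated = logical())
  if (!any(df$estimated)) df$estimated <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

cohort_meta_path <- function(path) sub("\\.csv$", ".json", path)

#' Read an anonymized cohort log from CSV plus JSON sidecar
#'
#' @param path path to a CSV with columns `event` (`"death"` or
#'   `"clutch"`), `day`, and `size` (empty for deaths).
#' @param meta_path path to the JSON header `{n0, label}`; defaults to
#'   `path` with the `.csv` extension replaced by `.json`.
#' @return a [cohort_log()].
#' @export
read_cohort_log <- function(path, meta_path = cohort_meta_path(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (!file.exists(meta_path))
    stop(sprintf("cohort sidecar not found: %s", meta_path), call. = FALSE)
  meta <- jsonlite::read_json(meta_path)
  if (is.null(meta$n0)) stop("cohort sidecar lacks n0", call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, comment.char = "#")
  need <- c("event", "day", "size")
  if (!all(need %in% names(raw)))
    stop(sprintf("missing required column(s): %s",
                 paste(setdiff(need, names(raw)), collapse = ", ")),
         call. = FALSE)
  rows <- seq_len(nrow(raw)) + 1L
  day <- parse_int_col(raw$day, "day", rows)
  size <- parse_int_col(raw$size, "size", rows)
  ev <- trimws(raw$event)
  if (!all(ev %in% c("death", "clutch")))
    stop("event column must be 'death' or 'clutch'", call. = FALSE)
  is_cl <- ev == "clutch"
  if (any(is.na(size[is_cl])))
    stop("clutch rows must carry a size", call. = FALSE)
  cohort_log(n0 = meta$n0,
             clutches = clutch_events(day[is_cl], size[is_cl]),
             death_days = day[!is_cl],
             label = if (is.null(meta$label)) NULL else meta$label)
}

#' Write a cohort log to canonical CSV plus JSON sidecar
#'
#' @param log a [cohort_log()].
#' @param path output CSV path.
#' @param meta_path sidecar JSON path (default: `path` with `.json`).
#' @return `path`, invisibly.
#' @export
write_cohort_log <- function(log, path, meta_path = cohort_meta_path(path)) {
  df <- rbind(
    if (length(log$death_days))
      data.frame(event = "death", day = log$death_days, size = NA_integer_)
    else NULL,
    if (nrow(log$clutches))
      data.frame(event = "clutch", day = log$clutches$day,
                 size = log$clutches$size)
    else NULL)
  if (is.null(df))
    df <- data.frame(event = character(), day = integer(), size = integer())
  df <- df[order(df$day), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  meta <- list(n0 = log$n0)
  if (!is.null(log$label)) meta$label <- log$label
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
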