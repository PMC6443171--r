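#' Construct a table of clutch events
#'
#' A clutch event is one egg-laying episode: the day of deposition (counted
#' in whole days from day 0, the focal animals' own deposition as zygotes)
#' and the number of embryos in the clutch.
#'
#' @param day integer vector of deposition days (>= 0).
#' @param size integer vector of embryo counts (>= 1).
#' @param estimated logical vector; `TRUE` when the laying date was
#'   back-estimated from the developmental stage rather than observed.
#' @return a `data.frame` with columns `day`, `size`, `estimated`.
#' @export
clutch_events <- function(day = integer(), size = integer(),
                          estimated = FALSE) {
  day <- as.integer(day)
  size <- as.integer(size)
  n <- length(day)
  if (length(size) != n)
    stop("`day` and `size` must have equal length", call. = FALSE)
  estimated <- rep_len(as.logical(estimated), n)
  data.frame(day = day, size = size, estimated = estimated)
}

#' Construct the reproductive record of one isolated individual
#'
#' @param id identifier (coerced to character).
#' @param clutches a data.frame as returned by [clutch_events()].
#' @param death_day integer day of death, or `NA` for a censored animal
#'   (still alive, or lost, when recording ended).
#' @param sort sort clutches by day (stable)? Default `TRUE`.
#' @return an object of class `individual_record`.
#' @export
individual_record <- function(id, clutches = clutch_events(),
                              death_day = NA, sort = TRUE) {
  if (!all(c("day", "size") %in% names(clutches)))
    stop("`clutches` needs columns day and size", call. = FALSE)
  if (is.null(clutches$estimated)) clutches$estimated <- FALSE
  clutches <- clutches[, c("day", "size", "estimated")]
  if (sort && nrow(clutches) > 1)
    clutches <- clutches[order(clutches$day), , drop = FALSE]
  rownames(clutches) <- NULL
  structure(
    list(id = as.character(id),
         death_day = if (is.na(death_day)) NA_integer_ else as.integer(death_day),
         censored = is.na(death_day),
         clutches = clutches),
    class = "individual_record")
}

#' @export
print.individual_record <- function(x, ...) {
  cat(sprintf("<individual_record> id=%s, %d clutch(es), death_day=%s%s\n",
              x$id, nrow(x$clutches),
              if (x$censored) "censored" else x$death_day,
              if (nrow(x$clutches))
                sprintf(", days [%s]", paste(x$clutches$day, collapse = ","))
              else ""))
  invisible(x)
}

#' Construct an anonymized cohort log
#'
#' The history of an interbreeding group observed collectively: the initial
#' group size, the days on which deaths were noted, and the clutch events,
#' which cannot be attributed to particular parents.
#'
#' An animal whose death was recorded on day `d` is counted as *present* on
#' day `d` (it was seen at that day's check); see [alive_at()].
#'
#' @param n0 initial cohort size (integer >= 1).
#' @param clutches data.frame as from [clutch_events()].
#' @param death_days integer vector of observed death days, at most `n0`
#'   long (survivors at the end of recording are simply absent).
#' @param label optional cohort label.
#' @param sort sort clutches by day (stable)? Default `TRUE`.
#' @return an object of class `cohort_log`.
#' @export
cohort_log <- function(n0, clutches = clutch_events(),
                       death_days = integer(), label = NULL, sort = TRUE) {
  n0 <- as.integer(n0)
  if (is.na(n0) || n0 < 1) stop("`n0` must be a positive integer", call. = FALSE)
  death_days <- as.integer(death_days)
  if (length(death_days) > n0)
    stop(sprintf("%d deaths recorded for a cohort of %d animals",
                 length(death_days), n0), call. = FALSE)
  if (is.null(clutches$estimated)) clutches$estimated <- FALSE
  clutches <- clutches[, c("day", "size", "estimated")]
  if (sort && nrow(clutches) > 1)
    clutches <- clutches[order(clutches$day), , drop = FALSE]
  rownames(clutches) <- NULL
  structure(
    list(n0 = n0, death_days = sort(death_days), clutches = clutches,
         label = label),
    class = "cohort_log")
}

#' @export
print.cohort_log <- function(x, ...) {
  cat(sprintf("<cohort_log>%s n0=%d, %d death(s), %d clutch(es), %d embryos\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n0, length(x$death_days), nrow(x$clutches),
              sum(x$clutches$size)))
  invisible(x)
}

#' Number of animals alive in a cohort on a given day
#'
#' Uses the last-seen-alive convention: an animal with `death_day == d` is
#' present on day `d`, so `alive_at(log, d) = n0 - #\{death_day < d\}`.
#'
#' @param log a [cohort_log()].
#' @param day integer day (vectorized).
#' @return integer vector of live counts.
#' @export
alive_at <- function(log, day) {
  vapply(as.integer(day),
         function(d) log$n0 - sum(log$death_days < d),
         integer(1))
}

new_validation_report <- function(id = character(), rule = character(),
                                  message = character()) {
  structure(data.frame(id = id, rule = rule, message = message,
                       stringsAsFactors = FALSE),
            class = c("validation_report", "data.frame"))
}

#' Validate records or a cohort log against the type invariants
#'
#' Returns a report listing every breach (empty data frame when the object
#' is well formed); it never throws.  Rules checked: non-negative integer
#' days, sizes >= 1, strictly increasing clutch days within an individual,
#' clutch days not after the recorded death day, and for cohort logs a
#' non-negative live count at every clutch day.
#'
#' @param x an `individual_record`, a list of them, or a `cohort_log`.
#' @param ... unused.
#' @return a `validation_report` data frame with columns `id`, `rule`,
#'   `message`.
#' @export
validate <- function(x, ...) UseMethod("validate")

#' @export
validate.individual_record <- function(x, ...) {
  bad <- function(rule, message)
    new_validation_report(x$id, rule, message)
  rep_ <- new_validation_report()
  cl <- x$clutches
  if (any(is.na(cl$day)) || any(cl$day < 0, na.rm = TRUE))
    rep_ <- rbind(rep_, bad("day_nonneg", "clutch days must be integers >= 0"))
  if (any(cl$size < 1, na.rm = TRUE) || any(is.na(cl$size)))
    rep_ <- rbind(rep_, bad("size_positive", "clutch sizes must be >= 1"))
  if (nrow(cl) > 1 && any(diff(cl$day) <= 0))
    rep_ <- rbind(rep_, bad("days_increasing",
                            "clutch days must be strictly increasing"))
  if (!x$censored && nrow(cl) && any(cl$day > x$death_day))
    rep_ <- rbind(rep_, bad("clutch_before_death",
                            sprintf("clutch on day %d after death day %d",
                                    max(cl$day), x$death_day)))
  rep_
}

#' @export
validate.list <- function(x, ...) {
  out <- lapply(x, validate)
  rep_ <- do.call(rbind, c(list(new_validation_report()), out))
  rownames(rep_) <- NULL
  rep_
}

#' @export
validate.cohort_log <- function(x, ...) {
  id <- if (is.null(x$label)) "cohort" else x$label
  bad <- function(rule, message) new_validation_report(id, rule, message)
  rep_ <- new_validation_report()
  cl <- x$clutches
  if (any(is.na(cl$day)) || any(cl$day < 0, na.rm = TRUE))
    rep_ <- rbind(rep_, bad("day_nonneg", "clutch days must be integers >= 0"))
  if (any(cl$size < 1, na.rm = TRUE) || any(is.na(cl$size)))
    rep_ <- rbind(rep_, bad("size_positive", "clutch sizes must be >= 1"))
  if (length(x$death_days) > x$n0)
    rep_ <- rbind(rep_, bad("deaths_le_n0", "more deaths than animals"))
  if (nrow(cl) && any(alive_at(x, cl$day) <= 0))
    rep_ <- rbind(rep_, bad("alive_nonneg",
                            "clutch recorded after the whole cohort died"))
  rep_
}
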