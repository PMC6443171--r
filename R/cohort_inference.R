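# Round assignment by the quota counting rule.  The inference rests on two
# assumptions: animals reared together breed in rough synchrony, and every
# animal in the cohort reproduces.  A round of egg laying opens with the
# first unassigned clutch; its quota is the number of animals alive on the
# opening day; the next quota clutches (in day order) belong to that round.
# The rule is deliberately simple and is itself the object of study: its
# failure modes (pre-round deaths inflating a quota, overlapping rounds)
# are measurable with the synthetic-data generator.

#' Partition a cohort's clutches into reproductive rounds
#'
#' @param log a valid [cohort_log()]; clutches are used in stable day
#'   order.
#' @return an object of class `round_assignment`: list with `labels`
#'   (1-based round index per clutch, in day order) and `rounds`, a
#'   data.frame with columns `round`, `open_day`, `quota`, `n`, `complete`.
#'   Zero clutches give an empty assignment.
#' @export
assign_rounds <- function(log) {
  stopifnot(inherits(log, "cohort_log"))
  days <- log$clutches$day
  m <- length(days)
  labels <- integer(m)
  rounds <- list()
  i <- 1L
  r <- 0L
  while (i <= m) {
    r <- r + 1L
    open <- days[i]
    quota <- max(1L, alive_at(log, open))  # guard: degenerate logs progress
    j <- min(i + quota - 1L, m)
    labels[i:j] <- r
    rounds[[r]] <- data.frame(round = r, open_day = open, quota = quota,
                              n = j - i + 1L, complete = (j - i + 1L) == quota)
    i <- j + 1L
  }
  rounds <- if (length(rounds)) do.call(rbind, rounds) else
    data.frame(round = integer(), open_day = integer(), quota = integer(),
               n = integer(), complete = logical())
  structure(list(labels = labels, rounds = rounds), class = "round_assignment")
}

#' @export
print.round_assignment <- function(x, ...) {
  cat(sprintf("<round_assignment> %d clutch(es) in %d round(s)\n",
              length(x$labels), nrow(x$rounds)))
  if (nrow(x$rounds)) print.data.frame(x$rounds, row.names = FALSE)
  invisible(x)
}

#' Per-round timing and clutch-size summaries with confidence intervals
#'
#' Student-t intervals on the mean, `mean +/- t(n-1, 1-alpha/2) * sd/sqrt(n)`,
#' computed separately for deposition day and clutch size; omitted
#' (reported `NA`) for singleton rounds.
#'
#' @param assignment a [assign_rounds()] result for `log`.
#' @param log the [cohort_log()] the assignment was computed from.
#' @param ci_level confidence level (default 0.95).
#' @return data.frame with columns `round`, `n`, `quota`, `complete`,
#'   `day_mean`, `day_lo`, `day_hi`, `size_mean`, `size_lo`, `size_hi`.
#' @export
round_summaries <- function(assignment, log, ci_level = 0.95) {
  stopifnot(inherits(assignment, "round_assignment"), inherits(log, "cohort_log"))
  if (length(assignment$labels) != nrow(log$clutches))
    stop("assignment does not match log (clutch counts differ)", call. = FALSE)
  ci <- function(x) {
    n <- length(x)
    if (n < 2) return(c(NA_real_, NA_real_))
    hw <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
    mean(x) + c(-hw, hw)
  }
  rows <- lapply(seq_len(nrow(assignment$rounds)), function(r) {
    sel <- assignment$labels == r
    d <- log$clutches$day[sel]
    s <- log$clutches$size[sel]
    dci <- ci(d); sci <- ci(s)
    data.frame(round = r, n = sum(sel), quota = assignment$rounds$quota[r],
               complete = assignment$rounds$complete[r],
               day_mean = mean(d), day_lo = dci[1], day_hi = dci[2],
               size_mean = mean(s), size_lo = sci[1], size_hi = sci[2])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(round = integer(), n = integer(), quota = integer(),
               complete = logical(), day_mean = numeric(), day_lo = numeric(),
               day_hi = numeric(), size_mean = numeric(), size_lo = numeric(),
               size_hi = numeric())
  structure(out, class = c("round_summaries", "data.frame"))
}

#' Pool individual records into an anonymized pseudo-cohort
#'
#' Merges the clutch events of individuals reared in isolation into one
#' cohort-style log (parent identities dropped, events day-sorted with
#' stable ties), as if the group had been observed collectively.  The true
#' parentage and per-individual clutch indices are retained in the `truth`
#' attribute so that round-inference error can be measured against them.
#'
#' @param records list of [individual_record()] objects sharing the
#'   day-0-at-birth convention.
#' @return a [cohort_log()] with `n0 = length(records)`; `attr(, "truth")`
#'   is a data.frame `day`, `size`, `parent_id`, `clutch_index` in the same
#'   row order as the log's clutches.
#' @export
build_pseudo_cohort <- function(records) {
  truth <- do.call(rbind, c(list(
    data.frame(day = integer(), size = integer(), parent_id = character(),
               clutch_index = integer())),
    lapply(records, function(r)
      if (nrow(r$clutches))
        data.frame(day = r$clutches$day, size = r$clutches$size,
                   parent_id = r$id, clutch_index = seq_len(nrow(r$clutches)))
      else NULL)))
  ord <- order(truth$day)   # stable: ties keep input (per-record) order
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  deaths <- unlist(lapply(records, function(r)
    if (r$censored) NULL else r$death_day))
  log <- cohort_log(n0 = length(records),
                    clutches = clutch_events(truth$day, truth$size),
                    death_days = if (is.null(deaths)) integer() else deaths,
                    sort = FALSE)
  attr(log, "truth") <- truth
  log
}

#' Histogram of clutch depositions in fixed-width day bins
#'
#' Half-open bins `[0, w), [w, 2w), ...`; counts sum to the number of
#' clutches.
#'
#' @param log a [cohort_log()].
#' @param width bin width in days (integer >= 1; default 5).
#' @return data.frame with columns `bin_start`, `count`; attribute `width`.
#' @export
bin_depositions <- function(log, width = 5L) {
  width <- as.integer(width)
  if (is.na(width) || width < 1) stop("`width` must be >= 1", call. = FALSE)
  days <- log$clutches$day
  if (length(days) == 0) {
    out <- data.frame(bin_start = integer(), count = integer())
  } else {
    idx <- days %/% width + 1L
    counts <- tabulate(idx, nbins = max(idx))
    out <- data.frame(bin_start = (seq_along(counts) - 1L) * width,
                      count = counts)
  }
  structure(out, width = width, class = c("deposition_histogram", "data.frame"))
}

#' Daily survival and cumulative production series for a cohort
#'
#' The plot-ready series behind survival / aggregate-production figures:
#' for every day from 0 to the last recorded event, the number of animals
#' alive (last-seen-alive convention, see [alive_at()]), the cumulative
#' number of clutches deposited, and the cumulative number of embryos.
#'
#' @param log a [cohort_log()].
#' @return data.frame with columns `day`, `alive`, `cum_clutches`,
#'   `cum_embryos`.
#' @export
cohort_series <- function(log) {
  last <- max(c(0L, log$clutches$day, log$death_days))
  day <- 0:last
  cum_cl <- vapply(day, function(d) sum(log$clutches$day <= d), integer(1))
  cum_em <- vapply(day, function(d)
    sum(log$clutches$size[log$clutches$day <= d]), integer(1))
  data.frame(day = day, alive = alive_at(log, day),
             cum_clutches = cum_cl, cum_embryos = cum_em)
}

#' Fraction of clutches misassigned by round inference
#'
#' Compares inferred round labels with ground-truth labels (e.g. the
#' per-individual clutch indices carried by [build_pseudo_cohort()] or the
#' synthetic generator).
#'
#' @param assignment a [assign_rounds()] result.
#' @param true_labels integer vector of true round labels, same length and
#'   row order as the assignment's labels.
#' @return the misassignment rate in `[0, 1]`.
#' @export
misassignment_rate <- function(assignment, true_labels) {
  if (length(assignment$labels) != length(true_labels))
    stop("label vectors differ in length", call. = FALSE)
  if (length(true_labels) == 0) return(0)
  mean(assignment$labels != true_labels)
}
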