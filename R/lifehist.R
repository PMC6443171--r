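# Summary statistics behind the per-clutch-number and interval tables.
# All statistics use the sample (n-1) standard deviation; a singleton
# group reports its value with sd = NA, matching how published tables
# print bare values for n = 1 rows.

sd_or_na <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

#' Per-clutch-number size statistics
#'
#' For each clutch index k (an individual's k-th laying), the number of
#' individuals that produced a k-th clutch and the mean, sample sd, min
#' and max of its embryo count.
#'
#' @param records list of [individual_record()] objects.
#' @return a data.frame with columns `k`, `n`, `mean`, `sd`, `min`, `max`,
#'   one row per clutch index present (empty for an empty record list).
#' @export
clutch_number_stats <- function(records) {
  kmax <- if (length(records)) max(vapply(records, function(r)
    nrow(r$clutches), integer(1))) else 0L
  rows <- lapply(seq_len(kmax), function(k) {
    sizes <- unlist(lapply(records, function(r)
      if (nrow(r$clutches) >= k) r$clutches$size[k] else NULL))
    data.frame(k = k, n = length(sizes), mean = mean(sizes),
               sd = sd_or_na(sizes), min = min(sizes), max = max(sizes))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(k = integer(), n = integer(), mean = numeric(),
               sd = numeric(), min = numeric(), max = numeric())
  structure(out, class = c("clutch_number_stats", "data.frame"))
}

#' Generation-time and inter-clutch interval statistics
#'
#' One row per interval: `ZD-C1` (deposition as a zygote to first clutch,
#' the egg-to-egg generation time, since birth is day 0) and `Ck-Ck+1` for
#' each consecutive pair observed.  The cumulative columns (`cum_*`)
#' summarize days from birth to the *later* clutch over the individuals
#' possessing it; `step_mean` is the mean of the per-individual differences
#' between the two consecutive clutch days (this is not in general the
#' difference of the cumulative means).
#'
#' @param records list of [individual_record()] objects; day 0 = birth.
#' @return data.frame with columns `label`, `n`, `cum_mean`, `cum_sd`,
#'   `cum_min`, `cum_max`, `step_mean`.
#' @export
interval_stats <- function(records) {
  rep_ <- validate(records)
  if (any(rep_$rule == "days_increasing"))
    stop("records contain unordered clutch days; see validate()", call. = FALSE)
  kmax <- if (length(records)) max(vapply(records, function(r)
    nrow(r$clutches), integer(1))) else 0L
  rows <- lapply(seq_len(kmax), function(k) {
    cum <- unlist(lapply(records, function(r)
      if (nrow(r$clutches) >= k) r$clutches$day[k] else NULL))
    step <- if (k == 1) NA_real_ else
      mean(unlist(lapply(records, function(r)
        if (nrow(r$clutches) >= k)
          r$clutches$day[k] - r$clutches$day[k - 1] else NULL)))
    data.frame(label = if (k == 1) "ZD-C1" else sprintf("C%d-C%d", k - 1, k),
               n = length(cum), cum_mean = mean(cum), cum_sd = sd_or_na(cum),
               cum_min = min(cum), cum_max = max(cum), step_mean = step)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), n = integer(), cum_mean = numeric(),
               cum_sd = numeric(), cum_min = numeric(), cum_max = numeric(),
               step_mean = numeric())
  structure(out, class = c("interval_stats", "data.frame"))
}

#' Reproductive capacity and schedule summary
#'
#' Reproductive capacity is the total number of young produced during one
#' individual's life.  The summary reports per-individual embryo totals and
#' clutch counts, lifespans, and post-last-clutch survival (days from the
#' last laying to death).  Censored animals count toward capacity means
#' (their observed totals are lower bounds) but are excluded from lifespan
#' and post-last-clutch survival means.
#'
#' @param records list of [individual_record()] objects.
#' @return an object of class `capacity_summary`: a list with
#'   `per_individual` (data.frame `id`, `total`, `n_clutches`, `death_day`,
#'   `censored`, `post_last`), and scalars `mean`, `max`, `total`,
#'   `clutches_mean`, `clutches_max`, `lifespan_mean`, `post_last_mean`.
#' @export
reproductive_capacity <- function(records) {
  per <- do.call(rbind, lapply(records, function(r) {
    nc <- nrow(r$clutches)
    data.frame(id = r$id, total = sum(r$clutches$size), n_clutches = nc,
               death_day = r$death_day, censored = r$censored,
               post_last = if (!r$censored && nc > 0)
                 r$death_day - r$clutches$day[nc] else NA_integer_)
  }))
  if (is.null(per))
    per <- data.frame(id = character(), total = integer(),
                      n_clutches = integer(), death_day = integer(),
                      censored = logical(), post_last = integer())
  rownames(per) <- NULL
  obs <- !per$censored
  structure(list(
    per_individual = per,
    mean = if (nrow(per)) mean(per$total) else NA_real_,
    max = if (nrow(per)) max(per$total) else NA_real_,
    total = sum(per$total),
    clutches_mean = if (nrow(per)) mean(per$n_clutches) else NA_real_,
    clutches_max = if (nrow(per)) max(per$n_clutches) else NA_real_,
    lifespan_mean = if (any(obs)) mean(per$death_day[obs]) else NA_real_,
    post_last_mean = if (any(!is.na(per$post_last)))
      mean(per$post_last, na.rm = TRUE) else NA_real_),
    class = "capacity_summary")
}

#' @export
print.capacity_summary <- function(x, ...) {
  cat(sprintf(paste0("<capacity_summary> %d individual(s): mean %.1f,",
                     " max %g, total %g embryos; %.2f clutches/individual\n"),
              nrow(x$per_individual), x$mean, x$max, x$total, x$clutches_mean))
  invisible(x)
}

#' Mean reproductive capacity from a per-clutch-number table
#'
#' Reconstructs the mean capacity (embryos per individual) from a published
#' per-clutch-number summary: the total is the sum over clutch indices of
#' (number of k-th clutches) x (mean k-th clutch size), divided by the
#' number of animals in the block.
#'
#' @param stats a [clutch_number_stats()] table (needs columns `n`, `mean`).
#' @param n_individuals number of animals the table describes (the block N).
#' @return list with `mean` (embryos/individual) and `total` (embryos).
#' @export
capacity_from_stats <- function(stats, n_individuals) {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1)
    stop("`n_individuals` must be a positive integer", call. = FALSE)
  total <- sum(stats$n * stats$mean)
  list(mean = total / n_individuals, total = total)
}
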