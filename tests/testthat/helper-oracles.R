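# Shared fixtures and independent brute-force oracles.  The oracles are
# written as direct transliterations of the definitions (explicit loops,
# no shared code with the implementation) so they can arbitrate.

rec <- function(id, days, sizes, death = NA) {
  individual_record(id, clutch_events(days, sizes), death_day = death)
}

# two-record fixture used across modules:
#   A: clutches day 50 (10 embryos) and 80 (30), died day 142
#   B: one clutch day 60 (20 embryos), died day 100
records_ab <- function() list(A = rec("A", c(50, 80), c(10, 30), 142),
                              B = rec("B", 60, 20, 100))

# Round assignment by literal re-execution of the counting rule: walk the
# day-sorted clutches; when no round is open, open one at the current
# clutch day with a quota equal to the number of animals whose recorded
# death day is >= that day (plus never-recorded survivors); close the
# round after quota clutches.
oracle_assign_rounds <- function(n0, death_days, clutch_days) {
  clutch_days <- sort(clutch_days)
  labels <- integer(length(clutch_days))
  round <- 0L
  remaining <- 0L
  for (i in seq_along(clutch_days)) {
    if (remaining == 0L) {
      round <- round + 1L
      d <- clutch_days[i]
      survivors <- n0 - length(death_days)
      present <- survivors + sum(death_days >= d)
      remaining <- max(1L, present)
    }
    labels[i] <- round
    remaining <- remaining - 1L
  }
  labels
}

# Per-clutch-number statistics recomputed from raw events with loops.
oracle_clutch_stats <- function(records) {
  out <- NULL
  k <- 1L
  repeat {
    sizes <- c()
    for (r in records)
      if (nrow(r$clutches) >= k) sizes <- c(sizes, r$clutches$size[k])
    if (length(sizes) == 0) break
    m <- sum(sizes) / length(sizes)
    s <- if (length(sizes) > 1)
      sqrt(sum((sizes - m)^2) / (length(sizes) - 1)) else NA_real_
    out <- rbind(out, data.frame(k = k, n = length(sizes), mean = m, sd = s,
                                 min = min(sizes), max = max(sizes)))
    k <- k + 1L
  }
  out
}

oracle_interval_stats <- function(records) {
  out <- NULL
  k <- 1L
  repeat {
    cum <- c(); step <- c()
    for (r in records)
      if (nrow(r$clutches) >= k) {
        cum <- c(cum, r$clutches$day[k])
        if (k > 1) step <- c(step, r$clutches$day[k] - r$clutches$day[k - 1])
      }
    if (length(cum) == 0) break
    m <- sum(cum) / length(cum)
    s <- if (length(cum) > 1)
      sqrt(sum((cum - m)^2) / (length(cum) - 1)) else NA_real_
    out <- rbind(out, data.frame(
      n = length(cum), cum_mean = m, cum_sd = s, cum_min = min(cum),
      cum_max = max(cum),
      step_mean = if (k == 1) NA_real_ else sum(step) / length(step)))
    k <- k + 1L
  }
  out
}

# Deterministic (point-mass) parameter set: 3 clutches at days 56/84/112,
# sizes 20/50/70, death 30 days after the last clutch.
point_mass_params <- function() {
  sim_params(zd_c1 = dist_spec(56),
             inter_clutch = list(dist_spec(28), dist_spec(28)),
             clutch_size = list(dist_spec(20), dist_spec(50), dist_spec(70)),
             clutch_count = c("3" = 1),
             post_last_survival = dist_spec(30),
             lifespan = dist_spec(142),
             label = "point-mass")
}

random_cohort_case <- function() {
  n0 <- sample(1:5, 1)
  n_deaths <- sample(0:n0, 1)
  death_days <- if (n_deaths) sort(sample(0:120, n_deaths)) else integer()
  # clutch days restricted so at least one animal is still present
  ceiling_day <- if (n_deaths == n0) max(death_days) else 120L
  m <- sample(0:8, 1)
  days <- if (m) sort(sample(0:ceiling_day, m, replace = TRUE)) else integer()
  list(n0 = n0, death_days = death_days, days = days)
}
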