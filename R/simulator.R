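# Monte Carlo model of one animal's reproductive schedule.  Each
# individual is independent (a null model with no interaction between
# cohort members): draw the number of clutches m from a categorical
# distribution, the day of the first clutch from the generation-time
# distribution, each later clutch day by adding an inter-clutch interval,
# each clutch size from its per-index distribution, and death either as
# last clutch day + post-last-clutch survival (m >= 1) or from the
# lifespan distribution (m = 0).  Draws are rounded to whole days /
# embryos; intervals are at least 1 day and sizes at least 1 embryo.

#' Assemble a simulation parameter set
#'
#' @param zd_c1 [dist_spec()] for the zygote-deposition-to-first-clutch
#'   time (days).
#' @param inter_clutch list of [dist_spec()]s, element k giving the
#'   interval between clutches k and k+1 (days).
#' @param clutch_size list of [dist_spec()]s, element k giving the size of
#'   the k-th clutch (embryos).
#' @param clutch_count named numeric vector of probabilities over clutch
#'   counts, names `"0"`, `"1"`, ...; normalized to sum to 1.
#' @param post_last_survival [dist_spec()] for days survived after the
#'   last clutch.
#' @param lifespan optional [dist_spec()] for total lifespan (days); used
#'   for individuals that never reproduce, and by the independent-lifespan
#'   simulation mode.
#' @param label parameter-set name.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(zd_c1, inter_clutch = list(), clutch_size = list(),
                       clutch_count, post_last_survival, lifespan = NULL,
                       label = "") {
  stopifnot(inherits(zd_c1, "dist_spec"),
            inherits(post_last_survival, "dist_spec"))
  if (is.null(names(clutch_count)) || any(clutch_count < 0))
    stop("`clutch_count` must be a named vector of non-negative probabilities",
         call. = FALSE)
  if (sum(clutch_count) <= 0) stop("`clutch_count` has no mass", call. = FALSE)
  clutch_count <- clutch_count / sum(clutch_count)
  counts <- as.integer(names(clutch_count))
  if (any(is.na(counts)) || any(counts < 0))
    stop("`clutch_count` names must be non-negative integers", call. = FALSE)
  kmax <- max(counts[clutch_count > 0])
  if (kmax >= 1 && length(clutch_size) < kmax)
    stop(sprintf("clutch_size defined up to index %d but counts reach %d",
                 length(clutch_size), kmax), call. = FALSE)
  if (kmax >= 2 && length(inter_clutch) < kmax - 1)
    stop(sprintf("inter_clutch defined up to transition %d but counts reach %d clutches",
                 length(inter_clutch), kmax), call. = FALSE)
  if (any(clutch_count[counts == 0] > 0) && is.null(lifespan))
    stop("`lifespan` spec required when P(0 clutches) > 0", call. = FALSE)
  structure(list(zd_c1 = zd_c1, inter_clutch = inter_clutch,
                 clutch_size = clutch_size, clutch_count = clutch_count,
                 post_last_survival = post_last_survival,
                 lifespan = lifespan, label = label),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params>%s first clutch %.4g d, up to %d clutch(es)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$zd_c1$mean,
              max(as.integer(names(x$clutch_count))[x$clutch_count > 0])))
  invisible(x)
}

spec_from_sample <- function(x) {
  if (length(x) == 0) return(NULL)
  dist_spec(mean(x), if (length(x) > 1) stats::sd(x) else 0, min(x), max(x))
}

#' Estimate simulation parameters from individual records
#'
#' Moment-matching: each metric's [dist_spec()] takes the sample mean, sd,
#' min and max of the corresponding life-history statistic; the clutch
#' count is the empirical categorical distribution of per-individual
#' clutch counts.
#'
#' @param records list of [individual_record()] objects (at least 2 for
#'   meaningful sds).
#' @param label parameter-set name.
#' @return a [sim_params()] object.
#' @export
estimate_params_from_individuals <- function(records, label = "individuals") {
  if (length(records) < 1) stop("no records", call. = FALSE)
  kmax <- max(vapply(records, function(r) nrow(r$clutches), integer(1)))
  first <- unlist(lapply(records, function(r)
    if (nrow(r$clutches) >= 1) r$clutches$day[1] else NULL))
  if (is.null(first)) stop("no clutches in any record", call. = FALSE)
  ic <- lapply(seq_len(max(0L, kmax - 1L)), function(k)
    spec_from_sample(unlist(lapply(records, function(r)
      if (nrow(r$clutches) >= k + 1)
        r$clutches$day[k + 1] - r$clutches$day[k] else NULL))))
  cs <- lapply(seq_len(kmax), function(k)
    spec_from_sample(unlist(lapply(records, function(r)
      if (nrow(r$clutches) >= k) r$clutches$size[k] else NULL))))
  counts <- vapply(records, function(r) nrow(r$clutches), integer(1))
  tab <- table(factor(counts, levels = 0:max(counts)))
  cc <- as.numeric(tab) / sum(tab)
  names(cc) <- names(tab)
  post <- unlist(lapply(records, function(r)
    if (!r$censored && nrow(r$clutches))
      r$death_day - r$clutches$day[nrow(r$clutches)] else NULL))
  life <- unlist(lapply(records, function(r)
    if (!r$censored) r$death_day else NULL))
  sim_params(zd_c1 = spec_from_sample(first),
             inter_clutch = ic, clutch_size = cs, clutch_count = cc,
             post_last_survival = if (is.null(post)) dist_spec(0) else
               spec_from_sample(post),
             lifespan = if (is.null(life)) NULL else spec_from_sample(life),
             label = label)
}

#' Estimate simulation parameters from an interbreeding cohort log
#'
#' Runs [assign_rounds()] and reads each metric off the inferred rounds:
#' generation time from round-1 deposition days; the k-th inter-clutch
#' interval mean as the difference of round k+1 and round k mean days,
#' with sd pooled from the two rounds' day spreads
#' (`sqrt((sd_k^2 + sd_{k+1}^2)/2)`); per-round clutch sizes; and the
#' clutch-count distribution from round-to-round attrition of clutch
#' counts.  Post-last-clutch survival uses deaths recorded after the final
#' clutch.
#'
#' @param log a [cohort_log()] with at least one clutch.
#' @param label parameter-set name.
#' @return a [sim_params()] object.
#' @export
estimate_params_from_cohort <- function(log, label = "cohort") {
  if (nrow(log$clutches) == 0)
    stop("cohort log has no clutches; cannot estimate parameters",
         call. = FALSE)
  asg <- assign_rounds(log)
  rs <- round_summaries(asg, log)
  day_sd <- vapply(seq_len(nrow(rs)), function(r) {
    d <- log$clutches$day[asg$labels == r]
    if (length(d) > 1) stats::sd(d) else 0
  }, numeric(1))
  r1 <- log$clutches$day[asg$labels == 1]
  zd <- dist_spec(mean(r1), if (length(r1) > 1) stats::sd(r1) else 0,
                  min(r1), max(r1))
  nr <- nrow(rs)
  ic <- lapply(seq_len(max(0L, nr - 1L)), function(k)
    dist_spec(max(1, rs$day_mean[k + 1] - rs$day_mean[k]),
              sqrt((day_sd[k]^2 + day_sd[k + 1]^2) / 2),
              min = 1))
  cs <- lapply(seq_len(nr), function(k) {
    s <- log$clutches$size[asg$labels == k]
    dist_spec(mean(s), if (length(s) > 1) stats::sd(s) else 0, min(s), max(s))
  })
  att <- pmax(rs$n - c(rs$n[-1], 0L), 0)
  if (sum(att) == 0) att[nr] <- 1
  cc <- c(0, att) / sum(att)
  names(cc) <- 0:nr
  last_day <- max(log$clutches$day)
  post <- log$death_days[log$death_days > last_day] - last_day
  sim_params(zd_c1 = zd, inter_clutch = ic, clutch_size = cs,
             clutch_count = cc,
             post_last_survival = if (length(post)) spec_from_sample(post)
               else dist_spec(0),
             lifespan = NULL, label = label)
}

# Per-individual substream: the seed for individual i of run r depends
# only on (seed, r, i), so changing n or runs never reshuffles the draws
# of other individuals.  All arithmetic stays exact in doubles.
derive_seed <- function(seed, run, indiv) {
  s <- (seed %% 1000003) * 2654435 + run * 979693 + indiv * 7919
  as.integer(s %% 2147483629) + 1L
}

#' Simulate the reproductive record of one individual
#'
#' Uses the current RNG stream; wrap in `set.seed()` (or use
#' [simulate_cohort()] / [run_replicates()], which manage per-individual
#' substreams) for reproducibility.
#'
#' @param params a [sim_params()] object.
#' @param id identifier for the simulated record.
#' @param law sampling law passed to [draw_dist()].
#' @return an [individual_record()].
#' @export
simulate_individual <- function(params, id = "sim",
                                law = c("calibrated", "clamp", "reject")) {
  law <- match.arg(law)
  counts <- as.integer(names(params$clutch_count))
  m <- counts[sample.int(length(counts), 1, prob = params$clutch_count)]
  if (m > length(params$clutch_size) ||
      (m >= 2 && m - 1 > length(params$inter_clutch)))
    stop(sprintf("drawn clutch count %d exceeds the defined specs", m),
         call. = FALSE)
  if (m == 0) {
    if (is.null(params$lifespan))
      stop("individual with 0 clutches needs a lifespan spec", call. = FALSE)
    death <- max(0, round(draw_dist(params$lifespan, 1, law)))
    return(individual_record(id, clutch_events(), death_day = death))
  }
  day <- max(0, round(draw_dist(params$zd_c1, 1, law)))
  days <- integer(m); sizes <- integer(m)
  days[1] <- day
  sizes[1] <- max(1, round(draw_dist(params$clutch_size[[1]], 1, law)))
  if (m >= 2) for (k in 2:m) {
    step <- max(1, round(draw_dist(params$inter_clutch[[k - 1]], 1, law)))
    days[k] <- days[k - 1] + step
    sizes[k] <- max(1, round(draw_dist(params$clutch_size[[k]], 1, law)))
  }
  death <- days[m] + max(0, round(draw_dist(params$post_last_survival, 1, law)))
  individual_record(id, clutch_events(days, sizes), death_day = death)
}

#' Simulate an anonymized cohort of independent individuals
#'
#' Simulates `n` individuals independently (no interaction or coordination
#' between them -- the null model) and pools them into a cohort log via
#' [build_pseudo_cohort()], ground truth attached.
#'
#' @param params a [sim_params()] object.
#' @param n cohort size (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG stream to pick
#'   one.
#' @param law sampling law.
#' @param run run index used in substream derivation (see
#'   [run_replicates()]).
#' @return a [cohort_log()]; `attr(, "truth")` carries parentage and true
#'   clutch indices, `attr(, "records")` the simulated records.
#' @export
simulate_cohort <- function(params, n, seed = NULL,
                            law = c("calibrated", "clamp", "reject"),
                            run = 1L) {
  law <- match.arg(law)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  records <- lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, run, i))
    simulate_individual(params, id = sprintf("sim%03d", i), law = law)
  })
  log <- build_pseudo_cohort(records)
  log$label <- sprintf("%s n=%d seed=%d", params$label, n, seed)
  attr(log, "records") <- records
  attr(log, "seed") <- seed
  log
}

#' Replicate simulations and summarize every metric
#'
#' Runs `runs` independent simulations of `n` individuals each, pools all
#' simulated individuals, and summarizes each metric (generation time,
#' each inter-clutch interval and all intervals pooled, each clutch size,
#' clutch count, post-last-clutch survival, lifespan, per-individual
#' capacity) with mean, sd, min, max and a 95% Student-t confidence
#' interval on the mean.
#'
#' @param params a [sim_params()] object.
#' @param n individuals per run.
#' @param runs number of runs (default 100).
#' @param seed integer seed (required for reproducibility; `NULL` picks
#'   one from the current stream).
#' @param law sampling law.
#' @param ci_level confidence level (default 0.95).
#' @return an object of class `replicate_summary`: a data.frame with
#'   columns `metric`, `n`, `mean`, `sd`, `min`, `max`, `ci_lo`, `ci_hi`;
#'   attributes `runs`, `n_per_run`, `seed`, and `pooled` (a named list of
#'   the raw pooled vectors).
#' @export
run_replicates <- function(params, n, runs = 100, seed = NULL,
                           law = c("calibrated", "clamp", "reject"),
                           ci_level = 0.95) {
  law <- match.arg(law)
  if (runs < 1) stop("`runs` must be >= 1", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  pool <- list(zd_c1 = numeric(), clutch_count = numeric(),
               post_last_survival = numeric(), lifespan = numeric(),
               capacity = numeric(), interval_all = numeric())
  for (r in seq_len(runs)) for (i in seq_len(n)) {
    set.seed(derive_seed(seed, r, i))
    rec <- simulate_individual(params, id = sprintf("r%d.i%d", r, i),
                               law = law)
    m <- nrow(rec$clutches)
    pool$clutch_count <- c(pool$clutch_count, m)
    pool$capacity <- c(pool$capacity, sum(rec$clutches$size))
    pool$lifespan <- c(pool$lifespan, rec$death_day)
    if (m >= 1) {
      pool$zd_c1 <- c(pool$zd_c1, rec$clutches$day[1])
      pool$post_last_survival <- c(pool$post_last_survival,
                                   rec$death_day - rec$clutches$day[m])
      for (k in seq_len(m)) {
        key <- sprintf("clutch_size_%d", k)
        pool[[key]] <- c(pool[[key]], rec$clutches$size[k])
      }
      if (m >= 2) {
        steps <- diff(rec$clutches$day)
        pool$interval_all <- c(pool$interval_all, steps)
        for (k in seq_len(m - 1)) {
          key <- sprintf("interval_%d_%d", k, k + 1)
          pool[[key]] <- c(pool[[key]], steps[k])
        }
      }
    }
  }
  summ <- do.call(rbind, lapply(names(pool), function(nm) {
    x <- pool[[nm]]
    nn <- length(x)
    if (nn == 0)
      return(data.frame(metric = nm, n = 0L, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    s <- if (nn > 1) stats::sd(x) else 0
    hw <- if (nn > 1)
      stats::qt(1 - (1 - ci_level) / 2, nn - 1) * s / sqrt(nn) else 0
    data.frame(metric = nm, n = nn, mean = mean(x), sd = s,
               min = min(x), max = max(x),
               ci_lo = mean(x) - hw, ci_hi = mean(x) + hw)
  }))
  structure(summ, runs = runs, n_per_run = n, seed = seed, pooled = pool,
            class = c("replicate_summary", "data.frame"))
}
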