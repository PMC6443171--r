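# Published per-clutch-number and interval summary blocks for the five
# study conditions, keyed by preset name:
#   hro_isolated  - H. robusta, self-fertilizing in isolation, N = 16
#   hro_cohort    - H. robusta, interbreeding cohort, N = 48
#   hau_cohort23  - H. austinensis, interbreeding cohort, N = 23
#   hau_cohort60  - H. austinensis, interbreeding cohort, N = 60
#   hoc_isolated  - H. octatestisaca, self-fertilizing in isolation, N = 5
#
# clutch blocks: S (number of k-th clutches), mean/sd/min/max embryo count
#   (sd NA for singleton rows, printed bare in the source tables).
# interval blocks: row 1 is ZD-C1 (generation time), row k > 1 is
#   C(k-1)-Ck; cum_* are days from birth to the later clutch, step is the
#   printed inter-clutch interval.
# lifespan_mean: reported mean lifespan in days where stated (isolated
#   blocks); post_last: survival after the final clutch where only an
#   anchor is known (cohort blocks).

.preset_tables <- list(
  hro_isolated = list(
    species = "H. robusta", condition = "self-fertilizing, snail diet",
    n_individuals = 16L,
    clutch = data.frame(
      n    = c(10L, 14L, 14L, 11L, 11L, 9L, 6L, 1L),
      mean = c(20.3, 51.1, 71.1, 77.6, 69.1, 51.0, 44.2, 13),
      sd   = c(4.1, 16.3, 19.5, 19.9, 23.5, 30.7, 27.3, NA),
      min  = c(15, 3, 34, 55, 30, 7, 12, 13),
      max  = c(25, 70, 99, 104, 105, 95, 81, 13)),
    interval = data.frame(
      n        = c(15L, 15L, 14L, 12L, 10L, 8L, 5L, 1L),
      cum_mean = c(56.3, 83.5, 107.4, 136.8, 170.4, 199.4, 243.3, 264),
      cum_sd   = c(8.7, 7.7, 10.5, 9.9, 16.0, 17.2, 29.6, NA),
      cum_min  = c(37, 72, 92, 117, 142, 169, 217, 264),
      cum_max  = c(68, 93, 121, 150, 193, 222, 295, 264),
      step     = c(NA, 28, 23, 30, 33, 29, 44, 21)),
    lifespan_mean = 229, post_last = NULL),
  hoc_isolated = list(
    species = "H. octatestisaca", condition = "self-fertilizing, bloodworm diet",
    n_individuals = 5L,
    clutch = data.frame(
      n    = c(5L, 5L, 3L),
      mean = c(26.4, 50.2, 70.3),
      sd   = c(7.5, 12.7, 4.7),
      min  = c(17, 33, 65),
      max  = c(37, 66, 74)),
    interval = data.frame(
      n        = c(5L, 4L, 3L),
      cum_mean = c(140.0, 160.8, 220.8),
      cum_sd   = c(25.8, 37.7, 43.2),
      cum_min  = c(120, 137, 191),
      cum_max  = c(180, 227, 270),
      step     = c(NA, 21, 60)),
    lifespan_mean = 246, post_last = NULL),
  hau_cohort23 = list(
    species = "H. austinensis", condition = "interbreeding cohort, bloodworm diet",
    n_individuals = 23L,
    clutch = data.frame(
      n    = c(23L, 16L, 1L),
      mean = c(94.2, 87.4, 26),
      sd   = c(41.0, 36.2, NA),
      min  = c(45, 22, 26),
      max  = c(179, 160, 26)),
    interval = data.frame(
      n        = c(23L, 16L, 1L),
      cum_mean = c(109.3, 188.4, 243),
      cum_sd   = c(20.4, 36.6, NA),
      cum_min  = c(80, 148, 243),
      cum_max  = c(148, 240, 243),
      step     = c(NA, 79, 55)),
    lifespan_mean = NULL,
    post_last = list(mean = 100, sd = 40, min = 0, max = NA)),
  hau_cohort60 = list(
    species = "H. austinensis", condition = "interbreeding cohort, bloodworm diet",
    n_individuals = 60L,
    clutch = data.frame(
      n    = c(60L, 54L, 31L),
      mean = c(43.8, 41.5, 38.9),
      sd   = c(20.8, 22.4, 25.2),
      min  = c(6, 7, 6),
      max  = c(117, 93, 97)),
    interval = data.frame(
      n        = c(60L, 54L, 31L),
      cum_mean = c(109.7, 189.8, 273.1),
      cum_sd   = c(19.3, 28.3, 57.2),
      cum_min  = c(70, 144, 237),
      cum_max  = c(143, 234, 346),
      step     = c(NA, 80, 83)),
    lifespan_mean = NULL,
    post_last = list(mean = 100, sd = 40, min = 0, max = NA)),
  hro_cohort = list(
    species = "H. robusta", condition = "interbreeding cohort, snail diet",
    n_individuals = 48L,
    clutch = data.frame(
      n    = c(48L, 34L, 28L, 26L, 13L),
      mean = c(24.0, 44.6, 68.4, 75.3, 48.1),
      sd   = c(10.0, 16.8, 18.4, 18.5, 22.3),
      min  = c(11, 15, 21, 29, 17),
      max  = c(65, 85, 102, 114, 85)),
    interval = data.frame(
      n        = c(48L, 34L, 28L, 26L, 13L),
      cum_mean = c(107.4, 146.8, 184.9, 221.1, 252.8),
      cum_sd   = c(10.7, 11.1, 11.0, 13.2, 9.2),
      cum_min  = c(94, 135, 171, 204, 241),
      cum_max  = c(134, 170, 204, 241, 276),
      step     = c(NA, 40, 48, 36, 32)),
    lifespan_mean = NULL,
    post_last = list(mean = 17, sd = 8, min = 0, max = 34))
)

#' Names of the built-in parameter presets
#' @return character vector of preset names.
#' @export
clutch_presets <- function() names(.preset_tables)

check_preset <- function(preset) {
  if (!preset %in% names(.preset_tables))
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(names(.preset_tables), collapse = ", ")),
         call. = FALSE)
  .preset_tables[[preset]]
}

#' Published per-clutch-number statistics for a preset
#'
#' @param preset one of [clutch_presets()].
#' @return a [clutch_number_stats()]-shaped data.frame (`k`, `n`, `mean`,
#'   `sd`, `min`, `max`); attribute `n_individuals` carries the block's N.
#' @export
preset_clutch_stats <- function(preset) {
  tb <- check_preset(preset)
  out <- cbind(data.frame(k = seq_len(nrow(tb$clutch))), tb$clutch)
  attr(out, "n_individuals") <- tb$n_individuals
  structure(out, class = c("clutch_number_stats", "data.frame"))
}

#' Published interval statistics for a preset
#'
#' @param preset one of [clutch_presets()].
#' @return an [interval_stats()]-shaped data.frame; attribute
#'   `n_individuals` carries the block's N.
#' @export
preset_interval_stats <- function(preset) {
  tb <- check_preset(preset)
  iv <- tb$interval
  lab <- c("ZD-C1", if (nrow(iv) > 1)
    sprintf("C%d-C%d", seq_len(nrow(iv) - 1), seq_len(nrow(iv) - 1) + 1))
  out <- data.frame(label = lab, n = iv$n, cum_mean = iv$cum_mean,
                    cum_sd = iv$cum_sd, cum_min = iv$cum_min,
                    cum_max = iv$cum_max, step_mean = iv$step)
  attr(out, "n_individuals") <- tb$n_individuals
  structure(out, class = c("interval_stats", "data.frame"))
}

# Inter-clutch step sd for transition k -> k+1 from cumulative sds: the
# quadrature difference sqrt(cum_sd[k+1]^2 - cum_sd[k]^2) under
# independence of the step and the earlier cumulative time; where the
# printed cumulative sds make that non-positive, fall back to the smaller
# of the two.  Singleton rows (sd NA) count as sd 0.
step_sd_from_cum <- function(cum_sd) {
  s <- ifelse(is.na(cum_sd), 0, cum_sd)
  vapply(seq_len(length(s) - 1), function(k) {
    d2 <- s[k + 1]^2 - s[k]^2
    if (d2 > 0) sqrt(d2) else min(s[k], s[k + 1])
  }, numeric(1))
}

# Clutch-count distribution from the S column: P(count = k) proportional
# to max(S_k - S_{k+1}, 0) (an animal whose last clutch is its k-th stops
# contributing after index k).  Published S columns are occasionally
# non-monotone; negative differences are clipped to 0.
clutch_count_from_s <- function(s_counts) {
  diffs <- pmax(s_counts - c(s_counts[-1], 0L), 0)
  if (sum(diffs) == 0) diffs[length(diffs)] <- 1
  cc <- c(0, diffs) / sum(diffs)
  names(cc) <- 0:length(s_counts)
  cc
}

#' Build simulation parameters from a published summary block
#'
#' Populates every [dist_spec()] from the preset's per-clutch-number and
#' interval tables: generation time and clutch sizes verbatim (mean, sd,
#' min, max); inter-clutch interval means from the printed step column
#' with sds derived from the cumulative sds (see the package vignette);
#' the clutch-count distribution from the attrition of the S column.
#' Post-last-clutch survival is anchored to the block's reported lifespan
#' where one is stated, otherwise to the reported survival after the final
#' clutch.
#'
#' @param preset one of [clutch_presets()].
#' @return a [sim_params()] object.
#' @export
make_params <- function(preset) {
  tb <- check_preset(preset)
  cl <- tb$clutch; iv <- tb$interval
  zd <- dist_spec(iv$cum_mean[1], ifelse(is.na(iv$cum_sd[1]), 0, iv$cum_sd[1]),
                  iv$cum_min[1], iv$cum_max[1])
  kmax <- nrow(cl)
  step_sd <- step_sd_from_cum(iv$cum_sd)
  ic <- lapply(seq_len(max(0L, nrow(iv) - 1L)), function(k)
    dist_spec(iv$step[k + 1], step_sd[k], min = 1))
  cs <- lapply(seq_len(kmax), function(k)
    dist_spec(cl$mean[k], ifelse(is.na(cl$sd[k]), 0, cl$sd[k]),
              cl$min[k], cl$max[k]))
  cc <- clutch_count_from_s(cl$n)
  if (!is.null(tb$lifespan_mean)) {
    # expected day of the last clutch under the clutch-count distribution
    pk <- cc[as.character(seq_len(kmax))]
    e_last <- sum(pk * iv$cum_mean[seq_len(kmax)]) / sum(pk)
    post_mean <- max(0, tb$lifespan_mean - e_last)
    post <- dist_spec(post_mean, post_mean / 2, min = 0)
    life <- dist_spec(tb$lifespan_mean, 40, min = 0)
  } else {
    post <- dist_spec(tb$post_last$mean, tb$post_last$sd,
                      tb$post_last$min, tb$post_last$max)
    life <- NULL
  }
  sim_params(zd_c1 = zd, inter_clutch = ic, clutch_size = cs,
             clutch_count = cc, post_last_survival = post, lifespan = life,
             label = preset)
}
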