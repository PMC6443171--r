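# Ground-truth dataset generator: simulated individual records with known
# per-clutch indices, the anonymized cohort log built from them, and the
# true round labels (under the independence null, an animal's k-th clutch
# belongs to round k).  Stands in for raw colony records so that the
# statistics, round inference and simulator are all testable end to end.

#' Generate a ground-truth dataset
#'
#' @param params a [sim_params()] object (e.g. from [make_params()] or an
#'   estimator).
#' @param n number of individuals (>= 1).
#' @param seed integer seed; the dataset is a pure function of
#'   `(params, n, seed)`.
#' @param dir optional directory; when given, writes `individuals.csv`,
#'   `cohort.csv` + `cohort.json`, `truth.csv` and `params.json` there.
#' @param law sampling law, see [draw_dist()].
#' @return an object of class `ground_truth_dataset`: list with `params`,
#'   `records`, `log` (anonymized [cohort_log()]), `truth` (data.frame
#'   `day`, `size`, `parent_id`, `clutch_index`, `true_round`, aligned
#'   with the log's clutch rows), and `seed`.
#' @export
generate_dataset <- function(params, n, seed, dir = NULL,
                             law = c("calibrated", "clamp", "reject")) {
  law <- match.arg(law)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  records <- lapply(seq_len(n), function(i) {
    set.seed(derive_seed(seed, 1L, i))
    simulate_individual(params, id = sprintf("ind%03d", i), law = law)
  })
  names(records) <- vapply(records, `[[`, character(1), "id")
  ds <- build_truth(params, records, seed)
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

build_truth <- function(params, records, seed) {
  log <- build_pseudo_cohort(records)
  truth <- attr(log, "truth")
  truth$true_round <- truth$clutch_index
  attr(log, "truth") <- NULL
  attr(log, "records") <- NULL
  structure(list(params = params, records = records, log = log,
                 truth = truth, seed = seed),
            class = "ground_truth_dataset")
}

#' @export
print.ground_truth_dataset <- function(x, ...) {
  cat(sprintf("<ground_truth_dataset> %d individual(s), %d clutch(es), seed %d\n",
              length(x$records), nrow(x$truth), x$seed))
  invisible(x)
}

write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_individual_records(ds$records, file.path(dir, "individuals.csv"))
  write_cohort_log(ds$log, file.path(dir, "cohort.csv"))
  utils::write.csv(ds$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_sim_params(ds$params, file.path(dir, "params.json"))
  invisible(dir)
}

#' Truncate simulated individuals at injected death days
#'
#' Emulates premature deaths: each scheduled animal's record is cut at its
#' new death day (clutches strictly after that day are removed; the
#' last-seen-alive convention keeps a clutch on the death day itself), and
#' the cohort log and truth table are rebuilt.  True round labels of the
#' surviving clutches are retained, so the misassignment a premature death
#' induces in [assign_rounds()] is directly measurable.
#'
#' @param dataset a [generate_dataset()] result.
#' @param schedule data.frame with columns `id` and `death_day`.
#' @return a new `ground_truth_dataset`.
#' @export
inject_deaths <- function(dataset, schedule) {
  stopifnot(inherits(dataset, "ground_truth_dataset"))
  if (nrow(schedule) == 0) return(dataset)
  if (!all(c("id", "death_day") %in% names(schedule)))
    stop("`schedule` needs columns id and death_day", call. = FALSE)
  unknown <- setdiff(schedule$id, names(dataset$records))
  if (length(unknown))
    stop(sprintf("unknown individual id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  records <- dataset$records
  for (j in seq_len(nrow(schedule))) {
    id <- schedule$id[j]
    d <- as.integer(schedule$death_day[j])
    r <- records[[id]]
    keep <- r$clutches$day <= d
    records[[id]] <- individual_record(
      id, r$clutches[keep, , drop = FALSE], death_day = d)
  }
  build_truth(dataset$params, records, dataset$seed)
}

spec_to_list <- function(spec) {
  if (is.null(spec)) return(NULL)
  out <- list(mean = spec$mean, sd = spec$sd)
  if (is.finite(spec$min)) out$min <- spec$min
  if (is.finite(spec$max)) out$max <- spec$max
  out
}

opt_num <- function(x) if (is.null(x) || length(x) == 0) NA else as.numeric(x)

spec_from_list <- function(x) {
  if (is.null(x) || length(x) == 0) return(NULL)
  dist_spec(x$mean, x$sd, opt_num(x$min), opt_num(x$max))
}

#' Write simulation parameters to JSON
#'
#' Schema: `{label, zd_c1:{mean,sd,min,max}, inter_clutch:[...],
#' clutch_size:[...], clutch_count:{"0":p0,...}, post_last_survival:{...},
#' lifespan:{...}}`.  Omitted bounds mean no truncation.
#'
#' @param params a [sim_params()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_params <- function(params, path) {
  out <- list(label = params$label,
              zd_c1 = spec_to_list(params$zd_c1),
              inter_clutch = lapply(params$inter_clutch, spec_to_list),
              clutch_size = lapply(params$clutch_size, spec_to_list),
              clutch_count = as.list(params$clutch_count),
              post_last_survival = spec_to_list(params$post_last_survival))
  if (!is.null(params$lifespan)) out$lifespan <- spec_to_list(params$lifespan)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read simulation parameters from JSON
#'
#' @param path path to a file written by [write_sim_params()].
#' @return a [sim_params()] object.
#' @export
read_sim_params <- function(path) {
  x <- jsonlite::read_json(path)
  cc <- unlist(x$clutch_count)
  sim_params(zd_c1 = spec_from_list(x$zd_c1),
             inter_clutch = lapply(x$inter_clutch, spec_from_list),
             clutch_size = lapply(x$clutch_size, spec_from_list),
             clutch_count = cc,
             post_last_survival = spec_from_list(x$post_last_survival),
             lifespan = spec_from_list(x$lifespan),
             label = if (is.null(x$label)) "" else x$label)
}
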