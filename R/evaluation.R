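# Apply one estimation method to one replicate table, returning the raw
# sensitivity/specificity pair or NULL when the method's denominators are
# degenerate for this draw (the replicate is then "dropped" for the method).
estimate_replicate <- function(method, table, ref) {
  res <- tryCatch(
    switch(method,
           classical = classical_estimate(table, ci = FALSE),
           staquet = staquet_correct(table, ref, ci = FALSE),
           gart_buck = gart_buck_correct(table, ref, ci = FALSE),
           brenner = brenner_correct(table, ref, ci = FALSE)),
    refcorrect_margin_degenerate = function(e) NULL,
    refcorrect_degenerate_reference = function(e) NULL,
    refcorrect_degenerate_input = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  c(sensitivity = res$sensitivity$value, specificity = res$specificity$value)
}

#' Monte-Carlo performance of the estimators on replicate tables
#'
#' Applies each requested method to every replicate and aggregates, per
#' method and measure: the mean estimate, the empirical SE (standard
#' deviation of the replicate estimates, the Morris simulation-study
#' convention), bias (mean minus truth), MSE (mean squared deviation from
#' truth), and counts of illogical (outside \[0, 1\]) and dropped
#' (degenerate-denominator) replicates.
#'
#' Illogical estimates are included in the aggregates by default - this is
#' what makes aggregate means explode when low-prevalence draws produce
#' near-zero correction denominators, a phenomenon the summary is meant to
#' surface - and can be excluded via `exclude_illogical` for sensitivity
#' analyses. With the n-denominator variance convention,
#' `MSE = bias^2 + emp_se^2 * (m - 1) / m` holds exactly per stratum
#' (`m` = replicates used).
#'
#' @param tables Non-empty list of [contingency_table()] replicates.
#' @param ref [ref_accuracy()] assumed known for the corrections.
#' @param truth A [scenario_spec()] (or list with `sn_it`, `sp_it`): the
#'   generating index-test accuracies, which are always the bias/MSE target.
#' @param methods Methods to evaluate.
#' @param exclude_illogical Drop illogical estimates from the aggregates
#'   (they are still counted in `n_illogical`).
#' @param scenario Scenario label for the output rows.
#' @return `data.frame` with one row per method and measure: columns
#'   `scenario, method, measure, truth, n_reps, n_used, mean, emp_se, bias,
#'   mse, n_illogical, n_dropped`.
#' @export
evaluate_methods <- function(tables, ref, truth,
                             methods = c("classical", "brenner", "staquet"),
                             exclude_illogical = FALSE,
                             scenario = if (!is.null(truth$id)) truth$id else "scenario") {
  if (!length(tables)) {
    abort("tables must be a non-empty list of replicates", "refcorrect_empty_summary")
  }
  check_ref(ref)
  methods <- match.arg(methods, c("classical", "brenner", "staquet", "gart_buck"),
                       several.ok = TRUE)
  truths <- c(sensitivity = truth$sn_it, specificity = truth$sp_it)
  reps <- length(tables)
  out <- list()
  for (m in methods) {
    est <- lapply(tables, function(tab) estimate_replicate(m, tab, ref))
    dropped <- sum(vapply(est, is.null, logical(1)))
    if (dropped == reps) {
      abort(sprintf("all %d replicates were degenerate for method '%s'", reps, m),
            "refcorrect_empty_summary")
    }
    kept <- do.call(rbind, est)
    for (measure in c("sensitivity", "specificity")) {
      x <- kept[, measure]
      illogical <- x < 0 | x > 1
      used <- if (exclude_illogical) x[!illogical] else x
      tval <- truths[[measure]]
      n_used <- length(used)
      out[[length(out) + 1L]] <- data.frame(
        scenario = scenario, method = m, measure = measure, truth = tval,
        n_reps = reps, n_used = n_used,
        mean = mean(used),
        emp_se = if (n_used > 1) stats::sd(used) else NA_real_,
        bias = mean(used) - tval,
        mse = mean((used - tval)^2),
        n_illogical = sum(illogical),
        n_dropped = dropped,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# Shared driver for the two sweep flavours: vary one field of the scenario
# over a grid, drawing each grid point from its own deterministic substream.
sweep_over <- function(spec, ref, axis, grid, methods, exclude_illogical) {
  if (!length(grid)) {
    abort("sweep grid must be non-empty", "refcorrect_invalid_scenario")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("sweep grid must be strictly increasing", "refcorrect_invalid_scenario")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  point_seeds <- sample.int(.Machine$integer.max, length(grid))
  rows <- lapply(seq_along(grid), function(i) {
    sp <- unclass(spec)
    sp[[axis]] <- grid[i]
    sp$seed <- point_seeds[i]
    sp <- do.call(scenario_spec, sp)
    summ <- evaluate_methods(sample_tables(sp), ref, sp, methods,
                             exclude_illogical, scenario = spec$id)
    cbind(data.frame(axis = axis, axis_value = grid[i]), summ)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Performance sweep over sample sizes
#'
#' Runs [evaluate_methods()] once per sample size in `n_grid`, with a
#' deterministic RNG substream per grid point so results are reproducible
#' under the scenario seed.
#'
#' @param spec A [scenario_spec()]; its `n` is overridden by the grid.
#' @param ref [ref_accuracy()] used by the corrections.
#' @param n_grid Strictly increasing sample sizes, default
#'   [default_n_grid()].
#' @param methods,exclude_illogical Passed to [evaluate_methods()].
#' @return A `sweep_result` data frame: `evaluate_methods` columns plus
#'   `axis` (`"n"`) and `axis_value`.
#' @export
sample_size_sweep <- function(spec, ref, n_grid = default_n_grid(),
                              methods = c("classical", "brenner", "staquet"),
                              exclude_illogical = FALSE) {
  sweep_over(spec, ref, "n", n_grid, methods, exclude_illogical)
}

#' Performance sweep over prevalence
#'
#' Varies the generating prevalence at fixed `n`. Grid endpoints 0 and 1
#' are excluded (degenerate multinomials); the default grid is 0.01 to 0.99
#' in steps of 0.01. Strata with illogical corrected estimates are
#' surfaced through the `n_illogical` counts, never masked.
#'
#' @param base A [scenario_spec()]; its `prevalence` is overridden.
#' @param ref [ref_accuracy()] used by the corrections.
#' @param prevalence_grid Strictly increasing values in (0, 1).
#' @param methods,exclude_illogical Passed to [evaluate_methods()].
#' @return A `sweep_result` data frame with `axis = "prevalence"`.
#' @export
prevalence_sweep <- function(base, ref,
                             prevalence_grid = seq(0.01, 0.99, by = 0.01),
                             methods = c("classical", "brenner", "staquet"),
                             exclude_illogical = FALSE) {
  if (any(prevalence_grid <= 0 | prevalence_grid >= 1)) {
    abort("prevalence grid values must lie strictly inside (0, 1)",
          "refcorrect_invalid_scenario")
  }
  sweep_over(base, ref, "prevalence", prevalence_grid, methods, exclude_illogical)
}

#' Export a performance summary as CSV
#'
#' Long-format table with a stable column order and full-precision values,
#' suitable for downstream plotting; a round-trip through
#' [utils::read.csv()] reproduces the numbers to 1e-12.
#'
#' @param result Data frame from [evaluate_methods()] or a sweep.
#' @param destination Output file path.
#' @return The destination path, invisibly.
#' @export
export_summary <- function(result, destination) {
  if (!is.data.frame(result) || !nrow(result)) {
    abort("result must be a non-empty summary data frame", "refcorrect_empty_summary")
  }
  ok <- tryCatch({
    utils::write.csv(result, destination, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) {
    abort(sprintf("cannot write summary to '%s'", destination), "refcorrect_io_error")
  }
  invisible(destination)
}
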