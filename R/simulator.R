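#' Simulation scenario specification
#'
#' Describes the generative truth for one simulation scenario: prevalence of
#' the target condition, index-test and reference-standard accuracies, the
#' fixed within-class covariance terms between the two tests (0 under
#' conditional independence), sample size per replicate, number of
#' replicates and RNG seed.
#'
#' The covariance terms are validated on construction against the
#' feasibility bounds of [validate_covariance_bounds()]; an infeasible
#' specification raises a constraint-violation error before any sampling
#' can happen.
#'
#' @param prevalence Disease prevalence, strictly inside (0, 1).
#' @param sn_it,sp_it True index-test sensitivity/specificity.
#' @param sn_rs,sp_rs True (and assumed known) reference-standard accuracy.
#' @param cov_d,cov_nd Fixed covariance between IT and RS positivity among
#'   diseased / non-diseased participants.
#' @param n Participants per replicate (>= 1).
#' @param reps Number of Monte-Carlo replicates (>= 1).
#' @param seed Optional integer seed; `NULL` leaves the RNG state alone.
#' @param id Optional scenario label carried into summaries.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec(0.3, 0.8, 0.7, 0.9, 0.9, n = 1000, reps = 200, seed = 1)
#' @export
scenario_spec <- function(prevalence, sn_it, sp_it, sn_rs, sp_rs,
                          cov_d = 0, cov_nd = 0, n = 1000, reps = 200,
                          seed = NULL, id = "scenario") {
  for (nm in c("sn_it", "sp_it", "sn_rs", "sp_rs")) {
    if (!is_prob(get(nm))) {
      abort(sprintf("%s must be a probability in [0, 1]", nm),
            "refcorrect_invalid_scenario")
    }
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("prevalence must lie strictly inside (0, 1)", "refcorrect_invalid_scenario")
  }
  if (!is.numeric(n) || n < 1 || !is.numeric(reps) || reps < 1) {
    abort("n and reps must be >= 1", "refcorrect_invalid_scenario")
  }
  spec <- structure(
    list(prevalence = prevalence, sn_it = sn_it, sp_it = sp_it,
         sn_rs = sn_rs, sp_rs = sp_rs, cov_d = cov_d, cov_nd = cov_nd,
         n = as.integer(n), reps = as.integer(reps), seed = seed, id = id),
    class = "scenario_spec"
  )
  viol <- validate_covariance_bounds(spec)
  if (length(viol)) {
    abort(paste0("infeasible covariance term(s):\n  ",
                 paste(viol, collapse = "\n  ")),
          "refcorrect_constraint_violation")
  }
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(paste0("Scenario '%s': p = %g, IT (Sn %g, Sp %g), RS (Sn %g, Sp %g),\n",
                     "  cov_d = %g, cov_nd = %g, n = %d, reps = %d, seed = %s\n"),
              x$id, x$prevalence, x$sn_it, x$sp_it, x$sn_rs, x$sp_rs,
              x$cov_d, x$cov_nd, x$n, x$reps,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

# Feasibility band for a within-class covariance between two conditionally
# Bernoulli tests with success probabilities q1, q2: all four class cell
# probabilities q1 q2 + cov, q1(1-q2) - cov, (1-q1) q2 - cov,
# (1-q1)(1-q2) + cov must lie in [0, 1].
cov_bounds <- function(q1, q2) {
  c(lower = max(-q1 * q2, -(1 - q1) * (1 - q2)),
    upper = min(q1 * (1 - q2), (1 - q1) * q2))
}

#' Check covariance feasibility for a scenario
#'
#' A fixed within-class covariance is feasible only if all four
#' class-conditional joint cell probabilities stay inside \[0, 1\]. For the
#' diseased class this means
#' `max(-Sn_IT*Sn_RS, -(1-Sn_IT)(1-Sn_RS)) <= cov_d <=
#'  min(Sn_IT(1-Sn_RS), (1-Sn_IT)Sn_RS)`, and analogously with the
#' specificities for `cov_nd`.
#'
#' @param spec A [scenario_spec()] or any list with fields `sn_it`, `sp_it`,
#'   `sn_rs`, `sp_rs`, `cov_d`, `cov_nd` (a plain list is accepted so that
#'   infeasible candidate configurations can be checked before
#'   construction).
#' @return Character vector describing each violated bound; empty when
#'   feasible.
#' @examples
#' validate_covariance_bounds(list(sn_it = 0.8, sp_it = 0.8,
#'                                 sn_rs = 0.9, sp_rs = 0.9,
#'                                 cov_d = 0.10, cov_nd = 0))
#' @export
validate_covariance_bounds <- function(spec) {
  out <- character()
  bd <- cov_bounds(spec$sn_it, spec$sn_rs)
  if (spec$cov_d < bd["lower"] || spec$cov_d > bd["upper"]) {
    out <- c(out, sprintf("cov_d = %g outside feasible range [%g, %g] for Sn_IT = %g, Sn_RS = %g",
                          spec$cov_d, bd["lower"], bd["upper"], spec$sn_it, spec$sn_rs))
  }
  bnd <- cov_bounds(spec$sp_it, spec$sp_rs)
  if (spec$cov_nd < bnd["lower"] || spec$cov_nd > bnd["upper"]) {
    out <- c(out, sprintf("cov_nd = %g outside feasible range [%g, %g] for Sp_IT = %g, Sp_RS = %g",
                          spec$cov_nd, bnd["lower"], bnd["upper"], spec$sp_it, spec$sp_rs))
  }
  out
}

#' Joint cell probabilities of the fixed-effects dependence model
#'
#' Mixes the two class-conditional joint distributions by prevalence. With
#' the covariance terms at 0 the joint probability factorises within each
#' disease class (conditional independence); positive covariance shifts
#' mass onto the concordant cells:
#' \deqn{p_{11} = p(Sn_{IT} Sn_{RS} + cov_d) +
#'       (1-p)((1-Sp_{IT})(1-Sp_{RS}) + cov_{nd})}
#' and analogously for the other three cells.
#'
#' @param spec A [scenario_spec()].
#' @return Named numeric vector `c(p11, p10, p01, p00)` in the order
#'   (IT+,RS+), (IT+,RS-), (IT-,RS+), (IT-,RS-), summing to 1.
#' @examples
#' cell_probabilities(scenario_spec(0.3, 0.8, 0.7, 0.9, 0.9))
#' @export
cell_probabilities <- function(spec) {
  viol <- validate_covariance_bounds(spec)
  if (length(viol)) {
    abort(paste0("infeasible covariance term(s):\n  ",
                 paste(viol, collapse = "\n  ")),
          "refcorrect_constraint_violation")
  }
  p <- spec$prevalence
  pr <- c(
    p11 = p * (spec$sn_it * spec$sn_rs + spec$cov_d) +
      (1 - p) * ((1 - spec$sp_it) * (1 - spec$sp_rs) + spec$cov_nd),
    p10 = p * (spec$sn_it * (1 - spec$sn_rs) - spec$cov_d) +
      (1 - p) * ((1 - spec$sp_it) * spec$sp_rs - spec$cov_nd),
    p01 = p * ((1 - spec$sn_it) * spec$sn_rs - spec$cov_d) +
      (1 - p) * (spec$sp_it * (1 - spec$sp_rs) - spec$cov_nd),
    p00 = p * ((1 - spec$sn_it) * (1 - spec$sn_rs) + spec$cov_d) +
      (1 - p) * (spec$sp_it * spec$sp_rs + spec$cov_nd)
  )
  stopifnot(abs(sum(pr) - 1) < 1e-12)
  pr
}

#' Draw multinomial replicate tables for a scenario
#'
#' Each replicate is a single multinomial draw of size `n` from
#' [cell_probabilities()]. When the scenario carries a seed, per-replicate
#' substream seeds are derived from it first, so any subset of replicates is
#' reproducible independently of how many are drawn.
#'
#' Degenerate draws (zero reference-positive or reference-negative margin,
#' possible at small `n * p`) are returned as-is; downstream evaluation
#' decides how to handle them.
#'
#' @param spec A [scenario_spec()].
#' @return List of `reps` [contingency_table()] objects.
#' @export
sample_tables <- function(spec) {
  pr <- cell_probabilities(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, spec$reps)
  lapply(seq_len(spec$reps), function(r) {
    set.seed(rep_seeds[r])
    x <- stats::rmultinom(1, spec$n, pr)
    contingency_table(x[1], x[2], x[3], x[4])
  })
}

#' Predefined simulation scenarios
#'
#' The four benchmark scenarios of the comparison study, each at prevalence
#' 0.3 with 200 replicates by default:
#' * `scenario_one` - reference better than index test (RS 0.9/0.9,
#'   IT 0.8/0.7), conditional independence;
#' * `scenario_two` - index test better than reference (IT 0.9/0.9,
#'   RS 0.8/0.7);
#' * `scenario_three` - all four accuracies 0.9;
#' * `dependence` - IT 0.8/0.8 vs RS 0.9/0.9 with within-class covariances
#'   of 0.05 in both the diseased and non-diseased groups.
#'
#' @param n Sample size per replicate.
#' @param reps Replicates per scenario.
#' @param seed Optional base seed; scenario k receives `seed + k - 1`.
#' @return Named list of [scenario_spec()] objects.
#' @export
predefined_scenarios <- function(n = 1000, reps = 200, seed = NULL) {
  sub <- function(k) if (is.null(seed)) NULL else seed + k - 1
  list(
    scenario_one = scenario_spec(0.3, sn_it = 0.8, sp_it = 0.7,
                                 sn_rs = 0.9, sp_rs = 0.9, n = n,
                                 reps = reps, seed = sub(1), id = "scenario_one"),
    scenario_two = scenario_spec(0.3, sn_it = 0.9, sp_it = 0.9,
                                 sn_rs = 0.8, sp_rs = 0.7, n = n,
                                 reps = reps, seed = sub(2), id = "scenario_two"),
    scenario_three = scenario_spec(0.3, sn_it = 0.9, sp_it = 0.9,
                                   sn_rs = 0.9, sp_rs = 0.9, n = n,
                                   reps = reps, seed = sub(3), id = "scenario_three"),
    dependence = scenario_spec(0.3, sn_it = 0.8, sp_it = 0.8,
                               sn_rs = 0.9, sp_rs = 0.9,
                               cov_d = 0.05, cov_nd = 0.05, n = n,
                               reps = reps, seed = sub(4), id = "dependence")
  )
}

#' Default sample-size grid
#'
#' Sizes 50 and 80 (where small-sample artefacts are of particular
#' interest) followed by 100, 150 and every 50 up to 1000.
#'
#' @return Integer vector.
#' @export
default_n_grid <- function() {
  as.integer(c(50, 80, 100, 150, seq(200, 1000, by = 50)))
}

#' Write replicate tables as a long-format CSV
#'
#' Columns `scenario, rep, n, a, b, c, d`, one row per replicate.
#'
#' @param spec A [scenario_spec()].
#' @param tables Result of [sample_tables()] on `spec`.
#' @param destination Output file path.
#' @return The destination path, invisibly.
#' @export
export_tables <- function(spec, tables, destination) {
  df <- do.call(rbind, lapply(seq_along(tables), function(r) {
    cbind(data.frame(scenario = spec$id, rep = r, n = spec$n),
          as.data.frame(tables[[r]]))
  }))
  utils::write.csv(df, destination, row.names = FALSE)
  invisible(destination)
}
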