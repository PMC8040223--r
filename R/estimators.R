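#' Wilson score confidence interval for a proportion
#'
#' Score-based binomial interval with good small-sample behaviour. The
#' interval is centred at `(p + z^2/2n) / (1 + z^2/n)` and both bounds are
#' guaranteed to lie in \[0, 1\].
#'
#' @param point Proportion in \[0, 1\]. Estimates outside the unit interval
#'   have no binomial interpretation and are rejected; callers must leave the
#'   CI absent for illogical estimates.
#' @param n Effective number of trials (>= 1). Need not be an integer: the
#'   corrected estimators use the relevant reference-standard margin.
#' @param conf Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' wilson_interval(40 / 62, 62)
#' @export
wilson_interval <- function(point, n, conf = 0.95) {
  if (!is_prob(point)) {
    abort("wilson_interval requires a point estimate in [0, 1]",
          "refcorrect_not_applicable")
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("n must be a single number >= 1", "refcorrect_not_applicable")
  }
  if (!is_prob(conf) || conf <= 0 || conf >= 1) {
    abort("conf must lie strictly between 0 and 1", "refcorrect_not_applicable")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (point + z^2 / (2 * n)) / denom
  half <- z * sqrt(point * (1 - point) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Wrap a raw point estimate, attaching a Wilson CI on margin n unless the
# estimate is illogical or CIs are switched off.
wrap_estimate <- function(value, n, conf, ci) {
  if (ci && value >= 0 && value <= 1) {
    accuracy_estimate(value, wilson_interval(value, n, conf))
  } else {
    accuracy_estimate(value)
  }
}

new_correction_result <- function(method, sensitivity, specificity,
                                  sample_prevalence, prevalence = NULL) {
  structure(list(method = method, sensitivity = sensitivity,
                 specificity = specificity, prevalence = prevalence,
                 sample_prevalence = sample_prevalence),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, digits = 2, ...) {
  cat(sprintf("%s estimates:\n", x$method))
  cat("  sensitivity:", format_estimate(x$sensitivity, digits), "\n")
  cat("  specificity:", format_estimate(x$specificity, digits), "\n")
  if (!is.null(x$prevalence)) {
    cat("  prevalence: ", format_estimate(x$prevalence, digits), "\n")
  }
  cat(sprintf("  sample prevalence (e/N): %.*f\n", digits + 2, x$sample_prevalence))
  invisible(x)
}

#' @export
as.data.frame.correction_result <- function(x, ...) {
  data.frame(
    method = x$method,
    sn = x$sensitivity$value, sn_lo = x$sensitivity$ci_lower,
    sn_hi = x$sensitivity$ci_upper, sn_illogical = x$sensitivity$illogical,
    sp = x$specificity$value, sp_lo = x$specificity$ci_lower,
    sp_hi = x$specificity$ci_upper, sp_illogical = x$specificity$illogical,
    prevalence = if (is.null(x$prevalence)) NA_real_ else x$prevalence$value,
    sample_prevalence = x$sample_prevalence,
    stringsAsFactors = FALSE
  )
}

check_ref <- function(ref) {
  if (!inherits(ref, "ref_accuracy")) {
    abort("ref must be a ref_accuracy object", "refcorrect_invalid_reference")
  }
  if (ref$j == 0) {
    abort("reference standard is uninformative: Youden's J = Sn_RS + Sp_RS - 1 is zero",
          "refcorrect_uninformative_reference")
  }
  invisible(ref)
}

#' Classical (unadjusted) sensitivity and specificity
#'
#' Treats the reference standard as a gold standard: `Sn = a/e`, `Sp = d/f`,
#' sample prevalence `Prr = e/N`. These are the "unadjusted" estimates that
#' the correction methods are compared against.
#'
#' @param table A [contingency_table()].
#' @param conf Confidence level for Wilson intervals.
#' @param ci Attach Wilson score intervals (`n = e` for sensitivity,
#'   `n = f` for specificity)?
#' @return A `correction_result` with method `"classical"`.
#' @examples
#' classical_estimate(contingency_table(40, 22, 22, 177))
#' @export
classical_estimate <- function(table, conf = 0.95, ci = TRUE) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$e == 0) {
    abort("reference-positive margin e = a + c is zero: sensitivity is undefined",
          "refcorrect_margin_degenerate")
  }
  if (table$f == 0) {
    abort("reference-negative margin f = b + d is zero: specificity is undefined",
          "refcorrect_margin_degenerate")
  }
  new_correction_result(
    "classical",
    wrap_estimate(table$a / table$e, table$e, conf, ci),
    wrap_estimate(table$d / table$f, table$f, conf, ci),
    table$e / table$N
  )
}

#' Staquet misclassification-corrected prevalence
#'
#' Corrects the apparent (reference-positive) prevalence `Prr = e/N` for the
#' known error rates of the reference standard:
#' `P = (N (Sp_RS - 1) + e) / (N J)` where `J` is the reference's Youden
#' index. This is the Rogan-Gladen-type adjustment; it can fall outside
#' \[0, 1\] (flagged `illogical`) when e.g. the reference sensitivity is
#' below the sample prevalence.
#'
#' @param table A [contingency_table()].
#' @param ref A [ref_accuracy()] with `j != 0`.
#' @return An [accuracy_estimate()] (no CI attached).
#' @export
staquet_prevalence <- function(table, ref) {
  stopifnot(inherits(table, "contingency_table"))
  check_ref(ref)
  accuracy_estimate((table$N * (ref$sp_rs - 1) + table$e) / (table$N * ref$j))
}

#' Staquet correction for an imperfect reference standard
#'
#' Closed-form correction assuming the index test and reference standard are
#' conditionally independent given true disease status and the reference's
#' sensitivity/specificity are known:
#' \deqn{Sn = (g\,Sp_{RS} - b) / (N(Sp_{RS}-1) + e), \quad
#'       Sp = (h\,Sn_{RS} - c) / (N\,Sn_{RS} - e)}
#' together with the corrected prevalence of [staquet_prevalence()].
#' Estimates may fall outside \[0, 1\] and are then flagged illogical with
#' no CI.
#'
#' @inheritParams classical_estimate
#' @param ref A [ref_accuracy()] with `j != 0`.
#' @return A `correction_result` with method `"staquet"` and a `prevalence`
#'   component.
#' @examples
#' staquet_correct(contingency_table(40, 22, 22, 177), ref_accuracy(0.74, 0.91))
#' @export
staquet_correct <- function(table, ref, conf = 0.95, ci = TRUE) {
  stopifnot(inherits(table, "contingency_table"))
  check_ref(ref)
  den_sn <- table$N * (ref$sp_rs - 1) + table$e
  den_sp <- table$N * ref$sn_rs - table$e
  if (den_sn == 0) {
    abort("degenerate reference configuration: N(Sp_RS - 1) + e is zero (corrected sensitivity undefined)",
          "refcorrect_degenerate_reference")
  }
  if (den_sp == 0) {
    abort("degenerate reference configuration: N * Sn_RS - e is zero (corrected specificity undefined)",
          "refcorrect_degenerate_reference")
  }
  new_correction_result(
    "staquet",
    wrap_estimate((table$g * ref$sp_rs - table$b) / den_sn, table$e, conf, ci),
    wrap_estimate((table$h * ref$sn_rs - table$c) / den_sp, table$f, conf, ci),
    table$e / table$N,
    prevalence = staquet_prevalence(table, ref)
  )
}

#' Gart-Buck correction for an imperfect reference standard
#'
#' The Gart-Buck estimators are parameterised through the classical
#' estimates (`Sn_IT`, `Sp_IT`, `Prr`) and the corrected prevalence `P`:
#' \deqn{Sn = \frac{Sp_{RS} Prr\, Sn_{IT} + (1-Sp_{RS})(1-Prr) Sp_{IT}
#'            - (1-Sp_{RS})(Sp_{RS} - \hat P J)}{\hat P J}}
#' and the analogous specificity form. Algebraically identical to
#' [staquet_correct()]; kept as an independent computational route so the
#' equivalence can be verified rather than assumed.
#'
#' @inheritParams staquet_correct
#' @return A `correction_result` with method `"gart_buck"`.
#' @export
gart_buck_correct <- function(table, ref, conf = 0.95, ci = TRUE) {
  stopifnot(inherits(table, "contingency_table"))
  check_ref(ref)
  cls <- classical_estimate(table, ci = FALSE)
  sn_it <- cls$sensitivity$value
  sp_it <- cls$specificity$value
  prr <- cls$sample_prevalence
  p_hat <- staquet_prevalence(table, ref)$value
  pj <- p_hat * ref$j
  if (pj == 0) {
    abort("degenerate reference configuration: P * J is zero (corrected sensitivity undefined)",
          "refcorrect_degenerate_reference")
  }
  if (ref$j * (1 - p_hat) == 0) {
    abort("degenerate reference configuration: J(1 - P) is zero (corrected specificity undefined)",
          "refcorrect_degenerate_reference")
  }
  sn <- (ref$sp_rs * prr * sn_it + (1 - ref$sp_rs) * (1 - prr) * sp_it -
           (1 - ref$sp_rs) * (ref$sp_rs - pj)) / pj
  sp <- (ref$sn_rs * (1 - prr) * sp_it + (1 - ref$sn_rs) * prr * sn_it -
           (1 - ref$sn_rs) * (1 - ref$sp_rs + pj)) / (ref$j * (1 - p_hat))
  new_correction_result(
    "gart_buck",
    wrap_estimate(sn, table$e, conf, ci),
    wrap_estimate(sp, table$f, conf, ci),
    prr,
    prevalence = accuracy_estimate(p_hat)
  )
}

#' Brenner estimators on the probability scale
#'
#' The Brenner correction written in terms of the apparent prevalence and
#' the classical estimates rather than raw counts:
#' \deqn{Sn = \frac{Prr\,Sn_{RS}\,Sn_{IT} + (1-Prr)(1-Sp_{RS})(1-Sp_{IT})}
#'            {Prr\,Sn_{RS} + (1-Prr)(1-Sp_{RS})}}
#' and analogously for specificity. Equivalent to the count form used by
#' [brenner_correct()], which verifies the agreement.
#'
#' @param prr Apparent prevalence `e/N`.
#' @param sn_it,sp_it Classical estimates of the index test.
#' @param ref A [ref_accuracy()].
#' @return Named numeric vector `c(sn, sp)`.
#' @export
brenner_probability_form <- function(prr, sn_it, sp_it, ref) {
  den_sn <- prr * ref$sn_rs + (1 - prr) * (1 - ref$sp_rs)
  den_sp <- prr * (1 - ref$sn_rs) + (1 - prr) * ref$sp_rs
  c(sn = (prr * ref$sn_rs * sn_it + (1 - prr) * (1 - ref$sp_rs) * (1 - sp_it)) / den_sn,
    sp = (prr * (1 - ref$sn_rs) * (1 - sn_it) + (1 - prr) * ref$sp_rs * sp_it) / den_sp)
}

#' Brenner correction for an imperfect reference standard
#'
#' Count-form Brenner estimators under conditional independence:
#' \deqn{Sn = (a\,Sn_{RS} + b(1-Sp_{RS})) / (e\,Sn_{RS} + f(1-Sp_{RS})),
#'   \quad Sp = (c(1-Sn_{RS}) + d\,Sp_{RS}) / (e(1-Sn_{RS}) + f\,Sp_{RS})}
#' Both estimates are convex combinations of observed proportions and thus
#' always lie in \[0, 1\]. When the classical estimates exist, the
#' probability-scale form ([brenner_probability_form()]) is recomputed and
#' agreement asserted as an internal consistency check.
#'
#' @inheritParams staquet_correct
#' @return A `correction_result` with method `"brenner"`.
#' @examples
#' brenner_correct(contingency_table(40, 22, 22, 177), ref_accuracy(0.74, 0.91))
#' @export
brenner_correct <- function(table, ref, conf = 0.95, ci = TRUE) {
  stopifnot(inherits(table, "contingency_table"))
  check_ref(ref)
  den_sn <- table$e * ref$sn_rs + table$f * (1 - ref$sp_rs)
  den_sp <- table$e * (1 - ref$sn_rs) + table$f * ref$sp_rs
  if (den_sn <= 0) {
    abort("degenerate input: e * Sn_RS + f(1 - Sp_RS) is not positive",
          "refcorrect_degenerate_input")
  }
  if (den_sp <= 0) {
    abort("degenerate input: e(1 - Sn_RS) + f * Sp_RS is not positive",
          "refcorrect_degenerate_input")
  }
  sn <- (table$a * ref$sn_rs + table$b * (1 - ref$sp_rs)) / den_sn
  sp <- (table$c * (1 - ref$sn_rs) + table$d * ref$sp_rs) / den_sp
  if (table$e > 0 && table$f > 0) {
    cls <- classical_estimate(table, ci = FALSE)
    prob <- brenner_probability_form(cls$sample_prevalence,
                                     cls$sensitivity$value,
                                     cls$specificity$value, ref)
    stopifnot(abs(prob[["sn"]] - sn) < 1e-10, abs(prob[["sp"]] - sp) < 1e-10)
  }
  new_correction_result(
    "brenner",
    wrap_estimate(sn, table$e, conf, ci),
    wrap_estimate(sp, table$f, conf, ci),
    table$e / table$N
  )
}

#' Apply several estimation methods to one table
#'
#' @inheritParams staquet_correct
#' @param methods Subset of `"classical"`, `"brenner"`, `"staquet"`,
#'   `"gart_buck"`.
#' @return Named list of `correction_result` objects.
#' @export
correct_all <- function(table, ref,
                        methods = c("classical", "brenner", "staquet"),
                        conf = 0.95, ci = TRUE) {
  methods <- match.arg(methods, c("classical", "brenner", "staquet", "gart_buck"),
                       several.ok = TRUE)
  out <- lapply(methods, function(m) {
    switch(m,
           classical = classical_estimate(table, conf, ci),
           brenner = brenner_correct(table, ref, conf, ci),
           staquet = staquet_correct(table, ref, conf, ci),
           gart_buck = gart_buck_correct(table, ref, conf, ci))
  })
  names(out) <- methods
  out
}
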