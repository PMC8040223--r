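case_study_path <- function() {
  system.file("extdata", "clinical_case_studies.csv", package = "refcorrect",
              mustWork = TRUE)
}

#' Identifiers of the packaged clinical case studies
#'
#' @return Character vector of valid ids for [load_case_study()].
#' @export
case_study_ids <- function() {
  utils::read.csv(case_study_path(), stringsAsFactors = FALSE)$id
}

#' Load a packaged clinical case study
#'
#' Five published 2x2 comparisons of an index test against an imperfect
#' reference standard with externally validated accuracy:
#' * `mathews_hra` - high-resolution anoscopy cytology vs punch biopsy
#'   (reference Sn 0.74, Sp 0.91), anal intraepithelial neoplasia;
#' * `matos_nc_lfpen`, `matos_nc_fc` - laser-fluorescence pen / fluorescence
#'   camera vs visual inspection for non-cavitated occlusal caries
#'   (reference Sn 0.796, Sp 0.799);
#' * `matos_d3_lfpen`, `matos_d3_fc` - the same devices for dentine caries
#'   (reference Sn 0.786, Sp 0.995).
#'
#' Each fixture is checked against the published margin totals at load time
#' so that a corrupted fixture cannot silently propagate.
#'
#' @param id One of [case_study_ids()].
#' @return An object of class `case_study`: list with `id`, `description`,
#'   `condition`, `table` ([contingency_table()]) and `ref`
#'   ([ref_accuracy()]).
#' @examples
#' cs <- load_case_study("mathews_hra")
#' cs$table$N
#' @export
load_case_study <- function(id) {
  fixtures <- utils::read.csv(case_study_path(), stringsAsFactors = FALSE)
  if (length(id) != 1L || !id %in% fixtures$id) {
    abort(sprintf("unknown case study '%s'; valid ids: %s",
                  paste(id, collapse = ","),
                  paste(fixtures$id, collapse = ", ")),
          "refcorrect_unknown_case")
  }
  row <- fixtures[fixtures$id == id, ]
  tab <- contingency_table(row$a, row$b, row$c, row$d)
  if (tab$e != row$e_check || tab$N != row$n_check) {
    abort(sprintf("fixture '%s' fails margin validation (e = %d vs %d, N = %d vs %d)",
                  id, tab$e, row$e_check, tab$N, row$n_check),
          "refcorrect_invalid_table")
  }
  structure(
    list(id = id, description = row$description, condition = row$condition,
         table = tab, ref = ref_accuracy(row$sn_rs, row$sp_rs)),
    class = "case_study"
  )
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("Case study '%s' (%s)\n%s\n", x$id, x$condition, x$description))
  print(x$table)
  print(x$ref)
  invisible(x)
}

#' Analyse a clinical case study with all estimation methods
#'
#' Applies the classical, Brenner and Staquet estimators (plus Gart-Buck as
#' a cross-check on Staquet) to the case-study table and attaches Wilson
#' score intervals (`n = e` for sensitivity, `n = f` for specificity).
#'
#' `ci_points` controls the point at which corrected-method intervals are
#' evaluated. `"published"` (default) recomputes them from the point
#' estimate rounded to 2 decimal places - the convention evidently used to
#' produce the published clinical tables - while `"full"` uses the
#' full-precision estimate. Classical intervals always use the exact count
#' ratio. Point estimates themselves are always kept at full precision;
#' rounding is a presentation concern.
#'
#' @param cs A `case_study` from [load_case_study()].
#' @param ci_points `"published"` or `"full"` (see Details).
#' @param conf Confidence level.
#' @return An object of class `case_study_analysis`: list with `id`,
#'   `results` (a data frame with one row per method and measure: columns
#'   `method, measure, estimate, ci_lower, ci_upper, illogical`),
#'   `prevalence` (Staquet-corrected, an [accuracy_estimate()]) and
#'   `sample_prevalence`.
#' @examples
#' analyze_case_study(load_case_study("mathews_hra"))
#' @export
analyze_case_study <- function(cs, ci_points = c("published", "full"),
                               conf = 0.95) {
  stopifnot(inherits(cs, "case_study"))
  ci_points <- match.arg(ci_points)
  fits <- correct_all(cs$table, cs$ref,
                      methods = c("classical", "brenner", "staquet", "gart_buck"),
                      conf = conf)
  # gart_buck is retained purely as an internal consistency check
  stopifnot(
    abs(fits$gart_buck$sensitivity$value - fits$staquet$sensitivity$value) < 1e-9,
    abs(fits$gart_buck$specificity$value - fits$staquet$specificity$value) < 1e-9
  )
  rows <- lapply(c("classical", "brenner", "staquet"), function(m) {
    fit <- fits[[m]]
    do.call(rbind, lapply(c("sensitivity", "specificity"), function(measure) {
      est <- fit[[measure]]
      n_ci <- if (measure == "sensitivity") cs$table$e else cs$table$f
      if (!est$illogical && ci_points == "published" && m != "classical") {
        ci <- wilson_interval(round(est$value, 2), n_ci, conf)
        est <- accuracy_estimate(est$value, ci)
      }
      data.frame(method = m, measure = measure, estimate = est$value,
                 ci_lower = est$ci_lower, ci_upper = est$ci_upper,
                 illogical = est$illogical, stringsAsFactors = FALSE)
    }))
  })
  structure(
    list(id = cs$id, condition = cs$condition,
         results = do.call(rbind, rows),
         prevalence = fits$staquet$prevalence,
         sample_prevalence = fits$staquet$sample_prevalence),
    class = "case_study_analysis"
  )
}

#' @export
print.case_study_analysis <- function(x, digits = 2, ...) {
  cat(sprintf("Unadjusted and corrected accuracy, case study '%s' (%s)\n",
              x$id, x$condition))
  wide <- function(measure) {
    sub <- x$results[x$results$measure == measure, ]
    vapply(seq_len(nrow(sub)), function(i) {
      format_estimate(accuracy_estimate(
        sub$estimate[i],
        if (is.na(sub$ci_lower[i])) NULL else c(sub$ci_lower[i], sub$ci_upper[i])
      ), digits)
    }, character(1))
  }
  m <- rbind(Sensitivity = wide("sensitivity"), Specificity = wide("specificity"))
  colnames(m) <- c("Unadjusted (95% CI)", "Brenner (95% CI)", "Staquet (95% CI)")
  print(m, quote = FALSE)
  cat(sprintf("Sample prevalence e/N: %.3f   Staquet estimated prevalence: %.*f%s\n",
              x$sample_prevalence, digits, x$prevalence$value,
              if (x$prevalence$illogical) " (illogical)" else ""))
  invisible(x)
}
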