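#' @keywords internal
abort <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "refcorrect_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

#' 2x2 contingency table of index test vs reference standard
#'
#' Builds the standard 2x2 cross-classification of a binary index test (IT)
#' against a binary reference standard (RS). Cell `a` counts IT+/RS+
#' participants, `b` IT+/RS-, `c` IT-/RS+ and `d` IT-/RS-. Margins are
#' derived: `e = a + c` (RS positive), `f = b + d` (RS negative),
#' `g = a + b` (IT positive), `h = c + d` (IT negative), `N = a+b+c+d`.
#'
#' @param a,b,c,d Non-negative cell counts. Must be whole numbers unless
#'   `fractional = TRUE`.
#' @param fractional Allow non-integer cells. Expected-count tables
#'   (`N * p_ij`) used for algebraic plug-in checks are fractional; observed
#'   data never are.
#' @return An object of class `contingency_table`: a list with components
#'   `a`, `b`, `c`, `d`, `e`, `f`, `g`, `h`, `N`.
#' @examples
#' tab <- contingency_table(40, 22, 22, 177)
#' tab$e  # reference-standard positive margin
#' @export
contingency_table <- function(a, b, c, d, fractional = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!is.numeric(cells) || length(cells) != 4L || anyNA(cells)) {
    abort("all four cell counts must be single non-missing numbers",
          "refcorrect_invalid_table")
  }
  if (any(cells < 0)) {
    abort("cell counts must be non-negative", "refcorrect_invalid_table")
  }
  if (!fractional && any(abs(cells - round(cells)) > 1e-8)) {
    abort("cell counts must be whole numbers (use fractional = TRUE for expected-count tables)",
          "refcorrect_invalid_table")
  }
  if (sum(cells) <= 0) {
    abort("total count N must be positive", "refcorrect_invalid_table")
  }
  structure(
    list(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
         e = unname(a + c), f = unname(b + d),
         g = unname(a + b), h = unname(c + d),
         N = unname(a + b + c + d)),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$e, x$b, x$d, x$f, x$g, x$h, x$N), nrow = 3,
              dimnames = list(c("IT+", "IT-", "Total"),
                              c("RS+", "RS-", "Total")))
  cat("2x2 contingency table (index test vs reference standard)\n")
  print(m)
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  data.frame(a = x$a, b = x$b, c = x$c, d = x$d)
}

#' Known accuracy of the imperfect reference standard
#'
#' Holds the (externally known) sensitivity and specificity of the reference
#' standard together with its Youden index `j = sn_rs + sp_rs - 1`. All
#' correction formulas divide by `j`; a reference with `j = 0` carries no
#' information about the latent disease status and is rejected at the point
#' of use.
#'
#' @param sn_rs,sp_rs Probabilities in \[0, 1\].
#' @return An object of class `ref_accuracy` with components `sn_rs`,
#'   `sp_rs`, `j`.
#' @examples
#' ref_accuracy(0.74, 0.91)
#' @export
ref_accuracy <- function(sn_rs, sp_rs) {
  if (!is_prob(sn_rs) || !is_prob(sp_rs)) {
    abort("sn_rs and sp_rs must be probabilities in [0, 1]",
          "refcorrect_invalid_reference")
  }
  structure(list(sn_rs = sn_rs, sp_rs = sp_rs, j = sn_rs + sp_rs - 1),
            class = "ref_accuracy")
}

#' @export
print.ref_accuracy <- function(x, ...) {
  cat(sprintf("Reference standard accuracy: Sn = %.4g, Sp = %.4g (Youden J = %.4g)\n",
              x$sn_rs, x$sp_rs, x$j))
  invisible(x)
}

#' Point estimate with illogical flag and optional Wilson interval
#'
#' Corrected estimates are deliberately not clamped to \[0, 1\]: a value
#' outside the unit interval ("illogical") is diagnostic information in its
#' own right. The `illogical` flag is true exactly when `value < 0` or
#' `value > 1`, in which case any confidence interval is suppressed
#' (`NA`), matching the convention of printing "NaN" for such estimates.
#'
#' @param value Real point estimate.
#' @param ci Optional numeric length-2 vector `(lower, upper)`; dropped when
#'   the estimate is illogical.
#' @return An object of class `accuracy_estimate` with components `value`,
#'   `illogical`, `ci_lower`, `ci_upper`.
#' @export
accuracy_estimate <- function(value, ci = NULL) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    abort("value must be a single non-missing number", "refcorrect_invalid_estimate")
  }
  illogical <- value < 0 || value > 1
  if (illogical || is.null(ci)) {
    lo <- NA_real_; hi <- NA_real_
  } else {
    lo <- ci[[1]]; hi <- ci[[2]]
  }
  structure(list(value = value, illogical = illogical,
                 ci_lower = lo, ci_upper = hi),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, digits = 2, ...) {
  cat(format_estimate(x, digits), "\n")
  invisible(x)
}

# "0.65 (0.52, 0.75)" presentation used by the clinical report; illogical
# estimates print the raw value with "(NaN)" like the published tables.
format_estimate <- function(x, digits = 2) {
  if (x$illogical) {
    sprintf("%.*f (NaN)", digits, x$value)
  } else if (is.na(x$ci_lower)) {
    sprintf("%.*f", digits, x$value)
  } else {
    sprintf("%.*f (%.*f, %.*f)", digits, x$value, digits, x$ci_lower,
            digits, x$ci_upper)
  }
}

#' Read a 2x2 table from a CSV or JSON file
#'
#' CSV input must have a header row containing columns `a,b,c,d`; JSON input
#' must be an object with those keys.
#'
#' @param path File path; format inferred from the `.json` / `.csv`
#'   extension (anything else is parsed as CSV).
#' @return A [contingency_table()].
#' @export
read_contingency_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), "refcorrect_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path)
  } else {
    rec <- utils::read.csv(path)[1, , drop = FALSE]
  }
  missing <- setdiff(c("a", "b", "c", "d"), names(rec))
  if (length(missing)) {
    abort(sprintf("table input is missing field(s): %s",
                  paste(missing, collapse = ", ")),
          "refcorrect_parse_error")
  }
  contingency_table(as.numeric(rec[["a"]]), as.numeric(rec[["b"]]),
                    as.numeric(rec[["c"]]), as.numeric(rec[["d"]]))
}
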