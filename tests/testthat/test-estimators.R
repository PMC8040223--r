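test_that("classical estimates match the published values and handle degeneracy", {
  res <- classical_estimate(tab_hra())
  expect_equal(round(res$sensitivity$value, 2), 0.65)
  expect_equal(round(res$specificity$value, 2), 0.89)
  expect_equal(res$sample_prevalence, 62 / 261)
  expect_false(res$sensitivity$illogical)

  fc <- classical_estimate(contingency_table(21, 38, 0, 348))
  expect_equal(round(fc$sensitivity$value, 2), 1.00)
  expect_equal(round(fc$specificity$value, 2), 0.90)

  perfect <- classical_estimate(contingency_table(10, 0, 0, 10))
  expect_equal(perfect$sensitivity$value, 1)
  expect_equal(perfect$specificity$value, 1)

  expect_error(classical_estimate(contingency_table(0, 5, 0, 5)),
               class = "refcorrect_margin_degenerate")
  expect_error(classical_estimate(contingency_table(5, 0, 5, 0)),
               class = "refcorrect_margin_degenerate")
})

test_that("Staquet correction reproduces the published estimates", {
  res <- staquet_correct(tab_hra(), ref_hra())
  expect_equal(round(res$sensitivity$value, 2), 0.89)
  expect_equal(round(res$specificity$value, 2), 0.96)

  lfpen <- staquet_correct(contingency_table(20, 45, 1, 341),
                           ref_accuracy(0.786, 0.995))
  expect_equal(round(lfpen$sensitivity$value, 2), 1.04)
  expect_true(lfpen$sensitivity$illogical)
  expect_true(is.na(lfpen$sensitivity$ci_lower))
  expect_false(lfpen$specificity$illogical)
})

test_that("Staquet prevalence matches the published values including illogical flag", {
  nc <- staquet_prevalence(contingency_table(241, 6, 110, 26),
                           ref_accuracy(0.796, 0.799))
  expect_equal(round(nc$value, 1), 1.2)
  expect_true(nc$illogical)

  d3 <- staquet_prevalence(contingency_table(20, 45, 1, 341),
                           ref_accuracy(0.786, 0.995))
  expect_equal(round(d3$value, 2), 0.06)
  expect_false(d3$illogical)

  # perfect reference: corrected prevalence collapses to e/N
  tab <- tab_hra()
  expect_equal(staquet_prevalence(tab, ref_accuracy(1, 1))$value, tab$e / tab$N)
  expect_error(staquet_prevalence(tab, ref_accuracy(0.3, 0.7)),
               class = "refcorrect_uninformative_reference")
})

test_that("Brenner correction reproduces the published estimates", {
  res <- brenner_correct(tab_hra(), ref_hra())
  expect_equal(round(res$sensitivity$value, 2), 0.50)
  expect_equal(round(res$specificity$value, 2), 0.85)

  fc <- brenner_correct(contingency_table(21, 38, 0, 348),
                        ref_accuracy(0.786, 0.995))
  expect_equal(round(fc$sensitivity$value, 2), 0.91)
})

test_that("Brenner closed form on scenario-one expected counts", {
  tab <- expected_table(0.3, 0.8, 0.7, 0.9, 0.9, N = 1)
  res <- brenner_correct(tab, ref_accuracy(0.9, 0.9), ci = FALSE)
  expect_equal(res$sensitivity$value, 0.2346 / 0.372, tolerance = 1e-12)
  expect_equal(res$specificity$value, 0.4126 / 0.628, tolerance = 1e-12)
})

test_that("Gart-Buck equals Staquet (algebraic equivalence, property check)", {
  gb <- gart_buck_correct(tab_hra(), ref_hra())
  st <- staquet_correct(tab_hra(), ref_hra())
  expect_equal(gb$sensitivity$value, 0.8937938, tolerance = 1e-6)
  expect_lt(abs(gb$sensitivity$value - st$sensitivity$value), 1e-9)
  expect_lt(abs(gb$specificity$value - st$specificity$value), 1e-9)

  # Table 5 LFpen published Gart-Buck specificity
  gb2 <- gart_buck_correct(contingency_table(241, 6, 110, 26),
                           ref_accuracy(0.796, 0.799))
  expect_equal(round(gb2$specificity$value, 2), 0.04)

  set.seed(421)
  for (i in 1:250) {
    rv <- random_valid_table()
    st <- staquet_correct(rv$table, rv$ref, ci = FALSE)
    gb <- gart_buck_correct(rv$table, rv$ref, ci = FALSE)
    expect_lt(abs(st$sensitivity$value - gb$sensitivity$value), 1e-9)
    expect_lt(abs(st$specificity$value - gb$specificity$value), 1e-9)
  }
})

test_that("perfect reference collapses all methods to the classical estimates", {
  set.seed(99)
  perfect <- ref_accuracy(1, 1)
  for (i in 1:25) {
    tab <- random_valid_table()$table
    cls <- classical_estimate(tab, ci = FALSE)
    for (fit in list(staquet_correct(tab, perfect, ci = FALSE),
                     gart_buck_correct(tab, perfect, ci = FALSE),
                     brenner_correct(tab, perfect, ci = FALSE))) {
      expect_equal(fit$sensitivity$value, cls$sensitivity$value, tolerance = 1e-12)
      expect_equal(fit$specificity$value, cls$specificity$value, tolerance = 1e-12)
    }
  }
})

test_that("Staquet recovers the truth exactly on expected-count tables", {
  set.seed(2024)
  for (i in 1:100) {
    p <- runif(1, 0.05, 0.95)
    sn_it <- runif(1, 0.05, 0.95); sp_it <- runif(1, 0.05, 0.95)
    repeat {
      sn_rs <- runif(1, 0.05, 0.95); sp_rs <- runif(1, 0.05, 0.95)
      if (abs(sn_rs + sp_rs - 1) > 0.05) break
    }
    tab <- expected_table(p, sn_it, sp_it, sn_rs, sp_rs, N = 750)
    fit <- staquet_correct(tab, ref_accuracy(sn_rs, sp_rs), ci = FALSE)
    expect_equal(fit$sensitivity$value, sn_it, tolerance = 1e-10)
    expect_equal(fit$specificity$value, sp_it, tolerance = 1e-10)
    expect_equal(fit$prevalence$value, p, tolerance = 1e-10)
  }
})

test_that("Wilson interval matches published intervals and respects bounds", {
  expect_equal(round(wilson_interval(40 / 62, 62), 2),
               c(lower = 0.52, upper = 0.75))
  expect_equal(round(wilson_interval(177 / 199, 199), 2),
               c(lower = 0.84, upper = 0.93))
  expect_equal(wilson_interval(0, 50)[["lower"]], 0)
  expect_equal(wilson_interval(1, 50)[["upper"]], 1)

  set.seed(11)
  z <- qnorm(0.975)
  for (i in 1:200) {
    p <- runif(1); n <- sample(1:500, 1)
    ci <- wilson_interval(p, n)
    expect_true(ci[["lower"]] >= 0 && ci[["upper"]] <= 1)
    expect_lte(ci[["lower"]], ci[["upper"]])
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    expect_lte(ci[["lower"]], centre + 1e-12)
    expect_gte(ci[["upper"]], centre - 1e-12)
  }
  expect_error(wilson_interval(1.04, 62), class = "refcorrect_not_applicable")
  expect_error(wilson_interval(0.5, 0), class = "refcorrect_not_applicable")
})

test_that("degenerate reference configurations raise typed errors", {
  # N(Sp_RS - 1) + e = 0: e = 10, N = 20, Sp_RS = 0.5
  expect_error(staquet_correct(contingency_table(5, 5, 5, 5),
                               ref_accuracy(0.9, 0.5)),
               class = "refcorrect_degenerate_reference")
  # N Sn_RS - e = 0
  expect_error(staquet_correct(contingency_table(5, 5, 5, 5),
                               ref_accuracy(0.5, 0.9)),
               class = "refcorrect_degenerate_reference")
  # Brenner denominator zero: e = 0 with Sn_RS = 1, or f = 0 with Sp_RS = 1
  expect_error(brenner_correct(contingency_table(0, 5, 0, 5),
                               ref_accuracy(0.8, 1)),
               class = "refcorrect_degenerate_input")
})

test_that("correct_all returns one tidy record per method", {
  fits <- correct_all(tab_hra(), ref_hra(),
                      methods = c("classical", "brenner", "staquet", "gart_buck"))
  df <- do.call(rbind, lapply(fits, as.data.frame))
  expect_equal(nrow(df), 4)
  expect_setequal(df$method, c("classical", "brenner", "staquet", "gart_buck"))
  expect_true(all(c("sn", "sn_lo", "sn_hi", "sp", "sp_lo", "sp_hi",
                    "prevalence", "sn_illogical", "sp_illogical") %in% names(df)))
  expect_false(any(df$sn_illogical))
})
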