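# Viability normalization and four-parameter logistic fitting.

test_that("two-step normalization maps the vehicle mean to exactly 1", {
  raw <- tibble::tibble(
    role = c(rep("cells", 4), rep("vehicle", 4), rep("drug", 4)),
    response = c(2000, 2100, 1900, 2000, 1800, 1900, 1850, 1850, 400, 380, 420, 410)
  )
  out <- normalize_viability(raw, raw$role == "cells", raw$role == "vehicle")
  expect_equal(mean(out$response_norm[raw$role == "vehicle"]), 1)
  # a plate of pure cells-alone values goes to 1 after step one
  ca <- normalize_viability(raw, raw$role == "cells", raw$role == "cells")
  expect_equal(mean(ca$response_norm[raw$role == "cells"]), 1)
  expect_error(normalize_viability(raw, raw$role == "cells", raw$role == "nope"),
               class = "nucmorph_normalization_error")
  zero <- dplyr::mutate(raw, response = 0)
  expect_error(normalize_viability(zero, raw$role == "cells", raw$role == "vehicle"),
               class = "nucmorph_normalization_error")
})

test_that("noiseless 4PL data are recovered to numerical precision", {
  tab <- make_viability_table(top = 100, bottom = 0, logic50 = 0, hill = -1,
                              noise_sd = 0, seed = 1)
  fit <- fit_4pl(tab$dose_um, tab$response)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 1, tolerance = 1e-6)
  expect_equal(fit$hill, -1, tolerance = 1e-5)
  # the fitted curve passes through its own midpoint at X = LogIC50
  mid <- fourpl(fit$logic50, fit$top, fit$bottom, fit$logic50, fit$hill)
  expect_equal(mid, (fit$top + fit$bottom) / 2)
})

test_that("fits are canonicalised to Top >= Bottom and stay monotone", {
  tab <- make_viability_table(logic50 = 0.5, hill = -1.3, noise_sd = 2, seed = 5)
  fit <- fit_4pl(tab$dose_um, tab$response)
  expect_gte(fit$top, fit$bottom)
  grid <- seq(-4, 3, length.out = 200)
  curve <- fourpl(grid, fit$top, fit$bottom, fit$logic50, fit$hill)
  expect_true(all(diff(curve) <= 1e-12) || all(diff(curve) >= -1e-12))
})

test_that("dose rescaling shifts the IC50 exactly proportionally", {
  tab <- make_viability_table(logic50 = -0.2, noise_sd = 2, seed = 8)
  f1 <- fit_4pl(tab$dose_um, tab$response)
  f2 <- fit_4pl(tab$dose_um * 1000, tab$response)
  expect_equal(f2$ic50 / f1$ic50, 1000, tolerance = 1e-6)
})

test_that("median IC50 recovery over 100 simulated plates is within 10%", {
  errs <- vapply(1:100, function(s) {
    tab <- make_viability_table(logic50 = log10(0.94), noise_sd = 3, seed = 600 + s)
    abs(fit_4pl(tab$dose_um, tab$response)$ic50 - 0.94) / 0.94
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("ic50_ratio reproduces the printed potency differentials", {
  t1 <- make_viability_table(logic50 = 0, noise_sd = 0)
  f1 <- fit_4pl(t1$dose_um, t1$response)
  expect_equal(ic50_ratio(f1, f1), 1)
  # arithmetic on the three 48-h IC50s: 11.19/0.94 and 23.16/0.94
  ta <- make_viability_table(logic50 = log10(11.19), noise_sd = 0)
  tb <- make_viability_table(logic50 = log10(0.94), noise_sd = 0)
  tc <- make_viability_table(logic50 = log10(23.16), noise_sd = 0)
  fa <- fit_4pl(ta$dose_um, ta$response)
  fb <- fit_4pl(tb$dose_um, tb$response)
  fc <- fit_4pl(tc$dose_um, tc$response)
  expect_equal(ic50_ratio(fa, fb), 11.90, tolerance = 0.005)
  expect_equal(ic50_ratio(fc, fb), 24.64, tolerance = 0.005)
})

test_that("dr_fit objects expose tidy, glance and autoplot views", {
  tab <- make_viability_table(logic50 = 0.2, noise_sd = 3, seed = 2)
  fit <- fit_4pl(tab$dose_um, tab$response)
  td <- tidy(fit)
  expect_identical(td$term, c("top", "bottom", "logic50", "hill"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_identical(names(gl), c("ic50", "sigma", "converged", "nobs"))
  expect_equal(gl$nobs, 60L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_error(fit_4pl(c(1, 10, 100), c(90, 50, 10)),
               class = "nucmorph_value_error") # < 4 distinct doses
})
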