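# Summaries, distribution comparisons, normality, Pfaffl, exports.

toy_features <- function(values_by_condition, feature = "nuclear_volume") {
  dplyr::bind_rows(purrr::imap(values_by_condition, function(v, cond) {
    tibble::tibble(cell_id = sprintf("c%03d", seq_along(v)), condition = cond,
                   feature = feature, value = v, unit = "um3")
  }))
}

test_that("summaries report mean, sd/sqrt(n) and n", {
  ft <- toy_features(list(a = c(1, 2, 3), b = c(5, 5, 5, 5)))
  s <- summarize_features(ft)
  sa <- s[s$condition == "a", ]
  expect_equal(sa$mean, 2)
  expect_equal(sa$sem, 1 / sqrt(3))
  expect_equal(sa$n, 3L)
  sb <- s[s$condition == "b", ]
  expect_equal(sb$sem, 0)
  expect_error(summarize_features(toy_features(list(a = 1))),
               class = "nucmorph_value_error")
  # permutation invariance
  ft2 <- ft[sample.int(nrow(ft)), ]
  expect_equal(summarize_features(ft2), s)
})

test_that("Mann-Whitney reports U with complete-separation and identity anchors", {
  mw <- compare_groups(c(1, 2, 3), c(10, 20, 30), "mann-whitney")
  expect_equal(mw$statistic, 0) # U for the first group under separation
  same <- compare_groups(c(1, 5, 9, 3), c(1, 5, 9, 3), "mann-whitney")
  expect_gte(same$p_value, 0.99)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), class = "nucmorph_value_error")
})

test_that("rank tests are invariant under common monotone transforms", {
  set.seed(4)
  a <- rnorm(40, 1)
  b <- rnorm(40, 1.6)
  f <- function(x) exp(x / 2) + x^3 / 50
  for (test in c("mann-whitney", "ks")) {
    r1 <- compare_groups(a, b, test)
    r2 <- compare_groups(f(a), f(b), test)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  }
})

test_that("condition comparisons apply a Bonferroni family correction", {
  set.seed(8)
  ft <- dplyr::bind_rows(lapply(c("volume", "nc", "concavity", "clumps"), function(f) {
    toy_features(list(dmso = rnorm(30), vstat = rnorm(30, 0.5)), feature = f)
  }))
  cmp <- compare_conditions(ft, "vstat", "dmso", "mann-whitney")
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$adjusted_p, pmin(1, cmp$p_value * 4))
  expect_true(all(cmp$adjusted_p >= cmp$p_value))
})

test_that("Anderson-Darling flags bimodality and passes normal samples", {
  set.seed(12)
  norm_p <- normality(rnorm(100))
  expect_gt(norm_p$p_value, 0.001)
  bimodal <- c(rnorm(50, -3, 1), rnorm(50, 3, 1))
  bi <- normality(bimodal)
  expect_lt(bi$p_value, 0.01)
  expect_gt(bi$a_stat, norm_p$a_stat)
  expect_error(normality(rep(1, 20)), class = "nucmorph_value_error")
  expect_error(normality(rnorm(5)), class = "nucmorph_value_error")
})

test_that("pfaffl_ratio satisfies its exact identities", {
  expect_equal(pfaffl_ratio(2, 2, 0, 0), 1)
  expect_equal(pfaffl_ratio(2, 2, 1, 0), 2)
  expect_equal(pfaffl_ratio(1.9, 1.7, 2.5, 2.5), 1.9^2.5 / 1.7^2.5)
  for (e in c(1.5, 1.8, 2)) expect_equal(pfaffl_ratio(e, e, 3.3, 3.3), 1)
  expect_error(pfaffl_ratio(2.4, 2, 1, 1), class = "nucmorph_domain_error")
  expect_error(pfaffl_ratio(2, 0.9, 1, 1), class = "nucmorph_domain_error")
})

test_that("histogram exports conserve counts and round-trip their CSV", {
  set.seed(3)
  ft <- toy_features(list(dmso = rnorm(200, 10), vstat = rnorm(200, 8)))
  dir <- withr::local_tempdir()
  out <- export_histograms(ft, dir, bins = 20)
  sums <- out$counts |>
    dplyr::group_by(condition) |>
    dplyr::summarise(n = sum(count))
  expect_true(all(sums$n == 200))
  back <- readr::read_csv(file.path(dir, "histograms.csv"), show_col_types = FALSE)
  expect_equal(back$count, out$counts$count)
  single <- export_histograms(toy_features(list(only = rnorm(50))), dir)
  expect_equal(sum(single$counts$count), 50)
})

test_that("box-plot summaries report median, quartiles and 1.5 IQR whiskers", {
  set.seed(6)
  v <- c(rnorm(99), 8) # one extreme point beyond the whisker
  ft <- toy_features(list(a = v))
  dir <- withr::local_tempdir()
  st <- export_boxplots(ft, dir)$stats
  expect_equal(st$median, median(v))
  expect_equal(st$q1, quantile(v, 0.25, names = FALSE))
  expect_lt(st$whisker_hi, 8)
  expect_true(file.exists(file.path(dir, "boxplots.csv")))
})
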