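#' Per-condition summary: mean, SEM, n
#'
#' Mean plus standard error of the mean (`sd / sqrt(n)`) for each
#' (condition, feature) cell of a feature table, the summary convention of
#' per-cell morphometry reporting.
#'
#' @param features a feature table ([feature_table()]).
#' @param feature,condition optional filters (character vectors).
#' @return Tibble with `condition`, `feature`, `mean`, `sem`, `n`, `unit`.
#' @export
summarize_features <- function(features, feature = NULL, condition = NULL) {
  features <- feature_table(features)
  if (!is.null(feature)) features <- dplyr::filter(features, .data$feature %in% !!feature)
  if (!is.null(condition)) features <- dplyr::filter(features, .data$condition %in% !!condition)
  out <- features |>
    dplyr::group_by(.data$condition, .data$feature, .data$unit) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("condition", "feature", "mean", "sem", "n", "unit")))
  if (any(out$n < 2)) {
    abort("need at least 2 observations per (condition, feature) for a SEM",
          class = "nucmorph_value_error")
  }
  out
}

#' Two-sample distribution comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) or Kolmogorov-Smirnov test.
#' Mann-Whitney uses the exact distribution when both groups have at most 20
#' observations and no ties, otherwise the normal approximation with mid-rank
#' tie handling and continuity correction. Identical samples short-circuit
#' to p = 1.
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param test `"mann-whitney"` or `"ks"`.
#' @return One-row tibble: `test`, `statistic` (U for Mann-Whitney, D for
#'   KS), `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, test = c("mann-whitney", "ks")) {
  test <- match.arg(test)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs at least 3 observations",
          class = "nucmorph_value_error")
  }
  if (length(a) == length(b) && all(sort(a) == sort(b))) {
    stat <- if (test == "mann-whitney") length(a) * length(b) / 2 else 0
    return(tibble::tibble(test = test, statistic = stat, p_value = 1,
                          n_a = length(a), n_b = length(b)))
  }
  if (test == "mann-whitney") {
    exact <- length(a) <= 20 && length(b) <= 20 &&
      !anyDuplicated(c(a, b))
    ht <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  } else {
    ht <- suppressWarnings(stats::ks.test(a, b))
  }
  tibble::tibble(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value, n_a = length(a), n_b = length(b))
}

#' Compare two conditions of a feature table, feature by feature
#'
#' Runs [compare_groups()] for every feature present in both conditions and
#' applies a Bonferroni correction across the family of features within the
#' pair (the morphometric family has 4 members), reported as
#' `adjusted_p`.
#'
#' @param features a feature table.
#' @param condition_a,condition_b condition labels to compare.
#' @param test passed to [compare_groups()].
#' @return Tibble with one row per feature: `feature`, `condition_a`,
#'   `condition_b`, `test`, `statistic`, `p_value`, `adjusted_p`, `n_a`,
#'   `n_b`.
#' @export
compare_conditions <- function(features, condition_a, condition_b,
                               test = c("mann-whitney", "ks")) {
  test <- match.arg(test)
  features <- feature_table(features)
  fa <- dplyr::filter(features, .data$condition == condition_a)
  fb <- dplyr::filter(features, .data$condition == condition_b)
  shared <- intersect(unique(fa$feature), unique(fb$feature))
  if (length(shared) == 0) {
    abort("no shared features between conditions", class = "nucmorph_value_error")
  }
  rows <- purrr::map(shared, function(ft) {
    compare_groups(fa$value[fa$feature == ft], fb$value[fb$feature == ft], test) |>
      dplyr::mutate(feature = ft, .before = 1)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      condition_a = condition_a, condition_b = condition_b,
      adjusted_p = pmin(1, .data$p_value * length(shared))
    ) |>
    dplyr::select(dplyr::all_of(c("feature", "condition_a", "condition_b", "test",
                                  "statistic", "p_value", "adjusted_p",
                                  "n_a", "n_b")))
}

#' Anderson-Darling normality assessment
#'
#' Case-3 Anderson-Darling test (mean and variance estimated from the
#' sample) with the small-sample correction, via `nortest::ad.test()`.
#' Large A means stronger departure from normality.
#'
#' @param x numeric sample, n >= 8.
#' @return One-row tibble: `a_stat`, `p_value`, `n`.
#' @export
normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8) {
    abort("Anderson-Darling needs at least 8 observations",
          class = "nucmorph_value_error")
  }
  if (sd(x) == 0) {
    abort("constant sample; normality test undefined",
          class = "nucmorph_value_error")
  }
  ht <- nortest::ad.test(x)
  tibble::tibble(a_stat = unname(ht$statistic), p_value = ht$p.value,
                 n = length(x))
}

#' Efficiency-corrected relative expression (Pfaffl ratio)
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, where each `dCt` is
#' control minus treated threshold cycle (in cycles) and efficiencies lie in
#' `(1, 2]`. Equal efficiencies and equal dCts give ratio 1 exactly.
#'
#' @param e_target,e_ref amplification efficiencies.
#' @param dct_target,dct_ref Ct differences (control - treated).
#' @return Fold change (> 0).
#' @export
pfaffl_ratio <- function(e_target, e_ref, dct_target, dct_ref) {
  check_efficiency(e_target)
  check_efficiency(e_ref)
  e_target^dct_target / e_ref^dct_ref
}

#' Pfaffl ratio from a Ct table
#'
#' Computes mean control-minus-treated dCt per gene from a table in the
#' layout of [make_qpcr_table()] and applies [pfaffl_ratio()].
#'
#' @param ct_table tibble with `gene`, `condition`, `ct` columns; genes
#'   `"target"` and `"reference"`, conditions `"control"` and `"treated"`.
#' @param e_target,e_ref amplification efficiencies.
#' @return One-row tibble: `dct_target`, `dct_ref`, `ratio`.
#' @export
pfaffl_from_ct <- function(ct_table, e_target = 2, e_ref = 2) {
  need <- c("gene", "condition", "ct")
  if (!all(need %in% names(ct_table))) {
    abort("ct_table needs gene, condition, ct columns",
          class = "nucmorph_format_error")
  }
  mean_ct <- function(g, cond) {
    v <- ct_table$ct[ct_table$gene == g & ct_table$condition == cond]
    if (length(v) == 0) abort(paste0("no Ct rows for ", g, "/", cond),
                              class = "nucmorph_format_error")
    mean(v)
  }
  dct_t <- mean_ct("target", "control") - mean_ct("target", "treated")
  dct_r <- mean_ct("reference", "control") - mean_ct("reference", "treated")
  tibble::tibble(dct_target = dct_t, dct_ref = dct_r,
                 ratio = pfaffl_ratio(e_target, e_ref, dct_t, dct_r))
}

#' Histogram export for feature distributions
#'
#' Bins each (feature, condition) distribution on a common per-feature grid
#' and writes the counts as CSV next to a ggplot figure, so downstream
#' checks are image-free. Bin counts always sum to the number of
#' observations.
#'
#' @param features a feature table.
#' @param out_dir output directory (created if needed).
#' @param bins number of bins per feature.
#' @param device figure device suffix (`"pdf"` by default).
#' @return Invisibly, a list with `counts` (tibble) and `plot`.
#' @export
export_histograms <- function(features, out_dir, bins = 20L, device = "pdf") {
  features <- feature_table(features)
  if (nrow(features) == 0) abort("empty feature table", class = "nucmorph_empty_error")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts <- features |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(d, key) {
      brk <- seq(min(d$value), max(d$value), length.out = bins + 1L)
      if (diff(range(d$value)) == 0) brk <- seq(d$value[1] - 0.5, d$value[1] + 0.5,
                                                length.out = bins + 1L)
      d |>
        dplyr::group_by(.data$condition) |>
        dplyr::group_modify(function(dd, kk) {
          h <- graphics::hist(dd$value, breaks = brk, plot = FALSE)
          tibble::tibble(bin_lo = utils::head(h$breaks, -1),
                         bin_hi = utils::tail(h$breaks, -1),
                         count = h$counts)
        }) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
  readr::write_csv(counts, file.path(out_dir, "histograms.csv"))
  p <- ggplot2::ggplot(features, ggplot2::aes(x = .data$value, fill = .data$condition)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.55, position = "identity") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::theme_minimal()
  try_save_plot(p, file.path(out_dir, paste0("histograms.", device)))
  invisible(list(counts = counts, plot = p))
}

#' Box-plot export for feature distributions
#'
#' Median, quartiles and 1.5 IQR whiskers per (feature, condition), written
#' as CSV next to the figure.
#'
#' @inheritParams export_histograms
#' @return Invisibly, a list with `stats` (tibble) and `plot`.
#' @export
export_boxplots <- function(features, out_dir, device = "pdf") {
  features <- feature_table(features)
  if (nrow(features) == 0) abort("empty feature table", class = "nucmorph_empty_error")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  box <- features |>
    dplyr::group_by(.data$feature, .data$condition) |>
    dplyr::summarise(
      median = median(.data$value),
      q1 = quantile(.data$value, 0.25, names = FALSE),
      q3 = quantile(.data$value, 0.75, names = FALSE),
      whisker_lo = min(.data$value[.data$value >= quantile(.data$value, 0.25, names = FALSE) -
                                     1.5 * stats::IQR(.data$value)]),
      whisker_hi = max(.data$value[.data$value <= quantile(.data$value, 0.75, names = FALSE) +
                                     1.5 * stats::IQR(.data$value)]),
      n = dplyr::n(),
      .groups = "drop"
    )
  readr::write_csv(box, file.path(out_dir, "boxplots.csv"))
  p <- ggplot2::ggplot(features,
                       ggplot2::aes(x = .data$condition, y = .data$value,
                                    fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  try_save_plot(p, file.path(out_dir, paste0("boxplots.", device)))
  invisible(list(stats = box, plot = p))
}

# save a ggplot without letting a missing graphics device kill a pipeline run
try_save_plot <- function(p, path) {
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, p, width = 8, height = 6)),
    error = function(e) warn(paste0("figure not written (", conditionMessage(e), ")"))
  )
  invisible(path)
}
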