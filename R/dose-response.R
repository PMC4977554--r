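#' Normalize raw viability readouts
#'
#' Two-step plate normalization: every response is divided by the mean of
#' the cells-alone (untreated growth) control, then by the mean of the
#' vehicle control (computed after step one), so the vehicle mean maps
#' exactly to 1 (100% viability).
#'
#' @param raw_table tibble with a `response` column.
#' @param cells_alone_rows,vehicle_rows row indices (or logical vectors)
#'   selecting the two control groups.
#' @return The table with an added `response_norm` column; control rows are
#'   kept so the construction is auditable.
#' @export
normalize_viability <- function(raw_table, cells_alone_rows, vehicle_rows) {
  if (!"response" %in% names(raw_table)) {
    abort("raw_table needs a `response` column", class = "nucmorph_format_error")
  }
  n <- nrow(raw_table)
  sel <- function(rows) {
    if (is.logical(rows)) which(rows) else as.integer(rows)
  }
  ca <- sel(cells_alone_rows)
  ve <- sel(vehicle_rows)
  if (length(ca) == 0 || length(ve) == 0) {
    abort("both control groups must be non-empty",
          class = "nucmorph_normalization_error")
  }
  m1 <- mean(raw_table$response[ca])
  if (!is.finite(m1) || m1 <= 0) {
    abort("cells-alone control mean must be positive",
          class = "nucmorph_normalization_error")
  }
  step1 <- raw_table$response / m1
  m2 <- mean(step1[ve])
  if (!is.finite(m2) || m2 <= 0) {
    abort("vehicle control mean must be positive",
          class = "nucmorph_normalization_error")
  }
  dplyr::mutate(tibble::as_tibble(raw_table), response_norm = step1 / m2)
}

#' Fit the four-parameter logistic dose-response model
#'
#' Ordinary nonlinear least squares on [fourpl()] with `X = log10(dose)`,
#' via Levenberg-Marquardt. Starting values are `Bottom = min(response)`,
#' `Top = max(response)`, `LogIC50 = median(X)`, with a multi-start over
#' HillSlope in `{-1, +1}`; the better-converged start wins. The fit is
#' canonicalised to `Top >= Bottom` (the equation is invariant under
#' swapping the asymptotes and negating the slope).
#'
#' @param doses_um dose vector, micromolar (at least 4 distinct values).
#' @param responses response vector, same length.
#' @return An object of class `dr_fit`: parameter estimates and standard
#'   errors, `ic50` (uM), residual SD, convergence flag and the underlying
#'   data. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_4pl <- function(doses_um, responses) {
  if (any(doses_um <= 0)) {
    abort("doses must be strictly positive", class = "nucmorph_domain_error")
  }
  if (length(doses_um) != length(responses)) {
    abort("doses and responses differ in length", class = "nucmorph_value_error")
  }
  if (length(unique(doses_um)) < 4) {
    abort("need at least 4 distinct doses", class = "nucmorph_value_error")
  }
  dat <- data.frame(x = log10(doses_um), y = responses)
  resid_fn <- function(p) dat$y - fourpl(dat$x, p[1], p[2], p[3], p[4])
  fits <- lapply(c(-1, 1), function(h) {
    start <- c(top = max(dat$y), bottom = min(dat$y),
               logic50 = median(dat$x), hill = h)
    tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) e
    )
  })
  ok <- vapply(fits, function(f) !inherits(f, "error") && f$info %in% 1:4,
               logical(1))
  if (!any(ok)) {
    msgs <- vapply(fits, function(f) {
      if (inherits(f, "error")) conditionMessage(f) else f$message
    }, character(1))
    abort(paste0("4PL fit failed from every start: ",
                 paste(unique(msgs), collapse = "; ")),
          class = "nucmorph_fit_error")
  }
  rss <- vapply(fits, function(f) {
    if (inherits(f, "error")) Inf else f$deviance
  }, numeric(1))
  rss[!ok] <- Inf
  best <- fits[[which.min(rss)]]
  est <- best$par
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(est)))
  # canonical ordering: Top >= Bottom (swap asymptotes, negate slope)
  if (est[["top"]] < est[["bottom"]]) {
    est[c("top", "bottom")] <- est[c("bottom", "top")]
    se[c("top", "bottom")] <- se[c("bottom", "top")]
    est[["hill"]] <- -est[["hill"]]
  }
  structure(list(
    top = est[["top"]], bottom = est[["bottom"]],
    logic50 = est[["logic50"]], hill = est[["hill"]],
    se = se[c("top", "bottom", "logic50", "hill")],
    ic50 = 10^est[["logic50"]],
    sigma = sqrt(min(rss) / max(nrow(dat) - 4L, 1L)),
    converged = best$info %in% 1:4,
    n = nrow(dat),
    data = tibble::as_tibble(dat),
    fit = best
  ), class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf(
    "<dr_fit> IC50 = %.4g uM  (Top %.3g, Bottom %.3g, LogIC50 %.4g, Hill %.3g)%s\n",
    x$ic50, x$top, x$bottom, x$logic50, x$hill,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @rdname fit_4pl
#' @param x a `dr_fit` object.
#' @param ... unused.
#' @export
tidy.dr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("top", "bottom", "logic50", "hill"),
    estimate = c(x$top, x$bottom, x$logic50, x$hill),
    std.error = unname(x$se)
  )
}

#' @rdname fit_4pl
#' @export
glance.dr_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, sigma = x$sigma, converged = x$converged,
                 nobs = x$n)
}

#' @rdname fit_4pl
#' @param object a `dr_fit` object.
#' @export
autoplot.dr_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x) - 0.2,
                                 max(object$data$x) + 0.2, length.out = 200))
  grid$y <- fourpl(grid$x, object$top, object$bottom, object$logic50, object$hill)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#b2182b") +
    ggplot2::geom_vline(xintercept = object$logic50, linetype = 2) +
    ggplot2::labs(x = "log10 dose (uM)", y = "response",
                  title = sprintf("IC50 = %.3g uM", object$ic50)) +
    ggplot2::theme_minimal()
}

#' Ratio of two fitted IC50s
#'
#' Fold difference in potency between two converged dose-response fits.
#'
#' @param fit_a,fit_b `dr_fit` objects.
#' @return `IC50_a / IC50_b`.
#' @export
ic50_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dr_fit"), inherits(fit_b, "dr_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    abort("both fits must have converged", class = "nucmorph_fit_error")
  }
  fit_a$ic50 / fit_b$ic50
}
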