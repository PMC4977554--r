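#' Four-parameter logistic (variable-slope) dose-response curve
#'
#' `Y = Bottom + (Top - Bottom) / (1 + 10^((LogIC50 - X) * HillSlope))`
#' with `X = log10(dose)`. At `X = LogIC50` the response is the midpoint
#' `(Top + Bottom) / 2`; the IC50 in concentration units is `10^LogIC50`.
#'
#' @param x log10(dose).
#' @param top,bottom upper / lower response asymptotes.
#' @param logic50 log10 of the IC50.
#' @param hill Hill slope (negative for inhibition curves on this X axis).
#' @return Response value(s).
#' @export
fourpl <- function(x, top, bottom, logic50, hill) {
  bottom + (top - bottom) / (1 + 10^((logic50 - x) * hill))
}

#' Simulate a viability plate readout
#'
#' Generates a (dose, replicate, response) table from the four-parameter
#' logistic curve plus additive Gaussian noise — the substrate for IC50
#' recovery tests. The default dose series is the 10-point, 3-fold serial
#' dilution starting at 100 uM used in viability screens.
#'
#' @param doses_um dose series in micromolar (all > 0).
#' @param top,bottom,logic50,hill true curve parameters; response scale is
#'   percent viability by default (Top = 100, Bottom = 0).
#' @param n_reps replicates per dose.
#' @param noise_sd Gaussian noise SD on the response scale.
#' @param seed RNG seed.
#' @return Tibble with columns `dose_um`, `replicate`, `response`.
#' @export
make_viability_table <- function(doses_um = 100 / 3^(0:9),
                                 top = 100, bottom = 0,
                                 logic50 = 0, hill = -1,
                                 n_reps = 6L, noise_sd = 3,
                                 seed = 1L) {
  if (any(doses_um <= 0)) {
    abort("doses must be strictly positive", class = "nucmorph_domain_error")
  }
  set.seed(seed)
  tab <- tidyr::expand_grid(dose_um = doses_um, replicate = seq_len(n_reps))
  mu <- fourpl(log10(tab$dose_um), top, bottom, logic50, hill)
  tab$response <- mu + rnorm(nrow(tab), 0, noise_sd)
  tab
}

#' Simulate a qPCR Ct table
#'
#' Generates threshold-cycle values consistent with exponential
#' amplification, `Ct = Ct0 - log_E(template amount)`: the target gene's
#' treated template is `fold_change` times its control template while the
#' reference gene is unchanged, so the efficiency-corrected (Pfaffl) ratio
#' recovers `fold_change`.
#'
#' @param e_target,e_ref amplification efficiencies in `(1, 2]` (2 = perfect
#'   doubling each cycle).
#' @param fold_change true expression fold change of the target (treated /
#'   control).
#' @param ct0_target,ct0_ref baseline Ct of one template unit.
#' @param n_reps technical replicates per (gene, condition).
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed RNG seed.
#' @return Tibble with columns `gene` (`"target"` / `"reference"`),
#'   `condition` (`"control"` / `"treated"`), `replicate`, `ct`.
#' @export
make_qpcr_table <- function(e_target = 2, e_ref = 2, fold_change = 1,
                            ct0_target = 28, ct0_ref = 20,
                            n_reps = 3L, noise_sd = 0.05, seed = 1L) {
  check_efficiency(e_target)
  check_efficiency(e_ref)
  if (fold_change <= 0) {
    abort("fold_change must be positive", class = "nucmorph_domain_error")
  }
  set.seed(seed)
  amounts <- tibble::tribble(
    ~gene, ~condition, ~amount, ~ct0, ~eff,
    "target", "control", 1, ct0_target, e_target,
    "target", "treated", fold_change, ct0_target, e_target,
    "reference", "control", 1, ct0_ref, e_ref,
    "reference", "treated", 1, ct0_ref, e_ref
  )
  tab <- tidyr::expand_grid(amounts, replicate = seq_len(n_reps))
  tab$ct <- tab$ct0 - log(tab$amount, base = tab$eff) +
    rnorm(nrow(tab), 0, noise_sd)
  dplyr::select(tab, dplyr::all_of(c("gene", "condition", "replicate", "ct")))
}

check_efficiency <- function(e) {
  if (!is.numeric(e) || e <= 1 || e > 2) {
    abort("amplification efficiency must lie in (1, 2]",
          class = "nucmorph_domain_error")
  }
  invisible(e)
}
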