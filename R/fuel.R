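#' Fuel savings from displacing a traditional stove
#'
#' Fuel savings follow from the ratio of thermal efficiencies and the
#' displacement fraction: `savings = (1 - eta_traditional / eta_new) * d`.
#' A tier-4 efficiency stove (50%) fully displacing the three-stone fire
#' (15%) saves 70% of fuel, the maximum in this framework.
#'
#' @param eta_traditional Traditional-stove thermal efficiency, fraction in
#'   (0, 1].
#' @param eta_new New-stove thermal efficiency, fraction in (0, 1].
#'   Must be >= `eta_traditional` unless `allow_negative = TRUE`.
#' @param displacement Fraction of cooking displaced, in \[0, 1\].
#'   Vectorised.
#' @param allow_negative Permit a less efficient new stove (negative
#'   savings)? Default FALSE.
#' @return Fraction of fuel saved.
#' @examples
#' fuel_savings(0.15, 0.50, 1)    # 0.70
#' fuel_savings(0.25, 0.50, 1)    # 0.50, charcoal baseline
#' @export
#' @family fuel
fuel_savings <- function(eta_traditional, eta_new, displacement = 1,
                         allow_negative = FALSE) {
  check_eta(eta_traditional, "eta_traditional")
  check_eta(eta_new, "eta_new")
  if (any(displacement < 0) || any(displacement > 1)) {
    abort("displacement must be in [0, 1].", class = "stoveuse_error_fuel")
  }
  if (!allow_negative && any(eta_new < eta_traditional)) {
    abort("eta_new < eta_traditional implies negative savings; set allow_negative = TRUE to permit.",
          class = "stoveuse_error_fuel")
  }
  (1 - eta_traditional / eta_new) * displacement
}

check_eta <- function(eta, name) {
  if (any(!is.finite(eta)) || any(eta <= 0) || any(eta > 1)) {
    abort(paste0(name, " must be a fraction in (0, 1]."),
          class = "stoveuse_error_fuel")
  }
}

#' Displacement needed for a fuel-savings target
#'
#' Inverts the savings formula: `d = target / (1 - eta_traditional /
#' eta_new)`. A 50% savings target against the three-stone fire needs full
#' displacement with a tier-2 efficiency stove, ~80% with tier 3, ~71%
#' with tier 4.
#'
#' @inheritParams fuel_savings
#' @param target Savings fraction sought, in \[0, 1\].
#' @return Required displacement fraction in \[0, 1\]. Errors with class
#'   `stoveuse_error_unreachable` when the target exceeds the full-
#'   displacement savings `1 - eta_traditional/eta_new`.
#' @examples
#' displacement_for_savings(0.15, 0.40, 0.50)  # 0.8
#' @export
#' @family fuel
displacement_for_savings <- function(eta_traditional, eta_new, target) {
  check_eta(eta_traditional, "eta_traditional")
  check_eta(eta_new, "eta_new")
  if (any(target < 0) || any(target > 1)) {
    abort("target must be in [0, 1].", class = "stoveuse_error_fuel")
  }
  if (any(eta_new <= eta_traditional)) {
    abort("eta_new must exceed eta_traditional to save fuel.",
          class = "stoveuse_error_fuel")
  }
  slope <- 1 - eta_traditional / eta_new
  if (any(target > slope + 1e-12)) {
    abort(sprintf("Target savings %.0f%% unreachable: full displacement saves only %.1f%%.",
                  max(target) * 100, min(slope) * 100),
          class = "stoveuse_error_unreachable")
  }
  pmin(target / slope, 1)
}

#' Fuel-savings ranges within a thermal-efficiency tier
#'
#' Savings curves evaluated at the tier band's lower bound, representative
#' value and upper bound, across a displacement grid.
#'
#' @param tier Thermal-efficiency tier index (1-4).
#' @param baseline_eta Baseline thermal efficiency. Default 0.15 (TSF);
#'   use 0.25 for the traditional charcoal baseline.
#' @param grid Displacement fractions.
#' @param bands Tier-band tibble (see [tier_bands()]).
#' @return Tibble: `tier`, `bound`, `eta`, `displacement`, `savings`.
#'   Band bounds at or below `baseline_eta` yield `NA` savings (no
#'   improvement to quantify).
#' @examples
#' savings_band(2)[savings_band(2)$displacement == 1, ]
#' @export
#' @family fuel
savings_band <- function(tier, baseline_eta = 0.15,
                         grid = seq(0, 1, by = 0.05), bands = tier_bands()) {
  b <- bands[bands$indicator == "thermal_efficiency" & bands$tier == tier, ,
             drop = FALSE]
  if (nrow(b) != 1L) {
    abort("Unknown thermal-efficiency tier.", class = "stoveuse_error_fuel")
  }
  long <- tibble::tibble(
    tier = tier,
    bound = c("lower", "representative", "upper"),
    eta = c(b$lower, b$representative, b$upper)
  )
  long <- long[is.finite(long$eta) & long$eta > 0, , drop = FALSE]
  tidyr::crossing(long, displacement = grid) |>
    dplyr::mutate(savings = ifelse(
      .data$eta > baseline_eta,
      (1 - baseline_eta / .data$eta) * .data$displacement,
      ifelse(.data$eta == baseline_eta, 0, NA_real_))) |>
    tibble::as_tibble()
}
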