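#' Round results the way the guidance tables print them
#'
#' Reported guidance is rounded for communication: usage times to the
#' nearest 5 minutes, displacement percentages to the nearest percent,
#' concentrations to the nearest unit. Usage limits quoted as conservative
#' bounds use `mode = "down"` (round down to the nearest 5 minutes).
#'
#' @param x Numeric vector (percent values already on the percent scale).
#' @param quantity One of `"minutes"`, `"percent"`, `"concentration"`.
#' @param mode `"nearest"` (default) or `"down"`.
#' @return Rounded numeric vector.
#' @examples
#' guidance_round(9.45, "minutes")          # 10
#' guidance_round(77.9, "minutes", "down")  # 75
#' @export
#' @family reporting
guidance_round <- function(x, quantity = c("minutes", "percent", "concentration"),
                        mode = c("nearest", "down")) {
  quantity <- match.arg(quantity)
  mode <- match.arg(mode)
  base <- switch(quantity, minutes = 5, percent = 1, concentration = 1)
  if (mode == "nearest") round(x / base) * base else floor(x / base) * base
}

#' Performance-usage guidance matrix
#'
#' For each (kitchen PM2.5 target level, new-stove tier) pair: the minimum
#' displacement of the baseline stove needed to bring the modelled 24-hr
#' mean kitchen concentration to the level, the equivalent weekly hours on
#' each stove (21-hr cooking week: 3 hr/day), and the implied exposure
#' reduction relative to exclusive baseline use. Unreachable combinations
#' (the new stove alone still exceeds the level) are flagged.
#'
#' @param kitchen A [kitchen()].
#' @param levels_ugm3 Kitchen PM2.5 target levels, ug/m3. Defaults to the
#'   graded levels 333, 166 and the WHO interim-1 35.
#' @param tiers New-stove registry names. Default tiers 1-4.
#' @param baseline Baseline stove. Default `"tsf"`.
#' @param total_minutes Daily cooking minutes. Default 180.
#' @param weekly_hours Weekly cooking hours for the hour conversion.
#'   Default 21.
#' @param ier Optional [ier_parameters()] / [calibrate_ier()] fit; if
#'   supplied, adds the ALRI relative risk at the target and its reduction
#'   relative to baseline.
#' @param rounding `"full_precision"` (default) or `"guidance_rounding"`
#'   (displacement to nearest percent, hours to one decimal).
#' @return Tibble: `target_ugm3`, `new_stove`, `required_displacement`
#'   (fraction, `NA` if unreachable), `reachable`, `baseline_weekly_hr`,
#'   `new_weekly_hr`, `exposure_reduction`, and optionally `rr_at_target`,
#'   `rr_reduction`.
#' @examples
#' guidance_matrix(levels_ugm3 = 166)
#' @export
#' @family reporting
guidance_matrix <- function(kitchen = stoveuse::kitchen(),
                            levels_ugm3 = c(333, 166, 35),
                            tiers = c("tier1", "tier2", "tier3", "tier4"),
                            baseline = "tsf", total_minutes = 180,
                            weekly_hours = 21, ier = NULL,
                            rounding = c("full_precision", "guidance_rounding")) {
  rounding <- match.arg(rounding)
  baseline <- as_stove(baseline)
  base_mean <- closed_form_daily_mean(baseline$pm_rate, total_minutes,
                                      kitchen) * 1000  # ug/m3
  out <- tidyr::crossing(target_ugm3 = levels_ugm3, new_stove = tiers) |>
    dplyr::rowwise() |>
    dplyr::mutate(d = list(tryCatch(
      required_displacement(baseline, .data$new_stove, kitchen,
                            goal_kitchen = .data$target_ugm3,
                            total_minutes = total_minutes),
      stoveuse_error_unreachable = function(e) NA_real_))) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      required_displacement = purrr::map_dbl(.data$d, identity),
      reachable = !is.na(.data$required_displacement),
      baseline_weekly_hr = (1 - .data$required_displacement) * weekly_hours,
      new_weekly_hr = .data$required_displacement * weekly_hours,
      exposure_reduction = pmax(1 - .data$target_ugm3 / base_mean, 0)
    ) |>
    dplyr::select(-"d")
  if (!is.null(ier)) {
    if (inherits(ier, "ier_fit")) ier <- ier$params
    ratio <- exposure_model()$ratio
    rr_base <- relative_risk(base_mean * ratio, ier)
    out <- dplyr::mutate(
      out,
      rr_at_target = relative_risk(.data$target_ugm3 * ratio, ier),
      rr_reduction = 1 - .data$rr_at_target / rr_base)
  }
  if (rounding == "guidance_rounding") {
    out <- dplyr::mutate(
      out,
      required_displacement = guidance_round(100 * .data$required_displacement,
                                          "percent") / 100,
      baseline_weekly_hr = round(.data$baseline_weekly_hr, 1),
      new_weekly_hr = round(.data$new_weekly_hr, 1))
  }
  out
}

#' Regenerate all guidance tables
#'
#' Runs the full analysis with one configuration and writes the tidy CSV
#' tables behind every figure-level result - single-stove usage curves and
#' limits, displacement sweeps with source shares (TSF and charcoal
#' baselines), exposure reductions (plus relative-risk curves when IER
#' parameters are supplied), fuel-savings curves, the guidance matrix, and
#' the within-tier concentration and fuel-savings bands - together with a
#' JSON run log. Output is deterministic for a given configuration:
#' rerunning yields byte-identical files. Writing is atomic: tables are
#' staged in a temporary directory and copied only if every table
#' succeeded.
#'
#' @param out_dir Output directory (created if needed).
#' @param kitchen A [kitchen()].
#' @param seed Integer seed recorded in the log (the tables themselves are
#'   deterministic).
#' @param grid Displacement grid for the sweeps.
#' @param ier Optional IER parameters for the relative-risk outputs.
#' @param rounding Rounding mode for the usage-limit and matrix tables.
#' @return Invisibly, a tibble of written files.
#' @export
#' @family reporting
reproduce_all <- function(out_dir, kitchen = stoveuse::kitchen(), seed = 1,
                          grid = seq(0, 1, by = 0.05), ier = NULL,
                          rounding = c("full_precision", "guidance_rounding")) {
  rounding <- match.arg(rounding)
  stage <- tempfile("stoveuse_report_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  wr <- function(x, name) {
    readr::write_csv(x, file.path(stage, name))
    name
  }

  reg <- stove_registry()
  usage_grid <- seq(0, 240, by = 5)
  usage_curves <- tidyr::crossing(
    stove = c("tsf", "charcoal_traditional"),
    pollutant = c("pm25", "co"),
    usage_minutes = usage_grid) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      rate = as_stove(.data$stove)[[rate_column(.data$pollutant)]],
      kitchen_mean = closed_form_daily_mean(.data$rate, .data$usage_minutes,
                                            kitchen) *
        report_factor(.data$pollutant),
      units = report_units(.data$pollutant)) |>
    dplyr::ungroup()

  limit_cases <- tidyr::crossing(
    stove = c("tsf", "charcoal_traditional", "tier1", "tier2", "tier3", "tier4"),
    target = c("pm25_interim1", "pm25_final", "co_24hr"))
  usage_limits <- limit_cases |>
    dplyr::rowwise() |>
    dplyr::mutate(
      max_minutes = max_usage_minutes(.data$stove, kitchen, .data$target),
      reported_minutes = if (rounding == "guidance_rounding") {
        guidance_round(.data$max_minutes, "minutes",
                    mode = ifelse(.data$target == "co_24hr", "down", "nearest"))
      } else .data$max_minutes) |>
    dplyr::ungroup()

  sweep_tsf <- displacement_sweep(kitchen = kitchen, grid = grid)
  sweep_charcoal <- displacement_sweep(baseline = "charcoal_traditional",
                                       kitchen = kitchen, grid = grid)
  exposure_tbl <- sweep_tsf |>
    tibble::as_tibble() |>
    dplyr::filter(.data$pollutant == "pm25") |>
    dplyr::mutate(exposure_reduction =
                    1 - .data$kitchen_mean / .data$kitchen_mean[
                      .data$displacement == 0][1])
  if (!is.null(ier)) {
    p <- if (inherits(ier, "ier_fit")) ier$params else ier
    exposure_tbl <- dplyr::mutate(exposure_tbl,
                                  relative_risk = relative_risk(.data$exposure, p))
  }

  etas <- reg[reg$stove %in% c("tier1", "tier2", "tier3", "tier4"), ]
  fuel_curves <- tidyr::crossing(
    new_stove = etas$stove, displacement = grid) |>
    dplyr::left_join(dplyr::select(etas, new_stove = "stove",
                                   eta_new = "thermal_efficiency"),
                     by = "new_stove") |>
    dplyr::mutate(savings = fuel_savings(0.15, .data$eta_new,
                                         .data$displacement))

  matrix_tbl <- guidance_matrix(kitchen, ier = ier, rounding = rounding)
  bands_pm <- tier_band_sweep("pm_indoor_emissions", kitchen, grid)
  bands_co <- tier_band_sweep("co_indoor_emissions", kitchen, grid)
  fuel_bands <- purrr::map_dfr(1:4, function(tr) {
    dplyr::bind_rows(
      dplyr::mutate(savings_band(tr, 0.15, grid), baseline = "tsf"),
      dplyr::mutate(savings_band(tr, 0.25, grid),
                    baseline = "charcoal_traditional"))
  })

  files <- c(
    wr(reg, "registry_stoves.csv"),
    wr(usage_curves, "usage_concentration_curves.csv"),
    wr(usage_limits, "usage_limits.csv"),
    wr(tibble::as_tibble(sweep_tsf), "displacement_sweep_tsf.csv"),
    wr(tibble::as_tibble(sweep_charcoal), "displacement_sweep_charcoal.csv"),
    wr(exposure_tbl, "exposure_reduction.csv"),
    wr(fuel_curves, "fuel_savings_curves.csv"),
    wr(matrix_tbl, "guidance_matrix.csv"),
    wr(bands_pm, "tier_bands_pm25.csv"),
    wr(bands_co, "tier_bands_co.csv"),
    wr(fuel_bands, "fuel_savings_bands.csv")
  )
  log <- list(
    package = "stoveuse",
    version = as.character(utils::packageVersion("stoveuse")),
    seed = seed,
    kitchen = list(volume = kitchen$volume, ach = kitchen$ach),
    rounding = rounding,
    grid = grid,
    ier_supplied = !is.null(ier),
    tables = files
  )
  jsonlite::write_json(log, file.path(stage, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "run_log.json")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(file.path(stage, files), file.path(out_dir, files),
                  overwrite = TRUE)
  if (!all(ok)) {
    file.remove(file.path(out_dir, files)[ok])
    abort("Failed to write all tables; partial outputs removed.",
          class = "stoveuse_error_io")
  }
  invisible(tibble::tibble(file = file.path(out_dir, files)))
}
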