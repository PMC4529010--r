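#' Define a stove-displacement scenario
#'
#' A displacement scenario moves a fraction `displacement` of the daily
#' cooking time from a baseline stove (typically the three-stone fire) to a
#' new stove, holding total cooking time fixed.
#'
#' @param baseline,new Stove identifiers or one-row performance records
#'   (see [as_stove()]).
#' @param displacement Fraction `d` of cooking time moved to the new stove,
#'   in \[0, 1\].
#' @param total_minutes Total daily cooking minutes, in (0, 1440\]. Default
#'   180 (three 1-hr events).
#' @return An object of class `displacement_scenario`.
#' @examples
#' displacement_scenario("tsf", "tier4", 0.5)
#' @export
#' @family scenarios
displacement_scenario <- function(baseline, new, displacement,
                                  total_minutes = 180) {
  baseline <- as_stove(baseline)
  new <- as_stove(new)
  if (!is.numeric(displacement) || length(displacement) != 1L ||
      !is.finite(displacement) || displacement < 0 || displacement > 1) {
    abort("displacement must be a single number in [0, 1].",
          class = "stoveuse_error_scenario")
  }
  if (!is.finite(total_minutes) || total_minutes <= 0 || total_minutes > 1440) {
    abort("total_minutes must be in (0, 1440].",
          class = "stoveuse_error_scenario")
  }
  structure(list(baseline = baseline, new = new,
                 displacement = displacement,
                 total_minutes = total_minutes),
            class = "displacement_scenario")
}

#' @export
print.displacement_scenario <- function(x, ...) {
  cat(sprintf("<displacement_scenario> %s -> %s, d = %.3f, %g min/day\n",
              x$baseline$stove, x$new$stove, x$displacement, x$total_minutes))
  invisible(x)
}

#' Time-weighted blended emission rate
#'
#' Splitting the cooking time between two stoves is, for daily means,
#' equivalent to cooking the whole time at the blended rate
#' `(1 - d) * baseline_g + d * new_g`.
#'
#' @param baseline_g,new_g Emission rates, mg/min.
#' @param d Displacement fraction in \[0, 1\] (vectorised).
#' @return Blended emission rate, mg/min.
#' @examples
#' blended_rate(40, 1, 0.5)  # 20.5
#' @export
#' @family scenarios
blended_rate <- function(baseline_g, new_g, d) {
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
    abort("d must be in [0, 1].", class = "stoveuse_error_scenario")
  }
  (1 - d) * baseline_g + d * new_g
}

# Three cooking events whose whole-minute durations sum exactly to
# total_minutes (base durations differ by at most 1 minute).
event_windows <- function(total_minutes, event_starts = c(420, 720, 1080)) {
  n <- length(event_starts)
  cs <- round(cumsum(rep(total_minutes / n, n)))
  tibble::tibble(start = event_starts, duration = diff(c(0, cs)))
}

# Per-source schedules for a scenario. Default "proportional" split lets
# both stoves share every event window at rates scaled by (1-d) and d,
# which is exact for any d; "blocks" reallocates whole minutes within each
# event (baseline first), rounding d to the nearest minute per event.
scenario_schedules <- function(scenario, pollutant,
                               event_starts = c(420, 720, 1080),
                               split = c("proportional", "blocks")) {
  split <- match.arg(split)
  col <- rate_column(pollutant)
  g_base <- scenario$baseline[[col]]
  g_new <- scenario$new[[col]]
  d <- scenario$displacement
  ev <- event_windows(scenario$total_minutes, event_starts)
  ev <- ev[ev$duration > 0, , drop = FALSE]

  if (split == "proportional") {
    base <- cooking_schedule(ev$start, ev$duration, (1 - d) * g_base,
                             source = "baseline")
    new <- cooking_schedule(ev$start, ev$duration, d * g_new, source = "new")
  } else {
    mins_base <- round((1 - d) * ev$duration)
    base <- new <- NULL
    if (any(mins_base > 0)) {
      i <- mins_base > 0
      base <- cooking_schedule(ev$start[i], mins_base[i], g_base,
                               source = "baseline")
    }
    if (any(ev$duration - mins_base > 0)) {
      i <- ev$duration - mins_base > 0
      new <- cooking_schedule(ev$start[i] + mins_base[i],
                              (ev$duration - mins_base)[i], g_new,
                              source = "new")
    }
  }
  list(baseline = base, new = new)
}

#' Evaluate a displacement scenario
#'
#' Simulates the scenario with the single-zone model, one pollutant at a
#' time: the baseline stove and the new stove are simulated as separate
#' sources over the shared cooking events and superposed. Returns 24-hr
#' mean kitchen concentrations, per-stove source shares, modelled personal
#' exposure (kitchen mean times the kitchen-to-person ratio), and
#' pass/fail flags against the guideline targets.
#'
#' @param scenario A [displacement_scenario()].
#' @param kitchen A [kitchen()]. Default the 30 m3 / 15 ACH reference.
#' @param pollutants Subset of `c("pm25", "co")`.
#' @param exposure An [exposure_model()] providing the kitchen-to-person
#'   ratio.
#' @param targets Guideline targets tibble (see [guideline_targets()]).
#' @param event_starts Start minutes of the cooking events.
#' @param split `"proportional"` (default, exact for any `d`) or `"blocks"`
#'   (whole-minute event reallocation).
#' @param keep_series Keep the minute-resolution traces in the result?
#' @return A `scenario_result` with components `summary` (tibble: one row
#'   per pollutant with `kitchen_mean` in reporting units - ug/m3 for
#'   PM2.5, mg/m3 for CO - `exposure`, `baseline_share`, `new_share`),
#'   `targets` (per-target pass flags), and optionally `series`.
#' @examples
#' s <- displacement_scenario("tsf", "tier4", 0.5)
#' evaluate_scenario(s)$summary
#' @export
#' @family scenarios
evaluate_scenario <- function(scenario, kitchen = stoveuse::kitchen(),
                              pollutants = c("pm25", "co"),
                              exposure = exposure_model(),
                              targets = guideline_targets(),
                              event_starts = c(420, 720, 1080),
                              split = c("proportional", "blocks"),
                              keep_series = FALSE) {
  stopifnot(inherits(scenario, "displacement_scenario"))
  kitchen <- as_kitchen(kitchen)
  pollutants <- match.arg(pollutants, several.ok = TRUE)
  split <- match.arg(split)

  series <- list()
  rows <- purrr::map(pollutants, function(p) {
    scheds <- scenario_schedules(scenario, p, event_starts, split)
    scheds <- scheds[!vapply(scheds, is.null, logical(1))]
    # sources are simulated independently (superposition), so the two
    # stoves may legitimately share event windows
    traces <- purrr::imap(scheds, function(s, nm) {
      simulate_day(s, kitchen, pollutant = p)
    })
    per_source <- purrr::map_dbl(traces, daily_mean)
    mean_mgm3 <- sum(per_source)
    if (keep_series) {
      joint <- dplyr::bind_rows(purrr::imap(
        traces, function(tr, nm) dplyr::mutate(tibble::as_tibble(tr), source = nm)
      ))
      series[[p]] <<- new_concentration_series(joint, kitchen, 1440)
    }
    shares <- if (mean_mgm3 > 0) per_source / mean_mgm3 else
      stats::setNames(rep(NA_real_, length(per_source)), names(per_source))
    tibble::tibble(
      pollutant = p,
      kitchen_mean_mgm3 = mean_mgm3,
      kitchen_mean = mean_mgm3 * report_factor(p),
      units = report_units(p),
      exposure = mean_mgm3 * report_factor(p) * exposure$ratio,
      baseline_share = shares[["baseline"]] %||% NA_real_,
      new_share = shares[["new"]] %||% 0
    )
  })
  summary <- dplyr::bind_rows(rows)

  target_tbl <- targets |>
    dplyr::filter(.data$pollutant %in% pollutants) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      kitchen_value = summary$kitchen_mean[summary$pollutant == .data$pollutant],
      meets = .data$kitchen_value <= .data$level
    ) |>
    dplyr::ungroup()

  structure(list(summary = summary, targets = target_tbl,
                 scenario = scenario, kitchen = kitchen,
                 series = if (keep_series) series else NULL),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$scenario)
  print(x$summary)
  invisible(x)
}

#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  x$summary
}

#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  wide <- x$summary |>
    dplyr::select("pollutant", "kitchen_mean", "exposure", "baseline_share") |>
    tidyr::pivot_wider(names_from = "pollutant",
                       values_from = c("kitchen_mean", "exposure",
                                       "baseline_share"))
  dplyr::mutate(wide,
                displacement = x$scenario$displacement,
                total_minutes = x$scenario$total_minutes,
                all_targets_met = all(x$targets$meets))
}

# 24-hr mean (mg/m3) for a single stove used t minutes/day; t may be
# fractional (the mean is linear in within-minute emitted mass, so the
# fractional part interpolates between adjacent whole-minute simulations).
usage_mean <- function(t, g, kitchen, start = 0) {
  tf <- floor(t)
  fr <- t - tf
  sim_mean <- function(mins) {
    if (mins == 0) return(0)
    daily_mean(simulate_day(
      cooking_schedule(start, mins, g), kitchen))
  }
  m <- sim_mean(tf)
  if (fr > 0 && tf < 1440) m <- m + fr * (sim_mean(tf + 1L) - m)
  m
}

#' Maximum daily usage before a guideline is exceeded
#'
#' The largest daily usage time (stove used alone, starting at `start`
#' minutes) such that the modelled 24-hr mean kitchen concentration stays
#' at or below the guideline level. Found by bisection on the
#' minute-stepped simulation; the closed-form inversion
#' `t = level * alpha * V * 1440 / G` is available as a cross-check.
#'
#' @param stove Stove identifier or record.
#' @param kitchen A [kitchen()].
#' @param target Guideline target name or record (see [as_target()]); its
#'   `pollutant` selects the emission rate.
#' @param method `"bisection"` (default, against [simulate_day()]) or
#'   `"closed_form"`.
#' @param start Start minute of the usage block. Default 0 so that long
#'   usage times fit the horizon.
#' @param tol Bisection tolerance on minutes. Default 0.01.
#' @return Usage time in minutes/day, capped at 1440 when even continuous
#'   use stays below the target.
#' @examples
#' max_usage_minutes("tsf", target = "pm25_interim1")       # ~9.45 min
#' max_usage_minutes("charcoal_traditional", target = "pm25_interim1")
#' @export
#' @family scenarios
max_usage_minutes <- function(stove, kitchen = stoveuse::kitchen(), target,
                              method = c("bisection", "closed_form"),
                              start = 0, tol = 0.01) {
  method <- match.arg(method)
  stove <- as_stove(stove)
  kitchen <- as_kitchen(kitchen)
  target <- as_target(target)
  g <- stove[[rate_column(target$pollutant)]]
  if (g <= 0) {
    abort("Stove emission rate for the target pollutant must be positive.",
          class = "stoveuse_error_scenario")
  }
  level <- target_level_mgm3(target)

  if (method == "closed_form") {
    return(min(level * kitchen$alpha * kitchen$volume * 1440 / g, 1440))
  }
  if (usage_mean(1440, g, kitchen, start) <= level) return(1440)
  lo <- 0; hi <- 1440
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (usage_mean(mid, g, kitchen, start) <= level) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Smallest displacement meeting an air-quality goal
#'
#' Inverts the scenario engine for the minimum displacement fraction `d`
#' at which the scenario meets a goal, stated either as an absolute 24-hr
#' mean kitchen concentration (`goal_kitchen`, reporting units: ug/m3 for
#' PM2.5, mg/m3 for CO), an absolute personal exposure (`goal_exposure`,
#' same units, kitchen mean times the exposure ratio), or a fractional
#' reduction relative to exclusive baseline use (`goal_reduction` in
#' \[0, 1\]; the exposure ratio cancels, so kitchen and exposure reductions
#' coincide). Exactly one goal must be given.
#'
#' Solved in closed form, `d = (G_base - G_goal) / (G_base - G_new)`, where
#' `G_goal` is the blended emission rate implied by the goal; the
#' `"bisection"` method cross-checks against [evaluate_scenario()].
#'
#' @param baseline,new Stove identifiers or records; the new stove must be
#'   strictly cleaner for the goal pollutant.
#' @param kitchen A [kitchen()].
#' @param goal_kitchen,goal_exposure,goal_reduction The goal (exactly one).
#' @param pollutant `"pm25"` (default) or `"co"`.
#' @param total_minutes Total daily cooking minutes. Default 180.
#' @param exposure An [exposure_model()]; used only for `goal_exposure`.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @param tol Bisection tolerance on `d`. Default 1e-6.
#' @return The smallest displacement fraction in \[0, 1\]. Errors with class
#'   `stoveuse_error_unreachable` if even full displacement misses the goal.
#' @examples
#' required_displacement("tsf", "tier4", goal_kitchen = 166)   # ~0.77
#' required_displacement("tsf", "tier3", goal_reduction = 0.5) # ~0.571
#' @export
#' @family scenarios
required_displacement <- function(baseline, new,
                                  kitchen = stoveuse::kitchen(),
                                  goal_kitchen = NULL, goal_exposure = NULL,
                                  goal_reduction = NULL,
                                  pollutant = "pm25", total_minutes = 180,
                                  exposure = exposure_model(),
                                  method = c("closed_form", "bisection"),
                                  tol = 1e-6) {
  method <- match.arg(method)
  baseline <- as_stove(baseline)
  new <- as_stove(new)
  kitchen <- as_kitchen(kitchen)
  goals <- list(goal_kitchen, goal_exposure, goal_reduction)
  if (sum(!vapply(goals, is.null, logical(1))) != 1L) {
    abort("Give exactly one of goal_kitchen, goal_exposure, goal_reduction.",
          class = "stoveuse_error_scenario")
  }
  col <- rate_column(pollutant)
  g_base <- baseline[[col]]
  g_new <- new[[col]]
  if (g_new >= g_base) {
    abort("The new stove must be strictly cleaner than the baseline for the goal pollutant.",
          class = "stoveuse_error_scenario")
  }

  # goal expressed as the blended emission rate it implies
  fac <- report_factor(pollutant)  # reporting units per mg/m3
  denom <- kitchen$alpha * kitchen$volume * 1440 / total_minutes
  g_goal <- if (!is.null(goal_reduction)) {
    if (goal_reduction < 0 || goal_reduction > 1) {
      abort("goal_reduction must be in [0, 1].",
            class = "stoveuse_error_scenario")
    }
    (1 - goal_reduction) * g_base
  } else {
    level_mgm3 <- if (!is.null(goal_kitchen)) goal_kitchen / fac
    else goal_exposure / fac / exposure$ratio
    level_mgm3 * denom
  }

  d <- (g_base - g_goal) / (g_base - g_new)
  if (d > 1 + 1e-12) {
    abort(sprintf("Goal unreachable: even full displacement leaves the blended rate at %.3g mg/min (> goal %.3g).",
                  g_new, g_goal),
          class = "stoveuse_error_unreachable")
  }
  d <- min(max(d, 0), 1)
  if (method == "closed_form") return(d)

  mean_at <- function(dd) {
    s <- displacement_scenario(baseline, new, dd, total_minutes)
    res <- evaluate_scenario(s, kitchen, pollutants = pollutant,
                             exposure = exposure)
    res$summary$kitchen_mean_mgm3
  }
  goal_mgm3 <- g_goal / denom
  if (mean_at(0) <= goal_mgm3) return(0)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mean_at(mid) <= goal_mgm3) hi <- mid else lo <- mid
  }
  hi
}

#' Sweep displacement scenarios across new stoves
#'
#' Evaluates every (new stove, displacement) combination against a common
#' baseline and returns a tidy table, one row per combination and
#' pollutant. The modelled 24-hr mean is affine in the displacement
#' fraction.
#'
#' @param baseline Baseline stove. Default `"tsf"`.
#' @param new_stoves Character vector of registry names, or list of stove
#'   records.
#' @param kitchen A [kitchen()].
#' @param grid Displacement fractions in \[0, 1\].
#' @inheritParams evaluate_scenario
#' @param total_minutes Total daily cooking minutes. Default 180.
#' @return A `displacement_sweep` tibble: `new_stove`, `displacement`,
#'   `pollutant`, `kitchen_mean`, `units`, `exposure`, `baseline_share`,
#'   `new_share`.
#' @examples
#' sweep <- displacement_sweep(grid = c(0, 0.5, 1))
#' sweep[sweep$pollutant == "pm25", ]
#' @export
#' @family scenarios
displacement_sweep <- function(baseline = "tsf",
                               new_stoves = c("tier1", "tier2", "tier3", "tier4"),
                               kitchen = stoveuse::kitchen(),
                               grid = seq(0, 1, by = 0.05),
                               pollutants = c("pm25", "co"),
                               total_minutes = 180,
                               exposure = exposure_model()) {
  if (any(grid < 0 | grid > 1)) {
    abort("grid must lie in [0, 1].", class = "stoveuse_error_scenario")
  }
  baseline <- as_stove(baseline)
  stoves <- if (is.character(new_stoves)) {
    purrr::map(new_stoves, as_stove)
  } else if (is.data.frame(new_stoves)) {
    list(as_stove(new_stoves))
  } else {
    purrr::map(new_stoves, as_stove)
  }
  out <- purrr::map_dfr(stoves, function(stv) {
    purrr::map_dfr(grid, function(d) {
      res <- evaluate_scenario(
        displacement_scenario(baseline, stv, d, total_minutes),
        kitchen, pollutants = pollutants, exposure = exposure)
      dplyr::mutate(res$summary, new_stove = stv$stove, displacement = d,
                    .before = 1)
    })
  })
  out <- dplyr::select(out, "new_stove", "displacement", "pollutant",
                       "kitchen_mean", "units", "exposure",
                       "baseline_share", "new_share")
  class(out) <- c("displacement_sweep", class(out))
  attr(out, "baseline") <- baseline$stove
  out
}

#' Concentration ranges within each performance tier
#'
#' Each IWA tier is a band, not a point: this sweep evaluates the
#' displacement curves at the band's lower bound, representative value and
#' upper bound, giving the range of kitchen concentrations attainable
#' within each tier. Uses the closed-form daily mean (exact here: the
#' blended rate is constant over the cooking events).
#'
#' @param indicator `"pm_indoor_emissions"` or `"co_indoor_emissions"`.
#' @param kitchen A [kitchen()].
#' @param grid Displacement fractions.
#' @param baseline Baseline stove. Default `"tsf"`.
#' @param tiers Tier indices to include. Default 1:4.
#' @param total_minutes Daily cooking minutes. Default 180.
#' @param bands Tier-band tibble.
#' @return Tibble: `tier`, `bound` (lower/representative/upper), `rate`
#'   (mg/min), `displacement`, `kitchen_mean` (reporting units), `units`.
#'   Non-finite band bounds (open tier-0 tops) yield no row.
#' @export
#' @family scenarios
tier_band_sweep <- function(indicator = "pm_indoor_emissions",
                            kitchen = stoveuse::kitchen(),
                            grid = seq(0, 1, by = 0.05),
                            baseline = "tsf", tiers = 1:4,
                            total_minutes = 180, bands = tier_bands()) {
  baseline <- as_stove(baseline)
  pollutant <- switch(indicator,
                      pm_indoor_emissions = "pm25",
                      co_indoor_emissions = "co",
                      abort("indicator must be an emission indicator.",
                            class = "stoveuse_error_bands"))
  g_base <- baseline[[rate_column(pollutant)]]
  b <- bands[bands$indicator == indicator & bands$tier %in% tiers, , drop = FALSE]
  long <- tidyr::pivot_longer(
    dplyr::select(b, "tier", "lower", "representative", "upper"),
    cols = c("lower", "representative", "upper"),
    names_to = "bound", values_to = "rate")
  long <- long[is.finite(long$rate), , drop = FALSE]
  out <- tidyr::crossing(long, displacement = grid) |>
    dplyr::mutate(
      kitchen_mean = closed_form_daily_mean(
        blended_rate(g_base, .data$rate, .data$displacement),
        total_minutes, kitchen) * report_factor(pollutant),
      units = report_units(pollutant),
      pollutant = pollutant
    )
  tibble::as_tibble(out)
}
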