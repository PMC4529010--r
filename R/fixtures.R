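#' Ranges for randomized synthetic fixtures
#'
#' Bounded uniform ranges emulating the variability reported for real
#' kitchens: air exchange 15-45 ACH (the reference value plus the higher
#' ventilation rates discussed for sensitivity), volume 15-60 m3, total
#' cooking time 120-280 min/day (spanning the 3.1-4.6 hr/day reported for
#' India), and emission rates spanning the printed tier bands. No
#' distributional claim beyond the bounds is intended; sampling is uniform.
#'
#' @param ach,volume,total_minutes,pm_rate,co_rate,efficiency Length-2
#'   numeric ranges `c(min, max)`.
#' @return An object of class `fixture_ranges`.
#' @export
#' @family fixtures
fixture_ranges <- function(ach = c(15, 45), volume = c(15, 60),
                           total_minutes = c(120, 280),
                           pm_rate = c(0.5, 45), co_rate = c(50, 1300),
                           efficiency = c(0.10, 0.60)) {
  rng <- list(ach = ach, volume = volume, total_minutes = total_minutes,
              pm_rate = pm_rate, co_rate = co_rate, efficiency = efficiency)
  ok <- vapply(rng, function(r) {
    length(r) == 2L && all(is.finite(r)) && all(r > 0) && r[1] <= r[2]
  }, logical(1))
  if (!all(ok)) {
    abort(paste0("Invalid range(s): ", paste(names(rng)[!ok], collapse = ", ")),
          class = "stoveuse_error_fixtures")
  }
  structure(rng, class = "fixture_ranges")
}

#' Sample randomized kitchen / scenario fixtures
#'
#' Draws `n` kitchens and displacement scenarios uniformly within the
#' ranges, deterministically for a given seed (the caller's RNG state is
#' left untouched). Within each fixture the baseline stove is assigned the
#' dirtier of the two sampled rates per pollutant and the lower thermal
#' efficiency, so every fixture satisfies the preconditions of the
#' inversion operations.
#'
#' @param n Number of fixtures (>= 1).
#' @param ranges A [fixture_ranges()].
#' @param seed Integer seed recorded in the output.
#' @return Tibble with one row per fixture: kitchen (`volume`, `ach`),
#'   scenario (`total_minutes`, `displacement`), stove rates/efficiencies
#'   (`baseline_pm`, `new_pm`, `baseline_co`, `new_co`, `baseline_eta`,
#'   `new_eta`) and the `seed`.
#' @examples
#' sample_fixtures(3, seed = 42)
#' @export
#' @family fixtures
sample_fixtures <- function(n, ranges = fixture_ranges(), seed = 1) {
  stopifnot(inherits(ranges, "fixture_ranges"), n >= 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  u <- function(r, n) stats::runif(n, r[1], r[2])
  pm <- cbind(u(ranges$pm_rate, n), u(ranges$pm_rate, n))
  co <- cbind(u(ranges$co_rate, n), u(ranges$co_rate, n))
  eta <- cbind(u(ranges$efficiency, n), u(ranges$efficiency, n))
  eta <- pmin(eta, 1)
  tibble::tibble(
    fixture = seq_len(n),
    volume = u(ranges$volume, n),
    ach = u(ranges$ach, n),
    total_minutes = round(u(ranges$total_minutes, n)),
    displacement = stats::runif(n),
    baseline_pm = pmax(pm[, 1], pm[, 2]),
    new_pm = pmin(pm[, 1], pm[, 2]),
    baseline_co = pmax(co[, 1], co[, 2]),
    new_co = pmin(co[, 1], co[, 2]),
    baseline_eta = pmin(eta[, 1], eta[, 2]),
    new_eta = pmax(eta[, 1], eta[, 2]),
    seed = seed
  )
}

#' Materialise one fixture row as model objects
#'
#' @param row One row of [sample_fixtures()] output.
#' @return List with `kitchen` and `scenario` objects.
#' @export
#' @family fixtures
fixture_objects <- function(row) {
  stopifnot(is.data.frame(row), nrow(row) == 1L)
  baseline <- tibble::tibble(stove = "fixture_baseline",
                             pm_rate = row$baseline_pm,
                             co_rate = row$baseline_co,
                             thermal_efficiency = row$baseline_eta)
  new <- tibble::tibble(stove = "fixture_new", pm_rate = row$new_pm,
                        co_rate = row$new_co,
                        thermal_efficiency = row$new_eta)
  list(kitchen = kitchen(row$volume, row$ach),
       scenario = displacement_scenario(baseline, new, row$displacement,
                                        row$total_minutes))
}

#' Write / read fixture sets for regression pinning
#'
#' @param fixtures Tibble from [sample_fixtures()].
#' @param path YAML file path.
#' @return `write_fixtures()` returns `path` invisibly; `read_fixtures()`
#'   the tibble.
#' @export
#' @family fixtures
write_fixtures <- function(fixtures, path) {
  yaml::write_yaml(as.data.frame(fixtures), path, precision = 15)
  invisible(path)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(path) {
  tibble::as_tibble(as.data.frame(yaml::read_yaml(path)))
}

#' Usage-time limits across ventilation rates
#'
#' Recomputes [max_usage_minutes()] over a grid of air-exchange rates. The
#' daily mean scales as `1/(alpha * V)`, so the allowed usage time scales
#' linearly with ACH (and with volume): doubling ventilation from 15 to 30
#' ACH doubles the usage budget.
#'
#' @param stove Stove identifier or record.
#' @param target Guideline target (see [as_target()]).
#' @param ach_grid Air exchange rates per hour.
#' @param volume Kitchen volume, m3. Default 30.
#' @param method Passed to [max_usage_minutes()].
#' @return Tibble: `ach`, `volume`, `max_minutes`.
#' @examples
#' ventilation_sensitivity("tsf", "pm25_interim1", ach_grid = c(15, 30, 45))
#' @export
#' @family fixtures
ventilation_sensitivity <- function(stove, target,
                                    ach_grid = seq(15, 45, by = 5),
                                    volume = 30,
                                    method = c("bisection", "closed_form")) {
  method <- match.arg(method)
  if (any(ach_grid <= 0)) {
    abort("ach_grid must be positive.", class = "stoveuse_error_fixtures")
  }
  purrr::map_dfr(ach_grid, function(a) {
    tibble::tibble(
      ach = a, volume = volume,
      max_minutes = max_usage_minutes(stove, kitchen(volume, a), target,
                                      method = method))
  })
}
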