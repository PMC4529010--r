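#' Built-in stove performance registry
#'
#' Emission rates and thermal efficiencies used throughout the package,
#' following the IWA 11:2012 indoor-emissions and efficiency tiers. Tier 0 is
#' the three-stone fire (TSF); tiers 1-3 use values equidistant between the
#' tier boundaries; tier 4 uses the midpoint between zero and the tier-4
#' indoor-emissions boundary, and a 50% thermal efficiency extrapolated from
#' tiers 1-3. The traditional charcoal stove is the rounded average of four
#' common charcoal stoves (Gyapa, ceramic jiko, metal jiko, Kenya ceramic
#' jiko).
#'
#' @return A tibble with one row per stove and columns `stove` (identifier),
#'   `label`, `pm_rate` (PM2.5 indoor emission rate, mg/min), `co_rate`
#'   (CO indoor emission rate, mg/min), and `thermal_efficiency` (fraction).
#' @examples
#' stove_registry()
#' @export
#' @family registry
stove_registry <- function() {
  tibble::tribble(
    ~stove,                 ~label,                              ~pm_rate, ~co_rate, ~thermal_efficiency,
    "tsf",                  "Three-stone fire (tier 0)",             40.0,      970,                0.15,
    "tier1",                "Indoor-emissions tier 1 stove",         28.5,      795,                0.20,
    "tier2",                "Indoor-emissions tier 2 stove",         12.5,      555,                0.30,
    "tier3",                "Indoor-emissions tier 3 stove",          5.0,      455,                0.40,
    "tier4",                "Indoor-emissions tier 4 stove",          1.0,      210,                0.50,
    "charcoal_traditional", "Traditional charcoal stove",            15.0,     1300,                0.25
  )
}

#' Resolve a stove to a one-row performance record
#'
#' Accepts either a registry identifier (e.g. `"tsf"`, `"tier4"`) or a
#' data frame with at least `pm_rate`, `co_rate` and `thermal_efficiency`
#' columns, and returns a validated one-row tibble.
#'
#' @param x Stove name (character scalar) or one-row data frame.
#' @param registry Registry tibble used to resolve names.
#' @return One-row tibble with stove performance columns.
#' @export
#' @family registry
as_stove <- function(x, registry = stove_registry()) {
  if (is.character(x)) {
    if (length(x) != 1L || !x %in% registry$stove) {
      abort(paste0("Unknown stove '", paste(x, collapse = ","),
                   "'. Known: ", paste(registry$stove, collapse = ", ")),
            class = "stoveuse_error_stove")
    }
    out <- registry[registry$stove == x, , drop = FALSE]
  } else if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      abort("A stove must be a single row.", class = "stoveuse_error_stove")
    }
    out <- tibble::as_tibble(x)
    if (!"stove" %in% names(out)) {
      out$stove <- if ("label" %in% names(out)) out$label else "custom"
    }
  } else {
    abort("A stove must be a registry name or a one-row data frame.",
          class = "stoveuse_error_stove")
  }
  validate_stove(out)
  out
}

validate_stove <- function(stove) {
  needed <- c("pm_rate", "co_rate", "thermal_efficiency")
  missing <- setdiff(needed, names(stove))
  if (length(missing)) {
    abort(paste0("Stove record lacks column(s): ", paste(missing, collapse = ", ")),
          class = "stoveuse_error_stove")
  }
  if (!is.finite(stove$pm_rate) || stove$pm_rate < 0 ||
      !is.finite(stove$co_rate) || stove$co_rate < 0) {
    abort("Emission rates must be finite and nonnegative.",
          class = "stoveuse_error_stove")
  }
  eta <- stove$thermal_efficiency
  if (!is.finite(eta) || eta <= 0 || eta > 1) {
    abort("thermal_efficiency must be in (0, 1].",
          class = "stoveuse_error_stove")
  }
  invisible(stove)
}

#' IWA 11:2012 performance tier bands
#'
#' The printed tier boundaries for the three indicators used by the model,
#' stored verbatim: tier-0 bands are open ("> 40" mg/min PM2.5, "> 970"
#' mg/min CO, "< 15%" efficiency) and the printed CO bands for tiers 1 and 2
#' overlap (620-970 vs 490-690 mg/min). `representative` is the single value
#' used for modelling.
#'
#' @return A tibble with columns `indicator`
#'   (`pm_indoor_emissions`, `co_indoor_emissions`, `thermal_efficiency`),
#'   `tier` (0-4), `lower`, `upper`, `lower_closed`, `upper_closed`,
#'   `representative`, and `units`.
#' @examples
#' tier_bands()
#' @export
#' @family registry
tier_bands <- function() {
  tibble::tribble(
    ~indicator,            ~tier, ~lower, ~upper, ~lower_closed, ~upper_closed, ~representative,
    "pm_indoor_emissions",     0,   40.0,    Inf,         FALSE,         FALSE,            40.0,
    "pm_indoor_emissions",     1,   17.0,   40.0,          TRUE,          TRUE,            28.5,
    "pm_indoor_emissions",     2,    8.0,   17.0,          TRUE,          TRUE,            12.5,
    "pm_indoor_emissions",     3,    2.0,    8.0,          TRUE,          TRUE,             5.0,
    "pm_indoor_emissions",     4,    0.0,    2.0,          TRUE,          TRUE,             1.0,
    "co_indoor_emissions",     0,    970,    Inf,         FALSE,         FALSE,             970,
    "co_indoor_emissions",     1,    620,    970,          TRUE,          TRUE,             795,
    "co_indoor_emissions",     2,    490,    690,          TRUE,          TRUE,             555,
    "co_indoor_emissions",     3,    420,    490,          TRUE,          TRUE,             455,
    "co_indoor_emissions",     4,      0,    420,          TRUE,          TRUE,             210,
    "thermal_efficiency",      0,      0,   0.15,         FALSE,         FALSE,            0.15,
    "thermal_efficiency",      1,   0.15,   0.25,          TRUE,          TRUE,            0.20,
    "thermal_efficiency",      2,   0.25,   0.35,          TRUE,          TRUE,            0.30,
    "thermal_efficiency",      3,   0.35,   0.45,          TRUE,          TRUE,            0.40,
    "thermal_efficiency",      4,   0.45,   1.00,          TRUE,          TRUE,            0.50
  ) |>
    dplyr::mutate(units = ifelse(.data$indicator == "thermal_efficiency",
                                 "fraction", "mg/min"))
}

#' Classify an indicator value into a performance tier
#'
#' Finds the tier band containing each value. A value on a shared boundary
#' (the printed emission bands meet at their endpoints, and the printed CO
#' bands for tiers 1-2 overlap) is assigned the cleaner band, i.e. the
#' higher tier index. A value falling in a gap between bands - impossible
#' for the built-in bands, which tile the half-line, but possible for
#' user-supplied bands - is assigned the nearest band with a warning.
#'
#' @param value Numeric vector of indicator values (mg/min for emission
#'   indicators, fraction for thermal efficiency).
#' @param indicator One of `"pm_indoor_emissions"`, `"co_indoor_emissions"`,
#'   `"thermal_efficiency"`.
#' @param bands Tier-band tibble, as [tier_bands()].
#' @return Integer vector of tier indices (0-4).
#' @examples
#' classify_tier(5, "pm_indoor_emissions")   # tier 3 ("2-8")
#' classify_tier(45, "pm_indoor_emissions")  # tier 0 ("> 40")
#' classify_tier(0.42, "thermal_efficiency") # tier 3
#' @export
#' @family registry
classify_tier <- function(value, indicator, bands = tier_bands()) {
  b <- bands[bands$indicator == indicator, , drop = FALSE]
  if (!nrow(b)) {
    abort(paste0("No tier bands for indicator '", indicator, "'."),
          class = "stoveuse_error_bands")
  }
  if (any(!is.finite(value) | value < 0)) {
    abort("Indicator values must be finite and nonnegative.",
          class = "stoveuse_error_bands")
  }
  gap_seen <- FALSE
  out <- vapply(value, function(v) {
    in_band <- (ifelse(b$lower_closed, v >= b$lower, v > b$lower)) &
      (ifelse(b$upper_closed, v <= b$upper, v < b$upper))
    if (any(in_band)) {
      return(as.integer(max(b$tier[in_band])))  # cleaner tier wins at shared boundaries
    }
    # gap: nearest band by interval distance, ties to the cleaner band
    gap_seen <<- TRUE
    dist <- pmax(b$lower - v, v - b$upper, 0)
    as.integer(max(b$tier[dist == min(dist)]))
  }, integer(1))
  if (gap_seen) {
    warn("Some values fall outside every band; assigned to the nearest band.",
         class = "stoveuse_warn_band_gap")
  }
  out
}

#' WHO guideline targets used for usage guidance
#'
#' The PM2.5 interim-1 target (35 ug/m3), the final PM2.5 guideline
#' (10 ug/m3) and the 24-hr CO guideline (7 mg/m3), all applied here to the
#' modelled 24-hr mean kitchen concentration.
#'
#' @return A tibble with columns `target`, `pollutant` (`pm25` or `co`),
#'   `level`, `units`, `averaging`.
#' @examples
#' guideline_targets()
#' @export
#' @family registry
guideline_targets <- function() {
  tibble::tribble(
    ~target,         ~pollutant, ~level, ~units,   ~averaging,
    "pm25_interim1", "pm25",         35, "ug/m3",  "24-hr mean",
    "pm25_final",    "pm25",         10, "ug/m3",  "24-hr mean",
    "co_24hr",       "co",            7, "mg/m3",  "24-hr mean"
  )
}

#' @rdname guideline_targets
#' @param x Target name (character) or one-row data frame with `pollutant`,
#'   `level`, `units` columns.
#' @param targets Target tibble used to resolve names.
#' @export
as_target <- function(x, targets = guideline_targets()) {
  if (is.character(x)) {
    if (length(x) != 1L || !x %in% targets$target) {
      abort(paste0("Unknown target '", paste(x, collapse = ","),
                   "'. Known: ", paste(targets$target, collapse = ", ")),
            class = "stoveuse_error_target")
    }
    out <- targets[targets$target == x, , drop = FALSE]
  } else if (is.data.frame(x) && nrow(x) == 1L &&
             all(c("pollutant", "level", "units") %in% names(x))) {
    out <- tibble::as_tibble(x)
  } else {
    abort("A target must be a name or a one-row data frame with pollutant/level/units.",
          class = "stoveuse_error_target")
  }
  if (!is.finite(out$level) || out$level <= 0) {
    abort("Target level must be positive.", class = "stoveuse_error_target")
  }
  out
}

# Concentration level in internal units (mg/m3).
target_level_mgm3 <- function(target) {
  target <- as_target(target)
  switch(target$units,
    "mg/m3" = target$level,
    "ug/m3" = target$level / 1000,
    abort(paste0("Unknown concentration units '", target$units, "'."),
          class = "stoveuse_error_target")
  )
}

# mg/m3 -> reporting units multiplier (PM2.5 reported in ug/m3, CO in mg/m3)
report_factor <- function(pollutant) {
  ifelse(pollutant == "pm25", 1000, 1)
}

report_units <- function(pollutant) {
  ifelse(pollutant == "pm25", "ug/m3", "mg/m3")
}

rate_column <- function(pollutant) {
  switch(pollutant, pm25 = "pm_rate", co = "co_rate",
         abort(paste0("Unknown pollutant '", pollutant, "'."),
               class = "stoveuse_error_pollutant"))
}

#' Write or read the parameter registry
#'
#' Serializes the stove registry, tier bands and guideline targets - with
#' explicit units - to a single JSON or YAML document, and reads it back.
#' The round trip is lossless.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @param stoves,bands,targets Registry components to write.
#' @return `write_registry()` returns `path` invisibly; `read_registry()`
#'   returns a list with tibbles `stoves`, `bands`, `targets`.
#' @export
#' @family registry
write_registry <- function(path, stoves = stove_registry(),
                           bands = tier_bands(), targets = guideline_targets()) {
  # unbounded band tops are serialized as missing and restored on read
  bands <- dplyr::mutate(bands,
                         upper = ifelse(is.finite(.data$upper), .data$upper,
                                        NA_real_))
  doc <- list(
    units = list(pm_rate = "mg/min", co_rate = "mg/min",
                 thermal_efficiency = "fraction"),
    stoves = stoves, bands = bands, targets = targets
  )
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else if (fmt %in% c("yaml", "yml")) {
    yaml::write_yaml(lapply(doc, function(x) if (is.data.frame(x)) as.data.frame(x) else x),
                     path, precision = 15)
  } else {
    abort("Registry format must be json or yaml.", class = "stoveuse_error_io")
  }
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  doc <- if (fmt == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (fmt %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    abort("Registry format must be json or yaml.", class = "stoveuse_error_io")
  }
  as_tbl <- function(x) {
    x <- if (is.data.frame(x)) x else as.data.frame(do.call(cbind.data.frame, x))
    tibble::as_tibble(x)
  }
  bands <- as_tbl(doc$bands)
  bands$upper <- ifelse(is.na(as.numeric(bands$upper)), Inf,
                        as.numeric(bands$upper))
  list(stoves = as_tbl(doc$stoves), bands = bands, targets = as_tbl(doc$targets))
}
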