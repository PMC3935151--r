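#' Compute the net area-normalized flux of one analyte over a time window
#'
#' Converts the change in an analyte's concentration between the start and
#' end of a window into an absolute amount (ideal-gas conversion for
#' headspace series; concentration x liquid volume for liquid series;
#' concentration x chamber volume for chamber series) and normalizes it to
#' mat area (core area for vial microcosms, chamber footprint for flux
#' chambers). Endpoint differencing is used, matching how net fluxes
#' between sampling times are reported; concentrations at the window
#' endpoints are linearly interpolated if they fall between samples.
#'
#' Sign convention: accumulation in the overlying compartment is positive;
#' negative fluxes are uptake into the mat.
#'
#' @param series A tibble holding one time series: columns `time_h`,
#'   `value`, and a single `compartment` value among `"headspace"`,
#'   `"liquid"`, `"chamber_water"`. An `analyte` column, if present, names
#'   the species in the output.
#' @param geometry A [mat_geometry()].
#' @param window Length-2 numeric `(t_start, t_end)` in hours since dawn,
#'   within the series time range, containing at least 2 samples.
#' @return A one-row tibble: `species`, `phase` (`NA`), `flux_mmol_m2`,
#'   `sd_mmol_m2` (`NA` for a single series), `n_replicates` (1).
#' @examples
#' geo <- mat_geometry()
#' ser <- tibble::tibble(analyte = "acetate", compartment = "liquid",
#'                       time_h = c(12, 24), value = c(0, 0.3544))
#' net_flux(ser, geo, c(12, 24)) # ~14.9 mmol m^-2
#' @export
net_flux <- function(series, geometry, window) {
  stopifnot(length(window) == 2)
  if (window[1] == window[2]) stop("degenerate window", call. = FALSE)
  comp <- unique(series$compartment)
  if (length(comp) != 1) {
    stop("`series` must have a single compartment", call. = FALSE)
  }
  t <- series$time_h
  lo <- min(window); hi <- max(window)
  if (lo < min(t) || hi > max(t)) {
    stop("window outside series time range", call. = FALSE)
  }
  if (sum(t >= lo & t <= hi) < 2) {
    stop("fewer than 2 samples in window", call. = FALSE)
  }
  conc <- stats::approx(t, series$value, xout = c(window[1], window[2]))$y
  d_conc <- conc[2] - conc[1]
  flux <- switch(comp,
    headspace = headspace_amount(abs(d_conc), geometry$headspace_mL,
                                 geometry$temperature_K,
                                 geometry$pressure_atm) * sign(d_conc) /
      core_area(geometry$core_diameter_mm),
    liquid = d_conc * (geometry$liquid_volume_mL / 1000) /
      core_area(geometry$core_diameter_mm),
    chamber_water = {
      if (is.na(geometry$chamber_area_m2)) {
        stop("`chamber_area_m2` is not set in the geometry; ",
             "supply it via mat_geometry(chamber_area_m2 = ...)",
             call. = FALSE)
      }
      d_conc * geometry$chamber_volume_L / geometry$chamber_area_m2
    },
    stop("unknown compartment: ", comp, call. = FALSE)
  )
  species <- if ("analyte" %in% names(series)) series$analyte[1] else comp
  tibble::tibble(species = species, phase = NA_character_,
                 flux_mmol_m2 = flux, sd_mmol_m2 = NA_real_,
                 n_replicates = 1L)
}

#' Net DIC fluxes from a benthic flux-chamber series
#'
#' Computes the net area-normalized DIC flux between consecutive window
#' boundaries: change in concentration x chamber volume / chamber area.
#' Negative values indicate DIC moving into the mat (daytime photosynthetic
#' uptake); positive values indicate release to the water column.
#'
#' @param series A chamber time series tibble (`time_h`, `value` in
#'   mmol/L; `compartment` `"chamber_water"` if present).
#' @param geometry A [mat_geometry()] with `chamber_area_m2` set.
#' @param windows Numeric vector of window boundaries (h since dawn),
#'   strictly increasing; one flux per consecutive pair.
#' @param day_hours Length of the light phase, used to label windows that
#'   fall entirely within the day or night as `"day"`/`"night"`.
#' @return A tibble with one row per window: `species`, `phase`,
#'   `window_start`, `window_end`, `flux_mmol_m2`.
#' @export
dic_flux <- function(series, geometry, windows, day_hours = 12) {
  if (is.na(geometry$chamber_area_m2)) {
    stop("`chamber_area_m2` is not set in the geometry; ",
         "supply it via mat_geometry(chamber_area_m2 = ...)", call. = FALSE)
  }
  stopifnot(length(windows) >= 2, all(diff(windows) > 0))
  ser <- series
  ser$compartment <- "chamber_water"
  purrr::map2(windows[-length(windows)], windows[-1], function(a, b) {
    fl <- net_flux(ser, geometry, c(a, b))
    phase <- if (b <= day_hours) "day" else if (a >= day_hours) "night"
             else "mixed"
    tibble::tibble(species = fl$species, phase = phase,
                   window_start = a, window_end = b,
                   flux_mmol_m2 = fl$flux_mmol_m2)
  }) |> purrr::list_rbind()
}

#' Day and night fluxes for every series in a microcosm dataset
#'
#' Applies [net_flux()] per analyte x treatment x replicate over the day
#' window `[0, day_hours]` and the night window
#' `[day_hours, day_hours + night_hours]`.
#'
#' @param ts A long time-series tibble as produced by
#'   [simulate_microcosm()] or [read_timeseries_csv()].
#' @param geometry A [mat_geometry()].
#' @param day_hours,night_hours Phase durations (h).
#' @return A tibble: `species`, `treatment`, `replicate`, `phase`
#'   (`"day"`/`"night"`), `flux_mmol_m2`.
#' @export
phase_fluxes <- function(ts, geometry, day_hours = 12, night_hours = 12) {
  windows <- list(day = c(0, day_hours),
                  night = c(day_hours, day_hours + night_hours))
  ts |>
    dplyr::group_by(.data$analyte, .data$treatment, .data$replicate,
                    .data$compartment) |>
    dplyr::group_modify(function(df, key) {
      ser <- dplyr::mutate(df, analyte = key$analyte,
                           compartment = key$compartment)
      purrr::imap(windows, function(w, phase) {
        fl <- net_flux(ser, geometry, w)
        tibble::tibble(phase = phase, flux_mmol_m2 = fl$flux_mmol_m2)
      }) |> purrr::list_rbind()
    }) |>
    dplyr::ungroup() |>
    dplyr::select(species = "analyte", "treatment", "replicate",
                  "phase", "flux_mmol_m2")
}

#' Aggregate replicate fluxes into a mean flux with SD
#'
#' @param fluxes A tibble of per-replicate fluxes for a single species and
#'   phase (columns `species`, `phase`, `flux_mmol_m2`).
#' @return A one-row tibble `species`, `phase`, `flux_mmol_m2` (mean),
#'   `sd_mmol_m2` (sample SD, n-1 denominator; 0 when n = 1),
#'   `n_replicates`.
#' @examples
#' aggregate_replicates(tibble::tibble(species = "acetate", phase = "night",
#'                                     flux_mmol_m2 = c(10, 20)))
#' @export
aggregate_replicates <- function(fluxes) {
  if (nrow(fluxes) < 1) stop("no fluxes to aggregate", call. = FALSE)
  if (dplyr::n_distinct(fluxes$species) > 1) {
    stop("mixed species in `fluxes`; aggregate one species at a time",
         call. = FALSE)
  }
  if ("phase" %in% names(fluxes) && dplyr::n_distinct(fluxes$phase) > 1) {
    stop("mixed phases in `fluxes`", call. = FALSE)
  }
  x <- fluxes$flux_mmol_m2
  tibble::tibble(
    species = fluxes$species[1],
    phase = if ("phase" %in% names(fluxes)) fluxes$phase[1] else NA_character_,
    flux_mmol_m2 = mean(x),
    sd_mmol_m2 = if (length(x) > 1) stats::sd(x) else 0,
    n_replicates = length(x)
  )
}

#' Summarize per-replicate fluxes across species, treatments, and phases
#'
#' Grouped wrapper around [aggregate_replicates()].
#'
#' @param fluxes Output of [phase_fluxes()].
#' @return A tibble with one row per species x treatment x phase: mean
#'   flux, sample SD, and replicate count.
#' @export
summarize_replicates <- function(fluxes) {
  fluxes |>
    dplyr::group_by(.data$species, .data$treatment, .data$phase) |>
    dplyr::summarise(
      sd_mmol_m2 = if (dplyr::n() > 1) stats::sd(.data$flux_mmol_m2) else 0,
      n_replicates = dplyr::n(),
      flux_mmol_m2 = mean(.data$flux_mmol_m2),
      .groups = "drop"
    ) |>
    dplyr::select("species", "treatment", "phase", "flux_mmol_m2",
                  "sd_mmol_m2", "n_replicates")
}

#' Compare replicate fluxes between a treatment and its control
#'
#' Unpaired two-tailed t-test of a treatment group against the control
#' group, the comparison used to mark manipulation effects on flux bar
#' charts.
#'
#' @param control,treatment Numeric vectors of replicate fluxes (n >= 2
#'   each).
#' @param alpha Significance level for the `significant` flag.
#' @param var_equal Use the pooled-variance Student's t-test (default);
#'   `FALSE` gives Welch.
#' @return A one-row tibble: `estimate` (treatment - control mean
#'   difference), `statistic`, `p.value`, `significant`, `method`.
#' @export
treatment_comparison <- function(control, treatment, alpha = 0.05,
                                 var_equal = TRUE) {
  if (length(control) < 2 || length(treatment) < 2) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  ht <- stats::t.test(treatment, control, var.equal = var_equal,
                      alternative = "two.sided")
  tibble::tibble(
    estimate = mean(treatment) - mean(control),
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    significant = ht$p.value < alpha,
    method = ht$method
  )
}

#' Fit a sulfide colorimetric calibration line
#'
#' Least-squares line through (concentration, absorbance at 670 nm)
#' standards for the methylene-blue sulfide assay; unknowns are read back
#' by inverse prediction with [sulfide_concentration()].
#'
#' @param standards A tibble/data frame with columns `concentration`
#'   (mmol/L) and `absorbance`; at least 2 distinct concentrations.
#' @return An object of class `sulfide_calibration` (fields `slope`,
#'   `intercept`, `r_squared`, `n`).
#' @export
sulfide_calibration <- function(standards) {
  stopifnot(all(c("concentration", "absorbance") %in% names(standards)))
  if (nrow(standards) < 2 ||
      dplyr::n_distinct(standards$concentration) < 2) {
    stop("need >= 2 standards with distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration, data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) {
    stop("singular calibration fit (zero or undefined slope)", call. = FALSE)
  }
  tss <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n = nrow(standards)),
    class = "sulfide_calibration"
  )
}

#' @rdname sulfide_calibration
#' @param absorbance Absorbance value(s) at 670 nm.
#' @param calibration A fitted `sulfide_calibration`.
#' @return For `sulfide_concentration()`, concentration(s) in mmol/L.
#' @export
sulfide_concentration <- function(absorbance, calibration) {
  stopifnot(inherits(calibration, "sulfide_calibration"))
  (absorbance - calibration$intercept) / calibration$slope
}
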