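#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an electron balance into its per-species rows
#'
#' @param x An [electron_balance()].
#' @param ... Unused.
#' @return The per-species tibble: category (`fixed_C`, `glycogen`,
#'   `net`, `total`), day/night fluxes and SDs, diel average, electron
#'   coefficient, and electron flux with SD, at full precision.
#' @export
tidy.electron_balance <- function(x, ...) {
  x$rows
}

#' One-row summary of an electron balance
#'
#' @param x An [electron_balance()].
#' @param ... Unused.
#' @return A one-row tibble: fixed-carbon, net- and total-fermentation
#'   electron fluxes, the two headline percentages with SDs, and the SD
#'   method used.
#' @export
glance.electron_balance <- function(x, ...) {
  p <- .bal_parts(x)
  tibble::tibble(
    fixed_c_e_flux = sum(p$fixed$e_flux),
    net_e_flux = sum(p$net$e_flux),
    total_e_flux = sum(p$total$e_flux),
    pct_fermented = x$summary$percent[x$summary$statistic == "pct_fermented"],
    pct_fermented_sd = x$summary$sd[x$summary$statistic == "pct_fermented"],
    pct_accessory = x$summary$percent[x$summary$statistic == "pct_accessory"],
    pct_accessory_sd = x$summary$sd[x$summary$statistic == "pct_accessory"],
    sd_method = x$sd_method
  )
}

#' Format an electron balance as a report table
#'
#' Rounds the balance to the 1-decimal presentation convention (half away
#' from zero) and lays it out with one row per species plus the summary
#' percentage rows.
#'
#' @param x An [electron_balance()].
#' @param digits Decimals in the report.
#' @param ... Unused.
#' @return A tibble of formatted character columns.
#' @export
format.electron_balance <- function(x, digits = 1, ...) {
  fmt <- function(v, s) {
    ifelse(is.na(v), "-",
           sprintf("%.*f (%.*f)", digits, round_half_up(v, digits),
                   digits, round_half_up(s, digits)))
  }
  rows <- x$rows
  body <- tibble::tibble(
    row = paste0(rows$category, ": ", rows$species),
    day = fmt(rows$day_flux, rows$day_sd),
    night = fmt(rows$night_flux, rows$night_sd),
    diel_avg = fmt(rows$diel_avg, rows$diel_sd),
    e_coeff = sprintf("%g", rows$e_coeff),
    e_flux = fmt(rows$e_flux, rows$e_flux_sd)
  )
  summary <- tibble::tibble(
    row = c("% fixed e- fermented", "% fixed e- to accessory microbes"),
    day = "", night = "", diel_avg = "", e_coeff = "",
    e_flux = fmt(x$summary$percent, x$summary$sd)
  )
  dplyr::bind_rows(body, summary)
}

#' @export
print.electron_balance <- function(x, digits = 1, ...) {
  cat("Diel electron mass balance (mmol m^-2; e- fluxes mmol e- m^-2)\n")
  cat("SD method:", x$sd_method, "\n\n")
  df <- as.data.frame(format(x, digits = digits))
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Plot the electron fluxes of a balance
#'
#' Bar chart of per-species electron fluxes with SD error bars, net and
#' total fermentation side by side against the fixed-carbon flux.
#'
#' @param object An [electron_balance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.electron_balance <- function(object, ...) {
  rows <- object$rows
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$species, y = .data$e_flux,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$e_flux - .data$e_flux_sd,
                   ymax = .data$e_flux + .data$e_flux_sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "electron flux (mmol e- m^-2 diel^-1)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot diel concentration time series
#'
#' Faceted concentration-vs-time plot of a microcosm dataset with the
#' night phase shaded.
#'
#' @param ts A long time-series tibble (see [simulate_microcosm()]).
#' @param day_hours,night_hours Phase durations used for shading.
#' @return A ggplot.
#' @export
plot_timeseries <- function(ts, day_hours = 12, night_hours = 12) {
  ggplot2::ggplot(ts, ggplot2::aes(x = .data$time_h, y = .data$value,
                                   colour = .data$treatment,
                                   group = interaction(.data$treatment,
                                                       .data$replicate))) +
    ggplot2::annotate("rect", xmin = day_hours,
                      xmax = day_hours + night_hours,
                      ymin = -Inf, ymax = Inf, alpha = 0.1) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "hours since dawn", y = "concentration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
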