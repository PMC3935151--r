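#' Electron-equivalent coefficients per chemical species
#'
#' Electrons transferable per mole used to place DIC uptake, glycogen
#' storage, and fermentation products on a common electron-equivalent
#' basis: fixed inorganic carbon 4 e- per C, glycogen 24 per glucosyl
#' unit, acetate 8, formate 1, propionate 13, H2 2. The `"paper"` preset
#' follows the total-charge-state bookkeeping of the original balance
#' (formate 1, propionate 13); the `"redox"` preset uses strict
#' electron-transfer counts for full oxidation to CO2 (formate 2,
#' propionate 14).
#'
#' @param preset `"paper"` (default) or `"redox"`.
#' @param ... Named overrides or additional species, e.g. `butyrate = 20`.
#' @return A named numeric vector of class `electron_coefficients`.
#' @examples
#' electron_coefficients()
#' electron_coefficients("redox")
#' @export
electron_coefficients <- function(preset = c("paper", "redox"), ...) {
  preset <- match.arg(preset)
  coeffs <- c(fixed_C = 4, glycogen = 24, acetate = 8, formate = 1,
              propionate = 13, H2 = 2)
  if (preset == "redox") {
    coeffs[["formate"]] <- 2
    coeffs[["propionate"]] <- 14
  }
  extra <- c(...)
  if (length(extra) > 0) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      stop("overrides must be named", call. = FALSE)
    }
    coeffs[names(extra)] <- extra
  }
  if (any(coeffs <= 0)) stop("coefficients must be positive", call. = FALSE)
  structure(coeffs, class = c("electron_coefficients", "numeric"))
}

#' Average a day and a night flux into one diel value
#'
#' The diel flux/storage is the mean of the day and night magnitudes,
#' `(|day| + |night|) / 2`. By default the combined SD is the arithmetic
#' mean of the two phase SDs, which is how the reported balance combines
#' replicate spreads; quadrature (`sqrt(sd_d^2 + sd_n^2)/2`, appropriate
#' for independent phases) is available.
#'
#' @param day_value,night_value Phase fluxes (mmol m^-2, signed).
#' @param day_sd,night_sd Phase SDs (>= 0).
#' @param sd_method `"mean_sd"` or `"quadrature"`.
#' @return A one-row tibble `avg`, `sd`.
#' @examples
#' diel_average(-121.4, 10.3, 77.5, 6.9) # 99.45, 8.6
#' @export
diel_average <- function(day_value, day_sd, night_value, night_sd,
                         sd_method = c("mean_sd", "quadrature")) {
  sd_method <- match.arg(sd_method)
  if (any(c(day_sd, night_sd) < 0)) stop("SDs must be >= 0", call. = FALSE)
  avg <- (abs(day_value) + abs(night_value)) / 2
  sd <- switch(sd_method,
               mean_sd = (day_sd + night_sd) / 2,
               quadrature = sqrt(day_sd^2 + night_sd^2) / 2)
  tibble::tibble(avg = avg, sd = sd)
}

#' Convert an amount of a chemical species to electron equivalents
#'
#' @param species Species name(s) present in `coeffs`.
#' @param amount_mmol_m2 Amount(s) in mmol m^-2.
#' @param coeffs An [electron_coefficients()] set.
#' @return Electron flux in mmol e- m^-2 (`amount x coefficient`).
#' @examples
#' electron_equivalents("acetate", 14.9) # 119.2
#' electron_equivalents("H2", 0.83)      # 1.66
#' @export
electron_equivalents <- function(species, amount_mmol_m2,
                                 coeffs = electron_coefficients()) {
  idx <- match(species, names(coeffs))
  if (anyNA(idx)) {
    stop("unknown species: ", paste(species[is.na(idx)], collapse = ", "),
         "; known species: ", paste(names(coeffs), collapse = ", "),
         call. = FALSE)
  }
  unname(amount_mmol_m2 * as.numeric(coeffs)[idx])
}

# Normalize a products table to columns species, flux, sd.
.as_products <- function(x, what) {
  x <- tibble::as_tibble(x)
  if ("flux_mmol_m2" %in% names(x)) x <- dplyr::rename(x, flux = "flux_mmol_m2")
  if ("sd_mmol_m2" %in% names(x)) x <- dplyr::rename(x, sd = "sd_mmol_m2")
  if (!"sd" %in% names(x)) x$sd <- 0
  if (!all(c("species", "flux") %in% names(x))) {
    stop("`", what, "` needs columns species and flux (or flux_mmol_m2)",
         call. = FALSE)
  }
  dplyr::select(x, "species", "flux", "sd")
}

.as_phase_pair <- function(x, what) {
  need <- c("day", "day_sd", "night", "night_sd")
  x <- unlist(x)
  if (!all(need %in% names(x))) {
    stop("`", what, "` needs named values ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x[need]
}

#' Build the diel electron mass-balance table
#'
#' Assembles the full balance: a fixed inorganic carbon row from day/night
#' DIC fluxes, an informational glycogen storage row, and nighttime net
#' (intact mats) and total (disrupted mats) fermentation-product rows.
#' Each row's diel average is converted to electron equivalents, and the
#' summary percentages are computed:
#' \deqn{\%\,fermented = 100 \frac{\sum_i e^-_{total,i}}{e^-_{fixed\,C}}, \qquad
#'       \%\,accessory = 100 \frac{\sum_i e^-_{total,i} - \sum_i e^-_{net,i}}{e^-_{fixed\,C}}.}
#' The glycogen row is reported but excluded from both percentages, whose
#' denominator is the DIC-derived fixed-carbon electron flux.
#'
#' @param fixed_c Named values `day`, `day_sd`, `night`, `night_sd`:
#'   daytime and nighttime DIC flux (mmol m^-2; daytime uptake negative).
#' @param net_products,total_products Tibbles of nighttime production with
#'   columns `species`, `flux`, `sd` (or `flux_mmol_m2`/`sd_mmol_m2`).
#'   Every net species must also appear in `total_products`.
#' @param glycogen Optional named values `day`, `day_sd`, `night`,
#'   `night_sd`: storage gain/loss (mmol glucosyl m^-2).
#' @param coeffs An [electron_coefficients()] set.
#' @param sd_method `"mean_sd"` (default), `"quadrature"`, or
#'   `"monte_carlo"` (see [propagate_uncertainty()]).
#' @param n_draws,seed Monte-Carlo settings, passed to
#'   [propagate_uncertainty()] when `sd_method = "monte_carlo"`.
#' @return An object of class `electron_balance` with elements `rows`
#'   (per-species tibble), `summary` (percentage tibble), `coeffs`, and
#'   `sd_method`. Internal values are kept at full precision; use
#'   [format()] / [print()] for the 1-decimal report layout.
#' @seealso [percent_fermented()], [percent_accessory()],
#'   [balance_from_fluxes()]
#' @export
electron_balance <- function(fixed_c, net_products, total_products,
                             glycogen = NULL,
                             coeffs = electron_coefficients(),
                             sd_method = c("mean_sd", "quadrature",
                                           "monte_carlo"),
                             n_draws = 10000, seed = 1L) {
  sd_method <- match.arg(sd_method)
  if (missing(fixed_c) || is.null(fixed_c)) {
    stop("`fixed_c` is required: the percentage denominator is undefined ",
         "without the DIC-derived fixed-carbon flux", call. = FALSE)
  }
  fc <- .as_phase_pair(fixed_c, "fixed_c")
  net <- .as_products(net_products, "net_products")
  total <- .as_products(total_products, "total_products")
  missing_sp <- setdiff(net$species, total$species)
  if (length(missing_sp) > 0) {
    stop("species in net but not total: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(net, total, by = "species",
                             suffix = c("_net", "_total"))
  low <- joined$flux_total < joined$flux_net
  if (any(low)) {
    warning("total flux < net flux for: ",
            paste(joined$species[low], collapse = ", "),
            " (plausible only as replicate noise)", call. = FALSE)
  }

  row_from_pair <- function(category, species, pair) {
    da <- diel_average(pair[["day"]], pair[["day_sd"]],
                       pair[["night"]], pair[["night_sd"]])
    tibble::tibble(category = category, species = species,
                   day_flux = pair[["day"]], day_sd = pair[["day_sd"]],
                   night_flux = pair[["night"]], night_sd = pair[["night_sd"]],
                   diel_avg = da$avg, diel_sd = da$sd)
  }
  row_from_night <- function(category, df) {
    tibble::tibble(category = category, species = df$species,
                   day_flux = NA_real_, day_sd = NA_real_,
                   night_flux = df$flux, night_sd = df$sd,
                   diel_avg = abs(df$flux), diel_sd = df$sd)
  }
  rows <- dplyr::bind_rows(
    row_from_pair("fixed_C", "fixed_C", fc),
    if (!is.null(glycogen)) {
      row_from_pair("glycogen", "glycogen", .as_phase_pair(glycogen, "glycogen"))
    },
    row_from_night("net", net),
    row_from_night("total", total)
  )
  rows$e_coeff <- as.numeric(coeffs)[match(rows$species, names(coeffs))]
  if (anyNA(rows$e_coeff)) {
    stop("no electron coefficient for: ",
         paste(unique(rows$species[is.na(rows$e_coeff)]), collapse = ", "),
         "; known species: ", paste(names(coeffs), collapse = ", "),
         call. = FALSE)
  }
  rows$e_flux <- rows$diel_avg * rows$e_coeff
  rows$e_flux_sd <- rows$diel_sd * rows$e_coeff

  bal <- structure(list(rows = rows, summary = NULL, coeffs = coeffs,
                        sd_method = "mean_sd"),
                   class = "electron_balance")
  propagate_uncertainty(bal, method = sd_method, n_draws = n_draws,
                        seed = seed)
}

.bal_parts <- function(bal) {
  rows <- bal$rows
  list(
    fixed = rows[rows$category == "fixed_C", ],
    net = rows[rows$category == "net", ],
    total = rows[rows$category == "total", ]
  )
}

#' Recompute the uncertainty of an electron balance
#'
#' Three propagation rules for the diel-average SDs, electron-flux SDs,
#' and percentage SDs of an [electron_balance()]:
#' \describe{
#'   \item{`mean_sd`}{Diel SD is the arithmetic mean of the phase SDs and
#'     propagates linearly (fully correlated): row e- SD = coefficient x
#'     diel SD; percentage SD = percentage x (relative SD of numerator +
#'     relative SD of denominator).}
#'   \item{`quadrature`}{Independent-error propagation: diel SD =
#'     `sqrt(sd_day^2 + sd_night^2)/2`, numerator SDs combine in
#'     quadrature, and the ratio SD is
#'     `pct * sqrt(rel_num^2 + rel_den^2)`.}
#'   \item{`monte_carlo`}{Parametric bootstrap: phase fluxes are drawn
#'     from normal distributions with the stated means and SDs, the whole
#'     table is recomputed per draw, and SDs are empirical over draws.
#'     Deterministic given `seed`.}
#' }
#'
#' @param bal An `electron_balance`.
#' @param method One of `"mean_sd"`, `"quadrature"`, `"monte_carlo"`.
#' @param n_draws Number of Monte-Carlo draws (>= 1000).
#' @param seed Integer seed for `"monte_carlo"`.
#' @return The balance with `rows$diel_sd`, `rows$e_flux_sd`, and
#'   `summary` SDs recomputed; `sd_method` updated.
#' @export
propagate_uncertainty <- function(bal, method = c("mean_sd", "quadrature",
                                                  "monte_carlo"),
                                  n_draws = 10000, seed = 1L) {
  stopifnot(inherits(bal, "electron_balance"))
  method <- match.arg(method)
  rows <- bal$rows
  paired <- rows$category %in% c("fixed_C", "glycogen")
  if (method %in% c("mean_sd", "quadrature")) {
    diel_sd <- ifelse(
      paired,
      if (method == "mean_sd") (rows$day_sd + rows$night_sd) / 2
      else sqrt(rows$day_sd^2 + rows$night_sd^2) / 2,
      rows$night_sd
    )
    rows$diel_sd <- diel_sd
    rows$e_flux_sd <- diel_sd * rows$e_coeff
    bal$rows <- rows
    p <- .bal_parts(bal)
    den <- sum(p$fixed$e_flux); den_sd <- sum(p$fixed$e_flux_sd)
    num_f <- sum(p$total$e_flux)
    num_a <- sum(p$total$e_flux) - sum(p$net$e_flux)
    if (method == "mean_sd") {
      num_f_sd <- sum(p$total$e_flux_sd)
      num_a_sd <- sum(p$total$e_flux_sd) + sum(p$net$e_flux_sd)
      pct_sd <- function(pct, num, num_sd) {
        if (num == 0) 0 else abs(pct) * (num_sd / abs(num) + den_sd / abs(den))
      }
    } else {
      num_f_sd <- sqrt(sum(p$total$e_flux_sd^2))
      num_a_sd <- sqrt(sum(p$total$e_flux_sd^2) + sum(p$net$e_flux_sd^2))
      pct_sd <- function(pct, num, num_sd) {
        if (num == 0) 0 else
          abs(pct) * sqrt((num_sd / num)^2 + (den_sd / den)^2)
      }
    }
    pf <- 100 * num_f / den
    pa <- 100 * num_a / den
    bal$summary <- tibble::tibble(
      statistic = c("pct_fermented", "pct_accessory"),
      percent = c(pf, pa),
      sd = c(pct_sd(pf, num_f, num_f_sd), pct_sd(pa, num_a, num_a_sd))
    )
  } else {
    if (n_draws < 1000) {
      stop("monte_carlo needs n_draws >= 1000", call. = FALSE)
    }
    k <- nrow(rows)
    diel_mat <- withr::with_seed(seed, {
      # rows x draws matrices of phase fluxes
      night <- matrix(stats::rnorm(k * n_draws, rows$night_flux,
                                   rows$night_sd), nrow = k)
      diel <- abs(night)
      if (any(paired)) {
        kp <- sum(paired)
        day <- matrix(stats::rnorm(kp * n_draws, rows$day_flux[paired],
                                   rows$day_sd[paired]), nrow = kp)
        diel[paired, ] <- (abs(day) + abs(night[paired, , drop = FALSE])) / 2
      }
      diel
    })
    e_mat <- diel_mat * rows$e_coeff
    rows$e_flux_sd <- apply(e_mat, 1, stats::sd)
    rows$diel_sd <- rows$e_flux_sd / rows$e_coeff
    bal$rows <- rows
    p <- .bal_parts(bal)
    den <- sum(p$fixed$e_flux)
    pf <- 100 * sum(p$total$e_flux) / den
    pa <- 100 * (sum(p$total$e_flux) - sum(p$net$e_flux)) / den
    den_d <- colSums(e_mat[rows$category == "fixed_C", , drop = FALSE])
    tot_d <- colSums(e_mat[rows$category == "total", , drop = FALSE])
    net_d <- colSums(e_mat[rows$category == "net", , drop = FALSE])
    bal$summary <- tibble::tibble(
      statistic = c("pct_fermented", "pct_accessory"),
      percent = c(pf, pa),
      sd = c(stats::sd(100 * tot_d / den_d),
             stats::sd(100 * (tot_d - net_d) / den_d))
    )
  }
  bal$sd_method <- method
  bal
}

#' Percent of photosynthetically fixed electrons released as fermentation
#' products
#'
#' `100 x sum(total fermentation e-) / fixed-carbon e-`. The numeric
#' method takes electron fluxes directly (e.g. a printed e- column); the
#' `electron_balance` method reads them from the table at full precision.
#'
#' @param x An `electron_balance`, or a numeric vector of total
#'   fermentation electron fluxes.
#' @param fixed_c_e For the numeric method, the fixed-carbon electron flux
#'   (denominator, > 0).
#' @param ... Unused.
#' @return For the balance method, a one-row tibble `percent`, `sd`; for
#'   the numeric method, a single percentage.
#' @examples
#' percent_fermented(c(224.2, 10.0, 85.3, 3.55), fixed_c_e = 397.9) # 81.19
#' @export
percent_fermented <- function(x, ...) UseMethod("percent_fermented")

#' @rdname percent_fermented
#' @export
percent_fermented.electron_balance <- function(x, ...) {
  x$summary[x$summary$statistic == "pct_fermented", c("percent", "sd")]
}

#' @rdname percent_fermented
#' @export
percent_fermented.numeric <- function(x, fixed_c_e, ...) {
  if (fixed_c_e == 0) stop("fixed-carbon electron flux is zero", call. = FALSE)
  100 * sum(x) / fixed_c_e
}

#' Percent of fixed electrons taken up by accessory microbes
#'
#' `100 x (sum(total e-) - sum(net e-)) / fixed-carbon e-`: the gap
#' between total (disrupted-mat) and net (intact-mat) fermentation-product
#' release, attributed to consumption by spatially associated accessory
#' populations (sulfate reducers, anoxygenic phototrophs).
#'
#' @param x An `electron_balance`, or a numeric vector of total
#'   fermentation electron fluxes.
#' @param net_e For the numeric method, net fermentation electron fluxes.
#' @param fixed_c_e For the numeric method, the fixed-carbon electron
#'   flux (> 0).
#' @param ... Unused.
#' @return As [percent_fermented()].
#' @examples
#' percent_accessory(c(224.2, 10.0, 85.3, 3.55),
#'                   net_e = c(119.2, 8.3, 31.7, 1.66),
#'                   fixed_c_e = 397.9) # 40.76
#' @export
percent_accessory <- function(x, ...) UseMethod("percent_accessory")

#' @rdname percent_accessory
#' @export
percent_accessory.electron_balance <- function(x, ...) {
  x$summary[x$summary$statistic == "pct_accessory", c("percent", "sd")]
}

#' @rdname percent_accessory
#' @export
percent_accessory.numeric <- function(x, net_e, fixed_c_e, ...) {
  if (fixed_c_e == 0) stop("fixed-carbon electron flux is zero", call. = FALSE)
  100 * (sum(x) - sum(net_e)) / fixed_c_e
}

#' Electron ratio of two products of a fermentation stoichiometry
#'
#' For a fermentation yielding `mol` moles of each product per mole of
#' substrate, returns `(mol_a x coeff_a) / (mol_b x coeff_b)` — e.g.
#' glucose -> 2 acetate + 2 CO2 + 4 H2 gives an acetate:H2 electron ratio
#' of (2 x 8)/(4 x 2) = 2.
#'
#' @param product_stoichiometry Named numeric: moles of product per mole
#'   of substrate.
#' @param species_a,species_b Product names to compare.
#' @param coeffs An [electron_coefficients()] set.
#' @return The electron ratio a:b.
#' @examples
#' stoichiometric_electron_ratio(c(acetate = 2, H2 = 4), "acetate", "H2")
#' @export
stoichiometric_electron_ratio <- function(product_stoichiometry,
                                          species_a, species_b,
                                          coeffs = electron_coefficients()) {
  for (sp in c(species_a, species_b)) {
    if (!sp %in% names(product_stoichiometry)) {
      stop("species not in stoichiometry: ", sp, call. = FALSE)
    }
  }
  num <- product_stoichiometry[[species_a]] *
    electron_equivalents(species_a, 1, coeffs)
  den <- product_stoichiometry[[species_b]] *
    electron_equivalents(species_b, 1, coeffs)
  if (den == 0) stop("zero denominator electron term", call. = FALSE)
  num / den
}

#' Build an electron balance directly from summarized fluxes
#'
#' Convenience glue from [summarize_replicates()] output to
#' [electron_balance()]: the fixed-carbon row is taken from the `"DIC"`
#' species (day and night phases of the control treatment), net products
#' from the night-phase fluxes of the control treatment, and total
#' products from the night-phase fluxes of the disruption treatment.
#'
#' @param flux_summary Output of [summarize_replicates()].
#' @param control,disruption Treatment labels providing net and total
#'   fluxes.
#' @param dic_species Species name holding the DIC fluxes.
#' @param glycogen Optional glycogen storage (passed through).
#' @inheritParams electron_balance
#' @return An [electron_balance()].
#' @export
balance_from_fluxes <- function(flux_summary, control = "control",
                                disruption = "disruption",
                                dic_species = "DIC", glycogen = NULL,
                                coeffs = electron_coefficients(),
                                sd_method = "mean_sd",
                                n_draws = 10000, seed = 1L) {
  fs <- flux_summary
  pick <- function(trt, phase, species_in = NULL, species_not = NULL) {
    out <- fs[fs$treatment == trt & fs$phase == phase, ]
    if (!is.null(species_in)) out <- out[out$species %in% species_in, ]
    if (!is.null(species_not)) out <- out[!out$species %in% species_not, ]
    out
  }
  dic_day <- pick(control, "day", species_in = dic_species)
  dic_night <- pick(control, "night", species_in = dic_species)
  if (nrow(dic_day) != 1 || nrow(dic_night) != 1) {
    stop("need exactly one day and one night '", dic_species,
         "' flux in the control treatment", call. = FALSE)
  }
  net <- pick(control, "night", species_not = dic_species)
  total <- pick(disruption, "night", species_not = dic_species)
  electron_balance(
    fixed_c = c(day = dic_day$flux_mmol_m2, day_sd = dic_day$sd_mmol_m2,
                night = dic_night$flux_mmol_m2,
                night_sd = dic_night$sd_mmol_m2),
    net_products = net, total_products = total, glycogen = glycogen,
    coeffs = coeffs, sd_method = sd_method, n_draws = n_draws, seed = seed
  )
}

# Round half away from zero, the presentation convention of the report.
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
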