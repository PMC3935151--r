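#' Scenario configuration for synthetic diel microcosm experiments
#'
#' Defines the ground truth for the synthetic-data generator: per-species
#' net and total nighttime fermentation-product fluxes, day/night DIC
#' fluxes, glycogen storage changes, treatment effects, and replicate
#' noise. Defaults reproduce the measured flux scale of an intertidal
#' *Lyngbya* mat microcosm study: net nighttime production of acetate >
#' formate > propionate plus H2, total (disrupted-mat) production roughly
#' double for acetate/propionate/H2, daytime DIC uptake and nighttime DIC
#' release, and diel glycogen accumulation/depletion.
#'
#' Treatment semantics: `"control"` emits the configured *net* fluxes;
#' `"disruption"` emits the configured *total* fluxes (physical disruption
#' operationally defines the total-production condition); any other
#' treatment multiplies the net fluxes by its per-species factor in
#' `treatment_effects`.
#'
#' @param species A tibble with columns `species`, `compartment`
#'   (`"liquid"` or `"headspace"`), `net`, `total` (nighttime fluxes,
#'   mmol m^-2).
#' @param day_hours,night_hours Photoperiod durations (h); time runs in
#'   hours since dawn, day is `[0, day_hours)`, night is
#'   `[day_hours, day_hours + night_hours)`.
#' @param dic_day_flux,dic_night_flux Net DIC flux over each phase
#'   (mmol m^-2, negative = uptake into the mat).
#' @param dic_baseline_mmol_L Chamber DIC concentration at dawn (mmol/L).
#' @param glycogen_day_gain,glycogen_night_loss Glycogen storage change
#'   over each phase (mmol glucosyl m^-2; loss is reported as a negative
#'   nighttime value downstream).
#' @param glycogen_sd Replicate SD of the glycogen storage changes.
#' @param treatment_effects Named list: treatment -> named numeric vector
#'   of multiplicative factors per species (missing species default to 1).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise on production rates (0 = noise-free).
#' @param n_replicates Replicates per treatment.
#' @param sample_times Sampling times (h since dawn), strictly increasing.
#' @param geometry A [mat_geometry()]; the scenario requires a known
#'   `chamber_area_m2` so chamber concentrations can be constructed.
#' @param seed Integer seed making the generated data reproducible.
#'
#' @return A list of class `scenario_config`.
#' @seealso [simulate_microcosm()], [scenario_percent_fermented()]
#' @export
scenario_config <- function(species = default_species_fluxes(),
                            day_hours = 12,
                            night_hours = 12,
                            dic_day_flux = -121.4,
                            dic_night_flux = 77.5,
                            dic_baseline_mmol_L = 5,
                            glycogen_day_gain = 21.2,
                            glycogen_night_loss = -31.6,
                            glycogen_sd = 27.8,
                            treatment_effects = default_treatment_effects(),
                            replicate_cv = 0.1,
                            n_replicates = 6,
                            sample_times = c(0, 6, 12, 18, 24),
                            geometry = mat_geometry(chamber_area_m2 = 0.005),
                            seed = 1L) {
  stopifnot(day_hours > 0, night_hours > 0, replicate_cv >= 0,
            n_replicates >= 1)
  species <- tibble::as_tibble(species)
  req <- c("species", "compartment", "net", "total")
  if (!all(req %in% names(species))) {
    stop("`species` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(species$total < species$net)) {
    stop("total flux must be >= net flux for every species", call. = FALSE)
  }
  if (any(diff(sample_times) <= 0)) {
    stop("`sample_times` must be strictly increasing", call. = FALSE)
  }
  if (max(sample_times) > day_hours + night_hours) {
    stop("`sample_times` extend past the diel cycle", call. = FALSE)
  }
  structure(
    list(species = species, day_hours = day_hours, night_hours = night_hours,
         dic_day_flux = dic_day_flux, dic_night_flux = dic_night_flux,
         dic_baseline_mmol_L = dic_baseline_mmol_L,
         glycogen_day_gain = glycogen_day_gain,
         glycogen_night_loss = glycogen_night_loss,
         glycogen_sd = glycogen_sd,
         treatment_effects = treatment_effects,
         replicate_cv = replicate_cv, n_replicates = n_replicates,
         sample_times = sample_times, geometry = geometry,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @rdname scenario_config
#' @export
default_species_fluxes <- function() {
  tibble::tribble(
    ~species,     ~compartment, ~net,  ~total,
    "acetate",    "liquid",     14.9,  28.0,
    "formate",    "liquid",      8.3,  10.0,
    "propionate", "liquid",      2.4,   6.6,
    "H2",         "headspace",   0.83,  1.77
  )
}

#' @rdname scenario_config
#' @export
default_treatment_effects <- function() {
  list(
    control = c(),
    disruption = c(),                      # emits configured total fluxes
    nh4cl = c(),                           # N-fixation suppression: no effect
    dcmu = c(H2 = 0.3, acetate = 1.5),     # PSII inhibition
    molybdate = c(H2 = 2)                  # SRB inhibition enhances H2
  )
}

# Log-normal multiplier with mean 1 and coefficient of variation cv.
.lnorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Fractions of the day/night phases elapsed at time t (h since dawn).
.phase_frac <- function(t, day_hours, night_hours) {
  list(day = pmin(pmax(t / day_hours, 0), 1),
       night = pmin(pmax((t - day_hours) / night_hours, 0), 1))
}

#' Simulate diel microcosm concentration time series
#'
#' Generates, for each treatment x replicate x analyte, a concentration
#' time series with the structure the flux pipeline assumes: fermentation
#' products (liquid organic acids, headspace H2) accumulate linearly only
#' during night hours at a rate implied by the configured areal flux and
#' vessel geometry; chamber DIC decreases during the day and increases at
#' night. Replicate noise is multiplicative log-normal on the production
#' rates. Output is deterministic given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @param treatments Character vector of treatments to simulate; must be
#'   names of `config$treatment_effects`.
#' @return A tibble with columns `analyte`, `treatment`, `replicate`,
#'   `compartment`, `time_h`, `value`, `unit` (`ppm` for headspace,
#'   `mmol_L` otherwise).
#' @examples
#' cfg <- scenario_config(replicate_cv = 0, n_replicates = 1, seed = 42)
#' ts <- simulate_microcosm(cfg, treatments = "control")
#' dplyr::count(ts, analyte, compartment)
#' @export
simulate_microcosm <- function(config, treatments = c("control", "disruption")) {
  stopifnot(inherits(config, "scenario_config"))
  unknown <- setdiff(treatments, names(config$treatment_effects))
  if (length(unknown) > 0) {
    stop("unknown treatment(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  geo <- config$geometry
  if (is.na(geo$chamber_area_m2)) {
    stop("scenario geometry needs `chamber_area_m2` to build DIC series",
         call. = FALSE)
  }
  area <- core_area(geo$core_diameter_mm)
  frac <- .phase_frac(config$sample_times, config$day_hours, config$night_hours)

  withr::with_seed(config$seed, {
    out <- purrr::map(treatments, function(trt) {
      purrr::map(seq_len(config$n_replicates), function(rep_i) {
        n_sp <- nrow(config$species)
        mult <- .lnorm_mult(n_sp + 1, config$replicate_cv)
        prod_rows <- purrr::pmap(
          c(config$species, list(m = mult[seq_len(n_sp)])),
          function(species, compartment, net, total, m) {
            base <- if (trt == "disruption") total else
              net * .treatment_factor(config$treatment_effects[[trt]], species)
            amount <- base * m * area * frac$night   # mmol per vial
            conc <- switch(compartment,
              liquid = amount / (geo$liquid_volume_mL / 1000),
              headspace = headspace_ppm(amount, geo$headspace_mL,
                                        geo$temperature_K, geo$pressure_atm),
              stop("unsupported compartment in scenario: ", compartment,
                   call. = FALSE))
            unit <- if (compartment == "headspace") "ppm" else "mmol_L"
            tibble::tibble(
              analyte = species, compartment = compartment,
              time_h = config$sample_times, value = conc, unit = unit)
          })
        dic_m <- mult[n_sp + 1]
        per_conc <- geo$chamber_area_m2 / geo$chamber_volume_L
        dic_value <- config$dic_baseline_mmol_L +
          dic_m * per_conc * (config$dic_day_flux * frac$day +
                              config$dic_night_flux * frac$night)
        dic_row <- tibble::tibble(
          analyte = "DIC", compartment = "chamber_water",
          time_h = config$sample_times, value = dic_value, unit = "mmol_L")
        dplyr::bind_rows(prod_rows, list(dic_row)) |>
          dplyr::mutate(treatment = trt, replicate = rep_i, .before = 1)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  dplyr::select(out, "analyte", "treatment", "replicate", "compartment",
                "time_h", "value", "unit")
}

.treatment_factor <- function(effects, species) {
  if (is.null(effects) || !species %in% names(effects)) return(1)
  unname(effects[species])
}

#' Ground-truth percent of fixed electrons fermented implied by a scenario
#'
#' Computes the percentage of photosynthetically fixed electrons released
#' as total fermentation products that the scenario's configured fluxes
#' imply, using the same electron accounting as the analysis pipeline
#' (total product fluxes x electron coefficients over diel-averaged DIC
#' uptake x 4 e- per C).
#'
#' @param config A [scenario_config()].
#' @param coeffs An [electron_coefficients()] set.
#' @return A single percentage.
#' @export
scenario_percent_fermented <- function(config, coeffs = electron_coefficients()) {
  fixed_e <- (abs(config$dic_day_flux) + abs(config$dic_night_flux)) / 2 *
    coeffs[["fixed_C"]]
  total_e <- sum(purrr::map2_dbl(config$species$species, config$species$total,
                                 ~ electron_equivalents(.x, .y, coeffs)))
  100 * total_e / fixed_e
}

#' Rescale a scenario to a target percent-fermented
#'
#' Multiplies all net and total product fluxes by a common factor so that
#' [scenario_percent_fermented()] equals `percent`, leaving DIC fluxes
#' untouched. Useful for parameter-recovery studies at controlled ground
#' truth.
#'
#' @inheritParams scenario_percent_fermented
#' @param percent Target percentage of fixed electrons fermented.
#' @return A modified `scenario_config`.
#' @export
scenario_with_percent_fermented <- function(config, percent,
                                            coeffs = electron_coefficients()) {
  stopifnot(percent > 0)
  p0 <- scenario_percent_fermented(config, coeffs)
  config$species$net <- config$species$net * percent / p0
  config$species$total <- config$species$total * percent / p0
  config
}

#' Simulate paired DNA/cDNA OTU tables
#'
#' Draws a log-normal OTU abundance profile (few dominant taxa), samples
#' DNA counts multinomially at `depth_dna`, and samples cDNA counts from a
#' profile in which the `n_dominant` most abundant OTUs are up-weighted by
#' `dominance_factor` — emulating communities where a small number of
#' clades carry most of the ribosomal expression. Dominant OTUs receive
#' recognisable cyanobacterial genus labels so expression-ratio behaviour
#' can be checked at genus level.
#'
#' @param n_otus Number of OTUs.
#' @param n_dominant Number of expression-dominant OTUs (`<= n_otus`).
#' @param depth_dna,depth_cdna Library sizes (column sums of the output).
#' @param dominance_factor Multiplicative cDNA up-weighting of dominant
#'   OTUs (1 = no differential expression).
#' @param sigma_log SD of the log-normal abundance profile.
#' @param sample_id Name of the single sample column.
#' @param seed Integer seed.
#' @return A list with tibbles `dna` and `cdna` in OTU-table layout
#'   (`otu_id`, one count column, `taxonomy` with semicolon-separated
#'   levels ending in genus).
#' @export
simulate_otu_tables <- function(n_otus = 200, n_dominant = 3,
                                depth_dna = 11500, depth_cdna = 11500,
                                dominance_factor = 20, sigma_log = 1.5,
                                sample_id = "S1", seed = 1L) {
  stopifnot(n_dominant <= n_otus, n_dominant >= 1)
  if (depth_dna <= 0 || depth_cdna <= 0) {
    stop("library depths must be positive", call. = FALSE)
  }
  phyla <- c("Cyanobacteria", "Proteobacteria", "Chloroflexi",
             "Bacteroidetes", "Spirochaetes")
  dominant_genera <- c("Microcoleus", "Lyngbya", "Oscillochloris",
                       "Desulfosarcina", "Pleurocapsa")
  withr::with_seed(seed, {
    p <- sort(stats::rlnorm(n_otus, meanlog = 0, sdlog = sigma_log),
              decreasing = TRUE)
    p <- p / sum(p)
    dominant <- seq_len(n_dominant)
    genus <- paste0("Genus_", seq_len(n_otus))
    genus[dominant] <- rep_len(dominant_genera, n_dominant)
    phylum <- sample(phyla, n_otus, replace = TRUE)
    phylum[dominant] <- rep_len(c("Cyanobacteria", "Cyanobacteria",
                                  "Chloroflexi", "Proteobacteria",
                                  "Cyanobacteria"), n_dominant)
    taxonomy <- paste("Bacteria", phylum, paste0("Class_", phylum),
                      paste0("Order_", phylum), paste0("Family_", genus),
                      genus, sep = ";")
    dna_counts <- as.integer(stats::rmultinom(1, depth_dna, p))
    w <- p
    w[dominant] <- w[dominant] * dominance_factor
    cdna_counts <- as.integer(stats::rmultinom(1, depth_cdna, w / sum(w)))
    otu_id <- sprintf("OTU_%04d", seq_len(n_otus))
    make_tbl <- function(counts) {
      tbl <- tibble::tibble(otu_id = otu_id, count = counts,
                            taxonomy = taxonomy)
      names(tbl)[2] <- sample_id
      tbl
    }
    list(dna = make_tbl(dna_counts), cdna = make_tbl(cdna_counts))
  })
}

#' Simulate NanoSIMS spot ion counts
#'
#' Generates Poisson-distributed C2- dimer secondary-ion counts for a
#' 13C-labeled group and an unlabeled (PFA-fixed) control group. For a
#' target delta-13C the 13C/12C atom ratio is
#' \code{r = R_VPDB * (1 + delta/1000)} and the expected 13C12C:12C12C count
#' ratio under binomial isotope pairing is `2 r`, so 12C12C counts are
#' Poisson(`mean_counts`) and 13C12C counts Poisson(`mean_counts * 2 r`).
#'
#' @param target_delta_permil delta-13C of the labeled population (permil
#'   vs VPDB, must exceed -1000).
#' @param control_delta_permil delta-13C of the control population.
#' @param mean_counts Expected 12C12C ion count per spot.
#' @param n_spots Spots per group (>= 2).
#' @param probe Probe label attached to the labeled group.
#' @param seed Integer seed.
#' @return A tibble with columns `region_id`, `probe`, `treatment`
#'   (`"labeled"` / `"control"`), `counts_12C12C`, `counts_13C12C`.
#' @export
simulate_spots <- function(target_delta_permil, control_delta_permil = 0,
                           mean_counts = 1e5, n_spots = 10,
                           probe = "CFX", seed = 1L) {
  stopifnot(mean_counts > 0, n_spots >= 2)
  if (target_delta_permil <= -1000 || control_delta_permil <= -1000) {
    stop("delta-13C <= -1000 permil implies a non-positive atom fraction",
         call. = FALSE)
  }
  draw <- function(delta, label, prb) {
    r <- .R_VPDB * (1 + delta / 1000)
    tibble::tibble(
      region_id = sprintf("%s_%02d", label, seq_len(n_spots)),
      probe = prb, treatment = label,
      counts_12C12C = stats::rpois(n_spots, mean_counts),
      counts_13C12C = stats::rpois(n_spots, mean_counts * 2 * r)
    )
  }
  withr::with_seed(seed, dplyr::bind_rows(
    draw(target_delta_permil, "labeled", probe),
    draw(control_delta_permil, "control", "none")
  ))
}
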