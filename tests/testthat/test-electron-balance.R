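table2_net <- tibble::tribble(
  ~species,     ~flux, ~sd,
  "acetate",    14.9,  0.9,
  "formate",     8.3,  1.2,
  "propionate",  2.4,  0.5,
  "H2",          0.83, 0.05
)
table2_total <- tibble::tribble(
  ~species,     ~flux, ~sd,
  "acetate",    28.0,  1.3,
  "formate",    10.0,  1.0,
  "propionate",  6.6,  1.2,
  "H2",          1.77, 0.18
)
table2_fixed <- c(day = -121.4, day_sd = 10.3, night = 77.5, night_sd = 6.9)
table2_glyc <- c(day = 21.2, day_sd = 25.2, night = -31.6, night_sd = 30.4)

test_that("diel averaging reproduces the printed diel values and SDs", {
  da <- diel_average(-121.4, 10.3, 77.5, 6.9)
  expect_equal(round_half_up(da$avg), 99.5)
  expect_equal(da$sd, 8.6)
  da2 <- diel_average(21.2, 25.2, -31.6, 30.4)
  expect_equal(da2$avg, 26.4)
  expect_equal(da2$sd, 27.8)
  # identity: equal phases with no spread
  expect_equal(diel_average(-7, 0, 7, 0), tibble::tibble(avg = 7, sd = 0))
  # quadrature option differs
  expect_equal(diel_average(-121.4, 10.3, 77.5, 6.9,
                            sd_method = "quadrature")$sd,
               sqrt(10.3^2 + 6.9^2) / 2)
})

test_that("electron equivalents are linear with the printed coefficients", {
  expect_equal(electron_equivalents("acetate", 14.9), 119.2)
  expect_equal(electron_equivalents("H2", 0.83), 1.66)
  expect_equal(electron_equivalents("formate", 10.0), 10.0)
  expect_equal(electron_equivalents("glycogen", 0), 0)
  expect_equal(electron_equivalents("propionate", 3) * 2,
               electron_equivalents("propionate", 6))
  expect_error(electron_equivalents("butyrate", 1), "known species")
  redox <- electron_coefficients("redox")
  expect_equal(electron_equivalents("formate", 1, redox), 2)
  expect_equal(electron_equivalents("propionate", 1, redox), 14)
})

test_that("the full balance reproduces the printed table within rounding", {
  bal <- electron_balance(table2_fixed, table2_net, table2_total,
                          glycogen = table2_glyc)
  rows <- tidy(bal)
  get <- function(cat, sp, col) rows[[col]][rows$category == cat &
                                              rows$species == sp]
  expect_equal(round_half_up(get("fixed_C", "fixed_C", "diel_avg")), 99.5)
  expect_equal(get("fixed_C", "fixed_C", "diel_sd"), 8.6)
  expect_equal(get("glycogen", "glycogen", "diel_avg"), 26.4)
  expect_equal(get("glycogen", "glycogen", "e_flux"), 26.4 * 24)
  expect_equal(get("net", "acetate", "e_flux"), 119.2)
  expect_equal(get("net", "formate", "e_flux"), 8.3)
  expect_equal(get("net", "H2", "e_flux"), 1.66)
  expect_equal(get("total", "formate", "e_flux"), 10.0)
  # printed e- entries derived from unrounded fluxes agree to ~1 decimal
  expect_equal(get("total", "acetate", "e_flux"), 224.2, tolerance = 1e-3)
  expect_equal(get("total", "propionate", "e_flux"), 85.3, tolerance = 6e-3)
  expect_equal(get("fixed_C", "fixed_C", "e_flux"), 397.9, tolerance = 1e-3)
  # percentages recomputed from the same printed fluxes land on the
  # reported scale
  expect_equal(percent_fermented(bal)$percent, 81.2, tolerance = 2e-3)
  expect_equal(percent_accessory(bal)$percent, 40.8, tolerance = 6e-3)
})

test_that("percentages from the printed electron column match exactly at 1 dp", {
  total_e <- c(224.2, 10.0, 85.3, 3.55)
  net_e <- c(119.2, 8.3, 31.7, 1.66)
  expect_equal(round_half_up(percent_fermented(total_e, fixed_c_e = 397.9)),
               81.2)
  expect_equal(round_half_up(percent_accessory(total_e, net_e = net_e,
                                               fixed_c_e = 397.9)), 40.8)
  expect_equal(percent_fermented(0, fixed_c_e = 397.9), 0)
  expect_equal(percent_accessory(total_e, net_e = total_e,
                                 fixed_c_e = 397.9), 0)
  expect_error(percent_fermented(total_e, fixed_c_e = 0), "zero")
})

test_that("percentages are invariant under rescaling all fluxes", {
  scale_products <- function(df, k) dplyr::mutate(df, flux = flux * k,
                                                  sd = sd * k)
  bal1 <- electron_balance(table2_fixed, table2_net, table2_total)
  bal2 <- electron_balance(table2_fixed * 3,
                           scale_products(table2_net, 3),
                           scale_products(table2_total, 3))
  expect_equal(percent_fermented(bal1)$percent,
               percent_fermented(bal2)$percent)
  expect_equal(percent_accessory(bal1)$percent,
               percent_accessory(bal2)$percent)
})

test_that("accessory share never exceeds fermented share for nonneg nets", {
  bal <- electron_balance(table2_fixed, table2_net, table2_total)
  expect_lte(percent_accessory(bal)$percent,
             percent_fermented(bal)$percent)
  # all products zero -> both percentages zero
  zero <- dplyr::mutate(table2_net, flux = 0, sd = 0)
  bal0 <- electron_balance(table2_fixed, zero,
                           dplyr::mutate(table2_total, flux = 0, sd = 0))
  expect_equal(percent_fermented(bal0)$percent, 0)
  expect_equal(percent_accessory(bal0)$percent, 0)
})

test_that("balance validates its inputs", {
  expect_error(electron_balance(NULL, table2_net, table2_total),
               "fixed_c")
  expect_error(electron_balance(table2_fixed, table2_net,
                                table2_total[-1, ]),
               "net but not total")
  swapped <- table2_total
  swapped$flux[1] <- 1 # total < net for acetate
  expect_warning(electron_balance(table2_fixed, table2_net, swapped),
                 "total flux < net")
  unknown <- dplyr::mutate(table2_net, species = paste0(species, "_x"))
  expect_error(electron_balance(table2_fixed, unknown,
                                dplyr::mutate(table2_total,
                                              species = unknown$species)),
               "coefficient")
})

test_that("mean_sd propagation reproduces the printed fixed-carbon e- SD", {
  bal <- electron_balance(table2_fixed, table2_net, table2_total)
  rows <- tidy(bal)
  expect_equal(rows$e_flux_sd[rows$species == "fixed_C"], 8.6 * 4) # 34.4
  expect_equal(rows$e_flux_sd[rows$category == "net" &
                                rows$species == "acetate"], 0.9 * 8)
})

test_that("zero input SDs give zero output SDs under every method", {
  zero_sd <- function(df) dplyr::mutate(df, sd = 0)
  fc0 <- c(day = -121.4, day_sd = 0, night = 77.5, night_sd = 0)
  for (m in c("mean_sd", "quadrature", "monte_carlo")) {
    bal <- electron_balance(fc0, zero_sd(table2_net),
                            zero_sd(table2_total), sd_method = m,
                            n_draws = 1000, seed = 1)
    expect_equal(tidy(bal)$e_flux_sd, rep(0, nrow(tidy(bal))),
                 info = m)
    expect_equal(bal$summary$sd, c(0, 0), info = m)
  }
})

test_that("monte carlo agrees with the analytic variance of a linear form", {
  # net = total (accessory = 0): pct_fermented numerator is a plain linear
  # combination, so an analytic variance oracle applies to the numerator.
  bal_q <- electron_balance(table2_fixed, table2_total, table2_total,
                            sd_method = "quadrature")
  bal_mc <- electron_balance(table2_fixed, table2_total, table2_total,
                             sd_method = "monte_carlo", n_draws = 1e5,
                             seed = 42)
  rows_q <- tidy(bal_q); rows_mc <- tidy(bal_mc)
  tot_q <- rows_q[rows_q$category == "total", ]
  tot_mc <- rows_mc[rows_mc$category == "total", ]
  # analytic: SD of coeff * |night| with night ~ N(flux, sd), flux >> sd
  analytic <- table2_total$sd * c(8, 1, 13, 2)
  expect_equal(tot_mc$e_flux_sd, analytic, tolerance = 0.05)
  expect_equal(tot_q$e_flux_sd, analytic)
  # deterministic given seed
  bal_mc2 <- electron_balance(table2_fixed, table2_total, table2_total,
                              sd_method = "monte_carlo", n_draws = 1e5,
                              seed = 42)
  expect_identical(bal_mc$summary, bal_mc2$summary)
  expect_error(propagate_uncertainty(bal_q, "monte_carlo", n_draws = 10),
               "1000")
})

test_that("stoichiometric electron ratios follow the coefficient algebra", {
  # glucose -> 2 acetate + 2 CO2 + 4 H2
  expect_identical(
    stoichiometric_electron_ratio(c(acetate = 2, H2 = 4), "acetate", "H2"),
    2)
  expect_equal(stoichiometric_electron_ratio(c(acetate = 2, H2 = 4),
                                             "acetate", "acetate"), 1)
  # measured net ratio from the printed electron column
  expect_equal(119.2 / 1.66, 71.8, tolerance = 1e-3)
  expect_error(stoichiometric_electron_ratio(c(acetate = 2), "acetate",
                                             "H2"), "not in stoichiometry")
  expect_error(stoichiometric_electron_ratio(c(acetate = 2, H2 = 0),
                                             "acetate", "H2"),
               "zero denominator")
})

test_that("tidy, glance, format, and autoplot expose the balance", {
  bal <- electron_balance(table2_fixed, table2_net, table2_total,
                          glycogen = table2_glyc)
  expect_s3_class(tidy(bal), "tbl_df")
  g <- glance(bal)
  expect_equal(g$pct_fermented, percent_fermented(bal)$percent)
  fmt <- format(bal)
  expect_true(any(grepl("fermented", fmt$row)))
  expect_true(any(grepl("119.2", fmt$e_flux)))
  expect_s3_class(autoplot(bal), "ggplot")
  expect_output(print(bal), "electron mass balance")
})
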