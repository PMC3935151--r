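# 13C/12C atom ratio of the VPDB standard.
.R_VPDB <- 0.0112372

#' Convert C2- dimer ion counts to a dimer-corrected delta-13C
#'
#' NanoSIMS measures carbon as diatomic secondary ions. Under binomial
#' isotope pairing with atom fraction `f` = 13C/(12C+13C), the dimer
#' channel probabilities are P(12C12C) = (1-f)^2 and P(13C12C) =
#' 2f(1-f), so the measured count ratio `m` = 13C12C/12C12C equals
#' `2f/(1-f) = 2r`. The atom ratio is therefore recovered exactly as
#' \code{r = m/2} (the dimer correction), from which
#' `delta13C = (r / R_VPDB - 1) x 1000` with `R_VPDB = 0.0112372`.
#'
#' @param counts_12C12C,counts_13C12C Ion counts (vectorized);
#'   `counts_12C12C` must be positive.
#' @return A tibble with columns `atom_ratio` (r), `atom_fraction` (f),
#'   and `delta13C_permil`.
#' @examples
#' dimer_to_ratio(1e6, 2 * 0.0112372 * 1e6) # delta = 0
#' @export
dimer_to_ratio <- function(counts_12C12C, counts_13C12C) {
  if (any(counts_12C12C <= 0)) {
    stop("`counts_12C12C` must be positive for ratio computation",
         call. = FALSE)
  }
  if (any(counts_13C12C < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  m <- counts_13C12C / counts_12C12C
  r <- m / 2
  tibble::tibble(
    atom_ratio = r,
    atom_fraction = r / (1 + r),
    delta13C_permil = (r / .R_VPDB - 1) * 1000
  )
}

#' Add delta-13C columns to a spot table
#'
#' @param spots A tibble with `counts_12C12C`, `counts_13C12C` columns
#'   (e.g. from [simulate_spots()] or [read_spot_csv()]).
#' @return `spots` with `atom_ratio`, `atom_fraction`, `delta13C_permil`
#'   appended.
#' @export
spot_deltas <- function(spots) {
  dplyr::bind_cols(spots,
                   dimer_to_ratio(spots$counts_12C12C, spots$counts_13C12C))
}

#' Normality-gated two-sample significance test
#'
#' Shapiro-Wilk normality is tested on each group; if either group departs
#' from normality (p < 0.05), the two-sample Wilcoxon rank-sum test is
#' used, otherwise Student's t-test. Zero-variance groups (on which
#' Shapiro-Wilk is undefined) are routed to the Wilcoxon path. With heavy
#' ties the Wilcoxon p-value uses the normal approximation rather than the
#' exact distribution.
#'
#' @param group_a,group_b Numeric vectors (n >= 3 each).
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row tibble: `test` (`"t"` or `"wilcoxon"`), `statistic`,
#'   `p.value`, `significant`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
gated_test <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs n >= 3 for normality gating", call. = FALSE)
  }
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }
  pa <- shapiro_p(group_a)
  pb <- shapiro_p(group_b)
  if (pa < 0.05 || pb < 0.05) {
    ht <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE))
    test <- "wilcoxon"
  } else {
    ht <- stats::t.test(group_a, group_b)
    test <- "t"
  }
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # identical constant groups
  tibble::tibble(test = test, statistic = unname(ht$statistic),
                 p.value = p, significant = p < alpha,
                 shapiro_p_a = pa, shapiro_p_b = pb)
}

#' Isotopic enrichment of labeled spots relative to unlabeled controls
#'
#' Converts both groups' dimer counts to delta-13C, summarizes the
#' per-group distributions, and tests the difference with the
#' normality-gated test. Enrichment is reported relative to the control
#' (unlabeled / PFA-fixed) reference group.
#'
#' @param labeled,control Spot tibbles with `counts_12C12C`,
#'   `counts_13C12C` (>= 2 spots each; >= 3 for the gated test).
#' @param alpha Significance level.
#' @return An object of class `isotope_enrichment`: list with `groups`
#'   (per-group n, mean, median, quartiles of delta-13C), `difference`
#'   (mean and median enrichment, permil), and `test` (gated-test row).
#' @export
enrichment_vs_control <- function(labeled, control, alpha = 0.05) {
  if (nrow(labeled) < 2 || nrow(control) < 2) {
    stop("each group needs >= 2 spots", call. = FALSE)
  }
  dl <- dimer_to_ratio(labeled$counts_12C12C,
                       labeled$counts_13C12C)$delta13C_permil
  dc <- dimer_to_ratio(control$counts_12C12C,
                       control$counts_13C12C)$delta13C_permil
  summ <- function(group, d) {
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(group = group, n = length(d), mean = mean(d),
                   median = q[2], q1 = q[1], q3 = q[3], sd = stats::sd(d))
  }
  test <- if (nrow(labeled) >= 3 && nrow(control) >= 3) {
    gated_test(dl, dc, alpha = alpha)
  } else {
    NULL
  }
  structure(
    list(
      groups = dplyr::bind_rows(summ("labeled", dl), summ("control", dc)),
      difference = tibble::tibble(mean_permil = mean(dl) - mean(dc),
                                  median_permil = stats::median(dl) -
                                    stats::median(dc)),
      test = test,
      deltas = list(labeled = dl, control = dc)
    ),
    class = "isotope_enrichment"
  )
}

#' @export
print.isotope_enrichment <- function(x, ...) {
  cat("Isotopic enrichment vs unlabeled control (delta-13C, permil)\n\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  cat("\nenrichment: mean", sprintf("%.1f", x$difference$mean_permil),
      "permil; median", sprintf("%.1f", x$difference$median_permil),
      "permil\n")
  if (!is.null(x$test)) {
    cat("gated test:", x$test$test, " p =",
        format.pval(x$test$p.value, digits = 3),
        if (x$test$significant) "(significant)" else "(not significant)",
        "\n")
  }
  invisible(x)
}

#' @rdname enrichment_vs_control
#' @param x An `isotope_enrichment`.
#' @param ... Unused.
#' @export
tidy.isotope_enrichment <- function(x, ...) {
  x$groups
}

#' @rdname enrichment_vs_control
#' @export
glance.isotope_enrichment <- function(x, ...) {
  out <- x$difference
  if (!is.null(x$test)) {
    out$test <- x$test$test
    out$p.value <- x$test$p.value
    out$significant <- x$test$significant
  }
  out
}

#' @rdname enrichment_vs_control
#' @param object An `isotope_enrichment`.
#' @export
autoplot.isotope_enrichment <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(group = "labeled", delta = object$deltas$labeled),
    tibble::tibble(group = "control", delta = object$deltas$control)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$delta)) +
    ggplot2::geom_boxplot(outlier.shape = 8) +
    ggplot2::labs(x = NULL, y = expression(delta^13 * C ~ "(permil)")) +
    ggplot2::theme_minimal()
}

#' Flag outliers by the 1.5 x IQR rule (flag, never remove)
#'
#' Points outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged; quartiles
#' use linear interpolation (R type 7). Flagged values are retained — the
#' flag marks them for plotting, analysis keeps every point.
#'
#' @param values Numeric vector; with n < 4 quartiles are unstable, so
#'   all points are left unflagged with a warning.
#' @return A logical vector, `TRUE` for flagged outliers.
#' @examples
#' flag_outliers(c(1, 2, 3, 4, 100))
#' @export
flag_outliers <- function(values) {
  if (length(values) < 4) {
    warning("n < 4: quartiles unstable, no points flagged", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}
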