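# OTU tables are tibbles with an `otu_id` column, one integer count column
# per sample, and a trailing `taxonomy` column of semicolon-separated
# levels (domain;phylum;...;genus, possibly truncated).

.otu_sample_cols <- function(table) {
  setdiff(names(table), c("otu_id", "taxonomy"))
}

#' Observed OTU richness of a count vector
#'
#' @param counts Non-negative integer counts.
#' @return Number of OTUs with count > 0.
#' @export
observed_richness <- function(counts) {
  sum(counts > 0)
}

#' Rarefy a count vector to a fixed depth
#'
#' Multivariate-hypergeometric subsampling without replacement (via
#' `vegan::rrarefy`) down to `depth` total counts, the standard
#' depth-normalization before comparing richness across libraries of
#' unequal size.
#'
#' @param counts Non-negative integer counts.
#' @param depth Target total (<= `sum(counts)`).
#' @param seed Optional integer seed; the subsample is deterministic
#'   given the seed and does not disturb the global RNG state.
#' @return An integer vector of the same length summing to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  total <- sum(counts)
  if (depth > total) {
    stop("depth (", depth, ") exceeds library size (", total, ")",
         call. = FALSE)
  }
  if (depth == total) return(as.integer(counts))
  run <- function() {
    # rrarefy warns heuristically when no count equals 1; inputs here are
    # genuine observed counts, so the warning is noise
    as.integer(suppressWarnings(
      vegan::rrarefy(matrix(counts, nrow = 1), depth))[1, ])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Chao1 nonparametric richness estimator
#'
#' `S_obs + F1^2 / (2 F2)` where `F1`, `F2` are the singleton and
#' doubleton counts (the classic form); when the sample has no doubletons
#' the bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used
#' so the estimate stays finite.
#'
#' @param counts Non-negative integer counts with at least one positive
#'   entry.
#' @return The Chao1 estimate (>= observed richness).
#' @examples
#' chao1(c(1, 1, 2, 5)) # 4 + 4/2 = 6
#' @export
chao1 <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("empty OTU table", call. = FALSE)
  }
  s_obs <- observed_richness(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
}

#' ACE (abundance-based coverage) richness estimator
#'
#' Splits OTUs into abundant (`> rare_threshold`) and rare groups and
#' estimates richness as
#' `S_abund + S_rare / C + (F1 / C) gamma^2`, where the sample coverage
#' is `C = 1 - F1 / N_rare` and the squared coefficient of variation of
#' rare abundances is
#' `gamma^2 = max(0, S_rare sum(k (k-1) F_k) / (C N_rare (N_rare - 1)) - 1)`.
#' When every rare individual is a singleton the coverage is zero and the
#' estimator falls back to [chao1()] with a warning.
#'
#' @param counts Non-negative integer counts.
#' @param rare_threshold Maximum abundance of a "rare" OTU (default 10).
#' @return The ACE estimate.
#' @export
ace <- function(counts, rare_threshold = 10) {
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("empty OTU table", call. = FALSE)
  }
  s_abund <- sum(counts > rare_threshold)
  rare <- counts[counts > 0 & counts <= rare_threshold]
  if (length(rare) == 0) return(s_abund)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE coverage is zero (all rare individuals are singletons); ",
            "falling back to Chao1", call. = FALSE)
    return(chao1(counts))
  }
  k <- seq_len(rare_threshold)
  f_k <- vapply(k, function(kk) sum(rare == kk), numeric(1))
  gamma2 <- max(0, s_rare * sum(k * (k - 1) * f_k) /
                  (c_ace * n_rare * (n_rare - 1)) - 1)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Richness summary over repeated rarefactions
#'
#' For each sample of an OTU table, subsamples to a common depth
#' `n_iter` times and reports the mean and SD of observed richness,
#' Chao1, and ACE over iterations — the subsampled "Avg. (SD)" richness
#' presentation for libraries of unequal depth.
#'
#' @param table An OTU table tibble.
#' @param depth Rarefaction depth (<= every sample's total; default the
#'   smallest library size).
#' @param n_iter Number of rarefaction iterations.
#' @param seed Integer seed (per-iteration subsamples are drawn from one
#'   seeded stream, so results are reproducible).
#' @param rare_threshold Passed to [ace()].
#' @return A tibble with one row per sample: `sample_id`, `depth`,
#'   `observed_mean/sd`, `chao1_mean/sd`, `ace_mean/sd`, `n_iterations`.
#' @export
richness_summary <- function(table, depth = NULL, n_iter = 100, seed = 1L,
                             rare_threshold = 10) {
  samples <- .otu_sample_cols(table)
  totals <- vapply(samples, function(s) sum(table[[s]]), numeric(1))
  if (is.null(depth)) depth <- min(totals)
  if (depth > min(totals)) {
    stop("depth exceeds the smallest library size (", min(totals), ")",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    purrr::map(samples, function(s) {
      est <- purrr::map(seq_len(n_iter), function(i) {
        sub <- rarefy_counts(table[[s]], depth)
        c(observed = observed_richness(sub), chao1 = chao1(sub),
          ace = ace(sub, rare_threshold))
      })
      m <- do.call(rbind, est)
      sds <- if (n_iter > 1) apply(m, 2, stats::sd) else c(0, 0, 0)
      tibble::tibble(
        sample_id = s, depth = depth,
        observed_mean = mean(m[, "observed"]), observed_sd = sds[1],
        chao1_mean = mean(m[, "chao1"]), chao1_sd = sds[2],
        ace_mean = mean(m[, "ace"]), ace_sd = sds[3],
        n_iterations = n_iter
      )
    }) |> purrr::list_rbind()
  })
}

.canonical_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

.taxon_at_level <- function(taxonomy, level) {
  idx <- if (is.character(level)) {
    i <- match(tolower(level), .canonical_ranks)
    if (is.na(i)) {
      stop("unknown taxonomy level '", level, "'; use an index or one of: ",
           paste(.canonical_ranks, collapse = ", "), call. = FALSE)
    }
    i
  } else {
    as.integer(level)
  }
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) >= idx && nzchar(p[idx])) trimws(p[idx]) else "unclassified"
  }, character(1))
}

#' Per-sample relative abundance at a taxonomy level
#'
#' Aggregates OTU counts to the requested taxonomy level (OTUs whose
#' taxonomy string is truncated above that level pool into
#' `"unclassified"`) and converts to proportions, which sum to 1 within
#' each sample.
#'
#' @param table An OTU table tibble.
#' @param level Taxonomy level: an integer position in the
#'   semicolon-separated string, or one of `"domain"`, `"phylum"`,
#'   `"class"`, `"order"`, `"family"`, `"genus"` (domain-first strings
#'   assumed).
#' @return A long tibble: `sample_id`, `taxon`, `count`, `proportion`.
#' @export
relative_abundance <- function(table, level = "phylum") {
  samples <- .otu_sample_cols(table)
  taxon <- .taxon_at_level(table$taxonomy, level)
  purrr::map(samples, function(s) {
    total <- sum(table[[s]])
    if (total == 0) stop("sample '", s, "' is empty", call. = FALSE)
    tibble::tibble(taxon = taxon, count = table[[s]]) |>
      dplyr::group_by(.data$taxon) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(sample_id = s, proportion = .data$count / total,
                    .before = 1)
  }) |> purrr::list_rbind()
}

#' cDNA:DNA ribosomal expression ratios per taxon
#'
#' For each sample present in both tables, computes each taxon's relative
#' abundance in the cDNA (rRNA transcript) and DNA (rRNA gene) libraries
#' and their ratio — a proxy for per-capita ribosomal activity. Only taxa
#' whose DNA relative abundance exceeds `min_dna_frac` (default 1%) are
#' assigned a ratio; rarer taxa (including taxa seen only in cDNA) are
#' retained in the output with `included = FALSE` and `ratio = NA`, since
#' their denominators are too poorly sampled to interpret.
#'
#' Ratios use the full (unrarefied) libraries: relative abundances are
#' scale-free, and the DNA filter applies to the DNA library directly.
#'
#' @param dna,cdna OTU table tibbles with matching sample columns.
#' @param level Taxonomy level for aggregation (default `"genus"`).
#' @param min_dna_frac DNA relative-abundance filter (exclusive bound).
#' @return A tibble: `sample_id`, `taxon`, `dna_frac`, `cdna_frac`,
#'   `ratio`, `included`, sorted by descending ratio within sample.
#' @export
expression_ratio <- function(dna, cdna, level = "genus",
                             min_dna_frac = 0.01) {
  samples <- intersect(.otu_sample_cols(dna), .otu_sample_cols(cdna))
  if (length(samples) == 0) {
    stop("no matching sample columns between DNA and cDNA tables",
         call. = FALSE)
  }
  ra_d <- relative_abundance(dna, level)
  ra_c <- relative_abundance(cdna, level)
  dplyr::full_join(
    dplyr::select(ra_d, "sample_id", "taxon", dna_frac = "proportion"),
    dplyr::select(ra_c, "sample_id", "taxon", cdna_frac = "proportion"),
    by = c("sample_id", "taxon")
  ) |>
    dplyr::filter(.data$sample_id %in% samples) |>
    dplyr::mutate(
      dna_frac = dplyr::coalesce(.data$dna_frac, 0),
      cdna_frac = dplyr::coalesce(.data$cdna_frac, 0),
      included = .data$dna_frac > min_dna_frac,
      ratio = ifelse(.data$included, .data$cdna_frac / .data$dna_frac,
                     NA_real_)
    ) |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$ratio))
}
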