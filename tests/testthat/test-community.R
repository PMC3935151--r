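toy_table <- tibble::tibble(
  otu_id = c("OTU_1", "OTU_2", "OTU_3"),
  S1 = c(10L, 30L, 60L),
  S2 = c(5L, 0L, 15L),
  taxonomy = c("Bacteria;Cyanobacteria;Cls;Ord;Fam;Microcoleus",
               "Bacteria;Chloroflexi;Cls;Ord;Fam;Oscillochloris",
               "Bacteria;Cyanobacteria;Cls;Ord;Fam;Lyngbya")
)

test_that("rarefaction preserves depth, integrality, and identity cases", {
  counts <- c(5L, 0L, 12L, 3L)
  expect_identical(rarefy_counts(counts, sum(counts)), counts)
  one <- rarefy_counts(counts, 1, seed = 2)
  expect_equal(sum(one), 1)
  expect_true(all(one %in% c(0L, 1L)))
  sub <- rarefy_counts(counts, 10, seed = 5)
  expect_equal(sum(sub), 10)
  expect_true(all(sub == floor(sub) & sub >= 0 & sub <= counts))
  expect_identical(rarefy_counts(counts, 10, seed = 5),
                   rarefy_counts(counts, 10, seed = 5))
  expect_error(rarefy_counts(counts, 100), "exceeds")
})

test_that("rarefaction inclusion frequencies match the hypergeometric mean", {
  counts <- c(20L, 10L, 5L, 10L, 5L)
  n <- sum(counts); depth <- 20L; n_rep <- 1e4
  draws <- withr::with_seed(77, {
    vapply(seq_len(n_rep), function(i) rarefy_counts(counts, depth),
           integer(length(counts)))
  })
  emp_mean <- rowMeans(draws)
  hyper_mean <- depth * counts / n
  hyper_var <- depth * (counts / n) * (1 - counts / n) *
    (n - depth) / (n - 1)
  se <- sqrt(hyper_var / n_rep)
  expect_true(all(abs(emp_mean - hyper_mean) < 3 * se))
})

test_that("Chao1 matches its formula by hand and the no-singleton identity", {
  expect_equal(chao1(c(1, 1, 2, 5)), 6) # S=4, F1=2, F2=1 -> 4 + 4/2
  expect_equal(chao1(c(1, 3, 3)), 3)    # F2=0 -> bias-corrected, F1=1
  expect_equal(chao1(c(4, 5, 9)), 3)    # no singletons -> S_obs
  expect_error(chao1(integer(0)), "empty")
  expect_error(chao1(c(0, 0)), "empty")
})

test_that("ACE reduces to observed richness on abundant-only data", {
  expect_equal(ace(c(50, 20, 11)), 3)
  # all rare individuals singletons -> Chao1 fallback with warning
  expect_warning(est <- ace(c(1, 1, 1, 50)), "falling back")
  expect_equal(est, chao1(c(1, 1, 1, 50)))
})

test_that("Chao1 and ACE match independent oracles on random tables", {
  withr::with_seed(101, {
    for (i in 1:50) {
      counts <- stats::rpois(sample(5:40, 1), lambda = sample(1:8, 1))
      if (sum(counts) == 0) counts[1] <- 1L
      expect_equal(chao1(counts), chao1_oracle(counts))
      suppressWarnings({
        expect_equal(ace(counts), ace_oracle(counts))
      })
    }
  })
})

test_that("ACE agrees with vegan's estimator on a bias-corrected-free case", {
  counts <- c(1, 1, 2, 3, 3, 4, 7, 12, 25, 40)
  ref <- vegan::estimateR(counts)
  expect_equal(ace(counts), unname(ref["S.ACE"]))
  # vegan's Chao1 is always bias-corrected; compare on an F2 = 0 table
  counts2 <- c(1, 3, 3, 15)
  expect_equal(chao1(counts2), unname(vegan::estimateR(counts2)["S.chao1"]))
})

test_that("richness estimators dominate observed richness", {
  withr::with_seed(55, {
    for (i in 1:20) {
      counts <- stats::rpois(30, 3)
      if (sum(counts) == 0) counts[1] <- 1L
      s <- observed_richness(counts)
      expect_gte(chao1(counts), s)
      suppressWarnings(expect_gte(ace(counts), sum(counts > 10)))
    }
  })
})

test_that("richness summaries are seeded, bounded, and degenerate correctly", {
  tabs <- simulate_otu_tables(n_otus = 80, n_dominant = 2,
                              depth_dna = 3000, depth_cdna = 1500, seed = 3)
  table <- tabs$dna
  table$S2 <- tabs$cdna$S1
  rs <- richness_summary(table, depth = 1000, n_iter = 10, seed = 9)
  expect_equal(nrow(rs), 2)
  expect_true(all(rs$chao1_mean >= rs$observed_mean))
  expect_true(all(rs$ace_mean >= rs$observed_mean))
  full_obs <- c(observed_richness(table$S1), observed_richness(table$S2))
  expect_true(all(rs$observed_mean <= full_obs))
  expect_identical(rs, richness_summary(table, depth = 1000, n_iter = 10,
                                        seed = 9))
  one <- richness_summary(table, depth = 500, n_iter = 1, seed = 2)
  expect_equal(one$observed_sd, c(0, 0))
  expect_error(richness_summary(table, depth = 1e6), "smallest library")
})

test_that("estimator means increase with rarefaction depth", {
  tabs <- simulate_otu_tables(n_otus = 120, n_dominant = 2,
                              depth_dna = 4000, depth_cdna = 4000, seed = 6)
  shallow <- richness_summary(tabs$dna, depth = 400, n_iter = 20, seed = 1)
  deep <- richness_summary(tabs$dna, depth = 3500, n_iter = 20, seed = 1)
  expect_lt(shallow$observed_mean, deep$observed_mean)
})

test_that("relative abundance aggregates taxonomy levels to unit sums", {
  ra <- relative_abundance(toy_table, "phylum")
  s1 <- dplyr::filter(ra, sample_id == "S1")
  expect_equal(sum(s1$proportion), 1, tolerance = 1e-12)
  expect_equal(dplyr::filter(s1, taxon == "Cyanobacteria")$proportion, 0.7)
  expect_equal(dplyr::filter(s1, taxon == "Chloroflexi")$proportion, 0.3)
  # single-OTU sample
  single <- toy_table[3, ]
  expect_equal(relative_abundance(single, "genus")$proportion, c(1, 1))
  # truncated taxonomy pools into unclassified
  trunc <- toy_table
  trunc$taxonomy[2] <- "Bacteria;Chloroflexi"
  ra_g <- relative_abundance(trunc, "genus")
  expect_true("unclassified" %in% ra_g$taxon)
  expect_error(relative_abundance(dplyr::mutate(toy_table, S1 = 0L),
                                  "phylum"), "empty")
  expect_error(relative_abundance(toy_table, "species"), "unknown taxonomy")
})

test_that("expression ratios apply the 1% DNA filter and detect enrichment", {
  # identical tables -> every included ratio exactly 1
  er <- expression_ratio(toy_table, toy_table)
  expect_true(all(dplyr::filter(er, included)$ratio == 1))

  dna <- tibble::tibble(
    otu_id = c("a", "b", "c"),
    S1 = c(5L, 500L, 495L),  # a = 0.5% DNA -> excluded
    taxonomy = c("Bacteria;P1;c;o;f;Rare",
                 "Bacteria;P1;c;o;f;Microcoleus",
                 "Bacteria;P2;c;o;f;Other"))
  cdna <- tibble::tibble(
    otu_id = c("a", "b", "c"),
    S1 = c(5L, 909L, 86L),
    taxonomy = dna$taxonomy)
  er2 <- expression_ratio(dna, cdna)
  rare <- dplyr::filter(er2, taxon == "Rare")
  expect_false(rare$included)
  expect_true(is.na(rare$ratio))
  mic <- dplyr::filter(er2, taxon == "Microcoleus")
  expect_equal(mic$ratio, (909 / 1000) / (500 / 1000))
  # 10x cDNA enrichment scenario
  dna3 <- tibble::tibble(otu_id = c("a", "b"), S1 = c(50L, 950L),
                         taxonomy = c("B;P;c;o;f;Up", "B;P;c;o;f;Down"))
  cdna3 <- tibble::tibble(otu_id = c("a", "b"), S1 = c(500L, 500L),
                          taxonomy = dna3$taxonomy)
  er3 <- expression_ratio(dna3, cdna3)
  expect_equal(dplyr::filter(er3, taxon == "Up")$ratio, 10)
  # cDNA-only taxon fails the DNA filter
  cdna4 <- dplyr::bind_rows(cdna3, tibble::tibble(
    otu_id = "z", S1 = 100L, taxonomy = "B;P;c;o;f;Ghost"))
  er4 <- expression_ratio(dna3, cdna4)
  expect_false(dplyr::filter(er4, taxon == "Ghost")$included)
})
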