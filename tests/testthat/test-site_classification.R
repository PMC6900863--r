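test_that("classify_specificity applies the threshold scheme", {
  cfg <- analysis_config()
  cl <- function(wt, dhet, a1, a2)
    classify_specificity(wt, dhet, a1, a2, cfg)$label
  expect_identical(cl(0.50, 0.50, 0.02, 0.45), "ADAR1_SPECIFIC")
  expect_identical(cl(0.20, 0.20, 0.01, 0.35), "ADAR1_SPECIFIC_ADAR2_INHIBITS")
  expect_identical(cl(0.30, 0.30, 0.25, 0.28), "SHARED")
  expect_identical(cl(0.30, 0.30, 0.02, 0.02), "NEITHER_RETAINED")
  expect_identical(cl(0.50, 0.50, 0.45, 0.02), "ADAR2_SPECIFIC")
  expect_identical(cl(0.20, 0.20, 0.35, 0.01), "ADAR2_SPECIFIC_ADAR1_INHIBITS")
  # one relative rate above the inhibits threshold with the other retained
  expect_identical(cl(0.30, 0.30, 0.20, 0.50), "UNCLASSIFIED")
  # control is the unweighted mean of WT and dHet rates
  out <- classify_specificity(0.2, 0.4, 0.1, 0.1, cfg)
  expect_equal(out$control_rate, 0.3)
  expect_equal(out$rel_a1, 1 / 3)
})

test_that("classification boundaries flip labels exactly at 0.10 and 1.50", {
  cfg <- analysis_config()
  cl <- function(a1, a2)
    classify_specificity(0.5, 0.5, a1 * 0.5, a2 * 0.5, cfg)$label
  expect_identical(cl(0.0999, 1.0), "ADAR1_SPECIFIC")
  expect_identical(cl(0.1001, 1.0), "SHARED")
  expect_identical(cl(0.0999, 1.4999), "ADAR1_SPECIFIC")
  expect_identical(cl(0.0999, 1.5001), "ADAR1_SPECIFIC_ADAR2_INHIBITS")
  expect_identical(cl(1.0, 1.4999), "SHARED")
  expect_identical(cl(1.0, 1.5001), "UNCLASSIFIED")
  # exactly at the lost threshold: neither lost nor inside the open interval
  expect_identical(cl(0.1, 1.0), "UNCLASSIFIED")
})

test_that("missing estimates and zero control yield no-calls with reasons", {
  cfg <- analysis_config()
  out <- classify_specificity(c(NA, 0), c(0.2, 0), c(0.1, 0.1), c(0.1, 0.1), cfg)
  expect_true(is.na(out$label[1]))
  expect_identical(out$reason[1], "missing_estimate")
  expect_identical(out$label[2], "UNCLASSIFIED")
  expect_identical(out$reason[2], "zero_control")
})

test_that("every considered site gets exactly one label (partition)", {
  cfg <- analysis_config()
  sc <- sim_config(seed = 61, n_selective_sites = 500, n_cluster_regions = 5,
                   chrom_length = 50000)
  tr <- simulate_editome_truth(sc, simulate_genome(sc))
  pu <- simulate_pileups(tr, sc)
  est <- pooled_rates(pu, truth_to_sites(tr), cfg)
  considered <- considered_sites(est, cfg)
  calls <- classify_sites(est, considered, cfg)
  expect_equal(nrow(calls), nrow(considered))
  expect_true(all(calls$label %in% specificity_classes))
  expect_equal(sum(table(calls$label)), nrow(considered))
})

test_that("hyperediting fixtures: 10 sites in 91 bp qualify, 9 spaced sites do not", {
  cfg <- analysis_config()
  s10 <- data.frame(chrom = "chr1", pos = seq(100L, 190L, by = 10L))
  r <- detect_hyperediting_regions(s10, cfg)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_sites, 10L)
  expect_equal(c(r$start, r$end), c(100L, 190L))
  expect_true(all(flag_hyperedited(s10, cfg)))

  s9 <- data.frame(chrom = "chr1", pos = seq(100L, 180L, by = 10L))
  expect_equal(nrow(detect_hyperediting_regions(s9, cfg)), 0L)
  expect_false(any(flag_hyperedited(s9, cfg)))

  expect_error(detect_hyperediting_regions(
    data.frame(chrom = "chr1", pos = c(5L, 1L)), cfg),
    "sorted", class = "editomekit_input_error")
})

test_that("hyperediting sweep matches the brute-force all-windows oracle", {
  cfg <- analysis_config(hyper_window = 100L, hyper_min_sites = 10L)
  set.seed(67)
  for (i in 1:150) {
    n <- sample(1:200, 1)
    pos <- sort(sample(1:5000, n))
    sites <- data.frame(chrom = "chr1", pos = pos)
    expect_identical(flag_hyperedited(sites, cfg),
                     brute_force_hyper(pos, 100L, 10L))
  }
  # and with varied thresholds
  for (i in 1:50) {
    w <- sample(20:200, 1); m <- sample(2:12, 1)
    cfg2 <- analysis_config(hyper_window = w, hyper_min_sites = m)
    pos <- sort(sample(1:2000, sample(1:120, 1)))
    sites <- data.frame(chrom = "chr1", pos = pos)
    expect_identical(flag_hyperedited(sites, cfg2), brute_force_hyper(pos, w, m))
  }
})

test_that("hyperediting is monotone in its thresholds", {
  set.seed(71)
  pos <- sort(sample(1:3000, 150))
  sites <- data.frame(chrom = "chr1", pos = pos)
  n_at <- function(w, m) sum(flag_hyperedited(
    sites, analysis_config(hyper_window = w, hyper_min_sites = m)))
  for (m in 2:8) expect_lte(n_at(100, m + 1), n_at(100, m))
  for (w in c(20, 50, 100, 150)) expect_lte(n_at(w, 5), n_at(w + 50, 5))
})

test_that("hyperediting regions cover their flagged sites and respect counts", {
  cfg <- analysis_config()
  set.seed(73)
  pos <- sort(sample(1:4000, 250))
  sites <- data.frame(chrom = "chr1", pos = pos)
  flags <- flag_hyperedited(sites, cfg)
  regions <- detect_hyperediting_regions(sites, cfg)
  in_region <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions)))
    in_region <- in_region | (pos >= regions$start[i] & pos <= regions$end[i])
  expect_identical(in_region, flags)
  expect_true(all(regions$n_sites >= cfg$hyper_min_sites))
})

test_that("conserved sites recover their planted class and keep uncovered rows", {
  cfg <- analysis_config()
  sc <- sim_config(seed = 79, n_selective_sites = 600, n_cluster_regions = 0,
                   control_rate_range = c(0.2, 0.8), conserved_fraction = 0.3)
  tr <- simulate_editome_truth(sc, simulate_genome(sc))
  pu <- simulate_pileups(tr, sc)
  sites <- truth_to_sites(tr)
  est <- pooled_rates(pu, sites, cfg)
  cons <- conserved_site_summary(est, sites, cfg)
  expect_equal(nrow(cons), sum(tr$conserved))
  m <- merge(cons, tr[, c("chrom", "pos", "strand", "class")],
             by = c("chrom", "pos", "strand"))
  expect_gte(mean(m$label == m$class), 0.95)
  # the double mutant column is present and ~0
  expect_true(all(m$rate_DKO < 0.01, na.rm = TRUE))

  empty <- conserved_site_summary(est, sites[sites$conserved == FALSE, ], cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("class_location_summary tabulates counts and bracket percentages", {
  calls <- data.frame(
    chrom = "chr1", pos = 1:10, strand = "+",
    label = c(rep("ADAR1_SPECIFIC", 2), rep("ADAR2_SPECIFIC", 3),
              rep("SHARED", 5)), stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr1", pos = 1:10, strand = "+", part = "exon",
                    stringsAsFactors = FALSE)
  out <- class_location_summary(calls, ann)
  exon <- out[out$part == "exon", ]
  expect_equal(exon$n_sites, 10)
  expect_equal(exon$pct_adar1_specific, 20)
  expect_equal(exon$pct_adar2_specific, 30)
  total <- out[out$part == "TOTAL", ]
  expect_equal(total$n_sites, sum(out$n_sites[out$part != "TOTAL"]))

  empty <- class_location_summary(calls[0, ], ann[0, ])
  expect_true(all(empty$n_sites == 0))
})
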