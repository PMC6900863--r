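test_that("simulate_genome is seed-deterministic with near-uniform composition", {
  sc <- sim_config(seed = 9, n_chromosomes = 1L, chrom_length = 100000L,
                   n_cluster_regions = 4L)
  g1 <- simulate_genome(sc)
  g2 <- simulate_genome(sc)
  expect_identical(g1, g2)

  comp <- table(strsplit(g1$genome[["chr1"]], "")[[1]]) / 100000
  expect_true(all(abs(comp - 0.25) < 0.015))

  sc0 <- sim_config(seed = 9, n_cluster_regions = 0L)
  expect_equal(nrow(simulate_genome(sc0)$clusters), 0L)
})

test_that("cluster regions are non-overlapping, labeled, and within bounds", {
  sc <- sim_config(seed = 21, n_chromosomes = 2L, chrom_length = 30000L,
                   n_cluster_regions = 11L)
  cl <- simulate_genome(sc)$clusters
  expect_equal(nrow(cl), 11L)
  expect_setequal(unique(cl$label), c("B1-like", "B2-like"))
  expect_true(all(cl$end - cl$start == sc$cluster_span))
  expect_true(all(cl$start >= 0 & cl$end <= sc$chrom_length))
  for (ch in unique(cl$chrom)) {
    sub <- cl[cl$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
})

test_that("truth table honors class patterns, strands, and the double-mutant zero", {
  sc <- sim_config(seed = 13, n_selective_sites = 800, n_cluster_regions = 6,
                   chrom_length = 50000)
  g <- simulate_genome(sc)
  tr <- simulate_editome_truth(sc, g)

  expect_true(all(tr$rate_DKO == 0))
  expect_true(all(tr$rate_WT == tr$control_rate))
  expect_true(all(tr$rate_DHET == tr$control_rate))

  # site strand reflects the reference base (A -> +, T -> -)
  base <- mapply(function(ch, p) substr(g$genome[[ch]], p, p), tr$chrom, tr$pos)
  expect_true(all(ifelse(base == "A", "+", "-") == tr$strand))

  rel1 <- tr$rate_ADAR1_E861A / tr$control_rate
  rel2 <- tr$rate_ADAR2_KO / tr$control_rate
  is_cls <- function(cl) tr$class == cl
  expect_true(all(rel1[is_cls("ADAR1_SPECIFIC")] < 0.10))
  expect_true(all(rel2[is_cls("ADAR1_SPECIFIC")] >= 0.10 &
                    rel2[is_cls("ADAR1_SPECIFIC")] <= 1.50))
  expect_true(all(rel2[is_cls("ADAR1_SPECIFIC_ADAR2_INHIBITS")] > 1.50))
  expect_true(all(rel2[is_cls("ADAR2_SPECIFIC")] < 0.10))
  expect_true(all(rel1[is_cls("SHARED")] > 0.10 & rel1[is_cls("SHARED")] < 1.50))
  expect_true(all(rel2[is_cls("SHARED")] > 0.10 & rel2[is_cls("SHARED")] < 1.50))
  expect_true(all(tr$rate_ADAR1_E861A <= 1 & tr$rate_ADAR2_KO <= 1))

  # every cluster holds at least sites_per_cluster sites within its span
  for (i in seq_len(nrow(g$clusters))) {
    inside <- tr$chrom == g$clusters$chrom[i] &
      tr$pos > g$clusters$start[i] & tr$pos <= g$clusters$end[i]
    expect_gte(sum(inside), sc$sites_per_cluster)
    expect_lte(diff(range(tr$pos[inside])), sc$cluster_span - 1L)
  }
})

test_that("planted class frequencies follow the mixture", {
  mix <- c(SHARED = 0.4, ADAR1_SPECIFIC = 0.3, ADAR2_SPECIFIC = 0.2,
           NEITHER_RETAINED = 0.1)
  sc <- sim_config(seed = 31, n_selective_sites = 10000, n_cluster_regions = 0,
                   n_chromosomes = 4, chrom_length = 100000, class_mixture = mix)
  tr <- simulate_editome_truth(sc, simulate_genome(sc))
  obs <- table(factor(tr$class, levels = names(mix))) / nrow(tr)
  # per-class normal-approximation 99% multinomial bound
  bound <- qnorm(0.995) * sqrt(mix * (1 - mix) / nrow(tr))
  expect_true(all(abs(obs - mix) < bound * 1.5))
})

test_that("pileups are exact in the noiseless corners", {
  sc <- sim_config(seed = 17, n_selective_sites = 50, n_cluster_regions = 0,
                   error_rate = 0, chrom_length = 20000,
                   class_mixture = c(SHARED = 1))
  g <- simulate_genome(sc)
  tr <- simulate_editome_truth(sc, g)

  # no editing, no error: plus-strand sites never show G; minus never show C
  tr0 <- tr
  tr0[, paste0("rate_", editome_genotypes)] <- 0
  pu <- simulate_pileups(tr0, sc)
  plus <- tr0$strand[match(paste(pu$chrom, pu$pos), paste(tr0$chrom, tr0$pos))] == "+"
  expect_true(all(pu$count_G[plus] == 0))
  expect_true(all(pu$count_C[!plus] == 0))

  # saturation: rate 1, no error
  tr1 <- tr
  tr1[, paste0("rate_", editome_genotypes)] <- 1
  pu <- simulate_pileups(tr1, sc)
  expect_true(all(pu$count_A[plus] == 0))
  expect_true(all(pu$count_G[plus] == rowSums(
    pu[plus, c("count_A", "count_C", "count_G", "count_T")])))
})

test_that("mean observed rate converges to the true rate at scale", {
  sc <- sim_config(seed = 23, n_selective_sites = 2000, n_cluster_regions = 0,
                   n_chromosomes = 2, error_rate = 0)
  g <- simulate_genome(sc)
  tr <- simulate_editome_truth(sc, g)
  tr[, paste0("rate_", editome_genotypes)] <- 0.30
  pu <- simulate_pileups(tr, sc)
  est <- pooled_rates(pu, truth_to_sites(tr), analysis_config())
  expect_lt(abs(mean(est$rate) - 0.30), 0.01)
})

test_that("the full simulation chain is byte-deterministic given the seed", {
  sc <- sim_config(seed = 29, n_selective_sites = 150, n_cluster_regions = 3,
                   chrom_length = 20000)
  run <- function() {
    g <- simulate_genome(sc)
    tr <- simulate_editome_truth(sc, g)
    list(g = g, tr = tr, pu = simulate_pileups(tr, sc))
  }
  expect_identical(run(), run())
})

test_that("strand mirroring with a complemented pileup leaves edited/total unchanged", {
  sc <- sim_config(seed = 37, n_selective_sites = 120, n_cluster_regions = 0,
                   chrom_length = 20000)
  g <- simulate_genome(sc)
  tr <- simulate_editome_truth(sc, g)
  pu <- simulate_pileups(tr, sc)
  sites <- truth_to_sites(tr)
  est <- pooled_rates(pu, sites, analysis_config())

  flip <- sites
  flip$strand <- ifelse(sites$strand == "+", "-", "+")
  pu2 <- pu
  pu2$count_A <- pu$count_T; pu2$count_T <- pu$count_A
  pu2$count_C <- pu$count_G; pu2$count_G <- pu$count_C
  est2 <- pooled_rates(pu2, flip, analysis_config())
  expect_equal(est$pooled_edited, est2$pooled_edited)
  expect_equal(est$pooled_total, est2$pooled_total)
})

test_that("config validation rejects malformed mixtures and rates", {
  expect_error(sim_config(class_mixture = c(SHARED = 0.5)),
               "sum to 1", class = "editomekit_config_error")
  expect_error(sim_config(class_mixture = c(BOGUS = 1)),
               class = "editomekit_config_error")
  expect_error(sim_config(error_rate = 0.5), class = "editomekit_config_error")
  expect_error(sim_config(control_rate_range = c(0.5, 0.2)),
               class = "editomekit_config_error")
})
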