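# Synthetic editing-study generator: a toy genome, an editome with planted
# ADAR-specificity classes and hyperedited clusters, and genotype-structured
# replicate pileups with known truth. Emulates a 5-genotype x 3-replicate
# whole-brain RNA-seq design at pileup (count) level, not read level.

#' Simulation configuration
#'
#' Parameters of the synthetic editing study. Defaults emulate the
#' five-genotype, three-replicate whole-brain design: negative-binomial
#' coverage (overdispersed RNA-seq depth), binomial sampling of edited reads,
#' and a small uniform per-read base-corruption error floor. Control (WT and
#' double-het) editing rates are drawn uniformly from
#' \code{control_rate_range}; the mutant genotypes' rates are the control rate
#' times a class-specific multiplier (see
#' \code{\link{simulate_editome_truth}}).
#'
#' @param seed Integer seed; all three simulation stages are deterministic
#'   given this value.
#' @param n_chromosomes,chrom_length Toy genome shape (uniform i.i.d. ACGT).
#' @param n_selective_sites Number of site-selective (non-cluster) sites.
#' @param n_cluster_regions Number of planted repeat-like cluster regions.
#' @param sites_per_cluster Editing sites planted per cluster region (>= 10 by
#'   default so clusters qualify as hyperedited).
#' @param cluster_span Width of each cluster region in bp (default 100).
#' @param class_mixture Named proportions over plantable specificity classes
#'   (must sum to 1). Default reflects a brain editome in which roughly half
#'   of sites are shared, ADAR2 accounts for more specific sites than ADAR1,
#'   and cross-enzyme inhibition is rare.
#' @param control_rate_range Length-2 numeric, bounds of the uniform control
#'   editing rate.
#' @param boundary_margin Distance kept between drawn class multipliers and
#'   the 0.10 / 1.50 classification thresholds so planted classes are
#'   recoverable (default 0.02).
#' @param coverage_mean,coverage_dispersion Negative-binomial per-replicate
#'   depth: mean and dispersion (variance = mu + dispersion * mu^2).
#' @param error_rate Per-read probability of corruption to a uniformly chosen
#'   other base (default 0.001).
#' @param n_replicates Replicates per genotype (default 3).
#' @param conserved_fraction Fraction of non-cluster sites flagged as
#'   evolutionarily conserved (a synthetic stand-in for an external conserved
#'   site list).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 100000L,
                       n_selective_sites = 2000L,
                       n_cluster_regions = 20L,
                       sites_per_cluster = 10L,
                       cluster_span = 100L,
                       class_mixture = c(SHARED = 0.50,
                                         ADAR1_SPECIFIC = 0.15,
                                         ADAR2_SPECIFIC = 0.25,
                                         ADAR1_SPECIFIC_ADAR2_INHIBITS = 0.05,
                                         ADAR2_SPECIFIC_ADAR1_INHIBITS = 0.05),
                       control_rate_range = c(0.05, 0.70),
                       boundary_margin = 0.02,
                       coverage_mean = 200,
                       coverage_dispersion = 0.3,
                       error_rate = 0.001,
                       n_replicates = 3L,
                       conserved_fraction = 0.05) {
  .chk_num <- function(x, name, lo = -Inf, hi = Inf, len = 1L) {
    if (!is.numeric(x) || length(x) != len || any(!is.finite(x)) ||
        any(x < lo) || any(x > hi))
      .config_error("invalid sim_config value for %s", name)
    x
  }
  seed <- as.integer(.chk_num(seed, "seed", 0, 2^31 - 3))
  n_chromosomes <- as.integer(.chk_num(n_chromosomes, "n_chromosomes", 1))
  chrom_length <- as.integer(.chk_num(chrom_length, "chrom_length", 100))
  n_selective_sites <- as.integer(.chk_num(n_selective_sites, "n_selective_sites", 0))
  n_cluster_regions <- as.integer(.chk_num(n_cluster_regions, "n_cluster_regions", 0))
  sites_per_cluster <- as.integer(.chk_num(sites_per_cluster, "sites_per_cluster", 1))
  cluster_span <- as.integer(.chk_num(cluster_span, "cluster_span", 10))
  .chk_num(class_mixture, "class_mixture", 0, 1, len = length(class_mixture))
  if (is.null(names(class_mixture)) ||
      !all(names(class_mixture) %in% .plantable_classes))
    .config_error("class_mixture must be named with plantable specificity classes")
  if (abs(sum(class_mixture) - 1) > 1e-9)
    .config_error("class_mixture proportions must sum to 1")
  .chk_num(control_rate_range, "control_rate_range", 0, 1, len = 2L)
  if (control_rate_range[1] >= control_rate_range[2])
    .config_error("control_rate_range must be increasing")
  .chk_num(boundary_margin, "boundary_margin", 0, 0.05)
  .chk_num(coverage_mean, "coverage_mean", 1e-6)
  .chk_num(coverage_dispersion, "coverage_dispersion", 1e-9)
  .chk_num(error_rate, "error_rate", 0, 0.0099999)
  n_replicates <- as.integer(.chk_num(n_replicates, "n_replicates", 1))
  .chk_num(conserved_fraction, "conserved_fraction", 0, 1)
  structure(list(seed = seed, n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length,
                 n_selective_sites = n_selective_sites,
                 n_cluster_regions = n_cluster_regions,
                 sites_per_cluster = sites_per_cluster,
                 cluster_span = cluster_span,
                 class_mixture = class_mixture,
                 control_rate_range = control_rate_range,
                 boundary_margin = boundary_margin,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 error_rate = error_rate,
                 n_replicates = n_replicates,
                 conserved_fraction = conserved_fraction,
                 genotypes = editome_genotypes),
            class = "sim_config")
}

#' Simulate a toy genome with planted repeat-like cluster regions
#'
#' Chromosomes are i.i.d. uniform ACGT. Cluster regions are non-overlapping
#' \code{cluster_span}-bp intervals labeled alternately \code{"B1-like"} and
#' \code{"B2-like"}, standing in for the SINE repeat elements that harbor
#' hyperedited clusters; they are distributed round-robin across chromosomes,
#' one per equal-sized block, at a random offset within the block.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genome} (named character vector) and
#'   \code{clusters} (0-based half-open interval data.frame with columns
#'   chrom, start, end, strand, label).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  k <- config$n_cluster_regions
  if (k > 0L) {
    chrom_of <- chroms[((seq_len(k) - 1L) %% config$n_chromosomes) + 1L]
    per_chrom <- table(factor(chrom_of, levels = chroms))
    if (any(per_chrom * config$cluster_span > config$chrom_length))
      .config_error("requested cluster regions exceed genome capacity")
    starts <- integer(k)
    for (ch in chroms) {
      idx <- which(chrom_of == ch)
      if (!length(idx)) next
      block <- config$chrom_length %/% length(idx)
      offs <- vapply(seq_along(idx), function(j) {
        sample.int(block - config$cluster_span + 1L, 1L) - 1L
      }, integer(1))
      starts[idx] <- (seq_along(idx) - 1L) * block + offs
    }
    clusters <- data.frame(chrom = chrom_of, start = starts,
                           end = starts + config$cluster_span,
                           strand = ".",
                           label = rep(c("B1-like", "B2-like"), length.out = k),
                           stringsAsFactors = FALSE)
    clusters <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           label = character(), stringsAsFactors = FALSE)
  }
  list(genome = genome, clusters = clusters)
}

# class-legal multiplier interval given control rate c; rates are capped at
# 0.99 so every planted pattern stays recoverable (a rate cannot exceed 1)
.mult_range <- function(class, ctrl, margin) {
  lo_thr <- 0.10; hi_thr <- 1.50
  cap <- 0.99 / ctrl
  switch(class,
    SHARED = list(a1 = c(lo_thr + margin, min(hi_thr - margin, cap)),
                  a2 = c(lo_thr + margin, min(hi_thr - margin, cap))),
    ADAR1_SPECIFIC = list(a1 = c(0, lo_thr - margin),
                          a2 = c(lo_thr + margin, min(hi_thr - margin, cap))),
    ADAR2_SPECIFIC = list(a1 = c(lo_thr + margin, min(hi_thr - margin, cap)),
                          a2 = c(0, lo_thr - margin)),
    ADAR1_SPECIFIC_ADAR2_INHIBITS = list(a1 = c(0, lo_thr - margin),
                                         a2 = c(hi_thr + margin, min(3, cap))),
    ADAR2_SPECIFIC_ADAR1_INHIBITS = list(a1 = c(hi_thr + margin, min(3, cap)),
                                         a2 = c(0, lo_thr - margin)),
    NEITHER_RETAINED = list(a1 = c(0, lo_thr - margin),
                            a2 = c(0, lo_thr - margin)),
    .config_error("unknown specificity class '%s'", class)
  )
}

# control rate upper bound keeping the class's multiplier interval non-empty
.ctrl_cap <- function(class, margin) {
  if (class %in% c("ADAR1_SPECIFIC_ADAR2_INHIBITS", "ADAR2_SPECIFIC_ADAR1_INHIBITS"))
    0.99 / (1.50 + 2 * margin)
  else
    0.99 / (0.10 + 2 * margin)
}

#' Simulate editome ground truth
#'
#' Places site-selective sites at reference A/T positions outside cluster
#' regions (T positions are emitted as minus-strand sites) and
#' \code{sites_per_cluster} sites inside each planted cluster interval. Each
#' site receives a specificity class drawn from \code{class_mixture}, a control
#' rate uniform in \code{control_rate_range} (truncated where needed so the
#' class pattern is representable with rates below 1), and per-genotype true
#' rates: WT and double-het equal the control rate, the ADAR1-dead and
#' ADAR2-null rates are control times a class-legal multiplier (lost < 0.10,
#' unchanged within [0.10, 1.50], inhibits within (1.50, 3.00], all kept
#' \code{boundary_margin} away from the thresholds), and the double mutant is
#' exactly 0 everywhere.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genome Output of \code{\link{simulate_genome}}.
#' @return data.frame (truth table): chrom, pos, strand, class, in_cluster,
#'   conserved, control_rate, and rate_WT, rate_DHET, rate_ADAR1_E861A,
#'   rate_ADAR2_KO, rate_DKO.
#' @export
simulate_editome_truth <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  seqs <- genome$genome
  clusters <- genome$clusters

  pick <- list()
  # cluster sites: A/T positions inside each planted interval
  if (nrow(clusters) > 0L) {
    for (i in seq_len(nrow(clusters))) {
      ch <- clusters$chrom[i]
      rng <- (clusters$start[i] + 1L):clusters$end[i]  # 1-based positions
      bases <- strsplit(substr(seqs[[ch]], rng[1], rng[length(rng)]), "")[[1]]
      at <- rng[bases %in% c("A", "T")]
      if (length(at) < config$sites_per_cluster)
        .config_error("cluster interval %s:%d-%d has too few A/T positions",
                      ch, clusters$start[i], clusters$end[i])
      pos <- sort(sample(at, config$sites_per_cluster))
      pick[[length(pick) + 1L]] <- data.frame(
        chrom = ch, pos = pos, in_cluster = TRUE, stringsAsFactors = FALSE)
    }
  }
  # selective sites: A/T positions outside all clusters, spread over chroms
  if (config$n_selective_sites > 0L) {
    avail <- lapply(names(seqs), function(ch) {
      bases <- strsplit(seqs[[ch]], "")[[1]]
      at <- which(bases %in% c("A", "T"))
      cl <- clusters[clusters$chrom == ch, , drop = FALSE]
      if (nrow(cl)) {
        in_cl <- rep(FALSE, length(at))
        for (j in seq_len(nrow(cl)))
          in_cl <- in_cl | (at > cl$start[j] & at <= cl$end[j])
        at <- at[!in_cl]
      }
      at
    })
    names(avail) <- names(seqs)
    pool <- data.frame(
      chrom = rep(names(seqs), lengths(avail)),
      pos = unlist(avail, use.names = FALSE), stringsAsFactors = FALSE)
    if (nrow(pool) < config$n_selective_sites)
      .config_error("genome capacity too small for %d selective sites",
                    config$n_selective_sites)
    sel <- pool[sort(sample.int(nrow(pool), config$n_selective_sites)), , drop = FALSE]
    sel$in_cluster <- FALSE
    pick[[length(pick) + 1L]] <- sel
  }
  if (!length(pick))
    .config_error("no sites requested (n_selective_sites = 0 and no clusters)")
  sites <- do.call(rbind, pick)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  base_at <- mapply(function(ch, p) substr(seqs[[ch]], p, p),
                    sites$chrom, sites$pos, USE.NAMES = FALSE)
  sites$strand <- ifelse(base_at == "A", "+", "-")

  n <- nrow(sites)
  cls <- sample(names(config$class_mixture), n, replace = TRUE,
                prob = config$class_mixture)
  m <- config$boundary_margin
  lo <- config$control_rate_range[1]
  hi <- config$control_rate_range[2]
  ctrl <- numeric(n); m1 <- numeric(n); m2 <- numeric(n)
  for (i in seq_len(n)) {
    hi_i <- min(hi, .ctrl_cap(cls[i], m))
    ctrl[i] <- stats::runif(1, lo, max(lo + 1e-6, hi_i))
    rg <- .mult_range(cls[i], ctrl[i], m)
    m1[i] <- stats::runif(1, rg$a1[1], rg$a1[2])
    m2[i] <- stats::runif(1, rg$a2[1], rg$a2[2])
  }
  conserved <- rep(FALSE, n)
  nc <- which(!sites$in_cluster)
  if (length(nc) && config$conserved_fraction > 0)
    conserved[nc] <- stats::runif(length(nc)) < config$conserved_fraction

  data.frame(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    class = cls, in_cluster = sites$in_cluster, conserved = conserved,
    control_rate = ctrl,
    rate_WT = ctrl, rate_DHET = ctrl,
    rate_ADAR1_E861A = pmin(ctrl * m1, 1),
    rate_ADAR2_KO = pmin(ctrl * m2, 1),
    rate_DKO = 0,
    stringsAsFactors = FALSE)
}

# distribute k corrupted reads uniformly over the three non-source bases
.spread_errors <- function(k) {
  if (k == 0L) return(c(0L, 0L, 0L))
  as.integer(stats::rmultinom(1, k, rep(1 / 3, 3)))
}

#' Simulate replicate pileup counts from editome truth
#'
#' For each site x genotype x replicate the read depth is negative binomial
#' (mean \code{coverage_mean}, variance mu + dispersion * mu^2, floored at 1),
#' the number of edited reads is Binomial(depth, true rate), and each read is
#' independently corrupted to a uniformly chosen other base with probability
#' \code{error_rate}. Counts are emitted on the forward reference strand: a
#' plus-strand site's reference reads appear as A and edited reads as G; a
#' minus-strand site's as T and C respectively.
#'
#' @param truth Truth table from \code{\link{simulate_editome_truth}}.
#' @param config A \code{\link{sim_config}}.
#' @return Pileup data.frame (see \code{\link{read_pileup_table}}), ordered by
#'   (chrom, pos, sample_id).
#' @export
simulate_pileups <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genotypes <- config$genotypes
  reps <- seq_len(config$n_replicates)
  grid <- expand.grid(site = seq_len(nrow(truth)), genotype = genotypes,
                      replicate = reps, stringsAsFactors = FALSE)
  N <- nrow(grid)
  rate <- as.numeric(as.matrix(
    truth[, paste0("rate_", genotypes)])[cbind(grid$site,
                                               match(grid$genotype, genotypes))])
  size <- 1 / config$coverage_dispersion
  depth <- pmax(1L, stats::rnbinom(N, size = size, mu = config$coverage_mean))
  edited <- stats::rbinom(N, depth, rate)
  n_ref <- depth - edited

  strand <- truth$strand[grid$site]
  ref_base <- ifelse(strand == "+", "A", "T")
  ed_base <- ifelse(strand == "+", "G", "C")
  counts <- matrix(0L, nrow = N, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_len(N), match(ref_base, colnames(counts)))] <- n_ref
  counts[cbind(seq_len(N), match(ed_base, colnames(counts)))] <- edited

  if (config$error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    err_ref <- stats::rbinom(N, n_ref, config$error_rate)
    err_ed <- stats::rbinom(N, edited, config$error_rate)
    hit <- which(err_ref > 0L | err_ed > 0L)
    for (i in hit) {
      if (err_ref[i] > 0L) {
        src <- ref_base[i]
        others <- setdiff(bases, src)
        spread <- .spread_errors(err_ref[i])
        counts[i, src] <- counts[i, src] - err_ref[i]
        counts[i, others] <- counts[i, others] + spread
      }
      if (err_ed[i] > 0L) {
        src <- ed_base[i]
        others <- setdiff(bases, src)
        spread <- .spread_errors(err_ed[i])
        counts[i, src] <- counts[i, src] - err_ed[i]
        counts[i, others] <- counts[i, others] + spread
      }
    }
  }

  out <- data.frame(
    chrom = truth$chrom[grid$site],
    pos = truth$pos[grid$site],
    sample_id = paste0(grid$genotype, "_R", grid$replicate),
    genotype = grid$genotype,
    replicate = grid$replicate,
    count_A = counts[, "A"], count_C = counts[, "C"],
    count_G = counts[, "G"], count_T = counts[, "T"],
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected observed edited-read proportion under the simulator's error model
#'
#' With true editing rate p and per-read corruption probability e, an edited
#' read is observed as the edited base with probability 1 - e and a reference
#' read is corrupted to the edited base with probability e/3; the editing-rate
#' denominator keeps only reference-base and edited-base reads. The observed
#' edited count, conditional on the informative depth n, is exactly
#' Binomial(n, p_obs) with
#' p_obs = (p (1 - e) + (1 - p) e / 3) / (1 - 2 e / 3).
#'
#' @param p True editing rate(s).
#' @param error_rate Per-read corruption probability.
#' @return Expected observed proportion(s), same length as \code{p}.
#' @export
expected_observed_rate <- function(p, error_rate) {
  e <- error_rate
  (p * (1 - e) + (1 - p) * e / 3) / (1 - 2 * e / 3)
}

#' Sites table view of a simulation truth table
#'
#' @param truth Truth table from \code{\link{simulate_editome_truth}}.
#' @return Site data.frame with columns chrom, pos, strand, sources,
#'   conserved (sources fixed to \code{"simulated"}).
#' @export
truth_to_sites <- function(truth) {
  data.frame(chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
             sources = "simulated", conserved = truth$conserved,
             stringsAsFactors = FALSE)
}
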