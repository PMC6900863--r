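# Pileup counts -> per-site, per-genotype editing rates with coverage and
# minimum-rate filters, and a two-proportion z statistic for differential
# editing between genotypes.

#' Analysis configuration
#'
#' Thresholds of the editing analysis. Defaults: sites need a pooled read
#' coverage of at least 50 in every genotype and an editing rate of at least
#' 0.01 (1\%) in both control genotypes to be considered; differential calls
#' use |z| >= 5; a site is "lost" below 10\% of the control rate and
#' "inhibited" above 150\%; hyperediting means at least 10 sites within a
#' 100-bp window; sequence context extends 5 nt either side of the edited
#' adenosine. All thresholds are inclusive at the boundary.
#'
#' @param min_depth Minimum pooled read coverage per genotype (default 50).
#' @param min_rate Minimum editing rate in the control genotypes (default 0.01).
#' @param z_threshold Significance threshold on |z| (default 5).
#' @param lost_fraction Relative-rate threshold below which editing is lost
#'   (default 0.10).
#' @param inhibits_fraction Relative-rate threshold above which the remaining
#'   enzyme edits more than control (default 1.50).
#' @param hyper_window Hyperediting window span in bp (default 100).
#' @param hyper_min_sites Minimum sites within one window (default 10).
#' @param context_flank Flank width in nt for sequence-context matrices
#'   (default 5).
#' @return Object of class \code{analysis_config}.
#' @export
analysis_config <- function(min_depth = 50L, min_rate = 0.01, z_threshold = 5,
                            lost_fraction = 0.10, inhibits_fraction = 1.50,
                            hyper_window = 100L, hyper_min_sites = 10L,
                            context_flank = 5L) {
  .chk <- function(x, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
      .config_error("invalid analysis_config value for %s", name)
    x
  }
  min_depth <- as.integer(.chk(min_depth, "min_depth", 1))
  .chk(min_rate, "min_rate", 1e-12, 1 - 1e-12)
  .chk(z_threshold, "z_threshold", 0)
  .chk(lost_fraction, "lost_fraction", 1e-12, 1 - 1e-12)
  .chk(inhibits_fraction, "inhibits_fraction", 1 + 1e-12)
  hyper_window <- as.integer(.chk(hyper_window, "hyper_window", 2))
  hyper_min_sites <- as.integer(.chk(hyper_min_sites, "hyper_min_sites", 2))
  context_flank <- as.integer(.chk(context_flank, "context_flank", 1))
  structure(list(min_depth = min_depth, min_rate = min_rate,
                 z_threshold = z_threshold, lost_fraction = lost_fraction,
                 inhibits_fraction = inhibits_fraction,
                 hyper_window = hyper_window,
                 hyper_min_sites = hyper_min_sites,
                 context_flank = context_flank),
            class = "analysis_config")
}

#' Strand-aware edited/total read counts at one site
#'
#' For a plus-strand site the edited reads are the G count and the reference
#' reads the A count; for a minus-strand site the edited reads are C and the
#' reference reads T (the library is stranded; counts are stored on the
#' forward reference strand). The total keeps only reference plus edited
#' reads, so unrelated mismatches do not enter the denominator.
#'
#' @param pileup One pileup row (list or one-row data.frame with chrom, pos
#'   and the four counts).
#' @param site One site (list or one-row data.frame with chrom, pos, strand).
#' @return Named integer vector \code{c(edited, total)}.
#' @export
strand_aware_counts <- function(pileup, site) {
  if (pileup$chrom[1] != site$chrom[1] || pileup$pos[1] != site$pos[1])
    .input_error("pileup (%s:%d) does not match site (%s:%d)",
                 pileup$chrom[1], pileup$pos[1], site$chrom[1], site$pos[1])
  if (site$strand[1] == "+") {
    edited <- pileup$count_G[1]; ref <- pileup$count_A[1]
  } else if (site$strand[1] == "-") {
    edited <- pileup$count_C[1]; ref <- pileup$count_T[1]
  } else {
    .input_error("site strand must be + or -")
  }
  c(edited = as.integer(edited), total = as.integer(edited + ref))
}

#' Pool replicate counts into one genotype rate estimate
#'
#' Pools by summation before division: rate = sum(edited) / sum(total), the
#' depth-weighted estimate (not the mean of per-replicate rates).
#'
#' @param edited Integer vector of per-replicate edited read counts.
#' @param total Integer vector of per-replicate informative read depths.
#' @param config An \code{\link{analysis_config}}.
#' @return List with pooled_edited, pooled_total, rate (NA when no coverage),
#'   n_replicates, passes_depth, passes_rate.
#' @export
pooled_rate <- function(edited, total, config = analysis_config()) {
  stopifnot(length(edited) == length(total), length(edited) >= 1,
            all(edited <= total))
  pe <- sum(edited); pt <- sum(total)
  rate <- if (pt > 0) pe / pt else NA_real_
  list(pooled_edited = pe, pooled_total = pt, rate = rate,
       n_replicates = length(edited),
       passes_depth = pt >= config$min_depth,
       passes_rate = !is.na(rate) && rate >= config$min_rate)
}

#' Per-site, per-genotype pooled editing rate estimates
#'
#' Joins pileups to the site table (site strand drives the edited/reference
#' base choice), derives per-replicate edited/total counts strand-awarely,
#' and pools replicates by summation.
#'
#' @param pileups Pileup data.frame (see \code{\link{read_pileup_table}}).
#' @param sites Site data.frame (chrom, pos, strand).
#' @param config An \code{\link{analysis_config}}.
#' @return data.frame: chrom, pos, strand, genotype, pooled_edited,
#'   pooled_total, rate, n_replicates, passes_depth, passes_rate, ordered by
#'   (chrom, pos, strand, genotype).
#' @export
pooled_rates <- function(pileups, sites, config = analysis_config()) {
  m <- merge(pileups, sites[, c("chrom", "pos", "strand")],
             by = c("chrom", "pos"))
  if (!nrow(m))
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      genotype = character(), pooled_edited = integer(),
                      pooled_total = integer(), rate = numeric(),
                      n_replicates = integer(), passes_depth = logical(),
                      passes_rate = logical(), stringsAsFactors = FALSE))
  plus <- m$strand == "+"
  edited <- ifelse(plus, m$count_G, m$count_C)
  total <- edited + ifelse(plus, m$count_A, m$count_T)
  key <- paste(m$chrom, m$pos, m$strand, m$genotype, sep = "\r")
  pe <- rowsum(edited, key)
  pt <- rowsum(total, key)
  nr <- rowsum(rep(1L, length(key)), key)
  parts <- strsplit(rownames(pe), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
    strand = vapply(parts, `[[`, character(1), 3L),
    genotype = vapply(parts, `[[`, character(1), 4L),
    pooled_edited = as.integer(pe[, 1]),
    pooled_total = as.integer(pt[, 1]),
    n_replicates = as.integer(nr[, 1]),
    stringsAsFactors = FALSE)
  out$rate <- ifelse(out$pooled_total > 0,
                     out$pooled_edited / out$pooled_total, NA_real_)
  out$passes_depth <- out$pooled_total >= config$min_depth
  out$passes_rate <- !is.na(out$rate) & out$rate >= config$min_rate
  out <- out[order(out$chrom, out$pos, out$strand, out$genotype),
             c("chrom", "pos", "strand", "genotype", "pooled_edited",
               "pooled_total", "rate", "n_replicates", "passes_depth",
               "passes_rate")]
  rownames(out) <- NULL
  out
}

#' Sites passing the coverage and control-rate filters
#'
#' A site is considered when every genotype's pooled depth reaches
#' \code{min_depth} and the editing rate is at least \code{min_rate} in each
#' control genotype. Sites lacking an estimate for some genotype are dropped.
#'
#' @param estimates Estimate data.frame from \code{\link{pooled_rates}}.
#' @param config An \code{\link{analysis_config}}.
#' @param control_genotypes Genotypes whose rate must clear \code{min_rate}
#'   (default WT and the double-het control).
#' @return data.frame of considered site keys (chrom, pos, strand), sorted.
#' @export
considered_sites <- function(estimates, config = analysis_config(),
                             control_genotypes = c("WT", "DHET")) {
  if (!nrow(estimates))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  unknown <- setdiff(unique(estimates$genotype), editome_genotypes)
  if (length(unknown))
    .input_error("unknown genotype label(s): %s", paste(unknown, collapse = ", "))
  unknown <- setdiff(control_genotypes, editome_genotypes)
  if (length(unknown))
    .input_error("unknown control genotype(s): %s", paste(unknown, collapse = ", "))
  genos <- unique(estimates$genotype)
  key <- .site_key(estimates$chrom, estimates$pos, estimates$strand)
  n_geno <- tapply(estimates$genotype, key, function(g) length(unique(g)))
  depth_ok <- tapply(estimates$passes_depth, key, all)
  is_ctrl <- estimates$genotype %in% control_genotypes
  rate_ok <- tapply(!is.na(estimates$rate) &
                      estimates$rate >= config$min_rate | !is_ctrl, key, all)
  keep <- names(which(n_geno == length(genos) & depth_ok & rate_ok))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
    strand = vapply(parts, `[[`, character(1), 3L),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-proportion z statistic for differential editing
#'
#' For each site present in both estimate sets, computes the pooled
#' two-proportion z statistic: with phat = (e_a + e_b) / (n_a + n_b),
#' z = (r_a - r_b) / sqrt(phat (1 - phat) (1/n_a + 1/n_b)). z is defined as 0
#' when phat is 0 or 1 (no evidence either way), and a site with zero depth
#' on either side yields no call (NA). A call is significant when |z| reaches
#' \code{z_threshold} and both genotypes pass the depth filter.
#'
#' This statistic is a defined, documented stand-in for the "z factor" of
#' Dirichlet-model-based editing callers; numerical agreement with those
#' tools is not claimed.
#'
#' @param est_a,est_b Estimate data.frames from \code{\link{pooled_rates}},
#'   each for a single genotype.
#' @param config An \code{\link{analysis_config}}.
#' @return data.frame: chrom, pos, strand, genotype_a, genotype_b, rate_a,
#'   rate_b, z, significant.
#' @export
differential_z <- function(est_a, est_b, config = analysis_config()) {
  m <- merge(est_a, est_b, by = c("chrom", "pos", "strand"),
             suffixes = c("_a", "_b"))
  e_a <- m$pooled_edited_a; n_a <- m$pooled_total_a
  e_b <- m$pooled_edited_b; n_b <- m$pooled_total_b
  ok <- n_a > 0L & n_b > 0L
  phat <- ifelse(ok, (e_a + e_b) / (n_a + n_b), NA_real_)
  se <- sqrt(phat * (1 - phat) * (1 / n_a + 1 / n_b))
  z <- ifelse(!ok, NA_real_,
              ifelse(phat <= 0 | phat >= 1, 0,
                     (m$rate_a - m$rate_b) / se))
  significant <- ifelse(!ok, NA,
                        abs(z) >= config$z_threshold &
                          m$passes_depth_a & m$passes_depth_b)
  out <- data.frame(
    chrom = m$chrom, pos = m$pos, strand = m$strand,
    genotype_a = m$genotype_a, genotype_b = m$genotype_b,
    rate_a = m$rate_a, rate_b = m$rate_b, z = z,
    significant = significant, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
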