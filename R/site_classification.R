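# ADAR specificity classification of considered sites, hyperediting region
# detection, and conserved-site / location summaries.

#' Classify ADAR specificity from per-genotype editing rates
#'
#' The control level is the unweighted mean of the WT and double-het pooled
#' rates; relative rates are the ADAR1-dead (rel_a1) and ADAR2-null (rel_a2)
#' rates over that control. With lost threshold L (default 0.10) and inhibits
#' threshold H (default 1.50):
#' \itemize{
#'   \item \code{SHARED}: both relative rates strictly inside (L, H);
#'   \item \code{ADAR1_SPECIFIC}: rel_a1 < L and rel_a2 in [L, H];
#'   \item \code{ADAR1_SPECIFIC_ADAR2_INHIBITS}: rel_a1 < L and rel_a2 > H;
#'   \item \code{ADAR2_SPECIFIC} / \code{ADAR2_SPECIFIC_ADAR1_INHIBITS}:
#'     the mirror images;
#'   \item \code{NEITHER_RETAINED}: both relative rates < L;
#'   \item \code{UNCLASSIFIED}: anything else (e.g. exactly one relative rate
#'     > H with the other retained, a relative rate exactly equal to L, or a
#'     non-positive control rate).
#' }
#' Boundary cases are deterministic: a relative rate exactly at L is neither
#' "lost" (< L) nor inside the open SHARED interval.
#'
#' @param rate_wt,rate_dhet,rate_a1,rate_a2 Numeric vectors of pooled editing
#'   rates for WT, double-het, ADAR1-dead, and ADAR2-null genotypes.
#' @param config An \code{\link{analysis_config}}.
#' @return data.frame: control_rate, rel_a1, rel_a2, label, reason (NA label
#'   with reason \code{"missing_estimate"} when an input rate is NA).
#' @export
classify_specificity <- function(rate_wt, rate_dhet, rate_a1, rate_a2,
                                 config = analysis_config()) {
  n <- length(rate_wt)
  stopifnot(length(rate_dhet) == n, length(rate_a1) == n, length(rate_a2) == n)
  L <- config$lost_fraction
  H <- config$inhibits_fraction
  control <- (rate_wt + rate_dhet) / 2
  rel_a1 <- ifelse(control > 0, rate_a1 / control, NA_real_)
  rel_a2 <- ifelse(control > 0, rate_a2 / control, NA_real_)
  label <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  missing <- is.na(rate_wt) | is.na(rate_dhet) | is.na(rate_a1) | is.na(rate_a2)
  zero_ctrl <- !missing & control <= 0
  label[zero_ctrl] <- "UNCLASSIFIED"
  reason[zero_ctrl] <- "zero_control"
  reason[missing] <- "missing_estimate"
  idx <- which(!missing & !zero_ctrl)
  r1 <- rel_a1[idx]; r2 <- rel_a2[idx]
  lab <- rep("UNCLASSIFIED", length(idx))
  lab[r1 < L & r2 < L] <- "NEITHER_RETAINED"
  lab[r1 < L & r2 >= L & r2 <= H] <- "ADAR1_SPECIFIC"
  lab[r1 < L & r2 > H] <- "ADAR1_SPECIFIC_ADAR2_INHIBITS"
  lab[r2 < L & r1 >= L & r1 <= H] <- "ADAR2_SPECIFIC"
  lab[r2 < L & r1 > H] <- "ADAR2_SPECIFIC_ADAR1_INHIBITS"
  lab[r1 > L & r1 < H & r2 > L & r2 < H] <- "SHARED"
  label[idx] <- lab
  data.frame(control_rate = control, rel_a1 = rel_a1, rel_a2 = rel_a2,
             label = label, reason = reason, stringsAsFactors = FALSE)
}

# wide per-genotype rate/depth columns for the given site keys
.rates_wide <- function(estimates, site_keys) {
  out <- site_keys[, c("chrom", "pos", "strand")]
  for (g in intersect(editome_genotypes, unique(estimates$genotype))) {
    sub <- estimates[estimates$genotype == g,
                     c("chrom", "pos", "strand", "rate", "pooled_total")]
    names(sub)[4:5] <- paste0(c("rate_", "depth_"), g)
    out <- merge(out, sub, by = c("chrom", "pos", "strand"), all.x = TRUE)
  }
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a set of sites from a pooled-rate estimate table
#'
#' Convenience wrapper around \code{\link{classify_specificity}}: reshapes the
#' estimate table to one row per site and attaches the class label.
#'
#' @param estimates Estimate data.frame from \code{\link{pooled_rates}}
#'   containing the four classification genotypes.
#' @param site_keys data.frame of site keys (chrom, pos, strand), e.g. from
#'   \code{\link{considered_sites}}.
#' @param config An \code{\link{analysis_config}}.
#' @return data.frame: chrom, pos, strand, per-genotype rates, control_rate,
#'   rel_a1, rel_a2, label, reason.
#' @export
classify_sites <- function(estimates, site_keys, config = analysis_config()) {
  w <- .rates_wide(estimates, site_keys)
  need <- paste0("rate_", c("WT", "DHET", "ADAR1_E861A", "ADAR2_KO"))
  miss <- setdiff(need, names(w))
  if (length(miss))
    .input_error("estimates lack genotype(s): %s",
                 paste(sub("rate_", "", miss), collapse = ", "))
  cl <- classify_specificity(w$rate_WT, w$rate_DHET,
                             w$rate_ADAR1_E861A, w$rate_ADAR2_KO, config)
  cbind(w, cl)
}

# core two-pointer sweep over sorted positions on one chromosome; returns
# per-site hyperedited flags and the qualifying windows as index pairs
.hyper_sweep <- function(pos, window, min_sites) {
  n <- length(pos)
  flags <- logical(n)
  wins <- list()
  if (n >= min_sites) {
    k <- 1L
    for (i in seq_len(n)) {
      if (k < i) k <- i
      while (k < n && pos[k + 1L] - pos[i] <= window - 1L) k <- k + 1L
      if (k - i + 1L >= min_sites) {
        flags[i:k] <- TRUE
        wins[[length(wins) + 1L]] <- c(i, k)
      }
    }
  }
  list(flags = flags, windows = wins)
}

#' Flag hyperedited sites
#'
#' A site is hyperedited when some window of \code{hyper_window} bp
#' (inclusive span: last position minus first position at most
#' \code{hyper_window} - 1) containing it holds at least
#' \code{hyper_min_sites} sites. Implemented as an O(n) two-pointer sweep per
#' chromosome. Input positions must be sorted ascending within chromosome.
#'
#' @param sites Site data.frame (chrom, pos), sorted by position within each
#'   chromosome.
#' @param config An \code{\link{analysis_config}}.
#' @return Logical vector aligned with the rows of \code{sites}.
#' @export
flag_hyperedited <- function(sites, config = analysis_config()) {
  flags <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    if (is.unsorted(pos))
      .input_error("site positions on %s are not sorted ascending", ch)
    flags[idx] <- .hyper_sweep(pos, config$hyper_window,
                               config$hyper_min_sites)$flags
  }
  flags
}

#' Detect hyperediting regions
#'
#' Qualifying windows (see \code{\link{flag_hyperedited}}) whose member-site
#' index ranges overlap are chained into maximal regions spanning their member
#' sites. Region coordinates are 1-based inclusive from first to last member
#' site.
#'
#' @param sites Site data.frame (chrom, pos), sorted by position within each
#'   chromosome.
#' @param config An \code{\link{analysis_config}}.
#' @return data.frame: chrom, start, end, n_sites, one row per region, sorted.
#' @export
detect_hyperediting_regions <- function(sites, config = analysis_config()) {
  regions <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    if (is.unsorted(pos))
      .input_error("site positions on %s are not sorted ascending", ch)
    wins <- .hyper_sweep(pos, config$hyper_window, config$hyper_min_sites)$windows
    if (!length(wins)) next
    # chain windows whose site-index ranges overlap
    cur <- wins[[1L]]
    for (w in wins[-1L]) {
      if (w[1L] <= cur[2L]) {
        cur[2L] <- max(cur[2L], w[2L])
      } else {
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = ch, start = pos[cur[1L]], end = pos[cur[2L]],
                     n_sites = cur[2L] - cur[1L] + 1L, stringsAsFactors = FALSE)
        cur <- w
      }
    }
    regions[[length(regions) + 1L]] <-
      data.frame(chrom = ch, start = pos[cur[1L]], end = pos[cur[2L]],
                 n_sites = cur[2L] - cur[1L] + 1L, stringsAsFactors = FALSE)
  }
  if (!length(regions))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, regions)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-genotype editing summary for conserved sites
#'
#' One row per conserved site with the pooled rate of every genotype, the
#' control level, relative rates, and the specificity class. Sites lacking
#' coverage for some genotype are flagged (\code{no_coverage}), not dropped.
#'
#' @param estimates Estimate data.frame from \code{\link{pooled_rates}}.
#' @param sites Site data.frame carrying a logical \code{conserved} column.
#' @param config An \code{\link{analysis_config}}.
#' @return data.frame with per-genotype rate columns, classification columns,
#'   and \code{no_coverage}.
#' @export
conserved_site_summary <- function(estimates, sites,
                                   config = analysis_config()) {
  cons <- sites[isTRUE_vec(sites$conserved), c("chrom", "pos", "strand"),
                drop = FALSE]
  if (!nrow(cons)) {
    out <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  w <- .rates_wide(estimates, cons)
  cl <- classify_specificity(w$rate_WT, w$rate_DHET,
                             w$rate_ADAR1_E861A, w$rate_ADAR2_KO, config)
  out <- cbind(w, cl)
  depth_cols <- grep("^depth_", names(out), value = TRUE)
  rate_cols <- grep("^rate_", names(out), value = TRUE)
  out$no_coverage <- apply(out[, rate_cols, drop = FALSE], 1,
                           function(r) any(is.na(r))) |
    apply(out[, depth_cols, drop = FALSE], 1,
          function(d) any(is.na(d) | d == 0))
  out
}

# tolerate NA in logical subsetting
isTRUE_vec <- function(x) !is.na(x) & x

#' Cross-tabulate specificity classes by genomic location
#'
#' Counts sites per gene part and class, with the percentage of
#' ADAR1-specific and ADAR2-specific sites per location in the style of a
#' figure legend bracket (the inhibits variants count toward their enzyme;
#' SHARED and fallback labels are excluded from the percentages). A TOTAL row
#' sums the location rows.
#'
#' @param calls Classification data.frame from \code{\link{classify_sites}}.
#' @param annotations Annotation data.frame from
#'   \code{\link{annotate_gene_part}} (keys chrom, pos, strand plus
#'   \code{part}).
#' @return data.frame: part, n_sites, one count column per class label,
#'   pct_adar1_specific, pct_adar2_specific.
#' @export
class_location_summary <- function(calls, annotations) {
  parts_order <- c("promoter", "3utr", "exon", "intron", "intergenic")
  m <- merge(calls[, c("chrom", "pos", "strand", "label")],
             annotations[, c("chrom", "pos", "strand", "part")],
             by = c("chrom", "pos", "strand"))
  labels <- specificity_classes
  tab <- table(factor(m$part, levels = parts_order),
               factor(m$label, levels = labels))
  counts <- as.data.frame.matrix(tab)
  out <- data.frame(part = rownames(counts), n_sites = rowSums(counts),
                    stringsAsFactors = FALSE)
  names(counts) <- paste0("n_", labels)
  out <- cbind(out, counts)
  a1 <- counts$n_ADAR1_SPECIFIC + counts$n_ADAR1_SPECIFIC_ADAR2_INHIBITS
  a2 <- counts$n_ADAR2_SPECIFIC + counts$n_ADAR2_SPECIFIC_ADAR1_INHIBITS
  out$pct_adar1_specific <- ifelse(out$n_sites > 0, 100 * a1 / out$n_sites, 0)
  out$pct_adar2_specific <- ifelse(out$n_sites > 0, 100 * a2 / out$n_sites, 0)
  total <- out[1, , drop = FALSE]
  total$part <- "TOTAL"
  for (cc in setdiff(names(out), "part")) total[[cc]] <- sum(out[[cc]])
  total$pct_adar1_specific <-
    ifelse(total$n_sites > 0,
           100 * (total$n_ADAR1_SPECIFIC + total$n_ADAR1_SPECIFIC_ADAR2_INHIBITS) /
             total$n_sites, 0)
  total$pct_adar2_specific <-
    ifelse(total$n_sites > 0,
           100 * (total$n_ADAR2_SPECIFIC + total$n_ADAR2_SPECIFIC_ADAR1_INHIBITS) /
             total$n_sites, 0)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}
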