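# Shared fixtures and independent oracles for the test suite.

# one pileup row on the forward strand
pileup_row <- function(chrom = "chr1", pos = 100L, sample_id = "WT_R1",
                       genotype = "WT", replicate = 1L,
                       A = 0L, C = 0L, G = 0L, T = 0L) {
  data.frame(chrom = chrom, pos = pos, sample_id = sample_id,
             genotype = genotype, replicate = replicate,
             count_A = A, count_C = C, count_G = G, count_T = T,
             stringsAsFactors = FALSE)
}

site_row <- function(chrom = "chr1", pos = 100L, strand = "+",
                     sources = "test", conserved = FALSE) {
  data.frame(chrom = chrom, pos = pos, strand = strand, sources = sources,
             conserved = conserved, stringsAsFactors = FALSE)
}

# pileups for one site across all genotypes/replicates from per-replicate
# (edited, total) pairs given as a list genotype -> matrix [rep x 2]
site_pileups <- function(counts, chrom = "chr1", pos = 100L, strand = "+") {
  rows <- list()
  for (g in names(counts)) {
    m <- counts[[g]]
    for (r in seq_len(nrow(m))) {
      ed <- m[r, 1]; ref <- m[r, 2] - m[r, 1]
      rows[[length(rows) + 1L]] <- if (strand == "+") {
        pileup_row(chrom, pos, paste0(g, "_R", r), g, r, A = ref, G = ed)
      } else {
        pileup_row(chrom, pos, paste0(g, "_R", r), g, r, T = ref, C = ed)
      }
    }
  }
  do.call(rbind, rows)
}

# independent brute-force oracle: a site is hyperedited iff it lies in some
# window [pos_i, pos_j] with pos_j - pos_i <= window - 1 holding >= min_sites
brute_force_hyper <- function(pos, window, min_sites) {
  n <- length(pos)
  flags <- logical(n)
  for (i in seq_len(n)) for (j in i:n) {
    if (pos[j] - pos[i] <= window - 1 && j - i + 1 >= min_sites)
      flags[i:j] <- TRUE
  }
  flags
}

# independent recomputation of the pooled two-proportion z statistic
brute_force_z <- function(e_a, n_a, e_b, n_b) {
  phat <- (e_a + e_b) / (n_a + n_b)
  if (phat <= 0 || phat >= 1) return(0)
  (e_a / n_a - e_b / n_b) / sqrt(phat * (1 - phat) * (1 / n_a + 1 / n_b))
}

# brute-force interval annotation: best label by precedence rank then width
brute_force_annotate <- function(sites, intervals, rank) {
  vapply(seq_len(nrow(sites)), function(i) {
    hit <- which(intervals$chrom == sites$chrom[i] &
                   intervals$start < sites$pos[i] &
                   intervals$end >= sites$pos[i])
    if (!length(hit)) return(NA_integer_)
    width <- intervals$end[hit] - intervals$start[hit]
    hit[order(rank[hit], width, hit)][1]
  }, integer(1))
}
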