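# Gene-part and repeat-family annotation of sites, and nucleotide
# sequence-context matrices around edited adenosines.

.gene_parts_order <- c("promoter", "3utr", "exon", "intron")

# best overlap per site under a precedence ranking; ties broken by smallest
# interval, then by interval order in the table (deterministic)
.best_overlap <- function(sites, intervals, rank) {
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  s <- .intervals_to_granges(intervals)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  if (!length(hits)) return(rep(NA_integer_, nrow(sites)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  width <- intervals$end[sh] - intervals$start[sh]
  ord <- order(qh, rank[sh], width, sh)
  first <- ord[!duplicated(qh[ord])]
  out <- rep(NA_integer_, nrow(sites))
  out[qh[first]] <- sh[first]
  out
}

#' Annotate sites with a gene part
#'
#' Each site receives exactly one part; overlaps are resolved by the fixed
#' precedence promoter > 3'UTR > exon > intron, ties within a level by the
#' smallest interval. Sites overlapping nothing are intergenic. Promoter
#' intervals are expected precomputed as TSS-flanking intervals (by default
#' 1,000 bp upstream through 200 bp downstream of the TSS; see
#' \code{\link{promoter_intervals}}).
#'
#' @param sites Site data.frame (chrom, pos, strand).
#' @param gene_parts Interval data.frame (chrom, start, end 0-based half-open,
#'   label one of promoter/3utr/exon/intron, optional \code{gene}).
#' @param precedence Character vector giving the part precedence order.
#' @return data.frame: chrom, pos, strand, gene_label, part.
#' @export
annotate_gene_part <- function(sites, gene_parts,
                               precedence = .gene_parts_order) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    strand = sites$strand, gene_label = NA_character_,
                    part = "intergenic", stringsAsFactors = FALSE)
  if (is.null(gene_parts) || !nrow(gene_parts)) return(out)
  bad <- setdiff(unique(gene_parts$label), precedence)
  if (length(bad))
    .input_error("unknown gene part label(s): %s", paste(bad, collapse = ", "))
  rank <- match(gene_parts$label, precedence)
  best <- .best_overlap(sites, gene_parts, rank)
  hit <- !is.na(best)
  out$part[hit] <- gene_parts$label[best[hit]]
  if (!is.null(gene_parts$gene))
    out$gene_label[hit] <- gene_parts$gene[best[hit]]
  out
}

#' TSS-flanking promoter intervals
#'
#' Builds promoter intervals from gene intervals: \code{upstream} bp before
#' through \code{downstream} bp after the transcription start site (the
#' strand-appropriate end of the gene interval), clipped at zero.
#'
#' @param genes Interval data.frame (chrom, start, end, strand, optional
#'   gene/label).
#' @param upstream,downstream Flank sizes in bp (defaults 1000 and 200).
#' @return Interval data.frame labeled \code{"promoter"}.
#' @export
promoter_intervals <- function(genes, upstream = 1000L, downstream = 200L) {
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  start <- ifelse(genes$strand == "-", tss - downstream + 1L, tss - upstream)
  end <- ifelse(genes$strand == "-", tss + upstream + 1L, tss + downstream)
  out <- data.frame(chrom = genes$chrom, start = pmax(0L, as.integer(start)),
                    end = as.integer(end), strand = genes$strand,
                    label = "promoter", stringsAsFactors = FALSE)
  if (!is.null(genes$gene)) out$gene <- genes$gene
  out
}

#' Annotate sites with a repeat family
#'
#' Repeat intervals carry family labels; labels beginning with "B1" or "B2"
#' are collapsed to those SINE families. Overlaps are resolved by the
#' precedence B1 > B2 > other (then alphabetically, then smallest interval).
#' Sites overlapping no repeat get \code{NA}.
#'
#' @param sites Site data.frame (chrom, pos, strand).
#' @param repeats Interval data.frame (chrom, start, end, label).
#' @return data.frame: chrom, pos, strand, repeat_family.
#' @export
annotate_repeat <- function(sites, repeats) {
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    strand = sites$strand, repeat_family = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.null(repeats) || !nrow(repeats)) return(out)
  family <- ifelse(startsWith(repeats$label, "B1"), "B1",
                   ifelse(startsWith(repeats$label, "B2"), "B2",
                          repeats$label))
  fam_rank <- match(family, c("B1", "B2"))
  other <- is.na(fam_rank)
  # others rank after B1/B2, ordered alphabetically among themselves
  fam_rank[other] <- 2L + as.integer(factor(family[other],
                                            levels = sort(unique(family[other]))))
  best <- .best_overlap(sites, repeats, fam_rank)
  hit <- !is.na(best)
  out$repeat_family[hit] <- family[best[hit]]
  out
}

#' Nucleotide sequence-context matrix around edited adenosines
#'
#' Extracts the reference window of \code{flank} nt either side of each site;
#' minus-strand windows are reverse-complemented so the edited base reads A
#' at position 0. Sites within \code{flank} of a contig edge are skipped and
#' counted; sites whose strand-adjusted center is not A are excluded with a
#' warning and counted. Frequencies are over the included sites.
#'
#' @param sites Site data.frame (chrom, pos, strand).
#' @param genome Named character vector of reference sequences (see
#'   \code{\link{read_fasta}}).
#' @param flank Flank width in nt (default 5).
#' @return List: \code{matrix} ((2 flank + 1) x 4 frequency matrix, rows
#'   named by offset -flank..flank, columns A/C/G/T), \code{n_sites} included,
#'   \code{n_skipped_edge}, \code{n_skipped_not_a}.
#' @export
sequence_context_matrix <- function(sites, genome, flank = 5L) {
  flank <- as.integer(flank)
  stopifnot(flank >= 1L)
  offsets <- seq(-flank, flank)
  empty <- matrix(0, nrow = length(offsets), ncol = 4,
                  dimnames = list(offsets, c("A", "C", "G", "T")))
  if (!nrow(sites))
    return(list(matrix = empty, n_sites = 0L, n_skipped_edge = 0L,
                n_skipped_not_a = 0L))
  miss <- setdiff(unique(sites$chrom), names(genome))
  if (length(miss))
    .input_error("genome lacks sequence(s): %s", paste(miss, collapse = ", "))
  len <- nchar(genome)[sites$chrom]
  ok_edge <- sites$pos - flank >= 1L & sites$pos + flank <= len
  n_edge <- sum(!ok_edge)
  sub <- sites[ok_edge, , drop = FALSE]
  if (!nrow(sub))
    return(list(matrix = empty, n_sites = 0L, n_skipped_edge = n_edge,
                n_skipped_not_a = 0L))
  win <- substring(genome[sub$chrom], sub$pos - flank, sub$pos + flank)
  minus <- sub$strand == "-"
  if (any(minus))
    win[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(win[minus])))
  center <- substr(win, flank + 1L, flank + 1L)
  bad <- center != "A"
  n_bad <- sum(bad)
  if (n_bad > 0L)
    warning(sprintf("%d site(s) excluded: strand-adjusted center base is not A",
                    n_bad))
  win <- win[!bad]
  if (!length(win))
    return(list(matrix = empty, n_sites = 0L, n_skipped_edge = n_edge,
                n_skipped_not_a = n_bad))
  chars <- do.call(rbind, strsplit(win, "", fixed = TRUE))
  freq <- t(apply(chars, 2, function(col)
    table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)))
  dimnames(freq) <- dimnames(empty)
  list(matrix = freq, n_sites = length(win), n_skipped_edge = n_edge,
       n_skipped_not_a = n_bad)
}

#' Write a sequence-context matrix as TSV
#'
#' Rows are positions relative to the edited adenosine, columns are base
#' frequencies; consumable by any logo plotter.
#'
#' @param cm Result of \code{\link{sequence_context_matrix}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_context_matrix <- function(cm, path) {
  df <- data.frame(position = as.integer(rownames(cm$matrix)), cm$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
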