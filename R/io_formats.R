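# Readers/writers for every on-disk artifact the pipeline touches.
#
# Conventions: site coordinates are 1-based internally (pileup convention);
# BED I/O converts to/from 0-based half-open at the boundary. Pileup counts
# are always stored on the forward reference strand; strand logic lives in
# the quantification layer, not here. All readers reject malformed rows with
# an error naming the offending row/line.

.IUPAC <- "ACGTURYSWKMBDHVN"

#' Read a FASTA file into a named character vector
#'
#' Sequence names are taken from the header line up to the first whitespace;
#' sequences are upper-cased. Lines are validated before parsing so that
#' malformed headers or non-IUPAC characters are reported with their line
#' number.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping sequence name to sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .input_error("FASTA file not found: %s", path)
  lines <- readLines(path)
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      nm <- strsplit(trimws(sub("^>", "", ln)), "\\s+")[[1]][1]
      if (is.na(nm) || !nzchar(nm))
        .input_error("%s: malformed FASTA header at line %d", path, i)
      seen_header <- TRUE
    } else {
      if (!seen_header)
        .input_error("%s: sequence data before any FASTA header at line %d", path, i)
      if (grepl(sprintf("[^%s]", .IUPAC), toupper(ln)))
        .input_error("%s: non-IUPAC character at line %d", path, i)
    }
  }
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(names(out)))
    .input_error("%s: duplicated sequence name '%s'", path,
                 names(out)[duplicated(names(out))][1])
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector (names become headers).
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

.empty_sites <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             sources = character(), conserved = logical(),
             stringsAsFactors = FALSE)
}

# union rows sharing (chrom,pos,strand): sources set-union, conserved OR
.merge_sites <- function(df) {
  if (!nrow(df)) return(.empty_sites())
  key <- .site_key(df$chrom, df$pos, df$strand)
  idx <- split(seq_len(nrow(df)), key)
  rows <- lapply(idx, function(i) {
    src <- unlist(strsplit(df$sources[i], ",", fixed = TRUE))
    src <- sort(unique(src[nzchar(src)]))
    data.frame(chrom = df$chrom[i[1]], pos = df$pos[i[1]], strand = df$strand[i[1]],
               sources = paste(src, collapse = ","),
               conserved = any(df$conserved[i]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a table of editing sites
#'
#' Expects a TSV with columns \code{chrom}, \code{pos} (1-based), \code{strand}
#' and optional \code{sources} (comma-separated provenance tags) and
#' \code{conserved} (logical). Duplicate (chrom, pos, strand) rows are merged:
#' sources are unioned and the conserved flag is OR-ed, mirroring how an
#' editing-site compendium is assembled from overlapping databases.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns chrom, pos, strand, sources, conserved;
#'   unique on (chrom, pos, strand), sorted.
#' @export
read_sites_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  required <- c("chrom", "pos", "strand")
  miss <- setdiff(required, names(df))
  if (length(miss))
    .input_error("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  if (!nrow(df)) return(.empty_sites())
  if (is.null(df$sources)) df$sources <- ""
  df$sources[is.na(df$sources)] <- ""
  if (is.null(df$conserved)) df$conserved <- FALSE
  df$conserved <- as.logical(df$conserved)
  df$conserved[is.na(df$conserved)] <- FALSE
  df$pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad))
    .input_error("%s: invalid pos (must be integer >= 1) at row %d", path, bad[1])
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad))
    .input_error("%s: invalid strand '%s' at row %d (must be + or -)",
                 path, df$strand[bad[1]], bad[1])
  .merge_sites(df[, c("chrom", "pos", "strand", "sources", "conserved")])
}

#' Write a sites table as TSV
#'
#' @param sites data.frame as returned by \code{\link{read_sites_table}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sites_table <- function(sites, path) {
  utils::write.table(sites[, c("chrom", "pos", "strand", "sources", "conserved")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge several editing-site tables into one compendium
#'
#' Union keyed on (chrom, pos, strand); provenance sources are unioned and the
#' conserved flag is OR-ed across inputs. Output is sorted by (chrom, pos,
#' strand). Merging is idempotent.
#'
#' @param tables List of site data.frames (each valid per
#'   \code{\link{read_sites_table}}).
#' @return A single merged site data.frame.
#' @export
merge_site_databases <- function(tables) {
  stopifnot(is.list(tables))
  if (!length(tables)) return(.empty_sites())
  tables <- lapply(tables, function(df) {
    if (is.null(df$sources)) df$sources <- ""
    if (is.null(df$conserved)) df$conserved <- FALSE
    df[, c("chrom", "pos", "strand", "sources", "conserved")]
  })
  .merge_sites(do.call(rbind, tables))
}

.pileup_cols <- c("chrom", "pos", "sample_id", "genotype", "replicate",
                  "count_A", "count_C", "count_G", "count_T")

#' Read a pileup table
#'
#' One row per (site x sample): forward-strand base counts \code{count_A},
#' \code{count_C}, \code{count_G}, \code{count_T} at a 1-based position, with
#' sample metadata (\code{sample_id}, \code{genotype}, \code{replicate}).
#'
#' @param path Path to the TSV.
#' @return data.frame with the pileup columns, ordered by (chrom, pos,
#'   sample_id).
#' @export
read_pileup_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(.pileup_cols, names(df))
  if (length(miss))
    .input_error("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  df <- df[, .pileup_cols]
  for (cc in c("pos", "replicate", "count_A", "count_C", "count_G", "count_T"))
    df[[cc]] <- suppressWarnings(as.integer(df[[cc]]))
  counts <- as.matrix(df[, c("count_A", "count_C", "count_G", "count_T")])
  bad <- which(is.na(counts) | counts < 0L, arr.ind = TRUE)
  if (nrow(bad))
    .input_error("%s: negative or non-integer count at row %d", path, bad[1, 1])
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad)) .input_error("%s: invalid pos at row %d", path, bad[1])
  bad <- which(!(df$genotype %in% editome_genotypes))
  if (length(bad))
    .input_error("%s: unknown genotype '%s' at row %d", path, df$genotype[bad[1]], bad[1])
  df <- df[order(df$chrom, df$pos, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a pileup table as TSV
#'
#' Rows are written in the deterministic order (chrom, pos, sample_id) so that
#' repeated writes of the same records are byte-identical.
#'
#' @param records Pileup data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pileup_table <- function(records, path) {
  miss <- setdiff(.pileup_cols, names(records))
  if (length(miss))
    .input_error("pileup records: missing column(s): %s", paste(miss, collapse = ", "))
  records <- records[order(records$chrom, records$pos, records$sample_id),
                     .pileup_cols, drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3 or BED6 file of genomic intervals
#'
#' Coordinates are kept 0-based half-open exactly as in the file. The two
#' dialects must not be mixed within one file. For BED6 the name column is
#' exposed as \code{label} and the strand column is honored; BED3 rows get
#' strand \code{"."} and label \code{NA}.
#'
#' @param path Path to the BED file.
#' @return data.frame with columns chrom, start, end, strand, label.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(fields))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), label = character(),
                      stringsAsFactors = FALSE))
  nf <- unique(lengths(fields))
  if (length(nf) > 1L)
    .input_error("%s: mixed BED dialects (rows with %s fields)", path,
                 paste(sort(nf), collapse = " and "))
  if (!nf %in% c(3L, 6L))
    .input_error("%s: expected BED3 or BED6, found %d fields", path, nf)
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    .input_error("%s: invalid interval (need 0 <= start < end) at line %d",
                 path, lineno[bad[1]])
  if (nf == 6L) {
    strand <- m[, 6]
    bad <- which(!(strand %in% c("+", "-", ".")))
    if (length(bad))
      .input_error("%s: invalid strand '%s' at line %d", path,
                   strand[bad[1]], lineno[bad[1]])
    label <- m[, 4]
  } else {
    strand <- rep(".", nrow(m))
    label <- rep(NA_character_, nrow(m))
  }
  data.frame(chrom = m[, 1], start = start, end = end, strand = strand,
             label = label, stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED
#'
#' Intervals carrying any strand or label information are written as BED6
#' (score 0, missing labels as \code{"."}); otherwise BED3.
#'
#' @param intervals data.frame with columns chrom, start, end and optionally
#'   strand, label (0-based half-open coordinates).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start < 0L | intervals$start >= intervals$end))
    .input_error("write_bed: invalid interval (need 0 <= start < end)")
  strand <- if (is.null(intervals$strand)) rep(".", nrow(intervals)) else intervals$strand
  label <- if (is.null(intervals$label)) rep(NA_character_, nrow(intervals)) else intervals$label
  bed6 <- any(strand != ".") || any(!is.na(label))
  if (bed6) {
    out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                      ifelse(is.na(label), ".", label), 0L, strand)
  } else {
    out <- data.frame(intervals$chrom, intervals$start, intervals$end)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges view of a 0-based half-open interval data.frame (1-based internally)
.intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = ifelse(intervals$strand %in% c("+", "-"), intervals$strand, "*")
  )
}
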