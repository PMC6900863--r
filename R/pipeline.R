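# Orchestration: simulate -> quantify -> classify -> annotate -> report,
# with a machine-readable run manifest for reproducibility checks.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full editing-analysis pipeline on simulated data
#'
#' Generates a synthetic editing study, quantifies per-genotype editing rates,
#' applies the coverage/rate filters, computes differential-editing z calls
#' for the requested genotype comparisons, classifies ADAR specificity,
#' detects hyperediting regions, annotates sites with repeat family (and gene
#' part if a gene-part table is given), emits sequence-context matrices, and
#' writes every artifact plus a JSON run manifest with per-file checksums to
#' \code{outdir}. Re-running with the same configuration and seed reproduces
#' byte-identical outputs.
#'
#' @param sim A \code{\link{sim_config}}.
#' @param config An \code{\link{analysis_config}}.
#' @param outdir Output directory (created if needed).
#' @param comparisons List of length-2 character vectors (genotype_a,
#'   genotype_b) for differential calls; defaults to each mutant against its
#'   control.
#' @param gene_parts Optional gene-part interval data.frame (see
#'   \code{\link{annotate_gene_part}}); when absent all sites are intergenic.
#' @return Invisibly, a list with the in-memory tables, the manifest, and
#'   \code{outdir}.
#' @export
run_pipeline <- function(sim, config = analysis_config(), outdir,
                         comparisons = list(c("ADAR1_E861A", "WT"),
                                            c("ADAR2_KO", "DHET"),
                                            c("DKO", "DHET")),
                         gene_parts = NULL) {
  if (!inherits(sim, "sim_config"))
    .config_error("'sim' must be a sim_config object")
  if (!inherits(config, "analysis_config"))
    .config_error("'config' must be an analysis_config object")
  for (cmp in comparisons)
    if (length(cmp) != 2L || !all(cmp %in% editome_genotypes))
      .config_error("comparisons must be pairs of known genotype labels")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()

  message(sprintf("[simulate] genome: %d chromosome(s) x %d bp, %d cluster region(s)",
                  sim$n_chromosomes, sim$chrom_length, sim$n_cluster_regions))
  genome <- simulate_genome(sim)
  truth <- simulate_editome_truth(sim, genome)
  pileups <- simulate_pileups(truth, sim)
  sites <- truth_to_sites(truth)
  message(sprintf("[simulate] %d sites (%d in clusters), %d pileup rows",
                  nrow(truth), sum(truth$in_cluster), nrow(pileups)))
  outputs <- c(outputs,
               write_fasta(genome$genome, file.path(outdir, "genome.fa")),
               write_bed(genome$clusters, file.path(outdir, "clusters.bed")),
               write_sites_table(sites, file.path(outdir, "sites.tsv")),
               .write_tsv(truth, file.path(outdir, "truth.tsv")),
               write_pileup_table(pileups, file.path(outdir, "pileups.tsv")))

  estimates <- pooled_rates(pileups, sites, config)
  outputs <- c(outputs, .write_tsv(estimates, file.path(outdir, "estimates.tsv")))
  considered <- considered_sites(estimates, config)
  message(sprintf("[quantify] %d site x genotype estimates; %d of %d sites pass depth >= %d and control rate >= %g",
                  nrow(estimates), nrow(considered), nrow(truth),
                  config$min_depth, config$min_rate))
  outputs <- c(outputs,
               .write_tsv(considered, file.path(outdir, "considered_sites.tsv")))

  calls_diff <- do.call(rbind, lapply(comparisons, function(cmp) {
    differential_z(estimates[estimates$genotype == cmp[1], , drop = FALSE],
                   estimates[estimates$genotype == cmp[2], , drop = FALSE],
                   config)
  }))
  message(sprintf("[differential] %d calls across %d comparison(s), %d significant",
                  nrow(calls_diff), length(comparisons),
                  sum(calls_diff$significant, na.rm = TRUE)))
  outputs <- c(outputs,
               .write_tsv(calls_diff, file.path(outdir, "differential_calls.tsv")))

  calls <- classify_sites(estimates, considered, config)
  message(sprintf("[classify] %d considered sites labeled (%d SHARED)",
                  nrow(calls), sum(calls$label == "SHARED", na.rm = TRUE)))
  outputs <- c(outputs,
               .write_tsv(calls, file.path(outdir, "classifications.tsv")))

  regions <- detect_hyperediting_regions(sites, config)
  hyper <- flag_hyperedited(sites, config)
  message(sprintf("[hyperediting] %d region(s), %d of %d sites hyperedited",
                  nrow(regions), sum(hyper), length(hyper)))
  regions_bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                            end = regions$end, strand = ".",
                            label = sprintf("hyper_%d", seq_len(nrow(regions))),
                            stringsAsFactors = FALSE)
  outputs <- c(outputs,
               write_bed(regions_bed, file.path(outdir, "hyperediting_regions.bed")))

  ann_gene <- annotate_gene_part(sites, gene_parts)
  ann_rep <- annotate_repeat(sites, genome$clusters)
  annotations <- cbind(ann_gene,
                       repeat_family = ann_rep$repeat_family,
                       hyperedited = hyper)
  outputs <- c(outputs,
               .write_tsv(annotations, file.path(outdir, "annotations.tsv")))

  cm <- sequence_context_matrix(sites, genome$genome, config$context_flank)
  outputs <- c(outputs,
               write_context_matrix(cm, file.path(outdir, "context_matrix.tsv")))

  crosstab <- class_location_summary(calls, annotations)
  outputs <- c(outputs, .write_tsv(crosstab, file.path(outdir, "class_location.tsv")))

  cons <- conserved_site_summary(estimates, sites, config)
  outputs <- c(outputs,
               .write_tsv(cons, file.path(outdir, "conserved_summary.tsv")))

  report <- report_summary(outdir)
  outputs <- c(outputs, .write_tsv(report, file.path(outdir, "report.tsv")))

  checksums <- as.list(tools::md5sum(outputs))
  names(checksums) <- basename(outputs)
  manifest <- list(
    tool = "editomekit",
    version = as.character(utils::packageVersion("editomekit")),
    seed = sim$seed,
    sim_config = unclass(sim),
    analysis_config = unclass(config),
    comparisons = lapply(comparisons, as.list),
    outputs = checksums,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message(sprintf("[done] %d output files in %s", length(outputs) + 1L, outdir))
  invisible(list(genome = genome, truth = truth, pileups = pileups,
                 sites = sites, estimates = estimates, considered = considered,
                 differential = calls_diff, calls = calls, regions = regions,
                 annotations = annotations, context = cm, crosstab = crosstab,
                 conserved = cons, report = report, manifest = manifest,
                 outdir = outdir))
}

#' Summarize pipeline outputs by recounting the written files
#'
#' Reads the artifact files in a pipeline output directory and tallies:
#' simulated and considered site counts, significant differential calls per
#' comparison, specificity-class counts, and the hyperedited-site fraction.
#' Because the counts are recomputed from the files, the report doubles as an
#' internal-consistency check.
#'
#' @param outdir A \code{\link{run_pipeline}} output directory.
#' @return data.frame with columns \code{metric} and \code{value}.
#' @export
report_summary <- function(outdir) {
  need <- c("sites.tsv", "considered_sites.tsv", "differential_calls.tsv",
            "classifications.tsv", "annotations.tsv")
  for (f in need)
    if (!file.exists(file.path(outdir, f)))
      .input_error("missing pipeline output: %s", f)
  sites <- utils::read.delim(file.path(outdir, "sites.tsv"))
  considered <- utils::read.delim(file.path(outdir, "considered_sites.tsv"))
  diffs <- utils::read.delim(file.path(outdir, "differential_calls.tsv"))
  calls <- utils::read.delim(file.path(outdir, "classifications.tsv"))
  ann <- utils::read.delim(file.path(outdir, "annotations.tsv"))
  rows <- list(
    c("n_sites", nrow(sites)),
    c("n_considered", nrow(considered)))
  if (nrow(diffs)) {
    for (cmp in unique(paste(diffs$genotype_a, diffs$genotype_b, sep = "_vs_"))) {
      sub <- diffs[paste(diffs$genotype_a, diffs$genotype_b, sep = "_vs_") == cmp, ]
      rows[[length(rows) + 1L]] <-
        c(paste0("n_significant_", cmp), sum(sub$significant %in% TRUE))
    }
  }
  for (lab in specificity_classes)
    rows[[length(rows) + 1L]] <-
      c(paste0("n_class_", lab), sum(calls$label %in% lab))
  rows[[length(rows) + 1L]] <-
    c("frac_hyperedited", if (nrow(ann)) mean(ann$hyperedited %in% TRUE) else 0)
  for (lab in setdiff(specificity_classes, "UNCLASSIFIED")) {
    sub <- calls[calls$label %in% lab & !is.na(calls$control_rate), ]
    rows[[length(rows) + 1L]] <-
      c(paste0("mean_control_rate_", lab),
        if (nrow(sub)) mean(sub$control_rate) else NA_real_)
  }
  data.frame(metric = vapply(rows, `[[`, character(1), 1L),
             value = as.numeric(vapply(rows, `[[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}
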