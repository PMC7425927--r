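# End-to-end pipeline: cleaning -> collapse -> signature selection ->
# assignment -> per-amplicon alignment and calling -> VCF/report.

#' Pipeline configuration
#'
#' Aggregates every tunable constant of the pipeline with its canonical
#' default: collapse threshold `phi = 1` (keep every distinct sequence),
#' automatic band half-width (`|m - n| + 1`), the 90% reference-fraction
#' rule, `k_max = 2`, index search mismatch budget 3.
#'
#' @param phi Minimum collapsed-sequence occurrence count.
#' @param epsilon Fixed band half-width, or `NULL` for the automatic rule.
#' @param snp_ref_fraction Reference-fraction threshold for SNP calls.
#' @param k_max Alignment acceptance cutoff on the k-statistic.
#' @param min_depth Minimum supporting depth for a call.
#' @param index_max_mismatch Mismatch budget for index trimming.
#' @param read_cap Platform read length (drives R1 truncation).
#' @param rescue Enable alignment-based rescue of unassigned sequences.
#' @param seed Seed recorded with the run (the calling stage itself is
#'   deterministic; the seed matters for simulation wrappers).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phi = 1L, epsilon = NULL,
                            snp_ref_fraction = 0.90, k_max = 2L,
                            min_depth = 10L, index_max_mismatch = 3L,
                            read_cap = 150L, rescue = FALSE, seed = 1L) {
  stopifnot(phi >= 1L, index_max_mismatch >= 0L)
  structure(list(phi = as.integer(phi), epsilon = epsilon,
                 snp_ref_fraction = snp_ref_fraction,
                 k_max = as.integer(k_max),
                 min_depth = as.integer(min_depth),
                 index_max_mismatch = as.integer(index_max_mismatch),
                 read_cap = as.integer(read_cap),
                 rescue = isTRUE(rescue), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_thresholds <- function(config) {
  calling_thresholds(snp_ref_fraction = config$snp_ref_fraction,
                     k_max = config$k_max, min_depth = config$min_depth,
                     epsilon = config$epsilon, read_cap = config$read_cap)
}

#' Run the full calling pipeline on in-memory read pairs
#'
#' Stages: public-sequence cleaning, index trimming, duplicate collapse at
#' `phi`, discriminating-position selection, signature assignment, then
#' per-amplicon banded alignment, pileup and SNP/indel calling.
#' Index trimming requires a panel-wide shared index (a single-sample
#' library): signatures are read from the start of the trimmed R2, so a
#' per-amplicon index could not be removed before the amplicon is known.
#' R1 truncation for targets shorter than the read cap is applied per
#' amplicon at the alignment stage, after assignment.
#'
#' @param pairs Read-pair tibble.
#' @param panel An `amplicon_panel`.
#' @param config A [pipeline_config()].
#' @return An `amplicall_result`: list with `variants` (variant tibble),
#'   `report` (stage counters, one row), `assignment` (collapsed table
#'   with amplicon labels), `pileups` (named list of pileup tibbles),
#'   `catalog`, `panel`, `config`.
#' @export
call_pipeline <- function(pairs, panel, config = pipeline_config()) {
  stopifnot(inherits(panel, "amplicon_panel"))
  idx <- unique(panel$index)
  if (length(idx) != 1L) {
    stop("call_pipeline requires a panel-wide shared index sequence",
         call. = FALSE)
  }
  cleaned <- clean_public(pairs, public_seq(panel))
  pub_report <- cleaning_report(cleaned)
  cleaned <- clean_index(cleaned, idx, target_len = NULL,
                         max_mismatch = config$index_max_mismatch,
                         read_cap = config$read_cap)
  idx_report <- cleaning_report(cleaned)
  collapsed <- collapse_pairs(cleaned, phi = config$phi)
  catalog <- select_positions(panel)
  assignment <- assign_reads(collapsed, catalog, rescue = config$rescue,
                             rescue_k_max = config$k_max)
  thresholds <- config_thresholds(config)
  variants <- variant_tibble()
  pileups <- list()
  aligned_freq <- stats::setNames(integer(nrow(panel)), panel$amplicon_id)
  for (a in seq_len(nrow(panel))) {
    id <- panel$amplicon_id[a]
    assigned <- assignment[!is.na(assignment$amplicon_id) &
                             assignment$amplicon_id == id, , drop = FALSE]
    if (nrow(assigned) == 0L) {
      pileups[[id]] <- pileup_amplicon(assigned, panel[a, ], thresholds,
                                       alignments = align_assigned(
                                         assigned, panel[a, ], thresholds))
      next
    }
    calls <- call_variants(assigned, panel[a, ], thresholds)
    pileups[[id]] <- attr(calls, "pileup")
    attr(calls, "pileup") <- NULL
    variants <- dplyr::bind_rows(variants, calls)
    aligned_freq[id] <- sum(assigned$frequency)
  }
  report <- dplyr::bind_cols(
    pub_report, idx_report,
    tibble::tibble(
      collapsed_sequences = nrow(collapsed),
      assigned_sequences = sum(!is.na(assignment$amplicon_id)),
      unassigned_sequences = sum(is.na(assignment$amplicon_id)),
      assigned_pairs = sum(assignment$frequency[
        !is.na(assignment$amplicon_id)]),
      n_snps = sum(variants$kind == "SNP"),
      n_indels = sum(variants$kind != "SNP")
    )
  )
  structure(list(variants = variants, report = report,
                 assignment = assignment, pileups = pileups,
                 catalog = catalog, panel = panel, config = config),
            class = "amplicall_result")
}

#' @export
print.amplicall_result <- function(x, ...) {
  cat("<amplicall_result>\n")
  r <- x$report
  cat(sprintf("  pairs: %d in, %d dropped (public), %d surviving\n",
              r$input_pairs, r$dropped_public, r$surviving_pairs))
  cat(sprintf("  collapse: %d unique sequences (%d assigned, %d unassigned)\n",
              r$collapsed_sequences, r$assigned_sequences,
              r$unassigned_sequences))
  cat(sprintf("  calls: %d SNPs, %d indels\n", r$n_snps, r$n_indels))
  invisible(x)
}

#' @describeIn call_pipeline Variant calls of a result as a tibble.
#' @param x An `amplicall_result`.
#' @param ... Unused.
#' @export
tidy.amplicall_result <- function(x, ...) x$variants

#' @describeIn call_pipeline One-row run summary (stage counters and call
#'   counts).
#' @export
glance.amplicall_result <- function(x, ...) x$report

#' @describeIn call_pipeline Reference-fraction profile per amplicon
#'   target position, with called sites highlighted.
#' @param object An `amplicall_result`.
#' @export
autoplot.amplicall_result <- function(object, ...) {
  df <- dplyr::bind_rows(object$pileups, .id = "amplicon_id")
  calls <- object$variants
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$p_ref)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$config$snp_ref_fraction,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$amplicon_id)) +
    ggplot2::labs(x = "target position",
                  y = "reference base fraction") +
    ggplot2::theme_minimal()
  if (nrow(calls)) {
    p <- p + ggplot2::geom_vline(
      data = calls,
      ggplot2::aes(xintercept = .data$position),
      colour = "steelblue", alpha = 0.5)
  }
  p
}

#' Base-count profile of one amplicon's pileup
#'
#' @param result An `amplicall_result`.
#' @param amplicon_id Which amplicon to plot.
#' @return A ggplot: stacked per-base counts along the target.
#' @export
plot_pileup <- function(result, amplicon_id) {
  columns <- result$pileups[[amplicon_id]]
  if (is.null(columns)) stop("unknown amplicon: ", amplicon_id)
  long <- tidyr::pivot_longer(columns, cols = c("A", "C", "G", "T", "N"),
                              names_to = "base", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$count,
                                     fill = .data$base)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(title = amplicon_id, x = "target position",
                  y = "frequency-weighted count") +
    ggplot2::theme_minimal()
}

# File-level wrappers --------------------------------------------------------

#' Run the calling pipeline on FASTQ inputs
#'
#' @param r1,r2 Paths to the R1/R2 FASTQ files.
#' @param panel Path to a panel TSV (see [load_panel()]) or an
#'   `amplicon_panel`.
#' @param out_vcf Optional path; when given, calls are written as VCF 4.2.
#' @param out_report Optional path; when given, the stage report is
#'   written as TSV.
#' @param config A [pipeline_config()].
#' @return The `amplicall_result`, invisibly when writing files.
#' @export
run_call <- function(r1, r2, panel, out_vcf = NULL, out_report = NULL,
                     config = pipeline_config()) {
  if (is.character(panel)) panel <- load_panel(panel)
  pairs <- read_fastq_pair(r1, r2)
  result <- call_pipeline(pairs, panel, config)
  if (!is.null(out_vcf)) {
    write_variants(result$variants, out_vcf,
                   contigs = tibble::tibble(
                     amplicon_id = panel$amplicon_id,
                     length = nchar(panel$target_seq)))
  }
  if (!is.null(out_report)) {
    utils::write.table(as.data.frame(result$report), out_report,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.null(out_vcf) && is.null(out_report)) result else invisible(result)
}

#' Simulate reads and write FASTQ + truth files
#'
#' @param panel An `amplicon_panel` or panel TSV path.
#' @param out_prefix Output prefix; writes `<prefix>_R1.fq`,
#'   `<prefix>_R2.fq` and `<prefix>_truth.tsv`.
#' @inheritParams sim_reads
#' @param n_snps,n_indels Truth set sizes (see [sim_truth()]).
#' @param allele_fraction Per-variant carrier fraction.
#' @return The read-pair tibble (with `truth` attribute), invisibly.
#' @export
run_simulate <- function(panel, out_prefix, depth = 50L, read_length = 150L,
                         n_snps = 30L, n_indels = 20L,
                         allele_fraction = 0.5, error_rate = 0,
                         capture_fail_rate = 0, seed = 1L) {
  if (is.character(panel)) panel <- load_panel(panel)
  truth <- sim_truth(panel, n_snps = n_snps, n_indels = n_indels,
                     allele_fraction = allele_fraction, seed = seed)
  pairs <- sim_reads(panel, truth, depth = depth,
                     read_length = read_length, error_rate = error_rate,
                     capture_fail_rate = capture_fail_rate, seed = seed)
  write_fastq_pair(pairs, paste0(out_prefix, "_R1.fq"),
                   paste0(out_prefix, "_R2.fq"))
  write_truth(truth, paste0(out_prefix, "_truth.tsv"))
  invisible(pairs)
}

#' Evaluate a call set (VCF) against a truth table
#'
#' @param vcf Path to a VCF written by this package, or a variant tibble.
#' @param truth Path to a truth TSV, or a truth tibble.
#' @param panel An `amplicon_panel` or panel TSV path.
#' @return A one-row metrics tibble (see [eval_metrics()]), with separate
#'   SNP and indel rows appended.
#' @export
run_evaluate <- function(vcf, truth, panel) {
  if (is.character(panel)) panel <- load_panel(panel)
  calls <- if (is.character(vcf)) read_variants(vcf) else vcf
  truth <- if (is.character(truth)) read_truth(truth) else truth
  subset_metrics <- function(calls, truth, label) {
    dplyr::mutate(eval_metrics(confusion_counts(calls, truth, panel)),
                  class = label, .before = 1L)
  }
  dplyr::bind_rows(
    subset_metrics(calls, truth, "all"),
    subset_metrics(calls[calls$kind == "SNP", , drop = FALSE],
                   truth[truth$kind == "SNP", , drop = FALSE], "SNP"),
    subset_metrics(calls[calls$kind != "SNP", , drop = FALSE],
                   truth[truth$kind != "SNP", , drop = FALSE], "indel")
  )
}
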