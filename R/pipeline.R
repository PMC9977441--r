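#' Run the full synthetic-cohort analysis pipeline
#'
#' Exercises every analysis stage end-to-end on one simulated cohort:
#' cohort-wide mixture fit and segment calling, per-sample PGA, group and
#' ancestry screens on the tumor locus matrix, germline locus derivation
#' from the normal-tissue cohort and filtering of both tumor hit lists,
#' per-locus Cox screens for both outcomes, gene-level gain calls with
#' Kaplan-Meier / log-rank at the hazard locus, beta-value simulation and
#' deconvolution, and the Treg-PGA correlation.
#'
#' @param config A [sim_config()]; its `seed` drives all randomness.
#' @param genome A [genome_model()].
#' @param tumor_fdr FDR threshold for the tumor screens (default 0.05).
#' @param germline_fdr FDR threshold for the germline screen (default
#'   0.001).
#' @param cox_fdr FDR threshold for the Cox screens (default 0.1).
#' @param signature Signature matrix for deconvolution (default
#'   [toy_signature()]).
#' @param beta_noise_sd Noise SD on simulated beta values (default 0.02).
#' @param outdir Optional directory; when given, stage outputs are
#'   written there (SEG, BED, TSV) along with a run report.
#' @return A list with every stage's result; see the vignette for a
#'   walk-through.
#' @export
run_pipeline <- function(config = sim_config(), genome = toy_genome(),
                         tumor_fdr = 0.05, germline_fdr = 0.001,
                         cox_fdr = 0.1, signature = toy_signature(),
                         beta_noise_sd = 0.02, outdir = NULL) {
  stopifnot(tumor_fdr > 0, tumor_fdr <= 1, germline_fdr > 0,
            germline_fdr <= 1, cox_fdr > 0, cox_fdr <= 1)
  sim <- simulate_cohort(config, genome)

  fit <- fit_mixture(sim$segments)
  calls <- call_segments(sim$segments, fit)
  pga <- compute_pga(calls, genome)

  race <- screen_group(sim$locus_matrix, sim$clinical, moderation = TRUE)
  ancestry <- screen_ancestry(sim$locus_matrix, sim$clinical)
  race_hits <- locus_set(race$locus_id[!is.na(race$q) & race$q < tumor_fdr],
                         "tumor_race", tumor_fdr)
  ancestry_hits <- locus_set(
    ancestry$locus_id[!is.na(ancestry$q) & ancestry$q < tumor_fdr],
    "tumor_ancestry", tumor_fdr)

  germline <- derive_germline_set(sim$normal$locus_matrix,
                                  sim$normal$clinical, fdr = germline_fdr)
  race_filtered <- filter_germline(race_hits, germline)
  ancestry_filtered <- filter_germline(ancestry_hits, germline)
  race_vs_ancestry <- overlap_sets(ancestry_hits, race_hits)

  cox_bcr <- cox_screen(sim$locus_matrix, sim$clinical, outcome = "bcr")
  cox_met <- cox_screen(sim$locus_matrix, sim$clinical,
                        outcome = "metastasis")

  gene_calls <- call_loci(sim$locus_matrix, fit)
  hz <- config$hazard_locus
  gain_freq <- frequency_of_gain(gene_calls, hz)
  gain <- gene_calls[, hz] == "gain"
  km <- km_logrank(gain, sim$clinical, outcome = "metastasis")

  set.seed(config$seed + 1L)
  betas <- simulate_betas(sim$truth$fractions, signature,
                          noise_sd = beta_noise_sd)
  deconv <- deconvolve(betas, signature)
  treg_pga <- correlate_with_pga(deconv, pga, cell_type = "Treg",
                                 clinical = sim$clinical)

  result <- list(sim = sim, mixture = fit, calls = calls, pga = pga,
                 screen_race = race, screen_ancestry = ancestry,
                 race_hits = race_hits, ancestry_hits = ancestry_hits,
                 germline = germline, race_filtered = race_filtered,
                 ancestry_filtered = ancestry_filtered,
                 race_vs_ancestry = race_vs_ancestry,
                 cox_bcr = cox_bcr, cox_met = cox_met,
                 gene_calls = gene_calls, gain_frequency = gain_freq,
                 km = km, deconv = deconv, treg_pga = treg_pga,
                 thresholds = c(tumor_fdr = tumor_fdr,
                                germline_fdr = germline_fdr,
                                cox_fdr = cox_fdr))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_seg(calls, file.path(outdir, "segments_called.seg"))
    write_bed(sim$annotation, file.path(outdir, "annotation.bed"))
    write_clinical(sim$clinical, file.path(outdir, "clinical.tsv"))
    write_locus_matrix(sim$locus_matrix, file.path(outdir,
                                                   "locus_matrix.tsv"))
    utils::write.table(pga, file.path(outdir, "pga.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_screen_result(race, file.path(outdir, "screen_race.tsv"))
    write_screen_result(ancestry, file.path(outdir, "screen_ancestry.tsv"))
    write_screen_result(cox_bcr, file.path(outdir, "cox_bcr.tsv"))
    write_screen_result(cox_met, file.path(outdir, "cox_metastasis.tsv"))
    write_report(result, file.path(outdir, "report.txt"))
  }
  result
}

#' Write a plain-text run report
#'
#' Aggregates per-stage summaries of a [run_pipeline()] result: locus
#' counts at the configured thresholds, germline overlap percentages, the
#' PGA distribution, hazard-locus gain frequency and the Treg-PGA
#' correlation.
#'
#' @param result A [run_pipeline()] result.
#' @param path File path.
#' @export
write_report <- function(result, path) {
  th <- result$thresholds
  pga <- result$pga
  lines <- c(
    "scnapipe run report",
    sprintf("samples: %d tumor, %d normal", nrow(result$sim$clinical),
            nrow(result$sim$normal$clinical)),
    sprintf("mixture means (loss/neutral/gain): %s",
            paste(signif(result$mixture$means, 4), collapse = " / ")),
    sprintf("PGA median %.2f%% (IQR %.2f-%.2f); %d samples excluded",
            stats::median(pga$pga_total),
            stats::quantile(pga$pga_total, 0.25),
            stats::quantile(pga$pga_total, 0.75), sum(pga$excluded)),
    sprintf("race screen hits (q < %g): %d", th[["tumor_fdr"]],
            length(result$race_hits)),
    sprintf("ancestry screen hits (q < %g): %d", th[["tumor_fdr"]],
            length(result$ancestry_hits)),
    sprintf("germline loci (q < %g): %d", th[["germline_fdr"]],
            length(result$germline)),
    sprintf("ancestry hits after germline filter: %d (%d%% removed)",
            result$ancestry_filtered$summary$n_retained,
            result$ancestry_filtered$summary$removed_pct),
    sprintf("ancestry/race hit overlap: %d%%",
            result$race_vs_ancestry$pct_of_a),
    sprintf("Cox hits at q < %g: %d (BCR), %d (metastasis)",
            th[["cox_fdr"]],
            sum(result$cox_bcr$q < th[["cox_fdr"]], na.rm = TRUE),
            sum(result$cox_met$q < th[["cox_fdr"]], na.rm = TRUE)),
    sprintf("hazard-locus gains: %d of %d (%d%%), log-rank p = %.3g",
            result$gain_frequency$n_gain, result$gain_frequency$n_total,
            result$gain_frequency$pct, result$km$p),
    sprintf("Treg vs PGA Spearman rho (overall): %.3f (p = %.3g, n = %d)",
            result$treg_pga$rho[1], result$treg_pga$p[1],
            result$treg_pga$n[1])
  )
  writeLines(lines, path)
  invisible(path)
}
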