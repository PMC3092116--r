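#' Run the full integrative pipeline on a cohort
#'
#' Executes every stage on the tables of a (synthetic or real) cohort:
#' transcript deconvolution from exon intensities, transcript- and
#' gene-level differential expression, DET selection, discretized-expression
#' survival screening, SNP survival screening, copy-number segmentation,
#' threshold estimation from control arrays, gain/loss calling and
#' aberration frequencies, amplification-expression permutation integration,
#' methylation combining, miRNA differential expression with target
#' filtering, siRNA screen scoring, and the fused gene report table. Set a
#' seed before calling for reproducible permutation/segmentation results.
#'
#' @param cohort List of cohort tables as produced by [generate_cohort()].
#' @param cbs_alpha,cbs_min_width,cbs_nperm Segmentation parameters (see
#'   [segment_profile()]).
#' @param integration_nperm Monte-Carlo permutations for
#'   [permutation_pvalue()] (default 2000).
#' @param out_dir Optional directory; when given, the fused table (TSV +
#'   JSON) and the static website are written there.
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return List with all stage outputs: `transcript_matrix`, `de_transcript`,
#'   `dets`, `fc_matrix`, `survival_screen`, `gene_survival_screen`,
#'   `de_gene`, `snp_screen`, `thresholds`, `segments`, `aberration_freqs`,
#'   `integration`, `methylation_beta`, `de_mirna`, `mirna_targets_kept`,
#'   `screen_scores`, `screen_hits`, `gene_table`.
#' @export
run_pipeline <- function(cohort, cbs_alpha = 0.01, cbs_min_width = 3L,
                         cbs_nperm = 1000L, integration_nperm = 2000L,
                         out_dir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  roles <- setNames(cohort$roles$role, cohort$roles$sample)
  samples <- cohort$roles$sample
  tumor_ids <- samples[roles[samples] == "tumor"]
  control_ids <- samples[roles[samples] == "control"]

  # --- expression stages -----------------------------------------------
  say("deconvolving transcripts")
  tx <- cohort_transcript_expression(cohort$exon_matrix, cohort$incidences)
  tx_mat <- tx$transcript_matrix
  de_tx <- differential_expression(tx_mat, roles[colnames(tx_mat)])
  dets <- select_dets(de_tx)
  control_means <- rowMeans(tx_mat[, control_ids, drop = FALSE])
  fc_matrix <- tx_mat[dets, tumor_ids, drop = FALSE] / control_means[dets]

  gene_exon_map <- unique(data.frame(gene_id = cohort$annotation$gene_id,
                                     exon_id = cohort$annotation$exon_id,
                                     stringsAsFactors = FALSE))
  gene_from_exons <- gene_level_from_exons(cohort$exon_matrix, gene_exon_map)
  de_gene_exon <- differential_expression(gene_from_exons,
                                          roles[colnames(gene_from_exons)])
  de_gene <- differential_expression(cohort$gene_matrix,
                                     roles[colnames(cohort$gene_matrix)])

  # --- survival stages ---------------------------------------------------
  say("survival screening")
  surv_screen <- expression_survival_screen(fc_matrix, cohort$clinical)
  gene_cm <- rowMeans(gene_from_exons[, control_ids, drop = FALSE])
  ok_gene <- gene_cm > 0
  gene_fc_matrix <- gene_from_exons[ok_gene, tumor_ids, drop = FALSE] /
    gene_cm[ok_gene]
  gene_surv <- expression_survival_screen(gene_fc_matrix, cohort$clinical)
  snp <- snp_survival_screen(cohort$genotypes, cohort$clinical,
                             sample_snr = cohort$sample_snr)

  # --- copy number -------------------------------------------------------
  say("segmenting copy-number profiles")
  thresholds <- estimate_thresholds(cohort$cn_controls$logratio)
  seg_list <- lapply(split(cohort$cn_probes, cohort$cn_probes$sample),
                     function(p) segment_profile(p, alpha = cbs_alpha,
                                                 min_width = cbs_min_width,
                                                 nperm = cbs_nperm,
                                                 sample_id = p$sample[1]))
  segments <- call_aberrations(do.call(rbind, seg_list), thresholds)
  rownames(segments) <- NULL
  freqs <- aberration_frequencies(segments, cohort$gene_coords,
                                  n_samples = length(tumor_ids))

  # --- integration -------------------------------------------------------
  say("integrating amplification and expression")
  tumor_gene_expr <- gene_from_exons[, tumor_ids, drop = FALSE]
  integration <- integrate_cn_expression(
    tumor_gene_expr, segments,
    cohort$gene_coords[cohort$gene_coords$feature %in%
                         rownames(tumor_gene_expr), ],
    n_permutations = integration_nperm)

  # --- methylation and miRNA --------------------------------------------
  meth_beta <- combine_promoter_probes(cohort$methylation)
  tumor_beta <- rowMeans(meth_beta[, intersect(colnames(meth_beta),
                                               tumor_ids), drop = FALSE],
                         na.rm = TRUE)
  de_mirna <- differential_expression(cohort$mirna_matrix,
                                      roles[colnames(cohort$mirna_matrix)])
  mirna_kept <- filter_mirna_targets(cohort$mirna_targets)

  # --- siRNA screen ------------------------------------------------------
  say("scoring the siRNA screen")
  screen_scores <- score_screen(cohort$plates)
  screen_hits <- gene_consistency_call(
    screen_scores[screen_scores$gene %in% unique(cohort$plates$gene) &
                    !is.na(screen_scores$gene), ])

  # --- fused gene table --------------------------------------------------
  say("fusing the gene table")
  tx_gene <- sub("_T\\d+$", "", de_tx$feature)
  tx_summary <- do.call(rbind, lapply(split(de_tx, tx_gene), function(d) {
    data.frame(gene = sub("_T\\d+$", "", d$feature[1]),
               fc_min = min(d$fc, na.rm = TRUE),
               fc_max = max(d$fc, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  surv_gene <- sub("_T\\d+$", "", surv_screen$feature)
  best_tx_surv <- do.call(rbind, lapply(split(surv_screen, surv_gene),
    function(d) data.frame(gene = sub("_T\\d+$", "", d$feature[1]),
                           survival_p = suppressWarnings(
                             min(d$p, na.rm = TRUE)),
                           stringsAsFactors = FALSE)))
  best_tx_surv$survival_p[!is.finite(best_tx_surv$survival_p)] <- NA_real_
  snp_gene_map <- cohort$ground_truth$snp_marker_gene
  snp_best <- NULL
  if (length(snp_gene_map)) {
    sr <- snp$results[snp$results$marker %in% names(snp_gene_map), ]
    if (nrow(sr)) {
      sr$gene <- snp_gene_map[sr$marker]
      snp_best <- do.call(rbind, lapply(split(sr, sr$gene), function(d)
        data.frame(gene = d$gene[1],
                   snp_p = suppressWarnings(min(d$p, na.rm = TRUE)),
                   stringsAsFactors = FALSE)))
      snp_best$snp_p[!is.finite(snp_best$snp_p)] <- NA_real_
    }
  }
  stages <- list(
    gene_expression = data.frame(gene = de_gene$feature,
                                 gene_fc = de_gene$fc,
                                 gene_adj_p = de_gene$adj_p,
                                 stringsAsFactors = FALSE),
    exon_platform = data.frame(gene = de_gene_exon$feature,
                               exon_fc = de_gene_exon$fc,
                               stringsAsFactors = FALSE),
    transcripts = tx_summary,
    transcript_survival = best_tx_surv,
    gene_survival = data.frame(gene = gene_surv$feature,
                               gene_survival_p = gene_surv$p,
                               stringsAsFactors = FALSE),
    copy_number = data.frame(gene = freqs$feature,
                             gain_freq = freqs$gain_freq,
                             loss_freq = freqs$loss_freq,
                             stringsAsFactors = FALSE),
    integration = data.frame(gene = integration$feature,
                             integration_p = integration$p_perm,
                             stringsAsFactors = FALSE),
    methylation = data.frame(gene = names(tumor_beta),
                             methylation_beta = unname(tumor_beta),
                             stringsAsFactors = FALSE))
  if (!is.null(snp_best)) stages$snp_survival <- snp_best
  gene_table <- build_gene_table(stages)

  result <- list(transcript_matrix = tx_mat, de_transcript = de_tx,
                 dets = dets, fc_matrix = fc_matrix,
                 survival_screen = surv_screen,
                 gene_survival_screen = gene_surv,
                 de_gene = de_gene, de_gene_exon = de_gene_exon,
                 snp_screen = snp, thresholds = thresholds,
                 segments = segments, aberration_freqs = freqs,
                 integration = integration, methylation_beta = meth_beta,
                 de_mirna = de_mirna, mirna_targets_kept = mirna_kept,
                 screen_scores = screen_scores, screen_hits = screen_hits,
                 gene_table = gene_table)

  if (!is.null(out_dir)) {
    write_gene_table(gene_table, out_dir)
    tx_pages <- data.frame(gene = sub("_T\\d+$", "", de_tx$feature),
                           transcript = de_tx$feature, fc = de_tx$fc,
                           stringsAsFactors = FALSE)
    tx_pages <- merge(tx_pages,
                      data.frame(transcript = surv_screen$feature,
                                 survival_p = surv_screen$p,
                                 stringsAsFactors = FALSE),
                      by = "transcript", all.x = TRUE)
    km_groups <- km_groups_for_features(
      surv_screen$feature[!is.na(surv_screen$p) & surv_screen$p < 0.01],
      fc_matrix, cohort$clinical)
    render_website(gene_table, out_dir, sort_key = "survival_p",
                   transcripts = tx_pages, km_groups = km_groups)
  }
  result
}

#' Kaplan-Meier group curves for selected features
#'
#' Builds, for each feature, the per-group KM tables used by the report's
#' embedded survival plots (groups = discretized per-sample fold-change
#' classes with >= `min_group` patients).
#'
#' @param features Feature ids (rows of `fc_matrix`).
#' @param fc_matrix Per-sample fold-change matrix.
#' @param clinical Clinical records.
#' @param min_group Minimum class size (default 20).
#' @return Named list (by feature) of named lists of [kaplan_meier()] tables.
#' @export
km_groups_for_features <- function(features, fc_matrix, clinical,
                                   min_group = 20L) {
  out <- list()
  common <- intersect(colnames(fc_matrix), clinical$patient_id)
  cl <- clinical[match(common, clinical$patient_id), ]
  for (f in features) {
    cls <- discretize_fc(fc_matrix[f, common])
    tab <- table(cls)
    keep <- names(tab)[tab >= min_group]
    if (length(keep) < 2L) next
    groups <- lapply(keep, function(k) {
      use <- !is.na(cls) & cls == as.integer(k)
      kaplan_meier(cl$months[use], cl$event[use])
    })
    names(groups) <- keep
    out[[f]] <- groups
  }
  out
}
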