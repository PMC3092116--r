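#' Robust LOESS plate-background correction
#'
#' Fits a robust locally-weighted polynomial surface (degree 2, span 0.35,
#' iterated robustness reweighting so statistical outliers such as real hits
#' are down-weighted) to the well intensities over the (row, column) plate
#' layout and subtracts the fitted background from each well. The background
#' is the spatial deviation of the surface from its plate-wide median, so
#' correction removes gradients and edge effects while preserving the
#' plate's overall signal level (a flat plate is returned unchanged). Empty
#' wells are excluded from the fit but still receive a background estimate.
#'
#' @param plate `data.frame` with columns `row`, `col`, `signal`, `role`
#'   (one plate).
#' @param span LOESS span (default 0.35).
#' @param degree Local polynomial degree (default 2).
#' @param iterations Robustness reweighting passes after the initial fit
#'   (default 2).
#' @return The plate `data.frame` with `signal` replaced by the corrected
#'   values and extra columns `raw_signal` and `background`.
#' @export
loess_plate_normalize <- function(plate, span = 0.35, degree = 2L,
                                  iterations = 2L) {
  stopifnot(all(c("row", "col", "signal") %in% names(plate)))
  use <- if ("role" %in% names(plate)) plate$role != "empty"
         else rep(TRUE, nrow(plate))
  if (sum(use) < 20L)
    stop("need >= 20 non-empty wells for the surface fit", call. = FALSE)
  fit <- loess(signal ~ row + col, data = plate[use, ],
               span = span, degree = degree, family = "symmetric",
               normalize = FALSE,
               control = loess.control(surface = "direct",
                                       iterations = iterations + 1L))
  bg <- predict(fit, newdata = plate[, c("row", "col")])
  bg <- bg - median(bg[use])
  plate$raw_signal <- plate$signal
  plate$background <- bg
  plate$signal <- plate$signal - bg
  plate
}

#' Relative signal against negative-control wells
#'
#' Scales well signals so the mean of the negative-control siRNA wells
#' equals one.
#'
#' @param values Well signals.
#' @param negative_controls Signals of the negative-control wells.
#' @return `values / mean(negative_controls)`.
#' @export
relative_signal <- function(values, negative_controls) {
  m <- mean(negative_controls)
  if (!is.finite(m) || m == 0)
    stop("negative-control mean is zero or non-finite", call. = FALSE)
  values / m
}

#' Robust z-scores
#'
#' `z = (x - reference_median) / (1.4826 * reference_mad)` where
#' `reference_mad` is the raw (unscaled) median absolute deviation; the
#' 1.4826 factor makes the scale consistent with the standard deviation
#' under normality.
#'
#' @param values Numeric values to score.
#' @param reference_median Location; defaults to `median(values)`.
#' @param reference_mad Raw MAD; defaults to the raw MAD of `values`.
#' @return Numeric z-scores; all-`NA` with a warning when the MAD is zero.
#' @export
robust_z <- function(values, reference_median = NULL, reference_mad = NULL) {
  if (is.null(reference_median)) reference_median <- median(values, na.rm = TRUE)
  if (is.null(reference_mad))
    reference_mad <- median(abs(values - reference_median), na.rm = TRUE)
  if (is.na(reference_mad) || reference_mad == 0) {
    warning("zero MAD: robust z-scores undefined")
    return(rep(NA_real_, length(values)))
  }
  (values - reference_median) / (1.4826 * reference_mad)
}

#' Per-siRNA significance against negative controls
#'
#' Welch two-sample t-test (two-tailed, unequal variances) of the replicate
#' signals of one siRNA against the negative-control wells, with
#' significance tiers at P < 0.05 (`*`), < 0.01 (`**`) and < 0.001 (`***`).
#'
#' @param replicates Replicate signals for the siRNA (>= 2).
#' @param negative_controls Negative-control well signals (>= 2).
#' @return List with `p` and `tier` (one of `"ns"`, `"*"`, `"**"`, `"***"`;
#'   `NA` when both sides have zero variance).
#' @export
sirna_significance <- function(replicates, negative_controls) {
  if (length(replicates) < 2L || length(negative_controls) < 2L)
    stop("need >= 2 replicates on each side", call. = FALSE)
  if (sd(replicates) == 0 && sd(negative_controls) == 0)
    return(list(p = NA_real_, tier = NA_character_))
  p <- stats::t.test(replicates, negative_controls,
                     var.equal = FALSE)$p.value
  list(p = p, tier = significance_tier(p))
}

#' Map a P-value to its significance tier
#'
#' @param p P-value(s).
#' @return `"***"` for P < 0.001, `"**"` for P < 0.01, `"*"` for P < 0.05,
#'   `"ns"` otherwise.
#' @export
significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Score an siRNA screen
#'
#' Per plate: optional LOESS background correction, scaling to the
#' negative-control mean (= 1), then per-siRNA summaries: the median of the
#' replicate relative signals, a robust z-score of that median against the
#' negative-control reference (median and raw MAD of the negative-control
#' relative signals), and a Welch t-test against the negative-control wells.
#'
#' @param plates `data.frame` with columns `plate`, `row`, `col`, `signal`,
#'   `role` (`"sample"`, `"negative"`, `"positive"`, `"death"`, `"empty"`),
#'   `sirna`, `gene` and optionally `cell_line`, `assay`.
#' @param loess_correct Apply [loess_plate_normalize()] per plate first
#'   (default `TRUE`).
#' @param ... Passed to [loess_plate_normalize()].
#' @return `data.frame` with one row per siRNA per plate: `plate`,
#'   (`cell_line`, `assay` when present), `gene`, `sirna`, `value`
#'   (median relative signal), `z`, `p`, `tier`.
#' @export
score_screen <- function(plates, loess_correct = TRUE, ...) {
  res <- lapply(split(plates, plates$plate), function(pl) {
    if (loess_correct) pl <- loess_plate_normalize(pl, ...)
    neg <- pl$signal[pl$role == "negative"]
    if (length(neg) < 2L)
      stop("plate ", pl$plate[1], ": needs >= 2 negative-control wells",
           call. = FALSE)
    pl$rel <- relative_signal(pl$signal, neg)
    neg_rel <- pl$rel[pl$role == "negative"]
    ref_med <- median(neg_rel)
    ref_mad <- median(abs(neg_rel - ref_med))
    wells <- pl[pl$role %in% c("sample", "positive", "death") &
                  !is.na(pl$sirna), ]
    per <- lapply(split(wells, wells$sirna), function(w) {
      val <- midpoint_median(w$rel)
      sig <- sirna_significance(w$rel, neg_rel)
      out <- data.frame(plate = w$plate[1], gene = w$gene[1],
                        sirna = w$sirna[1], value = val,
                        z = if (ref_mad > 0)
                          (val - ref_med) / (1.4826 * ref_mad)
                        else NA_real_,
                        p = sig$p, tier = sig$tier,
                        stringsAsFactors = FALSE)
      for (extra in c("cell_line", "assay"))
        if (extra %in% names(w)) out[[extra]] <- w[[extra]][1]
      out
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene-level consistency call across cell lines
#'
#' A gene is a consistent hit when at least `min_sirnas` distinct siRNAs
#' reach `|z| >= z_min` in the effect direction in every tested cell line.
#' Requiring two independent siRNAs guards against off-target effects of a
#' single construct.
#'
#' @param scores `data.frame` with columns `gene`, `sirna`, `cell_line`, `z`.
#' @param z_min Magnitude threshold (default 2).
#' @param min_sirnas Distinct active siRNAs required (default 2).
#' @param direction `-1` for inhibition (default), `+1` for activation.
#' @return `data.frame` with `gene`, `n_consistent_sirnas`, `n_cell_lines`,
#'   `hit`.
#' @export
gene_consistency_call <- function(scores, z_min = 2, min_sirnas = 2L,
                                  direction = -1) {
  res <- lapply(split(scores, scores$gene), function(g) {
    gene_id <- g$gene[1]
    lines <- unique(g$cell_line)
    g <- g[!is.na(g$z), ]
    if (nrow(g) == 0L)
      return(data.frame(gene = gene_id, n_consistent_sirnas = 0L,
                        n_cell_lines = length(lines), hit = FALSE,
                        stringsAsFactors = FALSE))
    active <- ifelse(direction < 0, list(g$z <= -z_min),
                     list(g$z >= z_min))[[1]]
    # siRNAs active in every tested cell line
    per_sirna <- tapply(seq_len(nrow(g)), g$sirna, function(idx) {
      all(lines %in% g$cell_line[idx][active[idx]])
    })
    n_cons <- sum(per_sirna, na.rm = TRUE)
    data.frame(gene = gene_id, n_consistent_sirnas = n_cons,
               n_cell_lines = length(lines),
               hit = n_cons >= min_sirnas, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
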