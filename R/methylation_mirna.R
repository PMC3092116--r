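#' Methylation beta value
#'
#' `beta = M / (M + U)` where `M` and `U` are the methylated and
#' unmethylated signal levels. Beta ranges from 0 (hypomethylated) to 1
#' (hypermethylated). Probes with `M + U = 0` get a missing beta.
#'
#' @param M,U Nonnegative signal vectors.
#' @return Numeric beta values in `[0, 1]` (or `NA`).
#' @export
beta_value <- function(M, U) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("negative methylation signal", call. = FALSE)
  tot <- M + U
  ifelse(is.na(tot) | tot == 0, NA_real_, M / tot)
}

#' Combine promoter probes into one beta per gene
#'
#' Probes targeting the same gene promoter are combined by taking the median
#' of their beta values per sample (midpoint for even counts), over
#' non-missing probes only; a gene whose probes are all missing in a sample
#' stays missing.
#'
#' @param meth Long `data.frame` with columns `probe`, `gene`, `sample` and
#'   either `beta` or both `M` and `U` (betas are then computed).
#' @return Genes x samples matrix of combined betas.
#' @export
combine_promoter_probes <- function(meth) {
  if (!"beta" %in% names(meth)) {
    if (!all(c("M", "U") %in% names(meth)))
      stop("need a 'beta' column or both 'M' and 'U'", call. = FALSE)
    meth$beta <- beta_value(meth$M, meth$U)
  }
  genes <- sort(unique(meth$gene))
  samples <- sort(unique(meth$sample))
  out <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  agg <- tapply(meth$beta, list(meth$gene, meth$sample),
                function(b) if (all(is.na(b))) NA_real_ else midpoint_median(b))
  out[rownames(agg), colnames(agg)] <- agg
  out
}

#' Filter miRNA target annotations by target-site P-value
#'
#' Keeps miRNA-gene pairs whose target-site P-value is below the threshold
#' (default 1e-5).
#'
#' @param annotation `data.frame` with columns `mirna`, `gene`, `p`.
#' @param p_threshold Retention threshold (default `1e-5`).
#' @return The retained rows.
#' @export
filter_mirna_targets <- function(annotation, p_threshold = 1e-5) {
  annotation[!is.na(annotation$p) & annotation$p < p_threshold, ,
             drop = FALSE]
}

#' Synthetic miRNA target annotation
#'
#' Stands in for a curated target-site database: draws `n_pairs` random
#' miRNA-gene pairs with target-site P-values log-uniform between `p_range`
#' bounds, so a controllable fraction survives [filter_mirna_targets()].
#'
#' @param mirnas,genes Character vectors of ids to pair.
#' @param n_pairs Number of pairs to draw.
#' @param p_range Range of target-site P-values (default `c(1e-8, 1e-2)`).
#' @return `data.frame` with `mirna`, `gene`, `p`. Uses the RNG.
#' @export
simulate_mirna_targets <- function(mirnas, genes, n_pairs = 100L,
                                   p_range = c(1e-8, 1e-2)) {
  data.frame(
    mirna = sample(mirnas, n_pairs, replace = TRUE),
    gene = sample(genes, n_pairs, replace = TRUE),
    p = exp(runif(n_pairs, log(p_range[1]), log(p_range[2]))),
    stringsAsFactors = FALSE)
}
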