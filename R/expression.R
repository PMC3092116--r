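#' Solve transcript expression from exon intensities
#'
#' Estimates transcript (splice-variant) expression values `t` from measured
#' exon intensities `e` by least squares against the gene's exon-transcript
#' incidence matrix `A`: `t` minimizes `||A t - e||_2`. The solve uses an
#' orthogonal factorization (QR) for numerical stability. When `A` is
#' rank-deficient the minimum-norm solution is returned (via the singular
#' value decomposition pseudoinverse) and flagged. Solutions are
#' unconstrained, so negative transcript values can occur; they are flagged
#' rather than truncated.
#'
#' @param A Binary exon x transcript incidence matrix (or an incidence object
#'   from [build_incidence()]).
#' @param e Numeric exon intensity vector, aligned with the rows of `A`.
#' @return List with `t` (named transcript values), `residual` (the 2-norm of
#'   `A t - e`), `rank_deficient` (logical) and `negative` (logical: any
#'   solved value < 0).
#' @export
solve_transcripts <- function(A, e) {
  if (is.list(A) && !is.null(A$A)) A <- A$A
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (nrow(A) != length(e))
    stop("dimension mismatch: nrow(A) != length(e)", call. = FALSE)
  qrA <- qr(A, LAPACK = FALSE)
  rank_def <- qrA$rank < ncol(A)
  if (!rank_def) {
    t_hat <- qr.coef(qrA, e)
  } else {
    sv <- svd(A)
    tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    t_hat <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], e)) / sv$d[pos])
    t_hat <- drop(t_hat)
    names(t_hat) <- colnames(A)
  }
  resid <- sqrt(sum((A %*% t_hat - e)^2))
  list(t = t_hat, residual = resid, rank_deficient = rank_def,
       negative = any(t_hat < 0))
}

#' Transcript expression matrix for a whole cohort
#'
#' Applies [solve_transcripts()] gene by gene and sample by sample to an
#' exon intensity matrix.
#'
#' @param exon_matrix Exons x samples numeric matrix (rownames = exon ids).
#' @param incidences Named list from [build_incidence()].
#' @return List with `transcript_matrix` (transcripts x samples),
#'   `rank_deficient_genes` (character vector).
#' @export
cohort_transcript_expression <- function(exon_matrix, incidences) {
  blocks <- vector("list", length(incidences))
  rank_def <- character(0)
  for (i in seq_along(incidences)) {
    inc <- incidences[[i]]
    miss <- setdiff(inc$exon_ids, rownames(exon_matrix))
    if (length(miss))
      stop("exon ids missing from matrix for gene ", inc$gene_id, call. = FALSE)
    E <- exon_matrix[inc$exon_ids, , drop = FALSE]
    if (!inc$full_rank) rank_def <- c(rank_def, inc$gene_id)
    tm <- matrix(NA_real_, length(inc$transcript_ids), ncol(E),
                 dimnames = list(inc$transcript_ids, colnames(E)))
    for (s in seq_len(ncol(E)))
      tm[, s] <- solve_transcripts(inc$A, E[, s])$t
    blocks[[i]] <- tm
  }
  list(transcript_matrix = do.call(rbind, blocks),
       rank_deficient_genes = rank_def)
}

#' Gene-level expression as the median over a gene's exons
#'
#' @param exon_matrix Exons x samples numeric matrix.
#' @param gene_exon_map `data.frame` with columns `gene_id`, `exon_id`.
#' @return Genes x samples matrix. Genes with no measured exon are dropped
#'   with a warning. Even exon counts use the midpoint of the two central
#'   values (the usual median convention).
#' @export
gene_level_from_exons <- function(exon_matrix, gene_exon_map) {
  gene_exon_map <- unique(gene_exon_map[, c("gene_id", "exon_id")])
  measured <- gene_exon_map$exon_id %in% rownames(exon_matrix)
  lost <- setdiff(gene_exon_map$gene_id[!measured],
                  gene_exon_map$gene_id[measured])
  if (length(lost))
    warning("dropped gene(s) with zero measured exons: ",
            paste(lost, collapse = ", "))
  gene_exon_map <- gene_exon_map[measured, , drop = FALSE]
  by_gene <- split(gene_exon_map$exon_id, gene_exon_map$gene_id)
  out <- t(vapply(by_gene, function(ex) {
    apply(exon_matrix[ex, , drop = FALSE], 2, midpoint_median)
  }, numeric(ncol(exon_matrix))))
  colnames(out) <- colnames(exon_matrix)
  out
}

#' Fold change between tumor and control groups
#'
#' FC = mean(tumor) / mean(control), on the intensity scale.
#'
#' @param tumor,control Numeric vectors.
#' @return The fold change; `NA` with a warning when the control mean is
#'   not positive (undefined FC).
#' @export
fold_change <- function(tumor, control) {
  cm <- mean(control)
  if (!is.finite(cm) || cm <= 0) {
    warning("control mean <= 0: fold change undefined")
    return(NA_real_)
  }
  mean(tumor) / cm
}

#' Per-sample fold change against the control mean
#'
#' @param value Sample expression value(s).
#' @param control_mean Mean of control expression values (must be > 0).
#' @return `value / control_mean`, vectorized over `value`.
#' @export
per_sample_fold_change <- function(value, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    warning("control mean <= 0: per-sample fold change undefined")
    return(rep(NA_real_, length(value)))
  }
  value / control_mean
}

# Internal: vectorized Welch two-sample t-test over matrix rows.
# Returns two-sided P; rows where both groups have zero variance get NA.
welch_rows <- function(x_tumor, x_control) {
  n1 <- ncol(x_tumor); n2 <- ncol(x_control)
  m1 <- rowMeans(x_tumor); m2 <- rowMeans(x_control)
  v1 <- rowSums((x_tumor - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_control - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero <- v1 == 0 & v2 == 0
  tstat[zero] <- NA_real_
  p[zero] <- NA_real_
  list(t = tstat, p = p)
}

#' Differential expression between tumor and control samples
#'
#' Per feature: fold change (tumor mean / control mean), a Welch two-sample
#' t-test (two-sided, unequal variances) and Benjamini-Hochberg adjusted
#' P-values across all tested features. Features where both groups have zero
#' variance get a missing P and are flagged.
#'
#' @param mat Features x samples numeric matrix.
#' @param roles Character vector (length `ncol(mat)`) of `"tumor"`/`"control"`,
#'   or a named vector/`data.frame` sidecar with columns `sample`, `role`.
#' @param log2_input If `TRUE`, the matrix is log2-scale: the t-test runs on
#'   the given scale and fold changes are computed from the unlogged values.
#' @return `data.frame` with columns `feature`, `fc`, `t`, `p`, `adj_p`,
#'   `flag_zero_variance`.
#' @export
differential_expression <- function(mat, roles, log2_input = FALSE) {
  if (is.data.frame(roles)) {
    roles <- setNames(roles$role, roles$sample)[colnames(mat)]
  }
  roles <- as.character(roles)
  if (length(roles) != ncol(mat))
    stop("roles must match the matrix columns", call. = FALSE)
  tum <- mat[, roles == "tumor", drop = FALSE]
  ctl <- mat[, roles == "control", drop = FALSE]
  if (ncol(tum) < 2L || ncol(ctl) < 2L)
    stop("need >= 2 samples per group for differential expression",
         call. = FALSE)
  wt <- welch_rows(tum, ctl)
  lin_t <- if (log2_input) 2^tum else tum
  lin_c <- if (log2_input) 2^ctl else ctl
  cm <- rowMeans(lin_c)
  fc <- ifelse(cm > 0, rowMeans(lin_t) / cm, NA_real_)
  adj <- rep(NA_real_, length(wt$p))
  ok <- !is.na(wt$p)
  adj[ok] <- p.adjust(wt$p[ok], method = "BH")
  data.frame(feature = rownames(mat), fc = fc, t = wt$t, p = wt$p,
             adj_p = adj, flag_zero_variance = is.na(wt$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select differentially expressed transcripts (DETs)
#'
#' Keeps features with absolute fold change > 2 -- symmetric on the ratio
#' scale, i.e. FC > 2 or FC < 0.5 -- and adjusted P < 0.05.
#'
#' @param de `data.frame` from [differential_expression()].
#' @param fc_threshold Fold-change gate (default 2).
#' @param adj_p_threshold Adjusted-P gate (default 0.05).
#' @return Character vector of selected feature ids.
#' @export
select_dets <- function(de, fc_threshold = 2, adj_p_threshold = 0.05) {
  keep <- !is.na(de$fc) & !is.na(de$adj_p) &
    (de$fc > fc_threshold | de$fc < 1 / fc_threshold) &
    de$adj_p < adj_p_threshold
  de$feature[keep]
}
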