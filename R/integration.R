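#' Amplification-expression weight statistic
#'
#' Splits the samples into amplified and non-amplified groups and computes
#' `w = (mean_amp - mean_nonamp) / (sd_amp + sd_nonamp)` with sample
#' standard deviations. Large positive `w` means amplification co-occurs
#' with overexpression.
#'
#' @param values Numeric expression values (one feature across samples).
#' @param amplified Logical mask, `TRUE` for amplified samples.
#' @return The weight, or `NA` (with attribute `"flag"`) when either group
#'   has fewer than 2 samples or both standard deviations are zero.
#' @export
amplification_weight <- function(values, amplified) {
  stopifnot(length(values) == length(amplified))
  a <- values[amplified]
  b <- values[!amplified]
  if (length(a) < 2L || length(b) < 2L) {
    out <- NA_real_
    attr(out, "flag") <- "group_too_small"
    return(out)
  }
  denom <- sd(a) + sd(b)
  if (denom == 0) {
    if (mean(a) == mean(b)) return(0)
    out <- NA_real_
    attr(out, "flag") <- "zero_variance"
    return(out)
  }
  (mean(a) - mean(b)) / denom
}

# Internal: weights for every mask column of a logical matrix (n x B) at
# fixed group size k = colSums(M). Vectorized over masks.
weights_for_masks <- function(values, M) {
  n <- length(values)
  k <- colSums(M)
  s1 <- as.numeric(crossprod(M, values))          # group sums
  q1 <- as.numeric(crossprod(M, values^2))        # group sums of squares
  st <- sum(values)
  qt <- sum(values^2)
  m_a <- s1 / k
  m_b <- (st - s1) / (n - k)
  v_a <- pmax(0, (q1 - k * m_a^2) / (k - 1))
  v_b <- pmax(0, ((qt - q1) - (n - k) * m_b^2) / (n - k - 1))
  denom <- sqrt(v_a) + sqrt(v_b)
  w <- (m_a - m_b) / denom
  w[denom == 0 & m_a == m_b] <- 0
  w
}

#' Permutation P-value for the amplification weight
#'
#' The observed weight is compared against weights from random
#' re-assignments of the samples into amplified and non-amplified groups of
#' the same sizes. When the number of distinct assignments `choose(n, k)` is
#' at most `exhaustive_limit` all assignments are enumerated and
#' `P = #\{w_perm >= w_obs\} / N`; otherwise `n_permutations` random masks are
#' drawn and the add-one estimator
#' `P = (1 + #\{w_perm >= w_obs\}) / (n_permutations + 1)` is used, which
#' avoids P = 0. The default alternative is one-sided toward
#' overexpression-with-amplification; `two_sided = TRUE` compares `|w|`.
#'
#' @param values Numeric expression values.
#' @param amplified Logical mask.
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param exhaustive_limit Enumerate exhaustively when `choose(n, k)` is at
#'   most this value (default 10000).
#' @param two_sided Compare absolute weights instead (default `FALSE`).
#' @return List with `w` (observed weight), `p`, `exhaustive` (logical) and
#'   `n_used` (assignments or permutations evaluated). Uses the RNG in the
#'   Monte-Carlo branch.
#' @export
permutation_pvalue <- function(values, amplified, n_permutations = 10000L,
                               exhaustive_limit = 10000L, two_sided = FALSE) {
  w_obs <- amplification_weight(values, amplified)
  if (is.na(w_obs))
    return(list(w = NA_real_, p = NA_real_, exhaustive = FALSE, n_used = 0L,
                flag = attr(w_obs, "flag")))
  n <- length(values)
  k <- sum(amplified)
  cmp <- function(w) if (two_sided) abs(w) else w
  # counting tolerance so the observed split always ties with itself despite
  # floating-point differences between the scalar and vectorized paths
  eps <- 1e-9 * max(1, abs(w_obs))
  if (choose(n, k) <= exhaustive_limit) {
    masks <- combn(n, k)
    M <- matrix(FALSE, n, ncol(masks))
    M[cbind(as.vector(masks),
            rep(seq_len(ncol(masks)), each = k))] <- TRUE
    w_perm <- weights_for_masks(values, M)
    ok <- !is.na(w_perm)
    p <- sum(cmp(w_perm[ok]) >= cmp(w_obs) - eps) / sum(ok)
    return(list(w = w_obs, p = p, exhaustive = TRUE, n_used = sum(ok)))
  }
  B <- as.integer(n_permutations)
  M <- matrix(FALSE, n, B)
  for (b in seq_len(B)) M[sample.int(n, k), b] <- TRUE
  w_perm <- weights_for_masks(values, M)
  w_perm[is.na(w_perm)] <- -Inf   # degenerate permuted splits never exceed
  p <- (1 + sum(cmp(w_perm) >= cmp(w_obs) - eps)) / (B + 1)
  list(w = w_obs, p = p, exhaustive = FALSE, n_used = B)
}

#' Integrate copy-number calls with expression, feature by feature
#'
#' For each feature, samples are partitioned by amplification status (from
#' the called segments overlapping the feature span) and the weight
#' statistic plus permutation P is computed. Ambiguous samples (overlapping
#' both gain and loss segments) are excluded. With `direction = "loss"`, the
#' mirrored statistic is computed for deletion-underexpression: the mask
#' marks lost samples and the sign of `w` is flipped, so large `w` again
#' means the aberration explains the expression change.
#'
#' @param expr Features x samples expression matrix (tumor samples).
#' @param called_segments Called segment table over the same samples.
#' @param features `data.frame` with `feature`, `chrom`, `start`, `end`;
#'   `feature` must match `rownames(expr)`.
#' @param direction `"gain"` (amplification-overexpression, default) or
#'   `"loss"` (deletion-underexpression).
#' @param n_permutations,exhaustive_limit,two_sided Passed to
#'   [permutation_pvalue()].
#' @return `data.frame` with `feature`, `w`, `p_perm`, `gain_freq`,
#'   `loss_freq`, `n_amplified`, `n_nonamplified`, `selected`.
#' @export
integrate_cn_expression <- function(expr, called_segments, features,
                                    direction = c("gain", "loss"),
                                    n_permutations = 10000L,
                                    exhaustive_limit = 10000L,
                                    two_sided = FALSE) {
  direction <- match.arg(direction)
  samples <- colnames(expr)
  freqs <- aberration_frequencies(called_segments, features,
                                  n_samples = length(samples))
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    status <- feature_aberration_status(called_segments, f, samples)
    use <- status != "ambiguous"
    mask <- status[use] == direction
    vals <- expr[f$feature, samples[use]]
    if (direction == "loss") vals <- -vals
    pr <- permutation_pvalue(vals, mask, n_permutations = n_permutations,
                             exhaustive_limit = exhaustive_limit,
                             two_sided = two_sided)
    data.frame(feature = f$feature, w = pr$w, p_perm = pr$p,
               n_amplified = sum(mask), n_nonamplified = sum(!mask),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, freqs[, c("feature", "gain_freq", "loss_freq")],
               by = "feature", sort = FALSE)
  out$selected <- out$feature %in% select_amplification_driven(out,
    freq_col = if (direction == "gain") "gain_freq" else "loss_freq")
  rownames(out) <- NULL
  out
}

#' Select features whose aberration explains their expression change
#'
#' Keeps features with permutation P < 0.01 and aberration frequency > 5%.
#'
#' @param results `data.frame` with `feature`, `p_perm` and a frequency
#'   column.
#' @param p_threshold P gate (default 0.01).
#' @param freq_threshold Frequency gate (default 0.05).
#' @param freq_col Which frequency column to gate on (default `gain_freq`).
#' @return Character vector of selected feature ids.
#' @export
select_amplification_driven <- function(results, p_threshold = 0.01,
                                        freq_threshold = 0.05,
                                        freq_col = "gain_freq") {
  keep <- !is.na(results$p_perm) & results$p_perm < p_threshold &
    results[[freq_col]] > freq_threshold
  results$feature[keep]
}
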