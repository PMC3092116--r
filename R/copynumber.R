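#' Segment an aCGH probe profile by circular binary segmentation
#'
#' Recursive change-point search on each chromosome: the maximal standardized
#' circular arc statistic is computed over all admissible arcs, its
#' significance assessed by permutation, and significant splits recursed
#' until no segment can be split further. Segment means are the means of the
#' member probes.
#'
#' @param profile `data.frame` with columns `chrom`, `pos`, `logratio` (one
#'   sample), positions sorted within chromosome.
#' @param alpha Permutation significance level for accepting a split
#'   (default 0.01).
#' @param min_width Minimum segment width in probes (default 3).
#' @param nperm Number of permutations per tested segment (default 1000).
#' @param sample_id Optional sample id recorded in the output.
#' @return Uncalled segment table: `data.frame` with `sample`, `chrom`,
#'   `start`, `end` (probe positions, inclusive), `n_probes`, `seg_mean`.
#'   Uses the RNG, so wrap in `set.seed()` for reproducibility.
#' @export
segment_profile <- function(profile, alpha = 0.01, min_width = 3L,
                            nperm = 1000L, sample_id = NA_character_) {
  stopifnot(all(c("chrom", "pos", "logratio") %in% names(profile)))
  out <- lapply(split(profile, profile$chrom), function(ch) {
    if (is.unsorted(ch$pos, strictly = TRUE))
      stop("probe positions must be sorted and unique within chromosome",
           call. = FALSE)
    if (nrow(ch) < 2L)
      stop("need >= 2 probes per chromosome", call. = FALSE)
    x <- ch$logratio
    bounds <- cbs_recurse(x, alpha, min_width, nperm)
    data.frame(sample = sample_id,
               chrom = ch$chrom[1],
               start = ch$pos[bounds$first],
               end = ch$pos[bounds$last],
               n_probes = bounds$last - bounds$first + 1L,
               seg_mean = vapply(seq_along(bounds$first), function(i)
                 mean(x[bounds$first[i]:bounds$last[i]]), 0.0),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Internal: recursive CBS on a numeric vector; returns parallel vectors of
# first/last probe indices for each segment.
cbs_recurse <- function(x, alpha, min_width, nperm) {
  segments <- list()
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * min_width) {
      segments[[length(segments) + 1L]] <<- c(lo, hi)
      return(invisible())
    }
    res <- cbs_test_segment(x[lo:hi], as.integer(min_width),
                            as.integer(nperm), alpha)
    if (!isTRUE(res$significant)) {
      segments[[length(segments) + 1L]] <<- c(lo, hi)
      return(invisible())
    }
    i <- res$i  # 0-based boundaries of the arc within [lo, hi]
    j <- res$j
    if (i > 0L) recurse(lo, lo + i - 1L)
    recurse(lo + i, lo + j - 1L)
    if (lo + j <= hi) recurse(lo + j, hi)
  }
  recurse(1L, length(x))
  m <- do.call(rbind, segments)
  m <- m[order(m[, 1]), , drop = FALSE]
  list(first = m[, 1], last = m[, 2])
}

#' Estimate gain/loss thresholds from control arrays
#'
#' Thresholds are mean +/- 2 standard deviations of the pooled control probe
#' log-ratios (all control arrays pooled). Degenerate controls (zero spread)
#' or absent controls fall back to the defaults +/- 0.632 with a warning.
#'
#' @param control_logratios Numeric vector (or list of vectors, one per
#'   control array) of normalized control probe log-ratios.
#' @param default_upper Fallback upper threshold (default 0.632).
#' @return List with `upper`, `lower`.
#' @export
estimate_thresholds <- function(control_logratios,
                                default_upper = 0.632) {
  defaults <- list(upper = default_upper, lower = -default_upper)
  if (is.list(control_logratios))
    control_logratios <- unlist(control_logratios, use.names = FALSE)
  control_logratios <- control_logratios[is.finite(control_logratios)]
  if (length(control_logratios) < 2L) {
    warning("no usable control probes; using default thresholds +/- ",
            default_upper)
    return(defaults)
  }
  m <- mean(control_logratios)
  s <- sd(control_logratios)
  if (s <= 0) {
    warning("control probes have zero spread; using default thresholds +/- ",
            default_upper)
    return(defaults)
  }
  list(upper = m + 2 * s, lower = m - 2 * s)
}

#' Call gains and losses on a segment table
#'
#' A segment is a gain when its mean is strictly above the upper threshold,
#' a loss when strictly below the lower threshold, else neutral.
#'
#' @param segments Segment table from [segment_profile()].
#' @param thresholds List with `upper`, `lower` (see [estimate_thresholds()]).
#' @return The segment table with a `call` column in
#'   `c("gain", "loss", "neutral")`.
#' @export
call_aberrations <- function(segments, thresholds) {
  if (!(thresholds$lower < 0 && 0 < thresholds$upper))
    stop("thresholds must satisfy lower < 0 < upper", call. = FALSE)
  segments$call <- ifelse(segments$seg_mean > thresholds$upper, "gain",
                          ifelse(segments$seg_mean < thresholds$lower,
                                 "loss", "neutral"))
  segments
}

#' Per-feature gain and loss frequencies across samples
#'
#' For each feature (gene or transcript span), each sample contributes one
#' status by any-base overlap with its called segments: gain if at least one
#' overlapping segment is a gain and none is a loss, loss symmetrically,
#' ambiguous (excluded from both counts) when both occur, neutral otherwise.
#' Samples with no covering segment count as neutral.
#'
#' @param called_segments Called segment table over all samples
#'   (columns `sample`, `chrom`, `start`, `end`, `call`).
#' @param features `data.frame` with `feature`, `chrom`, `start`, `end`.
#' @param n_samples Total number of samples in the denominator; defaults to
#'   the number of distinct samples in `called_segments`.
#' @return `data.frame` with `feature`, `gain_freq`, `loss_freq`,
#'   `n_ambiguous`.
#' @export
aberration_frequencies <- function(called_segments, features,
                                   n_samples = NULL) {
  if (is.null(n_samples))
    n_samples <- length(unique(called_segments$sample))
  res <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    ov <- called_segments[called_segments$chrom == f$chrom &
                            called_segments$start <= f$end &
                            called_segments$end >= f$start, ]
    gain_samples <- unique(ov$sample[ov$call == "gain"])
    loss_samples <- unique(ov$sample[ov$call == "loss"])
    ambiguous <- intersect(gain_samples, loss_samples)
    data.frame(feature = f$feature,
               gain_freq = length(setdiff(gain_samples, ambiguous)) / n_samples,
               loss_freq = length(setdiff(loss_samples, ambiguous)) / n_samples,
               n_ambiguous = length(ambiguous),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-sample aberration status of one feature
#'
#' Helper used by the integration stage to build the amplified /
#' non-amplified sample partition for a feature.
#'
#' @param called_segments Called segment table over all samples.
#' @param feature One-row `data.frame` with `chrom`, `start`, `end`.
#' @param samples Character vector of all sample ids (defines the output
#'   order; samples without a covering segment are neutral).
#' @return Named character vector over `samples` with values
#'   `"gain"`, `"loss"`, `"neutral"` or `"ambiguous"`.
#' @export
feature_aberration_status <- function(called_segments, feature, samples) {
  ov <- called_segments[called_segments$chrom == feature$chrom &
                          called_segments$start <= feature$end &
                          called_segments$end >= feature$start, ]
  status <- setNames(rep("neutral", length(samples)), samples)
  gain_samples <- unique(ov$sample[ov$call == "gain"])
  loss_samples <- unique(ov$sample[ov$call == "loss"])
  both <- intersect(gain_samples, loss_samples)
  status[setdiff(gain_samples, both)] <- "gain"
  status[setdiff(loss_samples, both)] <- "loss"
  status[both] <- "ambiguous"
  status
}
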