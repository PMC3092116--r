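# Shared fixture builders. Everything is generated in code; no data files.

# Tiny two-transcript annotation: T1 = {a, b}, T2 = {b, c}.
tiny_annotation <- function(gene = "GX") {
  data.frame(
    gene_id = gene,
    transcript_id = rep(c("T1", "T2"), each = 2),
    exon_id = c("a", "b", "b", "c"),
    chrom = "chr1",
    start = c(0L, 300L, 300L, 600L),
    end = c(200L, 500L, 500L, 800L),
    strand = "+", stringsAsFactors = FALSE)
}

# Random full-rank binary incidence matrix with m rows, n columns.
random_incidence <- function(m, n) {
  repeat {
    A <- matrix(rbinom(m * n, 1, 0.5), m, n)
    A[rowSums(A) == 0, sample(n, 1)] <- 1L
    if (qr(A)$rank == n) return(A)
  }
}

# Normal-equations least-squares oracle, independent of the solver path.
normal_equations_solve <- function(A, e) {
  drop(solve(t(A) %*% A, t(A) %*% e))
}

# One screen plate laid out deterministically: first wells are controls,
# rest samples, with a caller-supplied signal function of (row, col).
make_plate <- function(signal_fun, rows = 16, cols = 24, noise_sd = 0,
                       plate = "P1") {
  wells <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  wells$plate <- plate
  wells$role <- "sample"
  wells$role[1:12] <- "negative"
  wells$sirna <- NA_character_
  wells$sirna[1:12] <- "siNEG"
  wells$sirna[wells$role == "sample"] <-
    paste0("si", seq_len(sum(wells$role == "sample")))
  wells$gene <- NA_character_
  wells$signal <- signal_fun(wells$row, wells$col) +
    rnorm(nrow(wells), 0, noise_sd)
  wells
}

# Small survival cohort: two exponential arms with a given hazard ratio.
two_arm_cohort <- function(n_per_arm, hr, baseline = 0.05) {
  lp <- rep(c(0, log(hr)), each = n_per_arm)
  cl <- generate_survival(lp, baseline_hazard = baseline)
  cl$arm <- rep(c("low", "high"), each = n_per_arm)
  cl
}
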