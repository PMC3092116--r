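test_that("transcript deconvolution solves hand-checked systems", {
  # shared exon pair, oracle (A'A)^-1 A'e = 4
  r1 <- solve_transcripts(matrix(1, 2, 1), c(3, 5))
  expect_equal(unname(r1$t), 4)

  # identity incidence returns the exon values
  r2 <- solve_transcripts(diag(2), c(2, 7))
  expect_equal(unname(r2$t), c(2, 7))

  # overlapping structure with exact solution and zero residual
  A <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2)
  r3 <- solve_transcripts(A, c(2, 5, 3))
  expect_equal(unname(r3$t), c(2, 3))
  expect_equal(r3$residual, 0)
  expect_false(r3$rank_deficient)

  expect_error(solve_transcripts(A, c(1, 2)), "dimension mismatch")
})

test_that("rank-deficient incidence yields a flagged minimum-norm solution", {
  A <- matrix(c(1, 1, 1, 1), 2, 2)  # identical transcripts
  r <- solve_transcripts(A, c(2, 4))
  expect_true(r$rank_deficient)
  # minimum-norm solution splits the signal evenly
  expect_equal(unname(r$t), c(1.5, 1.5))
  expect_equal(r$residual, sqrt(2))
})

test_that("least-squares solution and residual match the normal-equations oracle", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(1:4, 1)
    m <- sample(n:8, 1)
    A <- random_incidence(m, n)
    e <- rnorm(m, 10, 4)
    got <- solve_transcripts(A, e)
    want <- normal_equations_solve(A, e)
    expect_equal(unname(got$t), unname(want), tolerance = 1e-8)
    expect_equal(got$residual, sqrt(sum((A %*% want - e)^2)),
                 tolerance = 1e-8)
  }
})

test_that("gene-level summaries are exon medians with midpoint convention", {
  m <- rbind(e1 = c(1, 1), e2 = c(2, 3), e3 = c(9, 9))
  colnames(m) <- c("s1", "s2")
  map <- data.frame(gene_id = c("G1", "G1", "G1", "G2"),
                    exon_id = c("e1", "e2", "e3", "e1"))
  g <- gene_level_from_exons(m, map)
  expect_equal(g["G1", ], c(s1 = 2, s2 = 3))   # odd count median
  expect_equal(g["G2", ], c(s1 = 1, s2 = 1))   # single exon passthrough
  g2 <- gene_level_from_exons(m[1:2, ], data.frame(gene_id = "G",
                                                   exon_id = c("e1", "e2")))
  expect_equal(unname(g2["G", 2]), 2)          # even count midpoint (1,3) -> 2

  expect_warning(
    gene_level_from_exons(m, rbind(map, data.frame(gene_id = "G9",
                                                   exon_id = "missing"))),
    "zero measured exons")
})

test_that("fold changes follow the mean-ratio definition", {
  expect_equal(fold_change(c(6, 6), c(3, 3)), 2)
  expect_equal(fold_change(c(5, 5), c(5, 5)), 1)
  expect_equal(fold_change(c(1, 2), c(4, 4)), 0.375)
  expect_warning(fc <- fold_change(c(1, 2), c(0, 0)), "undefined")
  expect_true(is.na(fc))

  expect_equal(per_sample_fold_change(8, 4), 2)
  expect_equal(per_sample_fold_change(4, 4), 1)
  expect_equal(per_sample_fold_change(1, 4), 0.25)
})

test_that("differential expression computes Welch t, BH adjustment and flags", {
  # BH step-up checked by hand: (0.01, 0.02, 0.04) -> (0.03, 0.03, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))

  set.seed(5)
  n_t <- 40; n_c <- 40
  mat <- rbind(null1 = rnorm(n_t + n_c, 10),
               up = c(rnorm(n_t, 40), rnorm(n_c, 10)),
               flat = rep(3, n_t + n_c))
  roles <- rep(c("tumor", "control"), c(n_t, n_c))
  de <- differential_expression(mat, roles)
  # per-feature agreement with stats::t.test (Welch)
  ref <- t.test(mat["up", roles == "tumor"], mat["up", roles == "control"],
                var.equal = FALSE)
  expect_equal(de$p[de$feature == "up"], ref$p.value)
  expect_equal(de$t[de$feature == "up"], unname(ref$statistic))
  expect_true(de$adj_p[de$feature == "null1"] > 0.5)
  expect_true(de$flag_zero_variance[de$feature == "flat"])
  expect_true(is.na(de$p[de$feature == "flat"]))
  expect_true(all(de$adj_p >= de$p, na.rm = TRUE))
})

test_that("DET selection applies the symmetric fold-change and adjusted-P gates", {
  de <- data.frame(feature = c("a", "b", "c", "d"),
                   fc = c(2.5, 0.4, 1.5, 3.0),
                   adj_p = c(0.03, 0.01, 0.001, 0.2))
  expect_equal(select_dets(de), c("a", "b"))  # 'c' fails FC, 'd' fails P
})

test_that("null-noise cohorts recover ground-truth transcript values exactly", {
  cfg <- cohort_config(n_tumor = 15, n_control = 5, n_genes = 8,
                       exon_noise_sd = 0, n_markers = 10,
                       n_cn_probes_per_chrom = 20, n_cn_controls = 2,
                       n_screen_genes = 4, seed = 3)
  co <- generate_cohort(cfg)
  tx <- cohort_transcript_expression(co$exon_matrix, co$incidences)
  expect_equal(length(tx$rank_deficient_genes), 0L)
  for (g in names(co$incidences)) {
    mu <- co$ground_truth$transcript_mu[[g]]
    got <- tx$transcript_matrix[names(mu), , drop = FALSE]
    expect_equal(got, matrix(rep(mu, ncol(got)), nrow = length(mu),
                             dimnames = dimnames(got)),
                 tolerance = 1e-8)
  }
  # and the exon matrix itself equals A %*% t exactly
  inc <- co$incidences[[1]]
  expect_equal(
    co$exon_matrix[inc$exon_ids, ],
    inc$A %*% tx$transcript_matrix[inc$transcript_ids, , drop = FALSE],
    tolerance = 1e-12)
})
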