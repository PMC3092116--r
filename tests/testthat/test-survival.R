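test_that("Kaplan-Meier estimates match hand product-limit computations", {
  # three deaths, no censoring: S = 2/3, 1/3, 0
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  # a single censored patient leaves the curve at 1
  km1 <- kaplan_meier(5, 0)
  expect_equal(km1$surv, 1)

  # mixed: deaths at 1 and 3, censored at 2; risk set shrinks to 1 at t = 3
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2/3)
  expect_equal(km2$surv[km2$time == 3], 0)

  expect_error(kaplan_meier(numeric(0), numeric(0)), "no usable")
})

test_that("KM at the last event time equals the empirical survival fraction", {
  set.seed(8)
  t <- rexp(40, 0.1)
  km <- kaplan_meier(t, rep(1, 40))
  expect_equal(km$surv[which.max(km$time)], 0)
  # at any event time with no censoring, S(t) = fraction surviving beyond t
  mid <- km$time[20]
  expect_equal(km$surv[km$time == mid], mean(t > mid))
})

test_that("log-rank matches the hand-built O/E/V table and is scale invariant", {
  t <- c(1, 3, 2, 4); ev <- rep(1, 4); g <- c("A", "A", "B", "B")
  lr <- logrank_test(t, ev, g)
  expect_equal(lr$chisq, 0.6153846, tolerance = 1e-6)
  expect_equal(lr$df, 1L)

  # identical groups: statistic 0, P = 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # invariance under common time rescaling
  set.seed(2)
  tt <- rexp(60, 0.1); evv <- rbinom(60, 1, 0.8); gg <- rep(c("A", "B"), 30)
  expect_equal(logrank_test(tt, evv, gg)$chisq,
               logrank_test(tt * 12, evv, gg)$chisq)

  expect_error(logrank_test(t, ev, rep("A", 4)), ">= 2 nonempty groups")
})

test_that("fold-change discretization and the group-size filter follow the rules", {
  expect_equal(discretize_fc(c(0.4, 2.5, 1.0, NA)), c(-1L, 1L, 0L, NA))

  # 19 patients in the overexpressed class -> class dropped, feature skipped
  set.seed(31)
  n <- 219
  cl <- generate_survival(rep(0, n), 0.05, patient_ids = sprintf("P%03d", 1:n))
  fc <- matrix(c(rep(2.5, 19), rep(1, 200)), 1,
               dimnames = list("f1", cl$patient_id))
  res <- expression_survival_screen(fc, cl)
  expect_true(is.na(res$p))
  expect_equal(res$n_groups, 1L)

  # 20 patients in the class -> tested
  fc2 <- matrix(c(rep(2.5, 20), rep(1, 199)), 1,
                dimnames = list("f1", cl$patient_id))
  res2 <- expression_survival_screen(fc2, cl)
  expect_false(is.na(res2$p))
  expect_equal(res2$n_groups, 2L)
})

test_that("a planted overexpression survival effect is detected", {
  set.seed(77)
  cfg <- cohort_config(n_tumor = 200, n_control = 10, n_genes = 10,
                       planted_effects = list(list(gene = "G03",
                                                   platform = "expression",
                                                   hr = 3, fc = 5,
                                                   frac = 0.4)),
                       n_markers = 20, n_cn_probes_per_chrom = 20,
                       n_cn_controls = 2, n_screen_genes = 4, seed = 77)
  co <- generate_cohort(cfg)
  tx <- cohort_transcript_expression(co$exon_matrix, co$incidences)
  cm <- rowMeans(tx$transcript_matrix[, co$roles$sample[co$roles$role == "control"]])
  tum <- co$roles$sample[co$roles$role == "tumor"]
  fc <- tx$transcript_matrix[, tum] / cm
  g3_tx <- grep("^G03_", rownames(fc), value = TRUE)
  res <- expression_survival_screen(fc[g3_tx, , drop = FALSE], co$clinical)
  expect_true(any(res$p < 0.01))
})

test_that("SNP screen applies QC, MAF, merging and study-time rules", {
  set.seed(12)
  n <- 200
  pats <- sprintf("P%03d", 1:n)
  cl <- generate_survival(rep(0, n), 0.03, patient_ids = pats)
  # marker m1: AA=100, AB=50, BB=10 -> rare homozygote merged into AB
  calls1 <- rep(c("AA", "AB", "BB"), c(100, 50, 10))
  # marker m2: AA=180, AB=18, BB=2 -> MAF 0.055 -> excluded
  calls2 <- rep(c("AA", "AB", "BB"), c(180, 18, 2))
  geno <- rbind(
    data.frame(marker = "m1", patient = pats[1:160], call = calls1,
               prob = 1, stringsAsFactors = FALSE),
    data.frame(marker = "m2", patient = pats, call = calls2, prob = 1,
               stringsAsFactors = FALSE))
  out <- snp_survival_screen(geno, cl)
  r1 <- out$results[out$results$marker == "m1", ]
  expect_equal(r1$groups, "AA,AB")     # BB (n=10 < 15) merged into AB
  r2 <- out$results[out$results$marker == "m2", ]
  expect_equal(r2$maf, 0.055)
  expect_true(is.na(r2$p))             # excluded from survival testing

  # events beyond 36 months are analyzed as censored at 36
  cl36 <- data.frame(patient_id = pats[1:40],
                     months = c(rep(10, 20), rep(48, 20)),
                     event = 1L)
  geno36 <- data.frame(marker = "m3", patient = pats[1:40],
                       call = rep(c("AA", "AB"), 20), prob = 1,
                       stringsAsFactors = FALSE)
  out36 <- snp_survival_screen(geno36, cl36)
  # survdiff on the truncated data must match manual administrative censoring
  manual <- logrank_test(pmin(cl36$months, 36),
                         ifelse(cl36$months > 36, 0L, 1L),
                         rep(c("AA", "AB"), 20))
  expect_equal(out36$results$chisq[out36$results$marker == "m3"],
               manual$chisq)

  # call-probability filter blanks low-confidence calls: the only BB calls
  # are low-confidence, so after filtering the marker has two groups, not 3
  geno_lp <- data.frame(marker = "m4", patient = pats,
                        call = rep(c("BB", "AA", "AB"), c(20, 90, 90)),
                        prob = c(rep(0.5, 20), rep(1, 180)),
                        stringsAsFactors = FALSE)
  out_lp <- snp_survival_screen(geno_lp, cl)
  expect_equal(out_lp$results$groups[out_lp$results$marker == "m4"], "AA,AB")

  # sample SNR filter drops whole samples: the heterozygotes all come from
  # low-SNR samples, leaving a monomorphic marker that is skipped
  geno_snr <- data.frame(marker = "m5", patient = pats,
                         call = rep(c("AB", "AA"), each = 100), prob = 1,
                         stringsAsFactors = FALSE)
  snr <- setNames(c(rep(2, 100), rep(20, 100)), pats)
  out_snr <- snp_survival_screen(geno_snr, cl, sample_snr = snr)
  expect_true(is.na(out_snr$results$p[out_snr$results$marker == "m5"]))
})

test_that("null genotypes produce about the expected number of chance hits", {
  set.seed(999)
  n <- 200
  pats <- sprintf("P%03d", 1:n)
  cl <- generate_survival(rep(0, n), 0.04, censoring_rate = 0.1,
                          horizon = 60, patient_ids = pats)
  n_markers <- 5000
  q <- runif(n_markers, 0.15, 0.45)
  geno <- data.frame(
    marker = rep(sprintf("M%04d", 1:n_markers), each = n),
    patient = rep(pats, n_markers),
    call = unlist(lapply(q, function(qq)
      sample(c("AA", "AB", "BB"), n, TRUE,
             prob = c((1 - qq)^2, 2 * qq * (1 - qq), qq^2)))),
    prob = 1, stringsAsFactors = FALSE)
  out <- snp_survival_screen(geno, cl)
  # expected count at P < 1e-4 is ~0.5; a Poisson bound allows at most 3
  expect_lte(nrow(out$hits), 3L)
})
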