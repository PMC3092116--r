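small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_tumor = 25, n_control = 6, n_genes = 8, n_markers = 15,
         n_cn_probes_per_chrom = 24, n_cn_controls = 3, n_screen_genes = 4),
    list(...))
  do.call(cohort_config, args)
}

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_tumor = 0), "n_tumor")
  expect_error(cohort_config(censoring_rate = 1.5), "censoring_rate")
  expect_error(cohort_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(cohort_config(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(cohort_config(planted_effects = list(list(gene = "G01",
                                                         platform = "bogus"))),
               "planted_effects")
  expect_error(cohort_config(planted_effects = list(
    list(gene = "G01", platform = "expression", hr = -2))),
    "hazard ratios")
})

test_that("the same configuration and seed reproduce the cohort byte for byte", {
  co1 <- generate_cohort(small_cfg(seed = 99))
  co2 <- generate_cohort(small_cfg(seed = 99))
  expect_identical(co1, co2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the data
  co3 <- generate_cohort(small_cfg(seed = 100))
  expect_false(identical(co1$exon_matrix, co3$exon_matrix))
})

test_that("cohort tables share identifier namespaces (referential integrity)", {
  co <- generate_cohort(small_cfg(seed = 5))
  expect_setequal(rownames(co$exon_matrix), co$annotation$exon_id)
  expect_setequal(co$clinical$patient_id,
                  co$roles$sample[co$roles$role == "tumor"])
  expect_true(all(co$cn_probes$sample %in% co$clinical$patient_id))
  expect_true(all(co$genotypes$patient %in% co$clinical$patient_id))
  expect_setequal(co$gene_coords$feature, unique(co$annotation$gene_id))
  expect_true(all(co$methylation$gene %in% co$gene_coords$feature))
  expect_true(all(na.omit(co$plates$gene) %in% co$gene_coords$feature))
  # incidence matrices are full column rank by construction
  expect_true(all(vapply(co$incidences, `[[`, TRUE, "full_rank")))
})

test_that("survival generation matches the exponential model", {
  set.seed(55)
  # null predictor, no censoring: empirical median ~ ln(2)/baseline
  cl <- generate_survival(rep(0, 2000), baseline_hazard = 0.05)
  expect_true(all(cl$event == 1))
  expect_lt(abs(median(cl$months) - log(2) / 0.05) / (log(2) / 0.05), 0.1)

  # censoring rate 1: every record censored
  cl1 <- generate_survival(rep(0, 100), 0.05, censoring_rate = 1,
                           horizon = 60)
  expect_true(all(cl1$event == 0))

  # administrative censoring caps observed times at the horizon
  cl2 <- generate_survival(rep(-3, 200), 0.05, horizon = 12)
  expect_true(all(cl2$months <= 12))
  expect_true(all(cl2$event[cl2$months == 12] == 0))

  expect_error(generate_survival(0, baseline_hazard = -1), "baseline_hazard")
  expect_error(generate_survival(0, 0.05, horizon = 0), "horizon")
})

test_that("a hazard ratio of 2 separates the KM curves in the right direction", {
  set.seed(66)
  ok <- vapply(1:20, function(i) {
    cl <- two_arm_cohort(500, hr = 2)
    km_lo <- kaplan_meier(cl$months[cl$arm == "low"],
                          cl$event[cl$arm == "low"])
    km_hi <- kaplan_meier(cl$months[cl$arm == "high"],
                          cl$event[cl$arm == "high"])
    s_lo <- stepfun(km_lo$time, c(1, km_lo$surv))
    s_hi <- stepfun(km_hi$time, c(1, km_hi$surv))
    grid <- quantile(cl$months[cl$event == 1], c(0.2, 0.4, 0.6, 0.8))
    all(s_hi(grid) < s_lo(grid))
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("planted copy-number segments appear in probes and ground truth", {
  cfg <- small_cfg(seed = 8, n_tumor = 40,
                   planted_effects = list(list(gene = "G03", platform = "cn",
                                               logratio = 0.9, frac = 0.5,
                                               fc = 4, hr = 2)))
  co <- generate_cohort(cfg)
  gt <- co$ground_truth$aberrant_segments
  expect_equal(nrow(gt), 20L)  # 50% of 40 samples
  # probes inside the planted span are elevated for affected samples
  s <- gt$sample[1]
  probes <- co$cn_probes[co$cn_probes$sample == s &
                           co$cn_probes$chrom == gt$chrom[1] &
                           co$cn_probes$pos >= gt$start[1] &
                           co$cn_probes$pos <= gt$end[1], ]
  expect_gt(mean(probes$logratio), 0.5)
  # overexpressed samples coincide with the amplified samples
  expect_setequal(co$ground_truth$overexpressed_samples[["G03"]], gt$sample)
})

test_that("a null cohort drives the expression survival screen to nominal rates", {
  co <- generate_cohort(cohort_config(n_tumor = 150, n_control = 8,
                                      n_genes = 25, n_markers = 10,
                                      n_cn_probes_per_chrom = 20,
                                      n_cn_controls = 2, n_screen_genes = 4,
                                      seed = 202))
  tx <- cohort_transcript_expression(co$exon_matrix, co$incidences)
  ctrl <- co$roles$sample[co$roles$role == "control"]
  tum <- co$roles$sample[co$roles$role == "tumor"]
  de <- differential_expression(tx$transcript_matrix,
                                ifelse(colnames(tx$transcript_matrix) %in% tum,
                                       "tumor", "control"))
  # nothing is planted: no transcript passes the DET gates
  expect_length(select_dets(de), 0L)
  # raw P-values are roughly uniform: about 5% below 0.05
  expect_lt(mean(de$p < 0.05), 0.15)
})
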