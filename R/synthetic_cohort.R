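#' Configuration for a synthetic multi-platform cohort
#'
#' Bundles and validates every knob of the cohort generator. The defaults
#' emulate the platform roster of a glioblastoma cohort at desk scale:
#' a large tumor arm with ten non-cancer control samples on the expression
#' platforms, exon intensities generated from known transcript values
#' through the gene's exon-transcript incidence structure, exponential
#' proportional-hazards survival with administrative censoring, aCGH probe
#' profiles with planted gain/loss segments, Hardy-Weinberg genotypes, and
#' 384-well screen plates with a smooth spatial background.
#'
#' @param n_tumor Tumor samples (default 200).
#' @param n_control Control samples (default 10).
#' @param n_genes Genes (default 40).
#' @param transcripts_per_gene Integer range, transcripts drawn per gene
#'   (default `c(1, 3)`).
#' @param exon_noise_sd Additive Gaussian noise on exon intensities
#'   (default 0.5, intensity scale).
#' @param baseline_hazard Exponential baseline hazard per month (default
#'   `log(2)/12`: a 12-month median survival under no effect).
#' @param censoring_rate Probability of independent uniform censoring on
#'   `[0, horizon]` (default 0.1).
#' @param study_horizon Administrative censoring horizon in months
#'   (default 60).
#' @param planted_effects List of planted effects; each element is a list
#'   with `gene`, `platform` (`"expression"`, `"snp"` or `"cn"`) and effect
#'   fields: `hr` (hazard ratio of affected patients), `fc` (expression
#'   multiplier, expression/cn platforms), `frac` (fraction of tumor samples
#'   affected), `logratio` (cn segment mean), `maf` (snp minor allele
#'   frequency).
#' @param maf_range Minor-allele-frequency range for background markers
#'   (default `c(0.1, 0.5)`).
#' @param n_markers SNP markers (default 200).
#' @param n_cn_probes_per_chrom aCGH probes per chromosome (default 120).
#' @param n_chrom Chromosomes in the synthetic genome (default 2).
#' @param n_cn_controls Blood-vs-blood control arrays (default 64).
#' @param cn_noise_sd Gaussian probe noise on log-ratios (default 0.15).
#' @param n_mirna miRNAs (default 30).
#' @param plate_rows,plate_cols Plate layout (default 16 x 24).
#' @param plate_replicates Replicate wells per siRNA (default 3).
#' @param n_screen_genes Genes carried into the siRNA screen (default 11).
#' @param sirnas_per_gene siRNA constructs per gene (default 4).
#' @param cell_lines Cell-line labels for the screen (default 4 lines).
#' @param seed Integer RNG seed.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_tumor = 200L, n_control = 10L, n_genes = 40L,
                          transcripts_per_gene = c(1L, 3L),
                          exon_noise_sd = 0.5,
                          baseline_hazard = log(2) / 12,
                          censoring_rate = 0.1, study_horizon = 60,
                          planted_effects = list(),
                          maf_range = c(0.1, 0.5), n_markers = 200L,
                          n_cn_probes_per_chrom = 120L, n_chrom = 2L,
                          n_cn_controls = 64L, cn_noise_sd = 0.15,
                          n_mirna = 30L, plate_rows = 16L, plate_cols = 24L,
                          plate_replicates = 3L, n_screen_genes = 11L,
                          sirnas_per_gene = 4L,
                          cell_lines = paste0("CL", 1:4), seed = 1L) {
  cfg <- list(
    n_tumor = check_count(n_tumor, "n_tumor"),
    n_control = check_count(n_control, "n_control"),
    n_genes = check_count(n_genes, "n_genes"),
    transcripts_per_gene = c(check_count(transcripts_per_gene[1],
                                         "transcripts_per_gene"),
                             check_count(transcripts_per_gene[2],
                                         "transcripts_per_gene")),
    exon_noise_sd = check_real(exon_noise_sd, "exon_noise_sd", lower = 0),
    baseline_hazard = check_real(baseline_hazard, "baseline_hazard",
                                 lower = 1e-12),
    censoring_rate = check_real(censoring_rate, "censoring_rate", 0, 1),
    study_horizon = check_real(study_horizon, "study_horizon", lower = 1e-9),
    planted_effects = planted_effects,
    maf_range = c(check_real(maf_range[1], "maf_range", 0, 1),
                  check_real(maf_range[2], "maf_range", 0, 1)),
    n_markers = check_count(n_markers, "n_markers"),
    n_cn_probes_per_chrom = check_count(n_cn_probes_per_chrom,
                                        "n_cn_probes_per_chrom", min = 10L),
    n_chrom = check_count(n_chrom, "n_chrom"),
    n_cn_controls = check_count(n_cn_controls, "n_cn_controls", min = 2L),
    cn_noise_sd = check_real(cn_noise_sd, "cn_noise_sd", lower = 0),
    n_mirna = check_count(n_mirna, "n_mirna"),
    plate_rows = check_count(plate_rows, "plate_rows"),
    plate_cols = check_count(plate_cols, "plate_cols"),
    plate_replicates = check_count(plate_replicates, "plate_replicates",
                                   min = 2L),
    n_screen_genes = check_count(n_screen_genes, "n_screen_genes"),
    sirnas_per_gene = check_count(sirnas_per_gene, "sirnas_per_gene"),
    cell_lines = as.character(cell_lines),
    seed = check_count(seed, "seed", min = 0L))
  if (cfg$transcripts_per_gene[1] > cfg$transcripts_per_gene[2])
    fail_field("transcripts_per_gene", "range must be increasing")
  if (cfg$maf_range[1] > cfg$maf_range[2])
    fail_field("maf_range", "range must be increasing")
  for (eff in cfg$planted_effects) {
    if (is.null(eff$gene) || is.null(eff$platform) ||
        !eff$platform %in% c("expression", "snp", "cn"))
      fail_field("planted_effects",
                 "each effect needs 'gene' and platform in expression/snp/cn")
    if (!is.null(eff$hr) && eff$hr <= 0)
      fail_field("planted_effects", "hazard ratios must be > 0")
  }
  if (cfg$n_screen_genes > cfg$n_genes)
    fail_field("n_screen_genes", "cannot exceed n_genes")
  structure(cfg, class = "cohort_config")
}

#' A representative planted-effect set
#'
#' One gene overexpressed in a patient subset with a survival effect
#' (hazard ratio 3), one gene whose amplification drives overexpression, and
#' one SNP with a survival effect. Used by the end-to-end pipeline runs.
#'
#' @param expr_gene,cn_gene,snp_gene Gene ids (defaults pick three distinct
#'   genes of the default 40-gene cohort).
#' @return List of planted-effect descriptors for [cohort_config()].
#' @export
default_planted_effects <- function(expr_gene = "G05", cn_gene = "G12",
                                    snp_gene = "G20") {
  list(
    list(gene = expr_gene, platform = "expression", hr = 3, fc = 5,
         frac = 0.4),
    list(gene = cn_gene, platform = "cn", logratio = 0.9, frac = 0.5,
         fc = 4, hr = 3),
    list(gene = snp_gene, platform = "snp", hr = 2, maf = 0.3))
}

#' Draw survival records from an exponential proportional-hazards model
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(linear_predictor)`. Censoring is administrative at
#' the study horizon plus, with probability `censoring_rate`, an independent
#' uniform censoring time on `[0, horizon]` (last follow-up before the
#' horizon). The event indicator is 1 = death, 0 = censored.
#'
#' @param linear_predictor Numeric vector, one value per patient (log hazard
#'   ratio scale).
#' @param baseline_hazard Positive baseline hazard per month.
#' @param censoring_rate Probability in `[0, 1]` of uniform censoring.
#' @param horizon Study horizon in months (> 0).
#' @param patient_ids Optional ids (default `P001`, ...).
#' @return `data.frame` with `patient_id`, `months`, `event`. Uses the RNG.
#' @export
generate_survival <- function(linear_predictor, baseline_hazard,
                              censoring_rate = 0, horizon = Inf,
                              patient_ids = NULL) {
  if (baseline_hazard <= 0)
    fail_field("baseline_hazard", "must be positive")
  if (horizon <= 0) fail_field("horizon", "must be positive")
  n <- length(linear_predictor)
  if (is.null(patient_ids))
    patient_ids <- sprintf("P%03d", seq_len(n))
  t_event <- rexp(n, rate = baseline_hazard * exp(linear_predictor))
  # a censoring_rate fraction of patients is lost to follow-up at a uniform
  # time before their (horizon-truncated) event; the rest are observed until
  # death or the administrative horizon
  dropout <- runif(n) < censoring_rate
  months <- pmin(t_event, horizon)
  event <- as.integer(t_event <= horizon)
  months[dropout] <- runif(sum(dropout), 0, months[dropout])
  event[dropout] <- 0L
  data.frame(patient_id = patient_ids, months = months, event = event,
             stringsAsFactors = FALSE)
}

# Internal: synthetic genome layout. Genes are placed round-robin on
# chromosomes at fixed spacing; each gene gets a shared-exon + private-exon
# transcript structure, which guarantees a full-column-rank incidence matrix.
build_synthetic_annotation <- function(cfg) {
  gene_ids <- sprintf("G%02d", seq_len(cfg$n_genes))
  spacing <- 10000L
  rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    chrom <- sprintf("chr%d", ((g - 1L) %% cfg$n_chrom) + 1L)
    offset <- (((g - 1L) %/% cfg$n_chrom)) * spacing + 1000L
    n_tx <- sample(seq(cfg$transcripts_per_gene[1],
                       cfg$transcripts_per_gene[2]), 1L)
    n_shared <- sample(1:2, 1L)
    priv_counts <- sample(1:2, n_tx, replace = TRUE)
    exon_ids <- sprintf("%s_E%d", gene_ids[g],
                        seq_len(n_shared + sum(priv_counts)))
    starts <- offset + (seq_along(exon_ids) - 1L) * 300L
    ends <- starts + 200L
    shared <- exon_ids[seq_len(n_shared)]
    priv_split <- split(exon_ids[-seq_len(n_shared)],
                        rep(seq_len(n_tx), priv_counts))
    for (k in seq_len(n_tx)) {
      ex <- c(shared, priv_split[[k]])
      idx <- match(ex, exon_ids)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_ids[g],
        transcript_id = sprintf("%s_T%d", gene_ids[g], k),
        exon_id = ex, chrom = chrom, start = starts[idx], end = ends[idx],
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic multi-platform cohort with ground truth
#'
#' Produces, under one seed, every table the pipeline consumes: a transcript
#' annotation; an exon intensity matrix generated as `e = A t + noise` from
#' known per-gene transcript values; a gene-expression platform matrix; a
#' miRNA matrix with a synthetic target annotation; clinical records from an
#' exponential proportional-hazards model; aCGH probe profiles for tumors
#' and blood-control arrays with planted aberrant segments; Hardy-Weinberg
#' genotypes with call probabilities and per-sample signal-to-noise ratios;
#' promoter methylation signals; and siRNA screen plates with a smooth
#' polynomial spatial background and spiked hits. The returned
#' `ground_truth` records every planted signal.
#'
#' @param config A [cohort_config()].
#' @return List with components `annotation`, `exon_matrix`, `roles`
#'   (`data.frame` sample/role), `gene_matrix`, `mirna_matrix`,
#'   `mirna_targets`, `clinical`, `cn_probes`, `cn_controls`, `genotypes`,
#'   `sample_snr`, `methylation`, `plates`, `gene_coords`, `incidences`,
#'   `ground_truth`, `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config", call. = FALSE)
  cfg <- config
  set.seed(cfg$seed)
  gene_ids <- sprintf("G%02d", seq_len(cfg$n_genes))
  tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  control_ids <- sprintf("C%03d", seq_len(cfg$n_control))
  samples <- c(tumor_ids, control_ids)
  roles <- data.frame(sample = samples,
                      role = rep(c("tumor", "control"),
                                 c(cfg$n_tumor, cfg$n_control)),
                      stringsAsFactors = FALSE)

  annotation <- build_synthetic_annotation(cfg)
  incidences <- build_incidence(annotation)
  gene_coords <- do.call(rbind, lapply(split(annotation, annotation$gene_id),
    function(a) data.frame(feature = a$gene_id[1], chrom = a$chrom[1],
                           start = min(a$start), end = max(a$end),
                           stringsAsFactors = FALSE)))
  rownames(gene_coords) <- NULL

  effects <- cfg$planted_effects
  eff_by_gene <- setNames(effects,
                          vapply(effects, function(e) e$gene, ""))

  # --- transcript ground truth and exon matrix -------------------------
  transcript_mu <- list()
  overexpressed_samples <- list()
  exon_blocks <- list()
  gene_expr_true <- matrix(NA_real_, cfg$n_genes, length(samples),
                           dimnames = list(gene_ids, samples))
  for (g in gene_ids) {
    inc <- incidences[[g]]
    n_tx <- length(inc$transcript_ids)
    mu <- setNames(runif(n_tx, 5, 20), inc$transcript_ids)
    transcript_mu[[g]] <- mu
    tmat <- matrix(rep(mu, length(samples)), nrow = n_tx,
                   dimnames = list(inc$transcript_ids, samples))
    eff <- eff_by_gene[[g]]
    if (!is.null(eff) && eff$platform %in% c("expression", "cn")) {
      frac <- if (is.null(eff$frac)) 0.4 else eff$frac
      fc <- if (is.null(eff$fc)) 4 else eff$fc
      n_aff <- round(frac * cfg$n_tumor)
      affected <- sample(tumor_ids, n_aff)
      tmat[, affected] <- tmat[, affected] * fc
      overexpressed_samples[[g]] <- affected
    }
    noise <- matrix(rnorm(nrow(inc$A) * length(samples), 0,
                          cfg$exon_noise_sd),
                    nrow = nrow(inc$A))
    exon_blocks[[g]] <- inc$A %*% tmat + noise
    gene_expr_true[g, ] <- colMeans(tmat)
  }
  exon_matrix <- do.call(rbind, exon_blocks)

  # gene-expression platform: true gene signal plus its own noise
  gene_matrix <- gene_expr_true +
    matrix(rnorm(length(gene_expr_true), 0, cfg$exon_noise_sd),
           nrow = nrow(gene_expr_true))
  gene_matrix[gene_matrix < 0.01] <- 0.01

  # --- miRNA platform ---------------------------------------------------
  mirna_ids <- sprintf("mir%03d", seq_len(cfg$n_mirna))
  mirna_mu <- runif(cfg$n_mirna, 5, 20)
  mirna_matrix <- matrix(rep(mirna_mu, length(samples)),
                         nrow = cfg$n_mirna,
                         dimnames = list(mirna_ids, samples))
  de_mirna <- mirna_ids[seq_len(min(3L, cfg$n_mirna))]
  mirna_matrix[de_mirna, tumor_ids] <- mirna_matrix[de_mirna, tumor_ids] * 3
  mirna_matrix <- mirna_matrix +
    matrix(rnorm(length(mirna_matrix), 0, cfg$exon_noise_sd),
           nrow = nrow(mirna_matrix))
  mirna_matrix[mirna_matrix < 0.01] <- 0.01
  mirna_targets <- simulate_mirna_targets(mirna_ids, gene_ids,
                                          n_pairs = 4L * cfg$n_mirna)

  # --- genotypes --------------------------------------------------------
  marker_ids <- sprintf("M%03d", seq_len(cfg$n_markers))
  snp_effects <- Filter(function(e) e$platform == "snp", effects)
  marker_gene <- setNames(rep(NA_character_, cfg$n_markers), marker_ids)
  mafs <- runif(cfg$n_markers, cfg$maf_range[1], cfg$maf_range[2])
  if (length(snp_effects)) {
    for (i in seq_along(snp_effects)) {
      marker_gene[i] <- snp_effects[[i]]$gene
      if (!is.null(snp_effects[[i]]$maf)) mafs[i] <- snp_effects[[i]]$maf
    }
  }
  geno_codes <- matrix(NA_integer_, cfg$n_markers, cfg$n_tumor,
                       dimnames = list(marker_ids, tumor_ids))
  for (m in seq_len(cfg$n_markers)) {
    q <- mafs[m]
    geno_codes[m, ] <- sample(0:2, cfg$n_tumor, replace = TRUE,
                              prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }
  genotypes <- data.frame(
    marker = rep(marker_ids, cfg$n_tumor),
    patient = rep(tumor_ids, each = cfg$n_markers),
    call = c("AA", "AB", "BB")[as.vector(geno_codes) + 1L],
    prob = runif(cfg$n_markers * cfg$n_tumor, 0.90, 1.0),
    stringsAsFactors = FALSE)
  sample_snr <- setNames(pmax(rnorm(cfg$n_tumor, 20, 4), 1), tumor_ids)

  # --- clinical records from planted hazards ---------------------------
  lp <- setNames(rep(0, cfg$n_tumor), tumor_ids)
  survival_effect_genes <- list()
  for (eff in effects) {
    hr <- eff$hr
    if (is.null(hr)) next
    if (eff$platform %in% c("expression", "cn")) {
      aff <- overexpressed_samples[[eff$gene]]
      lp[aff] <- lp[aff] + log(hr)
    } else if (eff$platform == "snp") {
      idx <- which(marker_gene == eff$gene)[1]
      carriers <- tumor_ids[geno_codes[idx, ] > 0]
      lp[carriers] <- lp[carriers] + log(hr)
    }
    survival_effect_genes[[length(survival_effect_genes) + 1L]] <-
      data.frame(gene = eff$gene, platform = eff$platform, hr = hr,
                 stringsAsFactors = FALSE)
  }
  clinical <- generate_survival(lp, cfg$baseline_hazard, cfg$censoring_rate,
                                cfg$study_horizon, patient_ids = tumor_ids)

  # --- copy number ------------------------------------------------------
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  chrom_len <- genes_per_chrom * 10000L + 2000L
  pos <- round(seq(500, chrom_len - 500,
                   length.out = cfg$n_cn_probes_per_chrom))
  probe_grid <- data.frame(chrom = rep(chroms, each = length(pos)),
                           pos = rep(pos, cfg$n_chrom),
                           stringsAsFactors = FALSE)
  cn_effects <- Filter(function(e) e$platform == "cn", effects)
  seg_truth <- list()
  true_means <- matrix(0, nrow(probe_grid), cfg$n_tumor,
                       dimnames = list(NULL, tumor_ids))
  for (eff in cn_effects) {
    gc <- gene_coords[gene_coords$feature == eff$gene, ]
    center <- (gc$start + gc$end) / 2
    on_chrom <- which(probe_grid$chrom == gc$chrom)
    d <- abs(probe_grid$pos[on_chrom] - center)
    span <- on_chrom[order(d)[1:15]]        # 15-probe aberrant segment
    span <- sort(span)
    lr <- if (is.null(eff$logratio)) 0.9 else eff$logratio
    aff <- overexpressed_samples[[eff$gene]]
    if (is.null(aff)) {
      frac <- if (is.null(eff$frac)) 0.5 else eff$frac
      aff <- sample(tumor_ids, round(frac * cfg$n_tumor))
    }
    true_means[span, aff] <- lr
    seg_truth[[length(seg_truth) + 1L]] <- data.frame(
      sample = aff, chrom = gc$chrom,
      start = probe_grid$pos[span[1]], end = probe_grid$pos[span[15]],
      true_mean = lr, stringsAsFactors = FALSE)
  }
  cn_probes <- data.frame(
    sample = rep(tumor_ids, each = nrow(probe_grid)),
    chrom = rep(probe_grid$chrom, cfg$n_tumor),
    pos = rep(probe_grid$pos, cfg$n_tumor),
    logratio = as.vector(true_means) +
      rnorm(nrow(probe_grid) * cfg$n_tumor, 0, cfg$cn_noise_sd),
    stringsAsFactors = FALSE)
  cn_controls <- data.frame(
    sample = rep(sprintf("B%03d", seq_len(cfg$n_cn_controls)),
                 each = nrow(probe_grid)),
    chrom = rep(probe_grid$chrom, cfg$n_cn_controls),
    pos = rep(probe_grid$pos, cfg$n_cn_controls),
    logratio = rnorm(nrow(probe_grid) * cfg$n_cn_controls, 0,
                     cfg$cn_noise_sd),
    stringsAsFactors = FALSE)

  # --- methylation ------------------------------------------------------
  meth_rows <- list()
  for (g in gene_ids) {
    n_probe <- sample(1:3, 1L)
    beta_g <- runif(1, 0.05, 0.95)
    for (p in seq_len(n_probe)) {
      b <- pmin(pmax(beta_g + rnorm(length(samples), 0, 0.03), 0), 1)
      intensity <- 1000
      meth_rows[[length(meth_rows) + 1L]] <- data.frame(
        probe = sprintf("%s_MP%d", g, p), gene = g, sample = samples,
        M = intensity * b, U = intensity * (1 - b),
        stringsAsFactors = FALSE)
    }
  }
  methylation <- do.call(rbind, meth_rows)

  # --- siRNA screen plates ---------------------------------------------
  screen_genes <- gene_ids[seq_len(cfg$n_screen_genes)]
  hit_gene <- if (length(effects)) effects[[1]]$gene else screen_genes[1]
  if (!hit_gene %in% screen_genes) screen_genes[1] <- hit_gene
  plates <- list()
  hit_wells <- list()
  for (cl in cfg$cell_lines) {
    plate_id <- sprintf("%s_prolif", cl)
    wells <- expand.grid(row = seq_len(cfg$plate_rows),
                         col = seq_len(cfg$plate_cols))
    wells$plate <- plate_id
    wells$cell_line <- cl
    wells$assay <- "proliferation"
    wells$role <- "empty"
    wells$sirna <- NA_character_
    wells$gene <- NA_character_
    wells$replicate <- NA_integer_
    sirnas <- as.vector(t(outer(screen_genes, seq_len(cfg$sirnas_per_gene),
                                function(g, k) sprintf("%s_si%d", g, k))))
    sirna_gene <- rep(screen_genes, each = cfg$sirnas_per_gene)
    slots <- rep(seq_along(sirnas), cfg$plate_replicates)
    n_ctrl <- 12L
    total <- length(slots) + 2L * n_ctrl
    if (total > nrow(wells))
      fail_field("plate_layout", "plate too small for the screen layout")
    # contents are printed into a contiguous block (as a robot would),
    # shuffled within it so position and treatment are not confounded;
    # unused wells stay empty at the trailing edge of the plate
    content <- sample(c(slots, rep(-1L, n_ctrl), rep(-2L, n_ctrl)))
    pos <- seq_len(total)
    s_idx <- pos[content > 0L]
    s_slots <- content[content > 0L]
    wells$role[s_idx] <- "sample"
    wells$sirna[s_idx] <- sirnas[s_slots]
    wells$gene[s_idx] <- sirna_gene[s_slots]
    wells$replicate[s_idx] <-
      as.integer(ave(s_slots, s_slots, FUN = seq_along))
    neg_idx <- pos[content == -1L]
    wells$role[neg_idx] <- "negative"
    wells$sirna[neg_idx] <- "siNEG"
    death_idx <- pos[content == -2L]
    wells$role[death_idx] <- "death"
    wells$sirna[death_idx] <- "siDEATH"
    # smooth polynomial spatial background + flat signal + noise
    base <- 1000
    r <- wells$row / cfg$plate_rows
    cc <- wells$col / cfg$plate_cols
    coefs <- runif(5, -0.1, 0.1)
    background <- base * (coefs[1] * r + coefs[2] * cc + coefs[3] * r^2 +
                            coefs[4] * cc^2 + coefs[5] * r * cc)
    signal <- base + background + rnorm(nrow(wells), 0, 0.03 * base)
    signal[wells$role == "death"] <- signal[wells$role == "death"] * 0.2
    hit_sirnas <- sprintf("%s_si%d", hit_gene, 1:3)
    is_hit <- !is.na(wells$sirna) & wells$sirna %in% hit_sirnas
    signal[is_hit] <- signal[is_hit] * 0.55
    signal[wells$role == "empty"] <- 0
    wells$signal <- signal
    plates[[plate_id]] <- wells
    hit_wells[[plate_id]] <- data.frame(
      plate = plate_id, row = wells$row[is_hit], col = wells$col[is_hit],
      sirna = wells$sirna[is_hit], spike_factor = 0.55,
      stringsAsFactors = FALSE)
  }
  plates <- do.call(rbind, plates)
  rownames(plates) <- NULL

  ground_truth <- list(
    transcript_mu = transcript_mu,
    overexpressed_samples = overexpressed_samples,
    aberrant_segments = if (length(seg_truth)) do.call(rbind, seg_truth)
                        else NULL,
    survival_effect_genes = if (length(survival_effect_genes))
      do.call(rbind, survival_effect_genes) else NULL,
    snp_marker_gene = marker_gene[!is.na(marker_gene)],
    de_mirna = de_mirna,
    hit_gene = hit_gene,
    hit_wells = do.call(rbind, hit_wells))

  list(annotation = annotation, incidences = incidences,
       exon_matrix = exon_matrix, roles = roles, gene_matrix = gene_matrix,
       mirna_matrix = mirna_matrix, mirna_targets = mirna_targets,
       clinical = clinical, cn_probes = cn_probes,
       cn_controls = cn_controls, genotypes = genotypes,
       sample_snr = sample_snr, methylation = methylation, plates = plates,
       gene_coords = gene_coords, ground_truth = ground_truth,
       config = cfg)
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' Rebuilds the in-memory cohort structure, including the per-gene incidence
#' matrices (re-derived from the annotation), so a cohort on disk and a
#' freshly generated one drive the pipeline identically.
#'
#' @param dir Directory holding the cohort TSV/JSON files.
#' @return A cohort list as from [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  annotation <- read_annotation(p("annotation.tsv"), format = "tsv")
  snr <- read_tsv_table(p("sample_snr.tsv"))
  cfg <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  list(annotation = annotation,
       incidences = build_incidence(annotation),
       exon_matrix = read_matrix_tsv(p("exon_matrix.tsv")),
       roles = read_tsv_table(p("sample_roles.tsv")),
       gene_matrix = read_matrix_tsv(p("gene_matrix.tsv")),
       mirna_matrix = read_matrix_tsv(p("mirna_matrix.tsv")),
       mirna_targets = read_tsv_table(p("mirna_targets.tsv")),
       clinical = read_tsv_table(p("clinical.tsv")),
       cn_probes = read_tsv_table(p("cn_probes.tsv")),
       cn_controls = read_tsv_table(p("cn_controls.tsv")),
       genotypes = read_tsv_table(p("genotypes.tsv")),
       sample_snr = setNames(snr$snr, snr$sample),
       methylation = read_tsv_table(p("methylation.tsv")),
       plates = read_tsv_table(p("plates.tsv")),
       gene_coords = read_tsv_table(p("gene_coords.tsv")),
       ground_truth = jsonlite::read_json(p("ground_truth.json"),
                                          simplifyVector = TRUE),
       config = cfg)
}

#' Write a synthetic cohort to TSV/JSON files
#'
#' Writes the same tab-separated formats the pipeline reads, plus the
#' configuration and ground truth as JSON for test harnesses.
#'
#' @param cohort From [generate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_matrix_tsv(cohort$exon_matrix, file.path(dir, "exon_matrix.tsv"),
                   id_col = "exon")
  write_matrix_tsv(cohort$gene_matrix, file.path(dir, "gene_matrix.tsv"),
                   id_col = "gene")
  write_matrix_tsv(cohort$mirna_matrix, file.path(dir, "mirna_matrix.tsv"),
                   id_col = "mirna")
  write_tsv_table(cohort$roles, file.path(dir, "sample_roles.tsv"))
  write_tsv_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_tsv_table(cohort$cn_probes, file.path(dir, "cn_probes.tsv"))
  write_tsv_table(cohort$cn_controls, file.path(dir, "cn_controls.tsv"))
  write_tsv_table(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv_table(data.frame(sample = names(cohort$sample_snr),
                             snr = unname(cohort$sample_snr)),
                  file.path(dir, "sample_snr.tsv"))
  write_tsv_table(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_tsv_table(cohort$mirna_targets, file.path(dir, "mirna_targets.tsv"))
  write_tsv_table(cohort$plates, file.path(dir, "plates.tsv"))
  write_tsv_table(cohort$gene_coords, file.path(dir, "gene_coords.tsv"))
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
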