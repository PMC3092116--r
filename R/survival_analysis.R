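#' Kaplan-Meier product-limit estimate with 95% confidence intervals
#'
#' Wraps [survival::survfit()] with Greenwood-variance plain (linear) 95%
#' confidence intervals, returning a tidy step-function table.
#'
#' @param time Survival time in months from initial diagnosis.
#' @param event Event indicator: 1 = death, 0 = censored.
#' @return `data.frame` with columns `time`, `n_risk`, `n_event`, `surv`,
#'   `lower`, `upper` (rows at event/censoring times).
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) < 1L || all(is.na(time)))
    stop("no usable survival times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "plain", conf.int = 0.95)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, lower = fit$lower, upper = fit$upper)
}

#' Log-rank test across survival groups
#'
#' Standard observed-minus-expected log-rank chi-square with
#' `df = groups - 1`, ties handled with the hypergeometric variance, two-sided
#' P from the chi-square upper tail. Implemented via
#' [survival::survdiff()].
#'
#' @param time,event Survival time and event indicator.
#' @param group Group labels (>= 2 nonempty groups).
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank test needs >= 2 nonempty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(unname(sd$chisq), df, lower.tail = FALSE))
}

#' Discretize per-sample fold changes into expression classes
#'
#' Class `-1` = underexpression (FC < 0.5), `1` = overexpression (FC > 2),
#' `0` = stable expression.
#'
#' @param fc_s Numeric per-sample fold changes.
#' @return Integer vector in \{-1, 0, 1\} (NA propagates).
#' @export
discretize_fc <- function(fc_s) {
  ifelse(is.na(fc_s), NA_integer_,
         ifelse(fc_s < 0.5, -1L, ifelse(fc_s > 2, 1L, 0L)))
}

#' Survival screen over discretized expression groups
#'
#' For each pre-selected feature (typically DETs from [select_dets()]),
#' per-sample fold changes are discretized into classes -1/0/1, classes with
#' fewer than 20 patients are excluded, and a log-rank test is run over the
#' remaining classes. Features with fewer than 2 remaining classes are
#' skipped.
#'
#' @param fc_matrix Features x patients matrix of per-sample fold changes
#'   (columns named by patient id).
#' @param clinical `data.frame` with `patient_id`, `months`, `event`.
#' @param min_group Minimum class size (default 20 patients).
#' @return `data.frame` with `feature`, `chisq`, `p`, `n_groups`,
#'   `classes_used`; skipped features carry `NA` P and `n_groups < 2`.
#' @export
expression_survival_screen <- function(fc_matrix, clinical, min_group = 20L) {
  common <- intersect(colnames(fc_matrix), clinical$patient_id)
  if (length(common) == 0L)
    stop("no shared patient ids between expression and clinical data",
         call. = FALSE)
  cl <- clinical[match(common, clinical$patient_id), ]
  fc_matrix <- fc_matrix[, common, drop = FALSE]
  res <- lapply(seq_len(nrow(fc_matrix)), function(i) {
    cls <- discretize_fc(fc_matrix[i, ])
    tab <- table(cls)
    keep_classes <- names(tab)[tab >= min_group]
    use <- !is.na(cls) & cls %in% as.integer(keep_classes)
    if (length(keep_classes) < 2L) {
      return(data.frame(feature = rownames(fc_matrix)[i], chisq = NA_real_,
                        p = NA_real_, n_groups = length(keep_classes),
                        classes_used = paste(keep_classes, collapse = ","),
                        stringsAsFactors = FALSE))
    }
    lr <- logrank_test(cl$months[use], cl$event[use], cls[use])
    data.frame(feature = rownames(fc_matrix)[i], chisq = lr$chisq, p = lr$p,
               n_groups = length(keep_classes),
               classes_used = paste(keep_classes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Internal: allele-count minor allele frequency from called genotypes.
maf_from_calls <- function(calls) {
  calls <- calls[!is.na(calls)]
  nb <- sum(calls == "AB") + 2L * sum(calls == "BB")
  tot <- 2L * length(calls)
  if (tot == 0L) return(NA_real_)
  f <- nb / tot
  min(f, 1 - f)
}

#' SNP survival screen
#'
#' Quality control and survival association for a genotype matrix:
#' samples with signal-to-noise ratio below 5 are dropped; calls with
#' probability below 0.95 are set missing; markers with minor allele
#' frequency below 0.1 (allele-counted over called genotypes) are excluded;
#' survival times are administratively censored at the 36-month study
#' horizon; when the rare-homozygote group has fewer than 15 patients or a
#' called-genotype frequency below 0.1 it is merged into the heterozygote
#' group; a log-rank test is run over the remaining genotype groups and
#' markers with raw P below the limit (default 1e-4) are reported.
#'
#' @param genotypes `data.frame` with columns `marker`, `patient`, `call`
#'   (AA/AB/BB or NA), `prob` (call probability).
#' @param clinical `data.frame` with `patient_id`, `months`, `event`.
#' @param sample_snr Named numeric vector of per-sample signal-to-noise
#'   ratios (names = patient ids); `NULL` skips the SNR filter.
#' @param snr_min,prob_min,maf_min,study_months,merge_min_n,merge_min_freq,p_limit
#'   Filter parameters; defaults follow the study design.
#' @return List with `results` (all tested markers: `marker`, `maf`,
#'   `groups`, `chisq`, `p`) and `hits` (markers with `p < p_limit`).
#' @export
snp_survival_screen <- function(genotypes, clinical, sample_snr = NULL,
                                snr_min = 5, prob_min = 0.95, maf_min = 0.1,
                                study_months = 36, merge_min_n = 15L,
                                merge_min_freq = 0.1, p_limit = 1e-4) {
  if (!is.null(sample_snr)) {
    ok_samples <- names(sample_snr)[sample_snr >= snr_min]
    genotypes <- genotypes[genotypes$patient %in% ok_samples, ]
  }
  genotypes$call[genotypes$prob < prob_min] <- NA
  cl <- clinical
  # administrative censoring at the study horizon
  over <- cl$months > study_months
  cl$event[over] <- 0L
  cl$months[over] <- study_months
  res <- lapply(split(genotypes, genotypes$marker), function(g) {
    g <- g[!is.na(g$call), ]
    g <- g[g$patient %in% cl$patient_id, ]
    maf <- maf_from_calls(g$call)
    row <- data.frame(marker = g$marker[1], maf = maf, groups = NA_character_,
                      chisq = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    if (nrow(g) == 0L || is.na(maf) || maf < maf_min) return(row)
    # identify the rare homozygote by allele counts
    nb <- sum(g$call == "AB") + 2L * sum(g$call == "BB")
    rare_hom <- if (nb <= nrow(g)) "BB" else "AA"
    grp <- g$call
    n_rare <- sum(grp == rare_hom)
    if (n_rare > 0L &&
        (n_rare < merge_min_n || n_rare / nrow(g) < merge_min_freq)) {
      grp[grp == rare_hom] <- "AB"
    }
    if (length(unique(grp)) < 2L) return(row)
    idx <- match(g$patient, cl$patient_id)
    lr <- logrank_test(cl$months[idx], cl$event[idx], grp)
    row$groups <- paste(sort(unique(grp)), collapse = ",")
    row$chisq <- lr$chisq
    row$p <- lr$p
    row
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  list(results = results,
       hits = results[!is.na(results$p) & results$p < p_limit, ])
}
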