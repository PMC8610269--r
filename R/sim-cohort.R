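# Synthetic two-cohort clinical + expression tables. Defaults are the study
# conditions the downstream analysis assumes: compartment score levels at
# the observed medians (benign stroma ~2x tumor stroma, tumor epithelium
# slightly below tumor stroma), duplicate cores per ROI, exponential
# survival with lymphovascular invasion (LVI) as the only systematic hazard
# effect, and independent exponential censoring.

#' Configuration for a synthetic two-compartment cohort
#'
#' @param n_tumor,n_benign Numbers of tumor and benign subjects.
#' @param benign_stroma_mean,tumor_stroma_mean,tumor_epi_mean Compartment
#'   score means (arbitrary AQUA-style units, >= 0). Defaults sit at the
#'   score levels the pipeline is calibrated to recover (benign stroma
#'   roughly twice tumor stroma).
#' @param benign_epi_mean Benign epithelium mean score.
#' @param dispersion Coefficient of variation of the between-subject score
#'   distribution (gamma-distributed subject means).
#' @param core_cv Coefficient of variation of within-subject duplicate-core
#'   replicate noise (lognormal).
#' @param duplicate_cores Cores sampled per subject x ROI (>= 1).
#' @param median_os_months Baseline median overall survival, months, for
#'   subjects without LVI (exponential model). The default 160, combined
#'   with the default LVI prevalence (0.77) and log hazard ratio, puts the
#'   marginal median OS near 50 months.
#' @param hazard_log_hr_lvi Log hazard ratio attached to the LVI flag; the
#'   only systematic survival effect in the generator.
#' @param censoring_rate Expected fraction of tumor subjects censored
#'   (independent exponential censoring), in `[0, 1)`.
#' @param missing_rate Fraction of optional clinical fields set missing.
#' @param cohort Cohort label (1 = IHC-scored, 2 = IF-scored) stamped on the
#'   clinical records.
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_tumor = 105L,
                              n_benign = 30L,
                              benign_stroma_mean = 308.9,
                              tumor_stroma_mean = 152.6,
                              tumor_epi_mean = 124.0,
                              benign_epi_mean = 180.0,
                              dispersion = 0.28,
                              core_cv = 0.08,
                              duplicate_cores = 2L,
                              median_os_months = 160,
                              hazard_log_hr_lvi = log(3.56),
                              censoring_rate = 0.11,
                              missing_rate = 0.03,
                              cohort = 2L,
                              seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_benign = as.integer(n_benign),
              benign_stroma_mean = benign_stroma_mean,
              tumor_stroma_mean = tumor_stroma_mean,
              tumor_epi_mean = tumor_epi_mean,
              benign_epi_mean = benign_epi_mean,
              dispersion = dispersion, core_cv = core_cv,
              duplicate_cores = as.integer(duplicate_cores),
              median_os_months = median_os_months,
              hazard_log_hr_lvi = hazard_log_hr_lvi,
              censoring_rate = censoring_rate,
              missing_rate = missing_rate,
              cohort = as.integer(cohort), seed = as.integer(seed))
  class(cfg) <- "cohort_sim_config"
  validate_cohort_sim_config(cfg)
  cfg
}

validate_cohort_sim_config <- function(cfg) {
  if (cfg$n_tumor < 0 || cfg$n_benign < 0)
    stop("invalid configuration: subject counts must be >= 0", call. = FALSE)
  means <- c(cfg$benign_stroma_mean, cfg$tumor_stroma_mean,
             cfg$tumor_epi_mean, cfg$benign_epi_mean)
  if (any(means < 0))
    stop("invalid configuration: compartment means must be >= 0",
         call. = FALSE)
  if (cfg$dispersion < 0 || cfg$core_cv < 0)
    stop("invalid configuration: dispersion and core_cv must be >= 0",
         call. = FALSE)
  if (cfg$duplicate_cores < 1)
    stop("invalid configuration: duplicate_cores must be >= 1", call. = FALSE)
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("invalid configuration: censoring_rate must be in [0, 1)",
         call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("invalid configuration: missing_rate must be in [0, 1]",
         call. = FALSE)
  if (cfg$median_os_months <= 0)
    stop("invalid configuration: median_os_months must be > 0", call. = FALSE)
  invisible(cfg)
}

# subject-level mean >= 0 with configured CV; gamma keeps scores positive
rsubject_mean <- function(n, mean, cv) {
  if (mean == 0 || cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Generate a synthetic cohort: per-core expression plus clinical records
#'
#' Subject-level compartment means are gamma-distributed around the
#' configured compartment means; duplicate cores are lognormal replicates
#' around the subject mean. Overall survival is exponential with baseline
#' median `median_os_months` and a proportional-hazards effect of the LVI
#' flag only; censoring is independent exponential, calibrated so the
#' expected censored fraction equals `censoring_rate`. All covariates
#' required by the downstream statistics (age, grade, stage, pT/pN,
#' response, debulking, TIL/cystic/LVI, dates, vital status) are generated.
#'
#' @param config A [cohort_sim_config()].
#' @return A list with `expression` (one row per subject x ROI x core:
#'   `subject_id`, `core_id`, `roi_class`, `compartment`, `score`) and
#'   `clinical` (one row per subject), plus `truth` (the generating values).
#' @export
generate_cohort <- function(config) {
  validate_cohort_sim_config(config)
  withr::with_seed(config$seed, {
    expr <- list()
    clin <- list()

    draw_cores <- function(subject_id, roi_class, compartment, subj_mean,
                           n_cores, cv) {
      score <- subj_mean * exp(stats::rnorm(n_cores, 0, cv) - cv^2 / 2)
      data.frame(subject_id = subject_id,
                 core_id = sprintf("%s_%s_c%d", subject_id, roi_class,
                                   seq_len(n_cores)),
                 roi_class = roi_class, compartment = compartment,
                 score = score, stringsAsFactors = FALSE)
    }

    k <- config$duplicate_cores
    if (config$n_tumor > 0) {
      ids <- sprintf("T%03d", seq_len(config$n_tumor))
      ms <- rsubject_mean(config$n_tumor, config$tumor_stroma_mean,
                          config$dispersion)
      me <- rsubject_mean(config$n_tumor, config$tumor_epi_mean,
                          config$dispersion)
      for (i in seq_len(config$n_tumor)) {
        expr[[length(expr) + 1L]] <-
          draw_cores(ids[i], "tumor_stroma", "stroma", ms[i], k, config$core_cv)
        expr[[length(expr) + 1L]] <-
          draw_cores(ids[i], "tumor_epithelium", "epithelium", me[i], k,
                     config$core_cv)
      }

      age <- round(pmin(83, pmax(24, stats::rnorm(config$n_tumor, 61, 10))))
      lvi <- stats::rbinom(config$n_tumor, 1, 0.77) == 1
      lambda0 <- log(2) / config$median_os_months
      lambda <- lambda0 * exp(config$hazard_log_hr_lvi * lvi)
      t_event <- stats::rexp(config$n_tumor, lambda)
      if (config$censoring_rate > 0) {
        # for T~Exp(l), C~Exp(mu): P(C < T) = mu / (l + mu)
        mu <- lambda * config$censoring_rate / (1 - config$censoring_rate)
        t_cens <- stats::rexp(config$n_tumor, mu)
      } else {
        t_cens <- rep(Inf, config$n_tumor)
      }
      os <- pmin(t_event, t_cens)
      dead <- t_event <= t_cens
      dx <- as.Date("2005-01-01") +
        round(stats::runif(config$n_tumor, 0, 2000))
      measurable <- stats::rbinom(config$n_tumor, 1, 0.7) == 1
      cr <- stats::rbinom(config$n_tumor, 1, 0.77) == 1
      lesion_response <- ifelse(measurable,
                                ifelse(cr, "complete",
                                       sample(c("partial", "stable",
                                                "progression"),
                                              config$n_tumor, replace = TRUE)),
                                NA_character_)
      clin[[1L]] <- data.frame(
        subject_id = ids, cohort = config$cohort, tumor = TRUE,
        age_dx = age,
        histology = "serous",
        grade = sample(c("low", "high"), config$n_tumor, TRUE,
                       prob = c(0.05, 0.95)),
        stage = sample(c("I", "II", "III", "IV"), config$n_tumor, TRUE,
                       prob = c(0.08, 0.09, 0.63, 0.20)),
        pT = sample(c("<=20mm", "20-50mm", ">50mm"), config$n_tumor, TRUE,
                    prob = c(0.10, 0.13, 0.77)),
        pN = sample(c("involved", "not_involved", NA), config$n_tumor, TRUE,
                    prob = c(0.13, 0.40, 0.47)),
        debulking = sample(c("optimal", "suboptimal"), config$n_tumor, TRUE,
                           prob = c(0.79, 0.21)),
        neoadjuvant = FALSE, recurrent_tissue = FALSE,
        measurable_disease = measurable,
        lesion_response = lesion_response,
        ca125_normalized_4wk = ifelse(measurable, NA, cr),
        ca125_drop_gt50_4wk = ifelse(measurable, NA, cr |
                                       stats::rbinom(config$n_tumor, 1, 0.5) == 1),
        dx_date = dx,
        last_contact_or_death_date = dx + round(os * 30.4375),
        vital_status = ifelse(dead, "dead", "alive"),
        til_present = stats::rbinom(config$n_tumor, 1, 0.43) == 1,
        cystic = stats::rbinom(config$n_tumor, 1, 0.69) == 1,
        lvi = lvi,
        stringsAsFactors = FALSE)
    }

    if (config$n_benign > 0) {
      ids <- sprintf("B%03d", seq_len(config$n_benign))
      ms <- rsubject_mean(config$n_benign, config$benign_stroma_mean,
                          config$dispersion)
      me <- rsubject_mean(config$n_benign, config$benign_epi_mean,
                          config$dispersion)
      for (i in seq_len(config$n_benign)) {
        expr[[length(expr) + 1L]] <-
          draw_cores(ids[i], "benign_stroma", "stroma", ms[i], k,
                     config$core_cv)
        expr[[length(expr) + 1L]] <-
          draw_cores(ids[i], "benign_epithelium", "epithelium", me[i], k,
                     config$core_cv)
      }
      age <- round(pmin(83, pmax(24, stats::rnorm(config$n_benign, 55, 11))))
      dx <- as.Date("2005-01-01") + round(stats::runif(config$n_benign, 0, 2000))
      clin[[length(clin) + 1L]] <- data.frame(
        subject_id = ids, cohort = config$cohort, tumor = FALSE,
        age_dx = age, histology = "benign", grade = NA_character_,
        stage = NA_character_, pT = NA_character_, pN = NA_character_,
        debulking = NA_character_, neoadjuvant = FALSE,
        recurrent_tissue = FALSE, measurable_disease = FALSE,
        lesion_response = NA_character_, ca125_normalized_4wk = NA,
        ca125_drop_gt50_4wk = NA, dx_date = dx,
        last_contact_or_death_date = dx +
          round(stats::runif(config$n_benign, 365, 3650)),
        vital_status = "alive", til_present = NA, cystic = NA, lvi = NA,
        stringsAsFactors = FALSE)
    }

    expression <- if (length(expr)) do.call(rbind, expr) else
      data.frame(subject_id = character(), core_id = character(),
                 roi_class = character(), compartment = character(),
                 score = numeric(), stringsAsFactors = FALSE)
    clinical <- if (length(clin)) do.call(rbind, clin) else
      data.frame(subject_id = character(), stringsAsFactors = FALSE)

    # configured missingness on optional pathology flags only
    if (config$missing_rate > 0 && nrow(clinical) > 0) {
      for (col in c("til_present", "cystic", "lvi")) {
        hit <- stats::runif(nrow(clinical)) < config$missing_rate
        clinical[[col]][hit] <- NA
      }
    }

    rownames(expression) <- NULL
    rownames(clinical) <- NULL
    list(expression = expression, clinical = clinical,
         truth = list(config = config))
  })
}
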