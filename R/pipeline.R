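# Orchestration: expression-by-subgroup summary tables, survival analyses,
# and the synthetic end-to-end driver. reproduce_tables() rebuilds the
# cohort summary tables (per-subgroup compartment location/spread with
# rank and mean-difference tests), the Kaplan-Meier analyses at the
# assay-appropriate cutoff, and the Cox models, from an analysis-ready
# per-subject table — whether that table comes from the published
# supplementary spreadsheet (via read_clinical_table() and a column
# mapping) or from the synthetic generator.

subgroup_vars_default <- c("age_group", "grade", "stage_group", "pT", "pN",
                           "response", "debulking", "survival_group",
                           "til_present", "cystic", "lvi")

#' Merge per-subject expression with clinical records
#'
#' Reshapes subject-level compartment scores (one row per subject x ROI x
#' compartment, as from [aggregate_duplicate_cores()]) into one row per
#' subject with `stroma_score`, `epithelium_score` and their difference
#' `delta` (stroma minus epithelium), restricted to a tissue class, then
#' joins clinical columns.
#'
#' @param expression Subject-level expression records.
#' @param clinical Annotated clinical table ([annotate_clinical()]).
#' @param tissue `"tumor"` or `"benign"` ROI classes.
#' @return One-row-per-subject analysis table.
#' @export
merge_expression_clinical <- function(expression, clinical,
                                      tissue = c("tumor", "benign")) {
  tissue <- match.arg(tissue)
  keep <- startsWith(expression$roi_class, tissue)
  e <- expression[keep, , drop = FALSE]
  if (nrow(e) == 0) {
    empty <- data.frame(subject_id = character(), stroma_score = numeric(),
                        epithelium_score = numeric(), delta = numeric(),
                        stringsAsFactors = FALSE)
    return(merge(empty, clinical, by = "subject_id"))
  }
  wide <- stats::reshape(
    e[, c("subject_id", "compartment", "score")],
    idvar = "subject_id", timevar = "compartment", direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  for (col in c("stroma", "epithelium"))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  names(wide)[names(wide) == "stroma"] <- "stroma_score"
  names(wide)[names(wide) == "epithelium"] <- "epithelium_score"
  wide$delta <- wide$stroma_score - wide$epithelium_score
  merge(wide, clinical, by = "subject_id", all.x = TRUE, sort = TRUE)
}

summarize_one <- function(v, location) {
  c(n = sum(!is.na(v)),
    location = if (location == "median") stats::median(v, na.rm = TRUE)
               else mean(v, na.rm = TRUE),
    sd = stats::sd(v, na.rm = TRUE))
}

#' Expression-by-subgroup summary table
#'
#' For each clinical subgroup variable present in the data, reports
#' per-level location (median for the IF assay, mean for IHC) and SD of
#' stroma score, epithelium score and their per-subject difference, with a
#' rank test (Wilcoxon rank-sum for 2 levels, Kruskal-Wallis for more) on
#' each compartment score and a mean-difference test (Student t / one-way
#' ANOVA) on the paired difference. The overall row carries the paired
#' one-sample t-test of the stroma-minus-epithelium difference.
#'
#' @param analysis One-row-per-subject table from
#'   [merge_expression_clinical()].
#' @param location `"median"` (IF convention) or `"mean"` (IHC convention).
#' @param subgroups Character vector of subgroup column names to tabulate;
#'   absent columns are silently skipped (the driver degrades to whatever
#'   is computable).
#' @return Data frame, one row per subgroup level plus an `overall` row.
#' @export
expression_summary_table <- function(analysis,
                                     location = c("median", "mean"),
                                     subgroups = subgroup_vars_default) {
  location <- match.arg(location)
  rows <- list()
  ov_s <- summarize_one(analysis$stroma_score, location)
  ov_e <- summarize_one(analysis$epithelium_score, location)
  d_ok <- analysis$delta[!is.na(analysis$delta)]
  overall_p <- if (length(d_ok) >= 2 && stats::sd(d_ok) > 0)
    mean_difference_test(deltas = analysis$delta)$p_value else NA_real_
  rows[["overall"]] <- data.frame(
    variable = "overall", level = "all", n = sum(!is.na(analysis$stroma_score) |
                                                   !is.na(analysis$epithelium_score)),
    stroma = ov_s[["location"]], stroma_sd = ov_s[["sd"]],
    epithelium = ov_e[["location"]], epithelium_sd = ov_e[["sd"]],
    delta = mean(analysis$delta, na.rm = TRUE),
    delta_sd = stats::sd(analysis$delta, na.rm = TRUE),
    p_stroma = NA_real_, p_epithelium = NA_real_, p_delta = overall_p,
    stringsAsFactors = FALSE)

  for (var in intersect(subgroups, names(analysis))) {
    g <- analysis[[var]]
    if (var == "survival_group") g[g %in% "excluded"] <- NA
    if (all(is.na(g))) next
    g <- factor(g)
    levs <- levels(g)
    if (length(levs) < 2) next
    split_scores <- function(col) lapply(levs, function(l)
      analysis[[col]][g %in% l & !is.na(analysis[[col]])])
    test_p <- function(col) {
      gr <- split_scores(col)
      if (any(lengths(gr) < 2)) return(NA_real_)
      if (length(gr) == 2) wilcoxon_rank_sum(gr[[1]], gr[[2]])$p_value
      else kruskal_wallis(gr)$p_value
    }
    delta_p <- {
      gr <- split_scores("delta")
      if (any(lengths(gr) < 2)) NA_real_
      else tryCatch(mean_difference_test(groups = gr)$p_value,
                    warning = function(w) NA_real_)
    }
    p_s <- test_p("stroma_score"); p_e <- test_p("epithelium_score")
    for (i in seq_along(levs)) {
      sel <- g %in% levs[i]
      ss <- summarize_one(analysis$stroma_score[sel], location)
      ee <- summarize_one(analysis$epithelium_score[sel], location)
      rows[[paste(var, levs[i])]] <- data.frame(
        variable = var, level = levs[i], n = sum(sel),
        stroma = ss[["location"]], stroma_sd = ss[["sd"]],
        epithelium = ee[["location"]], epithelium_sd = ee[["sd"]],
        delta = mean(analysis$delta[sel], na.rm = TRUE),
        delta_sd = stats::sd(analysis$delta[sel], na.rm = TRUE),
        p_stroma = if (i == 1) p_s else NA_real_,
        p_epithelium = if (i == 1) p_e else NA_real_,
        p_delta = if (i == 1) delta_p else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rebuild the cohort analysis tables from an analysis-ready table
#'
#' The reproduction driver. Accepts either a file path (CSV/TSV/XLS(X),
#' with an optional column `mapping` to the canonical names — see
#' [read_clinical_table()]) or an in-memory list with `expression` and
#' `clinical` components as produced by [generate_cohort()]. Produces:
#' the expression-by-subgroup summary table; the benign-versus-tumor
#' stroma (and epithelium) comparisons; Kaplan-Meier fits by dichotomized
#' expression (median cutoff for IF, zero H-score presence/absence for
#' IHC); and Cox models (continuous expression adjusted for age and
#' response; LVI model when pathology flags exist). Missing optional
#' columns degrade to the subset of outputs that remain computable.
#'
#' @param data File path or `list(expression=, clinical=)`.
#' @param mapping Optional column mapping for file input.
#' @param assay `"if"` (AQUA scores, medians) or `"ihc"` (H-scores, means).
#' @param out_dir Optional directory; each produced table is written there
#'   as CSV together with a `run_info.json` (seed/config hash provenance).
#' @param seed Seed recorded in the provenance metadata (the computations
#'   themselves are deterministic).
#' @param quiet Suppress stage-boundary messages.
#' @return A list of result tables/fits (class `cav_reproduction`).
#' @export
reproduce_tables <- function(data, mapping = NULL, assay = c("if", "ihc"),
                             out_dir = NULL, seed = NA_integer_,
                             quiet = FALSE) {
  assay <- match.arg(assay)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.character(data)) {
    tab <- read_clinical_table(data, mapping = mapping)
    say("read %d rows from %s", nrow(tab), basename(data))
    # analysis-ready flat table: per-subject scores already aggregated
    expression <- flat_to_expression(tab)
    clinical <- tab[!duplicated(tab$subject_id),
                    setdiff(names(tab),
                            c("stroma_score", "epithelium_score", "delta")),
                    drop = FALSE]
  } else {
    expression <- aggregate_duplicate_cores(data$expression)
    clinical <- data$clinical
  }
  annotated <- annotate_clinical(clinical, quiet = quiet)
  say("analysis set: %d records", nrow(annotated))

  tumor <- merge_expression_clinical(expression, annotated, "tumor")
  tumor <- tumor[!is.na(tumor$stroma_score) | !is.na(tumor$epithelium_score), ,
                 drop = FALSE]
  benign <- merge_expression_clinical(expression, annotated, "benign")

  location <- if (assay == "if") "median" else "mean"
  out <- list(assay = assay,
              n_tumor = nrow(tumor), n_benign = nrow(benign),
              summary_table = expression_summary_table(tumor, location))

  # benign vs tumor comparisons per compartment
  comp_tests <- list()
  for (cmp in c("stroma_score", "epithelium_score")) {
    b <- benign[[cmp]][!is.na(benign[[cmp]])]
    t_ <- tumor[[cmp]][!is.na(tumor[[cmp]])]
    if (length(b) >= 1 && length(t_) >= 1) {
      res <- wilcoxon_rank_sum(b, t_)
      comp_tests[[cmp]] <- data.frame(
        compartment = sub("_score$", "", cmp),
        benign_median = stats::median(b), tumor_median = stats::median(t_),
        benign_mean = mean(b), tumor_mean = mean(t_),
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  if (length(comp_tests))
    out$benign_vs_tumor <- do.call(rbind, c(comp_tests,
                                            make.row.names = FALSE))

  # survival analyses
  has_os <- all(c("os_months", "os_event") %in% names(tumor)) &&
    any(!is.na(tumor$os_months))
  if (has_os) {
    out$km_overall <- km_fit(tumor$os_months, tumor$os_event)
    for (cmp in c("stroma_score", "epithelium_score")) {
      v <- tumor[[cmp]]
      if (sum(!is.na(v)) < 2) next
      label <- if (assay == "if") {
        cutoff <- stats::median(v, na.rm = TRUE)
        ifelse(is.na(v), NA, ifelse(v >= cutoff, "high", "low"))
      } else {
        ifelse(is.na(v), NA, ifelse(v > 0, "present", "absent"))
      }
      if (length(unique(stats::na.omit(label))) == 2) {
        out[[paste0("km_", sub("_score$", "", cmp))]] <-
          km_fit(tumor$os_months, tumor$os_event, label)
      }
    }
    adj <- intersect(c("age_dx", "response"), names(tumor))
    for (cmp in c("stroma_score", "epithelium_score")) {
      covs <- tumor[, c(cmp, adj), drop = FALSE]
      keep <- stats::complete.cases(covs) & !is.na(tumor$os_months)
      if (sum(tumor$os_event[keep], na.rm = TRUE) >= 5 &&
          length(unique(covs[keep, cmp])) > 1) {
        out[[paste0("cox_", sub("_score$", "", cmp))]] <-
          cox_fit(tumor$os_months[keep], tumor$os_event[keep],
                  covs[keep, , drop = FALSE])
      }
    }
    if ("lvi" %in% names(tumor) && sum(!is.na(tumor$lvi)) >= 10 &&
        length(unique(stats::na.omit(tumor$lvi))) == 2) {
      keep <- !is.na(tumor$lvi) & !is.na(tumor$os_months)
      out$cox_lvi <- cox_fit(tumor$os_months[keep], tumor$os_event[keep],
                             data.frame(lvi = as.numeric(tumor$lvi[keep])))
    }
    say("survival analyses: %d tumor cases with follow-up",
        sum(!is.na(tumor$os_months)))
  }

  # response association (logistic)
  if ("response" %in% names(tumor) &&
      length(unique(stats::na.omit(tumor$response))) == 2 &&
      sum(!is.na(tumor$stroma_score) & !is.na(tumor$response)) >= 10) {
    keep <- !is.na(tumor$response)
    out$logistic_response <- logistic_fit(
      factor(tumor$response[keep], levels = c("CR", "IR")),
      data.frame(stroma_score = tumor$stroma_score[keep]))
  }

  class(out) <- "cav_reproduction"
  if (!is.null(out_dir)) write_reproduction(out, out_dir, seed)
  out
}

flat_to_expression <- function(tab) {
  req <- "subject_id"
  if (!req %in% names(tab))
    stop("required column missing from input table: subject_id",
         call. = FALSE)
  tissue <- if ("tumor" %in% names(tab))
    ifelse(tab$tumor %in% TRUE, "tumor", "benign") else "tumor"
  rows <- list()
  for (cmp in c("stroma", "epithelium")) {
    col <- paste0(cmp, "_score")
    if (!col %in% names(tab)) next
    rows[[cmp]] <- data.frame(subject_id = tab$subject_id,
                              roi_class = paste0(tissue, "_", cmp),
                              compartment = cmp, score = tab[[col]],
                              n_cores = 1L, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("required column missing from input table: stroma_score ",
         "and/or epithelium_score", call. = FALSE)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

write_reproduction <- function(out, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(out)) {
    x <- out[[nm]]
    if (is.data.frame(x))
      utils::write.csv(x, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    else if (inherits(x, "survival_fit")) {
      sf <- x$survfit
      utils::write.csv(
        data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                   surv = sf$surv,
                   group = rep(names(x$medians),
                               if (is.null(sf$strata)) length(sf$time)
                               else sf$strata)),
        file.path(out_dir, paste0(nm, "_curve.csv")), row.names = FALSE)
    } else if (inherits(x, c("cox_fit", "logistic_fit"))) {
      utils::write.csv(x$coef, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  info <- list(seed = seed,
               config_hash = rlang::hash(out$summary_table),
               package_version = as.character(utils::packageVersion("stromacav")))
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the full pipeline on synthetic data
#'
#' One-command, seed-deterministic exercise of every stage:
#' (1) simulate multiplex cores over a range of ground-truth Cav-1
#' concentrations, segment them and verify score-versus-truth recovery;
#' (2) simulate a two-compartment cohort, aggregate duplicate cores,
#' annotate the clinical records, and run the full association analysis
#' via [reproduce_tables()].
#'
#' @param seed Integer seed driving every random stage.
#' @param n_recovery_cores Number of simulated cores for the
#'   score-recovery stage.
#' @param image_config Base [image_sim_config()] for the recovery stage
#'   (its concentration and seed fields are varied per core).
#' @param cohort_config A [cohort_sim_config()]; its seed is replaced by
#'   one derived from `seed`.
#' @param noise_sd Noise level for the recovery cores.
#' @param quiet Suppress stage messages.
#' @return List of class `cav_e2e_report`: `imaging` (per-core truth vs
#'   recovered scores, Spearman correlation, mask agreement), `analysis`
#'   (the [reproduce_tables()] output), `recovered` (headline recovered
#'   quantities), `seed`, `config_hash`.
#' @export
end_to_end_synthetic <- function(seed = 1L,
                                 n_recovery_cores = 12L,
                                 image_config = image_sim_config(),
                                 cohort_config = cohort_sim_config(),
                                 noise_sd = 0.01,
                                 quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(seed)

  # stage 1: imaging recovery
  concs <- seq(0.1, 1.0, length.out = n_recovery_cores)
  per_core <- lapply(seq_along(concs), function(i) {
    cfg <- image_config
    cfg$stroma_cav1_conc <- concs[i]
    cfg$noise_sd <- noise_sd
    cfg$seed <- (seed * 1000L + i) %% .Machine$integer.max
    sim <- generate_core_image(cfg, core_id = sprintf("sim%02d", i),
                               subject_id = sprintf("S%02d", i))
    masks <- build_compartment_masks(sim$image)
    sc <- compute_aqua_score(sim$image, masks, "stroma")
    truth_sc <- compute_aqua_score(sim$image, sim$truth, "stroma")
    data.frame(core_id = sim$image$core_id, true_conc = concs[i],
               score = sc$value, score_truth_mask = truth_sc$value,
               mask_jaccard = sum(masks$stroma & sim$truth$stroma) /
                 sum(masks$stroma | sim$truth$stroma))
  })
  imaging <- do.call(rbind, per_core)
  spearman <- stats::cor(imaging$true_conc, imaging$score,
                         method = "spearman")
  say("imaging recovery: %d cores, Spearman(score, truth) = %.3f",
      nrow(imaging), spearman)

  # stage 2: cohort analysis
  cohort_config$seed <- (seed * 7919L + 1L) %% .Machine$integer.max
  cohort <- generate_cohort(cohort_config)
  analysis <- reproduce_tables(cohort, assay = "if", quiet = quiet)

  bt <- analysis$benign_vs_tumor
  stroma_row <- bt[bt$compartment == "stroma", , drop = FALSE]
  recovered <- list(
    spearman_score_vs_conc = spearman,
    mean_mask_jaccard = mean(imaging$mask_jaccard),
    benign_stroma_median = stroma_row$benign_median,
    tumor_stroma_median = stroma_row$tumor_median,
    tumor_epithelium_median =
      analysis$summary_table$epithelium[analysis$summary_table$variable == "overall"],
    benign_tumor_stroma_ratio =
      stroma_row$benign_median / stroma_row$tumor_median,
    benign_vs_tumor_stroma_p = stroma_row$p_value,
    lvi_hr = if (!is.null(analysis$cox_lvi)) analysis$cox_lvi$coef$hr[
      analysis$cox_lvi$coef$term == "lvi"] else NA_real_,
    km_median_os = unname(analysis$km_overall$medians[1]))
  say("cohort analysis: benign/tumor stroma medians %.1f / %.1f (p = %.2g)",
      recovered$benign_stroma_median, recovered$tumor_stroma_median,
      recovered$benign_vs_tumor_stroma_p)

  structure(list(imaging = imaging, analysis = analysis,
                 recovered = recovered, seed = seed,
                 config_hash = rlang::hash(list(image_config, cohort_config))),
            class = "cav_e2e_report")
}

#' @export
print.cav_e2e_report <- function(x, ...) {
  cat("end-to-end synthetic run (seed", x$seed, ")\n")
  r <- x$recovered
  cat(sprintf(" score~concentration Spearman: %.3f\n", r$spearman_score_vs_conc))
  cat(sprintf(" mask Jaccard vs truth:        %.3f\n", r$mean_mask_jaccard))
  cat(sprintf(" benign / tumor stroma median: %.1f / %.1f (ratio %.2f, p = %.3g)\n",
              r$benign_stroma_median, r$tumor_stroma_median,
              r$benign_tumor_stroma_ratio, r$benign_vs_tumor_stroma_p))
  cat(sprintf(" tumor epithelium median:      %.1f\n", r$tumor_epithelium_median))
  cat(sprintf(" LVI hazard ratio:             %.2f\n", r$lvi_hr))
  cat(sprintf(" KM median OS (months):        %.1f\n", r$km_median_os))
  invisible(x)
}
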