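# End-to-end orchestration: simulate (or load) data, build the GRS,
# compute clinical risks, fit the survival models, and evaluate
# discrimination, reclassification, lifetime risk and heterogeneity.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic cohort, or `NULL`
#'   when `paths` supplies real inputs.
#' @param paths optional list with `stats` (summary-stats TSV), `geno`
#'   (dosage TSV or VCF) and `cohort` (CSV); used instead of simulation.
#' @param grid LD r-squared threshold grid; must contain the value you want
#'   selectable (default includes 0.7).
#' @param window_bp LD thinning window (default 1 Mb).
#' @param bins a [risk_bins()] for reclassification.
#' @param horizon classification/discrimination horizon in years.
#' @param censor_age attained-age censoring limit.
#' @param min_baseline_age minimum baseline age.
#' @param age_split baseline-age cut for subgroup discrimination
#'   (default 60: subgroups `<60` and `>=60`).
#' @param crossing_level cumulative-risk level for the age-at-crossing
#'   summary (default 0.10).
#' @param out_dir optional output directory for artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            grid = c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.3, 0.1),
                            window_bp = 1e6, bins = risk_bins(),
                            horizon = 10, censor_age = 75,
                            min_baseline_age = 30, age_split = 60,
                            crossing_level = 0.10, out_dir = NULL) {
  if (is.null(sim) && is.null(paths))
    stop_grs("either a sim config or input paths must be given")
  if (!is.null(paths)) {
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files))
      stop_grs("input path(s) not found: ",
               paste(missing_files, collapse = ", "))
  }
  if (horizon <= 0) stop_grs("horizon must be positive")
  structure(list(sim = sim, paths = paths, grid = grid,
                 window_bp = window_bp, bins = bins, horizon = horizon,
                 censor_age = censor_age,
                 min_baseline_age = min_baseline_age, age_split = age_split,
                 crossing_level = crossing_level, out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e)
    stop_grs("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full genomic-risk-score evaluation pipeline
#'
#' Stages: simulate or load inputs; apply cohort exclusion/censoring rules;
#' harmonize alleles; select the LD threshold by AUC and build the
#' standardized GRS; compute clinical 10-year risks (FRS-style and pooled
#' cohort equations); fit age-timescale sex-stratified Cox models (GRS
#' alone, family history, clinical alone, clinical + GRS); compare
#' truncated C-indices with the correlated jackknife test, overall and in
#' baseline-age subgroups; compute categorical/continuous NRI and IDI for
#' clinical + GRS vs clinical; estimate Kaplan-Meier cumulative risk by GRS
#' quintile and sex with ages at the 10% crossing, the Aalen-Johansen
#' competing-risk incidence, smoking-stratified quintile curves, and
#' GRS-by-risk-factor interaction tests; pool per-subcohort GRS log hazard
#' ratios by fixed-effect meta-analysis.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` (a nested list); artifacts are
#'   written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  logs <- character(0)
  note <- function(...) logs <<- c(logs, log_line(...))

  ## ---- inputs -----------------------------------------------------------
  if (!is.null(config$paths)) {
    dat <- stage("load", logs, {
      geno <- if (grepl("\\.vcf(\\.gz)?$", config$paths$geno))
        read_vcf_dosage(config$paths$geno) else read_dosage_tsv(config$paths$geno)
      list(stats = read_summary_stats(config$paths$stats), geno = geno,
           cohort = read_cohort(config$paths$cohort), truth = NULL)
    })
    note("load", "loaded inputs from disk")
  } else {
    dat <- stage("simulate", logs, {
      geno <- simulate_genotypes(config$sim)
      truth <- true_model(geno, config$sim)
      list(stats = simulate_summary_stats(geno, truth, config$sim),
           geno = geno,
           cohort = simulate_phenotypes(geno, truth, config$sim),
           truth = truth)
    })
    note("simulate", sprintf("simulated %d subjects x %d SNPs (seed %d)",
                             config$sim$n_samples, config$sim$n_snps,
                             config$sim$seed))
  }

  ## ---- cohort filters ---------------------------------------------------
  cohort <- stage("filters", logs,
                  apply_cohort_filters(dat$cohort, config$min_baseline_age,
                                       config$censor_age))
  fl <- attr(cohort, "filter_log")
  note("filters", sprintf("%d in, %d out (%d prevalent, %d young, %d no follow-up)",
                          fl$n_in, fl$n_out, fl$prevalent, fl$young,
                          fl$invalid))

  ## ---- harmonize + score ------------------------------------------------
  geno <- subset_samples(dat$geno, cohort$sample_id)
  harm <- stage("harmonize", logs, harmonize_alleles(dat$stats, geno))
  note("harmonize", paste(names(harm$log), harm$log, collapse = ", "))

  fu_time <- cohort$exit_age - cohort$entry_age
  event10 <- as.integer(cohort$event == "chd" & fu_time <= config$horizon)

  thin <- stage("thin", logs,
                select_r2_threshold(harm$stats, harm$geno, event10,
                                    grid = config$grid,
                                    window_bp = config$window_bp))
  note("thin", sprintf("selected r2 threshold %.2f (%d SNPs)",
                       thin$r2_threshold, length(thin$kept_snp_ids)))
  score <- stage("score", logs,
                 standardize_score(compute_grs(harm$stats, harm$geno,
                                               thin$kept_snp_ids)))
  cohort$std_grs <- score$standardized[match(cohort$sample_id,
                                             score$sample_ids)]

  ## ---- clinical risks ---------------------------------------------------
  clin <- stage("clinical", logs, {
    frs <- clinical_risk10(cohort, load_clinical_score("frs"))
    acc <- clinical_risk10(cohort, load_clinical_score("accaha13"))
    list(frs = frs, acc = acc)
  })
  cohort$frs_risk <- clin$frs$risk
  cohort$acc_risk <- clin$acc$risk
  cohort$logit_frs <- qlogis(pmin(pmax(cohort$frs_risk, 1e-12), 1 - 1e-12))
  cohort$logit_acc <- qlogis(pmin(pmax(cohort$acc_risk, 1e-12), 1 - 1e-12))
  note("clinical", sprintf("FRS mean 10y risk %.3f, ACC/AHA13 mean %.3f",
                           mean(cohort$frs_risk, na.rm = TRUE),
                           mean(cohort$acc_risk, na.rm = TRUE)))

  ## ---- Cox models -------------------------------------------------------
  adj <- intersect(c("cohort", "region"), names(cohort))
  adj <- adj[vapply(adj, function(v) length(unique(cohort[[v]])) > 1, TRUE)]
  models <- stage("cox", logs, {
    list(grs = fit_cox(cohort, c("std_grs", adj)),
         family_history = fit_cox(cohort, c("family_history", adj)),
         frs = fit_cox(cohort, c("logit_frs", adj)),
         frs_grs = fit_cox(cohort, c("logit_frs", "std_grs")),
         acc = fit_cox(cohort, c("logit_acc", adj)),
         acc_grs = fit_cox(cohort, c("logit_acc", "std_grs")))
  })
  hr_grs <- models$grs$hr[models$grs$hr$term == "std_grs", ]
  note("cox", sprintf("GRS HR per SD %.3f (%.3f-%.3f)",
                      hr_grs$hr, hr_grs$lo, hr_grs$hi))

  ## ---- discrimination ---------------------------------------------------
  status10 <- event10
  scores <- list(
    frs = cohort$frs_risk,
    acc = cohort$acc_risk,
    grs = cohort$std_grs,
    family_history = cohort$family_history,
    frs_grs = predict_risk10(models$frs_grs, cohort, config$horizon),
    acc_grs = predict_risk10(models$acc_grs, cohort, config$horizon))

  disc <- stage("discrimination", logs, {
    cidx <- lapply(scores, function(s) {
      ok <- !is.na(s)
      cindex_truncated(fu_time[ok], status10[ok], s[ok], config$horizon)
    })
    dc <- list(
      frs_grs_vs_frs = delta_c_complete(fu_time, status10, scores$frs,
                                        scores$frs_grs, config$horizon),
      acc_grs_vs_acc = delta_c_complete(fu_time, status10, scores$acc,
                                        scores$acc_grs, config$horizon),
      grs_vs_family_history = delta_c_complete(fu_time, status10,
                                               scores$family_history,
                                               scores$grs, config$horizon))
    list(cindex = cidx, delta_c = dc)
  })
  note("discrimination",
       sprintf("delta C (FRS+GRS vs FRS) %+0.4f, p = %.3g",
               disc$delta_c$frs_grs_vs_frs$delta_c,
               disc$delta_c$frs_grs_vs_frs$p))

  subgroups <- stage("age_subgroups", logs, {
    young <- cohort$entry_age < config$age_split
    lapply(list(young = young, old = !young), function(sel) {
      if (sum(status10[sel]) < 5) return(NULL)
      delta_c_complete(fu_time[sel], status10[sel], scores$frs[sel],
                       scores$frs_grs[sel], config$horizon)
    })
  })

  ## ---- reclassification -------------------------------------------------
  reclass <- stage("reclassification", logs, {
    mk <- function(old, new) {
      tab <- reclass_table(old, new, status10, config$bins)
      list(table = tab, categorical = categorical_nri(tab),
           continuous = continuous_nri(old, new, status10),
           idi = idi(old, new, status10))
    }
    list(frs = mk(scores$frs, scores$frs_grs),
         acc = mk(scores$acc, scores$acc_grs))
  })
  note("reclassification",
       sprintf("categorical NRI total (FRS) %.4f; (ACC/AHA13) %.4f",
               reclass$frs$categorical$total$estimate,
               reclass$acc$categorical$total$estimate))

  ## ---- lifetime risk curves ---------------------------------------------
  curves <- stage("curves", logs, {
    q <- quintile_groups(cohort$std_grs)
    by_quintile <- list()
    crossing <- list()
    for (sx in unique(cohort$sex)) {
      for (qt in levels(q)) {
        sel <- cohort$sex == sx & q == qt
        if (sum(sel) < 10) next
        key <- paste(sx, qt, sep = ".")
        cv <- km_curve(cohort[sel, ], cuminc = TRUE)
        by_quintile[[key]] <- cv
        crossing[[key]] <- age_at_crossing(cv, config$crossing_level)
      }
    }
    smoking_strata <- list()
    for (sm in c(0, 1)) {
      for (qt in c(levels(q)[1], levels(q)[5])) {
        sel <- cohort$smoking == sm & q == qt
        if (sum(sel) < 10) next
        smoking_strata[[paste0("smoking", sm, ".", qt)]] <-
          km_curve(cohort[sel, ], cuminc = TRUE)
      }
    }
    list(quintile = by_quintile, crossing_age = crossing,
         smoking = smoking_strata,
         aj_chd = aj_cif(cohort, "chd"),
         aj_competing = aj_cif(cohort, "death_other"),
         quintiles = q)
  })

  ## ---- interactions ------------------------------------------------------
  interactions <- stage("interactions", logs, {
    lapply(c(smoking = "smoking", sbp = "sbp", tc = "tc"), function(v) {
      it <- interaction_test(cohort, "std_grs", v)
      it$fit <- NULL
      it
    })
  })
  note("interactions",
       sprintf("GRS x smoking p = %.3g", interactions$smoking$p))

  ## ---- per-subcohort meta -----------------------------------------------
  meta <- stage("meta", logs, {
    if (!"cohort" %in% names(cohort) ||
        length(unique(cohort$cohort)) < 2) return(NULL)
    ests <- lapply(split(cohort, cohort$cohort), function(d) {
      if (sum(d$event == "chd") < 10) return(NULL)
      f <- fit_cox(d, "std_grs")
      f$hr[f$hr$term == "std_grs", c("log_hr", "se")]
    })
    ests <- ests[!vapply(ests, is.null, TRUE)]
    if (length(ests) < 2) return(NULL)
    tab <- do.call(rbind, ests)
    fixed_effect_meta(tab$log_hr, tab$se, labels = rownames(tab))
  })

  report <- structure(list(
    n = nrow(cohort), n_events = sum(cohort$event == "chd"),
    n_events10 = sum(status10), filter_log = fl,
    harmonize_log = as.list(harm$log),
    thinning = list(r2_threshold = thin$r2_threshold,
                    n_kept = length(thin$kept_snp_ids), table = thin$table),
    score = list(n_snps_used = score$n_snps_used,
                 coverage = score$coverage),
    models = lapply(models, function(m)
      list(hr = m$hr, n = m$n, n_events = m$n_events)),
    cindex = disc$cindex, delta_c = disc$delta_c,
    age_subgroups = subgroups, reclass = reclass,
    curves = curves, interactions = interactions, meta = meta,
    provenance = list(
      seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_,
      horizon = config$horizon, censor_age = config$censor_age,
      grid = config$grid,
      combined_model = "Cox: logit(clinical 10y risk) + standardized GRS, sex-stratified",
      package_version = as.character(utils::packageVersion("grslife"))),
    log = logs), class = "run_report")

  if (!is.null(config$out_dir))
    write_run_report(report, score, thin, cohort, config$out_dir)
  report
}

# delta C on the subjects with both scores present
delta_c_complete <- function(time, status, a, b, horizon) {
  ok <- !is.na(a) & !is.na(b)
  delta_c_jackknife(time[ok], status[ok], a[ok], b[ok], horizon)
}

quintile_groups <- function(x) {
  qs <- quantile(x, probs = seq(0, 1, 0.2), type = 7, na.rm = TRUE)
  qs[1] <- -Inf; qs[6] <- Inf
  cut(x, qs, labels = paste0("Q", 1:5), include.lowest = TRUE)
}

subset_samples <- function(geno, sample_ids) {
  idx <- match(sample_ids, rownames(geno$dosage))
  if (anyNA(idx)) stop_grs("cohort samples missing from genotypes")
  genotype_dosage(geno$dosage[idx, , drop = FALSE], geno$map)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d subjects, %d incident CHD events (%d within horizon)\n",
              x$n, x$n_events, x$n_events10))
  hr <- x$models$grs$hr
  hr <- hr[hr$term == "std_grs", ]
  cat(sprintf("  GRS HR per SD: %.3f (95%% CI %.3f-%.3f)\n",
              hr$hr, hr$lo, hr$hi))
  cat(sprintf("  C-index FRS %.4f -> FRS+GRS %.4f (delta %+0.4f, p = %.3g)\n",
              x$cindex$frs$c, x$cindex$frs_grs$c,
              x$delta_c$frs_grs_vs_frs$delta_c, x$delta_c$frs_grs_vs_frs$p))
  cat(sprintf("  categorical NRI (FRS+GRS vs FRS): %.4f\n",
              x$reclass$frs$categorical$total$estimate))
  invisible(x)
}

write_run_report <- function(report, score, thin, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "curves"), showWarnings = FALSE)
  write_scores(score, file.path(out_dir, "scores.csv"))
  write.table(thin$table, file.path(out_dir, "thresholds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(thin$kept_snp_ids, file.path(out_dir, "kept_snps.tsv"))
  write_cohort(cohort, file.path(out_dir, "cohort_analyzed.csv"))
  for (nm in names(report$curves$quintile))
    write.table(report$curves$quintile[[nm]],
                file.path(out_dir, "curves", paste0("quintile_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$curves$aj_chd,
              file.path(out_dir, "curves", "aj_chd.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cind <- data.frame(model = names(report$cindex),
                     c = vapply(report$cindex, function(z) z$c, 0),
                     se = vapply(report$cindex, function(z) z$se, 0),
                     n_pairs = vapply(report$cindex,
                                      function(z) z$n_pairs, 0))
  write.table(cind, file.path(out_dir, "cindex.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  slim <- report
  slim$curves <- NULL
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Recompute categorical NRI from published cross-tab counts
#'
#' Reads a counts TSV with columns `group` (`events` / `nonevents`),
#' `old_category` and one column per new category, and recomputes the
#' categorical NRI triplet plus per-row reclassified percentages — the
#' worked-example path for published reclassification tables. Three such
#' tables ship with the package under `inst/extdata/reclass/`.
#'
#' @param path counts TSV path, or a name of a bundled table
#'   (`"finrisk_frs_grs"`, `"finrisk_accaha13_grs"`, `"fhs_frs_grs"`).
#' @return list `nri` (an `nri_result`), `reclass_pct` (per old-category,
#'   events), `events`, `nonevents` (count matrices).
#' @export
reproduce_tables <- function(path) {
  if (!file.exists(path)) {
    bundled <- system.file("extdata", "reclass", paste0(path, ".tsv"),
                           package = "grslife")
    if (nzchar(bundled)) path <- bundled
  }
  if (!file.exists(path)) stop_grs("counts file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("group", "old_category")
  if (!all(need %in% names(x)))
    stop_grs("counts TSV needs 'group' and 'old_category' columns")
  cat_cols <- setdiff(names(x), need)
  as_mat <- function(g) {
    m <- as.matrix(x[x$group == g, cat_cols, drop = FALSE])
    rownames(m) <- x$old_category[x$group == g]
    storage.mode(m) <- "double"
    m
  }
  events <- as_mat("events"); nonevents <- as_mat("nonevents")
  if (any(events < 0) || any(nonevents < 0))
    stop_grs("negative counts in ", path)
  if (nrow(events) != ncol(events))
    stop_grs("count table must be square (old x new categories)")
  nri <- categorical_nri(list(events = events, nonevents = nonevents))
  pct <- function(m) {
    rs <- rowSums(m)
    data.frame(old_category = rownames(m), row_total = rs,
               reclassified_pct = ifelse(rs > 0, 100 * (1 - diag(m) / rs), 0),
               row.names = NULL)
  }
  list(nri = nri, reclass_pct = pct(events),
       reclass_pct_nonevents = pct(nonevents),
       events = events, nonevents = nonevents)
}
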