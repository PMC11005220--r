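# End-to-end orchestration: screened group comparisons, the age-trajectory
# report, and the intervention (rejuvenation) evaluation.

#' Group comparison with the parametric/non-parametric screen
#'
#' Runs a Shapiro-Wilk normality screen per group and a Levene
#' variance-homogeneity screen across groups; if every screen passes at
#' `alpha`, the groups are compared by one-way ANOVA (with Sidak-adjusted
#' pairwise comparisons when more than two groups), otherwise by the
#' Kruskal-Wallis rank test. Groups with fewer than 3 observations, or an
#' all-degenerate (zero-variance) comparison, yield a descriptive-only
#' entry with a flag.
#'
#' @param values named list of numeric vectors, one per group.
#' @param alpha screen significance level (default 0.05).
#' @return list of class `ee_group_comparison`: `summary` (per-group n,
#'   mean, sd), `screens` (per-group Shapiro p, Levene p), `test`
#'   (`name`, `statistic`, `p_value`), `pairwise` (Sidak-adjusted, when
#'   parametric and > 2 groups), `flag`.
#' @export
compare_groups <- function(values, alpha = 0.05) {
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values)) || any(names(values) == ""))
    names(values) <- paste0("group", seq_along(values))
  values <- lapply(values, function(v) as.numeric(v[!is.na(v)]))
  summ <- data.frame(group = names(values),
                     n = lengths(values),
                     mean = vapply(values, mean, 0),
                     sd = vapply(values, stats::sd, 0),
                     stringsAsFactors = FALSE, row.names = NULL)
  out <- list(summary = summ, screens = NULL, test = NULL, pairwise = NULL,
              flag = NULL)
  class(out) <- "ee_group_comparison"
  if (any(lengths(values) < 3)) {
    out$flag <- "descriptive-only: group with n < 3"
    return(out)
  }
  pooled <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  if (stats::var(pooled) == 0) {
    out$flag <- "descriptive-only: zero variance in all groups"
    return(out)
  }
  shapiro_p <- vapply(values, function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate group: treat as non-normal
    stats::shapiro.test(v)$p.value
  }, 0)
  levene_p <- tryCatch(
    car::leveneTest(pooled ~ g)[1, "Pr(>F)"],
    error = function(e) 0)
  out$screens <- list(shapiro_p = shapiro_p, levene_p = levene_p)
  parametric <- all(shapiro_p > alpha) && !is.na(levene_p) &&
    levene_p > alpha
  if (parametric) {
    fit <- stats::aov(pooled ~ g)
    an <- summary(fit)[[1]]
    out$test <- list(name = "one-way ANOVA",
                     statistic = an[["F value"]][1],
                     p_value = an[["Pr(>F)"]][1])
    if (length(values) > 2) {
      mse <- an[["Mean Sq"]][2]
      df <- an[["Df"]][2]
      cmb <- utils::combn(names(values), 2)
      raw <- apply(cmb, 2, function(pr) {
        a <- values[[pr[1]]]; b <- values[[pr[2]]]
        se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
        2 * stats::pt(-abs((mean(a) - mean(b)) / se), df)
      })
      out$pairwise <- data.frame(
        group_a = cmb[1, ], group_b = cmb[2, ], p_raw = raw,
        p_sidak = sidak_adjust(raw), stringsAsFactors = FALSE)
    }
  } else {
    kw <- stats::kruskal.test(values)
    out$test <- list(name = "Kruskal-Wallis",
                     statistic = unname(kw$statistic),
                     p_value = kw$p.value)
  }
  out
}

#' @export
print.ee_group_comparison <- function(x, ...) {
  cat("<ee_group_comparison>\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  if (!is.null(x$test))
    cat(sprintf("%s: statistic %.3f, p = %.4g\n", x$test$name,
                x$test$statistic, x$test$p_value))
  invisible(x)
}

# Provenance block embedded in every report (no timestamp, so identical
# config + seed => byte-identical output).
.provenance <- function(config, seed) {
  list(package = "eeclock",
       version = as.character(utils::packageVersion("eeclock")),
       seed = seed,
       config_hash = rlang::hash(config))
}

#' Run the age-trajectory analysis
#'
#' From a set of recordings (already trimmed to the analysis window):
#' per-animal daily means and EE rhythm parameters, the feature table,
#' per-age summaries, PCoA ordination, screened group comparisons for the
#' key channels, and the decline of mean daily EE from the youngest to the
#' oldest group. Animals whose feature extraction fails (e.g. a missing
#' channel) are flagged in the QC section and excluded; the run completes.
#'
#' @param recordings list of `cage_recording` spanning >= 1 age group.
#' @param period_min common circadian period for the rhythm fits
#'   (default 1423 min); set `per_animal = TRUE` to use each animal's own
#'   top periodogram period instead.
#' @param per_animal fit rhythms at per-animal top periods (default
#'   `FALSE`).
#' @param compare_channels channels passed through [compare_groups()]
#'   across age groups.
#' @param seed seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @return list of class `ee_trajectory_report`.
#' @export
run_trajectory <- function(recordings, period_min = 1423,
                           per_animal = FALSE,
                           compare_channels = c("EE", "VO2", "VCO2", "RER"),
                           seed = 1) {
  qc <- list()
  rhythms <- list()
  keep <- list()
  top_periods <- list()
  for (rec in recordings) {
    res <- tryCatch({
      # fewer than k local maxima is routine for clean traces; the short
      # list is kept in the report, so the warning is muffled here
      tp <- withCallingHandlers(
        periodogram_top_periods(rec$channels$EE, rec$interval_min),
        warning = function(w) {
          if (grepl("local maxima", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      tau <- if (per_animal) tp$top_periods[1] else period_min
      list(rp = cosinor_fit_recording(rec, "EE", period_min = tau),
           top = tp$top_periods)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      qc[[rec$animal_id]] <- conditionMessage(res)
    } else {
      rhythms[[rec$animal_id]] <- res$rp
      top_periods[[rec$animal_id]] <- res$top
      keep[[rec$animal_id]] <- rec
    }
  }
  if (length(keep) == 0) stop("trajectory stage failed for every animal")
  feats <- build_feature_table(keep, rhythms)

  ages <- sort(unique(feats$age_weeks))
  fc <- feature_columns()
  by_age <- lapply(fc, function(col) {
    agg_m <- tapply(feats[[col]], feats$age_weeks, mean)
    agg_s <- tapply(feats[[col]], feats$age_weeks, stats::sd)
    data.frame(feature = col, age_weeks = as.numeric(names(agg_m)),
               mean = as.numeric(agg_m), sd = as.numeric(agg_s),
               stringsAsFactors = FALSE)
  })
  age_summary <- do.call(rbind, by_age)

  trend <- NULL
  ee_decline <- NULL
  if (length(ages) >= 2) {
    m_young <- mean(feats$EE[feats$age_weeks == min(ages)])
    m_old <- mean(feats$EE[feats$age_weeks == max(ages)])
    ee_decline <- 100 * (1 - m_old / m_young)
    trend <- do.call(rbind, lapply(fc, function(col) {
      sl <- stats::coef(stats::lm(feats[[col]] ~ feats$age_weeks))[2]
      data.frame(feature = col, slope_per_week = unname(sl),
                 stringsAsFactors = FALSE)
    }))
  }

  comparisons <- NULL
  if (length(ages) >= 2) {
    comparisons <- lapply(stats::setNames(nm = compare_channels),
                          function(ch)
      compare_groups(split(feats[[ch]], feats$age_weeks)))
  }

  ord <- if (nrow(feats) >= 3)
    pcoa(distance_matrix(feats[, fc], standardize = TRUE)) else NULL

  structure(list(
    features = feats, age_summary = age_summary, trend = trend,
    ee_decline_pct = ee_decline, comparisons = comparisons,
    ordination = ord, top_periods = top_periods, qc = qc,
    provenance = .provenance(
      list(period_min = period_min, per_animal = per_animal,
           compare_channels = compare_channels), seed)),
    class = "ee_trajectory_report")
}

#' @export
print.ee_trajectory_report <- function(x, ...) {
  cat(sprintf("<ee_trajectory_report> %d animals, ages {%s} wk\n",
              nrow(x$features),
              paste(sort(unique(x$features$age_weeks)), collapse = ", ")))
  if (!is.null(x$ee_decline_pct))
    cat(sprintf("  mean daily EE decline youngest -> oldest: %.1f%%\n",
                x$ee_decline_pct))
  if (length(x$qc))
    cat("  QC flags:", paste(names(x$qc), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate an intervention against the metabolic-age clock
#'
#' Predicts EE age for every group in the table, reports group
#' mean +/- SD, the rejuvenation delta of each group relative to the aged
#' control group, and a screened group comparison of the predicted ages.
#'
#' @param clock a trained `ee_clock`.
#' @param table feature table containing control and treated groups.
#' @param aged_group label of the aged control group the deltas are
#'   relative to.
#' @param seed seed recorded in provenance.
#' @return list of class `ee_intervention_report`: `prediction`
#'   (an `ee_age_prediction`), `rejuvenation` (per-group delta vs aged
#'   control; positive = younger than aged controls), `comparison`,
#'   `provenance`.
#' @export
run_intervention_eval <- function(clock, table, aged_group, seed = 1) {
  if (!aged_group %in% table$group)
    stop(sprintf("schema error: aged control group '%s' absent", aged_group))
  pred <- predict_ee_age(clock, table)
  gs <- pred$group_summary
  aged_mean <- gs$mean[gs$group == aged_group]
  rej <- data.frame(group = gs$group,
                    ee_age_mean = gs$mean, ee_age_sd = gs$sd,
                    delta_vs_aged = aged_mean - gs$mean,
                    stringsAsFactors = FALSE)
  cmp <- if (length(unique(pred$per_animal$group)) >= 2)
    compare_groups(split(pred$per_animal$ee_age_weeks,
                         pred$per_animal$group)) else NULL
  structure(list(prediction = pred, rejuvenation = rej, comparison = cmp,
                 provenance = .provenance(
                   list(aged_group = aged_group,
                        features = clock$selected_features), seed)),
            class = "ee_intervention_report")
}

#' @export
print.ee_intervention_report <- function(x, ...) {
  cat("<ee_intervention_report> EE age by group (delta vs aged control):\n")
  print(x$rejuvenation, row.names = FALSE)
  invisible(x)
}

#' Write a report's tables to CSV + JSON
#'
#' Emits each data.frame component as CSV and the whole report (minus
#' model objects) as JSON, provenance included.
#'
#' @param report an `ee_trajectory_report` or `ee_intervention_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drop <- c("ordination", "comparisons", "comparison", "prediction")
  flat <- report[!names(report) %in% drop]
  for (nm in names(flat))
    if (is.data.frame(flat[[nm]]))
      utils::write.csv(flat[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  if (inherits(report, "ee_intervention_report"))
    utils::write.csv(report$prediction$per_animal,
                     file.path(dir, "ee_age_per_animal.csv"),
                     row.names = FALSE)
  json <- flat[vapply(flat, function(x)
    is.data.frame(x) || is.atomic(x) || is.list(x), TRUE)]
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
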