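conc_columns <- c("subject", "group", "compound", "time_h",
                  "conc_ng_per_ml", "blq")
effect_columns <- c("subject", "group", "time_h", "lpo")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_arg(what, " is missing required column(s): ",
             paste(missing, collapse = ", "))
  }
}

#' Write a study dataset to CSV files
#'
#' Emits `concentrations.csv`, `effects.csv` and `ground_truth.csv` (plain
#' comma-separated UTF-8 with a header row) into `dir`.
#'
#' @param dataset A `study_dataset` from [generate_study()] or
#'   [load_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    concentrations = file.path(dir, "concentrations.csv"),
    effects = file.path(dir, "effects.csv"),
    ground_truth = file.path(dir, "ground_truth.csv")
  )
  write.csv(dataset$concentrations, paths["concentrations"],
            row.names = FALSE)
  write.csv(dataset$effects, paths["effects"], row.names = FALSE)
  if (!is.null(dataset$ground_truth)) {
    write.csv(dataset$ground_truth, paths["ground_truth"],
              row.names = FALSE)
  }
  invisible(paths)
}

#' Load a study dataset from CSV files
#'
#' Reads and validates concentration and effect records: required columns
#' must be present, each (subject, compound) concentration series must
#' have unique, sortable times, and rows are normalised to (subject,
#' compound, time) order.
#'
#' @param concentrations_path CSV with columns `subject`, `group`,
#'   `compound`, `time_h`, `conc_ng_per_ml`, `blq`.
#' @param effects_path CSV with columns `subject`, `group`, `time_h`,
#'   `lpo`; optional (`NULL` for a PK-only dataset).
#' @param ground_truth_path Optional ground-truth CSV (as written by
#'   [write_study()]).
#' @return A `study_dataset`.
#' @export
load_study <- function(concentrations_path, effects_path = NULL,
                       ground_truth_path = NULL) {
  conc <- read.csv(concentrations_path, stringsAsFactors = FALSE)
  check_columns(conc, conc_columns, "concentrations file")
  conc$blq <- as.logical(conc$blq)
  key <- paste(conc$subject, conc$compound, conc$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    d <- conc[duplicated(key), ][1, ]
    stop_arg("duplicate concentration record for subject=", d$subject,
             ", compound=", d$compound, ", time_h=", d$time_h)
  }
  conc <- conc[order(conc$subject, conc$compound, conc$time_h), ,
               drop = FALSE]
  rownames(conc) <- NULL
  effects <- NULL
  if (!is.null(effects_path)) {
    effects <- read.csv(effects_path, stringsAsFactors = FALSE)
    check_columns(effects, effect_columns, "effects file")
    ekey <- paste(effects$subject, effects$time_h, sep = "\r")
    if (anyDuplicated(ekey)) {
      d <- effects[duplicated(ekey), ][1, ]
      stop_arg("duplicate effect record for subject=", d$subject,
               ", time_h=", d$time_h)
    }
    effects <- effects[order(effects$subject, effects$time_h), ,
                       drop = FALSE]
    rownames(effects) <- NULL
  }
  truth <- if (!is.null(ground_truth_path)) {
    read.csv(ground_truth_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  structure(list(concentrations = conc, effects = effects,
                 ground_truth = truth, config = NULL),
            class = "study_dataset")
}

# One conc_profile per (subject, compound) from the long concentration
# table.
split_profiles <- function(conc) {
  parts <- split(conc, list(conc$subject, conc$compound), drop = TRUE)
  lapply(parts, function(d) {
    d <- d[order(d$time_h), ]
    conc_profile(d$time_h, ifelse(is.na(d$conc_ng_per_ml), 0,
                                  d$conc_ng_per_ml),
                 d$blq, compound = d$compound[1], subject = d$subject[1])
  })
}

# Mean profile across the subjects of one group for one compound; BLQ
# values enter as their stored convention (0) and the mean point is
# flagged BLQ only when every subject was BLQ there.
group_mean_profile <- function(conc, group, compound) {
  d <- conc[conc$group == group & conc$compound == compound, ]
  if (!nrow(d)) {
    stop_arg("no concentration records for group=", group, ", compound=",
             compound)
  }
  vals <- ifelse(is.na(d$conc_ng_per_ml), 0, d$conc_ng_per_ml)
  m <- tapply(vals, d$time_h, mean)
  allblq <- tapply(d$blq, d$time_h, all)
  tt <- as.numeric(names(m))
  o <- order(tt)
  conc_profile(tt[o], as.numeric(m)[o], as.logical(allblq)[o],
               compound = compound, subject = paste0(group, "(mean)"))
}

se <- function(x) sd(x) / sqrt(length(x))

#' Per-subject NCA with group-level aggregation
#'
#' Runs [nca_summary()] on every (subject, compound) concentration series
#' of a study and aggregates each parameter to group mean and standard
#' error. Profiles that fail NCA preconditions (e.g. all-BLQ) are skipped
#' with a message and listed in the `skipped` attribute.
#'
#' @param dataset A `study_dataset`.
#' @param auc_method,min_points Passed to [nca_summary()].
#' @return A list with data.frames `by_subject` and `by_group`
#'   (mean/se per group, compound and parameter).
#' @export
nca_study <- function(dataset,
                      auc_method = c("linear_up_log_down", "linear"),
                      min_points = 3L) {
  stopifnot(inherits(dataset, "study_dataset"))
  auc_method <- match.arg(auc_method)
  profiles <- split_profiles(dataset$concentrations)
  group_of <- setNames(dataset$concentrations$group,
                       dataset$concentrations$subject)
  rows <- list()
  skipped <- character()
  for (p in profiles) {
    res <- tryCatch(nca_summary(p, auc_method, min_points),
                    error = function(e) {
                      message("NCA skipped for ", profile_label(p), ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) {
      skipped <- c(skipped, profile_label(p))
      next
    }
    df <- as.data.frame(res)
    df$group <- unname(group_of[p$subject])
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) stop_arg("NCA failed for every profile")
  by_subject <- do.call(rbind, rows)
  params <- c("cmax", "tmax", "t_half", "auc_0_t", "auc_0_inf")
  agg <- lapply(split(by_subject,
                      list(by_subject$group, by_subject$compound),
                      drop = TRUE),
                function(d) {
                  out <- data.frame(group = d$group[1],
                                    compound = d$compound[1], n = nrow(d))
                  for (pp in params) {
                    out[[paste0(pp, "_mean")]] <- mean(d[[pp]])
                    out[[paste0(pp, "_se")]] <- if (nrow(d) > 1) {
                      se(d[[pp]])
                    } else {
                      NA_real_
                    }
                  }
                  out
                })
  by_group <- do.call(rbind, agg)
  by_group <- by_group[order(by_group$compound, by_group$group), ]
  rownames(by_group) <- NULL
  structure(list(by_subject = by_subject, by_group = by_group),
            skipped = skipped)
}

#' Run the full PK-PD analysis pipeline on a study dataset
#'
#' Chains the analysis stages the way the study was analysed:
#' per-subject NCA with group aggregation; per-compound compartmental
#' fitting with AIC model selection on the analysis group's mean profile;
#' control-corrected effect series (treated minus model-control group
#' means); and a direct-link sigmoid Emax fit per compound pairing the
#' group-mean concentrations with the delta-effect magnitudes at the
#' shared post-dose times, plus the hysteresis-loop diagnostic.
#'
#' @param dataset A `study_dataset`.
#' @param analysis_group Treated group used for model fitting and PK-PD
#'   (default `"LTG"`).
#' @param control_group Control subtracted from the treated effects
#'   (default `"MCG"`).
#' @param auc_method,weighting Method options forwarded to the stages.
#' @param hysteresis_tol Normalised-area tolerance for the loop direction.
#' @return An object of class `pkpd_results`: list with `nca`,
#'   `pk_models` (data.frame), `pkpd` (data.frame), `delta_effect`
#'   (an [effect_series()]), and `options`.
#' @export
run_study_pipeline <- function(dataset, analysis_group = "LTG",
                               control_group = "MCG",
                               auc_method = "linear_up_log_down",
                               weighting = "uniform",
                               hysteresis_tol = 0.05) {
  stopifnot(inherits(dataset, "study_dataset"))
  nca <- nca_study(dataset, auc_method)
  compounds <- sort(unique(dataset$concentrations$compound))

  pk_rows <- list()
  pkpd_rows <- list()

  trt_eff <- dataset$effects[dataset$effects$group == analysis_group, ]
  ctl_eff <- dataset$effects[dataset$effects$group == control_group, ]
  if (!nrow(trt_eff) || !nrow(ctl_eff)) {
    stop_arg("effect records missing for group ", analysis_group, " or ",
             control_group)
  }
  delta <- compute_delta_effect(trt_eff, ctl_eff)
  delta$group <- analysis_group
  delta$reference_group <- control_group

  for (cmp in compounds) {
    prof <- group_mean_profile(dataset$concentrations, analysis_group,
                               cmp)
    sel <- tryCatch(suppressWarnings(select_model(prof,
                                                  weighting = weighting)),
                    error = function(e) {
                      message("model selection failed for ", cmp, ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(sel)) {
      s <- sel$best$spec
      pk_rows[[cmp]] <- data.frame(
        compound = cmp,
        model = if (sel$model_kind == "one_compartment_ev") {
          "one-compartment"
        } else {
          "two-compartment"
        },
        ka = s$ka, coef_1 = s$coefs[1], rate_1 = s$rates[1],
        coef_2 = if (length(s$coefs) > 1) s$coefs[2] else NA_real_,
        rate_2 = if (length(s$rates) > 1) s$rates[2] else NA_real_,
        ssr = sel$best$ssr, aic = sel$best$aic,
        stringsAsFactors = FALSE
      )
    }

    # pair group-mean concentration with the delta-effect magnitude at
    # the shared nominal post-dose times (direct link, no interpolation)
    shared <- intersect(prof$times, delta$times)
    ci <- match(shared, prof$times)
    ei <- match(shared, delta$times)
    concs <- prof$conc[ci]
    effs <- -delta$values[ei]  # LPO falls under treatment: fit magnitude
    usable <- !prof$blq[ci]
    fit <- tryCatch(
      suppressWarnings(fit_sigmoid_emax(concs[usable], effs[usable])),
      error = function(e) {
        message("sigmoid Emax fit failed for ", cmp, ": ",
                conditionMessage(e))
        NULL
      })
    loop <- hysteresis_loop_area(concs, effs, tol = hysteresis_tol)
    if (!is.null(fit)) {
      pkpd_rows[[cmp]] <- data.frame(
        compound = cmp, emax = fit$params$emax, ed50 = fit$params$ed50,
        gamma = fit$params$gamma, ssr = fit$ssr,
        converged = fit$converged,
        loop_direction = loop$direction,
        loop_area = loop$signed_area,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(nca = nca,
         pk_models = do.call(rbind, unname(pk_rows)),
         pkpd = do.call(rbind, unname(pkpd_rows)),
         delta_effect = delta,
         options = list(analysis_group = analysis_group,
                        control_group = control_group,
                        auc_method = auc_method, weighting = weighting,
                        hysteresis_tol = hysteresis_tol)),
    class = "pkpd_results"
  )
}

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

#' Write pipeline results as deterministic CSV reports
#'
#' Emits `nca_summary.csv` (per-group mean and SE of the NCA parameters),
#' `pk_models.csv` (selected compartmental model, macro-parameters, SSR,
#' AIC per compound), `pkpd_equations.csv` (sigmoid Emax parameters, the
#' rendered equation string `E = Emax*C^g/(ED50^g + C^g)`, and the
#' hysteresis direction per compound), and `run_manifest.csv` (options and
#' package version). Numeric columns are rounded to 6 significant digits
#' and rows sorted, so identical inputs give byte-identical files.
#'
#' @param results A `pkpd_results` from [run_study_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, out_dir) {
  stopifnot(inherits(results, "pkpd_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  nca <- results$nca$by_group
  nca[] <- lapply(nca, fmt6)
  p <- file.path(out_dir, "nca_summary.csv")
  write.csv(nca, p, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(results$pk_models)) {
    pk <- results$pk_models[order(results$pk_models$compound), ]
    pk[] <- lapply(pk, fmt6)
    p <- file.path(out_dir, "pk_models.csv")
    write.csv(pk, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  if (!is.null(results$pkpd)) {
    pd <- results$pkpd[order(results$pkpd$compound), ]
    pd$equation <- sprintf("E = %g*C^%g/(%g^%g + C^%g)",
                           signif(pd$emax, 6), signif(pd$gamma, 6),
                           signif(pd$ed50, 6), signif(pd$gamma, 6),
                           signif(pd$gamma, 6))
    pd[] <- lapply(pd, fmt6)
    p <- file.path(out_dir, "pkpd_equations.csv")
    write.csv(pd, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  manifest <- data.frame(
    key = c("package_version", names(results$options)),
    value = c(as.character(packageVersion("wddpkpd")),
              vapply(results$options, function(x) paste(format(x),
                                                        collapse = ","),
                     character(1))),
    stringsAsFactors = FALSE
  )
  p <- file.path(out_dir, "run_manifest.csv")
  write.csv(manifest, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
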