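#' Extract the labeled feature table from a collection of records
#'
#' For each record: take the analysis window, run stage-1 preprocessing,
#' classify signal quality, segment trusted windows at the pulse feet, and
#' extract the 47-feature rows with reference pressures. Untrusted or
#' under-segmented windows are skipped and counted.
#'
#' @param records List of [bp_record()] objects.
#' @param start_s,duration_s Analysis-window placement (seconds).
#' @param cfg Denoise configuration.
#' @param rules SQI rules.
#' @param corr_threshold SQI template-correlation threshold.
#' @param with_abp Extract reference pressures / ABP features?
#' @return Tibble of feature rows; attribute `skipped` is a tibble of
#'   record_id + reason for every window that produced no rows.
#' @export
records_to_features <- function(records, start_s = 60, duration_s = 20,
                                cfg = denoise_config(), rules = sqi_rules(),
                                corr_threshold = 0.8, with_abp = TRUE) {
  skipped <- list()
  rows <- purrr::map_dfr(records, function(rec) {
    win <- tryCatch(extract_window(rec, start_s, duration_s),
                    error = function(e) NULL)
    if (is.null(win)) {
      skipped[[length(skipped) + 1L]] <<-
        tibble::tibble(record_id = record_id(rec), reason = "too_short")
      return(NULL)
    }
    pre <- preprocess_window(win, cfg)
    sqi <- classify_segment(pre, rules, corr_threshold)
    if (sqi$label != "trusted") {
      skipped[[length(skipped) + 1L]] <<-
        tibble::tibble(record_id = record_id(rec), reason = "untrusted")
      return(NULL)
    }
    fids <- tryCatch(detect_ppg_fiducials(pre$ppg, record_fs(pre)),
                     error = function(e) NULL)
    if (is.null(fids)) {
      skipped[[length(skipped) + 1L]] <<-
        tibble::tibble(record_id = record_id(rec), reason = "no_fiducials")
      return(NULL)
    }
    seg <- segment_window(pre, fids)
    if (!seg$accepted) {
      skipped[[length(skipped) + 1L]] <<-
        tibble::tibble(record_id = record_id(rec), reason = seg$reason)
      return(NULL)
    }
    extract_features(pre, seg, with_abp = with_abp)
  })
  attr(rows, "skipped") <- dplyr::bind_rows(skipped)
  rows
}

#' Fit the BP estimator on a labeled dataset
#'
#' Runs the weighted feature decision (MRMR ranking + cross-validated
#' boosting error over ranking prefixes) on the training split, then fits a
#' Gaussian process on the chosen feature subset. One model per target.
#'
#' @param dataset Output of [build_dataset()] (needs a `split` column).
#' @param target `"sbp"` or `"dbp"`.
#' @param use_wfd Run feature selection (TRUE) or keep all 47 features?
#' @param gba_cfg,gpr_cfg,folds Engine configurations.
#' @param seed Integer seed.
#' @param impute_mcorr Impute missing MCORR by the training median (done
#'   before fitting; the imputation value is stored on the model).
#' @return A `bp_model` list: `gpr`, `wfd` (or NULL), `features` used,
#'   `target`, `mcorr_impute`.
#' @export
fit_bp_model <- function(dataset, target = c("sbp", "dbp"), use_wfd = TRUE,
                         gba_cfg = gba_config(), gpr_cfg = gpr_config(),
                         folds = 5, seed = 1, impute_mcorr = TRUE) {
  target <- match.arg(target)
  train <- dataset[dataset$split == "train", , drop = FALSE]
  if (nrow(train) < 10) abort("Too few training rows.", class = "bpci_input_error")
  feats <- feature_names()
  Xtr <- as.matrix(train[, feats])
  mcorr_impute <- NA_real_
  if (impute_mcorr && anyNA(Xtr[, "MCORR"])) {
    mcorr_impute <- median(Xtr[, "MCORR"], na.rm = TRUE)
    Xtr[is.na(Xtr[, "MCORR"]), "MCORR"] <- mcorr_impute
  } else if (anyNA(Xtr[, "MCORR"])) {
    Xtr <- Xtr[, setdiff(feats, "MCORR")]
    feats <- setdiff(feats, "MCORR")
  }
  y <- train[[target]]
  wfd <- NULL
  use_cols <- seq_along(feats)
  if (use_wfd) {
    wfd <- wfd_select(Xtr, y, folds = folds, gba_cfg = gba_cfg, seed = seed)
    use_cols <- wfd$selected
  }
  gpr <- gpr_fit(Xtr[, use_cols, drop = FALSE], y, gpr_cfg, seed = seed)
  structure(list(gpr = gpr, wfd = wfd, features = feats[use_cols],
                 all_features = feats, target = target,
                 mcorr_impute = mcorr_impute),
            class = "bp_model")
}

#' Predict BP (with predictive SDs) for feature rows
#'
#' @param object A `bp_model` from [fit_bp_model()].
#' @param newdata Feature tibble (47 columns present).
#' @param level Interval level.
#' @param ... Unused.
#' @return Tibble `mean`, `sd`, `lo`, `hi`, plus `subject_id`/reference
#'   columns when present in `newdata`.
#' @export
predict.bp_model <- function(object, newdata, level = 0.95, ...) {
  X <- as.matrix(newdata[, object$all_features])
  if ("MCORR" %in% colnames(X) && anyNA(X[, "MCORR"]) &&
      is.finite(object$mcorr_impute)) {
    X[is.na(X[, "MCORR"]), "MCORR"] <- object$mcorr_impute
  }
  X <- X[, object$features, drop = FALSE]
  out <- predict(object$gpr, X, level = level)
  if ("subject_id" %in% names(newdata)) out$subject_id <- newdata$subject_id
  if (object$target %in% names(newdata)) out$reference <- newdata[[object$target]]
  out
}

#' Generate a synthetic cohort of subjects
#'
#' One record per subject with subject-specific baselines drawn around the
#' profile values, suitable for end-to-end pipeline exercises.
#'
#' All subjects share one coupling line `SBP = a - b * PTT` (arterial
#' stiffness rises with pressure across people too), so a subject's
#' baseline transit time is `(a - sbp0) / b`; within-subject beats then
#' wander along the same line. This is what makes the mapping learnable on
#' held-out subjects.
#'
#' @param n_subjects Number of subjects.
#' @param duration_s,fs Record geometry.
#' @param seed Integer seed (each subject derives its own sub-seed).
#' @param sbp_range,dbp_offset Between-subject baseline spread.
#' @param noise_sd Channel noise passed to each profile.
#' @param hr_range Between-subject heart-rate range (bpm).
#' @param coupling Global `c(a, b)` of the PTT line (mmHg, mmHg/s).
#' @return List of [bp_record()]s.
#' @export
generate_cohort <- function(n_subjects = 50, duration_s = 81, fs = 125,
                            seed = 1, sbp_range = c(100, 150),
                            dbp_offset = 40,
                            noise_sd = c(ppg = 0.01, ecg = 0.01, abp = 0.5),
                            hr_range = c(55, 95),
                            coupling = c(a = 167, b = 150)) {
  rng <- local_rng(seed)
  purrr::map(seq_len(n_subjects), function(i) {
    sbp0 <- rng$unif(1, sbp_range[1], sbp_range[2])
    hr <- rng$unif(1, hr_range[1], hr_range[2])
    prof <- subject_profile(hr_bpm = hr, sbp0 = sbp0, dbp0 = sbp0 - dbp_offset,
                            ptt0 = (coupling[["a"]] - sbp0) / coupling[["b"]],
                            b = coupling[["b"]], noise_sd = noise_sd)
    generate_record(prof, duration_s = duration_s, fs = fs,
                    seed = seed * 1000L + i,
                    record_id = sprintf("subj-%03d", i))
  })
}

#' Run the full desk-scale estimation pipeline on a synthetic cohort
#'
#' Generates a cohort, extracts features, splits by subject, fits the
#' SBP/DBP models (optionally with the weighted feature decision), predicts
#' on the test split, and computes error statistics and per-subject
#' confidence intervals. The work-horse behind the end-to-end regression
#' guard and the acceptance script.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param use_wfd Run feature selection?
#' @param gba_cfg,gpr_cfg Engine configurations.
#' @param noise_sd Channel noise (the ABP entry, in mmHg, doubles as the
#'   reference-label noise scale).
#' @param split Train/val/test fractions.
#' @param B Bootstrap replications for the subject CIs.
#' @return List: `features`, `dataset`, `models`, `predictions`,
#'   `evaluation`, `cis`, `ci_summary`.
#' @export
run_pipeline <- function(n_subjects = 50, seed = 1, use_wfd = TRUE,
                         gba_cfg = gba_config(), gpr_cfg = gpr_config(),
                         noise_sd = c(ppg = 0.01, ecg = 0.01, abp = 2),
                         split = c(0.8, 0.1, 0.1), B = 1000) {
  records <- generate_cohort(n_subjects, seed = seed, noise_sd = noise_sd)
  feats <- records_to_features(records)
  if (nrow(feats) == 0) abort("No trusted windows in the cohort.",
                              class = "bpci_input_error")
  dataset <- build_dataset(feats, split = split, seed = seed, mode = "by_subject")
  models <- list()
  predictions <- list()
  cis <- list()
  for (tg in c("sbp", "dbp")) {
    models[[tg]] <- fit_bp_model(dataset, tg, use_wfd = use_wfd,
                                 gba_cfg = gba_cfg, gpr_cfg = gpr_cfg,
                                 seed = seed)
    test <- dataset[dataset$split == "test", , drop = FALSE]
    pr <- predict(models[[tg]], test)
    pr$target <- tg
    predictions[[tg]] <- pr
    cis[[tg]] <- subject_cis(
      tibble::tibble(subject_id = pr$subject_id, estimate = pr$mean,
                     sd = pr$sd, reference = pr$reference),
      target = tg, B = B, seed = seed)
  }
  preds <- dplyr::bind_rows(predictions)
  evaluation <- evaluate_predictions(
    tibble::tibble(estimate = preds$mean, reference = preds$reference,
                   target = preds$target))
  all_cis <- dplyr::bind_rows(cis)
  list(records = records, features = feats, dataset = dataset, models = models,
       predictions = preds, evaluation = evaluation,
       cis = all_cis, ci_summary = ci_summary(all_cis))
}
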