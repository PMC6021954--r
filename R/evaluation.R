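# Performance measures and the three evaluation protocols
# (same-environment; cross-environment with/without calibration).

#' Classification accuracy in percent
#' @param pred,truth integer class vectors of equal, positive length.
#' @return `100 * mean(pred == truth)`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth))
    stop_named("invalid_input", "pred and truth must be non-empty and equal length")
  100 * mean(pred == truth)
}

#' Confusion matrix over the four classes
#' @param pred,truth integer class vectors (0-3).
#' @return 4 x 4 integer matrix, rows = true class, columns = predicted.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) == 0L || length(pred) != length(truth))
    stop_named("invalid_input", "pred and truth must be non-empty and equal length")
  tab <- table(factor(truth, levels = 0:3), factor(pred, levels = 0:3))
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(true = class_names(), pred = class_names()))
  m
}

#' Accuracy, specificity, precision and recall report
#'
#' Specificity, precision and recall are computed one-vs-rest per class and
#' macro-averaged over the four classes. A ratio with zero denominator is
#' reported as 0 and flagged.
#'
#' @param pred,truth integer class vectors (0-3).
#' @param protocol optional protocol id recorded in the report.
#' @return object of class `metric_report`: list with `accuracy`,
#'   `specificity`, `precision`, `recall` (percent, macro), `per_class`
#'   data frame, `confusion`, `undefined_flags`, `protocol`, `n_trials`.
#' @export
metric_report <- function(pred, truth, protocol = NA_character_) {
  cm <- confusion_counts(pred, truth)
  total <- sum(cm)
  per <- lapply(1:4, function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- total - tp - fn - fp
    safe <- function(num, den) if (den == 0) c(0, TRUE) else c(100 * num / den, FALSE)
    sp <- safe(tn, tn + fp); pr <- safe(tp, tp + fp); rc <- safe(tp, tp + fn)
    data.frame(class = class_names()[c], specificity = sp[1], precision = pr[1],
               recall = rc[1], undefined = as.logical(sp[2] | pr[2] | rc[2]))
  })
  per <- do.call(rbind, per)
  structure(list(
    accuracy = 100 * sum(diag(cm)) / total,
    specificity = mean(per$specificity),
    precision = mean(per$precision),
    recall = mean(per$recall),
    per_class = per, confusion = cm,
    undefined_flags = per$class[per$undefined],
    protocol = protocol, n_trials = total
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report>%s n = %d trials\n",
              if (is.na(x$protocol)) "" else paste0(" [", x$protocol, "]"),
              x$n_trials))
  cat(sprintf("  accuracy %.2f%% | specificity %.2f%% | precision %.2f%% | recall %.2f%% (macro)\n",
              x$accuracy, x$specificity, x$precision, x$recall))
  if (length(x$undefined_flags))
    cat("  note: undefined ratios reported as 0 for class(es):",
        paste(x$undefined_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Partition subjects into train and test sets
#'
#' Subjects, not trials, are partitioned (subject-independent protocol): no
#' subject appears on both sides.
#'
#' @param subjects character vector of subject ids (one per trial, or
#'   unique).
#' @param train_frac fraction of subjects assigned to training
#'   (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` subject-id vectors.
#' @export
split_by_subject <- function(subjects, train_frac = 0.7, seed = 0L) {
  us <- sort(unique(subjects))
  if (length(us) < 2L) stop_named("too_few_subjects", "need at least 2 subjects")
  n_train <- max(1L, min(length(us) - 1L, round(train_frac * length(us))))
  perm <- with_seed(seed, sample(us))
  list(train = sort(perm[seq_len(n_train)]), test = sort(perm[-seq_len(n_train)]))
}

#' Default configuration of the synthetic benchmark
#'
#' Study conditions for the desk-scale benchmark: 6 training and 3 test
#' subjects, 16 trials each, 120 s trials, a reduced grid (n in {50, 150},
#' beta in {1e-3, 1e-4}), and a nontrivial sensor-brand shift for the
#' cross-environment protocols (EDA gain 1.3 / offset +2 uS, ECG gain 1.2,
#' ST offset +0.8 degC).
#'
#' @param n_train_subjects,n_test_subjects subject counts.
#' @param trials_per_subject trials per subject.
#' @param duration_s trial length in seconds.
#' @param shift a [domain_shift()] for the cross-environment protocols.
#' @param grid_n,grid_beta classifier search grid.
#' @param folds cross-validation folds.
#' @param calib_mode calibration mode (`"directional"` or `"literal"`).
#' @param calib_alpha,max_k G-means parameters.
#' @param sensor_set sensors to use.
#' @return a named list of benchmark settings.
#' @export
benchmark_config <- function(n_train_subjects = 6L, n_test_subjects = 3L,
                             trials_per_subject = 16L, duration_s = 120,
                             shift = domain_shift(ecg_gain = 1.2,
                                                  eda_gain = 1.3, eda_offset = 2,
                                                  st_gain = 1, st_offset = 0.8),
                             grid_n = c(50, 150),
                             grid_beta = c(1e-3, 1e-4),
                             folds = 10L,
                             calib_mode = "directional",
                             calib_alpha = 0.10, max_k = 16L,
                             sensor_set = c("ecg", "eda", "st")) {
  if (n_train_subjects < 2L || n_test_subjects < 1L)
    stop_named("invalid_config", "need >= 2 training and >= 1 test subjects")
  as.list(environment())
}

per_subject_accuracy <- function(pred, features) {
  stats::aggregate(correct ~ subject_id,
                   data = data.frame(subject_id = features$subject_id,
                                     correct = pred == features$class_index),
                   FUN = function(z) 100 * mean(z))
}

#' Run the full synthetic benchmark (all three protocols, one training)
#'
#' Generates a training environment (subjects "S*"), a same-environment
#' test population and a cross-environment test population (fresh subjects
#' "E*" recorded under the configured sensor-brand shift), trains the
#' classifier once on the training subjects, and evaluates it on: the
#' same-environment test subjects; the shifted test subjects without
#' calibration; and the shifted test subjects after calibration against the
#' training subjects' G-means profiles.
#'
#' @param config a [benchmark_config()].
#' @param seed integer seed.
#' @return list with `same_env`, `cross_env_nocal`, `cross_env_cal`
#'   (each a `metric_report` with a `per_subject` accuracy table attached),
#'   the fitted `model`, `profiles`, and the calibration `audit`.
#' @export
run_benchmark <- function(config = benchmark_config(), seed = 0L) {
  cfg <- config
  train_trials <- gen_dataset(cfg$n_train_subjects, cfg$trials_per_subject,
                              cfg$duration_s, shift = NULL,
                              seed = derive_seed(seed, "train-env"),
                              subject_prefix = "S")
  same_trials <- gen_dataset(max(cfg$n_test_subjects, 2L), cfg$trials_per_subject,
                             cfg$duration_s, shift = NULL,
                             seed = derive_seed(seed, "same-env-test"),
                             subject_prefix = "Q")
  cross_trials <- gen_dataset(max(cfg$n_test_subjects, 2L), cfg$trials_per_subject,
                              cfg$duration_s, shift = cfg$shift,
                              seed = derive_seed(seed, "cross-env-test"),
                              subject_prefix = "E")
  keep_n <- cfg$n_test_subjects * cfg$trials_per_subject
  same_trials <- same_trials[seq_len(keep_n)]
  cross_trials <- cross_trials[seq_len(keep_n)]

  fc <- feature_config()
  f_train <- extract_features_dataset(train_trials, fc)
  f_same <- extract_features_dataset(same_trials, fc)
  f_cross <- extract_features_dataset(cross_trials, fc)

  model <- cnn_esn(f_train, sensor_set = cfg$sensor_set, grid_n = cfg$grid_n,
                   grid_beta = cfg$grid_beta, folds = cfg$folds,
                   seed = derive_seed(seed, "model"))
  profiles <- build_profiles(f_train, alpha = cfg$calib_alpha,
                             max_k = cfg$max_k,
                             seed = derive_seed(seed, "profiles"))
  cal <- calibrate_features(f_cross, profiles, mode = cfg$calib_mode)

  eval_on <- function(feats, protocol) {
    pred <- predict(model, feats)
    rep <- metric_report(pred, feats$class_index, protocol)
    rep$per_subject <- per_subject_accuracy(pred, feats)
    rep
  }
  list(same_env = eval_on(f_same, "same_env"),
       cross_env_nocal = eval_on(f_cross, "cross_env_nocal"),
       cross_env_cal = eval_on(cal$features, "cross_env_cal"),
       model = model, profiles = profiles, audit = cal$audit)
}

#' Run one evaluation protocol
#'
#' Thin wrapper over [run_benchmark()] returning the single requested
#' protocol's report: `"same_env"` (subject split within one recording
#' environment), `"cross_env_nocal"` (test environment under a sensor-brand
#' shift, no calibration) or `"cross_env_cal"` (the same with feature
#' calibration).
#'
#' @param protocol one of `"same_env"`, `"cross_env_nocal"`,
#'   `"cross_env_cal"`.
#' @param config a [benchmark_config()].
#' @param seed integer seed.
#' @return a `metric_report` (with per-subject accuracies attached).
#' @export
run_protocol <- function(protocol = c("same_env", "cross_env_nocal",
                                      "cross_env_cal"),
                         config = benchmark_config(), seed = 0L) {
  protocol <- match.arg(protocol)
  run_benchmark(config, seed)[[protocol]]
}
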