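# End-to-end orchestration: simulate or read a cohort, pre-process, balance,
# fit the strategy x modality classifier grid, evaluate classification and
# clinical stratification, rank strategies and report subtype markers.

#' Subset a cohort to a sample set
#'
#' @param cohort an \code{omics_cohort}.
#' @param samples sample identifiers to keep (order preserved as given).
#' @return an \code{omics_cohort}.
#' @export
subset_cohort <- function(cohort, samples) {
  miss <- setdiff(samples, cohort$samples)
  if (length(miss)) stop("unknown sample(s): ", paste(head(miss, 5), collapse = ", "))
  sub <- function(m) gene_sample_matrix(m$values[, samples, drop = FALSE], m$modality)
  structure(list(mutation = sub(cohort$mutation), cna = sub(cohort$cna),
                 meth = sub(cohort$meth),
                 clinical = cohort$clinical[match(samples, cohort$clinical$sample), ,
                                            drop = FALSE],
                 samples = samples,
                 labels = if (is.null(cohort$labels)) NULL else cohort$labels[samples]),
            class = "omics_cohort")
}

#' Stratified train/test split of a cohort
#'
#' @param cohort a labelled \code{omics_cohort}.
#' @param n_test held-out sample count.
#' @param seed split seed.
#' @return list with \code{train} and \code{test} cohorts.
#' @export
split_cohort <- function(cohort, n_test, seed = 1L) {
  if (is.null(cohort$labels)) stop("split_cohort needs labels for stratification")
  n <- length(cohort$samples)
  if (n_test <= 0 || n_test >= n) stop("n_test must be in (0, n)")
  with_seed(seed, {
    frac <- n_test / n
    test <- character()
    for (cl in unique(cohort$labels)) {
      idx <- sample(cohort$samples[cohort$labels == cl])
      test <- c(test, head(idx, round(length(idx) * frac)))
    }
    train <- setdiff(cohort$samples, test)
    list(train = subset_cohort(cohort, sort(train)),
         test = subset_cohort(cohort, sort(test)))
  })
}

#' Impute and scale a train/test cohort pair without leakage
#'
#' Drops methylation genes exceeding the missingness threshold on the
#' training set (the same genes are dropped from the test set), imputes
#' each split with \code{\link{impute_knn}}, then fits min-max scalers on
#' the training samples only and applies them to both splits with clipping.
#'
#' @param train,test \code{omics_cohort} objects (\code{test} may be NULL).
#' @param k imputation neighbour count.
#' @param max_missing_fraction gene-dropping threshold (on the training
#'   split).
#' @return list with \code{train}, \code{test}, \code{scalers}.
#' @export
preprocess_cohorts <- function(train, test = NULL, k = 10,
                               max_missing_fraction = 0.5) {
  frac <- rowMeans(is.na(train$meth$values))
  keep <- names(frac)[frac <= max_missing_fraction]
  if (!length(keep)) stop("all methylation genes exceed the missingness threshold")
  restrict <- function(co) {
    co$meth <- gene_sample_matrix(co$meth$values[keep, , drop = FALSE],
                                  "methylation")
    co$meth <- impute_knn(co$meth, k = k, max_missing_fraction = 1)
    co
  }
  train <- restrict(train)
  sc <- scale_cohort(train, train$samples)
  train <- sc$cohort
  if (!is.null(test)) {
    test <- restrict(test)
    test$mutation <- gene_sample_matrix(
      apply_scaler(test$mutation, sc$scalers$mutation)$values, "mutation")
    test$cna <- apply_scaler(test$cna, sc$scalers$cna)
    test$meth <- apply_scaler(test$meth, sc$scalers$meth)
  }
  list(train = train, test = test, scalers = sc$scalers)
}

#' Pipeline run configuration
#'
#' @param simulate list of \code{\link{sim_config}} overrides (or
#'   \code{NULL} to read from \code{paths}).
#' @param paths list with \code{dir} pointing at a cohort directory written
#'   by \code{\link{write_cohort}}.
#' @param n_train,n_test training and held-out sample counts for simulated
#'   cohorts (for \code{paths} input, \code{n_test} is drawn from the read
#'   cohort by stratified split).
#' @param strategies strategy names to evaluate.
#' @param modalities modality codes per classifier (subsets of G/C/M, or
#'   \code{"A"} for all three).
#' @param smote_k SMOTE neighbour count.
#' @param cv_folds,nlambda,decades cross-validation settings.
#' @param marker_alpha adjusted-p threshold for marker discovery.
#' @param reference_sex Cox reference sex.
#' @param seed master seed for the whole run.
#' @param out output directory (\code{NULL}: nothing written).
#' @return a \code{run_config} list.
#' @export
run_config <- function(simulate = list(), paths = NULL,
                       n_train = 600, n_test = 300,
                       strategies = c("I-MC", "II-HC", "III-HC"),
                       modalities = "A",
                       smote_k = 5, cv_folds = 5, nlambda = 30, decades = 3,
                       marker_alpha = 1e-5, reference_sex = "female",
                       seed = 1L, out = NULL) {
  cfg <- list(simulate = simulate, paths = paths, n_train = n_train,
              n_test = n_test, strategies = strategies,
              modalities = modalities, smote_k = smote_k,
              cv_folds = cv_folds, nlambda = nlambda, decades = decades,
              marker_alpha = marker_alpha, reference_sex = reference_sex,
              seed = as.integer(seed), out = out)
  if (!length(cfg$modalities)) stop("modalities must be non-empty")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in \code{\link{run_config}}.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full subtyping pipeline
#'
#' Simulates (or reads) a labelled cohort, splits it into training and
#' held-out sets, pre-processes without leakage, SMOTE-balances the
#' training set once, fits every configured strategy x modality classifier,
#' evaluates held-out classification metrics and whole-cohort clinical
#' stratification per classifier, ranks the classifiers, and reports
#' alteration rates and subtype-specific markers for the selected
#' classifier. All artifacts are written under \code{config$out} (when set)
#' with the seed and configuration embedded; reruns with the same
#' configuration and seed reproduce all outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with cohorts, fitted classifiers, metric and
#'   survival reports, the comparison table, rates and markers.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  if (!is.null(config$paths)) {
    dir <- config$paths$dir
    say("stage read: %s", dir)
    mut <- read_matrix(file.path(dir, "mutation.tsv"), "mutation")
    cna <- read_matrix(file.path(dir, "cna.tsv"), "cna")
    meth <- read_matrix(file.path(dir, "methylation.tsv"), "methylation")
    clin <- read_clinical(file.path(dir, "clinical.tsv"))
    lab <- read.delim(file.path(dir, "labels.tsv"), stringsAsFactors = FALSE)
    labels <- setNames(lab$subtype, lab$sample)
    cohort <- assemble_cohort(mut, cna, meth, clin, labels)
    truth <- NULL
  } else {
    sim_args <- config$simulate
    sim_args$n_samples <- config$n_train + config$n_test
    sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    say("stage simulate: n=%d, %d/%d/%d genes", scfg$n_samples,
        scfg$n_genes[1], scfg$n_genes[2], scfg$n_genes[3])
    sim <- simulate_cohort(scfg)
    cohort <- sim$cohort
    truth <- sim$truth
  }
  split <- split_cohort(cohort, config$n_test, seed = seed + 1L)
  say("stage split: train=%d test=%d", length(split$train$samples),
      length(split$test$samples))
  prep <- preprocess_cohorts(split$train, split$test)
  say("stage preprocess: %d methylation genes retained",
      nrow(prep$train$meth$values))

  X_train <- cohort_features(prep$train, "A")
  y_train <- prep$train$labels
  X_test <- cohort_features(prep$test, "A")
  y_test <- prep$test$labels

  classifiers <- list(); metric_reports <- list(); survival_reports <- list()
  predicted <- list()
  clin_all <- cohort$clinical
  # clinical stratification uses the classifier's predicted subtypes on all
  # samples (original training samples plus held-out samples)
  X_all <- rbind(cohort_features(prep$train, "A"), X_test)
  for (st in config$strategies) for (md in config$modalities) {
    nm <- sprintf("%s(%s)", st, md)
    cols <- colnames(cohort_features(prep$train, md))
    say("stage train+evaluate: %s (%d features)", nm, length(cols))
    casc <- fit_cascade(X_train[, cols, drop = FALSE], y_train,
                        tree = st, cv_folds = config$cv_folds,
                        nlambda = config$nlambda, decades = config$decades,
                        seed = seed + 3L, smote_k = config$smote_k)
    proba <- predict_subtype_proba(casc, X_test[, cols, drop = FALSE])
    rep_ <- evaluate_multiclass(y_test, proba)
    pred_all <- predict_subtype(casc, X_all[, cols, drop = FALSE])
    names(pred_all) <- rownames(X_all)
    pred_all <- pred_all[clin_all$sample]
    sr <- tryCatch(
      fit_multivariate_cox(pred_all, clin_all$age, clin_all$sex,
                           clin_all$os_time, clin_all$os_event,
                           reference_sex = config$reference_sex),
      error = function(e) {
        warning("survival model for ", nm, " failed: ", conditionMessage(e))
        structure(list(terms = NULL, overall_p = NA_real_,
                       reference = NULL, n = nrow(clin_all),
                       n_events = sum(clin_all$os_event)),
                  class = "survival_report")
      })
    classifiers[[nm]] <- casc
    metric_reports[[nm]] <- rep_
    survival_reports[[nm]] <- sr
    predicted[[nm]] <- pred_all
  }
  comparison <- rank_strategies(metric_reports, survival_reports)
  sel <- comparison$classifier[comparison$selected]
  say("stage rank: selected %s", sel)
  sel_casc <- classifiers[[sel]]
  sel_labels <- predicted[[sel]]
  # rates/markers on the full cohort (imputed, unscaled values) under the
  # selected classifier's labels
  full_imp <- cohort
  if (anyNA(full_imp$meth$values))
    full_imp$meth <- impute_knn(full_imp$meth)
  rates <- alteration_rates(full_imp, sel_labels)
  markers <- difference_tests(full_imp, sel_labels,
                              features = cascade_selected_features(sel_casc),
                              alpha = config$marker_alpha)
  say("stage markers: %d significant marker(s)", nrow(markers))

  result <- list(config = config, cohort = cohort, truth = truth,
                 split = split, classifiers = classifiers,
                 metric_reports = metric_reports,
                 survival_reports = survival_reports,
                 predicted = predicted, comparison = comparison,
                 selected = sel, rates = rates, markers = markers)
  if (!is.null(config$out)) write_run_artifacts(result, config$out)
  invisible(result)
}

write_run_artifacts <- function(result, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  meta <- list(seed = cfg$seed,
               config = cfg[setdiff(names(cfg), "out")])
  yaml::write_yaml(meta$config, file.path(out, "run_config.yaml"))
  for (nm in names(result$metric_reports)) {
    rep_ <- result$metric_reports[[nm]]
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    jsonlite::write_json(list(meta = meta, classifier = nm,
                              per_class = rep_$per_class,
                              overall = as.list(rep_$overall),
                              confusion = as.data.frame(rep_$confusion)),
                         file.path(out, paste0("metrics_", safe, ".json")),
                         auto_unbox = TRUE, digits = NA)
    sr <- result$survival_reports[[nm]]
    write.table(sr$terms, file.path(out, paste0("survival_", safe, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(result$comparison, file.path(out, "comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$rates, file.path(out, "rates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$markers, file.path(out, "markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pred <- data.frame(sample = names(result$predicted[[result$selected]]),
                     subtype = unname(result$predicted[[result$selected]]))
  write.table(pred, file.path(out, "predicted_subtypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Serialise a sparse node model to versioned JSON
#'
#' Stores classes, intercepts, lambda and the nonzero coefficients as
#' (feature, class, value) triplets.
#'
#' @param model a \code{sparse_model}.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  nz <- which(abs(model$coefficients) > 0, arr.ind = TRUE)
  jsonlite::write_json(
    list(format = "hcg-sparse-model", version = 1L,
         classes = model$classes, lambda = model$lambda,
         intercepts = as.list(setNames(model$intercepts, model$classes)),
         features = model$features,
         coefficients = data.frame(
           feature = model$features[nz[, 1]],
           class = model$classes[nz[, 2]],
           value = model$coefficients[nz])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sparse node model from JSON
#'
#' @param path file written by \code{\link{write_model_json}}.
#' @return a \code{sparse_model}.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "hcg-sparse-model"))
    stop("not a sparse-model JSON file")
  B <- matrix(0, length(x$features), length(x$classes),
              dimnames = list(x$features, x$classes))
  if (length(x$coefficients) && nrow(as.data.frame(x$coefficients))) {
    cf <- as.data.frame(x$coefficients)
    B[cbind(match(cf$feature, x$features), match(cf$class, x$classes))] <- cf$value
  }
  structure(list(classes = x$classes, coefficients = B,
                 intercepts = setNames(unlist(x$intercepts), x$classes),
                 lambda = x$lambda, features = x$features),
            class = "sparse_model")
}
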