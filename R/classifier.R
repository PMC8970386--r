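# Gender-specific linear classifier: genetic-algorithm feature-subset
# search wrapped around a linear SVM on the core features plus quadratic
# age terms, followed by calibration of the index scale (cut-off 0,
# AD-cohort standard-deviation units).

.standardize <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, s, "/"), mu = mu, sd = s)
}

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Hyperplane of a fitted linear SVM in input space, oriented so DLB
# scores high: f(x) = x . w - rho, with the decision value's positive
# class being levels[labels[1]].
.svm_hyperplane <- function(model) {
  w <- drop(t(model$coefs) %*% model$SV)
  b <- -model$rho
  if (model$levels[model$labels[1]] != "DLB") {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

# linear SVM decision values oriented so that DLB scores high
.svm_decision <- function(model, X) {
  h <- .svm_hyperplane(model)
  drop(X %*% h$w) + h$b
}

#' Cross-validated AUC of the linear SVM on a feature subset
#'
#' Stratified k-fold cross-validation; held-out decision values are
#' pooled over folds and summarized by a single ROC AUC (DLB positive).
#'
#' @param X numeric matrix (subjects x features), already standardized.
#' @param labels character vector (`"DLB"`/`"AD"`).
#' @param folds integer fold assignment per subject.
#' @param cost SVM cost parameter.
#' @return AUC in `[0, 1]`.
#' @export
svm_cv_auc <- function(X, labels, folds, cost = 1) {
  scores <- numeric(length(labels))
  y <- factor(labels, levels = c("DLB", "AD"))
  for (f in unique(folds)) {
    tr <- folds != f
    m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                    cost = cost, scale = FALSE)
    scores[!tr] <- .svm_decision(m, X[!tr, , drop = FALSE])
  }
  roc_auc(scores, labels)
}

#' Genetic-algorithm feature-subset selection
#'
#' Searches binary masks over the core features maximizing
#' `CV-AUC - parsimony * (mask size / n_features)`, where the CV-AUC is
#' the stratified k-fold cross-validated AUC of the linear SVM on the
#' masked features plus the age and age-squared columns (always
#' included).  Standard GA with tournament selection, uniform crossover,
#' per-bit mutation and elitism; the population is initialized sparse
#' (each bit on with probability `init_density`), which both speeds the
#' search up and starts it in the small-subset region the parsimony term
#' favors.  The search stops early once the best fitness has improved by
#' less than `min_improve` over `patience` consecutive generations.
#'
#' @param C core-feature matrix (subjects x n_features).
#' @param age ages in years.
#' @param labels `"DLB"`/`"AD"` per subject.
#' @param config GA configuration, see [default_config()]`$ga`.
#' @param cost SVM cost.
#' @param seed RNG seed for the whole search.
#' @return List: `mask` (logical), `fitness`, `history` (best fitness per
#'   generation), `feature_auc` (individual folded AUC per feature),
#'   `n_evaluated`.
#' @export
ga_select_features <- function(C, age, labels, config = default_config()$ga,
                               cost = 1, seed = 1L) {
  n <- nrow(C)
  nf <- ncol(C)
  labels <- as.character(labels)
  if (min(table(labels)) < 10)
    dlb_log("fewer than 10 subjects per class; GA selection may be unstable")
  set.seed(seed)
  std <- .standardize(cbind(C, age, age^2))
  X <- std$X
  folds <- .stratified_folds(labels, config$cv_folds)
  age_cols <- nf + 1:2

  feature_auc <- apply(C, 2, function(x) {
    a <- roc_auc(x, labels); max(a, 1 - a)
  })
  best_single <- which.max(feature_auc)

  fitness_cache <- new.env(hash = TRUE, parent = emptyenv())
  evals <- 0L
  fitness <- function(mask) {
    if (!any(mask)) mask[best_single] <- TRUE
    key <- paste(which(mask), collapse = ",")
    got <- fitness_cache[[key]]
    if (!is.null(got)) return(got)
    auc <- svm_cv_auc(X[, c(which(mask), age_cols), drop = FALSE],
                      labels, folds, cost)
    fit <- auc - config$parsimony * sum(mask) / nf
    fitness_cache[[key]] <- fit
    evals <<- evals + 1L
    fit
  }

  pop_n <- config$population
  pop <- matrix(stats::runif(pop_n * nf) < config$init_density, pop_n, nf)
  empty <- rowSums(pop) == 0
  pop[empty, best_single] <- TRUE
  fit <- apply(pop, 1, fitness)

  history <- numeric(0)
  best_ref <- -Inf
  stall <- 0L
  for (gen in seq_len(config$generations)) {
    o <- order(-fit)
    pop <- pop[o, , drop = FALSE]
    fit <- fit[o]
    history <- c(history, fit[1])
    # convergence: stop when the best fitness has stopped improving
    if (fit[1] > best_ref + config$min_improve) {
      best_ref <- fit[1]
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= config$patience) break
    if (gen == config$generations) break

    nxt <- matrix(FALSE, pop_n, nf)
    nxt[seq_len(config$elitism), ] <- pop[seq_len(config$elitism), ,
                                          drop = FALSE]
    for (i in (config$elitism + 1):pop_n) {
      # tournament selection for both parents
      t1 <- sample.int(pop_n, config$tournament_k)
      t2 <- sample.int(pop_n, config$tournament_k)
      p1 <- pop[t1[which.max(fit[t1])], ]
      p2 <- pop[t2[which.max(fit[t2])], ]
      take <- stats::runif(nf) < config$crossover_p
      child <- ifelse(take, p1, p2)
      # floor the per-bit rate at 1/nf so one bit flips per child in
      # expectation even on small problems
      flip <- stats::runif(nf) < max(config$mutation_p, 1 / nf)
      child <- xor(child, flip)
      if (!any(child)) child[best_single] <- TRUE
      nxt[i, ] <- child
    }
    pop <- nxt
    fit <- apply(pop, 1, fitness)
  }
  o <- order(-fit)
  mask <- pop[o[1], ]
  if (!any(mask)) mask[best_single] <- TRUE
  list(mask = as.logical(mask), fitness = fit[o[1]], history = history,
       feature_auc = feature_auc, n_evaluated = evals)
}

#' Fit the linear SVM and express it in index-formula coefficients
#'
#' Trains a linear soft-margin SVM on the standardized masked core
#' features plus age and age-squared, then de-standardizes the decision
#' function into the coefficients of the explicit index formula
#' `I_raw = sum(C * beta) + beta_age1 * A + beta_age2 * A^2 + rho`, which
#' reproduces the SVM decision value exactly.  Features dropped by the
#' mask (and zero-variance features) get `beta = 0`.
#'
#' @param C core-feature matrix (subjects x n_features).
#' @param age ages in years.
#' @param labels `"DLB"`/`"AD"`.
#' @param mask logical feature mask (default: all).
#' @param cost SVM cost.
#' @return List: `beta` (length n_features), `beta_age1`, `beta_age2`,
#'   `rho`, `mask`, `raw_index` (training decision values, DLB high).
#' @export
train_svm <- function(C, age, labels, mask = rep(TRUE, ncol(C)), cost = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    dlb_stop("dlb_value_error", "both classes required to train the SVM")
  Xraw <- cbind(C[, mask, drop = FALSE], age, age^2)
  sds <- apply(Xraw, 2, stats::sd)
  usable <- is.finite(sds) & sds > 1e-12
  if (!all(usable))
    dlb_log(sum(!usable), " zero-variance column(s) dropped from the SVM")
  std <- .standardize(Xraw[, usable, drop = FALSE])
  y <- factor(labels, levels = c("DLB", "AD"))
  m <- e1071::svm(std$X, y, kernel = "linear", cost = cost, scale = FALSE)
  h <- .svm_hyperplane(m)
  w_std <- h$w
  b_std <- h$b
  # de-standardize: f(x) = sum w_j (x_j - mu_j)/s_j + b
  w_raw_u <- w_std / std$sd
  b_raw <- b_std - sum(w_std * std$mu / std$sd)
  w_raw <- numeric(ncol(Xraw))
  w_raw[usable] <- w_raw_u
  k <- sum(mask)
  beta <- numeric(ncol(C))
  beta[mask] <- w_raw[seq_len(k)]
  beta_age1 <- w_raw[k + 1]
  beta_age2 <- w_raw[k + 2]
  raw <- drop(C %*% beta + beta_age1 * age + beta_age2 * age^2 + b_raw)
  list(beta = beta, beta_age1 = beta_age1, beta_age2 = beta_age2,
       rho = b_raw, mask = mask, raw_index = raw)
}

#' Calibrate the index scale
#'
#' Finds the raw-index cut-off maximizing Youden's J (sensitivity +
#' specificity - 1) on the training ROC -- candidate cut-offs are the
#' midpoints between consecutive sorted raw indices, ties resolved to the
#' midpoint closest to the midpoint of the class medians -- and the
#' standard deviation of the AD training cohort's raw indices.  The
#' scaled index is `(raw - cutoff) / sd_ad`, so 0 is the decision
#' threshold and units are AD-cohort standard deviations.
#'
#' @param raw_index raw decision values (DLB high).
#' @param labels `"DLB"`/`"AD"`.
#' @return List: `cutoff`, `sd_ad`.
#' @export
calibrate_index_scale <- function(raw_index, labels) {
  labels <- as.character(labels)
  stopifnot(length(raw_index) == length(labels))
  if (!all(c("DLB", "AD") %in% labels))
    dlb_stop("dlb_value_error", "both classes required for calibration")
  sd_ad <- stats::sd(raw_index[labels == "AD"])
  if (!is.finite(sd_ad) || sd_ad <= 0)
    dlb_stop("dlb_calibration_error",
             "AD training indices have zero or undefined spread")
  u <- sort(unique(raw_index))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  J <- vapply(cand, function(t) {
    mean(raw_index[labels == "DLB"] >= t) +
      mean(raw_index[labels == "AD"] < t) - 1
  }, 0)
  best <- which(J == max(J))
  if (length(best) > 1) {
    mid <- (stats::median(raw_index[labels == "DLB"]) +
              stats::median(raw_index[labels == "AD"])) / 2
    best <- best[which.min(abs(cand[best] - mid))]
  }
  list(cutoff = cand[best], sd_ad = sd_ad)
}

.train_stratum <- function(features, labels, config, seed, gender) {
  set.seed(seed)
  X <- .base_matrix(lapply(features, function(s) s$base))
  pca <- fit_pca_per_pair(X)
  ranking <- if (identical(config$pca$ranking, "auc"))
    rank_components_by_auc(pca, X, labels) else NULL
  basis <- select_top_components(pca, ranking)
  core <- lapply(features, project_core_features, basis = basis,
                 estimator = config$spectral$estimator)
  C <- do.call(rbind, lapply(core, function(x) x$C))
  ages <- vapply(features, function(s) as.numeric(s$age), 0)
  if (anyNA(ages))
    dlb_stop("dlb_age_required_error", "age is required for every subject")
  ga <- ga_select_features(C, ages, labels, config = config$ga,
                           cost = config$svm$cost, seed = seed + 1L)
  fit <- train_svm(C, ages, labels, mask = ga$mask, cost = config$svm$cost)
  cal <- calibrate_index_scale(fit$raw_index, labels)
  structure(list(
    gender = gender, beta = fit$beta, beta_age1 = fit$beta_age1,
    beta_age2 = fit$beta_age2, rho = fit$rho, feature_mask = ga$mask,
    calibration = cal, basis = basis, seed = seed,
    ga_history = ga$history, cv_fitness = ga$fitness,
    train = list(labels = labels, raw_index = fit$raw_index,
                 core = C,
                 index = (fit$raw_index - cal$cutoff) / cal$sd_ad)),
    class = "dlb_classifier")
}

#' Train the gender-specific classifier models
#'
#' Runs the full training chain per gender stratum: per-pair PCA on the
#' robust base features, AUC component ranking, top-2 selection, core
#' projection, GA feature selection, linear SVM fit and index
#' calibration.  Strata with fewer than `min_per_class` subjects in
#' either class fall back to a pooled model (classed warning); the pooled
#' model is also trained whenever any stratum needs it.
#'
#' @param features list of `subject_features` (must carry age and
#'   gender).
#' @param labels `"DLB"`/`"AD"` per subject.
#' @param config pipeline configuration.
#' @return Object of class `dlb_model_set` with elements `models` (named
#'   list with entries among `"M"`, `"F"`, `"pooled"`), `config`, `seed`.
#' @export
train_model <- function(features, labels, config = default_config()) {
  labels <- as.character(labels)
  stopifnot(length(features) == length(labels))
  genders <- vapply(features, function(s) as.character(s$gender), "")
  models <- list()
  need_pooled <- FALSE
  offs <- c(M = 101L, F = 202L)
  for (g in c("M", "F")) {
    idx <- which(genders == g)
    if (length(idx) == 0) next
    tab <- table(factor(labels[idx], levels = c("DLB", "AD")))
    if (min(tab) >= config$model$min_per_class) {
      models[[g]] <- .train_stratum(features[idx], labels[idx], config,
                                    seed = config$seed + offs[[g]],
                                    gender = g)
    } else {
      dlb_warn("dlb_pooled_fallback_warning",
               sprintf("gender stratum %s has %d/%d DLB/AD subjects; using pooled model",
                       g, tab[["DLB"]], tab[["AD"]]))
      need_pooled <- TRUE
    }
  }
  if (need_pooled || length(models) == 0) {
    models[["pooled"]] <- .train_stratum(features, labels, config,
                                         seed = config$seed + 303L,
                                         gender = "pooled")
  }
  structure(list(models = models, config = config, seed = config$seed,
                 config_hash = config_hash(config)),
            class = "dlb_model_set")
}

#' Compute the classification index for one recording
#'
#' Evaluates the calibrated index
#' `I = (sum(C * beta) + beta_age1 A + beta_age2 A^2 + rho - cutoff) / sd_ad`
#' and classifies as DLB when `I >= 0`, AD otherwise.
#'
#' @param core a `core_features` object (must carry age).
#' @param model a `dlb_classifier` (one gender stratum).
#' @return List: `index` (AD-SD units), `classification`.
#' @export
compute_index <- function(core, model) {
  stopifnot(inherits(core, "core_features"), inherits(model, "dlb_classifier"))
  if (is.na(core$age))
    dlb_stop("dlb_age_required_error", "subject age is required")
  raw <- sum(core$C * model$beta) + model$beta_age1 * core$age +
    model$beta_age2 * core$age^2 + model$rho
  idx <- (raw - model$calibration$cutoff) / model$calibration$sd_ad
  list(index = idx, classification = if (idx >= 0) "DLB" else "AD")
}

#' Classify one subject with the appropriate gender model
#'
#' Selects the subject's gender-specific model, falling back to the
#' pooled model when that stratum was not trained.
#'
#' @param subject a `subject_features` object.
#' @param model_set a `dlb_model_set`.
#' @return List: `subject_id`, `index`, `classification`.
#' @export
classify_subject <- function(subject, model_set) {
  stopifnot(inherits(subject, "subject_features"),
            inherits(model_set, "dlb_model_set"))
  g <- as.character(subject$gender)
  model <- model_set$models[[g]]
  if (is.null(model)) model <- model_set$models[["pooled"]]
  if (is.null(model))
    dlb_stop("dlb_value_error",
             paste0("no model available for gender ", g))
  core <- project_core_features(subject, model$basis,
                                estimator = model_set$config$spectral$estimator)
  res <- compute_index(core, model)
  list(subject_id = subject$subject_id, index = res$index,
       classification = res$classification)
}

#' Save / load a trained model set
#'
#' Versioned single-file archive (RDS).
#' @param model_set a `dlb_model_set`.
#' @param path archive path.
#' @return `path` (save) / the model set (load).
#' @export
save_model <- function(model_set, path) {
  stopifnot(inherits(model_set, "dlb_model_set"))
  saveRDS(list(format = "dlbindex-model", version = 1L, model = model_set),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dlbindex-model"))
    dlb_stop("dlb_format_error", "not a dlbindex model archive")
  obj$model
}
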