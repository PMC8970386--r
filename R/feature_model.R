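# Per-channel-pair PCA of the 180-dimensional (90 frequencies x re/im)
# base-feature blocks, ROC-AUC ranking of components, selection of the
# two most discriminative components per pair (380 core features), and
# projection of recordings into the core space.

.pair_block_idx <- function(p) ((p - 1) * 180 + 1):(p * 180)

.base_matrix <- function(training) {
  if (is.matrix(training)) return(training)
  do.call(rbind, lapply(training, function(s) {
    if (inherits(s, "subject_features")) {
      if (is.null(s$base))
        dlb_stop("dlb_value_error",
                 "features were extracted with with_base = FALSE; base features are required here")
      s$base$values
    } else if (inherits(s, "base_features")) s$values
    else dlb_stop("dlb_value_error", "expected base_features objects")
  }))
}

#' Fit the per-pair principal component bases
#'
#' For every channel pair, computes the principal components of the
#' mean-centred 180-dimensional per-pair feature block across training
#' subjects (covariance PCA; no variance scaling, which downstream SVM
#' standardization absorbs).  Up to `min(n_subjects - 1, 180)` components
#' with non-negligible variance are kept for ranking; zero-variance
#' directions are dropped with a log entry.
#'
#' @param training matrix (subjects x features) or list of
#'   `base_features` / `subject_features`.
#' @return Object of class `pca_full`: per-pair orthonormal loadings and
#'   singular values, plus the global training-mean vector `center`.
#' @export
fit_pca_per_pair <- function(training) {
  X <- .base_matrix(training)
  n <- nrow(X)
  stopifnot(n >= 2)
  if (any(!is.finite(X)))
    dlb_stop("dlb_value_error", "non-finite training features")
  n_pairs <- ncol(X) / 180
  center <- colMeans(X)
  pair_fits <- lapply(seq_len(n_pairs), function(p) {
    idx <- .pair_block_idx(p)
    B <- sweep(X[, idx, drop = FALSE], 2, center[idx])
    sv <- svd(B, nu = 0)
    keep <- sv$d > max(sv$d[1], 1) * 1e-12
    if (!any(keep)) {
      dlb_log("pair ", p, ": zero-variance block, no components")
      return(list(loadings = matrix(0, 180, 0), sdev = numeric()))
    }
    list(loadings = sv$v[, keep, drop = FALSE],
         sdev = sv$d[keep] / sqrt(max(n - 1, 1)))
  })
  structure(list(pairs = pair_fits, center = center, n_pairs = n_pairs,
                 n_subjects = n),
            class = "pca_full")
}

#' Per-subject component scores for all fitted components
#'
#' Projects centred subject-level feature blocks onto every fitted
#' component; used both for AUC ranking and for leakage checks.
#'
#' @param pca a `pca_full` fit.
#' @param training matrix or list accepted by [fit_pca_per_pair()].
#' @return Matrix (subjects x total components) with a `component_map`
#'   attribute (data frame: pair, component).
#' @export
pca_component_scores <- function(pca, training) {
  X <- .base_matrix(training)
  scores <- vector("list", pca$n_pairs)
  map <- vector("list", pca$n_pairs)
  for (p in seq_len(pca$n_pairs)) {
    idx <- .pair_block_idx(p)
    B <- sweep(X[, idx, drop = FALSE], 2, pca$center[idx])
    L <- pca$pairs[[p]]$loadings
    scores[[p]] <- B %*% L
    map[[p]] <- data.frame(pair = rep(p, ncol(L)),
                           component = seq_len(ncol(L)))
  }
  out <- do.call(cbind, scores)
  attr(out, "component_map") <- do.call(rbind, map)
  out
}

#' Rank principal components by discriminatory AUC
#'
#' Computes, for every fitted component, the area under the ROC curve of
#' its subject scores against the DLB/AD labels, folded as
#' `max(AUC, 1 - AUC)` because a component's orientation is arbitrary.
#' Within each pair the ranking is by folded AUC descending, ties broken
#' by explained-variance order for determinism.
#'
#' @param pca a `pca_full` fit.
#' @param training matrix or list accepted by [fit_pca_per_pair()].
#' @param labels factor/character vector with classes `"DLB"` and `"AD"`.
#' @return Data frame (pair, component, auc, rank_in_pair).
#' @export
rank_components_by_auc <- function(pca, training, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    dlb_stop("dlb_ranking_error", "both classes required for AUC ranking")
  S <- pca_component_scores(pca, training)
  map <- attr(S, "component_map")
  pos <- labels == "DLB"
  auc <- apply(S, 2, function(s) {
    a <- roc_auc(s, labels)
    max(a, 1 - a)
  })
  rk <- data.frame(map, auc = as.numeric(auc))
  rk$rank_in_pair <- unlist(lapply(split(seq_len(nrow(rk)), rk$pair),
    function(ix) {
      o <- order(-rk$auc[ix], rk$component[ix])
      r <- integer(length(ix)); r[o] <- seq_along(ix); r
    }), use.names = FALSE)
  rk
}

#' Select the two most discriminative components per pair
#'
#' Retains, for each channel pair, the two components with the best
#' folded AUC (ties by explained-variance order), yielding the
#' 2 x n_pairs core feature space (380 features for the full montage).
#' Pairs with fewer than two fitted components are padded with a zero
#' loading and logged.
#'
#' @param pca a `pca_full` fit.
#' @param ranking output of [rank_components_by_auc()]; `NULL` selects
#'   the first two components by explained variance instead.
#' @return Object of class `pca_basis`: `loadings` (180 x 2 n_pairs
#'   matrix, column `2(p-1)+a` = component a of pair p), `center`,
#'   `ranking`, `fitted_on`.
#' @export
select_top_components <- function(pca, ranking = NULL) {
  n_pairs <- pca$n_pairs
  L <- matrix(0, 180, 2 * n_pairs)
  sel <- data.frame(pair = rep(seq_len(n_pairs), each = 2),
                    slot = rep(1:2, n_pairs), component = NA_integer_,
                    auc = NA_real_)
  for (p in seq_len(n_pairs)) {
    m <- ncol(pca$pairs[[p]]$loadings)
    if (is.null(ranking)) {
      take <- seq_len(min(2, m))
      aucs <- rep(NA_real_, length(take))
    } else {
      rp <- ranking[ranking$pair == p, , drop = FALSE]
      rp <- rp[order(rp$rank_in_pair), , drop = FALSE]
      take <- utils::head(rp$component, 2)
      aucs <- utils::head(rp$auc, 2)
    }
    if (length(take) < 2)
      dlb_log("pair ", p, ": fewer than 2 components; padding with zeros")
    for (a in seq_along(take)) {
      L[, 2 * (p - 1) + a] <- pca$pairs[[p]]$loadings[, take[a]]
      sel$component[2 * (p - 1) + a] <- take[a]
      sel$auc[2 * (p - 1) + a] <- aucs[a]
    }
  }
  structure(list(loadings = L, center = pca$center, selection = sel,
                 n_pairs = n_pairs,
                 fitted_on = list(n_subjects = pca$n_subjects)),
            class = "pca_basis")
}

#' Project a recording into the core feature space
#'
#' Evaluates, for every pair and selected component, the inner product of
#' each segment's centred 180-dimensional covariance block with the
#' component loading, then takes the robust expectation over segments
#' (the same estimator as the base-feature aggregation).  Centring uses
#' the training means stored in the basis.
#'
#' @param x an `eeg_covariance` tensor, an `eeg_spectra` object, or a
#'   `subject_features` object.
#' @param basis a `pca_basis`.
#' @param estimator robust estimator over segments (default `"median"`).
#' @param age,gender,subject_id metadata attached to the result
#'   (taken from `x` when it is a `subject_features`).
#' @return Object of class `core_features` with `C` (numeric, length
#'   2 n_pairs), `age`, `gender`, `subject_id`.
#' @export
project_core_features <- function(x, basis, estimator = "median",
                                  age = NA_real_, gender = NA_character_,
                                  subject_id = "anon") {
  if (inherits(x, "subject_features")) {
    age <- x$age; gender <- x$gender; subject_id <- x$subject_id
    x <- x$spectra
  }
  if (inherits(x, "eeg_spectra")) {
    pairs <- enumerate_pairs(dim(x$sigma)[2])
    if (nrow(pairs) != basis$n_pairs)
      dlb_stop("dlb_projection_error",
               "spectra and basis disagree on the number of pairs")
    S <- cpp_segment_scores_sigma(x$sigma, cbind(pairs$c - 1L, pairs$k - 1L),
                                  basis$loadings, basis$center)
  } else {
    stopifnot(inherits(x, "eeg_covariance"), inherits(basis, "pca_basis"))
    if (dim(x$chi)[2] != basis$n_pairs)
      dlb_stop("dlb_projection_error",
               "covariance tensor and basis disagree on the number of pairs")
    S <- cpp_segment_scores(x$chi, basis$loadings, basis$center)
  }
  C <- cpp_col_aggregate(S, .estimator_code(estimator), .dlb_trim_default)
  structure(list(C = as.numeric(C), age = age, gender = gender,
                 subject_id = subject_id),
            class = "core_features")
}
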