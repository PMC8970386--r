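# Per-pair PCA, AUC component ranking, top-2 selection, and projection
# into the core feature space.

# small synthetic base-feature matrix: n subjects x (n_pairs * 180)
.toy_base <- function(n = 14, n_pairs = 3, seed = 9) {
  set.seed(seed)
  matrix(rnorm(n * n_pairs * 180), n, n_pairs * 180)
}

test_that("per-pair PCA agrees with prcomp on each block", {
  X <- .toy_base()
  pca <- fit_pca_per_pair(X)
  expect_s3_class(pca, "pca_full")
  expect_equal(pca$center, colMeans(X))
  for (p in c(1, 3)) {
    idx <- ((p - 1) * 180 + 1):(p * 180)
    ref <- stats::prcomp(X[, idx], center = TRUE, scale. = FALSE)
    L <- pca$pairs[[p]]$loadings
    expect_equal(ncol(L), 13)          # n - 1 non-degenerate directions
    expect_equal(pca$pairs[[p]]$sdev, ref$sdev[1:13], tolerance = 1e-9)
    # loadings match up to sign
    dots <- abs(colSums(L * ref$rotation[, 1:13]))
    expect_equal(dots, rep(1, 13), tolerance = 1e-9, ignore_attr = TRUE)
    # orthonormal
    expect_equal(crossprod(L), diag(13), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_error(fit_pca_per_pair(X * NA), class = "dlb_value_error")
})

test_that("component scores are the centred projections", {
  X <- .toy_base()
  pca <- fit_pca_per_pair(X)
  S <- pca_component_scores(pca, X)
  map <- attr(S, "component_map")
  expect_equal(nrow(map), ncol(S))
  q <- which(map$pair == 2 & map$component == 4)
  idx <- (180 + 1):(2 * 180)
  manual <- sweep(X[, idx], 2, pca$center[idx]) %*%
    pca$pairs[[2]]$loadings[, 4]
  expect_equal(S[, q], drop(manual))
})

test_that("AUC ranking puts a discriminative direction first", {
  X <- .toy_base(n = 20)
  labels <- rep(c("DLB", "AD"), each = 10)
  # plant a direction in pair 2 that separates the classes perfectly
  set.seed(11)
  v <- rnorm(180); v <- v / sqrt(sum(v^2))
  X[, 181:360] <- X[, 181:360] +
    outer(ifelse(labels == "DLB", 6, -6) + rnorm(20, sd = 0.5), v)
  pca <- fit_pca_per_pair(X)
  rk <- rank_components_by_auc(pca, X, labels)
  expect_true(all(rk$auc >= 0.5 & rk$auc <= 1))
  top2 <- rk[rk$pair == 2 & rk$rank_in_pair == 1, ]
  expect_equal(top2$auc, 1)
  expect_error(rank_components_by_auc(pca, X, rep("DLB", 20)),
               class = "dlb_ranking_error")
})

test_that("top-2 selection builds the 2-per-pair basis", {
  X <- .toy_base(n = 20)
  labels <- rep(c("DLB", "AD"), each = 10)
  pca <- fit_pca_per_pair(X)
  rk <- rank_components_by_auc(pca, X, labels)
  basis <- select_top_components(pca, rk)
  expect_s3_class(basis, "pca_basis")
  expect_equal(dim(basis$loadings), c(180, 6))
  # column 2(p-1)+a holds the a-th ranked component of pair p
  for (p in 1:3) {
    rp <- rk[rk$pair == p, ]
    rp <- rp[order(rp$rank_in_pair), ]
    expect_equal(basis$loadings[, 2 * (p - 1) + 1],
                 pca$pairs[[p]]$loadings[, rp$component[1]])
    expect_equal(basis$selection$component[2 * (p - 1) + 1:2],
                 rp$component[1:2])
    expect_true(rp$auc[1] >= rp$auc[2])
  }
  # without a ranking: first two variance directions
  b2 <- select_top_components(pca)
  expect_equal(b2$loadings[, 1], pca$pairs[[1]]$loadings[, 1])
  expect_equal(b2$loadings[, 2], pca$pairs[[1]]$loadings[, 2])
})

test_that("projection is the robust expectation of segment scores", {
  sigma <- random_sigma(nc = 3, ns = 9, seed = 5)
  sp <- structure(list(sigma = sigma, freqs = spectral_freqs(),
                       channel_labels = paste0("ch", 1:3), n_segments = 9),
                  class = "eeg_spectra")
  cov <- compute_covariances(sp)
  set.seed(6)
  basis <- structure(list(loadings = matrix(rnorm(180 * 12), 180, 12),
                          center = rnorm(6 * 180), n_pairs = 6,
                          selection = NULL, fitted_on = NULL),
                     class = "pca_basis")
  core <- project_core_features(cov, basis)
  expect_length(core$C, 12)

  # manual: per-segment centred inner products, then the median
  pairs <- cov$pairs
  manual <- sapply(seq_len(12), function(q) {
    p <- ceiling(q / 2)
    per_seg <- sapply(seq_len(9), function(i) {
      chi <- cov$chi[, p, i]
      x <- as.vector(rbind(Re(chi), Im(chi))) -
        basis$center[((p - 1) * 180 + 1):(p * 180)]
      sum(x * basis$loadings[, q])
    })
    median(per_seg)
  })
  expect_equal(core$C, manual)

  # spectra path and covariance path agree
  core2 <- project_core_features(sp, basis)
  expect_equal(core2$C, core$C)

  wrong <- basis
  wrong$n_pairs <- 4
  expect_error(project_core_features(cov, wrong),
               class = "dlb_projection_error")
})
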