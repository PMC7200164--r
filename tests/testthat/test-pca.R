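make_profiles <- function(counts_rows, vp_index = 10, flank = 0,
                          width = 100) {
  lapply(seq_len(nrow(counts_rows)), function(i)
    toy_counts(counts_rows[i, ], vp_index = vp_index, flank = flank,
               width = width, sample = paste0("s", i),
               n = ncol(counts_rows)))
}

test_that("bin matrices hold within-region read ratios", {
  set.seed(1)
  X <- matrix(rpois(60, 8) + 1, nrow = 3)  # 3 samples x 20 fragments
  profs <- make_profiles(X)
  map <- profs[[1]]$map
  grid <- make_bins(map$locus, 500)  # 4 bins of 5 fragments

  M <- build_bin_matrix(profs, grid)
  expect_true(M$normalized)
  expect_equal(rowSums(M$X), rep(1, 3), ignore_attr = TRUE)
  # brute-force: sum fragments per bin (vp fragment 10 carries no exclusion
  # flank here, but is still excluded as the viewpoint fragment itself)
  keepfrag <- setdiff(1:20, 10)
  for (r in 1:3) {
    bins <- vapply(1:4, function(b) {
      fr <- intersect(keepfrag, ((b - 1) * 5 + 1):(b * 5))
      sum(X[r, fr])
    }, numeric(1))
    expect_equal(M$X[r, ], bins / sum(bins), ignore_attr = TRUE)
  }

  # single-bin region -> all entries exactly 1
  g1 <- make_bins(map$locus, 2000)
  expect_equal(unname(build_bin_matrix(profs, g1)$X), matrix(1, 3, 1))
})

test_that("bins in the exclusion zone are dropped; empty samples error", {
  set.seed(2)
  X <- matrix(rpois(60, 8) + 1, nrow = 3)
  profs <- make_profiles(X, vp_index = 10, flank = 200)
  grid <- make_bins(profs[[1]]$map$locus, 500)
  # exclusion zone [700, 1200) contains bin 2's midpoint (750)
  M <- build_bin_matrix(profs, grid)
  expect_equal(nrow(M$bins), 3L)
  expect_false(2 %in% M$bins$index)

  X0 <- X; X0[2, ] <- 0
  expect_error(build_bin_matrix(make_profiles(X0), grid), "s2")
})

test_that("PCA matches an explicit covariance eigendecomposition", {
  set.seed(3)
  for (i in 1:5) {
    X <- matrix(rexp(120), nrow = 6)  # 6 samples x 20 bins
    X <- X / rowSums(X)
    M <- structure(list(X = X, samples = paste0("s", 1:6),
                        bins = data.frame(chrom = "chrT",
                                          start = 0:19 * 100,
                                          end = 1:20 * 100,
                                          index = 1:20, partial = FALSE),
                        normalized = TRUE),
                   class = "bin_matrix")
    res <- run_pca(M)
    # oracle: eigen() of the explicitly formed covariance matrix
    Xc <- scale(X, center = TRUE, scale = FALSE)
    eig <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
    k <- 5  # rank n - 1
    expect_equal(res$eigenvalues[1:k], eig$values[1:k], tolerance = 1e-8)
    for (j in 1:k) {
      v <- eig$vectors[, j]
      expect_equal(abs(sum(v * res$eigenvectors[, j])), 1, tolerance = 1e-8)
    }
    # scores are the centered data projected on the eigenvectors
    expect_equal(unname(Xc %*% res$eigenvectors), unname(res$scores),
                 tolerance = 1e-9)
    # variance conservation and orthonormality
    expect_equal(sum(res$eigenvalues), sum(apply(Xc, 2, stats::var)),
                 tolerance = 1e-9)
    G <- crossprod(res$eigenvectors)
    expect_equal(unname(G), diag(ncol(G)), tolerance = 1e-9)
    # deterministic sign: largest-magnitude entry of each component positive
    for (j in 1:k)
      expect_gte(res$eigenvectors[which.max(abs(res$eigenvectors[, j])), j], 0)
  }
})

test_that("two-sample PCA gives one component with opposite equal scores", {
  X <- rbind(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))
  M <- structure(list(X = X, samples = c("a", "b"),
                      bins = data.frame(chrom = "chrT", start = 0:2 * 10,
                                        end = 1:3 * 10, index = 1:3,
                                        partial = FALSE),
                      normalized = TRUE), class = "bin_matrix")
  res <- run_pca(M)
  expect_equal(res$scores[1, 1], -res$scores[2, 1])
  expect_gt(res$eigenvalues[1], 0)
  expect_equal(res$eigenvalues[-1], rep(0, length(res$eigenvalues) - 1),
               tolerance = 1e-12)
  # duplicated rows land on identical scores
  M$X <- rbind(X, X[1, ]); M$samples <- c("a", "b", "a2")
  res2 <- run_pca(M)
  expect_equal(res2$scores[1, ], res2$scores[3, ], ignore_attr = TRUE)
})

test_that("loadings are eigenvectors scaled by sqrt(eigenvalue)", {
  set.seed(4)
  X <- matrix(rexp(80), nrow = 4); X <- X / rowSums(X)
  M <- structure(list(X = X, samples = paste0("s", 1:4),
                      bins = data.frame(chrom = "chrT", start = 0:19 * 100,
                                        end = 1:20 * 100, index = 1:20,
                                        partial = FALSE),
                      normalized = TRUE), class = "bin_matrix")
  res <- run_pca(M)
  for (k in 1:3) {
    tr <- component_loadings(res, k)
    expect_equal(tr$loadings,
                 res$eigenvectors[, k] * sqrt(res$eigenvalues[k]))
    # sum of squared loadings recovers the eigenvalue
    expect_equal(sum(tr$loadings^2), res$eigenvalues[k], tolerance = 1e-9)
  }
  # a zero-variance component yields an all-zero track
  zk <- length(res$eigenvalues)
  expect_equal(component_loadings(res, zk)$loadings,
               rep(0, 20), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(component_loadings(res, 99), "out of range")
})

test_that("on unit-variance columns loadings equal bin-score correlations", {
  set.seed(5)
  X <- matrix(rnorm(6 * 15), nrow = 6)
  X <- scale(X)  # center and standardize columns
  # rescale so the n-1 variance is exactly 1 (scale() already does)
  M <- structure(list(X = X, samples = paste0("s", 1:6),
                      bins = data.frame(chrom = "chrT", start = 0:14 * 100,
                                        end = 1:15 * 100, index = 1:15,
                                        partial = FALSE),
                      normalized = TRUE), class = "bin_matrix")
  res <- run_pca(M)
  for (k in 1:3) {
    tr <- component_loadings(res, k)
    # with unit column variance, cor(X_j, score_k) = v_jk * sqrt(l_k)
    expect_equal(tr$loadings,
                 vapply(seq_len(ncol(X)), function(j)
                   stats::cor(X[, j], res$scores[, k]), numeric(1)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("changepoint detection finds step boundaries", {
  bins <- data.frame(chrom = "chrT", start = 0:4 * 100, end = 1:5 * 100,
                     index = 1:5, partial = FALSE)
  tr <- structure(list(component = 1, loadings = c(-1, -1, -1, 1, 1),
                       bins = bins), class = "loading_track")
  cp <- loading_changepoint(tr)
  expect_equal(cp$split_index, 3L)
  expect_equal(cp$boundary, 300)
  # sign flip leaves the boundary unchanged
  tr$loadings <- -tr$loadings
  expect_equal(loading_changepoint(tr)$split_index, 3L)

  trc <- tr; trc$loadings <- rep(0.4, 5)
  expect_error(loading_changepoint(trc), "no changepoint")
  tr2 <- tr; tr2$bins <- bins[1:2, ]; tr2$loadings <- c(-1, 1)
  expect_error(loading_changepoint(tr2), "at least 3")
})

test_that("noisy step tracks are localized within one bin", {
  set.seed(6)
  n <- 30; truth <- 18
  bins <- data.frame(chrom = "chrT", start = (0:(n - 1)) * 100,
                     end = (1:n) * 100, index = 1:n, partial = FALSE)
  hits <- 0
  for (i in 1:100) {
    l <- c(rep(-0.5, truth), rep(0.5, n - truth)) + rnorm(n, 0, 0.1)
    tr <- structure(list(component = 1, loadings = l, bins = bins),
                    class = "loading_track")
    cp <- loading_changepoint(tr)
    if (abs(cp$split_index - truth) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
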