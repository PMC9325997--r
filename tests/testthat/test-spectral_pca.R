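test_that("row-major flattening and reshaping are exact inverses", {
  gm <- matrix(1:6, 2, 3, byrow = TRUE)
  expect_equal(flatten_row_major(gm), 1:6)
  # full CCD frame dimensionality
  big <- matrix(0, 1040, 1392)
  expect_equal(length(flatten_row_major(big)), 1447680L)
  set.seed(1)
  r <- matrix(rnorm(35), 5, 7)
  expect_equal(reshape_row_major(flatten_row_major(r), 5, 7), r)
})

test_that("a rank-1 two-pattern cube concentrates all variance on component 1", {
  # channels 1-2 carry pattern A, channels 3-4 pattern B, with A and B
  # orthogonal: the centered matrix has rank 1 along the (A - B) direction
  h <- 8; w <- 8
  A <- matrix(0, h, w); A[, 1:4] <- 2
  B <- matrix(0, h, w); B[, 5:8] <- 2
  pre <- structure(list(channels = list(c1 = A, c2 = A, c3 = B, c4 = B),
                        branch = "std", channel_names = paste0("c", 1:4),
                        height = h, width = w, params_echo = list()),
                   class = "preprocessed_cube")
  eig <- spectral_pca(pre, 3)
  expect_equal(eig$explained_variance_ratio[1], 1.0, tolerance = 1e-12)
  expect_equal(eig$explained_variance_ratio[2:3], c(0, 0), tolerance = 1e-12)
  # component 1 is proportional to A - B (up to the sign rule)
  d <- flatten_row_major(A - B)
  v <- flatten_row_major(eig$components[[1]])
  corr <- abs(sum(d * v) / sqrt(sum(d^2) * sum(v^2)))
  expect_equal(corr, 1.0, tolerance = 1e-12)
})

test_that("explained variance ratios of 3 components sum to 1 for any 4-channel cube", {
  set.seed(11)
  for (rep in 1:5) {
    cube <- random_cube(4, 9, 13)
    pre <- preprocess(cube, "std", median_size = 1)
    eig <- spectral_pca(pre, 3)
    expect_lt(abs(sum(eig$explained_variance_ratio) - 1), 1e-9)
    expect_true(all(diff(eig$explained_variance_ratio) <= 1e-12))
    expect_true(all(eig$explained_variance_ratio >= 0 &
                      eig$explained_variance_ratio <= 1))
  }
})

test_that("the Gram-matrix route equals a dense pixel-covariance eigendecomposition", {
  set.seed(21)
  for (rep in 1:4) {
    mats <- replicate(4, matrix(rnorm(16 * 16), 16, 16), simplify = FALSE)
    names(mats) <- paste0("c", 1:4)
    eig <- spectral_pca(mats, 3)
    oracle <- dense_pca_oracle(mats, 3)
    expect_equal(eig$explained_variance_ratio, oracle$evr, tolerance = 1e-9)
    for (i in 1:3) {
      v <- flatten_row_major(eig$components[[i]])
      u <- oracle$axes[, i]
      # match up to sign
      if (sum(v * u) < 0) u <- -u
      expect_lt(max(abs(v - u)), 1e-8)
    }
  }
})

test_that("eigen-images are mutually orthogonal unit-norm pixel-space axes", {
  set.seed(31)
  cube <- random_cube(4, 12, 10)
  eig <- spectral_pca(preprocess(cube, "std", median_size = 1), 3)
  vs <- lapply(eig$components, flatten_row_major)
  for (i in 1:3) expect_equal(sqrt(sum(vs[[i]]^2)), 1, tolerance = 1e-9)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(sum(vs[[i]] * vs[[j]])),
              1e-6 * sqrt(sum(vs[[i]]^2) * sum(vs[[j]]^2)))
  }
})

test_that("the sign rule makes decompositions deterministic", {
  set.seed(41)
  cube <- random_cube(4, 10, 10)
  pre <- preprocess(cube, "std", median_size = 1)
  e1 <- spectral_pca(pre, 3)
  e2 <- spectral_pca(pre, 3)
  expect_identical(e1$components, e2$components)
  # largest-|loading| channel is positive on every component
  for (i in 1:3) {
    l <- e1$loadings[i, ]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("degenerate and invalid inputs are rejected", {
  flat <- replicate(3, matrix(4, 6, 6), simplify = FALSE)
  expect_error(spectral_pca(flat, 2), "zero total variance")
  cube <- random_cube(3, 6, 6)
  expect_error(spectral_pca(preprocess(cube, "std", median_size = 1), 4),
               "between 1 and the channel count")
})

test_that("normalize_to_255 is an affine min-max map with round-half-even", {
  comp <- matrix(c(-2, 0, 2, 1), 2, 2)
  out <- normalize_to_255(comp)
  expect_equal(out[comp == -2], 0)
  expect_equal(out[comp == 2], 255)
  expect_equal(out[comp == 0], 128)  # 127.5 rounds half-to-even -> 128
  expect_true(all(normalize_to_255(matrix(3.7, 4, 4)) == 0))
  set.seed(51)
  r <- matrix(rnorm(100), 10, 10)
  out <- normalize_to_255(r)
  expect_equal(min(out), 0); expect_equal(max(out), 255)
})

test_that("compose_rgb maps PC1/PC2/PC3 to red/green/blue and demands 3 components", {
  set.seed(61)
  cube <- random_cube(4, 10, 10)
  eig <- spectral_pca(preprocess(cube, "std", median_size = 1), 3)
  comp <- compose_rgb(eig)
  expect_identical(names(comp$planes), c("red", "green", "blue"))
  for (i in 1:3) {
    expect_equal(comp$planes[[i]], normalize_to_255(eig$components[[i]]))
  }
  eig2 <- spectral_pca(preprocess(cube, "std", median_size = 1), 2)
  expect_error(compose_rgb(eig2), "exactly 3")
  # permuting components permutes planes identically
  eig_p <- eig
  eig_p$components <- eig$components[c(2, 3, 1)]
  comp_p <- compose_rgb(eig_p)
  expect_equal(comp_p$planes$red, comp$planes$green)
  expect_equal(comp_p$planes$green, comp$planes$blue)
  expect_equal(comp_p$planes$blue, comp$planes$red)
})

test_that("run_pipeline returns both branches with 8-bit planes at source geometry", {
  ph <- generate_phantom(phantom_spec(height = 40, width = 60, seed = 5))
  res <- run_pipeline(ph$cube, pipeline_config(tile_grid = c(4, 4)))
  expect_setequal(names(res), c("std", "clahe"))
  for (br in names(res)) {
    comp <- res[[br]]$composite
    expect_equal(c(comp$height, comp$width), c(40L, 60L))
    for (p in comp$planes) {
      expect_gte(min(p), 0); expect_lte(max(p), 255)
    }
  }
  # the branches genuinely differ on data with non-uniform local contrast
  diffs <- vapply(1:3, function(i) {
    max(abs(res$std$composite$planes[[i]] - res$clahe$composite$planes[[i]]))
  }, numeric(1))
  expect_gt(max(diffs), 0)
  # branch selection is honored
  only_std <- run_pipeline(ph$cube, pipeline_config(branch = "std", tile_grid = c(4, 4)))
  expect_identical(names(only_std), "std")
})

test_that("with trivial filtering the clahe branch reduces to PCA of global equalization", {
  set.seed(71)
  cube <- random_cube(4, 20, 20)
  cfg <- pipeline_config(branch = "clahe", clip_limit = 1e9,
                         tile_grid = c(1, 1), median_size = 1)
  res <- run_pipeline(cube, cfg)
  eq_mats <- lapply(cube$channels, function(im) global_equalize_oracle(im$pixels))
  names(eq_mats) <- cube$channel_names
  eig_oracle <- spectral_pca(eq_mats, 3)
  for (i in 1:3) {
    expect_equal(res$clahe$eigen$components[[i]], eig_oracle$components[[i]],
                 tolerance = 1e-12)
  }
})

test_that("the std-branch composite is invariant to positive rescaling of the cube", {
  set.seed(81)
  mats <- replicate(4, matrix(rnorm(15 * 15), 15, 15), simplify = FALSE)
  pre1 <- structure(list(channels = mats, branch = "std",
                         channel_names = paste0("c", 1:4), height = 15, width = 15,
                         params_echo = list()), class = "preprocessed_cube")
  pre2 <- pre1
  pre2$channels <- lapply(mats, function(m) m * 37.5)
  c1 <- compose_rgb(spectral_pca(pre1, 3))
  c2 <- compose_rgb(spectral_pca(pre2, 3))
  for (i in 1:3) expect_equal(c1$planes[[i]], c2$planes[[i]])
})
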