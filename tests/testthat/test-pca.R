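test_that("profile matrix is normalized and validated", {
  set.seed(2)
  f <- (11:256) * 1000 / 512
  psds <- lapply(1:20, function(i) make_psd(f, rgamma(length(f), 2), 1000 / 512))
  groups <- rep(c("COPD", "control"), 10)
  pm <- build_profile_matrix(psds, groups)
  expect_equal(dim(pm$X), c(20, length(f)))
  expect_equal(rowSums(pm$X) * pm$df, rep(1, 20))
  # scaling a profile before normalization changes nothing
  psds2 <- psds
  psds2[[3]]$P_band <- psds2[[3]]$P_band * 77
  pm2 <- build_profile_matrix(psds2, groups)
  expect_equal(pm$X, pm2$X)
  # zero-power profiles are excluded with a warning
  psds3 <- psds
  psds3[[5]]$P_band <- psds3[[5]]$P_band * 0
  expect_warning(pm3 <- build_profile_matrix(psds3, groups), "excluded")
  expect_equal(nrow(pm3$X), 19)
  expect_error(build_profile_matrix(psds[1:3], groups[1:3]),
               "at least 2 profiles")
})

test_that("rank-1 variation loads almost entirely on PC1", {
  set.seed(3)
  f <- (11:256) * 1000 / 512
  tmpl <- shaping_psd(f, spectral_shape_params(60, 120))
  psds <- lapply(1:30, function(i)
    make_psd(f, runif(1, 0.5, 2) * tmpl + abs(rnorm(length(f), 0, 1e-5)),
             1000 / 512))
  pm <- build_profile_matrix(psds, rep(c("COPD", "control"), 15),
                             normalize = FALSE)
  model <- fit_pca_varimax(pm)
  expect_gt(model$proportions[1], 0.99)
})

test_that("varimax rotation preserves orthonormality, variance and subspace", {
  for (seed in 1:3) {
    fx <- two_template_fixture(seed, n_per_group = 30)
    pm <- build_profile_matrix(fx$psds, fx$groups, normalize = FALSE)
    model <- fit_pca_varimax(pm)
    k <- model$k
    # orthonormal components
    expect_lt(max(abs(crossprod(model$components) - diag(k))), 1e-8)
    # retained variance preserved by rotation
    expect_equal(sum(model$proportions), sum(model$proportions_unrotated),
                 tolerance = 1e-8)
    # unrotated proportions non-increasing
    expect_true(all(diff(model$proportions_unrotated) <= 1e-12))
    # same spanned subspace: projections agree
    Xc <- sweep(pm$X, 2, model$center)
    pc <- prcomp(pm$X, center = TRUE)
    V <- pc$rotation[, 1:k, drop = FALSE]
    expect_lt(max(abs(Xc %*% tcrossprod(V) -
                      Xc %*% tcrossprod(model$components))), 1e-8)
  }
})

test_that("two well-separated templates are recovered by the rotated PCs", {
  fx <- two_template_fixture(101, n_per_group = 45)
  pm <- build_profile_matrix(fx$psds, fx$groups, normalize = FALSE)
  model <- fit_pca_varimax(pm)
  expect_equal(model$k, 2)
  ctab <- abs(cor(model$components, cbind(fx$template_lo, fx$template_hi)))
  # each rotated PC correlates strongly with exactly one template
  expect_gte(max(ctab[1, ]), 0.9)
  expect_gte(max(ctab[2, ]), 0.9)
  expect_false(which.max(ctab[1, ]) == which.max(ctab[2, ]))
  # component centroid ordering is stable across noise seeds
  fx2 <- two_template_fixture(102, n_per_group = 45)
  pm2 <- build_profile_matrix(fx2$psds, fx2$groups, normalize = FALSE)
  model2 <- fit_pca_varimax(pm2)
  expect_equal(order(model$centroids), order(model2$centroids))
})

test_that("weighting coefficients are Pearson correlations with components", {
  fx <- two_template_fixture(7, n_per_group = 20)
  pm <- build_profile_matrix(fx$psds, fx$groups, normalize = FALSE)
  model <- fit_pca_varimax(pm)
  W <- weighting_coefficients(pm, model)
  expect_true(all(W >= -1 & W <= 1))
  # direct-formula oracle to 1e-12
  for (i in c(1, 10, 25)) for (j in 1:model$k)
    expect_equal(unname(W[i, j]), oracle_pearson(pm$X[i, ], model$components[, j]),
                 tolerance = 1e-12)
  # affine images of a component correlate exactly +/- 1
  Xa <- rbind(3 * model$components[, 1] + 0.2,
              -2 * model$components[, 2] + 1)
  Wa <- weighting_coefficients(Xa, model)
  expect_equal(unname(Wa[1, 1]), 1, tolerance = 1e-9)
  expect_equal(unname(Wa[2, 2]), -1, tolerance = 1e-9)
  # zero-variance rows are flagged
  Xz <- rbind(model$components[, 1], rep(0.5, nrow(model$components)))
  expect_warning(Wz <- weighting_coefficients(Xz, model), "zero-variance")
  expect_true(all(is.na(Wz[2, ])))
})

test_that("group comparison of weights: null, power and permutation oracle", {
  fx <- two_template_fixture(11, n_per_group = 30)
  pm <- build_profile_matrix(fx$psds, fx$groups, normalize = FALSE)
  model <- fit_pca_varimax(pm)
  # identical distributions: duplicate COPD rows as 'control'
  Wc <- model$W[fx$groups == "COPD", , drop = FALSE]
  W0 <- rbind(Wc, Wc)
  g0 <- rep(c("COPD", "control"), each = nrow(Wc))
  cmp0 <- compare_group_weights(W0, g0)
  expect_equal(cmp0$p, rep(1, model$k), tolerance = 1e-9)
  expect_equal(cmp0$mean_r_copd, cmp0$mean_r_control)
  # t-on-z p within 0.02 of a 10,000-draw permutation p
  cmp <- compare_group_weights(model$W, fx$groups)
  j <- which.max(cmp$p)  # use the least extreme component
  z <- atanh(pmin(pmax(model$W[, j], -1 + 1e-12), 1 - 1e-12))
  p_perm <- oracle_perm_p(z[fx$groups == "COPD"], z[fx$groups == "control"],
                          n_perm = 10000, seed = 99)
  expect_lt(abs(cmp$p[j] - p_perm), 0.02)
})
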