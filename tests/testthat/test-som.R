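test_that("two well-separated groups are perfectly partitioned with 2 units", {
  a <- c(10, 0, 0); b <- c(0, 0, 10)
  m <- two_group_map(a, b, na = 5, nb = 5)
  res <- fit_som(m, config = som_config(n_units = 2, seed = 3, window = c(1, 3)))
  labs <- as.vector(res$labels)
  expect_true(all(labs[1:5] == labs[1]))
  expect_true(all(labs[6:10] == labs[6]))
  expect_false(labs[1] == labs[6])
  expect_true(res$converged)
  expect_lte(utils::tail(res$reassign_trace, 1), res$config$converge_frac)
})

test_that("all-identical spectra collapse to the lowest unit index", {
  m <- two_group_map(c(5, 5, 5), c(5, 5, 5), na = 4, nb = 4)
  res <- fit_som(m, config = som_config(n_units = 3, seed = 1, max_iter = 50,
                                        window = c(1, 3)))
  expect_true(all(res$labels == 1L))
})

test_that("same seed gives bit-identical labels; different seeds may differ", {
  ph <- make_cell_phantom(phantom_spec("rod", height = 8, width = 12), seed = 6)
  bl <- subtract_baseline_map(ph$map)
  r1 <- fit_som(bl$corrected, config = som_config(n_units = 3, seed = 11))
  r2 <- fit_som(bl$corrected, config = som_config(n_units = 3, seed = 11))
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$prototypes, r2$prototypes)
})

test_that("radius-0 fit matches the brute-force k-means optimum on tiny instances", {
  set.seed(21)
  cases <- list(
    list(k = 2, centers = rbind(c(0, 0, 0), c(20, 20, 20)), n = c(6, 6)),
    list(k = 3, centers = rbind(c(0, 0, 0), c(25, 0, 0), c(0, 25, 0)),
         n = c(4, 4, 4)))
  for (cs in cases) {
    X <- do.call(rbind, lapply(seq_len(cs$k), function(j)
      sweep(matrix(rnorm(cs$n[j] * 3, sd = 0.5), ncol = 3), 2,
            cs$centers[j, ], "+")))
    cube <- array(0, c(1, nrow(X), 3))
    cube[1, , ] <- X
    m <- hyperspec_map(wn_axis(1:3), cube)
    res <- fit_som(m, config = som_config(n_units = cs$k, seed = 2,
                                          radius = 0, radius_iters = 0,
                                          window = c(1, 3)))
    labs <- as.vector(res$labels)
    expect_equal(wss_of_result(X, labs), brute_force_wss(X, cs$k),
                 tolerance = 1e-8)
  }
})

test_that("summaries are invariant under unit relabeling", {
  ph <- make_cell_phantom(phantom_spec("rod", height = 10, width = 14), seed = 7)
  bl <- subtract_baseline_map(ph$map)
  mask <- mask_cells(bl$corrected)
  res <- fit_som(bl$corrected, mask, som_config(n_units = 4, seed = 5))
  b <- default_bands()
  rm <- ratio_map(bl$corrected, b[["750"]], b[["1640"]], mask)
  sum1 <- cluster_ratio_summary(rm, res, n_boot = 500)
  ## permute unit identities and recompute
  perm <- c(3L, 1L, 4L, 2L)
  res2 <- res
  res2$labels[] <- ifelse(is.na(res$labels), NA_integer_, perm[res$labels])
  sum2 <- cluster_ratio_summary(rm, res2, n_boot = 500)
  for (j in 1:4) {
    r1 <- sum1[sum1$cluster == j, ]
    r2 <- sum2[sum2$cluster == perm[j], ]
    expect_equal(r1$n, r2$n)
    expect_equal(r1$mean, r2$mean)
  }
})

test_that("cluster mean spectra equal group means", {
  a <- c(10, 2, 0, 1); b <- c(0, 3, 10, 1)
  m <- two_group_map(a, b, na = 3, nb = 5, axis = wn_axis(1:4))
  res <- fit_som(m, config = som_config(n_units = 2, seed = 9,
                                        window = c(1, 4)))
  cm <- cluster_mean_spectra(m, res)
  expect_length(cm, 2)
  got <- lapply(cm, `[[`, "intensities")
  expect_true(any(vapply(got, function(g) isTRUE(all.equal(g, a)), TRUE)))
  expect_true(any(vapply(got, function(g) isTRUE(all.equal(g, b)), TRUE)))
  ## single-cluster result -> global masked mean
  res1 <- fit_som(m, config = som_config(n_units = 2, seed = 9,
                                         window = c(1, 4)))
  res1$labels[] <- 1L
  cm1 <- cluster_mean_spectra(m, res1)
  expect_equal(cm1$cluster_1$intensities, (3 * a + 5 * b) / 8)
})

test_that("insufficient masked pixels error; convergence trace is recorded", {
  m <- two_group_map(c(1, 2, 3), c(3, 2, 1), na = 2, nb = 1)
  expect_error(fit_som(m, config = som_config(n_units = 6, window = c(1, 3))),
               class = "rr_config_error")
  res <- fit_som(two_group_map(c(9, 0, 0), c(0, 0, 9), na = 6, nb = 6),
                 config = som_config(n_units = 2, seed = 4, window = c(1, 3)))
  expect_true(length(res$reassign_trace) >= 1)
  expect_true(all(res$reassign_trace >= 0 & res$reassign_trace <= 1))
})

test_that("internal ARI agrees with mclust on random labelings", {
  skip_if_not_installed("mclust")
  set.seed(33)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unclass(mclust::adjustedRandIndex(a, b)),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})
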