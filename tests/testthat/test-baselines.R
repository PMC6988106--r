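# Classical baselines: wall construction, thresholding rules, MGMM EM and
# its graph-cuts refinement.

test_that("wall mask is a dilation shell disjoint from the cavity", {
  # 0.5 mm grid keeps the digitization error of the 2 mm shell small
  sp <- sphere_mask(10, n = 55, spacing = c(0.5, 0.5, 0.5))
  wall <- wall_from_la(sp$mask, dilation_mm = 2, spacing = sp$spacing)
  expect_false(any(wall & sp$mask))
  shell_vol <- 4 * pi * (12^3 - 10^3) / 3
  expect_lt(abs(sum(wall) * 0.5^3 - shell_vol) / shell_vol, 0.15)
  expect_error(wall_from_la(sp$mask, dilation_mm = 0), "wall")
  expect_error(wall_from_la(array(FALSE, c(4, 4, 4)), 2), "empty")
})

test_that("n-SD thresholding follows the population-SD strict rule", {
  d <- c(5, 1, 1)
  img <- array(c(1, 1, 1, 1, 9), d)
  wall <- array(TRUE, d)
  # population SD = 3.2 -> threshold 2.6 + 6.4 = 9; strict > leaves nothing
  expect_equal(sum(threshold_nsd(img, wall, 2)), 0)
  # constant wall: SD 0, nothing strictly above the mean
  expect_equal(sum(threshold_nsd(array(4, d), wall, 2)), 0)
  expect_error(threshold_nsd(img, array(c(TRUE, rep(FALSE, 4)), d), 2),
               "2 voxels")
  # shift invariance
  withr::with_seed(2, {
    img2 <- array(stats::rnorm(125, 50, 10), c(5, 5, 5))
    w2 <- array(TRUE, c(5, 5, 5))
    expect_identical(threshold_nsd(img2, w2, 2),
                     threshold_nsd(img2 + 137, w2, 2))
  })
})

test_that("Otsu threshold separates a bimodal wall and matches a brute sweep", {
  withr::with_seed(9, {
    v <- c(stats::rnorm(400, 10, 2), stats::rnorm(400, 50, 2))
    thr <- atrialscar:::otsu_threshold(v)
    expect_gt(thr, 20)
    expect_lt(thr, 40)
    # brute-force: maximize between-class variance over all sample splits
    vs <- sort(v)
    n <- length(vs)
    bcv <- vapply(seq_len(n - 1), function(k) {
      w0 <- k / n
      (mean(vs[1:k]) - mean(vs[(k + 1):n]))^2 * w0 * (1 - w0)
    }, numeric(1))
    # the histogram threshold attains (nearly) the optimal objective
    k_thr <- sum(vs <= thr)
    expect_gt(bcv[k_thr], 0.999 * max(bcv))
  })
  # exactly two distinct values are separated
  d <- c(8, 1, 1)
  img <- array(rep(c(3, 12), each = 4), d)
  wall <- array(TRUE, d)
  expect_equal(threshold_otsu(img, wall), img == 12)
  expect_error(threshold_otsu(array(5, d), wall), "constant")
})

test_that("Otsu partition is invariant to positive affine rescaling", {
  withr::with_seed(4, {
    img <- array(c(stats::rnorm(200, 20, 3), stats::rnorm(143, 60, 3)),
                 c(7, 7, 7))
    wall <- array(TRUE, c(7, 7, 7))
    a <- threshold_otsu(img, wall)
    b <- threshold_otsu(img * 3.7 + 11, wall)
    expect_identical(a, b)
  })
})

test_that("Otsu agrees with the independent EBImage implementation", {
  skip_if_not_installed("EBImage")
  withr::with_seed(13, {
    v <- c(stats::rnorm(500, 0.25, 0.05), stats::rnorm(300, 0.7, 0.05))
    v <- pmin(1, pmax(0, v))
    ours <- atrialscar:::otsu_threshold(v)
    theirs <- EBImage::otsu(matrix(v, 40), range = range(v), levels = 256)
    # same partition of the samples
    expect_equal(v > ours, v > theirs)
  })
})

test_that("MGMM EM recovers well-separated components monotonically", {
  withr::with_seed(21, {
    x <- c(stats::rnorm(1000, 0, 1), stats::rnorm(1000, 5, 1))
  })
  fit <- mgmm_fit(x, K_scar = 1, K_normal = 1, tol = 1e-10)
  expect_lt(abs(fit$means[1] - 0), 0.2)
  expect_lt(abs(fit$means[2] - 5), 0.2)
  expect_true(all(diff(fit$loglik) > -1e-8))   # EM ascent property
  expect_true(fit$converged)
  # posteriors: scar class is the bright component
  post <- mgmm_posterior(fit, c(-1, 2.5, 6))
  expect_lt(post[1], 0.01)
  expect_gt(post[3], 0.99)
})

test_that("the 1+1-component model matches an independent 2-GMM fit", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  withr::with_seed(31, {
    x <- c(stats::rnorm(1000, 0, 1), stats::rnorm(1000, 5, 1))
  })
  ours <- mgmm_fit(x, K_scar = 1, K_normal = 1, tol = 1e-12)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  ord <- order(mc$parameters$mean)
  expect_equal(sort(ours$means), sort(unname(mc$parameters$mean)),
               tolerance = 1e-3)
  post_ours <- mgmm_posterior(ours, x)
  post_mc <- mc$z[, ord[2]]
  expect_lt(max(abs(post_ours - post_mc)), 1e-3)
})

test_that("MGMM + graph-cuts degenerates to the posterior argmax at lambda 0", {
  ph <- make_phantom(small_phantom_config(seed = 17))
  wall <- wall_from_la(ph$la_seg, 3, ph$spacing)
  v <- ph$image$data[wall]
  fit <- mgmm_fit(v, K_scar = 2, K_normal = 3)
  m0 <- mgmm_gc(ph$image, wall, fit, lambda = 0)
  post <- array(0, dim(wall))
  post[wall] <- mgmm_posterior(fit, v)
  expect_identical(m0, wall & post > 0.5)
  expect_true(all(wall[m0]))   # mask within the wall
})

test_that("graph-cuts smoothing shrinks the boundary as lambda grows", {
  ph <- make_phantom(small_phantom_config(seed = 19, noise_sigma = 20))
  wall <- wall_from_la(ph$la_seg, 3, ph$spacing)
  fit <- mgmm_fit(ph$image$data[wall], K_scar = 2, K_normal = 3)
  boundary_voxels <- function(mask) {
    d <- dim(mask)
    n <- 0
    for (ax in 1:3) {
      idx <- lapply(d, seq_len)
      lo <- idx; lo[[ax]] <- 1:(d[ax] - 1)
      hi <- idx; hi[[ax]] <- 2:d[ax]
      n <- n + sum(do.call(`[`, c(list(mask), lo)) !=
                   do.call(`[`, c(list(mask), hi)))
    }
    n
  }
  bd <- vapply(c(0, 0.5, 2), function(l)
    boundary_voxels(mgmm_gc(ph$image, wall, fit, lambda = l)), numeric(1))
  expect_true(all(diff(bd) <= 0))
})

test_that("min-cut on toy voxel walls matches exhaustive enumeration", {
  # small wall strips with random posteriors and intensity-based n-links
  withr::with_seed(55, {
    for (k in 1:10) {
      n <- sample(4:12, 1)
      post <- stats::runif(n)
      edges <- cbind(1:(n - 1), 2:n)
      w <- exp(-stats::rnorm(n - 1)^2)
      g <- graph_model(post, edges, w, lambda = stats::runif(1, 0, 1.5))
      expect_equal(graph_energy(g, min_cut(g)), brute_force_min_energy(g),
                   tolerance = 1e-12)
    }
  })
})

test_that("all baselines stay inside the wall mask on a phantom", {
  ph <- make_phantom(small_phantom_config(seed = 23))
  wall <- wall_from_la(ph$la_seg, 3, ph$spacing)
  # convergence is not under test here; the capped fit is still a valid model
  fit <- suppressWarnings(mgmm_fit(ph$image$data[wall], K_scar = 2,
                                   K_normal = 3))
  masks <- list(threshold_nsd(ph$image, wall, 2),
                threshold_otsu(ph$image, wall),
                mgmm_gc(ph$image, wall, fit, lambda = 0.5))
  for (m in masks) expect_true(all(wall[m]))
})
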