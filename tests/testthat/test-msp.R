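# Multi-scale patch extraction: local frames, oriented sampling, scales and
# the random-shift augmentation.

test_that("local frames are orthonormal, right-handed and world-aligned", {
  expect_equal(local_frame(c(0, 0, 1)), diag(3))
  fr <- local_frame(c(0, 0, -1))
  expect_equal(fr[, 3], c(0, 0, -1))
  expect_equal(abs(fr[, 1]), c(1, 0, 0))    # in-plane world-aligned up to sign
  expect_error(local_frame(c(0, 0, 0)), "zero")

  withr::with_seed(1, {
    for (k in 1:25) {
      n <- stats::rnorm(3)
      n <- n / sqrt(sum(n^2))
      fr <- local_frame(n)
      expect_equal(crossprod(fr), diag(3), tolerance = 1e-9)
      expect_equal(fr[, 3], n, tolerance = 1e-12)
      # right-handed: a1 x a2 = n
      a <- fr[, 1]; b <- fr[, 2]
      expect_equal(c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                     a[1] * b[2] - a[2] * b[1]), n, tolerance = 1e-9)
    }
  })
})

test_that("patches sample constant and linear fields exactly", {
  d <- c(21, 21, 21)
  cvol <- image_volume(array(7.5, d))
  p <- extract_patch(cvol, c(10, 10, 10), local_frame(c(1, 0, 0)),
                     dims = c(3, 3, 5), spacing_mm = 0.8)
  expect_equal(as.vector(p), rep(7.5, 45))

  zvol <- image_volume(array(rep(0:20, each = 21 * 21), d))   # f = z (mm)
  p2 <- extract_patch(zvol, c(0, 0, 10), diag(3), dims = c(1, 1, 5),
                      spacing_mm = 1)
  expect_equal(as.vector(p2), c(8, 9, 10, 11, 12))

  far <- extract_patch(zvol, c(500, 500, 500), diag(3), dims = c(3, 3, 3),
                       spacing_mm = 1)
  expect_true(all(far == 0))
})

test_that("patch values are invariant to shifting the world origin", {
  withr::with_seed(3, {
    arr <- array(stats::rnorm(20^3), c(20, 20, 20))
    v1 <- image_volume(arr, origin = c(0, 0, 0))
    v2 <- image_volume(arr, origin = c(13, -4, 2.5))
    fr <- local_frame(c(1, 2, 2) / 3)
    p1 <- extract_patch(v1, c(9, 9, 9), fr, c(5, 5, 7), 0.9)
    p2 <- extract_patch(v2, c(9, 9, 9) + c(13, -4, 2.5), fr, c(5, 5, 7), 0.9)
    expect_equal(p1, p2, tolerance = 1e-12)
  })
})

test_that("default-size patches flatten to 2873 elements", {
  cfg <- msp_config()
  vol <- image_volume(array(0, c(24, 24, 24)))
  p <- extract_patch(vol, c(12, 12, 12), diag(3), cfg$dims,
                     cfg$base_spacing_mm)
  expect_identical(length(p), 2873L)
})

test_that("multi-scale stacks share centre and double their spacing", {
  sp <- sphere_mask(8)
  mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
  vol <- image_volume(array(stats::rnorm(prod(sp$dims)), sp$dims))
  cfg <- msp_config(dims = c(3, 3, 5), n_scales = 3, base_spacing_mm = 1,
                    shift_R_mm = 0)
  st <- extract_msp(vol, mesh, 5L, cfg)
  expect_equal(st$spacings, c(1, 2, 4))
  expect_equal(st$shift_mm, 0)        # R = 0: centre exactly at the node
  expect_length(st$patches, 3)
  # centre sample of every scale is the value at the node itself
  ctrs <- vapply(st$patches, function(p) p[2, 2, 3], numeric(1))
  expect_equal(ctrs, rep(ctrs[1], 3))
})

test_that("random shifts are uniform on (-R, R) and reproducible", {
  sp <- sphere_mask(6)
  mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
  vol <- image_volume(array(0, sp$dims))
  cfg <- msp_config(dims = c(3, 3, 3), n_scales = 1, shift_R_mm = 8)
  withr::with_seed(10, {
    g <- replicate(10000, extract_msp(vol, mesh, 1L, cfg)$shift_mm)
  })
  expect_lte(max(abs(g)), 8)
  expect_lt(abs(mean(g)), 0.25)
  expect_gt(stats::var(g), 8^2 / 3 * 0.9)   # matches Var(U(-R,R)) = R^2/3

  set.seed(77)
  a <- extract_msp(vol, mesh, 3L, cfg)
  set.seed(77)
  b <- extract_msp(vol, mesh, 3L, cfg)
  expect_identical(a, b)
})

test_that("batched extraction agrees with per-node extraction", {
  ph <- make_phantom(small_phantom_config(seed = 4))
  mesh <- extract_surface(ph$la_seg, ph$spacing, ph$origin)
  cfg <- msp_config(dims = c(5, 5, 7), n_scales = 2, shift_R_mm = 0)
  nodes <- c(1L, 10L, 50L)
  b <- atrialscar:::extract_msp_batch(ph$image, mesh, nodes, cfg)
  for (k in seq_along(nodes)) {
    st <- extract_msp(ph$image, mesh, nodes[k], cfg)
    for (s in 1:2)
      expect_equal(b$X[[s]][k, ], as.vector(st$patches[[s]]),
                   tolerance = 1e-12)
  }
})

test_that("patch caches round-trip through the binary container", {
  ph <- make_phantom(small_phantom_config(seed = 6))
  mesh <- extract_surface(ph$la_seg, ph$spacing, ph$origin)
  cfg <- msp_config(dims = c(3, 3, 5), n_scales = 2, shift_R_mm = 2)
  set.seed(9)
  b <- atrialscar:::extract_msp_batch(ph$image, mesh, c(2L, 5L, 9L), cfg)
  prefix <- file.path(withr::local_tempdir(), "cache")
  write_msp_cache(b, prefix)
  back <- read_msp_cache(prefix)
  expect_equal(back$X, b$X, tolerance = 1e-15)
  expect_equal(back$shifts, b$shifts, tolerance = 1e-12)
  expect_identical(as.integer(back$nodes), c(2L, 5L, 9L))
})
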