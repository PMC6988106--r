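# Classical scar-segmentation baselines operating on a wall mask derived
# from an LA cavity segmentation: n-SD thresholding, Otsu thresholding, a
# two-class multi-component Gaussian mixture (MGMM), and MGMM regularized by
# voxel-level graph-cuts.

#' Construct a wall mask from an LA segmentation
#'
#' `wall = dilate(la_seg, dilation_mm) \\ la_seg`, with the dilation done in
#' millimetres via the Euclidean distance transform. The default 3 mm covers
#' the reported mean wall thickness plus a margin.
#'
#' @param la_seg Binary cavity segmentation ([image_volume()] or array).
#' @param dilation_mm Dilation radius (mm).
#' @param spacing Voxel spacing when `la_seg` is a bare array.
#' @return Logical wall mask.
#' @export
wall_from_la <- function(la_seg, dilation_mm = 3, spacing = c(1, 1, 1)) {
  if (inherits(la_seg, "image_volume")) {
    spacing <- la_seg$spacing
    la_seg <- la_seg$data
  }
  la_seg <- la_seg != 0
  if (!any(la_seg)) stop("empty LA segmentation")
  D <- distance_transform(la_seg, spacing, maxdist = dilation_mm + 2 * max(spacing))
  wall <- D > 0 & D <= dilation_mm
  if (!any(wall)) stop("empty wall mask: dilation_mm too small for this grid")
  wall
}

mask_values <- function(image, mask) {
  if (inherits(image, "image_volume")) image <- image$data
  image[mask != 0]
}

#' n-SD thresholding of wall intensities
#'
#' Scar = wall voxels whose intensity strictly exceeds
#' `mean(wall) + n_sd * SD(wall)`; the SD is the population SD (divide by
#' n). The default `n_sd = 2` is the widely used 2SD rule.
#'
#' @param image Intensity volume.
#' @param wall_mask Logical wall mask.
#' @param n_sd Number of standard deviations above the wall mean.
#' @return Logical scar mask (subset of `wall_mask`).
#' @export
threshold_nsd <- function(image, wall_mask, n_sd = 2) {
  v <- mask_values(image, wall_mask)
  if (length(v) < 2) stop("wall mask must contain at least 2 voxels")
  thr <- mean(v) + n_sd * sqrt(mean((v - mean(v))^2))
  img <- if (inherits(image, "image_volume")) image$data else image
  (wall_mask != 0) & (img > thr)
}

# 256-bin Otsu threshold of a numeric vector: maximize between-class
# variance; returns the upper edge of the chosen bin.
otsu_threshold <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) <= 0) stop("constant wall intensities: Otsu undefined")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(pmin(levels, findInterval(v, breaks, rightmost.closed = TRUE)),
                levels)
  p <- h / sum(h)
  centers <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[levels]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  bcv <- bcv[-levels]
  # The objective is flat across an empty gap between modes; resolve the
  # plateau to its midpoint, the conventional mid-gap threshold.
  cand <- which(bcv >= max(bcv) - 1e-12 * max(1, abs(max(bcv))))
  t_star <- as.integer(round(mean(cand)))
  breaks[t_star + 1L]
}

#' Otsu thresholding of wall intensities
#'
#' Threshold maximizing the between-class variance of a 256-bin histogram of
#' the wall intensities; scar = strictly-above-threshold wall voxels.
#'
#' @inheritParams threshold_nsd
#' @return Logical scar mask.
#' @export
threshold_otsu <- function(image, wall_mask) {
  v <- mask_values(image, wall_mask)
  thr <- otsu_threshold(v)
  img <- if (inherits(image, "image_volume")) image$data else image
  (wall_mask != 0) & (img > thr)
}

# ---------------------------------------------------------------------------
# Two-class multi-component Gaussian mixture (EM).

#' Fit a two-class multi-component Gaussian mixture
#'
#' EM on a 1-D mixture of `K_normal + K_scar` Gaussian components grouped
#' into two classes (normal wall, scar); multiple components per class
#' absorb the intensity heterogeneity of the myocardium. Components are
#' initialized from equal-count quantile bins and kept ordered by mean; the
#' brightest `K_scar` components form the scar class (scars are enhanced).
#'
#' @param intensities Numeric vector of wall-voxel intensities.
#' @param K_scar,K_normal Components per class.
#' @param tol EM stops when the log-likelihood gain drops below
#'   `tol * (1 + |loglik|)` (relative scale).
#' @param max_iter Iteration cap; non-convergence returns the best fit with
#'   `converged = FALSE` and a warning.
#' @param seed Unused for the deterministic quantile initialization; kept so
#'   callers can thread a seed through uniformly.
#' @return Object of class `mgmm_model`: `means`, `sds`, `weights`, `class`
#'   (factor `normal`/`scar` per component), `loglik` (per-iteration trace),
#'   `converged`.
#' @export
mgmm_fit <- function(intensities, K_scar = 2L, K_normal = 3L, tol = 1e-8,
                     max_iter = 1000L, seed = NULL) {
  x <- as.numeric(intensities)
  K <- K_scar + K_normal
  if (length(x) <= K) stop("need more samples than mixture components")
  # Quantile initialization.
  qs <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  mu <- qs
  sdev <- rep(max(stats::sd(x) / K, 1e-3), K)
  w <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      w[k] * stats::dnorm(x, mu[k], sdev[k]), numeric(length(x)))
    rowtot <- rowSums(dens)
    rowtot[rowtot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(rowtot))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rowtot
    nk <- colSums(resp)
    w <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sdev <- sqrt(pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, 1e-10))
    if (is.finite(ll_old) && ll - ll_old < tol * (1 + abs(ll)) && it > 1) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("MGMM EM did not converge within ", max_iter, " iterations")
  ord <- order(mu)
  cls <- factor(rep(c("normal", "scar"), c(K_normal, K_scar)),
                levels = c("normal", "scar"))
  structure(list(means = mu[ord], sds = sdev[ord], weights = w[ord],
                 class = cls, K_scar = K_scar, K_normal = K_normal,
                 loglik = ll_trace, converged = converged),
            class = "mgmm_model")
}

#' Scar posterior probabilities under an MGMM
#'
#' @param model An `mgmm_model`.
#' @param x Intensities.
#' @return `P(scar | x)`: the summed responsibilities of the scar-class
#'   components.
#' @export
mgmm_posterior <- function(model, x) {
  K <- length(model$means)
  dens <- vapply(seq_len(K), function(k)
    model$weights[k] * stats::dnorm(x, model$means[k], model$sds[k]),
    numeric(length(x)))
  if (length(x) == 1L) dens <- matrix(dens, 1)
  tot <- rowSums(dens)
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  rowSums(dens[, model$class == "scar", drop = FALSE]) / tot
}

#' MGMM segmentation refined by voxel-level graph-cuts
#'
#' Builds a 6-connected voxel graph over the wall mask: unary costs from the
#' MGMM class posteriors (assigning normal costs the scar posterior and vice
#' versa) and pairwise weights `exp(-(I_i - I_j)^2 / (2 sigma^2))`, solved
#' exactly by min-cut. With `lambda = 0` the result is the posterior argmax.
#'
#' @param image Intensity volume.
#' @param wall_mask Logical wall mask.
#' @param model A fitted `mgmm_model`.
#' @param lambda Regularization weight.
#' @param sigma_intensity Intensity scale of the pairwise weight; defaults
#'   to the SD of the wall intensities.
#' @return Logical scar mask.
#' @export
mgmm_gc <- function(image, wall_mask, model, lambda = 0.5,
                    sigma_intensity = NULL) {
  img <- if (inherits(image, "image_volume")) image$data else image
  wall <- wall_mask != 0
  ids <- which(wall)
  if (!length(ids)) stop("empty wall mask")
  v <- img[ids]
  if (is.null(sigma_intensity)) sigma_intensity <- stats::sd(v)
  if (!is.finite(sigma_intensity) || sigma_intensity <= 0) sigma_intensity <- 1
  post <- mgmm_posterior(model, v)
  # 6-connectivity edges within the wall.
  d <- dim(img)
  map <- array(0L, d)
  map[ids] <- seq_along(ids)
  co <- which(wall, arr.ind = TRUE)
  edges <- NULL
  wts <- NULL
  for (ax in 1:3) {
    ok <- co[, ax] < d[ax]
    nb <- co[ok, , drop = FALSE]
    nb[, ax] <- nb[, ax] + 1L
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
    j <- map[lin]
    keep <- j > 0L
    i <- map[ids[ok]][keep]
    j <- j[keep]
    edges <- rbind(edges, cbind(i, j))
    wts <- c(wts, exp(-(v[i] - v[j])^2 / (2 * sigma_intensity^2)))
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  g <- graph_model(post, edges, wts %||% numeric(0), lambda)
  lab <- min_cut(g)
  out <- array(FALSE, d)
  out[ids[lab == 1L]] <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
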