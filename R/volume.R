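# Image volumes, coordinate transforms, distance transforms and small
# volumetric utilities shared by all stages of the pipeline.

#' Construct a 3-D image volume
#'
#' A minimal container for a 3-D scalar grid with physical geometry. World
#' coordinates (mm) of the voxel with 0-based index `(i, j, k)` are
#' `origin + c(i, j, k) * spacing`.
#'
#' @param data 3-D numeric or logical array.
#' @param spacing Per-axis voxel size in mm (length 3, all > 0).
#' @param origin World coordinates (mm) of the first voxel centre (length 3).
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing` and `origin`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

as_volume <- function(x, like = NULL) {
  if (inherits(x, "image_volume")) return(x)
  if (!is.null(like))
    return(image_volume(x, spacing = like$spacing, origin = like$origin))
  image_volume(x)
}

# World coordinates (n x 3) of 0-based voxel indices (n x 3).
index_to_world <- function(idx, spacing, origin) {
  sweep(sweep(idx, 2, spacing, "*"), 2, origin, "+")
}

# Continuous 0-based voxel coordinates of world points (n x 3).
world_to_index <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} that carry the `image_volume` geometry
#' (spacing via `pixdim`, origin via the qform translation).
#'
#' @param vol An [image_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   an [image_volume()].
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  im <- RNifti::asNifti(vol$data * 1)
  RNifti::pixdim(im) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(im) <- structure(m, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  xf <- RNifti::xform(im)
  image_volume(array(as.numeric(im), dim(im)),
               spacing = RNifti::pixdim(im)[1:3],
               origin = xf[1:3, 4])
}

# ---------------------------------------------------------------------------
# Exact Euclidean distance transform.
#
# Squared-distance lower envelope computed axis by axis with the shift
# formulation: D'[x] = min_k (D[x +/- k] + (k*s)^2). Exact for values below
# `maxdist`; values above are only guaranteed to be >= maxdist, which is all
# the morphological operations here need.
edt_squared <- function(mask, spacing, maxdist = Inf) {
  d <- dim(mask)
  D <- array(ifelse(mask, 0, Inf), d)
  if (!any(mask)) return(D)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    Dp <- aperm(D, perm)
    n <- dim(Dp)[1]
    m <- prod(dim(Dp)[-1])
    G <- matrix(Dp, n, m)
    s <- spacing[ax]
    kmax <- if (is.finite(maxdist)) min(n - 1L, ceiling(maxdist / s)) else n - 1L
    Dn <- G
    if (kmax >= 1L) for (k in seq_len(kmax)) {
      w <- (s * k)^2
      lo <- seq_len(n - k)
      hi <- lo + k
      Dn[hi, ] <- pmin(Dn[hi, ], G[lo, ] + w)
      Dn[lo, ] <- pmin(Dn[lo, ], G[hi, ] + w)
    }
    D <- aperm(array(Dn, dim(Dp)), order(perm))
  }
  D
}

#' Euclidean distance transform of a binary volume
#'
#' Distance (mm) from every voxel centre to the nearest `TRUE` voxel centre,
#' honouring anisotropic spacing. Exact (per-axis parabolic envelope); with a
#' finite `maxdist` only distances below the cap are guaranteed exact, which
#' speeds up dilation-style queries considerably.
#'
#' @param mask Logical 3-D array (or `image_volume`).
#' @param spacing Voxel spacing (mm); taken from the volume when given one.
#' @param maxdist Optional accuracy cap (mm).
#' @return Numeric array of distances (`Inf` where `mask` is empty).
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1), maxdist = Inf) {
  if (inherits(mask, "image_volume")) {
    spacing <- mask$spacing
    mask <- mask$data
  }
  sqrt(edt_squared(mask != 0, spacing, maxdist))
}

# Signed distance (mm): negative inside `mask`, positive outside, ~0 at the
# boundary (voxelized, so the zero level lies between the two boundary layers).
signed_distance <- function(mask, spacing, maxdist = Inf) {
  mask <- mask != 0
  dout <- sqrt(edt_squared(mask, spacing, maxdist))   # distance to foreground
  din <- sqrt(edt_squared(!mask, spacing, maxdist))   # distance to background
  dout - din
}

# ---------------------------------------------------------------------------
# Connected components (6-connectivity), vectorized frontier flood fill.

label_components <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  n <- prod(d)
  comp <- integer(n)
  fg <- which(mask)
  if (!length(fg)) return(array(comp, d))
  d1 <- d[1]; d12 <- d[1] * d[2]
  # Precompute per-voxel coordinates for boundary masks.
  lab <- 0L
  unvisited <- rep(FALSE, n)
  unvisited[fg] <- TRUE
  neighbor_ok <- function(idx, off) {
    # Validity of idx + off without wrapping across rows/columns.
    if (off == 1L)  return(((idx - 1L) %% d1) + 1L < d1)
    if (off == -1L) return(((idx - 1L) %% d1) + 1L > 1L)
    if (off == d1)  return((((idx - 1L) %/% d1) %% d[2]) + 1L < d[2])
    if (off == -d1) return((((idx - 1L) %/% d1) %% d[2]) + 1L > 1L)
    if (off == d12)  return(((idx - 1L) %/% d12) + 1L < d[3])
    ((idx - 1L) %/% d12) + 1L > 1L
  }
  offs <- c(1L, -1L, d1, -d1, d12, -d12)
  while (any(unvisited)) {
    lab <- lab + 1L
    frontier <- which(unvisited)[1L]
    unvisited[frontier] <- FALSE
    comp[frontier] <- lab
    while (length(frontier)) {
      nxt <- integer(0)
      for (off in offs) {
        ok <- neighbor_ok(frontier, off)
        cand <- frontier[ok] + off
        cand <- cand[unvisited[cand]]
        if (length(cand)) {
          unvisited[cand] <- FALSE
          comp[cand] <- lab
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  array(comp, d)
}

largest_component <- function(mask) {
  comp <- label_components(mask)
  if (max(comp) <= 1L) return(comp > 0L)
  tab <- tabulate(comp[comp > 0L])
  comp == which.max(tab)
}

n_components <- function(mask) max(label_components(mask))

#' Z-score normalize an image volume
#'
#' Subtracts the mean and divides by the SD of all voxel intensities; the
#' standard input scaling for the patch networks.
#'
#' @param vol An [image_volume()] (or array).
#' @return An [image_volume()] with unit-scale intensities.
#' @export
normalize_volume <- function(vol) {
  vol <- as_volume(vol)
  v <- vol$data
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  image_volume((v - mean(v)) / s, vol$spacing, vol$origin)
}

#' Voxel-wise Dice coefficient of two binary volumes
#'
#' @param a,b Logical arrays (or `image_volume`s) on the same grid.
#' @return Dice overlap in \[0, 1\]; `NaN` when both are empty.
#' @export
dice_voxel <- function(a, b) {
  if (inherits(a, "image_volume")) a <- a$data
  if (inherits(b, "image_volume")) b <- b$data
  a <- a != 0; b <- b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

# ---------------------------------------------------------------------------
# Trilinear interpolation with zero padding outside the volume.
#
# `pts` are world coordinates (n x 3). Returns a numeric vector of n samples.
interp_trilinear <- function(vol, pts) {
  vol <- as_volume(vol)
  v <- vol$data
  d <- dim(v)
  ci <- world_to_index(pts, vol$spacing, vol$origin)
  i0 <- floor(ci)
  fr <- ci - i0
  out <- numeric(nrow(pts))
  for (corner in 0:7) {
    cx <- corner %% 2L
    cy <- (corner %/% 2L) %% 2L
    cz <- corner %/% 4L
    ii <- i0[, 1] + cx; jj <- i0[, 2] + cy; kk <- i0[, 3] + cz
    w <- ((if (cx == 1) fr[, 1] else 1 - fr[, 1]) *
          (if (cy == 1) fr[, 2] else 1 - fr[, 2]) *
          (if (cz == 1) fr[, 3] else 1 - fr[, 3]))
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3] & w > 0
    if (any(ok)) {
      lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      out[ok] <- out[ok] + w[ok] * v[lin]
    }
  }
  out
}

# Nearest-neighbour lookup; points outside the grid return `outside`.
sample_nearest <- function(vol, pts, outside = 0) {
  vol <- as_volume(vol)
  d <- dim(vol$data)
  ci <- round(world_to_index(pts, vol$spacing, vol$origin))
  out <- rep(outside, nrow(pts))
  ok <- ci[, 1] >= 0 & ci[, 1] < d[1] & ci[, 2] >= 0 & ci[, 2] < d[2] &
    ci[, 3] >= 0 & ci[, 3] < d[3]
  if (any(ok)) {
    lin <- ci[ok, 1] + d[1] * (ci[ok, 2] + d[2] * ci[ok, 3]) + 1
    out[ok] <- vol$data[lin]
  }
  out
}

# ---------------------------------------------------------------------------
# Seeded RNG helpers: evaluate with a temporary RNG state so that library
# functions are deterministic given a seed without clobbering the caller's
# stream.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed (< 2^31) from a base seed and a stream index.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}
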