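# Multi-scale, elongated, normal-oriented intensity patches (MSPs): the
# per-node image profile fed to the potential-learning networks. In training
# the patch centre receives a random shift along the node normal (uniform on
# (-R, +R), negative = into the blood cavity) so the learned classifier
# tolerates imperfect LA segmentation; at test time the shift is zero.

#' MSP extraction configuration
#'
#' @param dims Patch grid dimensions, all odd; the third dimension is the
#'   long axis, carried along the surface normal. The default 13 x 13 x 17
#'   (2873 samples per patch) matches the converged size of the patch-size
#'   study.
#' @param n_scales Number of scales `N_s` (>= 1); default 3.
#' @param base_spacing_mm Sampling step at scale 0 (mm); doubles per scale.
#' @param shift_R_mm Maximum random-shift magnitude R (mm) used in training;
#'   the default 8 mm is half the patch length. Use 0 at test time.
#' @return Object of class `msp_config`.
#' @export
msp_config <- function(dims = c(13, 13, 17), n_scales = 3L,
                       base_spacing_mm = 1, shift_R_mm = 8) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims %% 2L == 0L))
    stop("patch dims must be 3 odd integers")
  if (n_scales < 1) stop("n_scales must be >= 1")
  if (base_spacing_mm <= 0) stop("base_spacing_mm must be > 0")
  if (shift_R_mm < 0) stop("shift_R_mm (R) must be >= 0")
  structure(list(dims = dims, n_scales = as.integer(n_scales),
                 base_spacing_mm = base_spacing_mm, shift_R_mm = shift_R_mm),
            class = "msp_config")
}

# Per-scale sampling spacings (mm): base * 2^s.
msp_spacings <- function(cfg) cfg$base_spacing_mm * 2^(0:(cfg$n_scales - 1))

#' Local orthonormal patch frame for a surface normal
#'
#' The third axis is the normal (the patch long axis). The first axis is the
#' world axis least parallel to the normal, projected onto the normal's
#' orthogonal plane and normalized; the second completes a right-handed
#' orthonormal triple. In-plane axes thus stay maximally aligned with the
#' world coordinate system.
#'
#' @param normal Unit 3-vector.
#' @return 3 x 3 matrix with the axes as columns (third column = normal).
#' @export
local_frame <- function(normal) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < .Machine$double.eps) stop("zero normal")
  n <- normal / nn
  k <- which.min(abs(n))          # world axis least parallel to the normal
  e <- c(0, 0, 0); e[k] <- 1
  a1 <- e - sum(e * n) * n
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(n[2] * a1[3] - n[3] * a1[2],
          n[3] * a1[1] - n[1] * a1[3],
          n[1] * a1[2] - n[2] * a1[1])
  cbind(a1, a2, n, deparse.level = 0)
}

#' Sample one oriented patch from an image volume
#'
#' Samples a `dims` lattice centred at `center`, with axes given by `frame`
#' (columns) and step `spacing_mm`, using trilinear interpolation; samples
#' outside the volume are zero.
#'
#' @param image An [image_volume()].
#' @param center World point (mm).
#' @param frame 3 x 3 orthonormal axis matrix (see [local_frame()]).
#' @param dims Patch dimensions (odd).
#' @param spacing_mm Sampling step (mm).
#' @return Numeric array of dimension `dims`.
#' @export
extract_patch <- function(image, center, frame, dims = c(13, 13, 17),
                          spacing_mm = 1) {
  dims <- as.integer(dims)
  if (any(dims %% 2L == 0L)) stop("patch dims must be odd")
  offs <- as.matrix(expand.grid(
    (seq_len(dims[1]) - (dims[1] + 1) / 2) * spacing_mm,
    (seq_len(dims[2]) - (dims[2] + 1) / 2) * spacing_mm,
    (seq_len(dims[3]) - (dims[3] + 1) / 2) * spacing_mm))
  pts <- sweep(offs %*% t(frame), 2, as.numeric(center), "+")
  array(interp_trilinear(image, pts), dims)
}

#' Extract the multi-scale patch stack of a mesh node
#'
#' Draws one shift `gamma ~ Uniform(-R, R)` (from the current RNG stream),
#' moves the patch centre to `v_i + gamma * normal_i`, and samples one patch
#' per scale; all scales share the centre and frame, with sampling spacing
#' doubling per scale.
#'
#' @param image An [image_volume()].
#' @param mesh A [surface_mesh()].
#' @param node Vertex index.
#' @param cfg An [msp_config()]; set `shift_R_mm = 0` for the testing phase.
#' @return Object of class `msp_stack`: `patches` (list of `N_s` arrays),
#'   `spacings`, `node`, `shift_mm` (the applied gamma).
#' @export
extract_msp <- function(image, mesh, node, cfg = msp_config()) {
  gam <- if (cfg$shift_R_mm > 0)
    stats::runif(1, -cfg$shift_R_mm, cfg$shift_R_mm) else 0
  nrm <- mesh$normals[node, ]
  fr <- local_frame(nrm)
  ctr <- mesh$vertices[node, ] + gam * nrm
  sps <- msp_spacings(cfg)
  patches <- lapply(sps, function(s)
    extract_patch(image, ctr, fr, cfg$dims, s))
  structure(list(patches = patches, spacings = sps, node = node,
                 shift_mm = gam),
            class = "msp_stack")
}

# Batched MSP extraction: returns a list of N_s matrices, each
# (length(nodes) x prod(dims)), plus the applied shifts. One gamma per node.
# All patch lattices for one scale are interpolated in a single call.
extract_msp_batch <- function(image, mesh, nodes, cfg = msp_config()) {
  nn <- length(nodes)
  gam <- if (cfg$shift_R_mm > 0)
    stats::runif(nn, -cfg$shift_R_mm, cfg$shift_R_mm) else numeric(nn)
  nrm <- mesh$normals[nodes, , drop = FALSE]
  ctr <- mesh$vertices[nodes, , drop = FALSE] + gam * nrm
  nvox <- prod(cfg$dims)
  base_offs <- as.matrix(expand.grid(
    seq_len(cfg$dims[1]) - (cfg$dims[1] + 1) / 2,
    seq_len(cfg$dims[2]) - (cfg$dims[2] + 1) / 2,
    seq_len(cfg$dims[3]) - (cfg$dims[3] + 1) / 2))
  # Per-node frames (in-plane axes depend on the normal).
  frames <- lapply(seq_len(nn), function(i) local_frame(nrm[i, ]))
  sps <- msp_spacings(cfg)
  out <- vector("list", cfg$n_scales)
  for (s in seq_len(cfg$n_scales)) {
    pts <- matrix(0, nn * nvox, 3)
    for (i in seq_len(nn)) {
      p <- (base_offs * sps[s]) %*% t(frames[[i]])
      pts[(i - 1) * nvox + seq_len(nvox), ] <- sweep(p, 2, ctr[i, ], "+")
    }
    vals <- interp_trilinear(image, pts)
    out[[s]] <- matrix(vals, nn, nvox, byrow = TRUE)
  }
  list(X = out, shifts = gam, nodes = nodes, cfg = cfg)
}

#' Cache extracted patch stacks to disk
#'
#' Writes the per-scale patch matrices of a batched extraction as raw
#' little-endian doubles (one `.bin` per scale) plus a JSON sidecar holding
#' node ids, applied shifts, dims and spacings, for reuse across training
#' runs.
#'
#' @param batch Result of a batched MSP extraction (see [extract_msp()] for
#'   the per-node variant); a list with `X`, `shifts`, `nodes`, `cfg`.
#' @param prefix Output path prefix; files are `<prefix>_scale<k>.bin` and
#'   `<prefix>.json`.
#' @return The sidecar path, invisibly.
#' @export
write_msp_cache <- function(batch, prefix) {
  cfg <- batch$cfg
  for (s in seq_along(batch$X)) {
    con <- file(sprintf("%s_scale%d.bin", prefix, s), "wb")
    writeBin(as.vector(batch$X[[s]]), con, size = 8, endian = "little")
    close(con)
  }
  sidecar <- sprintf("%s.json", prefix)
  meta <- sprintf(
    paste0('{"nodes": [%s], "shifts_mm": [%s], "dims": [%s], ',
           '"spacings_mm": [%s], "n_scales": %d}'),
    paste(batch$nodes, collapse = ", "),
    paste(format(batch$shifts, digits = 17), collapse = ", "),
    paste(cfg$dims, collapse = ", "),
    paste(msp_spacings(cfg), collapse = ", "),
    cfg$n_scales)
  writeLines(meta, sidecar)
  invisible(sidecar)
}

#' @rdname write_msp_cache
#' @param prefix Path prefix used when writing.
#' @export
read_msp_cache <- function(prefix) {
  meta <- jsonlite::fromJSON(sprintf("%s.json", prefix))
  nvox <- prod(meta$dims)
  nn <- length(meta$nodes)
  X <- lapply(seq_len(meta$n_scales), function(s) {
    con <- file(sprintf("%s_scale%d.bin", prefix, s), "rb")
    on.exit(close(con))
    matrix(readBin(con, "double", nn * nvox, size = 8, endian = "little"),
           nn, nvox)
  })
  list(X = X, shifts = meta$shifts_mm, nodes = meta$nodes,
       cfg = msp_config(meta$dims, meta$n_scales,
                        meta$spacings_mm[1],
                        shift_R_mm = max(abs(meta$shifts_mm), 0)))
}
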