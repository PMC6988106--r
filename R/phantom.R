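# Synthetic LGE-MRI phantom: an LA-like cavity with a thin enhanced-scar wall,
# nearby confounding enhanced structures, noise, and a simulated (imperfect)
# automatic LA segmentation. Gives every downstream stage a ground truth.

#' Phantom configuration
#'
#' Describes a synthetic LGE volume: a roughly spherical blood cavity (radius
#' modulated by a smooth low-order spherical-harmonic field), a thin wall,
#' connected enhanced scar patches covering a target fraction of the wall,
#' bright confounding structures near the wall (aorta / right-atrial-wall
#' analogues), an additive smooth bias field, and noise. `seg_error_mm`
#' controls the amplitude of the smooth boundary perturbation used to emulate
#' an automatic LA segmentation.
#'
#' @param grid_shape Voxels per axis (length 3).
#' @param spacing_mm Voxel size per axis (mm).
#' @param cavity_radius_mm Base cavity radius (mm).
#' @param cavity_irregularity Amplitude (mm) of the smooth radial deformation.
#' @param wall_thickness_mm Nominal wall thickness (mm); must be > 0.
#' @param n_scar_patches Number of scar seed locations on the wall.
#' @param scar_area_fraction Target fraction of the wall surface that is scar,
#'   in `[0, 1)`.
#' @param intensity_means Named vector with mean intensities for `blood`,
#'   `wall`, `scar` and `confounder`; scar must be brighter than wall.
#' @param background_mean Mean intensity outside all structures.
#' @param bias_amplitude Amplitude (intensity units) of the additive smooth
#'   bias field; 0 disables it.
#' @param noise_sigma SD of the additive noise.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param confounders List of confounder descriptions (see Details), or
#'   `"default"` for one tube and one shell segment near the wall, enhanced at
#'   the scar mean.
#' @param seg_error_mm Maximum amplitude (mm) of the smooth boundary
#'   perturbation applied to the cavity to simulate automatic segmentation.
#' @param seed RNG seed; the phantom is deterministic given the seed.
#'
#' @details Each confounder is a list with `type = "tube"` (fields
#'   `offset_dir`, `gap_mm`, `radius_mm`) or `type = "shell"` (fields `dir`,
#'   `gap_mm`, `thickness_mm`, `half_angle_deg`), plus optional `intensity`
#'   (defaults to the scar mean).
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           spacing_mm = c(1, 1, 1),
                           cavity_radius_mm = 20,
                           cavity_irregularity = 2,
                           wall_thickness_mm = 2,
                           n_scar_patches = 4,
                           scar_area_fraction = 0.25,
                           intensity_means = c(blood = 110, wall = 80,
                                               scar = 160, confounder = 160),
                           background_mean = 30,
                           bias_amplitude = 5,
                           noise_sigma = 10,
                           noise_model = c("gaussian", "rician"),
                           confounders = "default",
                           seg_error_mm = 2,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            length(spacing_mm) == 3, all(spacing_mm > 0))
  if (wall_thickness_mm <= 0) stop("wall_thickness_mm must be > 0")
  if (scar_area_fraction < 0 || scar_area_fraction >= 1)
    stop("scar_area_fraction must be in [0, 1)")
  if (seg_error_mm < 0) stop("seg_error_mm must be >= 0")
  need <- c("blood", "wall", "scar", "confounder")
  if (!all(need %in% names(intensity_means)))
    stop("intensity_means must name blood, wall, scar and confounder")
  if (intensity_means["scar"] <= intensity_means["wall"])
    stop("scars are enhanced: intensity_means['scar'] must exceed ",
         "intensity_means['wall']")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  half_extent <- (grid_shape - 1) * spacing_mm / 2
  need_mm <- cavity_radius_mm + cavity_irregularity + wall_thickness_mm +
    2 * max(spacing_mm)
  if (need_mm > min(half_extent))
    stop("geometrically infeasible phantom: cavity + wall (", round(need_mm, 1),
         " mm) exceeds the grid half-extent (", round(min(half_extent), 1),
         " mm); enlarge grid_shape or shrink the cavity")
  if (identical(confounders, "default")) {
    # Enhanced structures abutting the outer wall (ascending-aorta tube and
    # right-atrial-wall shell analogues): the intensity confounders that make
    # purely threshold-based scar detection fail near them.
    confounders <- list(
      list(type = "tube", offset_dir = c(1, 0, 0), gap_mm = 0, radius_mm = 4),
      list(type = "shell", dir = c(-1, 0, 0), gap_mm = 0, thickness_mm = 2,
           half_angle_deg = 35))
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 cavity_radius_mm = cavity_radius_mm,
                 cavity_irregularity = cavity_irregularity,
                 wall_thickness_mm = wall_thickness_mm,
                 n_scar_patches = as.integer(n_scar_patches),
                 scar_area_fraction = scar_area_fraction,
                 intensity_means = intensity_means,
                 background_mean = background_mean,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 confounders = confounders,
                 seg_error_mm = seg_error_mm,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Real spherical harmonics Y_lm evaluated at unit directions (n x 3).
# Returns the field value of a random band-limited expansion whose N(0,1)
# coefficients are drawn from the current RNG stream.
random_sphere_field <- function(dirs, lmin = 1L, lmax = 4L) {
  theta <- acos(pmin(1, pmax(-1, dirs[, 3])))
  phi <- atan2(dirs[, 2], dirs[, 1])
  x <- cos(theta)
  f <- numeric(nrow(dirs))
  for (l in lmin:lmax) {
    P <- pracma::legendre(l, x)           # (l+1) x n, m = 0..l
    for (m in 0:l) {
      nlm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      if (m == 0) {
        f <- f + stats::rnorm(1) * nlm * P[1, ]
      } else {
        base <- sqrt(2) * nlm * P[m + 1, ]
        f <- f + stats::rnorm(1) * base * cos(m * phi) +
          stats::rnorm(1) * base * sin(m * phi)
      }
    }
  }
  f
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# Voxel-centre coordinate arrays relative to the grid centre (mm).
grid_coords <- function(d, spacing, origin) {
  ctr <- origin + (d - 1) * spacing / 2
  x <- (0:(d[1] - 1)) * spacing[1] + origin[1] - ctr[1]
  y <- (0:(d[2] - 1)) * spacing[2] + origin[2] - ctr[2]
  z <- (0:(d[3] - 1)) * spacing[3] + origin[3] - ctr[3]
  list(X = array(rep(x, times = d[2] * d[3]), d),
       Y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       Z = array(rep(z, each = d[1] * d[2]), d),
       center = ctr)
}

#' Generate a synthetic LGE phantom with ground truth
#'
#' Builds the tissue label volumes (cavity, wall, scar), the intensity image
#' (piecewise-constant tissue means + smooth bias + noise) and a perturbed
#' "automatic" cavity segmentation. Deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_truth`: list with `image`
#'   ([image_volume()]), logical volumes `la_seg`, `wall_seg`, `scar_seg`,
#'   `la_seg_auto`, the `config`, and geometry helpers `spacing`/`origin`.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    d <- config$grid_shape
    sp <- config$spacing_mm
    origin <- c(0, 0, 0)
    g <- grid_coords(d, sp, origin)
    r <- sqrt(g$X^2 + g$Y^2 + g$Z^2)
    dirs <- cbind(as.vector(g$X), as.vector(g$Y), as.vector(g$Z)) /
      ifelse(as.vector(r) > 0, as.vector(r), 1)
    dirs[as.vector(r) == 0, ] <- rep(c(1, 0, 0), each = sum(r == 0))

    # Cavity radius field.
    if (config$cavity_irregularity > 0) {
      f <- random_sphere_field(dirs, lmin = 2L, lmax = 4L)
      f <- f / max(abs(f))
      rad <- array(config$cavity_radius_mm + config$cavity_irregularity * f, d)
    } else {
      rad <- array(config$cavity_radius_mm, d)
    }
    cavity <- r <= rad
    wall <- r > rad & r <= rad + config$wall_thickness_mm

    # Scar patches: angular caps grown from random seed directions until the
    # covered solid-angle fraction reaches the target.
    scar <- array(FALSE, d)
    if (config$n_scar_patches > 0 && config$scar_area_fraction > 0) {
      seeds <- matrix(stats::rnorm(3 * config$n_scar_patches), ncol = 3)
      seeds <- seeds / sqrt(rowSums(seeds^2))
      ang_min <- function(dd) {
        cosang <- dd %*% t(seeds)
        acos(pmin(1, pmax(-1, apply(cosang, 1, max))))
      }
      ref <- fibonacci_sphere(2000L)
      rho <- stats::quantile(ang_min(ref), config$scar_area_fraction,
                             names = FALSE)
      md <- array(ang_min(dirs), d)
      scar <- wall & md <= rho
    }

    # Confounders: bright structures just outside the wall.
    conf <- array(FALSE, d)
    conf_int <- array(config$intensity_means[["confounder"]], d)
    outer_r <- rad + config$wall_thickness_mm
    for (cf in config$confounders) {
      if (identical(cf$type, "tube")) {
        u <- cf$offset_dir / sqrt(sum(cf$offset_dir^2))
        off <- (config$cavity_radius_mm + config$cavity_irregularity +
                config$wall_thickness_mm + cf$gap_mm + cf$radius_mm)
        m <- sqrt((g$X - off * u[1])^2 + (g$Y - off * u[2])^2) <= cf$radius_mm
      } else if (identical(cf$type, "shell")) {
        u <- cf$dir / sqrt(sum(cf$dir^2))
        cosang <- array(dirs %*% u, d)
        m <- r > outer_r + cf$gap_mm &
          r <= outer_r + cf$gap_mm + cf$thickness_mm &
          cosang >= cos(cf$half_angle_deg * pi / 180)
      } else stop("unknown confounder type: ", cf$type)
      conf <- conf | m
      if (!is.null(cf$intensity)) conf_int[m] <- cf$intensity
    }
    conf <- conf & !cavity & !wall

    # Intensity image.
    img <- array(config$background_mean, d)
    img[cavity] <- config$intensity_means[["blood"]]
    img[wall] <- config$intensity_means[["wall"]]
    img[scar] <- config$intensity_means[["scar"]]
    img[conf] <- conf_int[conf]
    if (config$bias_amplitude > 0) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      b <- g$X * u[1] + g$Y * u[2] + g$Z * u[3]
      img <- img + config$bias_amplitude * b / max(abs(b))
    }
    if (config$noise_sigma > 0) {
      if (config$noise_model == "gaussian") {
        img <- img + array(stats::rnorm(prod(d), sd = config$noise_sigma), d)
      } else {
        n1 <- array(stats::rnorm(prod(d), sd = config$noise_sigma), d)
        n2 <- array(stats::rnorm(prod(d), sd = config$noise_sigma), d)
        img <- sqrt((img + n1)^2 + n2^2)
      }
    }

    la_auto <- perturb_segmentation(cavity, config$seg_error_mm,
                                    spacing = sp,
                                    seed = stats::runif(1, 1, 2^30))

    structure(list(image = image_volume(img, sp, origin),
                   la_seg = cavity,
                   wall_seg = wall,
                   scar_seg = scar,
                   la_seg_auto = la_auto,
                   spacing = sp, origin = origin,
                   config = config),
              class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> grid ", paste(dim(x$la_seg), collapse = "x"),
      ", cavity ", sum(x$la_seg), " vox, wall ", sum(x$wall_seg),
      " vox, scar ", sum(x$scar_seg), " vox (",
      round(100 * sum(x$scar_seg) / max(1, sum(x$wall_seg)), 1),
      "% of wall)\n", sep = "")
  invisible(x)
}

#' Smoothly perturb a binary segmentation boundary
#'
#' Displaces the boundary of a (single-component) binary segmentation by a
#' smooth random radial field with maximum amplitude `seg_error_mm`,
#' emulating the over-/under-segmentation of an automatic LA delineation.
#' The output is `{x : signed_distance(x) <= f(direction(x))}` for a
#' band-limited spherical-harmonic field `f` about the segmentation centroid,
#' so every boundary point moves by at most `seg_error_mm` (up to
#' voxelization). The largest connected component is returned.
#'
#' @param seg Logical 3-D array or [image_volume()].
#' @param seg_error_mm Maximum boundary displacement (mm); 0 returns the
#'   input unchanged.
#' @param spacing Voxel spacing (mm); taken from `seg` when it is a volume.
#' @param seed RNG seed for the random field.
#' @return Logical array of the perturbed segmentation.
#' @export
perturb_segmentation <- function(seg, seg_error_mm, spacing = c(1, 1, 1),
                                 seed = NULL) {
  if (inherits(seg, "image_volume")) {
    spacing <- seg$spacing
    seg <- seg$data
  }
  seg <- seg != 0
  if (!any(seg)) stop("empty segmentation")
  if (seg_error_mm < 0) stop("seg_error_mm must be >= 0")
  if (seg_error_mm == 0) return(seg)
  with_seed(seed, {
    d <- dim(seg)
    sd_map <- signed_distance(seg, spacing,
                              maxdist = seg_error_mm + 3 * max(spacing))
    # Half-voxel correction: voxel-centre distances jump from -1 to +1 voxel
    # across the boundary, but the surface lies midway between the centres.
    sd_map <- sd_map - 0.5 * mean(spacing) * sign(sd_map)
    # Direction of each voxel from the segmentation centroid.
    idx <- which(seg, arr.ind = TRUE)
    ctr <- colMeans(idx - 1) * spacing
    g <- grid_coords(d, spacing, c(0, 0, 0))
    X <- g$X + g$center[1] - ctr[1]
    Y <- g$Y + g$center[2] - ctr[2]
    Z <- g$Z + g$center[3] - ctr[3]
    r <- sqrt(X^2 + Y^2 + Z^2)
    dirs <- cbind(as.vector(X), as.vector(Y), as.vector(Z)) /
      ifelse(as.vector(r) > 0, as.vector(r), 1)
    dirs[as.vector(r) == 0, ] <- rep(c(1, 0, 0), each = sum(r == 0))
    f <- random_sphere_field(dirs, lmin = 1L, lmax = 4L)
    f <- seg_error_mm * f / max(abs(f))
    out <- array(as.vector(sd_map) <= f, d)
    if (!any(out)) stop("perturbation removed the segmentation entirely")
    largest_component(out)
  })
}

#' Write a phantom to NIfTI files
#'
#' Writes `<case>_image`, `<case>_la`, `<case>_wall`, `<case>_scar` and
#' `<case>_la_auto` (`.nii.gz`) into `dir`.
#'
#' @param truth A `phantom_truth` from [make_phantom()].
#' @param dir Output directory (created if missing).
#' @param case Case name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(truth, dir, case = "case") {
  stopifnot(inherits(truth, "phantom_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vols <- list(image = truth$image,
               la = image_volume(truth$la_seg * 1, truth$spacing, truth$origin),
               wall = image_volume(truth$wall_seg * 1, truth$spacing, truth$origin),
               scar = image_volume(truth$scar_seg * 1, truth$spacing, truth$origin),
               la_auto = image_volume(truth$la_seg_auto * 1, truth$spacing,
                                      truth$origin))
  paths <- vapply(names(vols), function(nm) {
    p <- file.path(dir, paste0(case, "_", nm, ".nii.gz"))
    write_volume(vols[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
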