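# Endocardial surface extraction and mesh operations. The mesh vertices are
# the graph nodes X and its edges the neighborhood system N of the
# segmentation energy; scar ground truth is projected onto the nodes along
# the vertex normals.

#' Construct a triangular surface mesh
#'
#' @param vertices Numeric matrix (n x 3) of vertex positions in world mm.
#' @param faces Integer matrix (m x 3) of 1-based vertex indices.
#' @param normals Optional (n x 3) unit vertex normals; computed (outward,
#'   area-weighted) when omitted.
#' @return Object of class `surface_mesh`: `vertices`, `faces`, `normals`,
#'   `edges` (unique index pairs, `i < j`).
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  mesh <- structure(list(vertices = vertices, faces = faces,
                         normals = normals, edges = faces_to_edges(faces)),
                    class = "surface_mesh")
  if (is.null(normals)) mesh$normals <- vertex_normals(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, ", nrow(x$edges), " edges (Euler characteristic ",
      nrow(x$vertices) - nrow(x$edges) + nrow(x$faces), ")\n", sep = "")
  invisible(x)
}

faces_to_edges <- function(faces) {
  if (nrow(faces) == 0) return(matrix(integer(0), 0, 2))
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Signed volume of a closed oriented mesh (positive when faces wind outward).
mesh_signed_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c_))) / 6
}

#' Total surface area of a mesh (mm^2)
#' @param mesh A [surface_mesh()].
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
              v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  sum(sqrt(rowSums(n^2))) / 2
}

# ---------------------------------------------------------------------------
# Marching tetrahedra on the 0.5 iso-surface of a binary volume.
#
# Each cube of 8 voxel centres is split into the 6 Kuhn tetrahedra around the
# main diagonal; the subdivision is translation-invariant, so shared cube
# faces are triangulated consistently and the result is watertight. Iso
# vertices sit at edge midpoints (binary field, iso level 0.5).

# Monotone-path (Kuhn) tetrahedra; cube corners 0..7 with bit 0 -> x, etc.
.mt_tets <- rbind(c(0, 1, 3, 7), c(0, 1, 5, 7), c(0, 2, 3, 7),
                  c(0, 2, 6, 7), c(0, 4, 5, 7), c(0, 4, 6, 7)) + 1L
.mt_corner_off <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1),
                        c(0, 0, 1, 1, 0, 0, 1, 1),
                        c(0, 0, 0, 0, 1, 1, 1, 1))
.mt_edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

# Per-pattern triangle table: pattern p in 0..15 encodes which of the 4 tet
# corners are inside; triangles are triples of tet-edge ids.
.mt_pattern_table <- local({
  edge_id <- function(a, b) {
    which(.mt_edges[, 1] == min(a, b) & .mt_edges[, 2] == max(a, b))
  }
  tbl <- vector("list", 16)
  for (p in 0:15) {
    ins <- which(bitwAnd(p, as.integer(2^(0:3))) > 0)
    outs <- setdiff(1:4, ins)
    tbl[[p + 1]] <- if (length(ins) %in% c(0L, 4L)) {
      matrix(integer(0), 0, 3)
    } else if (length(ins) == 1L) {
      matrix(vapply(outs, function(b) edge_id(ins, b), 1L), 1, 3)
    } else if (length(ins) == 3L) {
      matrix(vapply(ins, function(b) edge_id(outs, b), 1L), 1, 3)
    } else {
      e11 <- edge_id(ins[1], outs[1]); e12 <- edge_id(ins[1], outs[2])
      e22 <- edge_id(ins[2], outs[2]); e21 <- edge_id(ins[2], outs[1])
      rbind(c(e11, e12, e22), c(e11, e22, e21))
    }
  }
  tbl
})

# Separable Gaussian smoothing (sigma in voxels), zero beyond the border.
gauss_smooth3 <- function(A, sigma) {
  r <- ceiling(2.5 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    Ap <- aperm(A, perm)
    n <- dim(Ap)[1]
    M <- matrix(Ap, n)
    out <- matrix(0, n, ncol(M))
    for (o in -r:r) {
      src <- max(1, 1 - o):min(n, n - o)
      out[src + o, ] <- out[src + o, ] + k[o + r + 1] * M[src, , drop = FALSE]
    }
    A <- aperm(array(out, dim(Ap)), order(perm))
  }
  A
}

#' Extract the endocardial surface of a binary segmentation
#'
#' Triangulates the 0.5 iso-surface by marching tetrahedra (Kuhn cube
#' subdivision: translation-invariant, watertight, consistently oriented).
#' The binary field is first smoothed with a small Gaussian so the
#' interpolated iso-crossings form a smooth surface rather than a voxelized
#' one (skipped automatically for objects too small to survive smoothing),
#' and a few Taubin passes regularize the triangle shapes. The mesh is
#' denser than the image grid, so small scars survive the projection. When
#' the segmentation has several connected components the largest is kept
#' with a warning.
#'
#' @param seg Logical/binary 3-D array or [image_volume()].
#' @param spacing,origin Grid geometry (mm); taken from `seg` when it is an
#'   [image_volume()].
#' @param smooth_sigma Gaussian pre-smoothing SD in voxels.
#' @param smooth_iter Taubin smoothing iterations (lambda/mu pairs).
#' @param densify If `TRUE`, one midpoint subdivision pass is applied when the
#'   mean edge length is not below the smallest voxel spacing.
#' @return A [surface_mesh()] with outward vertex normals.
#' @export
extract_surface <- function(seg, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            smooth_sigma = 0.9, smooth_iter = 5L,
                            densify = TRUE) {
  if (inherits(seg, "image_volume")) {
    spacing <- seg$spacing
    origin <- seg$origin
    seg <- seg$data
  }
  seg <- seg != 0
  if (!any(seg)) stop("empty segmentation: no surface to extract")
  if (n_components(seg) > 1L) {
    warning("segmentation has multiple connected components; keeping largest")
    seg <- largest_component(seg)
  }
  d <- dim(seg) + 2L
  V <- array(0, d)
  V[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- seg
  if (smooth_sigma > 0) {
    Vs <- gauss_smooth3(V, smooth_sigma)
    # Small/thin objects can be smoothed below the iso level; fall back.
    if (max(Vs) >= 0.55) V <- Vs
  }
  orig_p <- origin - spacing
  iso <- 0.5

  # Active cubes: corners straddle the iso level.
  IN <- V > iso
  n1 <- d - 1L
  S <- array(0L, n1)
  for (c8 in 1:8) {
    o <- .mt_corner_off[c8, ]
    S <- S + IN[(1 + o[1]):(n1[1] + o[1]),
                (1 + o[2]):(n1[2] + o[2]),
                (1 + o[3]):(n1[3] + o[3])]
  }
  act <- which(S > 0L & S < 8L, arr.ind = TRUE)
  if (nrow(act) == 0) stop("degenerate segmentation")
  dd <- dim(V)
  lin0 <- (act[, 1] - 1) + dd[1] * ((act[, 2] - 1) + dd[2] * (act[, 3] - 1)) + 1
  corner_lin <- function(rows, c8) {
    o <- .mt_corner_off[c8, ]
    lin0[rows] + o[1] + dd[1] * (o[2] + dd[2] * o[3])
  }
  CB <- matrix(FALSE, nrow(act), 8)   # inside flags per cube corner
  for (c8 in 1:8) CB[, c8] <- IN[corner_lin(seq_len(nrow(act)), c8)]
  corner_xyz <- function(rows, c8) {
    o <- .mt_corner_off[c8, ]
    cbind((act[rows, 1] - 1 + o[1]) * spacing[1] + orig_p[1],
          (act[rows, 2] - 1 + o[2]) * spacing[2] + orig_p[2],
          (act[rows, 3] - 1 + o[3]) * spacing[3] + orig_p[3])
  }

  tri_xyz <- vector("list", 0)   # interpolated vertex coordinates per slot
  tri_key <- vector("list", 0)   # global corner-pair keys per slot
  for (t in seq_len(nrow(.mt_tets))) {
    tc <- .mt_tets[t, ]
    patt <- CB[, tc[1]] + 2L * CB[, tc[2]] + 4L * CB[, tc[3]] + 8L * CB[, tc[4]]
    for (p in 1:14) {
      tris <- .mt_pattern_table[[p + 1]]
      if (nrow(tris) == 0) next
      rows <- which(patt == p)
      if (!length(rows)) next
      # Iso crossings on the needed tet edges (linear interpolation).
      need <- sort(unique(as.vector(tris)))
      crossing <- vector("list", 6)
      ckey <- vector("list", 6)
      for (e in need) {
        ca <- tc[.mt_edges[e, 1]]; cb <- tc[.mt_edges[e, 2]]
        la <- corner_lin(rows, ca); lb <- corner_lin(rows, cb)
        va <- V[la]; vb <- V[lb]
        tt <- (iso - va) / (vb - va)
        pa <- corner_xyz(rows, ca); pb <- corner_xyz(rows, cb)
        crossing[[e]] <- pa + tt * (pb - pa)
        ckey[[e]] <- paste(pmin(la, lb), pmax(la, lb))
      }
      # Centroid of inside tet corners fixes the outward orientation.
      ins <- which(bitwAnd(p, as.integer(2^(0:3))) > 0)
      gi <- 0
      for (a in ins) gi <- gi + corner_xyz(rows, tc[a]) / length(ins)
      for (k in seq_len(nrow(tris))) {
        e1 <- tris[k, 1]; e2 <- tris[k, 2]; e3 <- tris[k, 3]
        a <- crossing[[e1]]; b <- crossing[[e2]]; c_ <- crossing[[e3]]
        nrm <- cross3(b - a, c_ - a)
        flip <- rowSums(nrm * ((a + b + c_) / 3 - gi)) < 0
        B <- b; B[flip, ] <- c_[flip, ]
        C <- c_; C[flip, ] <- b[flip, ]
        kb <- ckey[[e2]]; kc <- ckey[[e3]]
        KB <- kb; KB[flip] <- kc[flip]
        KC <- kc; KC[flip] <- kb[flip]
        tri_xyz <- c(tri_xyz, list(a), list(B), list(C))
        tri_key <- c(tri_key, list(ckey[[e1]]), list(KB), list(KC))
      }
    }
  }
  P <- do.call(rbind, tri_xyz)
  keys <- unlist(tri_key)
  uk <- unique(keys)
  id <- match(keys, uk)
  verts <- P[match(uk, keys), , drop = FALSE]
  # Slots come in (v1, v2, v3) triples of equal-sized row blocks.
  sizes <- vapply(tri_xyz, nrow, 1L)
  offs <- cumsum(c(0, sizes))
  faces <- do.call(rbind, lapply(seq_len(length(tri_xyz) / 3), function(s) {
    cbind(id[offs[3 * s - 2] + seq_len(sizes[3 * s - 2])],
          id[offs[3 * s - 1] + seq_len(sizes[3 * s - 1])],
          id[offs[3 * s] + seq_len(sizes[3 * s])])
  }))

  if (densify) {
    el <- sqrt(rowSums((verts[faces[, 1], ] - verts[faces[, 2], ])^2))
    if (mean(el) >= min(spacing)) {
      sub <- subdivide_midpoint(verts, faces)
      verts <- sub$vertices; faces <- sub$faces
    }
  }
  if (smooth_iter > 0) verts <- taubin_smooth(verts, faces, smooth_iter)
  if (mesh_signed_volume(verts, faces) < 0) faces <- faces[, c(1, 3, 2)]
  surface_mesh(verts, faces)
}

# One midpoint (4-to-1) subdivision pass; new vertices at edge midpoints.
subdivide_midpoint <- function(vertices, faces) {
  edges <- faces_to_edges(faces)
  key <- paste(edges[, 1], edges[, 2])
  mid <- (vertices[edges[, 1], , drop = FALSE] +
          vertices[edges[, 2], , drop = FALSE]) / 2
  mid_id <- nrow(vertices) + seq_len(nrow(edges))
  eid <- function(a, b) mid_id[match(paste(pmin(a, b), pmax(a, b)), key)]
  m12 <- eid(faces[, 1], faces[, 2])
  m23 <- eid(faces[, 2], faces[, 3])
  m31 <- eid(faces[, 3], faces[, 1])
  list(vertices = rbind(vertices, mid),
       faces = rbind(cbind(faces[, 1], m12, m31),
                     cbind(faces[, 2], m23, m12),
                     cbind(faces[, 3], m31, m23),
                     cbind(m12, m23, m31)))
}

# Taubin lambda/mu smoothing (volume-preserving, unlike plain Laplacian).
taubin_smooth <- function(vertices, faces, iter = 10L, lambda = 0.5,
                          mu = -0.53) {
  edges <- faces_to_edges(faces)
  n <- nrow(vertices)
  adj_i <- c(edges[, 1], edges[, 2])
  adj_j <- c(edges[, 2], edges[, 1])
  deg <- tabulate(adj_i, n)
  step <- function(v, w) {
    nb <- rowsum(v[adj_j, , drop = FALSE], adj_i)  # ordered by index
    v + w * (nb / pmax(deg, 1) - v)
  }
  for (k in seq_len(iter)) {
    vertices <- step(vertices, lambda)
    vertices <- step(vertices, mu)
  }
  vertices
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals, normalized, with the
#' global orientation fixed by an interior test (the signed mesh volume), so
#' the result points outward even if the face windings are flipped.
#'
#' @param mesh A [surface_mesh()].
#' @return Numeric (n x 3) matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (any(tabulate(as.vector(f), nrow(v)) == 0))
    stop("mesh has isolated vertices")
  fn <- cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
               v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  # fn has magnitude 2*area: area weighting is built in.
  acc <- rowsum(rbind(fn, fn, fn), c(f[, 1], f[, 2], f[, 3]))
  acc <- acc[order(as.integer(rownames(acc))), , drop = FALSE]
  nrm <- acc / pmax(sqrt(rowSums(acc^2)), .Machine$double.eps)
  if (mesh_signed_volume(v, f) < 0) nrm <- -nrm
  nrm
}

# Weighted edge graph of the mesh (Euclidean edge lengths in mm).
mesh_graph <- function(mesh) {
  w <- sqrt(rowSums((mesh$vertices[mesh$edges[, 1], , drop = FALSE] -
                     mesh$vertices[mesh$edges[, 2], , drop = FALSE])^2))
  igraph::graph_from_edgelist(mesh$edges, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Geodesic (edge-graph shortest path) distance between mesh nodes
#'
#' Shortest-path length over the mesh edge graph with Euclidean edge lengths,
#' the distance that feeds the pairwise potential network. Exact polyhedral
#' geodesics are deliberately not used.
#'
#' @param mesh A [surface_mesh()].
#' @param i,j Vertex indices (`j` may be a vector).
#' @return Distance(s) in mm.
#' @export
geodesic_distance <- function(mesh, i, j) {
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = i, to = j)[1, ]
  if (any(!is.finite(d))) stop("nodes are not connected on the mesh")
  unname(d)
}

# Edge lengths (mm) for all mesh edges, in mesh$edges order.
edge_lengths <- function(mesh) {
  sqrt(rowSums((mesh$vertices[mesh$edges[, 1], , drop = FALSE] -
                mesh$vertices[mesh$edges[, 2], , drop = FALSE])^2))
}

#' Project volumetric scar labels onto mesh nodes
#'
#' A node receives label 1 when any scar voxel lies within its normal-line
#' corridor `v_i + t * normal_i`, `t` from `-depth_in_mm` (into the cavity) to
#' `+depth_out_mm` (into/through the wall), sampled at half-voxel steps.
#'
#' @param scar_seg Binary scar volume ([image_volume()] or array).
#' @param mesh A [surface_mesh()] extracted from the same grid.
#' @param depth_out_mm,depth_in_mm Corridor extent (mm) outside/inside the
#'   endocardial surface. Defaults cover the reported wall thickness plus a
#'   segmentation-error margin.
#' @param spacing,origin Grid geometry when `scar_seg` is a bare array.
#' @return Integer vector of 0/1 node labels (the ground-truth `L`).
#' @export
project_labels <- function(scar_seg, mesh, depth_out_mm = 4, depth_in_mm = 1,
                           spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vol <- if (inherits(scar_seg, "image_volume")) scar_seg else
    image_volume(scar_seg * 1, spacing, origin)
  step <- min(vol$spacing) / 2
  ts <- seq(-depth_in_mm, depth_out_mm, by = step)
  lab <- rep(FALSE, nrow(mesh$vertices))
  for (t in ts) {
    pts <- mesh$vertices + t * mesh$normals
    lab <- lab | (sample_nearest(vol, pts) > 0)
  }
  as.integer(lab)
}

# ---------------------------------------------------------------------------
# Mesh I/O: ASCII PLY (read/write) and legacy ASCII VTK polydata (write).
# Per-node scalars are stored as extra vertex properties / point data.

#' Read and write surface meshes
#'
#' ASCII PLY I/O with optional per-vertex scalar fields (stored as extra
#' float vertex properties), and legacy ASCII VTK polydata export with point
#' data. Scalars round-trip through PLY.
#'
#' @param mesh A [surface_mesh()].
#' @param path File path.
#' @param scalars Named list of per-vertex numeric vectors.
#' @return `write_ply()`/`write_vtk()` return `path` invisibly; `read_ply()`
#'   returns a list with `mesh` and `scalars`.
#' @export
write_ply <- function(mesh, path, scalars = list()) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  for (s in scalars) stopifnot(length(s) == n)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           paste("property float", names(scalars)),
           paste("element face", m),
           "property list uchar int vertex_indices",
           "end_header")
  vb <- cbind(mesh$vertices, do.call(cbind, unname(scalars)))
  vlines <- do.call(paste, c(as.data.frame(vb), list(sep = " ")))
  flines <- paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                  mesh$faces[, 3] - 1)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")
  hdr <- lines[1:end]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  vstart <- which(grepl("^element vertex", hdr))
  vprops <- character(0)
  for (i in (vstart + 1):length(hdr)) {
    if (!grepl("^property ", hdr[i])) break
    vprops <- c(vprops, utils::tail(strsplit(hdr[i], " ")[[1]], 1))
  }
  vb <- matrix(scan(text = lines[end + (1:nv)], quiet = TRUE),
               nrow = nv, byrow = TRUE)
  colnames(vb) <- vprops
  fb <- matrix(scan(text = lines[end + nv + (1:nf)], quiet = TRUE),
               nrow = nf, byrow = TRUE)
  mesh <- surface_mesh(vb[, c("x", "y", "z")], fb[, 2:4] + 1L)
  extra <- setdiff(vprops, c("x", "y", "z"))
  scalars <- lapply(extra, function(p) unname(vb[, p]))
  names(scalars) <- extra
  list(mesh = mesh, scalars = scalars)
}

#' @rdname write_ply
#' @export
write_vtk <- function(mesh, path, scalars = list()) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "surface mesh", "ASCII",
               "DATASET POLYDATA", paste("POINTS", n, "float")), con)
  writeLines(do.call(paste, as.data.frame(mesh$vertices)), con)
  writeLines(paste("POLYGONS", m, 4 * m), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
  if (length(scalars)) {
    writeLines(paste("POINT_DATA", n), con)
    for (nm in names(scalars)) {
      writeLines(c(paste("SCALARS", nm, "float 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(scalars[[nm]]), con)
    }
  }
  invisible(path)
}

#' Remove an angular cap from a mesh
#'
#' Deletes the faces whose vertices all lie within a cone around
#' `direction` from the mesh centroid, leaving an open boundary. This
#' approximates the exclusion of the mitral-valve plane from the LA
#' endocardium; phantom cavities are closed, so it is off by default in the
#' pipeline.
#'
#' @param mesh A [surface_mesh()].
#' @param direction 3-vector pointing at the cap to remove.
#' @param angle_deg Cap half-angle (degrees).
#' @return A `surface_mesh` without the cap (normals inherited from the
#'   closed mesh, unreferenced vertices dropped).
#' @export
remove_mesh_cap <- function(mesh, direction, angle_deg = 30) {
  u <- direction / sqrt(sum(direction^2))
  ctr <- colMeans(mesh$vertices)
  d <- sweep(mesh$vertices, 2, ctr)
  cosang <- (d %*% u) / sqrt(rowSums(d^2))
  inside <- cosang >= cos(angle_deg * pi / 180)
  drop_face <- inside[mesh$faces[, 1]] & inside[mesh$faces[, 2]] &
    inside[mesh$faces[, 3]]
  faces <- mesh$faces[!drop_face, , drop = FALSE]
  keep <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  structure(list(vertices = mesh$vertices[keep, , drop = FALSE],
                 faces = matrix(remap[faces], ncol = 3),
                 normals = mesh$normals[keep, , drop = FALSE],
                 edges = faces_to_edges(matrix(remap[faces], ncol = 3))),
            class = "surface_mesh")
}
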