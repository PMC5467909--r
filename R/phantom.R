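# Synthetic phantoms: layered slabs and a five-tissue head ellipsoid with
# embedded two-compartment spherical tumors. All geometry is in mm; labels
# are assigned by element centroid, with points exactly on a compartment
# surface assigned to the inner compartment.

#' Canonical tissue codes and integer ids used in mesh I/O
#' @export
tissue_codes <- function() {
  c(skin = 1L, bone = 2L, csf = 3L, gm = 4L, wm = 5L,
    tumor_shell = 6L, tumor_core = 7L)
}

#' Build a layered slab phantom
#'
#' A rectangular box stacked along z from layered tissues, meshed on a
#' structured tetrahedral lattice. The faces normal to the stacking axis are
#' exposed as boundary patches `"plate_lo"` (z = 0) and `"plate_hi"`
#' (z = total thickness) for use as plate electrodes.
#'
#' @param layers named numeric vector of layer thicknesses in mm, names are
#'   tissue codes, ordered from the lower plate upward
#'   (e.g. `c(wm = 5, csf = 5)`).
#' @param lateral_size lateral extent in mm (the slab spans
#'   `[-lateral_size/2, lateral_size/2]` in x and y).
#' @param resolution target lattice spacing in mm.
#' @return a [tet_mesh()] with per-element tissue labels and the two plate
#'   patches.
#' @export
build_slab_phantom <- function(layers, lateral_size = 20, resolution = 1) {
  if (length(layers) == 0) stop("layers must contain at least one layer")
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop("layers must be a named vector (names are tissue codes)")
  }
  bad <- which(layers <= 0)
  if (length(bad)) {
    stop("layer ", bad[1], " ('", names(layers)[bad[1]],
         "') has non-positive thickness")
  }
  total <- sum(layers)
  lat <- lateral_size / 2
  lat_res <- min(resolution, lateral_size)
  # mesh with explicit z breaks so layer interfaces fall on lattice planes
  # exactly even when thicknesses are not multiples of the resolution
  zb <- cumsum(c(0, layers))
  nz_per <- pmax(1L, as.integer(ceiling(layers / resolution - 1e-9)))
  zs <- unlist(lapply(seq_along(layers), function(l) {
    seq(zb[l], zb[l + 1], length.out = nz_per[l] + 1)[-1]
  }))
  zs <- c(0, zs)
  g <- tet_lattice_z(c(-lat, -lat), c(lat, lat), lat_res, zs)
  cz <- (g$nodes[g$tets[, 1], 3] + g$nodes[g$tets[, 2], 3] +
           g$nodes[g$tets[, 3], 3] + g$nodes[g$tets[, 4], 3]) / 4
  lab <- names(layers)[findInterval(cz, zb, rightmost.closed = TRUE)]
  mesh <- tet_mesh(g$nodes, g$tets, lab,
                   meta = list(kind = "slab", layers = layers,
                               lateral_size = lateral_size,
                               resolution = resolution, seed = 0L))
  surf <- mesh_surface(mesh)
  mesh$surface <- surf
  zc <- (mesh$nodes[surf[, 1], 3] + mesh$nodes[surf[, 2], 3] +
           mesh$nodes[surf[, 3], 3]) / 3
  tol <- 1e-9 * max(1, total)
  mesh$patches <- list(plate_lo = surf[abs(zc) < tol, , drop = FALSE],
                       plate_hi = surf[abs(zc - total) < tol, , drop = FALSE])
  mesh
}

# lattice with explicit z breaks (possibly non-uniform), uniform in x/y
tet_lattice_z <- function(lower_xy, upper_xy, resolution, zs) {
  ext <- upper_xy - lower_xy
  nc <- pmax(1L, as.integer(ceiling(ext / resolution - 1e-9)))
  xs <- seq(lower_xy[1], upper_xy[1], length.out = nc[1] + 1)
  ys <- seq(lower_xy[2], upper_xy[2], length.out = nc[2] + 1)
  nx <- nc[1] + 1L; ny <- nc[2] + 1L; nz <- length(zs)
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  nid <- function(i, j, k) 1L + i + nx * (j + ny * k)
  cells <- expand.grid(i = 0:(nc[1] - 1L), j = 0:(nc[2] - 1L),
                       k = 0:(nz - 2L))
  i <- cells$i; j <- cells$j; k <- cells$k
  v000 <- nid(i, j, k);           v100 <- nid(i + 1L, j, k)
  v010 <- nid(i, j + 1L, k);      v110 <- nid(i + 1L, j + 1L, k)
  v001 <- nid(i, j, k + 1L);      v101 <- nid(i + 1L, j, k + 1L)
  v011 <- nid(i, j + 1L, k + 1L); v111 <- nid(i + 1L, j + 1L, k + 1L)
  tets <- rbind(cbind(v000, v100, v110, v111),
                cbind(v000, v100, v101, v111),
                cbind(v000, v010, v110, v111),
                cbind(v000, v010, v011, v111),
                cbind(v000, v001, v101, v111),
                cbind(v000, v001, v011, v111))
  list(nodes = nodes, tets = tets)
}

#' Default head-phantom shell geometry
#'
#' Outer skin semi-axes (75, 95, 85) mm give the 150 mm left/right by 190 mm
#' anterior/posterior head extent typical of an adult head; shell thicknesses
#' (skin 6, bone 7, CSF 3, GM 4 mm, remainder WM) are representative adult
#' values exposed here as configuration.
#'
#' @return list with `semi_axes` (5 x 3 matrix, rows skin/bone/csf/gm/wm).
#' @export
default_head_geometry <- function() {
  outer <- c(75, 95, 85)
  thick <- c(skin = 0, bone = 6, csf = 13, gm = 16, wm = 20)
  sa <- t(vapply(thick, function(t) outer - t, numeric(3)))
  colnames(sa) <- c("a", "b", "c")
  list(semi_axes = sa)
}

#' Build a five-tissue ellipsoidal head phantom
#'
#' Five concentric ellipsoidal compartments (skin, bone, CSF, GM, WM) meshed
#' on a structured tetrahedral lattice; elements whose centroid falls outside
#' the outer ellipsoid are discarded, and each remaining element is labelled
#' by the innermost shell containing its centroid.
#'
#' @param semi_axes 5 x 3 numeric matrix of ellipsoid semi-axes in mm with
#'   rows named skin, bone, csf, gm, wm (outermost first); default
#'   [default_head_geometry()].
#' @param resolution target lattice spacing in mm.
#' @return a [tet_mesh()]; shell geometry is kept in `meta$semi_axes` for
#'   later containment checks.
#' @export
build_head_phantom <- function(semi_axes = default_head_geometry()$semi_axes,
                               resolution = 6) {
  tissues <- c("skin", "bone", "csf", "gm", "wm")
  semi_axes <- as.matrix(semi_axes)
  if (is.null(rownames(semi_axes))) rownames(semi_axes) <- tissues
  semi_axes <- semi_axes[tissues, , drop = FALSE]
  for (l in 2:5) {
    if (any(semi_axes[l, ] >= semi_axes[l - 1, ])) {
      stop("shells not strictly nested: '", tissues[l],
           "' is not strictly inside '", tissues[l - 1], "'")
    }
  }
  if (any(semi_axes <= 0)) stop("all semi-axes must be positive")
  outer <- semi_axes[1, ]
  g <- tet_lattice(-outer, outer, resolution)
  cen <- (g$nodes[g$tets[, 1], , drop = FALSE] +
            g$nodes[g$tets[, 2], , drop = FALSE] +
            g$nodes[g$tets[, 3], , drop = FALSE] +
            g$nodes[g$tets[, 4], , drop = FALSE]) / 4
  rho <- function(l) {
    (cen[, 1] / semi_axes[l, 1])^2 + (cen[, 2] / semi_axes[l, 2])^2 +
      (cen[, 3] / semi_axes[l, 3])^2
  }
  # innermost shell containing the centroid (ties go inward via <=)
  depth <- rowSums(vapply(1:5, function(l) rho(l) <= 1, logical(nrow(cen))))
  keep <- depth >= 1L
  lab <- tissues[depth[keep]]
  mesh <- tet_mesh(g$nodes, g$tets[keep, , drop = FALSE], lab,
                   meta = list(kind = "head", semi_axes = semi_axes,
                               resolution = resolution, seed = 0L))
  mesh <- subset_mesh(mesh, rep(TRUE, nrow(mesh$tets)))  # drop orphan nodes
  mesh$meta <- list(kind = "head", semi_axes = semi_axes,
                    resolution = resolution, seed = 0L)
  mesh$surface <- mesh_surface(mesh)
  mesh
}

#' Specify a spherical two-compartment tumor
#'
#' @param center tumor centre (x, y, z) in mm, montage coordinate frame.
#' @param outer_diameter outer diameter in mm (default 20).
#' @param core_diameter necrotic-core diameter in mm (default 14).
#' @param solid if `TRUE` the tumor has no necrotic core: active tumor tissue
#'   throughout the whole sphere.
#' @return object of class `tumor_spec`.
#' @export
tumor_spec <- function(center, outer_diameter = 20, core_diameter = 14,
                       solid = FALSE) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3)
  if (!(core_diameter > 0 && core_diameter < outer_diameter)) {
    stop("need 0 < core_diameter < outer_diameter")
  }
  structure(list(center = center, outer_diameter = outer_diameter,
                 core_diameter = core_diameter, solid = isTRUE(solid)),
            class = "tumor_spec")
}

#' Embed a spherical tumor into a phantom by relabelling
#'
#' Elements whose centroid falls inside the outer sphere are relabelled
#' `tumor_shell`; inside the core sphere they become `tumor_core` unless the
#' tumor is solid. The tumor must lie entirely within the brain compartments
#' (GM/WM); otherwise an error is raised so that tumors always stay inside
#' the dural (CSF) boundary.
#'
#' @param mesh a `tet_mesh`.
#' @param spec a [tumor_spec()].
#' @return the relabelled `tet_mesh`.
#' @export
embed_tumor <- function(mesh, spec) {
  stopifnot(inherits(spec, "tumor_spec"))
  cen <- mesh_centroids(mesh)
  d2 <- (cen[, 1] - spec$center[1])^2 + (cen[, 2] - spec$center[2])^2 +
    (cen[, 3] - spec$center[3])^2
  r_out <- spec$outer_diameter / 2
  r_core <- spec$core_diameter / 2
  inside <- d2 <= r_out^2
  ok_labels <- c("gm", "wm", "tumor_shell", "tumor_core")
  if (any(!mesh$label[inside] %in% ok_labels)) {
    bad <- setdiff(unique(mesh$label[inside]), ok_labels)
    stop("tumor at (", paste(spec$center, collapse = ", "),
         ") extends outside the GM/WM compartments (touches: ",
         paste(bad, collapse = ", "), ")")
  }
  # also require the analytic sphere itself to stay inside the GM ellipsoid
  # when the phantom records its shell geometry
  sa <- mesh$meta$semi_axes
  if (!is.null(sa) && "gm" %in% rownames(sa)) {
    a <- sa["gm", ]
    u <- sphere_probe_points()
    p <- sweep(u * r_out, 2, spec$center, "+")
    if (any((p[, 1] / a[1])^2 + (p[, 2] / a[2])^2 + (p[, 3] / a[3])^2 > 1)) {
      stop("tumor at (", paste(spec$center, collapse = ", "),
           ") extends outside the GM/WM compartments (crosses the GM shell)")
    }
  }
  lab <- mesh$label
  lab[inside] <- "tumor_shell"
  if (!spec$solid) lab[d2 <= r_core^2] <- "tumor_core"
  mesh$label <- lab
  mesh$meta$tumor <- spec
  mesh
}

# fixed quasi-uniform direction samples on the unit sphere (Fibonacci)
sphere_probe_points <- function(n = 64) {
  i <- seq_len(n) - 0.5
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Relabel a box region of a phantom
#'
#' Utility to carve simple inclusions, e.g. a CSF-filled slot emulating a
#' sulcus in a slab phantom for hot-spot experiments.
#'
#' @param mesh a `tet_mesh`.
#' @param lower,upper box corners in mm.
#' @param tissue tissue code for elements whose centroid lies in the box.
#' @export
add_box_region <- function(mesh, lower, upper, tissue) {
  cen <- mesh_centroids(mesh)
  inb <- cen[, 1] >= lower[1] & cen[, 1] <= upper[1] &
    cen[, 2] >= lower[2] & cen[, 2] <= upper[2] &
    cen[, 3] >= lower[3] & cen[, 3] <= upper[3]
  mesh$label[inb] <- tissue
  mesh
}

# ---- synthetic fiber/diffusion tensors ----

#' Prolate eigenvalue ratio achieving a target fractional anisotropy
#'
#' For a prolate tensor with eigenvalues (r, 1, 1) the fractional anisotropy
#' is FA = (r - 1) / sqrt(r^2 + 2); this inverts that relation.
#'
#' @param fa fractional anisotropy in [0, 1).
#' @return the major/minor eigenvalue ratio r >= 1.
#' @export
prolate_ratio <- function(fa) {
  stopifnot(fa >= 0, fa < 1)
  if (fa == 0) return(1)
  (1 + sqrt(1 - (1 - fa^2) * (1 - 2 * fa^2))) / (1 - fa^2)
}

#' Fractional anisotropy of a symmetric tensor's eigenvalues
#' @param ev numeric vector (3 eigenvalues) or matrix (rows of eigenvalues).
#' @export
fractional_anisotropy <- function(ev) {
  if (is.vector(ev)) ev <- matrix(ev, nrow = 1)
  m <- rowMeans(ev)
  num <- (ev[, 1] - m)^2 + (ev[, 2] - m)^2 + (ev[, 3] - m)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  sqrt(1.5 * num / den)
}

#' Generate a synthetic fiber (diffusion-like) tensor field
#'
#' Emulates white-matter fiber bundles with controllable orientation:
#' per-element prolate symmetric positive-definite tensors whose principal
#' eigenvector follows the requested pattern and whose eigenvalue ratio is
#' set to achieve the requested fractional anisotropy (two equal minor
#' eigenvalues, arbitrary units).
#'
#' @param mesh a `tet_mesh`.
#' @param pattern `"uniform"` (all fibers along `direction`),
#'   `"tangential_shells"` (fibers circumferential around the z axis, as in
#'   shell-following bundles) or `"radial"` (fibers along the outward radius).
#' @param fa requested fractional anisotropy, `0 <= fa < 1`.
#' @param direction principal direction for `pattern = "uniform"`.
#' @return object of class `fiber_field` with per-element unit `dir`
#'   (m x 3), `eigvals` (m x 3, major first), and symmetric tensors
#'   `tensor` (m x 6, order xx, yy, zz, xy, xz, yz).
#' @export
synth_fiber_field <- function(mesh, pattern = c("uniform",
                                                "tangential_shells",
                                                "radial"),
                              fa = 0.7, direction = c(0, 1, 0)) {
  pattern <- match.arg(pattern)
  if (!(fa >= 0 && fa < 1)) stop("fa must satisfy 0 <= fa < 1")
  m <- nrow(mesh$tets)
  cen <- mesh_centroids(mesh)
  dir <- switch(pattern,
    uniform = matrix(unit3(as.numeric(direction)), m, 3, byrow = TRUE),
    radial = {
      n <- sqrt(rowSums(cen^2))
      n[n < 1e-9] <- 1
      cen / n
    },
    tangential_shells = {
      t <- cbind(-cen[, 2], cen[, 1], 0)
      n <- sqrt(rowSums(t^2))
      deg <- which(n < 1e-9)  # on the z axis: any tangent direction works
      if (length(deg)) {
        t[deg, ] <- matrix(c(1, 0, 0), length(deg), 3, byrow = TRUE)
        n[deg] <- 1
      }
      t / n
    })
  r <- prolate_ratio(fa)
  ev <- cbind(rep(r, m), 1, 1)
  tensor <- cbind(1 + (r - 1) * dir[, 1]^2,
                  1 + (r - 1) * dir[, 2]^2,
                  1 + (r - 1) * dir[, 3]^2,
                  (r - 1) * dir[, 1] * dir[, 2],
                  (r - 1) * dir[, 1] * dir[, 3],
                  (r - 1) * dir[, 2] * dir[, 3])
  structure(list(dir = dir, eigvals = ev, tensor = tensor,
                 fa = fa, pattern = pattern),
            class = "fiber_field")
}
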