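# Electrode montages: the montage coordinate frame, 3x3 scalp disc arrays
# (Optune-style transducer layout) and the paired left/right and
# anterior/posterior montages. Discs are modelled as ideal Dirichlet patches
# directly on skin nodes, with all nine discs of an array equipotential.

#' Define the montage coordinate frame from scalp landmarks
#'
#' The origin is placed midway between the ear landmarks; x runs from the
#' left to the right ear (positive right), y towards the forehead landmark
#' (positive anterior, orthogonalized against x) and z completes the
#' right-handed frame. On the symmetric head phantom with canonical
#' landmarks this reduces to the identity transform.
#'
#' @param mesh a `tet_mesh`.
#' @param left_ear,right_ear,forehead landmark coordinates (mm) on the skin
#'   surface.
#' @param tol_mm landmarks further than this from the surface are rejected;
#'   default `1.5 * meta$resolution` (or 5 mm).
#' @return list with `origin` (mm) and `axes` (3 x 3, rows x/y/z) mapping
#'   world points to montage coordinates via `axes %*% (p - origin)`.
#' @export
define_coordinate_system <- function(mesh, left_ear, right_ear, forehead,
                                     tol_mm = NULL) {
  if (is.null(tol_mm)) {
    tol_mm <- if (!is.null(mesh$meta$resolution)) {
      1.5 * mesh$meta$resolution
    } else 5
  }
  surf <- mesh_surface(mesh)
  snodes <- mesh$nodes[unique(as.vector(surf)), , drop = FALSE]
  for (lm in list(left_ear = left_ear, right_ear = right_ear,
                  forehead = forehead)) {
    d <- sqrt(min(colSums((t(snodes) - as.numeric(lm))^2)))
    if (d > tol_mm) {
      stop("landmark (", paste(lm, collapse = ", "),
           ") is ", format(d), " mm off the surface (tolerance ",
           tol_mm, " mm)")
    }
  }
  origin <- (as.numeric(left_ear) + as.numeric(right_ear)) / 2
  x <- as.numeric(right_ear) - as.numeric(left_ear)
  if (sqrt(sum(x^2)) < 1e-9) stop("ear landmarks coincide")
  x <- x / sqrt(sum(x^2))
  yraw <- as.numeric(forehead) - origin
  y <- yraw - sum(yraw * x) * x
  if (sqrt(sum(y^2)) < 1e-6 * max(1, sqrt(sum(yraw^2)))) {
    stop("landmarks are collinear: cannot define the anterior axis")
  }
  y <- y / sqrt(sum(y^2))
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  list(origin = origin, axes = rbind(x = x, y = y, z = z))
}

# closest point on a triangle (Ericson), vectorized over triangles
closest_point_on_triangles <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  d1 <- dot3(ab, ap); d2 <- dot3(ac, ap)
  bp <- matrix(p, nrow(a), 3, byrow = TRUE) - b
  d3 <- dot3(ab, bp); d4 <- dot3(ac, bp)
  cp <- matrix(p, nrow(a), 3, byrow = TRUE) - c
  d5 <- dot3(ab, cp); d6 <- dot3(ac, cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  out <- a + v * ab + w * ac          # interior case
  # vertex regions
  reg_a <- d1 <= 0 & d2 <= 0
  reg_b <- d3 >= 0 & d4 <= d3
  reg_c <- d6 >= 0 & d5 <= d6
  # edge regions
  e_ab <- !reg_a & !reg_b & vc <= 0 & d1 >= 0 & d3 <= 0
  e_ac <- !reg_a & !reg_c & vb <= 0 & d2 >= 0 & d6 <= 0
  e_bc <- !reg_b & !reg_c & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  t_ab <- pmin(pmax(d1 / (d1 - d3), 0), 1)
  t_ac <- pmin(pmax(d2 / (d2 - d6), 0), 1)
  t_bc <- pmin(pmax((d4 - d3) / ((d4 - d3) + (d5 - d6)), 0), 1)
  out[reg_a, ] <- a[reg_a, , drop = FALSE]
  out[reg_b, ] <- b[reg_b, , drop = FALSE]
  out[reg_c, ] <- c[reg_c, , drop = FALSE]
  out[e_ab, ] <- a[e_ab, , drop = FALSE] + t_ab[e_ab] * ab[e_ab, , drop = FALSE]
  out[e_ac, ] <- a[e_ac, , drop = FALSE] + t_ac[e_ac] * ac[e_ac, , drop = FALSE]
  out[e_bc, ] <- b[e_bc, , drop = FALSE] +
    t_bc[e_bc] * (c[e_bc, , drop = FALSE] - b[e_bc, , drop = FALSE])
  out
}

#' Project points onto the mesh surface (nearest surface point)
#'
#' @param mesh a `tet_mesh`.
#' @param points k x 3 matrix of points (mm).
#' @return k x 3 matrix of the exact nearest points on the boundary surface.
#' @export
project_to_surface <- function(mesh, points) {
  surf <- mesh_surface(mesh)
  a <- mesh$nodes[surf[, 1], , drop = FALSE]
  b <- mesh$nodes[surf[, 2], , drop = FALSE]
  c <- mesh$nodes[surf[, 3], , drop = FALSE]
  cen <- (a + b + c) / 3
  max_edge <- sqrt(max(rowSums((a - b)^2), rowSums((b - c)^2),
                       rowSums((a - c)^2)))
  points <- matrix(as.numeric(points), ncol = 3)
  out <- matrix(0, nrow(points), 3)
  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    dc <- sqrt(colSums((t(cen) - p)^2))
    near <- dc <= min(dc) + 2 * max_edge
    q <- closest_point_on_triangles(p, a[near, , drop = FALSE],
                                    b[near, , drop = FALSE],
                                    c[near, , drop = FALSE])
    d2 <- rowSums((q - matrix(p, nrow(q), 3, byrow = TRUE))^2)
    out[k, ] <- q[which.min(d2), ]
  }
  out
}

# area-weighted average of nearby surface triangle normals; boundary faces
# are stored outward-oriented, so the nearest face seeds the orientation and
# faces pointing elsewhere (e.g. the far side of a thin slab) are excluded
local_surface_normal <- function(mesh, point, radius) {
  surf <- mesh_surface(mesh)
  a <- mesh$nodes[surf[, 1], , drop = FALSE]
  b <- mesh$nodes[surf[, 2], , drop = FALSE]
  c <- mesh$nodes[surf[, 3], , drop = FALSE]
  cen <- (a + b + c) / 3
  d2 <- colSums((t(cen) - as.numeric(point))^2)
  near <- which(d2 <= radius^2)
  if (!length(near)) stop("no surface triangles near the array centre")
  nrm <- cross3(b[near, , drop = FALSE] - a[near, , drop = FALSE],
                c[near, , drop = FALSE] - a[near, , drop = FALSE])
  seed <- nrm[which.min(d2[near]), ]
  seed <- seed / sqrt(sum(seed^2))
  aligned <- as.numeric(nrm %*% seed) > 0
  n <- colSums(nrm[aligned, , drop = FALSE])
  n / sqrt(sum(n^2))
}

#' Lay out a 3x3 electrode disc array on the scalp
#'
#' A planar 3x3 grid (centre-to-centre pitch `pitch_mm[1]` along `row_axis`,
#' `pitch_mm[2]` along the orthogonal in-plane axis) is projected onto the
#' scalp by nearest-surface-point projection; each disc footprint is the set
#' of surface nodes within a Euclidean `diameter_mm / 2` of the projected
#' disc centre.
#'
#' @param mesh a `tet_mesh`.
#' @param center desired array centre (mm); it is projected onto the scalp.
#' @param row_axis in-plane direction (mm frame) carrying the 45 mm pitch.
#' @param id array identifier, one of `"left"`, `"right"`, `"anterior"`,
#'   `"posterior"` (free-form ids are allowed for custom layouts).
#' @param pitch_mm the two centre-to-centre pitches (default `c(45, 22)`).
#' @param diameter_mm disc diameter (default 20).
#' @return object of class `electrode_array`: projected `centers` (9 x 3),
#'   per-disc surface-node sets `disc_nodes`, the union `all_nodes`, and the
#'   per-disc surface-triangle patches `disc_tris`.
#' @export
layout_array <- function(mesh, center, row_axis, id,
                         pitch_mm = c(45, 22), diameter_mm = 20) {
  surf <- mesh_surface(mesh)
  c0 <- as.numeric(project_to_surface(mesh, matrix(center, 1, 3)))
  n <- local_surface_normal(mesh, c0, radius = max(pitch_mm))
  u <- as.numeric(row_axis)
  u <- u - sum(u * n) * n
  if (sqrt(sum(u^2)) < 1e-9) stop("row_axis is parallel to the local normal")
  u <- u / sqrt(sum(u^2))
  w <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  off <- expand.grid(i = -1:1, j = -1:1)
  grid <- matrix(c0, 9, 3, byrow = TRUE) +
    outer(off$i * pitch_mm[1], u) + outer(off$j * pitch_mm[2], w)
  centers <- project_to_surface(mesh, grid)
  snodes <- sort(unique(as.vector(surf)))
  spos <- mesh$nodes[snodes, , drop = FALSE]
  r <- diameter_mm / 2
  tcen <- (mesh$nodes[surf[, 1], , drop = FALSE] +
             mesh$nodes[surf[, 2], , drop = FALSE] +
             mesh$nodes[surf[, 3], , drop = FALSE]) / 3
  # distance of every surface node/triangle to every disc centre; a node
  # belongs to the nearest centre within the disc radius, which keeps the
  # nine footprints pairwise disjoint even where scalp curvature crowds the
  # projected grid (the discs of an array are equipotential anyway)
  nd2 <- sapply(1:9, function(k) colSums((t(spos) - centers[k, ])^2))
  td2 <- sapply(1:9, function(k) colSums((t(tcen) - centers[k, ])^2))
  n_near <- max.col(-nd2, ties.method = "first")
  t_near <- max.col(-td2, ties.method = "first")
  disc_nodes <- vector("list", 9)
  disc_tris <- vector("list", 9)
  for (k in 1:9) {
    disc_nodes[[k]] <- snodes[n_near == k & nd2[, k] <= r^2 + 1e-9]
    if (!length(disc_nodes[[k]])) {
      stop("disc ", k, " of array '", id, "' has an empty footprint; ",
           "use a finer mesh resolution")
    }
    disc_tris[[k]] <- surf[t_near == k & td2[, k] <= r^2 + 1e-9, ,
                           drop = FALSE]
  }
  all_nodes <- unlist(disc_nodes)
  structure(list(id = id, centers = centers, disc_nodes = disc_nodes,
                 all_nodes = all_nodes, disc_tris = disc_tris,
                 diameter_mm = diameter_mm, pitch_mm = pitch_mm,
                 normal = n, row_axis = u),
            class = "electrode_array")
}

new_montage <- function(source, sink, current_A, id) {
  if (identical(source$id, sink$id)) stop("source and sink must differ")
  if (current_A <= 0) stop("target current must be positive")
  structure(list(source = source, sink = sink, current_A = current_A,
                 id = id),
            class = "tt_montage")
}

#' Place the paired left/right and anterior/posterior montages
#'
#' Arrays are centred on the scalp intersections of the +-x and +-y axes
#' (above the ear canals, and on the forehead/occiput). The 22 mm pitch runs
#' along the circumferential (z) direction for all arrays and the 45 mm
#' pitch along the orthogonal in-plane direction. Following the clinical
#' convention the left and posterior arrays act as sources; each montage
#' carries a 0.9 A target peak current per array pair.
#'
#' @param mesh a `tet_mesh` head phantom in the montage frame.
#' @param current_A target peak current per array pair (A).
#' @param pitch_mm the two centre-to-centre pitches (default `c(45, 22)`).
#' @param diameter_mm disc diameter (mm).
#' @return list with `LR` and `AP` montages (`tt_montage`), each holding a
#'   source and a sink `electrode_array`.
#' @export
place_clinical_montages <- function(mesh, current_A = 0.9,
                                 pitch_mm = c(45, 22), diameter_mm = 20) {
  ext <- apply(abs(mesh$nodes), 2, max)
  left <- layout_array(mesh, c(-2 * ext[1], 0, 0), row_axis = c(0, 1, 0),
                       id = "left", pitch_mm = pitch_mm,
                       diameter_mm = diameter_mm)
  right <- layout_array(mesh, c(2 * ext[1], 0, 0), row_axis = c(0, 1, 0),
                        id = "right", pitch_mm = pitch_mm,
                        diameter_mm = diameter_mm)
  anterior <- layout_array(mesh, c(0, 2 * ext[2], 0), row_axis = c(1, 0, 0),
                           id = "anterior", pitch_mm = pitch_mm,
                           diameter_mm = diameter_mm)
  posterior <- layout_array(mesh, c(0, -2 * ext[2], 0), row_axis = c(1, 0, 0),
                            id = "posterior", pitch_mm = pitch_mm,
                            diameter_mm = diameter_mm)
  arrays <- list(left, right, anterior, posterior)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      if (length(intersect(arrays[[i]]$all_nodes, arrays[[j]]$all_nodes))) {
        stop("arrays '", arrays[[i]]$id, "' and '", arrays[[j]]$id,
             "' overlap; the phantom is too small for this layout")
      }
    }
  }
  list(LR = new_montage(left, right, current_A, "LR"),
       AP = new_montage(posterior, anterior, current_A, "AP"))
}
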