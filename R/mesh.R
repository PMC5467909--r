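# ---- small vector helpers (row-wise on n x 3 matrices) ----

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

dot3 <- function(a, b) a[, 1] * b[, 1] + a[, 2] * b[, 2] + a[, 3] * b[, 3]

unit3 <- function(a) {
  n <- sqrt(sum(a^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  a / n
}

#' Construct a tetrahedral mesh object
#'
#' Low-level constructor for the mesh container used throughout the package.
#' Node coordinates are in millimetres; element volumes are computed (mm^3)
#' and any negatively oriented tetrahedron is repaired by swapping its last
#' two vertices, so that all stored elements are positively oriented.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param tets integer matrix, one row per element, 4 node indices.
#' @param label character vector, one tissue code per element
#'   (e.g. `"skin"`, `"bone"`, `"csf"`, `"gm"`, `"wm"`, `"tumor_shell"`,
#'   `"tumor_core"`).
#' @param patches named list of integer matrices (k x 3 node indices) marking
#'   labelled sets of surface triangles, e.g. electrode disc footprints.
#' @param meta list of free-form metadata (resolution, shell geometry, seed).
#' @return An object of class `tet_mesh` with fields `nodes`, `tets`,
#'   `label`, `patches`, `element_volume` (mm^3) and `meta`.
#' @export
tet_mesh <- function(nodes, tets, label, patches = list(), meta = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(nodes) <- NULL
  dimnames(tets) <- NULL
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4)
  if (length(label) != nrow(tets)) {
    stop("need exactly one tissue label per element")
  }
  v <- signed_tet_volume(nodes, tets)
  flip <- which(v < 0)
  if (length(flip)) {
    tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
    v[flip] <- -v[flip]
  }
  if (any(v <= 0)) {
    stop("degenerate (zero-volume) element at index ",
         which(v <= 0)[1])
  }
  structure(list(nodes = nodes, tets = tets,
                 label = as.character(label),
                 patches = patches,
                 element_volume = v,
                 meta = meta),
            class = "tet_mesh")
}

signed_tet_volume <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c <- nodes[tets[, 4], , drop = FALSE] - p1
  dot3(a, cross3(b, c)) / 6
}

#' Element centroids
#' @param mesh a `tet_mesh`.
#' @return numeric matrix of element centroids (mm).
#' @export
mesh_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
     mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
}

# Encode a set of (unordered) node triples as one double each; node counts
# stay far below 2^53^(1/3) so the encoding is exact.
face_key <- function(f) {
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  n <- max(hi) + 1
  (as.numeric(lo) * n + mid) * n + hi
}

all_faces <- function(tets) {
  rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
        tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
}

#' Boundary surface of a tetrahedral mesh
#'
#' Faces that belong to exactly one tetrahedron. The result is cached on the
#' mesh the first time the builders compute it.
#'
#' @param mesh a `tet_mesh`.
#' @return integer matrix of boundary triangles (k x 3 node indices).
#' @export
mesh_surface <- function(mesh) {
  if (!is.null(mesh$surface)) return(mesh$surface)
  f <- all_faces(mesh$tets)
  key <- face_key(f)
  o <- order(key)
  k <- key[o]
  r <- rle(k)
  once <- r$lengths == 1L
  idx <- o[cumsum(r$lengths)[once]]  # position of each singleton face
  f[idx, , drop = FALSE]
}

#' Face-sharing counts for mesh validity checks
#'
#' @param mesh a `tet_mesh`.
#' @return table of how many tetrahedra share each face (values must be 1 for
#'   boundary faces, 2 for interior faces in a valid conforming mesh).
#' @export
face_share_counts <- function(mesh) {
  key <- face_key(all_faces(mesh$tets))
  rle(sort(key))$lengths
}

#' Total mesh volume (mm^3)
#' @param mesh a `tet_mesh`.
#' @export
mesh_volume <- function(mesh) sum(mesh$element_volume)

#' Keep a subset of elements
#'
#' Drops all other elements and any node no longer referenced; patch triangle
#' indices are remapped (patch triangles whose nodes disappear are dropped).
#'
#' @param mesh a `tet_mesh`.
#' @param keep logical or integer element selector.
#' @return a `tet_mesh`.
#' @export
subset_mesh <- function(mesh, keep) {
  tets <- mesh$tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  map <- integer(nrow(mesh$nodes))
  map[used] <- seq_along(used)
  patches <- lapply(mesh$patches, function(tr) {
    ok <- tr[, 1] %in% used & tr[, 2] %in% used & tr[, 3] %in% used
    matrix(map[tr[ok, , drop = FALSE]], ncol = 3)
  })
  tet_mesh(mesh$nodes[used, , drop = FALSE],
           matrix(map[tets], ncol = 4),
           mesh$label[keep],
           patches = patches,
           meta = mesh$meta)
}

# Structured Kuhn lattice over a box: every cell is split into the six
# tetrahedra around its main diagonal, which is conforming across cells.
# Bounds are honoured exactly; the requested resolution is rounded so an
# integer number of cells fits (effective spacing <= requested).
tet_lattice <- function(lower, upper, resolution) {
  ext <- upper - lower
  if (any(ext <= 0)) stop("box must have positive extent")
  nc <- pmax(1L, as.integer(ceiling(ext / resolution - 1e-9)))
  xs <- seq(lower[1], upper[1], length.out = nc[1] + 1)
  ys <- seq(lower[2], upper[2], length.out = nc[2] + 1)
  zs <- seq(lower[3], upper[3], length.out = nc[3] + 1)
  nx <- nc[1] + 1L; ny <- nc[2] + 1L; nz <- nc[3] + 1L
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))
  nid <- function(i, j, k) 1L + i + nx * (j + ny * k)
  cells <- expand.grid(i = 0:(nc[1] - 1L), j = 0:(nc[2] - 1L),
                       k = 0:(nc[3] - 1L))
  i <- cells$i; j <- cells$j; k <- cells$k
  v000 <- nid(i, j, k);         v100 <- nid(i + 1L, j, k)
  v010 <- nid(i, j + 1L, k);    v110 <- nid(i + 1L, j + 1L, k)
  v001 <- nid(i, j, k + 1L);    v101 <- nid(i + 1L, j, k + 1L)
  v011 <- nid(i, j + 1L, k + 1L); v111 <- nid(i + 1L, j + 1L, k + 1L)
  tets <- rbind(cbind(v000, v100, v110, v111),
                cbind(v000, v100, v101, v111),
                cbind(v000, v010, v110, v111),
                cbind(v000, v010, v011, v111),
                cbind(v000, v001, v101, v111),
                cbind(v000, v001, v011, v111))
  list(nodes = nodes, tets = tets,
       spacing = ext / nc)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "elements\n")
  cat("  volume:", format(sum(x$element_volume)), "mm^3\n")
  tb <- table(x$label)
  cat("  tissues:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  if (length(x$patches)) {
    cat("  patches:", paste(names(x$patches), collapse = ", "), "\n")
  }
  invisible(x)
}
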