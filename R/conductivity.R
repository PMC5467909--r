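# Conductivity models: isotropic tissue table, anisotropic direct mapping of
# fiber tensors, and the arithmetic-mean (MC) isotropization used to isolate
# the effect of anisotropy. Conductivities in S/m; tensors are stored as
# m x 6 matrices in the order (xx, yy, zz, xy, xz, yz).

#' Default isotropic tissue conductivities (S/m)
#'
#' Skin 0.465, bone 0.010 and CSF 1.654 S/m follow in-vivo/in-vitro
#' measurements at TTFields-like intermediate frequencies; the tumor is a
#' well conducting necrotic core (1.00 S/m) in a 0.24 S/m active shell. The
#' GM (0.275 S/m) and WM (0.126 S/m) scalar references are literature-typical
#' stand-ins and deliberately exposed as configuration: they anchor the
#' anisotropic direct mapping as well.
#'
#' @return named numeric vector of conductivities in S/m.
#' @export
default_tissue_table <- function() {
  c(skin = 0.465, bone = 0.010, csf = 1.654,
    gm = 0.275, wm = 0.126,
    tumor_shell = 0.24, tumor_core = 1.00)
}

new_conductivity_field <- function(tensor) {
  colnames(tensor) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  structure(list(tensor = tensor), class = "conductivity_field")
}

#' Assign isotropic conductivity tensors from a tissue table
#'
#' @param mesh a `tet_mesh`.
#' @param table named conductivity vector (S/m), see
#'   [default_tissue_table()].
#' @return a `conductivity_field` (per-element symmetric tensors, S/m).
#' @export
assign_isotropic <- function(mesh, table = default_tissue_table()) {
  if (any(table <= 0)) stop("all conductivities must be positive")
  unknown <- setdiff(unique(mesh$label), names(table))
  if (length(unknown)) {
    stop("tissue label(s) missing from the conductivity table: ",
         paste(unknown, collapse = ", "))
  }
  s <- unname(table[mesh$label])
  new_conductivity_field(cbind(s, s, s, 0, 0, 0))
}

#' Map fiber tensors to anisotropic conductivity tensors (direct mapping)
#'
#' The conductivity tensor of each GM/WM element shares the eigenvectors of
#' its diffusion-like fiber tensor. Under the default volume-normalized
#' mapping the eigenvalues are scaled per element so that their geometric
#' mean equals the tissue's isotropic reference conductivity, keeping the
#' effective tissue conductivity consistent with the isotropic table. The
#' `"global"` variant instead applies one scale factor per tissue (matching
#' the tissue-average geometric mean), so individual elements may deviate.
#' All other tissues fall back to [assign_isotropic()].
#'
#' @param fibers a `fiber_field` from [synth_fiber_field()], or any object
#'   with an `m x 6` `tensor` matrix of symmetric positive-definite tensors.
#' @param mesh a `tet_mesh`.
#' @param table named isotropic reference conductivities (S/m).
#' @param normalization `"volume"` (per-element geometric mean pinned to the
#'   tissue reference; default) or `"global"`.
#' @param floor smallest admissible conductivity eigenvalue (S/m); tensors
#'   are floored to keep the finite-element system positive definite.
#' @return a `conductivity_field`.
#' @export
direct_map_tensors <- function(fibers, mesh, table = default_tissue_table(),
                               normalization = c("volume", "global"),
                               floor = 1e-6) {
  normalization <- match.arg(normalization)
  iso <- assign_isotropic(mesh, table)
  aniso <- mesh$label %in% c("gm", "wm")
  if (!any(aniso)) return(iso)
  dec <- fiber_eigen(fibers, which = aniso)
  ev <- pmax(dec$eigvals, floor)  # fiber-tensor eigenvalues, floored
  if (any(ev <= 0) || any(!is.finite(ev))) {
    stop("non-SPD fiber tensor after flooring at element index ",
         which(aniso)[which(rowSums(ev <= 0 | !is.finite(ev)) > 0)[1]])
  }
  ref <- unname(table[mesh$label[aniso]])
  gm <- exp(rowMeans(log(ev)))
  scale <- switch(normalization,
                  volume = ref / gm,
                  global = {
                    s <- ref / ave(gm, mesh$label[aniso],
                                   FUN = function(g) exp(mean(log(g))))
                    s
                  })
  sev <- ev * scale  # conductivity eigenvalues
  sev <- pmax(sev, floor)
  tensor <- iso$tensor
  tensor[aniso, ] <- tensors_from_eigen(sev, dec$vectors)
  new_conductivity_field(tensor)
}

# Eigen-decomposition of the fiber tensors for the selected elements.
# Fast path: prolate fields built by synth_fiber_field carry their principal
# direction and eigenvalues, so the frame is (dir, any two orthonormal
# complements). Generic path: per-element eigen() on the 3x3 tensors.
fiber_eigen <- function(fibers, which) {
  if (!is.null(fibers$dir) && !is.null(fibers$eigvals)) {
    d <- fibers$dir[which, , drop = FALSE]
    ev <- fibers$eigvals[which, , drop = FALSE]
    # complete the frame: pick the coordinate axis least aligned with d
    m <- nrow(d)
    ref <- diag(3)[apply(abs(d), 1, which.min), , drop = FALSE]
    u <- ref - d * dot3(ref, d)
    u <- u / sqrt(rowSums(u^2))
    w <- cross3(d, u)
    vectors <- array(0, c(m, 3, 3))
    vectors[, , 1] <- d; vectors[, , 2] <- u; vectors[, , 3] <- w
    return(list(eigvals = ev, vectors = vectors))
  }
  t6 <- fibers$tensor[which, , drop = FALSE]
  m <- nrow(t6)
  ev <- matrix(0, m, 3)
  vectors <- array(0, c(m, 3, 3))
  for (i in seq_len(m)) {
    M <- tensor6_to_mat(t6[i, ])
    e <- eigen(M, symmetric = TRUE)
    ev[i, ] <- e$values
    vectors[i, , ] <- e$vectors
  }
  list(eigvals = ev, vectors = vectors)
}

tensor6_to_mat <- function(t6) {
  matrix(c(t6[1], t6[4], t6[5],
           t6[4], t6[2], t6[6],
           t6[5], t6[6], t6[3]), 3, 3)
}

mat_to_tensor6 <- function(M) c(M[1, 1], M[2, 2], M[3, 3],
                                M[1, 2], M[1, 3], M[2, 3])

# assemble m x 6 tensors from eigenvalues (m x 3) and frames (m x 3 x 3,
# vectors[, , k] is the k-th eigenvector)
tensors_from_eigen <- function(ev, vectors) {
  out <- matrix(0, nrow(ev), 6)
  for (k in 1:3) {
    v <- vectors[, , k]
    if (is.null(dim(v))) v <- matrix(v, 1, 3)
    out <- out + ev[, k] * cbind(v[, 1]^2, v[, 2]^2, v[, 3]^2,
                                 v[, 1] * v[, 2], v[, 1] * v[, 3],
                                 v[, 2] * v[, 3])
  }
  out
}

#' Arithmetic-mean (MC) isotropization of a conductivity field
#'
#' Replaces every tensor by `(lambda1 + lambda2 + lambda3) / 3 * I`, i.e. the
#' arithmetic mean of its eigenvalues (equivalently trace/3). Used to isolate
#' the effect of anisotropy from that of the mean conductivity level.
#'
#' @param field a `conductivity_field`.
#' @return an isotropic `conductivity_field`.
#' @export
mean_conductivity <- function(field) {
  s <- (field$tensor[, 1] + field$tensor[, 2] + field$tensor[, 3]) / 3
  new_conductivity_field(cbind(s, s, s, 0, 0, 0))
}

#' Eigenvalues of every conductivity tensor
#'
#' @param field a `conductivity_field`.
#' @return m x 3 matrix of eigenvalues (descending).
#' @export
conductivity_eigenvalues <- function(field) {
  t6 <- field$tensor
  iso <- t6[, 4] == 0 & t6[, 5] == 0 & t6[, 6] == 0
  ev <- matrix(0, nrow(t6), 3)
  if (any(iso)) {
    d <- t6[iso, 1:3, drop = FALSE]
    ev[iso, ] <- t(apply(d, 1, sort, decreasing = TRUE))
  }
  for (i in which(!iso)) {
    ev[i, ] <- eigen(tensor6_to_mat(t6[i, ]), symmetric = TRUE,
                     only.values = TRUE)$values
  }
  ev
}

#' Check that every tensor of a field is symmetric positive definite
#' @param field a `conductivity_field`.
#' @return `TRUE` (invisibly) or an error naming the first failing element.
#' @export
check_spd <- function(field) {
  ev <- conductivity_eigenvalues(field)
  bad <- which(ev[, 3] <= 0)
  if (length(bad)) stop("tensor not positive definite at element ", bad[1])
  invisible(TRUE)
}
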