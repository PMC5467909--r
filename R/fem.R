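# Electrostatic finite elements: P1 tetrahedra, sparse symmetric stiffness
# assembly with per-element conductivity tensors, Jacobi-preconditioned
# conjugate gradients under Dirichlet electrode conditions, per-element
# field/current recovery, discrete electrode currents and current rescaling.
# Geometry enters in mm and is converted to SI metres here, so potentials
# are volts, fields V/m, current densities A/m^2 and currents amperes.

# P1 shape-function gradients (1/m) and element volumes (m^3)
p1_gradients <- function(mesh) {
  p <- mesh$nodes / 1000
  p1 <- p[mesh$tets[, 1], , drop = FALSE]
  a <- p[mesh$tets[, 2], , drop = FALSE] - p1
  b <- p[mesh$tets[, 3], , drop = FALSE] - p1
  c <- p[mesh$tets[, 4], , drop = FALSE] - p1
  bxc <- cross3(b, c)
  v6 <- dot3(a, bxc)
  vol <- v6 / 6
  mean_vol <- mean(abs(vol))
  bad <- which(abs(vol) < 1e-12 * mean_vol)
  if (length(bad)) stop("degenerate element at index ", bad[1])
  g2 <- bxc / v6
  g3 <- cross3(c, a) / v6
  g4 <- cross3(a, b) / v6
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = vol)
}

#' Assemble the electrostatic stiffness system
#'
#' Standard P1 stiffness matrix for `div(sigma grad V) = 0`:
#' `K[ij] = sum_e vol_e * grad(phi_i)' sigma_e grad(phi_j)`. The matrix is
#' sparse, symmetric and positive semidefinite, with zero row sums before
#' boundary conditions (constants are in its null space).
#'
#' @param mesh a `tet_mesh`.
#' @param field a `conductivity_field` (S/m).
#' @return object of class `fem_system` with the sparse matrix `K`
#'   (node x node, SI units: entries in siemens) and cached element data.
#' @export
assemble_system <- function(mesh, field) {
  stopifnot(inherits(field, "conductivity_field"))
  gp <- p1_gradients(mesh)
  S <- field$tensor
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  quad <- function(gi, gj) {
    S[, 1] * gi[, 1] * gj[, 1] + S[, 2] * gi[, 2] * gj[, 2] +
      S[, 3] * gi[, 3] * gj[, 3] +
      S[, 4] * (gi[, 1] * gj[, 2] + gi[, 2] * gj[, 1]) +
      S[, 5] * (gi[, 1] * gj[, 3] + gi[, 3] * gj[, 1]) +
      S[, 6] * (gi[, 2] * gj[, 3] + gi[, 3] * gj[, 2])
  }
  ii <- vector("list", 16); jj <- vector("list", 16); xx <- vector("list", 16)
  k <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      k <- k + 1
      ii[[k]] <- mesh$tets[, i]
      jj[[k]] <- mesh$tets[, j]
      xx[[k]] <- gp$vol * quad(gp$g[[i]], gp$g[[j]])
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(xx), dims = c(n, n))
  structure(list(K = K, n_nodes = n, n_elements = m, mesh = mesh),
            class = "fem_system")
}

#' Solve for the electric potential under Dirichlet electrode conditions
#'
#' Eliminates the fixed nodes and solves the reduced symmetric
#' positive-definite system with Jacobi-preconditioned conjugate gradients to
#' a relative residual below `tol` (measured against the right-hand side).
#' Dirichlet nodes are exact by construction. A sparse-Cholesky direct
#' solver is available via `method = "direct"`; it satisfies the same
#' residual requirement with margin and is useful for large batch runs.
#'
#' @param system a `fem_system`.
#' @param fixed_nodes integer node indices with prescribed potential.
#' @param fixed_values potentials (V) for `fixed_nodes`.
#' @param tol relative residual tolerance (default 1e-9).
#' @param maxit conjugate-gradient iteration cap.
#' @param method `"pcg"` (default) or `"direct"`.
#' @return numeric potential vector (V) over all nodes, with attributes
#'   `iterations` and `residual` (relative).
#' @export
solve_potential <- function(system, fixed_nodes, fixed_values,
                            tol = 1e-9, maxit = 50000,
                            method = c("pcg", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(system, "fem_system"))
  fixed_nodes <- as.integer(fixed_nodes)
  if (length(fixed_nodes) != length(fixed_values)) {
    stop("fixed_nodes and fixed_values must have equal length")
  }
  if (anyDuplicated(fixed_nodes)) stop("duplicate Dirichlet nodes")
  if (length(unique(fixed_values)) < 2) {
    stop("need at least two distinct Dirichlet potentials")
  }
  n <- system$n_nodes
  V <- numeric(n)
  V[fixed_nodes] <- fixed_values
  free <- setdiff(seq_len(n), fixed_nodes)
  Kff <- system$K[free, free]
  b <- -as.numeric(system$K[free, fixed_nodes, drop = FALSE] %*% fixed_values)
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    V[free] <- mean(fixed_values)
    attr(V, "iterations") <- 0L
    attr(V, "residual") <- 0
    return(V)
  }
  if (method == "direct") {
    x <- as.numeric(Matrix::solve(Matrix::forceSymmetric(Kff), b))
    res <- sqrt(sum((b - as.numeric(Kff %*% x))^2)) / nb
    it <- NA_integer_
  } else {
    d <- Matrix::diag(Kff)
    if (any(d <= 0)) stop("non-positive diagonal in reduced system")
    x <- numeric(length(b))
    r <- b
    z <- r / d
    p <- z
    rz <- sum(r * z)
    it <- 0L
    repeat {
      Ap <- as.numeric(Kff %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      it <- it + 1L
      res <- sqrt(sum(r^2)) / nb
      if (res < tol) break
      if (it >= maxit) {
        stop("conjugate gradients did not converge in ", maxit,
             " iterations (relative residual ", format(res), ")")
      }
      z <- r / d
      rz2 <- sum(r * z)
      p <- z + (rz2 / rz) * p
      rz <- rz2
    }
  }
  V[free] <- x
  attr(V, "iterations") <- it
  attr(V, "residual") <- res
  V
}

#' Per-element electric field from node potentials
#'
#' `E = -grad(V)`, constant on each P1 element.
#'
#' @param mesh a `tet_mesh`.
#' @param V node potentials (V).
#' @return m x 3 matrix of element fields (V/m).
#' @export
element_field <- function(mesh, V) {
  gp <- p1_gradients(mesh)
  t <- mesh$tets
  -(V[t[, 1]] * gp$g[[1]] + V[t[, 2]] * gp$g[[2]] +
      V[t[, 3]] * gp$g[[3]] + V[t[, 4]] * gp$g[[4]])
}

#' Current density via Ohm's law
#'
#' @param E m x 3 element fields (V/m).
#' @param field a `conductivity_field` (S/m).
#' @return m x 3 matrix of current densities `J = sigma E` (A/m^2).
#' @export
current_density <- function(E, field) {
  S <- field$tensor
  cbind(S[, 1] * E[, 1] + S[, 4] * E[, 2] + S[, 5] * E[, 3],
        S[, 4] * E[, 1] + S[, 2] * E[, 2] + S[, 6] * E[, 3],
        S[, 5] * E[, 1] + S[, 6] * E[, 2] + S[, 3] * E[, 3])
}

#' Total current through an electrode node set
#'
#' The discretely exact boundary flux: the sum over the electrode's Dirichlet
#' nodes of the residual of the unconstrained equations, `sum((K V)[nodes])`.
#' Positive values mean current injected into the volume.
#'
#' @param system a `fem_system`.
#' @param V node potentials (V).
#' @param nodes integer node indices of the electrode (e.g.
#'   `array$all_nodes`).
#' @return current in amperes.
#' @export
electrode_current <- function(system, V, nodes) {
  sum(as.numeric(system$K[nodes, , drop = FALSE] %*% as.numeric(V)))
}

#' Rescale a solution to a target electrode current
#'
#' Potentials, fields and current densities are multiplied by
#' `target_A / measured source current`; the applied factor accumulates in
#' `solution$rescale_factor`. Applying the rescale twice is a no-op.
#'
#' @param solution a `tt_solution` (see [solve_tt_montage()]).
#' @param target_A target peak current in amperes (default 0.9, i.e. 900 mA
#'   per array).
#' @return the rescaled `tt_solution`.
#' @export
rescale_to_target <- function(solution, target_A = 0.9) {
  f <- target_A / solution$source_current_A
  solution$V <- solution$V * f
  solution$E <- solution$E * f
  solution$J <- solution$J * f
  solution$normE <- solution$normE * f
  solution$source_current_A <- solution$source_current_A * f
  solution$sink_current_A <- solution$sink_current_A * f
  solution$rescale_factor <- solution$rescale_factor * f
  solution
}

#' Solve a montage end to end
#'
#' Applies the montage's Dirichlet conditions (all nine discs of an array
#' share one potential: +0.5 V on the source array, -0.5 V on the sink,
#' arbitrary before rescaling), solves for the potential, recovers the
#' element fields and current densities, measures the source current and
#' rescales everything linearly to the montage's target current.
#'
#' @param mesh a `tet_mesh` (must carry the montage's electrode nodes).
#' @param field a `conductivity_field`.
#' @param montage a `tt_montage` (see [place_clinical_montages()]).
#' @param tol,maxit,method passed to [solve_potential()].
#' @param system optional pre-assembled `fem_system` for `mesh`/`field`.
#' @param rescale set `FALSE` to keep the raw +-0.5 V solve.
#' @return object of class `tt_solution` with node potentials `V` (volts),
#'   element fields `E` and `normE` (V/m), current densities `J` (A/m^2),
#'   measured electrode currents (A) and the applied `rescale_factor`.
#' @export
solve_tt_montage <- function(mesh, field, montage, tol = 1e-9,
                             maxit = 50000, method = c("pcg", "direct"),
                             system = NULL, rescale = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(montage, "tt_montage"))
  if (is.null(system)) system <- assemble_system(mesh, field)
  src <- montage$source$all_nodes
  snk <- montage$sink$all_nodes
  if (length(intersect(src, snk))) stop("source and sink arrays overlap")
  V <- solve_potential(system,
                       fixed_nodes = c(src, snk),
                       fixed_values = c(rep(0.5, length(src)),
                                        rep(-0.5, length(snk))),
                       tol = tol, maxit = maxit, method = method)
  E <- element_field(mesh, V)
  J <- current_density(E, field)
  sol <- structure(list(V = as.numeric(V),
                        E = E, J = J,
                        normE = sqrt(rowSums(E^2)),
                        source_current_A = electrode_current(system, V, src),
                        sink_current_A = electrode_current(system, V, snk),
                        rescale_factor = 1,
                        montage_id = montage$id,
                        solver = list(iterations = attr(V, "iterations"),
                                      residual = attr(V, "residual"),
                                      method = method, tol = tol)),
                   class = "tt_solution")
  if (rescale) sol <- rescale_to_target(sol, montage$current_A)
  sol
}

#' @export
print.tt_solution <- function(x, ...) {
  cat("tt_solution [", x$montage_id, "]: ", length(x$V), " nodes, ",
      nrow(x$E), " elements\n", sep = "")
  cat("  source current:", format(x$source_current_A), "A",
      "(rescale factor", format(x$rescale_factor), ")\n")
  cat("  |E| range:", paste(format(range(x$normE)), collapse = " .. "),
      "V/m\n")
  invisible(x)
}
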