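# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# two-layer validation slab: sigma = 1 and 2 S/m, 5 + 5 mm, 20 x 20 mm
two_layer_slab <- function() {
  fixture("two_layer_slab", function() {
    build_slab_phantom(c(top = 5, bottom = 5), lateral_size = 20,
                       resolution = 1)
  })
}

two_layer_table <- c(top = 1, bottom = 2)

# default five-tissue head phantom at the coarse working resolution
head_phantom <- function() {
  fixture("head_phantom", function() build_head_phantom(resolution = 6))
}

head_montages <- function() {
  fixture("head_montages", function() place_clinical_montages(head_phantom()))
}

plate_nodes <- function(mesh) {
  list(lo = sort(unique(as.vector(mesh$patches$plate_lo))),
       hi = sort(unique(as.vector(mesh$patches$plate_hi))))
}

# solve a slab phantom between its two plates and return fields
solve_plates <- function(mesh, field, v_lo, v_hi, tol = 1e-9,
                         system = NULL) {
  pn <- plate_nodes(mesh)
  if (is.null(system)) system <- assemble_system(mesh, field)
  V <- solve_potential(system, c(pn$lo, pn$hi),
                       c(rep(v_lo, length(pn$lo)),
                         rep(v_hi, length(pn$hi))),
                       tol = tol)
  E <- element_field(mesh, V)
  list(V = V, E = E, normE = sqrt(rowSums(E^2)), system = system,
       lo = pn$lo, hi = pn$hi)
}

# minimal tt_solution wrapper around a per-element |E| vector, for the
# dosimetry operations that only consume normE
as_solution <- function(normE, id = "test") {
  structure(list(normE = normE, montage_id = id), class = "tt_solution")
}
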