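# Plain-text mesh interchange: Gmsh MSH 2.2 ASCII and legacy VTK
# unstructured grids. Tissue labels travel as integer cell data "tissue"
# (see tissue_codes()); boundary patches are written to MSH as surface
# triangles with their own physical groups.

label_to_int <- function(label) {
  codes <- tissue_codes()
  extra <- setdiff(unique(label), names(codes))
  if (length(extra)) {
    codes <- c(codes, stats::setNames(seq_along(extra) + max(codes), extra))
  }
  list(id = unname(codes[label]), codes = codes)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Volume tetrahedra carry their tissue code as physical/elementary tags
#' (named in `$PhysicalNames`); boundary patches are written as surface
#' triangles with physical groups offset by 100.
#'
#' @param mesh a `tet_mesh`.
#' @param file output path.
#' @export
write_mesh_msh <- function(mesh, file) {
  li <- label_to_int(mesh$label)
  codes <- li$codes
  used <- sort(unique(li$id))
  pn <- c(sprintf("2 %d \"patch:%s\"", seq_along(mesh$patches) + 100L,
                  names(mesh$patches)),
          sprintf("3 %d \"%s\"", unname(codes[match(used, codes)]),
                  names(codes)[match(used, codes)]))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines(c("$PhysicalNames", as.character(length(pn)), pn,
               "$EndPhysicalNames"), con)
  writeLines("$Nodes", con)
  writeLines(as.character(nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("$EndNodes", con)
  tri_lines <- character(0)
  eid <- 0L
  for (p in seq_along(mesh$patches)) {
    tr <- mesh$patches[[p]]
    if (!nrow(tr)) next
    tri_lines <- c(tri_lines,
                   sprintf("%d 2 2 %d %d %d %d %d",
                           eid + seq_len(nrow(tr)), p + 100L, p + 100L,
                           tr[, 1], tr[, 2], tr[, 3]))
    eid <- eid + nrow(tr)
  }
  tet_lines <- sprintf("%d 4 2 %d %d %d %d %d %d",
                       eid + seq_len(nrow(mesh$tets)), li$id, li$id,
                       mesh$tets[, 1], mesh$tets[, 2],
                       mesh$tets[, 3], mesh$tets[, 4])
  writeLines("$Elements", con)
  writeLines(as.character(length(tri_lines) + length(tet_lines)), con)
  writeLines(tri_lines, con)
  writeLines(tet_lines, con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' Read a Gmsh MSH 2.2 ASCII mesh
#'
#' Volume tetrahedra become elements labelled by their physical-group name
#' (or `tissue_codes()` entry); surface triangles in `patch:*` groups are
#' restored as boundary patches.
#'
#' @param file path to a `.msh` file.
#' @return a [tet_mesh()].
#' @export
read_mesh_msh <- function(file) {
  ln <- readLines(file)
  sec <- function(name) {
    i <- which(ln == paste0("$", name)) + 1L
    j <- which(ln == paste0("$End", name)) - 1L
    if (!length(i) || !length(j)) stop("missing $", name, " section")
    ln[i:j]
  }
  names_raw <- tryCatch(sec("PhysicalNames")[-1], error = function(e) {
    character(0)
  })
  pname <- character(0)
  if (length(names_raw)) {
    m <- regmatches(names_raw,
                    regexec('^\\s*\\d+\\s+(\\d+)\\s+"(.*)"\\s*$', names_raw))
    pname <- stats::setNames(vapply(m, `[`, "", 3), vapply(m, `[`, "", 2))
  }
  nd <- sec("Nodes")[-1]
  nm <- do.call(rbind, lapply(strsplit(nd, "\\s+"), as.numeric))
  nodes <- nm[order(nm[, 1]), 2:4, drop = FALSE]
  el <- sec("Elements")[-1]
  em <- strsplit(el, "\\s+")
  typ <- vapply(em, function(r) as.integer(r[2]), 0L)
  tags <- vapply(em, function(r) as.integer(r[4]), 0L)
  tets <- do.call(rbind, lapply(em[typ == 4L], function(r) {
    as.integer(utils::tail(r, 4))
  }))
  tet_tag <- tags[typ == 4L]
  inv_codes <- stats::setNames(names(tissue_codes()), tissue_codes())
  lab <- as.character(pname[as.character(tet_tag)])
  miss <- is.na(lab)
  lab[miss] <- inv_codes[as.character(tet_tag[miss])]
  lab[is.na(lab)] <- as.character(tet_tag[is.na(lab)])
  patches <- list()
  tri_rows <- which(typ == 2L)
  if (length(tri_rows)) {
    tri <- do.call(rbind, lapply(em[tri_rows], function(r) {
      as.integer(utils::tail(r, 3))
    }))
    ptag <- tags[tri_rows]
    for (tg in unique(ptag)) {
      nm_p <- pname[as.character(tg)]
      nm_p <- if (is.na(nm_p)) paste0("patch_", tg) else sub("^patch:", "",
                                                             nm_p)
      patches[[nm_p]] <- tri[ptag == tg, , drop = FALSE]
    }
  }
  tet_mesh(nodes, tets, lab, patches = patches)
}

#' Write a mesh (with optional fields) as legacy ASCII VTK
#'
#' Tetrahedra are written as an unstructured grid with integer cell data
#' `tissue`; optional per-element fields (e.g. `normE_Vpm`, vector `E_Vpm`,
#' `J_Apm2`) are appended as further cell data and node potentials
#' (`V_volts`) as point data.
#'
#' @param mesh a `tet_mesh`.
#' @param file output path.
#' @param solution optional `tt_solution` whose fields are exported.
#' @export
write_mesh_vtk <- function(mesh, file, solution = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "ttfieldsim unstructured mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$nodes[, 1],
                     mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L,
                     mesh$tets[, 2] - 1L, mesh$tets[, 3] - 1L,
                     mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(label_to_int(mesh$label)$id), con)
  if (!is.null(solution)) {
    writeLines(c("SCALARS normE_Vpm double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", solution$normE), con)
    writeLines("VECTORS E_Vpm double", con)
    writeLines(sprintf("%.10g %.10g %.10g", solution$E[, 1],
                       solution$E[, 2], solution$E[, 3]), con)
    writeLines("VECTORS J_Apm2 double", con)
    writeLines(sprintf("%.10g %.10g %.10g", solution$J[, 1],
                       solution$J[, 2], solution$J[, 3]), con)
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines(c("SCALARS V_volts double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", solution$V), con)
  }
  invisible(file)
}

#' Read a legacy ASCII VTK unstructured grid of tetrahedra
#'
#' @param file path to a `.vtk` file written by [write_mesh_vtk()] (or any
#'   legacy ASCII file of linear tetrahedra with integer `tissue` cell
#'   data).
#' @return a [tet_mesh()].
#' @export
read_mesh_vtk <- function(file) {
  ln <- readLines(file)
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  nodes <- matrix(as.numeric(unlist(strsplit(ln[(ip + 1):(ip + n)],
                                             "\\s+"))),
                  ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1]
  m <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cl <- strsplit(ln[(ic + 1):(ic + m)], "\\s+")
  tets <- do.call(rbind, lapply(cl, function(r) as.integer(r[2:5]) + 1L))
  it <- grep("^SCALARS tissue", ln)[1]
  lab_int <- as.integer(ln[(it + 2):(it + 1 + m)])
  inv <- stats::setNames(names(tissue_codes()), tissue_codes())
  lab <- inv[as.character(lab_int)]
  lab[is.na(lab)] <- as.character(lab_int[is.na(lab)])
  tet_mesh(nodes, tets, lab)
}
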