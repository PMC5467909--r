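# Montage construction: coordinate frame, array layout, paired montages.

test_that("canonical landmarks give the identity frame", {
  h <- head_phantom()
  cs <- define_coordinate_system(h, left_ear = c(-75, 0, 0),
                                 right_ear = c(75, 0, 0),
                                 forehead = c(0, 95, 0))
  expect_equal(cs$origin, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(cs$axes), diag(3), tolerance = 1e-12)
})

test_that("swapping the ear landmarks negates x and flips z", {
  h <- head_phantom()
  cs <- define_coordinate_system(h, left_ear = c(75, 0, 0),
                                 right_ear = c(-75, 0, 0),
                                 forehead = c(0, 95, 0))
  expect_equal(unname(cs$axes["x", ]), c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(unname(cs$axes["y", ]), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(unname(cs$axes["z", ]), c(0, 0, -1), tolerance = 1e-12)
  # right-handed: det = +1
  expect_equal(det(cs$axes), 1, tolerance = 1e-12)
})

test_that("off-surface or collinear landmarks are rejected", {
  h <- head_phantom()
  expect_error(define_coordinate_system(h, c(0, 0, 0), c(75, 0, 0),
                                        c(0, 95, 0)), "off the surface")
  expect_error(define_coordinate_system(h, c(-75, 0, 0), c(75, 0, 0),
                                        c(74, 0, 0)), "collinear")
})

test_that("a planar array keeps the exact 45 x 22 mm grid geometry", {
  m <- build_slab_phantom(c(skin = 10), lateral_size = 130, resolution = 5)
  arr <- layout_array(m, center = c(0, 0, 10), row_axis = c(1, 0, 0),
                      id = "test")
  # projection onto the flat top face leaves the grid in place:
  # extent 2*45 + 20 by 2*22 + 20 including the disc radius
  expect_equal(diff(range(arr$centers[, 1])) + 20, 110, tolerance = 1e-9)
  expect_equal(diff(range(arr$centers[, 2])) + 20, 64, tolerance = 1e-9)
  expect_true(all(abs(arr$centers[, 3] - 10) < 1e-9))
  # nearest-neighbour centre distance along a row is the 45 mm pitch
  d <- as.matrix(dist(arr$centers))
  row_mates <- abs(outer(arr$centers[, 2], arr$centers[, 2], "-")) < 1e-9 &
    abs(abs(outer(arr$centers[, 1], arr$centers[, 1], "-")) - 45) < 1e-9
  expect_equal(unique(round(d[row_mates], 9)), 45)
  # nine non-empty pairwise disjoint footprints
  expect_length(arr$disc_nodes, 9)
  expect_true(all(lengths(arr$disc_nodes) > 0))
  expect_false(anyDuplicated(unlist(arr$disc_nodes)) > 0)
})

test_that("too-coarse meshes yield empty disc footprints with advice", {
  m <- build_slab_phantom(c(skin = 10), lateral_size = 130, resolution = 40)
  expect_error(layout_array(m, c(0, 0, 10), c(1, 0, 0), "test"),
               "finer mesh")
})

test_that("clinical montages are symmetric, sourced and disjoint", {
  mons <- head_montages()
  expect_equal(mons$LR$current_A, 0.9)
  expect_equal(mons$AP$current_A, 0.9)
  expect_identical(mons$LR$source$id, "left")
  expect_identical(mons$AP$source$id, "posterior")
  # left/right disc centres mirror about x = 0 on the symmetric phantom
  lx <- sort(round(mons$LR$source$centers[, 1], 9))
  rx <- sort(round(-mons$LR$sink$centers[, 1], 9))
  expect_equal(lx, rx, tolerance = 1e-9)
  # all four arrays pairwise disjoint
  arrs <- list(mons$LR$source, mons$LR$sink, mons$AP$source, mons$AP$sink)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_length(intersect(arrs[[i]]$all_nodes, arrs[[j]]$all_nodes), 0)
    }
  }
  # all disc nodes lie on the outer surface
  surf_nodes <- unique(as.vector(mesh_surface(head_phantom())))
  expect_true(all(unlist(lapply(arrs, `[[`, "all_nodes")) %in% surf_nodes))
})

test_that("montage construction is deterministic", {
  h <- head_phantom()
  a1 <- layout_array(h, c(-150, 0, 0), c(0, 1, 0), "left")
  a2 <- layout_array(h, c(-150, 0, 0), c(0, 1, 0), "left")
  expect_identical(a1$centers, a2$centers)
  expect_identical(a1$disc_nodes, a2$disc_nodes)
})

test_that("disc footprint area converges to nine full discs on refinement", {
  tri_area <- function(mesh, tris) {
    a <- mesh$nodes[tris[, 1], , drop = FALSE]
    b <- mesh$nodes[tris[, 2], , drop = FALSE]
    c <- mesh$nodes[tris[, 3], , drop = FALSE]
    cr <- ttfieldsim:::cross3(b - a, c - a)
    sum(sqrt(rowSums(cr^2))) / 2
  }
  target <- 9 * pi * 10^2
  err <- vapply(c(5, 2.5), function(res) {
    m <- build_slab_phantom(c(skin = 10), lateral_size = 130,
                            resolution = res)
    arr <- layout_array(m, c(0, 0, 10), c(1, 0, 0), "test")
    a <- sum(vapply(arr$disc_tris, function(tr) tri_area(m, tr), numeric(1)))
    abs(a - target) / target
  }, numeric(1))
  expect_lt(err[2], err[1])
})
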