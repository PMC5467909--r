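# Phantom builders: slab and head geometry, labels, tumors, fiber fields.

test_that("slab phantom reproduces box volume and layer split", {
  m <- build_slab_phantom(c(wm = 10), lateral_size = 20, resolution = 1)
  expect_equal(mesh_volume(m), 20 * 20 * 10, tolerance = 1e-9)
  expect_setequal(unique(m$label), "wm")

  m2 <- two_layer_slab()
  tb <- table(m2$label)
  expect_equal(unname(tb["top"]), unname(tb["bottom"]))
  # brute-force centroid classification agrees with the stored labels
  cz <- mesh_centroids(m2)[, 3]
  expect_identical(unname(m2$label == "top"), unname(cz < 5))
  # plate patches sit on the outer faces
  expect_gt(nrow(m2$patches$plate_lo), 0)
  expect_gt(nrow(m2$patches$plate_hi), 0)
})

test_that("slab phantom rejects empty and non-positive layer lists", {
  expect_error(build_slab_phantom(numeric(0)), "at least one layer")
  expect_error(build_slab_phantom(c(wm = 5, csf = -1)), "csf")
  expect_error(build_slab_phantom(c(5, 5)), "named")
})

test_that("meshes are conforming with positively oriented elements", {
  for (m in list(two_layer_slab(), build_head_phantom(resolution = 10))) {
    expect_true(all(m$element_volume > 0))
    expect_true(all(face_share_counts(m) %in% 1:2))
  }
})

test_that("head phantom carries five nested tissue compartments", {
  h <- head_phantom()
  expect_setequal(unique(h$label), c("skin", "bone", "csf", "gm", "wm"))
  va <- 4 / 3 * pi * prod(c(75, 95, 85))
  expect_lt(abs(mesh_volume(h) - va) / va, 0.05)
  # every WM centroid lies inside the innermost shell
  sa <- h$meta$semi_axes["wm", ]
  cen <- mesh_centroids(h)[h$label == "wm", , drop = FALSE]
  expect_true(all((cen[, 1] / sa[1])^2 + (cen[, 2] / sa[2])^2 +
                    (cen[, 3] / sa[3])^2 <= 1))
})

test_that("head phantom rejects non-nested shells", {
  sa <- default_head_geometry()$semi_axes
  sa["bone", 1] <- sa["skin", 1] + 1
  expect_error(build_head_phantom(sa, resolution = 10), "bone")
})

test_that("compartment volumes converge under mesh refinement", {
  va <- 4 / 3 * pi * 10^3
  err <- vapply(c(2.5, 1.25), function(res) {
    m <- build_slab_phantom(c(wm = 40), lateral_size = 40, resolution = res)
    m <- embed_tumor(m, tumor_spec(c(0, 0, 20), solid = TRUE))
    abs(sum(m$element_volume[m$label == "tumor_shell"]) - va) / va
  }, numeric(1))
  expect_lt(err[2], err[1])  # strictly decreasing labelling error
  expect_lt(err[2], 0.03)    # 20 mm tumor within 3% of 4188.79 mm^3
})

test_that("tumor embedding labels shell and core at the analytic ratio", {
  m <- build_slab_phantom(c(wm = 40), lateral_size = 40, resolution = 1.25)
  m <- embed_tumor(m, tumor_spec(c(0, 0, 20)))
  v_core <- sum(m$element_volume[m$label == "tumor_core"])
  v_tot <- v_core + sum(m$element_volume[m$label == "tumor_shell"])
  expect_equal(v_core / v_tot, 0.343, tolerance = 0.05)  # (7/10)^3
})

test_that("solid tumors have no core and re-embedding is idempotent", {
  m <- build_slab_phantom(c(wm = 40), lateral_size = 40, resolution = 2)
  spec <- tumor_spec(c(0, 0, 20), solid = TRUE)
  m1 <- embed_tumor(m, spec)
  expect_false("tumor_core" %in% m1$label)
  m2 <- embed_tumor(m1, spec)
  expect_identical(m1$label, m2$label)
})

test_that("tumors crossing out of the brain compartments are rejected", {
  h <- head_phantom()
  expect_error(embed_tumor(h, tumor_spec(c(70, 0, 0))), "GM/WM")
  expect_error(embed_tumor(h, tumor_spec(c(55, 0, 0))), "GM/WM")
  expect_silent(embed_tumor(h, tumor_spec(c(40, 0, 0))))
  expect_error(tumor_spec(c(0, 0, 0), outer_diameter = 10,
                          core_diameter = 14), "core_diameter")
})

test_that("fiber fields honour pattern, FA and SPD requirements", {
  m <- build_slab_phantom(c(wm = 10), lateral_size = 10, resolution = 2.5)
  f0 <- synth_fiber_field(m, "uniform", fa = 0, direction = c(1, 0, 0))
  expect_true(all(abs(f0$tensor[, 1:3] - 1) < 1e-12))
  expect_true(all(abs(f0$tensor[, 4:6]) < 1e-12))

  fx <- synth_fiber_field(m, "uniform", fa = 0.7, direction = c(1, 0, 0))
  expect_true(all(fx$dir[, 1] == 1))
  # recomputed FA of every emitted tensor matches the request
  for (i in c(1, nrow(fx$tensor))) {
    ev <- eigen(ttfieldsim:::tensor6_to_mat(fx$tensor[i, ]),
                symmetric = TRUE, only.values = TRUE)$values
    expect_equal(unname(fractional_anisotropy(ev)), 0.7, tolerance = 1e-10)
  }

  for (pat in c("radial", "tangential_shells")) {
    fp <- synth_fiber_field(m, pat, fa = 0.5)
    expect_equal(rowSums(fp$dir^2), rep(1, nrow(fp$dir)), tolerance = 1e-12)
  }
  expect_error(synth_fiber_field(m, "uniform", fa = 1), "fa")
})
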