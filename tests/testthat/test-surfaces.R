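band_frame <- function(bands, n_per = 40, bx = box(30, 30, 60), seed = 5,
                       roles = "WATER") {
  set.seed(seed)
  slab <- cbind(runif(25, 0, bx$lx), runif(25, 0, bx$ly), runif(25, 0, 2))
  atoms <- do.call(rbind, lapply(bands, function(zc)
    cbind(runif(n_per, 0, bx$lx), runif(n_per, 0, bx$ly),
          runif(n_per, zc - 0.3, zc + 0.3))))
  xyz <- rbind(slab, atoms)
  pm <- point_molecule_frame(xyz, bx,
                             roles = c(rep("MINERAL", 25),
                                       rep(roles, nrow(atoms))),
                             elements = "O")
  pm
}

test_that("well-separated z-bands become exactly the first four layers", {
  bands <- c(4.5, 7.5, 10.5, 13.5)
  pm <- band_frame(bands)
  la <- assign_layers(pm$frame, pm$topology, n_layers = 4)
  expect_false(la$fallback)
  z <- pm$frame$atoms$z
  for (k in 1:4) {
    got <- sort(la$layers[[k]])
    want <- pm$frame$atoms$atom_id[abs(z - bands[k]) <= 0.31]
    expect_equal(got, sort(want), info = paste("layer", k))
  }
})

test_that("a far-away atom does not perturb the first four layers", {
  bands <- c(4.5, 7.5, 10.5, 13.5)
  pm <- band_frame(bands)
  la0 <- assign_layers(pm$frame, pm$topology, n_layers = 4)
  extra <- pm$frame$atoms[1, ]
  extra$atom_id <- max(pm$frame$atoms$atom_id) + 1L
  extra$molecule_id <- max(pm$frame$atoms$molecule_id) + 1L
  extra$role <- "WATER"
  extra$z <- 35
  fr2 <- pm$frame
  fr2$atoms <- rbind(fr2$atoms, extra)
  la1 <- assign_layers(fr2, pm$topology, n_layers = 4)
  for (k in 1:4) expect_equal(la1$layers[[k]], la0$layers[[k]])
})

test_that("an unstructured fluid engages the fixed-band fallback", {
  set.seed(9)
  bx <- box(30, 30, 60)
  slab <- cbind(runif(25, 0, 30), runif(25, 0, 30), runif(25, 0, 2))
  fluid <- cbind(runif(2000, 0, 30), runif(2000, 0, 30), runif(2000, 2, 40))
  pm <- point_molecule_frame(rbind(slab, fluid), bx,
                             roles = c(rep("MINERAL", 25), rep("WATER", 2000)),
                             elements = "O")
  la <- assign_layers(pm$frame, pm$topology, n_layers = 4)
  expect_true(la$fallback)
  expect_equal(unname(la$bounds[, "hi"] - la$bounds[, "lo"]), rep(3, 4))
  expect_error(assign_layers(point_molecule_frame(slab, bx,
                                                  roles = "MINERAL")$frame,
                             pm$topology),
               "above")
})

test_that("voronoi cell areas tile the periodic rectangle", {
  set.seed(21)
  for (case in 1:6) {
    n <- sample(5:120, 1)
    lx <- runif(1, 10, 50); ly <- runif(1, 10, 50)
    xy <- cbind(runif(n, 0, lx), runif(n, 0, ly))
    areas <- voronoi_cell_areas(xy, lx, ly)
    expect_equal(sum(areas), lx * ly, tolerance = 1e-9)
    expect_true(all(areas > 0))
  }
})

test_that("layer coverage handles pure, symmetric and empty layers", {
  bx <- box(20, 12, 30)
  # pure water layer
  set.seed(2)
  xyz <- cbind(runif(30, 0, 20), runif(30, 0, 12), 5)
  pm <- point_molecule_frame(xyz, bx, roles = "WATER", elements = "O")
  cov <- layer_coverage(pm$frame, pm$topology, pm$frame$atoms$atom_id)
  expect_equal(cov$fraction_water, 1.0, tolerance = 1e-9)

  # symmetric two-atom layer -> exactly half each
  xyz2 <- rbind(c(5, 6, 5), c(15, 6, 5))
  pm2 <- point_molecule_frame(xyz2, bx, roles = c("WATER", "SOM"),
                              elements = c("O", "C"))
  cov2 <- layer_coverage(pm2$frame, pm2$topology, c(0L, 1L))
  expect_equal(cov2$fraction_water, 0.5, tolerance = 1e-12)
  expect_equal(cov2$fraction_som, 0.5, tolerance = 1e-12)

  # empty layer -> flagged zero result
  cov3 <- layer_coverage(pm2$frame, pm2$topology, integer(0))
  expect_true(cov3$empty)
  expect_equal(cov3$fraction_water + cov3$fraction_ion + cov3$fraction_som, 0)
})

test_that("area fractions match the Monte-Carlo nearest-site oracle", {
  set.seed(33)
  lx <- 25; ly <- 20
  n <- 18
  xy <- cbind(runif(n, 0, lx), runif(n, 0, ly))
  roles <- sample(c("WATER", "CATION", "SOM"), n, replace = TRUE,
                  prob = c(0.5, 0.2, 0.3))
  pm <- point_molecule_frame(cbind(xy, 5), box(lx, ly, 30), roles = roles,
                             elements = "O")
  cov <- layer_coverage(pm$frame, pm$topology, pm$frame$atoms$atom_id)
  mc <- mc_role_fractions(xy, roles, lx, ly, n_points = 1e6, seed = 9)
  for (r in names(mc)) {
    got <- switch(r, WATER = cov$fraction_water, CATION = cov$fraction_ion,
                  SOM = cov$fraction_som)
    expect_lt(abs(got - mc[[r]]), 0.005)
  }
})

test_that("coverage is invariant to periodic translation and atom order", {
  set.seed(14)
  lx <- 22; ly <- 17
  n <- 25
  xy <- cbind(runif(n, 0, lx), runif(n, 0, ly))
  roles <- sample(c("WATER", "SOM"), n, replace = TRUE)
  base <- point_molecule_frame(cbind(xy, 4), box(lx, ly, 30), roles = roles,
                               elements = "O")
  c0 <- layer_coverage(base$frame, base$topology, base$frame$atoms$atom_id)
  # rigid wrap-around translation
  sh <- point_molecule_frame(cbind((xy[, 1] + 7.3) %% lx,
                                   (xy[, 2] + 3.9) %% ly, 4),
                             box(lx, ly, 30), roles = roles, elements = "O")
  c1 <- layer_coverage(sh$frame, sh$topology, sh$frame$atoms$atom_id)
  expect_equal(c1$fraction_water, c0$fraction_water, tolerance = 1e-9)
  expect_equal(c1$fraction_som, c0$fraction_som, tolerance = 1e-9)
  # permuted input order
  ord <- sample(n)
  pp <- point_molecule_frame(cbind(xy, 4)[ord, ], box(lx, ly, 30),
                             roles = roles[ord], elements = "O")
  c2 <- layer_coverage(pp$frame, pp$topology, pp$frame$atoms$atom_id)
  expect_equal(c2$fraction_water, c0$fraction_water, tolerance = 1e-9)
})

test_that("surface coverage of a generated scene is a valid partition", {
  sc <- build_scene(small_spec(seed = 19))
  cov <- surface_coverage(sc$frame, sc$topology)
  expect_equal(nrow(cov), 4)
  sums <- cov$fraction_water + cov$fraction_ion + cov$fraction_som
  expect_true(all(abs(sums[!cov$empty] - 1) < 1e-9))
})
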