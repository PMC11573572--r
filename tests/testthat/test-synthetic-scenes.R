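test_that("species library matches its stated composition rules", {
  lib <- default_species_library()
  expect_length(lib$species, 20)
  masses <- vapply(lib$species, molecular_mass, numeric(1))
  expect_true(all(masses >= 70 & masses <= 300))
  charges <- vapply(lib$species, `[[`, integer(1), "formal_charge")
  expect_true(all(charges %in% c(-2L, -1L, 0L)))
  expect_equal(sum(vapply(lib$species, `[[`, logical(1), "is_peptide")), 1)
  # stored masses agree with recomputation from counts to 0.01 Da
  w <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06, P = 30.974)
  for (s in lib$species) {
    m <- sum(w * c(s$C, s$H, s$N, s$O, s$S, s$P))
    expect_equal(s$mass, m, tolerance = 0.01 / m)
  }
})

test_that("template geometries are self-avoiding compact blobs", {
  lib <- default_species_library()
  for (i in seq_along(lib$templates)) {
    tpl <- lib$templates[[i]]
    s <- lib$species[[i]]
    expect_equal(nrow(tpl$coords), s$C + s$N + s$O + s$S + s$P)
    if (nrow(tpl$coords) > 1) {
      dmin <- min(dist(tpl$coords))
      expect_gte(dmin, 1.2)
    }
    expect_lte(max(sqrt(rowSums(tpl$coords^2))), 4.3)
  }
})

test_that("default composition is 4 of each species, 8 of the peptide", {
  lib <- default_species_library()
  comp <- default_composition(lib)
  expect_length(comp, 84)
  counts <- table(comp)
  pep_id <- vapply(lib$species, `[[`, logical(1), "is_peptide")
  pep <- lib$species[[which(pep_id)]]$species_id
  expect_equal(unname(counts[as.character(pep)]), 8L)
  expect_true(all(counts[names(counts) != as.character(pep)] == 4))
})

test_that("temperature ladder spans the replica range", {
  expect_length(temperature_ladder(300, 335, 5), 8)
  expect_equal(temperature_ladder(300, 300, 5), 300)
  expect_equal(temperature_ladder(300, 310, 5), c(300, 305, 310))
  expect_error(temperature_ladder(300, 312, 5), "divisible")
  expect_error(temperature_ladder(300, 335, -5), "> 0")
})

test_that("mineral slab construction follows the lattice spec", {
  spec <- small_spec(seed = 1)
  slab <- build_mineral_slab(spec)
  nx <- floor(spec$lx / 2.6); ny <- floor(spec$ly / 2.6)
  expect_equal(attr(slab, "n_lattice_sites"), nx * ny * 3)
  expect_equal(sum(slab$charge), attr(slab, "slab_charge"))
  expect_equal(-sum(slab$element == "Al"), attr(slab, "slab_charge"))

  ospec <- small_spec(seed = 1, mineral_kind = "OXIDE_LIKE")
  oslab <- build_mineral_slab(ospec)
  expect_equal(attr(oslab, "slab_charge"), 0)
  mlp <- attr(oslab, "metal_ligand_pairs")
  expect_gt(nrow(mlp), 0)
  expect_equal(sum(oslab$element == "Fe"), nrow(mlp))
  expect_error(build_mineral_slab(scene_spec(lx = 8, ly = 8, lz = 50,
                                             counts = c(direct = 0,
                                                        cation_bridged = 0,
                                                        som_bridged = 0,
                                                        free = 1,
                                                        interface = 0,
                                                        vapor = 0),
                                             composition = 1L,
                                             n_water = 60)),
               "4x4")
})

test_that("generated scenes satisfy their structural invariants", {
  for (seed in c(1, 9)) {
    sc <- build_scene(small_spec(seed = seed))
    expect_equal(system_charge(sc$frame, sc$topology), 0)
    expect_gte(min_interatomic_distance(sc$frame), 1.2)
    expect_length(validate_system(sc$frame, sc$topology), 0)
    gt <- sc$ground_truth$labels
    expect_equal(nrow(gt), length(sc$spec$composition))
    expect_true(all(table(gt$molecule_id) == 1))
    # the planted largest cluster is the unique maximum
    sizes <- table(gt$cluster_id)
    big <- sizes[as.character(sc$ground_truth$largest_cluster_id)]
    expect_true(all(sizes[names(sizes) !=
                          as.character(sc$ground_truth$largest_cluster_id)] < big))
    # vapor molecules are always neutral
    vap_sp <- gt$species_id[gt$label == "VAPOR"]
    ch <- vapply(vap_sp, function(id)
      sc$spec$library$species[[id + 1L]]$formal_charge, integer(1))
    expect_true(all(ch == 0))
  }
})

test_that("scene generation is deterministic under a fixed seed", {
  a <- build_scene(small_spec(seed = 31))
  b <- build_scene(small_spec(seed = 31))
  expect_identical(a$frame$atoms, b$frame$atoms)
  expect_identical(a$ground_truth$labels, b$ground_truth$labels)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scene(a, d1); write_scene(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  c3 <- build_scene(small_spec(seed = 32))
  expect_false(identical(a$frame$atoms$x, c3$frame$atoms$x))
})

test_that("an all-FREE scene has an edgeless contact graph", {
  counts <- c(direct = 0, cation_bridged = 0, som_bridged = 0,
              free = 10, interface = 0, vapor = 0)
  sc <- build_scene(small_spec(seed = 3, counts = counts))
  g <- contact_graph(sc$frame, sc$topology)
  expect_equal(nrow(g$edges), 0)
  cl <- find_clusters(g)
  expect_equal(length(unique(cl$membership)), 10)
})

test_that("jitter preserves labels, is deterministic, and respects margins", {
  sc <- build_scene(small_spec(seed = 6))
  f0 <- jitter_trajectory(sc, n_frames = 2, sigma = 0, seed = 1)
  expect_equal(f0[[1]]$atoms$x, sc$frame$atoms$x)
  expect_equal(f0[[2]]$atoms$z, sc$frame$atoms$z)
  fa <- jitter_trajectory(sc, n_frames = 3, sigma = 0.1, seed = 8)
  fb <- jitter_trajectory(sc, n_frames = 3, sigma = 0.1, seed = 8)
  for (k in 1:3) expect_identical(fa[[k]]$atoms, fb[[k]]$atoms)
  expect_error(jitter_trajectory(sc, n_frames = 1, sigma = 0.2), "sigma")
})

test_that("infeasible scene specifications fail loudly", {
  expect_error(small_spec(counts = c(direct = 0, cation_bridged = 0,
                                     som_bridged = 2, free = 7,
                                     interface = 1, vapor = 0)),
               "anchor")
  expect_error(small_spec(counts = c(direct = 1, cation_bridged = 1,
                                     som_bridged = 1, free = 3,
                                     interface = 1, vapor = 2)),
               "composition size|sum")
  # more vapor molecules than neutral species copies
  expect_error(
    build_scene(scene_spec(lx = 75, ly = 75, lz = 100,
                           counts = c(direct = 0, cation_bridged = 0,
                                      som_bridged = 0, free = 0,
                                      interface = 0, vapor = 3),
                           composition = c(0L, 1L, 2L), n_water = 900)),
    "neutral")
})
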