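make_water_slab <- function(n = 4000, z_hi = 40, bx = box(40, 40, 80),
                            seed = 1) {
  set.seed(seed)
  xyz <- cbind(runif(n, 0, bx$lx), runif(n, 0, bx$ly), runif(n, 0, z_hi))
  point_molecule_frame(xyz, bx, roles = "WATER", elements = "O")
}

test_that("liquid surface sits at the top of a uniform water slab", {
  w <- make_water_slab()
  z <- locate_liquid_surface(w$frame)
  expect_lt(abs(z - 40), 0.4 + 1e-9)  # within two bins

  # translation equivariance
  w5 <- w
  w5$frame$atoms$z <- w5$frame$atoms$z + 5
  z5 <- locate_liquid_surface(w5$frame)
  expect_lt(abs(z5 - z - 5), 0.4 + 1e-9)

  # halving the bin width moves z* by less than one original bin
  zf <- locate_liquid_surface(w$frame, sorption_params(density_bin = 0.1))
  expect_lt(abs(zf - z), 0.2 + 1e-9)

  expect_error(locate_liquid_surface(
    point_molecule_frame(matrix(1, 10, 3), box(40, 40, 80),
                         roles = "WATER", elements = "O")$frame),
    "50")
})

test_that("classification recovers planted labels on a margin-built scene", {
  sc <- build_scene(small_spec(seed = 21))
  g <- contact_graph(sc$frame, sc$topology)
  cl <- find_clusters(g)
  lab <- classify_sorption(sc$frame, sc$topology, cl, g)
  gt <- sc$ground_truth$labels
  expect_equal(lab$label, gt$label)
  expect_equal(lab$in_largest, gt$in_largest)
  expect_equal(lab$bridging, gt$bridging)
  expect_true(all(table(lab$molecule_id) == 1))  # one label per molecule
})

test_that("chain molecules two hops from the anchor are SOM_BRIDGED", {
  counts <- c(direct = 1, cation_bridged = 0, som_bridged = 3, free = 5,
              interface = 0, vapor = 1)
  sc <- build_scene(small_spec(seed = 2, counts = counts))
  gt <- sc$ground_truth$labels
  g <- contact_graph(sc$frame, sc$topology)
  cl <- find_clusters(g)
  lab <- classify_sorption(sc$frame, sc$topology, cl, g)
  anchor <- gt$molecule_id[gt$label == "DIRECT"]
  chain <- gt$molecule_id[gt$label == "SOM_BRIDGED"]
  # graph-reachability oracle: everything in the anchor's BFS tree and
  # not itself DIRECT must be SOM_BRIDGED
  comp <- bf_components(g$nodes, g$edges)
  reach <- as.integer(names(comp))[comp == comp[as.character(anchor)]]
  expect_setequal(setdiff(reach, anchor), chain)
  expect_true(all(lab$label[lab$molecule_id %in% setdiff(reach, anchor)] ==
                  "SOM_BRIDGED"))
})

test_that("bridging tags exactly the sorbed anchors of non-sorbed neighbors", {
  labels <- data.frame(molecule_id = 0:3,
                       label = c("DIRECT", "SOM_BRIDGED", "DIRECT", "FREE"))
  g <- structure(list(nodes = 0:3,
                      edges = data.frame(i = 0L, j = 1L, kind = "CONTACT")),
                 class = "maom_molecule_graph")
  expect_equal(tag_bridging(labels, g), 0L)      # anchor with a neighbor
  g2 <- structure(list(nodes = 0:3,
                       edges = data.frame(i = integer(0), j = integer(0),
                                          kind = character(0))),
                  class = "maom_molecule_graph")
  expect_length(tag_bridging(labels, g2), 0)     # monomer never bridges
  # planted scene: tagged set equals anchors with chain members
  sc <- build_scene(small_spec(seed = 13))
  g3 <- contact_graph(sc$frame, sc$topology)
  cl <- find_clusters(g3)
  lab <- classify_sorption(sc$frame, sc$topology, cl, g3)
  gt <- sc$ground_truth$labels
  expect_setequal(lab$molecule_id[lab$bridging],
                  gt$molecule_id[gt$bridging])
})

test_that("adsorbed percentages are exact label counts", {
  mk <- function(labs) data.frame(molecule_id = seq_along(labs) - 1L,
                                  label = labs)
  all_free <- list(mk(rep("FREE", 10)))
  a <- adsorbed_percentage(all_free)
  expect_equal(a$adsorbed, 0)
  expect_equal(a$desorbed, 100)
  half <- list(mk(c(rep("DIRECT", 21), rep("SOM_BRIDGED", 21),
                    rep("FREE", 42))))
  expect_equal(adsorbed_percentage(half)$adsorbed, 50)
  # multi-frame mixed plant equals the hand count
  f1 <- mk(c("DIRECT", "FREE", "VAPOR", "CATION_BRIDGED"))
  f2 <- mk(c("FREE", "FREE", "INTERFACE", "SOM_BRIDGED"))
  a2 <- adsorbed_percentage(list(f1, f2))
  expect_equal(a2$adsorbed, mean(c(2 / 4, 1 / 4)) * 100)
  expect_equal(sum(a2$by_mode), 100)
  # interface flip
  a3 <- adsorbed_percentage(list(f2), interface_adsorbed = TRUE)
  expect_equal(a3$adsorbed, 50)
})

test_that("enlarging d_direct never decreases the DIRECT count", {
  sc <- build_scene(small_spec(seed = 17))
  g <- contact_graph(sc$frame, sc$topology)
  cl <- find_clusters(g)
  prev <- -1
  for (d in c(2.0, 3.0, 3.5, 4.5, 6.0)) {
    lab <- classify_sorption(sc$frame, sc$topology, cl, g,
                             sorption_params(d_direct = d))
    ndir <- sum(lab$label == "DIRECT")
    expect_gte(ndir, prev)
    prev <- ndir
  }
})

test_that("ligand-exchange detection is purely geometric", {
  bx <- box(40, 40, 60)
  # metal at z 5, displaced ligand far, SOM O close
  atoms <- data.frame(
    atom_id = 0:2,
    element = c("Fe", "O", "O"),
    role = c("MINERAL", "MINERAL", "SOM"),
    molecule_id = c(0L, 0L, 1L),
    x = c(20, 24, 20), y = c(20, 20, 20), z = c(5, 5, 7.1),
    vdw_radius = 1.5, is_heavy = TRUE, charge = 0,
    stringsAsFactors = FALSE)
  topo <- topology(data.frame(molecule_id = 0:1, species_id = c(NA, 0L)),
                   list(species_record(0L, "x", C = 1, H = 0, O = 1)),
                   metal_ligand_pairs = data.frame(metal_atom_id = 0L,
                                                   ligand_atom_id = 1L))
  fr <- frame(atoms, bx)
  ev <- detect_ligand_exchange(fr, topo)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$metal_atom_id, 0L)
  expect_equal(ev$som_oxygen_id, 2L)
  # intact ligand water at 2.1 A, SOM O far -> no event
  atoms2 <- atoms
  atoms2$x[2] <- 20; atoms2$z[2] <- 7.1   # ligand back in place
  atoms2$z[3] <- 10                        # SOM O away
  ev2 <- detect_ligand_exchange(frame(atoms2, bx), topo)
  expect_equal(nrow(ev2), 0)
  # missing annotation errors
  topo0 <- topology(data.frame(molecule_id = 0:1, species_id = c(NA, 0L)),
                    list(species_record(0L, "x", C = 1, H = 0, O = 1)))
  expect_error(detect_ligand_exchange(fr, topo0), "annotation")
})

test_that("planted ligand-exchange scenes report exactly k metal events", {
  for (k in c(1L, 2L)) {
    sc <- build_scene(small_spec(seed = 40 + k, mineral_kind = "OXIDE_LIKE",
                                 n_ligand_exchange = k))
    ev <- detect_ligand_exchange(sc$frame, sc$topology)
    expect_equal(length(unique(ev$metal_atom_id)), k)
  }
})
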