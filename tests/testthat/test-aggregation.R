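test_that("contact edges respect the cutoff boundary", {
  bx <- box(40, 40, 40)
  mk <- function(sep) point_molecule_frame(
    rbind(c(10, 10, 10), c(10 + sep, 10, 10)), bx)
  near <- mk(3.0)
  g <- contact_graph(near$frame, near$topology)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$kind, "CONTACT")
  far <- mk(3.6)
  expect_equal(nrow(contact_graph(far$frame, far$topology)$edges), 0)
})

test_that("hydrogens are excluded from contact detection", {
  bx <- box(40, 40, 40)
  pm <- point_molecule_frame(rbind(c(10, 10, 10), c(12, 10, 10)), bx,
                             elements = c("C", "H"))
  g <- contact_graph(pm$frame, pm$topology)
  expect_equal(nrow(g$edges), 0)
})

test_that("cell-list contact search equals the brute-force oracle", {
  set.seed(7)
  for (case in 1:8) {
    n_mol <- 60
    atoms_per <- sample(1:6, n_mol, replace = TRUE)
    n <- sum(atoms_per)
    bx <- box(runif(1, 25, 60), runif(1, 25, 60), runif(1, 25, 60),
              c(TRUE, TRUE, sample(c(TRUE, FALSE), 1)))
    xyz <- cbind(runif(n, 0, bx$lx), runif(n, 0, bx$ly), runif(n, 0, bx$lz))
    mol <- rep(seq_len(n_mol) - 1L, times = atoms_per)
    pm <- point_molecule_frame(xyz, bx)
    pm$frame$atoms$molecule_id <- mol
    topo <- topology(data.frame(molecule_id = seq_len(n_mol) - 1L,
                                species_id = NA_integer_),
                     list(species_record(0L, "x", C = 1, H = 0)))
    g <- contact_graph(pm$frame, topo)
    bf <- bf_pairs(xyz, bx, 3.5)
    keep <- mol[bf$i] != mol[bf$j]
    ed <- unique(data.frame(i = pmin(mol[bf$i[keep]], mol[bf$j[keep]]),
                            j = pmax(mol[bf$i[keep]], mol[bf$j[keep]])))
    got <- g$edges[order(g$edges$i, g$edges$j), c("i", "j")]
    want <- ed[order(ed$i, ed$j), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("connected components equal the BFS oracle, with deterministic ties", {
  # edgeless graph -> singletons
  g0 <- structure(list(nodes = 0:4,
                       edges = data.frame(i = integer(0), j = integer(0),
                                          kind = character(0))),
                  class = "maom_molecule_graph")
  cl0 <- find_clusters(g0)
  expect_equal(length(unique(cl0$membership)), 5)
  expect_equal(cl0$largest_component, 0)  # tie broken by smallest id

  # planted chain
  gc <- structure(list(nodes = 0:9,
                       edges = data.frame(i = 0:8, j = 1:9,
                                          kind = "CONTACT")),
                  class = "maom_molecule_graph")
  clc <- find_clusters(gc)
  expect_equal(unname(clc$sizes["0"]), 10L)

  set.seed(11)
  for (case in 1:10) {
    n <- 40
    m <- sample(10:60, 1)
    e <- unique(data.frame(i = sample(0:(n - 1), m, replace = TRUE),
                           j = sample(0:(n - 1), m, replace = TRUE)))
    e <- e[e$i != e$j, ]
    ij <- data.frame(i = pmin(e$i, e$j), j = pmax(e$i, e$j),
                     kind = "CONTACT")
    g <- structure(list(nodes = 0:(n - 1), edges = ij),
                   class = "maom_molecule_graph")
    cl <- find_clusters(g)
    oracle <- bf_components(0:(n - 1), ij)
    expect_equal(unname(cl$membership), unname(oracle))
    # components >= n - edges
    expect_gte(length(unique(cl$membership)), n - nrow(ij))
  }
})

test_that("adding an edge never increases the component count", {
  set.seed(3)
  n <- 25
  edges <- data.frame(i = integer(0), j = integer(0), kind = character(0))
  prev <- n
  for (step in 1:40) {
    ij <- sort(sample(0:(n - 1), 2))
    edges <- unique(rbind(edges, data.frame(i = ij[1], j = ij[2],
                                            kind = "CONTACT")))
    g <- structure(list(nodes = 0:(n - 1), edges = edges),
                   class = "maom_molecule_graph")
    ncomp <- length(unique(find_clusters(g)$membership))
    expect_lte(ncomp, prev)
    prev <- ncomp
  }
})

test_that("graph edges are invariant under rigid periodic translation", {
  sc <- build_scene(small_spec(seed = 12))
  g0 <- contact_graph(sc$frame, sc$topology)
  fr <- sc$frame
  fr$atoms$x <- fr$atoms$x + 13.7
  fr$atoms$y <- fr$atoms$y - 5.1
  fr <- wrap_frame(fr)
  g1 <- contact_graph(fr, sc$topology)
  expect_equal(g0$edges[order(g0$edges$i, g0$edges$j), ],
               g1$edges[order(g1$edges$i, g1$edges$j), ],
               ignore_attr = TRUE)
})

test_that("divalent bridge edges require a divalent cation near both O/N", {
  bx <- box(40, 40, 40)
  xyz <- rbind(c(10, 10, 10), c(15, 10, 10), c(12.5, 10, 10))
  pm <- point_molecule_frame(xyz, bx,
                             roles = c("SOM", "SOM", "CATION"),
                             elements = c("O", "O", "Ca"),
                             charges = c(0, 0, 2))
  topo <- topology(data.frame(molecule_id = 0:2,
                              species_id = c(0L, 0L, NA)),
                   list(species_record(0L, "x", C = 1, H = 0, O = 1)))
  goff <- contact_graph(pm$frame, topo, contact_params())
  expect_equal(nrow(goff$edges), 0)  # 5 A apart, no direct contact
  gon <- contact_graph(pm$frame, topo,
                       contact_params(include_divalent_bridges = TRUE))
  expect_equal(nrow(gon$edges), 1)
  expect_equal(gon$edges$kind, "DIVALENT_BRIDGE")
  # a monovalent ion in the same spot bridges nothing
  pm$frame$atoms$charge[3] <- 1
  pm$frame$atoms$element[3] <- "Na"
  gna <- contact_graph(pm$frame, topo,
                       contact_params(include_divalent_bridges = TRUE))
  expect_equal(nrow(gna$edges), 0)
})

test_that("sodium preset graphs ignore the divalent-bridge switch", {
  sc <- build_scene(small_spec(seed = 8, counterion = "NA"))
  g0 <- contact_graph(sc$frame, sc$topology, contact_params())
  g1 <- contact_graph(sc$frame, sc$topology,
                      contact_params(include_divalent_bridges = TRUE))
  expect_identical(g0$edges, g1$edges)
})

test_that("largest-cluster probabilities count copy-frame membership", {
  topo <- topology(data.frame(molecule_id = 0:3,
                              species_id = c(0L, 0L, 1L, 1L)),
                   list(species_record(0L, "a", C = 1, H = 0),
                        species_record(1L, "b", C = 1, H = 0)))
  mk_cl <- function(membership) {
    sizes <- table(membership)
    structure(list(membership = membership,
                   sizes = setNames(as.integer(sizes), names(sizes)),
                   largest_component = as.integer(names(sizes)[
                     which.max(sizes)])),
              class = "maom_cluster_assignment")
  }
  # species 0 always in the largest cluster, species 1 half the time
  cl1 <- mk_cl(setNames(c(0L, 0L, 0L, 3L), as.character(0:3)))
  cl2 <- mk_cl(setNames(c(0L, 0L, 2L, 2L), as.character(0:3)))
  p <- largest_cluster_probability(list(cl1, cl1), topo)
  expect_equal(unname(p["0"]), 1.0)
  expect_equal(unname(p["1"]), 0.5)  # one of two copies, every frame
  # frame 1: molecule 2 in the largest; frame 2: the size tie resolves to
  # component 0, so neither copy counts -> (1 + 0) / 4
  p2 <- largest_cluster_probability(list(cl1, cl2), topo)
  expect_equal(unname(p2["1"]), 0.25)
  expect_error(largest_cluster_probability(list(), topo), "frame")
})
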