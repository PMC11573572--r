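# Scene-construction geometry constants (Angstrom). Placement distances are
# chosen strictly inside the classifier cutoffs (default cutoffs minus well
# over the placement margin), so planted labels survive thermal jitter.
SLAB_LATTICE_A <- 2.6     # in-plane lattice spacing
SLAB_PLANE_DZ <- 2.0      # inter-plane spacing
SLAB_NPLANES <- 3L
SLAB_Z0 <- 1.5            # z of the bottom plane
LIGAND_DZ <- 2.0          # ligand-water oxygen height above a metal site
SURF_GRID <- 24           # surface placement grid spacing
BULK_GRID <- 15           # bulk / interface / vapor grid spacing
D_ANCHOR <- 2.8           # direct-contact anchor-atom height above a slab atom
D_CHAIN <- 2.8            # planted SOM-SOM contact distance
D_CAT_SURF_PLANT <- 2.3   # planted cation height above a slab atom
D_CAT_SOM_PLANT <- 2.3    # planted cation - SOM O/N distance
D_EXCHANGE <- 2.0         # planted SOM O - metal site distance

slab_top_z <- function() SLAB_Z0 + (SLAB_NPLANES - 1L) * SLAB_PLANE_DZ

# reference plane for surface placements: top of the highest mineral
# feature (ligand-water oxygens for oxide slabs)
surface_ref_z <- function(spec) {
  slab_top_z() + if (spec$mineral_kind == "OXIDE_LIKE") LIGAND_DZ else 0
}

#' Specification of a synthetic MAOM scene
#'
#' Describes an orthorhombic box holding a mineral slab at low z, SOM
#' molecules planted with known sorption labels and cluster membership,
#' charge-balancing counterions, explicit water (oxygen sites) and a vapor
#' gap above the liquid. Placement margins guarantee that the planted
#' labels are recovered by the classifier.
#'
#' @param lx,ly,lz Box lengths (Angstrom).
#' @param mineral_kind `"SMECTITE_LIKE"` (charged slab) or `"OXIDE_LIKE"`
#'   (neutral slab with metal-site/ligand-water pairs).
#' @param counterion `"NA"` (monovalent) or `"CA"` (divalent).
#' @param counts Named integer vector of per-label molecule counts
#'   (`direct`, `cation_bridged`, `som_bridged`, `free`, `interface`,
#'   `vapor`); must sum to the composition size.
#' @param n_water Number of water molecules (oxygen sites); if `NULL`,
#'   derived from `water_density_target`.
#' @param water_density_target Molecules per cubic Angstrom used when
#'   `n_water` is `NULL` (bulk water is 0.0334; desk-scale scenes default
#'   to a thinner fill that still yields a clean density plateau).
#' @param vapor_fraction Fraction of `lz` left as vapor, in (0, 0.5].
#' @param margin Placement margin delta (Angstrom) separating every
#'   planted distance from its classifying cutoff.
#' @param seed Integer seed (< 2^31 - 1000) controlling every random
#'   choice in the build.
#' @param n_ligand_exchange Number of planted ligand-exchange events
#'   (OXIDE_LIKE only; uses that many DIRECT molecules as oxygen donors).
#' @param charged_site_fraction Fraction of mid-plane slab sites carrying
#'   a -1 charge for SMECTITE_LIKE slabs.
#' @param composition Integer vector of species ids, one per molecule;
#'   defaults to [default_composition()].
#' @param library Species library; defaults to [default_species_library()].
#' @return List of class `maom_scene_spec`.
#' @export
scene_spec <- function(lx = 120, ly = 120, lz = 100,
                       mineral_kind = c("SMECTITE_LIKE", "OXIDE_LIKE"),
                       counterion = c("NA", "CA"),
                       counts = c(direct = 8, cation_bridged = 6,
                                  som_bridged = 12, free = 42,
                                  interface = 10, vapor = 6),
                       n_water = 3500, water_density_target = NULL,
                       vapor_fraction = 0.4, margin = 0.5, seed = 1,
                       n_ligand_exchange = 0L,
                       charged_site_fraction = 0.05,
                       composition = NULL, library = NULL) {
  mineral_kind <- match.arg(mineral_kind)
  counterion <- match.arg(counterion)
  if (is.null(library)) library <- default_species_library()
  if (is.null(composition)) composition <- default_composition(library)
  need <- c("direct", "cation_bridged", "som_bridged", "free",
            "interface", "vapor")
  if (!all(need %in% names(counts))) stop("counts must name: ",
                                          paste(need, collapse = ", "))
  counts <- as.integer(counts[need])
  names(counts) <- need
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) != length(composition))
    stop("sum of label counts (", sum(counts),
         ") must equal composition size (", length(composition), ")")
  if (vapor_fraction <= 0 || vapor_fraction > 0.5)
    stop("vapor_fraction must be in (0, 0.5]")
  if (margin <= 0) stop("margin must be > 0")
  if (counts["som_bridged"] > 0 && counts["direct"] == 0)
    stop("som_bridged molecules require at least one direct anchor")
  if (n_ligand_exchange > 0 && mineral_kind != "OXIDE_LIKE")
    stop("ligand-exchange plants require an OXIDE_LIKE slab")
  if (n_ligand_exchange > counts["direct"])
    stop("n_ligand_exchange exceeds the number of DIRECT molecules")
  z_liq <- lz * (1 - vapor_fraction)
  if (is.null(n_water)) {
    if (is.null(water_density_target))
      stop("give n_water or water_density_target")
    n_water <- round(water_density_target * lx * ly *
                     (z_liq - slab_top_z() - 2.5))
  }
  structure(list(lx = lx, ly = ly, lz = lz, mineral_kind = mineral_kind,
                 counterion = counterion, counts = counts,
                 n_water = as.integer(n_water),
                 vapor_fraction = vapor_fraction, z_liq = z_liq,
                 margin = margin, seed = as.integer(seed),
                 n_ligand_exchange = as.integer(n_ligand_exchange),
                 charged_site_fraction = charged_site_fraction,
                 composition = as.integer(composition), library = library),
            class = "maom_scene_spec")
}

#' Preset scene specifications
#'
#' The four system chemistries: a charged smectite-like slab or a neutral
#' oxide-like slab, charge-balanced with sodium or calcium. Oxide presets
#' plant three ligand-exchange events.
#'
#' @param preset One of `"na-smectite"`, `"ca-smectite"`, `"na-oxide"`,
#'   `"ca-oxide"`.
#' @param seed Integer seed.
#' @param ... Further arguments to [scene_spec()].
#' @return A `maom_scene_spec`.
#' @export
scene_preset <- function(preset = c("na-smectite", "ca-smectite",
                                    "na-oxide", "ca-oxide"),
                         seed = 1, ...) {
  preset <- match.arg(preset)
  kind <- if (grepl("smectite", preset)) "SMECTITE_LIKE" else "OXIDE_LIKE"
  ion <- if (grepl("^na", preset)) "NA" else "CA"
  nlx <- if (kind == "OXIDE_LIKE") 3L else 0L
  scene_spec(mineral_kind = kind, counterion = ion, seed = seed,
             n_ligand_exchange = nlx, ...)
}

#' Build the mineral slab of a scene
#'
#' Rectangular lattice slab spanning x-y at low z, three atomic planes
#' (O / Si / O). SMECTITE_LIKE slabs mark a fraction of mid-plane sites
#' as charged (-1 each, element tag Al); OXIDE_LIKE slabs are neutral and
#' promote every second top-plane site (both axes) to a metal site (Fe),
#' each paired with one ligand-water oxygen placed above it.
#'
#' @param spec A `maom_scene_spec`.
#' @return Atoms `data.frame` (0-based `atom_id`), with attributes
#'   `metal_ligand_pairs` (OXIDE_LIKE) and `slab_charge`.
#' @export
build_mineral_slab <- function(spec) {
  a <- SLAB_LATTICE_A
  nx <- floor(spec$lx / a)
  ny <- floor(spec$ly / a)
  if (nx < 4 || ny < 4) stop("box too small for a 4x4 slab lattice")
  xs <- a / 2 + a * (seq_len(nx) - 1L)
  ys <- a / 2 + a * (seq_len(ny) - 1L)
  grid <- expand.grid(x = xs, y = ys)
  planes <- SLAB_Z0 + SLAB_PLANE_DZ * (seq_len(SLAB_NPLANES) - 1L)
  n_site <- nrow(grid)
  atoms <- do.call(rbind, lapply(seq_along(planes), function(p) {
    data.frame(x = grid$x, y = grid$y, z = planes[p],
               element = if (p == 2L) "Si" else "O",
               plane = p, stringsAsFactors = FALSE)
  }))
  atoms$charge <- 0
  mlp <- NULL
  if (spec$mineral_kind == "SMECTITE_LIKE") {
    mid <- which(atoms$plane == 2L)
    n_charged <- round(spec$charged_site_fraction * length(mid))
    # keep the total (slab + SOM) charge divisible by 2 for divalent ions
    q_som <- sum(vapply(spec$composition, function(id)
      spec$library$species[[id + 1L]]$formal_charge, numeric(1)))
    if (spec$counterion == "CA" && (n_charged - q_som) %% 2 != 0)
      n_charged <- n_charged + 1L
    sel <- mid[round(seq(1, length(mid), length.out = n_charged))]
    atoms$element[sel] <- "Al"
    atoms$charge[sel] <- -1
  } else {
    top <- which(atoms$plane == 3L)
    ix <- round((atoms$x[top] - a / 2) / a)
    iy <- round((atoms$y[top] - a / 2) / a)
    metal <- top[ix %% 2 == 0 & iy %% 2 == 0]
    atoms$element[metal] <- "Fe"
    lig <- data.frame(x = atoms$x[metal], y = atoms$y[metal],
                      z = atoms$z[metal] + LIGAND_DZ,
                      element = "O", plane = 4L, charge = 0,
                      stringsAsFactors = FALSE)
    mlp <- data.frame(metal_atom_id = metal - 1L,
                      ligand_atom_id = nrow(atoms) + seq_len(nrow(lig)) - 1L)
    atoms <- rbind(atoms, lig)
  }
  out <- data.frame(atom_id = seq_len(nrow(atoms)) - 1L,
                    element = atoms$element, role = "MINERAL",
                    molecule_id = 0L,
                    x = atoms$x, y = atoms$y, z = atoms$z,
                    vdw_radius = vdw_radius_for(atoms$element),
                    is_heavy = TRUE, charge = atoms$charge,
                    stringsAsFactors = FALSE)
  attr(out, "metal_ligand_pairs") <- mlp
  attr(out, "slab_charge") <- sum(atoms$charge)
  attr(out, "n_lattice_sites") <- n_site * SLAB_NPLANES
  out
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Swap elements so the designated template atom carries one of `need`.
assign_designated_element <- function(elements, idx, need) {
  if (elements[idx] %in% need) return(elements)
  for (want in need) {
    j <- which(elements == want)[1]
    if (!is.na(j)) {
      elements[j] <- elements[idx]
      elements[idx] <- want
      return(elements)
    }
  }
  stop("species has no ", paste(need, collapse = "/"),
       " atom for a designated placement")
}

# snap (x, y) to the nearest slab lattice node, optionally the metal
# sub-lattice (OXIDE_LIKE: even node indices on both axes)
snap_to_node <- function(x, y, spec, metal = FALSE, avoid_metal = FALSE) {
  a <- SLAB_LATTICE_A
  nx <- floor(spec$lx / a); ny <- floor(spec$ly / a)
  ix <- round((x - a / 2) / a); iy <- round((y - a / 2) / a)
  clamp <- function(i, n) pmin(pmax(i, 0), n - 1)
  if (metal) {
    ix <- clamp(2 * round(ix / 2), nx); iy <- clamp(2 * round(iy / 2), ny)
    if (ix %% 2 == 1) ix <- ix - 1
    if (iy %% 2 == 1) iy <- iy - 1
  } else {
    ix <- clamp(ix, nx); iy <- clamp(iy, ny)
    if (avoid_metal && ix %% 2 == 0 && iy %% 2 == 0) ix <- clamp(ix + 1, nx)
  }
  c(a / 2 + a * ix, a / 2 + a * iy)
}

#' Build a labeled synthetic scene
#'
#' Places every SOM molecule so that its planted sorption label holds with
#' a geometric margin: direct molecules anchor one heavy atom close above
#' a slab atom; cation-bridged molecules coordinate a counterion that
#' simultaneously touches the slab; SOM-bridged molecules stack in
#' vertical chains off direct anchors with planted inter-molecule
#' contacts; free molecules sit isolated in the bulk liquid; interface
#' molecules center on the liquid surface; vapor molecules (always
#' neutral species) float above it. Counterions balance the total charge
#' and water oxygens fill the liquid region by seeded rejection sampling
#' with 2.4 A minimum spacing.
#'
#' @param spec A `maom_scene_spec`.
#' @return List with elements `frame`, `topology`, `ground_truth` (class
#'   `maom_ground_truth`: data.frame of planted labels and cluster ids
#'   plus the planted largest-cluster id) and `spec`.
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "maom_scene_spec"))
  lib <- spec$library
  n_som <- length(spec$composition)
  z_top <- slab_top_z()
  z_liq <- spec$z_liq

  with_local_seed(spec$seed, {
    mineral <- build_mineral_slab(spec)
    mlp <- attr(mineral, "metal_ligand_pairs")
    slab_charge <- attr(mineral, "slab_charge")

    ## ---- label assignment -------------------------------------------------
    cnt <- spec$counts
    sp_charge <- vapply(spec$composition, function(id)
      lib$species[[id + 1L]]$formal_charge, numeric(1))
    perm <- sample.int(n_som)
    neutral <- perm[sp_charge[perm] == 0]
    if (length(neutral) < cnt["vapor"])
      stop("not enough neutral molecules for the requested vapor count")
    vapor_ids <- neutral[seq_len(cnt["vapor"])]
    rest <- setdiff(perm, vapor_ids)
    take <- function(n) {
      out <- rest[seq_len(n)]
      rest <<- rest[-seq_len(n)]
      out
    }
    direct_ids <- if (cnt["direct"]) take(cnt["direct"]) else integer(0)
    cation_ids <- if (cnt["cation_bridged"]) take(cnt["cation_bridged"]) else integer(0)
    bridged_ids <- if (cnt["som_bridged"]) take(cnt["som_bridged"]) else integer(0)
    interface_ids <- if (cnt["interface"]) take(cnt["interface"]) else integer(0)
    free_ids <- rest

    # distribute bridged molecules over anchors, unique maximum chain first
    n_anchor <- length(direct_ids)
    sizes <- integer(n_anchor)
    if (length(bridged_ids)) {
      base <- length(bridged_ids) %/% n_anchor
      extra <- length(bridged_ids) %% n_anchor
      sizes <- rep(base, n_anchor) + c(rep(1L, extra), rep(0L, n_anchor - extra))
      dup <- which(sizes == max(sizes))
      if (length(dup) > 1) {
        donor <- max(which(sizes > 0))
        sizes[donor] <- sizes[donor] - 1L
        sizes[1] <- sizes[1] + 1L
      }
    }
    chains <- vector("list", n_anchor)
    pos <- 0L
    for (k in seq_len(n_anchor)) {
      chains[[k]] <- if (sizes[k] > 0)
        bridged_ids[pos + seq_len(sizes[k])] else integer(0)
      pos <- pos + sizes[k]
    }

    ## ---- placement grids --------------------------------------------------
    surf_cells <- expand.grid(
      x = SURF_GRID / 2 + SURF_GRID * (0:(floor(spec$lx / SURF_GRID) - 1)),
      y = SURF_GRID / 2 + SURF_GRID * (0:(floor(spec$ly / SURF_GRID) - 1)))
    n_surface_units <- n_anchor + length(cation_ids)
    if (n_surface_units > nrow(surf_cells))
      stop("infeasible placement: too many surface molecules for the box")

    bulk_xy <- expand.grid(
      x = BULK_GRID / 2 + BULK_GRID * (0:(floor(spec$lx / BULK_GRID) - 1)),
      y = BULK_GRID / 2 + BULK_GRID * (0:(floor(spec$ly / BULK_GRID) - 1)))

    ## ---- per-molecule placement -------------------------------------------
    # Planted distances sit well inside the classifying cutoffs; cross-unit
    # separations are enforced by grids plus an explicit post-placement
    # verification with deterministic re-rotation retries.
    labels <- character(n_som)
    labels[direct_ids] <- "DIRECT"
    labels[cation_ids] <- "CATION_BRIDGED"
    labels[bridged_ids] <- "SOM_BRIDGED"
    labels[interface_ids] <- "INTERFACE"
    labels[free_ids] <- "FREE"
    labels[vapor_ids] <- "VAPOR"
    cluster_id <- seq_len(n_som) - 1L
    for (k in seq_len(n_anchor))
      cluster_id[chains[[k]]] <- cluster_id[direct_ids[k]]

    z_surf <- surface_ref_z(spec)
    metal_z <- z_top  # metal sites sit on the top lattice plane
    scene_box <- box(spec$lx, spec$ly, spec$lz, c(TRUE, TRUE, FALSE))
    q_ion <- if (spec$counterion == "NA") 1 else 2
    ion_el <- if (spec$counterion == "NA") "Na" else "Ca"

    # exchange donors: the anchors with the fewest members whose species
    # has an oxygen, re-anchored as donors on metal sites with their
    # ligand water displaced
    has_O <- vapply(direct_ids, function(mid)
      lib$species[[spec$composition[mid] + 1L]]$O > 0, logical(1))
    donor_order <- order(!has_O, sizes, seq_len(n_anchor))
    if (spec$n_ligand_exchange > sum(has_O))
      stop("not enough oxygen-bearing DIRECT molecules for ",
           spec$n_ligand_exchange, " ligand-exchange plants")
    donors <- if (spec$n_ligand_exchange > 0)
      donor_order[seq_len(spec$n_ligand_exchange)] else integer(0)

    # surface cells are consumed in a fixed order (anchors then
    # cation-bridged units), so unit nodes are known before placement
    unit_nodes <- matrix(NA_real_, nrow = n_anchor + length(cation_ids),
                         ncol = 2)
    for (u in seq_len(nrow(unit_nodes))) {
      cell <- as.numeric(surf_cells[u, ])
      metal_node <- spec$mineral_kind == "OXIDE_LIKE"
      if (u <= n_anchor && u %in% donors) metal_node <- TRUE
      unit_nodes[u, ] <- snap_to_node(cell[1], cell[2], spec,
                                      metal = metal_node)
    }

    # displace the ligand water of each donor metal BEFORE placement so
    # clash checks and verification see the final slab geometry
    exchange_plan <- list()
    for (k in donors) {
      node <- unit_nodes[k, ]
      metal_row <- which(abs(mineral$x - node[1]) < 1e-9 &
                         abs(mineral$y - node[2]) < 1e-9 &
                         mineral$element == "Fe")
      metal_id <- mineral$atom_id[metal_row[1]]
      lrow <- which(mineral$atom_id ==
                    mlp$ligand_atom_id[mlp$metal_atom_id == metal_id])
      mineral$x[lrow] <- mineral$x[metal_row[1]] + 3.0
      mineral$y[lrow] <- mineral$y[metal_row[1]] + 1.3
      mineral$z[lrow] <- mineral$z[metal_row[1]] - 0.5
      exchange_plan[[length(exchange_plan) + 1L]] <-
        list(metal_atom_id = metal_id)
    }
    min_xyz <- as.matrix(mineral[, c("x", "y", "z")])

    # minimum distance from candidate atoms to the slab, designated anchor
    # pair excluded (it is close by construction)
    mineral_clash <- function(coords, skip_atom = NULL) {
      p <- pairs_between(coords, min_xyz, scene_box, 3.3)
      if (!is.null(skip_atom)) p <- p[p$i != skip_atom, , drop = FALSE]
      nrow(p) > 0 && min(p$dist) < 1.3
    }
    min_cross <- function(a, b) {
      d <- pairs_between(a, b, scene_box, 6.0)
      if (nrow(d)) min(d$dist) else Inf
    }

    place_attempt <- function(attempt) {
      set.seed(spec$seed %% 2000000L + 997L * attempt + 13L)
      mol_coords <- vector("list", n_som)
      mol_elements <- vector("list", n_som)
      cation_rows <- list()

      rotated <- function(mol_id) {
        tpl <- lib$templates[[spec$composition[mol_id] + 1L]]
        list(coords = tpl$coords %*% t(random_rotation()),
             elements = tpl$elements)
      }

      chain_cells <- matrix(NA_real_, nrow = n_anchor, ncol = 2)
      for (k in seq_len(n_anchor)) {
        mol_id <- direct_ids[k]
        node <- unit_nodes[k, ]
        if (k %in% donors) {
          coords <- NULL
          for (try in 1:100) {
            t1 <- rotated(mol_id)
            bot <- which.min(t1$coords[, 3])
            cand <- sweep(t1$coords, 2,
                          c(node[1], node[2], metal_z + D_EXCHANGE) -
                            t1$coords[bot, ], `+`)
            if (!mineral_clash(cand, skip_atom = bot)) {
              coords <- cand
              elements <- assign_designated_element(t1$elements, bot, "O")
              break
            }
          }
          if (is.null(coords)) return(NULL)
        } else {
          t1 <- rotated(mol_id)
          bot <- which.min(t1$coords[, 3])
          coords <- sweep(t1$coords, 2,
                          c(node[1], node[2], z_surf + D_ANCHOR) -
                            t1$coords[bot, ], `+`)
          elements <- t1$elements
        }
        mol_coords[[mol_id]] <- coords
        mol_elements[[mol_id]] <- elements
        chain_cells[k, ] <- node

        # stack members above the anchor with planted 2.8 A contacts;
        # rotations are searched so the chain stays near the node column
        chain_so_far <- coords
        prev_top_atom <- coords[which.max(coords[, 3]), ]
        for (m in chains[[k]]) {
          placed <- NULL
          for (try in 1:150) {
            tm <- rotated(m)
            des <- which.max(rowSums(tm$coords^2))
            shift <- prev_top_atom + c(0, 0, D_CHAIN) - tm$coords[des, ]
            mc <- sweep(tm$coords, 2, shift, `+`)
            ctr <- colMeans(mc)
            if (min(mc[, 3]) < z_surf + 4.2) next
            if (ctr[3] > z_liq - 5.0) next
            if (sqrt((ctr[1] - node[1])^2 + (ctr[2] - node[2])^2) > 3.0) next
            if (min_cross(mc, chain_so_far) < 1.3) next
            placed <- list(coords = mc, elements = tm$elements)
            break
          }
          if (is.null(placed)) return(NULL)
          mol_coords[[m]] <- placed$coords
          mol_elements[[m]] <- placed$elements
          chain_so_far <- rbind(chain_so_far, placed$coords)
          prev_top_atom <- placed$coords[which.max(placed$coords[, 3]), ]
        }
      }

      # cation-bridged molecules: counterion between slab node and O/N atom
      for (q in seq_along(cation_ids)) {
        mol_id <- cation_ids[q]
        node <- unit_nodes[n_anchor + q, ]
        t1 <- rotated(mol_id)
        bot <- which.min(t1$coords[, 3])
        elements <- assign_designated_element(t1$elements, bot, c("O", "N"))
        cation_z <- z_surf + D_CAT_SURF_PLANT
        shift <- c(node[1], node[2], cation_z + D_CAT_SOM_PLANT) -
          t1$coords[bot, ]
        mol_coords[[mol_id]] <- sweep(t1$coords, 2, shift, `+`)
        mol_elements[[mol_id]] <- elements
        cation_rows[[length(cation_rows) + 1L]] <- data.frame(
          element = ion_el, role = "CATION", molecule_id = NA_integer_,
          x = node[1], y = node[2], z = cation_z,
          vdw_radius = vdw_radius_for(ion_el), is_heavy = TRUE,
          charge = q_ion, stringsAsFactors = FALSE)
      }

      # bulk free molecules on two z levels, laterally clear of chains
      lvl_z <- c(z_top + 26, z_top + 38.5)
      keep <- rep(TRUE, nrow(bulk_xy))
      for (k in seq_len(n_anchor)) {
        if (length(chains[[k]]) == 0) next
        d2 <- (bulk_xy$x - chain_cells[k, 1])^2 +
              (bulk_xy$y - chain_cells[k, 2])^2
        keep <- keep & d2 > 17^2
      }
      bulk_cells <- bulk_xy[keep, , drop = FALSE]
      if (length(free_ids) > nrow(bulk_cells) * length(lvl_z))
        stop("infeasible placement: too many FREE molecules for the box")
      for (q in seq_along(free_ids)) {
        mol_id <- free_ids[q]
        lv <- ((q - 1L) %% length(lvl_z)) + 1L
        cell <- as.numeric(bulk_cells[((q - 1L) %/% length(lvl_z)) + 1L, ])
        t1 <- rotated(mol_id)
        mol_coords[[mol_id]] <- sweep(t1$coords, 2,
                                      c(cell[1], cell[2], lvl_z[lv]), `+`)
        mol_elements[[mol_id]] <- t1$elements
      }

      # interface molecules: centroid on the nominal liquid surface
      if (length(interface_ids) > nrow(bulk_cells))
        stop("infeasible placement: too many INTERFACE molecules")
      for (q in seq_along(interface_ids)) {
        mol_id <- interface_ids[q]
        cell <- as.numeric(bulk_cells[q, ])
        t1 <- rotated(mol_id)
        mol_coords[[mol_id]] <- sweep(t1$coords, 2,
                                      c(cell[1], cell[2], z_liq), `+`)
        mol_elements[[mol_id]] <- t1$elements
      }

      # vapor molecules: well above the surface
      vap_z <- z_liq + 2 * 3.0 + 10
      if (vap_z + 5 > spec$lz)
        stop("infeasible placement: vapor layer exceeds the box")
      vap_cells <- bulk_xy[rev(seq_len(nrow(bulk_xy))), , drop = FALSE]
      for (q in seq_along(vapor_ids)) {
        mol_id <- vapor_ids[q]
        cell <- as.numeric(vap_cells[q, ])
        t1 <- rotated(mol_id)
        mol_coords[[mol_id]] <- sweep(t1$coords, 2,
                                      c(cell[1], cell[2], vap_z), `+`)
        mol_elements[[mol_id]] <- t1$elements
      }

      list(coords = mol_coords, elements = mol_elements,
           cation_rows = cation_rows)
    }

    # Verify margins: no SOM-SOM proximity across planted clusters within
    # 4.2 A (classifier cutoff 3.5 plus jitter headroom), and no non-DIRECT
    # molecule within 4.2 A of the slab; DIRECT molecules keep >= 1.3 A.
    verify_attempt <- function(res) {
      xyz <- do.call(rbind, res$coords)
      mol_of <- rep(seq_len(n_som) - 1L,
                    vapply(res$coords, nrow, integer(1)))
      p <- pairs_within(xyz, scene_box, 4.2)
      mi <- mol_of[p$i]; mj <- mol_of[p$j]
      cross <- mi != mj
      if (any(cross & (cluster_id[mi + 1L] != cluster_id[mj + 1L]))) {
        bad <- which(cross & (cluster_id[mi + 1L] != cluster_id[mj + 1L]))[1]
        if (isTRUE(getOption("maomtools.debug_placement")))
          message("verify fail: SOM pair mol ", mi[bad], " (", labels[mi[bad]+1L],
                  ") - mol ", mj[bad], " (", labels[mj[bad]+1L], ") at ",
                  round(p$dist[bad], 2), " A")
        return(FALSE)
      }
      pm <- pairs_between(xyz, min_xyz, scene_box, 4.2)
      if (nrow(pm)) {
        mols <- unique(mol_of[pm$i])
        if (!all(labels[mols + 1L] == "DIRECT")) {
          if (isTRUE(getOption("maomtools.debug_placement"))) {
            off <- mols[labels[mols + 1L] != "DIRECT"][1]
            sel <- pm[mol_of[pm$i] == off, ]
            message("verify fail: mol ", off, " (", labels[off + 1L],
                    ") within ", round(min(sel$dist), 2), " A of mineral")
          }
          return(FALSE)
        }
        if (min(pm$dist) < 1.29) {
          if (isTRUE(getOption("maomtools.debug_placement")))
            message("verify fail: mineral clash at ", round(min(pm$dist), 3))
          return(FALSE)
        }
      }
      TRUE
    }

    res <- NULL
    for (attempt in 1:25) {
      cand <- place_attempt(attempt)
      if (!is.null(cand) && verify_attempt(cand)) { res <- cand; break }
    }
    if (is.null(res))
      stop("infeasible placement: could not satisfy margins after 25 attempts")

    som_atoms <- do.call(rbind, lapply(seq_len(n_som), function(mol_id) {
      coords <- res$coords[[mol_id]]
      data.frame(element = res$elements[[mol_id]], role = "SOM",
                 molecule_id = mol_id - 1L,
                 x = coords[, 1], y = coords[, 2], z = coords[, 3],
                 vdw_radius = vdw_radius_for(res$elements[[mol_id]]),
                 is_heavy = TRUE, charge = 0, stringsAsFactors = FALSE)
    }))
    cation_rows <- res$cation_rows

    ## ---- counterions -------------------------------------------------------
    q_som <- sum(sp_charge)
    q_need <- -(slab_charge + q_som)
    if (q_need < 0) stop("net positive SOM+slab charge is not supported")
    if (q_need %% q_ion != 0)
      stop("total charge ", q_need, " not divisible by counterion valence")
    n_ion_total <- q_need %/% q_ion
    n_free_ion <- n_ion_total - length(cation_rows)
    if (n_free_ion < 0)
      stop("more bridging cations than charge balance allows")
    placed <- rbind(mineral[, c("x", "y", "z")], som_atoms[, c("x", "y", "z")],
                    if (length(cation_rows))
                      do.call(rbind, cation_rows)[, c("x", "y", "z")])
    free_ion_xyz <- NULL
    if (n_free_ion > 0) {
      free_ion_xyz <- cpp_place_points(
        n_free_ion, c(0, 0, z_top + 12), c(spec$lx, spec$ly, z_liq - 5),
        6.0, placed$x, placed$y, placed$z,
        spec$lx, spec$ly, spec$lz, TRUE, TRUE, FALSE,
        spec$seed + 101L, 2000L)
      if (nrow(free_ion_xyz) < n_free_ion)
        stop("failed to place ", n_free_ion, " counterions")
      cation_rows[[length(cation_rows) + 1L]] <- data.frame(
        element = ion_el, role = "CATION", molecule_id = NA_integer_,
        x = free_ion_xyz[, 1], y = free_ion_xyz[, 2], z = free_ion_xyz[, 3],
        vdw_radius = vdw_radius_for(ion_el), is_heavy = TRUE,
        charge = q_ion, stringsAsFactors = FALSE)
    }
    cation_atoms <- if (length(cation_rows)) do.call(rbind, cation_rows) else NULL

    ## ---- water --------------------------------------------------------------
    placed <- rbind(placed,
                    if (!is.null(cation_atoms)) cation_atoms[, c("x", "y", "z")])
    water_xyz <- cpp_place_points(
      spec$n_water, c(0, 0, z_top + 2.5), c(spec$lx, spec$ly, z_liq),
      2.4, placed$x, placed$y, placed$z,
      spec$lx, spec$ly, spec$lz, TRUE, TRUE, FALSE,
      spec$seed + 202L, 2000L)
    if (nrow(water_xyz) < spec$n_water)
      stop("failed to place ", spec$n_water, " waters (got ",
           nrow(water_xyz), "); lower n_water")
    water_atoms <- data.frame(
      element = "O", role = "WATER", molecule_id = NA_integer_,
      x = water_xyz[, 1], y = water_xyz[, 2], z = water_xyz[, 3],
      vdw_radius = vdw_radius_for("O"), is_heavy = TRUE, charge = 0,
      stringsAsFactors = FALSE)

    ## ---- assembly -----------------------------------------------------------
    mineral$molecule_id <- n_som
    next_mol <- n_som + 1L
    if (!is.null(cation_atoms)) {
      cation_atoms$molecule_id <- next_mol + seq_len(nrow(cation_atoms)) - 1L
      next_mol <- next_mol + nrow(cation_atoms)
    }
    water_atoms$molecule_id <- next_mol + seq_len(nrow(water_atoms)) - 1L

    cols <- c("element", "role", "molecule_id", "x", "y", "z",
              "vdw_radius", "is_heavy", "charge")
    atoms <- rbind(mineral[, cols], som_atoms[, cols],
                   if (!is.null(cation_atoms)) cation_atoms[, cols],
                   water_atoms[, cols])
    atoms <- cbind(atom_id = seq_len(nrow(atoms)) - 1L, atoms)
    rownames(atoms) <- NULL

    bx <- box(spec$lx, spec$ly, spec$lz, periodic = c(TRUE, TRUE, FALSE))
    fr <- wrap_frame(frame(atoms, bx, temperature = 300, frame_index = 0L))

    mol_df <- data.frame(
      molecule_id = sort(unique(atoms$molecule_id)),
      species_id = NA_integer_)
    mol_df$species_id[mol_df$molecule_id < n_som] <-
      spec$composition[mol_df$molecule_id[mol_df$molecule_id < n_som] + 1L]
    # mineral atom ids are unchanged by assembly (mineral block comes first)
    topo <- topology(mol_df, lib$species, metal_ligand_pairs = mlp)

    in_largest_cluster <- if (any(sizes > 0)) {
      cluster_id == cluster_id[direct_ids[which.max(sizes)]]
    } else {
      cluster_id == min(cluster_id)
    }
    bridging <- rep(FALSE, n_som)
    if (n_anchor > 0) bridging[direct_ids[sizes > 0]] <- TRUE
    gt <- structure(list(
      labels = data.frame(
        molecule_id = seq_len(n_som) - 1L,
        species_id = spec$composition,
        label = labels,
        cluster_id = cluster_id,
        in_largest = in_largest_cluster,
        bridging = bridging,
        stringsAsFactors = FALSE),
      largest_cluster_id = if (any(sizes > 0))
        cluster_id[direct_ids[which.max(sizes)]] else min(cluster_id),
      n_ligand_exchange = spec$n_ligand_exchange),
      class = "maom_ground_truth")

    list(frame = fr, topology = topo, ground_truth = gt, spec = spec)
  })
}

#' Jittered pseudo-trajectory from a scene
#'
#' Returns `n_frames` copies of the frame with i.i.d. Gaussian
#' displacements (`sigma` per coordinate) applied to every atom, wrapped
#' on periodic axes. Requires `3 * sigma < margin` so planted labels
#' remain valid.
#'
#' @param scene A list from [build_scene()] (or a bare `maom_frame`, in
#'   which case `margin` must be supplied).
#' @param n_frames Number of frames.
#' @param sigma Displacement standard deviation (Angstrom).
#' @param seed Integer seed.
#' @param margin Placement margin; defaults to the scene spec's.
#' @return List of `maom_frame`s with increasing `frame_index`.
#' @export
jitter_trajectory <- function(scene, n_frames, sigma = 0.1, seed = 1,
                              margin = NULL) {
  fr <- if (inherits(scene, "maom_frame")) scene else scene$frame
  if (is.null(margin)) {
    if (inherits(scene, "maom_frame"))
      stop("margin must be given when passing a bare frame")
    margin <- scene$spec$margin
  }
  if (3 * sigma >= margin)
    stop("3 * sigma (", 3 * sigma, ") must be < margin (", margin, ")")
  n_atoms <- nrow(fr$atoms)
  with_local_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      f <- fr
      if (sigma > 0) {
        f$atoms$x <- f$atoms$x + rnorm(n_atoms, sd = sigma)
        f$atoms$y <- f$atoms$y + rnorm(n_atoms, sd = sigma)
        f$atoms$z <- f$atoms$z + rnorm(n_atoms, sd = sigma)
      }
      f$frame_index <- k - 1L
      wrap_frame(f)
    })
  })
}

#' Minimum heavy-atom pair distance of a frame
#'
#' Convenience invariant check across all roles (minimum image).
#'
#' @param frame A `maom_frame`.
#' @param cutoff Search cutoff; pairs beyond it are ignored (returns
#'   `Inf` when no pair is closer).
#' @return Minimum pair distance in Angstrom.
#' @export
min_interatomic_distance <- function(frame, cutoff = 2.0) {
  a <- frame$atoms[frame$atoms$is_heavy, ]
  p <- pairs_within(atom_coords(a), frame$box, cutoff)
  if (!nrow(p)) Inf else min(p$dist)
}

#' Write a scene to disk
#'
#' Emits `scene.<ext>` (coordinates), `topology.json` (topology plus
#' per-atom metadata) and `ground_truth.csv` (planted labels).
#'
#' @param scene List from [build_scene()].
#' @param dir Output directory (created if missing).
#' @param format Coordinate format (`"GRO"`, `"XYZ"` or `"PDB"`).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, format = "GRO") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- tolower(format)
  write_configuration(scene$frame, file.path(dir, paste0("scene.", ext)),
                      format = format, topology = scene$topology)
  write_topology_json(scene$topology, file.path(dir, "topology.json"),
                      frame = scene$frame)
  write.csv(scene$ground_truth$labels, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir Scene directory.
#' @param format Coordinate format used when writing.
#' @return List with `frame`, `topology` and `ground_truth` (labels only).
#' @export
read_scene <- function(dir, format = "GRO") {
  ext <- tolower(format)
  tp <- read_topology_json(file.path(dir, "topology.json"))
  fr <- read_configuration(file.path(dir, paste0("scene.", ext)),
                           format = format, atom_meta = tp$atom_meta)
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path))
    read.csv(gt_path, stringsAsFactors = FALSE) else NULL
  list(frame = fr, topology = tp$topology, ground_truth = gt)
}
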