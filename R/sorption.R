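#' Sorption classification parameters
#'
#' Cutoffs (Angstrom) operationalizing the sorption-mode scheme: direct
#' mineral contact, cation bridging, the interfacial shell about the
#' liquid surface and metal-oxygen coordination for ligand-exchange
#' detection.
#'
#' @param d_direct SOM heavy atom to mineral atom cutoff.
#' @param d_cat_surf Cation to mineral cutoff.
#' @param d_cat_som Cation to SOM O/N cutoff.
#' @param interface_shell Half-width of the interfacial shell about the
#'   liquid surface.
#' @param density_bin Bin width of the water density profile.
#' @param d_fe_o Metal-site to oxygen coordination cutoff.
#' @return List of class `maom_sorption_params`.
#' @export
sorption_params <- function(d_direct = 3.5, d_cat_surf = 3.0,
                            d_cat_som = 3.0, interface_shell = 3.0,
                            density_bin = 0.2, d_fe_o = 2.6) {
  v <- c(d_direct, d_cat_surf, d_cat_som, interface_shell, density_bin, d_fe_o)
  if (any(v <= 0)) stop("all sorption parameters must be > 0")
  structure(list(d_direct = d_direct, d_cat_surf = d_cat_surf,
                 d_cat_som = d_cat_som, interface_shell = interface_shell,
                 density_bin = density_bin, d_fe_o = d_fe_o),
            class = "maom_sorption_params")
}

#' Locate the liquid surface from the water density profile
#'
#' Bins water-oxygen z coordinates into `density_bin` slices, estimates
#' the bulk plateau as the median count over the central liquid region
#' (10th-60th percentile of water z) and returns the upper edge of the
#' highest bin whose count still reaches 50% of that plateau.
#' Deterministic; interior noise dips below 50% are ignored because only
#' the highest crossing is reported.
#'
#' @param frame A `maom_frame` with at least 50 water molecules.
#' @param params A [sorption_params()] list.
#' @return The liquid-surface height z* (Angstrom).
#' @export
locate_liquid_surface <- function(frame, params = sorption_params()) {
  wz <- frame$atoms$z[frame$atoms$role == "WATER" &
                      frame$atoms$element == "O"]
  if (length(wz) < 50)
    stop("liquid-surface location requires >= 50 water molecules")
  bw <- params$density_bin
  edges <- seq(floor(min(wz) / bw) * bw, max(wz) + bw, by = bw)
  counts <- tabulate(findInterval(wz, edges), nbins = length(edges) - 1)
  qr <- stats::quantile(wz, c(0.1, 0.6), names = FALSE)
  centers <- edges[-length(edges)] + bw / 2
  central <- counts[centers >= qr[1] & centers <= qr[2]]
  plateau <- median(central)
  if (!is.finite(plateau) || plateau <= 0)
    stop("no bulk water density plateau detectable")
  above <- which(counts >= 0.5 * plateau)
  if (!length(above)) stop("no bulk water density plateau detectable")
  edges[max(above) + 1L]
}

#' Classify the sorption mode of every SOM molecule
#'
#' Priority order: VAPOR (centroid above z* + 2 shells), DIRECT (any
#' heavy atom within `d_direct` of a mineral atom), CATION_BRIDGED (a
#' cation within `d_cat_surf` of the mineral and within `d_cat_som` of
#' the molecule's O/N), SOM_BRIDGED (same graph component as a DIRECT or
#' CATION_BRIDGED molecule), INTERFACE (centroid within one shell of
#' z*), FREE otherwise. Each molecule receives exactly one label per
#' frame; the `bridging` flag tags sorbed molecules that anchor
#' non-sorbed neighbors (see [tag_bridging()]).
#'
#' @param frame A `maom_frame`.
#' @param topology A `maom_topology`.
#' @param clusters A `maom_cluster_assignment` for this frame.
#' @param graph The `maom_molecule_graph` used for `clusters`.
#' @param params A [sorption_params()] list.
#' @param z_star Optional precomputed liquid-surface height.
#' @return `data.frame` with columns `molecule_id`, `species_id`,
#'   `label`, `bridging`, `component`, `in_largest`.
#' @export
classify_sorption <- function(frame, topology, clusters, graph,
                              params = sorption_params(), z_star = NULL) {
  a <- frame$atoms
  som <- a[a$role == "SOM", , drop = FALSE]
  som_heavy <- som[som$is_heavy, , drop = FALSE]
  mineral <- a[a$role == "MINERAL", , drop = FALSE]
  cations <- a[a$role == "CATION", , drop = FALSE]
  mol_ids <- sort(unique(som$molecule_id))
  n <- length(mol_ids)

  if (is.null(z_star)) z_star <- locate_liquid_surface(frame, params)

  cen <- do.call(rbind, lapply(split(som[, c("x", "y", "z")],
                                     som$molecule_id),
                               colMeans))
  cen_ids <- as.integer(rownames(cen))
  centroid_z <- setNames(cen[, "z"], as.character(cen_ids))[as.character(mol_ids)]

  # DIRECT: any heavy atom within d_direct of any mineral atom
  direct <- logical(n)
  if (nrow(mineral) && nrow(som_heavy)) {
    p <- pairs_between(atom_coords(som_heavy), atom_coords(mineral),
                       frame$box, params$d_direct)
    direct <- mol_ids %in% unique(som_heavy$molecule_id[p$i])
  }

  # CATION_BRIDGED: a cation simultaneously near the slab and the
  # molecule's O/N atoms
  cation_br <- logical(n)
  if (nrow(cations) && nrow(mineral)) {
    pc <- pairs_between(atom_coords(cations), atom_coords(mineral),
                        frame$box, params$d_cat_surf)
    near_surf <- cations[unique(pc$i), , drop = FALSE]
    som_on <- som_heavy[som_heavy$element %in% c("O", "N"), , drop = FALSE]
    if (nrow(near_surf) && nrow(som_on)) {
      ps <- pairs_between(atom_coords(near_surf), atom_coords(som_on),
                          frame$box, params$d_cat_som)
      cation_br <- mol_ids %in% unique(som_on$molecule_id[ps$j])
    }
  }

  vapor <- centroid_z > z_star + 2 * params$interface_shell

  # SOM_BRIDGED: same component as a (non-vapor) directly/cation sorbed one
  comp <- clusters$membership[as.character(mol_ids)]
  sorbed_comp <- unique(comp[(direct | cation_br) & !vapor])
  som_bridged <- comp %in% sorbed_comp

  interface <- abs(centroid_z - z_star) <= params$interface_shell

  label <- rep("FREE", n)
  label[interface] <- "INTERFACE"
  label[som_bridged] <- "SOM_BRIDGED"
  label[cation_br] <- "CATION_BRIDGED"
  label[direct] <- "DIRECT"
  label[vapor] <- "VAPOR"

  out <- data.frame(
    molecule_id = mol_ids,
    species_id = topology$molecules$species_id[
      match(mol_ids, topology$molecules$molecule_id)],
    label = label,
    bridging = FALSE,
    component = as.integer(comp),
    in_largest = comp == clusters$largest_component,
    stringsAsFactors = FALSE)
  out$bridging <- out$molecule_id %in% tag_bridging(out, graph)
  out
}

#' Tag bridging molecules
#'
#' A molecule is bridging iff its label is DIRECT or CATION_BRIDGED and
#' it has at least one graph edge to a molecule that is neither DIRECT
#' nor CATION_BRIDGED: it anchors hydrophobically partitioned neighbors
#' to the surface.
#'
#' @param labels Classification data.frame from [classify_sorption()]
#'   (columns `molecule_id`, `label`).
#' @param graph The `maom_molecule_graph`.
#' @return Integer vector of bridging molecule ids.
#' @export
tag_bridging <- function(labels, graph) {
  sorbed <- labels$molecule_id[labels$label %in%
                               c("DIRECT", "CATION_BRIDGED")]
  if (!length(sorbed) || !nrow(graph$edges)) return(integer(0))
  lab_of <- setNames(labels$label, as.character(labels$molecule_id))
  e <- graph$edges
  out <- integer(0)
  li <- lab_of[as.character(e$i)]
  lj <- lab_of[as.character(e$j)]
  anchored_i <- e$i[li %in% c("DIRECT", "CATION_BRIDGED") &
                    !lj %in% c("DIRECT", "CATION_BRIDGED")]
  anchored_j <- e$j[lj %in% c("DIRECT", "CATION_BRIDGED") &
                    !li %in% c("DIRECT", "CATION_BRIDGED")]
  sort(unique(c(anchored_i, anchored_j)))
}

#' Adsorbed/desorbed percentages over frames
#'
#' Adsorbed = DIRECT + CATION_BRIDGED + SOM_BRIDGED; desorbed = FREE +
#' INTERFACE + VAPOR (interfacial molecules count as desorbed by
#' default; set `interface_adsorbed` to flip). Percentages are averaged
#' over frames and always sum to 100.
#'
#' @param labels_frames List of classification data.frames, one per
#'   frame.
#' @param interface_adsorbed Count INTERFACE molecules as adsorbed.
#' @return List with `adsorbed`, `desorbed` (percent) and `by_mode`
#'   (named percent vector over the six labels).
#' @export
adsorbed_percentage <- function(labels_frames, interface_adsorbed = FALSE) {
  if (!length(labels_frames)) stop("at least one frame is required")
  ads_modes <- c("DIRECT", "CATION_BRIDGED", "SOM_BRIDGED",
                 if (interface_adsorbed) "INTERFACE")
  per_frame <- vapply(labels_frames, function(lf) {
    mean(lf$label %in% ads_modes) * 100
  }, numeric(1))
  by_mode <- rowMeans(vapply(labels_frames, function(lf) {
    vapply(SORPTION_LEVELS, function(m) mean(lf$label == m) * 100,
           numeric(1))
  }, numeric(length(SORPTION_LEVELS))))
  list(adsorbed = mean(per_frame), desorbed = 100 - mean(per_frame),
       by_mode = setNames(by_mode, SORPTION_LEVELS))
}

#' Detect ligand-exchange-like coordination events
#'
#' Purely geometric detection on oxide-like slabs: a metal site reports
#' an event iff some SOM oxygen lies within `d_fe_o` of it while its
#' paired ligand-water oxygen lies farther than `d_fe_o`. No bond-order
#' claim is made.
#'
#' @param frame A `maom_frame`.
#' @param topology A `maom_topology` carrying `metal_ligand_pairs`.
#' @param params A [sorption_params()] list.
#' @return `data.frame` with columns `metal_atom_id`, `som_oxygen_id`,
#'   `dist` (one row per coordinating SOM oxygen).
#' @export
detect_ligand_exchange <- function(frame, topology,
                                   params = sorption_params()) {
  mlp <- topology$metal_ligand_pairs
  if (is.null(mlp) || !nrow(mlp))
    stop("slab has no metal-site/ligand-water annotation")
  a <- frame$atoms
  metals <- a[match(mlp$metal_atom_id, a$atom_id), , drop = FALSE]
  ligands <- a[match(mlp$ligand_atom_id, a$atom_id), , drop = FALSE]
  som_o <- a[a$role == "SOM" & a$element == "O", , drop = FALSE]
  empty <- data.frame(metal_atom_id = integer(0), som_oxygen_id = integer(0),
                      dist = numeric(0))
  if (!nrow(som_o)) return(empty)
  # per-pair metal-ligand distance
  dx <- metals$x - ligands$x; dy <- metals$y - ligands$y
  dz <- metals$z - ligands$z
  L <- c(frame$box$lx, frame$box$ly, frame$box$lz)
  if (frame$box$periodic[1]) dx <- dx - L[1] * round(dx / L[1])
  if (frame$box$periodic[2]) dy <- dy - L[2] * round(dy / L[2])
  if (frame$box$periodic[3]) dz <- dz - L[3] * round(dz / L[3])
  lig_far <- sqrt(dx^2 + dy^2 + dz^2) > params$d_fe_o
  cand <- metals[lig_far, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  p <- pairs_between(atom_coords(cand), atom_coords(som_o),
                     frame$box, params$d_fe_o)
  if (!nrow(p)) return(empty)
  data.frame(metal_atom_id = cand$atom_id[p$i],
             som_oxygen_id = som_o$atom_id[p$j],
             dist = p$dist)
}
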