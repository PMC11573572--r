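#' Contact-graph parameters
#'
#' @param r_c Heavy-atom SOM-SOM contact cutoff (Angstrom). The default
#'   3.5 is the conventional heavy-atom contact criterion.
#' @param include_divalent_bridges Add `DIVALENT_BRIDGE` edges between
#'   molecule pairs sharing a divalent cation coordinated (within
#'   `r_ion`) to an O/N atom of each.
#' @param r_ion Cation to SOM O/N cutoff (Angstrom).
#' @return List of class `maom_contact_params`.
#' @export
contact_params <- function(r_c = 3.5, include_divalent_bridges = FALSE,
                           r_ion = 3.0) {
  if (r_c <= 0 || r_ion <= 0) stop("cutoffs must be > 0")
  structure(list(r_c = r_c,
                 include_divalent_bridges = isTRUE(include_divalent_bridges),
                 r_ion = r_ion),
            class = "maom_contact_params")
}

#' Molecule-level contact graph
#'
#' Nodes are SOM molecules; a `CONTACT` edge joins molecules i and j iff
#' some heavy-atom pair (one atom in each) lies within `r_c` under the
#' minimum-image convention. Hydrogens are excluded. With
#' `include_divalent_bridges`, a `DIVALENT_BRIDGE` edge additionally
#' joins i and j iff a divalent cation lies within `r_ion` of an O/N
#' atom of each. Neighbor search uses a cell list and is exactly
#' equivalent to the brute-force pairwise scan.
#'
#' @param frame A `maom_frame`.
#' @param topology A `maom_topology`.
#' @param params A [contact_params()] list.
#' @return List of class `maom_molecule_graph` with elements `nodes`
#'   (0-based SOM molecule ids) and `edges` (data.frame `i`, `j`,
#'   `kind`; `i < j`).
#' @export
contact_graph <- function(frame, topology, params = contact_params()) {
  a <- frame$atoms
  som <- a[a$role == "SOM" & a$is_heavy, , drop = FALSE]
  nodes <- sort(unique(a$molecule_id[a$role == "SOM"]))
  edges <- data.frame(i = integer(0), j = integer(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (nrow(som) > 1) {
    p <- pairs_within(atom_coords(som), frame$box, params$r_c)
    if (nrow(p)) {
      mi <- som$molecule_id[p$i]
      mj <- som$molecule_id[p$j]
      keep <- mi != mj
      if (any(keep)) {
        lo <- pmin(mi[keep], mj[keep])
        hi <- pmax(mi[keep], mj[keep])
        uq <- !duplicated(paste(lo, hi))
        edges <- data.frame(i = lo[uq], j = hi[uq], kind = "CONTACT",
                            stringsAsFactors = FALSE)
      }
    }
  }
  if (params$include_divalent_bridges) {
    cat_div <- a[a$role == "CATION" & a$charge >= 2, , drop = FALSE]
    som_on <- som[som$element %in% c("O", "N"), , drop = FALSE]
    if (nrow(cat_div) && nrow(som_on)) {
      p <- pairs_between(atom_coords(cat_div), atom_coords(som_on),
                         frame$box, params$r_ion)
      if (nrow(p)) {
        per_cat <- split(som_on$molecule_id[p$j], p$i)
        bp <- unique(do.call(rbind, lapply(per_cat, function(mols) {
          mols <- sort(unique(mols))
          if (length(mols) < 2) return(NULL)
          t(utils::combn(mols, 2))
        })))
        if (!is.null(bp) && nrow(bp)) {
          have <- paste(edges$i, edges$j, edges$kind)
          new <- data.frame(i = bp[, 1], j = bp[, 2],
                            kind = "DIVALENT_BRIDGE",
                            stringsAsFactors = FALSE)
          new <- new[!paste(new$i, new$j, new$kind) %in% have, , drop = FALSE]
          edges <- rbind(edges, new)
        }
      }
    }
  }
  structure(list(nodes = nodes, edges = edges),
            class = "maom_molecule_graph")
}

#' Connected components of a molecule graph
#'
#' Union-find over all edges (both kinds). Component ids are the smallest
#' molecule id contained in each component; the largest component is the
#' one of maximal size, ties broken by the smallest contained molecule
#' id (which is the smallest component id).
#'
#' @param graph A `maom_molecule_graph`.
#' @return List of class `maom_cluster_assignment` with `membership`
#'   (named integer: molecule id -> component id), `sizes` (named by
#'   component id) and `largest_component` (component id).
#' @export
find_clusters <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  idx <- setNames(seq_len(n), as.character(nodes))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      ri <- find(idx[[as.character(graph$edges$i[e])]])
      rj <- find(idx[[as.character(graph$edges$j[e])]])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- nodes[roots]  # root has the smallest index = smallest molecule id
  membership <- setNames(as.integer(comp), as.character(nodes))
  sizes <- table(membership)
  sz <- as.integer(sizes)
  ids <- as.integer(names(sizes))
  best <- ids[sz == max(sz)]
  structure(list(membership = membership,
                 sizes = setNames(sz, names(sizes)),
                 largest_component = min(best)),
            class = "maom_cluster_assignment")
}

#' Per-species largest-cluster membership probability
#'
#' For each species, the fraction of (copy, frame) pairs found in the
#' largest cluster, over all supplied frames.
#'
#' @param assignments List of `maom_cluster_assignment`, one per frame.
#' @param topology A `maom_topology`.
#' @return Named numeric vector (names are species ids).
#' @export
largest_cluster_probability <- function(assignments, topology) {
  if (!length(assignments)) stop("at least one frame is required")
  mol <- topology$molecules
  som <- mol[!is.na(mol$species_id), , drop = FALSE]
  sp_ids <- sort(unique(som$species_id))
  hits <- setNames(numeric(length(sp_ids)), as.character(sp_ids))
  for (cl in assignments) {
    in_big <- cl$membership == cl$largest_component
    mids <- as.integer(names(cl$membership))[in_big]
    sp <- som$species_id[match(mids, som$molecule_id)]
    tb <- table(sp)
    hits[names(tb)] <- hits[names(tb)] + as.integer(tb)
  }
  copies <- table(som$species_id)
  denom <- as.numeric(copies[as.character(sp_ids)]) * length(assignments)
  hits / denom
}
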