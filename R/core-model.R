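#' @useDynLib maomtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd cor coef lm rnorm runif setNames
#' @importFrom utils read.csv write.csv head tail
NULL

ROLES <- c("MINERAL", "SOM", "WATER", "CATION")
SORPTION_LEVELS <- c("DIRECT", "CATION_BRIDGED", "SOM_BRIDGED",
                     "FREE", "INTERFACE", "VAPOR")

#' Default van der Waals radius table
#'
#' Bondi-style radii in Angstrom for the elements that occur in generated
#' scenes. Values for elements without a well-established Bondi radius
#' (Si, Al, Fe, Ca as an atom-in-solid) are conventional force-field-scale
#' stand-ins; the table is overridable per atom through the topology, and
#' every surface-area contract in this package is defined relative to
#' whatever table is in force.
#'
#' @return Named numeric vector of radii (Angstrom).
#' @export
vdw_radius_table <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    Na = 2.27, Ca = 2.31, Si = 2.10, Al = 1.84, Fe = 2.00, Mg = 1.73)
}

vdw_radius_for <- function(element) {
  tab <- vdw_radius_table()
  r <- unname(tab[element])
  r[is.na(r)] <- 1.70
  r
}

#' Construct an orthorhombic periodic box
#'
#' @param lx,ly,lz Box edge lengths in Angstrom (> 0).
#' @param periodic Logical vector of length 3; x and y must be periodic,
#'   z is configurable (slab geometries with a vapor gap typically use
#'   `c(TRUE, TRUE, FALSE)`).
#' @return An object of class `maom_box`.
#' @export
box <- function(lx, ly, lz, periodic = c(TRUE, TRUE, FALSE)) {
  stopifnot(is.numeric(lx), is.numeric(ly), is.numeric(lz),
            length(periodic) == 3, is.logical(periodic))
  if (!all(is.finite(c(lx, ly, lz))) || any(c(lx, ly, lz) <= 0))
    stop("box lengths must be finite and > 0")
  if (!periodic[1] || !periodic[2])
    stop("x and y axes must be periodic")
  structure(list(lx = lx, ly = ly, lz = lz,
                 periodic = as.logical(periodic)),
            class = "maom_box")
}

#' @export
print.maom_box <- function(x, ...) {
  cat(sprintf("<maom_box %.2f x %.2f x %.2f A, periodic = [%s]>\n",
              x$lx, x$ly, x$lz,
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  invisible(x)
}

#' Construct a frame (one atomic configuration)
#'
#' @param atoms `data.frame` with columns `atom_id` (0-based integer),
#'   `element`, `role` (one of MINERAL/SOM/WATER/CATION), `molecule_id`
#'   (0-based integer), `x`, `y`, `z` (Angstrom), `vdw_radius` (Angstrom),
#'   `is_heavy` (logical), `charge` (formal charge carried by the atom, e).
#' @param box A `maom_box`.
#' @param temperature Temperature tag in K.
#' @param frame_index Non-negative integer frame index.
#' @return An object of class `maom_frame`.
#' @export
frame <- function(atoms, box, temperature = 300, frame_index = 0L) {
  stopifnot(inherits(box, "maom_box"), is.data.frame(atoms))
  need <- c("atom_id", "element", "role", "molecule_id",
            "x", "y", "z", "vdw_radius", "is_heavy", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (frame_index < 0) stop("frame_index must be >= 0")
  structure(list(atoms = atoms, box = box,
                 temperature = temperature,
                 frame_index = as.integer(frame_index)),
            class = "maom_frame")
}

#' @export
print.maom_frame <- function(x, ...) {
  cat(sprintf("<maom_frame %d atoms, %d molecules, T = %g K, index %d>\n",
              nrow(x$atoms), length(unique(x$atoms$molecule_id)),
              x$temperature, x$frame_index))
  print(x$box)
  invisible(x)
}

#' Construct a species record
#'
#' Per-species chemistry driving all descriptors. Element counts refer to
#' the formula actually simulated (deprotonated forms for anions), so
#' half-integer double-bond-equivalent values are possible and expected for
#' odd-hydrogen anions.
#'
#' @param species_id Integer id (0-based).
#' @param name Species name.
#' @param C,H,N,O,S,P Element counts (>= 0).
#' @param formal_charge Formal charge in e, one of -2, -1, 0.
#' @param aromatic_ring_count,carboxylic_acid_count,n_amine_count
#'   Functional-group counts (supplied, not perceived from connectivity).
#' @param logp Optional octanol-water partition coefficient (pass-through).
#' @param is_peptide Logical; exactly one library species is a peptide.
#' @return A list of class `maom_species`.
#' @export
species_record <- function(species_id, name, C, H, N = 0, O = 0, S = 0, P = 0,
                           formal_charge = 0, aromatic_ring_count = 0,
                           carboxylic_acid_count = 0, n_amine_count = 0,
                           logp = NA_real_, is_peptide = FALSE) {
  counts <- c(C = C, H = H, N = N, O = O, S = S, P = P)
  if (any(counts < 0)) stop("element counts must be >= 0")
  if (!formal_charge %in% c(-2L, -1L, 0L))
    stop("formal_charge must be in {-2, -1, 0}")
  structure(list(species_id = as.integer(species_id), name = name,
                 C = as.integer(C), H = as.integer(H), N = as.integer(N),
                 O = as.integer(O), S = as.integer(S), P = as.integer(P),
                 formal_charge = as.integer(formal_charge),
                 aromatic_ring_count = as.integer(aromatic_ring_count),
                 carboxylic_acid_count = as.integer(carboxylic_acid_count),
                 n_amine_count = as.integer(n_amine_count),
                 logp = logp, is_peptide = isTRUE(is_peptide)),
            class = "maom_species")
}

#' Construct a topology
#'
#' @param molecules `data.frame` with columns `molecule_id` (0-based) and
#'   `species_id` (index into `species`; `NA` for water, cations and the
#'   mineral, which have no SOM species record).
#' @param species List of `maom_species` records.
#' @param metal_ligand_pairs Optional `data.frame` (`metal_atom_id`,
#'   `ligand_atom_id`) pairing oxide metal sites with their ligand-water
#'   oxygens, required by ligand-exchange detection.
#' @return An object of class `maom_topology`.
#' @export
topology <- function(molecules, species, metal_ligand_pairs = NULL) {
  stopifnot(is.data.frame(molecules),
            all(c("molecule_id", "species_id") %in% names(molecules)))
  sp_ids <- vapply(species, function(s) s$species_id, integer(1))
  if (anyDuplicated(sp_ids)) stop("duplicate species_id in species list")
  known <- molecules$species_id[!is.na(molecules$species_id)]
  if (length(known) && !all(known %in% sp_ids))
    stop("molecule references unknown species_id")
  structure(list(molecules = molecules,
                 species = setNames(species, as.character(sp_ids)),
                 metal_ligand_pairs = metal_ligand_pairs),
            class = "maom_topology")
}

species_by_id <- function(topo, id) topo$species[[as.character(id)]]

#' Species table of a topology
#'
#' Flattens the species records of a topology (or a plain species list)
#' into one row per species.
#'
#' @param x A `maom_topology` or a list of `maom_species`.
#' @return `data.frame`, one row per species.
#' @export
species_table <- function(x) {
  sp <- if (inherits(x, "maom_topology")) x$species else x
  do.call(rbind, lapply(sp, function(s) {
    data.frame(species_id = s$species_id, name = s$name,
               C = s$C, H = s$H, N = s$N, O = s$O, S = s$S, P = s$P,
               formal_charge = s$formal_charge,
               aromatic_ring_count = s$aromatic_ring_count,
               carboxylic_acid_count = s$carboxylic_acid_count,
               n_amine_count = s$n_amine_count,
               logp = s$logp, is_peptide = s$is_peptide,
               stringsAsFactors = FALSE)
  })) -> tab
  rownames(tab) <- NULL
  tab
}

#' Validate a frame/topology pair
#'
#' Reporting operation: returns a character vector of violations (empty iff
#' all structural invariants hold). Checked: finite coordinates, positive
#' radii, every atom assigned to a molecule known to the topology, molecule
#' membership consistency, atoms inside the box on periodic axes after
#' wrapping, valid roles.
#'
#' @param frame A `maom_frame`.
#' @param topology A `maom_topology`.
#' @return Character vector of human-readable violations.
#' @export
validate_system <- function(frame, topology) {
  a <- frame$atoms
  out <- character(0)
  if (!all(is.finite(c(a$x, a$y, a$z))))
    out <- c(out, "non-finite coordinates present")
  bad_r <- which(!is.finite(a$vdw_radius) | a$vdw_radius <= 0)
  if (length(bad_r))
    out <- c(out, sprintf("non-positive radius on atom %d", a$atom_id[bad_r]))
  if (anyDuplicated(a$atom_id))
    out <- c(out, "duplicate atom_id (overlapping molecule membership)")
  if (!all(a$role %in% ROLES))
    out <- c(out, sprintf("unknown role '%s'",
                          unique(a$role[!a$role %in% ROLES])))
  orphan <- setdiff(unique(a$molecule_id), topology$molecules$molecule_id)
  if (length(orphan))
    out <- c(out, sprintf("orphan atom: molecule %d not in topology", orphan))
  empty <- setdiff(topology$molecules$molecule_id, unique(a$molecule_id))
  if (length(empty))
    out <- c(out, sprintf("topology molecule %d has no atoms", empty))
  b <- frame$box
  L <- c(b$lx, b$ly, b$lz)
  for (ax in 1:3) {
    v <- a[[c("x", "y", "z")[ax]]]
    if (b$periodic[ax] && length(v) && (min(v) < -1e-9 || max(v) >= L[ax]))
      out <- c(out, sprintf("atoms outside box on periodic axis %s before wrapping",
                            c("x", "y", "z")[ax]))
  }
  out
}

#' Wrap a frame into the primary periodic cell
#'
#' Coordinates on periodic axes are mapped into `[0, L)`; non-periodic axes
#' are untouched. Idempotent.
#'
#' @param frame A `maom_frame`.
#' @return The wrapped frame.
#' @export
wrap_frame <- function(frame) {
  b <- frame$box
  L <- c(b$lx, b$ly, b$lz)
  for (ax in 1:3) {
    if (!b$periodic[ax]) next
    nm <- c("x", "y", "z")[ax]
    v <- frame$atoms[[nm]]
    v <- v - floor(v / L[ax]) * L[ax]
    # guard against v == L from floating-point round-off
    v[v >= L[ax]] <- 0
    frame$atoms[[nm]] <- v
  }
  frame
}

#' Minimum-image distance between two points
#'
#' @param a,b Numeric length-3 positions (Angstrom).
#' @param box A `maom_box`.
#' @return Distance in Angstrom, minimized over periodic images on
#'   periodic axes.
#' @export
minimum_image_distance <- function(a, b, box) {
  stopifnot(length(a) == 3, length(b) == 3, inherits(box, "maom_box"))
  d <- a - b
  L <- c(box$lx, box$ly, box$lz)
  for (ax in 1:3)
    if (box$periodic[ax]) d[ax] <- d[ax] - L[ax] * round(d[ax] / L[ax])
  sqrt(sum(d * d))
}

#' All atom pairs within a cutoff (one set)
#'
#' Cell-list neighbor search under the minimum-image convention. The
#' indices returned are row indices into the supplied coordinate matrix.
#'
#' @param coords n x 3 numeric matrix (Angstrom).
#' @param box A `maom_box`.
#' @param cutoff Distance cutoff (Angstrom); must be below half the
#'   smallest periodic box length.
#' @return `data.frame` with columns `i`, `j` (i < j) and `dist`.
#' @export
pairs_within <- function(coords, box, cutoff) {
  check_cutoff(box, cutoff)
  res <- cpp_pairs_within(coords[, 1], coords[, 2], coords[, 3],
                          box$lx, box$ly, box$lz,
                          box$periodic[1], box$periodic[2], box$periodic[3],
                          cutoff)
  data.frame(i = res$i, j = res$j, dist = res$dist)
}

#' All cross pairs within a cutoff (two sets)
#'
#' @param a,b n x 3 numeric matrices (Angstrom).
#' @inheritParams pairs_within
#' @return `data.frame` with columns `i` (row in `a`), `j` (row in `b`),
#'   `dist`.
#' @export
pairs_between <- function(a, b, box, cutoff) {
  check_cutoff(box, cutoff)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  res <- cpp_pairs_between(a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                           box$lx, box$ly, box$lz,
                           box$periodic[1], box$periodic[2], box$periodic[3],
                           cutoff)
  data.frame(i = res$i, j = res$j, dist = res$dist)
}

check_cutoff <- function(box, cutoff) {
  L <- c(box$lx, box$ly, box$lz)[box$periodic]
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (length(L) && cutoff >= min(L) / 2)
    stop(sprintf("cutoff %.3f A >= half the smallest periodic box length (%.3f A)",
                 cutoff, min(L) / 2))
  invisible(TRUE)
}

atom_coords <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

#' Total formal charge of a system
#'
#' Sum of per-atom formal charges (mineral charged sites, cations) plus
#' per-molecule species formal charges (SOM).
#'
#' @param frame A `maom_frame`.
#' @param topology A `maom_topology`.
#' @return Net charge in e.
#' @export
system_charge <- function(frame, topology) {
  q_atoms <- sum(frame$atoms$charge)
  mol <- topology$molecules
  som_mol <- mol[!is.na(mol$species_id), , drop = FALSE]
  q_som <- 0
  if (nrow(som_mol)) {
    q_som <- sum(vapply(som_mol$species_id,
                        function(id) species_by_id(topology, id)$formal_charge,
                        numeric(1)))
  }
  q_atoms + q_som
}
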