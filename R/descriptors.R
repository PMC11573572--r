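ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

#' Molecular mass from element counts
#'
#' Sum of element counts times standard atomic weights over C, H, N, O, S, P.
#'
#' @param species A `maom_species`.
#' @return Mass in Da.
#' @export
molecular_mass <- function(species) {
  counts <- c(C = species$C, H = species$H, N = species$N,
              O = species$O, S = species$S, P = species$P)
  sum(counts * ATOMIC_WEIGHTS[names(counts)])
}

#' Double bond equivalents
#'
#' Standard CHN formula `DBE = C - H/2 + N/2 + 1`; O, S and P are treated
#' as divalent/trivalent-neutral and contribute nothing. Applied to the
#' simulated (possibly deprotonated) formula, so anions with odd hydrogen
#' counts yield half-integer values.
#'
#' @param species A `maom_species` with `C >= 1`.
#' @return Dimensionless degrees of unsaturation.
#' @export
dbe <- function(species) {
  if (species$C < 1) stop("DBE requires C >= 1")
  species$C - species$H / 2 + species$N / 2 + 1
}

#' van Krevelen atomic ratios
#'
#' @param species A `maom_species` with `C >= 1`.
#' @return Named numeric vector `c(o_to_c, h_to_c)`.
#' @export
van_krevelen <- function(species) {
  if (species$C < 1) stop("van Krevelen ratios require C >= 1")
  c(o_to_c = species$O / species$C, h_to_c = species$H / species$C)
}

#' SASA parameters
#'
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points Number of quasi-uniform sphere points per atom
#'   (Fibonacci lattice; deterministic).
#' @return List of class `maom_sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960L) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 32) stop("n_sphere_points must be >= 32")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "maom_sasa_params")
}

# Quasi-uniform unit sphere points (golden-angle Fibonacci spiral);
# deterministic.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (3 - sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Point-sampling SASA on heavy atoms only: for each heavy atom, the
#' fraction of sphere points at the probe-expanded radius that fall inside no
#' other heavy atom's expanded sphere, times the expanded-sphere area.
#' Hydrogens contribute neither area nor occlusion. Polar area is the sum
#' over O and N atoms; apolar is everything else; total = polar + apolar
#' by partition.
#'
#' @param coords n x 3 matrix of atom positions (Angstrom).
#' @param radii Per-atom van der Waals radii (Angstrom).
#' @param elements Per-atom element symbols.
#' @param params A [sasa_params()] list.
#' @return Named numeric vector `c(total, polar, apolar)` in square
#'   Angstrom.
#' @export
shrake_rupley_sasa <- function(coords, radii, elements,
                               params = sasa_params()) {
  stopifnot(nrow(coords) == length(radii), length(radii) == length(elements))
  heavy <- elements != "H"
  if (!any(heavy)) stop("SASA requires at least one heavy atom")
  coords <- coords[heavy, , drop = FALSE]
  radii <- radii[heavy]
  elements <- elements[heavy]
  n <- nrow(coords)
  pts <- fibonacci_sphere(params$n_sphere_points)
  expanded <- radii + params$probe_radius
  per_atom <- numeric(n)
  eps <- 1e-8  # boundary shell: point-on-sphere ties resolve by index
  for (i in seq_len(n)) {
    sp <- sweep(pts * expanded[i], 2, coords[i, ], `+`)
    exposed <- rep(TRUE, nrow(sp))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (sp[, 1] - coords[j, 1])^2 + (sp[, 2] - coords[j, 2])^2 +
            (sp[, 3] - coords[j, 3])^2
      occluded <- d2 < (expanded[j] - eps)^2
      if (j < i)
        occluded <- occluded | d2 <= (expanded[j] + eps)^2
      exposed <- exposed & !occluded
      if (!any(exposed)) break
    }
    per_atom[i] <- mean(exposed) * 4 * pi * expanded[i]^2
  }
  polar <- sum(per_atom[elements %in% c("O", "N")])
  apolar <- sum(per_atom[!elements %in% c("O", "N")])
  c(total = polar + apolar, polar = polar, apolar = apolar)
}

#' Per-species descriptor table
#'
#' Assembles the full cheminformatic descriptor table for a species
#' library: mass, formal charge, DBE, functional-group counts, van
#' Krevelen ratios and polar/apolar SASA computed on each species'
#' template geometry (in isolation, no periodic images).
#'
#' @param library A species library as returned by
#'   [default_species_library()] (list with `species` and `templates`).
#' @param params A [sasa_params()] list.
#' @return `data.frame`, one row per species.
#' @export
species_descriptor_table <- function(library, params = sasa_params()) {
  tab <- species_table(library$species)
  tab$mass <- vapply(library$species, molecular_mass, numeric(1))
  tab$dbe <- vapply(library$species, dbe, numeric(1))
  vk <- t(vapply(library$species, van_krevelen, numeric(2)))
  tab$o_to_c <- vk[, "o_to_c"]
  tab$h_to_c <- vk[, "h_to_c"]
  sas <- t(vapply(seq_along(library$species), function(i) {
    tpl <- library$templates[[i]]
    shrake_rupley_sasa(tpl$coords, vdw_radius_for(tpl$elements),
                       tpl$elements, params)
  }, numeric(3)))
  tab$total_sasa <- sas[, 1]
  tab$polar_sasa <- sas[, 2]
  tab$apolar_sasa <- sas[, 3]
  tab
}
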