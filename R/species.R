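# Run code under a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Deterministic self-avoiding 3D blob: heavy atoms grown by branching
# random insertion, bond length 1.5 A, minimum pair distance 1.2 A,
# confined to a sphere of radius `rmax`. Chemistry is carried by the
# species record, not the geometry; these are abstract compact shapes.
blob_template <- function(n_heavy, seed, rmax = 4.0, rmax_centered = 4.3,
                          bond = 1.5, min_dist = 1.2) {
  with_local_seed(seed, {
    for (round in 1:100) {
      pts <- matrix(0, nrow = n_heavy, ncol = 3)
      k <- 1L
      ok <- TRUE
      while (k < n_heavy) {
        placed <- FALSE
        for (t in 1:500) {
          base <- pts[sample.int(k, 1L), ]
          u <- rnorm(3)
          u <- u / sqrt(sum(u * u))
          cand <- base + bond * u
          if (sqrt(sum(cand * cand)) > rmax) next
          d2 <- (pts[1:k, 1] - cand[1])^2 + (pts[1:k, 2] - cand[2])^2 +
                (pts[1:k, 3] - cand[3])^2
          if (min(d2) >= min_dist^2) {
            k <- k + 1L
            pts[k, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
      pts <- sweep(pts, 2, colMeans(pts))
      # hard radius cap keeps every placement-margin argument valid
      if (max(sqrt(rowSums(pts^2))) <= rmax_centered) return(pts)
    }
    stop("blob template generation failed")
  })
}

# name, C, H, N, O, S, P, q, aromatic rings, COOH, amine N, logP, mass (Da)
SPECIES_DEF <- list(
  list("pyruvate",           3,  3, 0, 3, 0, 0, -1, 0, 1, 0, -0.5,  87.054),
  list("glycerol",           3,  8, 0, 3, 0, 0,  0, 0, 0, 0, -1.8,  92.094),
  list("succinate",          4,  4, 0, 4, 0, 0, -2, 0, 2, 0, -0.6, 116.072),
  list("catechol",           6,  6, 0, 2, 0, 0,  0, 1, 0, 0,  0.9, 110.112),
  list("benzoate",           7,  5, 0, 2, 0, 0, -1, 1, 1, 0,  1.9, 121.115),
  list("salicylate",         7,  5, 0, 3, 0, 0, -1, 1, 1, 0,  2.3, 137.114),
  list("indole",             8,  7, 1, 0, 0, 0,  0, 2, 0, 0,  2.1, 117.151),
  list("vanillin",           8,  8, 0, 3, 0, 0,  0, 1, 0, 0,  1.2, 152.149),
  list("pyridoxine",         8, 11, 1, 3, 0, 0,  0, 1, 0, 0, -0.8, 169.180),
  list("coumarate",          9,  7, 0, 3, 0, 0, -1, 1, 1, 0,  1.5, 163.152),
  list("glucose",            6, 12, 0, 6, 0, 0,  0, 0, 0, 0, -3.2, 180.156),
  list("gallate",            7,  5, 0, 5, 0, 0, -1, 1, 1, 0,  0.7, 169.112),
  list("ferulate",          10,  9, 0, 4, 0, 0, -1, 1, 1, 0,  1.5, 193.178),
  list("glycylcysteine",     5, 10, 2, 3, 1, 0,  0, 0, 1, 1, -2.9, 178.206),
  list("laurate",           12, 23, 0, 2, 0, 0, -1, 0, 1, 0,  4.2, 199.314),
  list("glucuronate",        6,  9, 0, 7, 0, 0, -1, 0, 1, 0, -2.6, 193.131),
  list("n-acetylglucosamine",8, 15, 1, 6, 0, 0,  0, 0, 0, 0, -2.1, 221.209),
  list("sinapate",          11, 11, 0, 5, 0, 0, -1, 1, 1, 0,  1.3, 223.204),
  list("naringenin",        15, 12, 0, 5, 0, 0,  0, 2, 0, 0,  2.5, 272.256),
  list("catechin",          15, 14, 0, 6, 0, 0,  0, 2, 0, 0,  0.4, 290.271)
)

#' Default synthetic SOM species library
#'
#' Twenty dissolved-organic-matter-like species spanning roughly 87-290 Da
#' with formal charges in \{-2, -1, 0\} (deprotonated formulas for the
#' anions), one zwitterionic dipeptide species (glycylcysteine, net
#' neutral), and per-species template geometries: deterministic
#' self-avoiding heavy-atom blobs with 1.5 A bond spacing and a 1.2 A
#' minimum pair distance. The `mass` field stores the literature formula
#' mass and is independently reproducible from the element counts via
#' [molecular_mass()].
#'
#' Chemistry (ring, carboxylate and amine counts, logP) is supplied as
#' record fields, not perceived from geometry; the templates carry shape
#' only.
#'
#' @return List with elements `species` (list of 20 `maom_species`, each
#'   with a stored `mass`) and `templates` (per-species list with
#'   `coords`, `elements`, `radius`).
#' @export
default_species_library <- function() {
  species <- vector("list", length(SPECIES_DEF))
  templates <- vector("list", length(SPECIES_DEF))
  for (i in seq_along(SPECIES_DEF)) {
    d <- SPECIES_DEF[[i]]
    s <- species_record(i - 1L, d[[1]], C = d[[2]], H = d[[3]], N = d[[4]],
                        O = d[[5]], S = d[[6]], P = d[[7]],
                        formal_charge = d[[8]], aromatic_ring_count = d[[9]],
                        carboxylic_acid_count = d[[10]],
                        n_amine_count = d[[11]], logp = d[[12]],
                        is_peptide = identical(d[[1]], "glycylcysteine"))
    s$mass <- d[[13]]
    species[[i]] <- s
    n_heavy <- d[[2]] + d[[4]] + d[[5]] + d[[6]] + d[[7]]
    coords <- blob_template(n_heavy, seed = 7000L + i)
    elements <- c(rep("C", d[[2]]), rep("N", d[[4]]), rep("O", d[[5]]),
                  rep("S", d[[6]]), rep("P", d[[7]]))
    templates[[i]] <- list(coords = coords, elements = elements,
                           radius = max(sqrt(rowSums(coords^2))))
  }
  list(species = species, templates = templates)
}

#' Default scene composition
#'
#' Four copies of each non-peptide species plus eight copies of the
#' peptide: 84 molecules in total over the 20-species library.
#'
#' @param library A species library (see [default_species_library()]).
#' @return Integer vector of species ids (0-based), one entry per
#'   molecule to place.
#' @export
default_composition <- function(library = default_species_library()) {
  ids <- vapply(library$species, function(s) s$species_id, integer(1))
  pep <- vapply(library$species, function(s) s$is_peptide, logical(1))
  rep(ids, times = ifelse(pep, 8L, 4L))
}

#' Replica temperature ladder
#'
#' Inclusive arithmetic ladder from `t_min` to `t_max` in steps of `dt`.
#'
#' @param t_min,t_max Temperatures in K (`t_max >= t_min`).
#' @param dt Step in K (> 0); `(t_max - t_min)` must be divisible by `dt`.
#' @return Numeric vector of temperatures.
#' @export
temperature_ladder <- function(t_min = 300, t_max = 335, dt = 5) {
  if (dt <= 0) stop("dt must be > 0")
  if (t_max < t_min) stop("t_max must be >= t_min")
  k <- (t_max - t_min) / dt
  if (abs(k - round(k)) > 1e-9)
    stop("(t_max - t_min) must be divisible by dt")
  t_min + dt * (0:round(k))
}
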