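# Independent oracles used against the package implementations.

# Minimum-image distance by explicit enumeration of the 27 neighbor images.
bf_min_image <- function(a, b, box) {
  L <- c(box$lx, box$ly, box$lz)
  sx <- if (box$periodic[1]) -1:1 else 0
  sy <- if (box$periodic[2]) -1:1 else 0
  sz <- if (box$periodic[3]) -1:1 else 0
  best <- Inf
  for (i in sx) for (j in sy) for (k in sz) {
    d <- a - (b + c(i, j, k) * L)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# All pairs within cutoff by an O(N^2) vectorized scan (per-axis minimum
# image, exact for orthorhombic boxes).
bf_pairs <- function(coords, box, cutoff) {
  n <- nrow(coords)
  L <- c(box$lx, box$ly, box$lz)
  d2 <- matrix(0, n, n)
  for (ax in 1:3) {
    d <- outer(coords[, ax], coords[, ax], `-`)
    if (box$periodic[ax]) d <- d - L[ax] * round(d / L[ax])
    d2 <- d2 + d * d
  }
  idx <- which(d2 <= cutoff^2 & upper.tri(d2), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

# Connected components by BFS from every node.
bf_components <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), as.character(nodes))
  for (r in seq_len(nrow(edges))) {
    i <- as.character(edges$i[r]); j <- as.character(edges$j[r])
    adj[[i]] <- c(adj[[i]], edges$j[r])
    adj[[j]] <- c(adj[[j]], edges$i[r])
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), as.character(nodes))
  for (start in nodes) {
    if (!is.na(comp[as.character(start)])) next
    queue <- start
    seen <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[as.character(v)]]
      new <- setdiff(nb, seen)
      seen <- c(seen, new)
      queue <- c(queue, new)
    }
    comp[as.character(seen)] <- min(seen)
  }
  comp
}

# Spearman by explicit average ranks and the Pearson formula.
naive_spearman <- function(x, y) {
  avg_rank <- function(v)
    vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))
  rx <- avg_rank(x); ry <- avg_rank(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

# Exposed area of sphere 1 of two overlapping spheres (radii r1, r2,
# center distance d): full area minus the spherical cap hidden inside
# sphere 2.
two_sphere_exposed <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# Monte-Carlo nearest-site area fractions on the periodic rectangle.
mc_role_fractions <- function(xy, roles, lx, ly, n_points, seed) {
  set.seed(seed)
  px <- runif(n_points, 0, lx)
  py <- runif(n_points, 0, ly)
  shifts <- expand.grid(sx = c(-1, 0, 1), sy = c(-1, 0, 1))
  sx <- rep(xy[, 1], times = nrow(shifts)) +
    rep(shifts$sx, each = nrow(xy)) * lx
  sy <- rep(xy[, 2], times = nrow(shifts)) +
    rep(shifts$sy, each = nrow(xy)) * ly
  owner_role <- rep(roles, times = nrow(shifts))
  best <- rep(Inf, n_points)
  own <- integer(n_points)
  for (s in seq_along(sx)) {
    d2 <- (px - sx[s])^2 + (py - sy[s])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    own[upd] <- s
  }
  tapply(rep(1, n_points), owner_role[own], sum) / n_points
}

# Construct a frame of single-heavy-atom molecules at given positions.
point_molecule_frame <- function(xyz, box, roles = "SOM",
                                 elements = "C", charges = 0,
                                 species_ids = NA_integer_) {
  n <- nrow(xyz)
  roles <- rep_len(roles, n)
  elements <- rep_len(elements, n)
  charges <- rep_len(charges, n)
  species_ids <- rep_len(species_ids, n)
  atoms <- data.frame(
    atom_id = seq_len(n) - 1L, element = elements, role = roles,
    molecule_id = seq_len(n) - 1L,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw_radius = maomtools::vdw_radius_table()[elements],
    is_heavy = elements != "H", charge = charges,
    stringsAsFactors = FALSE)
  sp <- lapply(sort(unique(species_ids[!is.na(species_ids)])), function(s)
    species_record(s, paste0("sp", s), C = 1, H = 0))
  topo <- topology(
    data.frame(molecule_id = seq_len(n) - 1L, species_id = species_ids),
    sp)
  list(frame = frame(atoms, box), topology = topo)
}
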