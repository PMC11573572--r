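#' Assign non-mineral atoms to discrete layers above the mineral surface
#'
#' Bins the z-density profile of non-mineral heavy atoms above the top
#' mineral plane and places layer boundaries at successive resolvable
#' density minima (a smoothed valley falling below half of both flanking
#' peaks). When fewer than `n_layers` minima are resolvable -- e.g. for
#' unstructured uniform fluids -- fixed `fallback_width` bands are used
#' instead and flagged.
#'
#' @param frame A `maom_frame`.
#' @param topology A `maom_topology` (unused for membership, kept for
#'   interface symmetry).
#' @param n_layers Number of layers to return.
#' @param density_bin Histogram bin width (Angstrom).
#' @param fallback_width Fixed band width when minima are unresolvable.
#' @return List of class `maom_layer_assignment`: `layers` (list of
#'   atom-id vectors), `bounds` (matrix with `lo`/`hi` per layer),
#'   `fallback` (logical).
#' @export
assign_layers <- function(frame, topology, n_layers = 4L,
                          density_bin = 0.2, fallback_width = 3.0) {
  a <- frame$atoms
  mineral_z <- a$z[a$role == "MINERAL"]
  if (!length(mineral_z)) stop("no mineral slab present")
  z_top <- max(mineral_z)
  above <- a[a$role != "MINERAL" & a$is_heavy & a$z > z_top, , drop = FALSE]
  if (!nrow(above)) stop("no atoms above the mineral surface")

  span <- min(max(above$z - z_top), n_layers * fallback_width * 2.5)
  edges <- seq(0, span + density_bin, by = density_bin)
  h <- above$z - z_top
  counts <- tabulate(findInterval(h[h <= span], edges),
                     nbins = length(edges) - 1)
  sm <- smooth_counts(counts)

  boundaries <- resolvable_minima(sm, edges)
  fallback <- length(boundaries) < n_layers
  if (fallback) {
    bounds <- cbind(lo = z_top + fallback_width * (seq_len(n_layers) - 1),
                    hi = z_top + fallback_width * seq_len(n_layers))
  } else {
    cuts <- c(0, boundaries[seq_len(n_layers)])
    bounds <- cbind(lo = z_top + cuts[-length(cuts)],
                    hi = z_top + cuts[-1])
  }
  layers <- lapply(seq_len(n_layers), function(k) {
    sel <- above$z > bounds[k, "lo"] & above$z <= bounds[k, "hi"]
    above$atom_id[sel]
  })
  structure(list(layers = layers, bounds = bounds, fallback = fallback,
                 z_top = z_top),
            class = "maom_layer_assignment")
}

smooth_counts <- function(counts) {
  n <- length(counts)
  if (n < 3) return(counts)
  c(counts[1],
    (counts[-c(n - 1, n)] + counts[-c(1, n)] + counts[-c(1, 2)]) / 3,
    counts[n])
}

# positions (in z above the surface) of valleys resolvable as layer
# boundaries: a smoothed local minimum below half of the peak since the
# previous boundary, below half of the tallest remaining peak (or the
# trailing decay to zero after the last peak), and below half of the
# typical occupied level -- the last clause keeps Poisson noise in
# unstructured fluids from faking layer structure
resolvable_minima <- function(sm, edges) {
  n <- length(sm)
  if (n < 5) return(numeric(0))
  bw <- edges[2] - edges[1]
  typical <- median(sm[sm > 0])
  out <- numeric(0)
  seg_start <- 1L
  i <- 2L
  while (i <= n) {
    left_peak <- max(sm[seg_start:(i - 1)])
    right_peak <- if (i < n) max(sm[(i + 1):n]) else 0
    is_min <- sm[i] <= sm[i - 1] && (i == n || sm[i] <= sm[i + 1])
    if (is_min && left_peak > 0 && sm[i] < 0.5 * left_peak &&
        sm[i] < 0.5 * typical &&
        (right_peak <= sm[i] || sm[i] < 0.5 * right_peak)) {
      out <- c(out, edges[i] + bw / 2)
      while (i < n && sm[i + 1] < 0.5 * left_peak) i <- i + 1L
      seg_start <- i
    }
    i <- i + 1L
  }
  out
}

# --- periodic 2D Voronoi ----------------------------------------------------

# Sutherland-Hodgman clip of polygon `poly` (n x 2) by the half-plane of
# points closer to `p` than to `q`.
clip_halfplane <- function(poly, p, q) {
  m <- (p + q) / 2
  nvec <- q - p
  d <- (poly[, 1] - m[1]) * nvec[1] + (poly[, 2] - m[2]) * nvec[2]
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(NULL)
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * (y[c(2:length(y), 1)]) - y * (x[c(2:length(x), 1)]))) / 2
}

#' Periodic 2D Voronoi cell areas
#'
#' Computes the Voronoi cell area of each site in a periodic rectangle
#' by replicating the sites in the 3x3 image tile and clipping each
#' central-copy cell by the perpendicular bisectors with every other
#' site. First-ring image bisectors bound every cell inside half a box
#' length per axis, so 3x3 replication is exact; the cell areas sum to
#' `lx * ly`.
#'
#' @param xy n x 2 matrix of site positions in `[0, lx) x [0, ly)`.
#' @param lx,ly Rectangle edge lengths.
#' @return Numeric vector of cell areas.
#' @export
voronoi_cell_areas <- function(xy, lx, ly) {
  n <- nrow(xy)
  if (n == 0) return(numeric(0))
  # coincident sites (e.g. vertically stacked atoms projected to the same
  # point) share one cell: tessellate unique sites, split the area evenly
  key <- paste(round(xy[, 1] * 1e8), round(xy[, 2] * 1e8))
  if (anyDuplicated(key)) {
    uq <- !duplicated(key)
    areas_u <- voronoi_cell_areas(xy[uq, , drop = FALSE], lx, ly)
    names(areas_u) <- key[uq]
    mult <- table(key)
    return(unname(areas_u[key] / as.numeric(mult[key])))
  }
  shifts <- expand.grid(sx = c(-1, 0, 1), sy = c(-1, 0, 1))
  all_xy <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
    cbind(xy[, 1] + shifts$sx[s] * lx, xy[, 2] + shifts$sy[s] * ly)
  }))
  H <- max(lx, ly)
  areas <- numeric(n)
  # central copy occupies the (0, 0) shift block
  central0 <- which(shifts$sx == 0 & shifts$sy == 0)
  offset <- (central0 - 1L) * n
  for (i in seq_len(n)) {
    site <- xy[i, ]
    d2 <- (all_xy[, 1] - site[1])^2 + (all_xy[, 2] - site[2])^2
    ord <- order(d2)
    poly <- matrix(c(site[1] - H, site[2] - H,
                     site[1] + H, site[2] - H,
                     site[1] + H, site[2] + H,
                     site[1] - H, site[2] + H), ncol = 2, byrow = TRUE)
    for (k in ord) {
      if (k == offset + i) next   # the site itself
      dk <- d2[k]
      if (dk == 0) next           # coincident site: shared cell, keep first
      # a bisector at distance sqrt(dk)/2 cannot cut the polygon if it is
      # farther than the farthest current vertex
      rmax2 <- max((poly[, 1] - site[1])^2 + (poly[, 2] - site[2])^2)
      if (dk / 4 > rmax2) break
      poly <- clip_halfplane(poly, site, all_xy[k, ])
      if (is.null(poly) || nrow(poly) < 3) { poly <- NULL; break }
    }
    areas[i] <- if (is.null(poly)) 0 else shoelace_area(poly)
  }
  areas
}

#' Area coverage of one atomic layer
#'
#' Projects the layer's atoms to the x-y plane, tessellates periodically
#' ([voronoi_cell_areas()]) and attributes each cell's area to the owning
#' atom's role. Fractions are areas over `lx * ly`; count-weighted
#' fractions are also reported.
#'
#' @param frame A `maom_frame`.
#' @param topology A `maom_topology` (interface symmetry; roles come from
#'   the atoms table).
#' @param layer_atom_ids Atom ids of the layer (non-mineral heavy atoms).
#' @return One-row `data.frame`: `fraction_water`, `fraction_ion`,
#'   `fraction_som`, `count_water`, `count_ion`, `count_som`,
#'   `n_atoms`, `empty`.
#' @export
layer_coverage <- function(frame, topology, layer_atom_ids) {
  a <- frame$atoms
  sel <- a[match(layer_atom_ids, a$atom_id), , drop = FALSE]
  sel <- sel[sel$role %in% c("WATER", "CATION", "SOM") & sel$is_heavy, ,
             drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(fraction_water = 0, fraction_ion = 0, fraction_som = 0,
                      count_water = 0, count_ion = 0, count_som = 0,
                      n_atoms = 0L, empty = TRUE))
  }
  lx <- frame$box$lx; ly <- frame$box$ly
  xy <- cbind(sel$x %% lx, sel$y %% ly)
  areas <- voronoi_cell_areas(xy, lx, ly)
  total <- lx * ly
  frac <- function(role) sum(areas[sel$role == role]) / total
  cnt <- function(role) mean(sel$role == role)
  data.frame(fraction_water = frac("WATER"), fraction_ion = frac("CATION"),
             fraction_som = frac("SOM"),
             count_water = cnt("WATER"), count_ion = cnt("CATION"),
             count_som = cnt("SOM"),
             n_atoms = nrow(sel), empty = FALSE)
}

#' Coverage of the first N layers of a frame
#'
#' Convenience wrapper: [assign_layers()] then [layer_coverage()] per
#' layer.
#'
#' @inheritParams assign_layers
#' @return `data.frame` with one row per layer plus columns `layer` and
#'   `fallback`.
#' @export
surface_coverage <- function(frame, topology, n_layers = 4L,
                             density_bin = 0.2, fallback_width = 3.0) {
  la <- assign_layers(frame, topology, n_layers, density_bin, fallback_width)
  out <- do.call(rbind, lapply(seq_len(n_layers), function(k) {
    cbind(layer = k, layer_coverage(frame, topology, la$layers[[k]]))
  }))
  out$fallback <- la$fallback
  out
}
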