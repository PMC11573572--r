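#' Classify every frame of a trajectory
#'
#' Runs contact graph, clustering and sorption classification on each
#' frame and returns the per-frame label tables plus cluster
#' assignments.
#'
#' @param frames List of `maom_frame`s.
#' @param topology A `maom_topology`.
#' @param cparams A [contact_params()] list.
#' @param sparams A [sorption_params()] list.
#' @return List with `labels` (list of data.frames), `clusters` (list of
#'   assignments), `graphs` (list of molecule graphs).
#' @export
classify_trajectory <- function(frames, topology,
                                cparams = contact_params(),
                                sparams = sorption_params()) {
  out <- lapply(frames, function(fr) {
    g <- contact_graph(fr, topology, cparams)
    cl <- find_clusters(g)
    lab <- classify_sorption(fr, topology, cl, g, sparams)
    list(labels = lab, clusters = cl, graph = g)
  })
  list(labels = lapply(out, `[[`, "labels"),
       clusters = lapply(out, `[[`, "clusters"),
       graphs = lapply(out, `[[`, "graph"))
}

#' Per-species bridging probability over frames
#'
#' Fraction of (copy, frame) pairs tagged as bridging.
#'
#' @param labels_frames List of classification data.frames.
#' @return Named numeric vector (names are species ids).
#' @export
bridging_probability <- function(labels_frames) {
  if (!length(labels_frames)) stop("at least one frame is required")
  all_lab <- do.call(rbind, labels_frames)
  sp <- sort(unique(all_lab$species_id))
  vapply(sp, function(s) {
    sel <- all_lab$species_id == s
    mean(all_lab$bridging[sel])
  }, numeric(1)) -> p
  setNames(p, as.character(sp))
}

#' Run the full demo pipeline on one preset
#'
#' Generate a labeled scene, jitter a short pseudo-trajectory, classify
#' every frame, compute per-layer surface coverage, assemble the species
#' descriptor table, join the clustering/bridging probabilities,
#' correlate, and write the report. Deterministic under a fixed seed.
#'
#' @param out_dir Output directory.
#' @param preset Scene preset name (see [scene_preset()]).
#' @param seed Integer seed.
#' @param n_frames Number of jittered frames.
#' @param sigma Jitter amplitude (Angstrom).
#' @return Invisibly, a list with the scene, per-frame labels, coverage,
#'   descriptor table and correlations.
#' @export
run_demo_pipeline <- function(out_dir, preset = "na-smectite", seed = 1,
                              n_frames = 3, sigma = 0.1) {
  scene <- build_scene(scene_preset(preset, seed = seed))
  frames <- jitter_trajectory(scene, n_frames = n_frames, sigma = sigma,
                              seed = seed + 1L)
  cls <- classify_trajectory(frames, scene$topology)

  coverage <- do.call(rbind, lapply(seq_along(frames), function(k) {
    cbind(frame = k - 1L,
          surface_coverage(frames[[k]], scene$topology))
  }))

  lib <- scene$spec$library
  desc <- species_descriptor_table(lib)
  cp <- largest_cluster_probability(cls$clusters, scene$topology)
  bp <- bridging_probability(cls$labels)
  desc$cluster_probability <- as.numeric(cp[as.character(desc$species_id)])
  desc$bridging_probability <- as.numeric(bp[as.character(desc$species_id)])
  correlations <- correlate_features(desc)

  ads <- adsorbed_percentage(cls$labels)
  summary <- list(
    species = desc,
    adsorption = c(adsorbed = ads$adsorbed, desorbed = ads$desorbed,
                   ads$by_mode),
    coverage = coverage)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scene(scene, file.path(out_dir, "scene"))
  labels_all <- do.call(rbind, lapply(seq_along(cls$labels), function(k)
    cbind(frame = k - 1L, cls$labels[[k]])))
  write.csv(labels_all, file.path(out_dir, "labels.csv"), row.names = FALSE)
  write_report(summary, correlations, out_dir,
               manifest = list(preset = preset, seed = seed,
                               n_frames = n_frames, sigma = sigma))
  invisible(list(scene = scene, labels = cls$labels, coverage = coverage,
                 descriptors = desc, correlations = correlations,
                 adsorption = ads))
}

#' Per-species descriptor table from an on-disk configuration
#'
#' Like [species_descriptor_table()], but the SASA geometry comes from
#' the first placed copy of each species in the frame rather than from
#' library templates, so it works on any configuration read from disk.
#'
#' @param frame A `maom_frame`.
#' @param topology A `maom_topology`.
#' @param params A [sasa_params()] list.
#' @return `data.frame`, one row per species present in the topology.
#' @export
frame_descriptor_table <- function(frame, topology,
                                   params = sasa_params()) {
  mol <- topology$molecules
  present <- unique(mol$species_id[!is.na(mol$species_id)])
  tab <- species_table(topology)
  tab <- tab[tab$species_id %in% present, , drop = FALSE]
  rownames(tab) <- NULL
  species <- topology$species[as.character(tab$species_id)]
  tab$mass <- vapply(species, molecular_mass, numeric(1))
  tab$dbe <- vapply(species, dbe, numeric(1))
  vk <- t(vapply(species, van_krevelen, numeric(2)))
  tab$o_to_c <- vk[, "o_to_c"]
  tab$h_to_c <- vk[, "h_to_c"]
  a <- frame$atoms
  sas <- t(vapply(tab$species_id, function(sid) {
    mid <- mol$molecule_id[!is.na(mol$species_id) & mol$species_id == sid][1]
    sel <- a[a$molecule_id == mid, , drop = FALSE]
    shrake_rupley_sasa(atom_coords(sel), sel$vdw_radius, sel$element, params)
  }, numeric(3)))
  tab$total_sasa <- sas[, 1]
  tab$polar_sasa <- sas[, 2]
  tab$apolar_sasa <- sas[, 3]
  tab
}

# read a scene directory written by the `generate` subcommand:
# topology.json plus either frame_*.gro or scene.gro
read_frames_dir <- function(dir) {
  tp <- read_topology_json(file.path(dir, "topology.json"))
  paths <- sort(list.files(dir, pattern = "^frame_.*\\.gro$",
                           full.names = TRUE))
  if (!length(paths)) paths <- file.path(dir, "scene.gro")
  frames <- lapply(seq_along(paths), function(k) {
    fr <- read_configuration(paths[k], format = "GRO",
                             atom_meta = tp$atom_meta)
    fr$frame_index <- k - 1L
    fr
  })
  list(frames = frames, topology = tp$topology)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by `inst/scripts/maom`: `generate` (emit a
#' labeled scene plus jittered frames), `classify` (labels CSV from a
#' scene directory), `coverage` (per-layer coverage CSV), `descriptors`
#' (per-species descriptor CSV), `report` (correlations + summary from
#' the three CSVs) and `pipeline` (all of the above in one run).
#'
#' @param args Character vector of arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly.
#' @export
maom_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: maom <command> [options]",
    "  generate    --preset P --seed N --frames K --out DIR",
    "  classify    --frames DIR --out labels.csv",
    "  coverage    --frames DIR --layers 4 --out coverage.csv",
    "  descriptors --frames DIR --out descriptors.csv",
    "  report      --labels F --coverage F --descriptors F --seed N --out DIR",
    "  pipeline    --preset P --seed N --frames K --out DIR",
    "presets: na-smectite ca-smectite na-oxide ca-oxide", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(name, default) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  preset <- opt("preset", "na-smectite")
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", "maom_out")
  # --frames is a count for generate/pipeline, a directory elsewhere
  n_frames <- if (cmd %in% c("generate", "pipeline"))
    as.integer(opt("frames", "3")) else 3L

  if (cmd == "generate") {
    scene <- build_scene(scene_preset(preset, seed = seed))
    frames <- jitter_trajectory(scene, n_frames = n_frames, seed = seed + 1L)
    write_scene(scene, out)
    for (k in seq_along(frames))
      write_configuration(frames[[k]],
                          file.path(out, sprintf("frame_%03d.gro", k - 1L)),
                          format = "GRO")
    message("scene written to ", out)
  } else if (cmd == "classify") {
    sc <- read_frames_dir(opt("frames", "maom_out"))
    cls <- classify_trajectory(sc$frames, sc$topology)
    lab <- do.call(rbind, lapply(seq_along(cls$labels), function(k)
      cbind(frame = k - 1L, cls$labels[[k]])))
    write.csv(lab, out, row.names = FALSE)
    message("labels written to ", out)
  } else if (cmd == "coverage") {
    sc <- read_frames_dir(opt("frames", "maom_out"))
    n_layers <- as.integer(opt("layers", "4"))
    cov <- do.call(rbind, lapply(seq_along(sc$frames), function(k)
      cbind(frame = k - 1L,
            surface_coverage(sc$frames[[k]], sc$topology, n_layers))))
    write.csv(cov, out, row.names = FALSE)
    message("coverage written to ", out)
  } else if (cmd == "descriptors") {
    sc <- read_frames_dir(opt("frames", "maom_out"))
    write.csv(frame_descriptor_table(sc$frames[[1]], sc$topology), out,
              row.names = FALSE)
    message("descriptors written to ", out)
  } else if (cmd == "report") {
    lab <- read.csv(opt("labels", "labels.csv"), stringsAsFactors = FALSE)
    cov <- read.csv(opt("coverage", "coverage.csv"),
                    stringsAsFactors = FALSE)
    desc <- read.csv(opt("descriptors", "descriptors.csv"),
                     stringsAsFactors = FALSE)
    labels_frames <- split(lab, lab$frame)
    cp <- vapply(desc$species_id, function(s) {
      sel <- lab$species_id == s
      if (any(sel)) mean(lab$in_largest[sel]) else NA_real_
    }, numeric(1))
    bp <- vapply(desc$species_id, function(s) {
      sel <- lab$species_id == s
      if (any(sel)) mean(lab$bridging[sel]) else NA_real_
    }, numeric(1))
    desc$cluster_probability <- cp
    desc$bridging_probability <- bp
    ads <- adsorbed_percentage(labels_frames)
    summary <- list(species = desc,
                    adsorption = c(adsorbed = ads$adsorbed,
                                   desorbed = ads$desorbed, ads$by_mode),
                    coverage = cov)
    write_report(summary, correlate_features(desc), out,
                 manifest = list(seed = seed))
    message("report written to ", out)
  } else if (cmd == "pipeline") {
    run_demo_pipeline(out, preset = preset, seed = seed, n_frames = n_frames)
    message("report written to ", out)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
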