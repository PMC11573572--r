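#' Read a molecular configuration
#'
#' Parses a single-configuration coordinate file into a [frame()]. GRO
#' coordinates (nm) are converted to Angstrom on read; XYZ and PDB are
#' taken as Angstrom. The box is taken from the file when the format
#' carries one (GRO box record, PDB `CRYST1`, the `box lx ly lz pbc`
#' convention on the XYZ comment line written by [write_configuration()]);
#' otherwise `default_box` is used, and if that is `NULL` a non-periodic
#' error is raised when no box can be established.
#'
#' Coordinate formats carry no role/charge metadata. When an `atom_meta`
#' data.frame (as stored by [write_topology_json()]) is supplied, roles,
#' molecule ids, radii and formal charges are restored from it; otherwise
#' roles are inferred from residue names (`MIN`, `SOL`, `ION`, else SOM)
#' and charges default to zero.
#'
#' @param path File path.
#' @param format One of `"GRO"`, `"XYZ"`, `"PDB"`. Defaults to the file
#'   extension.
#' @param default_box Optional [box()] used when the file has none.
#' @param atom_meta Optional atom metadata data.frame.
#' @return A `maom_frame`.
#' @export
read_configuration <- function(path, format = NULL, default_box = NULL,
                               atom_meta = NULL) {
  format <- resolve_format(path, format)
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(format,
    GRO = parse_gro(lines, path),
    XYZ = parse_xyz(lines, path),
    PDB = parse_pdb(lines, path),
    stop("unsupported format: ", format))
  bx <- parsed$box
  if (is.null(bx)) bx <- default_box
  if (is.null(bx))
    stop("no box record in ", path, " and no default_box supplied; ",
         "a periodic box is required")
  a <- parsed$atoms
  if (!is.null(atom_meta)) {
    if (nrow(atom_meta) != nrow(a))
      stop("atom_meta has ", nrow(atom_meta), " rows but file has ",
           nrow(a), " atoms")
    a$role <- atom_meta$role
    a$molecule_id <- atom_meta$molecule_id
    a$element <- atom_meta$element
    a$vdw_radius <- atom_meta$vdw_radius
    a$charge <- atom_meta$charge
    a$is_heavy <- a$element != "H"
  }
  frame(a, bx, temperature = parsed$temperature %||% 300,
        frame_index = 0L)
}

#' Write a molecular configuration
#'
#' Emits a coordinate file re-readable by [read_configuration()].
#' Round-trips preserve atom count, order and coordinates to the format's
#' stated precision (GRO: 0.001 nm; XYZ: full double precision; PDB:
#' 0.001 Angstrom).
#'
#' @param frame A `maom_frame`.
#' @param path Output path.
#' @param format One of `"GRO"`, `"XYZ"`, `"PDB"`; defaults to the file
#'   extension.
#' @param topology Optional `maom_topology` used for residue naming.
#' @return `path`, invisibly.
#' @export
write_configuration <- function(frame, path, format = NULL, topology = NULL) {
  format <- resolve_format(path, format)
  a <- frame$atoms
  res_name <- residue_names(a, topology)
  lines <- switch(format,
    GRO = format_gro(frame, res_name),
    XYZ = format_xyz(frame),
    PDB = format_pdb(frame, res_name),
    stop("unsupported format: ", format))
  writeLines(lines, path)
  invisible(path)
}

resolve_format <- function(path, format) {
  if (is.null(format))
    format <- toupper(tools::file_ext(path))
  format <- toupper(format)
  if (!format %in% c("GRO", "XYZ", "PDB"))
    stop("unsupported format: ", format)
  format
}

`%||%` <- function(a, b) if (is.null(a)) b else a

residue_names <- function(atoms, topology = NULL) {
  nm <- ifelse(atoms$role == "MINERAL", "MIN",
        ifelse(atoms$role == "WATER", "SOL",
        ifelse(atoms$role == "CATION", "ION", "SOM")))
  nm
}

role_from_resname <- function(resname) {
  rn <- toupper(trimws(resname))
  ifelse(rn == "MIN", "MINERAL",
  ifelse(rn %in% c("SOL", "HOH", "WAT", "TIP3", "SPC"), "WATER",
  ifelse(rn %in% c("ION", "NA", "CA", "NA+", "CA2"), "CATION", "SOM")))
}

element_from_name <- function(name) {
  nm <- trimws(name)
  two <- c("Na", "Ca", "Fe", "Si", "Al", "Mg", "Cl")
  hit <- two[match(toupper(substr(nm, 1, 2)), toupper(two))]
  ifelse(!is.na(hit), hit, toupper(substr(nm, 1, 1)))
}

default_atom_frame <- function(element, molecule_id, xyz, role) {
  n <- length(element)
  data.frame(atom_id = seq_len(n) - 1L,
             element = element,
             role = role,
             molecule_id = as.integer(molecule_id),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             vdw_radius = vdw_radius_for(element),
             is_heavy = element != "H",
             charge = 0,
             stringsAsFactors = FALSE)
}

# ---- GRO ------------------------------------------------------------------

parse_gro <- function(lines, path) {
  if (length(lines) < 3) stop("malformed GRO file ", path, ": too short")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file ", path, " line 2: atom count")
  if (length(lines) < 2 + n + 1)
    stop("malformed GRO file ", path, ": expected ", n, " atom records")
  rec <- lines[3:(2 + n)]
  resid <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resname <- trimws(substr(rec, 6, 10))
  atname <- trimws(substr(rec, 11, 15))
  x <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record at line ", 2 + bad[1], " of ", path)
  bl <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  if (length(bl) < 3 || any(is.na(bl[1:3])))
    stop("malformed GRO box record at line ", 3 + n, " of ", path)
  xyz <- cbind(x, y, z) * 10  # nm -> Angstrom
  el <- element_from_name(atname)
  atoms <- default_atom_frame(el, resid - 1L, xyz, role_from_resname(resname))
  list(atoms = atoms, box = box(bl[1] * 10, bl[2] * 10, bl[3] * 10),
       temperature = NULL)
}

format_gro <- function(frame, res_name) {
  a <- frame$atoms
  hdr <- sprintf("maomtools frame %d, t = %g K", frame$frame_index,
                 frame$temperature)
  rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                 (a$molecule_id + 1L) %% 100000L,
                 substr(res_name, 1, 5),
                 substr(a$element, 1, 5),
                 (a$atom_id + 1L) %% 100000L,
                 a$x / 10, a$y / 10, a$z / 10)
  bx <- sprintf("%12.5f%12.5f%12.5f",
                frame$box$lx / 10, frame$box$ly / 10, frame$box$lz / 10)
  c(hdr, sprintf("%5d", nrow(a)), rec, bx)
}

# ---- XYZ ------------------------------------------------------------------

parse_xyz <- function(lines, path) {
  if (length(lines) < 2) stop("malformed XYZ file ", path, ": too short")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ file ", path, " line 1: atom count")
  if (length(lines) < 2 + n)
    stop("malformed XYZ file ", path, ": expected ", n, " atom records")
  comment <- lines[2]
  bx <- NULL
  m <- regmatches(comment,
                  regexec("box ([0-9.eE+-]+) ([0-9.eE+-]+) ([0-9.eE+-]+) ([TF]{3})",
                          comment))[[1]]
  if (length(m) == 5) {
    bx <- box(as.numeric(m[2]), as.numeric(m[3]), as.numeric(m[4]),
              strsplit(m[5], "")[[1]] == "T")
  }
  rec <- lines[3:(2 + n)]
  parts <- strsplit(trimws(rec), "\\s+")
  ok <- vapply(parts, length, integer(1)) >= 4
  if (!all(ok))
    stop("malformed XYZ record at line ", 2 + which(!ok)[1], " of ", path)
  el <- vapply(parts, `[[`, character(1), 1)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(is.na(xyz)))
    stop("malformed XYZ coordinates in ", path)
  atoms <- default_atom_frame(el, 0L, xyz, "SOM")
  list(atoms = atoms, box = bx, temperature = NULL)
}

format_xyz <- function(frame) {
  a <- frame$atoms
  b <- frame$box
  comment <- sprintf("maomtools box %.10g %.10g %.10g %s frame %d temp %g",
                     b$lx, b$ly, b$lz,
                     paste(ifelse(b$periodic, "T", "F"), collapse = ""),
                     frame$frame_index, frame$temperature)
  rec <- sprintf("%-3s %.10f %.10f %.10f", a$element, a$x, a$y, a$z)
  c(sprintf("%d", nrow(a)), comment, rec)
}

# ---- PDB ------------------------------------------------------------------

parse_pdb <- function(lines, path) {
  bx <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    v <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                       substr(cr[1], 16, 24),
                                       substr(cr[1], 25, 33))))
    if (!any(is.na(v))) bx <- box(v[1], v[2], v[3])
  }
  rec <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  atname <- trimws(substr(rec, 13, 16))
  resname <- trimws(substr(rec, 18, 20))
  resid <- suppressWarnings(as.integer(substr(rec, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
  elcol <- trimws(substr(rec, 77, 78))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad)) {
    ln <- grep("^(ATOM  |HETATM)", lines)[bad[1]]
    stop("malformed PDB record at line ", ln, " of ", path)
  }
  el <- ifelse(nzchar(elcol),
               paste0(substr(elcol, 1, 1),
                      tolower(substr(elcol, 2, 2))),
               element_from_name(atname))
  atoms <- default_atom_frame(el, resid - 1L, cbind(x, y, z),
                              role_from_resname(resname))
  list(atoms = atoms, box = bx, temperature = NULL)
}

format_pdb <- function(frame, res_name) {
  a <- frame$atoms
  b <- frame$box
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   b$lx, b$ly, b$lz, 90, 90, 90)
  el <- toupper(a$element)
  # standard columns: serial 7-11, name 13-16, resName 18-20, resSeq
  # 23-26, x/y/z 31-54, element 77-78
  rec <- sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 (a$atom_id + 1L) %% 100000L,
                 substr(a$element, 1, 4),
                 substr(res_name, 1, 3),
                 (a$molecule_id + 1L) %% 10000L,
                 a$x, a$y, a$z, 1, 0,
                 substr(el, 1, 2))
  c(cryst, rec, "END")
}

# ---- topology sidecar -----------------------------------------------------

#' Write a topology (plus optional per-atom metadata) as JSON
#'
#' The sidecar carries everything coordinate formats cannot: molecule ->
#' species membership, species chemistry, metal-site/ligand-water pairing,
#' and per-atom role/charge metadata, so that a frame written as GRO/XYZ
#' can be fully reconstructed.
#'
#' @param topology A `maom_topology`.
#' @param path Output path.
#' @param frame Optional `maom_frame`; when given, its atom metadata
#'   (role, molecule, element, radius, charge) is embedded.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path, frame = NULL) {
  obj <- list(
    molecules = topology$molecules,
    species = species_table(topology),
    metal_ligand_pairs = topology$metal_ligand_pairs
  )
  if (!is.null(frame)) {
    a <- frame$atoms
    obj$atom_meta <- a[, c("atom_id", "element", "role", "molecule_id",
                           "vdw_radius", "charge")]
  }
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a topology sidecar written by [write_topology_json()]
#'
#' @param path JSON path.
#' @return List with elements `topology` (a `maom_topology`) and
#'   `atom_meta` (data.frame or `NULL`).
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spt <- as.data.frame(obj$species)
  species <- lapply(seq_len(nrow(spt)), function(i) {
    r <- spt[i, ]
    species_record(r$species_id, r$name, r$C, r$H, r$N, r$O, r$S, r$P,
                   formal_charge = r$formal_charge,
                   aromatic_ring_count = r$aromatic_ring_count,
                   carboxylic_acid_count = r$carboxylic_acid_count,
                   n_amine_count = r$n_amine_count,
                   logp = if (is.null(r$logp) || is.na(r$logp)) NA_real_ else r$logp,
                   is_peptide = isTRUE(r$is_peptide))
  })
  mol <- as.data.frame(obj$molecules)
  mol$molecule_id <- as.integer(mol$molecule_id)
  mol$species_id <- as.integer(mol$species_id)
  mlp <- obj$metal_ligand_pairs
  if (!is.null(mlp) && length(mlp)) mlp <- as.data.frame(mlp) else mlp <- NULL
  am <- obj$atom_meta
  if (!is.null(am) && length(am)) {
    am <- as.data.frame(am)
    am$molecule_id <- as.integer(am$molecule_id)
    am$atom_id <- as.integer(am$atom_id)
    am$charge <- as.numeric(am$charge)
    am$vdw_radius <- as.numeric(am$vdw_radius)
  } else am <- NULL
  list(topology = topology(mol, species, metal_ligand_pairs = mlp),
       atom_meta = am)
}
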