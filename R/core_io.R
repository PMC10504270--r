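#' Construct an atomic model
#'
#' The central coordinate container: a flat atom table plus a mapping from
#' chains to subunit labels (so two chains can be copies of one subunit,
#' e.g. `"DRC8_copy1"` / `"DRC8_copy2"` both labelled subunit `"DRC8"` would
#' instead be distinct chains mapped to distinct subunit labels; the mapping
#' is free-form). All coordinates are Cartesian, in Angstrom, using author
#' residue numbering.
#'
#' @param atoms data.frame with columns `chain_id`, `residue_number`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z` and optionally
#'   `occupancy` (default 1) and `b_factor` (default 0).
#' @param subunit_map named character vector mapping every `chain_id` to a
#'   subunit label; defaults to the identity mapping.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, subunit_map = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("chain_id", "residue_number", "residue_name", "atom_name",
              "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- rep(1, nrow(atoms))
  if (!"b_factor" %in% names(atoms)) atoms$b_factor <- rep(0, nrow(atoms))
  atoms <- atoms[, c(needed, "occupancy", "b_factor")]
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$element <- as.character(atoms$element)
  if (nrow(atoms)) {
    rn <- atoms$residue_number
    if (any(is.na(suppressWarnings(as.integer(rn)))) ||
        any(as.numeric(rn) != round(as.numeric(rn))))
      stop("residue numbers must be integers (insertion codes are not supported)")
    atoms$residue_number <- as.integer(rn)
    pos <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(pos))) stop("all atom positions must be finite")
    key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
    if (anyDuplicated(key))
      stop("duplicate (chain, residue, atom_name) records: ",
           key[duplicated(key)][1])
  } else {
    atoms$residue_number <- integer(0)
  }
  chains <- unique(atoms$chain_id)
  if (is.null(subunit_map)) {
    subunit_map <- stats::setNames(chains, chains)
  } else {
    subunit_map <- stats::setNames(as.character(subunit_map), names(subunit_map))
    uncovered <- setdiff(chains, names(subunit_map))
    if (length(uncovered))
      stop("subunit_map does not cover chain(s): ",
           paste(uncovered, collapse = ", "))
  }
  structure(list(atoms = atoms, subunit_map = subunit_map),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, %d chain(s), %d subunit(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain_id)),
              length(unique(x$subunit_map[unique(x$atoms$chain_id)]))))
  invisible(x)
}

n_atoms <- function(model) nrow(model$atoms)

#' Coordinate matrix of a model
#'
#' @param model an `atomic_model`.
#' @param atom_name restrict to one atom name (e.g. `"CA"`); `NULL` keeps all.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords_matrix <- function(model, atom_name = NULL) {
  at <- model$atoms
  if (!is.null(atom_name)) at <- at[at$atom_name == atom_name, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z"), drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Per-atom subunit labels
#' @param model an `atomic_model`.
#' @return character vector, one label per atom row.
#' @export
atom_subunits <- function(model) {
  unname(model$subunit_map[model$atoms$chain_id])
}

# Standard atomic numbers; atom weight in density simulation.
.atomic_numbers <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, FE = 26,
                     ZN = 30, MG = 12, CA = 20, MN = 25, SE = 34)

atom_weights <- function(model) {
  el <- toupper(model$atoms$element)
  w <- .atomic_numbers[el]
  w[is.na(w)] <- 6
  unname(w)
}

# Approximate molecular mass in Da. CA-only models get the mean residue
# mass (110 Da per residue); otherwise a per-element mass sum.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, FE = 55.845, ZN = 65.38,
                    MG = 24.305, CA = 40.078, MN = 54.938, SE = 78.971)

#' Approximate model mass
#'
#' Reduced (C-alpha only) models are weighted at 110 Da per residue, the
#' mean amino-acid residue mass; all-atom models sum per-element masses.
#'
#' @param model an `atomic_model`.
#' @return mass in Dalton.
#' @export
model_mass <- function(model) {
  if (!nrow(model$atoms)) return(0)
  if (all(model$atoms$atom_name == "CA"))
    return(110 * nrow(model$atoms))
  m <- .atomic_masses[toupper(model$atoms$element)]
  m[is.na(m)] <- 12.011
  sum(m)
}

# ---- rigid transforms --------------------------------------------------

#' Construct a rigid transform
#'
#' A proper rotation plus translation acting on column position vectors as
#' `p -> R p + t`.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @param tol orthogonality tolerance.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-8) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rotation matrix is not orthogonal within tolerance ", tol)
  if (abs(det(rotation) - 1) > tol)
    stop("rotation matrix determinant is not +1 (improper rotation?)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation) * 180 / pi
  cat(sprintf("<rigid_transform> angle %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform applying `t1` first,
#' then `t2`.
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return `rigid_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Apply a rigid transform to a model or coordinate matrix
#'
#' @param model an `atomic_model` or an n x 3 coordinate matrix.
#' @param transform a `rigid_transform`.
#' @return same type as `model`, with every position `p` replaced by
#'   `rotation %*% p + translation`; all other fields unchanged.
#' @export
apply_transform <- function(model, transform) {
  if (!inherits(transform, "rigid_transform"))
    transform <- rigid_transform(transform$rotation, transform$translation)
  if (is.matrix(model))
    return(sweep(model %*% t(transform$rotation), 2,
                 transform$translation, "+"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Serialize / deserialize rigid transforms as JSON
#'
#' The record format is `{rotation: 9 numbers row-major, translation: 3}`.
#'
#' @param transform a `rigid_transform` (or list of them for `transforms_to_json`).
#' @param path file path.
#' @return `transform_from_json` returns a `rigid_transform` or list of them.
#' @export
transform_to_json <- function(transform, path) {
  transforms_to_json(list(transform), path)
}

#' @rdname transform_to_json
#' @param transforms named list of `rigid_transform`s.
#' @export
transforms_to_json <- function(transforms, path) {
  recs <- lapply(transforms, function(t)
    list(rotation = as.numeric(t(t$rotation)), translation = t$translation))
  jsonlite::write_json(recs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  out <- lapply(recs, function(r)
    rigid_transform(matrix(as.numeric(r$rotation), 3, 3, byrow = TRUE),
                    as.numeric(r$translation)))
  if (length(out) == 1 && is.null(names(out))) out[[1]] else out
}

# ---- structure files ---------------------------------------------------

#' Read an atomic structure (PDB or mmCIF)
#'
#' PDB files are parsed with bio3d; mmCIF files with a minimal
#' `_atom_site` loop reader. Author chain ids and author residue numbering
#' are preserved; chains appear in file order. Only the first alternate
#' location is kept (with a warning); insertion codes are rejected.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param subunit_map optional chain -> subunit mapping.
#' @return An `atomic_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           subunit_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  at <- if (format == "pdb") .read_pdb_atoms(path) else .read_mmcif_atoms(path)
  if (anyDuplicated(paste(at$chain_id, at$residue_number, at$atom_name))) {
    warning("alternate locations detected; keeping the first record of each")
    at <- at[!duplicated(paste(at$chain_id, at$residue_number, at$atom_name)), ]
  }
  atomic_model(at, subunit_map = subunit_map)
}

.read_pdb_atoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (any(!is.na(a$insert) & nzchar(a$insert)))
    stop("insertion codes are not supported (found in ", path, ")")
  data.frame(chain_id = as.character(a$chain),
             residue_number = as.integer(a$resno),
             residue_name = as.character(a$resid),
             atom_name = as.character(a$elety),
             element = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                              substr(gsub("[0-9']", "", a$elety), 1, 1),
                              as.character(a$elesy)),
             x = a$x, y = a$y, z = a$z,
             occupancy = ifelse(is.na(a$o), 1, a$o),
             b_factor = ifelse(is.na(a$b), 0, a$b),
             stringsAsFactors = FALSE)
}

# Minimal mmCIF _atom_site loop reader: whitespace-separated fields with
# single/double-quote handling; enough for coordinate files.
.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  tags <- character(0)
  rows <- list()
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      tg <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tg <- c(tg, sub("\\s.*$", "", sub("^\\s*", "", lines[j])))
        j <- j + 1L
      }
      if (length(tg) && all(grepl("^_atom_site\\.", tg))) {
        tags <- tg
        while (j <= n && !grepl("^\\s*(#|loop_|_|data_)", lines[j])) {
          if (nzchar(trimws(lines[j])))
            rows[[length(rows) + 1L]] <- .cif_tokens(lines[j])
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(tags)) stop("no _atom_site loop found in ", path)
  if (!length(rows))
    return(data.frame(chain_id = character(0), residue_number = integer(0),
                      residue_name = character(0), atom_name = character(0),
                      element = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), occupancy = numeric(0),
                      b_factor = numeric(0), stringsAsFactors = FALSE))
  bad <- which(vapply(rows, length, 1L) != length(tags))
  if (length(bad))
    stop("malformed _atom_site row (", length(tags), " fields expected): line ",
         bad[1])
  m <- do.call(rbind, rows)
  colnames(m) <- sub("^_atom_site\\.", "", tags)
  getcol <- function(primary, fallback) {
    if (primary %in% colnames(m)) m[, primary]
    else if (fallback %in% colnames(m)) m[, fallback]
    else stop("mmCIF file lacks both ", primary, " and ", fallback)
  }
  ins <- if ("pdbx_PDB_ins_code" %in% colnames(m))
    m[, "pdbx_PDB_ins_code"] else rep("?", nrow(m))
  if (any(!ins %in% c("?", ".", "")))
    stop("insertion codes are not supported (found in ", path, ")")
  resno <- suppressWarnings(as.integer(getcol("auth_seq_id", "label_seq_id")))
  if (any(is.na(resno)))
    stop("non-integer residue number in _atom_site row ",
         which(is.na(resno))[1])
  occ <- if ("occupancy" %in% colnames(m))
    suppressWarnings(as.numeric(m[, "occupancy"])) else rep(1, nrow(m))
  bfac <- if ("B_iso_or_equiv" %in% colnames(m))
    suppressWarnings(as.numeric(m[, "B_iso_or_equiv"])) else rep(0, nrow(m))
  data.frame(chain_id = getcol("auth_asym_id", "label_asym_id"),
             residue_number = resno,
             residue_name = getcol("auth_comp_id", "label_comp_id"),
             atom_name = gsub('"', "", getcol("label_atom_id", "auth_atom_id")),
             element = getcol("type_symbol", "type_symbol"),
             x = as.numeric(m[, "Cartn_x"]),
             y = as.numeric(m[, "Cartn_y"]),
             z = as.numeric(m[, "Cartn_z"]),
             occupancy = ifelse(is.na(occ), 1, occ),
             b_factor = ifelse(is.na(bfac), 0, bfac),
             stringsAsFactors = FALSE)
}

.cif_tokens <- function(line) {
  out <- character(0)
  s <- trimws(line)
  while (nzchar(s)) {
    first <- substr(s, 1, 1)
    if (first %in% c("'", '"')) {
      end <- regexpr(paste0(first, "(\\s|$)"), substr(s, 2, nchar(s)))
      if (end < 0) { out <- c(out, substr(s, 2, nchar(s))); s <- "" }
      else {
        out <- c(out, substr(s, 2, end))
        s <- trimws(substr(s, end + 2, nchar(s)))
      }
    } else {
      sp <- regexpr("\\s", s)
      if (sp < 0) { out <- c(out, s); s <- "" }
      else { out <- c(out, substr(s, 1, sp - 1)); s <- trimws(substr(s, sp, nchar(s)))}
    }
  }
  out
}

#' Write an atomic structure (PDB or mmCIF)
#'
#' Records are ordered by chain (file order of first appearance) then
#' residue number. The emitted file re-parses to an equal atom table
#' within format precision (1e-3 Angstrom for PDB).
#'
#' @param model an `atomic_model`.
#' @param path output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  at <- model$atoms
  if (nrow(at)) {
    chain_order <- match(at$chain_id, unique(at$chain_id))
    at <- at[order(chain_order, at$residue_number), , drop = FALSE]
  }
  if (format == "pdb") {
    if (!nrow(at)) { writeLines("END", path); return(invisible(path)) }
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$residue_number, chain = at$chain_id,
                     resid = at$residue_name, elety = at$atom_name,
                     eleno = seq_len(nrow(at)), o = at$occupancy,
                     b = at$b_factor, elesy = at$element)
  } else {
    # canonical PDBx/mmCIF atom_site column order
    hdr <- c("data_model", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
    body <- if (nrow(at)) sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      seq_len(nrow(at)), at$element, at$atom_name, at$residue_name,
      at$chain_id, at$residue_number, at$x, at$y, at$z, at$occupancy,
      at$b_factor, at$residue_number, at$residue_name, at$chain_id,
      at$atom_name)
    else character(0)
    writeLines(c(hdr, body, "#"), path)
  }
  invisible(path)
}

# ---- density maps ------------------------------------------------------

#' Construct a density map
#'
#' A regular cubic-voxel 3D grid. Voxel `(i,j,k)` (0-based) is centered at
#' `origin + voxel_size * c(i,j,k)`; the first array index runs along
#' world X (fastest), per the package's fixed internal axis order.
#'
#' @param values 3D numeric array.
#' @param voxel_size voxel edge in Angstrom (isotropic, > 0).
#' @param origin world coordinate (Angstrom) of the center of voxel (0,0,0).
#' @param resolution_hint optional nominal resolution in Angstrom.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0),
                        resolution_hint = NULL) {
  if (length(dim(values)) != 3 || any(dim(values) < 1))
    stop("values must be a 3D array with positive dimensions")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be > 0")
  if (!all(is.finite(values))) stop("map values must be finite")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 resolution_hint = resolution_hint),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.3g A/voxel, origin (%.1f, %.1f, %.1f)\n",
              d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Supports mode 2 (32-bit real) MRC2014 files. Files stored with a
#' permuted axis order (MAPC/MAPR/MAPS) are re-indexed on read so that the
#' in-memory array always has world X fastest; world coordinates of every
#' voxel are unchanged by this normalization. The origin is taken from the
#' ORIGIN header fields, falling back to NXSTART/NYSTART/NZSTART times the
#' voxel size when ORIGIN is all zero.
#'
#' @param path file path.
#' @return A `density_map`.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (mode != 2)
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit real)")
  nstart <- readBin(con, "integer", 3, size = 4, endian = "little")
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # cell angles
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")  # dmin dmax dmean
  ispg_nsymbt <- readBin(con, "integer", 2, size = 4, endian = "little")
  readBin(con, "integer", 25, size = 4, endian = "little") # extra
  orig <- readBin(con, "numeric", 3, size = 4, endian = "little")
  maptag <- rawToChar(readBin(con, "raw", 4))
  readBin(con, "raw", 4)                                    # machst
  readBin(con, "numeric", 1, size = 4, endian = "little")   # rms
  readBin(con, "raw", 1024 - 55 * 4)                        # rest of header
  if (ispg_nsymbt[2] > 0)
    readBin(con, "raw", ispg_nsymbt[2])                     # extended header
  if (!identical(substr(maptag, 1, 3), "MAP"))
    warning("file lacks the MAP stamp; attempting to read anyway")
  vs <- cella / mxyz
  if (any(!is.finite(vs)) || any(vs <= 0))
    stop("invalid cell/grid header (non-positive voxel size)")
  if (max(vs) - min(vs) > 1e-4 * max(vs))
    stop("anisotropic voxels are not supported")
  nvox <- prod(nxyz)
  vals <- readBin(con, "numeric", nvox, size = 4, endian = "little")
  if (length(vals) < nvox) stop("truncated map data in ", path)
  if (any(sort(mapcrs) != 1:3)) stop("invalid MAPC/MAPR/MAPS header")
  arr <- array(vals, dim = nxyz)                 # axes are (mapc, mapr, maps)
  perm <- match(1:3, mapcrs)                     # world axis -> storage slot
  arr <- aperm(arr, perm)
  voxel <- mean(vs)
  origin <- numeric(3)
  if (any(orig != 0)) {
    origin <- orig
  } else {
    origin[mapcrs] <- nstart * voxel
  }
  density_map(arr, voxel_size = voxel, origin = origin)
}

#' Write an MRC/CCP4 density map
#'
#' Emits MRC2014 mode 2. `axis_order` chooses the MAPC/MAPR/MAPS
#' permutation on disk (default X fastest); [read_map] normalizes any
#' permutation back, leaving voxel world coordinates unchanged.
#'
#' @param map a `density_map`.
#' @param path output path.
#' @param axis_order integer permutation of 1:3 written as MAPC/MAPR/MAPS.
#' @export
write_map <- function(map, path, axis_order = c(1, 2, 3)) {
  stopifnot(inherits(map, "density_map"))
  if (any(sort(axis_order) != 1:3)) stop("axis_order must be a permutation of 1:3")
  dm <- dim(map$values)
  arr <- aperm(map$values, axis_order)           # storage slots = world axes axis_order
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wint(dim(arr))                                  # NX NY NZ (columns/rows/sections)
  wint(2)                                         # MODE
  wint(c(0, 0, 0))                                # NSTART
  wint(dm)                                        # MX MY MZ (world axes)
  wflt(dm * map$voxel_size)                       # CELLA (world axes)
  wflt(c(90, 90, 90))                             # CELLB
  wint(axis_order)                                # MAPC MAPR MAPS
  v <- as.numeric(map$values)
  wflt(c(min(v), max(v), mean(v)))                # DMIN DMAX DMEAN
  wint(c(1, 0))                                   # ISPG NSYMBT
  wint(rep(0, 25))                                # EXTRA
  wflt(map$origin)                                # ORIGIN (world x,y,z)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wflt(sd(v))                                     # RMS
  wint(1)                                         # NLABL
  lab <- sprintf("%-80s", "written by xlassemble")
  writeBin(charToRaw(paste0(lab, strrep(" ", 80 * 9))), con)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

# World coordinates of voxel centers along each axis.
map_axis_coords <- function(map) {
  d <- dim(map$values)
  lapply(1:3, function(k) map$origin[k] + map$voxel_size * (seq_len(d[k]) - 1))
}
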