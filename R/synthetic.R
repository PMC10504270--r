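#' Specification of a synthetic multi-subunit complex
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' rigid subunits with known ground-truth placements, packed without
#' steric overlap and kept in contact so that informative inter-subunit
#' cross-links exist.
#'
#' @param n_subunits number of subunits (>= 1).
#' @param residues_per_subunit integer, recycled to `n_subunits`.
#' @param geometry `"random_walk"` (self-avoiding C-alpha walk, 3.8 A
#'   steps) or `"ideal_helix"` (rise 1.5 A/residue, radius 2.3 A,
#'   100 degrees/residue twist).
#' @param min_separation minimum inter-subunit C-alpha distance (Angstrom).
#' @param contact_max maximum allowed nearest-neighbour gap when placing a
#'   new subunit (keeps the complex connected).
#' @param identical_copies optional list of integer vectors: subunit index
#'   groups that share identical canonical coordinates (copies of one
#'   protein).
#' @param seed integer seed; generation is deterministic given it.
#' @return a `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(n_subunits = 3, residues_per_subunit = 60,
                             geometry = c("random_walk", "ideal_helix"),
                             min_separation = 8, contact_max = 10,
                             identical_copies = NULL, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(n_subunits >= 1, min_separation >= 0)
  residues_per_subunit <- rep_len(as.integer(residues_per_subunit),
                                  n_subunits)
  structure(list(n_subunits = as.integer(n_subunits),
                 residues_per_subunit = residues_per_subunit,
                 geometry = geometry, min_separation = min_separation,
                 contact_max = contact_max,
                 identical_copies = identical_copies,
                 seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# canonical C-alpha trace of one subunit, starting near the origin
.canonical_subunit <- function(n_res, geometry) {
  if (geometry == "ideal_helix") {
    i <- seq_len(n_res) - 1
    ang <- i * 100 * pi / 180
    cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  } else {
    xyz <- matrix(0, n_res, 3)
    for (i in seq_len(n_res - 1)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- xyz[i, ] + 3.8 * u
        prev <- xyz[seq_len(max(1, i - 1)), , drop = FALSE]
        if (i == 1 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= 3.5) {
          xyz[i + 1, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("self-avoiding walk failed; try another seed")
    }
    xyz
  }
}

.ca_model <- function(xyz, chain_id, subunit) {
  n <- nrow(xyz)
  atomic_model(data.frame(chain_id = chain_id,
                          residue_number = seq_len(n),
                          residue_name = "ALA", atom_name = "CA",
                          element = "C",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE),
               subunit_map = stats::setNames(subunit, chain_id))
}

#' Generate a ground-truth toy complex
#'
#' Builds canonical subunit models (identical-copy groups share
#' coordinates), then places them sequentially with uniform random
#' orientations so that the minimum inter-subunit C-alpha distance is at
#' least `min_separation` and each subunit touches the growing complex
#' within `contact_max` of that bound. Fully deterministic for a fixed
#' seed.
#'
#' @param spec a [toy_complex_spec].
#' @return a `ground_truth` list: `model` (placed C-alpha
#'   `atomic_model`, chains A, B, ...; subunits `S1`, `S2`, ...),
#'   `canonical` (named list of canonical-pose models), `transforms`
#'   (named list of `rigid_transform`s canonical -> placed), `spec`.
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  local_seed(spec$seed, {
    n <- spec$n_subunits
    labels <- paste0("S", seq_len(n))
    chains <- c(LETTERS, letters)[seq_len(n)]
    canon_xyz <- vector("list", n)
    group_of <- integer(n)
    if (!is.null(spec$identical_copies))
      for (gi in seq_along(spec$identical_copies))
        group_of[spec$identical_copies[[gi]]] <- gi
    made_groups <- list()
    for (i in seq_len(n)) {
      g <- group_of[i]
      if (g > 0 && !is.null(made_groups[[as.character(g)]])) {
        canon_xyz[[i]] <- made_groups[[as.character(g)]]
      } else {
        canon_xyz[[i]] <- .canonical_subunit(spec$residues_per_subunit[i],
                                             spec$geometry)
        if (g > 0) made_groups[[as.character(g)]] <- canon_xyz[[i]]
      }
    }
    radius <- vapply(canon_xyz, function(x) {
      c0 <- colMeans(x)
      max(sqrt(rowSums(sweep(x, 2, c0)^2)))
    }, numeric(1))
    placed <- vector("list", n)
    transforms <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(2000)) {
        R <- quat_to_matrix({q <- rnorm(4); q / sqrt(sum(q^2))})
        c0 <- colMeans(canon_xyz[[i]])
        if (i == 1) {
          target <- c(0, 0, 0)
        } else {
          j <- sample.int(i - 1, 1)
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          dmin <- 0.4 * (radius[i] + radius[j])
          dmax <- radius[i] + radius[j] + spec$min_separation
          target <- colMeans(placed[[j]]) + u * runif(1, dmin, dmax)
        }
        t_vec <- target - as.numeric(R %*% c0)
        tr <- rigid_transform(R, t_vec)
        xyz <- apply_transform(canon_xyz[[i]], tr)
        if (i == 1) { ok <- TRUE }
        else {
          others <- do.call(rbind, placed[seq_len(i - 1)])
          dcross <- cpp_min_cross_group_dist(
            rbind(xyz, others),
            c(rep(1L, nrow(xyz)), rep(2L, nrow(others))))
          ok <- dcross >= spec$min_separation &&
                dcross <= spec$min_separation + spec$contact_max
        }
        if (ok) { placed[[i]] <- xyz; transforms[[i]] <- tr; break }
      }
      if (!ok)
        stop("could not place subunit ", i,
             " after bounded retries; relax min_separation or enlarge the box")
    }
    canonical <- stats::setNames(lapply(seq_len(n), function(i)
      .ca_model(canon_xyz[[i]], chains[i], labels[i])), labels)
    tabs <- lapply(seq_len(n), function(i) {
      m <- .ca_model(placed[[i]], chains[i], labels[i])
      m$atoms
    })
    model <- atomic_model(do.call(rbind, tabs),
                          subunit_map = stats::setNames(labels, chains))
    structure(list(model = model, canonical = canonical,
                   transforms = stats::setNames(transforms, labels),
                   spec = spec),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d subunit(s) (%s geometry), %d atoms\n",
              x$spec$n_subunits, x$spec$geometry, nrow(x$model$atoms)))
  invisible(x)
}

#' Simulate a cross-link table over a ground-truth complex
#'
#' True links are drawn uniformly from C-alpha pairs within `true_max`
#' (a margin below the 35 A DSSO bound, so they stay satisfied under
#' small placement error); decoys are drawn from pairs beyond
#' `decoy_min`, so every decoy violates the bound in the ground truth.
#' Intramolecular pairs closer than 5 residues in sequence are excluded
#' (they would be satisfied by any placement). Proteins are named by
#' subunit label; identical-copy groups share a protein label.
#'
#' @param truth a [make_toy_complex] result.
#' @param n_true number of true links.
#' @param decoy_fraction decoys as a fraction of `n_true` (count is
#'   `ceiling(decoy_fraction * n_true)`).
#' @param true_max maximum ground-truth distance of a true link (Angstrom).
#' @param decoy_min minimum ground-truth distance of a decoy (Angstrom).
#' @param seed integer seed.
#' @return a `crosslink_set` whose `links` carry a provenance column
#'   `truth` (`"true"`/`"decoy"`).
#' @export
simulate_crosslinks <- function(truth, n_true = 12, decoy_fraction = 0.2,
                                true_max = 30, decoy_min = 45, seed = 1) {
  at <- truth$model$atoms[truth$model$atoms$atom_name == "CA", ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  sub <- atom_subunits(truth$model)[truth$model$atoms$atom_name == "CA"]
  # protein label: identical copies share one protein name
  spec <- truth$spec
  prot_of <- stats::setNames(paste0("P", seq_len(spec$n_subunits)),
                             paste0("S", seq_len(spec$n_subunits)))
  if (!is.null(spec$identical_copies))
    for (g in spec$identical_copies)
      prot_of[paste0("S", g)] <- paste0("P", g[1])
  n <- nrow(xyz)
  pr <- unname(prot_of[sub])
  d <- as.matrix(stats::dist(xyz))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[ij]
  same_sub <- sub[ij[, 1]] == sub[ij[, 2]]
  seqsep <- abs(at$residue_number[ij[, 1]] - at$residue_number[ij[, 2]])
  eligible_true <- which(dv <= true_max & (!same_sub | seqsep >= 5))
  eligible_decoy <- which(dv >= decoy_min)
  n_decoy <- ceiling(decoy_fraction * n_true)
  if (length(eligible_true) < n_true)
    stop("only ", length(eligible_true), " C-alpha pairs within ", true_max,
         " A; cannot draw ", n_true, " true links")
  if (n_decoy > 0 && length(eligible_decoy) < n_decoy)
    stop("only ", length(eligible_decoy), " C-alpha pairs beyond ",
         decoy_min, " A; cannot draw ", n_decoy, " decoys")
  local_seed(seed, {
    pick_true <- sample(eligible_true, n_true)
    pick_decoy <- if (n_decoy > 0) sample(eligible_decoy, n_decoy)
                  else integer(0)
    rows <- function(idx, label) {
      if (!length(idx)) return(NULL)
      data.frame(protein_a = pr[ij[idx, 1]],
                 residue_a = at$residue_number[ij[idx, 1]],
                 protein_b = pr[ij[idx, 2]],
                 residue_b = at$residue_number[ij[idx, 2]],
                 linker = "DSSO", truth = label,
                 stringsAsFactors = FALSE)
    }
    links <- rbind(rows(pick_true, "true"), rows(pick_decoy, "decoy"))
    # drop accidental duplicate unordered pairs (same residues via copies)
    key <- apply(links, 1, function(r)
      paste(sort(c(paste(r[["protein_a"]], r[["residue_a"]]),
                   paste(r[["protein_b"]], r[["residue_b"]]))),
            collapse = "|"))
    links <- links[!duplicated(key), ]
    crosslink_set(links, source = sprintf(
      "simulated (seed %d, %d true <= %g A, %d decoys >= %g A)",
      seed, n_true, true_max, n_decoy, decoy_min))
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Emits everything one pipeline run consumes: the ground-truth placed
#' structure (mmCIF), each subunit in canonical pose (the fitting inputs),
#' the simulated map (MRC) at the stated resolution, the cross-link table
#' (CSV), the ground-truth transforms (JSON), and a manifest recording
#' seed and parameters.
#'
#' @param spec a [toy_complex_spec].
#' @param resolution map resolution in Angstrom.
#' @param voxel_size map voxel edge in Angstrom.
#' @param padding map padding around the complex (Angstrom).
#' @param n_true,decoy_fraction cross-link table parameters
#'   (see [simulate_crosslinks]).
#' @param noise_sd optional uniform Gaussian voxel noise, as a fraction of
#'   the map maximum (0 disables).
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the in-memory objects (`truth`, `map`,
#'   `xl`) and the file `paths`.
#' @export
make_fixture_bundle <- function(spec = toy_complex_spec(), resolution = 8,
                                voxel_size = 2, padding = 12,
                                n_true = 12, decoy_fraction = 0.2,
                                noise_sd = 0, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_toy_complex(spec)
  map <- simulate_map(truth$model, resolution, voxel_size, padding)
  if (noise_sd > 0) {
    noise <- local_seed(spec$seed + 1L,
                        array(rnorm(length(map$values),
                                    sd = noise_sd * max(map$values)),
                              dim = dim(map$values)))
    map <- density_map(map$values + noise, map$voxel_size, map$origin,
                       resolution_hint = resolution)
  }
  xl <- simulate_crosslinks(truth, n_true = n_true,
                            decoy_fraction = decoy_fraction,
                            seed = spec$seed + 2L)
  paths <- list(
    ground_truth = file.path(outdir, "ground_truth.cif"),
    map = file.path(outdir, "map.mrc"),
    crosslinks = file.path(outdir, "crosslinks.csv"),
    transforms = file.path(outdir, "transforms.json"),
    manifest = file.path(outdir, "manifest.json"))
  write_structure(truth$model, paths$ground_truth, format = "cif")
  write_map(map, paths$map)
  write.csv(xl$links[, c("protein_a", "residue_a", "protein_b",
                         "residue_b", "linker", "truth")],
            paths$crosslinks, row.names = FALSE)
  transforms_to_json(truth$transforms, paths$transforms)
  for (s in names(truth$canonical)) {
    p <- file.path(outdir, sprintf("subunit_%s.cif", s))
    write_structure(truth$canonical[[s]], p, format = "cif")
    paths[[paste0("subunit_", s)]] <- p
  }
  manifest <- list(seed = spec$seed, n_subunits = spec$n_subunits,
                   residues_per_subunit = spec$residues_per_subunit,
                   geometry = spec$geometry,
                   min_separation = spec$min_separation,
                   identical_copies = spec$identical_copies,
                   resolution = resolution, voxel_size = voxel_size,
                   padding = padding, n_true = n_true,
                   decoy_fraction = decoy_fraction, noise_sd = noise_sd,
                   files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(truth = truth, map = map, xl = xl, paths = paths))
}

#' Read a fixture bundle back from disk
#'
#' @param outdir bundle directory written by [make_fixture_bundle].
#' @return list with `model`, `canonical`, `map`, `xl`, `transforms`,
#'   `manifest`.
#' @export
load_fixture_bundle <- function(outdir) {
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                                  simplifyVector = TRUE)
  labels <- paste0("S", seq_len(manifest$n_subunits))
  chains <- c(LETTERS, letters)[seq_len(manifest$n_subunits)]
  model <- read_structure(file.path(outdir, "ground_truth.cif"),
                          subunit_map = stats::setNames(labels, chains))
  canonical <- stats::setNames(lapply(seq_along(labels), function(i)
    read_structure(file.path(outdir, sprintf("subunit_%s.cif", labels[i])),
                   subunit_map = stats::setNames(labels[i], chains[i]))),
    labels)
  map <- read_map(file.path(outdir, "map.mrc"))
  map$resolution_hint <- manifest$resolution
  xl <- parse_xl_table(file.path(outdir, "crosslinks.csv"))
  transforms <- transform_from_json(file.path(outdir, "transforms.json"))
  list(model = model, canonical = canonical, map = map, xl = xl,
       transforms = transforms, manifest = manifest)
}
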