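#' Simulate a density map from an atomic model
#'
#' Each atom contributes an isotropic Gaussian of width
#' `sigma = resolution / (pi * sqrt(2))` with amplitude proportional to its
#' atomic number (uniform for C-alpha-only models). By default the grid
#' covers the model bounding box plus `padding`; pass `grid` to rasterize
#' onto an existing map's geometry instead (e.g. to compare against an
#' experimental map voxel by voxel).
#'
#' @param model an `atomic_model` (non-empty).
#' @param resolution nominal resolution in Angstrom; must be at least
#'   `2 * voxel_size` (sampling limit).
#' @param voxel_size voxel edge in Angstrom.
#' @param padding margin around the model bounding box in Angstrom.
#' @param grid optional `density_map` whose geometry (dimensions, origin,
#'   voxel size) is reused; `voxel_size`/`padding` are then ignored.
#' @param cutoff_sigmas per-atom Gaussian truncation radius in sigmas.
#' @return A `density_map` with `resolution_hint` set.
#' @export
simulate_map <- function(model, resolution, voxel_size = resolution / 4,
                         padding = 3 * resolution, grid = NULL,
                         cutoff_sigmas = 4.5) {
  if (!nrow(model$atoms)) stop("cannot simulate a map from an empty model")
  sigma <- resolution / (pi * sqrt(2))
  xyz <- coords_matrix(model)
  w <- atom_weights(model)
  if (is.null(grid)) {
    if (resolution < 2 * voxel_size)
      stop("resolution must be >= 2 * voxel_size (undersampling)")
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
    origin <- lo
  } else {
    dims <- dim(grid$values)
    origin <- grid$origin
    voxel_size <- grid$voxel_size
  }
  vals <- cpp_simulate_map(xyz, w, as.integer(dims), origin, voxel_size,
                           sigma, cutoff_sigmas)
  density_map(array(vals, dim = dims), voxel_size, origin,
              resolution_hint = resolution)
}

#' Pearson cross-correlation between two maps
#'
#' Zero-mean Pearson correlation over all voxels, or over a mask.
#'
#' @param map_a,map_b `density_map`s on identical grids.
#' @param mask optional logical array/vector (same length as the grid) or
#'   integer voxel indices selecting the voxels to correlate.
#' @return correlation in \[-1, 1\].
#' @export
cross_correlation <- function(map_a, map_b, mask = NULL) {
  .check_same_grid(map_a, map_b)
  a <- as.numeric(map_a$values)
  b <- as.numeric(map_b$values)
  if (!is.null(mask)) {
    idx <- if (is.logical(mask)) which(as.logical(mask)) else as.integer(mask)
    if (!length(idx)) stop("mask selects no voxels")
    a <- a[idx]; b <- b[idx]
  }
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined: constant map over the selected voxels")
  cor(a, b)
}

.check_same_grid <- function(map_a, map_b) {
  if (!all(dim(map_a$values) == dim(map_b$values)) ||
      abs(map_a$voxel_size - map_b$voxel_size) > 1e-6 ||
      max(abs(map_a$origin - map_b$origin)) > 1e-6)
    stop("maps are not on the same grid")
  invisible(TRUE)
}

#' Choose the envelope density threshold
#'
#' In `"volume"` mode, returns the density value whose super-level set
#' encloses `volume_scale * target_mass * 1.21` cubic Angstrom (the
#' conventional 1.21 A^3/Da protein specific volume), i.e. a deliberately
#' generous low-density envelope. In `"fixed"` mode simply returns `value`.
#'
#' @param map a `density_map`.
#' @param mode `"volume"` or `"fixed"`.
#' @param value threshold for fixed mode.
#' @param target_mass molecular mass in Dalton (volume mode).
#' @param volume_scale multiple of the nominal molecular volume to enclose.
#' @return a density value.
#' @export
envelope_threshold <- function(map, mode = c("volume", "fixed"), value = NULL,
                               target_mass = NULL, volume_scale = 1.5) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(value)) stop("fixed mode requires `value`")
    return(as.numeric(value))
  }
  if (is.null(target_mass) || target_mass <= 0)
    stop("volume mode requires target_mass > 0")
  target_volume <- volume_scale * target_mass * 1.21
  n_target <- target_volume / map$voxel_size^3
  v <- as.numeric(map$values)
  if (n_target > length(v))
    stop(sprintf("target volume (%.0f A^3) exceeds the whole grid (%.0f A^3)",
                 target_volume, length(v) * map$voxel_size^3))
  sorted <- sort(v, decreasing = TRUE)
  sorted[max(1L, ceiling(n_target))]
}

#' Fraction of atoms inside the map envelope
#'
#' Trilinearly interpolates the map at every (transformed) atom position
#' and reports the fraction at or above `threshold`. Atoms falling outside
#' the grid count as uncovered.
#'
#' @param model an `atomic_model`.
#' @param transform `rigid_transform` applied to the model first.
#' @param map a `density_map`.
#' @param threshold envelope density threshold.
#' @return fraction in \[0, 1\].
#' @export
envelope_coverage <- function(model, transform, map, threshold) {
  xyz <- apply_transform(coords_matrix(model), transform)
  vals <- cpp_trilinear(as.numeric(map$values), dim(map$values),
                        map$origin, map$voxel_size, xyz)
  mean(!is.na(vals) & vals >= threshold)
}

#' Sample uniform random rotations
#'
#' Uniform over SO(3) via normalized Gaussian quaternions (equivalently
#' the Haar measure); deterministic for a fixed seed.
#'
#' @param n number of rotations.
#' @param seed integer seed.
#' @return list of `rigid_transform`s with zero translation.
#' @export
sample_rotations <- function(n, seed = 1) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(list())
  q <- local_seed(seed, matrix(rnorm(4 * n), ncol = 4))
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i)
    rigid_transform(quat_to_matrix(q[i, ])))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Project a near-rotation back onto SO(3) (guards against accumulated
# floating-point drift in long move sequences).
.reorthogonalize <- function(R) {
  s <- svd(R)
  out <- s$u %*% t(s$v)
  if (det(out) < 0) out <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  out
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * (u %o% u)
}

# Mean interpolated map value at (weighted) atom positions: the fitmap-style
# overlap objective used inside library generation. Out-of-grid atoms score 0.
fit_overlap <- function(xyz, weights, map_vals, map_dim, origin, voxel) {
  v <- cpp_trilinear(map_vals, map_dim, origin, voxel, xyz)
  v[is.na(v)] <- 0
  sum(weights * v) / sum(weights)
}

# Masked Pearson cc of a placed model's simulated density against the map;
# the mask is the placed model's own significant density footprint.
placed_model_cc <- function(model, map, transform, resolution) {
  placed <- apply_transform(model, transform)
  xyz <- coords_matrix(placed)
  lo <- map$origin; hi <- map$origin + map$voxel_size * (dim(map$values) - 1)
  inside <- xyz[, 1] >= lo[1] & xyz[, 2] >= lo[2] & xyz[, 3] >= lo[3] &
            xyz[, 1] <= hi[1] & xyz[, 2] <= hi[2] & xyz[, 3] <= hi[3]
  if (!any(inside)) stop("model lies entirely outside the map grid")
  sim <- simulate_map(placed, resolution, grid = map)
  mask <- as.numeric(sim$values) > 1e-3 * max(sim$values)
  if (sum(mask) < 2) stop("placed model touches too few voxels")
  cross_correlation(map, sim, mask = mask)
}

#' Locally refine a rigid placement against a map
#'
#' Greedy pattern search over small translation and rotation steps (about
#' the model centroid), with step halving, until the objective improves by
#' less than `tol` or `max_iter` iterations. The default objective is the
#' masked model-to-map correlation; `"overlap"` (mean interpolated density
#' at atom positions) is the cheaper objective used during library
#' generation.
#'
#' @param model an `atomic_model`.
#' @param map a `density_map`.
#' @param start a `rigid_transform` placing the model at least partly on
#'   the grid.
#' @param resolution simulation resolution in Angstrom (defaults to the
#'   map's `resolution_hint`).
#' @param tol minimum objective improvement to continue.
#' @param max_iter maximum pattern-search iterations.
#' @param objective `"cc"` or `"overlap"`.
#' @param trans_step initial translation step (Angstrom).
#' @param rot_step initial rotation step (radians).
#' @param threshold envelope threshold used for the reported coverage
#'   (default: 5% of the map maximum).
#' @return a `fit_candidate`: list with `transform`, `cc`, `coverage`.
#' @export
refine_fit_local <- function(model, map, start,
                             resolution = map$resolution_hint,
                             tol = 1e-4, max_iter = 50,
                             objective = c("cc", "overlap"),
                             trans_step = map$voxel_size / 2,
                             rot_step = 2 * pi / 180,
                             threshold = 0.05 * max(map$values)) {
  objective <- match.arg(objective)
  if (is.null(resolution))
    stop("resolution is required (map has no resolution_hint)")
  xyz0 <- coords_matrix(model)
  w <- atom_weights(model)
  map_vals <- as.numeric(map$values)
  map_dim <- dim(map$values)
  score_fun <- if (objective == "overlap") {
    function(t) fit_overlap(apply_transform(xyz0, t), w, map_vals, map_dim,
                            map$origin, map$voxel_size)
  } else {
    function(t) placed_model_cc(model, map, t, resolution)
  }
  res <- .pattern_search(xyz0, start, score_fun, tol, max_iter,
                         trans_step, rot_step)
  cand <- list(transform = res$transform,
               cc = if (objective == "cc") res$score
                    else placed_model_cc(model, map, res$transform, resolution),
               coverage = envelope_coverage(model, res$transform, map,
                                            threshold),
               trace = res$trace)
  class(cand) <- "fit_candidate"
  cand
}

.pattern_search <- function(xyz0, start, score_fun, tol, max_iter,
                            trans_step, rot_step) {
  cur <- start
  cur_score <- score_fun(cur)
  trace <- cur_score
  ts <- trans_step; rs <- rot_step
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (it in seq_len(max_iter)) {
    centroid <- colMeans(apply_transform(xyz0, cur))
    best <- NULL; best_score <- cur_score
    for (d in 1:3) for (s in c(-1, 1)) {
      cand <- rigid_transform(cur$rotation, cur$translation + s * ts * axes[d, ])
      sc <- score_fun(cand)
      if (sc > best_score) { best <- cand; best_score <- sc }
      Rs <- rotation_about_axis(axes[d, ], s * rs)
      cand2 <- compose_transforms(
        rigid_transform(Rs, centroid - as.numeric(Rs %*% centroid)), cur)
      sc2 <- score_fun(cand2)
      if (sc2 > best_score) { best <- cand2; best_score <- sc2 }
    }
    if (is.null(best) || best_score - cur_score < tol) {
      if (ts <= trans_step / 4) break
      ts <- ts / 2; rs <- rs / 2
      if (!is.null(best)) { cur <- best; cur_score <- best_score }
      trace <- c(trace, cur_score)
      next
    }
    cur <- best
    cur_score <- best_score
    trace <- c(trace, cur_score)
  }
  list(transform = cur, score = cur_score, trace = trace)
}

#' Fit-search configuration
#'
#' Defaults follow the published protocol: 100,000 random searches with a
#' coverage filter requiring at least 60% of the input structure inside
#' the map envelope at a low-density threshold.
#'
#' @param n_searches number of random placement proposals.
#' @param coverage_min minimum envelope coverage to retain a candidate.
#' @param envelope_threshold density value, or `"auto"` for the
#'   volume-based low-density threshold (see [envelope_threshold]).
#' @param envelope_target_mass mass (Da) used by the auto threshold;
#'   supply the full assembly mass when fitting one subunit of a larger
#'   complex (defaults to the input model's own mass).
#' @param cluster_rmsd C-alpha RMSD (Angstrom) below which two placements
#'   are considered the same and only the better-scoring one is kept.
#' @param max_candidates library size cap after clustering.
#' @param seed integer seed (proposals are deterministic given it).
#' @param refine_max_iter pattern-search iterations per proposal.
#' @return a `fit_search_config` list.
#' @export
fit_search_config <- function(n_searches = 100000, coverage_min = 0.60,
                              envelope_threshold = "auto",
                              envelope_target_mass = NULL,
                              cluster_rmsd = 5.0, max_candidates = 1000,
                              seed = 1, refine_max_iter = 30) {
  stopifnot(n_searches >= 0, coverage_min > 0, coverage_min <= 1,
            cluster_rmsd >= 0, max_candidates >= 1)
  structure(list(n_searches = as.integer(n_searches),
                 coverage_min = coverage_min,
                 envelope_threshold = envelope_threshold,
                 envelope_target_mass = envelope_target_mass,
                 cluster_rmsd = cluster_rmsd,
                 max_candidates = as.integer(max_candidates),
                 seed = as.integer(seed),
                 refine_max_iter = as.integer(refine_max_iter)),
            class = "fit_search_config")
}

# RMSD between the same canonical coordinates under two placements
# (no superposition: placements are compared in the world frame).
placement_rmsd <- function(xyz0, t1, t2) {
  a <- apply_transform(xyz0, t1)
  b <- apply_transform(xyz0, t2)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Build a ranked rigid-body fit library for one subunit
#'
#' Proposes `n_searches` random placements (uniform rotations; centroid
#' translations uniform over the bounding box of the map envelope),
#' locally refines each against the map, discards placements with envelope
#' coverage below `coverage_min`, collapses near-duplicates within
#' `cluster_rmsd` C-alpha RMSD keeping the best-correlating representative,
#' and returns candidates sorted by descending correlation (ties broken by
#' higher coverage, then lower proposal index).
#'
#' @param model an `atomic_model` (one subunit, canonical pose).
#' @param map the target `density_map`.
#' @param config a [fit_search_config].
#' @param resolution simulation resolution (defaults to the map's hint).
#' @return a `fit_library`: list with `subunit`, `candidates` (each a
#'   `fit_candidate`), `threshold`, and `search_config`.
#' @export
build_fit_library <- function(model, map, config = fit_search_config(),
                              resolution = map$resolution_hint) {
  if (is.null(resolution))
    stop("resolution is required (map has no resolution_hint)")
  subunit <- unname(model$subunit_map[model$atoms$chain_id[1]])
  if (!nrow(model$atoms)) stop("empty model")
  thr <- if (identical(config$envelope_threshold, "auto")) {
    envelope_threshold(map, "volume",
                       target_mass = if (is.null(config$envelope_target_mass))
                         model_mass(model) else config$envelope_target_mass)
  } else as.numeric(config$envelope_threshold)
  empty_lib <- structure(list(subunit = subunit, candidates = list(),
                              threshold = thr, search_config = config),
                         class = "fit_library")
  if (config$n_searches == 0) {
    warning("n_searches = 0: returning an empty fit library")
    return(empty_lib)
  }
  xyz0 <- coords_matrix(model)
  w <- atom_weights(model)
  centroid0 <- colMeans(xyz0)
  env_idx <- which(as.numeric(map$values) >= thr)
  if (!length(env_idx)) {
    warning("no voxels above the envelope threshold; empty fit library")
    return(empty_lib)
  }
  d <- dim(map$values)
  ijk <- cbind((env_idx - 1) %% d[1],
               ((env_idx - 1) %/% d[1]) %% d[2],
               (env_idx - 1) %/% (d[1] * d[2]))
  env_world <- sweep(ijk * map$voxel_size, 2, map$origin, "+")
  bb_lo <- apply(env_world, 2, min)
  bb_hi <- apply(env_world, 2, max)
  rots <- sample_rotations(config$n_searches, seed = config$seed)
  targets <- local_seed(config$seed + 1L,
                        matrix(runif(3 * config$n_searches), ncol = 3))
  targets <- sweep(sweep(targets, 2, bb_hi - bb_lo, "*"), 2, bb_lo, "+")
  map_vals <- as.numeric(map$values)
  refined <- vector("list", config$n_searches)
  for (i in seq_len(config$n_searches)) {
    R <- rots[[i]]$rotation
    t0 <- targets[i, ] - as.numeric(R %*% centroid0)
    res <- cpp_refine_overlap(xyz0, w, map_vals, as.integer(d), map$origin,
                              map$voxel_size, R, t0,
                              trans_step = map$voxel_size,
                              rot_step = 10 * pi / 180,
                              max_iter = config$refine_max_iter, tol = 1e-5)
    refined[[i]] <- rigid_transform(.reorthogonalize(res$rotation),
                                    res$translation)
  }
  coverage <- vapply(refined, function(t)
    envelope_coverage(model, t, map, thr), numeric(1))
  keep <- which(coverage >= config$coverage_min)
  if (!length(keep)) {
    warning("no candidate passed the coverage filter; empty fit library")
    return(empty_lib)
  }
  cc <- vapply(keep, function(i)
    placed_model_cc(model, map, refined[[i]], resolution), numeric(1))
  ord <- order(-cc, -coverage[keep], keep)
  kept_t <- list(); kept_cc <- numeric(0); kept_cov <- numeric(0)
  for (j in ord) {
    t_j <- refined[[keep[j]]]
    dup <- FALSE
    for (t_k in kept_t)
      if (placement_rmsd(xyz0, t_j, t_k) <= config$cluster_rmsd) {
        dup <- TRUE; break
      }
    if (!dup) {
      kept_t[[length(kept_t) + 1L]] <- t_j
      kept_cc <- c(kept_cc, cc[j])
      kept_cov <- c(kept_cov, coverage[keep[j]])
      if (length(kept_t) >= config$max_candidates) break
    }
  }
  cands <- lapply(seq_along(kept_t), function(i)
    structure(list(transform = kept_t[[i]], cc = kept_cc[i],
                   coverage = kept_cov[i]), class = "fit_candidate"))
  structure(list(subunit = subunit, candidates = cands, threshold = thr,
                 search_config = config),
            class = "fit_library")
}

#' @export
print.fit_library <- function(x, ...) {
  cat(sprintf("<fit_library> subunit %s: %d candidate placement(s)\n",
              x$subunit, length(x$candidates)))
  if (length(x$candidates))
    cat(sprintf("  top cc %.3f, coverage %.2f\n",
                x$candidates[[1]]$cc, x$candidates[[1]]$coverage))
  invisible(x)
}

#' Serialize a fit library to JSON lines
#'
#' One record per candidate:
#' `{subunit, rotation (9, row-major), translation (3), cc, coverage}`.
#'
#' @param library a `fit_library`.
#' @param path output path.
#' @export
write_fit_library <- function(library, path) {
  lines <- vapply(library$candidates, function(cand)
    jsonlite::toJSON(list(subunit = library$subunit,
                          rotation = as.numeric(t(cand$transform$rotation)),
                          translation = cand$transform$translation,
                          cc = cand$cc, coverage = cand$coverage),
                     auto_unbox = TRUE, digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fit_library
#' @param path path to a JSON-lines fit library.
#' @export
read_fit_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty fit library file: ", path)
  recs <- lapply(lines, jsonlite::fromJSON)
  cands <- lapply(recs, function(r)
    structure(list(transform = rigid_transform(
                     matrix(as.numeric(r$rotation), 3, 3, byrow = TRUE),
                     as.numeric(r$translation)),
                   cc = r$cc, coverage = r$coverage),
              class = "fit_candidate"))
  structure(list(subunit = recs[[1]]$subunit, candidates = cands,
                 threshold = NA_real_, search_config = NULL),
            class = "fit_library")
}
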