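single_atom_model <- function(x = 0, y = 0, z = 0) {
  atomic_model(data.frame(chain_id = "A", residue_number = 1,
                          residue_name = "GLY", atom_name = "CA",
                          element = "C", x = x, y = y, z = z))
}

test_that("simulated maps peak at the atom and respect symmetry", {
  m <- single_atom_model()
  map <- simulate_map(m, resolution = 10, voxel_size = 2, padding = 12)
  peak <- which(map$values == max(map$values), arr.ind = TRUE)[1, ]
  world <- map$origin + map$voxel_size * (peak - 1)
  expect_true(all(abs(world) <= map$voxel_size / 2 + 1e-9))
  # the atom sits at the center of a symmetric grid: permuting coordinate
  # axes must leave the map invariant
  expect_equal(map$values, aperm(map$values, c(2, 1, 3)), tolerance = 1e-6)
  expect_equal(map$values, aperm(map$values, c(3, 2, 1)), tolerance = 1e-6)
})

test_that("simulated map integral matches the analytic Gaussian integral", {
  model <- random_ca_model(15, seed = 11, spread = 20)
  res <- 8
  sigma <- res / (pi * sqrt(2))
  map <- simulate_map(model, res, voxel_size = 1, padding = 5 * sigma)
  total <- sum(map$values) * map$voxel_size^3
  analytic <- sum(xlassemble:::atom_weights(model)) * (2 * pi * sigma^2)^1.5
  expect_equal(total, analytic, tolerance = 0.01)
})

test_that("two distant identical atoms give two equal maxima", {
  m <- atomic_model(data.frame(chain_id = "A", residue_number = 1:2,
                               residue_name = "GLY", atom_name = "CA",
                               element = "C", x = c(0, 40), y = 0, z = 0))
  map <- simulate_map(m, resolution = 10, voxel_size = 2, padding = 10)
  value_at <- function(p) {
    idx <- round((p - map$origin) / map$voxel_size) + 1
    map$values[idx[1], idx[2], idx[3]]
  }
  expect_equal(value_at(c(0, 0, 0)), value_at(c(40, 0, 0)),
               tolerance = 1e-6)
})

test_that("simulate_map rejects undersampled and empty inputs", {
  m <- single_atom_model()
  expect_error(simulate_map(m, resolution = 3, voxel_size = 2),
               "undersampling")
  empty <- atomic_model(data.frame(chain_id = character(0),
                                   residue_number = integer(0),
                                   residue_name = character(0),
                                   atom_name = character(0),
                                   element = character(0), x = numeric(0),
                                   y = numeric(0), z = numeric(0)))
  expect_error(simulate_map(empty, 8), "empty")
})

test_that("cross-correlation matches a brute-force voxel loop", {
  set.seed(12)
  a <- density_map(array(rnorm(16^3), dim = rep(16, 3)), 1)
  b <- density_map(array(rnorm(16^3), dim = rep(16, 3)), 1)
  expect_equal(cross_correlation(a, a), 1.0, tolerance = 1e-12)
  neg <- density_map(-a$values, 1)
  expect_equal(cross_correlation(a, neg), -1.0, tolerance = 1e-12)

  # brute force: explicit accumulation loop over voxels
  brute_pearson <- function(x, y) {
    n <- length(x); sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
    for (i in seq_len(n)) {
      sx <- sx + x[i]; sy <- sy + y[i]
      sxx <- sxx + x[i]^2; syy <- syy + y[i]^2; sxy <- sxy + x[i] * y[i]
    }
    (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  }
  expect_equal(cross_correlation(a, b),
               brute_pearson(as.numeric(a$values), as.numeric(b$values)),
               tolerance = 1e-6)
  mask <- as.numeric(a$values) > 0.5
  expect_equal(cross_correlation(a, b, mask = mask),
               brute_pearson(as.numeric(a$values)[mask],
                             as.numeric(b$values)[mask]),
               tolerance = 1e-6)
})

test_that("cross-correlation is invariant under affine rescaling", {
  set.seed(13)
  a <- density_map(array(rnorm(10^3), dim = rep(10, 3)), 2)
  b <- density_map(array(rnorm(10^3), dim = rep(10, 3)), 2)
  r0 <- cross_correlation(a, b)
  scaled <- density_map(3.7 * a$values + 11, 2)
  expect_equal(cross_correlation(scaled, b), r0, tolerance = 1e-12)

  expect_error(cross_correlation(a, density_map(array(0, dim = rep(10, 3)), 2)),
               "constant")
  expect_error(cross_correlation(a, density_map(array(1, dim = rep(9, 3)), 2)),
               "grid")
})

test_that("envelope threshold inverts volumes correctly", {
  uni <- density_map(array(5, dim = c(10, 10, 10)), 2)
  # request less volume than the grid: every voxel has the same value
  expect_equal(envelope_threshold(uni, "volume", target_mass = 1000), 5)
  expect_equal(envelope_threshold(uni, "fixed", value = 0.123), 0.123)
  expect_error(envelope_threshold(uni, "volume", target_mass = 1e9),
               "exceeds")

  # Gaussian ball: threshold for a requested volume should match the
  # analytic iso-surface radius within a voxel shell
  m <- single_atom_model()
  res <- 12
  sigma <- res / (pi * sqrt(2))
  map <- simulate_map(m, res, voxel_size = 1, padding = 6 * sigma)
  mass <- 500
  thr <- envelope_threshold(map, "volume", target_mass = mass,
                            volume_scale = 1)
  amp <- max(map$values)
  r_analytic <- sigma * sqrt(2 * log(amp / thr))
  r_volume <- (3 * mass * 1.21 / (4 * pi))^(1 / 3)
  expect_lt(abs(r_analytic - r_volume), map$voxel_size)
})

test_that("envelope coverage counts atoms above threshold", {
  # left half of the grid high, right half low; 10 atoms in each
  vals <- array(0, dim = c(20, 10, 10))
  vals[1:10, , ] <- 2
  map <- density_map(vals, voxel_size = 2, origin = c(0, 0, 0))
  at <- data.frame(chain_id = "A", residue_number = 1:20,
                   residue_name = "GLY", atom_name = "CA", element = "C",
                   x = c(seq(2, 11, by = 1), seq(26, 35, by = 1)),
                   y = 9, z = 9)
  m <- atomic_model(at)
  thr <- 1
  # direct per-atom check as the oracle
  direct <- mean(c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(envelope_coverage(m, rigid_transform(), map, thr), direct)

  all_out <- apply_transform(m, rigid_transform(diag(3), c(1000, 0, 0)))
  expect_equal(envelope_coverage(all_out, rigid_transform(), map, thr), 0)
  expect_equal(envelope_coverage(m, rigid_transform(), map, -1), 1)
})

test_that("rotation sampling is deterministic, orthogonal and uniform", {
  r1 <- sample_rotations(1, seed = 42)
  r2 <- sample_rotations(1, seed = 42)
  expect_identical(r1[[1]]$rotation, r2[[1]]$rotation)

  rots <- sample_rotations(200, seed = 8)
  for (r in rots[1:20]) {
    expect_lt(max(abs(crossprod(r$rotation) - diag(3))), 1e-8)
    expect_equal(det(r$rotation), 1, tolerance = 1e-8)
  }
  # mean rotation angle under the uniform (Haar) measure:
  # E[theta] = pi/2 + 2/pi (density (1 - cos t)/pi on [0, pi])
  rots <- sample_rotations(20000, seed = 9)
  ang <- vapply(rots, function(r)
    acos(pmin(1, pmax(-1, (sum(diag(r$rotation)) - 1) / 2))), numeric(1))
  expect_equal(mean(ang) * 180 / pi, (pi / 2 + 2 / pi) * 180 / pi,
               tolerance = 1 / 126.5)
})

test_that("local refinement converges and its objective never decreases", {
  truth <- bundle_truth()
  s <- "S1"
  model <- truth$canonical[[s]]
  placed <- apply_transform(model, truth$transforms[[s]])
  map <- simulate_map(placed, resolution = 8, voxel_size = 2, padding = 10)

  # fixed point: starting at the optimum stays at the optimum
  at_opt <- refine_fit_local(model, map, truth$transforms[[s]],
                             max_iter = 10)
  expect_lt(rmsd_to_truth(truth, s, at_opt$transform), 0.15)

  # displaced start converges back to ground truth
  start <- rigid_transform(truth$transforms[[s]]$rotation,
                           truth$transforms[[s]]$translation + c(2, 0, 0))
  ref <- refine_fit_local(model, map, start, max_iter = 60)
  expect_lt(rmsd_to_truth(truth, s, ref$transform), 0.5)
  expect_gte(ref$cc, placed_cc_start <- ref$trace[1] - 1e-12)
  # the accepted-score sequence is non-decreasing by construction
  expect_true(all(diff(ref$trace) >= -1e-12))
})

test_that("fit search config defaults follow the published protocol", {
  cfg <- fit_search_config()
  expect_identical(cfg$n_searches, 100000L)
  expect_identical(cfg$coverage_min, 0.60)
})

test_that("fit libraries recover a self-simulated ground truth", {
  truth <- bundle_truth()
  libs <- bundle_libs()
  for (s in names(libs)) {
    lib <- libs[[s]]
    expect_gt(length(lib$candidates), 0)
    expect_lt(rmsd_to_truth(truth, s, lib$candidates[[1]]$transform), 1.0)
    ccs <- vapply(lib$candidates, `[[`, numeric(1), "cc")
    covs <- vapply(lib$candidates, `[[`, numeric(1), "coverage")
    # sorted by cc; every candidate passed the coverage filter
    expect_true(all(diff(ccs) <= 1e-12))
    expect_true(all(covs >= lib$search_config$coverage_min))
    expect_true(all(ccs >= -1 & ccs <= 1))
    # no candidate beats the ground-truth placement's own correlation
    truth_cc <- refine_fit_local(truth$canonical[[s]], bundle_map(),
                                 truth$transforms[[s]], max_iter = 0)$cc
    expect_true(all(ccs <= truth_cc + 0.01))
  }
})

test_that("fit library clustering never keeps near-duplicate placements", {
  truth <- bundle_truth()
  libs <- bundle_libs()
  for (s in names(libs)) {
    lib <- libs[[s]]
    ca0 <- coords_matrix(truth$canonical[[s]], atom_name = "CA")
    n <- length(lib$candidates)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d <- sqrt(mean(rowSums((
        apply_transform(ca0, lib$candidates[[i]]$transform) -
        apply_transform(ca0, lib$candidates[[j]]$transform))^2)))
      expect_gt(d, lib$search_config$cluster_rmsd)
    }
  }
})

test_that("fit library generation is reproducible for a fixed seed", {
  truth <- bundle_truth()
  map <- bundle_map()
  cfg <- fit_search_config(n_searches = 120,
                           envelope_target_mass = model_mass(truth$model),
                           max_candidates = 5, seed = 77)
  lib1 <- build_fit_library(truth$canonical$S1, map, cfg)
  lib2 <- build_fit_library(truth$canonical$S1, map, cfg)
  expect_equal(length(lib1$candidates), length(lib2$candidates))
  for (i in seq_along(lib1$candidates)) {
    expect_identical(lib1$candidates[[i]]$transform$rotation,
                     lib2$candidates[[i]]$transform$rotation)
    expect_identical(lib1$candidates[[i]]$cc, lib2$candidates[[i]]$cc)
  }
})

test_that("degenerate fit searches return empty libraries with warnings", {
  truth <- bundle_truth()
  map <- bundle_map()
  cfg0 <- fit_search_config(n_searches = 0,
                            envelope_target_mass = model_mass(truth$model))
  expect_warning(lib0 <- build_fit_library(truth$canonical$S1, map, cfg0),
                 "empty")
  expect_length(lib0$candidates, 0)
})

test_that("fit libraries serialize to JSON lines and back", {
  libs <- bundle_libs()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_fit_library(libs$S2, f)
  back <- read_fit_library(f)
  expect_equal(back$subunit, libs$S2$subunit)
  expect_equal(length(back$candidates), length(libs$S2$candidates))
  expect_equal(back$candidates[[1]]$transform$rotation,
               libs$S2$candidates[[1]]$transform$rotation,
               tolerance = 1e-12)
  expect_equal(back$candidates[[1]]$cc, libs$S2$candidates[[1]]$cc)
})
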