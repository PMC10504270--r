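# Shared fixtures, built once per test run and memoized.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The default study-condition bundle: 3 random-walk subunits x 60 residues,
# 8 A map on 2 A voxels, 12 true cross-links + 20% decoys.
bundle_truth <- function() memo("truth", function()
  make_toy_complex(toy_complex_spec(seed = 7)))

bundle_map <- function() memo("map", function()
  simulate_map(bundle_truth()$model, resolution = 8, voxel_size = 2,
               padding = 12))

bundle_xl <- function() memo("xl", function()
  simulate_crosslinks(bundle_truth(), n_true = 12, decoy_fraction = 0.2,
                      seed = 3))

bundle_name_map <- function() list(P1 = "S1", P2 = "S2", P3 = "S3")

# Fit libraries at the desk-scale search depth (2000 proposals/subunit).
bundle_libs <- function() memo("libs", function() {
  truth <- bundle_truth()
  cfg <- fit_search_config(n_searches = 2000,
                           envelope_target_mass = model_mass(truth$model),
                           max_candidates = 10, seed = 11,
                           refine_max_iter = 60)
  lapply(truth$canonical, build_fit_library, map = bundle_map(),
         config = cfg)
})

# C-alpha RMSD of a placed subunit against its ground-truth placement.
rmsd_to_truth <- function(truth, subunit, transform) {
  ca0 <- coords_matrix(truth$canonical[[subunit]], atom_name = "CA")
  a <- apply_transform(ca0, transform)
  b <- apply_transform(ca0, truth$transforms[[subunit]])
  sqrt(mean(rowSums((a - b)^2)))
}

# Hand-built fit library from explicit transforms (first = ground truth).
manual_library <- function(subunit, transforms, cc = NULL, coverage = NULL) {
  cands <- lapply(seq_along(transforms), function(i)
    structure(list(transform = transforms[[i]],
                   cc = if (is.null(cc)) 1 - (i - 1) * 0.01 else cc[i],
                   coverage = if (is.null(coverage)) 1 else coverage[i]),
              class = "fit_candidate"))
  structure(list(subunit = subunit, candidates = cands,
                 threshold = NA_real_, search_config = NULL),
            class = "fit_library")
}

# Random small rigid perturbation of a transform (for decoy candidates).
perturb_transform <- function(t, trans_sd = 8, angle_sd = 0.6) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- xlassemble:::rotation_about_axis(ax, rnorm(1, sd = angle_sd))
  rigid_transform(R %*% t$rotation,
                  as.numeric(R %*% t$translation) + rnorm(3, sd = trans_sd))
}

# A tiny 3-subunit complex with 5-candidate synthetic libraries (ground
# truth + 4 perturbed decoys each), small enough for exhaustive search.
tiny_space <- function() memo("tiny", function() {
  truth <- make_toy_complex(toy_complex_spec(
    n_subunits = 3, residues_per_subunit = 30, seed = 21))
  map <- simulate_map(truth$model, resolution = 9, voxel_size = 3,
                      padding = 9)
  xl <- simulate_crosslinks(truth, n_true = 8, decoy_fraction = 0.25,
                            seed = 22)
  set.seed(23)
  libs <- lapply(names(truth$canonical), function(s) {
    tr <- c(list(truth$transforms[[s]]),
            lapply(1:4, function(i) perturb_transform(truth$transforms[[s]])))
    manual_library(s, tr)
  })
  names(libs) <- names(truth$canonical)
  list(truth = truth, map = map, xl = xl, libs = libs,
       name_map = bundle_name_map())
})

random_ca_model <- function(n, seed, chains = "A", spread = 30) {
  set.seed(seed)
  per <- ceiling(n / length(chains))
  tab <- do.call(rbind, lapply(seq_along(chains), function(ci)
    data.frame(chain_id = chains[ci], residue_number = seq_len(per),
               residue_name = "ALA", atom_name = "CA", element = "C",
               x = runif(per, 0, spread), y = runif(per, 0, spread),
               z = runif(per, 0, spread), stringsAsFactors = FALSE)))
  atomic_model(tab[seq_len(n), , drop = FALSE])
}
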