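test_that("the ground-truth configuration scores zero against its own map", {
  truth <- bundle_truth()
  libs <- lapply(names(truth$canonical), function(s)
    manual_library(s, list(truth$transforms[[s]])))
  names(libs) <- names(truth$canonical)
  sc <- composite_score(list(S1 = 1, S2 = 1, S3 = 1), truth$canonical,
                        libs, bundle_map(),
                        weights = score_weights(w_cc = 1, w_xl = 0,
                                                w_clash = 0))
  expect_equal(sc$total, 0, tolerance = 1e-6)
  expect_equal(sc$density_term, 0, tolerance = 1e-6)
})

test_that("the harmonic cross-link penalty arithmetic is exact", {
  # two single-residue subunits 45 A apart, one DSSO link between them:
  # pen = ((45 - 35)/10)^2 = 1 with the untruncated penalty
  mk <- function(chain, sub, x) atomic_model(
    data.frame(chain_id = chain, residue_number = 1, residue_name = "GLY",
               atom_name = "CA", element = "C", x = x, y = 0, z = 0),
    subunit_map = stats::setNames(sub, chain))
  models <- list(U = mk("A", "U", 0), V = mk("B", "V", 45))
  libs <- list(U = manual_library("U", list(rigid_transform())),
               V = manual_library("V", list(rigid_transform())))
  xl <- crosslink_set(data.frame(protein_a = "U", residue_a = 1,
                                 protein_b = "V", residue_b = 1))
  map <- simulate_map(atomic_model(rbind(models$U$atoms, models$V$atoms),
                                   c(A = "U", B = "V")),
                      resolution = 10, voxel_size = 2.5, padding = 10)
  w <- score_weights(w_cc = 0, w_xl = 1, w_clash = 0, xl_cap = Inf)
  sc <- composite_score(list(U = 1, V = 1), models, libs, map, xl,
                        name_map = list(U = "U", V = "V"), weights = w)
  expect_equal(sc$xl_term, 1.0, tolerance = 1e-12)
  expect_equal(sc$total, 1.0, tolerance = 1e-12)
  # the robust default truncates the same violation at xl_cap
  w2 <- score_weights(w_cc = 0, w_xl = 1, w_clash = 0)
  sc2 <- composite_score(list(U = 1, V = 1), models, libs, map, xl,
                         name_map = list(U = "U", V = "V"), weights = w2)
  expect_equal(sc2$xl_term, w2$xl_cap, tolerance = 1e-12)
})

test_that("enumerated totals match independently recomputed term sums", {
  sp <- tiny_space()
  w <- score_weights()
  ex <- enumerate_configurations(sp$truth$canonical, sp$libs, sp$map,
                                 sp$xl, sp$name_map, weights = w)
  expect_equal(ex$n_evaluated, 125)

  # independent recomputation: simulate each subunit map, sum, correlate;
  # distances and clashes by direct pairwise arithmetic
  recompute <- function(choices) {
    placed <- lapply(names(sp$libs), function(s)
      apply_transform(sp$truth$canonical[[s]],
                      sp$libs[[s]]$candidates[[choices[[s]]]]$transform))
    names(placed) <- names(sp$libs)
    combined <- Reduce(`+`, lapply(placed, function(p)
      simulate_map(p, resolution = 9, grid = sp$map)$values))
    density <- 1 - cor(as.numeric(sp$map$values), as.numeric(combined))
    ca <- lapply(placed, coords_matrix, atom_name = "CA")
    xlpen <- 0
    for (i in seq_len(nrow(sp$xl$links))) {
      li <- sp$xl$links[i, ]
      sa <- sp$name_map[[li$protein_a]]; sb <- sp$name_map[[li$protein_b]]
      d <- sqrt(sum((ca[[sa]][li$residue_a, ] - ca[[sb]][li$residue_b, ])^2))
      xlpen <- xlpen + min((max(0, d - li$max_dist) / w$soft_scale)^2,
                           w$xl_cap)
    }
    nclash <- 0
    subs <- names(ca)
    for (i in seq_len(length(subs) - 1)) for (j in seq(i + 1, length(subs))) {
      dd <- as.matrix(stats::dist(rbind(ca[[subs[i]]], ca[[subs[j]]])))
      ni <- nrow(ca[[subs[i]]])
      nclash <- nclash + sum(dd[seq_len(ni), -seq_len(ni)] < w$clash_cutoff)
    }
    w$w_cc * density + w$w_xl * xlpen + w$w_clash * nclash
  }
  set.seed(41)
  for (k in 1:8) {
    choices <- list(S1 = sample.int(5, 1), S2 = sample.int(5, 1),
                    S3 = sample.int(5, 1))
    sc <- composite_score(choices, sp$truth$canonical, sp$libs, sp$map,
                          sp$xl, sp$name_map, weights = w)
    expect_equal(sc$total, recompute(choices), tolerance = 1e-9)
  }
  expect_equal(ex$score$total, recompute(ex$choices), tolerance = 1e-9)
})

test_that("the exhaustive oracle lower-bounds annealing and handles edges", {
  sp <- tiny_space()
  ex <- enumerate_configurations(sp$truth$canonical, sp$libs, sp$map,
                                 sp$xl, sp$name_map)
  res <- anneal(sp$truth$canonical, sp$libs, sp$map, sp$xl, sp$name_map,
                schedule = anneal_schedule(n_steps = 400, seed = 2))
  expect_gte(res$score$total, ex$score$total - 1e-12)

  # single-candidate space: both methods must return it
  one_lib <- list(S1 = manual_library("S1", list(sp$truth$transforms$S1)))
  ex1 <- enumerate_configurations(sp$truth$canonical["S1"], one_lib,
                                  sp$map)
  expect_equal(ex1$choices$S1, 1)
  an1 <- anneal(sp$truth$canonical["S1"], one_lib, sp$map,
                schedule = anneal_schedule(n_steps = 50, seed = 1))
  expect_equal(an1$choices$S1, 1)

  # refusal bound
  expect_error(enumerate_configurations(sp$truth$canonical, sp$libs,
                                        sp$map, sp$xl, sp$name_map,
                                        max_configs = 100),
               "too large")
  # empty library named in the error
  bad <- sp$libs
  bad$S2 <- manual_library("S2", list())
  expect_error(anneal(sp$truth$canonical, bad, sp$map), "S2")
})

test_that("annealing is reproducible and tracks the best-ever score", {
  sp <- tiny_space()
  a1 <- anneal(sp$truth$canonical, sp$libs, sp$map, sp$xl, sp$name_map,
               schedule = anneal_schedule(n_steps = 300, seed = 5))
  a2 <- anneal(sp$truth$canonical, sp$libs, sp$map, sp$xl, sp$name_map,
               schedule = anneal_schedule(n_steps = 300, seed = 5))
  expect_identical(a1$choices, a2$choices)
  expect_identical(a1$trace, a2$trace)
  expect_true(all(diff(a1$trace$best_total) <= 1e-12))
  expect_true(all(a1$trace$best_total <= a1$trace$current_total + 1e-12))
})

test_that("zero-temperature annealing reduces to greedy descent", {
  sp <- tiny_space()
  res <- anneal(sp$truth$canonical, sp$libs, sp$map, sp$xl, sp$name_map,
                schedule = anneal_schedule(
                  t_start = 0, n_steps = 200, seed = 3,
                  move_probs = c(resample_fit = 1,
                                 swap_identical_copies = 0)))
  cur <- res$trace$current_total
  expect_true(all(diff(cur) <= 1e-12))
})

test_that("swapping geometrically identical copies leaves the score unchanged", {
  truth <- make_toy_complex(toy_complex_spec(
    n_subunits = 3, residues_per_subunit = 40,
    identical_copies = list(c(1, 2)), seed = 15))
  map <- simulate_map(truth$model, resolution = 8, voxel_size = 2,
                      padding = 10)
  xl <- simulate_crosslinks(truth, n_true = 8, decoy_fraction = 0,
                            seed = 16)
  # both copies share one library holding both true placements
  copy_lib_tr <- list(truth$transforms$S1, truth$transforms$S2)
  libs <- list(S1 = manual_library("S1", copy_lib_tr),
               S2 = manual_library("S2", copy_lib_tr),
               S3 = manual_library("S3", list(truth$transforms$S3)))
  nm <- list(P1 = c("S1", "S2"), P3 = "S3")
  sc_a <- composite_score(list(S1 = 1, S2 = 2, S3 = 1), truth$canonical,
                          libs, map, xl, nm)
  sc_b <- composite_score(list(S1 = 2, S2 = 1, S3 = 1), truth$canonical,
                          libs, map, xl, nm)
  expect_equal(sc_a$total, sc_b$total, tolerance = 1e-9)

  res <- anneal(truth$canonical, libs, map, xl, nm,
                schedule = anneal_schedule(n_steps = 300, seed = 6),
                identical_groups = list(c("S1", "S2")))
  # the optimum places the two copies on the two true positions
  expect_setequal(unlist(res$choices[c("S1", "S2")]), c(1, 2))
})

test_that("ensemble analysis separates placement modes with correct populations", {
  sp <- tiny_space()
  coords_for <- function(choices)
    configuration_coords(choices, sp$truth$canonical, sp$libs)
  identical_runs <- replicate(4, coords_for(list(S1 = 1, S2 = 1, S3 = 1)),
                              simplify = FALSE)
  ens <- ensemble_analysis(identical_runs)
  for (s in names(ens)) {
    expect_equal(ens[[s]]$n_modes, 1)
    expect_equal(ens[[s]]$spread, 0)
  }
  # planted 60/40 split for S1 (two well-separated library placements)
  runs <- c(replicate(6, coords_for(list(S1 = 1, S2 = 1, S3 = 1)),
                      simplify = FALSE),
            replicate(4, coords_for(list(S1 = 3, S2 = 1, S3 = 1)),
                      simplify = FALSE))
  ens2 <- ensemble_analysis(runs)
  expect_equal(ens2$S1$n_modes, 2)
  expect_equal(unname(ens2$S1$populations), c(0.6, 0.4))
  expect_equal(ens2$S2$n_modes, 1)
  expect_error(ensemble_analysis(identical_runs[1]), "at least 2")
})

test_that("candidate composition ranking discriminates a heterodimer", {
  # two distinguishable subunit shapes: compact walk (A) vs straight
  # helix (B); target map holds the AB heterodimer
  mk_dimer <- function(first, second) {
    s1 <- if (first == "A") walkA else helixB
    s2 <- if (second == "A") walkA else helixB
    a1 <- s1$atoms; a1$chain_id <- "A"
    a2 <- apply_transform(s2, rigid_transform(diag(3), c(25, 0, 0)))$atoms
    a2$chain_id <- "B"
    atomic_model(rbind(a1, a2), c(A = "c1", B = "c2"))
  }
  set.seed(51)
  walkA <- xlassemble:::.ca_model(
    xlassemble:::.canonical_subunit(40, "random_walk"), "A", "W")
  helixB <- xlassemble:::.ca_model(
    xlassemble:::.canonical_subunit(40, "ideal_helix"), "A", "H")
  target <- mk_dimer("A", "B")
  map <- simulate_map(target, resolution = 8, voxel_size = 2, padding = 10)
  cands <- list(AA = mk_dimer("A", "A"), BB = mk_dimer("B", "B"),
                AB = mk_dimer("A", "B"))
  cfg <- fit_search_config(n_searches = 400, max_candidates = 3,
                           coverage_min = 0.2,
                           envelope_target_mass = model_mass(target),
                           seed = 52, refine_max_iter = 60)
  ranked <- rank_candidate_models(cands, map, resolution = 8,
                                  config = cfg)
  expect_equal(ranked$candidate[1], "AB")
  others <- ranked$cc[-1]
  expect_true(all(is.na(others) | others < ranked$cc[1]))

  # self candidate, already placed, correlates near-perfectly
  self <- rank_candidate_models(list(self = target), map, resolution = 8,
                                pre_placed = TRUE)
  expect_equal(self$cc[1], 1, tolerance = 1e-6)
  expect_equal(self$rank[1], 1)
  expect_error(rank_candidate_models(list(), map), "empty")
})
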