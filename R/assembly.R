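#' Score weights for the assembly objective
#'
#' The composite objective (lower is better) is
#' `total = w_cc * (1 - cc) + w_xl * sum(pen(d)) + w_clash * n_clash`,
#' where `cc` is the correlation of the combined simulated map with the
#' target, `d` is each link's minimum C-alpha distance over copies, and
#' `n_clash` counts inter-subunit C-alpha pairs closer than `clash_cutoff`.
#' The per-link penalty is a truncated harmonic upper bound,
#' `pen(d) = min((pmax(0, d - max_dist) / soft_scale)^2, xl_cap)`:
#' the truncation makes the score robust to false-positive links, which
#' real cross-link sets always contain — a link that cannot be satisfied
#' contributes a bounded penalty instead of dragging the assembly into a
#' distorted configuration. Set `xl_cap = Inf` for the plain (untruncated)
#' harmonic penalty.
#'
#' @param w_cc,w_xl,w_clash term weights.
#' @param soft_scale softness of the harmonic upper-bound penalty (Angstrom).
#' @param clash_cutoff inter-subunit C-alpha contact distance (Angstrom).
#' @param xl_cap per-link penalty truncation; the default 0.1 is a tenth
#'   of the density term's range, keeping any single false link's
#'   influence below the density evidence for even a largely
#'   self-overlapping misplacement of one subunit.
#' @return a `score_weights` list.
#' @export
score_weights <- function(w_cc = 1, w_xl = 1, w_clash = 0.1,
                          soft_scale = 10, clash_cutoff = 4.0,
                          xl_cap = 0.1) {
  structure(list(w_cc = w_cc, w_xl = w_xl, w_clash = w_clash,
                 soft_scale = soft_scale, clash_cutoff = clash_cutoff,
                 xl_cap = xl_cap),
            class = "score_weights")
}

# Precompute everything score evaluation needs: per-candidate sparse
# simulated density on the target grid and placed C-alpha coordinates.
build_assembly_context <- function(models, libraries, map, xl = NULL,
                                   name_map = NULL,
                                   weights = score_weights(),
                                   resolution = map$resolution_hint) {
  stopifnot(length(models) >= 1)
  subunits <- names(libraries)
  if (is.null(subunits) || !all(subunits %in% names(models)))
    stop("`models` and `libraries` must be named lists over the same subunits")
  if (is.null(resolution)) stop("resolution required (no map resolution_hint)")
  empty <- subunits[vapply(libraries, function(l) !length(l$candidates),
                           logical(1))]
  if (length(empty))
    stop("empty fit library for subunit(s): ", paste(empty, collapse = ", "))
  target <- as.numeric(map$values)
  ctx <- list(subunits = subunits, map = map, target = target,
              weights = weights, resolution = resolution,
              n_cand = vapply(libraries, function(l) length(l$candidates),
                              integer(1)))
  ctx$cand <- lapply(subunits, function(s) {
    mdl <- models[[s]]
    ca0 <- coords_matrix(mdl, atom_name = "CA")
    resno <- mdl$atoms$residue_number[mdl$atoms$atom_name == "CA"]
    lapply(libraries[[s]]$candidates, function(cand) {
      placed <- apply_transform(mdl, cand$transform)
      sim <- simulate_map(placed, resolution, grid = map)
      v <- as.numeric(sim$values)
      idx <- which(v > 0)
      list(ca = apply_transform(ca0, cand$transform), resno = resno,
           sparse_idx = idx, sparse_val = v[idx])
    })
  })
  names(ctx$cand) <- subunits
  # resolve each cross-link to (subunit, CA row) index pairs once
  ctx$links <- list()
  if (!is.null(xl) && nrow(xl$links)) {
    if (is.null(name_map))
      name_map <- stats::setNames(as.list(subunits), subunits)
    for (i in seq_len(nrow(xl$links))) {
      li <- xl$links[i, ]
      subs_a <- intersect(name_map[[li$protein_a]], subunits)
      subs_b <- intersect(name_map[[li$protein_b]], subunits)
      pairs <- list()
      for (sa in subs_a) for (sb in subs_b) {
        ra <- match(li$residue_a, ctx$cand[[sa]][[1]]$resno)
        rb <- match(li$residue_b, ctx$cand[[sb]][[1]]$resno)
        if (is.na(ra) || is.na(rb)) next
        if (sa == sb && ra == rb) next
        pairs[[length(pairs) + 1L]] <- list(sa = sa, ra = ra, sb = sb, rb = rb)
      }
      if (length(pairs))
        ctx$links[[length(ctx$links) + 1L]] <-
          list(max_dist = li$max_dist, pairs = pairs)
    }
    if (length(ctx$links) < nrow(xl$links))
      warning(nrow(xl$links) - length(ctx$links),
              " cross-link(s) could not be mapped onto the assembly subunits")
  }
  ctx
}

# Score one choice vector (named integer: subunit -> candidate index).
score_in_context <- function(ctx, choices) {
  w <- ctx$weights
  combined <- numeric(length(ctx$target))
  all_ca <- list()
  group <- list()
  for (si in seq_along(ctx$subunits)) {
    s <- ctx$subunits[si]
    k <- choices[[s]]
    if (is.na(k) || k < 1 || k > ctx$n_cand[[s]])
      stop("invalid candidate index for subunit ", s)
    cand <- ctx$cand[[s]][[k]]
    combined[cand$sparse_idx] <- combined[cand$sparse_idx] + cand$sparse_val
    all_ca[[si]] <- cand$ca
    group[[si]] <- rep(si, nrow(cand$ca))
  }
  cc <- if (sd(combined) == 0) 0 else cor(ctx$target, combined)
  density_term <- 1 - cc
  xl_term <- 0
  for (lk in ctx$links) {
    dmin <- Inf
    for (p in lk$pairs) {
      ka <- choices[[p$sa]]; kb <- choices[[p$sb]]
      d <- sqrt(sum((ctx$cand[[p$sa]][[ka]]$ca[p$ra, ] -
                     ctx$cand[[p$sb]][[kb]]$ca[p$rb, ])^2))
      if (d < dmin) dmin <- d
    }
    xl_term <- xl_term +
      min((max(0, dmin - lk$max_dist) / w$soft_scale)^2, w$xl_cap)
  }
  clash_term <- if (length(all_ca) > 1)
    cpp_cross_group_contacts(do.call(rbind, all_ca),
                             as.integer(unlist(group)), w$clash_cutoff)
  else 0L
  total <- w$w_cc * density_term + w$w_xl * xl_term + w$w_clash * clash_term
  list(density_term = density_term, xl_term = xl_term,
       clash_term = clash_term, total = total)
}

#' Composite score of one assembly configuration
#'
#' Deterministically evaluates the density, cross-link, and clash terms of
#' a configuration (one fit-library candidate index per subunit); see
#' [score_weights] for the objective.
#'
#' @param choices named integer vector/list: subunit label -> candidate
#'   index into that subunit's fit library.
#' @param models named list of canonical-pose `atomic_model`s per subunit.
#' @param libraries named list of `fit_library` objects per subunit.
#' @param map the target `density_map`.
#' @param xl optional `crosslink_set`.
#' @param name_map named list: protein label -> subunit labels (copies).
#' @param weights a [score_weights].
#' @param resolution simulation resolution (defaults to the map's hint).
#' @return list with `density_term`, `xl_term`, `clash_term`, `total`.
#' @export
composite_score <- function(choices, models, libraries, map, xl = NULL,
                            name_map = NULL, weights = score_weights(),
                            resolution = map$resolution_hint) {
  ctx <- build_assembly_context(models, libraries, map, xl, name_map,
                                weights, resolution)
  score_in_context(ctx, as.list(choices))
}

#' Annealing schedule
#'
#' @param t_start starting temperature, or `"auto"` to calibrate so that
#'   roughly half of 100 random uphill moves from the initial
#'   configuration are accepted.
#' @param cooling geometric cooling factor per step (0 < cooling < 1).
#' @param n_steps number of Monte Carlo steps.
#' @param move_probs named probabilities for `resample_fit` (pick a new
#'   library candidate for a random subunit) and `swap_identical_copies`
#'   (exchange the placements of two copies in an identical group).
#' @param seed integer seed; the run is fully reproducible given it.
#' @return an `anneal_schedule` list.
#' @export
anneal_schedule <- function(t_start = "auto", cooling = 0.995,
                            n_steps = 10000,
                            move_probs = c(resample_fit = 0.8,
                                           swap_identical_copies = 0.2),
                            seed = 1) {
  stopifnot(cooling > 0, cooling < 1, n_steps >= 1)
  if (abs(sum(move_probs) - 1) > 1e-9)
    stop("move probabilities must sum to 1")
  structure(list(t_start = t_start, cooling = cooling,
                 n_steps = as.integer(n_steps), move_probs = move_probs,
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

# lexicographic comparison of two choice vectors (same subunit order)
.choices_less <- function(a, b, subunits) {
  for (s in subunits) {
    if (a[[s]] < b[[s]]) return(TRUE)
    if (a[[s]] > b[[s]]) return(FALSE)
  }
  FALSE
}

#' Simultaneous assembly by simulated-annealing Monte Carlo
#'
#' Optimizes one fit-library candidate choice per subunit under the
#' composite objective, with Metropolis acceptance and geometric cooling.
#' Placements stay frozen as precomputed in the libraries; moves only
#' re-pick library candidates (and optionally swap identical copies).
#' After the cooling schedule a deterministic best-response polish sweeps
#' each subunit's candidates until no single-subunit change improves the
#' score, so the result is always a coordinate-wise local optimum.
#' Returns the best configuration ever visited (ties broken by
#' lexicographic candidate indices) plus the accepted-score trace.
#'
#' @inheritParams composite_score
#' @param schedule an [anneal_schedule].
#' @param identical_groups optional list of character vectors naming
#'   subunits that are identical copies (enables swap moves).
#' @return list with `choices`, `score`, `trace` (data.frame of step,
#'   temperature, current and best totals, acceptance flag).
#' @export
anneal <- function(models, libraries, map, xl = NULL, name_map = NULL,
                   schedule = anneal_schedule(),
                   weights = score_weights(), identical_groups = NULL,
                   resolution = map$resolution_hint) {
  ctx <- build_assembly_context(models, libraries, map, xl, name_map,
                                weights, resolution)
  subunits <- ctx$subunits
  groups <- Filter(function(g) length(g) >= 2 && all(g %in% subunits),
                   if (is.null(identical_groups)) list() else identical_groups)
  p_swap <- if (length(groups)) schedule$move_probs[["swap_identical_copies"]]
            else 0
  local_seed(schedule$seed, {
    choices <- stats::setNames(
      as.list(vapply(subunits, function(s)
        sample.int(ctx$n_cand[[s]], 1), integer(1))), subunits)
    cur <- score_in_context(ctx, choices)
    best_choices <- choices
    best <- cur
    propose <- function(choices) {
      if (runif(1) < p_swap) {
        g <- groups[[sample.int(length(groups), 1)]]
        pair <- sample(g, 2)
        tmp <- choices[[pair[1]]]
        choices[[pair[1]]] <- choices[[pair[2]]]
        choices[[pair[2]]] <- tmp
      } else {
        s <- subunits[sample.int(length(subunits), 1)]
        choices[[s]] <- sample.int(ctx$n_cand[[s]], 1)
      }
      choices
    }
    t_cur <- schedule$t_start
    if (identical(t_cur, "auto")) {
      ups <- numeric(0)
      for (i in seq_len(100)) {
        sc <- score_in_context(ctx, propose(choices))
        if (sc$total > cur$total) ups <- c(ups, sc$total - cur$total)
      }
      t_cur <- if (length(ups)) mean(ups) / log(2) else 1
    }
    trace <- matrix(NA_real_, nrow = schedule$n_steps, ncol = 4,
                    dimnames = list(NULL, c("temperature", "current_total",
                                            "best_total", "accepted")))
    for (step in seq_len(schedule$n_steps)) {
      prop <- propose(choices)
      sc <- score_in_context(ctx, prop)
      delta <- sc$total - cur$total
      accept <- delta <= 0 ||
        (t_cur > 0 && runif(1) < exp(-delta / t_cur))
      if (accept) {
        choices <- prop
        cur <- sc
        if (cur$total < best$total ||
            (cur$total == best$total &&
             .choices_less(choices, best_choices, subunits))) {
          best <- cur
          best_choices <- choices
        }
      }
      trace[step, ] <- c(t_cur, cur$total, best$total, as.numeric(accept))
      t_cur <- t_cur * schedule$cooling
    }
    # deterministic best-response polish: sweep subunits, taking the best
    # candidate for each given the others, until a full sweep is stable
    repeat {
      improved <- FALSE
      for (s in subunits) {
        for (k in seq_len(ctx$n_cand[[s]])) {
          if (k == best_choices[[s]]) next
          cand <- best_choices
          cand[[s]] <- k
          sc <- score_in_context(ctx, cand)
          if (sc$total < best$total ||
              (sc$total == best$total &&
               .choices_less(cand, best_choices, subunits))) {
            best <- sc
            best_choices <- cand
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(choices = best_choices, score = best,
         trace = as.data.frame(cbind(step = seq_len(schedule$n_steps),
                                     trace)))
  })
}

#' Exhaustive configuration search (test oracle)
#'
#' Evaluates every combination of fit-library candidates and returns the
#' exact minimum of the composite score (ties broken by lexicographic
#' candidate indices). Refuses spaces larger than `max_configs`.
#'
#' @inheritParams composite_score
#' @param max_configs refusal bound on the configuration-space size.
#' @return list with `choices`, `score`, `n_evaluated`.
#' @export
enumerate_configurations <- function(models, libraries, map, xl = NULL,
                                     name_map = NULL,
                                     weights = score_weights(),
                                     resolution = map$resolution_hint,
                                     max_configs = 1e6) {
  ctx <- build_assembly_context(models, libraries, map, xl, name_map,
                                weights, resolution)
  sizes <- ctx$n_cand
  total_n <- prod(sizes)
  if (total_n > max_configs)
    stop(sprintf("configuration space too large: %s > %s (sizes: %s)",
                 format(total_n, big.mark = ","), format(max_configs),
                 paste(sizes, collapse = " x ")))
  grid <- do.call(expand.grid, lapply(ctx$subunits, function(s)
    seq_len(sizes[[s]])))
  names(grid) <- ctx$subunits
  best <- NULL; best_choices <- NULL
  for (i in seq_len(nrow(grid))) {
    choices <- as.list(grid[i, , drop = FALSE])
    sc <- score_in_context(ctx, choices)
    if (is.null(best) || sc$total < best$total ||
        (sc$total == best$total &&
         .choices_less(choices, best_choices, ctx$subunits))) {
      best <- sc
      best_choices <- choices
    }
  }
  list(choices = best_choices, score = best, n_evaluated = nrow(grid))
}

#' Placed coordinates of one assembly configuration
#'
#' @inheritParams composite_score
#' @param ca_only return C-alpha coordinates only (default) or full models.
#' @return named list: subunit -> placed coordinate matrix (or
#'   `atomic_model` when `ca_only = FALSE`).
#' @export
configuration_coords <- function(choices, models, libraries,
                                 ca_only = TRUE) {
  out <- lapply(names(libraries), function(s) {
    cand <- libraries[[s]]$candidates[[choices[[s]]]]
    if (ca_only)
      apply_transform(coords_matrix(models[[s]], atom_name = "CA"),
                      cand$transform)
    else apply_transform(models[[s]], cand$transform)
  })
  stats::setNames(out, names(libraries))
}

#' Combine a configuration into one placed model
#'
#' Chains are renamed per subunit (subunit label order) so that the result
#' is a valid multi-chain `atomic_model` with `subunit_map` set.
#'
#' @inheritParams configuration_coords
#' @return an `atomic_model`.
#' @export
configuration_model <- function(choices, models, libraries) {
  placed <- configuration_coords(choices, models, libraries, ca_only = FALSE)
  chain_letters <- c(LETTERS, letters)
  tabs <- list(); smap <- character(0)
  for (i in seq_along(placed)) {
    at <- placed[[i]]$atoms
    at$chain_id <- chain_letters[i]
    tabs[[i]] <- at
    smap[chain_letters[i]] <- names(placed)[i]
  }
  atomic_model(do.call(rbind, tabs), subunit_map = smap)
}

#' Cluster placements across independent runs
#'
#' For each subunit, placements from independent optimization runs are
#' clustered by C-alpha RMSD (leader clustering at `mode_rmsd`); reports
#' the number of distinct placement modes, their populations, and the
#' within-mode RMSD spread — the ensemble-precision layer that flags
#' ambiguous subunits (e.g. one placed equally well in two positions).
#'
#' @param placements list over runs; each element a named list
#'   subunit -> placed C-alpha coordinate matrix (see
#'   [configuration_coords]).
#' @param mode_rmsd RMSD radius (Angstrom) of one placement mode.
#' @return named list per subunit: `n_modes`, `populations` (sorted,
#'   fractions), `mode_members`, `spread` (mean within-mode RMSD to the
#'   mode leader).
#' @export
ensemble_analysis <- function(placements, mode_rmsd = 3.0) {
  if (length(placements) < 2)
    stop("ensemble analysis needs at least 2 runs")
  subunits <- names(placements[[1]])
  out <- lapply(subunits, function(s) {
    mats <- lapply(placements, `[[`, s)
    leaders <- list(); members <- list()
    for (r in seq_along(mats)) {
      hit <- 0L
      for (m in seq_along(leaders)) {
        d <- sqrt(mean(rowSums((mats[[r]] - leaders[[m]])^2)))
        if (d <= mode_rmsd) { hit <- m; break }
      }
      if (hit == 0L) {
        leaders[[length(leaders) + 1L]] <- mats[[r]]
        members[[length(members) + 1L]] <- r
      } else members[[hit]] <- c(members[[hit]], r)
    }
    pops <- vapply(members, length, 1L) / length(mats)
    ord <- order(-pops)
    spread <- vapply(ord, function(m) {
      ds <- vapply(members[[m]], function(r)
        sqrt(mean(rowSums((mats[[r]] - leaders[[m]])^2))), numeric(1))
      mean(ds)
    }, numeric(1))
    list(n_modes = length(leaders), populations = pops[ord],
         mode_members = members[ord], spread = spread)
  })
  stats::setNames(out, subunits)
}

#' Rank alternative candidate models against a map region
#'
#' Fits each candidate into the map (via a small fit-library search unless
#' `pre_placed`) and ranks candidates by best masked model-to-map
#' correlation — the discrimination step that, e.g., picks the right
#' heterodimer among alternative compositions for one density region.
#'
#' @param candidates named list of `atomic_model`s.
#' @param map the target `density_map`.
#' @param resolution simulation resolution.
#' @param pre_placed if `TRUE`, candidates are scored where they stand.
#' @param config [fit_search_config] for the per-candidate search. The
#'   default relaxes the coverage filter (0.2) so that poorly fitting
#'   compositions are still scored and ranked rather than dropped.
#' @return data.frame sorted by rank with columns `candidate`, `cc`,
#'   `coverage`.
#' @export
rank_candidate_models <- function(candidates, map,
                                  resolution = map$resolution_hint,
                                  pre_placed = FALSE,
                                  config = fit_search_config(
                                    n_searches = 300, max_candidates = 5,
                                    coverage_min = 0.2,
                                    refine_max_iter = 40)) {
  if (!length(candidates)) stop("empty candidate list")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  rows <- lapply(names(candidates), function(nm) {
    mdl <- candidates[[nm]]
    if (pre_placed) {
      cc <- placed_model_cc(mdl, map, rigid_transform(), resolution)
      thr <- if (identical(config$envelope_threshold, "auto"))
        envelope_threshold(map, "volume", target_mass = model_mass(mdl))
      else as.numeric(config$envelope_threshold)
      cov <- envelope_coverage(mdl, rigid_transform(), map, thr)
    } else {
      lib <- build_fit_library(mdl, map, config, resolution = resolution)
      if (!length(lib$candidates)) {
        cc <- NA_real_; cov <- 0
      } else {
        cc <- lib$candidates[[1]]$cc
        cov <- lib$candidates[[1]]$coverage
      }
    }
    data.frame(candidate = nm, cc = cc, coverage = cov,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-ifelse(is.na(df$cc), -Inf, df$cc)), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
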