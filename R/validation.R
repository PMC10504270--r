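#' Masked model-to-map correlation (CCmask)
#'
#' Pearson correlation between the experimental map and the model's
#' simulated density, restricted to voxels whose centers lie within
#' `mask_radius` of any model atom.
#'
#' @param model an `atomic_model`.
#' @param map a `density_map`.
#' @param resolution simulation resolution (defaults to the map's hint).
#' @param mask_radius mask radius around atoms in Angstrom.
#' @return correlation in \[-1, 1\].
#' @export
cc_mask <- function(model, map, resolution = map$resolution_hint,
                    mask_radius = 3.0) {
  if (is.null(resolution)) stop("resolution required (no resolution_hint)")
  mask <- cpp_near_atom_mask(dim(map$values), map$origin, map$voxel_size,
                             coords_matrix(model), mask_radius)
  if (!any(mask)) stop("mask is empty: model does not overlap the grid")
  sim <- simulate_map(model, resolution, grid = map)
  cross_correlation(map, sim, mask = mask)
}

#' Fraction of map density explained by a model
#'
#' Fraction of voxels at or above `threshold` whose centers lie within
#' `mask_radius` of any model atom — the "model explains X% of the
#' analyzed density" figure of merit.
#'
#' @param map a `density_map`.
#' @param model an `atomic_model` (may be empty: explains 0).
#' @param threshold density value defining the analyzed envelope.
#' @param mask_radius atom neighbourhood radius in Angstrom.
#' @return fraction in \[0, 1\].
#' @export
density_explained <- function(map, model, threshold, mask_radius = 4.0) {
  above <- as.numeric(map$values) >= threshold
  if (!any(above)) stop("no voxels at or above the threshold")
  if (!nrow(model$atoms)) return(0)
  near <- cpp_near_atom_mask(dim(map$values), map$origin, map$voxel_size,
                             coords_matrix(model), mask_radius)
  sum(above & near) / sum(above)
}

#' Count inter-subunit C-alpha clashes
#'
#' Number of C-alpha pairs belonging to different subunits closer than
#' `cutoff` (a simple excluded-volume check, not an all-atom clashscore).
#'
#' @param model an `atomic_model` with a subunit map.
#' @param cutoff contact distance in Angstrom.
#' @return integer count.
#' @export
clash_count <- function(model, cutoff = 4.0) {
  at <- model$atoms[model$atoms$atom_name == "CA", , drop = FALSE]
  if (nrow(at) < 2) return(0L)
  sub <- unname(model$subunit_map[at$chain_id])
  if (length(unique(sub)) < 2) return(0L)
  cpp_cross_group_contacts(as.matrix(at[, c("x", "y", "z")]),
                           as.integer(factor(sub)), cutoff)
}

#' Pearson correlation with F-test P value
#'
#' `r` is the Pearson correlation; the two-tailed P value comes from
#' `F = r^2 (n - 2) / (1 - r^2)` on (1, n - 2) degrees of freedom — the
#' F test on the slope of the simple linear regression, identical to the
#' two-sided t test.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-zero variance.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_ftest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a zero-variance vector")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    f <- r^2 * (n - 2) / (1 - r^2)
    pf(f, 1, n - 2, lower.tail = FALSE)
  }
  list(r = r, p_value = p, n = n)
}

#' Read a gene-by-tissue expression table
#'
#' CSV with genes as rows (first column = gene label) and tissues as
#' columns; cells are nTPM values (non-negative, no missing cells).
#'
#' @param path CSV file path.
#' @return matrix (genes x tissues) of nTPM values.
#' @export
read_coexpression <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression table has missing cells")
  if (any(m < 0)) stop("nTPM values must be non-negative")
  if (ncol(m) < 3) stop("need at least 3 tissues")
  m
}

#' Coexpression test between two genes
#'
#' @param ntpm genes x tissues matrix (see [read_coexpression]).
#' @param gene_a,gene_b row labels.
#' @return list with `r`, `p_value`, `n` (number of tissues).
#' @export
coexpression_test <- function(ntpm, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(ntpm)) stop("gene not in table: ", g)
  pearson_ftest(ntpm[gene_a, ], ntpm[gene_b, ])
}

#' Full validation report for a placed assembly
#'
#' Bundles the masked map-model correlation, density-explained fraction,
#' inter-subunit clash count, and cross-link satisfaction summary.
#'
#' @param model placed `atomic_model` of the assembly.
#' @param map the experimental (or simulated target) `density_map`.
#' @param xl optional `crosslink_set`.
#' @param name_map protein label -> chain ids (for cross-link mapping).
#' @param threshold envelope threshold for density accounting (default:
#'   volume-based from the model mass).
#' @param resolution simulation resolution.
#' @param mask_radius CCmask radius (Angstrom).
#' @param density_mask_radius atom neighbourhood for density accounting;
#'   defaults to `0.75 * resolution`, since density simulated at
#'   resolution R extends roughly that far beyond the atom centers.
#' @param clash_cutoff inter-subunit C-alpha contact cutoff (Angstrom).
#' @return a `validation_report` list.
#' @export
validation_report <- function(model, map, xl = NULL, name_map = NULL,
                              threshold = NULL,
                              resolution = map$resolution_hint,
                              mask_radius = 3.0,
                              density_mask_radius = max(4, 0.75 * resolution),
                              clash_cutoff = 4.0) {
  if (is.null(threshold))
    threshold <- envelope_threshold(map, "volume",
                                    target_mass = model_mass(model))
  xl_report <- if (!is.null(xl)) {
    if (is.null(name_map)) {
      chains <- unique(model$atoms$chain_id)
      subs <- model$subunit_map[chains]
      name_map <- split(chains, subs)
    }
    map_crosslinks(xl, model, name_map)
  } else NULL
  structure(list(
    cc_mask = cc_mask(model, map, resolution, mask_radius),
    density_explained = density_explained(map, model, threshold,
                                          mask_radius = density_mask_radius),
    clash_count = clash_count(model, clash_cutoff),
    threshold = threshold,
    xl_summary = if (is.null(xl_report)) NULL else xl_report$summary,
    xl_report = xl_report), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> CCmask %.3f | density explained %.1f%% | %d inter-subunit clash(es)\n",
              x$cc_mask, 100 * x$density_explained, x$clash_count))
  if (!is.null(x$xl_summary))
    cat(sprintf("  cross-links: %d mapped, %.1f%% satisfied\n",
                x$xl_summary$n_mapped,
                100 * x$xl_summary$fraction_satisfied))
  invisible(x)
}
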