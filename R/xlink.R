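.linker_max_dist <- c(DSSO = 35.0)

#' Construct a cross-link restraint set
#'
#' Each restraint is a residue pair on named proteins with a linker-specific
#' maximum C-alpha--C-alpha distance (DSSO: 35 Angstrom). Links between the
#' same protein label are classified intramolecular, otherwise
#' intermolecular.
#'
#' @param links data.frame with columns `protein_a`, `residue_a`,
#'   `protein_b`, `residue_b`, and optionally `linker` (default `"DSSO"`)
#'   and `max_dist` (default from the linker).
#' @param source free-text provenance.
#' @return An object of class `crosslink_set`.
#' @export
crosslink_set <- function(links, source = "unspecified") {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  needed <- c("protein_a", "residue_a", "protein_b", "residue_b")
  missing_cols <- setdiff(needed, names(links))
  if (length(missing_cols))
    stop("cross-link table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"linker" %in% names(links))
    links$linker <- rep("DSSO", nrow(links))
  links$linker[is.na(links$linker) | !nzchar(links$linker)] <- "DSSO"
  if (!"max_dist" %in% names(links))
    links$max_dist <- rep(NA_real_, nrow(links))
  known <- .linker_max_dist[links$linker]
  links$max_dist <- ifelse(is.na(links$max_dist),
                           ifelse(is.na(known), 35.0, known), links$max_dist)
  for (col in c("residue_a", "residue_b")) {
    v <- suppressWarnings(as.numeric(links[[col]]))
    bad <- which(is.na(v) | v != round(v) | v < 1)
    if (length(bad))
      stop("non-integer or non-positive residue number in row ", bad[1],
           " (", col, ")")
    links[[col]] <- as.integer(v)
  }
  if (any(links$max_dist <= 0)) stop("max_dist must be > 0")
  links$kind <- ifelse(links$protein_a == links$protein_b,
                       "intramolecular", "intermolecular")
  if (nrow(links)) {
    a <- paste(links$protein_a, links$residue_a)
    b <- paste(links$protein_b, links$residue_b)
    key <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
    if (anyDuplicated(key))
      stop("duplicate cross-link (unordered pair): ",
           key[duplicated(key)][1])
  }
  rownames(links) <- NULL
  structure(list(links = links, source = source), class = "crosslink_set")
}

#' @export
print.crosslink_set <- function(x, ...) {
  cat(sprintf("<crosslink_set> %d link(s) (%d intra, %d inter) from %s\n",
              nrow(x$links), sum(x$links$kind == "intramolecular"),
              sum(x$links$kind == "intermolecular"), x$source))
  invisible(x)
}

#' Parse a cross-link CSV table
#'
#' Expected header: `protein_a, residue_a, protein_b, residue_b` with
#' optional `linker` (default DSSO, maximum C-alpha distance 35 Angstrom)
#' and `max_dist` columns.
#'
#' @param path CSV file path.
#' @return A `crosslink_set`.
#' @export
parse_xl_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  crosslink_set(df, source = path)
}

#' C-alpha--C-alpha distance between two residues
#'
#' @param model an `atomic_model`.
#' @param chain_a,chain_b chain ids.
#' @param res_a,res_b author residue numbers.
#' @return Euclidean distance in Angstrom.
#' @export
crosslink_distance <- function(model, chain_a, res_a, chain_b, res_b) {
  p <- .ca_position(model, chain_a, res_a)
  q <- .ca_position(model, chain_b, res_b)
  sqrt(sum((p - q)^2))
}

.ca_position <- function(model, chain, resno) {
  at <- model$atoms
  hit <- which(at$chain_id == chain & at$residue_number == resno &
               at$atom_name == "CA")
  if (!length(hit))
    stop(sprintf("no CA atom for residue %s/%d", chain, resno))
  as.numeric(at[hit[1], c("x", "y", "z")])
}

#' Map cross-links onto a model and report satisfaction
#'
#' Every link is evaluated for every combination of chains its two protein
#' labels resolve to (paralog/extra-copy ambiguity), all per-copy distances
#' are reported, and satisfaction is judged on the minimum distance over
#' copies. Links whose proteins or residues cannot be found are listed as
#' unmapped, never silently dropped. An empty mapped set has
#' `fraction_satisfied = 1` (vacuous truth) with `n_mapped = 0`.
#'
#' @param xl a `crosslink_set`.
#' @param model an `atomic_model`.
#' @param name_map named list: protein label -> character vector of chain
#'   ids (multi-copy proteins map to several chains).
#' @param offsets optional named numeric vector: per-protein residue
#'   numbering offset added to table residue numbers before lookup.
#' @param max_dist optional single cutoff overriding each link's own.
#' @return An `xl_mapping_report`: list with `per_link` (data.frame with a
#'   `distances` list-column of per-copy-pair distances) and `summary`.
#' @export
map_crosslinks <- function(xl, model, name_map, offsets = NULL,
                           max_dist = NULL) {
  links <- xl$links
  n <- nrow(links)
  per <- vector("list", n)
  for (i in seq_len(n)) {
    li <- links[i, ]
    cutoff <- if (is.null(max_dist)) li$max_dist else max_dist
    chains_a <- name_map[[li$protein_a]]
    chains_b <- name_map[[li$protein_b]]
    off_a <- if (!is.null(offsets) && li$protein_a %in% names(offsets))
      offsets[[li$protein_a]] else 0L
    off_b <- if (!is.null(offsets) && li$protein_b %in% names(offsets))
      offsets[[li$protein_b]] else 0L
    dists <- numeric(0)
    if (length(chains_a) && length(chains_b)) {
      for (ca_ in chains_a) for (cb_ in chains_b) {
        if (ca_ == cb_ && li$residue_a + off_a == li$residue_b + off_b) next
        d <- tryCatch(crosslink_distance(model, ca_, li$residue_a + off_a,
                                         cb_, li$residue_b + off_b),
                      error = function(e) NA_real_)
        if (!is.na(d)) dists[paste(ca_, cb_, sep = ":")] <- d
      }
      # identical unordered chain pairs counted once
      if (length(dists) > 1) {
        pair_key <- vapply(strsplit(names(dists), ":"), function(p)
          paste(sort(p), collapse = ":"), character(1))
        dists <- dists[!duplicated(paste(pair_key,
                                         round(unname(dists), 9)))]
      }
    }
    mapped <- length(dists) > 0
    per[[i]] <- list(kind = li$kind, max_dist = cutoff, mapped = mapped,
                     n_pairs = length(dists), distances = dists,
                     min_dist = if (mapped) min(dists) else NA_real_,
                     satisfied = if (mapped) min(dists) <= cutoff else NA)
  }
  per_link <- data.frame(
    protein_a = links$protein_a, residue_a = links$residue_a,
    protein_b = links$protein_b, residue_b = links$residue_b,
    kind = links$kind,
    max_dist = vapply(per, `[[`, numeric(1), "max_dist"),
    mapped = vapply(per, `[[`, logical(1), "mapped"),
    n_pairs = vapply(per, `[[`, integer(1), "n_pairs"),
    min_dist = vapply(per, `[[`, numeric(1), "min_dist"),
    satisfied = vapply(per, `[[`, logical(1), "satisfied"),
    stringsAsFactors = FALSE)
  per_link$distances <- lapply(per, `[[`, "distances")
  mapped <- per_link$mapped
  n_mapped <- sum(mapped)
  if (n_mapped == 0 && n > 0)
    warning("no cross-link could be mapped onto the model")
  qd <- function(kind) {
    d <- per_link$min_dist[mapped & per_link$kind == kind]
    if (!length(d)) return(NULL)
    quantile(d, c(0, 0.25, 0.5, 0.75, 1))
  }
  summary <- list(
    n_links = n, n_mapped = n_mapped, n_unmapped = n - n_mapped,
    n_intra = sum(mapped & per_link$kind == "intramolecular"),
    n_inter = sum(mapped & per_link$kind == "intermolecular"),
    fraction_satisfied = if (n_mapped == 0) 1.0
                         else mean(per_link$satisfied[mapped]),
    intra_quantiles = qd("intramolecular"),
    inter_quantiles = qd("intermolecular"))
  structure(list(per_link = per_link, summary = summary),
            class = "xl_mapping_report")
}

#' @export
print.xl_mapping_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<xl_mapping_report> %d link(s): %d mapped (%d intra, %d inter), %d unmapped\n",
    s$n_links, s$n_mapped, s$n_intra, s$n_inter, s$n_unmapped))
  cat(sprintf("  fraction satisfied: %.3f%s\n", s$fraction_satisfied,
              if (s$n_mapped == 0) " (vacuous: nothing mapped)" else ""))
  invisible(x)
}

#' Write a cross-link mapping report
#'
#' Per-link rows as CSV (per-copy distances joined with `;`) plus the
#' summary as JSON.
#'
#' @param report an `xl_mapping_report`.
#' @param csv_path,json_path output paths (`NULL` to skip one).
#' @export
write_xl_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- report$per_link
    df$distances <- vapply(df$distances, function(d)
      paste(sprintf("%s=%.3f", names(d), d), collapse = ";"), character(1))
    write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(report)
}
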