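.hydrophobic_core <- c("A", "V", "L", "I", "M", "F", "W", "Y")
.aa_one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V")
.positive_aa <- c("K", "R", "H")
.negative_aa <- c("D", "E")

#' Assign a coiled-coil heptad register
#'
#' A canonical coiled-coil repeats every seven residues (positions
#' `abcdefg`) with hydrophobic residues at `a` and `d` forming the core.
#' All seven register phases are scored by the fraction of hydrophobic
#' residues (set A,V,L,I,M,F,W,Y) at `a`/`d`; the maximal phase wins (on
#' ties, all maximal phases are reported and the lowest phase index is
#' primary). Polar residues falling at `a`/`d` are listed as polar
#' inclusions; a proline at `a`/`d` triggers a register-breaking warning.
#'
#' @param sequence one-letter amino-acid string, length >= 7.
#' @param start_number author residue number of the first residue.
#' @return a `heptad_assignment`: list with `sequence`, `start_number`,
#'   `registers` (named per-residue `a`..`g`), `phase` (0-6 offset of the
#'   first residue within `abcdefg`), `phase_scores` (7 values),
#'   `tied_phases`, and `polar_inclusions` (data.frame).
#' @export
assign_heptad_register <- function(sequence, start_number = 1) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 7) stop("sequence must have at least 7 residues")
  bad <- which(!aa %in% .aa_one)
  if (length(bad))
    stop("non-standard amino acid '", aa[bad[1]], "' at position ",
         start_number + bad[1] - 1)
  hydro <- aa %in% .hydrophobic_core
  reg_letters <- letters[1:7]
  # phase p: residue i (1-based) gets register (i - 1 + p) mod 7
  scores <- vapply(0:6, function(p) {
    reg <- (seq_along(aa) - 1 + p) %% 7
    core <- reg %in% c(0, 3)           # a and d
    if (!any(core)) return(0)
    mean(hydro[core])
  }, numeric(1))
  best <- max(scores)
  tied <- which(scores == best) - 1L
  phase <- tied[1]
  reg <- reg_letters[(seq_along(aa) - 1 + phase) %% 7 + 1]
  resno <- start_number + seq_along(aa) - 1L
  names(reg) <- resno
  core_idx <- which(reg %in% c("a", "d"))
  polar_idx <- core_idx[!hydro[core_idx]]
  if (any(aa[core_idx] == "P"))
    warning("proline at a core (a/d) position: register-breaking residue at ",
            paste(resno[core_idx[aa[core_idx] == "P"]], collapse = ", "))
  polar <- data.frame(residue_number = resno[polar_idx],
                      residue = aa[polar_idx],
                      register = reg[polar_idx],
                      stringsAsFactors = FALSE)
  rownames(polar) <- NULL
  structure(list(sequence = paste(aa, collapse = ""),
                 start_number = as.integer(start_number),
                 registers = reg, phase = phase,
                 phase_scores = stats::setNames(scores, paste0("phase", 0:6)),
                 tied_phases = tied,
                 polar_inclusions = polar),
            class = "heptad_assignment")
}

#' @export
print.heptad_assignment <- function(x, ...) {
  cat("<heptad_assignment>\n")
  cat("  ", x$sequence, "\n  ", paste(x$registers, collapse = ""), "\n",
      sep = "")
  cat(sprintf("  phase %d, core hydrophobic fraction %.2f\n", x$phase,
              max(x$phase_scores)))
  if (nrow(x$polar_inclusions))
    cat("  polar inclusions at a/d: ",
        paste(sprintf("%s%d(%s)", x$polar_inclusions$residue,
                      x$polar_inclusions$residue_number,
                      x$polar_inclusions$register), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Annotate missense mutations on a heptad register
#'
#' Each mutation is annotated with its register position, whether it sits
#' at a core (`a`/`d`) position, and whether it changes the residue's
#' charge class.
#'
#' @param assignment a [assign_heptad_register] result.
#' @param mutations data.frame with columns `residue_number`, `from`, `to`
#'   (one-letter codes).
#' @return data.frame with one annotated row per mutation.
#' @export
map_missense_to_register <- function(assignment, mutations) {
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  stopifnot(all(c("residue_number", "from", "to") %in% names(mutations)))
  aa <- strsplit(assignment$sequence, "")[[1]]
  resno <- assignment$start_number + seq_along(aa) - 1L
  out <- lapply(seq_len(nrow(mutations)), function(i) {
    m <- mutations[i, ]
    pos <- match(m$residue_number, resno)
    if (is.na(pos))
      stop("mutation residue ", m$residue_number,
           " lies outside the assigned segment")
    if (aa[pos] != toupper(m$from))
      stop(sprintf("sequence mismatch at %d: segment has %s, mutation says %s",
                   m$residue_number, aa[pos], m$from))
    charge_of <- function(a)
      if (a %in% .positive_aa) "positive"
      else if (a %in% .negative_aa) "negative" else "neutral"
    data.frame(residue_number = m$residue_number, from = toupper(m$from),
               to = toupper(m$to),
               register = unname(assignment$registers[pos]),
               core_position = assignment$registers[pos] %in% c("a", "d"),
               charge_from = charge_of(toupper(m$from)),
               charge_to = charge_of(toupper(m$to)),
               charge_change = charge_of(toupper(m$from)) !=
                 charge_of(toupper(m$to)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
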