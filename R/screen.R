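# Library screening: warhead detection, covalent attachment, torsion-scan
# enumeration, scoring and top-fraction selection.

#' Run a covalent library screen
#'
#' For each library compound: parse, detect warheads (the first match in
#' ascending beta-carbon order is used), apply the Michael-addition transform,
#' build the attachment geometry, enumerate torsion-scan conformers, prune
#' internal clashes and keep the best score. Compounds without a warhead are
#' recorded as \code{no_warhead} and excluded from the ranking; per-compound
#' failures are recorded as \code{failed} and never abort the screen. The
#' whole pipeline is deterministic: identical inputs and configuration give
#' identical results.
#'
#' @param library data.frame with columns \code{id}, \code{smiles} (see
#'   [readLigandLibrary()]), or a named character vector of SMILES.
#' @param pocket a parameterized [Pocket-class] (carries its anchor).
#' @param config a [ScoringConfig-class] (default [scoringConfig()] on the
#'   pocket).
#' @param incrementDeg torsion increment in degrees (default 30).
#' @param cap conformer cap per compound (default 1000).
#' @param fraction top fraction to select (default 0.10).
#' @param bondLength covalent S-C bond length in Angstrom (default 1.81).
#' @param minClashDist intramolecular clash threshold in Angstrom
#'   (default 1.2).
#' @return A [ScreenResult-class].
#' @seealso [selectTopFraction()], [writeScreenResult()]
#' @export
runScreen <- function(library, pocket, config = scoringConfig(pocket),
                      incrementDeg = 30, cap = 1000L, fraction = 0.10,
                      bondLength = 1.81, minClashDist = 1.2) {
  if (is.character(library))
    library <- data.frame(id = if (is.null(names(library)))
      sprintf("L%04d", seq_along(library)) else names(library),
      smiles = unname(library), stringsAsFactors = FALSE)
  if (!is.data.frame(library) || !all(c("id", "smiles") %in% names(library)) ||
      nrow(library) < 1L)
    cyStop("cyslock_value_error",
           "library must be a non-empty data.frame with id and smiles columns")
  if (anyNA(pocket@atoms$charge))
    cyStop("cyslock_param_error", "pocket must be parameterized before screening")

  one <- function(i) {
    id <- library$id[i]
    base <- data.frame(compound_id = id, status = "failed",
                       pattern_id = NA_character_, n_conformers = NA_integer_,
                       electrostatic = NA_real_, vdw = NA_real_,
                       total = NA_real_, conformer_index = NA_integer_,
                       stringsAsFactors = FALSE)
    tryCatch({
      lig <- parseLigand(library$smiles[i], id = id)
      wh <- detectWarheads(lig)
      if (nrow(wh) == 0L) { base$status <- "no_warhead"; return(base) }
      anch <- applyMichaelAddition(lig, wh[1, ], bondLength = bondLength)
      start <- placeAnchor(anch, pocket, bondLength = bondLength)
      set <- enumerateConformers(start, incrementDeg = incrementDeg, cap = cap)
      set <- pruneInternalClashes(set, minDist = minClashDist)
      if (conformerCount(set) < 1L) {
        base$pattern_id <- anch@patternId
        base$n_conformers <- 0L
        return(base)
      }
      best <- bestScore(set, pocket, config)
      base$status <- "scored"
      base$pattern_id <- anch@patternId
      base$n_conformers <- conformerCount(set)
      base$electrostatic <- best$electrostatic
      base$vdw <- best$vdw
      base$total <- best$total
      base$conformer_index <- best$conformer_index
      base
    }, cyslock_error = function(e) base)
  }

  records <- do.call(rbind, lapply(seq_len(nrow(library)), one))
  scored <- records[records$status == "scored", , drop = FALSE]
  ord <- order(scored$total, scored$compound_id)
  rk <- scored$compound_id[ord]
  res <- new("ScreenResult", records = records, ranking = rk,
             selected = character(0), fraction = as.numeric(fraction))
  res@selected <- selectTopFraction(res, fraction)
  res
}

#' Select the top fraction of a screen
#'
#' The first \code{ceiling(fraction * n_scored)} compound ids of the
#' ascending-score ranking. Boundary ties are already resolved in the ranking
#' (ascending best total, then lexicographic compound id).
#'
#' @param result a [ScreenResult-class].
#' @param fraction selection fraction in (0, 1].
#' @return Character vector of selected compound ids.
#' @export
selectTopFraction <- function(result, fraction = 0.10) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1)
    cyStop("cyslock_value_error", "fraction must lie in (0, 1], got %s",
           format(fraction))
  n <- length(result@ranking)
  utils::head(result@ranking, ceiling(fraction * n))
}

#' Write screen scores as TSV
#'
#' Columns \code{compound_id}, \code{best_total}, \code{electrostatic},
#' \code{vdw}, \code{conformer_index}, \code{n_conformers}, scored compounds
#' in ranking order. Output is byte-identical across reruns of the same
#' screen.
#'
#' @param result a [ScreenResult-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeScreenResult <- function(result, path) {
  rec <- result@records
  rec <- rec[match(result@ranking, rec$compound_id), , drop = FALSE]
  out <- data.frame(compound_id = rec$compound_id,
                    best_total = sprintf("%.6f", rec$total),
                    electrostatic = sprintf("%.6f", rec$electrostatic),
                    vdw = sprintf("%.6f", rec$vdw),
                    conformer_index = rec$conformer_index,
                    n_conformers = rec$n_conformers)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
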