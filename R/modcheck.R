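# Covalent-modification evidence: elemental-formula masses, in-silico tryptic
# digestion, adduct mass matching, and NMR chemical-shift-perturbation
# classification.

# IUPAC atomic masses: monoisotopic (most abundant isotope) and standard
# atomic weights.
ATOMIC_MASS <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
              "NA", "K", "SE", "B", "SI"),
  monoisotopic = c(1.0078250319, 12.0, 14.0030740052, 15.9949146221,
                   31.97207069, 30.97376151, 18.99840320, 34.96885271,
                   78.9183376, 126.904473, 22.98976928, 38.96370649,
                   79.9165218, 11.00930536, 27.97692653),
  average = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998,
              35.45, 79.904, 126.904, 22.990, 39.098, 78.971, 10.81, 28.085),
  stringsAsFactors = FALSE)

#' Parse a Hill-notation elemental formula
#'
#' @param formula Hill-notation string, e.g. \code{"C12H10SO4"}; element
#'   symbols capitalized (one upper-case letter, optional lower-case second
#'   letter), counts default to 1. An empty string is the empty formula.
#' @return Named integer vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (is.numeric(formula) || is.integer(formula)) return(formula)
  s <- trimws(formula)
  if (!nzchar(s)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    cyStop("cyslock_value_error", "cannot parse formula '%s'", formula)
  els <- toupper(sub("[0-9]*$", "", parts))
  counts <- as.integer(ifelse(grepl("[0-9]", parts), sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(counts, els, sum)
  res <- as.integer(out)
  names(res) <- names(out)
  # restore Hill presentation order: C, H, then alphabetical
  hill <- c(intersect(c("C", "H"), names(res)),
            sort(setdiff(names(res), c("C", "H"))))
  res[hill]
}

#' Mass of an elemental formula
#'
#' Sums packaged IUPAC atomic masses over the formula.
#'
#' @param formula Hill-notation string or named count vector
#'   (see [parseFormula()]).
#' @param kind \code{"monoisotopic"} (default) or \code{"average"}.
#' @return Mass in Da; 0 for the empty formula.
#' @examples
#' formulaMass("C12H10SO4")   # the covalent-adduct mass shift
#' formulaMass("H2O")
#' @export
formulaMass <- function(formula, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  f <- parseFormula(formula)
  if (!length(f)) return(0.0)
  idx <- match(names(f), ATOMIC_MASS$element)
  if (anyNA(idx))
    cyStop("cyslock_value_error", "unknown element(s): %s",
           paste(names(f)[is.na(idx)], collapse = ", "))
  sum(ATOMIC_MASS[[kind]][idx] * as.numeric(f))
}

# residue formulas in peptide linkage (minus water)
RESIDUE_FORMULA <- c(
  G = "C2H3NO", A = "C3H5NO", S = "C3H5NO2", P = "C5H7NO", V = "C5H9NO",
  T = "C4H7NO2", C = "C3H5NOS", L = "C6H11NO", I = "C6H11NO", N = "C4H6N2O2",
  D = "C4H5NO3", Q = "C5H8N2O2", K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",
  H = "C6H7N3O", F = "C9H9NO", R = "C6H12N4O", Y = "C9H9NO2", W = "C11H10N2O")

#' Mass of a peptide
#'
#' Residue masses in peptide linkage plus one water.
#'
#' @param sequence 1-letter peptide sequence.
#' @param kind \code{"monoisotopic"} (default) or \code{"average"}.
#' @return Neutral peptide mass in Da.
#' @export
peptideMass <- function(sequence, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_FORMULA))
  if (length(bad))
    cyStop("cyslock_value_error", "invalid residue(s): %s",
           paste(unique(bad), collapse = ", "))
  sum(vapply(RESIDUE_FORMULA[aa], formulaMass, 0.0, kind = kind)) +
    formulaMass("H2O", kind)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine or arginine except when the next residue is
#' proline, and emits every peptide with at most \code{maxMissed} missed
#' cleavages, ordered by start position (then by missed-cleavage count).
#'
#' @param sequence protein sequence over the 20-letter alphabet.
#' @param maxMissed maximum missed cleavages (default 0).
#' @return data.frame with columns \code{sequence}, \code{start}, \code{end}
#'   (1-based inclusive), \code{missed_cleavages}.
#' @examples
#' trypticDigest("AAKRCC")$sequence
#' @export
trypticDigest <- function(sequence, maxMissed = 0L) {
  s <- toupper(trimws(sequence))
  aa <- strsplit(s, "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_FORMULA))
  if (length(bad))
    cyStop("cyslock_value_error", "invalid residue(s) in sequence: %s",
           paste(unique(bad), collapse = ", "))
  n <- length(aa)
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n & aa[pmin(cut + 1L, n)] != "P"]
  bounds <- c(0L, cut, n)            # peptide i spans bounds[i]+1 .. bounds[i+1]
  np <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(np)) {
    for (m in 0:maxMissed) {
      j <- i + m
      if (j > np) break
      st <- bounds[i] + 1L; en <- bounds[j + 1L]
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(s, st, en), start = st, end = en,
        missed_cleavages = m, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$missed_cleavages), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match an observed adduct mass shift against candidate formulas
#'
#' Converts the ppm tolerance to Da on the unmodified peptide mass and
#' returns the candidates whose monoisotopic mass falls within it, sorted by
#' absolute error (stable for ties).
#'
#' @param observedDelta observed mass shift in Da.
#' @param candidateFormulas character vector of Hill-notation formulas.
#' @param tolPpm tolerance in ppm (> 0).
#' @param baseMass unmodified peptide mass in Da (> 0), the ppm reference.
#' @return data.frame with columns \code{formula}, \code{mass},
#'   \code{error_da}, sorted by \code{abs(error_da)}; zero rows when nothing
#'   matches.
#' @export
matchAdduct <- function(observedDelta, candidateFormulas, tolPpm = 10,
                        baseMass) {
  if (!is.numeric(tolPpm) || tolPpm <= 0)
    cyStop("cyslock_value_error", "tolPpm must be > 0")
  if (!is.numeric(baseMass) || baseMass <= 0)
    cyStop("cyslock_value_error", "baseMass must be > 0")
  tol <- tolPpm * 1e-6 * baseMass
  mass <- vapply(candidateFormulas, formulaMass, 0.0,
                 kind = "monoisotopic", USE.NAMES = FALSE)
  err <- mass - observedDelta
  keep <- abs(err) <= tol
  out <- data.frame(formula = candidateFormulas[keep], mass = mass[keep],
                    error_da = err[keep], stringsAsFactors = FALSE)
  out <- out[order(abs(out$error_da)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an HSQC peak list
#'
#' Tab-separated with header columns \code{residue}, \code{h_ppm},
#' \code{n_ppm}, \code{intensity}.
#'
#' @param path file path.
#' @return Validated peak-list data.frame.
#' @export
readPeakList <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "h_ppm", "n_ppm", "intensity")
  if (!all(need %in% names(t)))
    cyStop("cyslock_value_error", "peak list lacks columns: %s",
           paste(setdiff(need, names(t)), collapse = ", "))
  validatePeakList(t, path)
  t
}

validatePeakList <- function(t, label = "peak list") {
  if (anyDuplicated(t$residue))
    cyStop("cyslock_value_error", "%s: duplicated residue rows (%s)", label,
           paste(unique(t$residue[duplicated(t$residue)]), collapse = ", "))
  if (any(t$intensity < 0))
    cyStop("cyslock_value_error", "%s: negative intensities", label)
  invisible(t)
}

#' Write an HSQC peak list as TSV
#'
#' @param peaks peak-list data.frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writePeakList <- function(peaks, path) {
  out <- data.frame(residue = peaks$residue,
                    h_ppm = sprintf("%.4f", peaks$h_ppm),
                    n_ppm = sprintf("%.4f", peaks$n_ppm),
                    intensity = sprintf("%.4f", peaks$intensity))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chemical-shift perturbations between apo and bound peak lists
#'
#' For residues present in both lists the combined CSP is
#' \eqn{\sqrt{\Delta\delta_H^2 + (w_N \Delta\delta_N)^2}} with the nitrogen
#' scaling \code{nWeight}; a residue is attenuated when its bound/apo
#' intensity ratio falls below \code{attenuationFloor}. Residues present in
#' the apo list but absent from the bound list have undefined CSP (NA) and
#' are attenuated (the resonance disappeared).
#'
#' @param apo,bound peak-list data.frames (see [readPeakList()]).
#' @param nWeight 15N scaling weight (default 0.2).
#' @param attenuationFloor intensity-ratio floor (default 0.2).
#' @return data.frame with columns \code{residue}, \code{csp},
#'   \code{attenuated}, ordered by residue number.
#' @export
computeCSP <- function(apo, bound, nWeight = 0.2, attenuationFloor = 0.2) {
  validatePeakList(apo, "apo"); validatePeakList(bound, "bound")
  common <- intersect(apo$residue, bound$residue)
  if (!length(common))
    cyStop("cyslock_value_error", "apo and bound lists share no residues")
  ia <- match(common, apo$residue); ib <- match(common, bound$residue)
  dh <- bound$h_ppm[ib] - apo$h_ppm[ia]
  dn <- bound$n_ppm[ib] - apo$n_ppm[ia]
  csp <- sqrt(dh^2 + (nWeight * dn)^2)
  att <- bound$intensity[ib] / apo$intensity[ia] < attenuationFloor
  gone <- setdiff(apo$residue, bound$residue)
  out <- rbind(
    data.frame(residue = common, csp = csp, attenuated = att),
    if (length(gone)) data.frame(residue = gone, csp = NA_real_,
                                 attenuated = TRUE))
  out <- out[order(out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify perturbed residues and summarize contiguous segments
#'
#' A residue is perturbed when its CSP strictly exceeds the threshold or its
#' resonance is attenuated. Segments are maximal runs of consecutive residue
#' numbers among the perturbed set.
#'
#' @param records output of [computeCSP()].
#' @param threshold CSP threshold in ppm (default 0.05; strict inequality).
#' @return list with \code{records} (input plus a \code{perturbed} column),
#'   \code{perturbed} (residue numbers) and \code{segments} (data.frame of
#'   \code{start}, \code{end}, \code{length}).
#' @export
classifyPerturbations <- function(records, threshold = 0.05) {
  perturbed <- (!is.na(records$csp) & records$csp > threshold) |
    records$attenuated
  res <- sort(records$residue[perturbed])
  segments <- if (length(res)) {
    brk <- c(0L, which(diff(res) != 1L), length(res))
    do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
      seg <- res[(brk[i] + 1L):brk[i + 1L]]
      data.frame(start = seg[1], end = seg[length(seg)], length = length(seg))
    }))
  } else data.frame(start = integer(0), end = integer(0), length = integer(0))
  records$perturbed <- perturbed
  list(records = records, perturbed = res, segments = segments)
}
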