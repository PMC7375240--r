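# Ligand parsing, Michael-acceptor warhead chemistry and rotatable bonds.
#
# Molecules are held as heavy-atom graphs with per-atom implicit hydrogen
# counts; SMILES/SDF interpretation is delegated to OpenBabel via
# ChemmineR/ChemmineOB, everything downstream works on the extracted graph.

DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                     F = 1, CL = 1, BR = 1, I = 1, H = 1)

# old-style SDF atom-line charge codes
SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                `5` = -1L, `6` = -2L, `7` = -3L)

elementLJTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- utils::read.delim(extdata("element_lj.tsv"),
                                                    stringsAsFactors = FALSE)
    cache
  }
})

ligandGraph <- function(ligand) {
  igraph::graph_from_data_frame(
    d = ligand@bonds[, c("from", "to"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(ligand@atoms))))
}

sdfToLigand <- function(sdf, id, smiles = "") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab)) || nrow(ab) < 1L)
    cyStop("cyslock_parse_error", "record '%s' contains no atoms", id)
  element <- toupper(sub("_[0-9]+$", "", rownames(ab)))
  n <- length(element)
  fc <- integer(n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(as.integer(ab[, "C6"]))
    fc <- unname(SDF_CHARGE[ifelse(code %in% names(SDF_CHARGE), code, "0")])
  }
  bonds <- if (!is.null(dim(bb)) && nrow(bb) > 0)
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  else data.frame(from = integer(0), to = integer(0), order = integer(0))

  # fold explicit hydrogens into the heavy-atom implicit counts
  explicitH <- integer(n)
  isH <- element == "H"
  if (any(isH)) {
    for (b in seq_len(nrow(bonds))) {
      f <- bonds$from[b]; t <- bonds$to[b]
      if (isH[f] && !isH[t]) explicitH[t] <- explicitH[t] + 1L
      if (isH[t] && !isH[f]) explicitH[f] <- explicitH[f] + 1L
    }
    keep <- which(!isH)
    remap <- match(seq_len(n), keep)
    bonds <- bonds[!isH[bonds$from] & !isH[bonds$to], , drop = FALSE]
    bonds$from <- remap[bonds$from]; bonds$to <- remap[bonds$to]
    element <- element[keep]; fc <- fc[keep]; explicitH <- explicitH[keep]
    n <- length(keep)
  }
  if (n < 1L) cyStop("cyslock_parse_error", "record '%s' has no heavy atoms", id)

  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    ord <- ifelse(bonds$order == 4L, 1.5, bonds$order)
    for (b in seq_len(nrow(bonds))) {
      bsum[bonds$from[b]] <- bsum[bonds$from[b]] + ord[b]
      bsum[bonds$to[b]] <- bsum[bonds$to[b]] + ord[b]
    }
  }
  bsum <- round(bsum)
  unknown <- setdiff(unique(element), names(DEFAULT_VALENCE))
  if (length(unknown))
    cyStop("cyslock_parse_error", "record '%s': unsupported element(s) %s",
           id, paste(unknown, collapse = ", "))
  val <- unname(DEFAULT_VALENCE[element])
  val <- ifelse(element == "C", val - abs(fc), val + fc)
  val <- pmax(val, bsum)              # hypervalent S/P keep zero implicit H
  implicitH <- pmax(0L, as.integer(val - bsum)) + explicitH

  atomsDf <- data.frame(element = element, formal_charge = fc,
                        implicit_h = implicitH, charge = NA_real_,
                        sigma = NA_real_, epsilon = NA_real_,
                        stringsAsFactors = FALSE)
  lj <- elementLJTable()
  idx <- match(element, lj$element)
  if (anyNA(idx))
    cyStop("cyslock_parse_error", "no Lennard-Jones parameters for element(s) %s",
           paste(unique(element[is.na(idx)]), collapse = ", "))
  atomsDf$sigma <- lj$sigma_A[idx]
  atomsDf$epsilon <- lj$epsilon_kcal[idx]

  lig <- new("Ligand", atoms = atomsDf, bonds = bonds, id = id,
             smiles = smiles, formula = graphFormula(atomsDf))
  if (nrow(atomsDf) > 1L) {
    comp <- igraph::components(ligandGraph(lig))
    if (comp$no != 1L)
      cyStop("cyslock_parse_error",
             "record '%s' is disconnected (%d fragments)", id, comp$no)
  }
  lig@atoms$charge <- peoeCharges(lig)
  lig
}

graphFormula <- function(atomsDf) {
  counts <- table(atomsDf$element)
  out <- as.integer(counts)
  names(out) <- names(counts)
  h <- sum(atomsDf$implicit_h)
  if (h > 0) out <- c(out, H = as.integer(h)) else out
  # Hill order: C, H, then alphabetical
  els <- names(out)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  out <- out[hill]
  agg <- tapply(out, names(out), sum)   # merge if H appeared twice
  out <- as.integer(agg[hill[!duplicated(hill)]])
  names(out) <- hill[!duplicated(hill)]
  out
}

#' Parse a ligand from SMILES or an SDF block
#'
#' SMILES strings are interpreted by OpenBabel (kekulized heavy-atom graph
#' with implicit hydrogen counts); records containing newlines or a V2000
#' counts line are read as SDF. Partial charges are assigned by the packaged
#' iterative partial-equalization-of-orbital-electronegativity scheme and
#' Lennard-Jones parameters by element; the elemental formula (implicit H
#' included) is computed from the graph.
#'
#' @param record SMILES string or SDF V2000 block (string or lines).
#' @param id compound identifier stored in the object.
#' @return A [Ligand-class].
#' @examples
#' lig <- parseLigand("C=CC(=O)N", "acrylamide")
#' atoms(lig)
#' @export
parseLigand <- function(record, id = "ligand") {
  isSdf <- length(record) > 1L || grepl("\n", record[1], fixed = TRUE) ||
    grepl("V2000", record[1], fixed = TRUE)
  sdfset <- tryCatch(suppressWarnings({
    if (isSdf) {
      lines <- if (length(record) > 1L) record else
        strsplit(record, "\n", fixed = TRUE)[[1]]
      ChemmineR::read.SDFset(lines)
    } else {
      ChemmineR::smiles2sdf(trimws(record))
    }
  }), error = function(e)
    cyStop("cyslock_parse_error", "cannot parse record '%s': %s",
           id, conditionMessage(e)))
  tryCatch(
    sdfToLigand(sdfset[[1]], id = id, smiles = if (isSdf) "" else trimws(record)),
    cyslock_error = function(e) stop(e),
    error = function(e)
      cyStop("cyslock_parse_error", "invalid molecule record '%s': %s",
             id, conditionMessage(e)))
}

#' Format an elemental formula in Hill notation
#'
#' @param formula named integer vector of element counts.
#' @return Character scalar, e.g. \code{"C3H5NO"}.
#' @export
formatFormula <- function(formula) {
  if (!length(formula)) return("")
  paste0(vapply(seq_along(formula), function(i) {
    el <- names(formula)[i]
    el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 10)))
    if (formula[i] == 1L) el else paste0(el, formula[i])
  }, ""), collapse = "")
}

# ---- PEOE partial charges ---------------------------------------------------

# Gasteiger-Marsili electronegativity polynomials chi(q) = a + b q + c q^2
PEOE_PARAMS <- rbind(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp1  = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp1  = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  S      = c(10.14, 9.13, 1.38),
  P      = c(8.90, 8.24, 0.96),
  F      = c(14.66, 13.85, 2.31),
  CL     = c(11.00, 9.69, 1.35),
  BR     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  B      = c(7.98, 9.18, 1.88))

peoeKey <- function(element, maxOrder, nDouble) {
  if (element %in% c("C", "N", "O")) {
    hyb <- if (maxOrder >= 3 || nDouble >= 2) "sp1"
           else if (maxOrder >= 1.5) "sp2" else "sp3"
    if (element == "O" && hyb == "sp1") hyb <- "sp2"
    paste(element, hyb, sep = ".")
  } else element
}

# Iterative partial equalization of orbital electronegativity over the
# implicit-H-expanded graph; hydrogen charges are folded back onto their
# heavy atom (united-atom collapse). Deterministic; conserves total formal
# charge exactly.
peoeCharges <- function(ligand, iterations = 6L) {
  a <- ligand@atoms; b <- ligand@bonds
  nH <- sum(a$implicit_h)
  n <- nrow(a)
  element <- c(a$element, rep("H", nH))
  parent <- c(seq_len(n), rep(NA_integer_, nH))
  ef <- b$from; et <- b$to
  hi <- n
  for (i in seq_len(n)) {
    if (a$implicit_h[i] > 0) for (k in seq_len(a$implicit_h[i])) {
      hi <- hi + 1L
      ef <- c(ef, i); et <- c(et, hi)
      parent[hi] <- i
    }
  }
  ordv <- c(ifelse(b$order == 4L, 1.5, as.numeric(b$order)), rep(1, nH))
  maxOrder <- numeric(hi); nDouble <- integer(hi)
  for (e in seq_along(ef)) {
    maxOrder[ef[e]] <- max(maxOrder[ef[e]], ordv[e])
    maxOrder[et[e]] <- max(maxOrder[et[e]], ordv[e])
    if (ordv[e] == 2) {
      nDouble[ef[e]] <- nDouble[ef[e]] + 1L
      nDouble[et[e]] <- nDouble[et[e]] + 1L
    }
  }
  key <- vapply(seq_len(hi),
                function(i) peoeKey(element[i], maxOrder[i], nDouble[i]), "")
  if (!all(key %in% rownames(PEOE_PARAMS)))
    cyStop("cyslock_value_error", "no electronegativity parameters for %s",
           paste(unique(key[!key %in% rownames(PEOE_PARAMS)]), collapse = ", "))
  P <- PEOE_PARAMS[key, , drop = FALSE]
  # cation electronegativity of the donor limits the transfer; 20.02 for H
  xplus <- rowSums(P)
  xplus[element == "H"] <- 20.02
  q <- c(as.numeric(a$formal_charge), rep(0, nH))
  for (it in seq_len(iterations)) {
    damp <- 0.5^it
    chi <- P[, 1] + P[, 2] * q + P[, 3] * q^2
    dq <- numeric(hi)
    for (e in seq_along(ef)) {
      i <- ef[e]; j <- et[e]
      if (chi[j] > chi[i]) {
        d <- (chi[j] - chi[i]) / xplus[i] * damp
        dq[i] <- dq[i] + d; dq[j] <- dq[j] - d
      } else if (chi[i] > chi[j]) {
        d <- (chi[i] - chi[j]) / xplus[j] * damp
        dq[j] <- dq[j] + d; dq[i] <- dq[i] - d
      }
    }
    q <- q + dq
  }
  out <- q[seq_len(n)]
  if (nH > 0) for (i in (n + 1L):hi) out[parent[i]] <- out[parent[i]] + q[i]
  out
}

# ---- warhead detection ------------------------------------------------------

#' Warhead pattern table
#'
#' Reads a pattern-per-line TSV describing Michael-acceptor classes (see the
#' packaged \code{warheads.tsv} for the column semantics); users may extend
#' the file with further EWG definitions. \code{defaultWarheadPatterns()}
#' returns the packaged five-class set: acrylamide, acrylate ester, enone,
#' vinyl sulfonate and vinyl sulfone.
#'
#' @param path file path.
#' @return data.frame of patterns in priority order.
#' @export
readWarheadPatterns <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("pattern_id", "ewg_element", "n_double_o", "x_element",
            "x_needs_carbon")
  if (!all(need %in% names(t)))
    cyStop("cyslock_value_error", "pattern table lacks columns: %s",
           paste(setdiff(need, names(t)), collapse = ", "))
  t
}

#' @rdname readWarheadPatterns
#' @export
defaultWarheadPatterns <- function() readWarheadPatterns(extdata("warheads.tsv"))

emptyWarheadMatches <- function() {
  data.frame(pattern_id = character(0), alpha_c = integer(0),
             beta_c = integer(0), ewg_atom = integer(0),
             stringsAsFactors = FALSE)
}

#' Detect Michael-acceptor warheads
#'
#' Scans the ligand for non-ring C=C double bonds whose alpha carbon is
#' conjugated to an electron-withdrawing group from the pattern table. For
#' each site the highest-priority pattern wins; overlapping sites (sharing a
#' vinyl carbon) are resolved greedily in ascending beta-carbon order. The
#' beta carbon is the site of thiol attack.
#'
#' @param ligand a [Ligand-class].
#' @param patterns pattern data.frame (default the packaged five classes).
#' @return data.frame with columns \code{pattern_id}, \code{alpha_c},
#'   \code{beta_c}, \code{ewg_atom}, ordered by \code{beta_c}; zero rows when
#'   the ligand carries no warhead.
#' @examples
#' detectWarheads(parseLigand("C=CC(=O)N"))
#' @export
detectWarheads <- function(ligand, patterns = defaultWarheadPatterns()) {
  a <- ligand@atoms; b <- ligand@bonds
  if (nrow(b) == 0L) return(emptyWarheadMatches())
  g <- ligandGraph(ligand)
  bridges <- igraph::bridges(g)
  inRing <- rep(TRUE, nrow(b))
  inRing[as.integer(bridges)] <- FALSE

  nb <- function(i) {
    rows <- which(b$from == i | b$to == i)
    data.frame(atom = ifelse(b$from[rows] == i, b$to[rows], b$from[rows]),
               order = b$order[rows])
  }
  matchSite <- function(alpha, beta) {
    na <- nb(alpha)
    for (p in seq_len(nrow(patterns))) {
      pat <- patterns[p, ]
      cand <- na$atom[na$order == 1L &
                      a$element[na$atom] == toupper(pat$ewg_element) &
                      na$atom != beta]
      for (k in cand) {
        nk <- nb(k)
        dblO <- nk$atom[nk$order == 2L & a$element[nk$atom] == "O"]
        if (length(dblO) < pat$n_double_o) next
        xs <- nk$atom[nk$order == 1L & !(nk$atom %in% c(alpha, dblO)) &
                      a$element[nk$atom] == toupper(pat$x_element)]
        if (isTRUE(pat$x_needs_carbon) && length(xs)) {
          keep <- vapply(xs, function(x) {
            nx <- nb(x)
            any(nx$atom != k & a$element[nx$atom] == "C")
          }, TRUE)
          xs <- xs[keep]
        }
        if (length(xs))
          return(data.frame(pattern_id = pat$pattern_id,
                            alpha_c = as.integer(alpha),
                            beta_c = as.integer(beta),
                            ewg_atom = as.integer(k),
                            stringsAsFactors = FALSE))
      }
    }
    NULL
  }

  hits <- list()
  dbl <- which(b$order == 2L & !inRing &
               a$element[b$from] == "C" & a$element[b$to] == "C")
  for (e in dbl) {
    i <- b$from[e]; j <- b$to[e]
    for (ori in list(c(i, j), c(j, i))) {
      m <- matchSite(ori[1], ori[2])
      if (!is.null(m)) hits[[length(hits) + 1L]] <- m
    }
  }
  if (!length(hits)) return(emptyWarheadMatches())
  m <- do.call(rbind, hits)
  m <- m[order(m$beta_c, m$alpha_c), , drop = FALSE]
  used <- integer(0); keep <- logical(nrow(m))
  for (r in seq_len(nrow(m))) {
    at <- c(m$alpha_c[r], m$beta_c[r])
    if (!any(at %in% used)) { keep[r] <- TRUE; used <- c(used, at) }
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the covalent Michael-addition transform
#'
#' Reduces the warhead C=C to a single bond, adds the thiol-derived hydrogen
#' at the alpha carbon and reserves the open valence at the beta carbon for
#' the S-gamma link. Because Michael addition incorporates the whole molecule
#' with no leaving group, the adduct mass shift equals the neutral
#' monoisotopic mass of the intact parent compound.
#'
#' @param ligand the parent [Ligand-class].
#' @param match one row of [detectWarheads()] output (data.frame or list).
#' @param bondLength S-C anchor bond length in Angstrom (default 1.81).
#' @return An [AnchoredLigand-class].
#' @examples
#' lig <- parseLigand("C=CC(=O)N")
#' anch <- applyMichaelAddition(lig, detectWarheads(lig)[1, ])
#' massDelta(anch)
#' @export
applyMichaelAddition <- function(ligand, match, bondLength = 1.81) {
  al <- as.integer(match$alpha_c[1]); be <- as.integer(match$beta_c[1])
  n <- nrow(ligand@atoms)
  if (is.na(al) || is.na(be) || al < 1L || al > n || be < 1L || be > n)
    cyStop("cyslock_consistency_error",
           "warhead match indices do not fit this ligand")
  b <- ligand@bonds
  row <- which((b$from == al & b$to == be) | (b$from == be & b$to == al))
  if (length(row) != 1L || b$order[row] != 2L)
    cyStop("cyslock_consistency_error",
           "stale warhead match: bond %d-%d is not a double bond", al, be)
  lig <- ligand
  lig@bonds$order[row] <- 1L
  lig@atoms$implicit_h[al] <- lig@atoms$implicit_h[al] + 1L
  new("AnchoredLigand", ligand = lig, alphaC = al, betaC = be,
      ewgAtom = as.integer(match$ewg_atom[1]),
      patternId = as.character(match$pattern_id[1]),
      anchorBondLength = as.numeric(bondLength),
      massDelta = formulaMass(ligand@formula, "monoisotopic"))
}

#' Rotatable bonds of an anchored ligand
#'
#' A bond is rotatable when it is single, acyclic and non-terminal (both ends
#' attached to at least one further heavy atom, the covalent S link counting
#' as an attachment of the beta carbon); amide C-N bonds are held planar and
#' excluded. The S-C anchor bond is always rotatable and always first; the
#' remaining bonds follow in breadth-first order from the anchor atom, each
#' oriented proximal to distal.
#'
#' @param anchored an [AnchoredLigand-class].
#' @return data.frame with columns \code{from}, \code{to}; row one is the
#'   anchor bond with \code{from = 0} standing for the pocket S-gamma.
#' @export
findRotatableBonds <- function(anchored) {
  lig <- anchored@ligand
  a <- lig@atoms; b <- lig@bonds
  anchorRow <- data.frame(from = 0L, to = anchored@betaC)
  if (nrow(b) == 0L) return(anchorRow)
  g <- ligandGraph(lig)
  bridge <- rep(FALSE, nrow(b))
  bridge[as.integer(igraph::bridges(g))] <- TRUE
  deg <- igraph::degree(g)
  deg[anchored@betaC] <- deg[anchored@betaC] + 1L
  hasDoubleO <- function(i) {
    rows <- which((b$from == i | b$to == i) & b$order == 2L)
    other <- ifelse(b$from[rows] == i, b$to[rows], b$from[rows])
    any(a$element[other] == "O")
  }
  amide <- vapply(seq_len(nrow(b)), function(e) {
    if (b$order[e] != 1L) return(FALSE)
    i <- b$from[e]; j <- b$to[e]
    (a$element[i] == "C" && a$element[j] == "N" && hasDoubleO(i)) ||
      (a$element[j] == "C" && a$element[i] == "N" && hasDoubleO(j))
  }, TRUE)
  eligible <- b$order == 1L & bridge & !amide &
    deg[b$from] >= 2L & deg[b$to] >= 2L
  if (!any(eligible)) return(anchorRow)
  dist <- as.integer(igraph::distances(g, v = anchored@betaC)[1, ])
  sel <- which(eligible)
  from <- ifelse(dist[b$from[sel]] <= dist[b$to[sel]], b$from[sel], b$to[sel])
  to <- ifelse(dist[b$from[sel]] <= dist[b$to[sel]], b$to[sel], b$from[sel])
  ord <- order(dist[to], dist[from], from, to)
  rbind(anchorRow,
        data.frame(from = as.integer(from[ord]), to = as.integer(to[ord])))
}

#' Read a SMILES ligand library
#'
#' One compound per line: a SMILES string optionally followed by a tab- or
#' space-separated identifier. Lines without an identifier get \code{Lnnnn}
#' ids in file order.
#'
#' @param x file path or character vector of lines.
#' @return data.frame with columns \code{id}, \code{smiles}.
#' @export
readLigandLibrary <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    cyStop("cyslock_value_error", "empty ligand library")
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, "", 1)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) > 1L) parts[[i]][2] else sprintf("L%04d", i), "")
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Write a SMILES ligand library
#'
#' @param library data.frame with columns \code{id}, \code{smiles}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeLigandLibrary <- function(library, path) {
  writeLines(paste(library$smiles, library$id, sep = "\t"), path)
  invisible(path)
}
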