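# Deterministic synthetic-data generators: toy pockets, warhead libraries,
# two-state trajectories and perturbed peak lists. Every generator is a pure
# function of (seed, parameters); repeated calls are byte-identical.

randomUnit <- function() vunit(stats::rnorm(3))

#' Generate a toy pocket structure
#'
#' A cysteine anchor (N, CA, C, O, CB, SG; residue 107 of chain A) with its
#' S-gamma at the origin and the S-CB bond along -x, ringed by
#' \code{nResidues - 1} small standard residues (ALA/SER/VAL/THR) whose
#' C-alpha atoms sit 5.2-6.6 Angstrom from the S-gamma, roughly perpendicular
#' to the ligand channel (+x) with side chains pointing outward. Every
#' non-anchor atom lies within 10 Angstrom of the S-gamma and the structure
#' parameterizes with the packaged table.
#'
#' @param seed integer seed; fully determines the output.
#' @param nResidues total residue count including the cysteine (>= 2).
#' @return Character vector of PDB lines (parse with [readStructure()]).
#' @export
makeToyPocket <- function(seed, nResidues = 8L) {
  if (nResidues < 2L)
    cyStop("cyslock_value_error", "nResidues must be >= 2")
  withSeed(seed, {
    rows <- list()
    addAtom <- function(name, resname, resno, xyz) {
      rows[[length(rows) + 1L]] <<- data.frame(
        name = name, resname = resname, resno = as.integer(resno),
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
    # anchor cysteine: SG at origin, CB anti to the ligand channel (+x)
    addAtom("N",  "CYS", 107L, c(-3.95, 0.85, 0.90))
    addAtom("CA", "CYS", 107L, c(-2.70, 1.20, 0.20))
    addAtom("C",  "CYS", 107L, c(-2.75, 2.66, -0.25))
    addAtom("O",  "CYS", 107L, c(-1.85, 3.16, -0.95))
    addAtom("CB", "CYS", 107L, c(-1.81, 0.00, 0.00))
    addAtom("SG", "CYS", 107L, c(0.00, 0.00, 0.00))

    sideAtoms <- list(
      ALA = character(0), SER = "OG", VAL = c("CG1", "CG2"),
      THR = c("OG1", "CG2"))
    kinds <- c("ALA", "SER", "VAL", "THR")
    for (i in seq_len(nResidues - 1L)) {
      res <- kinds[(i - 1L) %% length(kinds) + 1L]
      resno <- 100L + i + (i >= 7L)      # skip 107, the anchor
      phi <- 2 * pi * (i - 1) / (nResidues - 1L) + stats::runif(1, -0.15, 0.15)
      theta <- stats::runif(1, 80, 100) * pi / 180
      d <- c(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
      r <- stats::runif(1, 5.2, 6.6)
      ca <- d * r
      out <- d                             # outward, away from the S-gamma
      t1 <- vunit(vcross(d, c(0, 0, 1) + stats::rnorm(3, 0, 0.05)))
      t2 <- vunit(vcross(d, t1))
      jitterOut <- function() vunit(out + 0.25 * stats::rnorm(3))
      addAtom("N", res, resno, ca + 1.46 * t1)
      addAtom("CA", res, resno, ca)
      cpos <- ca + 1.53 * t2
      addAtom("C", res, resno, cpos)
      addAtom("O", res, resno, cpos + 1.23 * jitterOut())
      cb <- ca + 1.53 * jitterOut()
      addAtom("CB", res, resno, cb)
      for (sa in sideAtoms[[res]]) {
        len <- if (startsWith(sa, "O")) 1.43 else 1.53
        addAtom(sa, res, resno, cb + len * jitterOut())
      }
    }
    df <- do.call(rbind, rows)
    atomsDf <- data.frame(serial = seq_len(nrow(df)), name = df$name,
                          element = substr(df$name, 1, 1),
                          resname = df$resname, chain = "A",
                          resno = df$resno, stringsAsFactors = FALSE)
    co <- array(c(df$x, df$y, df$z), dim = c(nrow(df), 3, 1))
    s <- new("ProteinStructure", atoms = atomsDf, coords = co,
             sourceId = sprintf("toy_pocket_seed%d", as.integer(seed)))
    writeStructure(s)
  })
}

#' Generate a synthetic warhead ligand library
#'
#' Builds \code{round(n * warheadFraction)} compounds carrying exactly one
#' packaged Michael-acceptor warhead (the five classes cycled over a set of
#' inert alkyl/aryl tails) and fills the remainder with warhead-free
#' molecules, shuffles the order deterministically and assigns ids
#' \code{L0001...}.
#'
#' @param seed integer seed.
#' @param n library size (default 120).
#' @param warheadFraction fraction of warhead-bearing compounds (default 0.9).
#' @return data.frame with columns \code{id}, \code{smiles} and the
#'   generation-truth column \code{warhead}.
#' @export
makeLigandLibrary <- function(seed, n = 120L, warheadFraction = 0.9) {
  if (n < 1L) cyStop("cyslock_value_error", "n must be >= 1")
  if (warheadFraction < 0 || warheadFraction > 1)
    cyStop("cyslock_value_error", "warheadFraction must lie in [0, 1]")
  heads <- c("C=CC(=O)N%s", "C=CC(=O)%s", "C=CC(=O)O%s",
             "C=CS(=O)(=O)%s", "C=CS(=O)(=O)O%s")
  tails <- c("C", "CC", "CCC", "CCCC", "CCO", "CCOC", "CCN", "CC(C)C",
             "Cc1ccccc1", "CCc1ccccc1")
  inert <- c("CCC(=O)N", "CCC(=O)NC", "c1ccccc1", "Cc1ccccc1", "CCO",
             "CCOCC", "CCC(=O)OC", "CCS(=O)(=O)C", "CC(C)O", "CCNCC")
  nWar <- round(n * warheadFraction)
  warSmiles <- vapply(seq_len(nWar), function(i) {
    h <- (i - 1L) %% length(heads) + 1L
    t <- ((i - 1L) %/% length(heads)) %% length(tails) + 1L
    ext <- (i - 1L) %/% (length(heads) * length(tails))
    sprintf(heads[h], paste0(strrep("C", ext), tails[t]))
  }, "")
  inertSmiles <- vapply(seq_len(n - nWar), function(i) {
    p <- (i - 1L) %% length(inert) + 1L
    ext <- (i - 1L) %/% length(inert)
    paste0(strrep("C", ext), inert[p])
  }, "")
  smiles <- c(warSmiles, inertSmiles)
  truth <- rep(c(TRUE, FALSE), c(nWar, n - nWar))
  ord <- withSeed(seed, sample.int(n))
  data.frame(id = sprintf("L%04d", seq_len(n)), smiles = smiles[ord],
             warhead = truth[ord], stringsAsFactors = FALSE)
}

randomChain <- function(nRes, step = 3.8) {
  pos <- matrix(0, nRes, 3)
  dir <- randomUnit()
  for (i in 2:nRes) {
    dir <- vunit(dir + 0.6 * stats::rnorm(3))
    pos[i, ] <- pos[i - 1, ] + step * dir
  }
  pos
}

#' Generate a synthetic multi-state C-alpha trajectory
#'
#' Draws frames around \code{length(stateFractions)} reference conformations
#' (random persistent C-alpha walks, redrawn until every pair is at least
#' \code{separation} Angstrom apart in superposed RMSD) with isotropic
#' Gaussian noise, so that clustering with the generating k recovers the
#' states exactly. Generation labels are returned alongside the frames.
#'
#' @param seed integer seed.
#' @param nFrames number of frames (default 100).
#' @param stateFractions per-state frame fractions summing to 1
#'   (default \code{c(0.6, 0.4)}).
#' @param noise per-coordinate Gaussian noise sd in Angstrom (default 0.3);
#'   must stay below \code{separation / 10}.
#' @param separation minimum between-state RMSD in Angstrom (default 5).
#' @param nResidues chain length (default 40).
#' @return list with \code{pdb} (multi-model PDB lines) and \code{labels}
#'   (data.frame of \code{frame}, \code{state}).
#' @export
makeTrajectory <- function(seed, nFrames = 100L, stateFractions = c(0.6, 0.4),
                           noise = 0.3, separation = 5, nResidues = 40L) {
  m <- length(stateFractions)
  if (abs(sum(stateFractions) - 1) > 1e-9)
    cyStop("cyslock_value_error", "state fractions must sum to 1")
  if (any(stateFractions <= 0))
    cyStop("cyslock_value_error", "state fractions must be positive")
  if (nFrames < m)
    cyStop("cyslock_value_error", "need at least one frame per state")
  if (noise >= separation / 10)
    cyStop("cyslock_value_error",
           "noise (%g) must stay below separation/10 (%g)", noise,
           separation / 10)
  counts <- round(stateFractions * nFrames)
  counts[1] <- counts[1] + (nFrames - sum(counts))
  withSeed(seed, {
    repeat {
      refs <- lapply(seq_len(m), function(i) randomChain(nResidues))
      ok <- TRUE
      if (m > 1) for (i in seq_len(m - 1)) for (j in (i + 1):m)
        if (caRMSD(refs[[i]], refs[[j]]) < separation) ok <- FALSE
      if (ok) break
    }
    frames <- list(); labels <- integer(0)
    for (s in seq_len(m)) for (k in seq_len(counts[s])) {
      frames[[length(frames) + 1L]] <- refs[[s]] +
        matrix(stats::rnorm(nResidues * 3, sd = noise), nResidues, 3)
      labels <- c(labels, s)
    }
    atomsDf <- data.frame(serial = seq_len(nResidues), name = "CA",
                          element = "C", resname = "ALA", chain = "A",
                          resno = seq_len(nResidues), stringsAsFactors = FALSE)
    co <- array(NA_real_, dim = c(nResidues, 3, length(frames)))
    for (k in seq_along(frames)) co[, , k] <- frames[[k]]
    s <- new("ProteinStructure", atoms = atomsDf, coords = co,
             sourceId = sprintf("synthetic_trajectory_seed%d", as.integer(seed)))
    list(pdb = writeStructure(s),
         labels = data.frame(frame = seq_along(labels), state = labels))
  })
}

#' Generate apo/bound HSQC peak lists with known perturbations
#'
#' The bound list shifts the amide resonances inside \code{perturbedRanges}
#' so the combined CSP (1H/15N weight 0.2) equals \code{cspMagnitude} exactly,
#' leaves sub-0.01 jitter elsewhere, and scales the intensities of
#' \code{attenuatedSet} below the attenuation floor.
#'
#' @param seed integer seed.
#' @param nResidues protein length (default 180).
#' @param perturbedRanges list of inclusive \code{c(start, end)} residue
#'   ranges (default the two segments 64-78 and 90-113); must not overlap.
#' @param cspMagnitude CSP built into the perturbed ranges (default 0.1 ppm).
#' @param attenuatedSet residues whose bound peaks are attenuated
#'   (default none).
#' @return list with data.frames \code{apo} and \code{bound}.
#' @export
makePeakLists <- function(seed, nResidues = 180L,
                          perturbedRanges = list(c(64L, 78L), c(90L, 113L)),
                          cspMagnitude = 0.1, attenuatedSet = integer(0)) {
  covered <- integer(0)
  for (rg in perturbedRanges) {
    if (length(rg) != 2L || rg[1] > rg[2] || rg[1] < 1L || rg[2] > nResidues)
      cyStop("cyslock_value_error", "range (%s) outside 1..%d",
             paste(rg, collapse = ","), nResidues)
    span <- rg[1]:rg[2]
    if (any(span %in% covered))
      cyStop("cyslock_value_error", "perturbed ranges overlap")
    covered <- c(covered, span)
  }
  if (length(attenuatedSet) && (min(attenuatedSet) < 1 ||
                                max(attenuatedSet) > nResidues))
    cyStop("cyslock_value_error", "attenuated residues outside 1..%d", nResidues)
  withSeed(seed, {
    n <- nResidues
    apo <- data.frame(residue = seq_len(n),
                      h_ppm = stats::runif(n, 6.5, 9.5),
                      n_ppm = stats::runif(n, 105, 130),
                      intensity = stats::runif(n, 0.8, 1.2))
    dh <- stats::runif(n, -0.002, 0.002)
    dn <- stats::runif(n, -0.01, 0.01)
    signH <- sample(c(-1, 1), n, replace = TRUE)
    signN <- sample(c(-1, 1), n, replace = TRUE)
    pert <- seq_len(n) %in% covered
    # split the target CSP 0.36/0.64 between the 1H and weighted 15N terms
    dh[pert] <- signH[pert] * 0.6 * cspMagnitude
    dn[pert] <- signN[pert] * 0.8 * cspMagnitude / 0.2
    ratio <- stats::runif(n, 0.9, 1.1)
    ratio[seq_len(n) %in% attenuatedSet] <- 0.1
    bound <- data.frame(residue = seq_len(n),
                        h_ppm = apo$h_ppm + dh,
                        n_ppm = apo$n_ppm + dn,
                        intensity = apo$intensity * ratio)
    list(apo = apo, bound = bound)
  })
}
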