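# Shared test helpers: naive energy oracles and bare containers with fully
# controlled parameters.

# independent double-loop references for the energy terms
naiveCoulomb <- function(lxyz, lq, pxyz, pq, dielectric, cutoff) {
  e <- 0
  for (i in seq_len(nrow(lxyz))) for (j in seq_len(nrow(pxyz))) {
    r <- sqrt(sum((lxyz[i, ] - pxyz[j, ])^2))
    if (r <= cutoff) e <- e + 332.0637 * lq[i] * pq[j] / (dielectric * r)
  }
  e
}

naiveLJ <- function(lxyz, lsig, leps, pxyz, psig, peps, cutoff) {
  e <- 0
  for (i in seq_len(nrow(lxyz))) for (j in seq_len(nrow(pxyz))) {
    r <- sqrt(sum((lxyz[i, ] - pxyz[j, ])^2))
    if (r <= cutoff) {
      s <- (lsig[i] + psig[j]) / 2
      ep <- sqrt(leps[i] * peps[j])
      e <- e + 4 * ep * ((s / r)^12 - (s / r)^6)
    }
  }
  e
}

# a Pocket whose atoms/charges/LJ parameters are given directly
barePocket <- function(xyz, q, sigma = 3.4, epsilon = 0.1) {
  n <- nrow(xyz)
  sigma <- rep_len(sigma, n); epsilon <- rep_len(epsilon, n)
  atoms <- data.frame(serial = seq_len(n), name = "X", element = "C",
                      resname = "UNK", chain = "A", resno = seq_len(n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = rep_len(q, n), sigma = sigma,
                      epsilon = epsilon, stringsAsFactors = FALSE)
  new("Pocket", atoms = atoms,
      anchor = new("CysteineAnchor", chain = "A", resno = 1L, sgIndex = 1L),
      radius = 1e6, sgLocal = 1L, cbLocal = 0L)
}

# a Ligand whose charges/LJ parameters are given directly (no bonds)
bareLigand <- function(q, sigma = 3.4, epsilon = 0.1) {
  n <- length(q)
  new("Ligand",
      atoms = data.frame(element = "C", formal_charge = 0L, implicit_h = 0L,
                         charge = q, sigma = rep_len(sigma, n),
                         epsilon = rep_len(epsilon, n),
                         stringsAsFactors = FALSE),
      bonds = data.frame(from = integer(0), to = integer(0),
                         order = integer(0)),
      id = "bare", smiles = "", formula = c(C = n))
}

openConfig <- function(dielectric = 1, cutoff = 1e6, wEs = 1, wVdw = 1) {
  scoringConfig(dielectric = dielectric, cutoff = cutoff, wEs = wEs,
                wVdw = wVdw, excluded = integer(0))
}

# standard parameterized toy pocket
stdPocket <- function(seed = 1) {
  s <- readStructure(makeToyPocket(seed))
  parameterizePocket(extractPocket(s, findAnchor(s, "A", 107), 10))
}

# anchored acrylamide placed in a pocket
anchoredIn <- function(pocket, smiles = "C=CC(=O)N", id = "lig") {
  lig <- parseLigand(smiles, id)
  an <- applyMichaelAddition(lig, detectWarheads(lig)[1, ])
  list(anchored = an, start = placeAnchor(an, pocket))
}

# minimal PDB line for one atom
pdbAtomLine <- function(serial, name, resname, chain, resno, x, y, z,
                        element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, formatC(paste0(" ", name), width = -4, flag = "-"),
          resname, chain, resno, x, y, z, element)
}
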