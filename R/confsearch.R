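# Covalent attachment geometry and exhaustive torsion-scan enumeration.
#
# Geometry is realized deterministically from internal coordinates (NeRF
# placement over a BFS tree rooted at the anchored beta carbon): idealized
# bond lengths by element pair, angles by hybridization, planar-polygon ring
# closure. Only torsions vary between conformers of one anchored ligand.

COVALENT_RADIUS <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                     F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, B = 0.84)

BOND_LENGTH_OVERRIDE <- list(
  "C|C|1" = 1.53, "C|C|2" = 1.33, "C|C|3" = 1.20, "C|C|4" = 1.39,
  "C|N|1" = 1.45, "C|N|2" = 1.28, "C|N|4" = 1.34,
  "C|O|1" = 1.43, "C|O|2" = 1.22,
  "C|S|1" = 1.81, "S|O|1" = 1.60, "S|O|2" = 1.45,
  "N|O|1" = 1.40, "N|O|2" = 1.21,
  "C|F|1" = 1.35, "C|CL|1" = 1.77, "C|BR|1" = 1.94, "C|I|1" = 2.14)

bondLengthFor <- function(e1, e2, order) {
  key <- paste(sort(c(e1, e2))[1], sort(c(e1, e2))[2], order, sep = "|")
  key2 <- paste(sort(c(e1, e2))[2], sort(c(e1, e2))[1], order, sep = "|")
  if (!is.null(BOND_LENGTH_OVERRIDE[[key]])) return(BOND_LENGTH_OVERRIDE[[key]])
  if (!is.null(BOND_LENGTH_OVERRIDE[[key2]])) return(BOND_LENGTH_OVERRIDE[[key2]])
  r <- COVALENT_RADIUS[e1] + COVALENT_RADIUS[e2]
  unname(r * switch(as.character(order), "1" = 1, "2" = 0.90, "3" = 0.86,
                    "4" = 0.93, 1))
}

# Natural extension of reference frame: place X bonded to C with bond length
# r, angle X-C-B = theta and dihedral X-C-B-A = phi (radians).
nerfPlace <- function(A, B, C, r, theta, phi) {
  bc <- C - B
  nb <- vnorm(bc)
  bc <- bc / nb
  ab <- B - A
  n <- vcross(ab, bc)
  if (vnorm(n) < 1e-8) {
    # collinear reference: pick a deterministic perpendicular
    e <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- vcross(e, bc)
  }
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

atomHybrid <- function(ligand) {
  a <- ligand@atoms; b <- ligand@bonds
  maxOrd <- numeric(nrow(a)); nDbl <- integer(nrow(a))
  if (nrow(b)) for (e in seq_len(nrow(b))) {
    o <- if (b$order[e] == 4L) 1.5 else b$order[e]
    for (i in c(b$from[e], b$to[e])) {
      maxOrd[i] <- max(maxOrd[i], o)
      if (o == 2) nDbl[i] <- nDbl[i] + 1L
    }
  }
  ifelse(maxOrd >= 3 | nDbl >= 2, "sp1", ifelse(maxOrd >= 1.5, "sp2", "sp3"))
}

# smallest ring size through each bond (0 when the bond is acyclic)
bondRingSize <- function(ligand) {
  b <- ligand@bonds
  if (!nrow(b)) return(integer(0))
  g <- ligandGraph(ligand)
  bridge <- rep(FALSE, nrow(b))
  bridge[as.integer(igraph::bridges(g))] <- TRUE
  out <- integer(nrow(b))
  for (e in which(!bridge)) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, c(b$from[e], b$to[e])))
    d <- igraph::distances(g2, v = b$from[e], to = b$to[e])[1, 1]
    out[e] <- if (is.finite(d)) as.integer(d + 1L) else 0L
  }
  out
}

#' Build the covalent attachment geometry
#'
#' Places the anchored ligand's beta carbon at the configured bond length from
#' the pocket S-gamma along the direction maximizing distance from the
#' cysteine CB (anti to the S-CB bond), then builds the remaining atoms from
#' internal coordinates over a breadth-first tree. The start pose carries
#' torsion offsets of zero on every rotatable bond.
#'
#' @param anchored an [AnchoredLigand-class].
#' @param pocket a [Pocket-class] whose anchor residue contains a CB atom.
#' @param bondLength S-C bond length in Angstrom (default the anchored
#'   ligand's configured value, normally 1.81).
#' @return A [Conformer-class] in the pocket frame.
#' @export
placeAnchor <- function(anchored, pocket, bondLength = anchored@anchorBondLength) {
  if (pocket@cbLocal < 1L)
    cyStop("cyslock_geometry_error",
           "pocket anchor residue lacks a CB atom; cannot orient the S-C bond")
  xyz <- pocketXYZ(pocket)
  sg <- xyz[pocket@sgLocal, ]
  cb <- xyz[pocket@cbLocal, ]
  lig <- anchored@ligand
  a <- lig@atoms; b <- lig@bonds
  n <- nrow(a)
  pos <- matrix(NA_real_, n, 3)
  u <- vunit(sg - cb)
  pos[anchored@betaC, ] <- sg + bondLength * u

  hyb <- atomHybrid(lig)
  ringSize <- bondRingSize(lig)
  bondRow <- function(i, j)
    which((b$from == i & b$to == j) | (b$from == j & b$to == i))[1]

  g <- ligandGraph(lig)
  parent <- rep(NA_integer_, n)
  parent[anchored@betaC] <- 0L           # 0 = pocket S-gamma, -1 = CB
  bfs <- igraph::bfs(g, root = anchored@betaC, father = TRUE)
  ord <- as.integer(bfs$order)
  fa <- as.integer(bfs$father)
  for (v in ord) if (v != anchored@betaC) parent[v] <- fa[v]

  posOf <- function(k) {
    if (k == 0L) sg else if (k == -1L) cb else pos[k, ]
  }
  parentOf <- function(k) {
    if (k > 0L) parent[k] else if (k == 0L) -1L else NA_integer_
  }

  # place in BFS order, grouping siblings so dihedral slots can be assigned
  placedParents <- unique(parent[ord[ord != anchored@betaC]])
  for (P in placedParents) {
    kids <- ord[ord != anchored@betaC & parent[ord] == P & !is.na(parent[ord])]
    G <- parentOf(P)                     # NeRF frame: A-G-P, then the child
    A <- parentOf(G)
    if (is.na(A)) A <- -1L
    slots <- if (hyb[P] == "sp2") c(180, 0) else
             if (hyb[P] == "sp1") 180 else c(180, 60, 300)
    slotFree <- rep(TRUE, length(slots))
    for (X in kids) {
      br <- bondRow(P, X)
      rs <- ringSize[br]
      theta <- if (rs >= 3L) (180 - 360 / rs) else
               if (hyb[P] == "sp2") 120 else
               if (hyb[P] == "sp1") 179 else 109.47
      gpRing <- G > 0L && !is.na(bondRow(G, P)) && ringSize[bondRow(G, P)] >= 3L
      if (rs >= 3L && gpRing) {
        ggpRing <- A > 0L && !is.na(bondRow(A, G)) && ringSize[bondRow(A, G)] >= 3L
        phi <- if (ggpRing) 0 else 180
        d <- abs(((slots - phi + 180) %% 360) - 180)
        slotFree[which.min(d)] <- FALSE
      } else {
        idx <- which(slotFree)[1]
        if (is.na(idx)) idx <- 1L
        phi <- slots[idx]
        slotFree[idx] <- FALSE
      }
      r <- bondLengthFor(a$element[P], a$element[X], b$order[br])
      pos[X, ] <- nerfPlace(posOf(A), posOf(G), posOf(P),
                            r, theta * pi / 180, phi * pi / 180)
    }
  }
  rot <- findRotatableBonds(anchored)
  new("Conformer", coords = pos, torsions = rep(0, nrow(rot)),
      rotatable = rot, anchored = anchored, sg = sg, cb = cb)
}

# atoms moved by each rotatable bond (distal side of the bond)
distalFragments <- function(anchored, rotatable) {
  lig <- anchored@ligand
  n <- nrow(lig@atoms)
  lapply(seq_len(nrow(rotatable)), function(r) {
    f <- rotatable$from[r]; t <- rotatable$to[r]
    if (f == 0L) return(seq_len(n))           # anchor bond moves the ligand
    g <- ligandGraph(anchored@ligand)
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(f, t)))
    comp <- igraph::components(g2)
    which(comp$membership == comp$membership[t])
  })
}

rotateFragment <- function(coords, axisFrom, axisTo, fragment, angleDeg) {
  if (angleDeg == 0) return(coords)
  u <- vunit(axisTo - axisFrom)
  R <- rotationMatrix(u, angleDeg * pi / 180)
  shifted <- sweep(coords[fragment, , drop = FALSE], 2, axisFrom)
  coords[fragment, ] <- shifted %*% t(R) + rep(axisFrom, each = length(fragment))
  coords
}

#' Exhaustively enumerate torsion-scan conformers
#'
#' Drives every rotatable bond through the full circle in constant increments:
#' the conformer set is the Cartesian product of torsion values \{0,
#' increment, 2 increment, ...\} per bond, enumerated in lexicographic order
#' over the breadth-first bond ordering (first bond most significant) and
#' truncated at \code{cap}. Coordinates are realized by rigidly rotating each
#' bond's distal fragment; bond lengths, angles and the proximal atoms are
#' untouched, so enumeration is bit-for-bit reproducible.
#'
#' @param start a [Conformer-class] from [placeAnchor()].
#' @param incrementDeg torsion increment in degrees; must divide 360
#'   (default 30, i.e. 12 states per bond).
#' @param cap maximum number of conformers (default 10000).
#' @return A [ConformerSet-class].
#' @export
enumerateConformers <- function(start, incrementDeg = 30, cap = 10000L) {
  if (!is.numeric(incrementDeg) || incrementDeg <= 0 ||
      (360 %% incrementDeg) != 0)
    cyStop("cyslock_value_error",
           "increment must be a positive divisor of 360 (got %s)",
           format(incrementDeg))
  if (cap < 1L) cyStop("cyslock_value_error", "cap must be >= 1")
  rot <- start@rotatable
  nb <- nrow(rot)
  m <- as.integer(360 / incrementDeg)
  angles <- (seq_len(m) - 1L) * incrementDeg
  total <- min(if (nb == 0L) 1 else m^nb, as.numeric(cap))
  nAtoms <- nrow(start@coords)
  coords <- array(NA_real_, dim = c(nAtoms, 3, total))
  torsions <- matrix(NA_real_, total, max(nb, 0L))
  frags <- distalFragments(start@anchored, rot)
  axisPos <- function(coordsNow, k) {
    f <- rot$from[k]
    from <- if (f == 0L) start@sg else coordsNow[f, ]
    list(from = from, to = coordsNow[rot$to[k], ])
  }
  count <- 0L
  assign_one <- function(coordsNow, tors) {
    count <<- count + 1L
    coords[, , count] <<- coordsNow
    if (nb > 0L) torsions[count, ] <<- tors
  }
  rec <- function(coordsNow, tors, level) {
    if (count >= total) return()
    if (level > nb) { assign_one(coordsNow, tors); return() }
    ax <- axisPos(coordsNow, level)
    for (ang in angles) {
      if (count >= total) break
      c2 <- rotateFragment(coordsNow, ax$from, ax$to, frags[[level]], ang)
      rec(c2, c(tors, ang), level + 1L)
    }
  }
  if (nb == 0L) assign_one(start@coords, numeric(0)) else
    rec(start@coords, numeric(0), 1L)
  new("ConformerSet", anchored = start@anchored, coords = coords,
      torsions = torsions, rotatable = rot,
      incrementDeg = as.numeric(incrementDeg), cap = as.integer(cap),
      sg = start@sg, cb = start@cb)
}

#' Remove conformers with intramolecular clashes
#'
#' Drops every conformer in which any nonbonded ligand atom pair (graph
#' distance of three bonds or more, i.e. 1-4 and beyond) comes closer than
#' \code{minDist}. Survivor order is preserved. A non-positive threshold is
#' vacuous and returns the set unchanged.
#'
#' @param set a [ConformerSet-class].
#' @param minDist clash threshold in Angstrom (default 1.2).
#' @return The pruned [ConformerSet-class].
#' @export
pruneInternalClashes <- function(set, minDist = 1.2) {
  if (minDist <= 0) return(set)
  lig <- set@anchored@ligand
  n <- nrow(lig@atoms)
  if (n < 2L) return(set)
  gd <- igraph::distances(ligandGraph(lig))
  pairs <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  if (!nrow(pairs)) return(set)
  keep <- vapply(seq_len(dim(set@coords)[3]), function(k) {
    xyz <- set@coords[, , k]
    d2 <- rowSums((xyz[pairs[, 1], , drop = FALSE] -
                   xyz[pairs[, 2], , drop = FALSE])^2)
    all(d2 >= minDist^2)
  }, TRUE)
  out <- set
  out@coords <- set@coords[, , keep, drop = FALSE]
  out@torsions <- set@torsions[keep, , drop = FALSE]
  out
}

#' Export conformers as multi-model PDB
#'
#' Writes the anchor cysteine plus the ligand of every conformer as one MODEL
#' block each, for visual inspection in a molecular viewer.
#'
#' @param set a [ConformerSet-class].
#' @param pocket the [Pocket-class] the set was docked into.
#' @param file optional output path.
#' @return Character vector of PDB lines, invisibly when \code{file} is set.
#' @export
writeConformersPDB <- function(set, pocket, file = NULL) {
  pa <- pocket@atoms
  anchorRows <- which(pa$chain == pocket@anchor@chain &
                      pa$resno == pocket@anchor@resno)
  lig <- set@anchored@ligand
  out <- character(0)
  for (k in seq_len(conformerCount(set))) {
    out <- c(out, sprintf("MODEL     %4d", k))
    serial <- 0L
    for (i in anchorRows) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, formatC(paste0(" ", pa$name[i]), width = -4, flag = "-"),
        pa$resname[i], pa$chain[i], pa$resno[i],
        pa$x[i], pa$y[i], pa$z[i], 1, 0, pa$element[i]))
    }
    xyz <- set@coords[, , k]
    for (i in seq_len(nrow(lig@atoms))) {
      serial <- serial + 1L
      nm <- sprintf("%s%d", lig@atoms$element[i], i)
      out <- c(out, sprintf(
        "HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, formatC(paste0(" ", substr(nm, 1, 3)), width = -4, flag = "-"),
        "LIG", "X", 1L, xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
        lig@atoms$element[i]))
    }
    out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}
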