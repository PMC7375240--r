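#' @import methods
NULL

#' Parsed protein structure
#'
#' Holds the atoms of a PDB entry together with one coordinate set per MODEL
#' record. All models of one structure share atom count, atom ordering and
#' residue numbering; the coordinate slot is an \code{n_atoms x 3 x n_models}
#' array in Angstrom.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{chain}, \code{resno} (one row per
#'   atom, shared by all models).
#' @slot coords numeric array, \code{dim = c(n_atoms, 3, n_models)}.
#' @slot sourceId character scalar naming the origin of the structure.
#' @seealso [readStructure()], [findAnchor()], [extractPocket()]
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", coords = "array", sourceId = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms; x <- object@coords
  if (length(dim(x)) != 3L) return("coords must be a 3-d array")
  if (dim(x)[1] != nrow(a)) return("coords/atom count mismatch")
  if (dim(x)[2] != 3L) return("coords must have 3 columns")
  if (dim(x)[3] < 1L) return("structure needs at least one model")
  if (!all(is.finite(x))) return("non-finite coordinates")
  need <- c("serial", "name", "element", "resname", "chain", "resno")
  if (!all(need %in% names(a))) return("atom table lacks required columns")
  TRUE
})

#' Covalent anchor cysteine
#'
#' Identifies the nucleophilic cysteine whose S-gamma thiol receives the
#' Michael adduct, by chain, residue number and the index of the SG atom
#' within the parent structure's atom table.
#'
#' @slot chain single character chain identifier.
#' @slot resno integer residue number (1-based, as in the PDB record).
#' @slot sgIndex integer index of the SG atom in the structure atom table.
#' @seealso [findAnchor()]
#' @export
setClass("CysteineAnchor",
  representation(chain = "character", resno = "integer", sgIndex = "integer"))

#' Binding pocket around the anchor cysteine
#'
#' The atom subset of one structure model lying within \code{radius} Angstrom
#' of the anchor S-gamma, with per-atom partial charges and Lennard-Jones
#' parameters attached by [parameterizePocket()] (NA until then).
#'
#' @slot atoms data.frame with the structural columns plus \code{x,y,z},
#'   \code{charge} (e), \code{sigma} (Angstrom), \code{epsilon} (kcal/mol).
#' @slot anchor the [CysteineAnchor-class] the pocket was cut around.
#' @slot radius numeric cut radius in Angstrom.
#' @slot sgLocal index of the anchor SG within \code{atoms}.
#' @slot cbLocal index of the anchor residue CB within \code{atoms}
#'   (\code{0L} when outside the cut, which cannot happen at sane radii).
#' @seealso [extractPocket()], [parameterizePocket()]
#' @export
setClass("Pocket",
  representation(atoms = "data.frame", anchor = "CysteineAnchor",
                 radius = "numeric", sgLocal = "integer", cbLocal = "integer"))

setValidity("Pocket", function(object) {
  a <- object@atoms
  if (object@radius <= 0) return("radius must be positive")
  if (object@sgLocal < 1L || object@sgLocal > nrow(a))
    return("sgLocal out of range")
  sg <- as.numeric(a[object@sgLocal, c("x", "y", "z")])
  d <- sqrt((a$x - sg[1])^2 + (a$y - sg[2])^2 + (a$z - sg[3])^2)
  if (any(d > object@radius + 1e-6)) return("atom outside the pocket radius")
  ok <- is.na(a$sigma) | (a$sigma > 0 & a$epsilon >= 0)
  if (!all(ok)) return("parameterized atoms need sigma > 0 and epsilon >= 0")
  TRUE
})

#' Small-molecule ligand
#'
#' Heavy-atom molecular graph of one library compound. Hydrogens are implicit
#' (counted per atom); partial charges come from the packaged
#' electronegativity-equalization scheme and Lennard-Jones parameters from the
#' packaged element table, both assigned at parse time.
#'
#' @slot atoms data.frame with columns \code{element}, \code{formal_charge},
#'   \code{implicit_h}, \code{charge}, \code{sigma}, \code{epsilon}.
#' @slot bonds data.frame with columns \code{from}, \code{to}, \code{order}
#'   (1, 2, 3; 4 marks an aromatic bond read from SDF input).
#' @slot id character compound identifier.
#' @slot smiles character, the input record when parsed from SMILES.
#' @slot formula named integer vector of element counts (implicit H included).
#' @seealso [parseLigand()], [detectWarheads()]
#' @export
setClass("Ligand",
  representation(atoms = "data.frame", bonds = "data.frame", id = "character",
                 smiles = "character", formula = "integer"))

setValidity("Ligand", function(object) {
  n <- nrow(object@atoms); b <- object@bonds
  if (n < 1L) return("ligand needs at least one atom")
  if (nrow(b) > 0 && (any(b$from < 1 | b$from > n | b$to < 1 | b$to > n)))
    return("bond indices out of range")
  if (nrow(b) > 0 && any(b$from == b$to)) return("self-bond")
  TRUE
})

#' Covalently anchored ligand
#'
#' A ligand after the Michael-addition transform: the warhead C=C reduced to
#' C-C, one hydrogen (from the thiol) added at the alpha carbon, and an open
#' valence at the beta carbon reserved for the S-gamma link. The mass delta of
#' the adduct equals the neutral monoisotopic mass of the intact parent
#' compound (Michael addition adds the whole molecule, no leaving group).
#'
#' @slot ligand the post-addition [Ligand-class].
#' @slot alphaC,betaC integer atom indices of the former double bond;
#'   \code{betaC} is the site of thiol attack.
#' @slot ewgAtom integer index of the electron-withdrawing anchor atom.
#' @slot patternId character warhead class used.
#' @slot anchorBondLength numeric S-C bond length in Angstrom.
#' @slot massDelta numeric adduct mass shift in Da.
#' @seealso [applyMichaelAddition()], [findRotatableBonds()], [placeAnchor()]
#' @export
setClass("AnchoredLigand",
  representation(ligand = "Ligand", alphaC = "integer", betaC = "integer",
                 ewgAtom = "integer", patternId = "character",
                 anchorBondLength = "numeric", massDelta = "numeric"))

#' Single covalent-docking conformer
#'
#' One realized 3-D pose of an anchored ligand in the pocket frame, plus the
#' torsion offsets (degrees) applied to each rotatable bond relative to the
#' as-built geometry. The anchor S-C bond is torsion number one.
#'
#' @slot coords numeric matrix \code{n_atoms x 3}, Angstrom, pocket frame.
#' @slot torsions numeric vector of angles parallel to the rotatable-bond list.
#' @slot rotatable data.frame of rotatable bonds (\code{from}, \code{to});
#'   \code{from = 0} denotes the pocket S-gamma of the anchor bond.
#' @slot anchored the [AnchoredLigand-class] the pose realizes.
#' @slot sg,cb numeric 3-vectors: anchor S-gamma and CB positions.
#' @seealso [placeAnchor()], [enumerateConformers()]
#' @export
setClass("Conformer",
  representation(coords = "matrix", torsions = "numeric",
                 rotatable = "data.frame", anchored = "AnchoredLigand",
                 sg = "numeric", cb = "numeric"))

#' Exhaustively enumerated conformer set
#'
#' The Cartesian product of torsion values over the rotatable bonds of one
#' anchored ligand, realized as coordinates and truncated at \code{cap}.
#'
#' @slot anchored the [AnchoredLigand-class].
#' @slot coords numeric array \code{n_atoms x 3 x n_conformers}.
#' @slot torsions numeric matrix \code{n_conformers x n_bonds} (degrees).
#' @slot rotatable data.frame of rotatable bonds (see [Conformer-class]).
#' @slot incrementDeg numeric torsion increment in degrees.
#' @slot cap integer enumeration cap.
#' @slot sg,cb numeric 3-vectors of the pocket anchor atoms.
#' @seealso [enumerateConformers()], [pruneInternalClashes()], [bestScore()]
#' @export
setClass("ConformerSet",
  representation(anchored = "AnchoredLigand", coords = "array",
                 torsions = "matrix", rotatable = "data.frame",
                 incrementDeg = "numeric", cap = "integer",
                 sg = "numeric", cb = "numeric"))

setValidity("ConformerSet", function(object) {
  if (length(dim(object@coords)) != 3L) return("coords must be 3-d")
  if (dim(object@coords)[3] != nrow(object@torsions))
    return("conformer count mismatch between coords and torsions")
  if (dim(object@coords)[3] > object@cap) return("more conformers than cap")
  TRUE
})

#' Scoring configuration
#'
#' Knobs of the Coulomb + Lennard-Jones 6-12 score. The dielectric is
#' distance-independent; the anchor S-gamma and its residue's CB are excluded
#' from pairwise sums to avoid bonded self-interaction across the covalent
#' link.
#'
#' @slot dielectric relative dielectric constant (> 0).
#' @slot wEs,wVdw term weights of the total score.
#' @slot cutoff pair cutoff in Angstrom (> 0).
#' @slot excluded integer indices of pocket atoms skipped in both terms.
#' @seealso [scoringConfig()], [scoreConformer()]
#' @export
setClass("ScoringConfig",
  representation(dielectric = "numeric", wEs = "numeric", wVdw = "numeric",
                 cutoff = "numeric", excluded = "integer"))

setValidity("ScoringConfig", function(object) {
  if (object@dielectric <= 0) return("dielectric must be > 0")
  if (object@cutoff <= 0) return("cutoff must be > 0")
  TRUE
})

#' Library screening result
#'
#' Per-compound outcome of a covalent screen: best score breakdown, conformer
#' count, warhead used and status, with the ascending-score ranking over
#' scored compounds and the selected top fraction.
#'
#' @slot records data.frame, one row per library compound (columns
#'   \code{compound_id}, \code{status}, \code{pattern_id}, \code{n_conformers},
#'   \code{electrostatic}, \code{vdw}, \code{total}, \code{conformer_index}).
#' @slot ranking character vector of scored compound ids, best first.
#' @slot selected character vector, the top fraction of \code{ranking}.
#' @slot fraction numeric selection fraction.
#' @seealso [runScreen()], [selectTopFraction()], [writeScreenResult()]
#' @export
setClass("ScreenResult",
  representation(records = "data.frame", ranking = "character",
                 selected = "character", fraction = "numeric"))

setValidity("ScreenResult", function(object) {
  scored <- object@records$compound_id[object@records$status == "scored"]
  if (!setequal(object@ranking, scored))
    return("ranking must be a permutation of scored compound ids")
  if (!all(object@selected %in% object@ranking))
    return("selected ids must come from the ranking")
  TRUE
})

#' Trajectory C-alpha frame set
#'
#' C-alpha coordinates of evenly extracted trajectory frames. All frames share
#' residue count and ordering.
#'
#' @slot coords numeric array \code{n_res x 3 x n_frames}, Angstrom.
#' @slot residueNumbers integer vector of residue numbers.
#' @slot source character provenance string.
#' @seealso [extractEvenFrames()], [clusterFrames()], [caRMSD()]
#' @export
setClass("FrameSet",
  representation(coords = "array", residueNumbers = "integer",
                 source = "character"))

setValidity("FrameSet", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) return("coords must be n_res x 3 x n_frames")
  if (d[1] != length(object@residueNumbers)) return("residue count mismatch")
  TRUE
})

#' Frame clustering report
#'
#' k-medoids partition of a frame set on the pairwise superposed C-alpha RMSD
#' matrix. Clusters are numbered in descending occupancy (ties broken by the
#' lower medoid frame index); each medoid is the member frame minimizing the
#' summed RMSD to its cluster.
#'
#' @slot k integer number of clusters.
#' @slot labels integer per-frame cluster id (1..k).
#' @slot occupancies numeric per-cluster fraction, descending.
#' @slot medoids integer per-cluster representative frame index.
#' @seealso [clusterFrames()], [writeClusterReport()]
#' @export
setClass("ClusterReport",
  representation(k = "integer", labels = "integer", occupancies = "numeric",
                 medoids = "integer"))

setValidity("ClusterReport", function(object) {
  k <- object@k
  if (length(object@occupancies) != k || length(object@medoids) != k)
    return("occupancy/medoid length must equal k")
  if (abs(sum(object@occupancies) - 1) > 1e-9)
    return("occupancies must sum to 1")
  if (any(tabulate(object@labels, k) == 0L)) return("empty cluster")
  if (any(object@labels[object@medoids] != seq_len(k)))
    return("each medoid must carry its own cluster label")
  TRUE
})
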