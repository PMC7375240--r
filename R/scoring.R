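# Coulomb + Lennard-Jones 6-12 scoring of conformers against the pocket.
#
# The score characterizes the fit between a covalent pose and the residues
# lining the pocket: favorable electrostatic and dispersion pairs drive it
# negative, short-range 6-12 repulsion drives clashed poses strongly positive,
# so no separate clash term is needed.

COULOMB_K <- 332.0637  # kcal A mol^-1 e^-2

#' Scoring configuration
#'
#' @param pocket optional [Pocket-class]; when given, the anchor S-gamma and
#'   its residue's CB are excluded from pairwise sums (bonded self-interaction
#'   across the covalent link).
#' @param dielectric distance-independent relative dielectric (default 4, a
#'   typical buried-pocket choice).
#' @param wEs,wVdw weights of the electrostatic and van der Waals terms in the
#'   total (default 1 each).
#' @param cutoff pair distance cutoff in Angstrom (default 12).
#' @param excluded integer pocket atom indices to skip; overrides the
#'   pocket-derived default when supplied.
#' @return A [ScoringConfig-class].
#' @export
scoringConfig <- function(pocket = NULL, dielectric = 4, wEs = 1, wVdw = 1,
                          cutoff = 12, excluded = NULL) {
  if (is.null(excluded)) {
    excluded <- if (!is.null(pocket))
      c(pocket@sgLocal, if (pocket@cbLocal > 0L) pocket@cbLocal) else integer(0)
  }
  new("ScoringConfig", dielectric = as.numeric(dielectric),
      wEs = as.numeric(wEs), wVdw = as.numeric(wVdw),
      cutoff = as.numeric(cutoff), excluded = as.integer(excluded))
}

ligandCoords <- function(x) {
  if (is(x, "Conformer")) x@coords
  else if (is.matrix(x)) x
  else cyStop("cyslock_value_error", "expected a Conformer or coordinate matrix")
}

ligandOf <- function(x) {
  if (is(x, "Conformer")) x@anchored@ligand
  else cyStop("cyslock_value_error", "expected a Conformer")
}

scoringPocketTables <- function(pocket, config) {
  a <- pocket@atoms
  keep <- setdiff(seq_len(nrow(a)), config@excluded)
  a <- a[keep, , drop = FALSE]
  if (anyNA(a$charge) || anyNA(a$sigma))
    cyStop("cyslock_scoring_error", "pocket atoms are not parameterized")
  list(xyz = as.matrix(a[, c("x", "y", "z")]), q = a$charge,
       sigma = a$sigma, eps = a$epsilon)
}

scoringLigandTables <- function(ligand) {
  a <- ligand@atoms
  if (anyNA(a$charge) || anyNA(a$sigma))
    cyStop("cyslock_scoring_error", "ligand atoms are not parameterized")
  list(q = a$charge, sigma = a$sigma, eps = a$epsilon)
}

#' Coulomb electrostatic energy of a pose
#'
#' Sum over ligand-pocket atom pairs within the cutoff of
#' \eqn{332.0637 \, q_i q_j / (\epsilon_r r_{ij})} kcal/mol, with the
#' configured excluded pocket atoms skipped.
#'
#' @param conformer a [Conformer-class] (or bare coordinate matrix plus
#'   \code{ligand}).
#' @param pocket a parameterized [Pocket-class].
#' @param config a [ScoringConfig-class].
#' @param ligand the [Ligand-class] when \code{conformer} is a bare matrix.
#' @return Energy in kcal/mol.
#' @export
coulombEnergy <- function(conformer, pocket, config = scoringConfig(pocket),
                          ligand = NULL) {
  lt <- scoringLigandTables(if (is.null(ligand)) ligandOf(conformer) else ligand)
  pt <- scoringPocketTables(pocket, config)
  d2 <- crossDist2(ligandCoords(conformer), pt$xyz)
  r <- sqrt(d2)
  qq <- outer(lt$q, pt$q)
  mask <- r <= config@cutoff
  sum((COULOMB_K / config@dielectric) * qq[mask] / r[mask])
}

#' Lennard-Jones 6-12 energy of a pose
#'
#' Sum over ligand-pocket pairs within the cutoff of
#' \eqn{4\bar\epsilon[(\bar\sigma/r)^{12} - (\bar\sigma/r)^6]} with
#' Lorentz-Berthelot combining (arithmetic-mean sigma, geometric-mean
#' epsilon). A zero interatomic distance is a singular geometry and errors.
#'
#' @inheritParams coulombEnergy
#' @return Energy in kcal/mol.
#' @export
ljEnergy <- function(conformer, pocket, config = scoringConfig(pocket),
                     ligand = NULL) {
  lt <- scoringLigandTables(if (is.null(ligand)) ligandOf(conformer) else ligand)
  pt <- scoringPocketTables(pocket, config)
  d2 <- crossDist2(ligandCoords(conformer), pt$xyz)
  if (any(d2 < 1e-20))
    cyStop("cyslock_singular_error",
           "coincident ligand/pocket atoms (r = 0) in Lennard-Jones term")
  sig <- outer(lt$sigma, pt$sigma, function(a, b) (a + b) / 2)
  eps <- sqrt(outer(lt$eps, pt$eps))
  sr6 <- (sig^2 / d2)^3
  e <- 4 * eps * (sr6^2 - sr6)
  mask <- d2 <= config@cutoff^2
  sum(e[mask])
}

#' Score one conformer
#'
#' Combines the electrostatic and van der Waals terms with the configured
#' weights. Clashed poses come out strongly positive (6-12 repulsion);
#' favorable poses negative.
#'
#' @inheritParams coulombEnergy
#' @return One-row data.frame with columns \code{electrostatic}, \code{vdw},
#'   \code{total}, \code{conformer_index} (NA outside a set context).
#' @export
scoreConformer <- function(conformer, pocket, config = scoringConfig(pocket)) {
  es <- coulombEnergy(conformer, pocket, config)
  lj <- ljEnergy(conformer, pocket, config)
  data.frame(electrostatic = es, vdw = lj,
             total = config@wEs * es + config@wVdw * lj,
             conformer_index = NA_integer_)
}

#' Score every conformer of a set
#'
#' Vectorized evaluation of both energy terms for all conformers against the
#' pocket.
#'
#' @param set a [ConformerSet-class].
#' @param pocket a parameterized [Pocket-class].
#' @param config a [ScoringConfig-class].
#' @return data.frame with one row per conformer (columns as
#'   [scoreConformer()]), \code{conformer_index} running 1..n.
#' @export
scoreConformerSet <- function(set, pocket, config = scoringConfig(pocket)) {
  lt <- scoringLigandTables(set@anchored@ligand)
  pt <- scoringPocketTables(pocket, config)
  nConf <- conformerCount(set)
  nAtoms <- dim(set@coords)[1]
  flat <- matrix(aperm(set@coords, c(1, 3, 2)), nConf * nAtoms, 3)
  d2 <- crossDist2(flat, pt$xyz)
  if (any(d2 < 1e-20))
    cyStop("cyslock_singular_error",
           "coincident ligand/pocket atoms (r = 0) in Lennard-Jones term")
  qq <- outer(rep(lt$q, times = nConf), pt$q)
  sig <- outer(rep(lt$sigma, times = nConf), pt$sigma, function(a, b) (a + b) / 2)
  eps <- sqrt(outer(rep(lt$eps, times = nConf), pt$eps))
  mask <- d2 <= config@cutoff^2
  esM <- (COULOMB_K / config@dielectric) * qq / sqrt(d2) * mask
  sr6 <- (sig^2 / d2)^3
  ljM <- 4 * eps * (sr6^2 - sr6) * mask
  grp <- rep(seq_len(nConf), each = nAtoms)
  es <- as.numeric(rowsum(rowSums(esM), grp))
  lj <- as.numeric(rowsum(rowSums(ljM), grp))
  data.frame(electrostatic = es, vdw = lj,
             total = config@wEs * es + config@wVdw * lj,
             conformer_index = seq_len(nConf))
}

#' Best score of a conformer set
#'
#' Returns the breakdown with the minimum total; ties go to the lowest
#' conformer index.
#'
#' @inheritParams scoreConformerSet
#' @return One-row data.frame (see [scoreConformer()]).
#' @export
bestScore <- function(set, pocket, config = scoringConfig(pocket)) {
  if (conformerCount(set) < 1L)
    cyStop("cyslock_value_error", "empty conformer set")
  sc <- scoreConformerSet(set, pocket, config)
  sc[which.min(sc$total), , drop = FALSE]
}
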