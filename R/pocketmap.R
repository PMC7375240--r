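# Trajectory post-processing: even frame extraction, superposed C-alpha RMSD,
# k-medoids clustering with occupancies and medoids, and the cysteine
# conservation screen over an aligned FASTA.

#' Build a frame set from coordinate matrices
#'
#' @param frames list of \code{n_res x 3} C-alpha coordinate matrices sharing
#'   residue count and order.
#' @param residueNumbers integer residue numbers (default 1..n_res).
#' @param source provenance string.
#' @return A [FrameSet-class].
#' @export
frameSet <- function(frames, residueNumbers = NULL, source = "frames") {
  if (!length(frames)) cyStop("cyslock_value_error", "no frames")
  n <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 0L) != n))
    cyStop("cyslock_value_error", "frames differ in residue count")
  co <- array(NA_real_, dim = c(n, 3, length(frames)))
  for (k in seq_along(frames)) co[, , k] <- frames[[k]]
  if (is.null(residueNumbers)) residueNumbers <- seq_len(n)
  new("FrameSet", coords = co, residueNumbers = as.integer(residueNumbers),
      source = source)
}

frameCoords <- function(frames, k) {
  m <- frames@coords[, , k, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Evenly extract C-alpha frames from a trajectory
#'
#' Keeps models at indices \code{round(i (n_models - 1) / (n_keep - 1))} for
#' \code{i = 0..n_keep-1} (first and last model always kept; half-way values
#' round up), and reduces each kept model to its C-alpha atoms.
#'
#' @param x a multi-model [ProteinStructure-class], PDB text or a file path.
#' @param nKeep number of frames to keep.
#' @return A [FrameSet-class].
#' @export
extractEvenFrames <- function(x, nKeep) {
  s <- if (is(x, "ProteinStructure")) x else readStructure(x, "trajectory")
  nm <- nModels(s)
  if (nKeep > nm)
    cyStop("cyslock_value_error", "cannot keep %d of %d models", nKeep, nm)
  if (nKeep < 1L) cyStop("cyslock_value_error", "nKeep must be >= 1")
  idx <- if (nKeep == 1L) 1L else
    as.integer(floor((seq_len(nKeep) - 1L) * (nm - 1) / (nKeep - 1) + 0.5)) + 1L
  ca <- which(s@atoms$name == "CA")
  if (!length(ca))
    cyStop("cyslock_consistency_error", "structure contains no C-alpha atoms")
  frames <- lapply(idx, function(m) modelCoords(s, m)[ca, , drop = FALSE])
  frameSet(frames, residueNumbers = s@atoms$resno[ca],
           source = sprintf("%s[%d/%d]", s@sourceId, nKeep, nm))
}

# Kabsch optimal superposition of a onto b (both centered); proper rotation
# enforced via the determinant sign of the SVD factors.
kabschRotate <- function(a, b) {
  H <- t(a) %*% b
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  a %*% t(R)
}

#' C-alpha RMSD between two frames
#'
#' With \code{superpose = TRUE} (default), applies the optimal least-squares
#' rigid superposition (translation plus proper rotation, Kabsch) before
#' computing the root-mean-square deviation.
#'
#' @param a,b \code{n x 3} coordinate matrices of matched atoms.
#' @param superpose superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
caRMSD <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    cyStop("cyslock_value_error", "frames differ in size (%d vs %d atoms)",
           nrow(a), nrow(b))
  if (superpose) {
    ac <- sweep(a, 2, colMeans(a))
    bc <- sweep(b, 2, colMeans(b))
    ar <- kabschRotate(ac, bc)
    sqrt(mean(rowSums((ar - bc)^2)))
  } else {
    sqrt(mean(rowSums((a - b)^2)))
  }
}

#' Pairwise superposed RMSD matrix of a frame set
#'
#' @param frames a [FrameSet-class].
#' @param superpose superpose each pair (default TRUE).
#' @return Symmetric numeric matrix of RMSDs in Angstrom.
#' @export
rmsdMatrix <- function(frames, superpose = TRUE) {
  n <- nFrames(frames)
  centered <- lapply(seq_len(n), function(k) {
    m <- frameCoords(frames, k)
    sweep(m, 2, colMeans(m))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- if (superpose)
      sqrt(mean(rowSums((kabschRotate(centered[[i]], centered[[j]]) -
                           centered[[j]])^2)))
    else caRMSD(frameCoords(frames, i), frameCoords(frames, j),
                superpose = FALSE)
  }
  D
}

#' Shared C-alpha RMSD between two structures
#'
#' Matches residues of two (possibly different) structures by chain and
#' residue number over their C-alpha atoms and reports the superposed RMSD of
#' the shared set, e.g. for comparing an engineered construct to the
#' wild-type fold.
#'
#' @param a,b [ProteinStructure-class] objects (first model used).
#' @return RMSD in Angstrom, with attribute \code{n_shared}.
#' @export
sharedCaRMSD <- function(a, b) {
  caA <- which(a@atoms$name == "CA")
  caB <- which(b@atoms$name == "CA")
  keyA <- paste(a@atoms$chain[caA], a@atoms$resno[caA])
  keyB <- paste(b@atoms$chain[caB], b@atoms$resno[caB])
  shared <- intersect(keyA, keyB)
  if (length(shared) < 3L)
    cyStop("cyslock_value_error", "fewer than 3 shared C-alpha atoms")
  xa <- modelCoords(a, 1L)[caA[match(shared, keyA)], , drop = FALSE]
  xb <- modelCoords(b, 1L)[caB[match(shared, keyB)], , drop = FALSE]
  out <- caRMSD(xa, xb, superpose = TRUE)
  attr(out, "n_shared") <- length(shared)
  out
}

#' Cluster trajectory frames by C-alpha RMSD
#'
#' k-medoids (PAM) partition of the pairwise superposed-RMSD matrix. Clusters
#' are reported in descending occupancy (cluster size / n_frames), ties
#' broken by the lower medoid frame index; each cluster's medoid frame is its
#' representative structure. The PAM build/swap procedure is deterministic,
#' so the result does not depend on \code{seed} (kept for interface
#' stability).
#'
#' @param frames a [FrameSet-class].
#' @param k number of clusters (default 10).
#' @param seed unused by the deterministic PAM backend.
#' @return A [ClusterReport-class].
#' @export
clusterFrames <- function(frames, k = 10L, seed = NULL) {
  n <- nFrames(frames)
  if (k > n)
    cyStop("cyslock_value_error", "k = %d exceeds the %d frames", k, n)
  if (k < 1L) cyStop("cyslock_value_error", "k must be >= 1")
  k <- as.integer(k)
  if (k == n) {
    labels <- seq_len(n); med <- seq_len(n); occ <- rep(1 / n, n)
  } else {
    D <- rmsdMatrix(frames)
    fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
    labels <- as.integer(fit$clustering)
    med <- as.integer(fit$id.med)
    occ <- as.numeric(tabulate(labels, k)) / n
  }
  ord <- order(-occ, med)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  new("ClusterReport", k = k, labels = relabel[labels],
      occupancies = occ[ord], medoids = med[ord])
}

#' Write a cluster report as TSV
#'
#' Columns \code{cluster}, \code{occupancy}, \code{medoid_model}.
#'
#' @param report a [ClusterReport-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeClusterReport <- function(report, path) {
  utils::write.table(
    data.frame(cluster = seq_len(report@k),
               occupancy = sprintf("%.6f", report@occupancies),
               medoid_model = report@medoids),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one frame as a single-model C-alpha PDB
#'
#' Used to export cluster medoids ("representative structures").
#'
#' @param frames a [FrameSet-class].
#' @param frame frame index.
#' @param file optional output path.
#' @return Character vector of PDB lines, invisibly when \code{file} is set.
#' @export
writeFramePDB <- function(frames, frame, file = NULL) {
  xyz <- frameCoords(frames, frame)
  out <- c(vapply(seq_len(nrow(xyz)), function(i) sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    i, frames@residueNumbers[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0), ""),
    "END")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Cysteine-conservation screen over an aligned FASTA
#'
#' Locates the alignment column holding the reference sequence's Nth residue
#' (counting non-gap symbols) and reports every sequence's symbol there,
#' flagging which carry the target symbol — e.g. whether the anchor cysteine
#' is unique to one protein family across a superfamily alignment.
#'
#' @param alignment an aligned \code{Biostrings::AAStringSet}, or a FASTA
#'   path/text.
#' @param referenceId name (first whitespace-separated token) of the
#'   reference row.
#' @param referenceResidueNumber 1-based residue number within the ungapped
#'   reference sequence.
#' @param targetSymbol residue symbol screened for (default \code{"C"}).
#' @return list with \code{column} (1-based alignment column),
#'   \code{reference_id}, \code{reference_residue_number} and \code{table}, a
#'   data.frame of (\code{id}, \code{symbol}, \code{is_target}).
#' @export
conservationScreen <- function(alignment, referenceId, referenceResidueNumber,
                               targetSymbol = "C") {
  aln <- if (is(alignment, "AAStringSet")) alignment else {
    src <- alignment
    if (length(src) > 1L || grepl("\n", src[1], fixed = TRUE)) {
      tmp <- tempfile(fileext = ".fasta")
      writeLines(if (length(src) > 1L) src else
        strsplit(src, "\n", fixed = TRUE)[[1]], tmp)
      on.exit(unlink(tmp))
      src <- tmp
    }
    Biostrings::readAAStringSet(src)
  }
  ids <- vapply(strsplit(names(aln), "[ /]"), `[`, "", 1)
  ref <- which(ids == referenceId)
  if (length(ref) != 1L)
    cyStop("cyslock_value_error", "reference id '%s' not found in alignment",
           referenceId)
  if (length(unique(Biostrings::width(aln))) != 1L)
    cyStop("cyslock_value_error", "sequences are not aligned (unequal widths)")
  refChars <- strsplit(as.character(aln[[ref]]), "")[[1]]
  nonGap <- which(!refChars %in% c("-", "."))
  if (referenceResidueNumber < 1L || referenceResidueNumber > length(nonGap))
    cyStop("cyslock_value_error",
           "reference residue number %d outside the %d-residue reference",
           referenceResidueNumber, length(nonGap))
  col <- nonGap[referenceResidueNumber]
  symbols <- vapply(seq_along(aln),
                    function(i) substr(as.character(aln[[i]]), col, col), "")
  list(column = col, reference_id = referenceId,
       reference_residue_number = as.integer(referenceResidueNumber),
       table = data.frame(id = ids, symbol = symbols,
                          is_target = symbols == targetSymbol,
                          stringsAsFactors = FALSE))
}
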