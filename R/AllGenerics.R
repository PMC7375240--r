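#' Accessors for cyslock classes
#'
#' Small accessor generics: \code{atoms()} returns the atom table of a
#' structure, pocket or ligand; \code{nModels()} the model count of a
#' structure; \code{modelCoords()} one model's coordinate matrix;
#' \code{pocketCharge()} the summed partial charge of a parameterized pocket;
#' \code{conformerCount()} the number of conformers in a set;
#' \code{occupancies()}, \code{clusterLabels()} and \code{medoids()} the
#' corresponding slots of a [ClusterReport-class]; \code{nFrames()} the frame
#' count of a [FrameSet-class]; \code{screenRecords()}, \code{ranking()} and
#' \code{selectedCompounds()} the parts of a [ScreenResult-class];
#' \code{massDelta()} the adduct mass shift of an [AnchoredLigand-class].
#'
#' @param x the object.
#' @param model integer model index.
#' @return The accessed component (see description).
#' @name accessors
#' @aliases atoms nModels modelCoords pocketCharge conformerCount occupancies
#'   clusterLabels medoids nFrames screenRecords ranking selectedCompounds
#'   massDelta
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "Pocket", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "Ligand", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname accessors
#' @export
setMethod("nModels", "ProteinStructure", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setGeneric("modelCoords", function(x, model = 1L) standardGeneric("modelCoords"))
#' @rdname accessors
#' @export
setMethod("modelCoords", "ProteinStructure", function(x, model = 1L) {
  if (model < 1L || model > nModels(x))
    cyStop("cyslock_value_error", "model index %d out of range", model)
  m <- x@coords[, , model, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})

#' @rdname accessors
#' @export
setGeneric("pocketCharge", function(x) standardGeneric("pocketCharge"))
#' @rdname accessors
#' @export
setMethod("pocketCharge", "Pocket", function(x) {
  if (anyNA(x@atoms$charge))
    cyStop("cyslock_param_error", "pocket is not parameterized")
  sum(x@atoms$charge)
})

#' @rdname accessors
#' @export
setGeneric("conformerCount", function(x) standardGeneric("conformerCount"))
#' @rdname accessors
#' @export
setMethod("conformerCount", "ConformerSet", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setGeneric("occupancies", function(x) standardGeneric("occupancies"))
#' @rdname accessors
#' @export
setMethod("occupancies", "ClusterReport", function(x) x@occupancies)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterReport", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))
#' @rdname accessors
#' @export
setMethod("medoids", "ClusterReport", function(x) x@medoids)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSet", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setGeneric("screenRecords", function(x) standardGeneric("screenRecords"))
#' @rdname accessors
#' @export
setMethod("screenRecords", "ScreenResult", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))
#' @rdname accessors
#' @export
setMethod("ranking", "ScreenResult", function(x) x@ranking)

#' @rdname accessors
#' @export
setGeneric("selectedCompounds", function(x) standardGeneric("selectedCompounds"))
#' @rdname accessors
#' @export
setMethod("selectedCompounds", "ScreenResult", function(x) x@selected)

#' @rdname accessors
#' @export
setGeneric("massDelta", function(x) standardGeneric("massDelta"))
#' @rdname accessors
#' @export
setMethod("massDelta", "AnchoredLigand", function(x) x@massDelta)

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s': %d atoms, %d model(s), %d residue(s)\n",
              object@sourceId, nrow(object@atoms), nModels(object),
              nrow(unique(object@atoms[, c("chain", "resno")]))))
})

setMethod("show", "CysteineAnchor", function(object) {
  cat(sprintf("CysteineAnchor %s:%d (SG atom index %d)\n",
              object@chain, object@resno, object@sgIndex))
})

setMethod("show", "Pocket", function(object) {
  q <- if (anyNA(object@atoms$charge)) "unparameterized"
       else sprintf("total charge %+.3f e", sum(object@atoms$charge))
  cat(sprintf("Pocket: %d atoms within %.1f A of %s:%d SG (%s)\n",
              nrow(object@atoms), object@radius, object@anchor@chain,
              object@anchor@resno, q))
})

setMethod("show", "Ligand", function(object) {
  cat(sprintf("Ligand '%s': %d heavy atoms, %d bonds, formula %s\n",
              object@id, nrow(object@atoms), nrow(object@bonds),
              formatFormula(object@formula)))
})

setMethod("show", "AnchoredLigand", function(object) {
  cat(sprintf("AnchoredLigand '%s': %s warhead, S-C %.2f A, mass delta %+.4f Da\n",
              object@ligand@id, object@patternId, object@anchorBondLength,
              object@massDelta))
})

setMethod("show", "ConformerSet", function(object) {
  cat(sprintf("ConformerSet '%s': %d conformer(s), %d rotatable bond(s), %g deg increment\n",
              object@anchored@ligand@id, conformerCount(object),
              nrow(object@rotatable), object@incrementDeg))
})

setMethod("show", "ScreenResult", function(object) {
  n <- nrow(object@records)
  cat(sprintf("ScreenResult: %d compounds (%d scored, %d no_warhead, %d failed); top %.0f%% = %d selected\n",
              n, sum(object@records$status == "scored"),
              sum(object@records$status == "no_warhead"),
              sum(object@records$status == "failed"),
              100 * object@fraction, length(object@selected)))
})

setMethod("show", "FrameSet", function(object) {
  cat(sprintf("FrameSet '%s': %d frame(s) x %d C-alpha atoms\n",
              object@source, nFrames(object), dim(object@coords)[1]))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport: k = %d\n", object@k))
  for (i in seq_len(object@k))
    cat(sprintf("  cluster %d: occupancy %.3f, medoid frame %d\n",
                i, object@occupancies[i], object@medoids[i]))
})
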