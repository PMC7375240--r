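# PDB structures, anchor lookup, pocket extraction and parameterization.

STANDARD_AA <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                 "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

pdbLines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb))
    return(readLines(pdb))
  if (length(pdb) == 1L) return(strsplit(pdb, "\n", fixed = TRUE)[[1]])
  pdb
}

parseCoordField <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    cyStop("cyslock_parse_error",
           "line %d: malformed %s coordinate field '%s'", lineno, what, trimws(s))
  v
}

elementFromName <- function(name) {
  s <- gsub("[0-9']", "", trimws(name))
  if (!nzchar(s)) return("")
  two <- toupper(substr(s, 1, 2))
  if (two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")) return(two)
  toupper(substr(s, 1, 1))
}

#' Read a protein structure in PDB format
#'
#' Parses ATOM/HETATM records from PDB text (a string, a character vector of
#' lines, or a path to a file). MODEL/ENDMDL blocks become separate models; a
#' file without MODEL records is one model. Atom order is preserved and
#' coordinates are read at 0.001 Angstrom resolution. Alternate locations
#' other than blank or 'A' are dropped; insertion codes are rejected; all
#' models must agree in atom count and ordering.
#'
#' @param pdb PDB text, lines, or a file path.
#' @param sourceId provenance label stored in the object.
#' @return A [ProteinStructure-class].
#' @examples
#' s <- readStructure(makeToyPocket(1))
#' nModels(s)
#' @export
readStructure <- function(pdb, sourceId = "pdb") {
  lines <- pdbLines(pdb)
  rec <- substr(lines, 1, 6)
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(isAtom))
    cyStop("cyslock_parse_error", "no ATOM/HETATM records found")

  modelId <- integer(length(lines))
  cur <- 0L; inModel <- FALSE; sawModel <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") { cur <- cur + 1L; inModel <- TRUE; sawModel <- TRUE }
    else if (r == "ENDMDL") inModel <- FALSE
    modelId[i] <- if (sawModel) (if (inModel) cur else NA_integer_) else 1L
  }

  keep <- which(isAtom & !is.na(modelId))
  if (!length(keep))
    cyStop("cyslock_parse_error", "no ATOM/HETATM records inside MODEL blocks")

  parseOne <- function(i) {
    l <- lines[i]
    if (nchar(l) < 54)
      cyStop("cyslock_parse_error", "line %d: ATOM record too short", i)
    altloc <- substr(l, 17, 17)
    if (!altloc %in% c(" ", "A")) return(NULL)
    icode <- substr(l, 27, 27)
    if (icode != " ")
      cyStop("cyslock_structure_error",
             "line %d: insertion codes are not supported (found '%s')", i, icode)
    name <- trimws(substr(l, 13, 16))
    el <- if (nchar(l) >= 78) trimws(substr(l, 77, 78)) else ""
    if (!nzchar(el)) el <- elementFromName(name)
    list(serial = suppressWarnings(as.integer(trimws(substr(l, 7, 11)))),
         name = name,
         element = toupper(el),
         resname = trimws(substr(l, 18, 20)),
         chain = substr(l, 22, 22),
         resno = suppressWarnings(as.integer(trimws(substr(l, 23, 26)))),
         x = parseCoordField(substr(l, 31, 38), i, "x"),
         y = parseCoordField(substr(l, 39, 46), i, "y"),
         z = parseCoordField(substr(l, 47, 54), i, "z"),
         model = modelId[i])
  }

  parsed <- Filter(Negate(is.null), lapply(keep, parseOne))
  if (!length(parsed))
    cyStop("cyslock_parse_error", "no atoms left after altloc filtering")
  df <- do.call(rbind, lapply(parsed, as.data.frame))
  models <- sort(unique(df$model))
  perModel <- split(df, df$model)
  counts <- vapply(perModel, nrow, 0L)
  if (length(unique(counts)) != 1L)
    cyStop("cyslock_structure_error",
           "inconsistent atom counts across models: %s",
           paste(counts, collapse = ", "))
  first <- perModel[[1]]
  for (m in perModel[-1]) {
    if (!identical(first$name, m$name) || !identical(first$resno, m$resno) ||
        !identical(first$chain, m$chain))
      cyStop("cyslock_structure_error",
             "atom ordering or residue numbering differs between models")
  }
  n <- nrow(first)
  co <- array(NA_real_, dim = c(n, 3, length(models)))
  for (j in seq_along(models)) {
    pm <- perModel[[j]]
    co[, , j] <- cbind(pm$x, pm$y, pm$z)
  }
  atoms <- data.frame(serial = first$serial, name = first$name,
                      element = first$element, resname = first$resname,
                      chain = first$chain, resno = first$resno,
                      stringsAsFactors = FALSE)
  new("ProteinStructure", atoms = atoms, coords = co, sourceId = sourceId)
}

#' Write a structure back to PDB text
#'
#' Emits ATOM records (MODEL/ENDMDL blocks when the structure holds several
#' models) at 0.001 Angstrom precision, preserving atom order, so that
#' re-parsing reproduces the structure exactly.
#'
#' @param structure a [ProteinStructure-class].
#' @param file optional path; when given, lines are also written there.
#' @return Character vector of PDB lines, invisibly when \code{file} is set.
#' @export
writeStructure <- function(structure, file = NULL) {
  a <- structure@atoms
  nm <- nModels(structure)
  fmtAtom <- function(i, xyz) {
    name <- a$name[i]
    name4 <- if (nchar(name) >= 4L) substr(name, 1, 4) else
      formatC(paste0(" ", name), width = -4, flag = "-")
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$serial[i] %% 100000L, name4, a$resname[i], a$chain[i], a$resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, a$element[i])
  }
  out <- character(0)
  for (m in seq_len(nm)) {
    xyz <- modelCoords(structure, m)
    block <- vapply(seq_len(nrow(a)), fmtAtom, "", xyz = xyz)
    if (nm > 1L) block <- c(sprintf("MODEL     %4d", m), block, "ENDMDL")
    out <- c(out, block)
  }
  out <- c(out, "END")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Locate the anchor cysteine
#'
#' Finds the designated residue and returns an anchor pointing at its S-gamma
#' atom. The residue must exist, be a cysteine, and carry an SG atom.
#'
#' @param structure a [ProteinStructure-class].
#' @param chain chain identifier.
#' @param resno residue number.
#' @return A [CysteineAnchor-class].
#' @export
findAnchor <- function(structure, chain, resno) {
  a <- structure@atoms
  sel <- which(a$chain == chain & a$resno == resno)
  if (!length(sel))
    cyStop("cyslock_not_found_error", "residue %s:%d not found", chain, resno)
  rn <- unique(a$resname[sel])
  if (!identical(rn, "CYS"))
    cyStop("cyslock_anchor_error",
           "residue %s:%d is %s, not CYS", chain, resno, paste(rn, collapse = "/"))
  sg <- sel[a$name[sel] == "SG"]
  if (length(sg) != 1L)
    cyStop("cyslock_anchor_error", "residue %s:%d lacks an SG atom", chain, resno)
  new("CysteineAnchor", chain = chain, resno = as.integer(resno),
      sgIndex = as.integer(sg))
}

#' Extract the pocket around the anchor S-gamma
#'
#' Atom-wise distance cut: every atom of the chosen model within
#' \code{radius} Angstrom of the anchor S-gamma enters the pocket (whole
#' residues are not pulled in). The S-gamma itself is always included.
#'
#' @param structure a [ProteinStructure-class].
#' @param anchor a [CysteineAnchor-class] from [findAnchor()].
#' @param radius cut radius in Angstrom (default 10).
#' @param model model index to cut from (default first).
#' @return An unparameterized [Pocket-class].
#' @export
extractPocket <- function(structure, anchor, radius = 10, model = 1L) {
  if (!is.numeric(radius) || radius <= 0)
    cyStop("cyslock_value_error", "radius must be > 0 (got %s)", format(radius))
  xyz <- modelCoords(structure, model)
  sg <- xyz[anchor@sgIndex, ]
  d <- sqrt(colSums((t(xyz) - sg)^2))
  sel <- which(d <= radius)
  a <- structure@atoms[sel, , drop = FALSE]
  rownames(a) <- NULL
  a$x <- xyz[sel, 1]; a$y <- xyz[sel, 2]; a$z <- xyz[sel, 3]
  a$charge <- NA_real_; a$sigma <- NA_real_; a$epsilon <- NA_real_
  sgLocal <- match(anchor@sgIndex, sel)
  cbLocal <- which(a$chain == anchor@chain & a$resno == anchor@resno &
                   a$name == "CB")
  new("Pocket", atoms = a, anchor = anchor, radius = as.numeric(radius),
      sgLocal = as.integer(sgLocal),
      cbLocal = if (length(cbLocal)) as.integer(cbLocal[1]) else 0L)
}

#' Read a residue/atom parameter table
#'
#' Tab-separated table with columns \code{residue_name}, \code{atom_name},
#' \code{charge_e}, \code{sigma_A}, \code{epsilon_kcal}.
#'
#' @param path file path.
#' @return data.frame of parameters.
#' @export
readParameterTable <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("residue_name", "atom_name", "charge_e", "sigma_A", "epsilon_kcal")
  if (!all(need %in% names(t)))
    cyStop("cyslock_value_error", "parameter table lacks columns: %s",
           paste(setdiff(need, names(t)), collapse = ", "))
  t
}

#' Packaged default parameter table
#'
#' A compact united-atom-style set covering the heavy atoms of the 20 standard
#' residues: residue-typed partial charges with polar-hydrogen charge folded
#' into the bearing heavy atom, and element-typed Lennard-Jones parameters.
#' Absolute energies computed with this table differ from programs using
#' all-atom commercial preparation tools; rankings on a fixed pocket are the
#' intended use.
#'
#' @return data.frame of parameters (see [readParameterTable()]).
#' @export
defaultParameterTable <- function() {
  readParameterTable(extdata("residue_params.tsv"))
}

#' Attach charges and Lennard-Jones parameters to a pocket
#'
#' Looks every pocket atom up by (residue name, atom name) in the parameter
#' table. Any unmapped pair aborts with an error listing all misses.
#'
#' @param pocket a [Pocket-class].
#' @param table parameter data.frame (default the packaged table).
#' @return The parameterized [Pocket-class]; total charge is available via
#'   [pocketCharge()] and printed by \code{show()}.
#' @export
parameterizePocket <- function(pocket, table = defaultParameterTable()) {
  a <- pocket@atoms
  key <- paste(a$resname, a$name)
  tk <- paste(table$residue_name, table$atom_name)
  idx <- match(key, tk)
  if (anyNA(idx)) {
    miss <- sort(unique(key[is.na(idx)]))
    cyStop("cyslock_param_error",
           "no parameters for %d (residue, atom) pair(s): %s",
           length(miss), paste(miss, collapse = "; "))
  }
  a$charge <- table$charge_e[idx]
  a$sigma <- table$sigma_A[idx]
  a$epsilon <- table$epsilon_kcal[idx]
  out <- pocket
  out@atoms <- a
  validObject(out)
  out
}

pocketXYZ <- function(pocket) as.matrix(pocket@atoms[, c("x", "y", "z")])
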