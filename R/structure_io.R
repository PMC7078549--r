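## Structure input/output: single-chain Calpha models with optional
## all-atom records, plus the 11-bead coarse-grained CoA representation.

#' Construct a StructureModel
#'
#' A `StructureModel` holds one chain of a protein structure: an ordered
#' residue table with one Calpha position per residue, and optionally the
#' full heavy-atom records. Coordinates are in Angstrom throughout.
#'
#' @param id text label, conventionally "PDBID_CHAIN".
#' @param residues data.frame with columns `resname` (3-letter code),
#'   `resno` (author residue number), `insert` (insertion code, "" if none),
#'   `x`, `y`, `z` (Calpha position, A).
#' @param atoms optional data.frame with columns `res_index` (1-based index
#'   into `residues`), `atom` (PDB atom name), `element`, `x`, `y`, `z`.
#' @param source path of the originating file, if any.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(id, residues, atoms = NULL, source = NA_character_) {
  m <- structure(list(id = id, residues = residues, atoms = atoms,
                      source = source),
                 class = "StructureModel")
  validate_structure_model(m)
  m
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$id, "-", nrow(x$residues), "residues",
      if (!is.null(x$atoms)) sprintf("(%d atoms)", nrow(x$atoms)) else "(Calpha only)",
      "\n")
  invisible(x)
}

validate_structure_model <- function(m) {
  r <- m$residues
  stopifnot(is.data.frame(r),
            all(c("resname", "resno", "insert", "x", "y", "z") %in% names(r)))
  if (nrow(r) == 0L)
    stop("StructureModel '", m$id, "' has zero residues", call. = FALSE)
  key <- paste(r$resno, r$insert)
  if (anyDuplicated(key))
    stop("duplicate residue identifiers in model '", m$id, "'", call. = FALSE)
  if (!all(is.finite(as.matrix(r[, c("x", "y", "z")]))))
    stop("non-finite Calpha coordinates in model '", m$id, "'", call. = FALSE)
  if (!is.null(m$atoms)) {
    a <- m$atoms
    stopifnot(all(c("res_index", "atom", "element", "x", "y", "z") %in% names(a)))
    if (!all(a$res_index >= 1 & a$res_index <= nrow(r)))
      stop("atom res_index out of range in model '", m$id, "'", call. = FALSE)
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
      stop("non-finite atom coordinates in model '", m$id, "'", call. = FALSE)
  }
  invisible(m)
}

#' Calpha coordinates of a StructureModel
#' @param model a `StructureModel`.
#' @return N x 3 matrix (A).
#' @export
ca_xyz <- function(model) {
  as.matrix(model$residues[, c("x", "y", "z")])
}

#' Number of residues
#' @export
n_residues <- function(model) nrow(model$residues)

#' Read one chain of a PDB file into a StructureModel
#'
#' Parses a PDB file (via bio3d), keeps a single chain, resolves alternate
#' locations to the highest occupancy (ties broken alphabetically), and
#' drops residues that lack a Calpha record (with a warning). With
#' `strip_het = TRUE` (the default) all HETATM records -- waters, cofactor
#' and peptide ligands -- are removed from the model proper; they remain
#' available in the `het` field for cofactor-bead extraction.
#'
#' @param path PDB file.
#' @param chain chain identifier (single character).
#' @param strip_het drop heteroatoms from the model (default TRUE).
#' @return `StructureModel`; heteroatom records (if any) are attached as a
#'   data.frame in `$het` with columns resname, resno, atom, element, x, y, z.
#' @export
read_structure <- function(path, chain, strip_het = TRUE) {
  ## rm.alt = FALSE: alternate locations are resolved here (highest
  ## occupancy, then alphabetical), not by the parser's default policy
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  if (!chain %in% unique(at$chain))
    stop("chain '", chain, "' not present in ", path,
         " (chains: ", paste(unique(at$chain), collapse = ", "), ")",
         call. = FALSE)
  at <- at[at$chain == chain, , drop = FALSE]

  ## altloc policy: highest occupancy, then first alphabetically
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  akey <- paste(at$resno, at$insert, at$resid, at$elety)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(akey[duplicated(akey)])) {
    idx <- which(akey == k)
    ord <- idx[order(-occ[idx], alt[idx])]
    keep[setdiff(idx, ord[1])] <- FALSE
  }
  at <- at[keep, , drop = FALSE]

  het <- at[at$type == "HETATM", , drop = FALSE]
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (!strip_het) {
    ## retain modified residues etc. only if they carry a CA; waters never do
    extra <- het[het$elety == "CA" | het$resid != "HOH", , drop = FALSE]
    prot <- rbind(prot, extra[extra$resid %in% prot$resid, , drop = FALSE])
  }

  ins <- prot$insert; ins[is.na(ins)] <- ""
  rkey <- paste(prot$resno, ins)
  urk <- unique(rkey)
  ca_rows <- integer(0); dropped <- character(0)
  for (k in urk) {
    idx <- which(rkey == k)
    ca <- idx[prot$elety[idx] == "CA"]
    if (length(ca) == 0L) {
      dropped <- c(dropped, paste0(prot$resid[idx[1]], k))
    } else {
      ca_rows <- c(ca_rows, ca[1])
    }
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " residue(s) lacking a Calpha: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) " ..." else "", call. = FALSE)
  if (length(ca_rows) == 0L)
    stop("no residues with Calpha left in chain '", chain, "' of ", path,
         call. = FALSE)

  ca <- prot[ca_rows, , drop = FALSE]
  ins_ca <- ca$insert; ins_ca[is.na(ins_ca)] <- ""
  residues <- data.frame(resname = ca$resid, resno = ca$resno,
                         insert = ins_ca,
                         x = ca$x, y = ca$y, z = ca$z,
                         stringsAsFactors = FALSE)

  keyres <- paste(ca$resno, ins_ca)
  akeep <- prot[paste(prot$resno, ifelse(is.na(prot$insert), "", prot$insert))
                %in% keyres, , drop = FALSE]
  elem <- akeep$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[^A-Za-z].*", "", akeep$elety[bad]), 1, 1)
  atoms <- data.frame(
    res_index = match(paste(akeep$resno,
                            ifelse(is.na(akeep$insert), "", akeep$insert)),
                      keyres),
    atom = akeep$elety, element = trimws(elem),
    x = akeep$x, y = akeep$y, z = akeep$z, stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$res_index), , drop = FALSE]
  rownames(atoms) <- NULL

  m <- structure_model(id = paste0(sub("\\.pdb$", "", basename(path)), "_", chain),
                       residues = residues, atoms = atoms, source = path)
  if (nrow(het)) {
    helem <- het$elesy
    hbad <- is.na(helem) | helem == ""
    helem[hbad] <- substr(gsub("[^A-Za-z].*", "", het$elety[hbad]), 1, 1)
    m$het <- data.frame(resname = het$resid, resno = het$resno,
                        atom = het$elety, element = trimws(helem),
                        x = het$x, y = het$y, z = het$z,
                        stringsAsFactors = FALSE)
  }
  m
}

## Atom names defining the 11-bead CoA model, spaced 3-4 A apart along the
## cofactor from the thiol end to the adenine.
.coa_bead_atoms <- c("C", "C3P", "C6P", "C9P", "CCP",
                     "P1A", "C4B", "P3B", "N9A", "N6A", "N3A")

#' Extract the 11-bead coarse-grained CoA model
#'
#' Finds a CoA/acetyl-CoA heterogroup in the model's heteroatom records and
#' returns the positions of the 11 named atoms (C, C3P, C6P, C9P, CCP, P1A,
#' C4B, P3B, N9A, N6A, N3A), in that order, as cofactor beads.
#'
#' @param model a `StructureModel` read with `strip_het = TRUE` (the
#'   heterogroup is taken from its `$het` records) or any model carrying a
#'   `het` data.frame.
#' @return object of class `CofactorBeads`: list with `xyz` (11 x 3, A) and
#'   `atom_names`.
#' @export
extract_cofactor_beads <- function(model) {
  het <- model$het
  if (is.null(het) || nrow(het) == 0L)
    stop("model '", model$id, "' has no heteroatom records to search for CoA",
         call. = FALSE)
  grp <- paste(het$resname, het$resno)
  best <- NULL; best_hit <- -1L
  for (g in unique(grp)) {
    sub <- het[grp == g, , drop = FALSE]
    hit <- sum(.coa_bead_atoms %in% sub$atom)
    if (hit > best_hit) { best <- sub; best_hit <- hit }
  }
  missing <- setdiff(.coa_bead_atoms, best$atom)
  if (length(missing))
    stop("CoA bead atom(s) missing from heterogroup: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- match(.coa_bead_atoms, best$atom)
  beads <- structure(list(
    xyz = as.matrix(best[rows, c("x", "y", "z")]),
    atom_names = .coa_bead_atoms), class = "CofactorBeads")
  rownames(beads$xyz) <- .coa_bead_atoms
  beads
}

#' Append cofactor beads to a Calpha node set
#'
#' @param ca N x 3 Calpha coordinates.
#' @param beads `CofactorBeads`.
#' @return (N + 11) x 3 node coordinate matrix for network construction.
#' @export
with_cofactor_nodes <- function(ca, beads) {
  stopifnot(inherits(beads, "CofactorBeads"))
  rbind(as.matrix(ca), beads$xyz)
}

#' Write a StructureModel to a PDB file
#'
#' Coordinates are written in the fixed-width PDB convention (3 decimals),
#' so a write/read round trip preserves them to 1e-3 A. All-atom records
#' are written when present, otherwise a Calpha trace.
#'
#' @param model a `StructureModel`.
#' @param path output file.
#' @param chain chain identifier to stamp on the records (default "A").
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, chain = "A") {
  validate_structure_model(model)
  r <- model$residues
  if (is.null(model$atoms)) {
    xyz <- ca_xyz(model)
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(xyz)),
                     type = rep("ATOM", nrow(r)),
                     resno = r$resno, resid = r$resname,
                     insert = ifelse(r$insert == "", "", r$insert),
                     chain = rep(chain, nrow(r)),
                     elety = rep("CA", nrow(r)),
                     elesy = rep("C", nrow(r)))
  } else {
    a <- model$atoms
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(a)),
                     resno = r$resno[a$res_index],
                     resid = r$resname[a$res_index],
                     insert = ifelse(r$insert[a$res_index] == "", "",
                                     r$insert[a$res_index]),
                     chain = rep(chain, nrow(a)),
                     elety = a$atom,
                     elesy = a$element)
  }
  invisible(path)
}

#' Sequence of a StructureModel in 1-letter code
#' @export
model_sequence <- function(model) {
  s <- bio3d::aa321(model$residues$resname)
  s[is.na(s) | s == ""] <- "X"
  paste(s, collapse = "")
}
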