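## structure_io: parse PDB/mmCIF files into the in-memory model used by the
## rest of the pipeline, emit FASTA/PDB/manifest artifacts, and summarise
## pLDDT quality.

#' Construct a structure model
#'
#' The unit element of an orthogroup corpus: an ordered list of polymer
#' residues with C-alpha coordinates, the derived one-letter sequence,
#' optional per-residue pLDDT (predicted models store it in the B-factor
#' column), all heavy atoms, and any retained ligand heteroatoms.
#'
#' @param structure_id identifier (conventionally species tag + protein tag).
#' @param source "predicted" or "experimental".
#' @param residues data.frame with columns chain, seq_index, aa, resno_author,
#'   x, y, z (C-alpha, Angstrom) and optionally plddt.
#' @param atoms optional data.frame of heavy atoms (seq_index, elety, element,
#'   x, y, z).
#' @param ligand_atoms optional data.frame of retained ligand heavy atoms
#'   (resid, resno, elety, element, x, y, z).
#' @param dropped_no_ca number of residues dropped at parse time for lacking
#'   a C-alpha atom.
#' @return object of class "structure_model".
#' @export
new_structure_model <- function(structure_id, source = "predicted", residues,
                                atoms = NULL, ligand_atoms = NULL,
                                dropped_no_ca = 0L) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "seq_index", "aa", "x", "y", "z") %in% names(residues)))
  if (nrow(residues) == 0L) stop("empty structure: no standard residues")
  for (ch in unique(residues$chain)) {
    idx <- residues$seq_index[residues$chain == ch]
    if (!all(idx == seq_along(idx))) {
      stop("seq_index must be 1..n and strictly increasing within a chain")
    }
  }
  if (!is.null(residues$plddt)) {
    ok <- is.na(residues$plddt) | (residues$plddt >= 0 & residues$plddt <= 100)
    if (!all(ok)) stop("plddt values must lie in [0, 100]")
  }
  structure(list(structure_id = structure_id,
                 source = match.arg(source, c("predicted", "experimental")),
                 residues = residues,
                 atoms = atoms,
                 ligand_atoms = ligand_atoms,
                 sequence = paste(residues$aa, collapse = ""),
                 dropped_no_ca = as.integer(dropped_no_ca)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model", x$structure_id, sprintf("(%s)", x$source), "\n")
  cat("  residues:", nrow(x$residues),
      " chains:", length(unique(x$residues$chain)), "\n")
  if (!is.null(x$residues$plddt) && !all(is.na(x$residues$plddt))) {
    cat("  mean pLDDT:", round(mean(x$residues$plddt, na.rm = TRUE), 1), "\n")
  }
  if (!is.null(x$ligand_atoms) && nrow(x$ligand_atoms) > 0) {
    cat("  ligand atoms:", nrow(x$ligand_atoms), "\n")
  }
  invisible(x)
}

#' C-alpha coordinate matrix of a structure model
#' @param s structure_model.
#' @return numeric n x 3 matrix.
#' @export
ca_coords <- function(s) {
  as.matrix(s$residues[, c("x", "y", "z")])
}

.derive_element <- function(elety, elesy = NULL) {
  out <- character(length(elety))
  if (!is.null(elesy)) out <- ifelse(is.na(elesy) | elesy == "", "", toupper(elesy))
  need <- out == ""
  if (any(need)) {
    nm <- gsub("[^A-Za-z]", "", elety[need])
    two <- toupper(substr(nm, 1, 2))
    one <- toupper(substr(nm, 1, 1))
    known2 <- c("SE", "FE", "ZN", "MG", "MN", "CU", "CL", "BR", "NA")
    out[need] <- ifelse(two %in% known2, two, one)
  }
  out
}

#' Read a protein structure from PDB or mmCIF
#'
#' Waters are discarded; alternate locations are resolved to the highest
#' occupancy (ties broken in favour of altloc 'A'); residues lacking a
#' C-alpha are dropped and counted; modified residues (e.g. MSE) map to
#' their parent amino acid, anything unmappable to 'X'. Ligand heteroatoms
#' are retained separately for proximity-based binding-site detection.
#' Author residue numbering (with insertion codes flattened into sequential
#' 1-based indices) is kept in \code{resno_author}/\code{insert_author} for
#' annotation joins.
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "mmcif".
#' @param plddt_from_bfactor read per-residue pLDDT from the B-factor column.
#' @param merge_chains treat all chains as one model (multimer fixtures);
#'   default is one model per chain.
#' @param structure_id identifier; defaults to the file base name (plus chain
#'   suffix for multi-chain files).
#' @param source "predicted" or "experimental".
#' @return a structure_model, or a named list of them for multi-chain files
#'   when \code{merge_chains} is FALSE.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           plddt_from_bfactor = FALSE, merge_chains = FALSE,
                           structure_id = NULL,
                           source = if (plddt_from_bfactor) "predicted" else "experimental") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  }
  at$element <- .derive_element(at$elety, at$elesy)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  at <- at[!(toupper(at$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (is.na(at$chain[1])) at$chain <- "A"
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""

  ## altloc: highest occupancy wins, ties prefer 'A', then file order
  at$alt[is.na(at$alt)] <- ""
  if (any(at$alt != "")) {
    at$o[is.na(at$o)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, at$resid)
    pos <- seq_len(nrow(at))
    ord <- order(key, -at$o, at$alt != "" & at$alt != "A", pos)
    keep_pos <- sort(pos[ord][!duplicated(key[ord])])
    at <- at[keep_pos, , drop = FALSE]
  }

  aa_of_resid <- aa321(at$resid)
  is_polymer <- at$type == "ATOM" | aa_of_resid != "X"
  poly <- at[is_polymer, , drop = FALSE]
  lig <- at[!is_polymer, , drop = FALSE]
  if (nrow(poly) == 0L) stop("empty structure: no standard residues in ", path)

  build_chain <- function(chs, id) {
    sub <- poly[poly$chain %in% chs, , drop = FALSE]
    rkey <- paste(sub$chain, sub$resno, sub$insert)
    first <- !duplicated(rkey)
    res <- data.frame(chain = sub$chain[first], resno_author = sub$resno[first],
                      insert_author = sub$insert[first],
                      resid = sub$resid[first], stringsAsFactors = FALSE)
    res$aa <- aa321(res$resid)
    ## C-alpha per residue
    ca <- sub[sub$elety == "CA", , drop = FALSE]
    ca_key <- paste(ca$chain, ca$resno, ca$insert)
    m <- match(paste(res$chain, res$resno_author, res$insert_author), ca_key)
    res$x <- ca$x[m]; res$y <- ca$y[m]; res$z <- ca$z[m]
    if (plddt_from_bfactor) res$plddt <- ca$b[m]
    keep <- !is.na(res$x)
    dropped <- sum(!keep)
    res <- res[keep, , drop = FALSE]
    if (nrow(res) == 0L) stop("empty structure: no residues with C-alpha")
    res$seq_index <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
    rownames(res) <- NULL
    amap <- match(paste(sub$chain, sub$resno, sub$insert),
                  paste(res$chain, res$resno_author, res$insert_author))
    atoms <- data.frame(seq_index = res$seq_index[amap], elety = sub$elety,
                        element = sub$element, x = sub$x, y = sub$y, z = sub$z,
                        stringsAsFactors = FALSE)
    atoms <- atoms[!is.na(atoms$seq_index), , drop = FALSE]
    lig_df <- NULL
    if (nrow(lig) > 0L) {
      lig_df <- data.frame(resid = lig$resid, resno = lig$resno,
                           elety = lig$elety, element = lig$element,
                           x = lig$x, y = lig$y, z = lig$z,
                           stringsAsFactors = FALSE)
    }
    new_structure_model(id, source = source,
                        residues = res[, c("chain", "seq_index", "aa",
                                           "resno_author", "insert_author",
                                           "x", "y", "z",
                                           if (plddt_from_bfactor) "plddt")],
                        atoms = atoms, ligand_atoms = lig_df,
                        dropped_no_ca = dropped)
  }

  chains <- unique(poly$chain)
  if (merge_chains || length(chains) == 1L) {
    build_chain(chains, structure_id)
  } else {
    out <- lapply(chains, function(ch) build_chain(ch, paste0(structure_id, "_", ch)))
    names(out) <- paste0(structure_id, "_", chains)
    out
  }
}

#' Summarise per-residue pLDDT by sequence segment
#'
#' Splits the chain into the first \code{terminal_fraction}, the central
#' remainder, and the last \code{terminal_fraction} (boundaries at
#' \code{floor(f*L)} and \code{L - floor(f*L)}) and reports segment means
#' alongside the overall mean and coefficient of variation. Terminal regions
#' of predicted models are typically lower confidence than the central bulk.
#'
#' @param s structure_model with pLDDT on every residue.
#' @param terminal_fraction fraction of the chain per terminus (default 0.10).
#' @return list with mean_all, cv_all, mean_first, mean_central, mean_last.
#' @export
plddt_summary <- function(s, terminal_fraction = 0.10) {
  p <- s$residues$plddt
  if (is.null(p) || anyNA(p)) stop("pLDDT missing: structure has no complete per-residue pLDDT")
  L <- length(p)
  k <- floor(terminal_fraction * L)
  first <- if (k >= 1) p[seq_len(k)] else numeric(0)
  last <- if (k >= 1) p[(L - k + 1):L] else numeric(0)
  central <- p[(k + 1):(L - k)]
  list(mean_all = mean(p),
       cv_all = if (mean(p) > 0) stats::sd(p) / mean(p) else NA_real_,
       mean_first = if (length(first)) mean(first) else NA_real_,
       mean_central = mean(central),
       mean_last = if (length(last)) mean(last) else NA_real_)
}

#' Write structure sequences to FASTA
#'
#' @param structures list of structure_model (headers are structure_ids).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fasta <- function(structures, path) {
  if (length(structures) == 0L) {
    warning("writing empty FASTA: no structures supplied")
    cat("", file = path)
    return(invisible(path))
  }
  seqs <- vapply(structures, function(s) s$sequence, character(1))
  names(seqs) <- vapply(structures, function(s) s$structure_id, character(1))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Write a structure model as a PDB file
#'
#' Emits all heavy atoms when present (falling back to the C-alpha trace),
#' with pLDDT in the B-factor column; the synthetic generator uses this to
#' hand the alignment stage files in the same format as real inputs.
#'
#' @param s structure_model.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_structure_pdb <- function(s, path) {
  res <- s$residues
  b_res <- if (!is.null(res$plddt)) res$plddt else rep(0, nrow(res))
  if (!is.null(s$atoms) && nrow(s$atoms) > 0) {
    a <- s$atoms
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    m <- match(a$seq_index, res$seq_index)
    bio3d::write.pdb(file = path, xyz = xyz, resno = a$seq_index,
                     resid = aa123(res$aa[m]), elety = a$elety,
                     chain = res$chain[m], b = round(b_res[m], 2))
  } else {
    xyz <- as.numeric(t(ca_coords(s)))
    bio3d::write.pdb(file = path, xyz = xyz, resno = res$seq_index,
                     resid = aa123(res$aa), elety = rep("CA", nrow(res)),
                     chain = res$chain, b = round(b_res, 2))
  }
  invisible(path)
}

#' Structures manifest
#'
#' @param structures list of structure_model.
#' @param og_map optional named character vector structure_id -> og_id.
#' @return data.frame (structure_id, og_id, length, mean_plddt).
#' @export
structure_manifest <- function(structures, og_map = NULL) {
  ids <- vapply(structures, function(s) s$structure_id, character(1))
  data.frame(
    structure_id = ids,
    og_id = if (is.null(og_map)) NA_character_ else unname(og_map[ids]),
    length = vapply(structures, function(s) nrow(s$residues), integer(1)),
    mean_plddt = vapply(structures, function(s) {
      p <- s$residues$plddt
      if (is.null(p)) NA_real_ else mean(p, na.rm = TRUE)
    }, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Construct an orthogroup
#'
#' A set of orthologous (possibly paralogous) structures anchored to one or
#' more reference members. Every reference must itself be a member.
#'
#' @param og_id identifier.
#' @param reference_ids structure_ids designated as reference.
#' @param structures named list of structure_model, names = structure_ids.
#' @return object of class "orthogroup".
#' @export
new_orthogroup <- function(og_id, reference_ids, structures) {
  member_ids <- names(structures)
  stopifnot(length(member_ids) == length(structures), !is.null(member_ids))
  if (!all(reference_ids %in% member_ids)) {
    stop("every reference_id must also be a member_id")
  }
  structure(list(og_id = og_id, reference_ids = reference_ids,
                 member_ids = member_ids, structures = structures),
            class = "orthogroup")
}

#' @export
print.orthogroup <- function(x, ...) {
  cat("orthogroup", x$og_id, "-", length(x$member_ids), "members,",
      length(x$reference_ids), "reference(s)\n")
  invisible(x)
}
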