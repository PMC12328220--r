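## residue_features: solvent accessibility and the surface/core split,
## hydrogen-bond based secondary structure, and binding-site flags from
## ligand proximity (CSb) or curated annotation (UPb).

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  phi <- acos(1 - 2 * (i + 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each heavy atom carries a deterministic spherical lattice
#' of \code{n_points} test points at its solvated radius (van der Waals +
#' probe); the accessible area is the unoccluded fraction of the sphere,
#' summed per residue. Element radii come from the packaged table (unknown
#' elements fall back to carbon).
#'
#' @param s structure_model with heavy atoms.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_points lattice points per atom (default 960).
#' @return numeric vector of per-residue SASA (\eqn{\mathrm{\AA}^2}), one
#'   entry per residue, with per-atom values in attribute "atom_sasa".
#' @export
shrake_rupley_sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  atoms <- s$atoms
  if (is.null(atoms) || nrow(atoms) == 0L) stop("zero atoms: no heavy atoms present")
  radii <- vdw_radii()
  r <- unname(radii[atoms$element])
  r[is.na(r)] <- radii[["C"]]
  R <- r + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  sphere <- .fibonacci_sphere(n_points)
  area <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    pts <- sweep(sphere * R[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- dj >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  res_idx <- sort(unique(s$residues$seq_index))
  out <- vapply(res_idx, function(k) sum(area[atoms$seq_index == k]), numeric(1))
  names(out) <- res_idx
  attr(out, "atom_sasa") <- area
  out
}

#' Relative SASA and the surface/core partition
#'
#' rSASA = SASA / theoretical maximum for the amino acid; a residue is
#' surface when rSASA is at least \code{surface_threshold}, core otherwise,
#' so the partition is total. 'X' residues have undefined rSASA and fall
#' back to a raw-area rule (surface when SASA >= 25 A^2).
#'
#' @param sasa per-residue SASA vector.
#' @param aa one-letter amino acids, same length.
#' @param max_sasa_table named maxima (default packaged theoretical values).
#' @param surface_threshold rSASA cutoff (default 0.25).
#' @return data.frame (sasa, rsasa, exposure).
#' @export
relative_sasa <- function(sasa, aa, max_sasa_table = aa_lookup("max_sasa"),
                          surface_threshold = 0.25) {
  if (!all(AA_CANONICAL %in% names(max_sasa_table))) {
    stop("max_sasa_table must cover the 20 canonical amino acids")
  }
  rsasa <- unname(sasa / max_sasa_table[aa])
  exposure <- ifelse(is.na(rsasa), ifelse(sasa >= 25, "surface", "core"),
                     ifelse(rsasa >= surface_threshold, "surface", "core"))
  data.frame(sasa = unname(sasa), rsasa = rsasa, exposure = exposure,
             stringsAsFactors = FALSE)
}

## Backbone coordinate matrices (N, CA, C, O) per residue; NA rows where an
## atom is missing.
.backbone_matrix <- function(s, elety) {
  res_idx <- s$residues$seq_index
  out <- matrix(NA_real_, length(res_idx), 3)
  a <- s$atoms
  if (!is.null(a)) {
    sel <- a[a$elety == elety, , drop = FALSE]
    m <- match(res_idx, sel$seq_index)
    out <- as.matrix(sel[m, c("x", "y", "z")])
  }
  out
}

## Kabsch-Sander electrostatic H-bond energies (kcal/mol): partial charges
## on C=O and N-H, E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN); the
## amide H is placed 1 A from N opposite the bisector of the previous
## residue's C and O.
.hbond_matrix <- function(N, CA, C, O) {
  n <- nrow(N)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (anyNA(N[i, ]) || anyNA(C[i - 1, ]) || anyNA(O[i - 1, ])) next
    d1 <- N[i, ] - C[i - 1, ]; d1 <- d1 / sqrt(sum(d1^2))
    d2 <- N[i, ] - O[i - 1, ]; d2 <- d2 / sqrt(sum(d2^2))
    d <- d1 + d2
    H[i, ] <- N[i, ] + d / sqrt(sum(d^2))
  }
  dist2 <- function(A, B) {
    out <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sqrt(pmax(out, 0))
  }
  rON <- dist2(O, N); rCH <- dist2(C, H); rOH <- dist2(O, H); rCN <- dist2(C, N)
  E <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[!is.finite(E)] <- 0
  ## no bond to self or sequence neighbours
  E[abs(row(E) - col(E)) <= 1] <- 0
  E
}

#' Assign secondary-structure classes
#'
#' Four exclusive classes (helix, extended, turn, coil) from the model's own
#' geometry. With a full backbone, hydrogen bonds are detected by the
#' Kabsch-Sander electrostatic criterion (E < -0.5 kcal/mol): consecutive
#' i->i+4 (or i->i+3/i->i+5) turns define helices, bridge patterns between
#' strands define extended residues, isolated i->i+3 bends become turns and
#' everything else coil. Chains shorter than 5 residues are all coil. With
#' only C-alpha coordinates a geometric fallback based on i->i+3 / i->i+4
#' distances is used and flagged in the "method" attribute.
#'
#' @param s structure_model.
#' @return character vector of classes per residue with attribute "method"
#'   ("hbond" or "ca_fallback").
#' @export
assign_secondary_structure <- function(s) {
  n <- nrow(s$residues)
  if (n < 5) {
    out <- rep("coil", n)
    attr(out, "method") <- "hbond"
    return(out)
  }
  N <- .backbone_matrix(s, "N"); C <- .backbone_matrix(s, "C")
  O <- .backbone_matrix(s, "O"); CA <- ca_coords(s)
  have_bb <- mean(stats::complete.cases(cbind(N, C, O))) >= 0.9
  if (!have_bb) return(.ss_ca_fallback(CA))
  E <- .hbond_matrix(N, CA, C, O)
  hb <- E < -0.5         # hb[i, j]: CO of i accepts NH of j
  hbond <- function(i, j) {
    ok <- i >= 1 & j >= 1 & i <= n & j <= n
    out <- rep(FALSE, length(i))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }
  idx <- seq_len(n)
  T3 <- hbond(idx, idx + 3); T4 <- hbond(idx, idx + 4); T5 <- hbond(idx, idx + 5)
  cls <- rep("coil", n)
  ## turns first (lowest priority among the marked classes)
  for (i in which(T3)) cls[(i + 1):min(i + 2, n)] <- "turn"
  for (i in which(T4)) cls[(i + 1):min(i + 3, n)] <- "turn"
  ## bridges -> extended
  bridge <- rep(FALSE, n)
  cand <- which(rowSums(hb | t(hb)) > 0)
  for (i in cand) {
    js <- which((hb[i, ] | hb[, i]))
    js <- js[abs(js - i) >= 3]
    for (j in js) {
      par <- (hbond(i - 1, j) & hbond(j, i + 1)) | (hbond(j - 1, i) & hbond(i, j + 1))
      anti <- (hbond(i, j) & hbond(j, i)) | (hbond(i - 1, j + 1) & hbond(j - 1, i + 1))
      if (par || anti) bridge[c(i, j)] <- TRUE
    }
  }
  ## ladder fill: a residue flanked by bridge residues belongs to the strand
  ## (antiparallel ladders H-bond only every second residue)
  fill <- which(!bridge & c(FALSE, bridge[-n]) & c(bridge[-1], FALSE))
  bridge[fill] <- TRUE
  cls[bridge] <- "extended"
  ## helices (highest priority)
  helix <- rep(FALSE, n)
  mark <- function(tt, span) {
    for (i in which(tt[-n] & tt[-1])) helix[(i + 1):min(i + span, n)] <<- TRUE
  }
  mark(T4, 4); mark(T3, 3); mark(T5, 5)
  cls[helix] <- "helix"
  attr(cls, "method") <- "hbond"
  cls
}

.ss_ca_fallback <- function(CA) {
  n <- nrow(CA)
  d_k <- function(k) {
    d <- rep(NA_real_, n)
    d[seq_len(n - k)] <- sqrt(rowSums((CA[seq_len(n - k) + k, , drop = FALSE] -
                                       CA[seq_len(n - k), , drop = FALSE])^2))
    d
  }
  d3 <- d_k(3); d4 <- d_k(4)
  cls <- rep("coil", n)
  for (i in seq_len(n - 4)) {
    if (!is.na(d3[i]) && !is.na(d4[i]) && d3[i] > 4.2 && d3[i] < 6.2 &&
        d4[i] > 4.9 && d4[i] < 7.2) {
      cls[i:(i + 4)] <- "helix"
    }
  }
  for (i in seq_len(n - 3)) {
    if (!is.na(d3[i]) && d3[i] > 9.3 && cls[i] == "coil") {
      cls[i:(i + 3)][cls[i:(i + 3)] == "coil"] <- "extended"
    }
  }
  attr(cls, "method") <- "ca_fallback"
  cls
}

#' Flag binding-site residues by ligand proximity (CSb)
#'
#' A residue is CSb when any of its heavy atoms lies within
#' \code{distance_cutoff} of a heavy atom of a retained ligand;
#' crystallographic additives (waters, buffers, cryoprotectants) are
#' excluded via the packaged list. Flags grow monotonically with the
#' cutoff.
#'
#' @param s structure_model carrying ligand heteroatoms.
#' @param distance_cutoff heavy-atom distance, Angstrom (default 5.0).
#' @param exclusion residue names to ignore (default packaged list).
#' @return logical vector per residue; warns and returns all-FALSE when the
#'   structure has no retained ligands.
#' @export
csb_binding_sites <- function(s, distance_cutoff = 5.0,
                              exclusion = ligand_exclusion_list()) {
  nres <- nrow(s$residues)
  lig <- s$ligand_atoms
  if (!is.null(lig)) lig <- lig[!(toupper(lig$resid) %in% toupper(exclusion)), , drop = FALSE]
  if (is.null(lig) || nrow(lig) == 0L) {
    warning("no ligands retained: all CSb flags FALSE")
    return(rep(FALSE, nres))
  }
  atoms <- if (!is.null(s$atoms) && nrow(s$atoms) > 0) s$atoms else
    cbind(s$residues[, c("seq_index", "x", "y", "z")], elety = "CA")
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(axyz^2), rowSums(lxyz^2), `+`) - 2 * axyz %*% t(lxyz)
  near <- apply(d2 <= distance_cutoff^2, 1, any)
  flags <- rep(FALSE, nres)
  flags[sort(unique(atoms$seq_index[near]))] <- TRUE
  flags
}

#' Flag binding-site residues from a curated annotation table (UPb)
#'
#' Positions in the table refer to author numbering; they are joined via
#' the numbering metadata retained at parse time (insertion codes were
#' flattened into sequential indices). Site types substrate/cofactor set
#' the UPb flag; metal sites additionally set the metal flag. Positions
#' outside the chain are skipped with a warning and counted.
#'
#' @param s structure_model.
#' @param annotation data.frame with columns structure_id, position,
#'   site_type (substrate/cofactor/metal); optional column chain.
#' @return data.frame (upb, metal) of logical flags per residue, with
#'   attribute "n_skipped".
#' @export
upb_binding_sites <- function(s, annotation) {
  nres <- nrow(s$residues)
  upb <- metal <- rep(FALSE, nres)
  skipped <- 0L
  ann <- annotation[annotation$structure_id == s$structure_id, , drop = FALSE]
  if (nrow(ann) > 0) {
    key <- s$residues$resno_author
    if (is.null(key)) key <- s$residues$seq_index
    for (r in seq_len(nrow(ann))) {
      hit <- which(key == ann$position[r])
      if (!is.null(ann$chain) && !is.na(ann$chain[r])) {
        hit <- hit[s$residues$chain[hit] == ann$chain[r]]
      }
      if (length(hit) == 0L) { skipped <- skipped + 1L; next }
      if (identical(ann$site_type[r], "metal")) metal[hit] <- TRUE else upb[hit] <- TRUE
    }
    if (skipped > 0) warning(skipped, " annotated positions outside the chain skipped")
  }
  out <- data.frame(upb = upb, metal = metal)
  attr(out, "n_skipped") <- skipped
  out
}

#' Transfer per-residue flags through a residue mapping
#'
#' Moves annotation between a homologous structure and the reference using
#' the 1:1 mapping from the alignment stage (e.g. CSb flags detected on a
#' holo homologue onto the orthogroup reference). Unmapped flagged residues
#' are dropped and counted.
#'
#' @param flags logical vector on the source structure's residues.
#' @param mapping two-column (ref_idx, mem_idx) matrix.
#' @param n_target number of residues in the target structure.
#' @param direction "mem_to_ref" (default) or "ref_to_mem".
#' @return logical vector on the target with attribute "n_dropped".
#' @export
transfer_flags <- function(flags, mapping, n_target,
                           direction = c("mem_to_ref", "ref_to_mem")) {
  direction <- match.arg(direction)
  mapping <- as.matrix(mapping)
  from <- if (direction == "mem_to_ref") mapping[, 2] else mapping[, 1]
  to <- if (direction == "mem_to_ref") mapping[, 1] else mapping[, 2]
  out <- rep(FALSE, n_target)
  hit <- flags[from]
  out[to[hit]] <- TRUE
  n_dropped <- sum(flags) - sum(flags[from])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Full residue-feature table for a reference structure
#'
#' Convenience assembly of the per-residue feature TSV: SASA, rSASA and
#' exposure, secondary-structure class, CSb/UPb/metal flags and any
#' externally supplied per-residue logical annotations (e.g. ppi,
#' fold_member).
#'
#' @param s structure_model.
#' @param upb_table optional annotation table for \code{upb_binding_sites}.
#' @param csb logical: detect CSb flags from this structure's own ligands.
#' @param surface_threshold rSASA surface cutoff (default 0.25).
#' @param n_points SASA lattice size.
#' @param extra named list of per-residue logical vectors to append.
#' @return data.frame, one row per residue.
#' @export
residue_features <- function(s, upb_table = NULL, csb = TRUE,
                             surface_threshold = 0.25, n_points = 960,
                             extra = list()) {
  sasa <- shrake_rupley_sasa(s, n_points = n_points)
  rs <- relative_sasa(sasa, s$residues$aa, surface_threshold = surface_threshold)
  ss <- assign_secondary_structure(s)
  csb_flags <- if (csb && !is.null(s$ligand_atoms) && nrow(s$ligand_atoms) > 0) {
    csb_binding_sites(s)
  } else rep(FALSE, nrow(s$residues))
  upb <- if (!is.null(upb_table)) upb_binding_sites(s, upb_table) else
    data.frame(upb = rep(FALSE, nrow(s$residues)), metal = rep(FALSE, nrow(s$residues)))
  out <- data.frame(ref_idx = s$residues$seq_index, aa = s$residues$aa,
                    sasa = rs$sasa, rsasa = rs$rsasa, exposure = rs$exposure,
                    ss_class = as.character(ss), csb = csb_flags,
                    upb = upb$upb, metal = upb$metal, stringsAsFactors = FALSE)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  attr(out, "ss_method") <- attr(ss, "method")
  out
}
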