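## structural_alignment: Kabsch superposition, matchmaker-style iterative
## alignment producing 1:1 residue mappings, TM-scores, and TM-based
## orthogroup refinement.

#' Least-squares superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' \code{coords_b} (mobile) and \code{coords_a} (fixed). Reflections are
#' corrected by flipping the sign of the smallest singular vector when the
#' determinant of the candidate rotation is negative.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates, n >= 3.
#' @return list (class "superposition") with rotation (3x3, det +1),
#'   translation (length 3), rmsd, n_pairs, degenerate (TRUE when the point
#'   set is rank-deficient, e.g. collinear; a solution is still returned).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) stop("coordinate sets must be paired")
  n <- nrow(coords_a)
  if (n < 3) stop("insufficient pairs: need >= 3 paired points")
  if (anyNA(coords_a) || anyNA(coords_b)) stop("NaN/NA coordinates")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(B, A)                     # 3x3 covariance, mobile x fixed
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  moved <- B %*% R
  rmsd <- sqrt(mean(rowSums((moved - A)^2)))
  translation <- ca - as.numeric(cb %*% R)
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_pairs = n, degenerate = degenerate),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param coords n x 3 matrix (mobile frame).
#' @param sup superposition from \code{kabsch_superpose}.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, `+`)
}

## Global sequence alignment of two one-letter sequences; returns a two
## column matrix of aligned (ref_idx, mem_idx) pairs (gap columns dropped).
.sequence_align_pairs <- function(ref_seq, mem_seq, gap_open = 10, gap_extend = 1,
                                  substitution_matrix = "BLOSUM62") {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_seq), Biostrings::AAString(mem_seq),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  su <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ## aligned views need not start at position 1 (leading gap-free overhangs)
  ri <- Biostrings::start(Biostrings::pattern(aln)) - 1L + cumsum(pa != "-")
  mi <- Biostrings::start(Biostrings::subject(aln)) - 1L + cumsum(su != "-")
  keep <- pa != "-" & su != "-"
  cbind(ref_idx = ri[keep], mem_idx = mi[keep])
}

#' Align a member structure onto a reference and derive the 1:1 residue map
#'
#' Matchmaker-style procedure: (1) global sequence alignment (BLOSUM62,
#' affine gaps) seeds candidate C-alpha pairs; (2) Kabsch superposition on
#' the candidates; (3) pairs further apart than \code{prune_cutoff} after
#' superposition are iteratively pruned, re-superposing until the pair set
#' is stable or \code{max_iter} is reached; (4) the final mapping is the
#' set of sequence-aligned pairs whose post-superposition C-alpha distance
#' is at most \code{map_cutoff}. Reference residues without a partner count
#' toward N for that member.
#'
#' @param ref,mem structure_model (reference, member).
#' @param prune_cutoff C-alpha distance (Angstrom) above which pairs are
#'   pruned during iterative refinement (default 2.0).
#' @param map_cutoff distance ceiling for the final 1:1 mapping (default 5.0).
#' @param max_iter maximum pruning iterations (default 20).
#' @param gap_open,gap_extend affine gap penalties for the seeding alignment.
#' @return list (class "alignment_result") with mapping (matrix of
#'   ref_idx/mem_idx, monotone in both columns), superposition (fit on the
#'   pruned core), rmsd_core, tm_ref, tm_mem, tm_bidir, d0_ref, d0_mem,
#'   n_candidate, n_pruned_iterations.
#' @export
align_and_map <- function(ref, mem, prune_cutoff = 2.0, map_cutoff = 5.0,
                          max_iter = 20, gap_open = 10, gap_extend = 1) {
  pairs <- .sequence_align_pairs(ref$sequence, mem$sequence,
                                 gap_open = gap_open, gap_extend = gap_extend)
  if (nrow(pairs) < 3) stop("alignment failure: fewer than 3 aligned pairs")
  rxyz <- ca_coords(ref); mxyz <- ca_coords(mem)
  keep <- seq_len(nrow(pairs))
  sup <- NULL
  iters <- 0L
  repeat {
    sup <- kabsch_superpose(rxyz[pairs[keep, 1], , drop = FALSE],
                            mxyz[pairs[keep, 2], , drop = FALSE])
    moved <- apply_superposition(mxyz[pairs[keep, 2], , drop = FALSE], sup)
    d <- sqrt(rowSums((moved - rxyz[pairs[keep, 1], , drop = FALSE])^2))
    new_keep <- keep[d <= prune_cutoff]
    iters <- iters + 1L
    if (length(new_keep) < 3 || length(new_keep) == length(keep) ||
        iters >= max_iter) {
      if (length(new_keep) >= 3 && length(new_keep) < length(keep)) {
        keep <- new_keep
        sup <- kabsch_superpose(rxyz[pairs[keep, 1], , drop = FALSE],
                                mxyz[pairs[keep, 2], , drop = FALSE])
      }
      break
    }
    keep <- new_keep
  }
  moved_all <- apply_superposition(mxyz[pairs[, 2], , drop = FALSE], sup)
  d_all <- sqrt(rowSums((moved_all - rxyz[pairs[, 1], , drop = FALSE])^2))
  mapping <- pairs[d_all <= map_cutoff, , drop = FALSE]
  if (nrow(mapping) < 3) stop("alignment failure: fewer than 3 mapped pairs")
  tm_r <- tm_score(mapping, ref, mem, sup, normalize_by = "ref")
  tm_m <- tm_score(mapping, ref, mem, sup, normalize_by = "mem")
  structure(list(mapping = mapping, superposition = sup,
                 rmsd_core = sup$rmsd,
                 tm_ref = tm_r, tm_mem = tm_m,
                 tm_bidir = mean(c(tm_r, tm_m)),
                 d0_ref = .tm_d0(nrow(ref$residues)),
                 d0_mem = .tm_d0(nrow(mem$residues)),
                 n_candidate = nrow(pairs),
                 n_pruned_iterations = iters),
            class = "alignment_result")
}

## d0 floored at 0.5 A so short toy chains keep a defined score (the cube
## root is negative or undefined below L = 16)
.tm_d0 <- function(L) {
  if (L <= 15) return(0.5)
  max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8)
}

#' TM-score of a residue mapping
#'
#' \deqn{TM = \frac{1}{L_{norm}} \sum_i \frac{1}{1 + (d_i/d_0)^2}},
#' with \eqn{d_0 = \max(0.5,\; 1.24 (L_{norm}-15)^{1/3} - 1.8)} so short toy
#' chains keep a defined score. Distances are measured after applying the
#' superposition to the member coordinates.
#'
#' @param mapping two-column matrix of (ref_idx, mem_idx) pairs.
#' @param ref,mem structure_model.
#' @param superposition fit mapping member onto reference.
#' @param normalize_by "ref" (L_norm = reference length) or "mem".
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(mapping, ref, mem, superposition,
                     normalize_by = c("ref", "mem")) {
  normalize_by <- match.arg(normalize_by)
  mapping <- as.matrix(mapping)
  if (nrow(mapping) == 0) stop("undefined score: empty mapping")
  L <- if (normalize_by == "ref") nrow(ref$residues) else nrow(mem$residues)
  d0 <- .tm_d0(L)
  moved <- apply_superposition(ca_coords(mem)[mapping[, 2], , drop = FALSE],
                               superposition)
  d <- sqrt(rowSums((moved - ca_coords(ref)[mapping[, 1], , drop = FALSE])^2))
  sum(1 / (1 + (d / d0)^2)) / L
}

#' Bidirectional TM-score
#'
#' Symmetrises the two length normalisations of the TM-score; the default
#' is their arithmetic mean (min and max are available for comparison).
#'
#' @param tm_ref,tm_mem TM-scores normalised by each structure's length.
#' @param mode "mean" (default), "min" or "max".
#' @return symmetrised score.
#' @export
tm_bidirectional <- function(tm_ref, tm_mem, mode = c("mean", "min", "max")) {
  mode <- match.arg(mode)
  switch(mode, mean = (tm_ref + tm_mem) / 2,
         min = pmin(tm_ref, tm_mem), max = pmax(tm_ref, tm_mem))
}

#' Pairwise bidirectional TM-score matrix
#'
#' @param structures named list of structure_model.
#' @param ... passed to \code{align_and_map}.
#' @return symmetric matrix with unit diagonal; failed alignments yield NA.
#' @export
tm_matrix <- function(structures, ...) {
  ids <- vapply(structures, function(s) s$structure_id, character(1))
  n <- length(structures)
  M <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n < 2) return(M)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tm <- tryCatch(align_and_map(structures[[i]], structures[[j]], ...)$tm_bidir,
                     error = function(e) NA_real_)
      M[i, j] <- M[j, i] <- tm
    }
  }
  M
}

#' Refine orthogroups by hierarchical clustering on bidirectional TM-scores
#'
#' Distance is \code{1 - tm_bidir}; average-linkage agglomerative clustering
#' is cut at \code{linkage_cutoff}, so members of one refined orthogroup
#' share a cophenetic distance of at most the cutoff. Cluster labels are
#' renumbered deterministically by the lexicographically smallest member id.
#'
#' @param tm pairwise symmetric bidirectional TM matrix with unit diagonal.
#' @param linkage_cutoff flat-cluster height (default 0.2).
#' @return named integer vector of cluster labels keyed by structure_id.
#' @export
refine_orthogroups <- function(tm, linkage_cutoff = 0.2) {
  tm <- as.matrix(tm)
  if (!isTRUE(all.equal(tm, t(tm), tolerance = 1e-8))) {
    stop("input error: TM matrix must be symmetric")
  }
  ids <- rownames(tm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(tm)))
  ord <- order(ids)
  tm <- tm[ord, ord, drop = FALSE]
  ids <- ids[ord]
  if (length(ids) == 1L) return(stats::setNames(1L, ids))
  D <- stats::as.dist(1 - tm)
  hc <- stats::hclust(D, method = "average")
  cl <- stats::cutree(hc, h = linkage_cutoff)
  ## renumber clusters by their lexicographically first member
  firsts <- vapply(split(ids, cl), min, character(1))
  relabel <- stats::setNames(rank(firsts, ties.method = "first"), names(firsts))
  stats::setNames(as.integer(relabel[as.character(cl)]), ids)
}
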