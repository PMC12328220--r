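## conservation_metrics: per-member M/N/C bookkeeping, orthogroup MR/CR,
## per-reference-residue conservation tallies, class-based CR and
## hydrophobicity-change summaries.

#' Conservation profile of an orthogroup against one reference
#'
#' For every non-reference member with a residue mapping, counts on the
#' member side: M (residues in 1:1 correspondence with the reference),
#' N (member residues left unmapped, so M + N is the member length) and
#' C (mapped residues identical to the reference residue). Per member,
#' MR = M/(M+N) and CR = C/M; orthogroup MR/CR are unweighted means over
#' members. On the reference side, each position accumulates how many
#' members map it (n_mapped) and match it (n_identical); a position is
#' fully conserved when it is mapped and identical in every aligned member.
#' 'X' residues can map but never count as identical.
#'
#' @param og orthogroup.
#' @param mappings named list (member_id -> two-column ref_idx/mem_idx
#'   matrix) of residue mappings onto the reference; members absent from
#'   the list (e.g. failed alignments) are excluded and counted.
#' @param reference_id which reference to profile (default: first).
#' @param quorum fraction of aligned members that must map and match a
#'   position for it to be called fully conserved (default 1 = strict).
#' @return list of class "conservation_profile": og_id, reference_id,
#'   members (data.frame member_id, M, N, C, mr, cr), residues (data.frame
#'   ref_idx, aa, n_mapped, n_identical, fully_conserved), og_mr, og_cr,
#'   n_members_aligned, n_members_failed.
#' @export
conservation_profile <- function(og, mappings, reference_id = og$reference_ids[1],
                                 quorum = 1) {
  ref <- og$structures[[reference_id]]
  if (is.null(ref)) stop("reference ", reference_id, " not in orthogroup")
  others <- setdiff(og$member_ids, reference_id)
  aligned <- intersect(others, names(mappings))
  if (length(aligned) == 0L) stop("empty profile: no aligned members")
  ref_aa <- strsplit(ref$sequence, "")[[1]]
  Lref <- length(ref_aa)
  n_mapped <- integer(Lref)
  n_identical <- integer(Lref)
  mem_rows <- lapply(aligned, function(id) {
    map <- as.matrix(mappings[[id]])
    mem <- og$structures[[id]]
    mem_aa <- strsplit(mem$sequence, "")[[1]]
    ident <- ref_aa[map[, 1]] == mem_aa[map[, 2]] & ref_aa[map[, 1]] != "X"
    n_mapped[map[, 1]] <<- n_mapped[map[, 1]] + 1L
    n_identical[map[ident, 1]] <<- n_identical[map[ident, 1]] + 1L
    M <- nrow(map)
    N <- length(mem_aa) - M
    C <- sum(ident)
    data.frame(member_id = id, M = M, N = N, C = C,
               mr = M / (M + N), cr = C / M, stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, mem_rows)
  n_aligned <- length(aligned)
  need <- ceiling(quorum * n_aligned)
  residues <- data.frame(ref_idx = seq_len(Lref), aa = ref_aa,
                         n_mapped = n_mapped, n_identical = n_identical,
                         fully_conserved = n_mapped >= need & n_identical >= need,
                         stringsAsFactors = FALSE)
  structure(list(og_id = og$og_id, reference_id = reference_id,
                 members = members, residues = residues,
                 og_mr = mean(members$mr), og_cr = mean(members$cr),
                 n_members_aligned = n_aligned,
                 n_members_failed = length(setdiff(others, aligned)),
                 quorum = quorum),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("conservation_profile", x$og_id, "ref", x$reference_id, "\n")
  cat(sprintf("  members aligned: %d (failed: %d)\n",
              x$n_members_aligned, x$n_members_failed))
  cat(sprintf("  MR = %.3f  CR = %.3f  fully conserved: %d/%d\n",
              x$og_mr, x$og_cr, sum(x$residues$fully_conserved),
              nrow(x$residues)))
  invisible(x)
}

#' CR counting physicochemical-class matches as conserved
#'
#' As the conservation ratio, but a mapped pair counts as conserved when
#' the two residues share a physicochemical class (so D->E within "acidic"
#' still counts). Always at least the identity CR. 'X' residues are
#' excluded from the denominator.
#'
#' @param og,mappings,reference_id as in \code{conservation_profile}.
#' @param class_map named character vector amino acid -> class; defaults to
#'   the packaged grouping (aliphatic, aromatic, polar, acidic, basic, and
#'   G/P/C as singleton classes).
#' @return orthogroup-mean class CR (unweighted over members).
#' @export
cr_by_class <- function(og, mappings, reference_id = og$reference_ids[1],
                        class_map = aa_lookup("class")) {
  if (!all(AA_CANONICAL %in% names(class_map))) {
    stop("class_map must cover the 20 canonical amino acids")
  }
  ref <- og$structures[[reference_id]]
  ref_aa <- strsplit(ref$sequence, "")[[1]]
  aligned <- intersect(setdiff(og$member_ids, reference_id), names(mappings))
  if (length(aligned) == 0L) stop("empty profile: no aligned members")
  per_member <- vapply(aligned, function(id) {
    map <- as.matrix(mappings[[id]])
    mem_aa <- strsplit(og$structures[[id]]$sequence, "")[[1]]
    ra <- ref_aa[map[, 1]]; ma <- mem_aa[map[, 2]]
    ok <- ra != "X" & ma != "X"
    if (!any(ok)) return(NA_real_)
    mean(class_map[ra[ok]] == class_map[ma[ok]])
  }, numeric(1))
  mean(per_member, na.rm = TRUE)
}

#' Mean octanol-water partition change over substituted mapped pairs
#'
#' For each member, averages |logP(ref aa) - logP(member aa)| over mapped
#' pairs where the amino acid changed, then averages over members. Returns
#' 0 for an orthogroup with no substitutions. Divergent orthogroups shift
#' their hydrophobicity profile more, so this statistic runs inversely to
#' the CR.
#'
#' @param og,mappings,reference_id as in \code{conservation_profile}.
#' @param logp_table named numeric amino acid -> logP (default packaged
#'   Fauchere-Pliska side-chain values).
#' @return mean absolute logP change.
#' @export
mean_hydrophobicity_change <- function(og, mappings,
                                       reference_id = og$reference_ids[1],
                                       logp_table = aa_lookup("logp")) {
  if (!all(AA_CANONICAL %in% names(logp_table))) {
    stop("logp_table must cover the 20 canonical amino acids")
  }
  ref_aa <- strsplit(og$structures[[reference_id]]$sequence, "")[[1]]
  aligned <- intersect(setdiff(og$member_ids, reference_id), names(mappings))
  if (length(aligned) == 0L) stop("undefined: no aligned members")
  per_member <- vapply(aligned, function(id) {
    map <- as.matrix(mappings[[id]])
    if (nrow(map) == 0L) stop("undefined: member with no mapped pairs")
    mem_aa <- strsplit(og$structures[[id]]$sequence, "")[[1]]
    ra <- ref_aa[map[, 1]]; ma <- mem_aa[map[, 2]]
    sub <- ra != ma & ra != "X" & ma != "X"
    if (!any(sub)) return(0)
    mean(abs(logp_table[ra[sub]] - logp_table[ma[sub]]))
  }, numeric(1))
  mean(per_member)
}

#' CR restricted to a subset of reference residues
#'
#' Recomputes the conservation ratio using only reference positions passing
#' a selector (e.g. core, surface, binding site): per member, identical
#' counts over mapped counts within the subset, averaged over members.
#'
#' @param og,mappings,reference_id as in \code{conservation_profile}.
#' @param subset_idx integer vector of reference seq indices, or a logical
#'   vector over reference positions.
#' @return mean CR within the subset; NA (with attribute "reason") when no
#'   member maps any subset residue.
#' @export
cr_by_feature <- function(og, mappings, subset_idx,
                          reference_id = og$reference_ids[1]) {
  ref_aa <- strsplit(og$structures[[reference_id]]$sequence, "")[[1]]
  if (is.logical(subset_idx)) subset_idx <- which(subset_idx)
  aligned <- intersect(setdiff(og$member_ids, reference_id), names(mappings))
  if (length(aligned) == 0L) stop("empty profile: no aligned members")
  per_member <- vapply(aligned, function(id) {
    map <- as.matrix(mappings[[id]])
    map <- map[map[, 1] %in% subset_idx, , drop = FALSE]
    if (nrow(map) == 0L) return(NA_real_)
    mem_aa <- strsplit(og$structures[[id]]$sequence, "")[[1]]
    mean(ref_aa[map[, 1]] == mem_aa[map[, 2]] & ref_aa[map[, 1]] != "X")
  }, numeric(1))
  if (all(is.na(per_member))) {
    out <- NA_real_
    attr(out, "reason") <- "empty subset: no mapped residues"
    return(out)
  }
  mean(per_member, na.rm = TRUE)
}

#' Collapse paralogues to one representative per species
#'
#' Optional species deduplication before averaging: keeps, per species, the
#' member with the highest MR (ties by member_id). Species are taken from
#' the structure_id prefix up to the first underscore unless a map is given.
#'
#' @param profile conservation_profile.
#' @param species_map optional named character vector member_id -> species.
#' @return conservation_profile with deduplicated member table and
#'   recomputed og_mr/og_cr.
#' @export
dedupe_species <- function(profile, species_map = NULL) {
  m <- profile$members
  sp <- if (is.null(species_map)) sub("_.*$", "", m$member_id) else species_map[m$member_id]
  keep <- unlist(lapply(split(seq_len(nrow(m)), sp), function(ii) {
    ii[order(-m$mr[ii], m$member_id[ii])][1]
  }))
  m <- m[sort(keep), , drop = FALSE]
  profile$members <- m
  profile$og_mr <- mean(m$mr)
  profile$og_cr <- mean(m$cr)
  profile
}

#' Persist a profile as the standard per-orthogroup and per-residue tables
#'
#' @param profiles list of conservation_profile.
#' @return list of two data.frames: summary (og_id, reference_id, og_mr,
#'   og_cr, n_members) and residues (og_id, ref_idx, aa, n_mapped,
#'   n_identical, fully_conserved).
#' @export
profile_tables <- function(profiles) {
  summary <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(og_id = p$og_id, reference_id = p$reference_id,
               og_mr = p$og_mr, og_cr = p$og_cr,
               n_members = p$n_members_aligned, stringsAsFactors = FALSE)
  }))
  residues <- do.call(rbind, lapply(profiles, function(p) {
    cbind(og_id = p$og_id, p$residues, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- rownames(residues) <- NULL
  list(summary = summary, residues = residues)
}
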