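# Fixture builders shared across test files. Structures are constructed in
# code; PDB fixtures are written with fixed-width records so the parser is
# exercised against files we control completely.

write_fixture_pdb <- function(path, resid, elety, xyz, b = NULL, chain = "A",
                              resno = NULL, occ = NULL, alt = NULL,
                              type = NULL) {
  n <- nrow(xyz)
  if (is.null(b)) b <- rep(0, n)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(occ)) occ <- rep(1, n)
  if (is.null(alt)) alt <- rep(" ", n)
  if (is.null(type)) type <- rep("ATOM  ", n)
  chain <- rep_len(chain, n)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            type[i], i, elety[i], alt[i], resid[i], chain[i], resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], occ[i], b[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# three C-alpha residues on a line, B-factors carry pLDDT-like values
mini_pdb_fixture <- function(path = tempfile(fileext = ".pdb"),
                             b = c(90, 85, 70)) {
  write_fixture_pdb(path,
                    resid = c("ALA", "GLY", "TRP"),
                    elety = rep("CA", 3),
                    xyz = cbind(c(0, 3.8, 7.6), 0, 0),
                    b = b)
}

# a structure_model from a sequence with placeholder linear coordinates
seq_structure <- function(id, seq, spacing = 3.8, plddt = NULL) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  res <- data.frame(chain = "A", seq_index = seq_len(n), aa = aa,
                    resno_author = seq_len(n), insert_author = "",
                    x = spacing * (seq_len(n) - 1), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  if (!is.null(plddt)) res$plddt <- plddt
  new_structure_model(id, residues = res)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# full identity mapping helper
identity_mapping <- function(n) cbind(ref_idx = seq_len(n), mem_idx = seq_len(n))

# random rotation matrix (uniform via QR), deterministic under the caller's seed
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# single-helix and sheet blueprints used in several files
helix_blueprint <- function(len = 20) {
  list(segments = data.frame(type = "helix", length = len),
       pocket = c(2, 3))
}

sheet_blueprint <- function() {
  list(segments = data.frame(type = c("strand", "coil", "strand"),
                             length = c(8, 4, 8)),
       pocket = c(4, 5))
}

# evolve a small aligned orthogroup and return og + per-member mappings
aligned_orthogroup <- function(seed, spec = synthetic_spec(n_members = c(6, 6)),
                               ancestor = NULL, classes = NULL) {
  if (is.null(ancestor)) {
    ancestor <- build_toy_fold(default_blueprint(), seed = seed)
  }
  ev <- evolve_orthogroup(ancestor, spec, og_id = sprintf("og%d", seed),
                          seed = seed + 1, classes = classes)
  ref_id <- ev$og$reference_ids[1]
  maps <- list()
  for (id in setdiff(ev$og$member_ids, ref_id)) {
    aln <- tryCatch(align_and_map(ev$og$structures[[ref_id]],
                                  ev$og$structures[[id]]),
                    error = function(e) NULL)
    if (!is.null(aln)) maps[[id]] <- aln$mapping
  }
  list(og = ev$og, truth = ev$truth, mappings = maps, ancestor = ancestor)
}
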