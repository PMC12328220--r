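atom_structure <- function(elements, xyz, aa = NULL, elety = NULL) {
  n_res <- nrow(xyz)
  if (is.null(aa)) aa <- rep("G", n_res)
  if (is.null(elety)) elety <- rep("CA", n_res)
  res <- data.frame(chain = "A", seq_index = seq_len(n_res), aa = aa,
                    resno_author = seq_len(n_res), insert_author = "",
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  atoms <- data.frame(seq_index = seq_len(n_res), elety = elety,
                      element = elements, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  new_structure_model("atoms", residues = res, atoms = atoms)
}

test_that("SASA matches the analytic sphere and is additive when disjoint", {
  s1 <- atom_structure("C", cbind(0, 0, 0))
  sasa <- shrake_rupley_sasa(s1)
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(sasa[[1]] - analytic) / analytic, 0.01)

  ## two atoms beyond the sum of solvated radii: no occlusion
  s2 <- atom_structure(c("C", "C"), cbind(c(0, 10), 0, 0))
  sasa2 <- shrake_rupley_sasa(s2)
  expect_equal(unname(sum(sasa2)), 2 * analytic, tolerance = 0.01 * analytic)

  ## no atom ever exceeds its isolated-sphere area
  set.seed(3)
  s3 <- atom_structure(rep("C", 12), matrix(rnorm(36, sd = 2.5), 12, 3))
  a3 <- attr(shrake_rupley_sasa(s3), "atom_sasa")
  expect_true(all(a3 <= analytic + 1e-9))

  expect_error(shrake_rupley_sasa(seq_structure("x", "AAA")), "atoms")
})

test_that("SASA self-converges with lattice density", {
  set.seed(11)
  xyz <- matrix(rnorm(45, sd = 2), 15, 3)
  s <- atom_structure(rep(c("C", "N", "O"), 5), xyz)
  lo <- attr(shrake_rupley_sasa(s, n_points = 960), "atom_sasa")
  hi <- attr(shrake_rupley_sasa(s, n_points = 10000), "atom_sasa")
  ## per-atom error as a fraction of the atom's full solvated sphere (the
  ## scale on which the lattice quantises area)
  radii <- c(C = 1.7, N = 1.55, O = 1.52)
  sphere <- 4 * pi * (radii[rep(c("C", "N", "O"), 5)] + 1.4)^2
  expect_lt(max(abs(lo - hi) / sphere), 0.02)
})

test_that("relative SASA partitions residues into surface and core", {
  ## an isolated glycine C-alpha has rSASA near (or above) 1
  out <- relative_sasa(c(120.8), "G")
  expect_gt(out$rsasa, 0.9)
  expect_equal(out$exposure, "surface")

  expect_equal(relative_sasa(0, "A")$exposure, "core")
  ## 'X' falls back to the raw-area rule
  expect_equal(relative_sasa(30, "X")$exposure, "surface")
  expect_equal(relative_sasa(10, "X")$exposure, "core")

  ## partition is total on a real fold, and the split is monotone in the
  ## threshold (sensitivity at 0.20 / 0.25 / 0.30)
  s <- build_toy_fold(default_blueprint(), seed = 41)
  sasa <- shrake_rupley_sasa(s)
  rs <- relative_sasa(sasa, s$residues$aa)
  expect_true(all(rs$exposure %in% c("surface", "core")))
  surf_at <- function(th) relative_sasa(sasa, s$residues$aa,
                                        surface_threshold = th)$exposure == "surface"
  expect_true(all(surf_at(0.25)[surf_at(0.30)]))
  expect_true(all(surf_at(0.20)[surf_at(0.25)]))
})

test_that("the conservation hierarchy is insensitive to the surface threshold", {
  fx <- aligned_orthogroup(42, synthetic_spec(n_members = c(8, 8)))
  sasa <- shrake_rupley_sasa(fx$ancestor)
  pocket <- attr(fx$ancestor, "pocket")
  for (th in c(0.20, 0.25, 0.30)) {
    cls <- ifelse(relative_sasa(sasa, fx$ancestor$residues$aa,
                                surface_threshold = th)$exposure == "surface",
                  "surface", "core")
    cls[pocket] <- "bind"
    crs <- vapply(c("bind", "core", "surface"), function(k)
      cr_by_feature(fx$og, fx$mappings, which(cls == k)), numeric(1))
    expect_true(crs[["bind"]] > crs[["core"]],
                label = sprintf("bind > core at threshold %.2f", th))
    expect_true(crs[["core"]] > crs[["surface"]],
                label = sprintf("core > surface at threshold %.2f", th))
  }
})

test_that("ideal helices are assigned helix over their interiors", {
  s <- build_toy_fold(helix_blueprint(20), seed = 1)
  ss <- assign_secondary_structure(s)
  expect_equal(attr(ss, "method"), "hbond")
  expect_gte(mean(ss == "helix"), 0.8)
  expect_true(all(ss %in% c("helix", "extended", "turn", "coil")))
})

test_that("antiparallel strand pairs are extended where the oracle H-bonds", {
  s <- build_toy_fold(sheet_blueprint(), seed = 2)
  ss <- assign_secondary_structure(s)
  ## interiors of both strands are majority extended
  expect_gte(mean(ss[3:6] == "extended"), 0.5)
  expect_gte(mean(ss[15:18] == "extended"), 0.5)

  ## independent H-bond enumeration: inter-strand bonds must exist, and
  ## every extended residue sits within one residue of an H-bond partner
  get_bb <- function(s, name) {
    a <- s$atoms[s$atoms$elety == name, ]
    as.matrix(a[order(a$seq_index), c("x", "y", "z")])
  }
  E <- oracle_hbond_energy(get_bb(s, "N"), get_bb(s, "CA"),
                           get_bb(s, "C"), get_bb(s, "O"))
  hb <- E < -0.5
  inter <- hb[1:8, 13:20] | t(hb[13:20, 1:8])
  expect_gt(sum(inter), 0)
  bonded <- which(rowSums(hb) + colSums(hb) > 0)
  near_bond <- sort(unique(c(bonded - 1, bonded, bonded + 1)))
  expect_true(all(which(ss == "extended") %in% near_bond))
})

test_that("an isolated extended chain has no partners and stays coil", {
  bb <- list(segments = data.frame(type = "strand", length = 10),
             pocket = c(2, 3))
  s <- build_toy_fold(bb, seed = 3)
  ss <- assign_secondary_structure(s)
  expect_true(all(ss %in% c("coil", "turn")))
})

test_that("chains shorter than five residues are all coil", {
  s <- seq_structure("short", "ACD")
  expect_equal(as.character(assign_secondary_structure(s)), rep("coil", 3))
})

test_that("CSb flags follow ligand proximity and grow with the cutoff", {
  s <- seq_structure("x", "AAAAA")  # C-alphas at x = 0, 3.8, ..., 15.2
  s$atoms <- data.frame(seq_index = 1:5, elety = "CA", element = "C",
                        x = s$residues$x, y = 0, z = 0)
  s$ligand_atoms <- data.frame(resid = "LIG", resno = 1, elety = "C1",
                               element = "C", x = 0, y = 3, z = 0)
  fl <- csb_binding_sites(s, distance_cutoff = 5.0)
  expect_true(fl[1])            # 3.0 A away
  expect_true(fl[2])            # 4.84 A away, still below the cutoff
  expect_false(fl[3])           # 8.2 A away
  ## monotone in cutoff
  for (cut in c(3, 5, 8, 12)) {
    f1 <- csb_binding_sites(s, cut)
    f2 <- csb_binding_sites(s, cut + 2)
    expect_true(all(f2[f1]))
  }
  ## excluded additives do not count as ligands
  s$ligand_atoms$resid <- "HOH"
  expect_warning(fl2 <- csb_binding_sites(s), "no ligands")
  expect_false(any(fl2))
})

test_that("planted ligands flag the pocket neighbourhood exactly", {
  s <- plant_ligand(build_toy_fold(default_blueprint(), seed = 5))
  fl <- csb_binding_sites(s, distance_cutoff = 5.0)
  ## oracle: brute-force distance scan over atoms x ligand atoms
  lig <- s$ligand_atoms
  expected <- rep(FALSE, nrow(s$residues))
  for (i in seq_len(nrow(s$atoms))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt(sum((unlist(s$atoms[i, c("x", "y", "z")]) -
                       unlist(lig[j, c("x", "y", "z")]))^2))
      if (d <= 5.0) expected[s$atoms$seq_index[i]] <- TRUE
    }
  }
  expect_equal(fl, expected)
  ## the flagged set is dominated by the planted pocket
  pk <- attr(s, "pocket")
  expect_gte(sum(fl[pk]), length(pk) - 2)
})

test_that("UPb annotation joins through author numbering", {
  s <- seq_structure("prot1", "ACDEFGHIKL")
  ann <- data.frame(structure_id = "prot1", position = 10:12,
                    site_type = "substrate")
  ## positions 10:12 but the chain only has author numbers 1..10
  expect_warning(fl <- upb_binding_sites(s, ann), "skipped")
  expect_equal(which(fl$upb), 10L)
  expect_equal(attr(fl, "n_skipped"), 2L)

  ## empty table: all false
  fl2 <- upb_binding_sites(s, ann[0, ])
  expect_false(any(fl2$upb))

  ## author numbering with an offset (e.g. construct from a crystal that
  ## starts at 100): flags land on the right sequential indices
  s2 <- s
  s2$residues$resno_author <- 100:109
  ann2 <- data.frame(structure_id = "prot1", position = c(103, 105),
                     site_type = c("substrate", "metal"))
  fl3 <- upb_binding_sites(s2, ann2)
  expect_equal(which(fl3$upb), 4L)
  expect_equal(which(fl3$metal), 6L)
})

test_that("flags transfer through residue mappings with drops counted", {
  flags <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  mapping <- cbind(ref_idx = c(10, 11, 12), mem_idx = c(1, 2, 3))
  out <- transfer_flags(flags, mapping, n_target = 15)
  expect_equal(which(out), c(10L, 11L))
  expect_equal(attr(out, "n_dropped"), 1L)  # flagged member residue 4 unmapped
})

test_that("the full feature table assembles with exhaustive partitions", {
  s <- plant_ligand(build_toy_fold(default_blueprint(), seed = 6))
  ann <- data.frame(structure_id = s$structure_id, position = c(9, 10),
                    site_type = "substrate")
  f <- residue_features(s, upb_table = ann)
  expect_equal(nrow(f), nrow(s$residues))
  expect_true(all(f$exposure %in% c("surface", "core")))
  expect_true(all(f$ss_class %in% c("helix", "extended", "turn", "coil")))
  expect_equal(which(f$upb), c(9L, 10L))
  expect_true(any(f$csb))
})
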