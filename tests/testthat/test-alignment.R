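test_that("Kabsch superposition handles identity, known transforms and errors", {
  set.seed(7)
  A <- matrix(rnorm(30), 10, 3)
  sup <- kabsch_superpose(A, A)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  B <- sweep(A %*% t(Rz), 2, c(1, 2, 3), `+`)
  sup2 <- kabsch_superpose(A, B)
  expect_equal(sup2$rmsd, 0, tolerance = 1e-8)
  ## recovered rotation equals the applied one (row convention: B R = A)
  expect_equal(sup2$rotation, Rz, tolerance = 1e-6)
  expect_equal(apply_superposition(B, sup2), A, tolerance = 1e-8)

  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "insufficient")
  lin <- cbind(1:5, 0, 0)
  sup3 <- kabsch_superpose(lin, lin + 1)
  expect_true(sup3$degenerate)
  expect_equal(sup3$rmsd, 0, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches a rotation-grid oracle on random clouds", {
  set.seed(11)
  for (rep in 1:3) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    fit <- kabsch_superpose(A, B)
    oracle <- oracle_rmsd_grid(A, B)
    expect_lt(abs(fit$rmsd - oracle), 1e-2)
    expect_lte(fit$rmsd, oracle + 1e-9)  # least squares is optimal
  }
})

test_that("identity members map fully with perfect scores", {
  ref <- build_toy_fold(default_blueprint(), seed = 31, structure_id = "ref")
  mem <- ref; mem$structure_id <- "mem"
  aln <- align_and_map(ref, mem)
  expect_equal(nrow(aln$mapping), nrow(ref$residues))
  expect_equal(aln$rmsd_core, 0, tolerance = 1e-8)
  expect_equal(aln$tm_bidir, 1.0, tolerance = 1e-9)
})

test_that("terminal deletions leave the remaining residues mapped in register", {
  ref <- build_toy_fold(default_blueprint(), seed = 32, structure_id = "ref")
  mem <- ref
  mem$structure_id <- "mem"
  mem$residues <- mem$residues[-(1:6), , drop = FALSE]
  mem$residues$seq_index <- seq_len(nrow(mem$residues))
  mem$atoms <- mem$atoms[mem$atoms$seq_index > 6, , drop = FALSE]
  mem$atoms$seq_index <- mem$atoms$seq_index - 6L
  mem$sequence <- substr(ref$sequence, 7, nchar(ref$sequence))
  mem <- new_structure_model("mem", residues = mem$residues, atoms = mem$atoms)

  aln <- align_and_map(ref, mem)
  ## mapping covers reference residues 7..L in register
  expect_equal(sort(aln$mapping[, 1]), 7:nrow(ref$residues))
  expect_equal(aln$mapping[, 1], aln$mapping[, 2] + 6L)

  ## the member side is fully mapped; the reference's first 6 positions are
  ## unmapped in the profile
  og <- new_orthogroup("og", "ref", list(ref = ref, mem = mem))
  prof <- conservation_profile(og, list(mem = aln$mapping))
  expect_equal(prof$members$mr, 1.0)
  expect_equal(prof$residues$n_mapped[1:6], rep(0L, 6))
})

test_that("noisy members stay almost fully mapped", {
  ref <- build_toy_fold(default_blueprint(), seed = 33, structure_id = "ref")
  frac <- replicate(20, {
    noisy <- ref
    shift <- matrix(rnorm(3 * nrow(ref$residues), 0, 0.5),
                    nrow(ref$residues), 3)
    noisy$residues[, c("x", "y", "z")] <-
      noisy$residues[, c("x", "y", "z")] + shift
    noisy$atoms[, c("x", "y", "z")] <- noisy$atoms[, c("x", "y", "z")] +
      shift[noisy$atoms$seq_index, ]
    aln <- align_and_map(ref, noisy)
    nrow(aln$mapping) / nrow(ref$residues)
  })
  expect_gte(min(frac), 0.95)
})

test_that("TM-score follows its closed form", {
  ref <- seq_structure("r", strrep("A", 30))
  mem <- seq_structure("m", strrep("A", 30))
  idm <- identity_mapping(30)
  ident_sup <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                              rmsd = 0, n_pairs = 30), class = "superposition")
  expect_equal(tm_score(idm, ref, mem, ident_sup, "ref"), 1.0)

  ## every distance exactly d0 with full coverage -> 0.5
  d0 <- max(0.5, 1.24 * (30 - 15)^(1 / 3) - 1.8)
  mem2 <- mem
  mem2$residues$y <- mem2$residues$y + d0
  expect_equal(tm_score(idm, ref, mem2, ident_sup, "ref"), 0.5)

  ## 5-residue toy vs direct summation (d0 floored at 0.5)
  ref5 <- seq_structure("r5", "AAAAA")
  mem5 <- ref5
  dists <- c(0, 0.3, 0.5, 1.2, 2.0)
  mem5$residues$y <- dists
  expected <- sum(1 / (1 + (dists / 0.5)^2)) / 5
  expect_equal(tm_score(identity_mapping(5), ref5, mem5, ident_sup, "ref"),
               expected)
  expect_error(tm_score(idm[0, ], ref, mem, ident_sup), "empty")
})

test_that("bidirectional TM is symmetric and invariant to rigid transforms", {
  expect_equal(tm_bidirectional(0.8, 0.6), tm_bidirectional(0.6, 0.8))
  expect_equal(tm_bidirectional(0.8, 0.6, "min"), 0.6)

  ref <- build_toy_fold(default_blueprint(), seed = 34, structure_id = "a")
  spec <- synthetic_spec(n_members = c(2, 2), indel_prob = 0)
  ev <- evolve_orthogroup(ref, spec, seed = 9)
  mem <- ev$og$structures[[2]]
  aln1 <- align_and_map(ref, mem)
  aln2 <- align_and_map(mem, ref)
  expect_equal(aln1$tm_bidir, aln2$tm_bidir, tolerance = 1e-6)

  set.seed(5)
  R <- random_rotation()
  moved <- mem
  xyz <- as.matrix(moved$residues[, c("x", "y", "z")]) %*% t(R)
  moved$residues[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -3, 2), `+`)
  axyz <- as.matrix(moved$atoms[, c("x", "y", "z")]) %*% t(R)
  moved$atoms[, c("x", "y", "z")] <- sweep(axyz, 2, c(5, -3, 2), `+`)
  aln3 <- align_and_map(ref, moved)
  expect_equal(aln3$mapping, aln1$mapping)
  expect_equal(aln3$rmsd_core, aln1$rmsd_core, tolerance = 1e-6)
})

test_that("orthogroup refinement reproduces an average-linkage oracle", {
  ids <- paste0("s", 1:4)
  tm <- matrix(1, 4, 4, dimnames = list(ids, ids))
  expect_equal(unname(refine_orthogroups(tm)), rep(1L, 4))

  ## two separated blocks
  tm2 <- matrix(0.4, 4, 4, dimnames = list(ids, ids))
  tm2[1:2, 1:2] <- 0.95; tm2[3:4, 3:4] <- 0.95
  diag(tm2) <- 1
  cl <- refine_orthogroups(tm2, linkage_cutoff = 0.2)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(cl[["s1"]], cl[["s2"]])
  expect_false(cl[["s1"]] == cl[["s3"]])

  ## random matrices vs the from-first-principles oracle
  set.seed(13)
  for (rep in 1:10) {
    n <- 8
    D <- matrix(runif(n * n, 0, 0.6), n, n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    ids <- sprintf("x%02d", 1:n)
    dimnames(D) <- list(ids, ids)
    cl <- refine_orthogroups(1 - D, linkage_cutoff = 0.2)
    oracle <- oracle_average_linkage(D, 0.2)
    ## same partition (labels may differ): co-membership matrices agree
    expect_equal(length(unique(cl)), length(unique(oracle)))
    co1 <- outer(cl, cl, `==`)
    co2 <- outer(oracle, oracle, `==`)
    expect_equal(unname(co1), unname(co2))
  }

  bad <- matrix(c(1, 0.5, 0.2, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(refine_orthogroups(bad), "symmetric")

  ## identical structures are never separated at the 0.2 cutoff
  tm3 <- matrix(0.5, 3, 3); tm3[1, 2] <- tm3[2, 1] <- 1; diag(tm3) <- 1
  dimnames(tm3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cl3 <- refine_orthogroups(tm3, linkage_cutoff = 0.2)
  expect_equal(cl3[["a"]], cl3[["b"]])
})

test_that("iterative pruning never increases the core RMSD", {
  ref <- build_toy_fold(default_blueprint(), seed = 35, structure_id = "a")
  spec <- synthetic_spec(n_members = c(4, 4))
  ev <- evolve_orthogroup(ref, spec, seed = 3)
  for (id in ev$og$member_ids[-1]) {
    aln <- align_and_map(ref, ev$og$structures[[id]])
    ## final core rmsd is within the prune cutoff by construction
    expect_lte(aln$rmsd_core, 2.0)
  }
})
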