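make_profile_fixture <- function() {
  ## reference ACDEF; member1 fully mapped, identical at 3/5; member2 maps
  ## reference 2..5 with 4 of its 5 residues, identical at 2
  ref <- seq_structure("ref", "ACDEF")
  m1 <- seq_structure("m1", "ACDYW")          # identical at positions 1-3
  m2 <- seq_structure("m2", "GCDYW")          # maps ref 2:5 from mem 2:5
  og <- new_orthogroup("og1", "ref", list(ref = ref, m1 = m1, m2 = m2))
  maps <- list(m1 = identity_mapping(5),
               m2 = cbind(ref_idx = 2:5, mem_idx = 2:5))
  list(og = og, maps = maps)
}

test_that("MR/CR arithmetic matches the worked example", {
  fx <- make_profile_fixture()
  prof <- conservation_profile(fx$og, fx$maps)
  m <- prof$members
  expect_equal(m$cr[m$member_id == "m1"], 0.6)
  expect_equal(m$mr[m$member_id == "m1"], 1.0)
  expect_equal(m$M[m$member_id == "m2"], 4L)
  expect_equal(m$N[m$member_id == "m2"], 1L)
  expect_equal(m$mr[m$member_id == "m2"], 0.8)
  expect_equal(m$cr[m$member_id == "m2"], 0.5)
  expect_equal(prof$og_cr, 0.55)
  expect_equal(prof$og_mr, 0.9)

  ## per-residue tallies: position 2 (C) identical in both members
  expect_equal(prof$residues$n_identical[2], 2L)
  expect_true(prof$residues$fully_conserved[2])
  expect_false(prof$residues$fully_conserved[1])  # m2 does not map position 1
})

test_that("identity members give unit ratios and bookkeeping holds", {
  ref <- seq_structure("ref", "ACDEFGHIKL")
  m1 <- seq_structure("m1", "ACDEFGHIKL")
  og <- new_orthogroup("og", "ref", list(ref = ref, m1 = m1))
  prof <- conservation_profile(og, list(m1 = identity_mapping(10)))
  expect_equal(prof$members$mr, 1.0)
  expect_equal(prof$members$cr, 1.0)
  expect_true(all(prof$residues$fully_conserved))

  ## conservation bookkeeping identity on random orthogroups
  set.seed(99)
  for (rep in 1:5) {
    n <- 30
    ref_seq <- paste(sample(AA_CANONICAL, n, TRUE), collapse = "")
    ref <- seq_structure("ref", ref_seq)
    structures <- list(ref = ref)
    maps <- list()
    for (k in 1:4) {
      aa <- strsplit(ref_seq, "")[[1]]
      hit <- runif(n) < 0.3
      aa[hit] <- sample(AA_CANONICAL, sum(hit), TRUE)
      id <- paste0("m", k)
      structures[[id]] <- seq_structure(id, paste(aa, collapse = ""))
      keep <- sort(sample(n, n - sample(0:3, 1)))
      maps[[id]] <- cbind(ref_idx = keep, mem_idx = keep)
    }
    og <- new_orthogroup("og", "ref", structures)
    prof <- conservation_profile(og, maps)
    expect_equal(sum(prof$residues$n_identical), sum(prof$members$C))
    expect_equal(sum(prof$residues$n_mapped), sum(prof$members$M))
    ## naive double-loop CR oracle
    for (id in names(maps)) {
      mem_aa <- strsplit(structures[[id]]$sequence, "")[[1]]
      ref_aa <- strsplit(ref_seq, "")[[1]]
      cnt <- 0
      for (r in seq_len(nrow(maps[[id]]))) {
        if (ref_aa[maps[[id]][r, 1]] == mem_aa[maps[[id]][r, 2]]) cnt <- cnt + 1
      }
      expect_equal(prof$members$C[prof$members$member_id == id], cnt)
    }
  }
})

test_that("adding an identical member never decreases og_cr", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 20
    ref_seq <- paste(sample(AA_CANONICAL, n, TRUE), collapse = "")
    aa <- strsplit(ref_seq, "")[[1]]
    hit <- runif(n) < 0.5
    aa[hit] <- sample(AA_CANONICAL, sum(hit), TRUE)
    ref <- seq_structure("ref", ref_seq)
    m1 <- seq_structure("m1", paste(aa, collapse = ""))
    og1 <- new_orthogroup("og", "ref", list(ref = ref, m1 = m1))
    p1 <- conservation_profile(og1, list(m1 = identity_mapping(n)))
    m2 <- seq_structure("m2", ref_seq)
    og2 <- new_orthogroup("og", "ref", list(ref = ref, m1 = m1, m2 = m2))
    p2 <- conservation_profile(og2, list(m1 = identity_mapping(n),
                                         m2 = identity_mapping(n)))
    expect_gte(p2$og_cr, p1$og_cr)
    expect_true(p1$og_cr >= 0 && p1$og_cr <= 1)
    expect_true(p1$og_mr >= 0 && p1$og_mr <= 1)
  }
})

test_that("class-based CR dominates identity CR and honours the class map", {
  ## D -> E substitution is conserved by class, not by identity
  ref <- seq_structure("ref", "DDDDD")
  m1 <- seq_structure("m1", "EEEEE")
  og <- new_orthogroup("og", "ref", list(ref = ref, m1 = m1))
  maps <- list(m1 = identity_mapping(5))
  prof <- conservation_profile(og, maps)
  expect_equal(prof$og_cr, 0)
  expect_equal(cr_by_class(og, maps), 1.0)

  ## identity member: class CR is 1
  m2 <- seq_structure("m1", "DDDDD")
  og2 <- new_orthogroup("og", "ref", list(ref = ref, m1 = m2))
  expect_equal(cr_by_class(og2, maps), 1.0)

  ## property: class CR >= identity CR on random members
  set.seed(23)
  for (rep in 1:100) {
    n <- 25
    ref_seq <- paste(sample(AA_CANONICAL, n, TRUE), collapse = "")
    aa <- strsplit(ref_seq, "")[[1]]
    hit <- runif(n) < runif(1, 0.1, 0.8)
    aa[hit] <- sample(AA_CANONICAL, sum(hit), TRUE)
    og <- new_orthogroup("og", "ref",
                         list(ref = seq_structure("ref", ref_seq),
                              m1 = seq_structure("m1", paste(aa, collapse = ""))))
    maps <- list(m1 = identity_mapping(n))
    expect_gte(cr_by_class(og, maps),
               conservation_profile(og, maps)$og_cr - 1e-12)
  }
})

test_that("hydrophobicity change is exact for single substitutions", {
  logp <- aa_lookup("logp")
  ref <- seq_structure("ref", "AAAAA")
  m_id <- seq_structure("m1", "AAAAA")
  og <- new_orthogroup("og", "ref", list(ref = ref, m1 = m_id))
  maps <- list(m1 = identity_mapping(5))
  expect_equal(mean_hydrophobicity_change(og, maps), 0)

  m_sub <- seq_structure("m1", "AWAAA")
  og2 <- new_orthogroup("og", "ref", list(ref = ref, m1 = m_sub))
  expect_equal(mean_hydrophobicity_change(og2, maps),
               abs(logp[["A"]] - logp[["W"]]))
})

test_that("hydrophobicity change runs inversely to conservation", {
  set.seed(31)
  crs <- dlogp <- numeric(0)
  for (rate in seq(0.05, 0.8, length.out = 20)) {
    n <- 40
    ref_seq <- paste(sample(AA_CANONICAL, n, TRUE), collapse = "")
    structures <- list(ref = seq_structure("ref", ref_seq))
    maps <- list()
    for (k in 1:5) {
      aa <- strsplit(ref_seq, "")[[1]]
      hit <- runif(n) < rate
      for (i in which(hit)) aa[i] <- sample(setdiff(AA_CANONICAL, aa[i]), 1)
      id <- paste0("m", k)
      structures[[id]] <- seq_structure(id, paste(aa, collapse = ""))
      maps[[id]] <- identity_mapping(n)
    }
    og <- new_orthogroup("og", "ref", structures)
    crs <- c(crs, conservation_profile(og, maps)$og_cr)
    dlogp <- c(dlogp, mean_hydrophobicity_change(og, maps))
  }
  expect_lt(cor(crs, dlogp, method = "spearman"), 0)
})

test_that("feature-restricted CR behaves consistently", {
  fx <- make_profile_fixture()
  prof <- conservation_profile(fx$og, fx$maps)
  expect_equal(cr_by_feature(fx$og, fx$maps, 1:5), prof$og_cr)

  ## subset where every member is identical (positions 2:3, C and D)
  expect_equal(cr_by_feature(fx$og, fx$maps, 2:3), 1.0)

  ## empty subset reports missing
  out <- cr_by_feature(fx$og, fx$maps, integer(0))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "empty")
})

test_that("species deduplication keeps the best-mapping paralogue", {
  ref <- seq_structure("sc_ref", "ACDEF")
  a1 <- seq_structure("sp1_a", "ACDEF")
  a2 <- seq_structure("sp1_b", "ACDEF")
  og <- new_orthogroup("og", "sc_ref",
                       list(sc_ref = ref, sp1_a = a1, sp1_b = a2))
  maps <- list(sp1_a = identity_mapping(5),
               sp1_b = cbind(ref_idx = 1:3, mem_idx = 1:3))
  prof <- conservation_profile(og, maps)
  dd <- dedupe_species(prof)
  expect_equal(dd$members$member_id, "sp1_a")  # higher MR representative
  expect_equal(dd$og_mr, 1.0)
})
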