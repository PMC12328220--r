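chain_profile <- function(n, conserved) {
  ## minimal profile/reference pair: consecutive C-alphas 3.8 A apart
  ref <- seq_structure("ref", strrep("A", n))
  prof <- list(og_id = "og", reference_id = "ref",
               residues = data.frame(ref_idx = seq_len(n), aa = "A",
                                     n_mapped = 1L, n_identical = 1L,
                                     fully_conserved = seq_len(n) %in% conserved))
  class(prof) <- "conservation_profile"
  list(prof = prof, ref = ref)
}

test_that("the conserved contact network matches brute-force distances", {
  fx <- chain_profile(5, 1:5)
  net <- conserved_network(fx$prof, fx$ref, contact_cutoff = 10)
  ## 3.8 A spacing: |i - j| <= 2 within 10 A
  expected <- t(combn(1:5, 2))
  expected <- expected[(expected[, 2] - expected[, 1]) * 3.8 <= 10, ]
  expect_equal(net$edges[order(net$edges[, 1], net$edges[, 2]), ],
               expected[order(expected[, 1], expected[, 2]), ],
               ignore_attr = TRUE)

  ## no conserved residues: an empty network is valid
  net0 <- conserved_network(chain_profile(5, integer(0))$prof, fx$ref)
  expect_equal(length(net0$nodes), 0L)
  expect_equal(nrow(net0$edges), 0L)

  ## random conserved subsets on a toy fold vs a naive O(n^2) scan
  s <- build_toy_fold(default_blueprint(), seed = 51)
  set.seed(4)
  for (rep in 1:5) {
    cons <- sort(sample(nrow(s$residues), 25))
    fx2 <- chain_profile(nrow(s$residues), cons)
    net2 <- conserved_network(fx2$prof, s)
    xyz <- ca_coords(s)
    brute <- list()
    for (a in seq_along(cons)) {
      for (b in seq_along(cons)) {
        if (b <= a) next
        if (sqrt(sum((xyz[cons[a], ] - xyz[cons[b], ])^2)) <= 10) {
          brute[[length(brute) + 1]] <- c(cons[a], cons[b])
        }
      }
    }
    brute <- do.call(rbind, brute)
    expect_equal(net2$edges[order(net2$edges[, 1], net2$edges[, 2]), ],
                 brute[order(brute[, 1], brute[, 2]), ], ignore_attr = TRUE)
  }
})

test_that("clusters are connected components above the size floor", {
  net <- list(nodes = c(1:3, 10:12),
              edges = rbind(c(1, 2), c(2, 3), c(1, 3),
                            c(10, 11), c(11, 12), c(10, 12)))
  cl <- find_clusters(net)
  expect_equal(length(cl$clusters), 2L)
  expect_equal(cl$clusters[[1]], 1:3)
  expect_equal(cl$clusters[[2]], 10:12)

  ## singletons below the floor vanish but are counted
  net2 <- list(nodes = c(1, 5, 9), edges = matrix(integer(0), 0, 2))
  cl2 <- find_clusters(net2, min_cluster_size = 3)
  expect_equal(length(cl2$clusters), 0L)
  expect_equal(cl2$n_discarded, 3L)

  ## random graphs vs a DFS oracle
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    nodes <- sort(sample(1:100, n))
    m <- sample(0:(2 * n), 1)
    edges <- if (m > 0) {
      e <- t(replicate(m, sort(sample(nodes, 2))))
      e[e[, 1] != e[, 2], , drop = FALSE]
    } else matrix(integer(0), 0, 2)
    cl <- find_clusters(list(nodes = nodes, edges = edges),
                        min_cluster_size = 1)
    oracle <- oracle_components_dfs(nodes, edges)
    expect_equal(cl$clusters[order(vapply(cl$clusters, min, integer(1)))],
                 lapply(oracle, as.integer))
  }
})

test_that("cluster membership survives node order and rigid transforms", {
  s <- build_toy_fold(default_blueprint(), seed = 52)
  cons <- c(attr(s, "pocket"), 15, 16, 17)
  fx <- chain_profile(nrow(s$residues), cons)
  cl1 <- find_clusters(conserved_network(fx$prof, s))

  set.seed(9)
  R <- random_rotation()
  s2 <- s
  xyz <- as.matrix(s2$residues[, c("x", "y", "z")]) %*% t(R)
  s2$residues[, c("x", "y", "z")] <- sweep(xyz, 2, c(10, -4, 6), `+`)
  cl2 <- find_clusters(conserved_network(fx$prof, s2))
  expect_equal(cl1$clusters, cl2$clusters)
})

test_that("site overlap statistics follow their definitions", {
  s <- build_toy_fold(default_blueprint(), seed = 53)
  n <- nrow(s$residues)
  pocket <- attr(s, "pocket")
  fx <- chain_profile(n, pocket)
  net <- conserved_network(fx$prof, s)
  cl <- find_clusters(net)
  flags <- seq_len(n) %in% pocket

  ov <- cluster_site_overlap(cl, flags, s, fx$prof)
  expect_equal(ov$pct_sites_covered, 100)
  expect_equal(ov$enrichment_ratio, 1 / mean(flags))
  expect_equal(ov$pct_clusters_without_site, 0)

  ## clusters disjoint from all sites
  other <- setdiff(15:25, pocket)
  fx2 <- chain_profile(n, other)
  cl2 <- find_clusters(conserved_network(fx2$prof, s))
  ov2 <- cluster_site_overlap(cl2, flags, s, fx2$prof)
  expect_equal(ov2$pct_sites_covered, 0)

  ## no flagged sites: statistics undefined
  expect_warning(ov3 <- cluster_site_overlap(cl, rep(FALSE, n), s, fx$prof),
                 "no flagged")
  expect_true(is.na(ov3$enrichment_ratio))
})

test_that("coverage is monotone in contact cutoff and cluster-size floor", {
  fx <- aligned_orthogroup(61, synthetic_spec(n_members = c(8, 8),
                                              p_core = 0.4, p_surf = 0.4,
                                              indel_prob = 0))
  prof <- conservation_profile(fx$og, fx$mappings)
  ref <- fx$og$structures[[fx$og$reference_ids[1]]]
  flags <- seq_len(nrow(ref$residues)) %in% fx$truth$pocket
  cov_at <- function(cutoff, min_size) {
    cl <- find_clusters(conserved_network(prof, ref, cutoff), min_size)
    suppressWarnings(
      cluster_site_overlap(cl, flags, ref, prof)$pct_sites_covered)
  }
  expect_lte(cov_at(6, 3) %||% 0, cov_at(10, 3) %||% 0)
  expect_gte(cov_at(10, 1) %||% 0, cov_at(10, 5) %||% 0)
})

test_that("the cluster classifier separates, and its nulls hover at chance", {
  ## separable construction: one feature fully determines the label
  set.seed(10)
  n <- 150
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(size = sample(3:20, n, TRUE),
                  mean_rsasa = runif(n),
                  mean_cost = ifelse(y == 1, 2, -2) + rnorm(n, 0, 0.05),
                  contact_density = runif(n))
  res <- classify_clusters(X, y, n_repeats = 10, k = 5, seed = 2)
  expect_gte(res$model$balanced_accuracy, 0.95)
  expect_gte(res$model$auc, 0.95)

  ## permuted labels: AUC within 3 SE of 0.5
  perm_auc <- res$permuted_labels$per_fold$auc
  se <- sd(perm_auc) / sqrt(length(perm_auc))
  expect_lt(abs(mean(perm_auc) - 0.5), 3 * se + 0.05)

  expect_error(classify_clusters(X, rep(1, n)), "single-class")
  few <- c(1:5, (n / 2 + 1):(n / 2 + 5))   # both classes, too few clusters
  expect_error(classify_clusters(X[few, ], y[few]), ">= 20")
})

test_that("cluster feature vectors summarise their members", {
  s <- build_toy_fold(default_blueprint(), seed = 54)
  f <- residue_features(s, csb = FALSE)
  cl <- structure(list(clusters = list(1:5, 30:40),
                       sizes = c(5L, 11L), n_discarded = 0L,
                       n_nodes = 16L, edges = NULL),
                  class = "conserved_cluster_set")
  X <- cluster_feature_matrix(cl, f, s)
  expect_equal(nrow(X), 2L)
  expect_equal(X$size, c(5, 11))
  expect_equal(X$mean_rsasa[1], mean(f$rsasa[1:5]))
  ## ss fractions sum to one
  expect_equal(rowSums(X[, c("helix", "extended", "turn", "coil")]),
               c(1, 1), tolerance = 1e-9)
})
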