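## Validation studies on planted ground truth. Each function runs a
## self-contained simulation study end to end (generate -> align -> measure)
## and returns the per-run results plus summary rates; the acceptance script
## and the analysis drivers report these numbers.

.align_og <- function(og) {
  ref_id <- og$reference_ids[1]
  maps <- list()
  for (id in setdiff(og$member_ids, ref_id)) {
    aln <- tryCatch(align_and_map(og$structures[[ref_id]],
                                  og$structures[[id]]),
                    error = function(e) NULL)
    if (!is.null(aln)) maps[[id]] <- aln$mapping
  }
  maps
}

## pooled identical/mapped counts within a reference-residue subset
.class_counts <- function(og, maps, subset_idx, reference_id) {
  ref_aa <- strsplit(og$structures[[reference_id]]$sequence, "")[[1]]
  identical_n <- mapped_n <- 0L
  for (id in names(maps)) {
    map <- maps[[id]]
    map <- map[map[, 1] %in% subset_idx, , drop = FALSE]
    mem_aa <- strsplit(og$structures[[id]]$sequence, "")[[1]]
    mapped_n <- mapped_n + nrow(map)
    identical_n <- identical_n + sum(ref_aa[map[, 1]] == mem_aa[map[, 2]])
  }
  c(identical = identical_n, mapped = mapped_n)
}

#' Planted-hierarchy recovery study
#'
#' Simulates orthogroups under the class-dependent substitution rates
#' (binding < core < surface), runs the alignment and conservation pipeline,
#' and measures the class-restricted CR against the planted rates. Reports
#' the per-seed class CRs, the fraction of seeds recovering the ordering
#' CR(binding) > CR(core) > CR(surface), and pooled per-class counts for
#' comparison with the binomial expectation 1 - p.
#'
#' @param n_seeds number of simulated orthogroups.
#' @param n_members members per orthogroup (default 10).
#' @param spec synthetic_spec carrying the planted rates.
#' @param seed master seed.
#' @return list: per_seed (data.frame), hierarchy_rate, pooled (per-class
#'   identical/mapped counts), cr_pooled, expected (1 - p per class).
#' @export
study_planted_hierarchy <- function(n_seeds = 100, n_members = 10,
                                    spec = synthetic_spec(), seed = 1) {
  rows <- vector("list", n_seeds)
  pooled <- list(bind = c(identical = 0L, mapped = 0L),
                 core = c(identical = 0L, mapped = 0L),
                 surface = c(identical = 0L, mapped = 0L))
  for (s in seq_len(n_seeds)) {
    anc <- build_toy_fold(spec$blueprint, seed = derive_seed(seed, 10000, s))
    ev <- evolve_orthogroup(anc, spec, og_id = sprintf("og%03d", s),
                            seed = derive_seed(seed, 20000, s), n_members = n_members)
    maps <- .align_og(ev$og)
    ref_id <- ev$og$reference_ids[1]
    crs <- numeric(3); names(crs) <- c("bind", "core", "surface")
    for (k in names(crs)) {
      idx <- which(ev$truth$classes == k)
      cnt <- .class_counts(ev$og, maps, idx, ref_id)
      pooled[[k]] <- pooled[[k]] + cnt
      crs[k] <- if (cnt[["mapped"]] > 0) cnt[["identical"]] / cnt[["mapped"]] else NA
    }
    rows[[s]] <- data.frame(seed = s, cr_bind = crs[["bind"]],
                            cr_core = crs[["core"]],
                            cr_surface = crs[["surface"]])
  }
  per_seed <- do.call(rbind, rows)
  ok <- per_seed$cr_bind > per_seed$cr_core &
    per_seed$cr_core > per_seed$cr_surface
  list(per_seed = per_seed,
       hierarchy_rate = mean(ok),
       pooled = pooled,
       cr_pooled = vapply(pooled, function(x) x[["identical"]] / x[["mapped"]],
                          numeric(1)),
       expected = c(bind = 1 - spec$p_bind, core = 1 - spec$p_core,
                    surface = 1 - spec$p_surf))
}

#' Planted-pocket cluster recovery study
#'
#' Evolves orthogroups with a strongly conserved pocket against a uniform
#' background rate, detects clusters of fully conserved residues on the
#' 10 Angstrom contact graph, and measures how well the best cluster
#' recovers the planted pocket (Jaccard), whether the pocket site is
#' covered by a cluster, and the binding-site enrichment among fully
#' conserved residues.
#'
#' @param n_seeds number of simulated orthogroups.
#' @param n_members members per orthogroup.
#' @param p_background uniform core/surface substitution rate (default 0.4).
#' @param p_bind pocket substitution rate (default 0.02).
#' @param seed master seed.
#' @return list: per_seed (jaccard, covered, enrichment_ratio, n_clusters,
#'   median_cluster_size), jaccard_rate (fraction with Jaccard >= 0.6),
#'   coverage_rate, enrichment_rate (fraction with ratio > 1).
#' @export
study_cluster_recovery <- function(n_seeds = 100, n_members = 10,
                                   p_background = 0.4, p_bind = 0.02,
                                   seed = 1) {
  spec <- synthetic_spec(p_bind = p_bind, p_core = p_background,
                         p_surf = p_background)
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    anc <- build_toy_fold(spec$blueprint, seed = derive_seed(seed, 30000, s))
    ev <- evolve_orthogroup(anc, spec, og_id = sprintf("og%03d", s),
                            seed = derive_seed(seed, 40000, s), n_members = n_members)
    maps <- .align_og(ev$og)
    prof <- conservation_profile(ev$og, maps)
    ref <- ev$og$structures[[ev$og$reference_ids[1]]]
    cl <- find_clusters(conserved_network(prof, ref))
    pocket <- ev$truth$pocket
    jac <- if (length(cl$clusters)) {
      max(vapply(cl$clusters, function(x)
        length(intersect(x, pocket)) / length(union(x, pocket)), numeric(1)))
    } else 0
    flags <- seq_len(nrow(ref$residues)) %in% pocket
    ov <- suppressWarnings(cluster_site_overlap(cl, flags, ref, prof))
    rows[[s]] <- data.frame(seed = s, jaccard = jac,
                            covered = isTRUE(ov$pct_sites_covered == 100),
                            enrichment_ratio = ov$enrichment_ratio,
                            n_clusters = length(cl$clusters),
                            median_cluster_size =
                              if (length(cl$sizes)) stats::median(as.numeric(cl$sizes)) else NA_real_)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       jaccard_rate = mean(per_seed$jaccard >= 0.6),
       coverage_rate = mean(per_seed$covered),
       enrichment_rate = mean(per_seed$enrichment_ratio > 1, na.rm = TRUE))
}

#' Null calibration of the statistics layer
#'
#' Type-I error of the Mann-Whitney and signed-rank tests on equal
#' distributions, the significant fraction of BH-adjusted quartile
#' enrichment under independent random set membership, and the permuted-label
#' AUC distribution.
#'
#' @param n_null null replicates for the rank tests and enrichment (200).
#' @param n_perm label permutations for the AUC null (1000).
#' @param n_group sample size per group in the rank-test nulls.
#' @param seed master seed.
#' @return list with mw_type1, signed_rank_type1, bh_fp_fraction,
#'   null_auc_mean, null_auc_se.
#' @export
study_calibration <- function(n_null = 200, n_perm = 1000, n_group = 20,
                              seed = 1) {
  set.seed(seed)
  mw <- replicate(n_null, {
    group_compare(stats::rnorm(n_group), stats::rnorm(n_group))$p_value
  })
  sr <- replicate(n_null, {
    group_compare(stats::rnorm(n_group), stats::rnorm(n_group),
                  paired = TRUE)$p_value
  })
  bh_sig <- bh_tot <- 0
  for (r in seq_len(n_null)) {
    values <- stats::setNames(stats::rnorm(40), sprintf("og%02d", 1:40))
    membership <- lapply(1:10, function(i) sample(names(values), 8))
    names(membership) <- sprintf("set%02d", 1:10)
    res <- quartile_enrichment(values, membership, tail = "top25")
    bh_sig <- bh_sig + sum(res$p_adjusted < 0.05)
    bh_tot <- bh_tot + nrow(res)
  }
  scores <- stats::rnorm(40)
  labels <- rep(c(0, 1), 20)
  aucs <- replicate(n_perm, roc_enrichment(scores, sample(labels))$auc)
  list(mw_type1 = mean(mw < 0.05),
       signed_rank_type1 = mean(sr < 0.05),
       bh_fp_fraction = bh_sig / bh_tot,
       null_auc_mean = mean(aucs),
       null_auc_se = stats::sd(aucs) / sqrt(n_perm))
}

#' Coupling sign-recovery study
#'
#' Generates corpora whose orthogroups span a range of substitution rates,
#' draws property tables from the spec couplings, and checks that the
#' association layer recovers the planted signs (abundance-CR positive,
#' flux-variability-CR negative, kcat-variability-CR negative) and stays
#' quiet when the couplings are switched off.
#'
#' @param n_runs simulation runs (50).
#' @param n_og orthogroups per run (20).
#' @param seed master seed.
#' @param null_beta run with all coupling slopes set to zero instead.
#' @return list: per_run data.frame of correlation estimates and p-values,
#'   sign_rate_abundance, sign_rate_flux_cv, sign_rate_kcat (or, for the
#'   null, reject rates at alpha = 0.05).
#' @export
study_couplings <- function(n_runs = 50, n_og = 20, seed = 1,
                            null_beta = FALSE) {
  base <- synthetic_spec()
  spec <- if (null_beta) {
    synthetic_spec(abundance = utils::modifyList(base$abundance, list(beta = 0)),
                   flux_cv = utils::modifyList(base$flux_cv, list(beta = 0)),
                   kcat_log_sd = utils::modifyList(base$kcat_log_sd, list(beta = 0)))
  } else base
  anc <- build_toy_fold(spec$blueprint, seed = seed)
  cls <- residue_classes(anc)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, 50000, r))
    scales <- stats::runif(n_og, spec$og_rate_range[1], spec$og_rate_range[2])
    corpus <- list()
    for (g in seq_len(n_og)) {
      ev <- evolve_orthogroup(anc, spec, og_id = sprintf("og%03d", g),
                              seed = derive_seed(seed, 60000, r * 100 + g),
                              classes = cls, rate_scale = scales[g])
      corpus[[ev$og$og_id]] <- list(og = ev$og, truth = ev$truth)
    }
    attr(corpus, "ec_class") <- stats::setNames(rep_len(1:7, n_og),
                                                names(corpus))
    attr(corpus, "pathways") <- stats::setNames(
      sprintf("pw%d", rep_len(1:5, n_og)), names(corpus))
    props <- generate_property_tables(corpus, spec,
                                      seed = derive_seed(seed, 70000, r))
    ab <- correlate(props$abundance_log2, props$cr_true, "spearman")
    fc <- correlate(props$flux_cv, props$cr_true, "spearman")
    kc <- correlate(props$kcat_log_sd, props$cr_true, "spearman")
    rows[[r]] <- data.frame(run = r,
                            rho_abundance = ab$estimate, p_abundance = ab$p_value,
                            rho_flux_cv = fc$estimate, p_flux_cv = fc$p_value,
                            rho_kcat = kc$estimate, p_kcat = kc$p_value)
  }
  per_run <- do.call(rbind, rows)
  if (null_beta) {
    list(per_run = per_run,
         reject_rate_abundance = mean(per_run$p_abundance < 0.05),
         reject_rate_flux_cv = mean(per_run$p_flux_cv < 0.05),
         reject_rate_kcat = mean(per_run$p_kcat < 0.05))
  } else {
    list(per_run = per_run,
         sign_rate_abundance = mean(per_run$rho_abundance > 0),
         sign_rate_flux_cv = mean(per_run$rho_flux_cv < 0),
         sign_rate_kcat = mean(per_run$rho_kcat < 0))
  }
}

## random connected residue subset of a given size on the contact graph
.random_connected_subset <- function(ref, size, contact_cutoff = 10) {
  xyz <- ca_coords(ref)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= contact_cutoff
  diag(adj) <- FALSE
  start <- sample(n, 1)
  members <- start
  frontier <- which(adj[start, ])
  while (length(members) < size && length(frontier) > 0) {
    nxt <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    members <- c(members, nxt)
    frontier <- setdiff(unique(c(frontier, which(adj[nxt, ]))), members)
  }
  sort(members)
}

#' Cluster-classifier study on planted ground truth
#'
#' Per seed, builds a small corpus where positive examples are conserved
#' clusters grown around the planted pocket and negative examples are
#' random connected residue subsets with a matched size range, then runs
#' the gradient-boosted cluster classifier with both null baselines on the
#' shared feature representation.
#'
#' @param n_seeds simulation seeds (20).
#' @param n_ancestors distinct folds per seed (3).
#' @param ogs_per_ancestor evolved orthogroups per fold (3).
#' @param n_members members per orthogroup (8).
#' @param p_background uniform background substitution rate (0.4).
#' @param seed master seed.
#' @return list: per_seed (model/baseline balanced accuracy and AUC),
#'   beats_baselines_rate.
#' @export
study_classifier <- function(n_seeds = 20, n_ancestors = 3,
                             ogs_per_ancestor = 3, n_members = 8,
                             p_background = 0.4, seed = 1) {
  spec <- synthetic_spec(p_core = p_background, p_surf = p_background)
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    X <- NULL; y <- integer(0)
    for (a in seq_len(n_ancestors)) {
      anc <- build_toy_fold(spec$blueprint,
                            seed = derive_seed(seed, 80000, s * 100 + a))
      feats <- residue_features(anc, csb = FALSE)
      pocket <- attr(anc, "pocket")
      sizes <- integer(0)
      for (g in seq_len(ogs_per_ancestor)) {
        ev <- evolve_orthogroup(anc, spec,
                                og_id = sprintf("s%da%dg%d", s, a, g),
                                seed = derive_seed(seed, 90000, s * 1000 + a * 10 + g),
                                n_members = n_members)
        maps <- .align_og(ev$og)
        prof <- conservation_profile(ev$og, maps)
        ref <- ev$og$structures[[ev$og$reference_ids[1]]]
        cl <- find_clusters(conserved_network(prof, ref))
        keep <- vapply(cl$clusters, function(x) any(x %in% pocket), logical(1))
        pos <- cl$clusters[keep]
        if (length(pos) == 0) next
        cl_pos <- structure(list(clusters = pos,
                                 sizes = vapply(pos, length, integer(1))),
                            class = "conserved_cluster_set")
        X <- rbind(X, cluster_feature_matrix(cl_pos, feats, anc))
        y <- c(y, rep(1L, length(pos)))
        sizes <- c(sizes, cl_pos$sizes)
      }
      if (length(sizes) == 0) sizes <- c(9L, 10L)
      set.seed(derive_seed(seed, 95000, s * 100 + a))
      neg <- lapply(seq_len(ogs_per_ancestor + 1), function(i) {
        .random_connected_subset(anc, resample_one(sizes))
      })
      cl_neg <- structure(list(clusters = neg,
                               sizes = vapply(neg, length, integer(1))),
                          class = "conserved_cluster_set")
      X <- rbind(X, cluster_feature_matrix(cl_neg, feats, anc))
      y <- c(y, rep(0L, length(neg)))
    }
    res <- tryCatch(classify_clusters(X, y, seed = seed + s),
                    error = function(e) NULL)
    if (is.null(res)) next
    rows[[s]] <- data.frame(
      seed = s, n_clusters = length(y),
      model_ba = res$model$balanced_accuracy, model_auc = res$model$auc,
      random_site_auc = res$random_site_assignment$auc,
      permuted_auc = res$permuted_labels$auc)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       beats_baselines_rate = mean(
         per_seed$model_auc > per_seed$random_site_auc &
           per_seed$model_auc > per_seed$permuted_auc))
}
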