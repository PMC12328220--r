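## conserved_clusters: contact network of fully conserved residues,
## connected-component clusters, binding-site overlap statistics and the
## gradient-boosted cluster classifier with its null baselines.

#' Contact network of fully conserved residues
#'
#' Nodes are reference positions flagged fully conserved in the profile;
#' edges join nodes whose C-alpha atoms lie within \code{contact_cutoff}.
#' An empty network (no conserved residues) is valid output.
#'
#' @param profile conservation_profile.
#' @param ref reference structure_model.
#' @param contact_cutoff C-alpha distance, Angstrom (default 10).
#' @return list with nodes (integer ref indices) and edges (two-column
#'   matrix of node pairs, i < j).
#' @export
conserved_network <- function(profile, ref, contact_cutoff = 10.0) {
  if (nrow(profile$residues) != nrow(ref$residues)) {
    stop("profile and reference structure are inconsistent")
  }
  nodes <- profile$residues$ref_idx[profile$residues$fully_conserved]
  if (length(nodes) < 2) {
    return(list(nodes = nodes, edges = matrix(integer(0), 0, 2),
                contact_cutoff = contact_cutoff))
  }
  xyz <- ca_coords(ref)[nodes, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d <= contact_cutoff & upper.tri(d), arr.ind = TRUE)
  edges <- cbind(nodes[hit[, 1]], nodes[hit[, 2]])
  list(nodes = nodes, edges = edges, contact_cutoff = contact_cutoff)
}

#' Clusters of fully conserved residues
#'
#' Connected components of the conserved-residue contact network;
#' components below \code{min_cluster_size} are discarded and counted.
#'
#' @param network output of \code{conserved_network}.
#' @param min_cluster_size smallest component kept (default 3).
#' @return list of class "conserved_cluster_set": clusters (list of sorted
#'   integer vectors, ordered by smallest member), sizes, n_discarded,
#'   n_nodes, edges.
#' @export
find_clusters <- function(network, min_cluster_size = 3) {
  nodes <- network$nodes
  if (length(nodes) == 0L) {
    return(structure(list(clusters = list(), sizes = integer(0),
                          n_discarded = 0L, n_nodes = 0L,
                          edges = network$edges),
                     class = "conserved_cluster_set"))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(network$edges[, 1]),
                   to = as.character(network$edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  comp <- igraph::components(g)
  members <- split(as.integer(igraph::V(g)$name), comp$membership)
  members <- lapply(members, sort)
  keep <- vapply(members, length, integer(1)) >= min_cluster_size
  clusters <- members[keep]
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  names(clusters) <- NULL
  structure(list(clusters = clusters,
                 sizes = vapply(clusters, length, integer(1)),
                 n_discarded = sum(!keep), n_nodes = length(nodes),
                 edges = network$edges),
            class = "conserved_cluster_set")
}

#' @export
print.conserved_cluster_set <- function(x, ...) {
  cat("conserved_cluster_set:", length(x$clusters), "clusters",
      sprintf("(median size %.1f)", stats::median(as.numeric(x$sizes))),
      "-", x$n_discarded, "small components discarded\n")
  invisible(x)
}

## sites = connected components of flagged residues on the same C-alpha
## contact graph (spatial sites rather than sequence runs)
.flagged_sites <- function(flags, ref, contact_cutoff) {
  idx <- which(flags)
  if (length(idx) == 0L) return(list())
  if (length(idx) == 1L) return(list(idx))
  xyz <- ca_coords(ref)[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  g <- igraph::graph_from_adjacency_matrix(d <= contact_cutoff, mode = "undirected",
                                           diag = FALSE)
  unname(lapply(split(seq_along(idx), igraph::components(g)$membership),
                function(ii) sort(idx[ii])))
}

#' Overlap of conserved clusters with annotated sites
#'
#' A site (a spatially connected set of flagged residues) is covered when at
#' least one of its residues lies in at least one cluster. The enrichment
#' ratio compares the binding fraction among fully conserved residues with
#' the binding fraction among all residues; values above 1 mean conserved
#' residues over-represent the annotated sites.
#'
#' @param clusters conserved_cluster_set.
#' @param flags per-residue logical site flags (e.g. csb or upb column).
#' @param ref reference structure_model (for spatial site grouping).
#' @param profile conservation_profile (for the conserved-residue universe).
#' @param contact_cutoff cutoff used to group flagged residues into sites.
#' @return list: pct_sites_covered, pct_clusters_without_site,
#'   enrichment_ratio, n_sites, n_clusters. All NA with a warning when no
#'   residue is flagged.
#' @export
cluster_site_overlap <- function(clusters, flags, ref, profile,
                                 contact_cutoff = 10.0) {
  if (!any(flags)) {
    warning("no flagged sites: overlap statistics undefined")
    return(list(pct_sites_covered = NA_real_,
                pct_clusters_without_site = NA_real_,
                enrichment_ratio = NA_real_, n_sites = 0L,
                n_clusters = length(clusters$clusters)))
  }
  sites <- .flagged_sites(flags, ref, contact_cutoff)
  in_cluster <- unique(unlist(clusters$clusters))
  covered <- vapply(sites, function(site) any(site %in% in_cluster), logical(1))
  flagged_idx <- which(flags)
  cl_without <- vapply(clusters$clusters,
                       function(cl) !any(cl %in% flagged_idx), logical(1))
  conserved_idx <- profile$residues$ref_idx[profile$residues$fully_conserved]
  frac_cons <- if (length(conserved_idx)) mean(conserved_idx %in% flagged_idx) else NA_real_
  frac_all <- mean(flags)
  list(pct_sites_covered = 100 * mean(covered),
       pct_clusters_without_site = if (length(cl_without)) 100 * mean(cl_without) else NA_real_,
       enrichment_ratio = frac_cons / frac_all,
       n_sites = length(sites), n_clusters = length(clusters$clusters))
}

#' Physicochemical feature vector per cluster
#'
#' The declared, versioned feature set for the cluster classifier: cluster
#' size, contact density within the cluster, mean rSASA, surface fraction,
#' secondary-structure composition, mean residue cost, mean hydrophobicity
#' (logP), amino-acid class composition and mean pLDDT where available.
#'
#' @param clusters conserved_cluster_set.
#' @param features residue_features data.frame for the reference.
#' @param ref reference structure_model.
#' @param cost_table cost table from \code{read_cost_table}.
#' @return data.frame, one row per cluster.
#' @export
cluster_feature_matrix <- function(clusters, features, ref,
                                   cost_table = read_cost_table()) {
  logp <- aa_lookup("logp")
  classes <- aa_lookup("class")
  class_levels <- sort(unique(classes))
  xyz <- ca_coords(ref)
  rows <- lapply(clusters$clusters, function(cl) {
    f <- features[features$ref_idx %in% cl, , drop = FALSE]
    aa <- f$aa[f$aa != "X"]
    nd <- length(cl)
    dens <- if (nd > 1) {
      d <- as.matrix(stats::dist(xyz[cl, , drop = FALSE]))
      sum(d <= 10 & upper.tri(d)) / (nd * (nd - 1) / 2)
    } else 0
    ss_frac <- vapply(c("helix", "extended", "turn", "coil"),
                      function(k) mean(f$ss_class == k), numeric(1))
    cls_frac <- vapply(class_levels, function(k) mean(classes[aa] == k), numeric(1))
    data.frame(size = nd, contact_density = dens,
               mean_rsasa = mean(f$rsasa, na.rm = TRUE),
               surface_frac = mean(f$exposure == "surface"),
               t(ss_frac), mean_cost = mean(cost_table$values[aa]),
               mean_logp = mean(logp[aa]), t(cls_frac),
               mean_plddt = if (!is.null(ref$residues$plddt))
                 mean(ref$residues$plddt[cl]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.stratified_folds <- function(y, k, rng_labels) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    ii <- which(y == cls)
    ii <- ii[order(rng_labels[ii])]
    folds[ii] <- rep_len(seq_len(k), length(ii))
  }
  folds
}

.balanced_accuracy <- function(truth, pred) {
  sens <- mean(pred[truth == 1] == 1)
  spec <- mean(pred[truth == 0] == 0)
  (sens + spec) / 2
}

.cv_boost <- function(X, y, n_repeats, k, seed, nrounds, max_depth, eta) {
  ba <- auc <- numeric(0)
  for (rep in seq_len(n_repeats)) {
    set.seed(seed + rep)
    u <- stats::runif(length(y))
    folds <- .stratified_folds(y, k, u)
    for (fold in seq_len(k)) {
      tr <- folds != fold; te <- !tr
      if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
      dtr <- xgboost::xgb.DMatrix(as.matrix(X[tr, , drop = FALSE]),
                                  label = y[tr])
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", tree_method = "hist",
                      max_depth = max_depth, eta = eta, nthread = 1),
        data = dtr, nrounds = nrounds, verbose = 0)
      p <- stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(X[te, , drop = FALSE])))
      ba <- c(ba, .balanced_accuracy(y[te], as.integer(p >= 0.5)))
      auc <- c(auc, .auc_mann_whitney(p, y[te]))
    }
  }
  list(balanced_accuracy = mean(ba), auc = mean(auc),
       per_fold = data.frame(balanced_accuracy = ba, auc = auc))
}

## labels reassigned to random clusters of matched size distribution:
## clusters are binned by size tertile and labels permuted within bins
.matched_size_shuffle <- function(y, sizes, seed) {
  set.seed(seed)
  bins <- cut(rank(sizes, ties.method = "first"), breaks = 3, labels = FALSE)
  out <- y
  for (b in unique(bins)) {
    ii <- which(bins == b)
    out[ii] <- y[sample(ii)]
  }
  out
}

#' Classify conserved clusters as binding-site-containing
#'
#' Trains a histogram-based gradient boosting classification tree (xgboost,
#' \code{tree_method = "hist"}) on the cluster feature matrix to predict
#' whether a cluster contains a known binding site, evaluated by repeated
#' stratified k-fold cross-validation (default ten fivefold runs). Two null
#' baselines use the same folds and seed: labels reassigned to random
#' clusters with a matched size distribution, and fully permuted labels.
#'
#' @param X cluster feature matrix (data.frame or matrix).
#' @param labels logical/0-1 vector: cluster contains a known binding site.
#' @param n_repeats repeats of cross-validation (default 10).
#' @param k folds (default 5).
#' @param seed RNG seed driving folds and baselines.
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @return list with model, random_site_assignment and permuted_labels
#'   results (each: balanced_accuracy, auc, per_fold).
#' @export
classify_clusters <- function(X, labels, n_repeats = 10, k = 5, seed = 1,
                              nrounds = 50, max_depth = 3, eta = 0.3) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("single-class labels: classifier undefined")
  if (length(y) < 20) stop("need >= 20 labelled clusters")
  X <- as.matrix(X)
  X[is.na(X)] <- 0
  sizes <- if ("size" %in% colnames(X)) X[, "size"] else rowSums(X != 0)
  y_match <- .matched_size_shuffle(y, sizes, seed)
  set.seed(seed)
  y_perm <- sample(y)
  list(model = .cv_boost(X, y, n_repeats, k, seed, nrounds, max_depth, eta),
       random_site_assignment = .cv_boost(X, y_match, n_repeats, k, seed,
                                          nrounds, max_depth, eta),
       permuted_labels = .cv_boost(X, y_perm, n_repeats, k, seed,
                                   nrounds, max_depth, eta))
}
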