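## association_stats: correlations, rank tests with Cliff's delta, quartile
## (Fisher) enrichment, ROC/AUC enrichment, BH adjustment and phenotype
## subgrouping. All estimators return a common result row so reports can be
## concatenated.

.assoc_row <- function(test_name, estimate, p_value, n, effect_size = NA_real_,
                       meta = NA_character_) {
  data.frame(test_name = test_name, estimate = estimate,
             effect_size = effect_size, p_value = p_value,
             p_adjusted = NA_real_, n = n, meta = meta,
             stringsAsFactors = FALSE)
}

#' Correlation with the usual rank/linear estimators
#'
#' Spearman's rho, Kendall's tau (midranks for ties) or Pearson's r on
#' pairwise-complete observations; exact p for small samples where the
#' estimator supports it, large-sample approximations otherwise.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped and the
#'   retained n reported.
#' @param method "spearman", "kendall" or "pearson".
#' @return one-row association data.frame (estimate = rho/tau/r).
#' @export
correlate <- function(x, y, method = c("spearman", "kendall", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- .assoc_row(method, NA_real_, NA_real_, n, meta = "constant input")
    return(out)
  }
  exact <- n <= 10
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = exact))
  .assoc_row(method, unname(ct$estimate), ct$p.value, n)
}

#' Cliff's delta
#'
#' Nonparametric effect size: the difference between the probability that a
#' value from \code{a} exceeds one from \code{b} and the converse,
#' \eqn{\Delta = (\#(a>b) - \#(a<b)) / (n_a n_b)}, in [-1, 1].
#'
#' @param a,b numeric samples.
#' @return scalar delta.
#' @export
cliffs_delta <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  gt <- outer(a, b, `>`)
  lt <- outer(a, b, `<`)
  (sum(gt) - sum(lt)) / (length(a) * length(b))
}

#' Two-group comparison with effect size
#'
#' Two-sided Wilcoxon-Mann-Whitney U-test (unpaired) or Wilcoxon
#' signed-rank test (paired), reporting Cliff's delta as effect size. In
#' paired mode delta can be computed on the pooled values or on the paired
#' differences' groups; here the unpaired cross-pair definition is used on
#' the two samples for comparability.
#'
#' @param a,b numeric samples (equal length in paired mode).
#' @param paired signed-rank test on differences when TRUE.
#' @return one-row association data.frame; a paired comparison with all
#'   zero differences yields NA p and meta = "all differences zero".
#' @export
group_compare <- function(a, b, paired = FALSE) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  if (paired && length(a) != length(b)) stop("paired mode requires equal lengths")
  delta <- cliffs_delta(a, b)
  test_name <- if (paired) "wilcoxon_signed_rank" else "mann_whitney"
  if (paired && all(a - b == 0)) {
    return(.assoc_row(test_name, NA_real_, NA_real_, length(a),
                      effect_size = delta, meta = "all differences zero"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            alternative = "two.sided"))
  .assoc_row(test_name, unname(wt$statistic), wt$p.value,
             if (paired) length(a) else length(a) + length(b),
             effect_size = delta)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' returned in the input order.
#'
#' @param p raw p-values in [0, 1] (NA passed through).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Quartile enrichment by Fisher's exact test
#'
#' Selects the top or bottom quartile of orthogroups by value (boundary ties
#' are all included, so the tail is deterministic) and tests each annotation
#' set for enrichment in the tail with a two-sided Fisher's exact test on
#' the 2x2 (in-tail x in-set) table; BH adjustment across all sets tested
#' together. Sets with fewer than 2 members in the universe are skipped.
#'
#' @param values named numeric vector keyed by og_id.
#' @param membership named list: set name -> character vector of og_ids.
#' @param tail "top25" (largest values) or "bottom25".
#' @return data.frame, one row per tested set (estimate = odds ratio, Inf
#'   for perfect enrichment).
#' @export
quartile_enrichment <- function(values, membership, tail = c("top25", "bottom25")) {
  tail <- match.arg(tail)
  if (length(values) < 8) stop("need >= 8 orthogroups")
  universe <- names(values)
  q <- stats::quantile(values, if (tail == "top25") 0.75 else 0.25, names = FALSE)
  in_tail <- if (tail == "top25") values >= q else values <= q
  rows <- list()
  for (set_name in names(membership)) {
    set_ids <- intersect(membership[[set_name]], universe)
    if (length(set_ids) < 2) next
    in_set <- universe %in% set_ids
    tab <- table(factor(in_tail, levels = c(TRUE, FALSE)),
                 factor(in_set, levels = c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    r <- .assoc_row("fisher_exact", unname(ft$estimate), ft$p.value,
                    length(universe), meta = set_name)
    rows[[set_name]] <- r
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

## AUC via the Mann-Whitney identity, midranks for ties
.auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("single class: AUC undefined")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC of a ranking against binary labels
#'
#' Curve over all thresholds of the ranking; AUC from the Mann-Whitney
#' identity \eqn{AUC = U/(n_1 n_0)} with ties midranked.
#'
#' @param scores numeric ranking (higher = predicted positive).
#' @param labels binary labels.
#' @return list with auc and curve (data.frame fpr, tpr ordered from (0,0)
#'   to (1,1)).
#' @export
roc_enrichment <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("single class: ROC undefined")
  auc <- .auc_mann_whitney(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- !duplicated(sc, fromLast = TRUE)  # one point per distinct threshold
  tpr <- cumsum(lab) / sum(lab)
  fpr <- cumsum(!lab) / sum(!lab)
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep])))
}

#' Phenotype subgrouping of per-species conservation
#'
#' Temporarily subdivides each orthogroup by a binary species phenotype
#' (species labelled "variable" are excluded), averages the CR within the
#' yes- and no-subgroups, and compares the paired per-orthogroup means with
#' a two-sided Wilcoxon signed-rank test. Orthogroups missing one subgroup
#' are excluded from the pairing and counted.
#'
#' @param cr data.frame with columns og_id, species, cr (one row per
#'   orthogroup x species).
#' @param phenotype named character vector species -> "yes"/"no"/"variable".
#' @param min_species minimum species per subgroup (default 2).
#' @return list: per_og (og_id, mean_yes, mean_no, delta_cr, ranked by
#'   |delta_cr|), test (association row), n_excluded.
#' @export
phenotype_split <- function(cr, phenotype, min_species = 2) {
  ph <- phenotype[cr$species]
  keep <- !is.na(ph) & ph %in% c("yes", "no")
  cr <- cr[keep, , drop = FALSE]
  ph <- ph[keep]
  agg <- lapply(split(seq_len(nrow(cr)), cr$og_id), function(ii) {
    yes <- cr$cr[ii][ph[ii] == "yes"]
    no <- cr$cr[ii][ph[ii] == "no"]
    if (length(yes) < min_species || length(no) < min_species) return(NULL)
    data.frame(og_id = cr$og_id[ii[1]], mean_yes = mean(yes),
               mean_no = mean(no), delta_cr = mean(yes) - mean(no),
               stringsAsFactors = FALSE)
  })
  n_excluded <- sum(vapply(agg, is.null, logical(1)))
  per_og <- do.call(rbind, agg[!vapply(agg, is.null, logical(1))])
  if (is.null(per_og) || nrow(per_og) < 2) {
    stop("fewer than 2 orthogroups with both subgroups")
  }
  per_og <- per_og[order(-abs(per_og$delta_cr)), , drop = FALSE]
  rownames(per_og) <- NULL
  test <- group_compare(per_og$mean_yes, per_og$mean_no, paired = TRUE)
  list(per_og = per_og, test = test, n_excluded = n_excluded)
}

#' Adjusted Cliff's delta on per-orthogroup means
#'
#' Cliff's delta computed on one value per orthogroup (group means) rather
#' than pooled residue-level values, which removes the pseudo-replication
#' of pooled comparisons; the pooled variant is available via
#' \code{delta_mode = "pooled"}.
#'
#' @param a,b data.frames with columns og_id and value.
#' @param delta_mode "per_group" (default) or "pooled".
#' @return scalar delta.
#' @export
cliffs_delta_adjusted <- function(a, b, delta_mode = c("per_group", "pooled")) {
  delta_mode <- match.arg(delta_mode)
  if (delta_mode == "pooled") return(cliffs_delta(a$value, b$value))
  am <- tapply(a$value, a$og_id, mean)
  bm <- tapply(b$value, b$og_id, mean)
  cliffs_delta(as.numeric(am), as.numeric(bm))
}
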