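## cost_and_composition: amino-acid cost and composition profiling of whole
## proteins and structural elements, averaged over orthogroups.

#' Mean amino-acid cost of a residue subset
#'
#' @param aa one-letter amino acids ('X' excluded).
#' @param table cost table from \code{read_cost_table}.
#' @return mean per-residue cost; NA with a warning on an empty subset.
#' @export
average_cost <- function(aa, table = read_cost_table()) {
  aa <- aa[aa %in% AA_CANONICAL]
  if (length(aa) == 0L) {
    warning("empty subset: cost undefined")
    return(NA_real_)
  }
  mean(table$values[aa])
}

#' Relative amino-acid composition of a residue subset
#'
#' @param aa one-letter amino acids; 'X' is excluded from numerator and
#'   denominator.
#' @return named numeric over the 20 canonical amino acids, summing to 1;
#'   all-NA for an empty (or all-'X') subset.
#' @export
composition <- function(aa) {
  aa <- aa[aa %in% AA_CANONICAL]
  if (length(aa) == 0L) {
    return(stats::setNames(rep(NA_real_, 20), AA_CANONICAL))
  }
  counts <- table(factor(aa, levels = AA_CANONICAL))
  stats::setNames(as.numeric(counts) / length(aa), AA_CANONICAL)
}

## structural elements defined over a reference feature table; "all_mapped"
## restricts to residues mapped by at least one member when a profile is
## supplied, otherwise the whole chain
.element_subsets <- function(features, profile = NULL) {
  idx <- features$ref_idx
  mapped <- if (!is.null(profile)) {
    idx %in% profile$residues$ref_idx[profile$residues$n_mapped > 0]
  } else rep(TRUE, length(idx))
  list(all_mapped = mapped,
       core = mapped & features$exposure == "core",
       surface = mapped & features$exposure == "surface",
       binding_upb = mapped & features$upb,
       binding_csb = mapped & features$csb,
       helix = mapped & features$ss_class == "helix",
       extended = mapped & features$ss_class == "extended",
       turn = mapped & features$ss_class == "turn",
       coil = mapped & features$ss_class == "coil")
}

#' Per-element cost, composition and conservation report for one orthogroup
#'
#' For each structural element (all mapped residues, core, surface, UPb/CSb
#' binding sites, and the four secondary-structure classes), joins the
#' reference's mean cost per amino acid and relative composition with the
#' element-restricted CR. Empty elements stay missing, never zero.
#'
#' @param og orthogroup.
#' @param mappings residue mappings onto the reference.
#' @param features residue_features table of the reference.
#' @param cost_tables list of cost tables (default both packaged metrics).
#' @param profile optional precomputed conservation_profile.
#' @return data.frame: og_id, element, n_residues, cr, one cost column per
#'   metric, and the 20 composition columns (prefixed comp_).
#' @export
element_cost_report <- function(og, mappings, features,
                                cost_tables = lapply(cost_metrics(), read_cost_table),
                                profile = NULL) {
  if (is.null(profile)) profile <- conservation_profile(og, mappings)
  subsets <- .element_subsets(features, profile)
  aa <- features$aa
  rows <- lapply(names(subsets), function(el) {
    sel <- subsets[[el]]
    n <- sum(sel)
    cr <- if (n > 0) cr_by_feature(og, mappings, features$ref_idx[sel],
                                   reference_id = profile$reference_id)
          else NA_real_
    costs <- vapply(cost_tables, function(tb) {
      if (n > 0) suppressWarnings(average_cost(aa[sel], tb)) else NA_real_
    }, numeric(1))
    names(costs) <- paste0("cost_", vapply(cost_tables, `[[`, character(1), "metric_name"))
    comp <- if (n > 0) composition(aa[sel]) else
      stats::setNames(rep(NA_real_, 20), AA_CANONICAL)
    names(comp) <- paste0("comp_", names(comp))
    cbind(data.frame(og_id = og$og_id, element = el, n_residues = n,
                     cr = as.numeric(cr), stringsAsFactors = FALSE),
          as.data.frame(t(costs)), as.data.frame(t(comp)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
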