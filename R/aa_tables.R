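## Packaged amino-acid property tables. All tables live as TSV under
## inst/extdata so users can inspect or replace them; loaders cache per
## session.

.strucons_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "strucons")
  if (!nzchar(path)) stop("packaged table not found: ", file)
  path
}

.read_table_cached <- function(file) {
  if (!exists(file, envir = .strucons_cache)) {
    tab <- utils::read.delim(.extdata(file), stringsAsFactors = FALSE)
    assign(file, tab, envir = .strucons_cache)
  }
  get(file, envir = .strucons_cache)
}

#' Amino-acid property table
#'
#' One row per canonical amino acid: three-letter code, theoretical maximum
#' solvent-accessible surface area (\eqn{\mathrm{\AA}^2}, Tien-style
#' theoretical maxima used to normalise rSASA), Fauchere-Pliska side-chain
#' octanol-water partition value (logP), default physicochemical class, and
#' residue molecular weight (Da).
#'
#' @return data.frame with columns aa, name3, max_sasa, logp, class, mw.
#' @export
aa_properties <- function() .read_table_cached("aa_properties.tsv")

#' Named lookup vectors derived from the property table
#'
#' @param what one of "max_sasa", "logp", "class", "mw".
#' @return named vector keyed by one-letter amino-acid code.
#' @export
aa_lookup <- function(what = c("max_sasa", "logp", "class", "mw")) {
  what <- match.arg(what)
  tab <- aa_properties()
  stats::setNames(tab[[what]], tab$aa)
}

#' Read an amino-acid cost table
#'
#' Packaged metrics: \code{"akashi_gojobori"} (biosynthetic cost in
#' high-energy phosphate-bond equivalents) and \code{"molecular_weight"}
#' (residue mass as a size proxy). A file path pointing to any two-column
#' TSV (aa, cost) supplies an external metric in the same format.
#'
#' @param metric packaged metric name or a path to a TSV file.
#' @param normalize if TRUE (default) costs are divided by their median so
#'   metrics on different scales are comparable (median-normalised relative
#'   cost).
#' @return list with fields metric_name, values (named numeric, 20 entries),
#'   normalized.
#' @export
read_cost_table <- function(metric = "akashi_gojobori", normalize = TRUE) {
  if (file.exists(metric)) {
    tab <- utils::read.delim(metric, stringsAsFactors = FALSE)
    name <- basename(metric)
  } else {
    name <- metric
    tab <- .read_table_cached(paste0("cost_", metric, ".tsv"))
  }
  if (!all(c("aa", "cost") %in% names(tab))) {
    stop("cost table must have columns 'aa' and 'cost'")
  }
  values <- stats::setNames(as.numeric(tab$cost), tab$aa)
  if (!all(AA_CANONICAL %in% names(values))) {
    stop("cost table must cover all 20 canonical amino acids")
  }
  values <- values[AA_CANONICAL]
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("costs must be finite and positive")
  }
  if (normalize) values <- values / stats::median(values)
  list(metric_name = name, values = values, normalized = normalize)
}

#' @rdname read_cost_table
#' @export
cost_metrics <- function() c("akashi_gojobori", "molecular_weight")

## van der Waals radii by element symbol (Angstrom); unknown elements fall
## back to carbon.
vdw_radii <- function() {
  tab <- .read_table_cached("vdw_radii.tsv")
  stats::setNames(tab$radius, tab$element)
}

## Het residue names treated as crystallographic additives, not ligands.
ligand_exclusion_list <- function() .read_table_cached("ligand_exclusion.tsv")$resid

## Modified residues mapped to their parent amino acid at parse time.
nonstandard_residue_map <- function() {
  tab <- .read_table_cached("nonstandard_residues.tsv")
  stats::setNames(tab$parent, tab$resid)
}

#' @export
AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

## three-letter -> one-letter, routing modified residues through the parent
## table; anything else becomes 'X'.
aa321 <- function(resid) {
  resid <- toupper(resid)
  out <- unname(AA_THREE[resid])
  ns <- nonstandard_residue_map()
  miss <- is.na(out) & resid %in% names(ns)
  out[miss] <- unname(ns[resid[miss]])
  out[is.na(out)] <- "X"
  out
}

aa123 <- function(aa) {
  rev_map <- stats::setNames(names(AA_THREE), unname(AA_THREE))
  out <- unname(rev_map[aa])
  out[is.na(out)] <- "UNK"
  out
}
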