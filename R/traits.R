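# Per-taxon trait table: ornamentation state, log_e body mass (kg),
# Maniraptoriformes membership, and the derived giant flag (>= 1,000 kg).

#' Read a tab-separated trait table
#'
#' Expects a header with columns \code{taxon}, \code{ornamented} (0/1),
#' \code{log_mass} (log_e kg) and \code{maniraptoriform} (0/1). A
#' \code{giant} column (mass >= 1,000 kg, i.e. log_mass >= log(1000)) is
#' derived and appended.
#'
#' @param path file path of a TSV with header.
#' @return a validated data frame with derived \code{giant} column.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_trait_table(tab)
}

#' Validate (and complete) a trait table
#'
#' @param tab data frame with columns \code{taxon}, \code{ornamented},
#'   \code{log_mass}, \code{maniraptoriform}.
#' @return the table with a derived \code{giant} column.
#' @export
as_trait_table <- function(tab) {
  need <- c("taxon", "ornamented", "log_mass", "maniraptoriform")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trait table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(tab[need])) stop("missing values in trait table")
  if (!all(tab$ornamented %in% 0:1)) stop("ornamented must be 0/1")
  if (!all(tab$maniraptoriform %in% 0:1)) stop("maniraptoriform must be 0/1")
  if (anyDuplicated(tab$taxon)) stop("duplicate taxa in trait table")
  tab$giant <- as.integer(tab$log_mass >= log(1000))
  tab
}

#' Match a trait table against a tree's tips
#'
#' Errors with the symmetric difference when taxa and tips disagree;
#' otherwise returns the table reordered to the tree's tip order.
#'
#' @param tab a trait table (see [as_trait_table()]).
#' @param tree a \code{"phylo"}.
#' @return the reordered table.
#' @export
match_traits <- function(tab, tree) {
  tab <- as_trait_table(tab)
  only_tab <- setdiff(tab$taxon, tree$tip.label)
  only_tree <- setdiff(tree$tip.label, tab$taxon)
  if (length(only_tab) || length(only_tree))
    stop("taxon mismatch; only in table: {",
         paste(only_tab, collapse = ", "), "}; only in tree: {",
         paste(only_tree, collapse = ", "), "}")
  tab[match(tree$tip.label, tab$taxon), , drop = FALSE]
}

#' Body mass from femoral length (power-law allometry)
#'
#' Convenience converter \code{mass = a * femur^b}. The allometric
#' coefficients are inputs, not package constants: supply published values
#' appropriate to the clade.
#'
#' @param femur_mm femoral length(s), mm.
#' @param a,b power-law coefficients (mass in kg when \code{a}, \code{b}
#'   are calibrated for mm input).
#' @return body mass(es), kg.
#' @export
mass_from_femur <- function(femur_mm, a, b) {
  stopifnot(is.numeric(femur_mm), femur_mm > 0, a > 0)
  a * femur_mm^b
}
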