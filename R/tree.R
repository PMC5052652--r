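# Tree data model: ape "phylo" objects carrying a "root.time" attribute
# (age of the root in Ma before present), so non-ultrametric fossil trees
# have well-defined tip ages: tip_age = root.time - root-to-tip path length.

#' Parse a Newick string into a time tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Branch lengths are
#' mandatory: a tree without them (or with \code{NA} lengths) is rejected
#' rather than silently zero-filled. The root age is taken as the maximum
#' root-to-tip path length, i.e. the youngest tip is assumed to sit at
#' 0 Ma unless a \code{root.time} is supplied.
#'
#' @param text a single Newick string (terminating \code{;} required).
#' @param root.time optional root age in Ma before present; default places
#'   the youngest tip at 0 Ma.
#' @return an object of class \code{"phylo"} with a \code{root.time}
#'   attribute (Ma).
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' root_age(tr)           # 2
#' tip_ages(tr)           # all 0 (ultrametric)
parse_newick <- function(text, root.time = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: empty or malformed string",
                        call. = FALSE)
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("missing branch length(s): every edge must carry a length in Ma",
         call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  d <- node_depths(tr)
  attr(tr, "root.time") <- if (is.null(root.time)) max(d[seq_len(ape::Ntip(tr))])
                           else root.time
  tr
}

# cheap structural scan so malformed input fails with a character offset
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unbalanced ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(chars), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick: missing terminating ';' at character ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' Serialize a time tree to Newick
#'
#' @param tree a \code{"phylo"} object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string. Round-trips with [parse_newick()] up to numeric
#'   formatting.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Root-to-node path lengths
#'
#' @param tree a \code{"phylo"} object with branch lengths.
#' @return numeric vector over nodes (tips first, then internal nodes) of
#'   distance from the root in Ma.
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Root age of a time tree (Ma before present)
#'
#' @param tree a \code{"phylo"} object; if it lacks a \code{root.time}
#'   attribute the youngest tip is taken to be at 0 Ma.
#' @return scalar age in Ma.
#' @export
root_age <- function(tree) {
  rt <- attr(tree, "root.time")
  if (!is.null(rt)) return(rt)
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Tip ages of a time tree (Ma before present)
#'
#' @param tree a \code{"phylo"} object.
#' @return named numeric vector, \code{root_age(tree)} minus root-to-tip
#'   path length; 0 for tips reaching the present, positive for extinct tips.
#' @export
tip_ages <- function(tree) {
  n <- ape::Ntip(tree)
  ages <- root_age(tree) - node_depths(tree)[seq_len(n)]
  names(ages) <- tree$tip.label
  ages
}

#' Fossil time-scaling of a cladogram
#'
#' Dates a tree from stratigraphic tip dates and resolves the resulting
#' zero-length branches by one of three rules. The initial ("basic") dating
#' places each internal node at the age of its oldest descendant tip, which
#' leaves zero-length branches along the oldest lineages; \code{method}
#' then redistributes time:
#' \describe{
#'   \item{ABA}{"all branches additive": every branch gets \code{vartime}
#'     Ma added. Internal nodes (and the root) are pushed back; tips keep
#'     ages at least as old as their stratigraphic dates.}
#'   \item{MBL}{"minimum branch length": every branch is brought up to at
#'     least \code{vartime} Ma by debiting time from ancestral branches
#'     (immediate parent first, recursing rootward). Tip ages are preserved
#'     exactly. If the debit chain reaches the root, the root is pushed
#'     back when \code{root.extend = TRUE} (default), otherwise an error is
#'     thrown.}
#'   \item{Equal}{the root is first extended by \code{vartime} Ma, then
#'     each zero-length branch borrows time from the closest ancestral
#'     branch with positive length, spacing the intervening node ages
#'     evenly. Tip ages are preserved exactly.}
#' }
#'
#' @param tree a \code{"phylo"} topology (branch lengths, if any, are
#'   ignored; dating comes from \code{dates}).
#' @param dates data frame with columns \code{taxon}, \code{FAD},
#'   \code{LAD} (first/last appearance, Ma; \code{FAD >= LAD}); every tip
#'   must be listed.
#' @param method one of \code{"ABA"}, \code{"MBL"}, \code{"Equal"}.
#' @param vartime time increment in Ma (default 1).
#' @param tip.date \code{"midpoint"} uses the interval midpoint;
#'   \code{"uniform"} draws tip ages uniformly within \code{[LAD, FAD]}
#'   (seeded), reproducing a calibration-uncertainty tree set when called
#'   repeatedly.
#' @param root.extend for MBL: allow the root to be pushed back when
#'   ancestral branches cannot supply the required time.
#' @param seed optional integer seed used when \code{tip.date = "uniform"}.
#' @return a dated \code{"phylo"} with \code{root.time} attribute.
#' @export
timescale <- function(tree, dates,
                      method = c("ABA", "MBL", "Equal"),
                      vartime = 1,
                      tip.date = c("midpoint", "uniform"),
                      root.extend = TRUE,
                      seed = NULL) {
  method <- match.arg(method)
  tip.date <- match.arg(tip.date)
  stopifnot(vartime > 0)
  if (!all(c("taxon", "FAD", "LAD") %in% names(dates)))
    stop("dates must have columns taxon, FAD, LAD")
  if (any(dates$FAD < dates$LAD))
    stop("FAD must be >= LAD for every taxon")
  missing_tips <- setdiff(tree$tip.label, dates$taxon)
  if (length(missing_tips))
    stop("undatable tip(s): ", paste(missing_tips, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  idx <- match(tree$tip.label, dates$taxon)
  tage <- switch(tip.date,
                 midpoint = (dates$FAD[idx] + dates$LAD[idx]) / 2,
                 uniform  = stats::runif(length(idx), dates$LAD[idx],
                                         dates$FAD[idx]))
  names(tage) <- tree$tip.label

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # basic dating: node age = oldest descendant tip age (postorder sweep)
  age <- numeric(ntip + nnode)
  age[seq_len(ntip)] <- tage
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; c <- eo[k, 2]
    age[p] <- max(age[p], age[c])
  }

  age <- switch(method,
    ABA   = .ts_aba(tree, age, eo, vartime, ntip),
    MBL   = .ts_mbl(tree, age, eo, vartime, root, root.extend),
    Equal = .ts_equal(tree, age, eo, vartime, root, ntip))

  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(out$edge.length < -1e-9))
    stop("internal error: negative branch produced by time-scaling")
  out$edge.length <- pmax(out$edge.length, 0)
  attr(out, "root.time") <- age[root]
  out
}

# ABA keeps the anchor that no tip is younger than its stratigraphic date:
# every edge grows by vartime, so node ages are rebuilt tip-upward and the
# tree is re-anchored at max(tip date + new depth).
.ts_aba <- function(tree, age, eo, vartime, ntip) {
  tmp <- tree
  tmp$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]] + vartime
  depth <- ape::node.depth.edgelength(tmp)
  rt <- max(age[seq_len(ntip)] + depth[seq_len(ntip)])
  rt - depth
}

.ts_mbl <- function(tree, age, eo, vartime, root, root.extend) {
  new_age <- age
  # postorder: each parent must be at least vartime older than each child
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; c <- eo[k, 2]
    new_age[p] <- max(new_age[p], new_age[c] + vartime)
  }
  if (new_age[root] > age[root] + 1e-12 && !root.extend)
    stop("MBL infeasible: ancestral branches cannot supply ",
         format(new_age[root] - age[root]),
         " Ma without pushing the root back (set root.extend = TRUE)")
  new_age
}

.ts_equal <- function(tree, age, eo, vartime, root, ntip) {
  age[root] <- age[root] + vartime            # root extension
  parent <- integer(length(age))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  pre <- rev(seq_len(nrow(eo)))               # preorder over edges
  for (k in pre) {
    p <- eo[k, 1]; c <- eo[k, 2]
    if (age[p] - age[c] > 1e-12) next
    # zero branch: climb rootward to the nearest positive branch
    path <- c(c, p)
    x <- p
    while (x != root && age[parent[x]] - age[x] <= 1e-12) {
      x <- parent[x]
      path <- c(path, x)
    }
    donor_top <- if (x == root) root else parent[x]
    path <- c(setdiff(path, donor_top), donor_top)
    # evenly space ages of nodes strictly between donor_top and c
    kseg <- length(path) - 1L                  # number of edges on the path
    span <- age[donor_top] - age[c]
    if (span <= 1e-12)
      stop("Equal time-scaling failed: no ancestral time available above node ", c)
    for (j in seq_len(kseg - 1L)) {
      node <- path[1L + j]                     # from just above c upward
      age[node] <- age[c] + span * j / kseg
    }
  }
  age
}

#' Mean-branch-length consensus of a set of equally-shaped trees
#'
#' Summarizes calibration uncertainty across a set of time-scalings of one
#' topology: the consensus keeps the shared topology and assigns each edge
#' the arithmetic mean of its lengths across trees. Edges are matched by
#' the set of tip labels they subtend, so node numbering may differ freely.
#'
#' @param trees a list of \code{"phylo"} objects with identical topology
#'   (same tip set, same bipartitions).
#' @return a \code{"phylo"} consensus tree with \code{root.time} set to the
#'   mean root age.
#' @export
consensus_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  if (length(trees) == 1L) return(trees[[1L]])
  ref <- trees[[1L]]
  keys_ref <- .edge_keys(ref)
  acc <- ref$edge.length
  rt <- root_age(ref)
  for (i in 2:length(trees)) {
    tr <- trees[[i]]
    if (!setequal(tr$tip.label, ref$tip.label))
      stop("tip sets differ between trees 1 and ", i)
    keys <- .edge_keys(tr)
    m <- match(keys_ref, keys)
    if (anyNA(m)) {
      bad <- keys_ref[which(is.na(m))[1]]
      stop("topology mismatch at tree ", i, ": bipartition {", bad,
           "} absent")
    }
    acc <- acc + tr$edge.length[m]
    rt <- rt + root_age(tr)
  }
  out <- ref
  out$edge.length <- acc / length(trees)
  attr(out, "root.time") <- rt / length(trees)
  out
}

# key each edge by the sorted tip set below it
.edge_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    below[[eo[k, 1]]] <- c(below[[eo[k, 1]]], below[[eo[k, 2]]])
  vapply(tree$edge[, 2],
         function(n) paste(sort(below[[n]]), collapse = "|"), character(1))
}

#' Trim a tree at the most recent common ancestor of two tips
#'
#' Either keeps the clade defined by \code{MRCA(tipA, tipB)}
#' (\code{keep = "inside"}) or removes it (\code{keep = "outside"},
#' e.g. excluding Maniraptoriformes defined by a pair of spanning taxa).
#' Degree-2 nodes left by the removal are suppressed with branch lengths
#' summed, and tip ages of the retained taxa are preserved.
#'
#' @param tree a dated \code{"phylo"}.
#' @param tipA,tipB tip labels spanning the clade.
#' @param keep \code{"inside"} or \code{"outside"}.
#' @return a \code{"phylo"} with \code{root.time} preserved for the
#'   retained taxa.
#' @export
mrca_trim <- function(tree, tipA, tipB, keep = c("inside", "outside")) {
  keep <- match.arg(keep)
  for (t in c(tipA, tipB))
    if (!t %in% tree$tip.label) stop("tip absent from tree: ", t)
  ages_old <- tip_ages(tree)
  node <- ape::getMRCA(tree, c(tipA, tipB))
  clade_tips <- ape::extract.clade(tree, node)$tip.label
  retained <- if (keep == "inside") clade_tips
              else setdiff(tree$tip.label, clade_tips)
  if (length(retained) < 3)
    stop("trim would leave ", length(retained), " tips (< 3)")
  out <- ape::keep.tip(tree, retained)
  d <- node_depths(out)[seq_len(ape::Ntip(out))]
  attr(out, "root.time") <- ages_old[out$tip.label[1]] + d[1]
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' Shared-path-length matrix of a dated tree: diagonal entries are
#' root-to-tip distances, off-diagonals the depth of the pairwise MRCA.
#' This is the residual covariance (up to the rate \eqn{\sigma^2}) of a
#' Brownian-motion trait, and the substrate for the Pagel transforms.
#'
#' @param tree a \code{"phylo"} with non-negative branch lengths.
#' @return an \eqn{n \times n} symmetric positive semidefinite matrix in Ma,
#'   rows/columns ordered and named as \code{tree$tip.label}.
#' @export
phylo_vcv <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ape::vcv.phylo(tree)
}

#' Pagel branch-length / covariance transforms
#'
#' Applies the three standard Pagel transforms and returns the transformed
#' phylogenetic covariance. Order of application: \eqn{\kappa} raises every
#' branch length to the power \eqn{\kappa} (then the covariance is
#' rebuilt); \eqn{\delta} raises every matrix entry (node depth) to the
#' power \eqn{\delta}; \eqn{\lambda} multiplies the off-diagonal entries.
#' \code{(1, 1, 1)} is the identity; \eqn{\lambda = 0} gives the star
#' phylogeny (diagonal matrix).
#'
#' @param tree a dated \code{"phylo"}.
#' @param lambda phylogenetic signal, in \code{[0, 1]}.
#' @param kappa punctuation exponent on branch lengths, \code{>= 0}.
#' @param delta acceleration exponent on node depths, \code{> 0}.
#' @return transformed covariance matrix (taxon order of the tree).
#' @export
apply_transforms <- function(tree, lambda = 1, kappa = 1, delta = 1) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  if (!is.numeric(kappa) || kappa < 0) stop("kappa must be >= 0")
  if (!is.numeric(delta) || delta <= 0) stop("delta must be > 0")
  tr <- tree
  if (kappa != 1) tr$edge.length <- tr$edge.length^kappa
  C <- phylo_vcv(tr)
  if (delta != 1) C <- C^delta
  if (lambda != 1) {
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  C
}
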