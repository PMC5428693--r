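#' Parse a Newick tree
#'
#' Thin validating wrapper over [ape::read.tree()]. Label spelling is
#' preserved; polytomies are permitted on input (parsimony scoring is exact
#' on them via the dynamic-programming scorer; only tree search requires
#' binary trees) and flagged via the `"has_polytomy"` attribute.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file optional path to a Newick file.
#' @return a rooted `"phylo"` object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(file)) ape::read.tree(file) else
    ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed Newick string")
  if (inherits(phy, "multiPhylo")) stop("expected a single tree")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup) > 0L) stop("duplicate tip label '", dup[1], "'")
  if (any(!nzchar(phy$tip.label))) stop("empty tip label")
  attr(phy, "has_polytomy") <- has_polytomy(phy)
  phy
}

#' Serialize a tree to canonical Newick
#'
#' Deterministic output: at every internal node, children are ordered by the
#' lexicographically smallest tip label of their subtree. When node ages are
#' present (see [set_node_ages()]) they are emitted as branch lengths equal
#' to parent age minus child age.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path to write to.
#' @param ages emit ages as branch lengths when available (default `TRUE`).
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, ages = TRUE) {
  age <- if (ages) attr(tree, "node_ages") else NULL
  str <- canonical_newick_string(tree, age)
  if (!is.null(file)) {
    writeLines(str, file)
    return(invisible(str))
  }
  str
}

# children list indexed by node id
tree_children <- function(tree) {
  n_node <- max(tree$edge)
  kids <- vector("list", n_node)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2])
  }
  kids
}

tree_root <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

# rooted-sense binarity: no node (including the root) has more than 2
# children; ape::is.binary treats a basal trichotomy as binary-unrooted
has_polytomy <- function(tree) {
  any(tabulate(tree$edge[, 1]) > 2L)
}

# internal nodes in postorder (children always before parents)
postorder_nodes <- function(kids, root) {
  pops <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pops <- c(pops, v)
    stack <- c(stack, kids[[v]])
  }
  ord <- rev(pops)
  ord[vapply(ord, function(v) !is.null(kids[[v]]), logical(1))]
}

# all nodes in preorder
preorder_all_nodes <- function(kids, root) {
  ord <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    stack <- c(stack, rev(kids[[v]]))
  }
  ord
}

# smallest descendant tip label per node, and the sorted clade key
node_clades <- function(tree) {
  kids <- tree_children(tree)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  clade <- vector("list", n_node)
  for (v in seq_len(n_tip)) clade[[v]] <- tree$tip.label[v]
  root <- tree_root(tree)
  for (v in postorder_nodes(kids, root)) {
    clade[[v]] <- sort(unique(unlist(clade[kids[[v]]])))
  }
  clade
}

# branch key of an edge = sorted tip labels of the child subtree
branch_keys <- function(tree) {
  clade <- node_clades(tree)
  vapply(tree$edge[, 2], function(v) paste(clade[[v]], collapse = "+"),
         character(1))
}

canonical_newick_string <- function(tree, ages = NULL) {
  kids <- tree_children(tree)
  root <- tree_root(tree)
  n_tip <- length(tree$tip.label)
  rec <- function(v, parent_age) {
    brlen <- if (!is.null(ages) && !is.null(parent_age) &&
                 !is.na(ages[v]) && !is.na(parent_age)) {
      sprintf(":%g", parent_age - ages[v])
    } else ""
    if (v <= n_tip) {
      return(list(str = paste0(tree$tip.label[v], brlen),
                  min = tree$tip.label[v]))
    }
    parts <- lapply(kids[[v]], rec,
                    parent_age = if (is.null(ages)) NULL else ages[v])
    ord <- order(vapply(parts, `[[`, character(1), "min"))
    parts <- parts[ord]
    list(str = paste0("(", paste(vapply(parts, `[[`, character(1), "str"),
                                 collapse = ","), ")", brlen),
         min = parts[[1]]$min)
  }
  paste0(rec(root, NULL)$str, ";")
}

#' Canonical form of a tree
#'
#' Re-reads the canonical Newick serialization, giving a deterministic node
#' numbering and child order. Node ages (if any) are re-attached by clade.
#'
#' @param tree a `"phylo"` object.
#' @return a `"phylo"` object representing the same topology.
#' @export
canonicalize <- function(tree) {
  ages <- attr(tree, "node_ages")
  out <- ape::read.tree(text = canonical_newick_string(tree))
  if (!is.null(ages)) {
    old <- node_clades(tree)
    new <- node_clades(out)
    oldkey <- vapply(old, paste, character(1), collapse = "+")
    newkey <- vapply(new, paste, character(1), collapse = "+")
    attr(out, "node_ages") <- ages[match(newkey, oldkey)]
  }
  attr(out, "has_polytomy") <- has_polytomy(out)
  out
}

#' Reroot a tree on an outgroup terminal
#'
#' The returned tree is rooted on the branch subtending the outgroup; the
#' unrooted topology is unchanged, so any character's parsimony length is
#' invariant under this operation. Node ages are dropped (they are anchored
#' to the old root) and must be reassigned.
#'
#' @param tree a `"phylo"` object.
#' @param outgroup a terminal label.
#' @return a canonical rooted `"phylo"` object.
#' @export
reroot <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a terminal of the tree")
  }
  ut <- ape::unroot(tree)
  rt <- ape::root(ut, outgroup = outgroup, resolve.root = TRUE)
  attr(rt, "node_ages") <- NULL
  canonicalize(rt)
}

#' Enumerate all tree topologies over a taxon set
#'
#' Exhaustive enumeration by recursive leaf insertion; every distinct
#' topology is produced exactly once. Counts follow the closed forms
#' (2n-5)!! for unrooted and (2n-3)!! for rooted trees on n terminals.
#' Unrooted topologies are returned as rooted representatives (rooted on the
#' pendant edge of the first taxon), which is sufficient for parsimony
#' scoring since tree length is root-invariant.
#'
#' @param taxa character vector of 2-9 terminal labels (combinatorial guard).
#' @param rooted enumerate rooted (`TRUE`) or unrooted (`FALSE`, default)
#'   topologies.
#' @return list of `"phylo"` objects.
#' @export
enumerate_topologies <- function(taxa, rooted = FALSE) {
  n <- length(taxa)
  if (n < 2L || n > 9L) {
    stop("enumerate_topologies is guarded to 2-9 taxa (got ", n, ")")
  }
  if (anyNA(taxa) || any(duplicated(taxa))) stop("taxa must be unique labels")

  add_everywhere <- function(tr, tip) {
    res <- list(list(tr, tip))
    if (is.list(tr)) {
      for (i in 1:2) {
        for (sub in add_everywhere(tr[[i]], tip)) {
          t2 <- tr
          t2[[i]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  to_newick <- function(tr) {
    if (!is.list(tr)) return(tr)
    paste0("(", to_newick(tr[[1]]), ",", to_newick(tr[[2]]), ")")
  }
  build_rooted <- function(labels) {
    trees <- list(labels[1])
    for (tip in labels[-1]) {
      trees <- unlist(lapply(trees, add_everywhere, tip = tip),
                      recursive = FALSE)
    }
    trees
  }

  if (rooted) {
    shapes <- build_rooted(taxa)
    strs <- vapply(shapes, function(tr) {
      if (!is.list(tr)) paste0("(", tr, ");") else paste0(to_newick(tr), ";")
    }, character(1))
  } else {
    if (n == 2L) {
      strs <- paste0("(", taxa[1], ",", taxa[2], ");")
    } else {
      shapes <- build_rooted(taxa[-1])
      strs <- vapply(shapes, function(tr) {
        paste0("(", taxa[1], ",", to_newick(tr), ");")
      }, character(1))
    }
  }
  lapply(strs, function(s) canonicalize(ape::read.tree(text = s)))
}

#' Assign node ages from a calibration table
#'
#' Ages are in Ma before present and live on nodes; branch durations are
#' derived as parent age minus child age. Terminals default to age 0 (extant
#' taxa). Calibrated internal nodes are located as the most recent common
#' ancestor of a taxon pair, or as the clade spanning a `+`-separated label
#' set.
#'
#' @param tree a `"phylo"` object.
#' @param calibrations data frame with columns `clade` (either
#'   `"taxonA+taxonB"` naming an MRCA or `"root"`) and `age_ma`.
#' @param tip_ages optional named vector of non-zero terminal ages
#'   (fossil-flagged tips).
#' @param require_complete error when some internal node remains undated.
#' @return the tree with a `"node_ages"` attribute (vector indexed by node
#'   id).
#' @export
set_node_ages <- function(tree, calibrations, tip_ages = NULL,
                          require_complete = FALSE) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  ages <- rep(NA_real_, n_node)
  ages[seq_len(n_tip)] <- 0
  if (!is.null(tip_ages)) {
    idx <- match(names(tip_ages), tree$tip.label)
    ages[idx[!is.na(idx)]] <- tip_ages[!is.na(idx)]
  }
  root <- tree_root(tree)
  for (k in seq_len(nrow(calibrations))) {
    lab <- calibrations$clade[k]
    node <- if (identical(lab, "root")) root else {
      members <- strsplit(lab, "+", fixed = TRUE)[[1]]
      miss <- setdiff(members, tree$tip.label)
      if (length(miss) > 0L) {
        stop("calibration clade '", lab, "' names unknown taxa: ",
             paste(miss, collapse = ", "))
      }
      if (length(members) < 2L) match(members, tree$tip.label) else
        ape::getMRCA(tree, members)
    }
    ages[node] <- calibrations$age_ma[k]
  }
  if (require_complete && anyNA(ages)) {
    clade <- node_clades(tree)
    bad <- which(is.na(ages))[1]
    stop("no age for node spanning {",
         paste(clade[[bad]], collapse = ", "), "}")
  }
  # parent age must be at least child age wherever both are known
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (!is.na(ages[p]) && !is.na(ages[ch]) && ages[p] < ages[ch]) {
      stop("age inversion: parent younger than child at node ", ch)
    }
  }
  attr(tree, "node_ages") <- ages
  tree
}

#' Node ages of a tree
#'
#' @param tree a `"phylo"` with a `"node_ages"` attribute.
#' @return numeric vector indexed by node id, or `NULL`.
#' @export
node_ages <- function(tree) attr(tree, "node_ages")

#' Per-branch time spans
#'
#' @param tree a dated `"phylo"` (see [set_node_ages()]).
#' @return data frame with `branch` (key of the child clade), `branch_label`,
#'   `span_ma`.
#' @export
branch_spans <- function(tree) {
  ages <- node_ages(tree)
  if (is.null(ages)) stop("tree has no node ages; see set_node_ages()")
  keys <- branch_keys(tree)
  clade <- node_clades(tree)
  n_tip <- length(tree$tip.label)
  span <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (anyNA(span)) {
    bad <- tree$edge[which(is.na(span))[1], 2]
    stop("no age for node spanning {",
         paste(clade[[bad]], collapse = ", "), "}")
  }
  label <- vapply(tree$edge[, 2], function(v) {
    if (v <= n_tip) tree$tip.label[v] else paste(clade[[v]], collapse = "+")
  }, character(1))
  data.frame(branch = keys, branch_label = label, span_ma = span,
             stringsAsFactors = FALSE)
}

# canonical string of the unrooted topology (root on the pendant edge of the
# alphabetically first tip); used for topology identity checks
canonical_unrooted_string <- function(tree) {
  first <- sort(tree$tip.label)[1]
  canonical_newick_string(reroot(tree, first))
}

#' Test whether two trees share the same unrooted topology
#'
#' @param a,b `"phylo"` objects over the same terminal set.
#' @return `TRUE` or `FALSE`.
#' @export
same_unrooted_topology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  identical(canonical_unrooted_string(a), canonical_unrooted_string(b))
}
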