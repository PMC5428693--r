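# ---- scoring engines --------------------------------------------------------
#
# Two exact scorers:
#  * a vectorised Fitch set engine on state bitmasks (binary trees; scores all
#    characters of a matrix in one postorder pass) used throughout the
#    exhaustive and branch-and-bound searches;
#  * a Sankoff dynamic program with unit costs (per character), exact on
#    polytomies and the basis of most-parsimonious-reconstruction enumeration.
# Missing and inapplicable cells are full-domain wildcards in both: they can
# never force a step.

# edge: 2-column matrix (parent, child); tip ids must be <= ncol(M), internal
# ids above; M: n_char x n_tips bitmask matrix with columns indexed by tip id
fitch_engine <- function(edge, M, n_char) {
  n_node <- max(edge)
  kids <- vector("list", n_node)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]
    kids[[p]] <- c(kids[[p]], edge[k, 2])
  }
  root <- setdiff(unique(edge[, 1]), edge[, 2])[1]
  S <- matrix(0L, n_char, n_node)
  S[, seq_len(ncol(M))] <- M
  steps <- integer(n_char)
  for (v in postorder_nodes(kids, root)) {
    ks <- kids[[v]]
    a <- S[, ks[1]]
    for (kk in ks[-1]) {
      b <- S[, kk]
      iv <- bitwAnd(a, b)
      z <- iv == 0L
      if (any(z)) {
        steps[z] <- steps[z] + 1L
        u <- bitwOr(a, b)
        iv[z] <- u[z]
      }
      a <- iv
    }
    S[, v] <- a
  }
  list(steps = steps, sets = S, root = root)
}

# unit-cost Sankoff down-pass; tipsets: list indexed by node id (states,
# 0-based) for tips; returns nstates x n_node cost matrix
sankoff_costs <- function(kids, root, tipsets, nstates) {
  n_node <- length(kids)
  cost <- matrix(Inf, nstates, n_node)
  for (v in seq_len(n_node)) {
    if (is.null(kids[[v]])) cost[tipsets[[v]] + 1L, v] <- 0
  }
  for (v in postorder_nodes(kids, root)) {
    acc <- numeric(nstates)
    for (k in kids[[v]]) {
      ck <- cost[, k]
      acc <- acc + pmin(ck, min(ck) + 1)
    }
    cost[, v] <- acc
  }
  cost
}

# tip bitmask matrix aligned to a tree's tip numbering
tree_masks <- function(tree, m) {
  miss <- setdiff(tree$tip.label, m$taxa)
  if (length(miss) > 0L) {
    stop("terminals absent from the matrix: ", paste(miss, collapse = ", "))
  }
  cell_masks(m)[, match(tree$tip.label, m$taxa), drop = FALSE]
}

#' Fitch parsimony length of characters on a tree
#'
#' Minimum number of unordered state changes required by each character on
#' the given tree. Missing and inapplicable tips carry the full state domain
#' and never force a step; polymorphic tips carry their state set. Binary
#' trees are scored with the classic Fitch intersection/union pass;
#' polytomies are scored exactly with a unit-cost dynamic program.
#'
#' @param tree a rooted `"phylo"`; the length is invariant under rerooting.
#' @param m a `"char_matrix"` covering all terminals of the tree.
#' @param char optional single character id; when `NULL`, all characters.
#' @return integer steps, named by character id (scalar when `char` given).
#' @export
#' @examples
#' tre <- parse_newick("(Out,(A,(B,C)));")
#' m <- character_matrix(rbind(Out = "0", A = "0", B = "1", C = "1"))
#' fitch_length(tre, m)  # one step: a single gain on the (B,C) stem
fitch_length <- function(tree, m, char = NULL) {
  M <- tree_masks(tree, m)
  n_char <- nrow(M)
  if (!has_polytomy(tree)) {
    steps <- fitch_engine(tree$edge, M, n_char)$steps
  } else {
    kids <- tree_children(tree)
    root <- tree_root(tree)
    n_node <- max(tree$edge)
    steps <- integer(n_char)
    for (j in seq_len(n_char)) {
      ns <- m$chars$nstates[j]
      tipsets <- vector("list", n_node)
      for (v in seq_along(tree$tip.label)) {
        tipsets[[v]] <- mask_states(M[j, v])
      }
      cost <- sankoff_costs(kids, root, tipsets, ns)
      steps[j] <- as.integer(min(cost[, root]))
    }
  }
  names(steps) <- as.character(m$chars$id)
  if (!is.null(char)) steps <- steps[[as.character(char)]]
  steps
}

#' Minimum conceivable steps of a character (m_i)
#'
#' The fewest changes the character can require on any tree: one less than
#' the minimum number of distinct states needed to cover every scorable tip
#' (missing and inapplicable cells excluded). With no polymorphic cells this
#' is simply the number of observed states minus one; with polymorphism it is
#' the minimum hitting-set size minus one, so that `m_i <= s_i` always holds.
#'
#' @param m a `"char_matrix"`.
#' @param char optional single character id.
#' @return integer vector named by character id (scalar when `char` given).
#' @export
char_min_steps <- function(m, char = NULL) {
  out <- integer(nrow(m$chars))
  for (j in seq_len(nrow(m$chars))) {
    sets <- lapply(m$cells[, j], cell_states)
    sets <- sets[!vapply(sets, is.null, logical(1))]
    if (length(sets) == 0L) {
      out[j] <- 0L
      next
    }
    u <- sort(unique(unlist(sets)))
    hit <- NA_integer_
    for (k in seq_along(u)) {
      combos <- utils::combn(u, k, simplify = FALSE)
      for (D in combos) {
        if (all(vapply(sets, function(s) any(s %in% D), logical(1)))) {
          hit <- k
          break
        }
      }
      if (!is.na(hit)) break
    }
    out[j] <- hit - 1L
  }
  names(out) <- as.character(m$chars$id)
  if (!is.null(char)) out <- out[[as.character(char)]]
  out
}

#' Maximum conceivable steps of a character (g_i)
#'
#' Steps the character requires on a star (completely unresolved) tree: the
#' number of scorable tips minus the largest number of tips that can share
#' one state, with polymorphic tips counted toward their most favourable
#' state.
#'
#' @inheritParams char_min_steps
#' @return integer vector named by character id (scalar when `char` given).
#' @export
char_max_steps <- function(m, char = NULL) {
  out <- integer(nrow(m$chars))
  for (j in seq_len(nrow(m$chars))) {
    sets <- lapply(m$cells[, j], cell_states)
    sets <- sets[!vapply(sets, is.null, logical(1))]
    if (length(sets) == 0L) {
      out[j] <- 0L
      next
    }
    u <- sort(unique(unlist(sets)))
    best <- max(vapply(u, function(s) {
      sum(vapply(sets, function(x) s %in% x, logical(1)))
    }, integer(1)))
    out[j] <- length(sets) - best
  }
  names(out) <- as.character(m$chars$id)
  if (!is.null(char)) out <- out[[as.character(char)]]
  out
}

#' Tree length and ensemble homoplasy indices
#'
#' Scores a matrix on a tree: total length `L = sum(s_i)`, ensemble
#' consistency index `CI = sum(m_i)/sum(s_i)` and ensemble retention index
#' `RI = (sum(g_i) - sum(s_i)) / (sum(g_i) - sum(m_i))`.
#' Parsimony-uninformative characters (`g_i = m_i`) contribute identical
#' amounts to the RI numerator and denominator sums and are excluded from
#' them; for CI their inclusion is configurable (included by default, the
#' PAUP* convention). Percentages are rounded half away from zero; full
#' precision is retained in `ci` and `ri`.
#'
#' @param tree a rooted `"phylo"`.
#' @param m a `"char_matrix"`.
#' @param include_uninformative include parsimony-uninformative characters in
#'   the CI sums (default `TRUE`).
#' @return an object of class `"tree_score"`: list with `length`,
#'   `per_character_steps`, `min_steps`, `max_steps`, `ci`, `ri`,
#'   `ci_percent`, `ri_percent`, and `ci_defined` (`FALSE` when `L = 0`
#'   forces the conventional report of CI = 100).
#' @export
ensemble_indices <- function(tree, m, include_uninformative = TRUE) {
  s <- fitch_length(tree, m)
  mi <- char_min_steps(m)
  gi <- char_max_steps(m)
  L <- sum(s)
  informative <- gi > mi
  keep_ci <- if (include_uninformative) rep(TRUE, length(s)) else informative

  ci_defined <- sum(s[keep_ci]) > 0
  ci <- if (ci_defined) sum(mi[keep_ci]) / sum(s[keep_ci]) else 1
  den <- sum(gi[informative]) - sum(mi[informative])
  ri <- if (den > 0) {
    (sum(gi[informative]) - sum(s[informative])) / den
  } else NA_real_

  structure(list(
    length = as.integer(L),
    per_character_steps = s,
    min_steps = mi,
    max_steps = gi,
    ci = ci,
    ri = ri,
    ci_percent = round_half_up(100 * ci),
    ri_percent = if (is.na(ri)) NA_integer_ else round_half_up(100 * ri),
    ci_defined = ci_defined
  ), class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat(sprintf("L = %d, CI = %s, RI = %s\n", x$length,
              x$ci_percent,
              if (is.na(x$ri_percent)) "undefined" else x$ri_percent))
  if (!x$ci_defined) cat("  (zero-length tree: CI reported as 100 by convention)\n")
  invisible(x)
}

# ---- branch-and-bound search ------------------------------------------------

insert_tip_on_edge <- function(edge, eidx, tip, newnode) {
  v <- edge[eidx, 2]
  edge[eidx, 2] <- newnode
  rbind(edge, c(newnode, v), c(newnode, tip))
}

edge_matrix_to_newick <- function(edge, tip_labels) {
  n_node <- max(edge)
  kids <- vector("list", n_node)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]
    kids[[p]] <- c(kids[[p]], edge[k, 2])
  }
  root <- setdiff(unique(edge[, 1]), edge[, 2])[1]
  rec <- function(v) {
    if (is.null(kids[[v]])) return(tip_labels[v])
    paste0("(", paste(vapply(kids[[v]], rec, character(1)), collapse = ","),
           ")")
  }
  paste0(rec(root), ";")
}

#' Exact maximum-parsimony tree search by branch and bound
#'
#' Returns every unrooted topology attaining the global minimum length,
#' rooted on the outgroup for reporting. Taxa are added stepwise; a partial
#' tree is abandoned when its length plus a lower bound on the cost of the
#' unplaced taxa (one step for each state found only in fixed cells of
#' unplaced taxa) exceeds the best complete length seen. The incumbent is
#' seeded by greedy stepwise addition. Guaranteed identical to exhaustive
#' enumeration; practical to the default 16-taxon ceiling.
#'
#' @param m a `"char_matrix"`.
#' @param outgroup terminal used to root the reported trees.
#' @param max_taxa refuse larger problems (heuristic search is out of scope
#'   for this package).
#' @return an object of class `"mpt_search"`: list with `trees` (list of
#'   canonical rooted `"phylo"`), `length`, `score` (a `"tree_score"` for the
#'   first tree), and `outgroup`.
#' @export
branch_and_bound_search <- function(m, outgroup, max_taxa = 16L) {
  taxa <- m$taxa
  n <- length(taxa)
  if (!(outgroup %in% taxa)) stop("outgroup '", outgroup, "' not in matrix")
  if (n < 3L) stop("tree search needs at least 3 taxa")
  if (n > max_taxa) {
    stop(n, " taxa exceeds the exact-search ceiling of ", max_taxa,
         "; heuristic search is outside the scope of this package")
  }
  v <- validate_matrix(m)
  if (nrow(v) > 0L) stop("invalid matrix: ", v$message[1])

  M <- cell_masks(m)
  n_char <- nrow(M)
  ord <- seq_len(n)

  # lower-bound bookkeeping: states that occur only in fixed (singleton)
  # cells of not-yet-placed taxa each force at least one additional step
  pc <- matrix(mask_popcount(as.integer(M)), n_char, n)
  prefix <- matrix(0L, n_char, n)
  acc <- rep(0L, n_char)
  for (k in seq_len(n)) {
    acc <- bitwOr(acc, M[, ord[k]])
    prefix[, k] <- acc
  }
  extra <- integer(n)
  for (k in seq_len(n - 1L)) {
    forced <- rep(0L, n_char)
    for (t in ord[(k + 1L):n]) {
      sing <- pc[, t] == 1L
      if (any(sing)) {
        add <- M[, t]
        add[!sing] <- 0L
        forced <- bitwOr(forced, add)
      }
    }
    novel <- bitwAnd(forced, bitwNot(prefix[, k]))
    extra[k] <- sum(mask_popcount(novel))
  }

  root <- n + 1L
  o1 <- ord[1]
  edge0 <- rbind(c(root, o1), c(root, n + 2L),
                 c(n + 2L, ord[2]), c(n + 2L, ord[3]))
  score_len <- function(edge) sum(fitch_engine(edge, M, n_char)$steps)

  # greedy stepwise addition seeds the incumbent bound
  edge <- edge0
  for (k in seq_len(n)[-(1:3)]) {
    tip <- ord[k]
    newnode <- n + k - 1L
    lens <- rep(Inf, nrow(edge))
    for (e in seq_len(nrow(edge))) {
      if (edge[e, 1] == root && edge[e, 2] == o1) next
      lens[e] <- score_len(insert_tip_on_edge(edge, e, tip, newnode))
    }
    edge <- insert_tip_on_edge(edge, which.min(lens), tip, newnode)
  }
  best <- new.env(parent = emptyenv())
  best$len <- score_len(edge)
  best$trees <- list()

  recurse <- function(edge, k) {
    len <- score_len(edge)
    if (k > n) {
      if (len < best$len) {
        best$len <- len
        best$trees <- list(edge)
      } else if (len == best$len) {
        best$trees <- c(best$trees, list(edge))
      }
      return(invisible(NULL))
    }
    if (len + extra[k - 1L] > best$len) return(invisible(NULL))
    tip <- ord[k]
    newnode <- n + k - 1L
    for (e in seq_len(nrow(edge))) {
      if (edge[e, 1] == root && edge[e, 2] == o1) next
      recurse(insert_tip_on_edge(edge, e, tip, newnode), k + 1L)
    }
    invisible(NULL)
  }
  recurse(edge0, 4L)

  strs <- vapply(best$trees, edge_matrix_to_newick, character(1),
                 tip_labels = taxa)
  trees <- lapply(strs, function(s) reroot(ape::read.tree(text = s), outgroup))
  keys <- vapply(trees, canonical_newick_string, character(1), ages = NULL)
  trees <- trees[!duplicated(keys)]

  structure(list(
    trees = trees,
    length = as.integer(best$len),
    score = ensemble_indices(trees[[1]], m),
    outgroup = outgroup
  ), class = "mpt_search")
}

#' @export
print.mpt_search <- function(x, ...) {
  cat(length(x$trees),
      if (length(x$trees) == 1L) "most parsimonious tree," else
        "most parsimonious trees,", "L =", x$length, "\n")
  print(x$score)
  for (t in x$trees) cat(" ", write_newick(t, ages = FALSE), "\n")
  invisible(x)
}
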