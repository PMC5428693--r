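# ---- most-parsimonious reconstructions ---------------------------------------
#
# A reconstruction assigns one state to every node (terminals are fixed to an
# element of their state set; missing/inapplicable terminals may take any
# state) such that the number of branches whose endpoints differ equals the
# character's Fitch length. All reconstructions are enumerated by
# backtracking over the optimal choices of the unit-cost Sankoff dynamic
# program: given a parent state, the optimal states of a child subtree are
# exactly those minimising subtree cost plus the one-step change penalty.

mpr_setup <- function(tree, m, char) {
  j <- char_index(m, char)
  ns <- m$chars$nstates[j]
  sets <- char_state_sets(m, char)
  miss <- setdiff(tree$tip.label, names(sets))
  if (length(miss) > 0L) {
    stop("terminals absent from the matrix: ", paste(miss, collapse = ", "))
  }
  kids <- tree_children(tree)
  root <- tree_root(tree)
  n_node <- max(tree$edge)
  tipsets <- vector("list", n_node)
  for (v in seq_along(tree$tip.label)) {
    tipsets[[v]] <- sets[[tree$tip.label[v]]]
  }
  parent_of <- integer(n_node)
  for (k in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[k, 2]] <- tree$edge[k, 1]
  }
  clade <- node_clades(tree)
  node_names <- vapply(seq_len(n_node), function(v) {
    if (v <= length(tree$tip.label)) tree$tip.label[v] else
      paste(clade[[v]], collapse = "+")
  }, character(1))
  list(char_id = m$chars$id[j], nstates = ns, kids = kids, root = root,
       n_node = n_node, tipsets = tipsets, parent_of = parent_of,
       pre = preorder_all_nodes(kids, root), node_names = node_names,
       cost = sankoff_costs(kids, root, tipsets, ns), tree = tree)
}

# change table implied by one full node-state assignment
changes_from_states <- function(setup, states) {
  tree <- setup$tree
  root_state <- states[setup$root]
  rows <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    if (states[p] != states[ch]) {
      rows[[length(rows) + 1L]] <- data.frame(
        char = setup$char_id,
        branch = setup$node_names[ch],
        from = states[p],
        to = states[ch],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(char = integer(), branch = character(),
               from = integer(), to = integer(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  classify_changes(out, root_state)
}

#' Label changes as acquisitions or reversions
#'
#' A change is a reversion when it returns to the state held at the root of
#' the reconstruction (the outgroup-anchored ancestral condition, state 0 by
#' coding convention) from a different state; every other change is an
#' acquisition, i.e. a move away from the ancestral condition.
#'
#' @param changes data frame with `from` and `to` columns.
#' @param root_state the root state of the reconstruction under evaluation.
#' @return `changes` with a `direction` column set.
#' @export
classify_changes <- function(changes, root_state) {
  changes$direction <- ifelse(
    changes$to == root_state & changes$from != root_state,
    "reversion", "acquisition")
  changes
}

#' Enumerate all most-parsimonious reconstructions of one character
#'
#' Every distinct minimum-change assignment of states to the tree's nodes,
#' each with its implied branch changes. Terminals with polymorphic cells are
#' resolved to one of their states per reconstruction; missing and
#' inapplicable terminals range over the full domain. Multiple
#' reconstructions signal ambiguity in where changes are placed (e.g. a
#' single stem gain followed by reversions versus independent terminal
#' acquisitions of equal cost).
#'
#' @param tree a rooted `"phylo"` (the outgroup anchors the root state).
#' @param m a `"char_matrix"`.
#' @param char character id.
#' @param max_mprs guard against combinatorial explosion.
#' @return list of reconstructions, each a list with `char`, `node_states`
#'   (named integer vector over all nodes), `root_state`, `changes` (data
#'   frame: `char`, `branch`, `from`, `to`, `direction`) and `length`.
#' @export
enumerate_mprs <- function(tree, m, char, max_mprs = 200000L) {
  st <- mpr_setup(tree, m, char)
  dom <- 0:(st$nstates - 1L)
  root_opts <- dom[st$cost[, st$root] == min(st$cost[, st$root])]
  A <- matrix(NA_integer_, length(root_opts), st$n_node)
  A[, st$root] <- root_opts
  for (v in st$pre[-1]) {
    p <- st$parent_of[v]
    pieces <- list()
    for (ps in unique(A[, p])) {
      val <- st$cost[, v] + as.numeric(dom != ps)
      allowed <- dom[val == min(val)]
      sub <- A[A[, p] == ps, , drop = FALSE]
      for (s in allowed) {
        block <- sub
        block[, v] <- s
        pieces[[length(pieces) + 1L]] <- block
      }
    }
    A <- do.call(rbind, pieces)
    if (nrow(A) > max_mprs) {
      stop("more than ", max_mprs, " reconstructions for character ",
           st$char_id, "; raise max_mprs")
    }
  }
  lapply(seq_len(nrow(A)), function(i) {
    states <- A[i, ]
    names(states) <- st$node_names
    ch <- changes_from_states(st, states)
    list(char = st$char_id, node_states = states,
         root_state = states[st$root], changes = ch, length = nrow(ch))
  })
}

# single-pass policy selection over the Sankoff-optimal state sets:
# DELTRAN keeps the parent state whenever it is optimal (delaying changes
# toward the tips); ACCTRAN prefers a change on the current branch whenever
# one is optimal (accelerating changes toward the root). Remaining ties break
# to the smallest state.
select_mpr_states <- function(setup, policy = c("deltran", "acctran")) {
  policy <- match.arg(policy)
  dom <- 0:(setup$nstates - 1L)
  states <- integer(setup$n_node)
  rc <- setup$cost[, setup$root]
  states[setup$root] <- min(dom[rc == min(rc)])
  for (v in setup$pre[-1]) {
    ps <- states[setup$parent_of[v]]
    val <- setup$cost[, v] + as.numeric(dom != ps)
    allowed <- dom[val == min(val)]
    states[v] <- if (policy == "deltran") {
      if (ps %in% allowed) ps else min(allowed)
    } else {
      changed <- setdiff(allowed, ps)
      if (length(changed) > 0L) min(changed) else ps
    }
  }
  names(states) <- setup$node_names
  states
}

change_key <- function(df) paste(df$branch, df$from, df$to, sep = "\r")

#' Map character changes onto tree branches
#'
#' For every character, the branch changes of one most-parsimonious
#' reconstruction selected by `policy` (DELTRAN by default: ambiguous changes
#' are delayed toward the tips, favouring independent terminal acquisitions;
#' ACCTRAN accelerates them toward the root, favouring early gains with
#' later reversions). Each change is flagged `ambiguous = FALSE` only when
#' the identical branch/from/to change occurs in every most-parsimonious
#' reconstruction of that character.
#'
#' @param tree a rooted `"phylo"`.
#' @param m a `"char_matrix"`.
#' @param policy `"deltran"` (default) or `"acctran"`.
#' @param max_mprs guard for the ambiguity enumeration.
#' @return data frame with columns `char`, `branch` (tip label or
#'   `+`-separated clade of the branch's child node), `from`, `to`,
#'   `direction`, `ambiguous`, `n_mpr`; one row per change. The per-branch
#'   tallies are available via [branch_change_totals()].
#' @export
map_branch_changes <- function(tree, m, policy = c("deltran", "acctran"),
                               max_mprs = 200000L) {
  policy <- match.arg(policy)
  rows <- list()
  for (id in m$chars$id) {
    setup <- mpr_setup(tree, m, id)
    mprs <- enumerate_mprs(tree, m, id, max_mprs = max_mprs)
    sel <- changes_from_states(setup, select_mpr_states(setup, policy))
    if (nrow(sel) == 0L) next
    keys <- lapply(mprs, function(r) change_key(r$changes))
    everywhere <- Reduce(intersect, keys)
    sel$ambiguous <- !(change_key(sel) %in% everywhere)
    sel$n_mpr <- length(mprs)
    rows[[length(rows) + 1L]] <- sel
  }
  if (length(rows) == 0L) {
    return(data.frame(char = integer(), branch = character(),
                      from = integer(), to = integer(),
                      direction = character(), ambiguous = logical(),
                      n_mpr = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-branch change totals
#'
#' Tallies a change table over every branch of the tree, including branches
#' that carry no changes (e.g. a lineage in complete stasis).
#'
#' @param changes output of [map_branch_changes()].
#' @param tree the tree the changes were mapped on.
#' @return data frame with `branch`, `n_changes`, `n_unambiguous`.
#' @export
branch_change_totals <- function(changes, tree) {
  clade <- node_clades(tree)
  n_tip <- length(tree$tip.label)
  labels <- vapply(tree$edge[, 2], function(v) {
    if (v <= n_tip) tree$tip.label[v] else paste(clade[[v]], collapse = "+")
  }, character(1))
  n_changes <- vapply(labels, function(b) sum(changes$branch == b),
                      integer(1))
  n_unamb <- vapply(labels, function(b) {
    sum(changes$branch == b & !changes$ambiguous)
  }, integer(1))
  data.frame(branch = labels, n_changes = n_changes,
             n_unambiguous = n_unamb, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Synapomorphy table: unambiguous and candidate changes per branch
#'
#' For each branch, the characters whose change on it is present in every
#' most-parsimonious reconstruction (unambiguous synapomorphies of the
#' clade the branch subtends), and separately the ambiguous candidates: all
#' alternative placements that occur in at least one but not every
#' reconstruction.
#'
#' @inheritParams map_branch_changes
#' @return data frame with columns `branch`, `char`, `from`, `to`,
#'   `direction`, `status` (`"unambiguous"` or `"ambiguous"`); ambiguous
#'   rows enumerate every alternative placement.
#' @export
summarize_synapomorphies <- function(tree, m, policy = "deltran",
                                     max_mprs = 200000L) {
  rows <- list()
  for (id in m$chars$id) {
    mprs <- enumerate_mprs(tree, m, id, max_mprs = max_mprs)
    n_mpr <- length(mprs)
    all_changes <- do.call(rbind, lapply(mprs, `[[`, "changes"))
    if (is.null(all_changes) || nrow(all_changes) == 0L) next
    key <- change_key(all_changes)
    tab <- table(key)
    uni <- !duplicated(key)
    df <- all_changes[uni, , drop = FALSE]
    df$status <- ifelse(tab[change_key(df)] == n_mpr,
                        "unambiguous", "ambiguous")
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0L) {
    return(data.frame(char = integer(), branch = character(),
                      from = integer(), to = integer(),
                      direction = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$branch, out$char), ]
}
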