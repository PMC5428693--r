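# Independent oracles: brute-force enumeration over explicit node-state
# assignments. Deliberately naive -- no set dynamics, no dynamic programming --
# so they share nothing with the implementation they check.

# state sets per tip of `tree`, in tree tip order, from a char_matrix column
oracle_tipsets <- function(tree, m, char) {
  j <- match(char, m$chars$id)
  ns <- m$chars$nstates[j]
  lapply(tree$tip.label, function(tx) {
    tok <- m$cells[match(tx, m$taxa), j]
    st <- myoclad:::cell_states(tok)
    if (is.null(st)) 0:(ns - 1L) else st
  })
}

# all full node-state assignments and their change counts
oracle_assignments <- function(tree, tipsets, nstates) {
  n_node <- max(tree$edge)
  n_tip <- length(tree$tip.label)
  domains <- vector("list", n_node)
  for (v in seq_len(n_node)) {
    domains[[v]] <- if (v <= n_tip) tipsets[[v]] else 0:(nstates - 1L)
  }
  grid <- as.matrix(expand.grid(domains, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- NULL
  E <- tree$edge
  steps <- rowSums(vapply(seq_len(nrow(E)), function(k) {
    grid[, E[k, 1]] != grid[, E[k, 2]]
  }, logical(nrow(grid))))
  list(grid = grid, steps = steps)
}

# minimum change count over all assignments
oracle_fitch <- function(tree, m, char) {
  j <- match(char, m$chars$id)
  a <- oracle_assignments(tree, oracle_tipsets(tree, m, char),
                          m$chars$nstates[j])
  min(a$steps)
}

# the full set of optimal assignments, as sorted state-vector strings
oracle_mpr_set <- function(tree, m, char) {
  j <- match(char, m$chars$id)
  a <- oracle_assignments(tree, oracle_tipsets(tree, m, char),
                          m$chars$nstates[j])
  opt <- a$grid[a$steps == min(a$steps), , drop = FALSE]
  sort(apply(opt, 1, paste, collapse = ""))
}

# random binary/multistate matrix over given taxa
random_test_matrix <- function(taxa, n_char, nstates = 2L, seed,
                               p_missing = 0, p_poly = 0) {
  set.seed(seed)
  cells <- matrix("0", length(taxa), n_char, dimnames = list(taxa, NULL))
  for (j in seq_len(n_char)) {
    for (i in seq_along(taxa)) {
      r <- runif(1)
      cells[i, j] <- if (r < p_missing) {
        "?"
      } else if (r < p_missing + p_poly && nstates >= 2L) {
        paste(sort(sample(0:(nstates - 1L), 2L)), collapse = "")
      } else {
        as.character(sample(0:(nstates - 1L), 1L))
      }
    }
  }
  character_matrix(cells, chars = data.frame(id = seq_len(n_char),
                                             nstates = nstates))
}

# random rooted binary topology over given labels (via ape, independent of
# the package's own generator)
random_test_tree <- function(labels, seed) {
  set.seed(seed)
  phy <- ape::rtree(length(labels), tip.label = sample(labels))
  phy$edge.length <- NULL
  canonicalize(phy)
}

# convert a (non-polymorphic, complete) char_matrix to phangorn's phyDat
as_phydat <- function(m) {
  lv <- as.character(0:(max(m$chars$nstates) - 1L))
  phangorn::phyDat(m$cells, type = "USER", levels = lv, ambiguity = "?")
}
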