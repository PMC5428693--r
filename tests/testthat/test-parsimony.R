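test_that("worked-example characters score their printed step counts", {
  fx <- build_paper_fixtures()
  expect_equal(fitch_length(fx$tree, fx$matrix, 112), 3L)
  expect_equal(fitch_length(fx$tree, fx$matrix, 66), 2L)
  # a constant character needs no steps
  m <- character_matrix(matrix("0", 7, 1,
                               dimnames = list(fx$matrix$taxa, NULL)))
  expect_equal(unname(fitch_length(fx$tree, m)), 0L)
  expect_error(fitch_length(fx$tree, subset_matrix(fx$matrix,
                                                   taxa = fx$matrix$taxa[-1])),
               "absent from the matrix")
})

test_that("Fitch length equals the exhaustive-assignment minimum", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(4:7, 1)
    taxa <- sprintf("t%02d", seq_len(n))
    tre <- random_test_tree(taxa, seed)
    m <- random_test_matrix(taxa, 3, nstates = 3L, seed = seed + 500,
                            p_missing = 0.15, p_poly = 0.15)
    for (ch in m$chars$id) {
      expect_equal(unname(fitch_length(tre, m, ch)), oracle_fitch(tre, m, ch))
    }
  }
})

test_that("polytomous trees score exactly (checked against phangorn sankoff)", {
  skip_if_not_installed("phangorn")
  star <- parse_newick("(A,B,C,D,E,F);")
  m <- character_matrix(matrix(c("0", "0", "1", "1", "2", "0"), 6, 1,
                               dimnames = list(LETTERS[1:6], NULL)),
                        chars = data.frame(id = 1, nstates = 3))
  # two independent 1s and one 2 around the star centre at state 0
  expect_equal(unname(fitch_length(star, m)), 3L)
  pd <- as_phydat(m)
  expect_equal(unname(fitch_length(star, m, 1)),
               as.integer(phangorn::parsimony(star, pd, method = "sankoff")))
})

test_that("fitch_length agrees with phangorn on random binary trees", {
  skip_if_not_installed("phangorn")
  for (seed in 1:10) {
    taxa <- sprintf("t%02d", 1:8)
    tre <- random_test_tree(taxa, seed)
    m <- random_test_matrix(taxa, 12, nstates = 3L, seed = seed + 900)
    expect_equal(sum(fitch_length(tre, m)),
                 as.integer(phangorn::parsimony(tre, as_phydat(m),
                                                method = "fitch")))
  }
})

test_that("character step bounds follow their definitions", {
  cells <- rbind(A = c("0", "0", "?", "01"),
                 B = c("1", "1", "?", "0"),
                 C = c("0", "2", "?", "0"),
                 D = c("1", "2", "?", "0"))
  m <- character_matrix(cells, chars = data.frame(id = 1:4, nstates = 3L))
  expect_equal(unname(char_min_steps(m)), c(1L, 2L, 0L, 0L))
  # char 4: the polymorphic tip can collapse onto state 0, so m = 0 <= s
  expect_equal(unname(char_max_steps(m)), c(2L, 2L, 0L, 0L))

  seven3 <- character_matrix(
    matrix(c(rep("0", 7), rep("1", 3)), ncol = 1,
           dimnames = list(sprintf("t%d", 1:10), NULL)))
  expect_equal(unname(char_max_steps(seven3)), 3L)

  # multistate g equals the Fitch length on the star tree
  taxa <- LETTERS[1:6]
  star <- parse_newick(paste0("(", paste(taxa, collapse = ","), ");"))
  for (seed in 1:8) {
    m2 <- random_test_matrix(taxa, 4, nstates = 3L, seed = seed,
                             p_poly = 0.2)
    expect_equal(unname(char_max_steps(m2)), unname(fitch_length(star, m2)))
  }
})

test_that("m_i <= s_i <= g_i on every tree", {
  for (seed in 1:12) {
    n <- 4 + (seed %% 4)
    taxa <- sprintf("t%02d", seq_len(n))
    tre <- random_test_tree(taxa, seed)
    m <- random_test_matrix(taxa, 6, nstates = 3L, seed = seed + 300,
                            p_missing = 0.1, p_poly = 0.1)
    s <- fitch_length(tre, m)
    expect_true(all(char_min_steps(m) <= s))
    expect_true(all(s <= char_max_steps(m)))
  }
})

test_that("ensemble indices match their definitions and phangorn", {
  # hand-computed 5-taxon, 4-character example
  cells <- rbind(Out = c("0", "0", "0", "0"),
                 A   = c("1", "0", "1", "0"),
                 B   = c("1", "1", "0", "0"),
                 C   = c("0", "1", "1", "0"),
                 D   = c("0", "0", "1", "1"))
  m <- character_matrix(cells)
  tre <- parse_newick("(Out,(A,(B,(C,D))));")
  sc <- ensemble_indices(tre, m)
  # by hand: s = (2, 2, 2, 1), m = (1, 1, 1, 1), g = (2, 2, 2, 1)
  expect_equal(unname(sc$per_character_steps), c(2L, 2L, 2L, 1L))
  expect_equal(sc$length, 7L)
  expect_equal(sc$ci, 4 / 7)
  expect_equal(sc$ri, 0)
  expect_equal(sc$ci_percent, 57L)
  expect_equal(sc$ri_percent, 0L)

  skip_if_not_installed("phangorn")
  pd <- as_phydat(m)
  expect_equal(sc$ci, phangorn::CI(tre, pd))
  expect_equal(sc$ri, phangorn::RI(tre, pd))
})

test_that("homoplasy-free matrices score CI = RI = 100 on their tree", {
  tre <- parse_newick("(Out,(A,(B,(C,(D,E)))));")
  # one character marking each non-trivial clade plus a shared autapomorphy
  cells <- rbind(Out = c("0", "0", "0", "0"),
                 A   = c("1", "0", "0", "0"),
                 B   = c("1", "1", "0", "0"),
                 C   = c("1", "1", "1", "0"),
                 D   = c("1", "1", "1", "1"),
                 E   = c("1", "1", "1", "1"))
  m <- character_matrix(cells)
  sc <- ensemble_indices(tre, m)
  expect_equal(sc$ci_percent, 100L)
  expect_equal(sc$ri_percent, 100L)
  # zero-length tree: CI conventionally 100, flagged
  const <- character_matrix(matrix("0", 6, 1, dimnames = list(rownames(cells),
                                                              NULL)))
  sc0 <- ensemble_indices(tre, const)
  expect_false(sc0$ci_defined)
  expect_equal(sc0$ci_percent, 100L)
})

test_that("branch and bound equals exhaustive search", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:7, 1)
    taxa <- sprintf("t%02d", seq_len(n))
    m <- random_test_matrix(taxa, 8, nstates = 2L, seed = seed + 700,
                            p_missing = 0.05)
    bb <- branch_and_bound_search(m, outgroup = taxa[1])
    all_tops <- enumerate_topologies(taxa)
    lens <- vapply(all_tops, function(t) sum(fitch_length(t, m)), integer(1))
    expect_equal(bb$length, min(lens))
    exp_keys <- sort(vapply(all_tops[lens == min(lens)],
                            myoclad:::canonical_unrooted_string,
                            character(1)))
    got_keys <- sort(vapply(bb$trees, myoclad:::canonical_unrooted_string,
                            character(1)))
    expect_equal(got_keys, exp_keys)
  }
})

test_that("a homoplasy-free matrix recovers its generating tree exactly", {
  taxa <- sprintf("t%02d", 1:8)
  tre <- random_test_tree(taxa, 99)
  kids <- myoclad:::tree_children(tre)
  root <- myoclad:::tree_root(tre)
  clades <- myoclad:::node_clades(tre)
  internal <- setdiff(myoclad:::postorder_nodes(kids, root), root)
  cells <- vapply(internal, function(v) {
    ifelse(taxa %in% clades[[v]], "1", "0")
  }, character(length(taxa)))
  rownames(cells) <- taxa
  m <- character_matrix(cells)
  bb <- branch_and_bound_search(m, outgroup = taxa[1])
  expect_equal(length(bb$trees), 1L)
  expect_true(same_unrooted_topology(bb$trees[[1]], tre))
  expect_equal(bb$length, sum(char_min_steps(m)))
  expect_equal(bb$score$ci_percent, 100L)

  # an uninformative character shifts L by its fixed cost, not the tree set
  m2 <- character_matrix(cbind(cells, ifelse(taxa == "t03", "1", "0")))
  bb2 <- branch_and_bound_search(m2, outgroup = taxa[1])
  expect_equal(bb2$length, bb$length + 1L)
  expect_true(same_unrooted_topology(bb2$trees[[1]], bb$trees[[1]]))
  expect_equal(length(bb2$trees), 1L)

  expect_error(branch_and_bound_search(m, outgroup = taxa[1], max_taxa = 5),
               "heuristic")
})
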