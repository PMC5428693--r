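# change-set signature of one reconstruction, for set comparisons
change_sig <- function(changes) {
  paste(sort(paste(changes$branch, changes$from, changes$to)), collapse = ";")
}

test_that("character 112 yields the two described equal-parsimony scenarios", {
  fx <- build_paper_fixtures()
  mprs <- enumerate_mprs(fx$tree, fx$matrix, 112)
  expect_gte(length(mprs), 2L)
  expect_true(all(vapply(mprs, `[[`, integer(1), "length") == 3L))
  sigs <- vapply(mprs, function(r) change_sig(r$changes), character(1))
  great_apes <- "Gorilla+Homo+P_paniscus+P_troglodytes+Pongo"
  stem_gain <- change_sig(data.frame(
    branch = c(great_apes, "Homo", "P_paniscus"),
    from = c(0, 1, 1), to = c(1, 0, 0)))
  independent <- change_sig(data.frame(
    branch = c("Pongo", "Gorilla", "P_troglodytes"),
    from = c(0, 0, 0), to = c(1, 1, 1)))
  expect_true(stem_gain %in% sigs)
  expect_true(independent %in% sigs)
})

test_that("character 66 yields stem-gain-plus-bonobo-loss or two independent gains", {
  fx <- build_paper_fixtures()
  mprs <- enumerate_mprs(fx$tree, fx$matrix, 66)
  expect_equal(length(mprs), 2L)
  expect_true(all(vapply(mprs, `[[`, integer(1), "length") == 2L))
  sigs <- vapply(mprs, function(r) change_sig(r$changes), character(1))
  panins_humans <- "Homo+P_paniscus+P_troglodytes"
  expect_true(change_sig(data.frame(
    branch = c(panins_humans, "P_paniscus"),
    from = c(0, 1), to = c(1, 0))) %in% sigs)
  expect_true(change_sig(data.frame(
    branch = c("P_troglodytes", "Homo"),
    from = c(0, 0), to = c(1, 1))) %in% sigs)
})

test_that("a constant character has exactly one zero-change reconstruction", {
  fx <- build_paper_fixtures()
  m <- character_matrix(matrix("0", 7, 1,
                               dimnames = list(fx$matrix$taxa, NULL)))
  mprs <- enumerate_mprs(fx$tree, m, 1)
  expect_equal(length(mprs), 1L)
  expect_equal(mprs[[1]]$length, 0L)
  expect_true(all(mprs[[1]]$node_states == 0L))
})

test_that("MPR sets equal the brute-force optimal-assignment filter", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(4:6, 1)
    taxa <- sprintf("t%02d", seq_len(n))
    tre <- random_test_tree(taxa, seed)
    m <- random_test_matrix(taxa, 2, nstates = 3L, seed = seed + 40,
                            p_missing = 0.15, p_poly = 0.15)
    for (ch in m$chars$id) {
      mprs <- enumerate_mprs(tre, m, ch)
      got <- sort(vapply(mprs, function(r) {
        paste(unname(r$node_states), collapse = "")
      }, character(1)))
      expect_equal(got, oracle_mpr_set(tre, m, ch))
      # every reconstruction attains exactly the Fitch length
      expect_true(all(vapply(mprs, `[[`, integer(1), "length") ==
                        fitch_length(tre, m, ch)))
    }
  }
})

test_that("a change is unambiguous exactly when present in every MPR", {
  for (seed in 1:8) {
    taxa <- sprintf("t%02d", 1:6)
    tre <- random_test_tree(taxa, seed)
    m <- random_test_matrix(taxa, 4, nstates = 2L, seed = seed + 60,
                            p_poly = 0.1)
    mapped <- map_branch_changes(tre, m, policy = "deltran")
    for (ch in unique(mapped$char)) {
      mprs <- enumerate_mprs(tre, m, ch)
      keys <- lapply(mprs, function(r) {
        paste(r$changes$branch, r$changes$from, r$changes$to)
      })
      everywhere <- Reduce(intersect, keys)
      sub <- mapped[mapped$char == ch, ]
      expect_equal(!sub$ambiguous,
                   paste(sub$branch, sub$from, sub$to) %in% everywhere)
    }
    # per-character change counts under any policy sum to the Fitch length
    s <- fitch_length(tre, m)
    for (pol in c("deltran", "acctran")) {
      mp <- map_branch_changes(tre, m, policy = pol)
      counts <- table(factor(mp$char, levels = m$chars$id))
      expect_equal(as.integer(counts), unname(as.integer(s)))
    }
  }
})

test_that("direction classification is anchored to the root state", {
  ch <- data.frame(from = c(0, 1, 1, 2), to = c(1, 0, 2, 0))
  out <- classify_changes(ch, root_state = 0)
  expect_equal(out$direction,
               c("acquisition", "reversion", "acquisition", "reversion"))
})

test_that("fixture change placements match the described reassignments", {
  fx <- build_paper_fixtures()
  mapped <- map_branch_changes(fx$tree, fx$matrix, policy = "deltran")

  tro <- mapped[mapped$branch == "P_troglodytes" &
                  mapped$char %in% c(83, 140), ]
  expect_equal(sort(tro$char), c(83, 140))
  expect_true(all(tro$direction == "reversion"))
  expect_true(all(!tro$ambiguous))
  expect_true(all(tro$from == 1 & tro$to == 0))

  pan <- mapped[mapped$branch == "P_paniscus+P_troglodytes", ]
  expect_equal(sort(pan$char[!pan$ambiguous]), c(120, 131))
  expect_true(all(pan$direction[!pan$ambiguous] == "reversion"))

  expect_equal(sum(mapped$branch == "P_paniscus"), 0L)
})

test_that("DELTRAN delays ambiguous changes and ACCTRAN accelerates them", {
  fx <- build_paper_fixtures()
  del <- map_branch_changes(fx$tree, fx$matrix, policy = "deltran")
  acc <- map_branch_changes(fx$tree, fx$matrix, policy = "acctran")
  d112 <- del[del$char == 112, ]
  expect_setequal(d112$branch, c("Pongo", "Gorilla", "P_troglodytes"))
  a112 <- acc[acc$char == 112, ]
  expect_true("Gorilla+Homo+P_paniscus+P_troglodytes+Pongo" %in% a112$branch)
  a66 <- acc[acc$char == 66, ]
  expect_true("Homo+P_paniscus+P_troglodytes" %in% a66$branch)
  expect_true("P_paniscus" %in% a66$branch)  # subsequent loss in bonobos
})

test_that("the synapomorphy table separates unambiguous from candidate changes", {
  fx <- build_paper_fixtures()
  syn <- summarize_synapomorphies(fx$tree, fx$matrix)
  pan <- syn[syn$branch == "P_paniscus+P_troglodytes" &
               syn$status == "unambiguous", ]
  expect_equal(sort(pan$char), c(120, 131))
  s66 <- syn[syn$char == 66, ]
  expect_true(all(s66$status == "ambiguous"))
  expect_setequal(s66$branch[s66$to == 1],
                  c("Homo+P_paniscus+P_troglodytes", "P_troglodytes", "Homo"))

  # homoplasy-free data: every change unambiguous on exactly one branch
  tre <- parse_newick("(Out,(A,(B,(C,D))));")
  cells <- rbind(Out = c("0", "0"), A = c("0", "0"), B = c("1", "0"),
                 C = c("1", "1"), D = c("1", "1"))
  m <- character_matrix(cells)
  syn2 <- summarize_synapomorphies(tre, m)
  expect_true(all(syn2$status == "unambiguous"))
  expect_equal(nrow(syn2), 2L)
})
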