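chardef <- function(id = 1L, nstates = 2L) list(id = id, nstates = nstates)

test_that("the >= 50% rule codes presence inclusively", {
  # 6 of 11 specimens
  obs <- data.frame(taxon = "P_paniscus", specimen = paste0("s", 1:11),
                    char = 118, state = c(rep(1, 6), rep(0, 5)))
  expect_equal(code_majority(obs, chardef(118)), "1")
  # exactly 5 of 10: the boundary codes as present
  obs2 <- data.frame(taxon = "X", specimen = paste0("s", 1:10),
                     char = 1, state = c(rep(1, 5), rep(0, 5)))
  expect_equal(code_majority(obs2, chardef()), "1")
  # 0 of n codes absent
  obs3 <- data.frame(taxon = "X", specimen = paste0("s", 1:6),
                     char = 1, state = 0)
  expect_equal(code_majority(obs3, chardef()), "0")
  # never observed: missing, with a warning
  expect_warning(tok <- code_majority(obs3, chardef(id = 99)),
                 "no observations")
  expect_equal(tok, "?")
})

test_that("multistate coding is modal with polymorphic ties", {
  obs <- data.frame(taxon = "X", specimen = paste0("s", 1:5),
                    char = 7, state = c(2, 2, 2, 1, 0))
  expect_equal(code_majority(obs, chardef(7, nstates = 3L)), "2")
  tie <- data.frame(taxon = "X", specimen = paste0("s", 1:4),
                    char = 7, state = c(2, 2, 0, 0))
  expect_equal(code_majority(tie, chardef(7, nstates = 3L)), "02")
})

test_that("coding is invariant under reordering and proportional duplication", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:12, 1)
    obs <- data.frame(taxon = "X", specimen = paste0("s", seq_len(n)),
                      char = 1, state = sample(0:1, n, replace = TRUE))
    base <- code_majority(obs, chardef())
    shuffled <- obs[sample(n), ]
    expect_equal(code_majority(shuffled, chardef()), base)
    doubled <- rbind(obs,
                     transform(obs, specimen = paste0(specimen, "_dup")))
    expect_equal(code_majority(doubled, chardef()), base)
  }
})

test_that("side-specific records weight by unit choice", {
  # one specimen present on one side only, one absent on both sides
  obs <- data.frame(taxon = "X",
                    specimen = c("a", "a", "b", "b"),
                    side = c("L", "R", "L", "R"),
                    char = 1, state = c(1, 0, 0, 0))
  # unit=specimen: a contributes 0.5 present of 2 -> 25% -> absent
  expect_equal(code_majority(obs, chardef(), unit = "specimen"), "0")
  # unit=side: 1 of 4 sides -> absent too; but 2 present sides tip it
  obs$state <- c(1, 1, 0, 0)
  expect_equal(code_majority(obs, chardef(), unit = "side"), "1")
  expect_equal(code_majority(obs, chardef(), unit = "specimen"), "1")
})

test_that("specimen sources pool by union and refuse conflicts", {
  own <- data.frame(taxon = "P_paniscus", specimen = paste0("own", 1:7),
                    char = 118, state = 1)
  lit <- data.frame(taxon = "P_paniscus", specimen = paste0("lit", 1:4),
                    char = 118, state = 1)
  pooled <- merge_specimen_sources(own, lit)
  expect_equal(length(unique(pooled$specimen)), 11L)

  expect_identical(merge_specimen_sources(own, own[0, ]), own)

  dup <- lit
  dup$specimen[1] <- "own1"  # same record in both sources: deduplicated
  pooled2 <- merge_specimen_sources(own, dup)
  expect_equal(sum(pooled2$specimen == "own1"), 1L)

  conflict <- dup
  conflict$state[1] <- 0
  expect_error(merge_specimen_sources(own, conflict),
               "conflicting records.*own1.*1 vs 0")
})

test_that("a coded observation table becomes a valid character matrix", {
  obs <- rbind(
    data.frame(taxon = "A", specimen = paste0("a", 1:4), char = 1,
               state = c(1, 1, 1, 0)),
    data.frame(taxon = "B", specimen = paste0("b", 1:3), char = 1, state = 0),
    data.frame(taxon = "A", specimen = paste0("a", 1:4), char = 2, state = 1),
    data.frame(taxon = "B", specimen = "b1", char = 2, state = 0))
  m <- code_observations(obs, data.frame(id = 1:2, nstates = 2L))
  expect_s3_class(m, "char_matrix")
  expect_equal(unname(m$cells["A", ]), c("1", "1"))
  expect_equal(unname(m$cells["B", ]), c("0", "0"))
  expect_equal(nrow(validate_matrix(m)), 0L)
})
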