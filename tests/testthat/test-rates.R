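test_that("pairwise difference tallies reproduce the printed counts", {
  fx <- build_paper_fixtures()
  m <- fx$matrix
  cb <- pairwise_differences(m, "P_troglodytes", "P_paniscus")
  expect_equal(cb$count, 7L)
  expect_equal(pairwise_differences(m, "P_troglodytes", "P_paniscus",
                                    major_only = TRUE)$count, 2L)
  expect_equal(pairwise_differences(m, "P_troglodytes", "Homo",
                                    major_only = TRUE)$count, 20L)
  expect_equal(pairwise_differences(m, "P_troglodytes", "Homo",
                                    regions = "HL")$count, 12L)
  expect_equal(pairwise_differences(m, "P_troglodytes", "Homo")$count, 28L)
  # the two major chimp-bonobo differences are the described muscles
  majors <- pairwise_differences(m, "P_troglodytes", "P_paniscus",
                                 major_only = TRUE)$characters
  expect_setequal(majors$id, c(140, 179))
})

test_that("pairwise differences are symmetric, reflexive-zero, and partition by region", {
  fx <- build_paper_fixtures()
  m <- fx$matrix
  for (pair in list(c("P_troglodytes", "Homo"), c("Gorilla", "P_paniscus"))) {
    expect_equal(pairwise_differences(m, pair[1], pair[2])$count,
                 pairwise_differences(m, pair[2], pair[1])$count)
  }
  expect_equal(pairwise_differences(m, "Homo", "Homo")$count, 0L)
  total <- pairwise_differences(m, "P_troglodytes", "Homo")$count
  by_region <- vapply(c("HN", "FL", "HL", "trunk"), function(r) {
    pairwise_differences(m, "P_troglodytes", "Homo", regions = r)$count
  }, integer(1))
  expect_equal(sum(by_region), total)
  expect_lte(pairwise_differences(m, "P_troglodytes", "Homo",
                                  major_only = TRUE)$count, total)
  expect_error(pairwise_differences(m, "Pan", "Homo"), "unknown taxon")
})

test_that("overlapping polymorphism is not a consistent difference", {
  cells <- rbind(A = c("01", "0", "?"), B = c("1", "1", "1"))
  m <- character_matrix(cells)
  expect_equal(pairwise_differences(m, "A", "B")$count, 1L)
})

test_that("divergence rates follow the printed arithmetic", {
  expect_equal(divergence_rate(28, 8), 3.5)
  expect_equal(format_rate(divergence_rate(28, 8)), "3.5")
  expect_equal(format_rate(divergence_rate(2, 7.1)), "0.28")
  expect_equal(format_rate(divergence_rate(4, 8)), "0.50")
  expect_equal(divergence_rate(0, 2), 0)
  expect_error(divergence_rate(3, 0), "positive")
})

test_that("branch rate tables satisfy rate x span = count and the worked rates", {
  # date the working topology so the gorilla terminal spans 7.1 Ma
  tre <- fig4_topology(calibration = NULL)
  tre <- set_node_ages(tre, data.frame(
    clade = c("root", "Hylobatids+Homo", "Pongo+Homo", "Gorilla+Homo",
              "P_troglodytes+Homo", "P_troglodytes+P_paniscus"),
    age_ma = c(25, 20, 16, 7.1, 6, 2)), require_complete = TRUE)
  counts <- data.frame(branch = c("Homo", "Gorilla", "P_paniscus"),
                       n_changes = c(4L, 2L, 0L))
  rt <- branch_rate_table(tre, counts)
  expect_equal(rt$rate[rt$branch == "Gorilla"], 2 / 7.1)
  expect_equal(rt$rate_display[rt$branch == "Gorilla"], "0.28")
  expect_equal(rt$rate[rt$branch == "P_paniscus"], 0)
  expect_true(all(abs(rt$rate * rt$span_ma - rt$n_changes) < 1e-12))

  # the human terminal branch spans the full 8 Ma on the default calibration
  fig4 <- fig4_topology()
  rt2 <- branch_rate_table(fig4, data.frame(branch = "Homo", n_changes = 4L))
  expect_equal(rt2$rate[rt2$branch == "Homo"], 0.5)
  expect_equal(rt2$span_ma[rt2$branch == "Homo"], 8)

  # undated nodes are an error naming the node
  undated <- fig4_topology(calibration = NULL)
  undated <- set_node_ages(undated,
                           data.frame(clade = "root", age_ma = 25))
  expect_error(branch_rate_table(undated, counts), "no age for node")
})

test_that("lineage rows sum changes and spans from root to tip", {
  fig4 <- fig4_topology()
  counts <- data.frame(
    branch = c("Homo", "Homo+P_paniscus+P_troglodytes"),
    n_changes = c(3L, 1L))
  rt <- branch_rate_table(fig4, counts, lineages = "Homo")
  lin <- rt[rt$scope == "lineage" & rt$branch == "Homo", ]
  expect_equal(lin$n_changes, 4L)
  expect_equal(lin$span_ma, 25)
})

test_that("calibration presets carry the two dating schemes", {
  d <- calibration_preset("splits_8_2")
  expect_equal(d$age_ma[d$clade == "P_troglodytes+Homo"], 8)
  expect_equal(d$age_ma[d$clade == "P_troglodytes+P_paniscus"], 2)
  a <- calibration_preset("splits_7.5_3")
  expect_equal(a$age_ma[a$clade == "P_troglodytes+Homo"], 7.5)
  expect_equal(a$age_ma[a$clade == "P_troglodytes+P_paniscus"], 3)
})
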