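targets_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    protein_accession = sprintf("P%02d", seq_along(rows)),
    family = vapply(rows, function(r) if (r[[2]] %in% c("I", "II", "III")) "HCP" else "CODH",
                    character(1)),
    clade_label = vapply(rows, `[[`, character(1), 2),
    assembly_id = vapply(rows, `[[`, character(1), 1)
  )
}

test_that("count_by_assembly tallies one cell per target", {
  counts <- count_by_assembly(targets_tbl(
    list("GCA_1", "A"), list("GCA_1", "A"), list("GCA_2", "E")))
  expect_equal(counts$n[counts$assembly_id == "GCA_1" & counts$label == "A"], 2L)
  expect_equal(counts$n[counts$assembly_id == "GCA_2" & counts$label == "E"], 1L)
  expect_equal(nrow(counts), 2L)
  expect_equal(sum(counts$n), 3L)
  expect_equal(nrow(count_by_assembly(targets_tbl()[0, ])), 0L)
})

test_that("isoform_frequency sums to N_label", {
  counts <- count_by_assembly(targets_tbl(
    list("a1", "A"), list("a1", "A"), list("a2", "A"), list("a3", "A"),
    list("a3", "E")))
  freq <- isoform_frequency(counts)
  a <- freq[freq$label == "A", ]
  expect_equal(a$copies, c(1L, 2L))
  expect_equal(a$n_assemblies, c(2L, 1L))
  expect_equal(sum(a$n_assemblies), 3L)  # = N_A
  expect_equal(freq$n_assemblies[freq$label == "E"], 1L)

  one <- count_by_assembly(targets_tbl(rep(list(list("solo", "F")), 5)[[1]]))
  one$n <- 5L
  expect_equal(isoform_frequency(one)$copies, 5L)
})

test_that("conditional probabilities match hand-enumerated presence sets", {
  # assemblies {a1:{A,E}, a2:{A}, a3:{E,F}}
  counts <- count_by_assembly(targets_tbl(
    list("a1", "A"), list("a1", "E"), list("a2", "A"),
    list("a3", "E"), list("a3", "F")))
  m <- conditional_probability(counts)
  expect_equal(m$P["A", "E"], 1 / 2)
  expect_equal(m$P["E", "A"], 1 / 2)
  expect_equal(m$P["F", "E"], 1 / 2)
  expect_equal(m$P["A", "F"], 0)
  expect_equal(unname(diag(m$P)), rep(1, 3))  # P(X|X) = 1 where N_X > 0

  # a label never present: entire column missing, never 0
  m2 <- conditional_probability(counts, labels_y = c("A", "B"))
  expect_true(all(is.na(m2$P[, "B"])))
  expect_false(anyNA(m2$P[, "A"]))

  # long export carries the integer counts beside P
  expect_equal(sort(names(m$long)), sort(c("X", "Y", "N_Y", "N_XY", "P")))
  expect_equal(m$long$N_XY[m$long$X == "A" & m$long$Y == "E"], 1L)
})

test_that("integer identity P(X|Y)*N_Y = N_XY = P(Y|X)*N_X holds exactly", {
  set.seed(7)
  targets <- tibble::tibble(
    protein_accession = sprintf("T%03d", 1:300),
    family = "CODH",
    clade_label = sample(LETTERS[1:6], 300, replace = TRUE),
    assembly_id = sample(sprintf("GCA_%02d", 1:40), 300, replace = TRUE)
  )
  m <- conditional_probability(count_by_assembly(targets))
  for (x in rownames(m$P)) for (y in colnames(m$P)) {
    expect_equal(m$P[x, y] * m$N_Y[[y]], m$N_XY[x, y])
    expect_equal(m$N_XY[x, y], m$N_XY[y, x])
  }
  expect_true(all(m$P >= 0 & m$P <= 1, na.rm = TRUE))
})

test_that("unequal marginals give an asymmetric matrix", {
  # E common, F rare; every F-assembly also has E
  counts <- count_by_assembly(targets_tbl(
    list("a1", "E"), list("a2", "E"), list("a3", "E"), list("a4", "E"),
    list("a4", "F")))
  m <- conditional_probability(counts)
  expect_equal(m$P["E", "F"], 1)      # F implies E
  expect_equal(m$P["F", "E"], 1 / 4)  # E rarely implies F
})

test_that("cross-family matrices span the union assembly universe", {
  codh <- count_by_assembly(targets_tbl(list("a1", "A"), list("a2", "A")))
  hcp <- count_by_assembly(targets_tbl(list("a2", "I")))
  m <- cross_family_matrix(codh, hcp)
  expect_equal(m$P["I", "A"], 1 / 2)
  expect_equal(m$P["A", "I"], 1)

  # disjoint assemblies: all defined cross probabilities are 0
  hcp2 <- count_by_assembly(targets_tbl(list("b1", "I"), list("b2", "III")))
  m2 <- cross_family_matrix(codh, hcp2)
  expect_equal(unname(m2$P["I", "A"]), 0)
  expect_equal(unname(m2$P["A", "III"]), 0)

  # identical presence patterns: all cross probabilities are 1
  hcp3 <- count_by_assembly(targets_tbl(list("a1", "I"), list("a2", "I")))
  m3 <- cross_family_matrix(codh, hcp3)
  expect_equal(unname(m3$P["I", "A"]), 1)
  expect_equal(unname(m3$P["A", "I"]), 1)

  expect_error(cross_family_matrix(codh, codh), "share label")
})

test_that("estimated P(X|Y) recovers independent generator probabilities", {
  cfg <- simulation_config(
    n_assemblies = 800, seed = 5,
    clade_presence = c(A = 0.4, E = 0.6),
    copies_given_present = list(A = c(`1` = 1), E = c(`1` = 1)),
    operon_neighbor_model = list(), n_distractor_genes = 0L)
  sim <- simulate_assemblies(cfg)
  m <- conditional_probability(count_by_assembly(sim$targets))
  # exact binomial CI of N_XY successes in N_Y conditioning trials covers the
  # independent-model value P(X|Y) = P(X present) for X != Y
  ci <- stats::binom.test(m$N_XY["A", "E"], m$N_Y[["E"]])$conf.int
  expect_gt(0.4, ci[1]); expect_lt(0.4, ci[2])
  ci <- stats::binom.test(m$N_XY["A", "E"], m$N_Y[["A"]])$conf.int
  expect_gt(0.6, ci[1]); expect_lt(0.6, ci[2])
})
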