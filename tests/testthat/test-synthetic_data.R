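test_that("simulation honors trivial and degenerate configs", {
  sim <- simulate_assemblies(simulation_config(n_assemblies = 0, seed = 1))
  expect_equal(nrow(sim$genes), 0L)
  expect_equal(nrow(sim$targets), 0L)
  expect_equal(length(sim$ground_truth$category_sets), 0L)

  expect_error(simulation_config(clade_presence = c(A = 1.5)), "in \\[0, 1\\]")
  expect_error(simulation_config(clade_presence = c(Q = 0.5)), "unknown label")
  expect_error(simulation_config(operon_size_given_nonempty = c(`40` = 1)),
               "2\\.\\.31")
  expect_error(simulation_config(flank_gap = c(200L, 3000L)), "strictly exceed")
  expect_error(simulation_config(within_operon_gap = c(-80L, 300L)),
               "respect the paired")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- simulation_config(n_assemblies = 6, seed = 33, annotation_noise = 0.1)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_assemblies(cfg, out_dir = d1)
  simulate_assemblies(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 3)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("simulated annotations are consumable by the readers", {
  d <- tempfile()
  sim <- simulate_assemblies(simulation_config(n_assemblies = 4, seed = 12),
                             out_dir = d)
  genes <- read_gff3_dir(file.path(d, "annotations"))
  expect_equal(as.data.frame(genes), as.data.frame(sim$genes))
  targets <- read_targets(file.path(d, "targets.tsv"))
  expect_equal(as.data.frame(targets), as.data.frame(sim$targets))
  ann <- read_function_annotations(file.path(d, "function_annotations.tsv"),
                                   source = "eggnog")
  expect_equal(nrow(ann), sum(!is.na(sim$genes$protein_accession)))
})

test_that("every true operon obeys the chain rule and every flank junction breaks it", {
  params <- operon_params()
  sim <- simulate_assemblies(simulation_config(n_assemblies = 30, seed = 21,
                                               strand_flip_prob = 0.5))
  truth <- sim$ground_truth$operons
  by_contig <- split(sim$genes, sim$genes$contig_id)
  for (ctg in names(by_contig)) {
    cg <- by_contig[[ctg]]
    members <- truth$member_accession[truth$contig_id == ctg]
    in_op <- cg$protein_accession %in% members
    idx <- which(in_op)
    expect_equal(idx, seq(min(idx), max(idx)))  # contiguous block
    expect_equal(length(unique(cg$strand[in_op])), 1L)
    if (length(idx) > 1L) {
      gaps <- cg$start[idx[-1]] - cg$end[idx[-length(idx)]] - 1L
      expect_true(all(gaps <= params$max_intergenic_bp &
                        gaps >= -params$max_overlap_bp))
    }
    # junctions from the operon into the flanks must fail the chain rule
    lo <- min(idx); hi <- max(idx)
    if (lo > 1L) {
      d <- cg$start[lo] - cg$end[lo - 1L] - 1L
      expect_true(d > params$max_intergenic_bp ||
                    cg$strand[lo - 1L] != cg$strand[lo])
    }
    if (hi < nrow(cg)) {
      d <- cg$start[hi + 1L] - cg$end[hi] - 1L
      expect_true(d > params$max_intergenic_bp ||
                    cg$strand[hi + 1L] != cg$strand[hi])
    }
  }
})

test_that("empirical co-occurrence of a forced pair matches its binomial CI", {
  # clade A always present, clade E with probability 0.5
  cfg <- simulation_config(
    n_assemblies = 1000, seed = 77,
    clade_presence = c(A = 1, E = 0.5),
    copies_given_present = list(A = c(`1` = 1), E = c(`1` = 1)),
    operon_neighbor_model = list(), n_distractor_genes = 0L)
  sim <- simulate_assemblies(cfg)
  m <- conditional_probability(count_by_assembly(sim$targets))
  ci <- stats::binom.test(m$N_XY["E", "A"], m$N_Y[["A"]])$conf.int
  expect_gt(0.5, ci[1]); expect_lt(0.5, ci[2])
  expect_equal(m$P["A", "E"], 1)  # A is everywhere, so P(A|E) = 1 exactly
})

test_that("annotation noise sends neighbors to 'other' without breaking closure", {
  cfg <- simulation_config(n_assemblies = 25, seed = 55, annotation_noise = 0.5)
  sim <- simulate_assemblies(cfg)
  link <- suppressMessages(link_targets_to_annotations(sim$targets, sim$genes))
  ops <- call_all_operons(link$linked, sim$genes)
  assigned <- assign_categories(sim$genes, sim$annotations)
  sets <- lapply(ops, categorize_operon, assignments = assigned)
  expect_identical(sets[names(sim$ground_truth$category_sets)],
                   sim$ground_truth$category_sets)
  expect_gt(sum(assigned$category == "other"), 0)
})

test_that("edge-case fixtures carry their stated memberships", {
  fixtures <- edge_case_suite()
  needed <- c("gap_299", "gap_300", "gap_301", "overlap_49", "overlap_50",
              "overlap_51", "side_14", "side_15", "side_16",
              "strand_flip_pos_1", "size_1", "shared_operon",
              "cooC_opposite_strand")
  expect_true(all(needed %in% names(fixtures)))
  # the declared expectations are internally consistent with the generator
  f <- fixtures$gap_301
  expect_equal(f$expected[[f$targets[1]]], f$genes$protein_accession[1])
  f <- fixtures$overlap_50
  expect_equal(f$expected[[f$targets[1]]], f$genes$protein_accession[1:2])
  f <- fixtures$side_16
  expect_equal(length(f$expected[[f$targets[1]]]), 16L)  # target + 15, never 16
})
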