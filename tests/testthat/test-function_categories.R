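genes_with_products <- function(products, accessions = sprintf("P%02d", seq_along(products))) {
  n <- length(products)
  make_contig(gaps = rep(500L, n - 1L), strands = rep("+", n),
              contig_id = "CAT") |>
    dplyr::mutate(protein_accession = accessions, product = products)
}

test_that("default rules reproduce the curated 30-product fixture exactly", {
  fix <- readr::read_tsv(test_path("fixtures", "product_categories.tsv"),
                         col_types = "cc", progress = FALSE)
  expect_equal(nrow(fix), 30L)
  assigned <- assign_categories(genes_with_products(fix$product))
  expect_equal(assigned$category, fix$category)
})

test_that("precedence is override > lowest priority rule > other", {
  genes <- genes_with_products(
    c("hypothetical protein",                                  # override wins
      "carbon monoxide dehydrogenase accessory protein CooC",  # rule
      "completely unheard-of protein"),                        # fallback
    accessions = c("WP_COOJ.1", "WP_C", "WP_Z"))
  overrides <- tibble::tibble(protein_accession = "WP_COOJ", category = "cooJ")
  out <- assign_categories(genes, overrides = overrides)
  expect_equal(out$category, c("cooJ", "cooC", "other"))
  expect_equal(out$provenance[1], "override")
  expect_match(out$provenance[2], "^rule:10:cooC$")
  expect_equal(out$provenance[3], "fallback")

  # no accession / no annotation text -> other, never an error
  g <- genes_with_products("ferredoxin")
  g$protein_accession <- NA_character_
  expect_equal(assign_categories(g)$category, "other")
  g2 <- genes_with_products(NA_character_)
  expect_equal(assign_categories(g2)$category, "other")
})

test_that("multi-matching text resolves to the minimum priority", {
  # ferredoxin (40) beats fes_protein (65) and oxidoreductase (45)
  out <- assign_categories(genes_with_products(
    c("ferredoxin--NAD(P)+ oxidoreductase",
      "4Fe-4S ferredoxin iron-sulfur binding protein",
      "hydrogenase maturation factor HypB",       # maturase (20) beats hydrogenase (60)
      "ABC transporter permease")))               # abc (50) beats transporter (80)
  expect_equal(out$category, c("ferredoxin", "ferredoxin",
                               "hydrogenase_maturase", "abc_transporter"))
})

test_that("assignment is deterministic and honors eggNOG scope", {
  genes <- genes_with_products(c(NA, NA), accessions = c("WP_1", "WP_2"))
  ann <- tibble::tibble(
    protein_accession = c("WP_1.2", "WP_2"),
    description = c("nickel chaperone CooJ", NA),
    ortholog_group = c(NA, "COG0535@1|root ferredoxin family"),
    source = "eggnog")
  a1 <- assign_categories(genes, ann)
  a2 <- assign_categories(genes, ann)
  expect_identical(a1, a2)
  expect_equal(a1$category, c("cooJ", "ferredoxin"))  # via description, via OG
})

test_that("categorize_operon excludes target category and 'other', set semantics", {
  genes <- genes_with_products(
    c("carbon monoxide dehydrogenase accessory protein CooC",
      "hypothetical protein",
      "iron-sulfur cluster-binding protein CooF",
      "anaerobic carbon-monoxide dehydrogenase catalytic subunit",
      "CooC family protein"))
  genes$start <- genes$start - (genes$start[1] - 1L)  # irrelevant to categories
  assigned <- assign_categories(genes)
  op <- structure(list(target_accession = "P04", target_gene_index = 3L,
                       members = genes, size = nrow(genes)), class = "operon")
  expect_equal(categorize_operon(op, assigned), c("cooC", "fes_protein"))

  # size-1 operon -> empty set
  lone <- structure(list(target_accession = "P01", target_gene_index = 0L,
                         members = genes[1, ], size = 1L), class = "operon")
  expect_equal(categorize_operon(lone, assigned), character(0))

  # member without an assignment entry is an error
  expect_error(categorize_operon(op, assigned[-3, ]), "without category")

  # the target's own category is excluded from the set
  op2 <- structure(list(target_accession = "P01", target_gene_index = 0L,
                        members = genes, size = nrow(genes)), class = "operon")
  expect_false("cooC" %in% categorize_operon(op2, assigned))
})

test_that("regulation subtypes merge with union semantics", {
  sets <- list(t1 = c("cooC", "transcription_regulation"),
               t2 = c("other_regulation", "transcription_regulation"),
               t3 = "fes_protein")
  merged <- merge_category_sets(sets)
  expect_equal(merged$t1, c("cooC", "regulation"))
  expect_equal(merged$t2, "regulation")
  expect_equal(merged$t3, "fes_protein")
})

test_that("rule and override tables are validated", {
  p <- write_lines_tmp(c("category\tpriority\tpattern\tscope",
                         "not_a_category\t1\tx\tany"))
  expect_error(read_category_rules(p), "not in vocabulary")
  p <- write_lines_tmp(c("category\tpriority\tpattern\tscope",
                         "cooC\t1\t[unclosed\tany"))
  expect_error(read_category_rules(p), "does not compile")
  p <- write_lines_tmp(c("protein_accession\tcategory", "WP_1\tnot_a_category"))
  expect_error(read_category_overrides(p), "not in vocabulary")
})
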