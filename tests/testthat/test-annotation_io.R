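test_that("read_gff3 retains CDS only, sorts, merges segments, assigns gene_index", {
  # headers only -> empty
  p <- write_lines_tmp(c("##gff-version 3", "# comment"), ".gff3")
  expect_equal(nrow(read_gff3(p)), 0L)

  # out-of-order CDS get gene_index in start order; non-CDS rows dropped
  p <- write_lines_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t5000\t.\t+\t.\tID=gene-1",
    "c1\tsrc\tCDS\t2000\t2900\t.\t+\t0\tID=cds-b;protein_id=WP_B;product=beta",
    "c1\tsrc\tCDS\t100\t900\t.\t+\t0\tID=cds-a;protein_id=WP_A;product=alpha",
    "c1\tsrc\tCDS\t4000\t4900\t.\t-\t0\tID=cds-c;protein_id=WP_C;product=gamma"
  ), ".gff3")
  g <- read_gff3(p, assembly_id = "ASMX")
  expect_equal(g$gene_index, 0:2)
  expect_equal(g$protein_accession, c("WP_A", "WP_B", "WP_C"))
  expect_equal(g$strand, c("+", "+", "-"))
  expect_equal(g$assembly_id, rep("ASMX", 3))

  # two segments sharing an ID merge to min-start/max-end
  p <- write_lines_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tCDS\t100\t200\t.\t+\t0\tID=cds-x;protein_id=WP_X",
    "c1\tsrc\tCDS\t300\t400\t.\t+\t0\tID=cds-x;protein_id=WP_X"
  ), ".gff3")
  g <- read_gff3(p)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end), c(100L, 400L))
})

test_that("read_gff3 rejects malformed input with line numbers", {
  p <- write_lines_tmp(c(
    "##gff-version 3",
    "c1\tsrc\tCDS\t100\t900\t.\t+\t0\tID=a",
    "c1\tsrc\tCDS\t100\t900\t+\tID=b"
  ), ".gff3")
  expect_error(read_gff3(p), "line 3.*found 7")

  p <- write_lines_tmp(c("c1\tsrc\tCDS\t900\t100\t.\t+\t0\tID=a"), ".gff3")
  expect_error(read_gff3(p), "end < start at line 1")

  p <- write_lines_tmp(c("c1\tsrc\tCDS\t100\t900\t.\t?\t0\tID=a"), ".gff3")
  expect_error(read_gff3(p), "unknown strand symbol")
})

test_that("gff3 write/read and gene-table TSV round-trips are exact", {
  genes <- make_contig(gaps = c(10L, -30L, 500L), strands = c("+", "+", "+", "-"),
                       contig_id = "RT_c1", assembly_id = "RT",
                       products = c("hypothetical protein",
                                    "ABC transporter; ATP-binding, subunit=2",
                                    NA, "MFS transporter"))
  gp <- tempfile(fileext = ".gff3")
  write_gff3(genes, gp)
  back <- read_gff3(gp, assembly_id = "RT")
  expect_equal(as.data.frame(back), as.data.frame(genes))  # incl. escaped product

  tp <- tempfile(fileext = ".tsv")
  write_gene_table(genes, tp)
  expect_equal(as.data.frame(read_gene_table(tp)), as.data.frame(genes))
})

test_that("gene_index is a 0..n-1 bijection per contig on simulated data", {
  sim <- simulate_assemblies(simulation_config(n_assemblies = 8, seed = 3))
  idx <- split(sim$genes$gene_index,
               paste(sim$genes$assembly_id, sim$genes$contig_id))
  expect_true(all(vapply(idx, function(ix) identical(sort(ix), seq_along(ix) - 1L),
                         logical(1))))
})

test_that("read_targets validates vocabulary and collapses duplicates", {
  p <- write_lines_tmp(c("protein_accession\tfamily\tclade_label\tassembly_id",
                         "WP_X\tCODH\tA\tGCA_1"))
  expect_equal(nrow(read_targets(p)), 1L)

  p <- write_lines_tmp(c("protein_accession\tfamily\tclade_label\tassembly_id",
                         "WP_X\tCODH\tII\tGCA_1"))
  expect_error(read_targets(p), "clade label not in family vocabulary.*CODH/II")

  p <- write_lines_tmp(c("protein_accession\tfamily\tclade_label\tassembly_id",
                         "WP_X\tHCP\tII\tGCA_1",
                         "WP_X\tHCP\tII\tGCA_1"))
  expect_warning(t2 <- read_targets(p), "duplicate")
  expect_equal(nrow(t2), 1L)
})

test_that("read_function_annotations handles the eggNOG dialect", {
  p <- write_lines_tmp(c(
    "## emapper-style comment",
    "#query\tseed_ortholog\tDescription\teggNOG_OGs",
    "WP_1.1\tx\tcarbon monoxide dehydrogenase accessory protein CooC\tCOG3640",
    "WP_2\tx\thypothetical protein\t-"
  ))
  ann <- read_function_annotations(p, source = "eggnog")
  expect_equal(nrow(ann), 2L)
  # lookups are exact-string; version normalization is the caller's job
  expect_true("WP_1.1" %in% ann$protein_accession)
  expect_false("WP_1" %in% ann$protein_accession)
  expect_equal(ann$ortholog_group[ann$protein_accession == "WP_1.1"], "COG3640")

  p <- write_lines_tmp(c("## only", "## comments"))
  expect_equal(nrow(read_function_annotations(p, source = "eggnog")), 0L)

  p <- write_lines_tmp(c("#query\tseed_ortholog\teggNOG_OGs", "WP_1\tx\tOG1"))
  expect_error(read_function_annotations(p, source = "eggnog"), "Description")

  # later duplicates overwrite earlier, with a warning
  p <- write_lines_tmp(c("#query\tDescription", "WP_9\tfirst", "WP_9\tsecond"))
  expect_warning(ann <- read_function_annotations(p, source = "eggnog"),
                 "duplicate")
  expect_equal(ann$description, "second")
})
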