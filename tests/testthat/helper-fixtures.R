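# Build a one-contig gene table from junction gaps (all same length genes).
make_contig <- function(gaps, strands, lengths = rep(900L, length(strands)),
                        contig_id = "CTG", assembly_id = "ASM",
                        products = rep(NA_character_, length(strands))) {
  n <- length(strands)
  starts <- integer(n); ends <- integer(n)
  starts[1] <- 1000L; ends[1] <- starts[1] + lengths[1] - 1L
  for (i in seq_len(n - 1L)) {
    starts[i + 1L] <- ends[i] + 1L + gaps[i]
    ends[i + 1L] <- starts[i + 1L] + lengths[i + 1L] - 1L
  }
  tibble::tibble(
    assembly_id = assembly_id, contig_id = contig_id,
    gene_index = seq_len(n) - 1L, start = starts, end = ends, strand = strands,
    protein_accession = sprintf("%s_P%02d", contig_id, seq_len(n)),
    product = products
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
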