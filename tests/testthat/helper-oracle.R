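# Independent brute-force oracle for the operon caller: enumerate every
# contiguous gene window containing the target, check all rules directly on
# the window, return the maximal valid one. Shares no code with call_operon.
oracle_operon_members <- function(contig_genes, target_gene_index,
                                  params = operon_params()) {
  cg <- contig_genes[order(contig_genes$gene_index), , drop = FALSE]
  t <- match(target_gene_index, cg$gene_index)
  n <- nrow(cg)
  best <- NULL
  for (i in seq_len(t)) {
    for (j in t:n) {
      if (t - i > params$max_genes_each_side) next
      if (j - t > params$max_genes_each_side) next
      ok <- TRUE
      if (j > i) {
        for (k in i:(j - 1L)) {
          d <- cg$start[k + 1L] - cg$end[k] - 1L
          if (d > params$max_intergenic_bp || d < -params$max_overlap_bp) {
            ok <- FALSE; break
          }
        }
      }
      if (ok && params$require_same_strand &&
          !all(cg$strand[i:j] == cg$strand[t])) ok <- FALSE
      if (ok && (is.null(best) || (j - i) > (best[2] - best[1]))) best <- c(i, j)
    }
  }
  cg$protein_accession[best[1]:best[2]]
}

# Random contig generator biased toward the rule boundaries.
random_contig <- function(n_genes = NULL, contig_id = "RND") {
  if (is.null(n_genes)) n_genes <- sample(1:40, 1)
  gap_pool <- c(-80:-45, -51, -50, -49, 0:50, 280:320, 299, 300, 301,
                sample(350:2000, 20))
  gaps <- if (n_genes > 1) sample(gap_pool, n_genes - 1, replace = TRUE) else integer(0)
  lengths <- sample(300:2000, n_genes, replace = TRUE)
  strand <- character(n_genes)
  strand[1] <- sample(c("+", "-"), 1)
  for (i in seq_len(n_genes - 1L)) {
    strand[i + 1L] <- if (runif(1) < 0.25) setdiff(c("+", "-"), strand[i]) else strand[i]
  }
  starts <- integer(n_genes); ends <- integer(n_genes)
  starts[1] <- 100L; ends[1] <- starts[1] + lengths[1] - 1L
  for (i in seq_len(n_genes - 1L)) {
    starts[i + 1L] <- ends[i] + 1L + gaps[i]
    ends[i + 1L] <- starts[i + 1L] + lengths[i + 1L] - 1L
  }
  tibble::tibble(
    assembly_id = "RNDASM", contig_id = contig_id,
    gene_index = seq_len(n_genes) - 1L,
    start = starts, end = ends, strand = strand,
    protein_accession = sprintf("%s_P%03d", contig_id, seq_len(n_genes)),
    product = NA_character_
  )
}
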