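#' Strip an NCBI-style version suffix from protein accessions
#'
#' NCBI tables mix versioned (`WP_0123.1`) and unversioned (`WP_0123`)
#' accession forms. All map lookups in this package normalize through this
#' single point so the two forms always collide.
#'
#' @param x character vector of accessions (NA allowed).
#' @return character vector with a trailing `.<digits>` removed.
#' @export
#' @examples
#' strip_accession_version(c("WP_011305243.1", "WP_011305243", NA))
strip_accession_version <- function(x) {
  sub("\\.[0-9]+$", "", x)
}

# Internal: abort with a consistent message prefix.
stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Internal: empty gene-record tibble with canonical column order/types.
empty_gene_records <- function() {
  tibble::tibble(
    assembly_id = character(),
    contig_id = character(),
    gene_index = integer(),
    start = integer(),
    end = integer(),
    strand = character(),
    protein_accession = character(),
    product = character()
  )
}

# Internal: check a gene-record tibble invariants; returns invisibly.
validate_gene_records <- function(genes) {
  needed <- names(empty_gene_records())
  missing <- setdiff(needed, names(genes))
  if (length(missing)) {
    stop_validation("gene records missing column(s): %s",
                    paste(missing, collapse = ", "))
  }
  if (nrow(genes) == 0L) return(invisible(genes))
  if (any(genes$start < 1L)) stop_validation("gene start coordinates must be >= 1")
  if (any(genes$end < genes$start)) stop_validation("gene end < start")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_validation("strand must be '+' or '-'")
  }
  idx_ok <- genes |>
    dplyr::summarise(
      ok = all(sort(.data$gene_index) == seq_len(dplyr::n()) - 1L),
      .by = c("assembly_id", "contig_id")
    )
  if (!all(idx_ok$ok)) {
    stop_validation("gene_index must be 0..n-1 within each contig")
  }
  invisible(genes)
}
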