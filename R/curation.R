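#' Curation parameters
#'
#' Sequence-level filters applied before any neighborhood analysis: a minimum
#' protein length (the family's catalytic subunits are ~600 aa, so fragments
#' below 400 aa are discarded) and exact-duplicate removal.
#'
#' @param min_length_aa minimum kept length in amino acids; "below" is strict,
#'   so a sequence of exactly `min_length_aa` residues is kept. Default 400.
#' @param dedup_exact drop exact duplicate sequences (first kept). Default TRUE.
#' @return a `curation_params` list.
#' @export
curation_params <- function(min_length_aa = 400L, dedup_exact = TRUE) {
  min_length_aa <- as.integer(min_length_aa)
  if (is.na(min_length_aa) || min_length_aa < 1L) {
    stop_validation("min_length_aa must be >= 1")
  }
  structure(list(min_length_aa = min_length_aa, dedup_exact = isTRUE(dedup_exact)),
            class = "curation_params")
}

#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA file of protein sequences.
#' @return tibble with columns `protein_accession` (first whitespace-separated
#'   token of the header) and `sequence`.
#' @export
read_fasta_aa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_accession = sub("\\s.*$", "", names(aa)),
    sequence = as.character(aa)
  )
}

#' Length-filter protein sequences
#'
#' Keeps sequences of length `min_length_aa` or more; shorter ones are
#' removed (strictly "below" the threshold). Input order is preserved and the
#' removal count is reported via `message()`.
#'
#' @param sequences tibble with `protein_accession` and `sequence` columns
#'   (ungapped amino-acid strings).
#' @param min_length_aa threshold, default 400.
#' @return the kept rows.
#' @export
filter_by_length <- function(sequences, min_length_aa = 400L) {
  min_length_aa <- curation_params(min_length_aa)$min_length_aa
  stopifnot(all(c("protein_accession", "sequence") %in% names(sequences)))
  if (nrow(sequences) == 0L) return(sequences)
  bad <- grepl("[^A-Za-z]", sequences$sequence)
  if (any(bad)) {
    stop_validation("non-alphabetic characters in sequence(s): %s",
                    paste(utils::head(sequences$protein_accession[bad], 5),
                          collapse = ", "))
  }
  keep <- nchar(sequences$sequence) >= min_length_aa
  message(sprintf("filter_by_length: removed %d of %d sequences (< %d aa)",
                  sum(!keep), length(keep), min_length_aa))
  sequences[keep, , drop = FALSE]
}

#' Remove exact duplicate sequences
#'
#' The first occurrence of each identical amino-acid string is kept. The
#' mapping from removed to kept accessions is attached as the `dedup_map`
#' attribute and reported via `message()`.
#'
#' @param sequences tibble with `protein_accession` and `sequence` columns.
#' @return the unique rows, with attribute `dedup_map` (tibble
#'   `removed_accession`, `kept_accession`).
#' @export
deduplicate_exact <- function(sequences) {
  stopifnot(all(c("protein_accession", "sequence") %in% names(sequences)))
  dup <- duplicated(sequences$sequence)
  first_idx <- match(sequences$sequence, sequences$sequence)
  map <- tibble::tibble(
    removed_accession = sequences$protein_accession[dup],
    kept_accession = sequences$protein_accession[first_idx[dup]]
  )
  message(sprintf("deduplicate_exact: removed %d of %d sequences",
                  sum(dup), length(dup)))
  out <- sequences[!dup, , drop = FALSE]
  attr(out, "dedup_map") <- map
  out
}

#' Link targets to their annotated gene records
#'
#' A target is linked iff its accession occurs among the gene records of its
#' *stated* assembly (accession versions stripped on both sides). Unlinked
#' targets are returned separately and excluded downstream. A target whose
#' accession is found only in a different assembly than stated is flagged in
#' the mismatch report, never silently relinked.
#'
#' @param targets target tibble (see [read_targets()]).
#' @param genes gene-record tibble.
#' @return list with `linked` (targets joined to their located gene record:
#'   gains `contig_id`, `gene_index`, `start`, `end`, `strand`), `dropped`
#'   (unlinked target rows), and `mismatches` (accession found in another
#'   assembly). Always `nrow(linked) + nrow(dropped) == nrow(targets)`.
#' @export
link_targets_to_annotations <- function(targets, genes) {
  tkey <- paste(strip_accession_version(targets$protein_accession),
                targets$assembly_id)
  gacc <- strip_accession_version(genes$protein_accession)
  gkey <- paste(gacc, genes$assembly_id)
  hit <- match(tkey, gkey)
  linked <- targets[!is.na(hit), , drop = FALSE]
  loc <- genes[hit[!is.na(hit)], c("contig_id", "gene_index", "start", "end", "strand")]
  linked <- dplyr::bind_cols(linked, loc)
  dropped <- targets[is.na(hit), , drop = FALSE]

  elsewhere <- is.na(hit) &
    strip_accession_version(targets$protein_accession) %in% stats::na.omit(gacc)
  mismatches <- targets[elsewhere, , drop = FALSE]
  if (nrow(mismatches)) {
    found_in <- vapply(strip_accession_version(mismatches$protein_accession),
                       function(a) paste(unique(genes$assembly_id[!is.na(gacc) & gacc == a]),
                                         collapse = ","),
                       character(1))
    mismatches$found_in_assembly <- unname(found_in)
    warning(sprintf("%d target(s) found in a different assembly than stated",
                    nrow(mismatches)), call. = FALSE)
  } else {
    mismatches$found_in_assembly <- character(0)
  }
  message(sprintf("link_targets_to_annotations: %d linked, %d dropped",
                  nrow(linked), nrow(dropped)))
  list(linked = linked, dropped = dropped, mismatches = mismatches)
}
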