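#' Operon-calling parameters
#'
#' The operon around a target gene is approximated by a chain of consecutive
#' genes on the same contig. Walking outward from the target, the adjacent
#' gene joins the chain while all of these hold:
#'
#' * fewer than `max_genes_each_side` genes are already on that side;
#' * the intergenic distance across the junction is at most
#'   `max_intergenic_bp`, and any overlap is at most `max_overlap_bp`
#'   (the gap rule is applied between *consecutive* genes along the chain,
#'   not between each neighbor and the target);
#' * with `require_same_strand`, the gene lies on the target's strand.
#'
#' Extension on a side stops at the first failing gene — an oversized overlap
#' breaks the chain just like an oversized gap; genes are never skipped.
#'
#' @param max_genes_each_side positional window half-width, default 15.
#' @param max_intergenic_bp largest junction gap that still joins, default
#'   300 bp (a deliberately permissive threshold: unrelated genes picked up
#'   this way are expected to disappear in the noise).
#' @param max_overlap_bp largest junction overlap that still joins, default
#'   50 bp (generous; typical coding overlaps are 1-4 bp).
#' @param require_same_strand break the chain at a strand flip, default TRUE.
#' @return an `operon_params` list.
#' @export
operon_params <- function(max_genes_each_side = 15L,
                          max_intergenic_bp = 300L,
                          max_overlap_bp = 50L,
                          require_same_strand = TRUE) {
  p <- list(
    max_genes_each_side = as.integer(max_genes_each_side),
    max_intergenic_bp = as.integer(max_intergenic_bp),
    max_overlap_bp = as.integer(max_overlap_bp),
    require_same_strand = isTRUE(require_same_strand)
  )
  if (any(vapply(p[1:3], function(x) is.na(x) || x < 0L, logical(1)))) {
    stop_validation("operon thresholds must be >= 0")
  }
  structure(p, class = "operon_params")
}

#' Signed intergenic distance between two neighboring genes
#'
#' On 1-based inclusive coordinates the distance is
#' `next.start - prev.end - 1`: abutting genes are 0 bp apart and negative
#' values mean the genes overlap by that many bp.
#'
#' @param prev,nxt one-row gene records (or vectors of rows), `nxt`
#'   start-ordered after `prev` on the same contig.
#' @return integer vector of signed distances in bp.
#' @export
#' @examples
#' a <- tibble::tibble(contig_id = "c", start = 1L, end = 100L)
#' b <- tibble::tibble(contig_id = "c", start = 101L, end = 200L)
#' intergenic_distance(a, b)  # 0, abutting
intergenic_distance <- function(prev, nxt) {
  if (!all(prev$contig_id == nxt$contig_id)) {
    stop_validation("intergenic_distance: genes on different contigs")
  }
  as.integer(nxt$start) - as.integer(prev$end) - 1L
}

#' Call the operon around one target gene
#'
#' @param contig_genes gene records of one contig, ordered by `gene_index`.
#' @param target the target gene: either its `gene_index` on this contig or a
#'   one-row gene record.
#' @param params an [operon_params()] object.
#' @return an `operon` object: list with `target_accession`, `members`
#'   (gene records ordered by start, always containing the target),
#'   `left_boundary_reason`, `right_boundary_reason` (one of `gap_exceeded`,
#'   `overlap_exceeded`, `strand_change`, `gene_limit`, `contig_end`) and
#'   `size`.
#' @export
call_operon <- function(contig_genes, target, params = operon_params()) {
  contig_genes <- dplyr::arrange(contig_genes, .data$gene_index)
  if (is.numeric(target)) {
    t_pos <- match(as.integer(target), contig_genes$gene_index)
  } else {
    t_pos <- match(target$gene_index, contig_genes$gene_index)
    if (!is.na(t_pos) && !identical(contig_genes$contig_id[t_pos], target$contig_id)) {
      t_pos <- NA_integer_
    }
  }
  if (is.na(t_pos)) stop_validation("call_operon: target not found on contig")

  n <- nrow(contig_genes)
  starts <- contig_genes$start
  ends <- contig_genes$end
  strands <- contig_genes$strand
  t_strand <- strands[t_pos]

  # gap across the junction between gene i and gene i+1
  junction_gap <- function(i) starts[i + 1L] - ends[i] - 1L

  walk <- function(step) {
    # step = -1 walks left, +1 walks right; returns list(limit index, reason)
    pos <- t_pos
    added <- 0L
    repeat {
      nxt <- pos + step
      if (nxt < 1L || nxt > n) return(list(pos = pos, reason = "contig_end"))
      if (added >= params$max_genes_each_side) {
        return(list(pos = pos, reason = "gene_limit"))
      }
      d <- if (step > 0L) junction_gap(pos) else junction_gap(nxt)
      if (d > params$max_intergenic_bp) {
        return(list(pos = pos, reason = "gap_exceeded"))
      }
      if (d < -params$max_overlap_bp) {
        return(list(pos = pos, reason = "overlap_exceeded"))
      }
      if (params$require_same_strand && strands[nxt] != t_strand) {
        return(list(pos = pos, reason = "strand_change"))
      }
      pos <- nxt
      added <- added + 1L
    }
  }

  left <- walk(-1L)
  right <- walk(+1L)
  members <- contig_genes[seq(left$pos, right$pos), , drop = FALSE]
  structure(
    list(
      target_accession = contig_genes$protein_accession[t_pos],
      target_gene_index = contig_genes$gene_index[t_pos],
      contig_id = contig_genes$contig_id[t_pos],
      assembly_id = contig_genes$assembly_id[t_pos],
      members = members,
      left_boundary_reason = left$reason,
      right_boundary_reason = right$reason,
      size = nrow(members)
    ),
    class = "operon"
  )
}

#' @export
print.operon <- function(x, ...) {
  cat(sprintf("<operon> target %s (%s/%s): %d gene(s), boundaries %s | %s\n",
              x$target_accession %||% "<no accession>", x$assembly_id,
              x$contig_id, x$size,
              x$left_boundary_reason, x$right_boundary_reason))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Call operons for every linked target
#'
#' Targets are processed independently: two targets on one contig may yield
#' overlapping operons, and a target may be a member of another target's
#' operon.
#'
#' @param linked_targets linked targets from [link_targets_to_annotations()]
#'   (must carry `contig_id` and `gene_index`).
#' @param genes gene-record tibble covering the targets' assemblies.
#' @param params an [operon_params()] object.
#' @return named list of `operon` objects, keyed by target accession.
#' @export
call_all_operons <- function(linked_targets, genes, params = operon_params()) {
  if (nrow(linked_targets) == 0L) return(stats::setNames(list(), character(0)))
  stopifnot(all(c("contig_id", "gene_index", "assembly_id") %in% names(linked_targets)))
  ops <- vector("list", nrow(linked_targets))
  split_genes <- split(genes, paste(genes$assembly_id, genes$contig_id, sep = "\r"))
  for (i in seq_len(nrow(linked_targets))) {
    key <- paste(linked_targets$assembly_id[i], linked_targets$contig_id[i], sep = "\r")
    cg <- split_genes[[key]]
    if (is.null(cg)) {
      stop_validation("call_all_operons: contig %s of assembly %s has no gene records",
                      linked_targets$contig_id[i], linked_targets$assembly_id[i])
    }
    ops[[i]] <- call_operon(cg, linked_targets$gene_index[i], params)
  }
  keys <- linked_targets$protein_accession
  if (anyDuplicated(keys)) {
    warning("duplicate target accessions across assemblies; keys suffixed with @assembly",
            call. = FALSE)
    dup <- keys %in% keys[duplicated(keys)]
    keys[dup] <- paste0(keys[dup], "@", linked_targets$assembly_id[dup])
  }
  stats::setNames(ops, keys)
}

#' Flatten operons to a tidy member table
#'
#' One row per (target, member) with the junction distance to the previous
#' member and the operon's boundary reasons — the package's on-disk operon
#' format.
#'
#' @param operons named list of `operon` objects.
#' @return tibble with columns `target_accession`, `assembly_id`, `contig_id`,
#'   `member_accession`, `member_gene_index`, `start`, `end`, `strand`,
#'   `gap_to_previous`, `is_target`, `operon_size`, `left_boundary_reason`,
#'   `right_boundary_reason`.
#' @export
operons_to_table <- function(operons) {
  if (!length(operons)) {
    return(tibble::tibble(
      target_accession = character(), assembly_id = character(),
      contig_id = character(), member_accession = character(),
      member_gene_index = integer(), start = integer(), end = integer(),
      strand = character(), gap_to_previous = integer(),
      is_target = logical(), operon_size = integer(),
      left_boundary_reason = character(), right_boundary_reason = character()
    ))
  }
  purrr::map_dfr(operons, function(op) {
    m <- op$members
    gaps <- c(NA_integer_, m$start[-1L] - m$end[-nrow(m)] - 1L)
    tibble::tibble(
      target_accession = op$target_accession,
      assembly_id = op$assembly_id,
      contig_id = op$contig_id,
      member_accession = m$protein_accession,
      member_gene_index = m$gene_index,
      start = m$start, end = m$end, strand = m$strand,
      gap_to_previous = gaps,
      is_target = m$gene_index == op$target_gene_index,
      operon_size = op$size,
      left_boundary_reason = op$left_boundary_reason,
      right_boundary_reason = op$right_boundary_reason
    )
  })
}
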