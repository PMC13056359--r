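#' Per-assembly isoform counts
#'
#' The counting unit for all co-occurrence statistics is the genome
#' *assembly*, not the organism/taxid: isoforms are only counted together
#' when their genes sit in the same deposited assembly (which underestimates
#' organism-level co-occurrence for species split across assemblies).
#'
#' @param targets target tibble (typically the linked targets); each row
#'   contributes exactly 1 to one (assembly, label) cell.
#' @param label_col column holding the clade/class label, default
#'   `"clade_label"`.
#' @return tibble `assembly_id`, `label`, `n` (class `assembly_counts`).
#' @export
count_by_assembly <- function(targets, label_col = "clade_label") {
  if (nrow(targets) == 0L) {
    out <- tibble::tibble(assembly_id = character(), label = character(), n = integer())
  } else {
    out <- targets |>
      dplyr::count(.data$assembly_id, label = .data[[label_col]]) |>
      dplyr::arrange(.data$assembly_id, .data$label)
    out$n <- as.integer(out$n)
  }
  class(out) <- c("assembly_counts", class(out))
  out
}

#' Isoform-frequency distribution
#'
#' For each label, how many assemblies carry exactly k copies (k >= 1).
#' Summing over k recovers N_label, the number of assemblies containing the
#' label at all.
#'
#' @param counts an `assembly_counts` tibble from [count_by_assembly()].
#' @return tibble `label`, `copies`, `n_assemblies`.
#' @export
isoform_frequency <- function(counts) {
  if (nrow(counts) == 0L) {
    return(tibble::tibble(label = character(), copies = integer(),
                          n_assemblies = integer()))
  }
  counts |>
    tibble::as_tibble() |>
    dplyr::filter(.data$n >= 1L) |>
    dplyr::count(.data$label, copies = .data$n, name = "n_assemblies") |>
    dplyr::arrange(.data$label, .data$copies) |>
    dplyr::mutate(n_assemblies = as.integer(.data$n_assemblies))
}

#' Conditional co-occurrence probability matrix
#'
#' Presence/absence co-occurrence across assemblies:
#' `P(X|Y) = N_XY / N_Y`, where `N_Y` counts assemblies containing at least
#' one member of label Y and `N_XY` counts assemblies containing both X and
#' Y. The matrix is asymmetric whenever marginals differ; columns with
#' `N_Y = 0` are emitted as missing (`NA`), never as 0.
#'
#' @param counts an `assembly_counts` tibble (copy numbers are thresholded at
#'   presence >= 1; they matter only for [isoform_frequency()]).
#' @param labels_x,labels_y label sets for rows/columns; default all labels
#'   observed in `counts`.
#' @param assemblies the assembly universe; defaults to the assemblies in
#'   `counts`. Supply explicitly to condition on a wider universe.
#' @return a `cooccurrence_matrix`: list with `N_Y` (named vector), `N_XY`
#'   and `P` (matrices, rows = X, cols = Y) and `long`, the long-format table
#'   (`X`, `Y`, `N_Y`, `N_XY`, `P`).
#' @export
conditional_probability <- function(counts, labels_x = NULL, labels_y = NULL,
                                    assemblies = NULL) {
  counts <- tibble::as_tibble(counts)
  obs_labels <- sort(unique(counts$label))
  if (is.null(labels_x)) labels_x <- obs_labels
  if (is.null(labels_y)) labels_y <- obs_labels
  if (is.null(assemblies)) assemblies <- sort(unique(counts$assembly_id))
  labels <- union(labels_x, labels_y)

  M <- matrix(FALSE, nrow = length(assemblies), ncol = length(labels),
              dimnames = list(assemblies, labels))
  present <- counts[counts$n >= 1L & counts$label %in% labels, , drop = FALSE]
  if (nrow(present)) {
    M[cbind(match(present$assembly_id, assemblies), match(present$label, labels))] <- TRUE
  }
  storage.mode(M) <- "integer"
  N <- stats::setNames(as.integer(colSums(M)), labels)
  N_XY <- crossprod(M)  # integer co-presence counts, symmetric
  N_XY <- N_XY[labels_x, labels_y, drop = FALSE]
  N_Y <- N[labels_y]
  P <- sweep(N_XY, 2L, N_Y, `/`)
  P[, N_Y == 0L] <- NA_real_

  long <- tibble::tibble(
    X = rep(labels_x, times = length(labels_y)),
    Y = rep(labels_y, each = length(labels_x)),
    N_Y = rep(unname(N_Y), each = length(labels_x)),
    N_XY = as.integer(N_XY),
    P = as.vector(P)
  )
  structure(list(labels_x = labels_x, labels_y = labels_y,
                 N_Y = N_Y, N_XY = N_XY, P = P, long = long),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<cooccurrence_matrix> P(X|Y), %d x %d\n",
              length(x$labels_x), length(x$labels_y)))
  print(round(x$P, digits))
  invisible(x)
}

#' Cross-family co-occurrence matrix
#'
#' Conditional co-occurrence between two gene families (e.g. CODH clades vs
#' HCP classes), both orientations, over the union of the two assembly
#' universes.
#'
#' @param counts_a,counts_b `assembly_counts` for the two families; their
#'   label sets must be disjoint.
#' @return a `cooccurrence_matrix` over all labels of both families (the
#'   cross-family blocks are the quantity of interest; within-family blocks
#'   come along for free).
#' @export
cross_family_matrix <- function(counts_a, counts_b) {
  la <- sort(unique(counts_a$label))
  lb <- sort(unique(counts_b$label))
  if (length(intersect(la, lb))) {
    stop_validation("cross_family_matrix: families share label(s): %s",
                    paste(intersect(la, lb), collapse = ", "))
  }
  combined <- dplyr::bind_rows(tibble::as_tibble(counts_a),
                               tibble::as_tibble(counts_b))
  conditional_probability(combined, labels_x = c(la, lb), labels_y = c(la, lb),
                          assemblies = sort(unique(combined$assembly_id)))
}

#' Write a co-occurrence matrix as long-format TSV
#'
#' Columns `X`, `Y`, `N_Y`, `N_XY`, `P`; undefined cells (`N_Y = 0`) keep an
#' empty `P` field.
#'
#' @param m a `cooccurrence_matrix`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_cooccurrence_tsv <- function(m, path) {
  readr::write_tsv(m$long, path, na = "", progress = FALSE)
  invisible(path)
}
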