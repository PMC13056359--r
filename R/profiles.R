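#' Profile reporting parameters
#'
#' @param report_cutoff proportion below/at which a category is not reported;
#'   default 0.10. The cutoff is a reporting filter only — profiles always
#'   retain every proportion.
#' @param cutoff_strict report only categories *strictly* above the cutoff
#'   (a category at exactly 0.10 is excluded); default TRUE.
#' @return a `profile_params` list.
#' @export
profile_params <- function(report_cutoff = 0.10, cutoff_strict = TRUE) {
  if (is.na(report_cutoff) || report_cutoff < 0 || report_cutoff > 1) {
    stop_validation("report_cutoff must be in [0, 1]")
  }
  structure(list(report_cutoff = report_cutoff, cutoff_strict = isTRUE(cutoff_strict)),
            class = "profile_params")
}

#' Operon-content profile of one clade/class
#'
#' Proportions are per *target*, not per operon gene: a category is counted
#' once for a target if its operon contains one or more genes of that
#' category. Targets without any operon neighbor (size-1 operons) stay in
#' the denominator, so `proportion + no_neighbor_fraction` style comparisons
#' are meaningful.
#'
#' @param operons named list of `operon` objects keyed by target accession.
#' @param category_sets named list of category sets (see
#'   [categorize_operon()]) under the same keys.
#' @param targets target tibble; profiled rows are those with
#'   `clade_label == label`.
#' @param label the clade/class to profile; zero targets is an error.
#' @return a `clade_profile`: list with `label`, `n_targets`,
#'   `proportion_by_category` (named over [category_vocabulary()] minus
#'   `other`, plus any merged categories present), `no_neighbor_fraction`
#'   and `size_histogram` (named integer vector).
#' @export
clade_profile <- function(operons, category_sets, targets, label) {
  rows <- targets[targets$clade_label == label, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_validation("clade_profile: no targets with label '%s'", label)
  }
  keys <- rows$protein_accession
  missing <- setdiff(keys, intersect(names(operons), names(category_sets)))
  if (length(missing)) {
    stop_validation("clade_profile: target(s) without operon/category set: %s",
                    paste(utils::head(missing, 5), collapse = ", "))
  }
  sets <- category_sets[keys]
  sizes <- vapply(operons[keys], function(op) op$size, integer(1))
  n <- length(keys)

  cats <- union(setdiff(category_vocabulary(), "other"),
                sort(unique(unlist(sets))))
  prop <- vapply(cats, function(cc) sum(vapply(sets, function(s) cc %in% s,
                                               logical(1))) / n,
                 numeric(1))
  hist <- table(factor(sizes, levels = sort(unique(sizes))))
  structure(
    list(label = label,
         n_targets = n,
         proportion_by_category = prop,
         no_neighbor_fraction = sum(sizes == 1L) / n,
         size_histogram = stats::setNames(as.integer(hist), names(hist))),
    class = "clade_profile")
}

#' @export
print.clade_profile <- function(x, ...) {
  cat(sprintf("<clade_profile> %s: %d targets, %.0f%% without neighbors\n",
              x$label, x$n_targets, 100 * x$no_neighbor_fraction))
  top <- sort(x$proportion_by_category[x$proportion_by_category > 0],
              decreasing = TRUE)
  if (length(top)) {
    cat(paste(sprintf("  %-28s %5.1f%%", names(top), 100 * top), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Operon-size distribution of a group of operons
#'
#' @param operons named list of `operon` objects (pre-filtered to the family
#'   or label of interest).
#' @return tibble `size`, `n`; sizes range 1..(2*max_genes_each_side + 1).
#' @export
operon_size_distribution <- function(operons) {
  if (!length(operons)) return(tibble::tibble(size = integer(), n = integer()))
  sizes <- vapply(operons, function(op) op$size, integer(1))
  tab <- table(sizes)
  tibble::tibble(size = as.integer(names(tab)), n = as.integer(tab))
}

#' Tidy profile table, full and cutoff-filtered
#'
#' @param profiles list of `clade_profile` objects.
#' @param params a [profile_params()] object.
#' @return list with `full` (every label x category proportion plus the
#'   `no_neighbor` fraction rows) and `report` (rows passing the cutoff:
#'   strictly above it by default, mirroring a "more than 10%" rule).
#' @export
report_profiles <- function(profiles, params = profile_params()) {
  full <- purrr::map_dfr(profiles, function(p) {
    tibble::tibble(
      label = p$label,
      category = c(names(p$proportion_by_category), "no_neighbor"),
      n_targets = p$n_targets,
      proportion = c(unname(p$proportion_by_category), p$no_neighbor_fraction)
    )
  })
  if (nrow(full) == 0L) {
    return(list(full = full, report = full))
  }
  keep <- if (params$cutoff_strict) {
    full$proportion > params$report_cutoff
  } else {
    full$proportion >= params$report_cutoff
  }
  report <- full[keep & full$category != "no_neighbor", , drop = FALSE]
  list(full = full, report = report)
}
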