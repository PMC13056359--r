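#' The functional-category vocabulary
#'
#' Categories used to summarize operon content, ordered; `other` is always
#' last and acts as the fallback for genes that match no rule, carry no
#' annotation, or have no protein accession at all. `transcription_regulation`
#' and `other_regulation` are kept separate but can be merged into a single
#' "regulation" group for reporting (see [merge_category_sets()]).
#'
#' @return character vector of category names.
#' @export
category_vocabulary <- function() {
  c("one_carbon_pool", "cooC", "cooT", "cooJ", "ferredoxin", "fes_protein",
    "hydrogenase", "hydrogenase_maturase", "nadp_fad_oxidoreductase",
    "transcription_regulation", "other_regulation", "abc_transporter",
    "transporter", "other")
}

#' Load a category rule table
#'
#' Rules are data, not code: a TSV with columns `category`, `priority`,
#' `pattern` (case-insensitive regular expression) and `scope` (`product`,
#' `eggnog` or `any` — which annotation text the pattern may match). Lower
#' priority wins; ties are broken by file order. The shipped default rule set
#' (`system.file("extdata", "category_rules.tsv", package = "operonscape")`)
#' is a best-effort reconstruction from public product-name conventions —
#' the original manual curation criteria are not published — and is fully
#' user-editable.
#'
#' @param path rule TSV; `NULL` loads the shipped defaults.
#' @return tibble of rules sorted stably by priority.
#' @export
read_category_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "category_rules.tsv", package = "operonscape")
  }
  rules <- readr::read_tsv(path, col_types = "cicc", na = character(), progress = FALSE)
  needed <- c("category", "priority", "pattern", "scope")
  missing <- setdiff(needed, names(rules))
  if (length(missing)) {
    stop_validation("rule table missing column(s): %s", paste(missing, collapse = ", "))
  }
  bad_cat <- setdiff(rules$category, category_vocabulary())
  if (length(bad_cat)) {
    stop_validation("rule categories not in vocabulary: %s", paste(bad_cat, collapse = ", "))
  }
  if (!all(rules$scope %in% c("product", "eggnog", "any"))) {
    stop_validation("rule scope must be product, eggnog or any")
  }
  for (p in rules$pattern) {
    ok <- tryCatch({grepl(p, "", perl = TRUE); TRUE}, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop_validation("rule pattern does not compile: %s", p)
  }
  rules$.file_order <- seq_len(nrow(rules))
  rules <- dplyr::arrange(rules, .data$priority, .data$.file_order)
  rules$.file_order <- NULL
  rules
}

#' Load an accession-to-category override table
#'
#' Curated accession lists (e.g. a manually assembled CooJ list: CooJ cannot
#' be told apart from other nickel chaperones by product strings alone) take
#' precedence over every pattern rule.
#'
#' @param path TSV with columns `protein_accession`, `category`.
#' @return tibble of overrides (accession versions stripped).
#' @export
read_category_overrides <- function(path) {
  ov <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  needed <- c("protein_accession", "category")
  missing <- setdiff(needed, names(ov))
  if (length(missing)) {
    stop_validation("override table missing column(s): %s", paste(missing, collapse = ", "))
  }
  bad <- setdiff(ov$category, category_vocabulary())
  if (length(bad)) {
    stop_validation("override categories not in vocabulary: %s", paste(bad, collapse = ", "))
  }
  ov$protein_accession <- strip_accession_version(ov$protein_accession)
  ov
}

#' Assign a functional category to every gene
#'
#' Precedence: accession override, then the lowest-priority matching rule,
#' then `other`. Patterns are matched case-insensitively against the gene's
#' NCBI product string (`scope = "product"`), its eggNOG description and
#' ortholog group (`scope = "eggnog"`), or both (`scope = "any"`). Genes with
#' no accession or no annotation text fall through to `other`. The function
#' is total: every gene receives exactly one category.
#'
#' @param genes gene-record tibble.
#' @param annotations optional annotation tibble from
#'   [read_function_annotations()]; matched on version-stripped accessions.
#' @param rules rule tibble from [read_category_rules()]; defaults to the
#'   shipped rule set.
#' @param overrides optional override tibble from [read_category_overrides()].
#' @return `genes` with added columns `category` and `provenance` (which
#'   override/rule fired, or `fallback`).
#' @export
assign_categories <- function(genes, annotations = NULL,
                              rules = read_category_rules(),
                              overrides = NULL) {
  n <- nrow(genes)
  category <- rep("other", n)
  provenance <- rep("fallback", n)
  acc <- strip_accession_version(genes$protein_accession)

  text_product <- ifelse(is.na(genes$product), "", genes$product)
  text_eggnog <- rep("", n)
  if (!is.null(annotations) && nrow(annotations)) {
    hit <- match(acc, strip_accession_version(annotations$protein_accession))
    desc <- ifelse(is.na(hit), NA, annotations$description[hit])
    og <- ifelse(is.na(hit), NA, annotations$ortholog_group[hit])
    text_eggnog <- paste(ifelse(is.na(desc), "", desc), ifelse(is.na(og), "", og))
    text_eggnog <- trimws(text_eggnog)
  }
  text_any <- trimws(paste(text_product, text_eggnog))
  # genes without an accession can never leave "other"
  assignable <- !is.na(acc) & nzchar(text_any)

  unset <- rep(TRUE, n)
  for (k in seq_len(nrow(rules))) {
    if (!any(unset & assignable)) break
    txt <- switch(rules$scope[k],
                  product = text_product, eggnog = text_eggnog, any = text_any)
    hit <- unset & assignable &
      stringr::str_detect(txt, stringr::regex(rules$pattern[k], ignore_case = TRUE))
    if (any(hit)) {
      category[hit] <- rules$category[k]
      provenance[hit] <- sprintf("rule:%d:%s", rules$priority[k], rules$category[k])
      unset[hit] <- FALSE
    }
  }
  if (!is.null(overrides) && nrow(overrides)) {
    hit <- match(acc, overrides$protein_accession)
    ov <- !is.na(hit)
    category[ov] <- overrides$category[hit[ov]]
    provenance[ov] <- "override"
  }
  genes$category <- category
  genes$provenance <- provenance
  genes
}

#' Category set of an operon's neighbors
#'
#' The set of functional categories present among the operon's *non-target*
#' members. The target's own category and `other` are excluded; the result
#' may be empty (the "no neighbor" case of a size-1 operon, or an operon of
#' uninformative genes).
#'
#' @param operon an `operon` object from [call_operon()].
#' @param assignments gene table with `category` from [assign_categories()],
#'   covering the operon's members, or a named character vector keyed by
#'   version-stripped accession. Members without a protein accession are
#'   `other` by construction and need no entry; any other member missing from
#'   `assignments` is an error.
#' @return sorted character vector of categories.
#' @export
categorize_operon <- function(operon, assignments) {
  m <- operon$members
  if (is.data.frame(assignments)) {
    lut <- stats::setNames(assignments$category,
                           strip_accession_version(assignments$protein_accession))
  } else {
    lut <- assignments
  }
  acc <- strip_accession_version(m$protein_accession)
  cat_m <- ifelse(is.na(acc), "other", unname(lut[acc]))
  if (anyNA(cat_m)) {
    stop_validation("categorize_operon: member(s) without category assignment: %s",
                    paste(stats::na.omit(acc[is.na(cat_m)]), collapse = ", "))
  }
  is_target <- m$gene_index == operon$target_gene_index
  target_cat <- cat_m[is_target][1]
  out <- setdiff(unique(cat_m[!is_target]), c("other", target_cat))
  sort(out)
}

#' Merge categories inside category sets
#'
#' Union semantics at the target level: a merged group is present in a set
#' iff any of its constituents is. Used to collapse
#' `transcription_regulation` + `other_regulation` into a single `regulation`
#' group for figure-style reporting.
#'
#' @param category_sets named list of character vectors.
#' @param merges named list, e.g.
#'   `list(regulation = c("transcription_regulation", "other_regulation"))`.
#' @return list of rewritten sets.
#' @export
merge_category_sets <- function(category_sets,
                                merges = list(regulation = c("transcription_regulation",
                                                             "other_regulation"))) {
  lapply(category_sets, function(s) {
    for (grp in names(merges)) {
      if (any(s %in% merges[[grp]])) {
        s <- c(setdiff(s, merges[[grp]]), grp)
      }
    }
    sort(unique(s))
  })
}
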