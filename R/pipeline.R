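#' Run the genomic-context pipeline
#'
#' Orchestrates the analysis as composable stages over a run directory with
#' fixed file names, mirroring a subcommand-style CLI. Stages communicate
#' only through their TSV outputs, so running them one at a time is
#' identical to `stages = "all"`:
#'
#' * `simulate` — write a synthetic data set ([simulate_assemblies()]):
#'   `annotations/*.gff3`, `targets.tsv`, `function_annotations.tsv`,
#'   ground truth.
#' * `curate` — read annotations + targets, link targets to gene records:
#'   `genes.tsv`, `linked_targets.tsv`, `dropped_targets.tsv`.
#' * `call_operons` — delineate operons: `operons.tsv`.
#' * `classify` — assign functional categories: `assignments.tsv`,
#'   `category_sets.tsv`.
#' * `cooccur` — assembly-level counts and conditional probabilities:
#'   `counts.tsv`, `isoform_frequency.tsv`, `cooccurrence_codh.tsv`,
#'   `cooccurrence_hcp.tsv`, `cooccurrence_cross.tsv` (as applicable).
#' * `profile` — per-clade operon-content profiles: `profiles.tsv`,
#'   `profile_report.tsv`, `operon_sizes.tsv`.
#'
#' A `manifest.json` (tool version, resolved parameters, input digests,
#' seed, timestamps, per-stage record counts) is written for every run.
#'
#' @param out_dir run directory.
#' @param stages character vector of stage names, or `"all"`.
#' @param config a [simulation_config()] (needed by the `simulate` stage).
#' @param params an [operon_params()].
#' @param curation a [curation_params()] (recorded in the manifest; sequence
#'   filters apply when a `sequences.fasta` is present in `out_dir`).
#' @param profile a [profile_params()].
#' @param rules category rules tibble, default the shipped set.
#' @param overrides optional override tibble ([read_category_overrides()]).
#' @return invisibly, a list of the stage outputs produced in this call.
#' @export
run_pipeline <- function(out_dir,
                         stages = "all",
                         config = simulation_config(),
                         params = operon_params(),
                         curation = curation_params(),
                         profile = profile_params(),
                         rules = read_category_rules(),
                         overrides = NULL) {
  all_stages <- c("simulate", "curate", "call_operons", "classify",
                  "cooccur", "profile")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    stop_validation("unknown stage(s): %s (known: %s, or 'all')",
                    paste(bad, collapse = ", "), paste(all_stages, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "operonscape",
    version = as.character(utils::packageVersion("operonscape")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = list(
      operon = unclass(params), curation = unclass(curation),
      profile = unclass(profile),
      simulation = unclass(config)[setdiff(names(config), "operon_size_given_nonempty")]
    ),
    stages = list(), inputs = list()
  )
  outputs <- list()
  for (s in stages) {
    res <- switch(s,
      simulate = stage_simulate(out_dir, config, params),
      curate = stage_curate(out_dir, curation),
      call_operons = stage_call_operons(out_dir, params),
      classify = stage_classify(out_dir, rules, overrides),
      cooccur = stage_cooccur(out_dir),
      profile = stage_profile(out_dir, profile)
    )
    manifest$stages[[s]] <- res$counts
    manifest$inputs[[s]] <- res$inputs
    outputs[[s]] <- res$outputs
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outputs)
}

need_file <- function(out_dir, name, producer) {
  path <- file.path(out_dir, name)
  if (!file.exists(path)) {
    stop_validation("missing input '%s' in %s: run the '%s' stage first",
                    name, out_dir, producer)
  }
  path
}

digests <- function(paths) as.list(tools::md5sum(paths))

stage_simulate <- function(out_dir, config, params) {
  sim <- simulate_assemblies(config, out_dir = out_dir, params = params)
  list(counts = list(assemblies = config$n_assemblies,
                     genes = nrow(sim$genes), targets = nrow(sim$targets)),
       inputs = list(), outputs = sim)
}

stage_curate <- function(out_dir, curation) {
  ann_dir <- file.path(out_dir, "annotations")
  if (!dir.exists(ann_dir)) {
    stop_validation("missing input 'annotations/' in %s: provide GFF3 annotations or run the 'simulate' stage",
                    out_dir)
  }
  targets_path <- need_file(out_dir, "targets.tsv", "simulate")
  genes <- read_gff3_dir(ann_dir)
  targets <- read_targets(targets_path)

  seq_path <- file.path(out_dir, "sequences.fasta")
  seq_note <- list()
  if (file.exists(seq_path)) {
    seqs <- read_fasta_aa(seq_path)
    kept <- filter_by_length(seqs, curation$min_length_aa)
    if (curation$dedup_exact) kept <- deduplicate_exact(kept)
    keep_acc <- strip_accession_version(kept$protein_accession)
    pre <- nrow(targets)
    targets <- targets[strip_accession_version(targets$protein_accession) %in%
                         keep_acc, , drop = FALSE]
    seq_note <- list(sequences_in = nrow(seqs), sequences_kept = nrow(kept),
                     targets_removed_by_sequence_filters = pre - nrow(targets))
  }

  link <- link_targets_to_annotations(targets, genes)
  write_gene_table(genes, file.path(out_dir, "genes.tsv"))
  readr::write_tsv(link$linked, file.path(out_dir, "linked_targets.tsv"),
                   na = ".", progress = FALSE)
  readr::write_tsv(link$dropped, file.path(out_dir, "dropped_targets.tsv"),
                   na = ".", progress = FALSE)
  list(counts = c(list(genes = nrow(genes), targets = nrow(targets),
                       linked = nrow(link$linked), dropped = nrow(link$dropped)),
                  seq_note),
       inputs = digests(c(targets_path,
                          list.files(ann_dir, full.names = TRUE))),
       outputs = link)
}

stage_call_operons <- function(out_dir, params) {
  genes_path <- need_file(out_dir, "genes.tsv", "curate")
  linked_path <- need_file(out_dir, "linked_targets.tsv", "curate")
  genes <- read_gene_table(genes_path)
  linked <- readr::read_tsv(linked_path, na = ".", progress = FALSE,
                            col_types = readr::cols(gene_index = "i", start = "i",
                                                    end = "i", .default = "c"))
  ops <- call_all_operons(linked, genes, params)
  tab <- operons_to_table(ops)
  readr::write_tsv(tab, file.path(out_dir, "operons.tsv"), na = ".",
                   progress = FALSE)
  list(counts = list(operons = length(ops), member_rows = nrow(tab)),
       inputs = digests(c(genes_path, linked_path)),
       outputs = ops)
}

# Rebuild operon objects from the on-disk member table.
read_operons <- function(out_dir) {
  genes <- read_gene_table(need_file(out_dir, "genes.tsv", "curate"))
  tab <- readr::read_tsv(
    need_file(out_dir, "operons.tsv", "call_operons"), na = ".", progress = FALSE,
    col_types = readr::cols(member_gene_index = "i", start = "i", end = "i",
                            gap_to_previous = "i", operon_size = "i",
                            is_target = "l", .default = "c"))
  gkey <- paste(genes$assembly_id, genes$contig_id, genes$gene_index)
  split_rows <- split(seq_len(nrow(tab)), factor(tab$target_accession,
                                                 levels = unique(tab$target_accession)))
  ops <- lapply(split_rows, function(ix) {
    rows <- tab[ix, , drop = FALSE]
    members <- genes[match(paste(rows$assembly_id, rows$contig_id,
                                 rows$member_gene_index), gkey), , drop = FALSE]
    structure(list(
      target_accession = rows$target_accession[1],
      target_gene_index = rows$member_gene_index[rows$is_target][1],
      contig_id = rows$contig_id[1],
      assembly_id = rows$assembly_id[1],
      members = members,
      left_boundary_reason = rows$left_boundary_reason[1],
      right_boundary_reason = rows$right_boundary_reason[1],
      size = rows$operon_size[1]
    ), class = "operon")
  })
  ops
}

stage_classify <- function(out_dir, rules, overrides) {
  genes_path <- need_file(out_dir, "genes.tsv", "curate")
  operons_path <- need_file(out_dir, "operons.tsv", "call_operons")
  genes <- read_gene_table(genes_path)
  ann_path <- file.path(out_dir, "function_annotations.tsv")
  annotations <- if (file.exists(ann_path)) {
    read_function_annotations(ann_path, source = "eggnog")
  } else NULL
  assigned <- assign_categories(genes, annotations, rules, overrides)
  readr::write_tsv(
    assigned[, c("assembly_id", "contig_id", "gene_index", "protein_accession",
                 "category", "provenance")],
    file.path(out_dir, "assignments.tsv"), na = ".", progress = FALSE)

  ops <- read_operons(out_dir)
  sets <- lapply(ops, categorize_operon, assignments = assigned)
  set_tab <- purrr::map_dfr(names(sets), function(k) {
    tibble::tibble(target_accession = k,
                   category = if (length(sets[[k]])) sets[[k]] else NA_character_)
  })
  readr::write_tsv(set_tab, file.path(out_dir, "category_sets.tsv"),
                   na = ".", progress = FALSE)
  list(counts = list(genes_assigned = nrow(assigned),
                     targets_with_sets = length(sets)),
       inputs = digests(c(genes_path, operons_path,
                          if (file.exists(ann_path)) ann_path)),
       outputs = list(assignments = assigned, category_sets = sets))
}

read_category_sets <- function(out_dir) {
  tab <- readr::read_tsv(need_file(out_dir, "category_sets.tsv", "classify"),
                         na = ".", progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  sets <- split(tab$category, factor(tab$target_accession,
                                     levels = unique(tab$target_accession)))
  lapply(sets, function(x) sort(x[!is.na(x)]))
}

stage_cooccur <- function(out_dir) {
  linked_path <- need_file(out_dir, "linked_targets.tsv", "curate")
  linked <- readr::read_tsv(linked_path, na = ".", progress = FALSE,
                            col_types = readr::cols(.default = "c"))
  counts <- count_by_assembly(linked)
  readr::write_tsv(counts, file.path(out_dir, "counts.tsv"), progress = FALSE)
  readr::write_tsv(isoform_frequency(counts),
                   file.path(out_dir, "isoform_frequency.tsv"), progress = FALSE)
  out <- list(counts = counts)
  fams <- split(linked, linked$family)
  universe <- sort(unique(linked$assembly_id))
  for (fam in names(fams)) {
    m <- conditional_probability(count_by_assembly(fams[[fam]]),
                                 assemblies = universe)
    write_cooccurrence_tsv(m, file.path(out_dir,
                                        sprintf("cooccurrence_%s.tsv", tolower(fam))))
    out[[paste0("matrix_", tolower(fam))]] <- m
  }
  if (all(c("CODH", "HCP") %in% names(fams))) {
    m <- cross_family_matrix(count_by_assembly(fams$CODH),
                             count_by_assembly(fams$HCP))
    write_cooccurrence_tsv(m, file.path(out_dir, "cooccurrence_cross.tsv"))
    out$matrix_cross <- m
  }
  list(counts = list(assemblies = length(universe), count_rows = nrow(counts)),
       inputs = digests(linked_path), outputs = out)
}

stage_profile <- function(out_dir, profile) {
  linked_path <- need_file(out_dir, "linked_targets.tsv", "curate")
  linked <- readr::read_tsv(linked_path, na = ".", progress = FALSE,
                            col_types = readr::cols(.default = "c"))
  ops <- read_operons(out_dir)
  sets <- read_category_sets(out_dir)
  labels <- sort(unique(linked$clade_label))
  profiles <- lapply(labels, function(lb) clade_profile(ops, sets, linked, lb))
  rep <- report_profiles(profiles, profile)
  readr::write_tsv(rep$full, file.path(out_dir, "profiles.tsv"), progress = FALSE)
  readr::write_tsv(rep$report, file.path(out_dir, "profile_report.tsv"),
                   progress = FALSE)
  sizes <- purrr::map_dfr(split(linked, linked$family), function(rows) {
    dist <- operon_size_distribution(ops[rows$protein_accession])
    dist$family <- rows$family[1]
    dist
  })
  readr::write_tsv(sizes[, c("family", "size", "n")],
                   file.path(out_dir, "operon_sizes.tsv"), progress = FALSE)
  list(counts = list(labels = length(labels), report_rows = nrow(rep$report)),
       inputs = digests(linked_path), outputs = list(profiles = profiles,
                                                     report = rep))
}
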