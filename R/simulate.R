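#' Simulation configuration
#'
#' Describes a population of synthetic multi-contig prokaryotic assemblies
#' with operon-structured gene spacing and known ground truth. Defaults
#' emulate the data regime of the real CODH/HCP survey: per-clade presence
#' probabilities proportional to the reported clade sizes, copy-number
#' distributions that put roughly 30% of CODH-containing assemblies at more
#' than one CODH, and per-clade neighbor-category probabilities equal to the
#' reported per-clade operon-content proportions.
#'
#' @param n_assemblies number of assemblies to simulate.
#' @param clade_presence named vector of independent per-label Bernoulli
#'   presence probabilities. CODH clades are `A`-`F`, HCP classes `I`-`III`.
#' @param copies_given_present named list: per label, a probability vector
#'   over copy numbers 1..k. Labels absent from the list use one copy.
#' @param operon_neighbor_model named list: per label, a named vector of
#'   per-category probabilities that the target's operon contains >= 1 gene
#'   of that category (independent across categories). Labels absent from
#'   the list get size-1 operons.
#' @param operon_size_given_nonempty optional probability vector over operon
#'   sizes 2..31 (names = sizes); when set, operons with at least one
#'   category gene are padded with `other`-category genes up to a size drawn
#'   from it (never below 1 + number of category genes).
#' @param within_operon_gap integer range (2-vector) of within-operon
#'   junction gaps in bp; default `c(-50, 300)`, matching the default
#'   [operon_params()].
#' @param flank_gap integer range of operon-to-flank junction gaps; must lie
#'   strictly above the paired `max_intergenic_bp`. Default `c(301, 3000)`.
#' @param gene_length_bp integer range of gene lengths; default
#'   `c(300, 3000)` (the minimum must exceed the overlap allowance so gene
#'   order is well defined).
#' @param strand_flip_prob probability that the flanking gene adjacent to the
#'   operon sits on the opposite strand (with a small gap, so the chain
#'   breaks by strand, emulating the known case of a maturase encoded just
#'   outside its operon on the other strand); otherwise the chain breaks by
#'   an oversized gap. Default 0.5.
#' @param n_distractor_genes flanking non-operon genes per side, default 3.
#' @param annotation_noise fraction of neighbor genes whose product is
#'   replaced by "hypothetical protein" (their true category becomes
#'   `other`), exercising the fallback path. Default 0.
#' @param seed integer seed; all randomness flows from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_assemblies = 100L,
                              clade_presence = default_clade_presence(),
                              copies_given_present = default_copies_given_present(),
                              operon_neighbor_model = default_neighbor_model(),
                              operon_size_given_nonempty = NULL,
                              within_operon_gap = c(-50L, 300L),
                              flank_gap = c(301L, 3000L),
                              gene_length_bp = c(300L, 3000L),
                              strand_flip_prob = 0.5,
                              n_distractor_genes = 3L,
                              annotation_noise = 0,
                              seed = 1L) {
  cfg <- list(
    n_assemblies = as.integer(n_assemblies),
    clade_presence = clade_presence,
    copies_given_present = copies_given_present,
    operon_neighbor_model = operon_neighbor_model,
    operon_size_given_nonempty = operon_size_given_nonempty,
    within_operon_gap = as.integer(within_operon_gap),
    flank_gap = as.integer(flank_gap),
    gene_length_bp = as.integer(gene_length_bp),
    strand_flip_prob = strand_flip_prob,
    n_distractor_genes = as.integer(n_distractor_genes),
    annotation_noise = annotation_noise,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_clade_presence <- function() {
  # proportional to reported clade sizes over their assembly universes
  c(A = 0.12, B = 0.13, C = 0.17, D = 0.25, E = 0.40, F = 0.24,
    I = 0.60, II = 0.02, III = 0.25)
}

#' @rdname simulation_config
#' @export
default_copies_given_present <- function() {
  multi <- c(`1` = 0.70, `2` = 0.20, `3` = 0.10)   # clades prone to isoforms
  single <- c(`1` = 0.95, `2` = 0.05)              # clades almost always single
  list(A = multi, B = single, C = single, D = single, E = multi, F = multi,
       I = c(`1` = 0.94, `2` = 0.06), II = single, III = single)
}

#' @rdname simulation_config
#' @export
default_neighbor_model <- function() {
  list(
    A = c(one_carbon_pool = 0.93, cooC = 0.62, fes_protein = 0.31),
    B = c(abc_transporter = 0.64, transcription_regulation = 0.12),
    C = c(fes_protein = 0.72, nadp_fad_oxidoreductase = 0.71,
          transcription_regulation = 0.58, other_regulation = 0.10),
    D = c(transcription_regulation = 0.099, other_regulation = 0.095),
    E = c(cooC = 0.59, one_carbon_pool = 0.49, fes_protein = 0.29,
          nadp_fad_oxidoreductase = 0.22, transcription_regulation = 0.17,
          cooT = 0.16, cooJ = 0.12),
    F = c(cooC = 0.68, fes_protein = 0.53, nadp_fad_oxidoreductase = 0.42,
          one_carbon_pool = 0.37, transcription_regulation = 0.35,
          hydrogenase = 0.25, hydrogenase_maturase = 0.17,
          transporter = 0.11, cooT = 0.061, cooJ = 0.04),
    I = c(fes_protein = 0.18, transcription_regulation = 0.17),
    II = c(nadp_fad_oxidoreductase = 0.96, transporter = 0.78),
    III = c(fes_protein = 0.10)
  )
}

validate_simulation_config <- function(cfg, params = operon_params()) {
  if (is.na(cfg$n_assemblies) || cfg$n_assemblies < 0L) {
    stop_validation("n_assemblies must be >= 0")
  }
  probs <- c(cfg$clade_presence, cfg$strand_flip_prob, cfg$annotation_noise,
             unlist(cfg$operon_neighbor_model))
  if (any(probs < 0 | probs > 1)) stop_validation("probabilities must be in [0, 1]")
  bad <- setdiff(names(cfg$clade_presence), c(LETTERS[1:6], "I", "II", "III"))
  if (length(bad)) stop_validation("unknown label(s): %s", paste(bad, collapse = ", "))
  bad_cat <- setdiff(unlist(lapply(cfg$operon_neighbor_model, names)),
                     setdiff(category_vocabulary(), "other"))
  if (length(bad_cat)) {
    stop_validation("neighbor model categories not in vocabulary: %s",
                    paste(unique(bad_cat), collapse = ", "))
  }
  max_size <- 2L * params$max_genes_each_side + 1L
  if (!is.null(cfg$operon_size_given_nonempty)) {
    sizes <- as.integer(names(cfg$operon_size_given_nonempty))
    if (anyNA(sizes) || any(sizes < 2L) || any(sizes > max_size)) {
      stop_validation("operon_size_given_nonempty support must lie in 2..%d", max_size)
    }
  }
  if (cfg$within_operon_gap[1] < -params$max_overlap_bp ||
      cfg$within_operon_gap[2] > params$max_intergenic_bp) {
    stop_validation("within_operon_gap support must respect the paired operon params")
  }
  if (cfg$flank_gap[1] <= params$max_intergenic_bp) {
    stop_validation("flank_gap support must strictly exceed max_intergenic_bp")
  }
  if (cfg$gene_length_bp[1] <= params$max_overlap_bp) {
    stop_validation("gene lengths must exceed the overlap allowance")
  }
  invisible(cfg)
}

# label -> family
family_of_label <- function(label) {
  ifelse(label %in% LETTERS[1:6], "CODH", "HCP")
}

# product-string pools; every string resolves to its category under the
# shipped default rules, so rule-engine solvability is guaranteed
simulated_product_pool <- function() {
  list(
    one_carbon_pool = c("formate dehydrogenase subunit alpha",
                        "acetyl-CoA decarbonylase/synthase complex subunit beta",
                        "methylenetetrahydrofolate reductase",
                        "formate--tetrahydrofolate ligase"),
    cooC = c("carbon monoxide dehydrogenase accessory protein CooC",
             "CooC family protein"),
    cooT = c("nickel-binding protein CooT"),
    cooJ = c("nickel chaperone CooJ"),
    ferredoxin = c("4Fe-4S dicluster domain-containing ferredoxin"),
    fes_protein = c("iron-sulfur cluster-binding protein CooF",
                    "Fe-S cluster assembly protein SufB"),
    hydrogenase = c("energy-converting hydrogenase subunit EchE",
                    "[NiFe] hydrogenase large subunit"),
    hydrogenase_maturase = c("hydrogenase maturation protease HycI",
                             "hydrogenase expression/formation protein HypE"),
    nadp_fad_oxidoreductase = c("NAD(P)H-dependent FAD-containing oxidoreductase",
                                "FAD-dependent oxidoreductase"),
    transcription_regulation = c("LysR family transcriptional regulator",
                                 "RNA polymerase sigma factor SigA"),
    other_regulation = c("two-component system response regulator",
                         "signal transduction histidine kinase"),
    abc_transporter = c("ABC transporter ATP-binding protein",
                        "branched-chain amino acid ABC transporter permease"),
    transporter = c("MFS transporter", "Na+/H+ antiporter"),
    other = c("hypothetical protein", "DUF1284 domain-containing protein")
  )
}

target_product <- function(family) {
  switch(family,
         CODH = "anaerobic carbon-monoxide dehydrogenase catalytic subunit",
         HCP = "hydroxylamine reductase")
}

# sample() that never treats a length-1 x as 1:x
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)
shuffle <- function(x) if (length(x) <= 1L) x else sample(x)
rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate annotated assemblies with known ground truth
#'
#' Draws, per assembly, an independent presence indicator for every label,
#' a copy number for each present label, and — per target copy — a contig
#' holding the target's operon (neighbor categories from the per-label
#' model, within-operon gaps inside the chain rule) flanked on both sides by
#' distractor genes whose junctions violate the chain rule by gap or by
#' strand. Every true operon therefore satisfies the paired
#' [operon_params()] exactly, and every flanking junction breaks it, so the
#' operon caller must reproduce the ground truth gene-for-gene.
#'
#' Output is byte-identical for identical `(config, seed)`.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, writes per-assembly GFF3
#'   under `annotations/`, `targets.tsv`, an eggNOG-mapper-dialect
#'   `function_annotations.tsv`, and the ground truth
#'   (`ground_truth_operons.tsv`, `assembly_clades.tsv`, `config.json`).
#' @param params the [operon_params()] the simulated spacing is paired with.
#' @return list with `genes` (gene records), `targets`, `annotations`,
#'   and `ground_truth` (list: `operons` long tibble, `category_sets` named
#'   list, `assembly_clades` counts tibble, `config`).
#' @export
simulate_assemblies <- function(config = simulation_config(), out_dir = NULL,
                                params = operon_params()) {
  validate_simulation_config(config, params)
  set.seed(config$seed)
  pool <- simulated_product_pool()
  all_products <- unlist(pool, use.names = FALSE)

  gene_rows <- list()
  target_rows <- list()
  truth_rows <- list()
  clade_rows <- list()

  labels <- names(config$clade_presence)
  for (a in seq_len(config$n_assemblies)) {
    assembly_id <- sprintf("ASM%05d", a)
    present <- labels[stats::runif(length(labels)) < config$clade_presence]
    contig_no <- 0L
    for (lab in present) {
      cp <- config$copies_given_present[[lab]]
      k <- if (is.null(cp)) 1L else sample_one_weighted(cp)
      clade_rows[[length(clade_rows) + 1L]] <-
        tibble::tibble(assembly_id = assembly_id, label = lab, n = k)
      for (copy in seq_len(k)) {
        contig_no <- contig_no + 1L
        built <- simulate_target_contig(assembly_id, contig_no, lab, config,
                                        params, pool, all_products)
        gene_rows[[length(gene_rows) + 1L]] <- built$genes
        target_rows[[length(target_rows) + 1L]] <- built$target
        truth_rows[[length(truth_rows) + 1L]] <- built$truth
      }
    }
  }

  genes <- if (length(gene_rows)) dplyr::bind_rows(gene_rows) else empty_gene_records()
  targets <- if (length(target_rows)) dplyr::bind_rows(target_rows) else
    tibble::tibble(protein_accession = character(), family = character(),
                   clade_label = character(), assembly_id = character())
  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
    tibble::tibble(target_accession = character(), assembly_id = character(),
                   contig_id = character(), member_accession = character(),
                   member_category = character(), is_target = logical())
  assembly_clades <- if (length(clade_rows)) dplyr::bind_rows(clade_rows) else
    tibble::tibble(assembly_id = character(), label = character(), n = integer())

  annotations <- tibble::tibble(
    protein_accession = genes$protein_accession[!is.na(genes$protein_accession)],
    description = genes$product[!is.na(genes$protein_accession)],
    ortholog_group = NA_character_,
    source = "eggnog"
  )

  category_sets <- split(
    truth$member_category[!truth$is_target],
    factor(truth$target_accession[!truth$is_target],
           levels = unique(truth$target_accession)))
  category_sets <- lapply(category_sets, function(x) sort(setdiff(unique(x), "other")))
  # size-1 operons have no non-target rows; give them empty sets explicitly
  lone <- setdiff(targets$protein_accession, names(category_sets))
  category_sets[lone] <- list(character(0))

  out <- list(
    genes = genes, targets = targets, annotations = annotations,
    ground_truth = list(operons = truth, category_sets = category_sets,
                        assembly_clades = assembly_clades, config = config)
  )
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  out
}

sample_one_weighted <- function(prob) {
  k <- as.integer(names(prob))
  if (length(k) == 1L) return(k)
  sample(k, 1L, prob = prob)
}

# Build one contig around one target; returns genes/target/truth tibbles.
simulate_target_contig <- function(assembly_id, contig_no, label, config,
                                   params, pool, all_products) {
  contig_id <- sprintf("%s_c%03d", assembly_id, contig_no)
  family <- family_of_label(label)

  nm <- config$operon_neighbor_model[[label]]
  cats <- if (is.null(nm)) character(0) else
    names(nm)[stats::runif(length(nm)) < nm]
  n_pad <- 0L
  if (!is.null(config$operon_size_given_nonempty) && length(cats)) {
    want <- sample_one_weighted(config$operon_size_given_nonempty)
    n_pad <- max(0L, want - 1L - length(cats))
  }
  neighbor_cats <- shuffle(c(cats, rep("other", n_pad)))
  # annotation noise: product collapses to an uninformative string; the true
  # category of that gene is then "other" by construction
  if (config$annotation_noise > 0 && length(neighbor_cats)) {
    noisy <- stats::runif(length(neighbor_cats)) < config$annotation_noise
    neighbor_cats[noisy] <- "other"
  }
  n_nb <- length(neighbor_cats)
  n_left <- if (n_nb == 0L) 0L else
    sample_one(seq(max(0L, n_nb - params$max_genes_each_side),
                   min(params$max_genes_each_side, n_nb)))
  n_right <- n_nb - n_left

  strand <- sample_one(c("+", "-"))
  n_d <- config$n_distractor_genes
  n_total <- n_d + n_left + 1L + n_right + n_d
  op_lo <- n_d + 1L
  op_hi <- n_d + n_nb + 1L
  t_pos <- n_d + n_left + 1L

  strands <- rep(NA_character_, n_total)
  strands[op_lo:op_hi] <- strand
  gaps <- rep(NA_integer_, n_total - 1L)  # gap k sits between gene k and k+1
  if (op_hi > op_lo) {
    gaps[op_lo:(op_hi - 1L)] <- rint(op_hi - op_lo, config$within_operon_gap)
  }
  # flanking junctions and distractor strands
  opposite <- if (strand == "+") "-" else "+"
  if (n_d > 0L) {
    # left boundary junction = gap between gene n_d and op_lo
    if (stats::runif(1) < config$strand_flip_prob) {
      gaps[n_d] <- rint(1L, config$within_operon_gap)
      strands[n_d] <- opposite
    } else {
      gaps[n_d] <- rint(1L, config$flank_gap)
      strands[n_d] <- sample_one(c("+", "-"))
    }
    if (stats::runif(1) < config$strand_flip_prob) {
      gaps[op_hi] <- rint(1L, config$within_operon_gap)
      strands[op_hi + 1L] <- opposite
    } else {
      gaps[op_hi] <- rint(1L, config$flank_gap)
      strands[op_hi + 1L] <- sample_one(c("+", "-"))
    }
    rest <- which(is.na(strands))
    strands[rest] <- sample(c("+", "-"), length(rest), replace = TRUE)
    rest_gaps <- which(is.na(gaps))
    gaps[rest_gaps] <- rint(length(rest_gaps), config$flank_gap)
  }

  lengths <- rint(n_total, config$gene_length_bp)
  starts <- integer(n_total)
  ends <- integer(n_total)
  starts[1] <- 1L
  ends[1] <- lengths[1]
  for (i in seq_len(n_total - 1L)) {
    starts[i + 1L] <- ends[i] + 1L + gaps[i]
    ends[i + 1L] <- starts[i + 1L] + lengths[i + 1L] - 1L
  }

  acc <- sprintf("%s_P%04d", contig_id, seq_len(n_total))
  category <- rep(NA_character_, n_total)
  category[setdiff(op_lo:op_hi, t_pos)] <- neighbor_cats
  products <- character(n_total)
  for (i in seq_len(n_total)) {
    products[i] <- if (i == t_pos) {
      target_product(family)
    } else if (!is.na(category[i])) {
      sample_one(pool[[category[i]]])
    } else {
      sample_one(all_products)  # distractor: any realistic product
    }
  }

  genes <- tibble::tibble(
    assembly_id = assembly_id, contig_id = contig_id,
    gene_index = seq_len(n_total) - 1L,
    start = starts, end = ends, strand = strands,
    protein_accession = acc, product = products
  )
  target <- tibble::tibble(
    protein_accession = acc[t_pos], family = family,
    clade_label = label, assembly_id = assembly_id
  )
  member_idx <- op_lo:op_hi
  truth <- tibble::tibble(
    target_accession = acc[t_pos],
    assembly_id = assembly_id, contig_id = contig_id,
    member_accession = acc[member_idx],
    member_category = ifelse(member_idx == t_pos, "target", category[member_idx]),
    is_target = member_idx == t_pos
  )
  list(genes = genes, target = target, truth = truth)
}

# Serialize a simulation to the on-disk layout the pipeline consumes.
write_simulation <- function(sim, out_dir) {
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
  for (asm in unique(sim$genes$assembly_id)) {
    write_gff3(sim$genes[sim$genes$assembly_id == asm, , drop = FALSE],
               file.path(ann_dir, paste0(asm, ".gff3")))
  }
  readr::write_tsv(sim$targets, file.path(out_dir, "targets.tsv"),
                   na = ".", progress = FALSE)
  write_eggnog_annotations(sim$annotations,
                           file.path(out_dir, "function_annotations.tsv"))
  readr::write_tsv(sim$ground_truth$operons,
                   file.path(out_dir, "ground_truth_operons.tsv"),
                   na = ".", progress = FALSE)
  readr::write_tsv(sim$ground_truth$assembly_clades,
                   file.path(out_dir, "assembly_clades.tsv"),
                   na = ".", progress = FALSE)
  cfg <- sim$ground_truth$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "operon_size_given_nonempty")],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# eggNOG-mapper .annotations dialect writer (the format the reader consumes)
write_eggnog_annotations <- function(annotations, path) {
  lines <- c(
    "## operonscape simulated annotations",
    "## emulates the eggNOG-mapper .annotations dialect",
    paste("#query", "Description", "eggNOG_OGs", sep = "\t"),
    paste(annotations$protein_accession,
          annotations$description,
          ifelse(is.na(annotations$ortholog_group), "-", annotations$ortholog_group),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic boundary-case fixtures
#'
#' Hand-constructed contigs that pin the operon caller to its thresholds:
#' junction gaps of 299/300/301 bp (300 joins, 301 splits), overlaps of
#' 49/50/51 bp (50 joins, 51 splits), 14/15/16 genes on one side (the 15th
#' joins, a 16th is never included), strand flips at each chain position,
#' a size-1 operon, two targets sharing one operon, and a maturase-like gene
#' adjacent to the target but on the opposite strand (excluded by the strand
#' rule even though its gap is small).
#'
#' @return named list of fixtures; each has `genes` (one contig),
#'   `targets` (accessions) and `expected` (named list: target accession ->
#'   expected member accessions, in start order) under default
#'   [operon_params()].
#' @export
edge_case_suite <- function() {
  mk <- function(name, gaps, strands, lengths = NULL, products = NULL) {
    n <- length(strands)
    stopifnot(length(gaps) == n - 1L || n == 1L)
    if (is.null(lengths)) lengths <- rep(900L, n)
    if (is.null(products)) products <- rep("hypothetical protein", n)
    starts <- integer(n); ends <- integer(n)
    starts[1] <- 1000L; ends[1] <- starts[1] + lengths[1] - 1L
    for (i in seq_len(n - 1L)) {
      starts[i + 1L] <- ends[i] + 1L + gaps[i]
      ends[i + 1L] <- starts[i + 1L] + lengths[i + 1L] - 1L
    }
    tibble::tibble(
      assembly_id = "FIXTURE", contig_id = name,
      gene_index = seq_len(n) - 1L,
      start = starts, end = ends, strand = strands,
      protein_accession = sprintf("%s_P%02d", name, seq_len(n)),
      product = products
    )
  }
  acc <- function(genes, idx) genes$protein_accession[idx]
  fixtures <- list()
  add <- function(name, genes, targets_idx, expected_idx) {
    targets <- acc(genes, targets_idx)
    expected <- lapply(expected_idx, function(ix) acc(genes, ix))
    names(expected) <- targets
    fixtures[[name]] <<- list(name = name, genes = genes, targets = targets,
                              expected = expected)
  }

  for (g in c(299L, 300L, 301L)) {
    genes <- mk(paste0("gap", g), gaps = g, strands = c("+", "+"))
    add(paste0("gap_", g), genes, 1L,
        list(if (g <= 300L) 1:2 else 1L))
  }
  for (ov in c(49L, 50L, 51L)) {
    genes <- mk(paste0("ovl", ov), gaps = -ov, strands = c("+", "+"))
    add(paste0("overlap_", ov), genes, 1L,
        list(if (ov <= 50L) 1:2 else 1L))
  }
  for (k in c(14L, 15L, 16L)) {
    genes <- mk(paste0("side", k), gaps = rep(0L, k), strands = rep("+", k + 1L))
    add(paste0("side_", k), genes, 1L, list(1:(min(k, 15L) + 1L)))
  }
  for (p in 1:4) {
    strands <- rep("+", 6L); strands[p + 1L] <- "-"
    genes <- mk(paste0("flip", p), gaps = rep(10L, 5L), strands = strands)
    add(paste0("strand_flip_pos_", p), genes, 1L, list(1:p))
  }
  add("size_1", mk("lone", gaps = integer(0), strands = "+"), 1L, list(1L))
  genes <- mk("shared", gaps = rep(0L, 3L), strands = rep("+", 4L))
  add("shared_operon", genes, c(2L, 3L), list(1:4, 1:4))
  genes <- mk("coocflip", gaps = 10L, strands = c("+", "-"),
              products = c("anaerobic carbon-monoxide dehydrogenase catalytic subunit",
                           "carbon monoxide dehydrogenase accessory protein CooC"))
  add("cooC_opposite_strand", genes, 1L, list(1L))
  fixtures
}
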