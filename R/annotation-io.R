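#' Read CDS features from a GFF3 annotation into gene records
#'
#' Parses a GFF3 file (via [rtracklayer::import()]) and reduces it to the flat
#' gene-record table the neighborhood analysis runs on: one row per CDS, with
#' 1-based inclusive coordinates. Multi-segment CDS (shared `ID` attribute,
#' e.g. programmed frameshifts) are merged to their min-start/max-end span.
#' Records are sorted per contig by (start, end) — ties broken by accession for
#' determinism — and `gene_index` is assigned 0..n-1 within each contig.
#'
#' Genes without a `protein_id` attribute (pseudogenes, unannotated products)
#' are kept: they occupy positional slots in the 15-gene window and take part
#' in intergenic-gap arithmetic, they just can never receive a functional
#' category other than "other".
#'
#' @param path path to a GFF3 file.
#' @param assembly_id assembly identifier to stamp on every record; defaults
#'   to the file name without its `.gff`/`.gff3` extension.
#' @return a tibble of gene records with columns `assembly_id`, `contig_id`,
#'   `gene_index`, `start`, `end`, `strand`, `protein_accession`, `product`.
#' @export
read_gff3 <- function(path, assembly_id = NULL) {
  if (!file.exists(path)) stop_validation("GFF3 file not found: %s", path)
  if (is.null(assembly_id)) {
    assembly_id <- sub("\\.gff3?$", "", basename(path), ignore.case = TRUE)
  }

  lines <- readLines(path, warn = FALSE)
  fasta_at <- match("##FASTA", lines)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!is.na(fasta_at)) body <- body[body < fasta_at]
  if (!length(body)) return(empty_gene_records())

  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop_validation("malformed GFF3 at line %d: expected 9 tab-separated columns, found %d",
                    body[bad], nf[bad])
  }
  # Pre-scan CDS rows so coordinate/strand problems get line-numbered errors
  # instead of an opaque GRanges failure.
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (f[3] != "CDS") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop_validation("non-numeric coordinates at line %d", body[k])
    }
    if (end < start) {
      stop_validation("end < start at line %d (%d < %d)", body[k], end, start)
    }
    if (!f[7] %in% c("+", "-")) {
      stop_validation("unknown strand symbol '%s' at line %d (expected '+' or '-')",
                      f[7], body[k])
    }
  }

  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(df)) return(empty_gene_records())

  get_attr <- function(col) {
    if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))
  }
  raw <- tibble::tibble(
    contig_id = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = as.character(df$strand),
    id = get_attr("ID"),
    protein_accession = get_attr("protein_id"),
    product = get_attr("product")
  )
  # segment key: shared ID merges, rows without ID stay singletons
  raw$.seg <- ifelse(is.na(raw$id), paste0(".row", seq_len(nrow(raw))), raw$id)

  first_non_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[1] else NA_character_
  }
  genes <- raw |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      protein_accession = first_non_na(.data$protein_accession),
      product = first_non_na(.data$product),
      .by = c("contig_id", ".seg")
    ) |>
    dplyr::select(-".seg") |>
    dplyr::arrange(.data$contig_id, .data$start, .data$end, .data$protein_accession) |>
    dplyr::mutate(gene_index = seq_len(dplyr::n()) - 1L, .by = "contig_id") |>
    dplyr::mutate(assembly_id = assembly_id) |>
    dplyr::select(!!!rlang::syms(names(empty_gene_records())))

  validate_gene_records(genes)
}

#' Read every GFF3 annotation in a directory
#'
#' @param dir directory containing `*.gff3`/`*.gff` files, one per assembly;
#'   the file stem is used as the assembly id.
#' @return gene records for all assemblies, row-bound.
#' @export
read_gff3_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.gff3?$", full.names = TRUE))
  if (!length(paths)) return(empty_gene_records())
  dplyr::bind_rows(lapply(paths, read_gff3))
}

#' Read a target-gene table
#'
#' Targets are family members (CODH or HCP) carrying a clade/class label from
#' an upstream phylogenetic assignment — labels are inputs here, never
#' computed. CODH clades are `A`-`F`; HCP classes are `I`-`III`.
#'
#' @param path TSV with header columns `protein_accession`, `family`,
#'   `clade_label`, `assembly_id` (optional `organism_taxid`).
#' @return validated tibble; duplicate (accession, assembly) rows are
#'   collapsed with a warning.
#' @export
read_targets <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "."), progress = FALSE)
  validate_targets(tab)
}

#' Validate an in-memory target table
#'
#' @param tab a data frame with the [read_targets()] columns.
#' @return validated tibble (see [read_targets()]).
#' @export
validate_targets <- function(tab) {
  needed <- c("protein_accession", "family", "clade_label", "assembly_id")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop_validation("target table missing column(s): %s", paste(missing, collapse = ", "))
  }
  tab <- tibble::as_tibble(tab)
  if (nrow(tab) == 0L) return(tab)
  if (any(is.na(tab$assembly_id) | !nzchar(tab$assembly_id))) {
    stop_validation("target table has empty assembly_id")
  }
  vocab <- list(CODH = c("A", "B", "C", "D", "E", "F"),
                HCP = c("I", "II", "III"))
  bad_family <- !tab$family %in% names(vocab)
  if (any(bad_family)) {
    stop_validation("unknown family in rows: %s",
                    paste(which(bad_family), collapse = ", "))
  }
  ok <- mapply(function(fam, cl) cl %in% vocab[[fam]], tab$family, tab$clade_label)
  if (!all(ok)) {
    bad <- which(!ok)
    stop_validation(
      "clade label not in family vocabulary, rows: %s",
      paste(sprintf("%d (%s/%s)", bad, tab$family[bad], tab$clade_label[bad]),
            collapse = ", "))
  }
  dup <- duplicated(tab[, c("protein_accession", "assembly_id")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate (accession, assembly) target row(s)",
                    sum(dup)), call. = FALSE)
    tab <- tab[!dup, , drop = FALSE]
  }
  tab
}

#' Read a functional-annotation table
#'
#' Two dialects are supported. `source = "eggnog"` reads the eggNOG-mapper
#' `.annotations` format: `##` comment lines ignored, header line beginning
#' `#query`, tab-separated columns including `Description` and (optionally)
#' `eggNOG_OGs`. Other sources read a plain TSV with header
#' `protein_accession`, `description` and optional `ortholog_group`.
#'
#' Query ids are kept verbatim — accession-version normalization is the
#' caller's job (see [strip_accession_version()]).
#'
#' @param path annotation file.
#' @param source one of `"eggnog"`, `"ncbi_product"`, `"manual"`.
#' @return tibble with one row per accession: `protein_accession`,
#'   `description`, `ortholog_group`, `source`. Later duplicates overwrite
#'   earlier ones with a warning.
#' @export
read_function_annotations <- function(path,
                                      source = c("eggnog", "ncbi_product", "manual")) {
  source <- match.arg(source)
  if (source == "eggnog") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "##")]
    header_at <- which(startsWith(lines, "#query"))
    if (!length(header_at)) {
      # no data at all (only ## comments) -> empty map
      if (!length(lines) || all(!nzchar(trimws(lines)))) {
        return(empty_annotations(source))
      }
      stop_validation("eggNOG annotations: missing '#query' header line")
    }
    header <- sub("^#", "", lines[header_at[1]])
    data_lines <- lines[seq_along(lines) > header_at[1] & nzchar(trimws(lines))]
    cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
    if (!"Description" %in% cols) {
      stop_validation("eggNOG annotations: missing required column 'Description'")
    }
    if (!length(data_lines)) return(empty_annotations(source))
    tab <- readr::read_tsv(I(paste(data_lines, collapse = "\n")),
                           col_names = cols, col_types = readr::cols(.default = "c"),
                           na = c("", "-"), progress = FALSE)
    out <- tibble::tibble(
      protein_accession = tab$query,
      description = tab$Description,
      ortholog_group = if ("eggNOG_OGs" %in% cols) tab$eggNOG_OGs else NA_character_,
      source = source
    )
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           na = c("", "."), progress = FALSE)
    needed <- c("protein_accession", "description")
    missing <- setdiff(needed, names(tab))
    if (length(missing)) {
      stop_validation("annotation table missing column(s): %s",
                      paste(missing, collapse = ", "))
    }
    out <- tibble::tibble(
      protein_accession = tab$protein_accession,
      description = tab$description,
      ortholog_group = if ("ortholog_group" %in% names(tab)) tab$ortholog_group else NA_character_,
      source = source
    )
  }
  dup <- duplicated(out$protein_accession, fromLast = TRUE)
  if (any(dup)) {
    warning(sprintf("%d duplicate annotation row(s): later entries overwrite earlier",
                    sum(dup)), call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  out
}

empty_annotations <- function(source) {
  tibble::tibble(protein_accession = character(), description = character(),
                 ortholog_group = character(), source = character())
}

#' Write / read the internal gene-record TSV
#'
#' Round-trip safe: re-reading a written table yields the identical tibble.
#' Missing values are written as `.` per the package's tabular conventions.
#'
#' @param genes gene-record tibble.
#' @param path output TSV path.
#' @return `path`, invisibly (writer); gene-record tibble (reader).
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path, na = ".", progress = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  genes <- readr::read_tsv(
    path, na = ".", progress = FALSE,
    col_types = readr::cols(
      assembly_id = "c", contig_id = "c", gene_index = "i",
      start = "i", end = "i", strand = "c",
      protein_accession = "c", product = "c"
    ))
  validate_gene_records(tibble::as_tibble(genes))
}

# ---- GFF3 writing (simulator output) ---------------------------------------
# Reading always goes through rtracklayer; writing is a deliberately tiny
# formatter so simulator output is byte-stable across runs.

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

#' Write gene records for one assembly as GFF3
#'
#' Emits one `CDS` line per gene record, with `ID`, `protein_id` and
#' `product` attributes (reserved characters percent-encoded). Output is
#' byte-identical for identical input, which the simulator's determinism
#' contract relies on.
#'
#' @param genes gene records of a single assembly.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  validate_gene_records(genes)
  stopifnot(length(unique(genes$assembly_id)) <= 1L)
  genes <- dplyr::arrange(genes, .data$contig_id, .data$gene_index)
  attrs <- paste0("ID=cds-", gene_key(genes))
  has_acc <- !is.na(genes$protein_accession)
  attrs[has_acc] <- paste0(attrs[has_acc], ";protein_id=",
                           gff3_escape(genes$protein_accession[has_acc]))
  has_prod <- !is.na(genes$product)
  attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                            gff3_escape(genes$product[has_prod]))
  lines <- c(
    "##gff-version 3",
    paste(genes$contig_id, "operonscape", "CDS", genes$start, genes$end,
          ".", genes$strand, "0", attrs, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

# Internal: a unique per-gene key usable as a GFF3 ID.
gene_key <- function(genes) {
  ifelse(is.na(genes$protein_accession),
         paste0(genes$contig_id, "_g", genes$gene_index),
         genes$protein_accession)
}
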