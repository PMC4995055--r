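# Pipeline drivers tying the analysis stages together. Each driver
# validates its inputs, runs one stage end to end, writes TSV/JSON
# outputs into an output directory, and records a manifest (inputs,
# parameters, seed, package version) so identical manifests imply
# identical outputs.

write_manifest <- function(out_dir, stage, inputs, params, seed = NA) {
  manifest <- list(
    stage = stage,
    inputs = inputs,
    params = params,
    seed = seed,
    package = "mitocomp",
    version = as.character(utils::packageVersion("mitocomp"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

check_input <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  invisible(path)
}

#' Genome-organization report
#'
#' Reads a feature table (or GenBank record), writes the regenerated
#' feature table, the adjacency (overlap/IGN) report from both the
#' declared and the coordinate source, composition statistics when the
#' sequence is available, and the declared-vs-computed mismatch list.
#'
#' @param input Path to a TSV feature table or GenBank flat file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the computed objects.
#' @export
report_stats <- function(input, out_dir) {
  check_input(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  is_genbank <- any(grepl("^LOCUS", readLines(input, n = 5, warn = FALSE)))
  sequence <- NULL
  if (is_genbank) {
    gb <- read_genbank(input)
    ann <- gb$annotation
    sequence <- gb$sequence
  } else {
    ann <- read_feature_table(input)
  }
  write_feature_table(ann, file.path(out_dir, "feature_table.tsv"),
                      genome = sequence)
  adjacency <- list(
    coordinates = as.list(glance(summarize_junctions(ann, "coordinates")))
  )
  if (!all(is.na(ann$declared_ign))) {
    adjacency$declared <- as.list(glance(summarize_junctions(ann, "declared")))
  }
  jsonlite::write_json(adjacency, file.path(out_dir, "adjacency.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  census <- strand_census(ann)
  comp <- if (!is.null(sequence)) base_composition(sequence) else NULL
  jsonlite::write_json(
    list(strand_census = census, composition = comp),
    file.path(out_dir, "composition.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  mismatches <- validate_annotation(ann)
  readr::write_tsv(mismatches$size_mismatches,
                   file.path(out_dir, "size_mismatches.tsv"), progress = FALSE)
  write_manifest(out_dir, "stats", list(input = input), list())
  invisible(list(annotation = ann, adjacency = adjacency, census = census,
                 composition = comp, mismatches = mismatches))
}

#' Ka/Ks panel report
#'
#' @param fasta_paths Named character vector of per-gene FASTA files,
#'   each holding one aligned CDS per species; names are gene names
#'   (defaults to file base names).
#' @param out_dir Output directory.
#' @param table Genetic code id.
#' @return Invisibly, the panel tibble.
#' @export
report_kaks <- function(fasta_paths, out_dir, table = "5") {
  purrr::walk(fasta_paths, check_input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nm <- names(fasta_paths) %||%
    sub("\\.(fa|fasta|fna)$", "", basename(fasta_paths))
  genes <- stats::setNames(purrr::map(fasta_paths, read_fasta_seqs), nm)
  panel <- kaks_panel(genes, table)
  readr::write_tsv(panel, file.path(out_dir, "kaks_panel.tsv"),
                   progress = FALSE)
  write_manifest(out_dir, "kaks", as.list(fasta_paths),
                 list(code_table = table))
  invisible(panel)
}

#' Gene-order comparison report
#'
#' @param orders_path Gene orders in the one-line text format
#'   (see [read_gene_orders()]).
#' @param out_dir Output directory.
#' @param reference A `gene_order`, a name present in `orders_path`, or
#'   `"ancestral-insect"` (default) for the shipped ancestral reference.
#' @return Invisibly, a list with the distance matrix, per-taxon
#'   rearrangement reports and (for >= 3 taxa) the NJ tree.
#' @export
report_order <- function(orders_path, out_dir,
                         reference = "ancestral-insect") {
  check_input(orders_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  orders <- read_gene_orders(orders_path)
  ref <- if (inherits(reference, "gene_order")) {
    reference
  } else if (identical(reference, "ancestral-insect")) {
    ancestral_insect_order()
  } else {
    orders[[reference]] %||% abort(paste0("unknown reference: ", reference))
  }
  reports <- purrr::map(orders, describe_events, reference = ref)
  summary <- purrr::imap_dfr(reports, function(r, nm) {
    dplyr::bind_cols(tibble(taxon = nm), glance(r)) |>
      dplyr::mutate(missing_genes = paste(r$missing_in_query, collapse = ","))
  })
  readr::write_tsv(summary, file.path(out_dir, "rearrangements.tsv"),
                   progress = FALSE)
  m <- order_distance_matrix(c(list(reference = ref), orders))
  readr::write_tsv(
    dplyr::bind_cols(tibble(taxon = rownames(m)), as_tibble(m)),
    file.path(out_dir, "distance_matrix.tsv"), progress = FALSE
  )
  tree <- NULL
  if (nrow(m) >= 3) {
    tree <- nj_order_tree(m)
    ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
  }
  write_manifest(out_dir, "order", list(orders = orders_path),
                 list(reference = if (inherits(reference, "gene_order"))
                   format(reference) else reference,
                   tree = "breakpoint-distance NJ (stand-in for rearrangement-count search)"))
  invisible(list(distance_matrix = m, reports = reports, tree = tree))
}

#' Control-region dissection report
#'
#' @param fasta_path FASTA with the CR sequence (first record used).
#' @param out_dir Output directory.
#' @param ... Passed to [dissect_control_region()].
#' @return Invisibly, the `cr_report`.
#' @export
report_cr <- function(fasta_path, out_dir, ...) {
  check_input(fasta_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- read_fasta_seqs(fasta_path)
  rep <- dissect_control_region(seqs[[1]], ...)
  readr::write_tsv(rep$segments, file.path(out_dir, "cr_elements.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(segments = rep$segments, glance = as.list(glance(rep))),
    file.path(out_dir, "cr_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(out_dir, "cr", list(fasta = fasta_path), list(...))
  invisible(rep)
}

#' Synthetic-genome bundle
#'
#' Generates a mitogenome from a spec and writes FASTA, GenBank and
#' feature-table renderings plus the CR ground truth.
#'
#' @param spec A [mitogenome_spec()] (its seed drives all randomness).
#' @param out_dir Output directory.
#' @return Invisibly, the generated bundle.
#' @export
report_simulate <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_mitogenome(spec)
  write_fasta_seqs(c(synthetic_mitogenome = g$sequence),
                   file.path(out_dir, "genome.fasta"))
  write_genbank(g$sequence, g$annotation, file.path(out_dir, "genome.gb"))
  write_feature_table(g$annotation, file.path(out_dir, "feature_table.tsv"),
                      genome = g$sequence)
  readr::write_tsv(g$cr_elements, file.path(out_dir, "cr_truth.tsv"),
                   progress = FALSE)
  write_manifest(out_dir, "simulate", list(),
                 list(n_genes = nrow(spec$genes),
                      composition = as.list(spec$composition)),
                 seed = spec$seed)
  invisible(g)
}
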