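# Annotated circular mitogenomes as tidy feature tables.
#
# A `mito_annotation` is a tibble with one row per annotated feature in
# the annotation's listing order, plus two attributes: `genome_length`
# (bp) and `topology` ("circular" or "linear"). Coordinates are 1-based
# inclusive throughout, the GenBank convention; `end < start` encodes a
# feature spanning the origin of a circular molecule.

ANNOTATION_COLS <- c(
  "gene", "category", "start", "end", "strand",
  "codons", "declared_size", "declared_ign", "declared_at"
)

#' Construct a mitogenome annotation
#'
#' @param features Data frame with at least `gene`, `start`, `end`,
#'   `strand` (`"forward"`/`"reverse"`); optional `codons`,
#'   `declared_size`, `declared_ign`, `declared_at`, `category`.
#'   Row order is the annotation's listing order and is preserved.
#' @param genome_length Total length of the molecule in bp.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return A `mito_annotation` tibble.
#' @export
mito_annotation <- function(features, genome_length,
                            topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  tbl <- as_tibble(features)
  if (!all(c("gene", "start", "end", "strand") %in% names(tbl))) {
    abort("`features` must have columns gene, start, end, strand")
  }
  if (!"category" %in% names(tbl)) tbl$category <- gene_category(tbl$gene)
  for (col in setdiff(ANNOTATION_COLS, names(tbl))) {
    tbl[[col]] <- if (col == "codons") NA_character_ else NA_real_
  }
  tbl <- tbl[, ANNOTATION_COLS]
  tbl$start <- as.integer(tbl$start)
  tbl$end <- as.integer(tbl$end)
  bad <- which(tbl$start < 1L | tbl$end < 1L |
                 tbl$start > genome_length | tbl$end > genome_length |
                 is.na(tbl$start) | is.na(tbl$end))
  if (length(bad)) {
    abort(paste0("feature '", tbl$gene[bad[1]], "' (row ", bad[1],
                 ") has coordinates outside 1..", genome_length))
  }
  if (!all(tbl$strand %in% c("forward", "reverse"))) {
    abort("strand must be 'forward' or 'reverse'")
  }
  if (topology == "linear" && any(tbl$end < tbl$start)) {
    abort("wraparound feature (end < start) is invalid on a linear molecule")
  }
  structure(tbl,
    genome_length = as.integer(genome_length),
    topology = topology,
    class = c("mito_annotation", class(tbl))
  )
}

#' Feature category from the gene symbol
#'
#' `trn*` -> tRNA, `rrn*` -> rRNA, `CR` -> CR, anything else -> PCG.
#'
#' @param gene Character vector of gene symbols.
#' @return Character vector of categories.
#' @export
gene_category <- function(gene) {
  dplyr::case_when(
    toupper(gene) == "CR" ~ "CR",
    startsWith(gene, "trn") ~ "tRNA",
    startsWith(gene, "rrn") ~ "rRNA",
    TRUE ~ "PCG"
  )
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("# A mito_annotation: %d features, %s %s bp\n",
              nrow(x), attr(x, "topology"), attr(x, "genome_length")))
  NextMethod()
}

#' Genome length and topology of an annotation
#' @param ann A `mito_annotation`.
#' @return Integer length in bp / character topology.
#' @export
genome_length <- function(ann) attr(ann, "genome_length")

#' @rdname genome_length
#' @export
topology <- function(ann) attr(ann, "topology")

#' Read a tab-separated feature table
#'
#' Reads a feature table laid out like the gene-structure table of a
#' mitogenome paper: columns `Gene`, `Start`, `End`, `Size`, `Direction`,
#' `IGN`, `Codons`, `AT_percent`. `Size`, `IGN`, `Codons` and
#' `AT_percent` may be blank; they are kept as the *declared* values and
#' never overwrite coordinate-derived quantities.
#'
#' @param path TSV path.
#' @param genome_length Molecule length; defaults to the maximum
#'   coordinate in the table.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return A `mito_annotation`.
#' @export
read_feature_table <- function(path, genome_length = NULL,
                               topology = "circular") {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("Gene", "Start", "End", "Direction")
  if (nrow(tbl) == 0 || !all(required %in% names(tbl))) {
    abort(paste0("'", path, "' is not a feature table: need non-empty TSV ",
                 "with columns ", paste(required, collapse = ", ")))
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  start <- num_or_na(tbl$Start)
  end <- num_or_na(tbl$End)
  bad <- which(is.na(start) | is.na(end) | start %% 1 != 0 | end %% 1 != 0)
  if (length(bad)) {
    abort(paste0("malformed coordinates in row ", bad[1],
                 " (gene '", tbl$Gene[bad[1]], "') of ", path))
  }
  dir <- tbl$Direction
  # the control region is not transcribed and may leave Direction blank
  dir[is.na(dir) & gene_category(tbl$Gene) == "CR"] <- "Forward"
  bad <- which(!dir %in% c("Forward", "Reverse"))
  if (length(bad)) {
    abort(paste0("unknown Direction '", dir[bad[1]], "' in row ", bad[1],
                 " of ", path))
  }
  features <- tibble(
    gene = tbl$Gene,
    start = as.integer(start),
    end = as.integer(end),
    strand = ifelse(dir == "Forward", "forward", "reverse"),
    codons = if ("Codons" %in% names(tbl)) tbl$Codons else NA_character_,
    declared_size = if ("Size" %in% names(tbl)) num_or_na(tbl$Size) else NA_real_,
    declared_ign = if ("IGN" %in% names(tbl)) num_or_na(tbl$IGN) else NA_real_,
    declared_at = if ("AT_percent" %in% names(tbl)) num_or_na(tbl$AT_percent) else NA_real_
  )
  genome_length <- genome_length %||% max(features$start, features$end)
  mito_annotation(features, genome_length, topology)
}

#' Write an annotation back to the tabular layout
#'
#' Emits the same column set accepted by [read_feature_table()]. When the
#' genome sequence is supplied, `Size` and `AT_percent` are recomputed
#' from coordinates and sequence; otherwise the declared values are
#' echoed (computed `Size` is used when no declared value exists).
#'
#' @param ann A `mito_annotation`.
#' @param path Output TSV path.
#' @param genome Optional genome sequence (single string) to recompute
#'   per-feature A+T content from.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ann, path, genome = NULL) {
  size <- feature_length(ann$start, ann$end, genome_length(ann), topology(ann))
  at <- ann$declared_at
  if (!is.null(genome)) {
    seqs <- extract_feature_seq(genome, ann)
    at <- round(purrr::map_dbl(seqs, ~ base_composition(.x)$at_content), 1)
  }
  out <- tibble(
    Gene = ann$gene,
    Start = ann$start,
    End = ann$end,
    Size = if (is.null(genome)) dplyr::coalesce(ann$declared_size, as.numeric(size)) else as.numeric(size),
    Direction = ifelse(ann$strand == "forward", "Forward", "Reverse"),
    IGN = ann$declared_ign,
    Codons = ann$codons,
    AT_percent = at
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Feature length on a possibly circular molecule
#'
#' For ordinary features the length is `end - start + 1`; a feature with
#' `end < start` wraps through the origin of a circular molecule and has
#' length `(L - start + 1) + end`.
#'
#' @param start,end 1-based inclusive coordinates (vectorized).
#' @param genome_length Molecule length L.
#' @param topology `"circular"` or `"linear"`.
#' @return Integer vector of lengths in bp.
#' @examples
#' feature_length(1, 1539, 15220)     # 1539
#' feature_length(15000, 50, 15220)   # wraps: 271
#' @export
feature_length <- function(start, end, genome_length, topology = "circular") {
  wrap <- end < start
  if (any(wrap) && topology != "circular") {
    abort("end < start requires a circular molecule")
  }
  as.integer(ifelse(wrap, (genome_length - start + 1) + end, end - start + 1))
}

# Signed spacer between two features adjacent in listing order.
# Positive = intergenic gap, negative = overlap, 0 = contiguous.
junction_spacer <- function(prev_end, next_start, genome_length = NULL,
                            wrap = FALSE) {
  if (wrap) {
    (genome_length - prev_end) + (next_start - 1)
  } else {
    next_start - prev_end - 1
  }
}

#' Per-junction signed spacers of an annotation
#'
#' Evaluates junctions in listing order (the order of the feature table,
#' which is how the IGN column of a published gene-structure table is
#' laid out). On a circular molecule the last feature is adjacent to the
#' first and contributes one wrap junction.
#'
#' @param ann A `mito_annotation` with at least 2 features.
#' @return Tibble with columns `from`, `to`, `spacer`
#'   (coordinate-derived signed bp) and `declared_ign`.
#' @export
junction_spacers <- function(ann) {
  if (nrow(ann) < 2) abort("need at least 2 features")
  L <- genome_length(ann)
  n <- nrow(ann)
  idx_next <- c(seq_len(n - 1) + 1L, 1L)
  wrap <- c(rep(FALSE, n - 1), TRUE)
  keep <- if (topology(ann) == "circular") seq_len(n) else seq_len(n - 1)
  tibble(
    from = ann$gene[keep],
    to = ann$gene[idx_next][keep],
    spacer = purrr::map_dbl(keep, function(i) {
      junction_spacer(ann$end[i], ann$start[idx_next[i]], L, wrap[i])
    }),
    declared_ign = ann$declared_ign[keep]
  )
}

#' Summarize intergenic spacers and overlaps
#'
#' Sign-partitions the per-junction spacer list into intergenic
#' nucleotides (IGN, positive spacers) and overlaps (negative spacers)
#' and reports totals, counts and the longest of each, following the
#' accounting convention of mitogenome gene-structure tables.
#'
#' @param ann A `mito_annotation`.
#' @param source `"coordinates"` (derive spacers from start/end) or
#'   `"declared"` (use the table's own IGN column; junctions with a blank
#'   declared IGN are skipped).
#' @return An `adjacency_report` object; see [tidy()][generics::tidy] for
#'   the per-junction table and [glance()][generics::glance] for the
#'   one-row summary.
#' @export
summarize_junctions <- function(ann, source = c("coordinates", "declared")) {
  source <- match.arg(source)
  jx <- junction_spacers(ann)
  if (source == "declared") {
    if (all(is.na(jx$declared_ign))) {
      abort("source = 'declared' requires a populated IGN column")
    }
    jx$spacer <- jx$declared_ign
    jx <- dplyr::filter(jx, !is.na(.data$spacer))
  }
  ovl <- dplyr::filter(jx, .data$spacer < 0)
  ign <- dplyr::filter(jx, .data$spacer > 0)
  pick <- function(d, which_max) {
    if (nrow(d) == 0) return(list(bp = 0L, pair = NA_character_))
    i <- if (which_max) which.max(d$spacer) else which.min(d$spacer)
    list(bp = abs(d$spacer[i]), pair = paste0(d$from[i], "->", d$to[i]))
  }
  structure(list(
    source = source,
    junctions = jx,
    total_overlap_bp = sum(abs(ovl$spacer)),
    n_overlap_pairs = nrow(ovl),
    total_ign_bp = sum(ign$spacer),
    n_ign_pairs = nrow(ign),
    longest_overlap = pick(ovl, which_max = FALSE),
    longest_ign = pick(ign, which_max = TRUE)
  ), class = "adjacency_report")
}

#' @export
print.adjacency_report <- function(x, ...) {
  cat(sprintf("# Adjacency report (%s source)\n", x$source))
  cat(sprintf("  overlaps: %d bp over %d pairs (longest %d bp, %s)\n",
              x$total_overlap_bp, x$n_overlap_pairs,
              x$longest_overlap$bp, x$longest_overlap$pair))
  cat(sprintf("  IGN:      %d bp over %d pairs (longest %d bp, %s)\n",
              x$total_ign_bp, x$n_ign_pairs,
              x$longest_ign$bp, x$longest_ign$pair))
  invisible(x)
}

#' @method tidy adjacency_report
#' @export
tidy.adjacency_report <- function(x, ...) x$junctions

#' @method glance adjacency_report
#' @export
glance.adjacency_report <- function(x, ...) {
  tibble(
    source = x$source,
    total_overlap_bp = x$total_overlap_bp,
    n_overlap_pairs = x$n_overlap_pairs,
    total_ign_bp = x$total_ign_bp,
    n_ign_pairs = x$n_ign_pairs,
    longest_overlap_bp = x$longest_overlap$bp,
    longest_overlap_pair = x$longest_overlap$pair,
    longest_ign_bp = x$longest_ign$bp,
    longest_ign_pair = x$longest_ign$pair
  )
}

#' Strand and category census
#'
#' Counts annotated genes per strand and per category. The control
#' region is a feature, not a gene, and is excluded from the counts.
#'
#' @param ann A `mito_annotation`.
#' @return A list with `by_strand` and `by_category` count tibbles and
#'   `n_genes`.
#' @export
strand_census <- function(ann) {
  genes <- dplyr::filter(as_tibble(ann), .data$category != "CR")
  strands <- dplyr::count(genes, strand = factor(.data$strand, c("forward", "reverse")),
                          .drop = FALSE)
  cats <- dplyr::count(genes, category = factor(.data$category, c("PCG", "tRNA", "rRNA")),
                       .drop = FALSE)
  list(
    by_strand = as_tibble(strands),
    by_category = as_tibble(cats),
    n_genes = nrow(genes)
  )
}

#' Extract a feature's sequence from the genome
#'
#' Slices 1-based inclusive coordinates; features with `end < start` on a
#' circular molecule wrap through the origin (tail + head). Reverse-strand
#' features are returned reverse-complemented, i.e. in coding orientation.
#'
#' @param genome Genome sequence as a single string.
#' @param features A `mito_annotation` or any data frame with `start`,
#'   `end`, `strand` columns.
#' @return Character vector of feature sequences, named by gene when a
#'   `gene` column is present.
#' @export
extract_feature_seq <- function(genome, features) {
  genome <- toupper(genome)
  L <- nchar(genome)
  circular <- !inherits(features, "mito_annotation") ||
    topology(features) == "circular"
  if (any(features$start > L | features$end > L)) {
    abort("feature coordinates exceed genome length")
  }
  out <- purrr::pmap_chr(
    list(features$start, features$end, features$strand),
    function(s, e, strand) {
      piece <- if (e >= s) {
        seq_slice(genome, s, e)
      } else {
        if (!circular) abort("wraparound feature on a linear molecule")
        paste0(seq_slice(genome, s, L), seq_slice(genome, 1, e))
      }
      if (strand == "reverse") revcomp(piece) else piece
    }
  )
  if ("gene" %in% names(features)) names(out) <- features$gene
  out
}

#' Cross-check declared columns against coordinate-derived values
#'
#' Compares each feature's declared size against the coordinate-derived
#' length, and each junction's declared IGN against the coordinate
#' spacer. Mismatches are reported, never silently corrected: published
#' tables do contain internal inconsistencies and those are findings,
#' not errors.
#'
#' @param ann A `mito_annotation`.
#' @return A list of tibbles `size_mismatches` and `ign_mismatches`.
#' @export
validate_annotation <- function(ann) {
  len <- feature_length(ann$start, ann$end, genome_length(ann), topology(ann))
  sizes <- tibble(
    gene = ann$gene,
    declared_size = ann$declared_size,
    computed_size = as.numeric(len)
  ) |>
    dplyr::filter(!is.na(.data$declared_size),
                  .data$declared_size != .data$computed_size)
  jx <- junction_spacers(ann) |>
    dplyr::filter(!is.na(.data$declared_ign),
                  .data$declared_ign != .data$spacer)
  list(size_mismatches = sizes, ign_mismatches = jx)
}

#' Path to the packaged whitefly gene-structure table
#'
#' A TSV transcription of the published gene-structure table of the
#' citrus spiny whitefly mitogenome (36 genes plus the control region on
#' a 15,220 bp circle), used as the worked example throughout the
#' package.
#'
#' @return File path.
#' @export
whitefly_table_path <- function() {
  system.file("extdata", "aleurocanthus_table1.tsv", package = "mitocomp",
              mustWork = TRUE)
}

#' Load the packaged whitefly annotation
#' @return A `mito_annotation` (37 features, circular, 15,220 bp).
#' @export
whitefly_annotation <- function() {
  read_feature_table(whitefly_table_path())
}
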