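# Minimal GenBank flat-file I/O for annotated mitogenomes. Covers the
# subset of the format mitogenome records actually use: LOCUS length
# and topology, gene/CDS/tRNA/rRNA/misc_feature/D-loop features with
# plain, complement() or origin-spanning join() locations, /gene and
# /note qualifiers, and an ORIGIN sequence block.

#' Read a GenBank flat file
#'
#' @param path GenBank file path.
#' @return List with `sequence` (uppercase string) and `annotation`
#'   (a [mito_annotation]). `D-loop`/`misc_feature` features named as a
#'   control region become gene `"CR"`. Only origin-spanning `join()`
#'   locations are supported; other multi-interval features error.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1) abort("not a GenBank record: missing LOCUS line")
  L <- as.integer(sub("^LOCUS\\s+\\S+\\s+(\\d+)\\s+bp.*$", "\\1", locus))
  topo <- if (grepl("circular", locus)) "circular" else "linear"
  # sequence
  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1) abort("missing ORIGIN block")
  seq_lines <- lines[(ori + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != L) {
    abort(sprintf("LOCUS declares %d bp but ORIGIN holds %d", L, nchar(sequence)))
  }
  # features
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) != 1) abort("missing FEATURES block")
  flines <- lines[(fstart + 1):(ori - 1)]
  feat_idx <- grep("^ {5}\\S", flines)
  feats <- list()
  for (k in seq_along(feat_idx)) {
    i <- feat_idx[k]
    j <- if (k < length(feat_idx)) feat_idx[k + 1] - 1 else length(flines)
    header <- flines[i]
    key <- sub("^ {5}(\\S+)\\s.*$", "\\1", header)
    if (key %in% c("source")) next
    loc <- trimws(sub("^ {5}\\S+\\s+", "", header))
    quals <- flines[seq(i, j)][-1]
    gene <- sub('.*?/gene="([^"]*)".*', "\\1",
                grep('/gene=', quals, value = TRUE)[1])
    note <- sub('.*?/note="([^"]*)".*', "\\1",
                grep('/note=', quals, value = TRUE)[1])
    if (key %in% c("D-loop", "D_loop") ||
        (key == "misc_feature" && !is.na(note) &&
           grepl("control region", note, ignore.case = TRUE))) {
      gene <- "CR"
    }
    if (is.na(gene)) next  # unannotated feature keys (e.g. bare gene spans)
    strand <- "forward"
    if (startsWith(loc, "complement(")) {
      strand <- "reverse"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (startsWith(loc, "join(")) {
      inner <- sub("^join\\((.*)\\)$", "\\1", loc)
      parts <- strsplit(inner, ",")[[1]]
      rng <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
      wrap_ok <- length(rng) == 2 && rng[[1]][2] == L && rng[[2]][1] == 1
      if (!wrap_ok) {
        abort(paste0("unsupported multi-interval feature at ", loc,
                     " (only origin-spanning join is handled)"))
      }
      start <- rng[[1]][1]; end <- rng[[2]][2]
    } else {
      rng <- as.integer(strsplit(loc, "\\.\\.")[[1]])
      if (length(rng) == 1) rng <- c(rng, rng)
      start <- rng[1]; end <- rng[2]
    }
    feats[[length(feats) + 1]] <- tibble(
      gene = gene, start = start, end = end, strand = strand, key = key
    )
  }
  if (!length(feats)) abort("no annotated features found")
  tbl <- dplyr::bind_rows(feats)
  # one row per gene: CDS/tRNA/rRNA/misc entries carry the annotation;
  # drop duplicate bare 'gene' rows for the same symbol
  tbl <- dplyr::distinct(tbl, .data$gene, .data$start, .data$end,
                         .data$strand)
  ann <- mito_annotation(tbl[, c("gene", "start", "end", "strand")], L, topo)
  list(sequence = sequence, annotation = ann)
}

#' Write a GenBank flat file
#'
#' @param sequence Genome sequence (single string).
#' @param ann A [mito_annotation] for the sequence.
#' @param path Output path.
#' @param name LOCUS name.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(sequence, ann, path, name = "SYNTHETIC") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L != genome_length(ann)) {
    abort("annotation genome_length does not match the sequence")
  }
  topo <- if (topology(ann) == "circular") "circular" else "linear"
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s INV", name, L, topo),
    sprintf("DEFINITION  %s synthetic mitochondrial genome.", name),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L)
  )
  fmt_loc <- function(start, end, strand) {
    loc <- if (end >= start) {
      sprintf("%d..%d", start, end)
    } else {
      sprintf("join(%d..%d,1..%d)", start, L, end)
    }
    if (strand == "reverse") sprintf("complement(%s)", loc) else loc
  }
  for (i in seq_len(nrow(ann))) {
    key <- switch(ann$category[i],
      PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "misc_feature"
    )
    out <- c(out, sprintf("     %-15s %s", key,
                          fmt_loc(ann$start[i], ann$end[i], ann$strand[i])))
    if (ann$category[i] == "CR") {
      out <- c(out, '                     /note="control region"')
    } else {
      out <- c(out, sprintf('                     /gene="%s"', ann$gene[i]))
    }
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1, L, by = 60)
  for (s in starts) {
    chunk <- substr(sequence, s, min(s + 59, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(tolower(tens), collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
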