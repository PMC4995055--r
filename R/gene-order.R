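# Mitogenome gene orders as signed circular permutations.
#
# A circular genome has no distinguished start and no distinguished
# strand: rotating the order or reading the whole molecule from the
# other strand (reversing it and flipping all signs) leaves the genome
# unchanged, and all comparisons here quotient those symmetries out.
# The breakpoint distance counts gene adjacencies of one order that are
# absent from the other, using the standard gene-extremity encoding
# (each gene has a tail and a head; +g is traversed tail->head).

#' Construct a signed circular gene order
#'
#' @param genes Character vector of gene symbols, in genomic order.
#' @param sign Integer vector of +1/-1 (strand); or pass `genes` as
#'   signed strings like `"+cox1"`/`"-trnF"` and omit `sign`.
#' @return A `gene_order` object.
#' @export
gene_order <- function(genes, sign = NULL) {
  if (is.null(sign)) {
    sign <- ifelse(startsWith(genes, "-"), -1L, 1L)
    genes <- sub("^[+-]", "", genes)
  }
  stopifnot(length(genes) == length(sign), all(sign %in% c(-1L, 1L)))
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene symbol: ",
                 genes[duplicated(genes)][1]))
  }
  structure(list(genes = genes, sign = as.integer(sign)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.gene_order <- function(x, ...) {
  paste(paste0(ifelse(x$sign > 0, "+", "-"), x$genes), collapse = " ")
}

#' @export
length.gene_order <- function(x) length(x$genes)

#' Gene order of an annotation
#'
#' @param ann A `mito_annotation` with unique gene names.
#' @param include_cr Keep the control region as an (unsigned-forward)
#'   element? Default `FALSE`: the CR is not a gene.
#' @return A `gene_order` starting from the annotation's first feature.
#' @export
extract_order <- function(ann, include_cr = FALSE) {
  tbl <- as_tibble(ann)
  if (!include_cr) tbl <- dplyr::filter(tbl, .data$category != "CR")
  gene_order(tbl$gene, ifelse(tbl$strand == "forward", 1L, -1L))
}

#' Read gene orders from the one-line text format
#'
#' Each line is `name: +gene1 -gene2 ...`.
#'
#' @param path File path.
#' @return Named list of `gene_order` objects.
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort(paste0("malformed gene-order line: ", ln))
    out[[trimws(parts[1])]] <- gene_order(strsplit(trimws(parts[2]), "\\s+")[[1]])
  }
  out
}

#' Write gene orders in the one-line text format
#' @param orders Named list of `gene_order` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path) {
  writeLines(paste0(names(orders), ": ",
                    vapply(orders, format, "")), path)
  invisible(path)
}

#' The canonical ancestral insect gene order
#'
#' The conserved gene order of the model insect mitogenome (the
#' Drosophila-type arrangement also found in the most mitogenome-
#' conserved whiteflies), shipped as the default rearrangement
#' reference. Leucine tRNA naming follows the whitefly table convention
#' used throughout the package: `trnL1` = L(UUR) between `cox1` and
#' `cox2`, `trnL2` = L(CUN) next to `rrnL`.
#'
#' @return A `gene_order` of 37 genes (control region excluded).
#' @export
ancestral_insect_order <- function() {
  read_gene_orders(system.file("extdata", "ancestral_insect_order.txt",
                               package = "mitocomp", mustWork = TRUE))[[1]]
}

#' Restrict two gene orders to their common gene set
#'
#' @param a,b `gene_order` objects.
#' @return List with restricted orders `a` and `b` (relative order
#'   preserved) and `removed_a`/`removed_b`, the symbols dropped from
#'   each side.
#' @export
restrict_to_common <- function(a, b) {
  common <- intersect(a$genes, b$genes)
  if (length(common) == 0) abort("gene orders share no genes")
  keep_a <- a$genes %in% common
  keep_b <- b$genes %in% common
  list(
    a = gene_order(a$genes[keep_a], a$sign[keep_a]),
    b = gene_order(b$genes[keep_b], b$sign[keep_b]),
    removed_a = setdiff(a$genes, common),
    removed_b = setdiff(b$genes, common)
  )
}

# Adjacency set of a circular signed order: one unordered pair of gene
# extremities per junction. +g contributes (g.t -> g.h); the adjacency
# between consecutive genes x, y is {right extremity of x, left
# extremity of y}. Stored as sorted "ext|ext" strings.
adjacency_set <- function(ord) {
  n <- length(ord$genes)
  right <- ifelse(ord$sign > 0, paste0(ord$genes, ".h"), paste0(ord$genes, ".t"))
  left <- ifelse(ord$sign > 0, paste0(ord$genes, ".t"), paste0(ord$genes, ".h"))
  nxt <- c(seq_len(n)[-1], 1L)
  pairs <- cbind(right, left[nxt])
  apply(pairs, 1, function(p) paste(sort(p), collapse = "|"))
}

#' Breakpoint distance between signed circular gene orders
#'
#' The number of adjacencies of `a` not present in `b`. Invariant under
#' rotation and under whole-molecule reversal (reverse the order and
#' flip every sign), so two readings of the same circle are at distance
#' 0. Apply [restrict_to_common()] first if the gene sets differ.
#'
#' @param a,b `gene_order` objects over the same gene set.
#' @return Integer distance in `0..n`.
#' @export
breakpoint_distance <- function(a, b) {
  if (!setequal(a$genes, b$genes)) {
    abort("gene orders must share the same gene set; see restrict_to_common()")
  }
  sum(!adjacency_set(a) %in% adjacency_set(b))
}

#' Describe rearrangement blocks of a query order against a reference
#'
#' Decomposes the query into maximal runs of genes that are consecutive
#' in the reference (in either direction of reading). Each block is
#' labelled `in-place`, `inverted`, `translocated` or
#' `inverted+translocated`: a block is *inverted* when it reads the
#' reference segment backwards (for single genes, when its strand sign
#' differs from the reference), and *translocated* when the blocks
#' flanking it in the query are not its reference neighbours.
#'
#' @param query,reference `gene_order` objects; gene sets may differ
#'   (the comparison is made on the common set).
#' @return A `rearrangement_report` with the block table, missing-gene
#'   sets, and breakpoint/shared-adjacency counts on the common set.
#' @export
describe_events <- function(query, reference) {
  r <- restrict_to_common(query, reference)
  q <- r$a; ref <- r$b
  n <- length(q$genes)
  ref_pos <- match(q$genes, ref$genes)
  ref_sign <- ref$sign[ref_pos]
  circ_step <- function(i, j, m) ((j - i) %% m + m) %% m  # j - i mod m
  m <- length(ref$genes)
  # direction of reading the reference: +1 if next query gene sits one
  # step clockwise in the reference, -1 if one step counter-clockwise.
  # A run also requires a uniform strand relation (sign agreeing with
  # the reference, or uniformly flipped) so that a lone strand-flipped
  # gene breaks out as its own block.
  flipped <- q$sign != ref_sign
  block_id <- integer(n)
  dir <- integer(n)
  cur <- 1L
  block_id[1] <- cur
  dir[1] <- 0L
  for (i in seq_len(n - 1)) {
    step <- circ_step(ref_pos[i], ref_pos[i + 1], m)
    d <- if (step == 1) 1L else if (step == m - 1) -1L else 0L
    extend <- d != 0L && (dir[i] == 0L || dir[i] == d) &&
      flipped[i + 1] == flipped[i]
    if (extend) {
      block_id[i + 1] <- cur
      dir[i + 1] <- d
      if (dir[i] == 0L) dir[i] <- d
    } else {
      cur <- cur + 1L
      block_id[i + 1] <- cur
      dir[i + 1] <- 0L
    }
  }
  blocks <- purrr::map_dfr(unique(block_id), function(bid) {
    idx <- which(block_id == bid)
    bdir <- dir[idx][dir[idx] != 0L]
    bdir <- if (length(bdir)) bdir[1] else 0L
    # inverted: the block reads the reference backwards, or sits in
    # reference order with every strand flipped
    inverted <- bdir == -1L || all(flipped[idx])
    tibble(
      block = bid,
      genes = paste(q$genes[idx], collapse = "-"),
      n_genes = length(idx),
      ref_from = min(ref_pos[idx]),
      ref_to = max(ref_pos[idx]),
      inverted = inverted
    )
  })
  # a block is in place when its query predecessor block ends exactly
  # one reference step before it (circularly)
  nb <- nrow(blocks)
  prev <- c(nb, seq_len(nb - 1))
  translocated <- vapply(seq_len(nb), function(k) {
    if (nb == 1) return(FALSE)
    p <- prev[k]
    gap <- circ_step(blocks$ref_to[p], blocks$ref_from[k], m)
    gap != 1
  }, logical(1))
  blocks$translocated <- translocated
  blocks$status <- dplyr::case_when(
    blocks$inverted & blocks$translocated ~ "inverted+translocated",
    blocks$inverted ~ "inverted",
    blocks$translocated ~ "translocated",
    TRUE ~ "in-place"
  )
  bp <- breakpoint_distance(q, ref)
  structure(list(
    blocks = blocks,
    missing_in_query = r$removed_b,
    missing_in_reference = r$removed_a,
    n_breakpoints = bp,
    n_shared_adjacencies = length(q$genes) - bp
  ), class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("# Rearrangement report: %d blocks, %d breakpoints, %d shared adjacencies\n",
              nrow(x$blocks), x$n_breakpoints, x$n_shared_adjacencies))
  if (length(x$missing_in_query)) {
    cat("  absent from query:", paste(x$missing_in_query, collapse = ", "), "\n")
  }
  if (length(x$missing_in_reference)) {
    cat("  absent from reference:", paste(x$missing_in_reference, collapse = ", "), "\n")
  }
  print(x$blocks)
  invisible(x)
}

#' @method tidy rearrangement_report
#' @export
tidy.rearrangement_report <- function(x, ...) x$blocks

#' @method glance rearrangement_report
#' @export
glance.rearrangement_report <- function(x, ...) {
  tibble(
    n_blocks = nrow(x$blocks),
    n_breakpoints = x$n_breakpoints,
    n_shared_adjacencies = x$n_shared_adjacencies,
    n_missing_in_query = length(x$missing_in_query),
    n_missing_in_reference = length(x$missing_in_reference)
  )
}

#' Pairwise breakpoint distance matrix
#'
#' Each pair is compared on its common gene set, so taxa with lost
#' tRNAs remain comparable.
#'
#' @param orders Named list of `gene_order` objects.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
order_distance_matrix <- function(orders) {
  k <- length(orders)
  nm <- names(orders) %||% paste0("taxon", seq_len(k))
  m <- matrix(0, k, k, dimnames = list(nm, nm))
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        r <- restrict_to_common(orders[[i]], orders[[j]])
        m[i, j] <- m[j, i] <- breakpoint_distance(r$a, r$b)
      }
    }
  }
  m
}

#' Neighbor-joining tree from a breakpoint distance matrix
#'
#' A distance-based stand-in for rearrangement-count tree searches:
#' neighbor joining (via [ape::nj()]) on the breakpoint distance matrix,
#' with negative branch lengths clamped to 0.
#'
#' @param m Symmetric distance matrix (>= 3 taxa).
#' @return An [ape] `phylo` tree.
#' @export
nj_order_tree <- function(m) {
  if (nrow(m) < 3) abort("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
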