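# Synthetic mitogenome generator: fully specified sequence + annotation
# with planted ground truth for every analysis stage. All randomness is
# driven by the spec's mandatory seed; the same spec yields
# byte-identical output.
#
# Composition targets are honoured almost exactly: unconstrained regions
# are drawn as seeded permutations of a fixed-count base pool, and
# coding regions sample codons from a distribution calibrated (by
# iterative proportional fitting over sense codons) so that its base
# marginal equals the target composition, with deterministic
# largest-remainder counts.

# Integer counts summing to n, proportional to p (largest remainder).
largest_remainder <- function(p, n) {
  raw <- p / sum(p) * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

# Seeded permutation of an exact-count base pool.
random_seq_exact <- function(n, comp) {
  counts <- largest_remainder(comp, n)
  pool <- rep(c("A", "T", "G", "C"), counts)
  paste(sample(pool), collapse = "")
}

# Codon distribution over sense codons whose base marginal matches the
# target composition (iterative proportional fitting).
calibrate_codon_probs <- function(comp, table = "5") {
  comp <- comp / sum(comp)
  names(comp) <- c("A", "T", "G", "C")
  sense <- sense_codons(table)
  mat <- do.call(rbind, strsplit(sense, ""))  # codon x position
  w <- comp
  for (iter in 1:60) {
    q <- w[mat[, 1]] * w[mat[, 2]] * w[mat[, 3]]
    q <- q / sum(q)
    marg <- vapply(c("A", "T", "G", "C"), function(b) {
      sum(q * rowSums(mat == b)) / 3
    }, 0)
    if (max(abs(marg - comp)) < 1e-12) break
    w <- w * comp / marg
    w <- w / sum(w)
  }
  stats::setNames(q, sense)
}

# A CDS of total length len (including start codon and stop tail):
# start codon, calibrated random body codons, then the stop implied by
# len mod 3 (0 -> stop_codon, 1 -> "T", 2 -> "TA").
random_cds <- function(len, comp, start_codon = "ATG", stop_codon = "TAA",
                       table = "5") {
  tail_len <- len %% 3
  tail <- switch(as.character(tail_len), "0" = stop_codon, "1" = "T", "2" = "TA")
  body_len <- len - tail_len - if (tail_len == 0) 3 else 0
  n_body <- body_len / 3
  if (n_body < 2) abort("CDS length too short")
  q <- calibrate_codon_probs(comp, table)
  counts <- largest_remainder(q, n_body - 1)
  codons <- sample(rep(names(q), counts))
  paste0(start_codon, paste(codons, collapse = ""), tail)
}

#' Specification for a synthetic mitogenome
#'
#' The default emulates the whitefly architecture: the 36 genes of the
#' packaged annotation in their published order, strands and sizes on a
#' circular molecule, an A+T-rich composition (A 31.0, T 39.8, G 16.8,
#' C 12.4 percent on the coding strand), the invertebrate mitochondrial
#' code, and a control region planted with a GC-elevated block, a 69-nt
#' poly-T run, a 44-bp stem-loop, two 128-bp tandem-repeat copies, a
#' low-A+T spacer, and three 38-bp repeat copies of which the third
#' carries a 6-bp deletion.
#'
#' @param genes Tibble with `gene`, `category`, `strand`, `length`, and
#'   (for PCGs) `start_codon`, `stop_codon`. Default: derived from the
#'   packaged whitefly table.
#' @param composition Base fractions `c(a, t, g, c)` on the coding
#'   strand.
#' @param cr_plan List of CR elements (in order); see
#'   [default_cr_plan()].
#' @param code_table Genetic code id.
#' @param seed Mandatory RNG seed.
#' @return A `genome_spec` list.
#' @export
mitogenome_spec <- function(genes = NULL,
                            composition = c(a = 0.310, t = 0.398,
                                            g = 0.168, c = 0.124),
                            cr_plan = default_cr_plan(),
                            code_table = "5",
                            seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (is.null(genes)) genes <- default_gene_plan()
  stopifnot(all(genes$length > 0), abs(sum(composition) - 1) < 1e-6)
  structure(list(
    genes = genes, composition = composition, cr_plan = cr_plan,
    code_table = code_table, seed = as.integer(seed)
  ), class = "genome_spec")
}

#' Default whitefly-like gene plan
#'
#' Gene order, strands and sizes of the packaged whitefly annotation
#' (control region excluded; it is built from the CR plan). PCG start
#' codons follow the published calls; stop signals are implied by each
#' gene's length mod 3 (0 = complete stop, 1 = `T--`, 2 = `TA-`).
#'
#' @return Tibble usable as the `genes` field of [mitogenome_spec()].
#' @export
default_gene_plan <- function() {
  ann <- whitefly_annotation()
  genes <- dplyr::filter(as_tibble(ann), .data$category != "CR")
  start <- ifelse(
    genes$category == "PCG" & !is.na(genes$codons),
    sub("^([A-Z]{3}).*$", "\\1", genes$codons), "ATG"
  )
  stop <- ifelse(
    genes$category == "PCG" & grepl(", (TAA|TAG)$", genes$codons),
    sub("^.*, (TA[AG])$", "\\1", genes$codons), "TAA"
  )
  tibble(
    gene = genes$gene,
    category = genes$category,
    strand = genes$strand,
    length = as.integer(genes$declared_size),
    start_codon = ifelse(genes$category == "PCG", start, NA),
    stop_codon = ifelse(genes$category == "PCG", stop, NA)
  )
}

#' Default control-region element plan
#'
#' Mirrors the five-part structure described for the whitefly CR: a
#' 293-bp GC-elevated block (G+C 39 percent), a 69-bp poly-T run, a
#' 63-bp segment containing a 44-bp stem-loop (20-bp arms, 4-nt loop),
#' two 128-bp tandem-repeat copies, a 94-bp spacer with A+T 56 percent,
#' and three 38-bp repeat copies, the third carrying a 6-bp deletion.
#'
#' @return List of element descriptors.
#' @export
default_cr_plan <- function() {
  list(
    list(type = "block", length = 293, gc = 0.39),
    list(type = "polyt", length = 69),
    list(type = "hairpin", stem = 20, loop = 4, flank_before = 9,
         flank_after = 10),
    list(type = "repeat", unit_length = 128, copies = 2),
    list(type = "block", length = 94, gc = 0.44),
    list(type = "repeat", unit_length = 38, copies = 3,
         deletion = list(copy = 3, length = 6))
  )
}

# comp for a block of given gc, splitting each pair evenly
block_comp <- function(gc) {
  at <- 1 - gc
  c(a = at / 2, t = at / 2, g = gc / 2, c = gc / 2)
}

# Build the CR from its plan; returns the sequence and a ground-truth
# element table with 1-based coordinates relative to the CR.
#
# Boundary guards keep planted elements exactly recoverable: the base
# preceding a poly-T run (and the one following it) is forced to a
# non-T, and the base preceding a tandem array must differ from the
# unit's final base so the array cannot extend leftward by chance.
build_cr <- function(plan, comp) {
  pieces <- character()
  types <- character()
  truth <- list()
  pos <- 1L
  no_t_start <- FALSE
  add <- function(s, type, extra = list()) {
    if (no_t_start && startsWith(s, "T")) {
      s <- paste0("C", substr(s, 2, nchar(s)))
    }
    no_t_start <<- FALSE
    pieces[[length(pieces) + 1]] <<- s
    types[[length(types) + 1]] <<- type
    row <- tibble(type = type, start = pos, end = pos + nchar(s) - 1L)
    if (length(extra)) row <- dplyr::bind_cols(row, as_tibble(extra))
    truth[[length(truth) + 1]] <<- row
    pos <<- pos + nchar(s)
  }
  set_prev_last <- function(avoid) {
    i <- length(pieces)
    if (i == 0 || types[i] == "polyt") return(invisible())
    s <- pieces[[i]]
    last <- substr(s, nchar(s), nchar(s))
    if (last %in% avoid) {
      repl <- setdiff(c("C", "G", "A"), avoid)[1]
      pieces[[i]] <<- paste0(substr(s, 1, nchar(s) - 1), repl)
    }
    invisible()
  }
  for (el in plan) {
    switch(el$type,
      block = add(random_seq_exact(el$length, block_comp(el$gc)), "block",
                  list(gc = el$gc)),
      polyt = {
        set_prev_last(avoid = "T")
        add(strrep("T", el$length), "polyt")
        no_t_start <- TRUE
      },
      hairpin = {
        if (el$flank_before > 0) {
          # terminal base A cannot pair with the arm-flanking C below,
          # so the planted stem is not extendable outward
          fb <- paste0(random_seq_exact(max(el$flank_before - 1, 0), comp), "A")
          add(fb, "flank")
        }
        arm1 <- random_seq_exact(el$stem, comp)
        # loop chosen so the innermost flanks cannot pair either
        loop <- paste0("AA", strrep("C", el$loop - 2))
        add(paste0(arm1, loop, revcomp(arm1)), "hairpin",
            list(stem = el$stem, loop = el$loop))
        if (el$flank_after > 0) {
          fa <- paste0("C", random_seq_exact(max(el$flank_after - 1, 0), comp))
          add(fa, "flank")
        }
      },
      "repeat" = {
        unit <- random_seq_exact(el$unit_length, comp)
        set_prev_last(avoid = c("T", substr(unit, el$unit_length,
                                            el$unit_length)))
        copies <- rep(unit, el$copies)
        if (!is.null(el$deletion)) {
          d <- el$deletion
          keep_to <- el$unit_length - d$length
          mid <- floor((el$unit_length - d$length) / 2)
          copies[d$copy] <- paste0(substr(unit, 1, mid),
                                   substr(unit, mid + d$length + 1,
                                          el$unit_length))
        }
        add(paste(copies, collapse = ""), "repeat",
            list(period = el$unit_length, copies = el$copies))
      },
      abort(paste0("unknown CR element type: ", el$type))
    )
  }
  list(seq = paste(pieces, collapse = ""), elements = dplyr::bind_rows(truth))
}

#' Generate a synthetic mitogenome from a spec
#'
#' Lays the planned genes head-to-tail on a circular molecule (the CR,
#' built from the CR plan, takes the position the gene plan gives it or
#' is appended after the last gene), with PCGs generated as valid ORFs
#' under the code table carrying the planned start and stop (incomplete
#' stops included) and reverse-strand genes inserted as reverse
#' complements of their coding sequence.
#'
#' @param spec A `genome_spec` from [mitogenome_spec()].
#' @param cr_after Gene after which the control region is inserted
#'   (default `"cox3"`, the whitefly position; `NA` appends it last).
#' @return List: `sequence`, `annotation` (a [mito_annotation]),
#'   `coding` (named coding-orientation gene sequences),
#'   `cr_elements` (ground-truth CR element table, CR-relative
#'   coordinates), `spec`.
#' @export
generate_mitogenome <- function(spec, cr_after = "cox3") {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    comp <- spec$composition
    genes <- spec$genes
    coding <- purrr::pmap(genes, function(gene, category, strand, length,
                                          start_codon, stop_codon, ...) {
      if (category == "PCG") {
        random_cds(length, comp, start_codon, stop_codon, spec$code_table)
      } else {
        random_seq_exact(length, comp)
      }
    })
    names(coding) <- genes$gene
    cr <- build_cr(spec$cr_plan, comp)
    # assemble: genes in order, CR after `cr_after`
    slot <- if (!is.na(cr_after)) match(cr_after, genes$gene) else nrow(genes)
    if (is.na(slot)) abort(paste0("cr_after gene '", cr_after, "' not in plan"))
    order_names <- append(genes$gene, "CR", after = slot)
    placed <- purrr::map_chr(order_names, function(g) {
      if (g == "CR") return(cr$seq)
      i <- match(g, genes$gene)
      if (genes$strand[i] == "reverse") revcomp(coding[[i]]) else coding[[i]]
    })
    lens <- nchar(placed)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    strands <- purrr::map_chr(order_names, function(g) {
      if (g == "CR") "forward" else genes$strand[match(g, genes$gene)]
    })
    ann <- mito_annotation(
      tibble(gene = order_names, start = starts, end = as.integer(ends),
             strand = strands),
      genome_length = sum(lens), topology = "circular"
    )
    list(
      sequence = paste(placed, collapse = ""),
      annotation = ann,
      coding = stats::setNames(as.character(coding), genes$gene),
      cr_elements = cr$elements,
      spec = spec
    )
  })
}

#' Evolve a CDS under a fixed Ka/Ks (omega)
#'
#' Event-count substitution process with exact planted truth: random
#' single-nucleotide changes are proposed uniformly over sites and
#' alternative bases; proposals creating a stop codon are rejected,
#' synonymous proposals are accepted with relative probability 1 and
#' nonsynonymous ones with relative probability `omega` (scaled so the
#' larger of the two is 1). Proposals continue until
#' `round(expected_subs_per_codon * n_codons)` substitutions have been
#' accepted.
#'
#' @param cds In-frame, stop-free CDS string (no stop codon at the end).
#' @param omega Nonsynonymous/synonymous acceptance ratio (>= 0).
#' @param expected_subs_per_codon Realized substitutions per codon.
#' @param seed RNG seed.
#' @param table Genetic code id.
#' @return List: `cds` (derived sequence), `n_syn`, `n_nonsyn` (realized
#'   event counts).
#' @export
evolve_cds <- function(cds, omega, expected_subs_per_codon, seed,
                       table = "5") {
  if (omega < 0) abort("omega must be >= 0")
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) abort("CDS must be in frame")
  code <- mito_code(table)
  chars <- seq_chars(cds)
  n_codons <- length(chars) / 3
  target <- round(expected_subs_per_codon * n_codons)
  p_syn <- min(1, 1 / max(1, omega))
  p_non <- min(1, omega / max(1, omega))
  n_syn <- 0L; n_nonsyn <- 0L
  withr::with_seed(seed, {
    while (n_syn + n_nonsyn < target) {
      pos <- sample.int(length(chars), 1)
      b <- sample(setdiff(BASES, chars[pos]), 1)
      ci <- (pos - 1) %/% 3
      idx <- ci * 3 + 1:3
      old_codon <- paste(chars[idx], collapse = "")
      new <- chars[idx]
      new[pos - ci * 3] <- b
      new_codon <- paste(new, collapse = "")
      if (code[new_codon] == "*") next
      syn <- code[new_codon] == code[old_codon]
      if (stats::runif(1) <= (if (syn) p_syn else p_non)) {
        chars[pos] <- b
        if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      }
    }
  })
  list(cds = paste(chars, collapse = ""), n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Scramble a gene order with random inversions and translocations
#'
#' @param order A [gene_order()].
#' @param n_inversions Number of random segment inversions (reverse the
#'   segment and flip its signs).
#' @param n_translocations Number of random segment translocations
#'   (move a segment elsewhere, orientation kept).
#' @param seed RNG seed.
#' @return List: `order` (scrambled), `events` (log tibble).
#' @export
scramble_order <- function(order, n_inversions = 0, n_translocations = 0,
                           seed) {
  stopifnot(inherits(order, "gene_order"))
  genes <- order$genes; sign <- order$sign
  events <- list()
  withr::with_seed(seed, {
    for (e in seq_len(n_inversions)) {
      n <- length(genes)
      ij <- sort(sample.int(n, 2))
      seg <- ij[1]:ij[2]
      genes[seg] <- rev(genes[seg])
      sign[seg] <- -rev(sign[seg])
      events[[length(events) + 1]] <- tibble(
        event = "inversion", from = ij[1], to = ij[2], dest = NA_integer_
      )
    }
    for (e in seq_len(n_translocations)) {
      n <- length(genes)
      ij <- sort(sample.int(n, 2))
      seg <- ij[1]:ij[2]
      rest_genes <- genes[-seg]; rest_sign <- sign[-seg]
      k <- sample.int(length(rest_genes) + 1, 1) - 1  # insert after position k
      genes <- append(rest_genes, genes[seg], after = k)
      sign <- append(rest_sign, sign[seg], after = k)
      events[[length(events) + 1]] <- tibble(
        event = "translocation", from = ij[1], to = ij[2], dest = k
      )
    }
  })
  list(
    order = gene_order(genes, sign),
    events = if (length(events)) dplyr::bind_rows(events) else
      tibble(event = character(), from = integer(), to = integer(),
             dest = integer())
  )
}
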