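# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Synonymous/nonsynonymous *sites* are counted per codon as the fraction
# of single-nucleotide mutations that are synonymous, with mutations to
# stop codons excluded from the denominator. *Differences* between two
# codons are averaged over all minimal mutational pathways (orderings of
# the differing positions), excluding pathways that pass through a stop
# codon and renormalizing over the remainder. Proportions are corrected
# with the Jukes-Cantor formula d = -(3/4) ln(1 - (4/3) p).

.mitocomp_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

# Memoized per-code lookup tables: synonymous site counts per sense
# codon, and pathway-averaged (sd, nd) for every ordered codon pair.
ng86_tables <- function(table = "5") {
  key <- paste0("ng86_", table)
  if (!is.null(.mitocomp_cache[[key]])) return(.mitocomp_cache[[key]])
  code <- mito_code(table)
  sense <- names(code)[code != "*"]
  s_sites <- vapply(sense, function(cod) count_sites(cod, table)[["s_sites"]], 0)
  k <- length(sense)
  sd <- matrix(0, k, k, dimnames = list(sense, sense))
  nd <- sd
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- count_differences(sense[i], sense[j], table)
      sd[i, j] <- sd[j, i] <- d[["sd"]]
      nd[i, j] <- nd[j, i] <- d[["nd"]]
    }
  }
  res <- list(sense = sense, s_sites = s_sites, sd = sd, nd = nd)
  .mitocomp_cache[[key]] <- res
  res
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-nucleotide changes that are synonymous; changes creating a
#' stop codon are excluded from the denominator. The two counts always
#' sum to 3.
#'
#' @param codon A sense codon (3-letter DNA string).
#' @param table Genetic code id (default `"5"`).
#' @return Named numeric vector `c(s_sites, n_sites)`.
#' @examples
#' count_sites("TTT")  # s_sites = 1/3 under table 5
#' @export
count_sites <- function(codon, table = "5") {
  codon <- toupper(codon)
  code <- mito_code(table)
  if (is.na(code[codon])) abort(paste0("'", codon, "' is not a codon"))
  if (code[codon] == "*") abort("site counting is undefined for stop codons")
  aa <- code[codon]
  chars <- seq_chars(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (b in setdiff(BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      mut_aa <- code[paste(mut, collapse = "")]
      if (mut_aa == "*") next
      tot <- tot + 1
      if (mut_aa == aa) syn <- syn + 1
    }
    s <- s + if (tot > 0) syn / tot else 0
  }
  c(s_sites = s, n_sites = 3 - s)
}

#' Pathway-averaged synonymous/nonsynonymous differences between codons
#'
#' Averages the synonymous and nonsynonymous step counts over all
#' orderings of the differing positions, dropping orderings whose
#' intermediate codons are stops and renormalizing. If every ordering is
#' blocked by stops (possible only for some 3-difference pairs), the
#' average is taken over all orderings with stop-crossing steps
#' classified by their amino-acid change.
#'
#' @param c1,c2 Sense codons.
#' @param table Genetic code id.
#' @return Named numeric vector `c(sd, nd)` with `sd + nd` equal to the
#'   Hamming distance between the codons.
#' @export
count_differences <- function(c1, c2, table = "5") {
  c1 <- toupper(c1); c2 <- toupper(c2)
  code <- mito_code(table)
  if (is.na(code[c1]) || is.na(code[c2])) abort("inputs must be codons")
  if (code[c1] == "*" || code[c2] == "*") abort("stop codons are not compared")
  a <- seq_chars(c1); b <- seq_chars(c2)
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0) return(c(sd = 0, nd = 0))
  orderings <- perms(diff_pos)
  walk <- function(order, allow_stops) {
    cur <- a
    s <- 0; n <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- code[paste(cur, collapse = "")]
      aa2 <- code[paste(nxt, collapse = "")]
      if (aa2 == "*" && !allow_stops) return(NULL)
      if (aa1 == aa2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- purrr::compact(purrr::map(orderings, walk, allow_stops = FALSE))
  if (length(res) == 0) {
    res <- purrr::map(orderings, walk, allow_stops = TRUE)
  }
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# All permutations of a small vector (n <= 3 here).
perms <- function(x) {
  n <- length(x)
  if (n <= 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance, or `NA` when `p >= 3/4` (saturation).
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori Ka/Ks for a pairwise codon alignment
#'
#' Takes two equal-length, in-frame coding sequences (a gap-free codon
#' alignment; codon columns containing gaps or ambiguity characters are
#' dropped first), counts sites and pathway-averaged differences, and
#' applies the Jukes-Cantor correction to both proportions.
#'
#' @param seq1,seq2 Aligned CDS strings of equal length.
#' @param table Genetic code id (default `"5"`).
#' @return An `ng86` object with fields `S`, `N` (site counts averaged
#'   over both sequences), `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio`,
#'   `n_codons` and a `flag` (`"ok"`, `"identical"`, or
#'   `"saturated"`). `ratio` is `NA` unless both distances are defined
#'   and `Ks > 0`.
#' @seealso [tidy.ng86()], [glance.ng86()], [kaks_panel()]
#' @export
ng86 <- function(seq1, seq2, table = "5") {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) abort("sequences must be aligned (equal length)")
  n <- nchar(seq1) - nchar(seq1) %% 3
  split3 <- function(s) substring(s, seq(1, n - 2, 3), seq(3, n, 3))
  cod1 <- split3(seq1); cod2 <- split3(seq2)
  tabs <- ng86_tables(table)
  ok <- cod1 %in% tabs$sense & cod2 %in% tabs$sense
  cod1 <- cod1[ok]; cod2 <- cod2[ok]
  if (length(cod1) == 0) abort("no comparable codon columns")
  S <- (sum(tabs$s_sites[cod1]) + sum(tabs$s_sites[cod2])) / 2
  N <- 3 * length(cod1) - S
  idx <- cbind(match(cod1, tabs$sense), match(cod2, tabs$sense))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  flag <- if (Sd + Nd == 0) {
    "identical"
  } else if ((is.na(Ks) && !is.na(pS)) || (is.na(Ka) && !is.na(pN))) {
    "saturated"
  } else {
    "ok"
  }
  ratio <- if (flag == "ok" && !is.na(Ks) && !is.na(Ka) && Ks > 0) {
    Ka / Ks
  } else {
    NA_real_
  }
  structure(list(
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    Ks = Ks, Ka = Ka, ratio = ratio, n_codons = length(cod1), flag = flag
  ), class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf(
    "# NG86 over %d codons [%s]\n  S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n  Ks = %s, Ka = %s, Ka/Ks = %s\n",
    x$n_codons, x$flag, x$S, x$N, x$Sd, x$Nd,
    format(x$Ks, digits = 4), format(x$Ka, digits = 4),
    format(x$ratio, digits = 4)
  ))
  invisible(x)
}

#' Tidy an NG86 fit
#' @param x An `ng86` object.
#' @param ... Unused.
#' @return Long tibble of quantity/value pairs.
#' @method tidy ng86
#' @export
tidy.ng86 <- function(x, ...) {
  tibble(
    quantity = c("S", "N", "Sd", "Nd", "pS", "pN", "Ks", "Ka", "ratio"),
    value = c(x$S, x$N, x$Sd, x$Nd, x$pS, x$pN, x$Ks, x$Ka, x$ratio)
  )
}

#' @rdname tidy.ng86
#' @return `glance`: one-row tibble of all quantities plus `n_codons`
#'   and `flag`.
#' @method glance ng86
#' @export
glance.ng86 <- function(x, ...) {
  tibble(
    S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN,
    Ks = x$Ks, Ka = x$Ka, ratio = x$ratio,
    n_codons = x$n_codons, flag = x$flag
  )
}

#' Per-gene Ka/Ks panel across species
#'
#' Runs NG86 over all unordered species pairs for each gene and averages
#' the defined pairwise values (pairs flagged identical or saturated are
#' excluded from the means, not clamped). Sequences for one gene must be
#' pre-aligned and equal length.
#'
#' @param genes Named list; each element a named character vector of
#'   aligned CDS, one per species.
#' @param table Genetic code id.
#' @return Tibble with one row per gene: `gene`, `n_species`, `n_pairs`,
#'   `n_undefined`, `mean_ka`, `mean_ks`, `mean_ratio`, `selection`.
#' @export
kaks_panel <- function(genes, table = "5") {
  purrr::imap_dfr(genes, function(seqs, gene) {
    seqs <- unlist(seqs)
    if (length(seqs) < 2) abort(paste0("gene '", gene, "': need >= 2 species"))
    pairs <- utils::combn(length(seqs), 2)
    fits <- purrr::map(seq_len(ncol(pairs)), function(k) {
      ng86(seqs[pairs[1, k]], seqs[pairs[2, k]], table)
    })
    ratios <- purrr::map_dbl(fits, "ratio")
    kas <- purrr::map_dbl(fits, "Ka")
    kss <- purrr::map_dbl(fits, "Ks")
    mean_ratio <- if (all(is.na(ratios))) NA_real_ else mean(ratios, na.rm = TRUE)
    tibble(
      gene = gene,
      n_species = length(seqs),
      n_pairs = ncol(pairs),
      n_undefined = sum(is.na(ratios)),
      mean_ka = if (all(is.na(kas))) NA_real_ else mean(kas, na.rm = TRUE),
      mean_ks = if (all(is.na(kss))) NA_real_ else mean(kss, na.rm = TRUE),
      mean_ratio = mean_ratio,
      selection = classify_selection(mean_ratio)
    )
  })
}

#' Classify selection from a Ka/Ks ratio
#'
#' @param ratio Numeric vector of Ka/Ks ratios (`NA` = undefined).
#' @return Character vector: `"positive"` (> 1), `"purifying"` (< 1),
#'   `"neutral"` (= 1) or `"undefined"`.
#' @export
classify_selection <- function(ratio) {
  dplyr::case_when(
    is.na(ratio) ~ "undefined",
    ratio > 1 ~ "positive",
    ratio < 1 ~ "purifying",
    TRUE ~ "neutral"
  )
}
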