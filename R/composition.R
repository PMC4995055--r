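# Base composition and strand-asymmetry statistics.
#
# Strand asymmetry follows the standard skew definitions
#   AT skew = (A - T) / (A + T),   GC skew = (G - C) / (G + C),
# computed on the strand as given. Ambiguity codes are excluded from all
# denominators and reported separately.

#' Base composition and strand skews of a sequence
#'
#' @param seq DNA sequence as a single string.
#' @return One-row tibble with counts (`n_a`, `n_t`, `n_g`, `n_c`,
#'   `n_ambiguous`), fractions over unambiguous bases, `at_content` (in
#'   percent), `at_skew` and `gc_skew`. A skew whose denominator is zero
#'   is `NA` (undefined).
#' @examples
#' base_composition("AAAT")$at_skew  # (3 - 1) / 4 = 0.5
#' @export
base_composition <- function(seq) {
  if (length(seq) != 1 || is.na(seq) || !nzchar(seq)) {
    abort("`seq` must be a single non-empty string")
  }
  chars <- seq_chars(seq)
  n_a <- sum(chars == "A"); n_t <- sum(chars == "T")
  n_g <- sum(chars == "G"); n_c <- sum(chars == "C")
  n_unambig <- n_a + n_t + n_g + n_c
  n_ambiguous <- length(chars) - n_unambig
  if (n_unambig == 0) abort("sequence contains no unambiguous bases")
  skew <- function(x, y) if (x + y == 0) NA_real_ else (x - y) / (x + y)
  tibble(
    n_a = n_a, n_t = n_t, n_g = n_g, n_c = n_c, n_ambiguous = n_ambiguous,
    frac_a = n_a / n_unambig, frac_t = n_t / n_unambig,
    frac_g = n_g / n_unambig, frac_c = n_c / n_unambig,
    at_content = 100 * (n_a + n_t) / n_unambig,
    at_skew = skew(n_a, n_t),
    gc_skew = skew(n_g, n_c)
  )
}

#' Strand skews from printed base percentages
#'
#' Applies the skew formulas directly to published percentage
#' compositions, rounding to 3 decimals as such values are customarily
#' reported.
#'
#' @param a,t,g,c Base percentages (need not sum to exactly 100).
#' @return One-row tibble with `at_skew` and `gc_skew` (`NA` when the
#'   respective denominator is zero).
#' @examples
#' skews_from_percentages(31.0, 39.8, 16.8, 12.4)
#' @export
skews_from_percentages <- function(a, t, g, c) {
  stopifnot(a >= 0, t >= 0, g >= 0, c >= 0)
  skew <- function(x, y) if (x + y == 0) NA_real_ else round((x - y) / (x + y), 3)
  tibble(at_skew = skew(a, t), gc_skew = skew(g, c))
}

#' Composition by codon position
#'
#' Pools first, second and third codon positions across a set of
#' in-frame coding sequences (incomplete stop tails of 1-2 nt are
#' trimmed first) and returns one composition row per position.
#'
#' @param cds_list Named list or character vector of CDS given 5'->3' on
#'   the coding strand.
#' @return Tibble with a `position` column (1, 2, 3) plus the
#'   [base_composition()] columns.
#' @export
codon_position_composition <- function(cds_list) {
  cds_list <- as.list(cds_list)
  nm <- names(cds_list) %||% paste0("cds", seq_along(cds_list))
  trimmed <- purrr::imap_chr(cds_list, function(s, i) {
    s <- toupper(s)
    tail_len <- nchar(s) %% 3
    substr(s, 1, nchar(s) - tail_len)
  })
  bad <- which(nchar(trimmed) == 0 | nchar(trimmed) %% 3 != 0)
  if (length(bad)) {
    abort(paste0("CDS '", nm[bad[1]], "' is not in frame after trimming"))
  }
  pooled <- paste(trimmed, collapse = "")
  chars <- seq_chars(pooled)
  pos <- rep_len(1:3, length(chars))
  purrr::map_dfr(1:3, function(p) {
    dplyr::bind_cols(tibble(position = p),
                     base_composition(paste(chars[pos == p], collapse = "")))
  })
}

#' Summary statistics over a declared table column
#'
#' Unweighted min/max/mean of a declared column of the annotation
#' (e.g. `declared_at`, `declared_size`) over a category subset, with
#' the genes attaining the extremes. Published per-category averages
#' (such as a mean tRNA A+T content) are unweighted means of the table
#' column, which this reproduces.
#'
#' @param ann A `mito_annotation`.
#' @param column Column name, e.g. `"declared_at"` or `"declared_size"`.
#' @param categories Categories to keep (default all but CR).
#' @return One-row tibble: `n`, `min`, `max`, `mean`, `argmin`, `argmax`.
#' @export
table_column_stats <- function(ann, column = "declared_at",
                               categories = c("PCG", "tRNA", "rRNA")) {
  stopifnot(column %in% names(ann))
  sub <- dplyr::filter(as_tibble(ann), .data$category %in% categories,
                       !is.na(.data[[column]]))
  if (nrow(sub) == 0) abort("no features with that column in the subset")
  v <- sub[[column]]
  tibble(
    n = nrow(sub),
    min = min(v), max = max(v), mean = mean(v),
    argmin = sub$gene[which.min(v)],
    argmax = sub$gene[which.max(v)]
  )
}
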