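# Codon usage under the invertebrate mitochondrial code (NCBI table 5),
# including the incomplete stop codons characteristic of compact
# mitogenomes: a CDS may end in a bare "T" or "TA" at the annotation
# boundary, completed to TAA by post-transcriptional polyadenylation.

#' Classify the start and stop codon of a CDS
#'
#' The start is the first codon. The stop is read from the tail: a CDS
#' whose length is 1 mod 3 and ends in `T` carries the incomplete stop
#' `T--`; length 2 mod 3 ending in `TA` carries `TA-`; otherwise the
#' final complete codon must be a stop under the genetic code.
#'
#' @param cds CDS sequence, 5'->3' on the coding strand.
#' @param table Genetic code id (default `"5"`).
#' @return One-row tibble: `start_codon`, `stop_codon` (one of `TAA`,
#'   `TAG`, `T`, `TA`), `complete` (logical).
#' @export
classify_start_stop <- function(cds, table = "5") {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 4) abort("CDS too short to carry a start and a stop")
  start <- substr(cds, 1, 3)
  tail_len <- n %% 3
  tail <- substr(cds, n - tail_len + 1, n)
  if (tail_len == 1 && tail == "T") {
    return(tibble(start_codon = start, stop_codon = "T", complete = FALSE))
  }
  if (tail_len == 2 && tail == "TA") {
    return(tibble(start_codon = start, stop_codon = "TA", complete = FALSE))
  }
  if (tail_len != 0) {
    abort(paste0("CDS length ", n, " is out of frame and its tail '", tail,
                 "' is not an incomplete stop"))
  }
  last <- substr(cds, n - 2, n)
  if (!last %in% stop_codons(table)) {
    abort(paste0("final codon '", last, "' is not a stop under code table ",
                 table))
  }
  tibble(start_codon = start, stop_codon = last, complete = TRUE)
}

#' Split a CDS into codons for usage statistics
#'
#' Trims an incomplete stop tail (1-2 nt) before splitting, and excludes
#' a final complete stop codon from the returned list, so the result is
#' the sense-codon content of the gene. Internal stops trigger a warning
#' (with position) but are kept; a CDS without any stop signal warns.
#'
#' @inheritParams classify_start_stop
#' @return Character vector of codons.
#' @examples
#' extract_codons("ATGAAATAA")  # ATG AAA; stop excluded
#' @export
extract_codons <- function(cds, table = "5") {
  cds <- toupper(cds)
  n <- nchar(cds)
  tail_len <- n %% 3
  body <- substr(cds, 1, n - tail_len)
  codons <- substring(body, seq(1, nchar(body) - 2, by = 3),
                      seq(3, nchar(body), by = 3))
  stops <- stop_codons(table)
  has_tail_stop <- tail_len == 1 && endsWith(cds, "T") ||
    tail_len == 2 && endsWith(cds, "TA")
  complete_stop <- tail_len == 0 && length(codons) > 0 &&
    codons[length(codons)] %in% stops
  if (complete_stop) codons <- codons[-length(codons)]
  internal <- which(codons %in% stops)
  if (length(internal)) {
    warn(paste0("internal stop codon at codon position ",
                paste(internal, collapse = ", ")))
  }
  if (!complete_stop && !has_tail_stop) {
    warn("CDS carries no stop signal (complete or incomplete)")
  }
  codons
}

#' Codon usage profile with RSCU
#'
#' Counts sense codons pooled across one or more CDS and computes the
#' relative synonymous codon usage, RSCU(c) = count(c) divided by the
#' mean count over c's synonymous family. Families are the amino-acid
#' classes of the genetic code (stops excluded); under table 5 the Ser
#' family has 8 members and both ATA (Met) and TGA (Trp) are sense
#' codons. Unobserved families get RSCU 0 for all members.
#'
#' @param cds CDS string, character vector/list of CDS, or a character
#'   vector of pre-split codons (`split = FALSE`).
#' @param table Genetic code id (default `"5"`).
#' @param split If `TRUE` (default) `cds` holds full CDS to be run
#'   through [extract_codons()]; if `FALSE`, `cds` is already codons.
#' @return A `codon_profile`: tibble with `codon`, `aa`, `family_size`,
#'   `count`, `rscu`, carrying `total_codons` and `code_table`
#'   attributes.
#' @export
codon_profile <- function(cds, table = "5", split = TRUE) {
  codons <- if (split) {
    unlist(purrr::map(as.list(cds), extract_codons, table = table))
  } else {
    toupper(cds)
  }
  code <- mito_code(table)
  sense <- names(code)[code != "*"]
  counts <- table(factor(codons[codons %in% sense], levels = sense))
  prof <- tibble(
    codon = sense,
    aa = unname(code[sense]),
    count = as.integer(counts)
  ) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      family_size = dplyr::n(),
      rscu = rscu(.data$count)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "aa", "family_size", "count", "rscu") |>
    dplyr::arrange(.data$aa, .data$codon)
  structure(prof,
    total_codons = sum(prof$count),
    code_table = as.character(table),
    class = c("codon_profile", class(prof))
  )
}

#' RSCU from counts over one synonymous family
#'
#' @param counts Integer vector of codon counts belonging to a single
#'   synonymous family.
#' @return Numeric RSCU values; all 0 when the family is unobserved.
#' @examples
#' rscu(c(TTT = 30, TTC = 10))  # 1.5, 0.5
#' @export
rscu <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(rep(0, length(counts)))
  counts / (total / length(counts))
}

#' Most frequently used codons
#'
#' @param profile A `codon_profile`.
#' @param k Number of codons to return (capped at the number observed).
#' @return Tibble of the top-`k` codons by count, ties broken
#'   alphabetically by codon.
#' @export
top_codons <- function(profile, k = 5) {
  dplyr::arrange(as_tibble(profile), dplyr::desc(.data$count), .data$codon) |>
    utils::head(k)
}
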