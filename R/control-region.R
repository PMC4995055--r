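# Structural dissection of mitochondrial control regions (CR / D-loop):
# tandem-repeat arrays, stem-loop (inverted repeat) candidates,
# homopolymer runs, and a tiling of the CR into labelled segments.
# Coordinates are 1-based inclusive throughout.

#' Find maximal homopolymer runs
#'
#' @param seq DNA sequence string.
#' @param base Single base to scan for (default `"T"`).
#' @param min_run Minimum run length to report (>= 2).
#' @return Tibble with `start`, `length`.
#' @examples
#' find_homopolymers("AATTTTA", "T", 3)
#' @export
find_homopolymers <- function(seq, base = "T", min_run = 2) {
  stopifnot(min_run >= 2, nchar(base) == 1)
  chars <- seq_chars(seq)
  r <- rle(chars == toupper(base))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  tibble(start = starts[keep], length = r$lengths[keep])
}

# Can positions p and q pair in a stem? Watson-Crick, plus G.T wobble
# (the DNA rendering of G.U) when allow_gu.
pair_ok_matrix <- function(chars, allow_gu = TRUE) {
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  ok <- outer(chars, chars, function(x, y) comp[x] == y & !is.na(comp[x]))
  if (allow_gu) {
    ok <- ok | outer(chars, chars, function(x, y) {
      (x == "G" & y == "T") | (x == "T" & y == "G")
    })
  }
  ok
}

#' Scan for stem-loop (hairpin) structures
#'
#' Considers every placement of two arms separated by a loop whose
#' length lies in `loop_range`; the arms must be reverse-complementary
#' with at most `max_mismatches` non-pairing positions (G.U counted as
#' pairing when `allow_gu`). Only maximal, non-extendable stems are
#' reported: a hit is dropped if the stem can grow outward (one more
#' pair flanking the arms) or inward (consuming two loop bases) without
#' breaching the mismatch budget or the loop range.
#'
#' @param seq DNA sequence string.
#' @param min_stem Minimum stem length in bp (>= 4).
#' @param loop_range Length-2 vector `(lmin, lmax)` of allowed loop sizes.
#' @param max_mismatches Mismatch budget within the stem.
#' @param allow_gu Count G.U as a pair (default `TRUE`).
#' @return Tibble sorted by stem length (descending): `start`,
#'   `arm1_end`, `loop_start`, `loop_len`, `arm2_start`, `end`, `stem`,
#'   `mismatches`, `span`.
#' @export
find_hairpins <- function(seq, min_stem = 4, loop_range = c(3, 12),
                          max_mismatches = 0, allow_gu = TRUE) {
  stopifnot(min_stem >= 4, length(loop_range) == 2)
  lmin <- loop_range[1]; lmax <- loop_range[2]
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 2 * min_stem + lmin) {
    return(tibble(start = integer(), arm1_end = integer(),
                  loop_start = integer(), loop_len = integer(),
                  arm2_start = integer(), end = integer(), stem = integer(),
                  mismatches = integer(), span = integer()))
  }
  ok <- pair_ok_matrix(chars, allow_gu)
  # mismatches of (i, s, l): pairs (i+k-1, i+2s+l-k), k = 1..s
  mism <- function(i, s, l) {
    ks <- seq_len(s)
    sum(!ok[cbind(i + ks - 1L, i + 2L * s + l - ks)])
  }
  valid <- function(i, s, l) {
    i >= 1 && l >= lmin && l <= lmax && s >= 1 &&
      (i + 2 * s + l - 1) <= n && mism(i, s, l) <= max_mismatches
  }
  hits <- list()
  for (j in 2:n) {          # loop starts at j (arm1 ends at j - 1)
    for (l in lmin:lmax) {
      if (j + l > n) next
      # grow the stem outward from the anchor until budget or bounds
      s <- 0L; bad <- 0L
      while (TRUE) {
        p <- j - s - 1L; q <- j + l + s
        if (p < 1 || q > n) break
        bad2 <- bad + !ok[p, q]
        if (bad2 > max_mismatches) break
        s <- s + 1L; bad <- bad2
      }
      if (s < min_stem) next
      i <- j - s
      # inward extension: stem + 1, loop - 2, same outer boundaries
      if (l - 2 >= lmin && valid(i, s + 1L, l - 2L)) next
      hits[[length(hits) + 1]] <- tibble(
        start = i, arm1_end = j - 1L, loop_start = j, loop_len = l,
        arm2_start = j + l, end = i + 2L * s + l - 1L,
        stem = s, mismatches = mism(i, s, l), span = 2L * s + l
      )
    }
  }
  out <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble(start = integer(), arm1_end = integer(), loop_start = integer(),
           loop_len = integer(), arm2_start = integer(), end = integer(),
           stem = integer(), mismatches = integer(), span = integer())
  dplyr::distinct(out) |>
    dplyr::arrange(dplyr::desc(.data$stem), .data$start, .data$loop_len)
}

#' Find tandem-repeat arrays by seed-and-extend
#'
#' A simplified tandem-repeat finder: for each candidate period `p`, a
#' self-match at lag `p` sustained over `min(p, seed_k)` positions seeds
#' an array, whose first `p` bases become the consensus unit. Further
#' copies are accepted while the best-length alignment of the consensus
#' against the following bases (lengths `p` plus/minus
#' `max_indels_per_copy`, scored by edit distance) reaches
#' `min_identity`; a partial final copy at the end of the sequence may
#' contribute fractionally. Overlapping arrays are resolved
#' leftmost-longest.
#'
#' @param seq DNA sequence string.
#' @param period_range Length-2 vector `(pmin, pmax)`, `pmin >= 2`,
#'   `pmax < nchar(seq)`.
#' @param min_copies Minimum copy number to report (fractional allowed;
#'   default 2).
#' @param min_identity Per-copy identity threshold in (0.5, 1]
#'   (default 0.8, which tolerates a deletion of ~1/6 of a unit).
#' @param max_indels_per_copy Indel budget per copy (default 6).
#' @param seed_k Seed length cap (default 10).
#' @return Tibble: `start`, `period`, `copies`, `total_span`, `end`,
#'   `consensus`, `min_copy_identity`, and `per_copy_identity` (list
#'   column).
#' @export
find_tandem_repeats <- function(seq, period_range = c(5, 150),
                                min_copies = 2, min_identity = 0.8,
                                max_indels_per_copy = 6, seed_k = 10) {
  stopifnot(period_range[1] >= 2, min_identity > 0.5, min_identity <= 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (period_range[2] >= n) abort("pmax must be smaller than the sequence")
  chars <- seq_chars(seq)
  hits <- list()
  for (p in period_range[1]:min(period_range[2], floor(n / 2))) {
    k <- min(p, seed_k)
    eq <- chars[seq_len(n - p)] == chars[(p + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seeds <- starts[r$values & r$lengths >= k]
    for (s in seeds) {
      hit <- extend_repeat(seq, n, s, p, min_identity, max_indels_per_copy)
      # homopolymer runs are trivially periodic at every lag; they are
      # the business of find_homopolymers(), not a tandem array
      if (!is.null(hit) && hit$copies >= min_copies &&
          length(unique(seq_chars(hit$consensus))) > 1) {
        hits[[length(hits) + 1]] <- hit
      }
    }
  }
  empty <- tibble(start = integer(), period = integer(), copies = numeric(),
                  total_span = integer(), end = integer(),
                  consensus = character(), min_copy_identity = numeric(),
                  per_copy_identity = list())
  if (!length(hits)) return(empty)
  out <- dplyr::bind_rows(hits) |>
    dplyr::distinct(.data$start, .data$period, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$total_span), .data$start, .data$period)
  # longest-first (ties leftmost, then smallest period) resolution of
  # overlapping candidates, so a long array is never shadowed by a
  # short accidental one starting a base earlier
  chosen <- list()
  taken <- logical(n)
  for (i in seq_len(nrow(out))) {
    span <- out$start[i]:out$end[i]
    if (!any(taken[span])) {
      chosen[[length(chosen) + 1]] <- out[i, ]
      taken[span] <- TRUE
    }
  }
  dplyr::bind_rows(chosen) |> dplyr::arrange(.data$start)
}

# Greedy copy-wise extension of a tandem array seeded at `s`, period `p`.
extend_repeat <- function(seq, n, s, p, min_identity, max_indels) {
  unit <- substr(seq, s, s + p - 1)
  pos <- s + p
  identities <- 1  # first copy defines the consensus
  copies <- 1
  repeat {
    lens <- (p - max_indels):(p + max_indels)
    lens <- lens[lens >= 1 & pos + lens - 1 <= n]
    if (!length(lens)) break
    cands <- substring(seq, pos, pos + lens - 1)
    d <- as.vector(utils::adist(unit, cands))
    ident <- 1 - d / pmax(p, lens)
    best <- which.max(ident - abs(lens - p) * 1e-9)  # ties: closest to p
    if (ident[best] < min_identity) break
    identities <- c(identities, ident[best])
    copies <- copies + 1
    pos <- pos + lens[best]
  }
  if (copies >= 2) {
    rest <- n - pos + 1
    if (rest >= 4 && rest < p) {  # fractional final copy at sequence end
      d <- as.vector(utils::adist(substr(unit, 1, rest),
                                  substr(seq, pos, pos + rest - 1)))
      ident <- 1 - d / rest
      if (ident >= min_identity) {
        identities <- c(identities, ident)
        copies <- copies + rest / p
        pos <- pos + rest
      }
    }
  }
  if (copies < 2) return(NULL)
  tibble(
    start = s, period = p, copies = copies,
    total_span = pos - s, end = pos - 1L,
    consensus = unit,
    min_copy_identity = min(identities),
    per_copy_identity = list(identities)
  )
}

#' Partition a control region into labelled segments
#'
#' Tiles the CR with the detector hits (precedence: repeat-array >
#' stem-loop > poly-T; lower-precedence hits overlapping an accepted
#' higher-precedence hit are dropped) and classifies every remaining
#' interval as `gc-elevated` when its G+C fraction exceeds
#' `gc_threshold`, else `spacer`. Segments tile the sequence exactly,
#' with no overlap.
#'
#' @param seq CR sequence string.
#' @param repeats Tibble from [find_tandem_repeats()] (may be empty).
#' @param hairpins Tibble from [find_hairpins()]; pass the hit(s) you
#'   consider real, e.g. the top hit.
#' @param polyt Tibble from [find_homopolymers()].
#' @param gc_threshold G+C fraction above which a non-hit interval is
#'   `gc-elevated` (default 0.35; compare a typical whole-mitogenome
#'   G+C near 0.29).
#' @return A `cr_report`: segment tibble (`start`, `end`, `length`,
#'   `class`, `at_content`, `gc_content`) plus the hit tables.
#' @export
partition_cr <- function(seq, repeats = NULL, hairpins = NULL, polyt = NULL,
                         gc_threshold = 0.35) {
  seq <- toupper(seq)
  n <- nchar(seq)
  iv <- tibble(start = integer(), end = integer(), class = character())
  add_hits <- function(iv, d, class) {
    if (is.null(d) || nrow(d) == 0) return(iv)
    ends <- if ("end" %in% names(d)) d$end else d$start + d$length - 1L
    cand <- tibble(start = as.integer(d$start), end = as.integer(ends),
                   class = class)
    cand <- dplyr::arrange(cand, .data$start)
    for (i in seq_len(nrow(cand))) {
      overlaps <- any(cand$start[i] <= iv$end & cand$end[i] >= iv$start)
      if (!overlaps) iv <- dplyr::bind_rows(iv, cand[i, ])
    }
    iv
  }
  iv <- add_hits(iv, repeats, "repeat-array")
  iv <- add_hits(iv, hairpins, "stem-loop")
  iv <- add_hits(iv, polyt, "poly-T")
  iv <- dplyr::arrange(iv, .data$start)
  if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
    abort("internal error: overlapping segments after precedence resolution")
  }
  # fill gaps
  segs <- list()
  cursor <- 1L
  bounds <- rbind(iv[, c("start", "end")],
                  tibble(start = n + 1L, end = n + 1L))
  for (i in seq_len(nrow(bounds))) {
    if (cursor < bounds$start[i]) {
      gap <- tibble(start = cursor, end = bounds$start[i] - 1L,
                    class = NA_character_)
      segs[[length(segs) + 1]] <- gap
    }
    if (bounds$start[i] <= n) segs[[length(segs) + 1]] <- iv[i, ]
    cursor <- max(cursor, bounds$end[i] + 1L)
  }
  segs <- dplyr::bind_rows(segs)
  segs$length <- segs$end - segs$start + 1L
  comp <- purrr::map(seq_len(nrow(segs)), function(i) {
    base_composition(substr(seq, segs$start[i], segs$end[i]))
  }) |> dplyr::bind_rows()
  segs$at_content <- comp$at_content
  segs$gc_content <- 100 - comp$at_content
  segs$class <- ifelse(
    is.na(segs$class),
    ifelse(segs$gc_content / 100 > gc_threshold, "gc-elevated", "spacer"),
    segs$class
  )
  if (sum(segs$length) != n) {
    abort("internal error: segments do not tile the sequence")
  }
  structure(list(
    segments = segs[, c("start", "end", "length", "class",
                        "at_content", "gc_content")],
    repeats = repeats, hairpins = hairpins, polyt = polyt,
    seq_length = n
  ), class = "cr_report")
}

#' @export
print.cr_report <- function(x, ...) {
  cat(sprintf("# Control-region report: %d bp, %d segments\n",
              x$seq_length, nrow(x$segments)))
  print(x$segments)
  invisible(x)
}

#' @method tidy cr_report
#' @export
tidy.cr_report <- function(x, ...) x$segments

#' @method glance cr_report
#' @export
glance.cr_report <- function(x, ...) {
  tibble(
    seq_length = x$seq_length,
    n_segments = nrow(x$segments),
    n_repeat_arrays = sum(x$segments$class == "repeat-array"),
    n_stem_loops = sum(x$segments$class == "stem-loop"),
    n_polyt = sum(x$segments$class == "poly-T")
  )
}

#' One-call control-region dissection
#'
#' Runs the three detectors with defaults tuned for whitefly-scale CRs
#' (~1 kb, A+T-rich) and partitions the sequence. Only the top-scoring
#' hairpin is kept, since mitochondrial CRs typically carry a single
#' functional stem-loop.
#'
#' @param seq CR sequence string.
#' @param period_range,min_identity Passed to [find_tandem_repeats()].
#' @param min_stem,loop_range,max_mismatches Passed to [find_hairpins()].
#' @param polyt_min_run Passed to [find_homopolymers()] (base T).
#' @param gc_threshold Passed to [partition_cr()].
#' @return A `cr_report`.
#' @export
dissect_control_region <- function(seq, period_range = c(5, 150),
                                   min_identity = 0.8,
                                   min_stem = 10, loop_range = c(3, 20),
                                   max_mismatches = 0,
                                   polyt_min_run = 15,
                                   gc_threshold = 0.35) {
  reps <- find_tandem_repeats(seq, period_range, min_identity = min_identity)
  hp <- find_hairpins(seq, min_stem, loop_range, max_mismatches)
  hp <- utils::head(hp, 1)
  pt <- find_homopolymers(seq, "T", polyt_min_run)
  partition_cr(seq, reps, hp, pt, gc_threshold)
}
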