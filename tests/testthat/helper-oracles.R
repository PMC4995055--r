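# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation of the quantity it
# checks, sharing no code with the package implementation.

# ---- NG86 pathway oracle: exhaustive DFS over mutation orderings ----

oracle_count_diffs <- function(c1, c2, table = "5") {
  code <- mito_code(table)
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  complete <- list()
  dfs <- function(cur, remaining, s, n, through_stop) {
    if (!length(remaining)) {
      complete[[length(complete) + 1]] <<- c(s, n, through_stop)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- b[pos]
      syn <- code[paste(cur, collapse = "")] == code[paste(nxt, collapse = "")]
      hit_stop <- through_stop || code[paste(nxt, collapse = "")] == "*"
      dfs(nxt, setdiff(remaining, pos), s + syn, n + !syn, hit_stop)
    }
  }
  dfs(a, which(a != b), 0, 0, FALSE)
  m <- do.call(rbind, complete)
  if (is.null(m)) return(c(0, 0))
  ok <- m[, 3] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(mean(m[, 1]), mean(m[, 2]))
}

random_sense_codons <- function(n, table = "5") {
  sample(sense_codons(table), n, replace = TRUE)
}

# ---- breakpoint-distance oracle: consecutive signed pairs ----

oracle_breakpoint <- function(a, b) {
  signed <- function(o) paste0(ifelse(o$sign > 0, "+", "-"), o$genes)
  pairs_of <- function(o) {
    s <- signed(o)
    n <- length(s)
    cbind(s, s[c(seq_len(n)[-1], 1)])
  }
  flip <- function(x) ifelse(startsWith(x, "+"),
                             sub("^\\+", "-", x), sub("^-", "+", x))
  pb <- pairs_of(b)
  present <- function(x, y) {
    any(pb[, 1] == x & pb[, 2] == y) ||
      any(pb[, 1] == flip(y) & pb[, 2] == flip(x))
  }
  pa <- pairs_of(a)
  sum(!mapply(present, pa[, 1], pa[, 2]))
}

random_order <- function(n) {
  gene_order(paste0("g", sample(n)), sample(c(-1L, 1L), n, replace = TRUE))
}

# ---- hairpin oracle: all placements, naive loops ----

oracle_hairpins <- function(seq, min_stem, loop_range, max_mm,
                            allow_gu = TRUE) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  pairok <- function(x, y) {
    (x == "A" && y == "T") || (x == "T" && y == "A") ||
      (x == "G" && y == "C") || (x == "C" && y == "G") ||
      (allow_gu && ((x == "G" && y == "T") || (x == "T" && y == "G")))
  }
  mm <- function(i, s, l) {
    sum(!mapply(pairok, ch[i:(i + s - 1)], ch[(i + 2 * s + l - 1):(i + s + l)]))
  }
  valid <- function(i, s, l) {
    i >= 1 && s >= 1 && l >= loop_range[1] && l <= loop_range[2] &&
      (i + 2 * s + l - 1) <= n && mm(i, s, l) <= max_mm
  }
  res <- list()
  for (i in seq_len(n)) {
    for (l in loop_range[1]:loop_range[2]) {
      for (s in min_stem:floor((n - l) / 2)) {
        if (!valid(i, s, l)) next
        if (valid(i - 1, s + 1, l)) next
        if (l - 2 >= loop_range[1] && valid(i, s + 1, l - 2)) next
        res[[length(res) + 1]] <- c(start = i, stem = s, loop_len = l)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), stem = integer(),
                      loop_len = integer()))
  }
  out <- as.data.frame(do.call(rbind, res))
  out[order(out$start, out$stem, out$loop_len), ]
}

random_dna <- function(n, probs = c(0.31, 0.398, 0.168, 0.124)) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# small annotation builder
toy_annotation <- function(lengths, L = sum(lengths),
                           strand = rep("forward", length(lengths))) {
  ends <- cumsum(lengths)
  mito_annotation(
    tibble::tibble(
      gene = paste0("g", seq_along(lengths)),
      start = ends - lengths + 1L, end = ends, strand = strand
    ),
    genome_length = L
  )
}
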