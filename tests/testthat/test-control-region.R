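test_that("homopolymer runs are reported maximally", {
  expect_equal(find_homopolymers("AATTTTA", "T", 3),
               tibble::tibble(start = 3L, length = 4L))
  expect_equal(nrow(find_homopolymers("ATATAT", "T", 3)), 0)
  expect_equal(find_homopolymers("TTTTA", "T", 2)$start, 1L)
})

test_that("planted hairpins are recovered exactly", {
  set.seed(61)
  arm <- "GATTACAGCG"
  hp <- paste0(arm, "AACTC", revcomp(arm))
  seq <- paste0(random_dna(150), "A", hp, "C", random_dna(149))
  hits <- find_hairpins(seq, min_stem = 8, loop_range = c(3, 8),
                        max_mismatches = 0)
  top <- hits[1, ]
  expect_equal(top$span, 25L)
  expect_equal(top$stem, 10L)
  expect_equal(top$mismatches, 0L)
  expect_equal(top$start, 152L)
  expect_equal(nrow(find_hairpins("AAAAAAAAAAAAAAAAAAAAAA")), 0)
})

test_that("the hairpin scanner equals the exhaustive oracle", {
  set.seed(73)
  cases <- list(
    list(seq = random_dna(150), min_stem = 4, loop = c(3, 6), mm = 0),
    list(seq = random_dna(120), min_stem = 5, loop = c(3, 8), mm = 1),
    list(seq = random_dna(80), min_stem = 4, loop = c(4, 7), mm = 1,
         gu = FALSE)
  )
  for (cs in cases) {
    gu <- cs$gu %||% TRUE
    got <- find_hairpins(cs$seq, cs$min_stem, cs$loop, cs$mm, allow_gu = gu)
    got <- got[order(got$start, got$stem, got$loop_len),
               c("start", "stem", "loop_len")]
    want <- oracle_hairpins(cs$seq, cs$min_stem, cs$loop, cs$mm, allow_gu = gu)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("planted tandem arrays are recovered with exact period and copies", {
  set.seed(91)
  seq <- paste0(random_dna(100), strrep("ACGTT", 4), "GG", random_dna(98))
  hits <- find_tandem_repeats(seq, period_range = c(3, 20),
                              min_identity = 0.9)
  hit <- hits[which.max(hits$total_span), ]
  expect_equal(hit$period, 5L)
  expect_equal(hit$copies, 4)
  expect_equal(hit$min_copy_identity, 1)
  expect_equal(hit$start, 101L)
})

test_that("random sequence yields no high-identity long-period arrays", {
  set.seed(17)
  seq <- random_dna(500, probs = rep(0.25, 4))
  hits <- find_tandem_repeats(seq, period_range = c(20, 100),
                              min_identity = 0.9)
  expect_equal(nrow(hits), 0)
})

test_that("repeat recovery holds across many seeded plants", {
  set.seed(23)
  recovered <- 0
  trials <- 40
  for (i in seq_len(trials)) {
    p <- sample(6:15, 1)
    copies <- sample(2:5, 1)
    unit <- random_dna(p, probs = rep(0.25, 4))
    seq <- paste0(random_dna(80, probs = rep(0.25, 4)),
                  strrep(unit, copies),
                  random_dna(80, probs = rep(0.25, 4)))
    hits <- find_tandem_repeats(seq, period_range = c(4, 30),
                                min_identity = 0.95)
    ok <- any(abs(hits$period - p) <= 1 & abs(hits$copies - copies) <= 0.5)
    recovered <- recovered + ok
  }
  expect_equal(recovered, trials)  # identity-1 plants: recall 1
})

test_that("partition tiles the CR and honours precedence", {
  # whole-sequence repeat array
  seq <- strrep("ACGTTGGA", 6)
  reps <- find_tandem_repeats(seq, c(4, 16), min_identity = 1)
  rep1 <- partition_cr(seq, repeats = reps)
  expect_equal(rep1$segments$class, "repeat-array")
  expect_equal(sum(rep1$segments$length), nchar(seq))
  # hit-free uniform sequence: one spacer
  rep2 <- partition_cr(strrep("AT", 100))
  expect_equal(rep2$segments$class, "spacer")
  expect_equal(glance(rep2)$n_segments, 1L)
})

test_that("the planted whitefly-style CR dissects into its five-part plan", {
  g <- generate_mitogenome(mitogenome_spec(seed = 42))
  cr <- extract_feature_seq(g$sequence, g$annotation)[["CR"]]
  truth <- g$cr_elements
  rep <- dissect_control_region(cr)
  segs <- tidy(rep)
  expect_equal(sum(segs$length), nchar(cr))
  expect_false(any(segs$start[-1] <= segs$end[-nrow(segs)]))
  # the two arrays: periods 128 and 38, the deleted copy below identity 1
  reps <- rep$repeats[order(-rep$repeats$period), ]
  expect_equal(reps$period, c(128L, 38L))
  expect_equal(reps$copies, c(2, 3))
  expect_equal(reps$min_copy_identity[1], 1)
  expect_equal(reps$min_copy_identity[2], 32 / 38, tolerance = 1e-6)
  # hairpin: planted 44-bp span with a 20-bp stem
  expect_equal(rep$hairpins$span, 44L)
  expect_equal(rep$hairpins$stem, 20L)
  expect_equal(rep$hairpins$start,
               truth$start[truth$type == "hairpin"])
  # poly-T run of 69
  expect_equal(rep$polyt$length, 69L)
  # element class walk (ignoring short spacers between elements)
  classes <- segs$class[segs$class != "spacer"]
  expect_equal(classes, c("gc-elevated", "poly-T", "stem-loop",
                          "repeat-array", "gc-elevated", "repeat-array"))
})
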