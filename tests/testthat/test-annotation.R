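test_that("the packaged whitefly table loads with its published shape", {
  ann <- whitefly_annotation()
  expect_equal(nrow(ann), 37)
  expect_equal(genome_length(ann), 15220L)
  expect_equal(topology(ann), "circular")
  census <- strand_census(ann)
  expect_equal(census$n_genes, 36)
  expect_equal(census$by_category$n, c(13L, 21L, 2L))  # PCG, tRNA, rRNA
  expect_equal(census$by_strand$n, c(20L, 16L))        # forward, reverse
})

test_that("feature_length handles plain and origin-wrapping features", {
  expect_equal(feature_length(1, 1539, 15220), 1539L)
  expect_equal(feature_length(9423, 10700, 15220), 1278L)
  expect_equal(feature_length(15000, 50, 15220), 271L)
  expect_error(feature_length(15000, 50, 15220, topology = "linear"),
               "circular")
})

test_that("junction spacers reproduce the IGN column convention", {
  ann <- whitefly_annotation()
  jx <- junction_spacers(ann)
  expect_equal(jx$spacer[jx$from == "cox1"], 2)    # gap to trnL1
  expect_equal(jx$spacer[jx$from == "atp8"], -1)   # overlap with atp6
  # wrap junction: last feature back to first
  expect_equal(jx$to[nrow(jx)], "cox1")
  # contiguity
  toy <- toy_annotation(c(10, 10))
  expect_equal(junction_spacers(toy)$spacer, c(0, 0))
})

test_that("declared-source adjacency report reproduces the published totals", {
  ann <- whitefly_annotation()
  g <- glance(summarize_junctions(ann, "declared"))
  expect_equal(g$total_overlap_bp, 51)
  expect_equal(g$n_overlap_pairs, 10L)
  expect_equal(g$total_ign_bp, 91)
  expect_equal(g$n_ign_pairs, 14L)
  expect_equal(g$longest_ign_bp, 25)
  expect_match(g$longest_ign_pair, "trnP")
  expect_equal(g$longest_overlap_bp, 20)
  expect_match(g$longest_overlap_pair, "trnF")
})

test_that("coordinate source differs from declared where the table is inconsistent", {
  ann <- whitefly_annotation()
  v <- validate_annotation(ann)
  # CR prints 920 bp but spans 922
  expect_equal(v$size_mismatches$gene, "CR")
  expect_equal(v$size_mismatches$computed_size, 922)
  # trnF declared -20 vs coordinate-derived -15, and the wrap IGN 1 vs 0
  expect_true(all(c("trnF", "trnC") %in% v$ign_mismatches$from))
  expect_equal(
    v$ign_mismatches$spacer[v$ign_mismatches$from == "trnF"], -15)
})

test_that("spacers plus lengths tile a circular non-overlapping annotation", {
  for (seed in 1:5) {
    set.seed(seed)
    lens <- sample(50:500, 8)
    ann <- toy_annotation(lens)
    total <- sum(feature_length(ann$start, ann$end, genome_length(ann))) +
      sum(junction_spacers(ann)$spacer)
    expect_equal(total, genome_length(ann))
  }
})

test_that("feature tables round-trip through write and read", {
  ann <- whitefly_annotation()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ann, path)
  ann2 <- read_feature_table(path, genome_length = genome_length(ann))
  expect_equal(ann2$gene, ann$gene)
  expect_equal(ann2$start, ann$start)
  expect_equal(ann2$end, ann$end)
  expect_equal(ann2$strand, ann$strand)
  expect_equal(ann2$declared_ign, ann$declared_ign)
})

test_that("malformed feature tables fail with informative errors", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_feature_table(empty), "feature table")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tStart\tEnd\tDirection", "cox1\t1\tx\tForward"), bad)
  expect_error(read_feature_table(bad), "malformed coordinates")
  baddir <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tStart\tEnd\tDirection", "cox1\t1\t10\tUp"), baddir)
  expect_error(read_feature_table(baddir), "unknown Direction")
})

test_that("extract_feature_seq slices, wraps and reverse-complements", {
  feats <- tibble::tibble(
    gene = c("a", "b", "c"),
    start = c(1L, 1L, 5L), end = c(3L, 3L, 2L),
    strand = c("forward", "reverse", "forward")
  )
  out <- extract_feature_seq("ATGCCC", feats)
  expect_equal(unname(out), c("ATG", "CAT", "CCAT"))
  expect_error(
    extract_feature_seq("ATG", tibble::tibble(gene = "x", start = 1L,
                                              end = 9L, strand = "forward")),
    "exceed")
})

test_that("an empty annotation yields an all-zero census", {
  ann <- mito_annotation(
    tibble::tibble(gene = character(), start = integer(), end = integer(),
                   strand = character()),
    genome_length = 100
  )
  census <- strand_census(ann)
  expect_equal(sum(census$by_strand$n), 0L)
  expect_equal(sum(census$by_category$n), 0L)
})
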