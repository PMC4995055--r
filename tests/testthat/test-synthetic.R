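test_that("generation is deterministic and matches its own plan", {
  g1 <- generate_mitogenome(mitogenome_spec(seed = 11))
  g2 <- generate_mitogenome(mitogenome_spec(seed = 11))
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$annotation$start, g2$annotation$start)
  g3 <- generate_mitogenome(mitogenome_spec(seed = 12))
  expect_false(identical(g1$sequence, g3$sequence))

  census <- strand_census(g1$annotation)
  expect_equal(census$by_strand$n, c(20L, 16L))
  expect_equal(census$by_category$n, c(13L, 21L, 2L))
  # planted sizes are the annotated sizes (CR comes from its plan)
  ann <- tibble::as_tibble(g1$annotation)
  genes <- ann[ann$category != "CR", ]
  expect_equal(
    feature_length(genes$start, genes$end, genome_length(g1$annotation)),
    g1$spec$genes$length
  )
  expect_error(mitogenome_spec(), "seed")
})

test_that("an all-forward genome hits the target strand composition", {
  plan <- default_gene_plan()
  plan$strand <- "forward"
  g <- generate_mitogenome(mitogenome_spec(genes = plan, seed = 7))
  b <- base_composition(g$sequence)
  target_skew <- (0.310 - 0.398) / (0.310 + 0.398)
  expect_equal(b$at_skew, target_skew, tolerance = 0.01)
  expect_equal(b$at_content, 70.8, tolerance = 1)
})

test_that("synthetic GenBank output re-reads to the generating annotation", {
  g <- generate_mitogenome(mitogenome_spec(seed = 19))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$sequence, g$annotation, path)
  back <- read_genbank(path)
  expect_identical(back$sequence, g$sequence)
  expect_equal(back$annotation$gene, g$annotation$gene)
  expect_equal(back$annotation$start, g$annotation$start)
  expect_equal(back$annotation$end, g$annotation$end)
  expect_equal(back$annotation$strand, g$annotation$strand)
  expect_equal(topology(back$annotation), "circular")
})

test_that("GenBank parsing covers linear records, wrap joins and errors", {
  gb <- c(
    "LOCUS       TOY              12 bp    DNA     linear INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..12",
    "     tRNA            2..7",
    '                     /gene="trnX"',
    "ORIGIN",
    "        1 atgcatgcat gc",
    "//"
  )
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  r <- read_genbank(path)
  expect_equal(topology(r$annotation), "linear")
  expect_equal(r$annotation$start, 2L)

  wrap <- sub("linear", "circular", gb)
  wrap[4] <- "     CDS             join(9..12,1..5)"
  wrap[5] <- '                     /gene="cox1"'
  writeLines(wrap, path)
  r <- read_genbank(path)
  expect_equal(
    feature_length(r$annotation$start, r$annotation$end, 12),
    9L  # 4 + 5 across the origin
  )

  badlen <- sub("12 bp", "99 bp", gb)
  writeLines(badlen, path)
  expect_error(read_genbank(path), "declares 99")

  badjoin <- gb
  badjoin[4] <- "     CDS             join(2..4,8..10)"
  badjoin[5] <- '                     /gene="cox1"'
  writeLines(badjoin, path)
  expect_error(read_genbank(path), "unsupported multi-interval")
})

test_that("evolve_cds respects omega limits and reports true counts", {
  set.seed(3)
  cds <- paste(random_sense_codons(200), collapse = "")
  frozen <- evolve_cds(cds, omega = 0, expected_subs_per_codon = 0.2,
                       seed = 4)
  aa <- function(s) paste(translate <- unname(
    mito_code()[substring(s, seq(1, nchar(s) - 2, 3),
                          seq(3, nchar(s), 3))]), collapse = "")
  expect_equal(aa(frozen$cds), aa(cds))     # omega 0: protein unchanged
  expect_equal(frozen$n_nonsyn, 0L)
  expect_gt(frozen$n_syn, 0L)

  none <- evolve_cds(cds, omega = 1, expected_subs_per_codon = 0, seed = 4)
  expect_identical(none$cds, cds)

  ev <- evolve_cds(cds, omega = 0.5, expected_subs_per_codon = 0.1, seed = 4)
  expect_equal(ev$n_syn + ev$n_nonsyn, 20L)
  expect_error(evolve_cds(cds, omega = -1, 0.1, seed = 1), "omega")
})

test_that("scramble_order events are logged and reproducible", {
  ord <- gene_order(paste0("+g", 1:10))
  s1 <- scramble_order(ord, 2, 1, seed = 99)
  s2 <- scramble_order(ord, 2, 1, seed = 99)
  expect_identical(s1$order$genes, s2$order$genes)
  expect_equal(s1$events$event, c("inversion", "inversion", "translocation"))
  expect_setequal(s1$order$genes, ord$genes)
})

test_that("a planted whitefly-style rearrangement is labelled like the real one", {
  # ancestral order; invert+translocate (cox3, trnG, nad3) as a cluster and
  # translocate (trnA, trnR, trnN), mirroring the whitefly's principal changes
  ref <- ancestral_insect_order()
  g <- ref$genes; s <- ref$sign
  i <- match(c("cox3", "trnG", "nad3"), g)
  stopifnot(all(diff(i) == 1))
  # remove the cluster, re-insert reversed (order flipped, strands kept)
  cluster_g <- rev(g[i]); cluster_s <- rev(s[i])
  g2 <- g[-i]; s2 <- s[-i]
  at <- match("trnN", g2)
  g2 <- append(g2, cluster_g, after = at)
  s2 <- append(s2, cluster_s, after = at)
  q <- gene_order(g2, s2)
  ev <- describe_events(q, ref)
  blocks <- tidy(ev)
  b <- blocks[blocks$genes == "nad3-trnG-cox3", ]
  expect_equal(nrow(b), 1)
  expect_equal(b$status, "inverted+translocated")
})
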