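test_that("start/stop classification covers complete and incomplete stops", {
  expect_equal(
    as.list(classify_start_stop("ATGAAATAA")),
    list(start_codon = "ATG", stop_codon = "TAA", complete = TRUE)
  )
  # cox2-like: length 664 = 1 mod 3, ends in T
  cds <- paste0("ATT", strrep("AAA", 220), "T")
  call <- classify_start_stop(cds)
  expect_equal(call$start_codon, "ATT")
  expect_equal(call$stop_codon, "T")
  expect_false(call$complete)
  # 2-nt tail TA
  expect_equal(classify_start_stop(paste0("ATA", strrep("GGG", 5), "TA"))$stop_codon,
               "TA")
  expect_error(classify_start_stop("ATGAAAAAA"), "not a stop")
  expect_error(classify_start_stop(paste0("ATG", strrep("AAA", 4), "G")),
               "out of frame")
})

test_that("extract_codons trims stops and satisfies the length law", {
  expect_equal(extract_codons("ATGAAATAA"), c("ATG", "AAA"))
  cds664 <- paste0("ATT", strrep("AAA", 220), "T")
  expect_length(extract_codons(cds664), 221)
  expect_warning(expect_equal(extract_codons("ATG"), "ATG"), "no stop")
  expect_warning(extract_codons("ATGTAAAAATAA"), "internal stop")
  # length law: 3*codons + tail + complete stop reconstructs the CDS length
  set.seed(7)
  for (i in 1:20) {
    n_cod <- sample(3:40, 1)
    tail <- sample(c("TAA", "TAG", "T", "TA"), 1)
    body <- paste(random_sense_codons(n_cod), collapse = "")
    cds <- paste0(body, tail)
    codons <- suppressWarnings(extract_codons(cds))
    reconstructed <- 3 * length(codons) + nchar(tail)
    expect_equal(reconstructed, nchar(cds))
  }
})

test_that("RSCU follows the family-mean definition", {
  expect_equal(rscu(c(TTT = 30, TTC = 10)), c(TTT = 1.5, TTC = 0.5))
  expect_equal(rscu(c(2, 2, 2, 2)), rep(1, 4))
  expect_equal(rscu(c(TTA = 12, 0, 0, 0, 0, 0))[[1]], 6)  # all mass on one of 6
  expect_equal(rscu(c(0, 0)), c(0, 0))  # unobserved family
})

test_that("codon_profile family sums equal family sizes when observed", {
  set.seed(21)
  prof <- codon_profile(random_sense_codons(500), split = FALSE)
  sums <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(prof), aa),
                           total = sum(rscu), size = dplyr::n(),
                           observed = sum(count) > 0)
  expect_equal(sums$total[sums$observed], as.numeric(sums$size[sums$observed]))
  expect_equal(attr(prof, "total_codons"), 500L)
  # table 5 specifics: 8-codon Ser family, ATA is Met, TGA is Trp
  expect_equal(unique(prof$family_size[prof$aa == "S"]), 8L)
  expect_equal(prof$aa[prof$codon == "ATA"], "M")
  expect_equal(prof$aa[prof$codon == "TGA"], "W")
})

test_that("top_codons ranks by count with alphabetical ties", {
  prof <- codon_profile(c(rep("AAA", 5), rep("TTT", 5), "GGG"), split = FALSE)
  top <- top_codons(prof, 2)
  expect_equal(top$codon, c("AAA", "TTT"))
  expect_lte(nrow(top_codons(prof, 99)), nrow(prof))
})

test_that("generated PCGs carry their planned starts/stops and AT-biased usage", {
  g <- generate_mitogenome(mitogenome_spec(seed = 303))
  seqs <- extract_feature_seq(g$sequence, g$annotation)
  plan <- g$spec$genes
  pcgs <- plan$gene[plan$category == "PCG"]
  for (gene in pcgs) {
    call <- classify_start_stop(seqs[[gene]])
    expect_equal(call$start_codon, plan$start_codon[plan$gene == gene])
    len <- plan$length[plan$gene == gene]
    expected_stop <- switch(as.character(len %% 3),
                            "0" = plan$stop_codon[plan$gene == gene],
                            "1" = "T", "2" = "TA")
    expect_equal(call$stop_codon, expected_stop)
  }
  prof <- codon_profile(unname(seqs[pcgs]))
  top5 <- top_codons(prof, 5)$codon
  expect_true(all(substr(top5, 3, 3) %in% c("A", "T")))
})
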