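test_that("gene orders extract from annotations in genomic order", {
  ann <- whitefly_annotation()
  ord <- extract_order(ann)
  expect_length(ord, 36)
  expect_equal(ord$genes[1:3], c("cox1", "trnL1", "cox2"))
  expect_equal(ord$sign[1:3], c(1L, 1L, 1L))
  expect_false("trnS1" %in% ord$genes)
  expect_false("CR" %in% ord$genes)
  expect_length(extract_order(toy_annotation(10)), 1)
  expect_error(gene_order(c("a", "a")), "duplicate")
})

test_that("orders round-trip through the one-line text format", {
  orders <- list(x = gene_order(c("+a", "-b", "+c")),
                 y = gene_order(c("-c", "+a", "+b")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_orders(orders, path)
  back <- read_gene_orders(path)
  expect_equal(names(back), c("x", "y"))
  expect_equal(back$x$genes, orders$x$genes)
  expect_equal(back$x$sign, orders$x$sign)
})

test_that("restriction to the common gene set reports removals", {
  q <- extract_order(whitefly_annotation())
  ref <- ancestral_insect_order()
  r <- restrict_to_common(q, ref)
  expect_equal(r$removed_b, "trnS1")  # absent from the whitefly
  expect_equal(r$removed_a, character())
  expect_length(r$a, 36)
  same <- restrict_to_common(q, q)
  expect_equal(same$removed_a, character())
  expect_error(restrict_to_common(gene_order("+a"), gene_order("+b")),
               "no genes")
})

test_that("breakpoint distance respects circular and strand symmetry", {
  a <- gene_order(c("+g1", "+g2", "+g3", "+g4", "+g5"))
  expect_equal(breakpoint_distance(a, a), 0)
  # one inversion of (2,3)
  b <- gene_order(c("+g1", "-g3", "-g2", "+g4", "+g5"))
  expect_equal(breakpoint_distance(a, b), 2)
  # whole-molecule reversal: same circle read from the other strand
  rev_a <- gene_order(rev(a$genes), -rev(a$sign))
  expect_equal(breakpoint_distance(a, rev_a), 0)
  # rotation: same circle, different origin
  rot <- gene_order(a$genes[c(3:5, 1:2)], a$sign[c(3:5, 1:2)])
  expect_equal(breakpoint_distance(a, rot), 0)
  expect_error(breakpoint_distance(a, gene_order("+z")), "same gene set")
})

test_that("breakpoint distance matches the adjacency oracle and is a metric", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    x <- random_order(n); y <- random_order(n); z <- random_order(n)
    dxy <- breakpoint_distance(x, y)
    expect_equal(dxy, oracle_breakpoint(x, y))
    expect_equal(dxy, breakpoint_distance(y, x))
    expect_equal(breakpoint_distance(x, x), 0)
    expect_lte(dxy, breakpoint_distance(x, z) + breakpoint_distance(z, y))
  }
})

test_that("k inversions move the distance by at most 2k", {
  set.seed(31)
  base <- random_order(10)
  for (k in c(1, 3, 5)) {
    sc <- scramble_order(base, n_inversions = k, seed = 100 + k)
    expect_lte(breakpoint_distance(base, sc$order), 2 * k)
    expect_equal(nrow(sc$events), k)
  }
  expect_equal(scramble_order(base, 0, 0, seed = 1)$order$genes, base$genes)
})

test_that("rearrangement blocks label the whitefly-vs-ancestor events", {
  ev <- describe_events(extract_order(whitefly_annotation()),
                        ancestral_insect_order())
  blocks <- tidy(ev)
  nad3_block <- blocks[grepl("nad3", blocks$genes), ]
  expect_equal(nad3_block$genes, "nad3-trnG-cox3")
  expect_equal(nad3_block$status, "inverted+translocated")
  expect_equal(ev$missing_in_query, "trnS1")
  expect_equal(ev$n_breakpoints + ev$n_shared_adjacencies, 36L)
})

test_that("identical orders form one in-place block; a lone inversion two extra breakpoints", {
  a <- gene_order(paste0("+g", 1:8))
  same <- describe_events(a, a)
  expect_equal(nrow(tidy(same)), 1)
  expect_equal(tidy(same)$status, "in-place")
  expect_equal(same$n_breakpoints, 0L)
  flip <- gene_order(c("+g1", "+g2", "-g3", paste0("+g", 4:8)))
  ev <- describe_events(flip, a)
  b <- tidy(ev)
  expect_equal(b$status[b$genes == "g3"], "inverted")
  expect_equal(ev$n_breakpoints, 2L)
})

test_that("distance matrices and NJ trees behave on planted divergence", {
  ords <- list(a = gene_order(paste0("+g", 1:6)),
               b = gene_order(paste0("+g", 1:6)),
               c = gene_order(paste0("+g", 1:6)))
  m <- order_distance_matrix(ords)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  tr <- nj_order_tree(m)
  expect_equal(sum(tr$edge.length), 0)
  expect_error(nj_order_tree(m[1:2, 1:2]), "3 taxa")

  set.seed(8)
  ref <- random_order(12)
  near <- scramble_order(ref, 1, seed = 21)$order
  far <- scramble_order(ref, 6, seed = 22)$order
  farther <- scramble_order(far, 4, seed = 23)$order
  m <- order_distance_matrix(list(ref = ref, near = near, far = far,
                                  farther = farther))
  tr <- nj_order_tree(m)
  pd <- stats::cophenetic(tr)
  expect_lt(pd["ref", "near"], pd["ref", "far"])
  expect_lt(pd["ref", "near"], pd["near", "farther"])
})
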