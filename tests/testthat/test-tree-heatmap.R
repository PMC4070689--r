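test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  # leaf depths 1, 2, 3 from the central node
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tree <- neighbor_joining(d)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  cd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-9)
  depths <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                     tree$tip.label)
  expect_equal(depths[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ recovers additive trees exactly (property over random trees)", {
  withr::with_seed(61, {
    for (i in 1:10) {
      n <- sample(4:12, 1)
      ref <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
      d <- ape::cophenetic.phylo(ref)
      tree <- neighbor_joining(d)
      expect_equal(ape::dist.topo(ape::unroot(ref), tree), 0,
                   ignore_attr = TRUE)
      cd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
      expect_equal(cd, d, tolerance = 1e-8)
    }
  })
})

test_that("NJ is invariant to taxon order and validates its input", {
  withr::with_seed(63, {
    ref <- ape::rtree(7, br = function(k) runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(ref)
    perm <- sample(nrow(d))
    t1 <- neighbor_joining(d)
    t2 <- neighbor_joining(d[perm, perm])
    expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  })
  bad <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3)
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(neighbor_joining(neg), "non-negative")
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})

test_that("NJ agrees with the reference implementation on identity distances", {
  # a family of related sequences (accumulating substitutions), so distances
  # are informative rather than saturated
  mutate <- function(s, n) {
    pos <- sample(nchar(s), n)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  seqs <- withr::with_seed(65, {
    root <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
    a <- mutate(root, 10)
    b <- mutate(a, 12)
    c2 <- mutate(root, 35)
    d2 <- mutate(c2, 15)
    e2 <- mutate(root, 70)
    setNames(c(a, b, c2, d2, e2, mutate(e2, 18)), paste0("OTU", 1:6))
  })
  d <- identity_distances(seqs)
  expect_equal(d, t(d))
  expect_true(all(d[upper.tri(d)] > 0 & d[upper.tri(d)] < 0.5))
  mine <- neighbor_joining(d)
  theirs <- ape::nj(d)
  expect_equal(ape::dist.topo(mine, theirs), 0, ignore_attr = TRUE)

  # Jukes-Cantor correction enlarges raw distances
  dj <- identity_distances(seqs, model = "JC69")
  expect_true(all(dj[upper.tri(dj)] >= d[upper.tri(d)]))
})

test_that("newick parsing and writing round-trip and reject malformed input", {
  txt <- "(A:1,(B:2,C:3):4);"
  tree <- parse_newick(txt)
  expect_equal(write_newick(tree), txt)

  nolen <- parse_newick("(A,(B,C));")
  expect_null(nolen$edge.length)

  withr::with_seed(67, {
    big <- ape::rtree(22)
    big$tip.label <- paste0("OTU", 1:22)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(big, path)
    back <- parse_newick(path)
    expect_equal(ape::dist.topo(ape::unroot(big), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
  })

  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("(A,B));"), "position")
  expect_error(parse_newick("(A:1,(A:2,C:3):4);"), "duplicate")
})

test_that("leaf order is the depth-first tip sequence and covers all leaves", {
  expect_equal(leaf_order(parse_newick("(A,(B,C));")), c("A", "B", "C"))
  withr::with_seed(69, {
    tree <- ape::rtree(9)
    ord <- leaf_order(tree)
    expect_setequal(ord, tree$tip.label)
    lad <- leaf_order(tree, ladderize = TRUE)
    expect_setequal(lad, tree$tip.label)
    expect_identical(lad, leaf_order(tree, ladderize = TRUE))  # deterministic
  })
})

test_that("heatmap matrices follow the tree order exactly", {
  counts <- matrix(c(10L, 5L, 5L, 5L, 5L, 10L), 3, 2,
                   dimnames = list(c("d010", "d005", "d001"), c("A", "B")))
  ser <- compute_fractions(counts, ci = FALSE)
  hm <- build_heatmap(ser, c("A", "B"), order = c("B", "A"))
  expect_equal(rownames(hm), c("B", "A"))
  # columns sorted by day
  expect_equal(attr(hm, "days"), c(1, 5, 10))
  expect_equal(unname(hm["A", ]), unname(100 * counts[c("d001", "d005", "d010"), "A"] /
                                           rowSums(counts)[c("d001", "d005", "d010")]))

  expect_error(build_heatmap(ser, c("A", "Z")), "absent")
  expect_error(build_heatmap(ser, c("A", "B"), order = "A"), "cover")
})

test_that("an end-to-end tree-ordered heatmap renders to file", {
  fx <- fixture_simulation(n_taxa = 5, depth = 40, seed = 71)
  tab <- sample_counts(fx$truth, 400, seed = 4)
  ser <- compute_fractions(tab, ci = FALSE)
  major <- select_major_otus(ser, 0.5)
  seqs <- setNames(fx$taxa$sequence, fx$taxa$taxon_id)[major]
  tree <- neighbor_joining(identity_distances(seqs))
  ord <- leaf_order(tree, ladderize = TRUE)
  hm <- build_heatmap(ser, major, ord)
  expect_equal(rownames(hm), ord[ord %in% major])
  expect_equal(dim(hm), c(length(major), length(fx$truth$sampling_days)))
  img <- withr::local_tempfile(fileext = ".png")
  render_heatmap(hm, img, scale = "log10")
  expect_true(file.exists(img) && file.size(img) > 0)
})
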