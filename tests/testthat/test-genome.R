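test_that("parsing follows the dialect", {
  gs <- parse_genomes(">A\na b $\n")
  expect_length(gs, 1L)
  expect_equal(gs$A$chromosomes[[1]]$markers, c("a", "b"))
  expect_false(gs$A$chromosomes[[1]]$circular)

  gs <- parse_genomes(">B\na -b @\n")
  expect_equal(gs$B$chromosomes[[1]]$signs, c(1L, -1L))
  expect_true(gs$B$chromosomes[[1]]$circular)

  ## comments, blank lines, several genomes per file
  gs <- parse_genomes(c("# comment", ">A", "a b $", "", ">B", "c @"))
  expect_named(gs, c("A", "B"))

  expect_error(parse_genomes(">X\na b a $\n"), "duplicated marker.*a")
  expect_error(parse_genomes(">X\na b\n"), "terminator at line 2")
})

test_that("writing round-trips through parsing", {
  e <- empty_genome("E")
  expect_equal(write_genomes(e), ">E\n")

  g <- genome("G", "a @")
  expect_equal(write_genomes(g), ">G\na @\n")

  for (s in 1:25) {
    pr <- random_genome_pair(3, 2, max_chromosomes = 3, seed = s)
    for (g in pr) {
      back <- parse_genomes(write_genomes(g))[[1]]
      expect_true(genomes_equal(g, back))
    }
  }
})

test_that("canonical form normalizes rotation and reflection and is idempotent", {
  expect_true(genomes_equal(genome("G", "b a @"), genome("G", "a b @")))
  expect_equal(canonical_form(genome("G", "-b -a $"))$chromosomes[[1]]$markers,
               c("a", "b"))
  ## a circular molecule read on the other strand is the same molecule
  expect_true(genomes_equal(genome("G", "a b -c @"), genome("G", "c -b -a @")))
  ## but a different sign pattern is not
  expect_false(genomes_equal(genome("G", "a b c @"), genome("G", "a -b c @")))

  for (s in 1:40) {
    pr <- random_genome_pair(3, 2, max_chromosomes = 3, seed = 1000 + s)
    g1 <- canonical_form(pr$A)
    expect_identical(write_genomes(canonical_form(g1)), write_genomes(g1))
  }
})

test_that("marker partitions cover both genomes and are disjoint", {
  p <- marker_partition(genome("A", "a x $"), genome("B", "a y $"))
  expect_equal(sort(p$common), "a")
  expect_equal(p$onlyA, "x")
  expect_equal(p$onlyB, "y")
  expect_equal(p$u, 2L)

  fam5 <- make_tightness_family(5)[[5]]
  expect_equal(marker_partition(fam5$A, fam5$B)$u, 10L)

  for (s in 1:30) {
    pr <- random_genome_pair(3, 2, seed = 2000 + s)
    p <- marker_partition(pr$A, pr$B)
    expect_length(intersect(p$common, p$onlyA), 0L)
    expect_length(intersect(p$common, p$onlyB), 0L)
    expect_setequal(c(p$common, p$onlyA), genome_markers(pr$A))
    expect_setequal(c(p$common, p$onlyB), genome_markers(pr$B))
  }
})

test_that("triple partition is consistent with pairwise partitions", {
  a <- genome("A", "m $")
  tp <- triple_partition(a, a, a)
  expect_equal(tp$commonABC, "m")
  expect_true(all(lengths(tp[names(tp) != "commonABC"]) == 0L))

  tp <- triple_partition(genome("A", "a x $"), genome("B", "a y $"),
                         empty_genome("C"))
  expect_equal(tp$commonAB, "a")
  expect_length(tp$onlyC, 0L)
  expect_length(tp$commonAC, 0L)

  for (s in 1:40) {
    pr <- random_genome_pair(2, 1, seed = 3000 + s)
    pc <- random_genome_pair(2, 1, seed = 9000 + s)
    C <- dcjmetric:::rename_markers(pc$B, c(yu1 = "zu1"))
    tp <- triple_partition(pr$A, pr$B, C)
    expect_equal(marker_partition(pr$A, pr$B)$u,
                 length(tp$onlyA) + length(tp$commonAC) +
                   length(tp$onlyB) + length(tp$commonBC))
    sets <- unlist(tp, use.names = FALSE)
    expect_false(anyDuplicated(sets) > 0)
    expect_setequal(sets, union(genome_markers(pr$A),
                                union(genome_markers(pr$B), genome_markers(C))))
  }
})
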