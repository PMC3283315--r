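test_that("exact search reproduces hand-checked distances", {
  expect_equal(exact_distance_search(genome("A", "a b $"), genome("B", "a b $"),
                                     "dcj-indel"), 0)
  ## one deletion
  expect_equal(exact_distance_search(genome("A", "a x b $"), genome("B", "a b $"),
                                     "dcj-indel"), 1)
  ## delete x, insert y vs a single substitution
  A <- genome("A", "a x b $"); B <- genome("B", "a y b $")
  expect_equal(exact_distance_search(A, B, "dcj-indel"), 2)
  expect_equal(exact_distance_search(A, B, "dcj-substitution"), 1)
  ## two DCJs for the transposed pair; content must match in the pure model
  expect_equal(exact_distance_search(genome("A", "a b $"), genome("B", "b a $"),
                                     "dcj"), 2)
  expect_error(exact_distance_search(genome("A", "a x $"), genome("B", "a $"),
                                     "dcj"), "equal marker content")
  expect_error(exact_distance_search(genome("A", "a b c d e f $"),
                                     genome("B", "a $"), "dcj-indel"),
               "limit exceeded")
})

test_that("recovered optimal paths affect each unique marker exactly once", {
  for (s in c(3, 42)) {
    pr <- random_genome_pair(1, 1, seed = s)
    for (model in c("dcj-indel", "dcj-substitution")) {
      res <- exact_distance_search(pr$A, pr$B, model, return_path = TRUE)
      msum <- sum(vapply(res$ops, function(o)
        if (o$type == "dcj") 0L else as.integer(o$m), integer(1)))
      expect_equal(msum, marker_partition(pr$A, pr$B)$u)
    }
  }
})

test_that("in-component sorting matches the worked component values", {
  ## already-sorted labeled 2-cycle: one substitution replaces x by y
  r <- make_component_realization("cycle", 2)
  expect_equal(unlist(component_sorting_search(r$A, r$B)),
               c(dcj_cost = 0L, min_runs = 2L, min_substitutions = 1L))
  ## unlabeled component: table DCJ cost, no runs, no substitutions
  bare <- restrict_labels(make_component_realization("cycle", 4)$A,
                          make_component_realization("cycle", 4)$B, character())
  expect_equal(unlist(component_sorting_search(bare$A, bare$B)),
               c(dcj_cost = 1L, min_runs = 0L, min_substitutions = 0L))
  expect_error(component_sorting_search(make_path7_fixture()$A,
                                        make_path7_fixture()$B, max_size = 5),
               "exceeds limit")
})

test_that("potential formulas agree with exhaustive sorting on components up to size 5", {
  set.seed(99)
  shapes <- list(c("cycle", 2), c("cycle", 4), c("AA-path", 3), c("AA-path", 5),
                 c("AB-path", 2), c("AB-path", 4),
                 c("linear-singleton", 1), c("circular-singleton", 1))
  ## size 6, all labeled (the case where one-sided sorting would get
  ## the substitution minimum wrong: 2, not 3)
  r6 <- make_component_realization("cycle", 6)
  cs6 <- component_sorting_search(r6$A, r6$B)
  expect_equal(unlist(cs6),
               c(dcj_cost = 2L, min_runs = 4L, min_substitutions = 2L))
  for (spec in shapes) {
    r <- make_component_realization(spec[1], as.integer(spec[2]))
    part <- marker_partition(r$A, r$B)
    uniq <- c(part$onlyA, part$onlyB)
    subsets <- unlist(lapply(0:length(uniq), function(s)
      utils::combn(uniq, s, simplify = FALSE)), recursive = FALSE)
    if (length(subsets) > 24) subsets <- subsets[sample(length(subsets), 24)]
    for (keep in subsets) {
      res <- restrict_labels(r$A, r$B, keep)
      ag <- adjacency_graph(res$A, res$B)
      lam <- sum(vapply(ag$components, count_runs, integer(1)))
      cs <- component_sorting_search(res$A, res$B)
      expect_equal(cs$min_runs, indel_potential(lam))
      expect_equal(cs$min_substitutions, substitution_potential(lam))
      expect_equal(cs$dcj_cost, dcj_distance(ag))
    }
  }
})

test_that("state-graph distances are symmetric and agree with the direct search", {
  gr <- cache_graph("dcj-indel")
  for (s in c(2, 9, 17)) {
    tp <- template_pair(s)
    d0 <- graph_distance(gr, tp$A, tp$B)
    expect_equal(d0, graph_distance(gr, tp$B, tp$A))
    expect_equal(d0, exact_distance_search(tp$A, tp$B, "dcj-indel"))
  }
})

test_that("genome enumeration covers all canonical genomes over a tiny set", {
  gs <- enumerate_genomes(c("a", "b"))
  ## empty, 2 one-marker forms each, 10 two-marker genomes
  expect_length(gs, 1L + 4L + 10L)
  expect_false(anyDuplicated(names(gs)) > 0)
  expect_error(enumerate_genomes(letters[1:5]), "at most 4")
})
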