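rotate_vertices <- function(comp, r) {
  s <- comp$size
  if (r > 0L) comp$vertices <- comp$vertices[c((r + 1L):s, 1L:r)]
  comp
}

test_that("run counting matches hand-worked cases", {
  ## no labels -> 0 runs
  ag <- adjacency_graph(genome("A", "a b $"), genome("B", "a b $"))
  expect_true(all(vapply(ag$components, count_runs, integer(1)) == 0L))

  ## size-2 cycle labeled on both sides: one run per side
  ag <- adjacency_graph(genome("A", "a x b $"), genome("B", "a y b $"))
  cyc <- ag$components[[which(vapply(ag$components, `[[`, character(1), "kind") == "cycle")]]
  expect_equal(count_runs(cyc), 2L)

  ## a cycle labeled on one side only merges circularly into a single run
  fam <- make_tightness_family(3)[[3]]
  res <- restrict_labels(fam$A, fam$B, c("x1", "x2", "x3"))
  ag <- adjacency_graph(res$A, res$B)
  expect_equal(count_runs(ag$components[[1]]), 1L)

  ## all-labeled 7-vertex path attains the maximum Lambda = |P|
  p7 <- make_path7_fixture()
  ag <- adjacency_graph(p7$A, p7$B)
  expect_equal(count_runs(ag$components[[1]]), 7L)
})

test_that("run counts are invariant under traversal start and direction", {
  cases <- list(make_tightness_family(3)[[3]],
                list(A = make_path7_fixture()$A, B = make_path7_fixture()$B))
  for (cs in cases) {
    for (keep_n in c(0L, 2L, 4L)) {
      part <- marker_partition(cs$A, cs$B)
      uniq <- c(part$onlyA, part$onlyB)
      res <- restrict_labels(cs$A, cs$B, head(uniq, keep_n))
      ag <- adjacency_graph(res$A, res$B)
      for (comp in ag$components) {
        lam <- count_runs(comp)
        rev_comp <- comp
        rev_comp$vertices <- rev(comp$vertices)
        expect_equal(count_runs(rev_comp), lam)
        if (comp$kind == "cycle")
          for (r in seq_len(comp$size - 1L))
            expect_equal(count_runs(rotate_vertices(comp, r)), lam)
      }
    }
  }
})

test_that("potentials follow the closed forms and their ordering", {
  expect_equal(indel_potential(0), 0L)
  expect_equal(indel_potential(6), 4L)
  expect_equal(indel_potential(7), 4L)
  expect_equal(substitution_potential(c(0, 1, 4, 7)), c(0L, 1L, 2L, 2L))
  expect_error(indel_potential(-1), "non-negative")
  expect_error(substitution_potential(-2), "non-negative")

  lam <- 1:200
  l <- indel_potential(lam); s <- substitution_potential(lam)
  expect_true(all(diff(l) >= 0))
  expect_true(all(diff(s) >= 0))
  expect_true(all(s <= l))
  expect_true(all(l <= lam))
})

test_that("the per-component worst-case table matches the printed rows", {
  expect_equal(unname(component_bound_row(3)), c(1L, 3L, 2L, 1L))
  expect_equal(unname(component_bound_row(5)), c(2L, 5L, 3L, 2L))
  expect_equal(unname(component_bound_row(7)), c(3L, 7L, 4L, 2L))
  tab <- component_bound_table(7)
  expect_equal(tab$dcj_cost, c(0L, 0L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(tab$max_lambda, c(1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(tab$max_sigma, c(1L, 1L, 1L, 2L, 2L, 2L, 2L))
  ## the maxima are the potentials at Lambda = |P|
  expect_equal(tab$max_lambda, indel_potential(1:7))
  expect_equal(tab$max_sigma, substitution_potential(1:7))
  expect_error(component_bound_row(0), "positive")
})
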