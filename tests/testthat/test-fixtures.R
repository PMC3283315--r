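test_that("tightness family construction is verified at build time", {
  fam <- cache_family(200)
  expect_length(fam, 200L)
  ## the constructor asserts single all-labeled cycle, Lambda = 2n, d = n-1;
  ## spot-check the n = 2 extremity matching and a large member directly
  f2 <- fam[[2]]
  ag <- adjacency_graph(f2$A, f2$B)
  expect_equal(ag$components[[1]]$kind, "cycle")
  expect_equal(ag$components[[1]]$size, 4L)
  f500 <- dcjmetric:::tightness_member(500)
  expect_equal(marker_partition(f500$A, f500$B)$u, 1000L)
  expect_equal(dcj_indel_bound(f500$A, f500$B)$bound_value, 1000L)
  expect_equal(dcj_substitution_bound(f500$A, f500$B)$bound_value,
               499L + as.integer(ceiling(1001 / 4)))
})

test_that("the 7-vertex fixture is a single all-labeled AA-path", {
  p7 <- make_path7_fixture()
  ag <- adjacency_graph(p7$A, p7$B)
  expect_length(ag$components, 1L)
  expect_equal(ag$components[[1]]$kind, "AA-path")
  expect_equal(ag$components[[1]]$size, 7L)
  expect_equal(count_runs(ag$components[[1]]), 7L)
  expect_equal(ag$n, 3L); expect_equal(ag$c, 0L); expect_equal(ag$b, 0L)
  expect_equal(dcj_distance(ag), 3L)  # = floor((7-1)/2)
})

test_that("component realizations produce the requested shapes", {
  for (spec in list(c("cycle", 2), c("cycle", 6), c("AA-path", 5),
                    c("AB-path", 2), c("AB-path", 4),
                    c("linear-singleton", 1), c("circular-singleton", 1))) {
    r <- make_component_realization(spec[1], as.integer(spec[2]))
    ag <- adjacency_graph(r$A, r$B)
    comp <- ag$components[[r$target]]
    expect_equal(comp$kind, spec[1])
    expect_equal(comp$size, as.integer(spec[2]))
    expect_equal(count_runs(comp), as.integer(spec[2]))
    ## companions (if any) are sorted and unlabeled
    others <- ag$components[-r$target]
    expect_true(all(vapply(others, `[[`, integer(1), "size") <= 2L))
    expect_true(all(vapply(others, count_runs, integer(1)) == 0L))
  }
})

test_that("random pairs are reproducible with the stated content profile", {
  expect_error(random_genome_pair(2, 1), "seed")
  p0 <- random_genome_pair(0, 0, seed = 7)
  expect_length(p0$A$chromosomes, 0L)
  expect_length(p0$B$chromosomes, 0L)
  p1 <- random_genome_pair(3, 2, seed = 11)
  p2 <- random_genome_pair(3, 2, seed = 11)
  expect_identical(write_genomes(p1$A), write_genomes(p2$A))
  expect_identical(write_genomes(p1$B), write_genomes(p2$B))
  for (s in 1:50)
    expect_equal(marker_partition(random_genome_pair(2, 3, seed = s)$A,
                                  random_genome_pair(2, 3, seed = s)$B)$u, 6L)
})
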