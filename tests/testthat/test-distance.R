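test_that("DCJ distance matches worked examples", {
  expect_equal(dcj_distance(genome("A", "a b $"), genome("B", "a b $")), 0L)
  expect_equal(dcj_distance(genome("A", "a b $"), genome("B", "b a $")), 2L)
  expect_equal(dcj_distance(genome("A", "a x b $"), genome("B", "a b $")), 0L)
})

test_that("bound reports assemble distance plus potentials", {
  r <- dcj_indel_bound(genome("A", "a x b $"), genome("B", "a b $"))
  expect_equal(r$bound_value, 1L)
  expect_equal(r$exactness, "bound")

  r <- dcj_indel_bound(genome("A", "a x b $"), genome("B", "a y b $"))
  expect_equal(r$bound_value, 2L)
  expect_equal(dcj_substitution_bound(genome("A", "a x b $"),
                                      genome("B", "a y b $"))$bound_value, 1L)

  ## tightness family: indel bound 2n, substitution bound (n-1)+ceil((2n+1)/4)
  for (fam in cache_family(200)[c(1, 2, 5, 10, 50, 200)]) {
    n <- fam$n
    expect_equal(dcj_indel_bound(fam$A, fam$B)$bound_value, 2L * n)
    expect_equal(dcj_substitution_bound(fam$A, fam$B)$bound_value,
                 (n - 1L) + as.integer(ceiling((2 * n + 1) / 4)))
    ## one whole-chromosome deletion sorts either genome into the empty one
    expect_equal(dcj_indel_bound(fam$A, fam$C)$bound_value, 1L)
    expect_equal(dcj_substitution_bound(fam$B, fam$C)$bound_value, 1L)
  }
})

test_that("distances are symmetric, zero exactly on canonically equal pairs, and diameter-bounded", {
  for (s in 1:60) {
    pr <- random_genome_pair(sample(0:3, 1), sample(0:2, 1), seed = 5000 + s)
    ri <- dcj_indel_bound(pr$A, pr$B)
    rs <- dcj_substitution_bound(pr$A, pr$B)
    expect_equal(ri$bound_value, dcj_indel_bound(pr$B, pr$A)$bound_value)
    expect_equal(rs$bound_value, dcj_substitution_bound(pr$B, pr$A)$bound_value)
    expect_lte(rs$bound_value, ri$bound_value)
    expect_equal(ri$bound_value == 0L, genomes_equal(pr$A, pr$B))
    ag <- adjacency_graph(pr$A, pr$B)
    expect_lte(ri$bound_value,
               diameter_bound("dcj-indel", ag$n, ag$L_A, ag$S_A, ag$L_B, ag$S_B))
    expect_lte(rs$bound_value,
               diameter_bound("dcj-substitution", ag$n, ag$L_A, ag$S_A, ag$L_B, ag$S_B))
  }
})

test_that("diameter bounds take the stated values", {
  expect_equal(diameter_bound("dcj-indel", 5), 10L)
  expect_equal(diameter_bound("dcj-substitution", 200), 300L)
  expect_equal(diameter_bound("dcj-indel", 0, L_A = 1, S_B = 1), 2L)
  expect_equal(diameter_bound("dcj-substitution", 0, L_A = 1, S_B = 1), 2L)
  expect_error(diameter_bound("nope", 3), "unknown model")
})
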