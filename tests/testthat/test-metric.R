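test_that("rational representation and weight schemes", {
  expect_equal(as_rational(0.75), list(num = 3, den = 4))
  expect_equal(as_rational(0.01)$den, 100)
  expect_equal(as_rational(2), list(num = 2, den = 1))
  expect_error(weight_scheme(p = 0), "p > 0")
  expect_error(weight_scheme(k = -1), "k >= 0")
})

test_that("corrected distance adds k per unique marker", {
  r <- dcj_indel_bound(genome("A", "a b $"), genome("B", "a b $"))
  expect_equal(corrected_distance(r, weight_scheme(k = 5)), 0)
  r <- dcj_indel_bound(genome("A", "a x b $"), genome("B", "a b $"))
  expect_equal(corrected_distance(r, weight_scheme(k = 1)), 2)
  fam5 <- cache_family(200)[[5]]
  r <- dcj_indel_bound(fam5$A, fam5$B)
  expect_equal(corrected_distance(r, weight_scheme(k = 1)), 20)
})

test_that("triple audits reproduce the tightness-family algebra", {
  fam5 <- cache_family(200)[[5]]
  ## violation = n(1-k)-1 scaled by 2: 2n - 2 - 2nk
  a <- audit_triple(fam5$A, fam5$B, fam5$C, "dcj-indel", weight_scheme(k = 0.75))
  expect_equal(a$violation, 0.5)
  expect_false(a$holds)
  a <- audit_triple(fam5$A, fam5$B, fam5$C, "dcj-indel", weight_scheme(k = 1))
  expect_equal(a$violation, -2)
  expect_true(a$holds)
  ## degenerate triple always holds
  a <- audit_triple(fam5$A, fam5$A, fam5$A, "dcj-indel", weight_scheme(k = 0))
  expect_true(a$holds)
  expect_equal(a$violation, 0)
})

test_that("the reduced inequality agrees with the direct one when C has no private markers", {
  for (s in 1:25) {
    pr <- random_genome_pair(2, 1, seed = 6000 + s)
    prc <- random_genome_pair(2, 0, seed = 6500 + s)
    C <- prc$B  # markers drawn from the common pool only
    for (k in c(0, 0.5, 1)) {
      a <- audit_triple(pr$A, pr$B, C, "dcj-indel", weight_scheme(k = k))
      direct <- a$m[["AB"]] - a$m[["AC"]] - a$m[["BC"]]
      expect_equal(direct, a$reduced_check)
    }
  }
})

test_that("grid search recovers the smallest passing surcharge", {
  fam5 <- cache_family(200)[[5]]
  trivial <- list(list(A = fam5$A, B = fam5$A, C = fam5$A))
  expect_equal(min_k_grid(trivial, "dcj-indel"), 0)
  ## family up to n = 10: threshold 1 - 1/10 = 0.90, attained on the grid
  ## (the violation 2n - 2 - 2nk is exactly 0 at n = 10, k = 0.9)
  fam10 <- cache_family(200)[1:10]
  expect_equal(min_k_grid(fam10, "dcj-indel", step = 0.01), 0.9)
  ## coarser grid rounds up
  expect_equal(min_k_grid(fam10, "dcj-indel", step = 0.5), 1)
  expect_error(min_k_grid(fam10, "dcj-indel", k_max = 0.5),
               "no k <= 0.5")
})
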