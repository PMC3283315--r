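## Shared expensive fixtures, built once per test run.

.dcj_test_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.dcj_test_cache[[key]])) .dcj_test_cache[[key]] <- builder()
  .dcj_test_cache[[key]]
}

## state graph over the template pair universe {g1, g2, u1, v1}
cache_graph <- function(model) {
  cached(paste0("graph_", model), function()
    oracle_state_graph(c("g1", "g2", "u1", "v1"), model))
}

## exhaustive-scan distance/unique matrices (oracle backend)
cache_scan <- function(model, k = 1) {
  key <- paste0("scan_", model)
  if (is.null(.dcj_test_cache[[key]])) {
    sc <- exhaustive_triple_scan(model, k = k, backend = "oracle",
                                 graph = cache_graph(model))
    .dcj_test_cache[[key]] <- sc$cache
    return(sc)
  }
  exhaustive_triple_scan(model, k = k, cache = .dcj_test_cache[[key]])
}

## component-wise bound matrix over the scan's genome templates
cache_bounds <- function(model) {
  cached(paste0("bounds_", model), function() {
    sc <- cache_scan(model)
    X <- sc$cache$X; Y <- sc$cache$Y
    M <- matrix(0L, length(X), length(Y))
    for (i in seq_along(X)) for (j in seq_along(Y))
      M[i, j] <- distance_report(X[[i]], Y[[j]], model)$bound_value
    M
  })
}

cache_family <- function(n_max = 200L) {
  cached(paste0("family_", n_max), function() make_tightness_family(n_max))
}

cache_path7_sort <- function() {
  cached("path7_sort", function() {
    p7 <- make_path7_fixture()
    component_sorting_search(p7$A, p7$B, max_size = 9L)
  })
}

## map a random_genome_pair() output onto the template universe
template_pair <- function(seed, n_common = 2L) {
  pr <- random_genome_pair(n_common, 1L, seed = seed)
  list(A = dcjmetric:::rename_markers(pr$A, c(xu1 = "u1")),
       B = dcjmetric:::rename_markers(pr$B, c(yu1 = "v1")))
}
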