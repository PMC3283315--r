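## Distances: classical DCJ distance and the tight component-wise upper
## bounds for the DCJ-indel and DCJ-substitution distances.
##
## The headline distances of this package are the component-wise bounds
## d^DCJ + sum of potentials, labeled exactness = "bound".  The exact
## linear-time distances require path-recombination corrections that are out
## of scope here; the bounds are validated against the exact search oracle
## at tiny scale, where they are almost always attained.

#' Classical DCJ distance
#'
#' `d^DCJ(A,B) = n - (c + b/2)` where `n` is the number of common markers
#' and `c`, `b` the numbers of cycles and AB-paths in the adjacency graph.
#' `b` is always even, so the division is exact.
#'
#' @param x a `dcj_adjacency_graph`, or a `dcj_genome` (then `B` required).
#' @param B optional second genome.
#' @return non-negative integer.
#' @export
dcj_distance <- function(x, B = NULL) {
  ag <- if (inherits(x, "dcj_adjacency_graph")) x else adjacency_graph(x, B)
  stopifnot(ag$b %% 2L == 0L)
  d <- ag$n - (ag$c + ag$b %/% 2L)
  stopifnot(d >= 0L)
  d
}

new_distance_report <- function(model, ag, potential_sum, exactness = "bound") {
  d <- dcj_distance(ag)
  structure(list(
    model = model,
    n = ag$n, c = ag$c, b = ag$b,
    dcj_distance = d,
    potential_sum = as.integer(potential_sum),
    bound_value = d + as.integer(potential_sum),
    u = ag$partition$u,
    exactness = exactness
  ), class = "dcj_distance_report")
}

#' Tight upper bound for the DCJ-indel distance
#'
#' `d^DCJ(A,B) + sum of indel-potentials over all components`: sorting each
#' component with its minimum number of optimal DCJs leaves lambda(P) runs,
#' each removable by one indel.
#'
#' @param A,B `dcj_genome` objects.
#' @return a `dcj_distance_report` with `model = "dcj-indel"`.
#' @export
dcj_indel_bound <- function(A, B) {
  ag <- adjacency_graph(A, B)
  lam <- indel_potential(vapply(ag$components, count_runs, integer(1)))
  new_distance_report("dcj-indel", ag, sum(lam))
}

#' Tight upper bound for the DCJ-substitution distance
#'
#' `d^DCJ(A,B) + sum of substitution-potentials`: a substitution can remove
#' a pair of consecutive runs at once, so this bound never exceeds the
#' DCJ-indel bound.
#'
#' @param A,B `dcj_genome` objects.
#' @return a `dcj_distance_report` with `model = "dcj-substitution"`.
#' @export
dcj_substitution_bound <- function(A, B) {
  ag <- adjacency_graph(A, B)
  sig <- substitution_potential(vapply(ag$components, count_runs, integer(1)))
  new_distance_report("dcj-substitution", ag, sum(sig))
}

#' Distance bound for a chosen model
#' @param A,B `dcj_genome` objects.
#' @param model one of `"dcj"`, `"dcj-indel"`, `"dcj-substitution"`.
#' @return a `dcj_distance_report` (for `"dcj"` the potential sum is 0 and
#'   the value is exact for equal-content genomes).
#' @export
distance_report <- function(A, B, model = c("dcj-indel", "dcj-substitution", "dcj")) {
  model <- match.arg(model)
  switch(model,
         "dcj" = new_distance_report("dcj", adjacency_graph(A, B), 0L),
         "dcj-indel" = dcj_indel_bound(A, B),
         "dcj-substitution" = dcj_substitution_bound(A, B))
}

#' Diameter bound of a distance model
#'
#' Maximum possible distance between two genomes with `n` common markers and
#' the given chromosome counts: `2n + L_A + S_A + L_B + S_B` for DCJ-indel
#' (reconstructed from the per-component bound d + lambda <= |P| summed over
#' the vertex-count identity) and `ceiling(3n/2) + L_A + L_B + S_A + S_B`
#' for DCJ-substitution.
#'
#' @param model `"dcj-indel"` or `"dcj-substitution"`.
#' @param n number of common markers.
#' @param L_A,S_A,L_B,S_B linear chromosome / circular singleton counts.
#' @return integer bound.
#' @export
diameter_bound <- function(model, n, L_A = 0L, S_A = 0L, L_B = 0L, S_B = 0L) {
  stopifnot(n >= 0L, L_A >= 0L, S_A >= 0L, L_B >= 0L, S_B >= 0L)
  extra <- L_A + S_A + L_B + S_B
  switch(model,
         "dcj-indel" = 2L * as.integer(n) + extra,
         "dcj-substitution" = as.integer(ceiling(3 * n / 2)) + extra,
         stop("unknown model: ", model))
}

#' @export
print.dcj_distance_report <- function(x, ...) {
  cat(sprintf("%s: n=%d c=%d b=%d  d_DCJ=%d  potentials=%d  bound=%d  u=%d (%s)\n",
              x$model, x$n, x$c, x$b, x$dcj_distance, x$potential_sum,
              x$bound_value, x$u, x$exactness))
  invisible(x)
}
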