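## Runs of unique markers and the indel/substitution potentials.
##
## Concatenating the labels of a component P yields a string over the unique
## markers of the two genomes; a run is a maximal block of that string coming
## from one genome.  Lambda(P), the number of runs, determines how many
## indels (or substitutions) remain after P has been DCJ-sorted with the
## minimum number of optimal DCJs: runs can be accumulated and merged during
## the sorting, and each remaining run costs one indel, while a pair of
## consecutive runs costs one substitution.

#' Count the runs of a component
#'
#' The number of maximal same-side blocks of labeled vertices along the
#' component traversal, ignoring unlabeled vertices.  For a cycle labeled on
#' both sides the count is circular (reading starts between a labeled
#' A-vertex and a labeled B-vertex), so a leading and trailing block on the
#' same side merge.  The count is invariant under the traversal start and
#' direction.
#'
#' @param comp a component of a [adjacency_graph()].
#' @return non-negative integer `Lambda(P) <= |P|`.
#' @export
count_runs <- function(comp) {
  labeled <- vapply(comp$vertices, function(v) length(v$label) > 0L, logical(1))
  sides <- vapply(comp$vertices, `[[`, character(1), "side")[labeled]
  if (length(sides) == 0L) return(0L)
  blocks <- rle(sides)$values
  if (comp$kind == "cycle" && length(blocks) > 1L &&
      blocks[1] == blocks[length(blocks)])
    blocks <- blocks[-length(blocks)]
  length(blocks)
}

#' Indel-potential from a run count
#'
#' Minimum number of runs (hence indels) attainable by sorting a component
#' with its minimum number of optimal DCJs: 0 if `Lambda = 0`, otherwise
#' `floor(Lambda/2) + 1`.  Validated at small scale against the exhaustive
#' in-component sorting search ([component_sorting_search()]).
#'
#' @param lambda_runs vector of non-negative run counts.
#' @return integer vector of indel-potentials.
#' @export
indel_potential <- function(lambda_runs) {
  lambda_runs <- as.integer(lambda_runs)
  if (any(lambda_runs < 0L)) stop("run counts must be non-negative")
  ifelse(lambda_runs == 0L, 0L, lambda_runs %/% 2L + 1L)
}

#' Substitution-potential from a run count
#'
#' Minimum number of substitutions attainable by sorting a component with
#' its minimum number of optimal DCJs: 0 if `Lambda = 0`, otherwise
#' `ceiling((Lambda + 1)/4)`.  Validated against
#' [component_sorting_search()].
#'
#' @param lambda_runs vector of non-negative run counts.
#' @return integer vector of substitution-potentials.
#' @export
substitution_potential <- function(lambda_runs) {
  lambda_runs <- as.integer(lambda_runs)
  if (any(lambda_runs < 0L)) stop("run counts must be non-negative")
  ifelse(lambda_runs == 0L, 0L, as.integer(ceiling((lambda_runs + 1L) / 4)))
}

#' Per-component worst-case table
#'
#' For a component with `size` vertices: the DCJ sorting cost
#' `floor((size-1)/2)`, the maximum run count (`size`, all vertices
#' labeled), and the maximum indel- and substitution-potentials (attained at
#' `Lambda = size`): `ceiling((size+1)/2)` and `ceiling((size+1)/4)`.
#'
#' @param size positive integer vertex count.
#' @return named integer vector `(dcj_cost, max_runs, max_lambda, max_sigma)`.
#' @export
component_bound_row <- function(size) {
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L)
    stop("component size must be a positive integer")
  c(dcj_cost = (size - 1L) %/% 2L,
    max_runs = size,
    max_lambda = as.integer(ceiling((size + 1L) / 2)),
    max_sigma = as.integer(ceiling((size + 1L) / 4)))
}

#' Worst-case table for all component sizes up to a maximum
#' @param max_size largest vertex count to tabulate.
#' @return data.frame with columns `size`, `dcj_cost`, `max_runs`,
#'   `max_lambda`, `max_sigma`.
#' @export
component_bound_table <- function(max_size) {
  rows <- t(vapply(seq_len(max_size), component_bound_row, integer(4)))
  data.frame(size = seq_len(max_size), rows)
}
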