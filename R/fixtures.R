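## Deterministic constructors for the tightness families used in the
## minimal-k analysis, realizations of single adjacency-graph components for
## the sorting-search oracle, and seeded random genome generators.

#' Tightness family for the minimal-k analysis
#'
#' Member n: `A_n` is one circular chromosome `(g1 x1 g2 x2 ... gn xn)`,
#' `B_n` one circular chromosome `(g1 y1 -g2 y2 ... -gn yn)`, and `C` the
#' empty genome.  The construction is verified, not trusted: the adjacency
#' graph of each pair must be a single cycle with `2n` vertices, all
#' labeled, giving `Lambda = 2n` and `d^DCJ = n - 1`.  On this family the
#' corrected DCJ-indel distance violates the triangle inequality exactly
#' when `n(1 - k) > 1`, which drives the minimal surcharge to `k = 1` (and,
#' with substitutions, to `k = 3/4`).
#'
#' @param n_max largest family index.
#' @return list of members, each `list(n, A, B, C)`.
#' @export
make_tightness_family <- function(n_max) {
  stopifnot(n_max >= 1L)
  lapply(seq_len(n_max), tightness_member)
}

## single family member, construction verified (single all-labeled cycle)
tightness_member <- function(n) {
  gs <- paste0("g", seq_len(n))
  xa <- paste0("x", seq_len(n))
  yb <- paste0("y", seq_len(n))
  A <- structure(list(name = paste0("A", n), chromosomes = list(
    chromosome(as.vector(rbind(gs, xa)), 1L, circular = TRUE))),
    class = "dcj_genome")
  signs_b <- rep(1L, 2L * n)
  if (n > 1L) signs_b[2L * (2:n) - 1L] <- -1L  # -g2 ... -gn
  B <- structure(list(name = paste0("B", n), chromosomes = list(
    chromosome(as.vector(rbind(gs, yb)), signs_b, circular = TRUE))),
    class = "dcj_genome")
  ag <- adjacency_graph(A, B)
  stopifnot(length(ag$components) == 1L,
            ag$components[[1]]$kind == "cycle",
            ag$components[[1]]$size == 2L * n,
            all(vapply(ag$components[[1]]$vertices,
                       function(v) length(v$label) > 0L, logical(1))),
            count_runs(ag$components[[1]]) == 2L * n,
            dcj_distance(ag) == n - 1L)
  list(n = n, A = A, B = B, C = empty_genome("C"))
}

#' Seven-vertex all-labeled AA-path fixture
#'
#' `A = x0 a x1 b x2 c x3` (linear), `B = (a y1 c y2 b y3)` (circular).
#' The adjacency graph is asserted to be a single AA-path with 7 vertices,
#' all labeled (`Lambda = 7`), and `d^DCJ = 3`; this is the worst-case
#' component of size 7 used to validate the potential formulas.
#'
#' @return `list(A, B)`.
#' @export
make_path7_fixture <- function() {
  A <- genome("P7A", "x0 a x1 b x2 c x3 $")
  B <- genome("P7B", "a y1 c y2 b y3 @")
  ag <- adjacency_graph(A, B)
  stopifnot(length(ag$components) == 1L,
            ag$components[[1]]$kind == "AA-path",
            ag$components[[1]]$size == 7L,
            count_runs(ag$components[[1]]) == 7L,
            dcj_distance(ag) == 3L)
  list(A = A, B = B)
}

#' Realize an adjacency-graph component of given kind and size
#'
#' Constructs a genome pair whose adjacency graph contains a component of
#' the requested `kind` and `size` with a unique marker in every label slot
#' (so `Lambda = size`), plus — only where unavoidable (AB-paths come in
#' pairs) — one extra size-2 component.  The target component is found by a
#' small arrangement search and asserted, never trusted.  Use
#' [restrict_labels()] to keep a chosen subset of label slots.
#'
#' @param kind one of `"cycle"`, `"AA-path"`, `"AB-path"`,
#'   `"linear-singleton"`, `"circular-singleton"`.
#' @param size vertex count (even for cycles and AB-paths, odd for
#'   AA-paths, 1 for singletons).
#' @return `list(A, B, target)` where `target` is the index of the
#'   component in `adjacency_graph(A, B)`.
#' @export
make_component_realization <- function(kind, size) {
  if (kind == "linear-singleton") {
    stopifnot(size == 1L)
    return(assert_realization(genome("RA", "x1 $"), empty_genome("RB"), kind, size))
  }
  if (kind == "circular-singleton") {
    stopifnot(size == 1L)
    return(assert_realization(genome("RA", "x1 @"), empty_genome("RB"), kind, size))
  }
  if (kind == "cycle") {
    stopifnot(size %% 2L == 0L, size >= 2L)
    m <- size %/% 2L
    fam <- make_tightness_family(m)[[m]]
    return(assert_realization(fam$A, fam$B, kind, size))
  }
  if (kind == "AA-path") {
    stopifnot(size %% 2L == 1L, size >= 3L)
    m <- (size - 1L) %/% 2L
    gs <- paste0("g", seq_len(m))
    xa <- paste0("x", 0:m)
    a_mk <- c(rbind(xa[1:m], gs), xa[m + 1L])
    A <- structure(list(name = "RA", chromosomes = list(chromosome(a_mk, 1L))),
                   class = "dcj_genome")
    for (arr in marker_arrangements(gs)) {
      b_mk <- as.vector(rbind(arr$markers, paste0("y", seq_len(m))))
      b_sg <- as.vector(rbind(arr$signs, rep(1L, m)))
      B <- structure(list(name = "RB", chromosomes = list(
        chromosome(b_mk, b_sg, circular = TRUE))), class = "dcj_genome")
      out <- try_realization(A, B, kind, size, n_components = 1L)
      if (!is.null(out)) return(out)
    }
    stop("no AA-path realization found for size ", size)
  }
  if (kind == "AB-path") {
    stopifnot(size %% 2L == 0L, size >= 2L)
    if (size == 2L)
      return(assert_realization(genome("RA", "x0 g1 x1 $"),
                                genome("RB", "y0 g1 y1 $"), kind, size,
                                n_components = 2L))
    m <- size %/% 2L
    gs <- paste0("g", seq_len(m))
    xa <- paste0("x", 0:m)
    a_mk <- c(rbind(xa[1:m], gs), xa[m + 1L])
    A <- structure(list(name = "RA", chromosomes = list(chromosome(a_mk, 1L))),
                   class = "dcj_genome")
    for (arr in marker_arrangements(gs)) {
      ys <- paste0("y", 0:m)
      b_mk <- c(ys[1], as.vector(rbind(arr$markers, ys[2:(m + 1L)])))
      b_sg <- c(1L, as.vector(rbind(arr$signs, rep(1L, m))))
      B <- structure(list(name = "RB", chromosomes = list(chromosome(b_mk, b_sg))),
                     class = "dcj_genome")
      out <- try_realization(A, B, kind, size, n_components = 2L)
      if (!is.null(out)) return(out)
    }
    stop("no AB-path realization found for size ", size)
  }
  stop("unknown component kind: ", kind)
}

## all sign/permutation arrangements of a marker set (first sign fixed "+"
## for circular-symmetry economy is not assumed; enumerate fully, small m)
marker_arrangements <- function(markers) {
  m <- length(markers)
  perms <- permutations_of(m)
  out <- list()
  sign_rows <- as.matrix(expand.grid(rep(list(c(1L, -1L)), m)))
  for (i in seq_len(nrow(perms))) {
    for (j in seq_len(nrow(sign_rows))) {
      out[[length(out) + 1L]] <- list(markers = markers[perms[i, ]],
                                      signs = as.integer(sign_rows[j, ]))
    }
  }
  out
}

permutations_of <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

try_realization <- function(A, B, kind, size, n_components) {
  ag <- adjacency_graph(A, B)
  if (length(ag$components) != n_components) return(NULL)
  kinds <- vapply(ag$components, `[[`, character(1), "kind")
  sizes <- vapply(ag$components, `[[`, integer(1), "size")
  hit <- which(kinds == kind & sizes == size)
  if (length(hit) < 1L) return(NULL)
  hit <- hit[1L]
  if (n_components == 2L && !all(sizes[-hit] == 2L)) return(NULL)
  ## keep only the unique markers labeling the target component, so that any
  ## companion component (AB-paths come in pairs) is unlabeled
  labels <- unlist(lapply(ag$components[[hit]]$vertices, `[[`, "label"),
                   use.names = FALSE)
  keep <- sub("^-", "", labels %||% character())
  res <- restrict_labels(A, B, keep)
  ag2 <- adjacency_graph(res$A, res$B)
  kinds2 <- vapply(ag2$components, `[[`, character(1), "kind")
  sizes2 <- vapply(ag2$components, `[[`, integer(1), "size")
  hit2 <- which(kinds2 == kind & sizes2 == size)
  if (length(hit2) < 1L) return(NULL)
  hit2 <- hit2[1L]
  all_lab <- all(vapply(ag2$components[[hit2]]$vertices,
                        function(v) length(v$label) > 0L, logical(1)))
  if (!all_lab) return(NULL)
  list(A = res$A, B = res$B, target = hit2)
}

assert_realization <- function(A, B, kind, size, n_components = 1L) {
  out <- try_realization(A, B, kind, size, n_components)
  if (is.null(out)) stop("realization assertion failed for ", kind, " size ", size)
  out
}

#' Restrict the unique markers of a pair to a kept subset
#'
#' Drops from both genomes every marker private to one genome except those
#' in `keep`; common markers are untouched.  Used to produce partial
#' labelings of a realized component.
#'
#' @param A,B `dcj_genome` objects.
#' @param keep character vector of unique marker names to keep.
#' @return `list(A, B)`.
#' @export
restrict_labels <- function(A, B, keep = character()) {
  part <- marker_partition(A, B)
  drop <- setdiff(c(part$onlyA, part$onlyB), keep)
  list(A = drop_markers(A, drop), B = drop_markers(B, drop))
}

#' Seeded random genome pair
#'
#' A reproducible pair with `n_common` shared markers and `n_unique_each`
#' private markers per genome, arranged independently at random into up to
#' `max_chromosomes` chromosomes; each chromosome is circular with
#' probability `circular_prob`.
#'
#' @param n_common,n_unique_each non-negative counts.
#' @param max_chromosomes maximum number of chromosomes per genome.
#' @param circular_prob probability that a chromosome is circular.
#' @param seed integer seed (required; the generator is deterministic).
#' @return `list(A, B)`.
#' @export
random_genome_pair <- function(n_common, n_unique_each, max_chromosomes = 2L,
                               circular_prob = 0.3, seed) {
  stopifnot(n_common >= 0L, n_unique_each >= 0L, !missing(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gs <- if (n_common > 0L) paste0("g", seq_len(n_common)) else character()
  mk <- function(uniq, name) {
    all_m <- c(gs, uniq)
    if (length(all_m) == 0L)
      return(empty_genome(name))
    ord <- sample(length(all_m))
    signs <- sample(c(-1L, 1L), length(all_m), replace = TRUE)
    k <- sample.int(min(max_chromosomes, length(all_m)), 1L)
    splits <- if (k > 1L && length(all_m) > 1L)
      sort(sample.int(length(all_m) - 1L, k - 1L)) else integer()
    bounds <- c(0L, splits, length(all_m))
    chroms <- lapply(seq_len(k), function(i) {
      idx <- (bounds[i] + 1L):bounds[i + 1L]
      chromosome(all_m[ord][idx], signs[idx],
                 circular = stats::runif(1) < circular_prob)
    })
    structure(list(name = name, chromosomes = chroms), class = "dcj_genome")
  }
  A <- mk(if (n_unique_each > 0L) paste0("xu", seq_len(n_unique_each)) else character(), "A")
  B <- mk(if (n_unique_each > 0L) paste0("yu", seq_len(n_unique_each)) else character(), "B")
  list(A = A, B = B)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
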