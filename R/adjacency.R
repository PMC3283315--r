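## Labeled adjacency graph AG(A,B) of two genomes.
##
## Vertices are the adjacencies of each genome: pairs of consecutive
## common-marker extremities (or extremity + telomere), carrying as label the
## unique markers lying between them.  A chromosome with no common markers is
## a single labeled vertex (linear or circular singleton).  For each common
## marker g one edge joins the two vertices containing g^h and one the two
## containing g^t, so the graph decomposes into cycles, AB-/AA-/BB-paths and
## singletons, with vertices strictly alternating genome sides.

TEL <- "TEL"

ext <- function(marker, end) paste0(marker, ".", end)

## Extremity pair of a signed marker in reading direction: +g exposes tail
## then head, -g head then tail.
marker_ends <- function(marker, sign) {
  if (sign > 0L) c(ext(marker, "t"), ext(marker, "h"))
  else           c(ext(marker, "h"), ext(marker, "t"))
}

new_vertex <- function(side, e1, e2, label, singleton = NA_character_) {
  list(side = side, ends = c(e1, e2), label = label, singleton = singleton)
}

vertex_key <- function(v) {
  paste(v$side, v$ends[1], v$ends[2], paste(v$label, collapse = ","))
}

## Vertices contributed by one chromosome of one genome side.
chromosome_vertices <- function(ch, common, side) {
  is_common <- ch$markers %in% common
  toks <- chromosome_tokens(ch)
  if (!any(is_common)) {
    return(list(new_vertex(side, TEL, TEL, toks,
                           singleton = if (ch$circular) "circular" else "linear")))
  }
  pos <- which(is_common)
  k <- length(pos)
  left <- character(k); right <- character(k)
  for (i in seq_len(k)) {
    e <- marker_ends(ch$markers[pos[i]], ch$signs[pos[i]])
    left[i] <- e[1]; right[i] <- e[2]
  }
  verts <- list()
  m <- length(ch$markers)
  if (!ch$circular) {
    lab0 <- if (pos[1] > 1L) toks[seq_len(pos[1] - 1L)] else character()
    verts[[1]] <- new_vertex(side, TEL, left[1], lab0)
    if (k > 1L) for (i in seq_len(k - 1L)) {
      between <- if (pos[i + 1L] - pos[i] > 1L)
        toks[(pos[i] + 1L):(pos[i + 1L] - 1L)] else character()
      verts[[i + 1L]] <- new_vertex(side, right[i], left[i + 1L], between)
    }
    labk <- if (pos[k] < m) toks[(pos[k] + 1L):m] else character()
    verts[[k + 1L]] <- new_vertex(side, right[k], TEL, labk)
  } else {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      between <- if (i == k) {
        c(if (pos[k] < m) toks[(pos[k] + 1L):m] else character(),
          if (pos[1] > 1L) toks[seq_len(pos[1] - 1L)] else character())
      } else if (pos[j] - pos[i] > 1L) {
        toks[(pos[i] + 1L):(pos[j] - 1L)]
      } else character()
      verts[[i]] <- new_vertex(side, right[i], left[j], between)
    }
  }
  verts
}

#' Build the labeled adjacency graph of two genomes
#'
#' @param A,B valid `dcj_genome` objects (no duplicated markers).
#' @return an object of class `dcj_adjacency_graph` with fields `n` (number
#'   of common markers), `components` (list; each has `kind`, `vertices`,
#'   `size`), cycle count `c`, AB-path count `b`, linear chromosome counts
#'   `L_A`, `L_B`, circular singleton counts `S_A`, `S_B`, and the marker
#'   `partition` of the pair.
#' @export
adjacency_graph <- function(A, B) {
  validate_genome(A); validate_genome(B)
  part <- marker_partition(A, B)
  common <- part$common

  build_side <- function(g, side) {
    out <- list()
    for (ch in g$chromosomes)
      out <- c(out, chromosome_vertices(ch, common, side))
    out
  }
  va <- build_side(A, "A")
  vb <- build_side(B, "B")
  verts <- c(va, vb)
  nv <- length(verts)
  side_of <- vapply(verts, `[[`, character(1), "side")

  ## extremity -> vertex index, per side (each common extremity occurs once)
  ext_map <- function(idx) {
    ends <- unlist(lapply(verts[idx], `[[`, "ends"), use.names = FALSE)
    owner <- rep(idx, each = 2L)
    keep <- ends != TEL
    stats::setNames(owner[keep], ends[keep])
  }
  mapA <- ext_map(which(side_of == "A"))
  mapB <- ext_map(which(side_of == "B"))

  is_singleton <- vapply(verts, function(v) !is.na(v$singleton), logical(1))
  degree <- vapply(verts, function(v) sum(v$ends != TEL), integer(1))
  degree[is_singleton] <- 0L

  visited <- logical(nv)
  components <- list()
  membership <- integer(nv)  # component id per vertex (A-side first, build order)

  ## Follow the alternating walk: enter vertex i via extremity `via`
  ## (NA at a path start), leave via the other end, cross to the vertex on
  ## the opposite side holding the same extremity.
  walk <- function(start, via) {
    order_ <- integer(0)
    i <- start
    repeat {
      visited[i] <<- TRUE
      order_ <- c(order_, i)
      e <- verts[[i]]$ends
      out <- if (is.na(via)) e[e != TEL] else e[e != via]
      if (length(out) == 0L || out[1] == TEL) return(list(order_, closed = FALSE))
      out <- out[1]
      nxt <- if (side_of[i] == "A") mapB[[out]] else mapA[[out]]
      if (nxt == start && out %in% verts[[start]]$ends && visited[nxt] &&
          length(order_) > 1L) {
        ## closed the cycle
        return(list(order_, closed = TRUE))
      }
      if (visited[nxt]) return(list(order_, closed = TRUE))
      via <- out
      i <- nxt
    }
  }

  for (i in seq_len(nv)) {
    if (visited[i] || !is_singleton[i]) next
    visited[i] <- TRUE
    v <- verts[[i]]
    components[[length(components) + 1L]] <- list(
      kind = paste0(v$singleton, "-singleton"), vertices = list(v), size = 1L)
    membership[i] <- length(components)
  }
  ## paths start at telomere-carrying vertices (degree 1)
  for (i in seq_len(nv)) {
    if (visited[i] || degree[i] != 1L) next
    res <- walk(i, NA_character_)
    ord <- res[[1]]
    ends_side <- side_of[c(ord[1], ord[length(ord)])]
    kind <- if (all(ends_side == "A")) "AA-path"
    else if (all(ends_side == "B")) "BB-path"
    else "AB-path"
    components[[length(components) + 1L]] <-
      list(kind = kind, vertices = verts[ord], size = length(ord))
    membership[ord] <- length(components)
  }
  ## what remains are cycles
  for (i in seq_len(nv)) {
    if (visited[i]) next
    e1 <- verts[[i]]$ends[1]
    res <- walk(i, e1)  # leave via ends[2], come back through ends[1]
    ord <- res[[1]]
    components[[length(components) + 1L]] <-
      list(kind = "cycle", vertices = verts[ord], size = length(ord))
    membership[ord] <- length(components)
  }

  components <- lapply(components, canonicalize_component)

  kinds <- vapply(components, `[[`, character(1), "kind")
  b <- sum(kinds == "AB-path")
  stopifnot(b %% 2L == 0L)
  count_linear <- function(g) sum(vapply(g$chromosomes,
                                         function(ch) !ch$circular, logical(1)))
  S_A <- sum(vapply(va, function(v) identical(v$singleton, "circular"), logical(1)))
  S_B <- sum(vapply(vb, function(v) identical(v$singleton, "circular"), logical(1)))

  structure(list(
    n = length(common),
    components = components,
    c = sum(kinds == "cycle"),
    b = b,
    L_A = count_linear(A), L_B = count_linear(B),
    S_A = S_A, S_B = S_B,
    partition = part,
    membership = membership,
    n_vertices_A = length(va)
  ), class = "dcj_adjacency_graph")
}

## Deterministic vertex order: paths start at the A-side endpoint (AB) or the
## lexicographically smaller endpoint (AA/BB); cycles rotate the smallest
## vertex first and run toward the smaller neighbour.  Run counting is
## invariant under this choice; it only fixes serialization.
canonicalize_component <- function(comp) {
  v <- comp$vertices
  s <- comp$size
  if (s == 1L) return(comp)
  keys <- vapply(v, vertex_key, character(1))
  if (comp$kind == "cycle") {
    i0 <- order_radix(keys)[1L]
    fwd <- c(i0:s, if (i0 > 1L) 1:(i0 - 1L))
    bwd <- c(i0, rev(setdiff(fwd, i0)))
    pick <- if (s >= 3L &&
                order_radix(c(keys[fwd[2]], keys[bwd[2]]))[1L] == 2L) bwd else fwd
    comp$vertices <- v[pick]
  } else if (comp$kind %in% c("AA-path", "BB-path")) {
    if (order_radix(c(keys[1], keys[s]))[1L] == 2L) comp$vertices <- rev(v)
  } else if (comp$kind == "AB-path") {
    if (v[[1]]$side != "A") comp$vertices <- rev(v)
  }
  comp
}

#' Vertex-count identity check
#'
#' The total vertex count of the adjacency graph must equal
#' `2n + L_A + S_A + L_B + S_B`: each common marker contributes a head and a
#' tail on each side (4n extremity occurrences, two per vertex), each linear
#' chromosome two telomeres, and each circular singleton one vertex.
#'
#' @param ag a `dcj_adjacency_graph`.
#' @return logical.
#' @export
vertex_count_check <- function(ag) {
  total <- sum(vapply(ag$components, `[[`, integer(1), "size"))
  total == 2L * ag$n + ag$L_A + ag$S_A + ag$L_B + ag$S_B
}

#' @export
print.dcj_adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency graph: n=%d c=%d b=%d  L_A=%d L_B=%d S_A=%d S_B=%d\n",
              x$n, x$c, x$b, x$L_A, x$L_B, x$S_A, x$S_B))
  cat(format_components(x), sep = "\n")
  invisible(x)
}

#' Tab-separated debug dump of the components
#' @param ag a `dcj_adjacency_graph`.
#' @return character vector, one line per component.
#' @export
format_components <- function(ag) {
  vapply(seq_along(ag$components), function(i) {
    p <- ag$components[[i]]
    vtx <- vapply(p$vertices, function(v) {
      lab <- if (length(v$label)) paste0("(", paste(v$label, collapse = " "), ")") else ""
      paste0(v$side, "{", v$ends[1], ",", v$ends[2], "}", lab)
    }, character(1))
    paste(i, p$kind, p$size, paste(vtx, collapse = " "), sep = "\t")
  }, character(1))
}
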