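## Brute-force exact computations at tiny scale.
##
## The oracle works on the full operation model: DCJs (two cuts, rejoin),
## deletions/insertions of contiguous blocks (at most one chromosome touched
## at once) and, in the substitution model, replacement of one contiguous
## block by another at the same location (either block may be empty, so a
## substitution subsumes an indel).  Organizational operations weigh 1,
## content-modifying operations p + k*m where m is the number of affected
## markers.  States are deduplicated under canonical form; uniform-cost
## search gives exact minimum-weight sorting distances, and a level-wise
## search over optimal in-component DCJs validates the potential formulas.

## ---- genome <-> adjacency-set representation (for DCJ enumeration) ------

## Rows of a 2-column matrix of extremity tokens ("a.t", "a.h") or TEL.
## `with_gaps` additionally returns, per row, the chromosome index and gap
## position it represents (gap g = between marker g and g+1; 0 = before the
## first marker of a linear chromosome).
genome_to_adjset <- function(g, with_gaps = FALSE) {
  rows <- list(); gchrom <- integer(); ggap <- integer()
  for (ci in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[ci]]
    L <- length(ch$markers)
    le <- character(L); re <- character(L)
    for (t in seq_len(L)) {
      e <- marker_ends(ch$markers[t], ch$signs[t])
      le[t] <- e[1]; re[t] <- e[2]
    }
    add <- function(x, y, gap) {
      rows[[length(rows) + 1L]] <<- c(x, y)
      gchrom[length(gchrom) + 1L] <<- ci
      ggap[length(ggap) + 1L] <<- gap
    }
    if (!ch$circular) {
      add(TEL, le[1], 0L)
      if (L > 1L) for (t in seq_len(L - 1L)) add(re[t], le[t + 1L], t)
      add(re[L], TEL, L)
    } else {
      if (L > 1L) for (t in seq_len(L - 1L)) add(re[t], le[t + 1L], t)
      add(re[L], le[1], L)
    }
  }
  m <- if (length(rows)) do.call(rbind, rows) else matrix(character(), 0, 2)
  if (with_gaps) list(rows = m, chrom = gchrom, gap = ggap) else m
}

ext_marker <- function(e) sub("\\.[th]$", "", e)
ext_is_tail <- function(e) endsWith(e, ".t")
other_end <- function(e)
  paste0(ext_marker(e), if (ext_is_tail(e)) ".h" else ".t")

## Rebuild a genome from an adjacency set (chromosome walk).
adjset_to_genome <- function(rows, name = "g") {
  if (nrow(rows) == 0L) return(empty_genome(name))
  partner <- character(0)
  tel_ext <- character(0)
  for (i in seq_len(nrow(rows))) {
    x <- rows[i, 1]; y <- rows[i, 2]
    if (x == TEL && y == TEL) next
    if (x == TEL) { partner[y] <- TEL; tel_ext <- c(tel_ext, y); next }
    if (y == TEL) { partner[x] <- TEL; tel_ext <- c(tel_ext, x); next }
    partner[x] <- y; partner[y] <- x
  }
  all_markers <- unique(ext_marker(names(partner)))
  seen <- stats::setNames(rep(FALSE, length(all_markers)), all_markers)
  chroms <- list()
  walk_from <- function(e, circular) {
    mk <- character(0); sg <- integer(0)
    start_marker <- ext_marker(e)
    repeat {
      m <- ext_marker(e)
      seen[m] <<- TRUE
      mk <- c(mk, m)
      sg <- c(sg, if (ext_is_tail(e)) 1L else -1L)
      nxt <- partner[[other_end(e)]]
      if (!circular && identical(nxt, TEL)) break
      if (circular && ext_marker(nxt) == start_marker) break
      e <- nxt
    }
    new_chrom(mk, sg, circular)
  }
  for (e in sort(tel_ext, method = "radix")) {
    if (seen[[ext_marker(e)]]) next
    chroms[[length(chroms) + 1L]] <- walk_from(e, circular = FALSE)
  }
  for (m in all_markers) {
    if (seen[[m]]) next
    chroms[[length(chroms) + 1L]] <- walk_from(paste0(m, ".t"), circular = TRUE)
  }
  structure(list(name = name, chromosomes = chroms), class = "dcj_genome")
}

## ---- DCJ moves -----------------------------------------------------------

## All DCJ rewrites of an adjacency set: for two adjacencies {x,y},{z,w} the
## two rejoinings {x,z},{y,w} and {x,w},{y,z}; fission of one adjacency into
## two telomeric ones (the rejoin with a null adjacency); fusions arise from
## pairs of telomeric adjacencies.  Returns a list of
## list(rows, cut = involved row indices).
dcj_moves <- function(rows) {
  r <- nrow(rows)
  out <- list()
  if (r == 0L) return(out)
  for (i in seq_len(r)) {
    x <- rows[i, 1]; y <- rows[i, 2]
    if (x != TEL && y != TEL) {
      nr <- rows
      nr[i, ] <- c(x, TEL)
      nr <- rbind(nr, c(y, TEL))
      out[[length(out) + 1L]] <- list(rows = nr, cut = i)
    }
    if (i == r) next
    for (j in (i + 1L):r) {
      z <- rows[j, 1]; w <- rows[j, 2]
      nr1 <- rows; nr1[i, ] <- c(x, z); nr1[j, ] <- c(y, w)
      nr2 <- rows; nr2[i, ] <- c(x, w); nr2[j, ] <- c(y, z)
      out[[length(out) + 1L]] <- list(rows = nr1, cut = c(i, j))
      out[[length(out) + 1L]] <- list(rows = nr2, cut = c(i, j))
    }
  }
  out
}

drop_null_rows <- function(rows) {
  keep <- !(rows[, 1] == TEL & rows[, 2] == TEL)
  rows[keep, , drop = FALSE]
}

## Distinct genomes one DCJ away (canonical, excluding the state itself).
dcj_neighbors <- function(g) {
  rows <- genome_to_adjset(g)
  key0 <- genome_key(g)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mv in dcj_moves(rows)) {
    g2 <- canonical_form(adjset_to_genome(drop_null_rows(mv$rows), g$name))
    k2 <- genome_key(g2)
    if (k2 == key0 || !is.null(seen[[k2]])) next
    seen[[k2]] <- TRUE
    out[[length(out) + 1L]] <- g2
  }
  out
}

## ---- content-modifying moves --------------------------------------------

## All deletions of one contiguous block (within one chromosome; a whole
## chromosome may go at once).  Each record carries the resulting genome,
## its key, the junction closed by the deletion (sorted flanking-extremity
## pair, or "CHROM" for a whole-chromosome deletion) and the block size m.
## Insertions are the reversals of these records; substitutions pair two
## records closing the same junction of the same intermediate state.
deletion_records <- function(g) {
  recs <- list()
  keyed_junction <- function(f1, f2) paste(sort(c(f1, f2)), collapse = "|")
  for (ci in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[ci]]
    L <- length(ch$markers)
    le <- character(L); re <- character(L)
    for (t in seq_len(L)) {
      e <- marker_ends(ch$markers[t], ch$signs[t])
      le[t] <- e[1]; re[t] <- e[2]
    }
    add <- function(new_ch, junction, m) {
      g2 <- g
      g2$chromosomes[[ci]] <- new_ch
      g2$chromosomes <- g2$chromosomes[!vapply(g2$chromosomes, is.null, logical(1))]
      g2 <- canonical_form(g2)
      recs[[length(recs) + 1L]] <<-
        list(genome = g2, key = genome_key(g2), junction = junction, m = m)
    }
    if (!ch$circular) {
      for (i in seq_len(L)) for (j in i:L) {
        if (i == 1L && j == L) { add(NULL, "CHROM", L); next }
        keep <- setdiff(seq_len(L), i:j)
        f1 <- if (i > 1L) re[i - 1L] else TEL
        f2 <- if (j < L) le[j + 1L] else TEL
        add(new_chrom(ch$markers[keep], ch$signs[keep], FALSE), keyed_junction(f1, f2),
            j - i + 1L)
      }
    } else {
      add(NULL, "CHROM", L)
      if (L > 1L) for (s in seq_len(L)) for (l in seq_len(L - 1L)) {
        block <- ((s - 1L + 0:(l - 1L)) %% L) + 1L
        kept <- ((s - 1L + l + 0:(L - l - 1L)) %% L) + 1L
        f1 <- re[kept[length(kept)]]
        f2 <- le[kept[1L]]
        add(new_chrom(ch$markers[kept], ch$signs[kept], TRUE),
            keyed_junction(f1, f2), l)
      }
    }
  }
  recs
}

## All signed arrangements (order + orientation) of subsets of `pool`, up to
## `cap` markers per block.
block_arrangements <- function(pool, cap = 3L) {
  out <- list()
  n <- length(pool)
  for (s in seq_len(min(cap, n))) {
    subs <- utils::combn(n, s, simplify = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), s)))
    perms <- permutations_of(s)
    for (sub in subs) for (pi in seq_len(nrow(perms))) for (si in seq_len(nrow(signs))) {
      out[[length(out) + 1L]] <-
        list(markers = pool[sub][perms[pi, ]], signs = as.integer(signs[si, ]))
    }
  }
  out
}

insert_into_chromosome <- function(ch, gap, markers, signs) {
  L <- length(ch$markers)
  idx1 <- if (gap >= 1L) seq_len(gap) else integer()
  idx2 <- if (gap < L) (gap + 1L):L else integer()
  new_chrom(c(ch$markers[idx1], markers, ch$markers[idx2]),
            c(ch$signs[idx1], signs, ch$signs[idx2]), ch$circular)
}

## Pure insertions of markers from `pool` (blocks of up to `cap`), as a new
## chromosome (either topology) or into any gap of an existing chromosome.
insertion_records <- function(g, pool, cap = 3L) {
  recs <- list()
  if (length(pool) == 0L) return(recs)
  add <- function(g2, m) {
    g2 <- canonical_form(g2)
    recs[[length(recs) + 1L]] <<- list(genome = g2, key = genome_key(g2), m = m)
  }
  for (arr in block_arrangements(pool, cap)) {
    m <- length(arr$markers)
    for (circ in c(FALSE, TRUE)) {
      g2 <- g
      g2$chromosomes[[length(g2$chromosomes) + 1L]] <-
        new_chrom(arr$markers, arr$signs, circ)
      add(g2, m)
    }
    for (ci in seq_along(g$chromosomes)) {
      ch <- g$chromosomes[[ci]]
      L <- length(ch$markers)
      gaps <- if (ch$circular) seq_len(L) else 0:L
      for (gap in gaps) {
        g2 <- g
        g2$chromosomes[[ci]] <- insert_into_chromosome(ch, gap, arr$markers, arr$signs)
        add(g2, m)
      }
    }
  }
  recs
}

## Substitutions: replace one contiguous (possibly empty) block by another
## (possibly empty) at the same location, in one operation of size
## m = |deleted| + |inserted|; pure indels are the empty-block cases.
substitution_records <- function(g, pool, cap = 3L) {
  recs <- list()
  add <- function(g2, m, del) {
    g2 <- canonical_form(g2)
    recs[[length(recs) + 1L]] <<-
      list(genome = g2, key = genome_key(g2), m = m, del = del)
  }
  arrs <- c(list(list(markers = character(), signs = integer())),
            if (length(pool)) block_arrangements(pool, cap) else list())
  for (arr in arrs) {
    mi <- length(arr$markers)
    ## replacement of a whole chromosome / insertion of a new one
    for (circ in c(FALSE, TRUE)) {
      if (mi == 0L) next
      g2 <- g
      g2$chromosomes[[length(g2$chromosomes) + 1L]] <-
        new_chrom(arr$markers, arr$signs, circ)
      add(g2, mi, character())  # pure insertion (empty deleted block)
      for (ci in seq_along(g$chromosomes)) {
        g3 <- g2
        md <- length(g$chromosomes[[ci]]$markers)
        g3$chromosomes[[ci]] <- NULL
        add(g3, mi + md, g$chromosomes[[ci]]$markers)  # whole chromosome replaced
      }
    }
    for (ci in seq_along(g$chromosomes)) {
      ch <- g$chromosomes[[ci]]
      L <- length(ch$markers)
      if (!ch$circular) {
        ## non-empty deleted blocks
        for (i in seq_len(L)) for (j in i:L) {
          keep <- setdiff(seq_len(L), i:j)
          mk <- c(ch$markers[keep[keep < i]], arr$markers, ch$markers[keep[keep > j]])
          sg <- c(ch$signs[keep[keep < i]], arr$signs, ch$signs[keep[keep > j]])
          g2 <- g
          if (length(mk) == 0L) g2$chromosomes[[ci]] <- NULL
          else g2$chromosomes[[ci]] <- new_chrom(mk, sg, FALSE)
          add(g2, (j - i + 1L) + mi, ch$markers[i:j])
        }
        if (mi > 0L) for (gap in 0:L) {  # empty deleted block = insertion
          g2 <- g
          g2$chromosomes[[ci]] <- insert_into_chromosome(ch, gap, arr$markers, arr$signs)
          add(g2, mi, character())
        }
      } else {
        for (l in seq_len(L)) for (s in seq_len(if (l == L) 1L else L)) {
          kept <- if (l == L) integer() else ((s - 1L + l + 0:(L - l - 1L)) %% L) + 1L
          mk <- c(ch$markers[kept], arr$markers)
          sg <- c(ch$signs[kept], arr$signs)
          g2 <- g
          if (length(mk) == 0L) g2$chromosomes[[ci]] <- NULL
          else g2$chromosomes[[ci]] <- new_chrom(mk, sg, TRUE)
          add(g2, l + mi, ch$markers[setdiff(seq_len(L), kept)])
        }
        if (mi > 0L) for (gap in seq_len(L)) {
          g2 <- g
          g2$chromosomes[[ci]] <- insert_into_chromosome(ch, gap, arr$markers, arr$signs)
          add(g2, mi, character())
        }
      }
    }
  }
  recs
}

## ---- exact weighted sorting distance ------------------------------------

#' Exact sorting distance by uniform-cost search
#'
#' Minimum total weight of an operation sequence transforming `A` into `B`,
#' with DCJs of weight 1 and content-modifying operations of weight
#' `p + k*m`.  States are canonical genomes; insertions are restricted to
#' markers of `B` absent from the current state (an optimal sequence never
#' inserts anything else) and to blocks of at most `cap` markers.
#'
#' @param A,B `dcj_genome` objects whose marker union has at most
#'   `max_markers` distinct markers.
#' @param model `"dcj"`, `"dcj-indel"` or `"dcj-substitution"`.
#' @param p,k weights of the scheme (numeric; keep them dyadic or use the
#'   default grid values for exact arithmetic).
#' @param max_markers search size limit.
#' @param cap maximum markers per inserted block.
#' @param return_path if `TRUE`, also return the recovered optimal operation
#'   list (type and m per step).
#' @return the distance, or `list(distance, ops)` if `return_path`.
#' @export
exact_distance_search <- function(A, B,
                                  model = c("dcj-indel", "dcj-substitution", "dcj"),
                                  p = 1, k = 0, max_markers = 5L, cap = 3L,
                                  return_path = FALSE) {
  model <- match.arg(model)
  universe <- union(genome_markers(A), genome_markers(B))
  if (length(universe) > max_markers)
    stop("search limit exceeded: ", length(universe), " markers > ", max_markers)
  if (model == "dcj" &&
      marker_partition(A, B)$u > 0L)
    stop("pure DCJ model requires equal marker content")
  A <- canonical_form(A); B <- canonical_form(B)
  target_key <- genome_key(B)
  target_markers <- genome_markers(B)

  ## content ops act on unique markers only: a deletion may not remove
  ## markers of the target (no churn of shared content), an insertion only
  ## adds target markers absent from the state
  touches_target <- function(del) length(intersect(del, target_markers)) > 0L
  neighbors <- function(g) {
    out <- list()
    for (nb in dcj_neighbors(g))
      out[[length(out) + 1L]] <- list(genome = nb, w = 1, type = "dcj", m = 0L)
    if (model == "dcj-indel") {
      for (r in deletion_records(g)) {
        if (touches_target(setdiff(genome_markers(g), genome_markers(r$genome)))) next
        out[[length(out) + 1L]] <- list(genome = r$genome, w = p + k * r$m,
                                        type = "deletion", m = r$m)
      }
      pool <- setdiff(target_markers, genome_markers(g))
      for (r in insertion_records(g, pool, cap))
        out[[length(out) + 1L]] <- list(genome = r$genome, w = p + k * r$m,
                                        type = "insertion", m = r$m)
    } else if (model == "dcj-substitution") {
      pool <- setdiff(target_markers, genome_markers(g))
      for (r in substitution_records(g, pool, cap)) {
        if (touches_target(r$del)) next
        out[[length(out) + 1L]] <- list(genome = r$genome, w = p + k * r$m,
                                        type = "substitution", m = r$m)
      }
    }
    out
  }

  dist <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  parent <- new.env(parent = emptyenv())
  done <- new.env(parent = emptyenv())
  k0 <- genome_key(A)
  assign(k0, 0, envir = dist)
  assign(k0, A, envir = store)
  frontier <- stats::setNames(0, k0)
  eps <- 1e-9

  while (length(frontier)) {
    i <- which.min(frontier)
    key <- names(frontier)[i]
    d <- frontier[[i]]
    frontier <- frontier[-i]
    if (!is.null(done[[key]])) next
    done[[key]] <- TRUE
    if (key == target_key) {
      if (!return_path) return(d)
      ops <- list()
      kk <- key
      while (!is.null(parent[[kk]])) {
        st <- parent[[kk]]
        ops <- c(list(st$op), ops)
        kk <- st$from
      }
      return(list(distance = d, ops = ops))
    }
    for (nb in neighbors(store[[key]])) {
      k2 <- genome_key(nb$genome)
      nd <- d + nb$w
      old <- dist[[k2]]
      if (is.null(old) || nd < old - eps) {
        assign(k2, nd, envir = dist)
        assign(k2, nb$genome, envir = store)
        assign(k2, list(from = key, op = list(type = nb$type, m = nb$m, w = nb$w)),
               envir = parent)
        frontier[k2] <- nd
      }
    }
  }
  stop("target unreachable (should not happen)")
}

#' Check the a-posteriori surcharge identity
#'
#' The weighted distance with scheme `(p, k)` must equal the distance with
#' scheme `(p, 0)` plus `k * u(A,B)`: every unique marker is affected by
#' exactly one content-modifying operation in a parsimonious sequence, so
#' the per-marker surcharge can be applied after the fact.
#'
#' @inheritParams exact_distance_search
#' @return logical.
#' @export
posterior_correction_check <- function(A, B, model = "dcj-indel", p = 1, k = 0.5,
                                       max_markers = 5L, cap = 3L) {
  d_k <- exact_distance_search(A, B, model, p = p, k = k,
                               max_markers = max_markers, cap = cap)
  d_0 <- exact_distance_search(A, B, model, p = p, k = 0,
                               max_markers = max_markers, cap = cap)
  u <- marker_partition(A, B)$u
  abs(d_k - (d_0 + k * u)) < 1e-9
}

## ---- in-component optimal-DCJ sorting search ----------------------------

## Map each adjacency-set row of genome `g` (side A) to the component of
## AG(g, B) that contains it: the row's gap lies inside one labeled
## adjacency of the graph.
gap_components <- function(g, ag, side = "A") {
  common <- ag$partition$common
  adj <- genome_to_adjset(g, with_gaps = TRUE)
  comp <- integer(nrow(adj$rows))
  offset <- if (side == "A") 0L else ag$n_vertices_A
  per_chrom_offset <- integer(length(g$chromosomes))
  per_chrom_nvert <- integer(length(g$chromosomes))
  for (ci in seq_along(g$chromosomes)) {
    ch <- g$chromosomes[[ci]]
    kc <- sum(ch$markers %in% common)
    per_chrom_offset[ci] <- offset
    per_chrom_nvert[ci] <- if (kc == 0L) 1L else if (ch$circular) kc else kc + 1L
    offset <- offset + per_chrom_nvert[ci]
  }
  for (r in seq_len(nrow(adj$rows))) {
    ci <- adj$chrom[r]; gap <- adj$gap[r]
    ch <- g$chromosomes[[ci]]
    kc <- sum(ch$markers %in% common)
    local <- if (kc == 0L) 1L else {
      cnt <- if (gap == 0L) 0L else sum(ch$markers[seq_len(gap)] %in% common)
      if (ch$circular) (if (cnt >= 1L) cnt else kc) else cnt + 1L
    }
    comp[r] <- ag$membership[per_chrom_offset[ci] + local]
  }
  comp
}

#' Exhaustive in-component sorting search
#'
#' Explores every way of DCJ-sorting the single non-trivial component of
#' `AG(A, B)` using only optimal DCJs applied within the component (each
#' step increases the cycle count by one or the AB-path count by two).
#' Cuts may fall on either genome and anywhere inside a label, so runs
#' accumulate and merge on both sides as adjacencies are cut and rejoined.
#' Over all terminal states the search reports the minimum total number of
#' remaining runs (each removable by one indel) and the minimum number of
#' substitutions (one per terminal component holding one or two runs).
#'
#' Every component of `AG(A, B)` other than the target must already be
#' sorted (size at most 2) and unlabeled; [make_component_realization()]
#' produces such pairs.
#'
#' @param A,B `dcj_genome` realization of the component.
#' @param max_size largest component size searched.
#' @return `list(dcj_cost, min_runs, min_substitutions)`.
#' @export
component_sorting_search <- function(A, B, max_size = 9L) {
  A <- canonical_form(A); B <- canonical_form(B)
  ag <- adjacency_graph(A, B)
  sizes <- vapply(ag$components, `[[`, integer(1), "size")
  runs <- vapply(ag$components, count_runs, integer(1))
  target <- which(sizes > 2L | runs > 0L)
  if (length(target) > 1L)
    stop("realization must isolate a single non-trivial component")
  if (length(target) == 1L && sizes[target] > max_size)
    stop("component size ", sizes[target], " exceeds limit ", max_size)
  d_total <- dcj_distance(ag)

  terminal_stats <- function(ag_t) {
    lam <- vapply(ag_t$components, count_runs, integer(1))
    c(runs = sum(lam), subs = sum(ceiling(lam / 2)))
  }

  state_key <- function(ga, gb) paste(genome_key(ga), genome_key(gb), sep = " || ")
  level <- list(list(A = A, B = B, ag = ag))
  depth <- 0L
  while (depth < d_total) {
    nxt <- list()
    nxt_keys <- new.env(parent = emptyenv())
    for (st in level) {
      ag_s <- st$ag
      d_s <- dcj_distance(ag_s)
      for (side in c("A", "B")) {
        g <- if (side == "A") st$A else st$B
        comp_of_row <- gap_components(g, ag_s, side)
        adj <- genome_to_adjset(g)
        for (mv in dcj_moves(adj)) {
          if (length(mv$cut) == 2L &&
              comp_of_row[mv$cut[1]] != comp_of_row[mv$cut[2]]) next
          g2 <- canonical_form(adjset_to_genome(drop_null_rows(mv$rows), g$name))
          ga <- if (side == "A") g2 else st$A
          gb <- if (side == "A") st$B else g2
          k2 <- state_key(ga, gb)
          if (!is.null(nxt_keys[[k2]])) next
          ag2 <- adjacency_graph(ga, gb)
          if (dcj_distance(ag2) != d_s - 1L) next  # only optimal DCJs
          nxt_keys[[k2]] <- TRUE
          nxt[[length(nxt) + 1L]] <- list(A = ga, B = gb, ag = ag2)
        }
      }
    }
    if (length(nxt) == 0L) stop("no optimal DCJ available before sorting finished")
    level <- nxt
    depth <- depth + 1L
  }
  stats <- vapply(level, function(st) terminal_stats(st$ag), numeric(2))
  list(dcj_cost = d_total,
       min_runs = as.integer(min(stats["runs", ])),
       min_substitutions = as.integer(min(stats["subs", ])))
}

## ---- exhaustive enumeration and the oracle state graph ------------------

set_partitions <- function(v) {
  if (length(v) == 0L) return(list(list()))
  first <- v[1]
  rest <- set_partitions(v[-1])
  out <- list()
  for (pp in rest) {
    out[[length(out) + 1L]] <- c(list(first), pp)
    for (i in seq_along(pp)) {
      q <- pp
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

## distinct canonical chromosomes over exactly this marker set
chromosome_arrangements <- function(markers) {
  m <- length(markers)
  out <- list(); seen <- character()
  for (arr in marker_arrangements(markers)) {
    for (circ in c(FALSE, TRUE)) {
      ch <- canonical_chromosome(new_chrom(arr$markers, arr$signs, circ))
      key <- paste(c(chromosome_tokens(ch), if (circ) "@" else "$"), collapse = " ")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- ch
    }
  }
  out
}

#' Enumerate all canonical genomes over subsets of a marker set
#'
#' Every genome (including the empty one) whose markers form a subset of
#' `markers`: all set partitions into chromosomes, all signed arrangements,
#' both topologies, deduplicated under canonical form.
#'
#' @param markers character vector (kept small; the count grows fast).
#' @return list of `dcj_genome` objects; names are the canonical keys.
#' @export
enumerate_genomes <- function(markers) {
  if (length(markers) > 4L)
    stop("enumeration limit: at most 4 markers")
  out <- list(empty_genome("g"))
  names(out) <- genome_key(out[[1]])
  subsets <- unlist(lapply(seq_along(markers), function(s)
    utils::combn(markers, s, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    for (pp in set_partitions(S)) {
      blocks <- lapply(pp, chromosome_arrangements)
      idx <- rep(1L, length(blocks))
      repeat {
        chroms <- lapply(seq_along(blocks), function(b) blocks[[b]][[idx[b]]])
        g <- canonical_form(structure(list(name = "g", chromosomes = chroms),
                                      class = "dcj_genome"))
        key <- genome_key(g)
        if (is.null(out[[key]])) out[[key]] <- g
        j <- length(blocks)
        repeat {
          idx[j] <- idx[j] + 1L
          if (idx[j] <= length(blocks[[j]])) break
          idx[j] <- 1L
          j <- j - 1L
          if (j == 0L) break
        }
        if (j == 0L) break
      }
    }
  }
  out
}

#' Precomputed operation graph over all genomes on a marker universe
#'
#' Nodes are all canonical genomes over subsets of `markers`; undirected
#' edges connect genomes one operation apart (DCJ, deletion/insertion and —
#' in the substitution model — block substitutions, found by pairing
#' deletions that close the same junction of the same intermediate).  With
#' `p = 1, k = 0` every edge has weight 1, so breadth-first search gives
#' exact distances; this is what makes exhaustive triple scans feasible.
#'
#' @param markers marker universe (at most 4).
#' @param model `"dcj-indel"` or `"dcj-substitution"`.
#' @return `list(genomes, keys, adj)` with `adj` an adjacency list of node
#'   indices.
#' @export
oracle_state_graph <- function(markers, model = c("dcj-indel", "dcj-substitution")) {
  model <- match.arg(model)
  genomes <- enumerate_genomes(markers)
  keys <- names(genomes)
  idx <- stats::setNames(seq_along(keys), keys)
  mask <- vapply(genomes, function(g)
    sum(2L^(match(genome_markers(g), markers) - 1L)), numeric(1))
  ## per edge: m = affected markers (0 => DCJ) and vm = content mask of the
  ## intermediate state (after the deleted block, before the inserted one),
  ## from which the actual deleted/inserted blocks are recovered
  chunks <- list()  # each: list(i, j, m, v) vectors
  del_src <- integer(0); del_m <- integer(0); del_group <- character(0)
  del_mid <- integer(0)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    nb <- dcj_neighbors(g)
    if (length(nb)) {
      j <- vapply(nb, function(x) idx[[genome_key(x)]], integer(1))
      chunks[[length(chunks) + 1L]] <-
        list(i = rep(i, length(j)), j = j, m = integer(length(j)),
             v = rep(mask[i], length(j)))
    }
    recs <- deletion_records(g)
    if (length(recs)) {
      j <- vapply(recs, function(r) idx[[r$key]], integer(1))
      rm_ <- vapply(recs, `[[`, integer(1), "m")
      chunks[[length(chunks) + 1L]] <-
        list(i = rep(i, length(j)), j = j, m = rm_, v = mask[j])
      if (model == "dcj-substitution") {
        del_src <- c(del_src, rep(i, length(j)))
        del_m <- c(del_m, rm_); del_mid <- c(del_mid, j)
        del_group <- c(del_group,
                       vapply(recs, function(r) paste(r$key, r$junction), character(1)))
      }
    }
  }
  if (model == "dcj-substitution") {
    for (grp in split(seq_along(del_src), factor(del_group))) {
      if (length(grp) < 2L) next
      prs <- utils::combn(grp, 2L)
      a <- del_src[prs[1, ]]; b <- del_src[prs[2, ]]
      sel <- a != b
      if (!any(sel)) next
      chunks[[length(chunks) + 1L]] <-
        list(i = a[sel], j = b[sel],
             m = del_m[prs[1, sel]] + del_m[prs[2, sel]],
             v = mask[del_mid[prs[1, sel]]])
    }
  }
  ei <- unlist(lapply(chunks, `[[`, "i"), use.names = FALSE)
  ej <- unlist(lapply(chunks, `[[`, "j"), use.names = FALSE)
  em <- unlist(lapply(chunks, `[[`, "m"), use.names = FALSE)
  ev <- unlist(lapply(chunks, `[[`, "v"), use.names = FALSE)
  ## symmetrize and drop exact duplicates; distinct (m, vm) variants between
  ## the same pair are all kept — their validity differs by target
  a <- c(ei, ej); b <- c(ej, ei); m <- c(em, em); v <- c(ev, ev)
  keep <- !duplicated(paste(a, b, m, v)) & a != b
  a <- a[keep]; b <- b[keep]; m <- m[keep]; v <- v[keep]
  lev <- factor(a, levels = seq_along(keys))
  list(genomes = genomes, keys = keys, markers = markers, mask = mask,
       adj = split(b, lev), adj_m = split(m, lev), adj_vm = split(v, lev))
}

## Content-modifying operations act on unique markers only: while sorting a
## genome toward a target with marker content T, a deletion may not remove
## markers of T and an insertion may only add markers of T (otherwise
## shared markers could be churned through delete+reinsert, which the
## distance models exclude — and which would collapse every distance to
## "replace everything").  For edge y -> x with intermediate mask vm the
## deleted block is content(y) \ vm and the inserted one content(x) \ vm;
## DCJ edges change no content and are always valid.
edge_valid_towards <- function(graph, from, to, vm, target_mask) {
  del <- bitwAnd(graph$mask[from], bitwNot(vm))
  ins <- bitwAnd(graph$mask[to], bitwNot(vm))
  bitwAnd(del, target_mask) == 0 & bitwAnd(ins, target_mask) == ins
}

## Distances from every state to `target` (all weights equal; p=1, k=0):
## reverse BFS from the target under the content restriction above.
graph_bfs <- function(graph, target) {
  nv <- length(graph$keys)
  tmask <- graph$mask[target]
  dist <- rep(-1L, nv)
  dist[target] <- 0L
  frontier <- target
  d <- 0L
  while (length(frontier)) {
    cand_from <- integer(0)
    for (x in frontier) {
      y <- graph$adj[[x]]; vm <- graph$adj_vm[[x]]
      sel <- dist[y] < 0L
      y <- y[sel]; vm <- vm[sel]
      if (length(y)) cand_from <- c(cand_from, y[edge_valid_towards(graph, y, x, vm, tmask)])
    }
    frontier <- unique(cand_from)
    frontier <- frontier[dist[frontier] < 0L]
    d <- d + 1L
    dist[frontier] <- d
  }
  dist
}

## Weighted variant (weights 1 for DCJ, p + k*m for content ops): reverse
## Dijkstra from the target under the same restriction.
graph_dijkstra <- function(graph, target, p = 1, k = 0) {
  nv <- length(graph$keys)
  tmask <- graph$mask[target]
  dist <- rep(Inf, nv)
  dist[target] <- 0
  done <- logical(nv)
  repeat {
    i <- which.min(ifelse(done, Inf, dist))
    if (length(i) == 0L || !is.finite(dist[i]) || done[i]) break
    done[i] <- TRUE
    y <- graph$adj[[i]]; nm <- graph$adj_m[[i]]; vm <- graph$adj_vm[[i]]
    if (length(y)) {
      ok <- edge_valid_towards(graph, y, i, vm, tmask)
      y <- y[ok]; nm <- nm[ok]
      if (length(y)) {
        w <- ifelse(nm == 0L, 1, p + k * nm)
        nd <- dist[i] + w
        upd <- nd < dist[y]
        dist[y[upd]] <- nd[upd]
      }
    }
    if (all(done | !is.finite(dist))) break
  }
  dist
}

#' Exact pair distance looked up on a precomputed state graph
#'
#' @param graph result of [oracle_state_graph()] whose universe contains
#'   both genomes' markers.
#' @param A,B `dcj_genome` objects.
#' @param p,k weight scheme.
#' @return numeric distance.
#' @export
graph_distance <- function(graph, A, B, p = 1, k = 0) {
  ia <- match(genome_key(A), graph$keys)
  ib <- match(genome_key(B), graph$keys)
  if (is.na(ia) || is.na(ib)) stop("genome outside the graph universe")
  if (p == 1 && k == 0) graph_bfs(graph, ib)[ia]
  else graph_dijkstra(graph, ib, p, k)[ia]
}

## ---- exhaustive triple scan ---------------------------------------------

rename_markers <- function(g, map) {
  g$chromosomes <- lapply(g$chromosomes, function(ch) {
    hit <- ch$markers %in% names(map)
    ch$markers[hit] <- unname(map[ch$markers[hit]])
    ch
  })
  g
}

#' Exhaustive triangle-inequality scan over a tiny marker universe
#'
#' Enumerates every genome triple (A, B, C) where each genome draws from
#' `n_common` shared markers plus `n_unique_each` private ones, audits the
#' corrected distance `m = d + k*u` on each triple, and returns the worst
#' (largest) violation `max pairwise m - sum of the other two`.  A
#' non-positive worst violation certifies the triangle inequality on the
#' whole universe.  With `backend = "oracle"` the pair distances are exact
#' (state-graph BFS at `p = 1, k = 0`); with `"bound"` they are the
#' component-wise bound distances.  All comparisons are exact: `k` is used
#' as a rational number.
#'
#' @param model `"dcj-indel"` or `"dcj-substitution"`.
#' @param k surcharge constant (numeric, interpreted as a rational).
#' @param n_common,n_unique_each universe sizes (defaults 2 and 1).
#' @param backend `"oracle"` or `"bound"`.
#' @param cache optionally, the list returned by a previous scan with the
#'   same universe/model/backend, to reuse the distance matrices.
#' @param graph optionally, a matching [oracle_state_graph()] to reuse.
#' @return list with `worst_violation` (numeric), `worst_triple` (list of
#'   three genomes), `n_triples`, and the reusable `cache`.
#' @export
exhaustive_triple_scan <- function(model = c("dcj-indel", "dcj-substitution"),
                                   k = 1, n_common = 2L, n_unique_each = 1L,
                                   backend = c("oracle", "bound"), cache = NULL,
                                   graph = NULL) {
  model <- match.arg(model)
  backend <- match.arg(backend)
  if (n_common > 2L || n_unique_each > 1L)
    stop("universe too large to enumerate (at most 2 common + 1 unique)")
  gs <- if (n_common > 0L) paste0("g", seq_len(n_common)) else character()
  us <- if (n_unique_each > 0L) paste0("u", seq_len(n_unique_each)) else character()
  vs <- if (n_unique_each > 0L) paste0("v", seq_len(n_unique_each)) else character()

  if (is.null(cache)) {
    X <- enumerate_genomes(c(gs, us))   # template for the first pair member
    Y <- enumerate_genomes(c(gs, vs))   # template for the second
    nx <- length(X); ny <- length(Y)
    mx <- lapply(X, genome_markers); my <- lapply(Y, genome_markers)
    U <- matrix(0L, nx, ny)
    for (i in seq_len(nx)) for (j in seq_len(ny))
      U[i, j] <- length(mx[[i]]) + length(my[[j]]) -
        2L * length(intersect(mx[[i]], my[[j]]))
    D <- matrix(0L, nx, ny)
    if (backend == "oracle") {
      if (is.null(graph)) graph <- oracle_state_graph(c(gs, us, vs), model)
      stopifnot(identical(graph$markers, c(gs, us, vs)))
      gidx <- stats::setNames(seq_along(graph$keys), graph$keys)
      xi <- gidx[names(X)]; yi <- gidx[names(Y)]
      for (j in seq_len(ny)) {  # reverse BFS from each target
        dist <- graph_bfs(graph, yi[[j]])
        D[, j] <- dist[xi]
      }
    } else {
      for (i in seq_len(nx)) for (j in seq_len(ny))
        D[i, j] <- distance_report(X[[i]], Y[[j]], model)$bound_value
    }
    cache <- list(X = X, Y = Y, D = D, U = U)
  }
  D <- cache$D; U <- cache$U
  kr <- as_rational(k)
  MD <- kr$den * D + kr$num * U  # den-scaled corrected distances (exact ints)
  nx <- nrow(D)
  worst <- -Inf; worst_idx <- NULL
  for (ci in seq_len(ncol(D))) {
    mac <- MD[, ci]          # m(A, C) over all A
    mbc <- MD[, ci]          # same template serves the B role
    s <- outer(mac, mbc, "+")
    v <- pmax(MD - s, outer(mac, -mbc, "+") - MD, outer(-mac, mbc, "+") - MD)
    w <- max(v)
    if (w > worst) {
      worst <- w
      ij <- which(v == w, arr.ind = TRUE)[1, ]
      worst_idx <- c(ij[[1]], ij[[2]], ci)
    }
  }
  uA <- if (length(us)) stats::setNames(paste0(us, "a"), us) else character()
  list(worst_violation = worst / kr$den,
       worst_triple = list(A = rename_markers(cache$X[[worst_idx[1]]],
                                              stats::setNames(paste0(us, "a"), us)),
                           B = rename_markers(cache$X[[worst_idx[2]]],
                                              stats::setNames(paste0(us, "b"), us)),
                           C = rename_markers(cache$X[[worst_idx[3]]],
                                              stats::setNames(paste0(us, "c"), us))),
       n_triples = nx^2 * ncol(D),
       cache = cache)
}

#' Triangle check under the shared-content condition
#'
#' When every marker common to `A` and `B` also occurs in `C`, concatenating
#' an optimal sequence sorting A into C with one sorting C into B yields a
#' valid sequence sorting A into B, so the plain (k = 0) distances already
#' satisfy `d(A,B) <= d(A,C) + d(B,C)` for any positive `p`.  Checked here
#' with oracle-exact distances.
#'
#' @param A,B,C tiny genomes (within oracle limits).
#' @param model distance model.
#' @param p weight offset of content-modifying operations.
#' @param max_markers,cap search limits, see [exact_distance_search()].
#' @return logical.
#' @export
shared_content_triangle_check <- function(A, B, C, model = "dcj-indel", p = 1,
                                          max_markers = 6L, cap = 3L) {
  tp <- triple_partition(A, B, C)
  if (length(tp$commonAB) > 0L)
    stop("precondition violated: A and B share markers absent from C: ",
         paste(tp$commonAB, collapse = ", "))
  dAB <- exact_distance_search(A, B, model, p = p, k = 0, max_markers = max_markers, cap = cap)
  dAC <- exact_distance_search(A, C, model, p = p, k = 0, max_markers = max_markers, cap = cap)
  dBC <- exact_distance_search(B, C, model, p = p, k = 0, max_markers = max_markers, cap = cap)
  dAB <= dAC + dBC + 1e-9
}
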