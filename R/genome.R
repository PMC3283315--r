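## Genome model: signed multichromosomal genomes without duplicated markers.
##
## A chromosome is an ordered sequence of signed markers, linear or circular.
## A genome is a named collection of chromosomes; the empty genome (zero
## chromosomes) is legal and first-class.  Marker names are arbitrary
## alphanumeric tokens; a "-" prefix denotes reverse orientation.

## fast internal constructor: no validation (hot path of the oracles)
new_chrom <- function(markers, signs, circular) {
  structure(list(markers = markers, signs = signs, circular = circular),
            class = "dcj_chromosome")
}

#' Create a chromosome
#'
#' @param markers character vector of marker names (no sign prefix).
#' @param signs integer vector of +1/-1, recycled if length 1.
#' @param circular logical; `TRUE` for a circular chromosome.
#' @return an object of class `dcj_chromosome`.
#' @export
chromosome <- function(markers, signs = 1L, circular = FALSE) {
  markers <- as.character(markers)
  if (length(signs) == 1L) signs <- rep(as.integer(signs), length(markers))
  stopifnot(length(signs) == length(markers), all(signs %in% c(-1L, 1L)),
            length(markers) >= 1L)
  structure(list(markers = markers, signs = as.integer(signs),
                 circular = isTRUE(circular)),
            class = "dcj_chromosome")
}

#' Create a genome from chromosome strings
#'
#' Convenience constructor mirroring the text dialect: each chromosome is a
#' whitespace-separated string of signed marker tokens terminated by `"$"`
#' (linear) or `"@"` (circular), e.g. `genome("A", "a -b $", "c @")`.
#'
#' @param name genome identifier.
#' @param ... chromosome strings (or `dcj_chromosome` objects).
#' @return an object of class `dcj_genome`.
#' @export
genome <- function(name, ...) {
  parts <- list(...)
  chroms <- lapply(parts, function(p) {
    if (inherits(p, "dcj_chromosome")) return(p)
    toks <- strsplit(trimws(p), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    term <- toks[length(toks)]
    if (!term %in% c("$", "@"))
      stop("chromosome string must end in '$' or '@': ", p)
    tokens_to_chromosome(toks[-length(toks)], circular = term == "@")
  })
  g <- structure(list(name = as.character(name), chromosomes = chroms),
                 class = "dcj_genome")
  validate_genome(g)
  g
}

#' The empty genome
#' @param name genome identifier.
#' @return a `dcj_genome` with zero chromosomes.
#' @export
empty_genome <- function(name = "empty") {
  structure(list(name = as.character(name), chromosomes = list()),
            class = "dcj_genome")
}

tokens_to_chromosome <- function(tokens, circular) {
  if (length(tokens) == 0L)
    stop("a chromosome must contain at least one marker")
  rev_or <- startsWith(tokens, "-")
  names_ <- ifelse(rev_or, substring(tokens, 2L), tokens)
  if (any(!nzchar(names_))) stop("empty marker token")
  chromosome(names_, ifelse(rev_or, -1L, 1L), circular = circular)
}

chromosome_tokens <- function(ch) {
  ifelse(ch$signs < 0L, paste0("-", ch$markers), ch$markers)
}

#' Validate a genome
#'
#' Checks the no-duplicated-markers invariant by a full scan.
#'
#' @param g a `dcj_genome`.
#' @return `g`, invisibly; errors naming the offending marker otherwise.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "dcj_genome"))
  m <- genome_markers(g)
  if (anyDuplicated(m)) {
    dup <- unique(m[duplicated(m)])
    stop("duplicated marker(s) in genome '", g$name, "': ",
         paste(dup, collapse = ", "))
  }
  invisible(g)
}

#' Marker names occurring in a genome
#' @param g a `dcj_genome`.
#' @return character vector of marker names (unsigned).
#' @export
genome_markers <- function(g) {
  unlist(lapply(g$chromosomes, `[[`, "markers"), use.names = FALSE) %||% character()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

n_chromosomes <- function(g) length(g$chromosomes)

#' Parse genomes from text in the GRIMM-like dialect
#'
#' Dialect: a header line `>name` starts a genome; each subsequent non-empty
#' line is one chromosome, whitespace-separated signed marker tokens
#' terminated by `$` (linear) or `@` (circular); lines starting with `#` are
#' comments.  Multiple genomes per file are allowed.
#'
#' @param text a single string or character vector of lines.
#' @return named list of `dcj_genome` objects.
#' @export
parse_genomes <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  flush <- function() {
    if (!is.null(cur_name)) {
      g <- structure(list(name = cur_name, chromosomes = cur_chroms),
                     class = "dcj_genome")
      validate_genome(g)
      genomes[[cur_name]] <<- g
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      flush()
      cur_name <- trimws(substring(line, 2L))
      if (!nzchar(cur_name)) stop("empty genome name at line ", i)
      cur_chroms <- list()
    } else {
      if (is.null(cur_name)) stop("chromosome before any '>' header at line ", i)
      toks <- strsplit(line, "[[:space:]]+")[[1]]
      term <- toks[length(toks)]
      if (!term %in% c("$", "@"))
        stop("missing '$' or '@' terminator at line ", i)
      cur_chroms[[length(cur_chroms) + 1L]] <-
        tokens_to_chromosome(toks[-length(toks)], circular = term == "@")
    }
  }
  flush()
  genomes
}

#' Read genomes from a file
#' @param path file in the dialect of [parse_genomes()].
#' @return named list of `dcj_genome`.
#' @export
read_genomes <- function(path) parse_genomes(readLines(path))

#' Serialize genomes to text
#'
#' Round-trip property: `parse_genomes(write_genomes(g))` is canonically
#' equal to `g`.
#'
#' @param genomes a `dcj_genome` or list of them.
#' @param file optional path; if given, text is written there.
#' @return the text, invisibly if `file` is given.
#' @export
write_genomes <- function(genomes, file = NULL) {
  if (inherits(genomes, "dcj_genome")) genomes <- list(genomes)
  out <- unlist(lapply(genomes, function(g) {
    c(paste0(">", g$name),
      vapply(g$chromosomes, function(ch) {
        paste(c(chromosome_tokens(ch), if (ch$circular) "@" else "$"),
              collapse = " ")
      }, character(1)))
  }), use.names = FALSE)
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(text))
  }
  text
}

#' @export
print.dcj_genome <- function(x, ...) {
  cat(write_genomes(x))
  invisible(x)
}

## Reverse a chromosome and flip all orientations (reading the other strand).
revflip_chromosome <- function(ch) {
  new_chrom(rev(ch$markers), -rev(ch$signs), ch$circular)
}

rotate_chromosome <- function(ch, r) {
  if (r == 0L) return(ch)
  idx <- c((r + 1L):length(ch$markers), 1L:r)
  new_chrom(ch$markers[idx], ch$signs[idx], ch$circular)
}

## comparison key sorting marker name before orientation, so that the
## all-forward reading "a b" beats its reflection "-b -a"
chromosome_cmp_key <- function(ch) {
  paste(ch$markers, ifelse(ch$signs < 0L, "-", "+"), collapse = " ")
}

canonical_chromosome <- function(ch) {
  L <- length(ch$markers)
  mk <- ch$markers; sg <- ifelse(ch$signs < 0L, "-", "+")
  rmk <- rev(mk); rsg <- rev(ifelse(ch$signs < 0L, "+", "-"))
  if (!ch$circular) {
    k1 <- paste(mk, sg, collapse = " ")
    k2 <- paste(rmk, rsg, collapse = " ")
    if (order_radix(c(k1, k2))[1L] == 1L) return(ch)
    return(new_chrom(rev(ch$markers), -rev(ch$signs), FALSE))
  }
  best_key <- NULL; best <- NULL
  for (r in 0:(L - 1L)) {
    idx <- if (r == 0L) seq_len(L) else c((r + 1L):L, 1L:r)
    k1 <- paste(mk[idx], sg[idx], collapse = " ")
    if (is.null(best_key) || order_radix(c(best_key, k1))[1L] == 2L) {
      best_key <- k1; best <- list(ch$markers[idx], ch$signs[idx])
    }
    k2 <- paste(rmk[idx], rsg[idx], collapse = " ")
    if (order_radix(c(best_key, k2))[1L] == 2L) {
      best_key <- k2
      best <- list(rev(ch$markers)[idx], -rev(ch$signs)[idx])
    }
  }
  new_chrom(best[[1]], best[[2]], TRUE)
}

## locale-independent ordering
order_radix <- function(x) order(x, method = "radix")

#' Canonical form of a genome
#'
#' Circular chromosomes are rotated/reflected to their lexicographically
#' minimal representative (a circular DNA molecule has no distinguished
#' start or strand), linear chromosomes reflected to the smaller of the two
#' readings, and chromosomes sorted.  Idempotent; used for round-trip
#' equality and as the state key of the search oracles.
#'
#' @param g a `dcj_genome`.
#' @return a canonically equal `dcj_genome`.
#' @export
canonical_form <- function(g) {
  chroms <- lapply(g$chromosomes, canonical_chromosome)
  keys <- vapply(chroms, function(ch)
    paste(c(chromosome_tokens(ch), if (ch$circular) "@" else "$"), collapse = " "),
    character(1))
  g$chromosomes <- chroms[order_radix(keys)]
  g
}

## Canonical serialization, independent of the genome name: the state key.
genome_key <- function(g) {
  if (length(g$chromosomes) == 0L) return("(empty)")
  g <- canonical_form(g)
  keys <- vapply(g$chromosomes, function(ch)
    paste(c(chromosome_tokens(ch), if (ch$circular) "@" else "$"), collapse = " "),
    character(1))
  paste(keys, collapse = " / ")
}

#' Canonical genome equality
#' @param a,b `dcj_genome` objects.
#' @return logical; `TRUE` iff the genomes are equal up to chromosome order,
#'   circular rotation and strand reflection.
#' @export
genomes_equal <- function(a, b) genome_key(a) == genome_key(b)

#' Marker partition of two genomes
#'
#' Splits the marker universe of a pair into the common set and the two
#' private ("unique") sets; `u` is the total number of unique markers, the
#' quantity surcharged by the metric correction.
#'
#' @param A,B `dcj_genome` objects.
#' @return list with `common`, `onlyA`, `onlyB` (character vectors) and
#'   integer `u = |onlyA| + |onlyB|`.
#' @export
marker_partition <- function(A, B) {
  ma <- genome_markers(A); mb <- genome_markers(B)
  common <- intersect(ma, mb)
  onlyA <- setdiff(ma, common)
  onlyB <- setdiff(mb, common)
  list(common = common, onlyA = onlyA, onlyB = onlyB,
       u = length(onlyA) + length(onlyB))
}

#' Seven-set marker partition of three genomes
#'
#' The disjoint sets of markers private to each genome, shared by exactly
#' one pair, or shared by all three.  Satisfies
#' `u(A,B) = |onlyA| + |commonAC| + |onlyB| + |commonBC|` (and symmetric
#' identities), which ties the pairwise corrections of a triple together.
#'
#' @param A,B,C `dcj_genome` objects.
#' @return list of seven character vectors: `onlyA`, `onlyB`, `onlyC`,
#'   `commonAB`, `commonBC`, `commonAC`, `commonABC`.
#' @export
triple_partition <- function(A, B, C) {
  ma <- genome_markers(A); mb <- genome_markers(B); mc <- genome_markers(C)
  abc <- intersect(intersect(ma, mb), mc)
  list(onlyA = setdiff(ma, union(mb, mc)),
       onlyB = setdiff(mb, union(ma, mc)),
       onlyC = setdiff(mc, union(ma, mb)),
       commonAB = setdiff(intersect(ma, mb), abc),
       commonBC = setdiff(intersect(mb, mc), abc),
       commonAC = setdiff(intersect(ma, mc), abc),
       commonABC = abc)
}

## Remove a set of markers from a genome, joining the flanks (used by the
## reduced triangle check, which discards C-only markers).
drop_markers <- function(g, markers) {
  chroms <- list()
  for (ch in g$chromosomes) {
    keep <- !(ch$markers %in% markers)
    if (!any(keep)) next
    chroms[[length(chroms) + 1L]] <-
      new_chrom(ch$markers[keep], ch$signs[keep], ch$circular)
  }
  g$chromosomes <- chroms
  g
}
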