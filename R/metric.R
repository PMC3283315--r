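## Weight framework and a-posteriori metric correction.
##
## Organizational operations (DCJs) weigh 1; a content-modifying operation
## affecting m markers weighs p + k*m.  For p = 1 the weighted distance
## equals the plain model distance plus k*u(A,B), so the surcharge can be
## applied after the fact: m(A,B) = d(A,B) + k*u(A,B).  The audits below
## test on which triples this corrected value satisfies the triangle
## inequality, and recover the smallest k that repairs it on a family.
## All violation tests are exact: k is carried as a rational number and
## comparisons are made on denominator-scaled integers.

#' Represent a numeric as a rational number
#'
#' Smallest denominator up to `max_den` reproducing `x` to within 1e-9.
#' Used so that triangle-violation tests are exact integer comparisons.
#'
#' @param x numeric scalar.
#' @param max_den largest denominator tried.
#' @return `list(num, den)`.
#' @export
as_rational <- function(x, max_den = 10000L) {
  for (den in seq_len(max_den)) {
    num <- round(x * den)
    if (abs(x * den - num) < 1e-9 * den) return(list(num = num, den = den))
  }
  stop("cannot represent ", x, " as a rational with denominator <= ", max_den)
}

#' Weight scheme of the hybrid model
#'
#' @param p positive weight offset of content-modifying operations.
#' @param k non-negative per-marker surcharge.
#' @return object of class `dcj_weight_scheme`.
#' @export
weight_scheme <- function(p = 1, k = 0) {
  stopifnot(p > 0, k >= 0)
  kr <- as_rational(k)
  structure(list(p = p, k = k, k_num = kr$num, k_den = kr$den),
            class = "dcj_weight_scheme")
}

#' A-posteriori corrected distance
#'
#' `m(A,B) = d(A,B) + k * u(A,B)` where `d` is the model distance of the
#' report and `u` the number of unique markers of the pair.  `p` enters only
#' through the underlying distance (for `p = 1` that is the plain distance).
#'
#' @param report a `dcj_distance_report`.
#' @param scheme a `dcj_weight_scheme` (or numeric `k`).
#' @return numeric corrected value.
#' @export
corrected_distance <- function(report, scheme) {
  k <- if (inherits(scheme, "dcj_weight_scheme")) scheme$k else scheme
  report$bound_value + k * report$u
}

pair_distance <- function(A, B, model, backend, max_markers = 6L) {
  if (backend == "bound") distance_report(A, B, model)$bound_value
  else exact_distance_search(A, B, model, p = 1, k = 0, max_markers = max_markers)
}

#' Audit the triangle inequality on one genome triple
#'
#' Computes the three corrected values `m = d + k*u`, orders them so the
#' largest is on the left, and reports
#' `violation = max(m) - (sum of the other two)`; the triangle inequality
#' holds iff `violation <= 0`.  Also reports the reduced quantity
#' `d(A,B) - d(A,C') - d(B,C') - 2k*|G_AB|`, where `C'` is `C` with its
#' private markers removed and `G_AB` the markers common to exactly A and
#' B — an equivalent sign test derived from the seven-set partition.
#'
#' @param A,B,C `dcj_genome` objects.
#' @param model `"dcj-indel"` or `"dcj-substitution"`.
#' @param scheme a `dcj_weight_scheme` or numeric `k`.
#' @param backend `"bound"` (component-wise bound distances) or `"oracle"`
#'   (exact search; tiny genomes only).
#' @return object of class `dcj_triple_audit`.
#' @export
audit_triple <- function(A, B, C, model = "dcj-indel", scheme = weight_scheme(k = 1),
                         backend = c("bound", "oracle")) {
  backend <- match.arg(backend)
  if (!inherits(scheme, "dcj_weight_scheme")) scheme <- weight_scheme(k = scheme)
  d <- c(AB = pair_distance(A, B, model, backend),
         AC = pair_distance(A, C, model, backend),
         BC = pair_distance(B, C, model, backend))
  u <- c(AB = marker_partition(A, B)$u,
         AC = marker_partition(A, C)$u,
         BC = marker_partition(B, C)$u)
  num <- scheme$k_num; den <- scheme$k_den
  m_scaled <- den * d + num * u
  viol_scaled <- 2 * max(m_scaled) - sum(m_scaled)

  tp <- triple_partition(A, B, C)
  Cp <- drop_markers(C, tp$onlyC)
  red_scaled <- den * (d[["AB"]] -
                         pair_distance(A, Cp, model, backend) -
                         pair_distance(B, Cp, model, backend)) -
    2 * num * length(tp$commonAB)

  structure(list(model = model, k = scheme$k, backend = backend,
                 d = d, u = u, m = (den * d + num * u) / den,
                 violation = viol_scaled / den,
                 violation_scaled = viol_scaled,
                 reduced_check = red_scaled / den,
                 holds = viol_scaled <= 0),
            class = "dcj_triple_audit")
}

#' @export
print.dcj_triple_audit <- function(x, ...) {
  cat(sprintf("triple audit (%s, k=%g, %s): m = %s; violation = %g (%s)\n",
              x$model, x$k, x$backend,
              paste(sprintf("%s=%g", names(x$m), x$m), collapse = ", "),
              x$violation, if (x$holds) "holds" else "DISRUPTED"))
  invisible(x)
}

#' Smallest surcharge k restoring the triangle inequality on a family
#'
#' Grid search over `k = 0, step, 2*step, ..., k_max`: for each triple the
#' three pair distances and unique-marker counts are computed once; a grid
#' value passes when no triple has a positive violation.  Monotonicity (if
#' the inequality holds at k it holds at any larger k) is verified along
#' the way: the set of passing grid values must be upward closed.
#'
#' @param triples list of triples `list(A, B, C)` (family members from
#'   [make_tightness_family()] are accepted directly).
#' @param model `"dcj-indel"` or `"dcj-substitution"`.
#' @param step grid spacing (rational; default 0.01).
#' @param k_max largest k tried.
#' @param backend `"bound"` or `"oracle"`.
#' @return smallest passing k (numeric); error if none passes.
#' @export
min_k_grid <- function(triples, model = "dcj-indel", step = 0.01, k_max = 2,
                       backend = "bound") {
  stopifnot(length(triples) >= 1L, step > 0)
  sr <- as_rational(step)
  n_steps <- floor(k_max / step + 1e-9)
  dmat <- vapply(triples, function(tr) {
    c(pair_distance(tr$A, tr$B, model, backend),
      pair_distance(tr$A, tr$C, model, backend),
      pair_distance(tr$B, tr$C, model, backend))
  }, numeric(3))
  umat <- vapply(triples, function(tr) {
    c(marker_partition(tr$A, tr$B)$u,
      marker_partition(tr$A, tr$C)$u,
      marker_partition(tr$B, tr$C)$u)
  }, numeric(3))
  pass <- logical(n_steps + 1L)
  for (i in 0:n_steps) {
    ## k = i * step = (i * num) / den, exact on den-scaled integers
    m <- sr$den * dmat + i * sr$num * umat
    viol <- 2 * apply(m, 2L, max) - colSums(m)
    pass[i + 1L] <- all(viol <= 0)
  }
  if (!all(pass == cummax(pass)))  # upward closure must hold
    stop("monotonicity violated: passing grid values are not upward closed")
  if (!any(pass)) stop("no k <= ", k_max, " restores the triangle inequality")
  (which(pass)[1L] - 1L) * step
}
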