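#' Four-gamete compatibility of two sites
#'
#' Two sites are incompatible under an infinite-sites, no-recombination model
#' iff all four joint carrier configurations (0,0), (0,1), (1,0) and (1,1)
#' occur among the samples.
#'
#' @param col_a,col_b Carrier vectors (0/1) of equal length.
#' @return `TRUE` if the pair passes the four-gamete test.
#' @examples
#' four_gamete_compatible(c(0, 0, 1, 1), c(0, 1, 0, 1))
#' @export
four_gamete_compatible <- function(col_a, col_b) {
  stopifnot(length(col_a) == length(col_b))
  a <- col_a >= 1; b <- col_b >= 1
  !(any(a & b) && any(a & !b) && any(!a & b) && any(!a & !b))
}

# All-pairs compatibility matrix via cross products of the carrier matrix.
compatibility_matrix <- function(carriers) {
  a <- (carriers >= 1) * 1
  n11 <- crossprod(a)
  cs <- colSums(a)
  n10 <- outer(cs, cs, function(x, y) x) - n11  # carrier in a, not in b
  n01 <- t(n10)
  n00 <- nrow(a) - n11 - n10 - n01
  !(n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0)
}

# Is [lo, hi] (1-based, inclusive) fully pairwise compatible?
interval_ok <- function(cm, lo, hi) all(cm[lo:hi, lo:hi])

new_interval_set <- function(start, end, provenance) {
  tibble(start = as.integer(start), end = as.integer(end),
         provenance = provenance)
}

#' Greedy scans for maximal compatible intervals
#'
#' `scan_left_right()` extends an interval from its left anchor until the
#' first site incompatible with any site already included, emits it and
#' restarts; `scan_right_left()` is the mirror scan. Both return the same
#' number of intervals K. Compatibility within an interval is pairwise-all.
#'
#' @param carriers Carrier matrix (samples by sites), typically the case half.
#' @param cm Optional precomputed compatibility matrix.
#' @return Interval tibble (`start`, `end` 0-based half-open, `provenance`).
#' @export
scan_left_right <- function(carriers, cm = NULL) {
  cm <- cm %||% compatibility_matrix(carriers)
  m <- ncol(cm)
  starts <- ends <- integer(0)
  lo <- 1L
  while (lo <= m) {
    hi <- lo
    while (hi < m && all(cm[hi + 1L, lo:hi])) hi <- hi + 1L
    starts <- c(starts, lo - 1L); ends <- c(ends, hi)
    lo <- hi + 1L
  }
  new_interval_set(starts, ends, "lr")
}

#' @rdname scan_left_right
#' @export
scan_right_left <- function(carriers, cm = NULL) {
  cm <- cm %||% compatibility_matrix(carriers)
  m <- ncol(cm)
  starts <- ends <- integer(0)
  hi <- m
  while (hi >= 1L) {
    lo <- hi
    while (lo > 1L && all(cm[lo - 1L, lo:hi])) lo <- lo - 1L
    starts <- c(lo - 1L, starts); ends <- c(hi, ends)
    hi <- lo - 1L
  }
  new_interval_set(starts, ends, "rl")
}

#' Merge same-index scan intervals into cores
#'
#' Pairs the i-th left-to-right interval with the i-th right-to-left interval
#' and keeps the intersection ("core"); empty intersections are dropped. Both
#' scans of the same matrix always produce the same count K, so a length
#' mismatch signals inconsistent inputs.
#'
#' @param i_lr,i_rl Interval tibbles from the two scans.
#' @return Core interval tibble (provenance `"core"`).
#' @export
merge_cores <- function(i_lr, i_rl) {
  if (nrow(i_lr) == 0 || nrow(i_rl) == 0) abort("Empty interval set.")
  if (nrow(i_lr) != nrow(i_rl))
    abort("Scan interval counts differ; scans are inconsistent.")
  start <- pmax(i_lr$start, i_rl$start)
  end <- pmin(i_lr$end, i_rl$end)
  keep <- start < end
  new_interval_set(start[keep], end[keep], "core")
}

# Maximal compatible intervals containing the (1-based, inclusive) core
# [clo, chi]: for each feasible left end, extend right as far as possible,
# keeping only non-dominated intervals.
maximal_intervals_containing <- function(cm, clo, chi) {
  m <- ncol(cm)
  out <- list()
  best_hi <- -1L
  lo <- clo
  while (lo >= 1L && interval_ok(cm, lo, chi)) {
    hi <- chi
    while (hi < m && all(cm[hi + 1L, lo:hi])) hi <- hi + 1L
    if (hi > best_hi) {  # not dominated by a wider interval already found
      out[[length(out) + 1L]] <- c(lo, hi)
      best_hi <- hi
    }
    lo <- lo - 1L
  }
  do.call(rbind, rev(out))
}

#' Candidate enumeration and maximal cover by dynamic programming
#'
#' Enumerates, for each core, the maximal pairwise-compatible intervals that
#' contain it, then selects a disjoint chain of candidates maximising the
#' total number of covered sites by weighted-interval-scheduling dynamic
#' programming. Sites left uncovered are appended as singleton intervals so
#' the result is a partition of the site axis.
#'
#' @param carriers Carrier matrix (samples by sites).
#' @param cores Core tibble from [merge_cores()].
#' @param cm Optional precomputed compatibility matrix.
#' @return Final partition tibble (provenance `"final"`), sorted, disjoint,
#'   covering all sites, each interval four-gamete compatible.
#' @export
uber_scan_and_cover <- function(carriers, cores, cm = NULL) {
  cm <- cm %||% compatibility_matrix(carriers)
  m <- ncol(cm)
  if (nrow(cores) == 0)
    return(new_interval_set(seq_len(m) - 1L, seq_len(m), "final"))
  cand <- unique(do.call(rbind, purrr::map(seq_len(nrow(cores)), function(i) {
    maximal_intervals_containing(cm, cores$start[i] + 1L, cores$end[i])
  })))
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  n <- nrow(cand)
  # DP over candidates sorted by right end: best coverage using first i.
  best <- numeric(n + 1L)
  take <- logical(n)
  prev <- integer(n)
  for (i in seq_len(n)) {
    # latest candidate ending at or before this one's start
    p <- 0L
    for (j in seq_len(i - 1L)) if (cand[j, 2] <= cand[i, 1] - 1L) p <- j
    prev[i] <- p
    w <- cand[i, 2] - cand[i, 1] + 1L
    if (best[p + 1L] + w > best[i]) {
      best[i + 1L] <- best[p + 1L] + w
      take[i] <- TRUE
    } else {
      best[i + 1L] <- best[i]
      take[i] <- FALSE
    }
  }
  chosen <- integer(0)
  i <- n
  while (i >= 1L) {
    if (take[i]) { chosen <- c(i, chosen); i <- prev[i] } else i <- i - 1L
  }
  sel <- cand[chosen, , drop = FALSE]
  covered <- logical(m)
  for (j in seq_len(nrow(sel))) covered[sel[j, 1]:sel[j, 2]] <- TRUE
  singles <- which(!covered)
  out <- rbind(
    if (nrow(sel)) cbind(sel[, 1] - 1L, sel[, 2]),
    if (length(singles)) cbind(singles - 1L, singles))
  out <- out[order(out[, 1]), , drop = FALSE]
  new_interval_set(out[, 1], out[, 2], "final")
}

#' Partition the site axis into four-gamete-compatible intervals
#'
#' The full maximal-cover pipeline: left-to-right and right-to-left greedy
#' scans, same-index core extraction, candidate enumeration around each core,
#' and a dynamic-programming cover. Interactions and region structure are only
#' modelled within the resulting intervals. The scan uses the case half of the
#' cohort by default.
#'
#' @param ds A `rare_dataset` or a carrier matrix.
#' @param cases_only Use only case samples (default) or the whole cohort.
#' @return Final interval tibble (`start`, `end` 0-based half-open).
#' @examples
#' ds <- generate_dataset(sim_config(n_cases = 100, n_controls = 100,
#'                                   n_sites = 20, n_causal = 5), seed = 2)
#' find_compatible_intervals(ds)
#' @export
find_compatible_intervals <- function(ds, cases_only = TRUE) {
  carriers <- if (inherits(ds, "rare_dataset")) {
    cm0 <- carrier_matrix(ds)
    if (cases_only) cm0[ds$labels == "case", , drop = FALSE] else cm0
  } else (ds >= 1) * 1
  if (ncol(carriers) == 1L) return(new_interval_set(0L, 1L, "final"))
  cm <- compatibility_matrix(carriers)
  i_lr <- scan_left_right(carriers, cm)
  i_rl <- scan_right_left(carriers, cm)
  cores <- merge_cores(i_lr, i_rl)
  uber_scan_and_cover(carriers, cores, cm)
}
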