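# Net-charge spectra and hypergeometric enrichment with FDR control.
#
# A "fragment" is one fixed-frame window. For a charge value j, the urn model
# is: m = reference fragments at charge j, n = reference fragments at any
# other charge, k = fragments drawn into the tested group, x = group
# fragments observed at charge j. Enrichment is the right tail P[X >= x].

#' Net-charge frequency spectrum of a set of windows
#'
#' @param windows Tibble of charge windows with a `q` column (e.g. the output
#'   of [scan_fixed()] rows bound over a group).
#' @param group Optional group label stored on the result.
#' @return Tibble with columns `group`, `j` (charge value), `count`,
#'   `frequency` (count / total windows in the group).
#' @export
build_spectrum <- function(windows, group = NA_character_) {
  if (nrow(windows) == 0L) stop("no windows to build a spectrum from",
                                call. = FALSE)
  dplyr::mutate(
    dplyr::summarise(dplyr::group_by(windows, j = .data$q),
                     count = dplyr::n(), .groups = "drop"),
    frequency = .data$count / sum(.data$count),
    group = group, .before = 1)
}

#' Right-tailed hypergeometric probability
#'
#' P\[X >= x\] for X hypergeometric with `m` marked and `n` unmarked balls
#' and `k` draws without replacement, computed as `1 - CDF(x - 1)` in a
#' numerically stable way (log-space tail summation via [stats::phyper()]).
#'
#' @param x Observed count (the tail includes `x` itself).
#' @param m Marked balls in the urn.
#' @param n Unmarked balls in the urn.
#' @param k Number of draws.
#' @return Probability in (0, 1].
#' @examples
#' hypergeom_right_tail(3, 5, 5, 4) # 55/210
#' @export
hypergeom_right_tail <- function(x, m, n, k) {
  stopifnot(length(x) == 1L, x >= 0, m >= 0, n >= 0, k >= 0)
  if (k > m + n) stop("k exceeds the urn size m + n", call. = FALSE)
  if (x > k || x > m) stop("x exceeds min(m, k): impossible observation",
                           call. = FALSE)
  if (x == 0) return(1)
  stats::phyper(x - 1, m, n, k, lower.tail = FALSE)
}

#' Expected fragment count under the urn model
#'
#' @inheritParams hypergeom_right_tail
#' @return `m * k / (m + n)`.
#' @export
expected_count <- function(m, n, k) {
  if (any(m + n == 0)) stop("empty urn: m + n must be positive",
                            call. = FALSE)
  m * k / (m + n)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] that enforces the domain p in
#' (0, 1] and preserves input order.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted q-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric enrichment table of a group against a reference
#'
#' One right-sided test per charge value present in either set. The group may
#' be a subset of the reference (it is not removed from it). Depletion is
#' visible as `fold < 1` but carries no left-tail p-value.
#'
#' @param group_windows,reference_windows Tibbles with a `q` column.
#' @param significance FDR level used for the `significant` flag
#'   (default 0.05).
#' @return Tibble with one row per charge value `j`: `x`, `m`, `n`, `k`,
#'   `expected`, `fold`, `p`, `q`, `significant`.
#' @export
enrichment_table <- function(group_windows, reference_windows,
                             significance = 0.05) {
  if (nrow(group_windows) == 0L || nrow(reference_windows) == 0L) {
    stop("group and reference must both be non-empty", call. = FALSE)
  }
  ref_counts <- table(reference_windows$q)
  grp_counts <- table(group_windows$q)
  js <- sort(unique(c(as.integer(names(ref_counts)),
                      as.integer(names(grp_counts)))))
  total_ref <- nrow(reference_windows)
  k <- nrow(group_windows)
  rows <- purrr::map(js, function(j) {
    m <- if (as.character(j) %in% names(ref_counts))
      as.integer(ref_counts[[as.character(j)]]) else 0L
    x <- if (as.character(j) %in% names(grp_counts))
      as.integer(grp_counts[[as.character(j)]]) else 0L
    n <- total_ref - m
    if (x > m) {
      # group not contained in the reference at this charge: no urn model
      stop("group has ", x, " fragments at charge ", j,
           " but the reference only has ", m,
           "; the group must be drawn from the reference", call. = FALSE)
    }
    expected <- expected_count(m, n, k)
    tibble::tibble(
      j = j, x = x, m = m, n = n, k = k, expected = expected,
      fold = if (expected > 0) x / expected else NA_real_,
      p = hypergeom_right_tail(x, m, n, k))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- fdr_adjust(out$p)
  out$significant <- out$q < significance
  out
}
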