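# Fixed- and variable-frame net-charge scanning.
#
# Charge scheme: K, R = +1; D, E = -1; every other residue (including H and
# the ambiguity codes B, Z, X, U, O) = 0. Terminal amine/carboxyl charges are
# not counted. Positions are 1-based and windows include both ends.

#' Accepted amino-acid alphabet
#'
#' The 20 canonical residues plus the ambiguity/rare codes B, Z, X, U, O.
#' A terminal stop mark `*` is stripped at parse time and is not part of the
#' alphabet.
#'
#' @return Character vector of accepted single-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
    "R", "S", "T", "V", "W", "Y", "B", "Z", "X", "U", "O")
}

# residue -> charge lookup, built once
.charge_map <- local({
  m <- integer(0)
  m[c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
      "R", "S", "T", "V", "W", "Y", "B", "Z", "X", "U", "O")] <- 0L
  m[c("K", "R")] <- 1L
  m[c("D", "E")] <- -1L
  m
})

#' Net charge of single residues
#'
#' @param residue Character vector of single-letter amino-acid codes
#'   (uppercase, see [aa_alphabet()]).
#' @return Integer vector in \{-1, 0, +1\}: K and R are +1, D and E are -1,
#'   everything else 0. Histidine is treated as neutral.
#' @examples
#' residue_charge(c("R", "E", "H"))
#' @export
residue_charge <- function(residue) {
  out <- unname(.charge_map[residue])
  if (anyNA(out)) {
    bad <- unique(residue[is.na(out)])
    stop("residue(s) outside the accepted alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

# charge vector of a whole sequence string
.charge_vector <- function(sequence) {
  residue_charge(strsplit(sequence, "", fixed = TRUE)[[1]])
}

#' Net charge of one window
#'
#' @param sequence Amino-acid string.
#' @param start 1-based index of the first residue of the window.
#' @param length Window length in residues.
#' @return Integer net charge of the window.
#' @examples
#' window_net_charge("KKDDE", 3, 3) # DDE -> -3
#' @export
window_net_charge <- function(sequence, start, length) {
  L <- nchar(sequence)
  if (start < 1 || length < 1 || start + length - 1 > L) {
    stop("window [", start, ", ", start + length - 1,
         "] out of range for sequence of length ", L, call. = FALSE)
  }
  sum(.charge_vector(substr(sequence, start, start + length - 1)))
}

#' Fixed-frame charge scan
#'
#' Slides a frame of fixed length along the sequence and reports the net
#' charge of every window (positions 1..L-frame+1), computed as a rolling
#' update in one pass.
#'
#' @param sequence Amino-acid string.
#' @param frame Window length in residues (default 30).
#' @return A tibble with columns `start`, `length`, `q`, `qc` (= q/length),
#'   one row per window. If the sequence is shorter than the frame the tibble
#'   has zero rows and carries attribute `truncated = TRUE`.
#' @examples
#' scan_fixed("KKDDE", frame = 3)
#' @export
scan_fixed <- function(sequence, frame = 30L) {
  frame <- as.integer(frame)
  stopifnot(frame >= 1L)
  L <- nchar(sequence)
  if (L < frame) {
    out <- tibble::tibble(start = integer(), length = integer(),
                          q = integer(), qc = double())
    attr(out, "truncated") <- TRUE
    return(out)
  }
  ch <- .charge_vector(sequence)
  # rolling update via cumulative sums: q_i = cs[i+f-1] - cs[i-1]
  cs <- cumsum(ch)
  q <- cs[frame:L] - c(0L, cs)[seq_len(L - frame + 1L)]
  out <- tibble::tibble(start = seq_len(L - frame + 1L),
                        length = frame, q = as.integer(q), qc = q / frame)
  attr(out, "truncated") <- FALSE
  out
}

#' Most positively charged fixed-frame window
#'
#' Keeps the earliest window of maximal charge: a stored window is replaced
#' only when a later one has a strictly higher charge. Sequences shorter than
#' the frame are scored as a single whole-sequence window and flagged
#' truncated.
#'
#' @inheritParams scan_fixed
#' @return One-row tibble: `start`, `length`, `q`, `qc`, `truncated`.
#' @examples
#' max_fixed_window("KRAAKR", frame = 2) # tie broken to start 1
#' @export
max_fixed_window <- function(sequence, frame = 30L) {
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence", call. = FALSE)
  if (L < frame) {
    q <- sum(.charge_vector(sequence))
    return(tibble::tibble(start = 1L, length = L, q = as.integer(q),
                          qc = q / L, truncated = TRUE))
  }
  w <- scan_fixed(sequence, frame)
  i <- which.max(w$q) # first maximum = earliest window
  tibble::tibble(start = w$start[i], length = w$length[i], q = w$q[i],
                 qc = w$qc[i], truncated = FALSE)
}

#' Variable-frame search for the most positively charged domain
#'
#' Starts from the best window at `min_frame` (accepted unconditionally),
#' then grows the frame one residue at a time up to the sequence length. At
#' each size the best window of that size replaces the stored domain only if
#' its charge is strictly higher and an acceptance gate passes:
#'
#' * `mode = "fixed-threshold"` (default): the candidate's charge
#'   concentration must satisfy `qc >= qc_threshold`.
#' * `mode = "monotone-ratio"`: the candidate's `qc` must exceed the stored
#'   domain's own `qc`.
#'
#' The gate suppresses long stretches that dilute the charge (low Qc).
#'
#' @inheritParams scan_fixed
#' @param min_frame Smallest frame size searched (default 10).
#' @param qc_threshold Charge-concentration gate for the default mode
#'   (default 0.23).
#' @param mode Replacement rule, see above.
#' @return One-row tibble: `start`, `length`, `q`, `qc`, `truncated`.
#' @examples
#' variable_frame_search(strrep("R", 30))
#' @export
variable_frame_search <- function(sequence, min_frame = 10L,
                                  qc_threshold = 0.23,
                                  mode = c("fixed-threshold",
                                           "monotone-ratio")) {
  mode <- match.arg(mode)
  min_frame <- as.integer(min_frame)
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence", call. = FALSE)
  if (L < min_frame) {
    q <- sum(.charge_vector(sequence))
    return(tibble::tibble(start = 1L, length = L, q = as.integer(q),
                          qc = q / L, truncated = TRUE))
  }
  ch <- .charge_vector(sequence)
  cs <- c(0L, cumsum(ch))
  best <- NULL
  for (f in min_frame:L) {
    q <- cs[(f + 1L):(L + 1L)] - cs[seq_len(L - f + 1L)]
    i <- which.max(q)
    cand <- list(start = i, length = f, q = q[i], qc = q[i] / f)
    if (is.null(best)) {
      best <- cand # min_frame winner accepted unconditionally
    } else {
      gate <- if (mode == "fixed-threshold") cand$qc >= qc_threshold
              else cand$qc > best$qc
      if (cand$q > best$q && gate) best <- cand
    }
  }
  tibble::tibble(start = as.integer(best$start),
                 length = as.integer(best$length),
                 q = as.integer(best$q), qc = best$qc, truncated = FALSE)
}

#' Per-protein table of maximal charged domains
#'
#' Applies [max_fixed_window()] or [variable_frame_search()] to every record
#' and binds the results into one table, preserving input order.
#'
#' @param records Tibble of protein records with columns `id` and `sequence`
#'   (as returned by [read_fasta()] or [gen_proteome()]).
#' @param frame Frame size (fixed mode) or minimum frame size (variable
#'   mode).
#' @param mode `"fixed"` or `"variable"`.
#' @param qc_threshold Passed to [variable_frame_search()] in variable mode.
#' @return Tibble with columns `id`, `q_max`, `start`, `length`, `qc`,
#'   `truncated`.
#' @export
qmax_table <- function(records, frame = 30L,
                       mode = c("fixed", "variable"), qc_threshold = 0.23) {
  mode <- match.arg(mode)
  stopifnot(nrow(records) > 0L)
  rows <- purrr::map2(records$id, records$sequence, function(id, seq) {
    res <- tryCatch(
      if (mode == "fixed") max_fixed_window(seq, frame)
      else variable_frame_search(seq, min_frame = frame,
                                 qc_threshold = qc_threshold),
      error = function(e) stop("record '", id, "': ", conditionMessage(e),
                               call. = FALSE))
    tibble::tibble(id = id, q_max = res$q, start = res$start,
                   length = res$length, qc = res$qc,
                   truncated = res$truncated)
  })
  dplyr::bind_rows(rows)
}
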