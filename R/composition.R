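# Arginine/lysine composition of charged windows, positional distribution
# along the normalized protein, amino-acid enrichment of selected segments,
# and the threshold census.

# per-window R and K counts for every fixed-frame window of a set of records
#' All fixed-frame windows of a record set, with R/K counts
#'
#' Expands every record into its fixed-frame charge windows and counts
#' arginines and lysines inside each window. Records shorter than the frame
#' contribute no windows (they are excluded from fragment statistics).
#'
#' @param records Tibble with `id`, `sequence` and any annotation columns
#'   (`group`, `family`, ...), which are carried through.
#' @param frame Window length (default 30).
#' @return Tibble with one row per window: annotations, `id`, `start`,
#'   `length`, `q`, `qc`, `r`, `k`, `protein_length`.
#' @export
window_table <- function(records, frame = 30L) {
  stopifnot(nrow(records) > 0L)
  carry <- intersect(c("group", "functional_class", "family"),
                     names(records))
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    seq <- records$sequence[i]
    w <- scan_fixed(seq, frame)
    if (nrow(w) == 0L) return(NULL)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    isr <- cumsum(c(0L, ch == "R"))
    isk <- cumsum(c(0L, ch == "K"))
    w$r <- as.integer(isr[w$start + w$length] - isr[w$start])
    w$k <- as.integer(isk[w$start + w$length] - isk[w$start])
    w$id <- records$id[i]
    w$protein_length <- nchar(seq)
    for (col in carry) w[[col]] <- records[[col]][i]
    w
  })
  dplyr::bind_rows(rows)
}

#' Arginine/lysine ratio per net-charge value
#'
#' For each charge value j, pools the arginine and lysine counts of all
#' windows at that charge and reports the ratio J_j = sum(R) / sum(K) and its
#' log2 (for heatmap display). With no lysines and at least one arginine the
#' ratio is `Inf`; an optional pseudo-count mode uses (R+1)/(K+1) instead.
#'
#' @param windows Tibble with columns `q`, `r`, `k` (see [window_table()]).
#' @param min_charge Smallest charge value reported (default 0: positive
#'   spectrum only).
#' @param pseudo_count Use (R+1)/(K+1) instead of the literal ratio
#'   (default `FALSE`).
#' @return Tibble: `j`, `r_total`, `k_total`, `ratio`, `log2_ratio`.
#' @export
rk_ratio_by_charge <- function(windows, min_charge = 0L,
                               pseudo_count = FALSE) {
  tab <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(windows, .data$q >= min_charge),
                    j = .data$q),
    r_total = sum(.data$r), k_total = sum(.data$k), .groups = "drop")
  dplyr::mutate(
    tab,
    ratio = if (pseudo_count) (.data$r_total + 1) / (.data$k_total + 1)
            else ifelse(.data$k_total > 0, .data$r_total / .data$k_total,
                        ifelse(.data$r_total > 0, Inf, NaN)),
    log2_ratio = log2(.data$ratio))
}

#' Positional distribution of highly charged windows
#'
#' Maps every window with `q >= q_threshold` to a bin of width 0.01 over the
#' normalized protein length, anchored at the window start:
#' bin = floor(100 * (start - 1) / (L - frame + 1)), clamped to 99. Per-group
#' frequencies are normalized by the group's qualifying-window count; groups
#' with no qualifying window keep an all-zero row, flagged.
#'
#' @param windows Tibble from [window_table()] with a grouping column.
#' @param by Name of the grouping column (default `"family"`).
#' @param q_threshold Minimum window charge (default +7).
#' @return Tibble: grouping column, `bin` (0..99), `frequency`, `n_windows`
#'   (qualifying windows in the group).
#' @export
positional_heatmap <- function(windows, by = "family", q_threshold = 7L) {
  stopifnot(by %in% names(windows))
  groups <- unique(windows[[by]])
  qual <- dplyr::filter(windows, .data$q >= q_threshold)
  if (nrow(qual) > 0L) {
    n_pos <- qual$protein_length - qual$length + 1L
    qual$bin <- pmin(floor(100 * (qual$start - 1) / n_pos), 99)
  }
  rows <- purrr::map(groups, function(g) {
    sub <- qual[qual[[by]] == g, , drop = FALSE]
    counts <- integer(100)
    if (nrow(sub) > 0L) {
      tb <- table(sub$bin)
      counts[as.integer(names(tb)) + 1L] <- as.integer(tb)
    }
    out <- tibble::tibble(bin = 0:99,
                          frequency = if (nrow(sub) > 0L)
                            counts / sum(counts) else 0,
                          n_windows = nrow(sub))
    out[[by]] <- g
    out[, c(by, "bin", "frequency", "n_windows")]
  })
  dplyr::bind_rows(rows)
}

#' Amino-acid enrichment of selected segments over a background
#'
#' @param selected_segments Character vector of segment sequences (e.g. the
#'   maximal charged windows of a protein group).
#' @param background_frequencies Named 20-vector of background amino-acid
#'   frequencies summing to 1 (names = canonical residues).
#' @return Tibble: `aa`, `selected_frequency`, `background_frequency`,
#'   `fold` (selected/background; `NA` where the background is 0).
#' @export
aa_enrichment <- function(selected_segments, background_frequencies) {
  if (length(selected_segments) == 0L) stop("empty selection",
                                            call. = FALSE)
  stopifnot(abs(sum(background_frequencies) - 1) < 1e-8)
  aas <- names(background_frequencies)
  res <- unlist(strsplit(selected_segments, "", fixed = TRUE))
  counts <- table(factor(res, levels = aas))
  sel <- as.numeric(counts) / length(res)
  bg <- as.numeric(background_frequencies)
  tibble::tibble(
    aa = aas, selected_frequency = sel,
    background_frequency = bg,
    fold = ifelse(bg > 0, sel / bg, NA_real_))
}

#' Census of proteins with highly charged, R- or K-biased segments
#'
#' A protein passes when at least one fixed-frame window satisfies both
#' `q >= q_threshold` and the chosen composition ratio (computed within that
#' same window) `>= ratio_threshold`. A window with zero counts in the
#' denominator residue and a positive numerator counts as an infinite ratio
#' and passes.
#'
#' @param records Tibble with `id`, `sequence` (+ optional annotations).
#' @param frame Window length (default 30).
#' @param q_threshold Minimum window charge (+7 or +14 in the reference
#'   analysis).
#' @param ratio_threshold Minimum within-window ratio (default 4).
#' @param mode `"R/K"` (arginine over lysine) or `"K/R"`.
#' @return Tibble: `id`, annotations, `passes`, and for passing proteins the
#'   best qualifying window (`start`, `length`, `q`, `r`, `k`; highest q
#'   among qualifying windows, earliest on ties).
#' @export
census_filter <- function(records, frame = 30L, q_threshold = 7L,
                          ratio_threshold = 4, mode = c("R/K", "K/R")) {
  mode <- match.arg(mode)
  stopifnot(nrow(records) > 0L)
  w <- window_table(records, frame)
  if (nrow(w) > 0L) {
    num <- if (mode == "R/K") w$r else w$k
    den <- if (mode == "R/K") w$k else w$r
    w$pass <- w$q >= q_threshold &
      (den > 0 & num / den >= ratio_threshold | den == 0 & num > 0)
  }
  carry <- intersect(c("group", "functional_class", "family"),
                     names(records))
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    sub <- w[w$id == records$id[i] & w$pass, , drop = FALSE]
    passes <- nrow(sub) > 0L
    best <- if (passes) sub[order(-sub$q, sub$start)[1L], ] else NULL
    out <- tibble::tibble(
      id = records$id[i], passes = passes,
      start = if (passes) best$start else NA_integer_,
      length = if (passes) best$length else NA_integer_,
      q = if (passes) best$q else NA_integer_,
      r = if (passes) best$r else NA_integer_,
      k = if (passes) best$k else NA_integer_)
    for (col in carry) out[[col]] <- records[[col]][i]
    out
  })
  dplyr::bind_rows(rows)
}
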