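# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's vectorized code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len, charged_bias = 0.3) {
  # mix of charged and neutral residues so window charges vary
  probs <- rep((1 - charged_bias) / 16, 20)
  probs[aa20 %in% c("K", "R", "D", "E")] <- charged_bias / 4
  paste(sample(aa20, len, replace = TRUE, prob = probs), collapse = "")
}

charge_of <- function(ch) {
  if (ch %in% c("K", "R")) 1L else if (ch %in% c("D", "E")) -1L else 0L
}

# naive per-window summation (no rolling update, no cumsum)
naive_scan <- function(sequence, frame) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  if (L < frame) return(integer(0))
  vapply(seq_len(L - frame + 1L), function(s) {
    total <- 0L
    for (i in s:(s + frame - 1L)) total <- total + charge_of(res[i])
    total
  }, integer(1))
}

# brute force over every substring of length >= min_frame, applying the
# replacement rule literally: sizes ascending, starts ascending; the
# min_frame best is seeded unconditionally, afterwards replacement needs a
# strictly higher charge plus the acceptance gate
brute_variable_search <- function(sequence, min_frame, qc_threshold,
                                  mode = "fixed-threshold") {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  best <- NULL
  for (f in min_frame:L) {
    frame_best <- NULL
    for (s in seq_len(L - f + 1L)) {
      q <- 0L
      for (i in s:(s + f - 1L)) q <- q + charge_of(res[i])
      if (is.null(frame_best) || q > frame_best$q) {
        frame_best <- list(start = s, length = f, q = q, qc = q / f)
      }
    }
    if (f == min_frame) {
      best <- frame_best
    } else {
      gate <- if (mode == "fixed-threshold") frame_best$qc >= qc_threshold
              else frame_best$qc > best$qc
      if (frame_best$q > best$q && gate) best <- frame_best
    }
  }
  best
}

# exhaustive hypergeometric right tail by enumerating all C(m+n, k) draws
enum_hypergeom_right_tail <- function(x, m, n, k) {
  balls <- c(rep(1L, m), rep(0L, n))
  draws <- utils::combn(m + n, k)
  hits <- apply(draws, 2, function(idx) sum(balls[idx]) >= x)
  mean(hits)
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

write_temp_table <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
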