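# Total capsid charge vs genome charge: robust straight-line fit with
# FDR-based outlier detection (ROUT-style), Pearson correlation on inliers,
# and the capsid/genome charge ratio.
#
# The robust fit minimises the Lorentzian (Cauchy) loss by iteratively
# reweighted least squares; the residual scale is the RSDR (68.27th
# percentile of |residuals| with an N/(N-2) degrees-of-freedom correction).
# Points whose RSDR-scaled residual t-ratios survive a Benjamini-Hochberg
# step at rate Q are flagged as outliers; slope/intercept and Pearson r are
# then recomputed on the inliers by ordinary least squares.

#' Total capsid charge of one particle
#'
#' Sum over capsid protein species of (copies per particle x that species'
#' maximal window charge). Deviations from strict icosahedral symmetry are
#' carried by the actual copy numbers.
#'
#' @param components Tibble with columns `protein`, `copies` and `q_max`
#'   (one row per capsid protein species).
#' @return Integer total charge.
#' @examples
#' total_qmax(tibble::tibble(protein = c("L1", "L2"),
#'                           copies = c(360L, 72L), q_max = c(10, 20)))
#' @export
total_qmax <- function(components) {
  stopifnot(nrow(components) > 0L)
  if (!("q_max" %in% names(components)) || anyNA(components$q_max)) {
    bad <- if ("q_max" %in% names(components))
      components$protein[is.na(components$q_max)] else components$protein
    stop("missing q_max for component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sum(components$copies * components$q_max)
}

#' Genome charge magnitude
#'
#' One negative charge per nucleotide residue; reported as a positive
#' magnitude. For multipartite genomes only the longest segment counts. A
#' double-stranded genome carries residues on both strands, so each bp
#' contributes two charges unless `single_strand_count = TRUE`.
#'
#' @param genome_segments Integer vector of segment lengths (nt for
#'   single-stranded genomes, bp for double-stranded).
#' @param genome_type One of `"ssDNA"`, `"dsDNA"`, `"+ssRNA"`, `"dsRNA"`.
#' @param single_strand_count Count only one strand of a double-stranded
#'   genome (default `FALSE`).
#' @return Integer charge magnitude.
#' @export
genome_charge <- function(genome_segments, genome_type,
                          single_strand_count = FALSE) {
  stopifnot(genome_type %in% c("ssDNA", "dsDNA", "+ssRNA", "dsRNA"))
  if (length(genome_segments) == 0L || any(genome_segments < 1)) {
    stop("genome segments must all have length >= 1", call. = FALSE)
  }
  longest <- max(genome_segments)
  double <- genome_type %in% c("dsDNA", "dsRNA") && !single_strand_count
  as.integer(longest * (if (double) 2L else 1L))
}

# BH step-up rejection at level q: TRUE = rejected (outlier)
.bh_reject <- function(p, q) {
  n <- length(p)
  o <- order(p)
  thresh <- q * seq_len(n) / n
  ok <- which(p[o] <= thresh)
  rej <- logical(n)
  if (length(ok) > 0L) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

.rsdr <- function(residuals, n_param = 2L) {
  n <- length(residuals)
  unname(stats::quantile(abs(residuals), 0.6827, type = 7) *
           sqrt(n / (n - n_param)))
}

#' Robust straight-line fit with FDR-based outlier detection
#'
#' Fits `y ~ x` by iteratively reweighted least squares under the Lorentzian
#' loss (weights 1 / (1 + (r/s)^2), scale s = RSDR, re-estimated each
#' iteration), starting from ordinary least squares, until the relative
#' parameter change falls below `tol`. Residual t-ratios |r|/RSDR are
#' converted to two-tailed p-values on N-2 degrees of freedom and screened
#' by a Benjamini-Hochberg step at rate `q_fdr`; flagged points are outliers.
#' Slope, intercept, and the Pearson correlation are then recomputed on the
#' inliers by ordinary least squares.
#'
#' @param x,y Numeric vectors (x = genome charge, y = total capsid charge in
#'   the balance analysis).
#' @param q_fdr Maximum desired FDR among flagged outliers (default 0.05,
#'   i.e. "ROUT 5\%").
#' @param tol Convergence tolerance on the relative parameter change.
#' @param max_iter Iteration cap.
#' @return Object of class `rout_fit`: a list with `slope`, `intercept`
#'   (inlier OLS), `robust_slope`, `robust_intercept` (IRLS), `rsdr`,
#'   `outlier` (logical per point), `n`, `n_inlier`, `pearson_r`, `p_value`,
#'   `charge_ratio` (= 1/slope), and the per-point tibble `points`.
#' @export
rout_fit <- function(x, y, q_fdr = 0.05, tol = 1e-8, max_iter = 100L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5L) stop("need at least 5 points for outlier-aware fitting",
                   call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit0 <- stats::lm.fit(cbind(1, x), y)
  beta <- fit0$coefficients
  for (i in seq_len(max_iter)) {
    r <- y - beta[1] - beta[2] * x
    s <- .rsdr(r)
    if (s == 0) break # perfect fit
    w <- 1 / (1 + (r / s)^2)
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    delta <- max(abs(fit$coefficients - beta) /
                   pmax(abs(beta), .Machine$double.eps))
    beta <- fit$coefficients
    if (delta < tol) break
  }
  r <- y - beta[1] - beta[2] * x
  s <- .rsdr(r)
  if (s > 0) {
    t_ratio <- abs(r) / s
    p <- 2 * stats::pt(t_ratio, df = n - 2L, lower.tail = FALSE)
    outlier <- .bh_reject(p, q_fdr)
  } else {
    t_ratio <- rep(0, n)
    p <- rep(1, n)
    outlier <- rep(FALSE, n)
  }
  xi <- x[!outlier]
  yi <- y[!outlier]
  ols <- stats::lm.fit(cbind(1, xi), yi)
  slope <- unname(ols$coefficients[2])
  intercept <- unname(ols$coefficients[1])
  if (stats::var(yi) > 0 && stats::var(xi) > 0) {
    ct <- stats::cor.test(xi, yi)
    pearson_r <- unname(ct$estimate)
    p_value <- ct$p.value
  } else {
    pearson_r <- 0
    p_value <- 1
  }
  structure(list(
    slope = slope, intercept = intercept,
    robust_slope = unname(beta[2]), robust_intercept = unname(beta[1]),
    rsdr = s, outlier = outlier, n = n, n_inlier = sum(!outlier),
    pearson_r = pearson_r, p_value = p_value,
    charge_ratio = 1 / slope,
    points = tibble::tibble(x = x, y = y, residual = r, t_ratio = t_ratio,
                            p = p, outlier = outlier)),
    class = "rout_fit")
}

#' Pearson correlation with a two-tailed p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return Named list with `r` and `p` (t-transform, n - 2 df, two-tailed).
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Capsid-genome charge balance analysis
#'
#' Joins a capsid stoichiometry table with per-component maximal window
#' charges, computes the total capsid charge and genome charge per virus,
#' optionally drops motor-packaged phages, and fits the balance line with
#' [rout_fit()].
#'
#' @param entries Capsid table from [read_capsid_table()] or
#'   [gen_capsid_dataset()]. Component `q_max` values must either be present
#'   in the `components` list column or be supplied via `records`.
#' @param records Optional protein records tibble; when given, each
#'   component's `q_max` is computed from its sequence (matched by component
#'   protein id) with [max_fixed_window()].
#' @param frame Frame size for `q_max` computation (default 30).
#' @param exclude_motor_packaged Drop viruses with `motor_packaged = TRUE`
#'   before fitting (default `TRUE`, mirroring the exclusion of
#'   motor-driven phage clusters from the balance fit).
#' @param q_fdr Outlier FDR rate (default 0.05).
#' @param single_strand_count Passed to [genome_charge()].
#' @return List with `fit` (a `rout_fit`) and `points`, a per-virus tibble
#'   (virus, family, genome_type, t_number, host_class, motor_packaged,
#'   capsid_charge, genome_charge, residual, t_ratio, outlier; excluded
#'   motor-packaged viruses appear with `excluded = TRUE` and no flags).
#' @export
balance_report <- function(entries, records = NULL, frame = 30L,
                           exclude_motor_packaged = TRUE, q_fdr = 0.05,
                           single_strand_count = FALSE) {
  stopifnot(nrow(entries) > 0L)
  qmap <- NULL
  if (!is.null(records)) {
    qt <- qmax_table(records, frame = frame, mode = "fixed")
    qmap <- stats::setNames(qt$q_max, qt$id)
  }
  cap <- vapply(seq_len(nrow(entries)), function(i) {
    comp <- entries$components[[i]]
    if (!is.null(qmap)) {
      miss <- setdiff(comp$protein, names(qmap))
      if (length(miss) > 0L) {
        stop("virus '", entries$virus[i], "': no sequence for component(s) ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      comp$q_max <- unname(qmap[comp$protein])
    }
    total_qmax(comp)
  }, numeric(1))
  gen <- vapply(seq_len(nrow(entries)), function(i) {
    as.numeric(genome_charge(entries$genome_segments[[i]],
                             entries$genome_type[i],
                             single_strand_count = single_strand_count))
  }, numeric(1))
  pts <- tibble::tibble(
    virus = entries$virus, family = entries$family,
    genome_type = entries$genome_type, t_number = entries$t_number,
    host_class = entries$host_class,
    motor_packaged = entries$motor_packaged,
    capsid_charge = cap, genome_charge = gen)
  pts$excluded <- exclude_motor_packaged & pts$motor_packaged
  used <- !pts$excluded
  fit <- rout_fit(pts$genome_charge[used], pts$capsid_charge[used],
                  q_fdr = q_fdr)
  pts$residual <- NA_real_
  pts$t_ratio <- NA_real_
  pts$outlier <- NA
  pts$residual[used] <- fit$points$residual
  pts$t_ratio[used] <- fit$points$t_ratio
  pts$outlier[used] <- fit$points$outlier
  # second reading of the inlier correlation: drop every FAMILY that
  # contains at least one flagged outlier, not just the flagged viruses
  out_families <- unique(pts$family[used][fit$points$outlier])
  fam_in <- used & !(pts$family %in% out_families)
  pearson_family_excluded <-
    if (sum(fam_in) >= 3L &&
        stats::var(pts$genome_charge[fam_in]) > 0 &&
        stats::var(pts$capsid_charge[fam_in]) > 0) {
      pearson_with_p(pts$genome_charge[fam_in], pts$capsid_charge[fam_in])
    } else list(r = NA_real_, p = NA_real_)
  list(fit = fit, points = pts,
       pearson_family_excluded = pearson_family_excluded)
}
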