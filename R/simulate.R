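# Seeded synthetic-data generators: proteomes with implanted positively
# charged domains, capsid datasets with a known charge-balance relation and
# planted outliers, and spiked window multisets for the enrichment tests.
#
# Every generator draws from its own substream derived from one global seed
# and a stream name, so adding a generator never shifts another's stream.

# deterministic 32-bit-safe substream seed from (seed, stream name)
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

.neutral_pad <- c("A", "G", "S", "T", "P")

#' Generate a synthetic proteome with implanted charged domains
#'
#' Background residues are drawn i.i.d. from `background_frequencies`; a
#' chosen fraction of proteins receives an implanted positively charged
#' domain of net charge `implant_q`, length `implant_length`, and an R:K mix
#' `rho` (the implant holds `round(rho / (1 + rho) * implant_q)` arginines,
#' the remaining positives as lysines, padded to length with neutral
#' residues from A, G, S, T, P). The truth table records what was implanted
#' where.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer vector `c(min, max)`; lengths are uniform on
#'   this range.
#' @param background_frequencies Named 20-vector summing to 1 (default
#'   uniform over the canonical residues).
#' @param implant_fraction Fraction of proteins receiving a domain.
#' @param implant_q Net charge of the implanted domain (positive).
#' @param implant_length Domain length (must not exceed the minimum protein
#'   length).
#' @param rho R:K mix of the implant (ratio of arginines to lysines among
#'   the positive residues; `Inf` = all R).
#' @param position One of `"N-terminal"`, `"C-terminal"`, `"uniform"`.
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @return List with `records` (tibble: id, sequence, group,
#'   functional_class, family) and `truth` (tibble: id, implanted,
#'   implant_start, implant_q, implant_length, rho).
#' @export
gen_proteome <- function(n_proteins = 100L,
                         length_range = c(100L, 500L),
                         background_frequencies = NULL,
                         implant_fraction = 0,
                         implant_q = 17L, implant_length = 30L,
                         rho = 4, position = c("N-terminal", "C-terminal",
                                               "uniform"),
                         seed = 1L) {
  position <- match.arg(position)
  canonical <- setdiff(aa_alphabet(), c("B", "Z", "X", "U", "O"))
  if (is.null(background_frequencies)) {
    background_frequencies <- stats::setNames(rep(1 / 20, 20), canonical)
  }
  stopifnot(abs(sum(background_frequencies) - 1) < 1e-8,
            implant_fraction >= 0, implant_fraction <= 1)
  if (implant_fraction > 0) {
    if (abs(implant_q) > implant_length) {
      stop("infeasible implant: |implant_q| exceeds implant_length",
           call. = FALSE)
    }
    if (implant_length > length_range[1]) {
      stop("implant_length exceeds the minimum protein length",
           call. = FALSE)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "proteome"))
  lens <- sample(length_range[1]:length_range[2], n_proteins,
                 replace = TRUE)
  implanted <- stats::runif(n_proteins) < implant_fraction
  n_r <- if (is.infinite(rho)) implant_q
         else round(rho / (1 + rho) * implant_q)
  n_k <- implant_q - n_r
  seqs <- character(n_proteins)
  starts <- rep(NA_integer_, n_proteins)
  for (i in seq_len(n_proteins)) {
    s <- sample(names(background_frequencies), lens[i], replace = TRUE,
                prob = background_frequencies)
    if (implanted[i]) {
      dom <- sample(c(rep("R", n_r), rep("K", n_k),
                      sample(.neutral_pad, implant_length - implant_q,
                             replace = TRUE)))
      st <- switch(position,
                   "N-terminal" = 1L,
                   "C-terminal" = lens[i] - implant_length + 1L,
                   "uniform" = sample.int(lens[i] - implant_length + 1L, 1L))
      s[st:(st + implant_length - 1L)] <- dom
      starts[i] <- st
    }
    seqs[i] <- paste(s, collapse = "")
  }
  ids <- sprintf("SYN%05d", seq_len(n_proteins))
  list(
    records = tibble::tibble(id = ids, sequence = seqs,
                             group = "Synthetic",
                             functional_class = NA_character_,
                             family = NA_character_),
    truth = tibble::tibble(id = ids, implanted = implanted,
                           implant_start = starts,
                           implant_q = ifelse(implanted, implant_q, NA),
                           implant_length = ifelse(implanted,
                                                   implant_length, NA),
                           rho = ifelse(implanted, rho, NA)))
}

#' Generate a synthetic capsid dataset with a known charge balance
#'
#' Genome lengths are uniform on `genome_range`; the capsid charge follows
#' `capsid = beta * genome * (1 + eps)` with `eps ~ Normal(0, sigma)`,
#' rounded to an integer. `n_outliers` viruses are displaced from the line
#' by `displacement * sigma * beta * genome` (alternating sign). Subunit
#' copy numbers are drawn from `subunit_choices` and the per-subunit q_max
#' back-derived (remainder absorbed in the stored capsid charge). The truth
#' table marks the planted outliers.
#'
#' @param n_viruses Number of viruses.
#' @param beta Generating capsid/genome charge ratio (slope of capsid on
#'   genome).
#' @param sigma Relative noise level.
#' @param genome_range Genome length range in nt.
#' @param n_outliers Number of planted outliers.
#' @param displacement Outlier displacement in multiples of the local noise
#'   SD.
#' @param subunit_choices Candidate subunit copy numbers.
#' @param seed Integer seed.
#' @return List with `entries` (capsid table as from [read_capsid_table()],
#'   with per-component `q_max` filled) and `truth` (tibble: virus,
#'   genome_length, true_capsid_charge, planted_outlier).
#' @export
gen_capsid_dataset <- function(n_viruses = 50L, beta = 1 / 1.4,
                               sigma = 0.02,
                               genome_range = c(1000L, 12000L),
                               n_outliers = 0L, displacement = 10,
                               subunit_choices = c(60L, 120L, 180L, 240L),
                               seed = 1L) {
  stopifnot(beta > 0, sigma >= 0, n_outliers >= 0,
            n_outliers <= n_viruses)
  if (n_outliers > 0L && (sigma == 0 || displacement <= 0)) {
    stop("planted outliers need sigma > 0 and displacement > 0",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "capsid"))
  g <- sample(genome_range[1]:genome_range[2], n_viruses, replace = TRUE)
  eps <- stats::rnorm(n_viruses, 0, sigma)
  cap <- beta * g * (1 + eps)
  is_out <- rep(FALSE, n_viruses)
  if (n_outliers > 0L) {
    idx <- sample.int(n_viruses, n_outliers)
    is_out[idx] <- TRUE
    sign <- rep_len(c(1, -1), n_outliers)
    cap[idx] <- cap[idx] + sign * displacement * sigma * beta * g[idx]
  }
  cap <- round(cap)
  copies <- sample(subunit_choices, n_viruses, replace = TRUE)
  ids <- sprintf("VIR%04d", seq_len(n_viruses))
  per_subunit <- cap / copies
  comp <- purrr::map(seq_len(n_viruses), function(i) {
    tibble::tibble(protein = paste0(ids[i], "_CP"), copies = copies[i],
                   q_max = per_subunit[i])
  })
  entries <- tibble::tibble(
    virus = ids,
    family = paste0("SynFam", (seq_len(n_viruses) - 1L) %% 10L + 1L),
    genome_type = "+ssRNA",
    t_number = as.character(copies %/% 60L),
    components = comp,
    genome_segments = purrr::map(g, identity),
    host_class = "eukaryotic",
    motor_packaged = FALSE)
  list(entries = entries,
       truth = tibble::tibble(virus = ids, genome_length = g,
                              true_capsid_charge = cap,
                              planted_outlier = is_out))
}

#' Generate reference and spiked-group window multisets
#'
#' Draws a reference multiset of window charges from a discretized,
#' zero-centred charge distribution, then samples a group from the same
#' distribution with one charge value `j_star` oversampled by `spike_fold`.
#'
#' @param reference_size,group_size Multiset sizes.
#' @param j_star Spiked charge value in \[-30, 30\].
#' @param spike_fold Oversampling factor (>= 1; 1 = unbiased null draw).
#' @param seed Integer seed.
#' @return List of two tibbles (`reference`, `group`), each with a `q`
#'   column.
#' @export
gen_enrichment_groups <- function(reference_size = 1e5L,
                                  group_size = 1e3L,
                                  j_star = 17L, spike_fold = 1,
                                  seed = 1L) {
  stopifnot(spike_fold >= 1, group_size >= 1,
            group_size <= reference_size)
  if (j_star < -30 || j_star > 30) {
    stop("j_star outside [-30, +30]", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "enrichment"))
  js <- -30:30
  # discrete null spectrum: near-Gaussian core with a heavy uniform tail,
  # so extreme charge values occur at realistic (rare but non-zero) rates
  base <- stats::dnorm(js, 0, 4)
  base <- 0.98 * base / sum(base) + 0.02 / length(js)
  ref_q <- sample(js, reference_size, replace = TRUE, prob = base)
  grp_prob <- base
  grp_prob[js == j_star] <- grp_prob[js == j_star] * spike_fold
  grp_prob <- grp_prob / sum(grp_prob)
  grp_q <- sample(js, group_size, replace = TRUE, prob = grp_prob)
  # the group must be drawable from the reference: top up reference counts
  # so every group charge is at least as frequent there
  need <- table(factor(grp_q, levels = js)) -
    table(factor(ref_q, levels = js))
  short <- which(need > 0)
  if (length(short) > 0L) {
    ref_q <- c(ref_q, rep(js[short], need[short]))
  }
  list(reference = tibble::tibble(q = as.integer(ref_q)),
       group = tibble::tibble(q = as.integer(grp_q)))
}

# save/restore the global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
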