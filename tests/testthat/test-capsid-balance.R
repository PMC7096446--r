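test_that("total capsid charge sums copies times per-component q_max", {
  expect_equal(total_qmax(tibble::tibble(protein = "CP", copies = 180L,
                                         q_max = 14)), 2520)
  two <- tibble::tibble(protein = c("L1", "L2"), copies = c(360L, 72L),
                        q_max = c(10, 20))
  expect_equal(total_qmax(two), 5040)
  three <- tibble::tibble(protein = c("F", "J", "H"),
                          copies = c(60L, 60L, 12L), q_max = c(2, 12, 10))
  expect_equal(total_qmax(three), 960)
  # linear in copy numbers
  doubled <- dplyr::mutate(two, copies = copies * 2L)
  expect_equal(total_qmax(doubled), 2 * total_qmax(two))
  expect_error(total_qmax(dplyr::select(two, -q_max)), "L1")
})

test_that("genome charge counts nucleotide residues of the longest
           segment", {
  expect_equal(genome_charge(4000L, "+ssRNA"), 4000L)
  expect_equal(genome_charge(c(3000L, 2000L), "ssDNA"), 3000L)
  expect_equal(genome_charge(5000L, "dsDNA"), 10000L) # both strands
  expect_equal(genome_charge(5000L, "dsDNA", single_strand_count = TRUE),
               5000L)
  expect_error(genome_charge(integer(0), "ssDNA"), "length >= 1")
})

test_that("robust fit is exact on noiseless data and flat data", {
  x <- seq(100, 2000, length.out = 20)
  fit <- rout_fit(x, 1.4 * x)
  expect_equal(fit$slope, 1.4, tolerance = 1e-10)
  expect_equal(sum(fit$outlier), 0)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-10)
  expect_equal(fit$charge_ratio, 1 / 1.4, tolerance = 1e-10)

  flat <- rout_fit(x, rep(5, 20))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$pearson_r, 0)
  expect_error(rout_fit(rep(1, 10), 1:10), "zero variance")
  expect_error(rout_fit(1:4, 1:4), "at least 5")
})

test_that("planted gross outliers are recovered exactly", {
  set.seed(42)
  x <- seq(500, 5000, length.out = 32)
  sigma <- 0.02 * mean(1.4 * x)
  y <- 1.4 * x + rnorm(32, 0, sigma)
  planted <- c(5L, 25L)
  y[planted] <- y[planted] + c(10, -10) * sigma
  fit <- rout_fit(x, y)
  expect_equal(which(fit$outlier), planted)
  expect_equal(fit$n_inlier, 30L)
})

test_that("false-positive flagging on clean Gaussian data stays below the
           FDR rate", {
  rates <- vapply(1:100, function(r) {
    set.seed(3000 + r)
    x <- runif(50, 1, 10)
    y <- 2 * x + 1 + rnorm(50)
    mean(rout_fit(x, y)$outlier)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("generating slopes are recovered within tight tolerance", {
  errs <- vapply(c(0.5, 0.7, 1.0), function(beta) {
    rec <- vapply(1:40, function(r) {
      sim <- gen_capsid_dataset(n_viruses = 50, beta = beta, sigma = 0.02,
                                seed = 7000 + r)
      rep <- balance_report(sim$entries)
      abs(rep$fit$slope - beta) / beta
    }, numeric(1))
    stats::median(rec)
  }, numeric(1))
  expect_true(all(errs < 0.02))
})

test_that("pearson_with_p matches the closed form", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1)
  set.seed(9)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  got <- pearson_with_p(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((40 - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(abs(t_hand), 38, lower.tail = FALSE)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)
  # independent coordinates give negligible correlation
  set.seed(10)
  big <- pearson_with_p(rnorm(10000), rnorm(10000))
  expect_lt(abs(big$r), 0.05)
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("balance_report joins sequences, excludes motor-packaged phages,
           and emits both inlier-Pearson readings", {
  sim <- gen_capsid_dataset(n_viruses = 30, beta = 1 / 1.4, sigma = 0.02,
                            seed = 77)
  base <- balance_report(sim$entries)
  # adding far-displaced motor-packaged phages must not move the fit
  phage <- tibble::tibble(
    virus = c("PH1", "PH2", "PH3"), family = "SynPhage",
    genome_type = "dsDNA", t_number = "7",
    components = list(tibble::tibble(protein = "MCP", copies = 415L,
                                     q_max = 3)),
    genome_segments = list(60000L, 70000L, 80000L),
    host_class = "bacteriophage", motor_packaged = TRUE)
  both <- balance_report(dplyr::bind_rows(sim$entries, phage),
                         exclude_motor_packaged = TRUE)
  expect_equal(both$fit$slope, base$fit$slope, tolerance = 1e-12)
  expect_true(all(both$points$excluded[31:33]))
  # family-level Pearson variant present
  expect_true(is.numeric(both$pearson_family_excluded$r))

  # q_max computed from sequences matches precomputed values
  arm <- function(q) paste0(strrep("R", q), strrep("A", 60))
  recs <- tibble::tibble(id = c("CPa", "CPb"),
                         sequence = c(arm(12), arm(18)))
  entries <- tibble::tibble(
    virus = c("V1", "V2", "V3", "V4", "V5"), family = "F",
    genome_type = "+ssRNA", t_number = "3",
    components = list(
      tibble::tibble(protein = "CPa", copies = 60L),
      tibble::tibble(protein = "CPa", copies = 180L),
      tibble::tibble(protein = "CPb", copies = 60L),
      tibble::tibble(protein = "CPb", copies = 180L),
      tibble::tibble(protein = c("CPa", "CPb"), copies = c(60L, 60L))),
    genome_segments = list(1000L, 2100L, 1500L, 4500L, 2500L),
    host_class = "eukaryotic", motor_packaged = FALSE)
  rep <- balance_report(entries, records = recs)
  expect_equal(rep$points$capsid_charge,
               c(60 * 12, 180 * 12, 60 * 18, 180 * 18, 60 * 12 + 60 * 18))
  expect_error(balance_report(entries,
                              records = recs[recs$id == "CPa", ]),
               "CPb")
})

test_that("broom-style accessors expose the fit", {
  x <- seq(1, 100, length.out = 25)
  fit <- rout_fit(x, 0.7 * x + rnorm(25, 0, 0.5))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  gl <- glance(fit)
  expect_equal(gl$n, 25L)
  expect_equal(gl$charge_ratio, 1 / gl$slope)
  expect_equal(nrow(augment(fit)), 25L)
  expect_s3_class(autoplot(fit), "ggplot")
})
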