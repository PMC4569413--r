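test_that("block parameters honor densities, ranges and symmetry", {
  cat2 <- symptom_catalog(data.frame(
    symptom_id = paste0(rep(c("A", "B"), each = 3), "_", rep(1:3, 2)),
    diagnosis_code = rep(c("A", "B"), each = 3),
    within_diagnosis_number = rep(1:3, 2), criterion_label = "c",
    is_screener = FALSE, timeframe = "past3y"))
  prm <- make_block_parameters(cat2, within_density = 1, between_density = 0,
                               within_weight_range = c(0.5, 0.5), seed = 1)
  ut <- prm$couplings[upper.tri(prm$couplings)]
  expect_equal(sum(ut != 0), 6)            # both 3-cliques, nothing between
  expect_true(all(ut[ut != 0] == 0.5))     # degenerate interval
  expect_equal(prm$couplings, t(prm$couplings))
  expect_true(all(diag(prm$couplings) == 0))
  # same seed, same output
  prm2 <- make_block_parameters(cat2, within_density = 1, between_density = 0,
                                within_weight_range = c(0.5, 0.5), seed = 1)
  expect_identical(prm, prm2)
})

test_that("within-block edge frequency follows the sampling rule", {
  cat1 <- symptom_catalog(data.frame(
    symptom_id = paste0("A_", 1:17), diagnosis_code = "A",
    within_diagnosis_number = 1:17, criterion_label = "c",
    is_screener = FALSE, timeframe = "past3y"))
  n_pairs <- 17 * 16 / 2
  frac <- vapply(1:200, function(s) {
    prm <- make_block_parameters(cat1, within_density = 0.75, seed = s)
    sum(prm$couplings[upper.tri(prm$couplings)] != 0) / n_pairs
  }, numeric(1))
  se <- sqrt(0.75 * 0.25 / (200 * n_pairs))
  expect_lt(abs(mean(frac) - 0.75), 3 * se)
})

test_that("Gibbs draws match exact Ising enumeration", {
  # independence case: zero couplings, zero thresholds
  prm0 <- ising_parameters(c(0, 0, 0), matrix(0, 3, 3))
  d0 <- gibbs_sample(prm0, 20000, burn_in = 100, thin = 1, seed = 1)
  se <- sqrt(0.25 / 20000)
  expect_true(all(abs(colMeans(d0$values) - 0.5) < 3 * se))

  # p = 2, omega = 1: P(1,1) = e / (3 + e) by direct enumeration
  prm2 <- ising_parameters(c(0, 0), matrix(c(0, 1, 1, 0), 2))
  d2 <- gibbs_sample(prm2, 50000, burn_in = 200, thin = 2, seed = 2)
  p11 <- mean(d2$values[, 1] == 1 & d2$values[, 2] == 1)
  expect_lt(abs(p11 - exp(1) / (3 + exp(1))), 0.01)

  # p = 3, arbitrary small parameters: TV distance to enumeration < 0.02
  tau <- c(-0.5, 0.3, 0.1)
  om <- matrix(0, 3, 3)
  om[1, 2] <- om[2, 1] <- 0.8
  om[2, 3] <- om[3, 2] <- -0.5
  prm3 <- ising_parameters(tau, om)
  exact <- enumerate_ising(tau, om)
  d3 <- gibbs_sample(prm3, 50000, burn_in = 500, thin = 2, seed = 3)
  emp <- empirical_state_probs(d3$values, exact$states)
  expect_lt(total_variation(emp, exact$prob), 0.02)

  # determinism and argument errors
  expect_identical(gibbs_sample(prm3, 100, seed = 9)$values,
                   gibbs_sample(prm3, 100, seed = 9)$values)
  expect_error(gibbs_sample(prm3, 0), "positive")
  expect_error(gibbs_sample(prm3, 10, thin = 0), "positive")
})

test_that("skip logic gates exactly the right cells", {
  cat0 <- toy_catalog()   # A_1 screens A_2, A_3; B unscreened
  v <- rbind(c(1, 1, 0, 1, 0, 1),
             c(0, 1, 1, 0, 1, 0),
             c(0, 0, 0, 1, 1, 1))
  d <- binary_dataset(v, column_ids = cat0$symptoms$symptom_id)
  sk <- apply_skip_logic(d, cat0)
  # screener-positive row untouched
  expect_identical(sk$values[1, ], d$values[1, ])
  # screener-negative rows: gated items missing, everything else untouched
  expect_true(all(is.na(sk$values[2:3, c("A_2", "A_3")])))
  expect_identical(sk$values[2:3, c("A_1", "B_1", "B_2", "B_3")],
                   d$values[2:3, c("A_1", "B_1", "B_2", "B_3")])
  # no-skip-rule catalog: identity
  cat_plain <- symptom_catalog(transform(toy_catalog()$symptoms,
                                         is_screener = FALSE))
  expect_identical(apply_skip_logic(d, cat_plain)$values, d$values)
  # observed, non-gated cells are never altered (cell-wise, many rows)
  set.seed(4)
  v2 <- matrix(rbinom(600, 1, 0.5), 100, 6,
               dimnames = list(NULL, cat0$symptoms$symptom_id))
  d2 <- binary_dataset(v2)
  sk2 <- apply_skip_logic(d2, cat0)
  untouched <- !is.na(sk2$values)
  expect_identical(sk2$values[untouched], d2$values[untouched])
})

test_that("ALL vs ANY gating differ only for partially positive screens", {
  # two screeners: rows (1,0) are gated under ANY but not under ALL
  cat2 <- symptom_catalog(data.frame(
    symptom_id = c("A_1", "A_2", "A_3"), diagnosis_code = "A",
    within_diagnosis_number = 1:3, criterion_label = "c",
    is_screener = c(TRUE, TRUE, FALSE), timeframe = "past3y"))
  d <- binary_dataset(rbind(c(1, 0, 1), c(0, 0, 1), c(1, 1, 1)),
                      column_ids = c("A_1", "A_2", "A_3"))
  all_rule <- apply_skip_logic(d, cat2, gate = "all")
  any_rule <- apply_skip_logic(d, cat2, gate = "any")
  expect_identical(unname(is.na(all_rule$values[, "A_3"])),
                   c(FALSE, TRUE, FALSE))
  expect_identical(unname(is.na(any_rule$values[, "A_3"])),
                   c(TRUE, TRUE, FALSE))
})

test_that("zero-imputation fills exactly the missing cells", {
  d <- binary_dataset(matrix(c(1L, NA, NA), 1, 3),
                      column_ids = c("a", "b", "c"))
  expect_identical(unname(impute_skip_zeros(d)$values[1, ]), c(1L, 0L, 0L))
  # identity on complete data
  full <- binary_dataset(matrix(c(0L, 1L), 2, 2), column_ids = c("a", "b"))
  expect_identical(impute_skip_zeros(full)$values, full$values)
  # composition: skip then impute makes gated columns 0 for screen-negative
  cat0 <- toy_catalog()
  v <- rbind(c(0, 1, 1, 1, 0, 1))
  comp <- impute_skip_zeros(apply_skip_logic(
    binary_dataset(v, column_ids = cat0$symptoms$symptom_id), cat0))
  expect_identical(unname(comp$values[1, c("A_2", "A_3")]), c(0L, 0L))
  expect_false(anyNA(comp$values))
})

test_that("missing fractions and the strict filter behave as specified", {
  m <- matrix(NA_integer_, 4, 10)
  m[1, ] <- 1L
  m[2, ] <- c(NA, rep(0L, 9))
  m[3, ] <- c(NA, NA, rep(1L, 8))
  m[4, ] <- c(rep(NA, 5), rep(0L, 5))
  d <- binary_dataset(m, column_ids = paste0("s", 1:10))
  expect_equal(unname(row_missing_fraction(d)), c(0, 0.1, 0.2, 0.5))
  # strict "<": 0.2 keeps only the first two rows
  expect_equal(nrow(filter_rows_by_missingness(d, 0.2)$values), 2L)
  expect_equal(nrow(filter_rows_by_missingness(d, 1.0)$values), 4L)
  expect_equal(nrow(filter_rows_by_missingness(d, 0.0)$values), 1L)
  # mean of fractions equals overall missing-cell share
  expect_equal(mean(row_missing_fraction(d)), mean(is.na(d$values)))
  # a 120-column row with 90 gated items missing is 75% missing
  row120 <- matrix(c(rep(1L, 30), rep(NA_integer_, 90)), 1, 120)
  d120 <- binary_dataset(row120, column_ids = paste0("s", 1:120))
  expect_equal(unname(row_missing_fraction(d120)), 0.75)
  # an all-missing dataset filters down to zero rows
  allna <- binary_dataset(matrix(NA_integer_, 2, 3),
                          column_ids = c("a", "b", "c"))
  expect_equal(nrow(filter_rows_by_missingness(allna, 0.5)$values), 0L)
})

test_that("the simulate-skip-impute pipeline is reproducible end to end", {
  cat0 <- toy_catalog()
  run <- function() {
    prm <- make_block_parameters(cat0, seed = 11)
    d <- gibbs_sample(prm, 300, burn_in = 100, thin = 2, seed = 12)
    impute_skip_zeros(apply_skip_logic(d, cat0))$values
  }
  expect_identical(run(), run())
})

test_that("datasets round-trip through CSV with empty-field missing cells", {
  v <- matrix(c(1L, 0L, NA, NA, 1L, 0L), 2, 3)
  d <- binary_dataset(v, column_ids = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f, provenance = list(seed = 5))
  back <- read_dataset(f)
  expect_identical(unname(back$values), unname(d$values))
  expect_identical(colnames(back$values), colnames(d$values))
  expect_true(file.exists(paste0(f, ".json")))
})
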