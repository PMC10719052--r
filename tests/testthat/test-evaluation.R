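make_field <- function(mag_true, mag_est, inside = NULL) {
  n <- length(mag_true)
  if (is.null(inside)) inside <- rep(TRUE, n)
  grid <- tibble::tibble(grid_i = seq_len(n) - 1L, grid_j = 0L,
                         x_um = seq_len(n), y_um = 0,
                         inside_cell = inside)
  truth <- grid
  truth$fx <- mag_true
  truth$fy <- 0
  est <- grid
  est$fx <- mag_est
  est$fy <- 0
  list(truth = truth, est = est)
}

test_that("AUC is 1 for perfect separation and 0.5 for constant scores", {
  f <- make_field(mag_true = c(1, 1, 0, 0, 0), mag_est = c(5, 4, 1, 2, 0.5))
  expect_equal(roc_auc(f$est, f$truth)$auc, 1)
  g <- make_field(mag_true = c(1, 1, 0, 0, 0), mag_est = rep(2, 5))
  expect_equal(roc_auc(g$est, g$truth)$auc, 0.5)
})

test_that("AUC equals brute-force Mann-Whitney pair counting", {
  mag_true <- c(2, 1, 0, 0, 0, 0)
  mag_est <- c(1.5, 0.7, 0.9, 0.1, 0.7, 0.2)
  f <- make_field(mag_true, mag_est)
  res <- roc_auc(f$est, f$truth)
  # exhaustive pairwise comparison oracle with 0.5 for ties
  pos <- mag_est[mag_true > 0]
  neg <- mag_est[mag_true == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  expect_equal(res$auc, wins / (length(pos) * length(neg)))
  expect_identical(res$m_pos, 2L)
  expect_identical(res$m_neg, 4L)
  # ROC table is a proper staircase from (0,0) to (1,1)
  expect_equal(res$roc$tpr[1], 0)
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(res$roc$tpr[nrow(res$roc)], 1)
  expect_true(all(diff(res$roc$tpr) >= 0))
  expect_true(all(diff(res$roc$fpr) >= 0))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(14, {
    mag_true <- ifelse(runif(40) < 0.3, runif(40, 1, 2), 0)
    mag_est <- runif(40)
  })
  if (all(mag_true == 0)) mag_true[1] <- 1
  f <- make_field(mag_true, mag_est)
  a0 <- roc_auc(f$est, f$truth)$auc
  g <- make_field(mag_true, log1p(3 * mag_est))
  expect_equal(roc_auc(g$est, g$truth)$auc, a0)
})

test_that("AUC restricts to the cellular region and validates inputs", {
  inside <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  f <- make_field(c(1, 0, 0, 0, 0), c(0.1, 5, 0.2, 9, 9), inside = inside)
  # the outside points with huge scores are ignored
  res <- roc_auc(f$est, f$truth)
  expect_identical(res$m_pos + res$m_neg, 3L)
  all_pos <- make_field(c(1, 1, 1), c(1, 2, 3))
  expect_error(roc_auc(all_pos$est, all_pos$truth), "positive and one negative")
})

test_that("DTM identities: perfect, null, and balanced estimates", {
  f <- make_field(c(2, 4, 0), c(2, 4, 1))
  expect_equal(dtm(f$est, f$truth), 0)
  z <- make_field(c(2, 4, 0), c(0, 0, 0))
  expect_equal(dtm(z$est, z$truth), -1)
  b <- make_field(c(2, 2, 0), c(1, 3, 0))  # ratios 0.5 and 1.5
  expect_equal(dtm(b$est, b$truth), 0)
  # random toy vs an independent loop oracle
  withr::with_seed(15, {
    tm <- c(runif(5, 1, 3), rep(0, 5))
    em <- runif(10, 0, 3)
  })
  r <- make_field(tm, em)
  acc <- 0
  for (i in 1:5) acc <- acc + (em[i] - tm[i]) / tm[i]
  expect_equal(dtm(r$est, r$truth), acc / 5)
})

test_that("DTMB identities: silent background and true-scale background", {
  f <- make_field(c(2, 4, 0, 0), c(2, 4, 0, 0))
  expect_equal(dtmb(f$est, f$truth), 0)
  g <- make_field(c(2, 4, 0, 0), c(0, 0, 3, 3))  # mean true = 3
  expect_equal(dtmb(g$est, g$truth), 1)
  h <- make_field(c(3, 3, 0, 0, 0), c(0, 0, 1, 2, 3))
  expect_equal(dtmb(h$est, h$truth), mean(c(1, 2, 3)) / 3)
  none <- make_field(c(0, 0), c(1, 1))
  expect_error(dtmb(none$est, none$truth), "positive")
})

test_that("the benchmark table is tidy, complete, and seed-deterministic", {
  cells <- list(round = tiny_config(shape = "blob", blob_amplitude = 0.05))
  b1 <- run_benchmark(cells, densities = 0.4, algorithms = c("ridge"),
                      n_replicates = 2, seed = 5)
  expect_identical(nrow(b1), 2L)
  expect_true(all(c("cell", "density", "replicate", "algorithm", "auc",
                    "dtm", "dtmb", "n_beads", "error") %in% names(b1)))
  expect_true(all(is.na(b1$error)))
  b2 <- run_benchmark(cells, densities = 0.4, algorithms = c("ridge"),
                      n_replicates = 2, seed = 5)
  expect_identical(b1$auc, b2$auc)
  s <- summarize_benchmark(b1)
  expect_identical(nrow(s), 1L)
  expect_true(all(c("auc_mean", "auc_se", "dtm_mean", "dtmb_mean") %in%
                    names(s)))
  expect_equal(s$auc_mean, mean(b1$auc))
})

test_that("headline aggregation picks the right slices of a benchmark table", {
  tb <- tibble::tibble(
    cell = rep(c("complex1", "round1"), each = 6),
    boundary_class = rep(c("complex", "round"), each = 6),
    density = rep(c(0.4, 0.4, 0.4, 0.4, 1.6, 1.6), 2),
    replicate = 1L,
    algorithm = rep(c("btfe", "ridge", "lasso", "btfe", "btfe", "btfe"), 2),
    auc = c(0.8, 0.7, 0.5, 0.81, 0.9, 0.91,
            0.6, 0.5, 0.5, 0.61, 0.62, 0.63),
    dtm = c(-0.5, -0.9, -0.8, -0.5, -0.3, -0.3,
            -0.6, -1, -1, -0.6, -0.5, -0.5),
    dtmb = c(0.1, 0.05, 0.02, 0.12, 0.2, 0.21,
             0.1, 0.02, 0.01, 0.1, 0.15, 0.16),
    error = NA_character_)
  h <- benchmark_headline(tb)
  expect_equal(h$lasso_auc_complex_low$value, 0.5)
  expect_equal(h$btfe_auc_round$value, mean(c(0.6, 0.61, 0.62, 0.63)))
  expect_equal(h$baseline_dtm_complex_low$value, mean(c(-0.9, -0.8)))
  # max per-condition mean dtmb of btfe: complex1 @1.6 = (0.2 + 0.21)/2
  expect_equal(h$btfe_dtmb_max$value, 0.205)
  expect_identical(h$lasso_auc_complex_low$n, 1L)
})
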