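make_mm <- make_matrix_fixture

test_that("the discrepancy formula behaves at its anchors", {
  fmax <- c(a = 10, b = 4, c = 2)
  p <- c(a = 3, b = 1, c = 0.5)
  expect_equal(pair_discrepancy(p, p, names(fmax), fmax), 0)
  # one of n features differing by exactly its maximum contributes 1/n
  q <- p; q[["b"]] <- p[["b"]] + fmax[["b"]]
  expect_equal(pair_discrepancy(p, q, names(fmax), fmax), 1 / 3)
  expect_error(pair_discrepancy(p, q, names(fmax), c(a = 10, b = 0, c = 2)),
               "positive")
  q[["a"]] <- NA
  expect_true(is.na(pair_discrepancy(p, q, names(fmax), fmax)))
})

test_that("the discrepancy matches an independent arithmetic oracle", {
  set.seed(100)
  fmax <- setNames(runif(5, 1, 10), letters[1:5])
  for (i in 1:50) {
    a <- setNames(runif(5, 0, 10), letters[1:5])
    b <- setNames(runif(5, 0, 10), letters[1:5])
    expect_equal(pair_discrepancy(a, b, letters[1:5], fmax),
                 discrepancy_oracle(a, b, letters[1:5], fmax),
                 tolerance = 1e-12)
    expect_identical(pair_discrepancy(a, b, letters[1:5], fmax),
                     pair_discrepancy(b, a, letters[1:5], fmax))
  }
})

test_that("pair selection is discordant, thresholded, greedy and reuse-free", {
  set.seed(101)
  n <- 120
  x <- cbind(imp1 = runif(n), imp2 = runif(n), probe = rnorm(n))
  y <- rep(c(0L, 1L), n / 2)
  mm <- make_mm(x, y)
  imp <- c(imp1 = 3, imp2 = 2, probe = 0.5)
  pairs <- select_pairs(mm, "probe", imp, threshold = 0.15)
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$discrepancy < 0.15))
  # the probe is never in its own importance set
  expect_identical(sort(attr(pairs, "important")), c("imp1", "imp2"))
  # discordance and no patient reuse
  expect_true(all(mm$outcome[match(pairs$id_event, mm$patient_id)] == 1))
  expect_true(all(mm$outcome[match(pairs$id_control, mm$patient_id)] == 0))
  expect_false(any(duplicated(c(pairs$id_event, pairs$id_control))))
  # selected discrepancies match a recomputation from the raw rows
  fmax <- apply(mm$x[, c("imp1", "imp2")], 2, max)
  for (i in seq_len(min(5, nrow(pairs)))) {
    a <- mm$x[pairs$id_event[i], c("imp1", "imp2")]
    b <- mm$x[pairs$id_control[i], c("imp1", "imp2")]
    expect_equal(pairs$discrepancy[i],
                 discrepancy_oracle(a, b, c("imp1", "imp2"), fmax),
                 tolerance = 1e-12)
  }
})

test_that("features tied with the probe are excluded by the strict comparison", {
  set.seed(102)
  x <- cbind(big = runif(60), tie = runif(60), probe = runif(60))
  mm <- make_mm(x, rep(c(0L, 1L), 30))
  imp <- c(big = 2, tie = 1, probe = 1)
  pairs <- select_pairs(mm, "probe", imp, threshold = 0.5)
  expect_identical(attr(pairs, "important"), "big")
})

test_that("threshold zero yields an empty set; candidates grow with threshold", {
  set.seed(103)
  x <- cbind(imp1 = runif(80), probe = rnorm(80))
  mm <- make_mm(x, rep(c(0L, 1L), 40))
  imp <- c(imp1 = 2, probe = 1)
  expect_warning(p0 <- select_pairs(mm, "probe", imp, threshold = 0),
                 "no candidate|no eligible")
  expect_equal(nrow(p0), 0L)
  thresholds <- c(0.02, 0.05, 0.1, 0.3)
  cands <- vapply(thresholds, function(th) {
    attr(select_pairs(mm, "probe", imp, threshold = th), "n_candidates")
  }, numeric(1))
  expect_false(is.unsorted(cands))
})

test_that("patients missing an important feature are ineligible", {
  set.seed(104)
  x <- cbind(imp1 = runif(60), probe = rnorm(60))
  x[1:10, "imp1"] <- NA
  mm <- make_mm(x, rep(c(0L, 1L), 30))
  pairs <- select_pairs(mm, "probe", c(imp1 = 2, probe = 1), threshold = 0.9)
  excluded <- mm$patient_id[1:10]
  expect_false(any(c(pairs$id_event, pairs$id_control) %in% excluded))
})

test_that("the paired t-test matches the textbook formula", {
  pairs <- structure(data.frame(id_event = paste0("E", 1:5),
                                id_control = paste0("C", 1:5),
                                discrepancy = 0.01),
                     probe = "probe", important = "imp", threshold = 0.1,
                     n_candidates = 5L,
                     class = c("ril_paired_set", "data.frame"))
  ve <- c(4.1, 5.2, 3.9, 6.0, 5.5); vc <- c(3.8, 4.9, 4.2, 5.1, 5.0)
  values <- setNames(c(ve, vc), c(paste0("E", 1:5), paste0("C", 1:5)))
  res <- paired_test(pairs, values)
  d <- ve - vc
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(t_manual), df = 4), tolerance = 1e-10)
  expect_equal(res$mean_difference, mean(d))

  # all-zero differences are degenerate, not a p-value
  same <- setNames(rep(1, 10), c(paste0("E", 1:5), paste0("C", 1:5)))
  res0 <- paired_test(pairs, same)
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p_value))
})
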