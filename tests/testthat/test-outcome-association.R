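test_that("current asthma is any 2 of 3 features, missing-propagating", {
  expect_true(derive_asthma(TRUE, TRUE, FALSE))
  expect_false(derive_asthma(TRUE, FALSE, FALSE))
  expect_true(derive_asthma(TRUE, TRUE, TRUE))
  expect_identical(derive_asthma(NA, TRUE, TRUE), NA)
  expect_identical(
    derive_asthma(c(TRUE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE)),
    c(TRUE, FALSE)
  )
})

test_that("sensitization profiles follow the one-positive-member rule", {
  comps <- c("D1", "D2", "G1", "X1")
  m <- matrix(0L, 4, 4, dimnames = list(paste0("s", 1:4), comps))
  m["s1", "D1"] <- 1L # one mite-cluster member only
  m["s3", ] <- 1L # positive to everything
  cl <- tibble::tibble(
    component_id = comps, cluster = c(1, 1, 2, 3)
  )
  pr <- build_profiles(bin_panel(m), cl)
  expect_identical(names(pr), c("subject_id", "cluster_1", "cluster_2", "cluster_3", "nonsensitized"))
  expect_identical(unname(unlist(pr[pr$subject_id == "s1", -1])), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(unname(unlist(pr[pr$subject_id == "s2", -1])), c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(unlist(pr[pr$subject_id == "s3", c("cluster_1", "cluster_2", "cluster_3")])))
  # nonsensitized implies all cluster indicators are off
  expect_true(all(!pr$cluster_1[pr$nonsensitized]))
  # unmeasured subjects are dropped with a log entry
  m2 <- rbind(m, s5 = NA_integer_)
  df <- tibble::as_tibble(m2)
  df <- tibble::add_column(df, subject_id = rownames(m2), .before = 1)
  p_na <- binarize_panel(quant_panel(df), 0.5)
  expect_message(pr2 <- build_profiles(p_na, cl), "dropping 1")
  expect_false("s5" %in% pr2$subject_id)
})

test_that("univariable OR equals the cross-product ratio, with sane edge handling", {
  y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  r <- univariable_or(y, x)
  expect_equal(r$or, 2.25, tolerance = 1e-6)
  expect_true(r$ci_low < 2.25 && 2.25 < r$ci_high)
  # equal case fractions in both arms
  xb <- rep(c(1, 0), each = 50)
  y0 <- c(rep(1, 10), rep(0, 40), rep(1, 10), rep(0, 40))
  expect_equal(univariable_or(y0, xb)$or, 1, tolerance = 1e-9)
  # zero unexposed cases: separation flagged, no crash
  ys <- c(rep(1, 5), rep(0, 45), rep(0, 50))
  rs <- univariable_or(ys, xb)
  expect_identical(rs$flag, "separation")
  expect_true(is.infinite(rs$or) || is.nan(rs$or))
  # random tables: closed form to 1e-6 relative tolerance
  set.seed(73)
  for (rix in 1:10) {
    cells <- sample(5:60, 4, replace = TRUE)
    yy <- rep(c(1, 0, 1, 0), cells)
    xx <- rep(c(1, 1, 0, 0), cells)
    expect_equal(
      univariable_or(yy, xx)$or,
      (cells[1] * cells[4]) / (cells[2] * cells[3]),
      tolerance = 1e-6
    )
    # recoding the outcome inverts the OR
    expect_equal(
      univariable_or(1 - yy, xx)$or,
      1 / univariable_or(yy, xx)$or,
      tolerance = 1e-6
    )
  }
})

test_that("joint model recovers planted adjusted ORs and flags degenerate columns", {
  set.seed(79)
  n <- 2000
  X <- tibble::tibble(
    cluster_1 = rbinom(n, 1, 0.3) == 1,
    cluster_2 = rbinom(n, 1, 0.25) == 1,
    cluster_3 = rbinom(n, 1, 0.2) == 1
  )
  lp <- qlogis(0.10) + log(3.5) * X$cluster_1
  y <- rbinom(n, 1, plogis(lp)) == 1
  res <- multiple_or(y, X)
  est <- res$or[match(paste0("cluster_", 1:3), res$exposure)]
  expect_true(abs(est[1] - 3.5) / 3.5 < 0.30)
  expect_true(est[2] > 1 / 1.4 && est[2] < 1.4)
  expect_true(est[3] > 1 / 1.4 && est[3] < 1.4)
  # an all-false column is flagged and the others unchanged
  X2 <- X
  X2$cluster_4 <- FALSE
  res2 <- multiple_or(y, X2)
  expect_identical(
    res2$flag[res2$exposure == "cluster_4"], "degenerate_exposure"
  )
  expect_equal(
    res2$or[match(paste0("cluster_", 1:3), res2$exposure)], est,
    tolerance = 1e-10
  )
  # a single exposure reduces to the univariable model
  r1 <- multiple_or(y, X[, "cluster_1", drop = FALSE])
  r2 <- univariable_or(y, X$cluster_1, exposure_name = "cluster_1")
  expect_equal(r1$or, r2$or, tolerance = 1e-8)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-6)
})

test_that("planted log odds ratios are recovered without bias across replicates", {
  set.seed(83)
  n <- 2000
  ests <- vapply(1:50, function(r) {
    profiles <- tibble::tibble(
      subject_id = as.character(1:n),
      cluster_1 = rbinom(n, 1, 0.3) == 1
    )
    out <- simulate_outcomes(
      profiles,
      baseline_logodds = qlogis(0.10),
      cluster_logors = log(3.5)
    )
    log(univariable_or(out$current_asthma, profiles$cluster_1)$or)
  }, numeric(1))
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - log(3.5)), 2 * mc_se)
})

test_that("cross-age confusion counts shared sensitization", {
  mk_prof <- function(ids, c1, c2) {
    tibble::tibble(
      subject_id = ids, cluster_1 = c1, cluster_2 = c2,
      nonsensitized = !(c1 | c2)
    )
  }
  p1 <- mk_prof(paste0("s", 1:6), c(T, T, F, F, T, F), c(F, T, T, F, F, F))
  p2 <- mk_prof(paste0("s", 1:6), c(T, F, F, F, T, F), c(T, T, T, F, F, T))
  cm <- cross_age_confusion(p1, p2)
  # hand count: cluster_1 at t1 = {s1,s2,s5}; of those cluster_1 at t2 = {s1,s5}
  expect_identical(cm["cluster_1", "cluster_1"], 2L)
  expect_identical(cm["cluster_1", "cluster_2"], 2L) # s1, s2
  expect_identical(cm["cluster_2", "cluster_2"], 2L) # s2, s3
  expect_identical(cm["cluster_2", "cluster_1"], 0L)
  # identical profiles: diagonal equals per-cluster sensitized counts
  cm2 <- cross_age_confusion(p1, p1)
  expect_identical(diag(cm2), c(cluster_1 = 3L, cluster_2 = 2L))
  # disjoint subject sets warn and return an empty count matrix
  p3 <- mk_prof(paste0("t", 1:3), c(T, F, T), c(F, F, T))
  expect_warning(cm3 <- cross_age_confusion(p1, p3), "both ages")
  expect_true(all(cm3 == 0L))
})
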