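test_that("panels round-trip through delimited text cell for cell", {
  set.seed(11)
  for (ext in c(".csv", ".tsv")) {
    for (r in 1:3) {
      p <- rand_quant_panel(sample(3:8, 1), sample(2:6, 1), age = "5")
      f <- withr::local_tempfile(fileext = ext)
      write_panel(p, f)
      p2 <- read_panel(f, age_label = "5")
      expect_identical(dim(p), dim(p2))
      expect_equal(panel_matrix(p), panel_matrix(p2))
    }
  }
})

test_that("malformed panels are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,CompA,CompA", "s1,0.1,0.2"), f)
  expect_error(read_panel(f), "CompA")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,CompA,CompB", "s1,0.1,-0.2"), f2)
  expect_error(read_panel(f2), "negative")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,CompA", "s1,0.1", "s1,0.2"), f3)
  expect_error(read_panel(f3), "s1")
  # partially missing subject rows are not allowed
  expect_error(
    quant_panel(tibble::tibble(id = c("a", "b"), X = c(NA, 1), Y = c(1, 2))),
    "whole subject rows"
  )
})

test_that("binarization is inclusive at the threshold and monotone", {
  df <- tibble::tibble(id = c("s1", "s2"), A = c(0.30, 0.29), B = c(0, 5))
  b <- binarize_panel(quant_panel(df), threshold = 0.30)
  expect_identical(unname(panel_matrix(b)[, "A"]), c(1L, 0L))
  expect_identical(attr(b, "threshold_used"), 0.30)
  # all-zero panel stays all zero at any threshold
  z <- quant_panel(tibble::tibble(id = c("s1", "s2"), A = c(0, 0), B = c(0, 0)))
  expect_true(all(panel_matrix(binarize_panel(z, 0.01)) == 0))
  # raising the threshold never turns a 0 into a 1
  set.seed(21)
  p <- rand_quant_panel(6, 5)
  for (th in list(c(0.3, 1), c(1, 5), c(0.1, 0.3))) {
    lo <- panel_matrix(binarize_panel(p, th[1]))
    hi <- panel_matrix(binarize_panel(p, th[2]))
    expect_true(all(hi <= lo))
  }
})

test_that("activity rule keeps components with enough responders, nested in min_positive", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  m[1:3, "A"] <- 1L
  m[1:2, "B"] <- 1L
  b <- bin_panel(m)
  expect_identical(active_components(b, 3), "A")
  expect_identical(active_components(b, 1), c("A", "B"))
  # idempotent on the restricted panel
  act <- active_components(b, 3)
  sub <- bin_panel(m[, act, drop = FALSE])
  expect_identical(active_components(sub, 3), act)
  # nesting across thresholds
  set.seed(31)
  mm <- matrix(rbinom(60, 1, 0.4), 10, 6,
    dimnames = list(paste0("s", 1:10), paste0("c", 1:6))
  )
  bp <- bin_panel(mm)
  for (mp in 1:4) {
    expect_true(all(active_components(bp, mp + 1) %in% active_components(bp, mp)))
  }
})

test_that("responder set uses active components only and shrinks with the active set", {
  m <- matrix(0L, 4, 4, dimnames = list(paste0("s", 1:4), c("A", "B", "C", "D")))
  m[1:3, "A"] <- 1L # A active
  m[4, "D"] <- 1L # s4 positive only to inactive D
  b <- bin_panel(m)
  act <- active_components(b, 3)
  expect_identical(responder_subjects(b, act), c("s1", "s2", "s3"))
  expect_false("s4" %in% responder_subjects(b, act))
  expect_warning(r0 <- responder_subjects(b, character(0)), "empty")
  expect_length(r0, 0)
  # all-zero panel has no responders
  zz <- bin_panel(matrix(0L, 2, 2, dimnames = list(c("x", "y"), c("A", "B"))))
  expect_length(suppressWarnings(responder_subjects(zz, character(0))), 0)
  # weakly shrinking
  expect_true(all(
    responder_subjects(b, "A") %in% responder_subjects(b, c("A", "B"))
  ))
})

test_that("activity timeline records drop-outs and re-activations", {
  mk <- function(n_pos) {
    m <- matrix(0L, 4, 2, dimnames = list(paste0("s", 1:4), c("A", "B")))
    if (n_pos > 0) m[seq_len(n_pos), "A"] <- 1L
    m[1:3, "B"] <- 1L # B constantly active
    m
  }
  panels <- list(
    "3" = bin_panel(mk(3)), "5" = bin_panel(mk(3)),
    "8" = bin_panel(mk(1)), "11" = bin_panel(mk(4))
  )
  tl <- build_activity_timeline(panels, min_positive = 3)
  a <- tl[tl$component_id == "A", ]
  expect_identical(a$status, c("active", "active", "inactive", "active"))
  expect_identical(a$dropout, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(a$first_active_age[1], 3)
  b <- tl[tl$component_id == "B", ]
  expect_true(all(!b$dropout))
  # never-active component
  m2 <- mk(3)
  m2[, "A"] <- 0L
  tl2 <- build_activity_timeline(list("3" = bin_panel(m2), "5" = bin_panel(m2)))
  expect_true(all(tl2$status[tl2$component_id == "A"] == "never-active"))
  # a single panel yields no dropout annotations
  tl3 <- build_activity_timeline(list("3" = bin_panel(mk(3))))
  expect_true(all(!tl3$dropout))
})

test_that("drop-out causes separate resolution from attrition", {
  subj <- paste0("s", 1:5)
  m3 <- matrix(0L, 5, 2, dimnames = list(subj, c("A", "B")))
  m3[1:3, "A"] <- 1L
  m3[1:3, "B"] <- 1L
  scenarios <- list(
    resolution = list(present = subj, expect = "resolution"),
    attrition = list(present = c("s4", "s5"), expect = "attrition"),
    undetermined = list(present = c("s1", "s4", "s5"), expect = "undetermined")
  )
  for (sc in scenarios) {
    m5 <- matrix(0L, length(sc$present), 2,
      dimnames = list(sc$present, c("A", "B"))
    )
    panels <- list("3" = bin_panel(m3), "5" = bin_panel(m5))
    tl <- classify_dropout_cause(build_activity_timeline(panels), panels)
    got <- tl$dropout_cause[tl$component_id == "A" & tl$age == 5]
    expect_identical(got, sc$expect)
  }
})

test_that("percentages follow the half-up two-decimal convention", {
  expect_identical(percent(47, 225), 20.89)
  expect_identical(percent(588, 1184), 49.66)
  expect_identical(percent(0, 100), 0)
  expect_error(percent(1, 0), "denominator")
  expect_error(percent(5, 3), "numerator")
  # complement sums to 100 within rounding tolerance
  set.seed(41)
  for (r in 1:20) {
    d <- sample(50:2000, 1)
    n <- sample(0:d, 1)
    s <- percent(n, d) + percent(d - n, d)
    expect_true(s >= 99.99 && s <= 100.01)
  }
})

test_that("group comparison reproduces direction of association and is monotone", {
  # near-identical proportions carry no signal
  flat <- matrix(c(50, 100, 50, 100), 2)
  expect_gt(compare_groups(flat)$p_value, 0.9)
  # maternal-asthma-like table is clearly significant
  tab <- matrix(c(47, 125, 178, 829), 2)
  expect_lt(compare_groups(tab)$p_value, 0.01)
  # doubling all cells strengthens the evidence
  set.seed(51)
  for (r in 1:10) {
    t1 <- matrix(sample(20:60, 4), 2)
    t1[1, 1] <- t1[1, 1] + 40 # plant an association
    r1 <- compare_groups(t1)
    r2 <- compare_groups(2 * t1)
    expect_gte(r2$statistic, r1$statistic)
    expect_lte(r2$p_value, r1$p_value)
  }
  expect_warning(res <- compare_groups(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_identical(res$p_value, 1)
})
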