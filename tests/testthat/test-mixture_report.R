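# Published six-component DNA mixture: per-category unique-read counts and
# concentrations, with their printed derived columns, used as arithmetic
# fixtures.
h1_counts <- c(Mutton = 340607, Beef = 461551, Rabbit = 200063, Rat = 116047,
               Pork = 35332, Chicken = 7865, Venison = 1854, Horse = 1,
               Camel = 1, Bear = 1)
h1_props <- c(Beef = 39.68, Mutton = 29.28, Rabbit = 17.20, Rat = 9.98,
              Pork = 3.04, Chicken = 0.68, Venison = 0.16, Horse = 0.00,
              Camel = 0.00, Bear = 0.00)
h1_conc <- c(Mutton = 149.83, Beef = 84.45, Rabbit = 83.13, Rat = 40.17,
             Pork = 9.46, Chicken = 4.01)

test_that("compute_proportions reproduces the printed proportion column", {
  res <- compute_proportions(h1_counts)
  expect_identical(res$category, names(h1_props))
  expect_equal(stats::setNames(res$proportion_pct, res$category), h1_props)
  expect_identical(attr(res, "denominator"), sum(h1_counts))
  # unrounded proportions sum to exactly 100
  expect_equal(sum(attr(res, "proportion_raw")), 100, tolerance = 1e-12)
})

test_that("compute_proportions handles trivial and random inputs", {
  res <- compute_proportions(c(Pork = 10))
  expect_identical(res$proportion_pct, 100.00)
  expect_identical(nrow(compute_proportions(integer(0))), 0L)

  set.seed(21)
  for (i in 1:5) {
    x <- stats::setNames(sample(1e6, 5), letters[1:5])
    res <- compute_proportions(x)
    # direct-arithmetic oracle
    want <- sort(x, decreasing = TRUE) / sum(x) * 100
    expect_equal(stats::setNames(res$proportion_pct, res$category),
                 round(want + 1e-9, 2), tolerance = 1e-9)
    expect_equal(sum(attr(res, "proportion_raw")), 100, tolerance = 1e-9)
  }
})

test_that("target_from_concentrations reproduces the reproducible printed rows", {
  tgt <- target_from_concentrations(h1_conc)
  expect_identical(unname(tgt["Mutton"]), 40.38)
  expect_identical(unname(tgt["Rabbit"]), 22.40)
  expect_identical(unname(tgt["Rat"]), 10.83)
  expect_identical(unname(tgt["Chicken"]), 1.08)
  # the printed beef/pork targets (22.70 / 2.54) are NOT the ratio of the
  # printed concentrations; the arithmetic definition gives 22.76 / 2.55
  expect_identical(unname(tgt["Beef"]), 22.76)
  expect_identical(unname(tgt["Pork"]), 2.55)

  expect_identical(unname(target_from_concentrations(c(X = 5.0))), 100.00)
  expect_error(target_from_concentrations(c(a = 0, b = 0)), "zero")

  set.seed(31)
  conc <- stats::setNames(stats::runif(4, 1, 100), letters[1:4])
  expect_equal(target_from_concentrations(conc),
               round(conc / sum(conc) * 100 + 1e-9, 2), tolerance = 1e-9)
})

test_that("compare_to_target reproduces the printed difference columns", {
  target <- c(Mutton = 40.38, Beef = 22.70, Rabbit = 22.40, Rat = 10.83,
              Pork = 2.54, Chicken = 1.08)
  res <- compute_proportions(h1_counts)
  cmp <- compare_to_target(res, target)
  row <- function(cat) cmp[cmp$category == cat, ]
  expect_identical(row("Beef")$diff_abs_pct, 16.98)
  expect_identical(row("Beef")$diff_rel_pct, 74.80)
  expect_identical(row("Pork")$diff_abs_pct, 0.50)
  expect_identical(row("Pork")$diff_rel_pct, 19.69)
  expect_identical(row("Mutton")$diff_abs_pct, 11.10)
  expect_identical(row("Mutton")$diff_rel_pct, 27.49)
  expect_identical(row("Rabbit")$diff_abs_pct, 5.20)
  expect_identical(row("Rabbit")$diff_rel_pct, 23.21)
  expect_identical(row("Rat")$diff_abs_pct, 0.85)
  expect_identical(row("Rat")$diff_rel_pct, 7.85)
  expect_identical(row("Chicken")$diff_abs_pct, 0.40)
  expect_identical(row("Chicken")$diff_rel_pct, 37.04)
  # zero-target rows have defined abs but undefined rel
  expect_identical(row("Venison")$diff_abs_pct, 0.16)
  expect_true(is.na(row("Venison")$diff_rel_pct))

  # equal target and measured
  eq <- compare_to_target(c(A = 10), c(A = 10))
  expect_identical(eq$diff_abs_pct, 0.00)
  expect_identical(eq$diff_rel_pct, 0.00)

  # categories only in the target appear with measured 0
  extra <- compare_to_target(c(A = 100), c(A = 90, B = 10))
  expect_identical(extra$measured_pct[extra$category == "B"], 0)
  expect_identical(extra$diff_abs_pct[extra$category == "B"], 10.00)
})

test_that("diff_rel is antitone in the target for fixed diff_abs", {
  d <- vapply(c(5, 10, 20, 40), function(t) {
    compare_to_target(stats::setNames(t + 2, "x"),
                      stats::setNames(t, "x"))$diff_rel_pct
  }, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("call_presence thresholds proportions", {
  res <- compute_proportions(h1_counts)
  calls <- call_presence(res, threshold_pct = 0.5)
  call_of <- stats::setNames(calls$call, calls$category)
  # the venison conserved-marker false positive (0.16%) falls below threshold
  expect_identical(unname(call_of["Venison"]), "-")
  expect_identical(unname(call_of["Chicken"]), "+")
  expect_identical(unname(call_of["Beef"]), "+")

  one <- compute_proportions(c(X = 5))
  expect_identical(call_presence(one, 0.5)$call, "+")

  # threshold 0: every category with at least one read is +
  calls0 <- call_presence(res, threshold_pct = 0)
  expect_true(all(calls0$call == "+"))

  # extra categories default to -
  calls2 <- call_presence(one, 0.5, categories = c("X", "Y"))
  expect_identical(calls2$call[calls2$category == "Y"], "-")
})

test_that("compute_concordance counts and rates follow the definitions", {
  mk <- function(calls) {
    data.frame(sample_id = paste0("s", seq_along(calls)), category = "Pork",
               call = calls, stringsAsFactors = FALSE)
  }
  same <- mk(c("+", "+", "-"))
  conc <- compute_concordance(same, same)
  expect_identical(conc$tpr, 100.00)
  expect_identical(conc$fpr, 0.00)
  expect_identical(conc$fnr, 0.00)

  # 8 TP, 1 FN, 1 FP, 0 TN
  test <- mk(c(rep("+", 8), "-", "+"))
  ref <- mk(c(rep("+", 8), "+", "-"))
  conc <- compute_concordance(test, ref)
  expect_identical(c(conc$tp, conc$fp, conc$fn, conc$tn), c(8L, 1L, 1L, 0L))
  expect_identical(conc$tpr, 88.89)
  expect_identical(conc$fnr, 11.11)
  expect_identical(conc$fpr, 100.00)
  expect_identical(conc$tp + conc$fp + conc$fn + conc$tn, 10L)

  # degenerate all-negative: undefined rates are NA by convention
  neg <- mk(c("-", "-"))
  conc <- compute_concordance(neg, neg)
  expect_identical(c(conc$tp, conc$fp, conc$fn), c(0L, 0L, 0L))
  expect_true(is.na(conc$tpr))
  expect_identical(conc$fpr, 0.00)

  # mismatched universes error
  expect_error(compute_concordance(mk(c("+", "-")), mk(c("+", "-", "-"))),
               "universes")
})

test_that("mean_depth is plain fold coverage", {
  expect_identical(mean_depth(10 * 100, 1000), 1.0)
  expect_identical(mean_depth(0, 500), 0)
  expect_error(mean_depth(10, 0), "positive")
  set.seed(3)
  b <- sample(1e8, 3)
  l <- sample(1e5, 3)
  expect_identical(mean_depth(b, l), b / l)
})

test_that("write_result_csv round-trips and writes header-only files", {
  path <- withr::local_tempfile(fileext = ".csv")
  res <- compute_proportions(h1_counts)
  write_result_csv(res, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 10L)
  expect_equal(back$proportion_pct, res$proportion_pct)
  expect_identical(back$category, res$category)

  empty <- compute_proportions(integer(0))
  write_result_csv(empty, path)
  expect_identical(length(readLines(path)), 1L)

  conc <- compute_concordance(
    data.frame(sample_id = "s", category = "Pork", call = "+"),
    data.frame(sample_id = "s", category = "Pork", call = "+"))
  write_result_csv(conc, path)
  expect_equal(utils::read.csv(path)$tpr, 100)
})
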