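test_that("summed intensity adds the group's peptides in one sample", {
  obs <- rbind(make_obs("s1", "skin", c("P1", "P2"), c(3e5, 2e5)),
               make_obs("s2", "skin", "P1", 7e5),
               make_obs("s1", "skin", "P9", 1e6))  # not in support
  expect_equal(summed_intensity(obs, c("P1", "P2"), "s1"), 5e5)
  expect_equal(summed_intensity(obs, c("P1", "P2"), "s3"), 0)
  # permutation invariance
  perm <- obs[sample(nrow(obs)), ]
  expect_equal(summed_intensity(perm, c("P1", "P2"), "s1"), 5e5)
  # region restriction
  obs$gel_region <- c(1, 2, 1, 1)
  expect_equal(summed_intensity(obs, c("P1", "P2"), "s1", region = 1), 3e5)
})

test_that("fold differences substitute the detection limit for zeros", {
  eq <- fold_difference(c(5, 5, 5), c(5, 5), lod = 1)
  expect_equal(eq$ratio, 1.0)
  expect_identical(eq$bound, "point")
  # liver all censored: bound from below, rendered with '>'
  lb <- fold_difference(rep(6.7, 10), rep(0, 5), lod = 1)
  expect_equal(lb$ratio, 6.7)
  expect_identical(lb$bound, "lower-bound")
  expect_identical(render_fold(lb$ratio, lb$bound), ">6.7")
  ub <- fold_difference(rep(0, 10), rep(5, 5), lod = 1)
  expect_identical(ub$bound, "upper-bound")
  expect_match(render_fold(ub$ratio, ub$bound), "^<")
  # partial censoring is a point estimate with substitution
  pt <- fold_difference(c(0, 4), c(2, 2), lod = 2)
  expect_equal(pt$ratio, (2 + 4) / 2 / 2)
  expect_identical(pt$bound, "point")
  expect_error(fold_difference(1, 1, lod = 0), "configuration error")
  expect_error(fold_difference(numeric(0), 1, lod = 1), "sample")
})

test_that("fold difference with substitution is scale-equivariant", {
  set.seed(31)
  for (rep in 1:10) {
    skin <- round(runif(10, 0, 10)) * 1e5
    liver <- round(runif(5, 0, 10)) * 1e5
    if (all(skin == 0) && all(liver == 0)) next
    lod <- 5e4
    base <- fold_difference(skin, liver, lod)
    for (c in c(0.01, 3, 1e4)) {
      scaled <- fold_difference(skin * c, liver * c, lod * c)
      expect_equal(scaled$ratio, base$ratio)
      expect_identical(scaled$bound, base$bound)
    }
  }
})

test_that("exact Mann-Whitney matches full enumeration for all n <= 6 vs 6", {
  set.seed(32)
  for (n1 in 1:6) {
    for (n2 in 1:6) {
      for (rep in 1:2) {
        # draws with deliberate ties
        x <- sample(1:4, n1, replace = TRUE)
        y <- sample(1:4, n2, replace = TRUE)
        expect_equal(mann_whitney(x, y)$p.value, oracle_mann_whitney(x, y),
                     info = sprintf("n1=%d n2=%d", n1, n2))
      }
    }
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test when tie-free", {
  set.seed(33)
  for (rep in 1:10) {
    x <- sample(1:100, 8)
    y <- sample(101:200, 5)  # disjoint ranges guarantee no ties
    expect_equal(mann_whitney(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("complete separation at 10 vs 5 reaches the exact floor", {
  p <- mann_whitney(1:10, 11:15)$p.value
  expect_equal(p, 2 / 3003)
  expect_identical(p_display(p), "<0.001")
  # the floor is the minimum: any other arrangement is larger
  set.seed(34)
  x <- rnorm(10); y <- rnorm(5)
  expect_gte(mann_whitney(x, y)$p.value, 2 / 3003)
})

test_that("Mann-Whitney is symmetric and handles identical samples", {
  set.seed(35)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(4)
    expect_equal(mann_whitney(x, y)$p.value, mann_whitney(y, x)$p.value)
  }
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2))$p.value, 1.0)
  expect_equal(mann_whitney(1:5, 1:5)$p.value, 1.0)
})

test_that("large samples use a tie-corrected normal approximation", {
  set.seed(36)
  x <- rnorm(20); y <- rnorm(15) + 1.5
  res <- mann_whitney(x, y)
  expect_false(res$exact)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(res$p.value, ref, tolerance = 1e-8)
})

test_that("p-value display follows the table convention", {
  expect_identical(p_display(0.0005), "<0.001")
  expect_identical(p_display(0.31), "0.31")
  expect_identical(p_display(0.0012), "0.0012")
  expect_identical(p_display(1), "1")
  expect_error(p_display(0))
})

test_that("peptide-count profiles count distinct sequences per column", {
  support <- data.frame(group_id = c("G001", "G001", "G001", "G002"),
                        peptide = c("P1", "P2", "P3", "Q1"),
                        stringsAsFactors = FALSE)
  model_a <- make_obs("m1", "model", c("P1", "P2", "P3", "P1"),
                      c(1, 1, 1, 1))
  model_b <- make_obs("m2", "model", c("P1", "Q1"), c(1, 1))
  prof <- peptide_count_profile(support,
                                list(A = model_a, B = model_b))
  expect_identical(prof["G001", "A"], 3L)
  expect_identical(prof["G001", "B"], 1L)
  expect_identical(prof["G002", "B"], 1L)
  # identical columns have rank correlation 1
  both <- peptide_count_profile(support,
                                list(A = model_a, B = model_a),
                                rank_cor = TRUE)
  expect_equal(both$rank_correlation["A", "B"], 1.0)
})

test_that("a decaying protein shows a non-increasing timecourse profile", {
  support <- data.frame(group_id = "G001",
                        peptide = sprintf("P%d", 1:4),
                        stringsAsFactors = FALSE)
  days <- list(
    day0 = make_obs("d0", "model", sprintf("P%d", 1:4), rep(1, 4)),
    day1 = make_obs("d1", "model", sprintf("P%d", 1:3), rep(1, 3)),
    day2 = make_obs("d2", "model", sprintf("P%d", 1:1), 1),
    day3 = make_obs("d3", "model", "ZZZ", 1))  # undetectable by day 3
  prof <- peptide_count_profile(support, days)
  expect_true(all(diff(prof["G001", ]) <= 0))
  expect_identical(prof["G001", "day3"], 0L)
})
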