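test_that("CES-D-10 scoring sums items with positive items reversed", {
  # all-zero items: the two reversed items become 3 each
  expect_identical(score_cesd10(rep(0L, 10)), 6L)
  # all-3 items: eight contribute 3, the two reversed contribute 0
  expect_identical(score_cesd10(rep(3L, 10)), 24L)
  # no reversed items: plain sum
  expect_identical(score_cesd10(rep(3L, 10), reverse_positions = integer()), 30L)
  # worked example
  expect_identical(score_cesd10(c(1, 0, 2, 0, 3, 0, 1, 3, 0, 0)), 4L)
  # matrix input scores row-wise
  m <- rbind(rep(0L, 10), rep(3L, 10))
  expect_identical(score_cesd10(m), c(6L, 24L))
})

test_that("the attainable score range is exactly 0..30", {
  # brute-force oracle over random item vectors plus the two extremes
  set.seed(101)
  vecs <- matrix(sample(0:3, 500 * 10, replace = TRUE), ncol = 10)
  best <- rep(3L, 10); best[c(5, 8)] <- 0L
  worst <- rep(0L, 10); worst[c(5, 8)] <- 3L
  scores <- score_cesd10(rbind(vecs, best, worst))
  expect_true(all(scores >= 0 & scores <= 30))
  expect_identical(max(scores), 30L)
  expect_identical(min(scores), 0L)
})

test_that("scoring is monotone in the expected direction per item", {
  set.seed(7)
  for (rep in 1:20) {
    items <- sample(0:3, 10, replace = TRUE)
    pos <- sample(10, 1)
    bumped <- items
    bumped[pos] <- min(3, items[pos] + 1)
    delta <- score_cesd10(bumped) - score_cesd10(items)
    if (pos %in% c(5, 8)) expect_lte(delta, 0) else expect_gte(delta, 0)
  }
})

test_that("scoring validates its inputs", {
  expect_error(score_cesd10(rep(1L, 9)), "exactly 10")
  expect_error(score_cesd10(c(rep(1L, 9), 4L)), "position 10")
  expect_error(score_cesd10(rep(1L, 10), reverse_positions = 11), "1..10")
  expect_true(is.na(score_cesd10(c(NA, rep(1L, 9)))))
})

test_that("depression classification thresholds at the cutoff", {
  expect_false(classify_depression(7, 8))
  expect_true(classify_depression(8, 8))
  expect_false(classify_depression(9, 10))
  expect_true(classify_depression(10, 10))
  expect_error(classify_depression(31, 8), "0..30")
  expect_warning(classify_depression(5, 9), "non-standard")
  # stricter cutoff gives a subset of cases for any score vector
  scores <- 0:30
  expect_true(all(which(classify_depression(scores, 10)) %in%
                    which(classify_depression(scores, 8))))
})

test_that("alcohol classification follows the guideline rules", {
  expect_equal(as.character(classify_alcohol(0, 0, FALSE, "female")), "abstainer")
  expect_equal(as.character(classify_alcohol(2, 1, FALSE, "female")), "moderate")
  expect_equal(as.character(classify_alcohol(3, 3, FALSE, "female")), "above_guideline")
  expect_equal(as.character(classify_alcohol(3, 3, FALSE, "male")), "moderate")
  # heavy episodic drinking overrides frequency
  expect_equal(as.character(classify_alcohol(0.5, 1, TRUE, "male")), "above_guideline")
  # exact equality at the weekly limit stays moderate (partition rule)
  expect_equal(as.character(classify_alcohol(7, 1, FALSE, "female")), "moderate")
  expect_equal(as.character(classify_alcohol(7, 2, FALSE, "male")), "moderate")
  # directly supplied weekly volume overrides the product
  expect_equal(as.character(classify_alcohol(2, 1, FALSE, "female",
                                             weekly_drinks = 10)),
               "above_guideline")
})

test_that("alcohol classification is a partition over a dense input grid", {
  grid <- expand.grid(days = c(0, 0.2, 0.5, 0.99, 1, 2, 3.5, 5, 7),
                      drinks = c(0, 0.5, 1, 2, 3, 5, 8),
                      heavy = c(FALSE, TRUE),
                      sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  # remove inconsistent combinations that the classifier rejects by design
  grid <- grid[!((grid$days == 0) != (grid$drinks == 0)) &
                 !(grid$heavy & grid$days == 0 & grid$drinks == 0), ]
  out <- classify_alcohol(grid$days, grid$drinks, grid$heavy, grid$sex)
  expect_false(anyNA(out))                   # total function
  expect_true(all(out %in% alcohol_levels))  # exactly one category each
})

test_that("inconsistent or invalid consumption fields are rejected", {
  expect_error(classify_alcohol(0, 2, FALSE, "male"), "inconsistent")
  expect_error(classify_alcohol(2, 0, FALSE, "male"), "inconsistent")
  expect_error(classify_alcohol(0, 0, TRUE, "male"), "inconsistent")
  expect_error(classify_alcohol(-1, 1, FALSE, "male"), "days_per_week")
  expect_error(classify_alcohol(1, -2, FALSE, "male"), "drinks_per_day")
  expect_error(classify_alcohol(1, 1, FALSE, "other"), "coded")
})
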