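test_that("min-max scaling maps features onto [0, 1]", {
  tab <- tibble::tibble(subject_id = c("a", "b", "c"), label = "NSR",
                        f1 = c(2, 4, 6), f2 = c(5, 5, 5), f3 = c(-1, 0, 3))
  sc <- minmax_scale(tab)
  expect_equal(sc$f1, c(0, 0.5, 1))
  expect_equal(sc$f2, c(0, 0, 0)) # constant-column policy
  expect_equal(range(sc$f3), c(0, 1))
  expect_identical(minmax_scale(sc), sc) # idempotence
  expect_equal(sc$subject_id, tab$subject_id)
})

test_that("KNN prediction follows the nearest labelled neighbours", {
  train <- matrix(c(0, 1, 10), ncol = 1)
  labs <- c("A", "A", "B")
  expect_equal(knn_predict(train, labs, 0.4, k = 3), "A")
  expect_equal(knn_predict(train, labs, matrix(c(0, 10), ncol = 1), k = 1),
               c("A", "B"))
  expect_error(knn_predict(train, labs, 0.4, k = 2), "odd")
  expect_error(knn_predict(train, labs, 0.4, k = 5), "exceeds")
  expect_error(knn_predict(train[0, , drop = FALSE], character(0), 0.4),
               "empty")
})

test_that("KNN agrees with an exhaustive distance-sort oracle", {
  set.seed(99)
  brute_knn <- function(train, labs, q, k) {
    d <- sqrt(colSums((t(train) - q)^2))
    nn <- sort.int(d, index.return = TRUE)$ix[1:k]
    tt <- table(labs[nn])
    names(tt)[which.max(tt)]
  }
  for (i in 1:200) {
    n <- sample(5:30, 1)
    p <- sample(1:6, 1)
    k <- sample(c(1, 3, 5), 1)
    train <- matrix(rnorm(n * p), n, p)
    labs <- sample(c("NSR", "CHF"), n, replace = TRUE)
    q <- rnorm(p)
    expect_identical(knn_predict(train, labs, q, k = k),
                     brute_knn(train, labs, q, k))
  }
})

test_that("fold plans partition the data with near-equal sizes", {
  f <- make_folds(69, 23, seed = 3)
  expect_length(f, 69)
  expect_equal(as.numeric(table(f)), rep(3, 23))
  expect_equal(sort(unique(f)), 1:23)
  loo <- make_folds(10, 10, seed = 1)
  expect_equal(sort(loo), 1:10)
  f2 <- make_folds(70, 23, seed = 3)
  expect_true(all(abs(table(f2) - 70 / 23) < 1))
  expect_identical(make_folds(69, 23, seed = 5), make_folds(69, 23, seed = 5))
  expect_error(make_folds(10, 23), "exceed")
})

test_that("confusion metrics implement the standard definitions", {
  perfect <- confusion_metrics(29, 40, 0, 0)
  expect_equal(c(perfect$Ac, perfect$Se, perfect$Sp), c(100, 100, 100))
  expect_equal(perfect$theta, 0)
  blind <- confusion_metrics(0, 40, 0, 29)
  expect_equal(blind$Ac, 100 * 40 / 69, tolerance = 1e-10)
  expect_equal(blind$Se, 0)
  near <- confusion_metrics(20, 45, 2, 2)
  expect_equal(near$Ac, 100 * 65 / 69, tolerance = 1e-10)
  # undefined ratios are missing, not zero
  no_pos <- confusion_metrics(0, 40, 0, 0)
  expect_true(is.na(no_pos$Se))
  expect_error(confusion_metrics(0, 0, 0, 0), "invalid")
})

test_that("cross-validation pools one prediction per sample", {
  tab <- toy_feature_table(n_nsr = 40, n_chf = 29, n_features = 16,
                           n_informative = 16, effect = 8, seed = 2) |>
    minmax_scale()
  folds <- make_folds(69, 23, seed = 2)
  cv <- cross_validate(tab, folds = folds, k = 5)
  expect_equal(cv$TP + cv$TN + cv$FP + cv$FN, 69)
  expect_equal(cv$theta, 1 - cv$Ac / 100, tolerance = 1e-12)
  # a strongly separated table is classified perfectly
  expect_equal(cv$Ac, 100)
  expect_equal(cv$Se, 100)
  expect_equal(cv$Sp, 100)
  expect_error(cross_validate(tab, mask = rep(FALSE, 16)), "at least one")
  expect_error(cross_validate(tab, mask = c(1, 0)), "length")
})

test_that("permuted labels fall to chance-level accuracy", {
  tab <- toy_feature_table(effect = 8, seed = 4) |> minmax_scale()
  set.seed(5)
  acc <- replicate(20, {
    perm <- tab
    perm$label <- sample(perm$label)
    cross_validate(perm, folds = 23, seed = 1)$Ac
  })
  expect_gt(mean(acc), 40)
  expect_lt(mean(acc), 75)
})

test_that("fold-wise scaling variant stays self-contained", {
  tab <- toy_feature_table(effect = 8, seed = 6)
  cv <- cross_validate(tab, folds = 23, seed = 1, scale_in_fold = TRUE)
  expect_equal(cv$TP + cv$TN + cv$FP + cv$FN, 69)
  expect_gte(cv$Ac, 90)
  expect_s3_class(glance(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 8)
})
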