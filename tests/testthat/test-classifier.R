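test_that("gini impurity matches hand-computed values", {
  expect_equal(gini(c(10, 0)), 0)
  expect_equal(gini(c(5, 5)), 0.5)
  expect_equal(gini(c(2, 1)), 4 / 9)
  expect_error(gini(c(0, 0)), "positive total")
  expect_error(gini(c(-1, 2)), "nonnegative")
})

test_that("best_split finds the hand-enumerated optimum", {
  X <- matrix(c(1, 2, 8, 9), ncol = 1)
  y <- c("non_aggressive", "non_aggressive", "aggressive", "aggressive")
  sp <- best_split(X, y)
  expect_equal(sp$feature_index, 1)
  expect_equal(sp$threshold, 5)          # midpoint of 2 and 8
  expect_equal(sp$impurity_decrease, 0.5)

  expect_null(best_split(X, rep("aggressive", 4)))      # pure node
  expect_null(best_split(matrix(1, 4, 2), y))           # constant features
})

test_that("best_split agrees exactly with brute force on 200 random instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    p <- sample(1:5, 1)
    # duplicate values on a coarse grid exercise midpoint/tie handling
    X <- matrix(sample(seq(0, 5, by = 0.5), n * p, replace = TRUE), n, p)
    y <- sample(c("aggressive", "non_aggressive"), n, replace = TRUE)
    got <- best_split(X, y)
    want <- brute_force_split(X, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$feature_index, want$feature_index)
      expect_identical(got$threshold, want$threshold)
      expect_equal(got$impurity_decrease, want$impurity_decrease,
                   tolerance = 1e-14)
    }
  }
})

test_that("fitted trees respect depth, purity, and counts invariants", {
  set.seed(7)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- ifelse(X[, 2] + 0.5 * X[, 4] > 0, "aggressive", "non_aggressive")
  tree <- fit_tree(X, y, max_depth = 2)

  depth_of <- function(node) {
    if (node$leaf) 0 else 1 + max(depth_of(node$left), depth_of(node$right))
  }
  check_counts <- function(node) {
    if (node$leaf) return(invisible())
    expect_equal(node$counts, node$left$counts + node$right$counts)
    check_counts(node$left)
    check_counts(node$right)
  }
  expect_lte(depth_of(tree$root), 2)
  check_counts(tree$root)

  # training accuracy at least the majority baseline
  acc <- mean(predict(tree, X) == y)
  expect_gte(acc, max(table(y)) / length(y))

  # pure input -> single leaf
  pure <- fit_tree(X[1:10, ], rep("aggressive", 10))
  expect_true(pure$root$leaf)
  expect_equal(unique(predict(pure, X)), "aggressive")

  # determinism: bit-identical refits
  expect_identical(tree, fit_tree(X, y, max_depth = 2))
  expect_error(fit_tree(X[0, , drop = FALSE], character(0)), "empty")
})

test_that("prediction routes rows as a hand-traced table", {
  X <- matrix(c(1, 2, 8, 9), ncol = 1)
  y <- c("non_aggressive", "non_aggressive", "aggressive", "aggressive")
  tree <- fit_tree(X, y, max_depth = 1)
  # threshold 5: 4.9 goes left (non-aggressive), 5.1 right (aggressive)
  expect_equal(predict(tree, matrix(c(4.9, 5, 5.1, -3), ncol = 1)),
               c("non_aggressive", "non_aggressive", "aggressive",
                 "non_aggressive"))
  expect_equal(predict(tree, X), y)
  expect_error(predict(tree, matrix(0, 1, 3)), "features")
})

test_that("tree agrees with rpart on a cleanly separable problem", {
  skip_if_not_installed("rpart")
  set.seed(31)
  X <- matrix(rnorm(300 * 3), 300, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  X[, 1] <- X[, 1] + ifelse(seq_len(300) <= 120, 4, 0)
  y <- rep(c("aggressive", "non_aggressive"), c(120, 180))
  ours <- fit_tree(X, y, max_depth = 2)
  rp <- rpart::rpart(factor(y) ~ ., data = as.data.frame(X),
                     method = "class",
                     control = rpart::rpart.control(maxdepth = 2,
                                                    minsplit = 2, cp = 0))
  expect_equal(predict(ours, X),
               as.character(predict(rp, as.data.frame(X), type = "class")))
  # both pick the informative feature at the root
  expect_equal(ours$root$feature_index, 1)
})

test_that("stratified splits preserve proportions and determinism", {
  set.seed(5)
  X <- matrix(rnorm(1000 * 2), 1000, 2)
  y <- rep(c("aggressive", "non_aggressive"), c(300, 700))
  sp <- split_data(X, y, train_frac = 0.7, seed = 9)
  expect_equal(length(sp$train$y), 700)
  expect_equal(length(sp$test$y), 300)
  expect_equal(sum(sp$train$y == "aggressive"), 210)  # 0.7 * 300
  sp2 <- split_data(X, y, train_frac = 0.7, seed = 9)
  expect_identical(sp$train$idx, sp2$train$idx)
  expect_false(identical(sp$train$idx,
                         split_data(X, y, seed = 10)$train$idx))
  expect_error(split_data(X, y, train_frac = 1.2), "train_frac")

  # ragged class sizes stay within one row of exact proportions
  y2 <- rep(c("aggressive", "non_aggressive"), c(333, 667))
  sp3 <- split_data(X, y2, train_frac = 0.7, seed = 1)
  expect_equal(length(sp3$train$y), 700)
  expect_lte(abs(sum(sp3$train$y == "aggressive") - 0.7 * 333), 1)

  # grouped split keeps whole groups on one side
  gid <- rep(sprintf("p%d", 1:10), each = 100)
  spg <- split_data(X, y, seed = 3, group_ids = gid)
  expect_length(intersect(unique(gid[spg$train$idx]),
                          unique(gid[spg$test$idx])), 0)
})

test_that("feature importance attributes Gini decrease to split features", {
  X <- matrix(c(1, 2, 8, 9), ncol = 1)
  y <- c("non_aggressive", "non_aggressive", "aggressive", "aggressive")
  one <- fit_tree(X, y)
  imp1 <- feature_importance(one)
  expect_equal(unname(imp1), 1)

  set.seed(11)
  X2 <- matrix(rnorm(400 * 3), 400, 3)
  y2 <- ifelse(X2[, 1] > 0 & X2[, 3] > 0, "aggressive", "non_aggressive")
  multi <- fit_tree(X2, y2, max_depth = 2)
  imp2 <- feature_importance(multi)
  expect_equal(sum(imp2), 1)
  expect_true(all(imp2 >= 0))

  leaf_tree <- fit_tree(X2[1:5, ], rep("aggressive", 5))
  imp0 <- feature_importance(leaf_tree)
  expect_true(all(imp0 == 0))
  expect_true(attr(imp0, "no_splits"))
})

test_that("tree JSON serialisation round-trips predictions", {
  set.seed(13)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- ifelse(X[, 2] > 0.2, "aggressive", "non_aggressive")
  tree <- fit_tree(X, y, max_depth = 2)
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, path)
  back <- tree_from_json(path)
  expect_equal(predict(back, X), predict(tree, X))
  expect_equal(back$max_depth, 2)
})
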