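test_that("one-vs-one decomposition enumerates all class pairs", {
  set.seed(1)
  mk <- function(C, per = 4L) {
    make_ds(matrix(runif(C * per * 2L), C * per), rep(seq_len(C), each = per))
  }
  expect_length(make_ovo_tasks(mk(3L)), 3L)
  expect_length(make_ovo_tasks(mk(2L)), 1L)
  expect_length(make_ovo_tasks(mk(5L)), 10L)
  tasks <- make_ovo_tasks(mk(3L))
  for (tk in tasks) expect_length(tk$idx, 8L)
})

test_that("tasks for absent classes are skipped with a warning", {
  full <- make_ds(matrix(runif(18), 9L), rep(1:3, 3L),
                  class_names = c("A", "B", "C"))
  ds <- edst:::subset_dataset(full, which(full$labels != 3L))
  expect_warning(tasks <- make_ovo_tasks(ds), "absent")
  expect_length(tasks, 1L)
  # DST on such a subset carries a single tree
  expect_warning(d <- dst_fit(ds), "absent")
  expect_length(d$trees, 1L)
})

test_that("a separable task reduces to a single root stump", {
  X <- cbind(rep(c(1, 2), each = 5L), rep(c(3, 4), 5L))
  y <- rep(c(1L, 2L), each = 5L)
  tr <- grow_stump_tree(X, y, theta = 1L)
  expect_equal(tr$depth, 1L)
  expect_equal(tr$root$feature, 1L)
  lp <- edst:::tree_leaf_probs(tr, X)
  expect_equal(apply(lp, 1L, which.max), y)
})

test_that("theta larger than the task makes a single leaf", {
  X <- matrix(runif(20), 10L)
  y <- rep(c(1L, 2L), 5L)
  tr <- grow_stump_tree(X, y, theta = 50L)
  expect_equal(tr$depth, 0L)
  expect_equal(tr$n_leaves, 1L)
  expect_equal(edst:::tree_leaf_probs(tr, X)[1L, ], c(0.5, 0.5))
})

test_that("an XOR-style task needs exactly two stump layers", {
  # 4 points on a 2x2 grid, labels A,B,B,A: no single feature separates,
  # two do. Replicated so interval majorities are well defined.
  # uneven replication (5/4) keeps per-value majorities unambiguous
  grid <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  reps <- c(5L, 4L, 5L, 4L)
  X <- grid[rep(1:4, times = reps), ]
  y <- rep(c(1L, 2L, 2L, 1L), times = reps)
  tr <- grow_stump_tree(X, y, theta = 1L, max_depth = 10L)
  expect_equal(tr$depth, 2L)
  lp <- edst:::tree_leaf_probs(tr, X)
  expect_equal(apply(lp, 1L, which.max), y)   # zero training error
  # exhaustive check: no depth-1 tree (either single feature) separates
  for (j in 1:2) {
    s <- build_stump(X[, j], y, 2L, min_interval = 1L)
    grp <- stump_group(s, X[, j])
    expect_gt(sum(s$majority[grp] != y), 0L)
  }
})

test_that("tiny or pure tasks yield leaves with sensible distributions", {
  tr0 <- grow_stump_tree(matrix(numeric(0), 0L, 2L), integer(0L), theta = 1L)
  expect_equal(tr0$root$prob, c(0.5, 0.5))
  tr1 <- grow_stump_tree(matrix(1, 1L, 2L), 1L, theta = 1L)
  expect_equal(tr1$root$prob, c(0.5, 0.5))   # single sample: uniform
  trp <- grow_stump_tree(matrix(runif(6), 3L), rep(2L, 3L), theta = 1L)
  expect_equal(trp$root$prob, c(0, 1))
})

test_that("no feature repeats along a root-to-leaf path", {
  set.seed(21)
  X <- matrix(runif(300), 100L, 3L)
  y <- 1L + as.integer(X[, 1L] + X[, 2L] > 1)
  tr <- grow_stump_tree(X, y, theta = 5L, max_depth = 10L)
  check <- function(node, seen) {
    if (node$type == "leaf") return(invisible())
    expect_false(node$feature %in% seen)
    for (ch in node$children) check(ch, c(seen, node$feature))
  }
  check(tr$root, integer(0L))
  expect_lte(tr$depth, 3L)   # path length <= number of features
})

test_that("a DST holds one tree per class pair present", {
  set.seed(2)
  ds <- make_ds(matrix(runif(60), 30L), rep(1:3, each = 10L))
  d <- dst_fit(ds)
  expect_length(d$trees, 3L)
  expect_equal(ncol(d$pairs), 3L)
  # refit determinism
  d2 <- dst_fit(ds)
  expect_identical(d, d2)
})

test_that("soft voting accumulates pairwise leaf mass and normalizes", {
  cn <- c("A", "B", "C")
  dst <- fake_dst(
    trees = list(fake_leaf_tree(c(0.6, 0.4)),   # A vs B
                 fake_leaf_tree(c(0.5, 0.5)),   # A vs C
                 fake_leaf_tree(c(0.2, 0.8))),  # B vs C
    pairs = matrix(c(1L, 2L, 1L, 3L, 2L, 3L), 2L), class_names = cn)
  pr <- dst_predict_proba(dst, matrix(0, 1L, 2L))
  expect_equal(pr[1L, ], c(1.1, 0.6, 1.3) / 3)
  # two-class single tree passes its leaf through
  dst2 <- fake_dst(list(fake_leaf_tree(c(0.9, 0.1))),
                   matrix(c(1L, 2L), 2L), c("A", "B"))
  expect_equal(dst_predict_proba(dst2, matrix(0, 1L, 1L))[1L, ], c(0.9, 0.1))
  # unanimous confidence concentrates all mass
  dst3 <- fake_dst(
    trees = list(fake_leaf_tree(c(0, 1)),       # A vs B -> B
                 fake_leaf_tree(c(1, 0)),       # B vs C -> B
                 fake_leaf_tree(c(0.5, 0.5))),  # A vs C
    pairs = matrix(c(1L, 2L, 2L, 3L, 1L, 3L), 2L), class_names = cn)
  expect_equal(dst_predict_proba(dst3, matrix(0, 1L, 1L))[1L, ],
               c(0.5, 2, 0.5) / 3)
})

test_that("probability rows are stochastic on random inputs", {
  set.seed(3)
  ds <- make_ds(matrix(runif(90), 30L), rep(1:3, 10L))
  d <- dst_fit(ds)
  pr <- dst_predict_proba(d, matrix(runif(60), 20L))
  expect_equal(rowSums(pr), rep(1, 20L))
  expect_true(all(pr >= 0))
})

test_that("a threshold-labeled task recovers its single stump", {
  set.seed(8)
  X <- matrix(runif(200), 100L, 2L)
  y <- 1L + as.integer(X[, 2L] > 0.55)
  tr <- grow_stump_tree(X, y, theta = 10L)
  expect_equal(tr$root$feature, 2L)
  expect_lte(tr$depth, 2L)   # one boundary bin may need a second layer
})
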