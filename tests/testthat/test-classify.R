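small_grid <- function() {
  svm_grid(degree = c(1, 2), cost = c(1, 10), gamma = 0.1)
}

test_that("information gain matches the stated cases", {
  # feature exactly encodes balanced labels
  lab <- rep(c(0, 1), each = 20)
  expect_equal(information_gain(c(rnorm(20), rnorm(20) + 100), lab), 1)
  expect_equal(information_gain(c(1, 2, 9, 10), c(0, 0, 1, 1),
                                n_bins = 2), 1)
  set.seed(15)
  expect_lte(information_gain(rnorm(1000), rep(c(0, 1), 500)), 0.05)
  expect_equal(information_gain(rep(1, 50), rep(c(0, 1), 25)), 0)
  expect_error(information_gain(rnorm(10), rep(1, 10)), "constant")
})

test_that("select_top_k ranks by gain with lexicographic ties", {
  set.seed(16)
  n <- 80
  lab <- rep(c("x", "y"), each = n / 2)
  signal <- c(rnorm(n / 2), rnorm(n / 2) + 5)
  vals <- cbind(noise1 = rnorm(n), signal = signal, noise2 = rnorm(n))
  tab <- feature_table(vals, lab)
  expect_identical(select_top_k(tab, 3)$feature_names[1], "signal")
  expect_identical(sort(select_top_k(tab, 3)$feature_names),
                   sort(colnames(vals)))  # k = p is the identity set
  # duplicated top feature: lexicographically first name wins
  vals2 <- cbind(bdup = signal, adup = signal, noise = rnorm(n))
  t2 <- select_top_k(feature_table(vals2, lab), 1)
  expect_identical(t2$feature_names, "adup")
})

test_that("feature_table drops non-finite rows and keeps both classes", {
  v <- cbind(a = c(1, NA, 3, 4), b = c(1, 2, Inf, 4))
  expect_message(tab <- feature_table(v, c("u", "u", "v", "v")),
                 "dropping 2")
  expect_equal(nrow(tab$values), 2)
  expect_error(suppressMessages(
    feature_table(cbind(a = c(NA, NA, 1)), c("u", "u", "v"))), "empty")
})

test_that("confusion metrics match definitions and the oracle", {
  # TP=8 FN=2 TN=8 FP=2 -> all macro metrics 0.8
  truth <- factor(rep(c("pos", "neg"), each = 10),
                  levels = c("pos", "neg"))
  pred <- factor(c(rep("pos", 8), rep("neg", 2),
                   rep("pos", 2), rep("neg", 8)),
                 levels = c("pos", "neg"))
  m <- structmark:::confusion_metrics(pred, truth)
  expect_equal(unname(m), rep(0.8, 6))
  # random confusion tables against the independent oracle
  set.seed(17)
  for (rep in 1:10) {
    cnt <- sample(1:10, 4, replace = TRUE)  # tp, fn, fp, tn for class A
    truth <- factor(c(rep("A", cnt[1] + cnt[2]),
                      rep("B", cnt[3] + cnt[4])), levels = c("A", "B"))
    pred <- factor(c(rep("A", cnt[1]), rep("B", cnt[2]),
                     rep("A", cnt[3]), rep("B", cnt[4])),
                   levels = c("A", "B"))
    m <- structmark:::confusion_metrics(pred, truth)
    o <- oracle_macro_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m, o, tolerance = 1e-12)
    # macro sensitivity == macro specificity, structurally
    expect_identical(m[["sensitivity"]], m[["specificity"]])
    expect_identical(m[["sensitivity"]], m[["recall"]])
  }
})

test_that("SVM separates linearly separable and ring data", {
  set.seed(18)
  x <- rbind(matrix(rnorm(60), 30, 2),
             matrix(rnorm(60) + 7, 30, 2))
  y <- rep(c("a", "b"), each = 30)
  fit <- svm_train(x, y, cost = 10, gamma = 0.5, degree = 1,
                   max_iter = 300)
  expect_equal(mean(predict(fit, x) == y), 1)
  # concentric classes need the nonlinear kernel
  r <- c(runif(40, 0, 0.8), runif(40, 1.6, 2.4))
  th <- runif(80, 0, 2 * pi)
  x2 <- cbind(r * cos(th), r * sin(th))
  y2 <- rep(c("in", "out"), each = 40)
  fit2 <- svm_train(x2, y2, cost = 10, gamma = 1, degree = 2)
  expect_gte(mean(predict(fit2, x2) == y2), 0.95)
})

test_that("cross_validated_svm: separable data scores perfectly", {
  set.seed(20)
  v <- rbind(matrix(rnorm(100), 50, 2),
             matrix(rnorm(100) + 6, 50, 2))
  tab <- feature_table(v, rep(c("a", "b"), each = 50))
  rep1 <- cross_validated_svm(tab, grid = small_grid(), folds = 5,
                              seed = 1)
  expect_equal(rep1$mean[["accuracy"]], 1)
  expect_equal(rep1$se[["accuracy"]], 0)
  expect_true(all(rep1$mean >= 0 & rep1$mean <= 1))
  expect_equal(rep1$mean[["accuracy"]],
               mean(rep1$per_fold$accuracy), tolerance = 1e-12)
  # deterministic given the seed
  rep2 <- cross_validated_svm(tab, grid = small_grid(), folds = 5,
                              seed = 1)
  expect_identical(rep1$per_fold, rep2$per_fold)
})

test_that("label-permuted data stays at chance", {
  set.seed(21)
  accs <- vapply(1:3, function(s) {
    set.seed(s)
    v <- matrix(rnorm(100 * 4), 100, 4)
    tab <- feature_table(v, sample(rep(c("a", "b"), 50)))
    cross_validated_svm(tab, grid = small_grid(), folds = 5,
                        seed = s)$mean[["accuracy"]]
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("in-fold selection avoids the leakage that whole-data selection shows", {
  # many noise features, random labels: selecting features on ALL rows
  # before CV inflates apparent accuracy; in-fold selection must not
  run <- function(leak, s) {
    set.seed(s)
    v <- matrix(rnorm(40 * 400), 40, 400,
                dimnames = list(NULL, sprintf("f%04d", 1:400)))
    lab <- sample(rep(c("a", "b"), 20))
    tab <- feature_table(v, lab)
    if (leak) tab <- select_top_k(tab, 5, n_bins = 4)  # uses all labels
    cross_validated_svm(tab, grid = svm_grid(degree = 1, cost = 1,
                                             gamma = 0.1),
                        folds = 5, seed = s, ig_bins = 4,
                        k_features = if (leak) NULL else 5)$mean[["accuracy"]]
  }
  leaky <- mean(vapply(1:4, function(s) run(TRUE, s), numeric(1)))
  proper <- mean(vapply(1:4, function(s) run(FALSE, s), numeric(1)))
  expect_gte(leaky, 0.6)            # the canary detects leakage
  expect_gte(proper, 0.3)           # proper pipeline stays at chance
  expect_lte(proper, 0.65)
  expect_gt(leaky, proper + 0.05)
})

test_that("degenerate requests fail loudly", {
  v <- matrix(rnorm(40), 20, 2)
  tab <- feature_table(v, rep(c("a", "b"), 10))
  expect_error(cross_validated_svm(tab, folds = 15), "at least")
  expect_error(select_top_k(tab, 5), "k <= ")
})
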