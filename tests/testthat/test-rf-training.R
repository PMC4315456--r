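# Small synthetic feature sets for forest protocol tests.
separable_set <- function(n_per = 40, p = 16, n_labels = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(n_per * n_labels * p), n_per * n_labels, p,
              dimnames = list(NULL, kmer_alphabet(2)))
  y <- rep(letters[seq_len(n_labels)], each = n_per)
  for (i in seq_len(n_labels)) X[y == letters[i], i] <- X[y == letters[i], i] + 10
  list(X = X, y = y)
}

test_that("default mtry is half the square root of the k-mer space", {
  expect_equal(default_mtry(4), 8L)
  expect_equal(default_mtry(2), 2L)
  expect_equal(default_mtry(5), 16L)
  expect_equal(default_mtry(1), 1L)
})

test_that("mtry tuning finds zero OOB error on separable labels", {
  d <- separable_set()
  tr <- tune_mtry(d$X, d$y, ntree = 50, seed = 3)
  expect_equal(min(tr$oob_error), 0)
  chosen <- attr(tr, "chosen_mtry")
  expect_equal(tr$oob_error[match(chosen, tr$mtry)], min(tr$oob_error))
  expect_true(all(tr$mtry >= 1 & tr$mtry <= ncol(d$X)))
})

test_that("mtry tuning is deterministic per seed and rejects one label", {
  d <- separable_set()
  tr1 <- tune_mtry(d$X, d$y, ntree = 50, seed = 9)
  tr2 <- tune_mtry(d$X, d$y, ntree = 50, seed = 9)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_identical(attr(tr1, "chosen_mtry"), attr(tr2, "chosen_mtry"))
  expect_error(tune_mtry(d$X, rep("a", nrow(d$X)), ntree = 10, seed = 1),
               "degenerate label space")
})

test_that("cross-validated tuning mode is available and deterministic", {
  d <- separable_set(n_per = 25)
  tr1 <- tune_mtry(d$X, d$y, ntree = 30, seed = 2, error_estimate = "cv",
                   cv_folds = 5)
  tr2 <- tune_mtry(d$X, d$y, ntree = 30, seed = 2, error_estimate = "cv",
                   cv_folds = 5)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_equal(min(tr1$oob_error), 0)  # separable under CV too
})

test_that("labels independent of features give near-null OOB error", {
  set.seed(8)
  X <- matrix(stats::runif(240 * 16), 240, 16,
              dimnames = list(NULL, kmer_alphabet(2)))
  y <- sample(rep(c("a", "b"), c(180, 60)))  # majority error 0.25
  tr <- tune_mtry(X, y, ntree = 200, seed = 4)
  # every visited mtry should hover near the 0.25 null error
  expect_true(all(abs(tr$oob_error - 0.25) < 0.12))
})

test_that("rank model training records OOB error and importance", {
  d <- separable_set(n_labels = 3)
  b <- train_rank_model(d$X, d$y, rank = "genus", k = 2, ntree = 100,
                        seed = 2)
  expect_s3_class(b, "rank_model")
  expect_equal(b$oob_error, 0)
  expect_equal(b$label_space, c("a", "b", "c"))
  expect_length(b$permutation_importance, ncol(d$X))
  expect_true(all(b$model$predicted == d$y))
  expect_true(b$mtry >= 1 && b$mtry <= ncol(d$X))
})

test_that("permutation importance: constants score zero, planted signal first", {
  set.seed(5)
  X <- matrix(stats::runif(200 * 16), 200, 16,
              dimnames = list(NULL, kmer_alphabet(2)))
  X[, "GG"] <- 0.5                    # zero-variance feature
  y <- ifelse(X[, "AC"] > 0.5, "hi", "lo")  # label a function of one k-mer
  b <- train_rank_model(X, y, rank = "genus", k = 2, ntree = 200, seed = 2)
  expect_lt(abs(b$permutation_importance[["GG"]]), 1e-8)
  expect_equal(names(which.max(b$permutation_importance)), "AC")
})

test_that("training reproduces exactly under a fixed seed", {
  d <- separable_set(n_labels = 3)
  b1 <- train_rank_model(d$X, d$y, "genus", k = 2, ntree = 60, seed = 7)
  b2 <- train_rank_model(d$X, d$y, "genus", k = 2, ntree = 60, seed = 7)
  expect_identical(b1$oob_error, b2$oob_error)
  expect_identical(b1$permutation_importance, b2$permutation_importance)
  expect_identical(b1$model$predicted, b2$model$predicted)
})

test_that("rare labels are dropped with a warning or rejected per config", {
  d <- separable_set(n_per = 10, n_labels = 2)
  X <- rbind(d$X, d$X[1, , drop = FALSE])
  y <- c(d$y, "singleton")
  expect_warning(b <- train_rank_model(X, y, "genus", k = 2, ntree = 20,
                                       seed = 1), "dropping 1 label")
  expect_equal(b$label_space, c("a", "b"))
  expect_error(train_rank_model(X, y, "genus", k = 2, ntree = 20, seed = 1,
                                rare_label_action = "error"), "< 2 training")
})

test_that("variable pruning visits 256, 231, 206 and 181 variables", {
  set.seed(6)
  X <- matrix(stats::runif(120 * 256), 120, 256,
              dimnames = list(NULL, kmer_alphabet(4)))
  y <- rep(c("a", "b"), each = 60)
  X[y == "a", 1:10] <- X[y == "a", 1:10] + 1  # 10 informative variables
  pe <- variable_pruning_experiment(X, y, ntree = 60, seed = 2)
  expect_equal(pe$n_variables, c(256, 231, 206, 181))
  # informative variables are never pruned, so error stays at floor
  expect_true(all(pe$oob_error <= 0.05))
  pe0 <- variable_pruning_experiment(X, y, block = 0, ntree = 40, seed = 2)
  expect_equal(nrow(pe0), 1)
  expect_error(variable_pruning_experiment(X, y, block = 100, steps = 3,
                                           ntree = 10, seed = 1),
               "smaller than")
})

test_that("OOB error saturates with more trees", {
  d <- separable_set()
  # grid starts at 50 trees so every example has out-of-bag votes
  grid <- c(50, 100, 150)
  cur <- ntree_saturation_curve(d$X, d$y, mtry = 2, ntree_grid = grid,
                                seed = 3)
  expect_equal(cur$ntree, grid)
  expect_equal(cur$oob_error, rep(0, 3))  # separable at every size
  expect_equal(nrow(ntree_saturation_curve(d$X, d$y, 2, 50, seed = 1)), 1)
  # noisy labels: error non-increasing in ntree (median over 5 seeds)
  set.seed(12)
  X <- matrix(stats::runif(150 * 16), 150, 16,
              dimnames = list(NULL, kmer_alphabet(2)))
  y <- ifelse(X[, 1] + stats::rnorm(150, sd = 0.4) > 0.5, "a", "b")
  deltas <- vapply(1:5, function(s) {
    cc <- ntree_saturation_curve(X, y, mtry = 4,
                                 ntree_grid = c(25, 500), seed = s)
    cc$oob_error[2] - cc$oob_error[1]
  }, numeric(1))
  expect_lte(stats::median(deltas), 0.02)
})

test_that("a genus model recovers held-out unmutated fixture reads", {
  fx <- shared_fixture()
  groups <- group_by_rank(fx$records, "genus")
  clusters <- lapply(groups, function(ids) list(member_ids = ids))
  sp <- split_per_cluster(clusters, 0.10, seed = 11)
  tr <- generate_reads(fx, "V3", ids = sp$train)
  feats <- featurize_batch(tr$reads, 4)
  b <- train_rank_model(feats, tr$truth$genus, rank = "genus", k = 4,
                        ntree = 150, seed = 5)
  te <- generate_reads(fx, "V3", ids = sp$test)
  pred <- as.character(stats::predict(b$model, featurize_batch(te$reads, 4)))
  expect_gte(mean(pred == te$truth$genus), 0.95)
})
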