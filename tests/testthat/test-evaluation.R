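test_that("per-cluster splitting allocates ~10% with a minimum of one", {
  cl10 <- list(list(member_ids = paste0("s", 1:10)))
  sp <- split_per_cluster(cl10, 0.10, seed = 1)
  expect_length(sp$test, 1)
  expect_length(sp$train, 9)
  expect_setequal(c(sp$train, sp$test), paste0("s", 1:10))
  # all singletons: empty test with a warning
  singles <- lapply(1:5, function(i) list(member_ids = paste0("x", i)))
  expect_warning(sp0 <- split_per_cluster(singles, 0.10, seed = 1),
                 "singleton")
  expect_length(sp0$test, 0)
  expect_length(sp0$train, 5)
})

test_that("split sizes equal the per-cluster arithmetic", {
  sizes <- c(1, 2, 5, 10, 14, 15, 25, 100)
  clusters <- lapply(seq_along(sizes), function(i) {
    list(member_ids = paste0("c", i, "_", seq_len(sizes[i])))
  })
  sp <- split_per_cluster(clusters, 0.10, seed = 3)
  # by hand: singletons contribute 0; else max(1, round(0.1 * size))
  expected <- sum(ifelse(sizes < 2, 0, pmax(1, floor(0.10 * sizes + 0.5))))
  expect_length(sp$test, expected)
  expect_length(sp$train, sum(sizes) - expected)
  expect_length(intersect(sp$train, sp$test), 0)
  # deterministic per seed
  expect_identical(sp, split_per_cluster(clusters, 0.10, seed = 3))
})

test_that("mutation injection respects rate 0 and rate 1", {
  s <- "ACGTACGTAC"
  expect_identical(inject_mutations(s, 0, seed = 1), s)
  mut <- inject_mutations("AAAA", 1, seed = 2)
  expect_equal(nchar(mut), 4)
  expect_false(grepl("A", mut))
  # deterministic per seed, different across seeds
  long <- strrep("ACGT", 200)
  expect_identical(inject_mutations(long, 0.05, seed = 7),
                   inject_mutations(long, 0.05, seed = 7))
  expect_false(identical(inject_mutations(long, 0.05, seed = 7),
                         inject_mutations(long, 0.05, seed = 8)))
})

test_that("observed substitution fraction matches the nominal rate", {
  set.seed(101)
  seqs <- replicate(300, rand_dna(200))
  mut <- inject_mutations(seqs, rate = 0.01, seed = 55)
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, seqs, mut)
  frac <- sum(diffs) / (300 * 200)
  se <- sqrt(0.01 * 0.99 / (300 * 200))
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("confusion counts match hand-built and brute-force tallies", {
  ids <- paste0("r", 1:10)
  truth <- stats::setNames(rep(c("A", "B"), each = 5), ids)
  # perfect predictions
  perfect <- confusion_by_group(truth, truth)
  expect_equal(perfect$tp, c(5, 5))
  expect_equal(perfect$fp, c(0, 0))
  expect_equal(perfect$fn, c(0, 0))
  expect_equal(perfect$tn, c(5, 5))
  # everything predicted as A
  all_a <- confusion_by_group(truth, stats::setNames(rep("A", 10), ids))
  expect_equal(all_a[all_a$group == "A", c("tp", "fp", "fn", "tn")],
               data.frame(tp = 5, fp = 5, fn = 0, tn = 0),
               ignore_attr = TRUE)
  expect_equal(all_a[all_a$group == "B", c("tp", "fp", "fn", "tn")],
               data.frame(tp = 0, fp = 0, fn = 5, tn = 5),
               ignore_attr = TRUE)
  # random predictions vs a per-read brute-force tally
  set.seed(23)
  labs <- LETTERS[1:4]
  t2 <- stats::setNames(sample(labs, 60, TRUE), paste0("q", 1:60))
  p2 <- stats::setNames(sample(labs, 60, TRUE), paste0("q", 1:60))
  got <- confusion_by_group(t2, p2)
  for (g in unique(t2)) {
    tally <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (id in names(t2)) {
      is_t <- t2[[id]] == g; is_p <- p2[[id]] == g
      key <- if (is_t && is_p) "tp" else if (!is_t && is_p) "fp"
             else if (is_t && !is_p) "fn" else "tn"
      tally[key] <- tally[key] + 1
    }
    row <- got[got$group == g, ]
    expect_equal(unlist(row[, c("tp", "fp", "fn", "tn")]), tally,
                 ignore_attr = TRUE)
    expect_equal(sum(tally), 60)  # TP+FP+FN+TN covers every read
  }
  # unlabelled truth excluded and counted; id mismatch errors
  t3 <- stats::setNames(c("A", "", "B"), paste0("u", 1:3))
  p3 <- stats::setNames(c("A", "A", "B"), paste0("u", 1:3))
  cf <- confusion_by_group(t3, p3)
  expect_equal(attr(cf, "n_excluded"), 1)
  expect_error(confusion_by_group(t3, p3[1:2]), "same query ids")
})

test_that("the seven metrics hit exact values on canonical counts", {
  perfect <- compute_metrics(data.frame(rank = NA, group = "g",
                                        tp = 50, fp = 0, fn = 0, tn = 50))
  for (m in c("sensitivity", "specificity", "precision", "accuracy",
              "g_mean", "f_measure", "mcc")) {
    expect_equal(perfect[[m]], 1.0, info = m)
  }
  symm <- compute_metrics(data.frame(rank = NA, group = "g",
                                     tp = 25, fp = 25, fn = 25, tn = 25))
  expect_equal(symm$sensitivity, 0.5)
  expect_equal(symm$specificity, 0.5)
  expect_equal(symm$precision, 0.5)
  expect_equal(symm$accuracy, 0.5)
  expect_equal(symm$mcc, 0.0)
})

test_that("metric formulas match an independent implementation to 1e-12", {
  set.seed(91)
  for (i in 1:50) {
    q <- sample(0:200, 4, replace = TRUE)
    got <- compute_metrics(data.frame(rank = NA, group = "g", tp = q[1],
                                      fp = q[2], fn = q[3], tn = q[4]))
    want <- oracle_metrics(q[1], q[2], q[3], q[4])
    for (m in names(want)) {
      expect_equal(got[[m]], unname(want[m]), tolerance = 1e-12, info = m)
    }
    # bounds: MCC in [-1,1]; G-mean below the larger of sens/spec
    if (!is.na(got$mcc)) expect_true(abs(got$mcc) <= 1 + 1e-12)
    if (!is.na(got$g_mean)) {
      expect_lte(got$g_mean,
                 max(got$sensitivity, got$specificity) + 1e-12)
    }
  }
})

test_that("macro-averaging is unweighted and skips undefined rows", {
  rows <- compute_metrics(data.frame(
    rank = NA, group = c("a", "b"),
    tp = c(8, 9), fp = c(2, 1), fn = c(2, 1), tn = c(88, 89)))
  avg <- macro_average(rows)
  expect_equal(avg$precision, mean(c(0.8, 0.9)))
  expect_equal(avg$n_groups, 2)
  # identical rows average to themselves
  same <- compute_metrics(data.frame(rank = NA, group = c("x", "y"),
                                     tp = 5, fp = 5, fn = 5, tn = 5))
  expect_equal(macro_average(same)$mcc, 0)
  # mixed defined/undefined: mean over defined only, exclusions counted
  mixed <- compute_metrics(data.frame(
    rank = NA, group = c("a", "b"),
    tp = c(0, 10), fp = c(0, 0), fn = c(5, 0), tn = c(95, 90)))
  avg_m <- macro_average(mixed)
  expect_equal(avg_m$precision, 1.0)  # group a precision undefined (0/0)
  expect_equal(attr(avg_m, "n_undefined")[["precision"]], 1L)
})

test_that("specificity and accuracy approach one as groups multiply", {
  # with many one-vs-rest groups, true negatives dominate every group
  set.seed(17)
  n_groups <- 60
  truth <- stats::setNames(rep(paste0("g", seq_len(n_groups)), each = 4),
                           paste0("r", seq_len(4 * n_groups)))
  pred <- truth
  flip <- sample(length(pred), 30)  # imperfect predictor
  pred[flip] <- sample(paste0("g", seq_len(n_groups)), 30, TRUE)
  met <- compute_metrics(confusion_by_group(truth, pred))
  avg <- macro_average(met)
  expect_gt(avg$specificity, 0.99)
  expect_gt(avg$accuracy, 0.99)
  expect_lt(avg$sensitivity, avg$specificity)
})
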