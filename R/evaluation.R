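# Test harness: per-cluster splitting, substitution-error injection,
# one-vs-rest confusion counts and the seven macro-averaged metrics.

#' Per-cluster train/test split
#'
#' From each cluster with at least two members, `round(test_fraction *
#' size)` members (minimum 1) are drawn into the test set; singleton
#' clusters go wholly to train. Train and test are disjoint and together
#' cover every id.
#'
#' @param clusters a `cluster_set` (see [dereplicate_exact()]) or any list
#'   of lists with a `member_ids` field.
#' @param test_fraction fraction of each cluster held out (default 0.10).
#' @param seed integer seed for the within-cluster draws.
#' @return a list with character vectors `train` and `test`.
#' @export
split_per_cluster <- function(clusters, test_fraction = 0.10, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  train <- character(0)
  test <- character(0)
  with_seed(seed, {
    for (cl in clusters) {
      m <- cl$member_ids
      if (length(m) < 2) {
        train <- c(train, m)
      } else {
        n_test <- max(1L, round_half_up(test_fraction * length(m)))
        picked <- sample(m, n_test)
        test <- c(test, picked)
        train <- c(train, setdiff(m, picked))
      }
    }
  })
  if (length(test) == 0) {
    warning("all clusters are singletons; test set is empty")
  }
  list(train = train, test = test)
}

#' Inject random substitution errors
#'
#' Each position is independently substituted with probability `rate`; a
#' substitution draws uniformly from the three other bases, so it is never
#' silent and length is preserved. Models sequencing error on fixed-length
#' regions; no indels.
#'
#' @param sequences character vector of DNA sequences.
#' @param rate per-base substitution probability in \[0,1\].
#' @param seed integer seed (one stream for the whole batch).
#' @return character vector of mutated sequences, names preserved.
#' @export
inject_mutations <- function(sequences, rate = 0.01, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- vapply(sequences, function(s) {
      chars <- strsplit(s, "")[[1]]
      if (length(chars) == 0) return(s)
      hit <- stats::runif(length(chars)) < rate
      if (any(hit)) {
        chars[hit] <- vapply(chars[hit], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
      }
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  names(out) <- names(sequences)
  out
}

#' One-vs-rest confusion counts per taxon at a rank
#'
#' For every taxon appearing in the truth labels, counts TP (truth and
#' prediction both the taxon), FP (prediction the taxon, truth another),
#' FN (truth the taxon, prediction another) and TN (neither). Reads whose
#' truth label is empty or NA are excluded; their count is the
#' `n_excluded` attribute.
#'
#' @param truth named character vector of true taxon labels (names are
#'   query ids).
#' @param predicted named character vector of predicted labels; must carry
#'   the same ids as `truth`.
#' @param rank optional rank name recorded in the result.
#' @return a data.frame with columns `rank`, `group`, `tp`, `fp`, `fn`,
#'   `tn`, with attribute `n_excluded`.
#' @export
confusion_by_group <- function(truth, predicted, rank = NA_character_) {
  if (is.null(names(truth)) || is.null(names(predicted)) ||
      !setequal(names(truth), names(predicted)) ||
      anyDuplicated(names(truth))) {
    stop("truth and predicted must carry the same query ids",
         call. = FALSE)
  }
  predicted <- predicted[names(truth)]
  labelled <- !is.na(truth) & truth != ""
  n_excluded <- sum(!labelled)
  t <- truth[labelled]
  p <- predicted[labelled]
  n <- length(t)
  groups <- unique(t)
  rows <- lapply(groups, function(g) {
    tp <- sum(t == g & p == g)
    fp <- sum(t != g & p == g)
    fn <- sum(t == g & p != g)
    data.frame(rank = rank, group = g, tp = tp, fp = fp, fn = fn,
               tn = n - tp - fp - fn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' The seven classification metrics from confusion counts
#'
#' Per group: sensitivity TP/(TP+FN); specificity TN/(TN+FP); precision
#' TP/(TP+FP); accuracy (TP+TN)/(TP+FP+FN+TN); G-mean
#' sqrt(sensitivity x specificity); F-measure 2 x precision x recall /
#' (precision + recall) with recall = sensitivity; MCC
#' (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any metric with a
#' zero denominator is `NA` (undefined) and is excluded from
#' macro-averaging.
#'
#' @param counts data.frame from [confusion_by_group()] (columns `tp`,
#'   `fp`, `fn`, `tn`).
#' @return `counts` with seven metric columns appended.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  acc <- safe_div(tp + tn, tp + fp + fn + tn)
  gmean <- sqrt(sens * spec)
  fmeas <- ifelse(!is.na(prec) & !is.na(sens) & (prec + sens) > 0,
                  2 * prec * sens / (prec + sens), NA_real_)
  mcc_den <- sqrt(as.numeric(tp + fp) * as.numeric(tp + fn) *
                  as.numeric(tn + fp) * as.numeric(tn + fn))
  mcc <- ifelse(mcc_den > 0,
                (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den,
                NA_real_)
  cbind(counts, data.frame(
    sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, g_mean = gmean, f_measure = fmeas, mcc = mcc))
}

METRIC_NAMES <- c("sensitivity", "specificity", "precision", "accuracy",
                  "g_mean", "f_measure", "mcc")

#' Macro-average metric rows over rank groups
#'
#' Unweighted arithmetic mean of each metric over the groups where it is
#' defined; the number of excluded (undefined) groups per metric is
#' reported alongside.
#'
#' @param metrics data.frame from [compute_metrics()].
#' @return a one-row data.frame of the seven macro-averaged metrics plus
#'   `n_groups` and an `n_undefined` attribute (named integer per metric).
#' @export
macro_average <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  means <- vapply(METRIC_NAMES, function(m) {
    v <- metrics[[m]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out <- as.data.frame(as.list(means))
  out$n_groups <- nrow(metrics)
  attr(out, "n_undefined") <- vapply(METRIC_NAMES, function(m) {
    sum(is.na(metrics[[m]]))
  }, integer(1))
  out
}

#' Evaluate classifications against true lineages
#'
#' Convenience wrapper: for each rank, builds one-vs-rest confusion counts,
#' the seven per-group metrics, their macro-average, and the plain
#' multi-class accuracy (fraction of labelled reads assigned their true
#' taxon).
#'
#' @param results data.frame from [classify_reads()].
#' @param truth data.frame with column `query_id` (or ids as rownames) and
#'   one column per rank giving the true taxon.
#' @param ranks ranks to evaluate (default: those present in both inputs).
#' @return a list with `per_group` (data.frame over all ranks and groups),
#'   `summary` (one macro-averaged row per rank, plus `multiclass_accuracy`).
#' @export
evaluate_assignments <- function(results, truth,
                                 ranks = intersect(CLASSIFICATION_RANKS,
                                                   names(results))) {
  ids <- truth$query_id %||% rownames(truth)
  per_group <- list()
  summaries <- list()
  for (rank in ranks) {
    tr <- stats::setNames(truth[[rank]], ids)
    pr <- stats::setNames(results[[rank]], results$query_id)
    counts <- confusion_by_group(tr, pr, rank = rank)
    met <- compute_metrics(counts)
    per_group[[rank]] <- met
    s <- macro_average(met)
    labelled <- !is.na(tr) & tr != ""
    s <- cbind(data.frame(rank = rank), s)
    s$multiclass_accuracy <- mean(pr[names(tr)[labelled]] == tr[labelled])
    summaries[[rank]] <- s
  }
  list(per_group = do.call(rbind, per_group),
       summary = do.call(rbind, summaries))
}

#' Write a metric report as TSV plus JSON summary
#'
#' @param evaluation list from [evaluate_assignments()].
#' @param tsv_path per-group metric table destination.
#' @param json_path macro-averaged summary destination.
#' @return invisibly, `evaluation`.
#' @export
write_metric_report <- function(evaluation, tsv_path, json_path) {
  utils::write.table(evaluation$per_group, tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(evaluation$summary, json_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null",
                       pretty = TRUE)
  invisible(evaluation)
}
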