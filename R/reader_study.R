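#' Reader-study analytics
#'
#' Tools for two-task reader studies: raters diagnose a set of lesion images
#' unaided (task 1) and re-diagnose the same images supported by retrieved
#' similar lesions with known labels (task 2), each time recording a 5-point
#' Likert confidence. Records are plain data.frames with columns `rater_id`,
#' `task` (1 or 2), `image_id`, `diagnosis`, `confidence` (integer 1-5) and
#' `truth`.
#'
#' @name reader-study
NULL

validate_records <- function(records) {
  need <- c("rater_id", "task", "image_id", "diagnosis", "confidence",
            "truth")
  stopifnot(is.data.frame(records), all(need %in% names(records)),
            nrow(records) > 0)
  if (!all(records$task %in% c(1, 2)))
    stop("task must be 1 or 2", call. = FALSE)
  if (!all(records$confidence %in% 1:5))
    stop("confidence must be an integer in 1..5", call. = FALSE)
  bad <- setdiff(unique(c(records$diagnosis, records$truth)),
                 lesion_classes())
  if (length(bad))
    stop("unknown class codes in records: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

#' Diagnostic accuracy of a set of records, in percent
#'
#' @param records Reader records (any subset, e.g. one rater and task).
#' @return `100 * correct / total`.
#' @export
rater_accuracy <- function(records) {
  validate_records(records)
  100 * mean(records$diagnosis == records$truth)
}

#' Confidence summary: absolute and stratified by correctness
#'
#' @param records Reader records.
#' @return List with `absolute` (mean of all confidences), `correct` and
#'   `incorrect` (means within each stratum; `NA` when a stratum is empty).
#' @export
confidence_summary <- function(records) {
  validate_records(records)
  ok <- records$diagnosis == records$truth
  list(absolute = mean(records$confidence),
       correct = if (any(ok)) mean(records$confidence[ok]) else NA_real_,
       incorrect = if (any(!ok)) mean(records$confidence[!ok]) else NA_real_)
}

#' Cohen's kappa between two categorical label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with observed
#' agreement `p_o` and chance agreement `p_e` from the product of marginal
#' proportions. When `p_e = 1` (both sequences constant and equal
#' categories), returns 1 if agreement is perfect and `NA` otherwise.
#'
#' @param labels_a,labels_b Equal-length character vectors.
#' @return Scalar in \[-1, 1\] (or `NA` in the degenerate case).
#' @export
#' @examples
#' cohen_kappa(c("x","x","y","y"), c("x","y","x","y"))  # 0
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label sequences have different lengths", call. = FALSE)
  stopifnot(length(labels_a) >= 1)
  lv <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lv)
  b <- factor(labels_b, levels = lv)
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (abs(1 - p_e) < 1e-12) {
    if (p_o == 1) return(1)
    warning("kappa undefined: chance agreement is 1 but observed is not")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Aggregated 7x7 confusion matrix for one task
#'
#' Rows are truth classes, columns diagnosed classes, summed over all raters.
#'
#' @param records Reader records.
#' @param task 1 or 2.
#' @return 7 x 7 integer matrix with dimnames over [lesion_classes()].
#' @export
aggregate_confusion <- function(records, task) {
  validate_records(records)
  r <- records[records$task == task, ]
  classes <- lesion_classes()
  as.matrix(table(factor(r$truth, levels = classes),
                  factor(r$diagnosis, levels = classes)))
}

#' Relative reduction between two counts
#'
#' `(before - after) / before`; `NA` with a warning when `before` is 0.
#'
#' @param before,after Nonnegative counts.
#' @return Fraction (may be negative when `after > before`).
#' @export
relative_reduction <- function(before, after) {
  if (before == 0) {
    warning("relative reduction undefined: baseline count is 0")
    return(NA_real_)
  }
  (before - after) / before
}

#' Melanoma over- and under-diagnosis from task confusion matrices
#'
#' Overdiagnosis counts non-melanoma truths diagnosed as `mel` (column `mel`
#' off the diagonal); underdiagnosis counts `mel` truths diagnosed as
#' anything else (row `mel` off the diagonal). Rates are relative to the
#' relevant truth totals, and the task-2 vs task-1 relative reductions use
#' [relative_reduction()].
#'
#' @param conf_task1,conf_task2 7x7 confusion matrices as returned by
#'   [aggregate_confusion()].
#' @return List with per-task `overdiagnosis` / `underdiagnosis` counts and
#'   rates, and `overdiagnosis_reduction` / `underdiagnosis_reduction`.
#' @export
melanoma_misdiagnosis <- function(conf_task1, conf_task2) {
  count_over <- function(M) sum(M[rownames(M) != "mel", "mel"])
  count_under <- function(M) sum(M["mel", colnames(M) != "mel"])
  mel_total <- function(M) sum(M["mel", ])
  nonmel_total <- function(M) sum(M[rownames(M) != "mel", ])
  o1 <- count_over(conf_task1); o2 <- count_over(conf_task2)
  u1 <- count_under(conf_task1); u2 <- count_under(conf_task2)
  list(task1 = list(overdiagnosis = o1,
                    overdiagnosis_rate = o1 / nonmel_total(conf_task1),
                    underdiagnosis = u1,
                    underdiagnosis_rate = u1 / mel_total(conf_task1)),
       task2 = list(overdiagnosis = o2,
                    overdiagnosis_rate = o2 / nonmel_total(conf_task2),
                    underdiagnosis = u2,
                    underdiagnosis_rate = u2 / mel_total(conf_task2)),
       overdiagnosis_reduction = relative_reduction(o1, o2),
       underdiagnosis_reduction = relative_reduction(u1, u2))
}

#' Assemble the full study summary
#'
#' Per-rater and cross-rater accuracy and confidence for both tasks, Cohen
#' kappa of each rater against the ground truth (each rater saw a different
#' image set, so rater-vs-truth is the computable agreement) with the
#' unweighted average over raters, per-task aggregated confusion matrices,
#' melanoma over/under-diagnosis, and diagnosis-change counts between tasks
#' joined on (rater, image).
#'
#' @param records Reader records covering both tasks.
#' @param retrieval_predictions Optional named vector image_id -> predicted
#'   class (e.g. majority-vote predictions); adds the algorithm's accuracy on
#'   each rater's image set.
#' @return A `study_summary` list; see fields in the description.
#' @export
study_summary <- function(records, retrieval_predictions = NULL) {
  validate_records(records)
  raters <- sort(unique(records$rater_id))
  per_rater <- do.call(rbind, lapply(raters, function(rid) {
    do.call(rbind, lapply(c(1, 2), function(tk) {
      r <- records[records$rater_id == rid & records$task == tk, ]
      if (nrow(r) == 0) return(NULL)
      cs <- confidence_summary(r)
      alg <- NA_real_
      if (!is.null(retrieval_predictions)) {
        hit <- r$image_id %in% names(retrieval_predictions)
        if (any(hit))
          alg <- 100 * mean(retrieval_predictions[r$image_id[hit]] ==
                              r$truth[hit])
      }
      data.frame(rater_id = rid, task = tk,
                 accuracy = rater_accuracy(r),
                 confidence = cs$absolute,
                 confidence_correct = cs$correct,
                 confidence_incorrect = cs$incorrect,
                 kappa = cohen_kappa(r$diagnosis, r$truth),
                 algorithm_accuracy = alg,
                 n = nrow(r), stringsAsFactors = FALSE)
    }))
  }))
  cross <- do.call(rbind, lapply(c(1, 2), function(tk) {
    pr <- per_rater[per_rater$task == tk, ]
    data.frame(task = tk,
               accuracy_mean = mean(pr$accuracy),
               accuracy_sd = sd(pr$accuracy),
               confidence_mean = mean(pr$confidence),
               confidence_sd = sd(pr$confidence),
               confidence_correct_mean = mean(pr$confidence_correct,
                                              na.rm = TRUE),
               confidence_incorrect_mean = mean(pr$confidence_incorrect,
                                                na.rm = TRUE),
               kappa_mean = mean(pr$kappa))
  }))
  conf1 <- aggregate_confusion(records, 1)
  conf2 <- aggregate_confusion(records, 2)
  # diagnosis changes between tasks, joined on (rater, image)
  t1 <- records[records$task == 1, c("rater_id", "image_id", "diagnosis",
                                     "truth")]
  t2 <- records[records$task == 2, c("rater_id", "image_id", "diagnosis")]
  j <- merge(t1, t2, by = c("rater_id", "image_id"),
             suffixes = c("_t1", "_t2"))
  ok1 <- j$diagnosis_t1 == j$truth
  ok2 <- j$diagnosis_t2 == j$truth
  structure(list(
    per_rater = per_rater,
    cross_rater = cross,
    confusion_task1 = conf1,
    confusion_task2 = conf2,
    melanoma = melanoma_misdiagnosis(conf1, conf2),
    changes = list(correct_to_incorrect = sum(ok1 & !ok2),
                   incorrect_to_correct = sum(!ok1 & ok2),
                   n_paired = nrow(j))),
    class = "study_summary")
}

#' Simulate reader records with a confusable-class error model
#'
#' Each simulated rater diagnoses a personal random image subset in both
#' tasks. In each task a diagnosis is correct with the task's per-class
#' accuracy; errors are drawn from a class-confusability kernel (the three
#' brownish classes confuse with one another, melanoma with nevus, etc.).
#' Confidence is correlated with correctness: correct diagnoses draw from a
#' higher Likert mean than incorrect ones, higher again in task 2.
#'
#' @param truth data.frame with `image_id` and `dx` (the image pool).
#' @param n_raters Number of raters (default 9).
#' @param n_images Images per rater (default 100, capped at pool size).
#' @param accuracy_task1,accuracy_task2 Either a single correct-probability
#'   applied to all classes or a named per-class vector.
#' @param seed Integer seed.
#' @return Reader records data.frame (both tasks, all raters).
#' @export
simulate_readers <- function(truth, n_raters = 9, n_images = 100,
                             accuracy_task1 = 0.62, accuracy_task2 = 0.85,
                             seed = 1L) {
  stopifnot(all(c("image_id", "dx") %in% names(truth)))
  classes <- lesion_classes()
  expand_acc <- function(a) {
    if (length(a) == 1) setNames(rep(a, length(classes)), classes)
    else { stopifnot(all(classes %in% names(a))); a[classes] }
  }
  acc <- list(`1` = expand_acc(accuracy_task1),
              `2` = expand_acc(accuracy_task2))
  # confusability kernel: which wrong class an error lands in
  confus <- list(
    akiec = c(bkl = 0.5, bcc = 0.3, mel = 0.2),
    bcc   = c(akiec = 0.4, bkl = 0.3, mel = 0.3),
    bkl   = c(nv = 0.4, mel = 0.3, akiec = 0.3),
    df    = c(nv = 0.5, bkl = 0.3, mel = 0.2),
    mel   = c(nv = 0.6, bkl = 0.3, bcc = 0.1),
    nv    = c(mel = 0.6, bkl = 0.3, df = 0.1),
    vasc  = c(nv = 0.4, mel = 0.3, bcc = 0.3))
  conf_mean <- list(`1` = c(correct = 3.3, incorrect = 2.7),
                    `2` = c(correct = 4.0, incorrect = 2.9))
  n_images <- min(n_images, nrow(truth))
  with_seed_local(derive_seed(seed, 211, 7), {
    out <- list()
    for (rid in seq_len(n_raters)) {
      pick <- truth[sample.int(nrow(truth), n_images), ]
      for (tk in c(1, 2)) {
        pc <- acc[[as.character(tk)]]
        correct <- runif(n_images) < pc[pick$dx]
        diag <- pick$dx
        for (i in which(!correct)) {
          kern <- confus[[pick$dx[i]]]
          diag[i] <- sample(names(kern), 1, prob = kern)
        }
        mu <- conf_mean[[as.character(tk)]]
        cf <- ifelse(correct, rnorm(n_images, mu["correct"], 0.8),
                     rnorm(n_images, mu["incorrect"], 0.8))
        cf <- pmin(pmax(round(cf), 1), 5)
        out[[length(out) + 1]] <- data.frame(
          rater_id = sprintf("rater%02d", rid), task = tk,
          image_id = pick$image_id, diagnosis = diag,
          confidence = as.integer(cf), truth = pick$dx,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
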