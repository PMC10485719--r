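mk_records <- function(diag, truth, conf = NULL, rater = "r1", task = 1) {
  if (is.null(conf)) conf <- rep(3L, length(diag))
  data.frame(rater_id = rater, task = task,
             image_id = sprintf("I%03d", seq_along(diag)),
             diagnosis = diag, confidence = as.integer(conf),
             truth = truth, stringsAsFactors = FALSE)
}

test_that("accuracy and confidence summaries follow their definitions", {
  r <- mk_records(c(rep("nv", 62), rep("mel", 38)), rep("nv", 100))
  expect_equal(rater_accuracy(r), 62)
  expect_equal(rater_accuracy(mk_records("nv", "nv")), 100)

  r2 <- mk_records(c("nv", "mel"), c("nv", "nv"), conf = c(5, 1))
  cs <- confidence_summary(r2)
  expect_equal(cs$absolute, 3)
  expect_equal(cs$correct, 5)
  expect_equal(cs$incorrect, 1)
  all4 <- confidence_summary(mk_records(c("nv", "mel"), c("nv", "mel"),
                                        conf = c(4, 4)))
  expect_equal(all4$absolute, 4)
  expect_true(is.na(all4$incorrect))
  expect_error(rater_accuracy(mk_records("nv", "nv", conf = 7)),
               "confidence")
})

test_that("confidence mixture identity: absolute is the correctness-weighted
           mean of the strata", {
  withr::with_seed(41, {
    for (i in 1:25) {
      n <- sample(5:60, 1)
      truth <- sample(lesion_classes(), n, replace = TRUE)
      diag <- ifelse(runif(n) < 0.6, truth,
                     sample(lesion_classes(), n, replace = TRUE))
      r <- mk_records(diag, truth, conf = sample(1:5, n, replace = TRUE))
      cs <- confidence_summary(r)
      w <- mean(r$diagnosis == r$truth)
      mix <- sum(c(w, 1 - w) * c(cs$correct, cs$incorrect), na.rm = TRUE)
      if (w %in% c(0, 1)) mix <- cs$absolute
      expect_equal(cs$absolute, mix, tolerance = 1e-12)
    }
  })
})

test_that("Cohen kappa matches hand-derived and library values", {
  expect_equal(cohen_kappa(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "x", "y")), 0)
  expect_warning(k <- cohen_kappa(c("x", "x"), c("x", "y")), NA)
  # degenerate: both constant and equal
  expect_equal(cohen_kappa(c("x", "x"), c("x", "x")), 1)
  expect_error(cohen_kappa("a", c("a", "b")), "lengths")

  # contingency-table oracle, coded independently
  kappa_oracle <- function(a, b) {
    lv <- sort(unique(c(a, b)))
    tab <- table(factor(a, lv), factor(b, lv))
    n <- sum(tab)
    po <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    (po - pe) / (1 - pe)
  }
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(4:80, 1)
      a <- sample(lesion_classes()[1:sample(2:7, 1)], n, replace = TRUE)
      b <- ifelse(runif(n) < 0.5, a,
                  sample(lesion_classes(), n, replace = TRUE))
      if (length(unique(c(a, b))) < 2) next
      expect_equal(cohen_kappa(a, b), kappa_oracle(a, b), tolerance = 1e-12)
    }
  })
  # cross-check against e1071's implementation on one fixed case
  if (requireNamespace("e1071", quietly = TRUE)) {
    withr::with_seed(43, {
      a <- sample(lesion_classes(), 60, replace = TRUE)
      b <- ifelse(runif(60) < 0.6, a,
                  sample(lesion_classes(), 60, replace = TRUE))
    })
    tab <- table(factor(a, lesion_classes()), factor(b, lesion_classes()))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }

  # invariance to a consistent relabeling
  withr::with_seed(44, {
    a <- sample(c("nv", "mel", "bkl"), 40, replace = TRUE)
    b <- sample(c("nv", "mel", "bkl"), 40, replace = TRUE)
  })
  perm <- c(nv = "df", mel = "vasc", bkl = "akiec")
  expect_equal(cohen_kappa(a, b),
               cohen_kappa(unname(perm[a]), unname(perm[b])))
})

test_that("aggregated confusion matrices conserve records", {
  one <- mk_records("mel", "nv")
  M <- aggregate_confusion(one, 1)
  expect_equal(sum(M), 1)
  expect_equal(M["nv", "mel"], 1)

  withr::with_seed(45, {
    truth <- sample(lesion_classes(), 200, replace = TRUE)
    diag <- sample(lesion_classes(), 200, replace = TRUE)
  })
  r <- mk_records(diag, truth)
  M2 <- aggregate_confusion(r, 1)
  expect_equal(sum(M2), 200)
  want_rows <- table(factor(truth, lesion_classes()))
  expect_equal(as.vector(rowSums(M2)), as.vector(want_rows))
  expect_equal(sum(aggregate_confusion(r, 2)), 0)
})

test_that("melanoma over/under-diagnosis counts and reductions", {
  zero <- matrix(0, 7, 7, dimnames = list(lesion_classes(),
                                          lesion_classes()))
  # perfect matrices: zero misdiagnoses, reductions undefined (warns)
  z <- suppressWarnings(melanoma_misdiagnosis(zero + diag(7),
                                              zero + diag(7)))
  expect_equal(z$task1$overdiagnosis, 0)
  expect_equal(z$task1$underdiagnosis, 0)

  m1 <- zero; m2 <- zero
  m1["nv", "mel"] <- 10; m1["bkl", "mel"] <- 5; m1["mel", "mel"] <- 20
  m1["mel", "nv"] <- 6
  m2["nv", "mel"] <- 4; m2["mel", "mel"] <- 24; m2["mel", "bkl"] <- 2
  out <- melanoma_misdiagnosis(m1, m2)
  expect_equal(out$task1$overdiagnosis, 15)
  expect_equal(out$task1$underdiagnosis, 6)
  expect_equal(out$task2$overdiagnosis, 4)
  expect_equal(out$overdiagnosis_reduction, (15 - 4) / 15)
  expect_equal(out$task1$underdiagnosis_rate, 6 / 26)
  expect_warning(rr <- relative_reduction(0, 5), "undefined")
  expect_true(is.na(rr))
})

test_that("study summary on truth-copying raters is perfect", {
  withr::with_seed(46, truth <- data.frame(
    image_id = sprintf("I%03d", 1:40),
    dx = sample(lesion_classes(), 40, replace = TRUE)))
  recs <- do.call(rbind, lapply(c("r1", "r2"), function(rid)
    do.call(rbind, lapply(1:2, function(tk)
      mk_records(truth$dx, truth$dx, conf = 5, rater = rid, task = tk)))))
  s <- suppressWarnings(study_summary(recs))  # zero-misdiagnosis baselines
  expect_true(all(s$per_rater$accuracy == 100))
  expect_true(all(s$per_rater$kappa == 1))
  expect_equal(s$changes$correct_to_incorrect, 0)
  expect_equal(s$changes$incorrect_to_correct, 0)
  expect_equal(sum(s$confusion_task1), 80)
})

test_that("simulated raters reproduce their configured accuracy and are
           seed-deterministic", {
  pool <- data.frame(image_id = sprintf("I%04d", 1:500),
                     dx = rep(lesion_classes(), length.out = 500))
  recs <- simulate_readers(pool, n_raters = 6, n_images = 100,
                           accuracy_task1 = 0.62, accuracy_task2 = 0.85,
                           seed = 9)
  expect_identical(recs, simulate_readers(pool, 6, 100, 0.62, 0.85,
                                          seed = 9))
  expect_true(all(recs$confidence %in% 1:5))
  s <- study_summary(recs)
  # binomial CI around the configured rates (600 records per task)
  for (tk in 1:2) {
    target <- c(0.62, 0.85)[tk]
    acc <- mean(s$per_rater$accuracy[s$per_rater$task == tk]) / 100
    ci <- qnorm(0.995) * sqrt(target * (1 - target) / 600)
    expect_lt(abs(acc - target), ci + 0.01)
  }
  # confidence correlates with correctness in both tasks
  expect_true(all(s$cross_rater$confidence_correct_mean >
                    s$cross_rater$confidence_incorrect_mean))
})
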