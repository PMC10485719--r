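make_metadata <- function(n, props = c(.02, .05, .11, .01, .11, .67, .03),
                          seed = 1) {
  withr::with_seed(seed, {
    dx <- sample(lesion_classes(), n, replace = TRUE, prob = props)
    # ~10% of lesions contribute two images
    lesion <- character(n)
    i <- 1; lid <- 0
    while (i <= n) {
      lid <- lid + 1
      if (runif(1) < 0.1 && i < n && dx[i + 1] == dx[i]) {
        lesion[i:(i + 1)] <- sprintf("L%04d", lid); i <- i + 2
      } else {
        lesion[i] <- sprintf("L%04d", lid); i <- i + 1
      }
    }
    data.frame(image_id = sprintf("I%04d", seq_len(n)), lesion_id = lesion,
               dx = dx, stringsAsFactors = FALSE)
  })
}

test_that("stratified split hits 80:10:10, keeps lesions whole, reproduces", {
  md <- make_metadata(1000)
  sp <- stratified_split(md, c(0.8, 0.1, 0.1), seed = 4)
  sizes <- table(sp$table$subset)
  # stratification allocates lesion groups (<= 2 images here) within each of
  # the 7 classes, so each total can drift by up to one group per class
  expect_lte(abs(sizes[["train"]] - 800), 14)
  expect_lte(abs(sizes[["validation"]] - 100), 14)
  expect_lte(abs(sizes[["test"]] - 100), 14)
  # and within each class the subset counts match the ratios to one group
  for (cl in lesion_classes()) {
    n_cl <- sum(sp$table$dx == cl)
    tr_cl <- sum(sp$table$dx == cl & sp$table$subset == "train")
    expect_lte(abs(tr_cl - 0.8 * n_cl), 2 + 1e-9)
  }
  # no lesion spans subsets
  by_lesion <- split(sp$table$subset, sp$table$lesion_id)
  expect_true(all(vapply(by_lesion, function(x) length(unique(x)) == 1,
                         logical(1))))
  # per-class proportions within 2 percentage points of the whole
  overall <- prop.table(table(factor(md$dx, levels = lesion_classes())))
  for (sub in c("train", "validation", "test")) {
    t_sub <- sp$table[sp$table$subset == sub, ]
    p_sub <- prop.table(table(factor(t_sub$dx, levels = lesion_classes())))
    expect_lt(max(abs(p_sub - overall)), 0.02 + 1e-9)
  }
  expect_identical(stratified_split(md, seed = 4)$assignment,
                   sp$assignment)
  expect_false(identical(stratified_split(md, seed = 5)$assignment,
                         sp$assignment))
})

test_that("split degenerate cases: one lesion, scarce class", {
  md <- data.frame(image_id = sprintf("I%d", 1:10),
                   lesion_id = "L1", dx = "nv")
  sp <- stratified_split(md, seed = 1)
  expect_length(unique(sp$table$subset), 1L)

  md2 <- rbind(make_metadata(60, props = c(0, 0, 0, 0, 0, 1, 0)),
               data.frame(image_id = "IDF1", lesion_id = "LDF1", dx = "df"))
  expect_warning(sp2 <- stratified_split(md2, seed = 1), "kept whole")
  expect_identical(sp2$table$subset[sp2$table$dx == "df"], "train")
})

test_that("focal loss matches its definition and reduces to cross-entropy", {
  p_half <- c(0.5, 0.5, rep(0, 5)); names(p_half) <- lesion_classes()
  expect_equal(focal_loss(p_half, "akiec", focal_loss_params(1, 0)), log(2),
               tolerance = 1e-12)
  sure <- c(1, rep(0, 6))
  expect_equal(focal_loss(sure, "akiec", focal_loss_params(1, 2)), 0)

  # gamma=2, alpha=0.25, p_true=0.9 against the independent scalar oracle
  p <- c(0.9, 0.05, 0.02, 0.01, 0.01, 0.005, 0.005)
  expect_equal(focal_loss(p, "akiec", focal_loss_params(0.25, 2)),
               focal_oracle(0.9, 0.25, 2), tolerance = 1e-12)

  # property: nonnegative, decreasing in p_true, CE-equivalent at gamma=0
  withr::with_seed(8, {
    for (i in 1:50) {
      pr <- runif(7); pr <- pr / sum(pr)
      cl <- sample(lesion_classes(), 1)
      fp <- focal_loss_params(runif(1, 0.1, 2), runif(1, 0, 4))
      expect_gte(focal_loss(pr, cl, fp), 0)
      expect_equal(focal_loss(pr, cl, focal_loss_params(1, 0)),
                   -log(pr[match(cl, lesion_classes())]), tolerance = 1e-9)
    }
    grid <- seq(0.05, 0.95, by = 0.05)
    losses <- vapply(grid, function(pt) {
      pv <- c(pt, rep((1 - pt) / 6, 6))
      focal_loss(pv, "akiec", focal_loss_params(0.5, 2))
    }, numeric(1))
    expect_true(all(diff(losses) < 0))
  })
  expect_error(focal_loss(c(2, rep(0, 6)), "akiec"), "probability")
})

test_that("learning-rate schedule ramps, decays, and stays positive", {
  # paper-scale defaults: backbone base rates at end of ramp-up
  expect_equal(learning_rate(5, "pretrained", stage = 1), 5e-5)
  expect_equal(learning_rate(5, "adapted", stage = 2), 1e-3)
  expect_equal(learning_rate(5, "new_layers", stage = 1), 1e-2)

  sch <- lr_schedule(1e-3, 1e-2, rampup_epochs = 4, decay_rate = 1,
                     total_epochs = 20)
  post <- vapply(4:19, learning_rate, numeric(1), group = "pretrained",
                 params = sch)
  expect_true(all(post == 1e-3))  # decay 1 -> constant after ramp

  sch2 <- lr_schedule(1e-3, 1e-2, 5, 0.9, 30)
  rates <- vapply(0:29, learning_rate, numeric(1), group = "pretrained",
                  params = sch2)
  expect_true(all(rates > 0))
  # continuity at the ramp/decay boundary
  expect_lt(abs(rates[6] - rates[5]), rates[6] * 0.25)
  expect_true(all(diff(rates[1:6]) > 0))
  expect_true(all(diff(rates[6:30]) < 0))
  expect_error(learning_rate(30, "pretrained", params = sch2), "horizon")
  expect_error(lr_schedule(1e-3, 1e-2, rampup_epochs = 10,
                           total_epochs = 10))
})

test_that("augmentation respects stage restrictions and seeding", {
  img <- generate_image("bkl", 64, seed = 3)$pixels
  # stage 2: output is one of the 8 dihedral symmetries
  out2 <- augment(img, stage = 2, seed = 9, target_size = 64)
  syms <- lapply(0:7, function(k) secbir:::dihedral_transform(img, k))
  expect_true(any(vapply(syms, identical, logical(1), y = out2)))

  # all-probability-zero stage 1 reduces to resize + deterministic center crop
  cfg0 <- augment_config(1, p = list(geom = 0, distort = 0, noise = 0,
                                     brightness = 0, color = 0, crop = 0,
                                     coarse = 0))
  out1 <- augment(img, stage = 1, seed = 1, target_size = 64, config = cfg0)
  big <- secbir:::resize_image(img, ceiling(64 * 1.15))
  off <- floor((ceiling(64 * 1.15) - 64) / 2) + 1
  expected <- big[off:(off + 63), off:(off + 63), , drop = FALSE]
  expected[expected < 0] <- 0; expected[expected > 1] <- 1
  expect_equal(out1, expected)

  # seeded determinism and bounded range
  a <- augment(img, stage = 1, seed = 77)
  b <- augment(img, stage = 1, seed = 77)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("zero learning rates leave parameters untouched", {
  ds <- small_dataset()
  sp <- stratified_split(ds$metadata, c(0.6, 0.2, 0.2), seed = 2)
  m <- tiny_model()
  sch <- lr_schedule(0, 0, rampup_epochs = 0, decay_rate = 1,
                     total_epochs = 1)
  fit <- train_stage1(ds, sp, m, loss_params = focal_loss_params(1, 2),
                      schedule = sch, epochs = 1, seed = 1)
  for (i in seq_along(m$conv)) {
    expect_identical(fit$conv[[i]]$W, m$conv[[i]]$W)
  }
  expect_identical(fit$fc1$W, m$fc1$W)
  expect_identical(fit$fc2$W, m$fc2$W)
  expect_s3_class(fit$training_log, "data.frame")
  expect_identical(nrow(fit$training_log), 1L)
})

test_that("stage-2 fine-tuning demands a saliency map per training image", {
  ds <- small_dataset()
  sp <- stratified_split(ds$metadata, c(0.6, 0.2, 0.2), seed = 2)
  m <- tiny_model()
  sal <- saliency_for_dataset(m, ds)
  victim <- split_image_ids(sp, "train")[1]
  sal[[victim]] <- NULL
  expect_error(
    train_stage2(ds, sp, m, sal, schedule = lr_schedule(0, 0, 0, 1, 1),
                 epochs = 1, seed = 1),
    victim, fixed = TRUE)
})

test_that("stage-2 with zero rates and zero-init expansion preserves stage-1
           behaviour on RGB inputs", {
  ds <- small_dataset()
  sp <- stratified_split(ds$metadata, c(0.6, 0.2, 0.2), seed = 2)
  m <- tiny_model()
  sal <- saliency_for_dataset(m, ds)
  m4 <- train_stage2(ds, sp, m, sal, schedule = lr_schedule(0, 0, 0, 1, 1),
                     epochs = 1, seed = 1, init_mode = "zero")
  # batch-norm inference moments are recalibrated on the training subset at
  # each epoch; apply the same calibration to the stage-1 model so the
  # comparison isolates the zero-init expansion
  tr <- secbir:::prep_subset(ds, sp, "train")
  m_cal <- secbir:::bn_calibrate(m, lapply(tr$xs, secbir:::resize_image,
                                           size = 64))
  img <- ds$images[[3]]
  x4 <- compose_four_channel(img$pixels, sal[[img$image_id]])
  p4 <- classify_image(m4, x4)$probabilities
  p3 <- classify_image(m_cal, img$pixels)$probabilities
  expect_equal(p4, p3, tolerance = 1e-8)
})
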