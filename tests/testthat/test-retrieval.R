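test_that("cosine similarity matches hand arithmetic and its contracts", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / (sqrt(14) * sqrt(77)), tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 2), c(4, 8)), 1)
  # symmetry and scale invariance
  a <- c(0.3, -1, 2); b <- c(5, 0.1, -2)
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  expect_equal(cosine_similarity(3.7 * a, b), cosine_similarity(a, b))
  expect_warning(z <- cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_true(is.na(z))
  expect_error(cosine_similarity(1:3, 1:4))
})

toy_index <- function(features, labels, lesions = NULL) {
  ids <- sprintf("IMG_%03d", seq_len(nrow(features)))
  rownames(features) <- ids
  if (is.null(lesions)) lesions <- ids
  structure(list(features = features, labels = labels,
                 lesion_ids = lesions, feature_dim = ncol(features),
                 model_id = "toy"), class = "feature_index")
}

test_that("query ranking equals the brute-force oracle on a toy index", {
  withr::with_seed(21, {
    feats <- matrix(rnorm(10 * 5), 10, 5)
    labels <- sample(lesion_classes(), 10, replace = TRUE)
  })
  idx <- toy_index(feats, labels)
  qf <- c(1, -0.5, 2, 0, 0.3)
  got <- query_index(idx, qf, NA, k = 6)
  oracle <- brute_force_query(idx$features, idx$labels, idx$lesion_ids,
                              qf, NA, 6)
  expect_identical(got$ranking$image_id, oracle$image_id)
  expect_equal(got$ranking$similarity, oracle$similarity, tolerance = 1e-12)
  expect_identical(got$ranking$label, oracle$label)
  # an exact duplicate of an entry ranks first at similarity 1
  got2 <- query_index(idx, feats[4, ], NA, k = 3)
  expect_identical(got2$ranking$image_id[1], "IMG_004")
  expect_equal(got2$ranking$similarity[1], 1)
})

test_that("query excludes the query lesion completely and flags truncation", {
  withr::with_seed(22, feats <- matrix(rnorm(10 * 4), 10, 4))
  lesions <- c(rep("LES_A", 3), sprintf("LES_%d", 4:10))
  idx <- toy_index(feats, rep("nv", 10), lesions)
  res <- query_index(idx, rnorm(4), "LES_A", k = 20)
  expect_false(any(res$ranking$image_id %in% sprintf("IMG_%03d", 1:3)))
  expect_identical(nrow(res$ranking), 7L)
  expect_true(res$truncated)
  expect_error(query_index(idx, rnorm(4), "LES_A", k = 0))
  idx_one <- toy_index(matrix(1:4, 1), "nv", "LES_A")
  expect_error(query_index(idx_one, c(1, 2, 3, 4), "LES_A", 1),
               "no eligible")
})

test_that("rankings are invariant to positive feature rescaling and ties
           break by ascending image id", {
  withr::with_seed(23, feats <- matrix(rnorm(30 * 6), 30, 6))
  idx <- toy_index(feats, rep("mel", 30))
  qf <- rnorm(6)
  r1 <- query_index(idx, qf, NA, k = 10)$ranking$image_id
  idx2 <- idx; idx2$features <- idx$features * 41.7
  r2 <- query_index(idx2, qf, NA, k = 10)$ranking$image_id
  expect_identical(r1, r2)
  # exact ties: three identical entries must come back in id order
  tied <- matrix(rep(c(1, 1), 3), 3, byrow = TRUE)
  idx3 <- toy_index(rbind(tied, c(-1, 1)), rep("nv", 4))
  r3 <- query_index(idx3, c(2, 2), NA, k = 3)$ranking
  expect_identical(r3$image_id, sprintf("IMG_%03d", 1:3))
})

test_that("query equals brute force over many random seeded trials", {
  withr::with_seed(99, {
    for (trial in 1:200) {
      n <- sample(5:60, 1); d <- sample(3:8, 1)
      feats <- matrix(rnorm(n * d), n, d)
      labels <- sample(lesion_classes(), n, replace = TRUE)
      lesions <- sprintf("LES_%d", sample.int(max(2, n %/% 2), n,
                                              replace = TRUE))
      idx <- toy_index(feats, labels, lesions)
      qf <- rnorm(d)
      ql <- sample(lesions, 1)
      k <- sample(1:10, 1)
      if (!any(lesions != ql)) next
      got <- query_index(idx, qf, ql, k = k)$ranking
      want <- brute_force_query(idx$features, labels, lesions, qf, ql, k)
      expect_identical(got$image_id, want$image_id)
      expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
    }
  })
})

test_that("index building is canonical, complete, and round-trips", {
  m <- tiny_model()
  ds <- small_dataset()
  ids <- ds$metadata$image_id[1:12]
  idx <- build_index(m, ds, ids)
  expect_identical(nrow(idx$features), 12L)
  expect_identical(rownames(idx$features), sort(ids))
  # input order does not matter
  idx_sh <- build_index(m, ds, rev(ids))
  expect_identical(idx_sh$features, idx$features)

  dir <- withr::local_tempdir()
  write_index(idx, dir)
  back <- read_index(dir)
  expect_identical(rownames(back$features), rownames(idx$features))
  expect_equal(back$features, idx$features, tolerance = 1e-10)
  expect_identical(back$labels, idx$labels)
  expect_identical(back$model_id, idx$model_id)

  expect_error(build_index(m, ds, c(ids, "IMG_99999")), "not in dataset")
  # model/index fingerprint mismatch is refused at query time
  other <- build_classifier(backbone_config("tiny_test"), seed = 777)
  expect_error(run_queries(idx, other, ds, ids[1], k = 3),
               "fingerprint mismatch")
})
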