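# shared fixtures, built in code and memoised for the session

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small balanced dataset for plumbing tests (no training quality implied)
small_dataset <- function() {
  fixture("small_dataset", {
    generate_dataset(synthetic_spec(n_images = 42,
                                    class_proportions = rep(1 / 7, 7),
                                    follow_up_rate = 0.2, seed = 5))
  })
}

# an untrained tiny model shared across structural tests
tiny_model <- function() {
  fixture("tiny_model", build_classifier(backbone_config("tiny_test"),
                                         seed = 42))
}

random_rgb <- function(size = 64, seed = 1) {
  withr::with_seed(seed, array(runif(size * size * 3), c(size, size, 3)))
}

# independent scalar focal-loss oracle, coded directly from the definition
focal_oracle <- function(p_true, alpha_t, gamma) {
  -alpha_t * (1 - p_true)^gamma * log(p_true)
}

# brute-force retrieval oracle: cosine to every eligible entry via plain
# arithmetic, full sort, no package ranking code
brute_force_query <- function(features, labels, lesions, qf, qlesion, k,
                              qid = NA_character_) {
  ids <- rownames(features)
  elig <- if (is.na(qlesion)) rep(TRUE, nrow(features))
          else lesions != qlesion
  if (!is.na(qid)) elig <- elig & ids != qid
  sims <- apply(features[elig, , drop = FALSE], 1, function(v)
    sum(v * qf) / sqrt(sum(v^2) * sum(qf^2)))
  ord <- order(-sims, ids[elig])
  take <- utils::head(ord, k)
  data.frame(image_id = ids[elig][take], similarity = unname(sims[take]),
             label = labels[elig][take], stringsAsFactors = FALSE)
}
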