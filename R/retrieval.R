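#' Cosine similarity between two feature vectors
#'
#' `S_c = dot(A, B) / (||A|| ||B||)`, in \[-1, 1\]; symmetric and invariant
#' to positive rescaling of either vector. Retrieval ranks candidates by
#' DESCENDING `S_c` (most similar first); equivalently by ascending cosine
#' distance `1 - S_c`.
#'
#' @param a,b Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return Scalar in \[-1, 1\], or `NA` with a warning when either vector is
#'   all-zero (similarity undefined).
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))  # 32 / (sqrt(14)*sqrt(77))
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("cosine similarity undefined for a zero vector; returning NA")
    return(NA_real_)
  }
  min(max(sum(a * b) / (na * nb), -1), 1)
}

#' Build a deep-feature retrieval index
#'
#' Extracts one feature vector per image of a subset with
#' [extract_features()] and stores them with labels and lesion ids. Entries
#' are kept in canonical (ascending `image_id`) order so the index is
#' independent of input order.
#'
#' @param model Trained `secbir_model`.
#' @param dataset Dataset list (`images`, `metadata`).
#' @param ids Image ids to index (e.g. the training subset); default all.
#' @param saliency_maps Named list image_id -> map, required when the model
#'   takes 4-channel input.
#' @return A `feature_index`: list with `features` (n x D matrix, rownames =
#'   image ids), `labels`, `lesion_ids`, `feature_dim`, `model_id`.
#' @export
build_index <- function(model, dataset, ids = NULL, saliency_maps = NULL) {
  if (is.null(ids)) ids <- vapply(dataset$images, `[[`, "", "image_id")
  ids <- sort(ids)
  res <- model$config$input_resolution
  want4 <- model$config$in_channels == 4L
  by_id <- setNames(dataset$images,
                    vapply(dataset$images, `[[`, "", "image_id"))
  missing <- setdiff(ids, names(by_id))
  if (length(missing))
    stop("images not in dataset: ", paste(head(missing, 3), collapse = ", "),
         call. = FALSE)
  feats <- matrix(0, length(ids), model$config$feature_dim,
                  dimnames = list(ids, NULL))
  labels <- character(length(ids)); lesions <- character(length(ids))
  for (i in seq_along(ids)) {
    im <- by_id[[ids[i]]]
    x <- resize_image(im$pixels, res)
    if (want4) {
      if (is.null(saliency_maps[[im$image_id]]))
        stop("feature extraction failed for '", im$image_id,
             "': no saliency map for 4-channel model", call. = FALSE)
      x <- compose_four_channel(x, saliency_maps[[im$image_id]])
    }
    feats[i, ] <- extract_features(model, x)
    labels[i] <- im$label
    lesions[i] <- im$lesion_id
  }
  structure(list(features = feats, labels = labels, lesion_ids = lesions,
                 feature_dim = model$config$feature_dim,
                 model_id = model$model_id),
            class = "feature_index")
}

#' Ranked similarity query against a feature index
#'
#' Ranks eligible index entries by descending cosine similarity to the query
#' features, with ties broken by ascending `image_id`. The query's own image
#' and every entry sharing the query's `lesion_id` (follow-up images of the
#' same lesion) are excluded before ranking, to maximise diversity of the
#' retrieved set.
#'
#' @param index A `feature_index`.
#' @param query_features Numeric vector of length `index$feature_dim`.
#' @param query_lesion_id Lesion id of the query (its images are excluded);
#'   `NA` to exclude nothing.
#' @param k Number of entries to return (>= 1).
#' @param query_image_id Optional id of the query image (excluded, recorded).
#' @return A `retrieval_result`: data.frame-backed list with `ranking`
#'   (columns `rank`, `image_id`, `similarity`, `label`), `query_image_id`,
#'   `k`, and `truncated` (TRUE when fewer than `k` eligible entries exist).
#' @export
query_index <- function(index, query_features, query_lesion_id = NA,
                        k = 6L, query_image_id = NA_character_) {
  stopifnot(inherits(index, "feature_index"), k >= 1,
            length(query_features) == index$feature_dim)
  elig <- rep(TRUE, nrow(index$features))
  if (!is.na(query_lesion_id))
    elig <- elig & (index$lesion_ids != query_lesion_id)
  if (!is.na(query_image_id))
    elig <- elig & (rownames(index$features) != query_image_id)
  if (!any(elig))
    stop("no eligible index entries after exclusions", call. = FALSE)
  qn <- sqrt(sum(query_features^2))
  if (qn == 0) stop("query feature vector is all-zero", call. = FALSE)
  Fm <- index$features[elig, , drop = FALSE]
  norms <- sqrt(rowSums(Fm^2))
  sims <- as.numeric(Fm %*% query_features) / (norms * qn)
  sims <- pmin(pmax(sims, -1), 1)
  ids <- rownames(Fm)
  ord <- order(-sims, ids)
  take <- head(ord, k)
  structure(list(
    query_image_id = query_image_id,
    k = as.integer(k),
    truncated = length(ord) < k,
    ranking = data.frame(rank = seq_along(take),
                         image_id = ids[take],
                         similarity = sims[take],
                         label = index$labels[elig][take],
                         stringsAsFactors = FALSE)),
    class = "retrieval_result")
}

#' Persist / reload a feature index
#'
#' The feature matrix is stored as a plain-text matrix file alongside a CSV
#' manifest (`image_id`, `lesion_id`, `dx`) and a JSON header recording the
#' feature dimension and model fingerprint.
#'
#' @param index A `feature_index`.
#' @param dir Output directory.
#' @return `dir` invisibly (`write_index`); the index (`read_index`).
#' @export
write_index <- function(index, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(image_id = rownames(index$features),
                       lesion_id = index$lesion_ids,
                       dx = index$labels, stringsAsFactors = FALSE),
            file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  write.table(index$features, file.path(dir, "features.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(feature_dim = index$feature_dim,
                            model_id = index$model_id),
                       file.path(dir, "header.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_index
#' @export
read_index <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  feats <- as.matrix(read.table(file.path(dir, "features.tsv"), sep = "\t"))
  dimnames(feats) <- list(man$image_id, NULL)
  structure(list(features = feats, labels = man$dx,
                 lesion_ids = man$lesion_id,
                 feature_dim = hdr$feature_dim, model_id = hdr$model_id),
            class = "feature_index")
}
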