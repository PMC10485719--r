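#' Evaluation of retrieval quality
#'
#' Retrieval is scored with the cut-off precision P@k — the fraction of the
#' top-k retrieved images sharing the query's class, averaged over the
#' queries of each class — and the macro average AP@k, the unweighted mean of
#' the per-class P@k over the M = 7 classes.
#'
#' @name retrieval-evaluation
NULL

# normalise heterogeneous inputs to list(labels=..., query_label=...,
# truncated=...)
as_eval_entries <- function(results) {
  lapply(results, function(r) {
    if (!is.null(r$result) && inherits(r$result, "retrieval_result")) {
      list(labels = r$result$ranking$label, query_label = r$query_label,
           truncated = isTRUE(r$result$truncated))
    } else if (inherits(r, "retrieval_result")) {
      stop("each result needs a query_label; wrap as ",
           "list(result = <retrieval_result>, query_label = <class>)",
           call. = FALSE)
    } else {
      list(labels = r$labels, query_label = r$query_label,
           truncated = isTRUE(r$truncated))
    }
  })
}

#' Per-class retrieval precision at cut-off k
#'
#' For each query, precision is the number of top-k retrieved images whose
#' label equals the query's label, divided by k; per-class P@k averages this
#' over the queries of the class. Queries with fewer than k retrieved entries
#' (truncated lists) are excluded with a warning rather than padded.
#'
#' @param results List of entries, each either
#'   `list(result = <retrieval_result>, query_label = <class>)` or
#'   `list(labels = <retrieved labels>, query_label = <class>)`.
#' @param k Cut-off (>= 1).
#' @return Named numeric vector of per-class P@k over [lesion_classes()];
#'   `NA` for classes with no queries.
#' @export
precision_at_k <- function(results, k) {
  stopifnot(k >= 1)
  entries <- as_eval_entries(results)
  ok <- vapply(entries, function(e) length(e$labels) >= k, logical(1))
  if (any(!ok))
    warning(sum(!ok), " quer", if (sum(!ok) == 1) "y" else "ies",
            " with fewer than k=", k, " retrieved entries excluded")
  entries <- entries[ok]
  classes <- lesion_classes()
  prec <- vapply(entries, function(e)
    mean(e$labels[seq_len(k)] == e$query_label), numeric(1))
  qcls <- vapply(entries, `[[`, "", "query_label")
  out <- setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    if (any(qcls == cl)) out[cl] <- mean(prec[qcls == cl])
  }
  out
}

#' Macro average precision at cut-off k
#'
#' The unweighted mean of the per-class P@k values over the M classes.
#' Classes with no queries (undefined P@k) are excluded with a warning.
#'
#' @param per_class Named per-class P@k vector (from [precision_at_k()]) or a
#'   `precision_report`.
#' @param k When a report is given, which cut-off to average.
#' @return Scalar AP@k in \[0,1\].
#' @export
average_precision_at_k <- function(per_class, k = NULL) {
  if (inherits(per_class, "precision_report")) {
    stopifnot(!is.null(k))
    pc <- per_class$per_class
    per_class <- setNames(pc$p_at_k[pc$k == k], pc$class[pc$k == k])
  }
  if (anyNA(per_class)) {
    warning("classes with no queries excluded from AP: ",
            paste(names(per_class)[is.na(per_class)], collapse = ", "))
    per_class <- per_class[!is.na(per_class)]
  }
  if (!length(per_class)) stop("no class has a defined P@k", call. = FALSE)
  mean(per_class)
}

#' Full precision report over a set of cut-offs
#'
#' @param results As in [precision_at_k()].
#' @param ks Cut-offs to evaluate, default `c(1, 3, 6, 9)`.
#' @param method Label stored in the report (e.g. "CBIR", "SE-CBIR").
#' @return A `precision_report`: list with `per_class` (data.frame `method`,
#'   `class`, `k`, `p_at_k`, `n_queries`) and `ap` (data.frame `method`, `k`,
#'   `ap_at_k`).
#' @export
precision_report <- function(results, ks = c(1, 3, 6, 9),
                             method = "method") {
  entries <- as_eval_entries(results)
  qcls <- vapply(entries, `[[`, "", "query_label")
  nq <- as.numeric(table(factor(qcls, levels = lesion_classes())))
  per_class <- do.call(rbind, lapply(ks, function(k) {
    p <- suppressWarnings(precision_at_k(results, k))
    data.frame(method = method, class = names(p), k = k, p_at_k = unname(p),
               n_queries = nq, stringsAsFactors = FALSE)
  }))
  ap <- data.frame(method = method, k = ks,
                   ap_at_k = vapply(ks, function(k) {
                     p <- per_class$p_at_k[per_class$k == k]
                     mean(p, na.rm = TRUE)
                   }, numeric(1)))
  structure(list(per_class = per_class, ap = ap), class = "precision_report")
}

#' Majority-vote diagnosis from a retrieval result
#'
#' Predicts the query's class as the most frequent label among the top-k
#' retrieved images. Frequency ties are broken by the larger sum of cosine
#' similarities; remaining ties by ascending class-code order.
#'
#' @param result A `retrieval_result` (or data.frame with `label` and
#'   `similarity` columns).
#' @param k Number of neighbours to vote over, default 6.
#' @return A class code.
#' @export
majority_vote <- function(result, k = 6L) {
  if (!inherits(result, "retrieval_result") && !is.null(result$result))
    result <- result$result
  rk <- if (inherits(result, "retrieval_result")) result$ranking else result
  if (is.null(rk) || nrow(rk) == 0)
    stop("empty retrieval result", call. = FALSE)
  top <- head(rk, k)
  counts <- tapply(rep(1, nrow(top)), top$label, sum)
  simsum <- tapply(top$similarity, top$label, sum)
  cand <- names(counts)
  ord <- order(-counts, -simsum, cand)
  cand[ord][1]
}

#' Compare two precision reports (e.g. CBIR vs SE-CBIR)
#'
#' @param report_a,report_b Two `precision_report`s over the same classes
#'   and cut-offs; deltas are `report_b - report_a`.
#' @return List with `per_class` (signed per-class deltas), `ap` (signed
#'   AP@k deltas) and `summary` (largest and smallest per-class improvement).
#' @export
compare_methods <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "precision_report"),
            inherits(report_b, "precision_report"))
  if (!identical(sort(unique(report_a$ap$k)), sort(unique(report_b$ap$k))))
    stop("reports evaluated at different k-sets", call. = FALSE)
  a <- report_a$per_class[order(report_a$per_class$k,
                                report_a$per_class$class), ]
  b <- report_b$per_class[order(report_b$per_class$k,
                                report_b$per_class$class), ]
  stopifnot(identical(a$class, b$class), identical(a$k, b$k))
  per_class <- data.frame(class = a$class, k = a$k,
                          delta = b$p_at_k - a$p_at_k,
                          stringsAsFactors = FALSE)
  apm <- merge(report_a$ap, report_b$ap, by = "k",
               suffixes = c("_a", "_b"))
  ap <- data.frame(k = apm$k, delta = apm$ap_at_k_b - apm$ap_at_k_a)
  finite <- per_class[!is.na(per_class$delta), ]
  list(per_class = per_class, ap = ap,
       summary = list(
         max_improvement = finite[which.max(finite$delta), ],
         min_improvement = finite[which.min(finite$delta), ]))
}

#' Run retrieval queries for an image subset and collect labeled results
#'
#' Convenience wrapper: extracts features of each query image with the given
#' model, queries the index with same-lesion exclusion, and pairs each
#' ranking with the query's true label — the shape consumed by
#' [precision_at_k()] and [precision_report()].
#'
#' @param index A `feature_index` (typically built from the training split).
#' @param model The model the index was built from.
#' @param dataset Dataset list.
#' @param query_ids Image ids to use as queries (e.g. the test split).
#' @param k Retrieval depth per query.
#' @param saliency_maps Required for a 4-channel model.
#' @return List of `list(result = <retrieval_result>, query_label,
#'   query_image_id)`.
#' @export
run_queries <- function(index, model, dataset, query_ids, k = 9L,
                        saliency_maps = NULL) {
  if (!identical(index$model_id, model$model_id))
    stop("index/model fingerprint mismatch: index was built from '",
         index$model_id, "', model is '", model$model_id, "'",
         call. = FALSE)
  res <- model$config$input_resolution
  want4 <- model$config$in_channels == 4L
  by_id <- setNames(dataset$images,
                    vapply(dataset$images, `[[`, "", "image_id"))
  lapply(query_ids, function(id) {
    im <- by_id[[id]]
    if (is.null(im)) stop("query image '", id, "' not in dataset",
                          call. = FALSE)
    x <- resize_image(im$pixels, res)
    if (want4) {
      if (is.null(saliency_maps[[id]]))
        stop("missing saliency map for query '", id, "'", call. = FALSE)
      x <- compose_four_channel(x, saliency_maps[[id]])
    }
    qf <- extract_features(model, x)
    list(result = query_index(index, qf, im$lesion_id, k = k,
                              query_image_id = id),
         query_label = im$label, query_image_id = id)
  })
}
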