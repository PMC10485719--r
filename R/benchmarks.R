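#' Published dermoscopy retrieval-precision benchmark
#'
#' Per-class P@k values (k = 1, 3, 6, 9) reported by a published dermoscopy
#' reader study for a conventional CBIR retriever and its saliency-enhanced
#' variant on the HAM10000 test set. Shipped as a worked-example input: the
#' package's metric arithmetic (macro AP@k, method deltas) can be exercised
#' on these printed values at full precision.
#'
#' @return Named list of two `precision_report`s: `cbir` and `secbir`.
#' @export
retrieval_precision_benchmark <- function() {
  path <- system.file("extdata", "retrieval_precision_benchmark.csv",
                      package = "secbir", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  mk <- function(method) {
    pc <- tab[tab$method == method, ]
    pc <- pc[order(pc$k, pc$class), ]
    pc$n_queries <- NA_real_
    ks <- sort(unique(pc$k))
    ap <- data.frame(method = method, k = ks,
                     ap_at_k = vapply(ks, function(k)
                       mean(pc$p_at_k[pc$k == k]), numeric(1)))
    structure(list(per_class = pc[, c("method", "class", "k", "p_at_k",
                                      "n_queries")],
                   ap = ap),
              class = "precision_report")
  }
  list(cbir = mk("CBIR"), secbir = mk("SE-CBIR"))
}

#' Published reader-study benchmark table
#'
#' Per-participant accuracy (%) and Likert confidence (absolute and split by
#' correctness) for both study tasks, plus the retrieval algorithm's
#' majority-vote accuracy on each participant's image set, and the melanoma
#' over/under-diagnosis counts per task — as printed by the same published
#' study. Used as worked-example input for the cross-rater aggregation
#' arithmetic.
#'
#' @return List with `per_rater` (data.frame, one row per participant) and
#'   `misdiagnosis` (data.frame with per-task overdiagnosis and
#'   underdiagnosis counts and the melanoma truth total).
#' @export
reader_study_benchmark <- function() {
  per_rater <- read.csv(system.file("extdata", "reader_study_benchmark.csv",
                                    package = "secbir", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  mis <- read.csv(system.file("extdata",
                              "melanoma_misdiagnosis_benchmark.csv",
                              package = "secbir", mustWork = TRUE))
  list(per_rater = per_rater, misdiagnosis = mis)
}
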