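#' Pipeline configuration
#'
#' Bundles every knob of the five-step retrieval pipeline: dataset source
#' (synthetic spec or an on-disk HAM10000-layout directory), backbone, split,
#' focal loss, per-stage schedules, epochs, retrieval cut-offs, output
#' directory and the global seed.
#'
#' @param synthetic A [synthetic_spec()] (ignored when `data_dir` is given).
#' @param data_dir Optional directory readable by [read_dataset()].
#' @param backbone Backbone name, `"tiny_test"` or `"reference_b4"`.
#' @param split_ratios,split_seed Split configuration.
#' @param gamma Focal-loss focusing exponent; alpha is inverse-frequency.
#' @param epochs Epochs per stage (the fine-tuning stage reuses the same
#'   number).
#' @param batch_size Minibatch size.
#' @param schedule_stage1,schedule_stage2 Optional [lr_schedule()]s; defaults
#'   are backbone-from-scratch rates (2e-3/2e-3 stage 1, 2e-4/1e-3 stage 2)
#'   since no pretrained weights are used.
#' @param ks Retrieval cut-offs for evaluation.
#' @param out_dir Output directory for artifacts; `NULL` keeps everything
#'   in memory.
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(),
                            data_dir = NULL,
                            backbone = "tiny_test",
                            split_ratios = c(0.8, 0.1, 0.1),
                            split_seed = NULL,
                            gamma = 2,
                            epochs = 20L,
                            batch_size = 32L,
                            schedule_stage1 = NULL,
                            schedule_stage2 = NULL,
                            ks = c(1, 3, 6, 9),
                            out_dir = NULL,
                            seed = 1L) {
  if (!is.null(data_dir) && !dir.exists(data_dir))
    stop("data_dir '", data_dir, "' does not exist", call. = FALSE)
  if (is.null(split_seed)) split_seed <- seed
  if (is.null(schedule_stage1))
    schedule_stage1 <- lr_schedule(3e-3, 3e-3, min(2L, epochs - 1L), 0.93,
                                   epochs)
  if (is.null(schedule_stage2))
    schedule_stage2 <- lr_schedule(2e-4, 1e-3, min(2L, epochs - 1L), 0.93,
                                   epochs)
  structure(list(synthetic = synthetic, data_dir = data_dir,
                 backbone = backbone, split_ratios = split_ratios,
                 split_seed = split_seed, gamma = gamma,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 schedule_stage1 = schedule_stage1,
                 schedule_stage2 = schedule_stage2,
                 ks = ks, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full retrieval pipeline
#'
#' Executes the five pipeline steps in order — (1) train the 3-channel
#' classifier, (2) extract vanilla-gradient saliency maps, (3) fine-tune the
#' 4-channel classifier, (4) extract deep features and build the index,
#' (5) answer ranked similarity queries — and, for comparison, the
#' conventional-CBIR baseline that uses only steps 1, 4 and 5. The retrieval
#' set is the training split; queries are the test split. When
#' `config$out_dir` is set, every artifact (models, saliency maps, indices,
#' evaluation CSVs and a provenance manifest with all seeds) is written to
#' disk.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return List with `dataset`, `split`, `model_stage1`, `saliency`,
#'   `model_stage2`, `index_cbir`, `index_secbir`, `report_cbir`,
#'   `report_secbir`, `comparison`, `majority_vote_accuracy` (per method).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  stage <- "data"
  result <- list()
  tryCatch({
    dataset <- if (!is.null(config$data_dir)) read_dataset(config$data_dir)
               else generate_dataset(config$synthetic)
    result$dataset <- dataset
    say("dataset: ", nrow(dataset$metadata), " images")

    stage <- "split"
    split <- stratified_split(dataset$metadata, config$split_ratios,
                              config$split_seed)
    result$split <- split

    stage <- "stage1-training"
    cfg3 <- backbone_config(config$backbone, in_channels = 3L)
    model3 <- build_classifier(cfg3, seed = config$seed)
    md_tr <- split$table[split$table$subset == "train", ]
    loss_params <- focal_loss_params(alpha_from_frequencies(md_tr),
                                     config$gamma)
    say("stage 1: training ", config$backbone, " for ", config$epochs,
        " epochs")
    model3 <- train_stage1(dataset, split, model3,
                           loss_params = loss_params,
                           schedule = config$schedule_stage1,
                           epochs = config$epochs,
                           batch_size = config$batch_size,
                           seed = config$seed, verbose = verbose)
    result$model_stage1 <- model3

    stage <- "saliency"
    say("stage 2: extracting saliency maps")
    sal <- saliency_for_dataset(model3, dataset)
    result$saliency <- sal

    stage <- "stage2-finetuning"
    say("stage 3: fine-tuning 4-channel model")
    model4 <- train_stage2(dataset, split, model3, sal,
                           loss_params = loss_params,
                           schedule = config$schedule_stage2,
                           epochs = config$epochs,
                           batch_size = config$batch_size,
                           seed = config$seed + 1L, verbose = verbose)
    result$model_stage2 <- model4

    stage <- "indexing"
    train_ids <- split_image_ids(split, "train")
    test_ids <- split_image_ids(split, "test")
    say("steps 4-5: indexing ", length(train_ids), " images, querying ",
        length(test_ids))
    index_cbir <- build_index(model3, dataset, train_ids)
    index_secbir <- build_index(model4, dataset, train_ids,
                                saliency_maps = sal)
    result$index_cbir <- index_cbir
    result$index_secbir <- index_secbir

    stage <- "evaluation"
    kmax <- max(config$ks)
    q_cbir <- run_queries(index_cbir, model3, dataset, test_ids, k = kmax)
    q_secbir <- run_queries(index_secbir, model4, dataset, test_ids,
                            k = kmax, saliency_maps = sal)
    report_cbir <- precision_report(q_cbir, config$ks, method = "CBIR")
    report_secbir <- precision_report(q_secbir, config$ks,
                                      method = "SE-CBIR")
    result$queries_cbir <- q_cbir
    result$queries_secbir <- q_secbir
    result$report_cbir <- report_cbir
    result$report_secbir <- report_secbir
    result$comparison <- compare_methods(report_cbir, report_secbir)
    mv_acc <- function(qs) {
      pred <- vapply(qs, function(q) majority_vote(q$result, 6L), "")
      truth <- vapply(qs, `[[`, "", "query_label")
      100 * mean(pred == truth)
    }
    result$majority_vote_accuracy <- c(cbir = mv_acc(q_cbir),
                                       secbir = mv_acc(q_secbir))

    if (!is.null(config$out_dir)) {
      stage <- "artifacts"
      od <- config$out_dir
      dir.create(od, recursive = TRUE, showWarnings = FALSE)
      save_model(model3, file.path(od, "model_stage1.rds"))
      save_model(model4, file.path(od, "model_stage2.rds"))
      write_saliency(sal, file.path(od, "saliency"), model3$model_id)
      write_index(index_cbir, file.path(od, "index_cbir"))
      write_index(index_secbir, file.path(od, "index_secbir"))
      write.csv(rbind(report_cbir$per_class, report_secbir$per_class),
                file.path(od, "precision_per_class.csv"), row.names = FALSE)
      write.csv(rbind(report_cbir$ap, report_secbir$ap),
                file.path(od, "precision_ap.csv"), row.names = FALSE)
      write.csv(split$table, file.path(od, "split.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(seed = config$seed, split_seed = config$split_seed,
             backbone = config$backbone, epochs = config$epochs,
             gamma = config$gamma, ks = config$ks,
             model_stage1 = model3$model_id,
             model_stage2 = model4$model_id,
             majority_vote_accuracy = as.list(
               result$majority_vote_accuracy)),
        file.path(od, "manifest.json"), auto_unbox = TRUE, digits = NA)
    }
    result
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
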