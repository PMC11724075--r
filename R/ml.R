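## Random-forest hit expansion on circular fingerprints: train on labeled
## screen compounds, rank unscreened library compounds by predicted
## activity probability.

#' Train a random-forest activity classifier
#'
#' Fits a probability forest (default 500 trees, class weights inverse to
#' class frequency, single-threaded for reproducibility) and reports
#' stratified k-fold cross-validation AUROC, precision and recall.
#'
#' @param fp a \linkS4class{FingerprintMatrix} of the training compounds.
#' @param labels logical activity labels, parallel to the fingerprint
#'   rows; both classes must be present.
#' @param nTrees number of trees (default 500).
#' @param seed integer RNG seed (forest and CV folds).
#' @param nFolds stratified CV folds (default 5; 0 skips CV).
#' @param threshold probability threshold stored for prediction (default
#'   0.5).
#' @return an \linkS4class{ActivityModel}.
#' @export
trainActivityModel <- function(fp, labels, nTrees = 500L, seed = 1L,
                               nFolds = 5L, threshold = 0.5) {
  stopifnot(is(fp, "FingerprintMatrix"))
  labels <- as.logical(labels)
  if (length(labels) != nrow(fp@bits))
    stop("labels must parallel the fingerprint rows", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: both classes must be present", call. = FALSE)
  y <- factor(ifelse(labels, "active", "inactive"),
              levels = c("inactive", "active"))
  w <- 1 / table(y)[levels(y)]
  bits <- fp@bits
  colnames(bits) <- paste0("X", seq_len(ncol(bits)))
  df <- data.frame(y = y, bits)
  fitOne <- function(d, s) ranger::ranger(
    y ~ ., data = d, num.trees = nTrees, probability = TRUE,
    class.weights = as.numeric(w), seed = s, num.threads = 1L)
  cv <- list()
  if (nFolds > 1L) {
    folds <- withSeed(seed, {
      f <- integer(length(y))
      for (cl in levels(y)) {
        idx <- which(y == cl)
        f[idx] <- resample(rep_len(seq_len(nFolds), length(idx)), length(idx))
      }
      f
    })
    prob <- numeric(length(y))
    for (k in seq_len(nFolds)) {
      hold <- folds == k
      m <- fitOne(df[!hold, , drop = FALSE], seed + k)
      prob[hold] <- predict(m, df[hold, , drop = FALSE],
                            num.threads = 1L)$predictions[, "active"]
    }
    pred <- prob >= threshold
    roc <- suppressMessages(pROC::roc(response = labels, predictor = prob,
                                      quiet = TRUE, direction = "<"))
    cv <- list(auroc = as.numeric(pROC::auc(roc)),
               precision = if (any(pred)) sum(pred & labels) / sum(pred) else NA_real_,
               recall = sum(pred & labels) / sum(labels),
               folds = nFolds)
  }
  forest <- fitOne(df, seed)
  new("ActivityModel", forest = forest,
      config = list(nTrees = as.integer(nTrees), seed = as.integer(seed),
                    classWeights = as.numeric(w), threshold = threshold),
      cvMetrics = cv, trainingIds = fp@ids,
      fpConfig = list(radius = fp@radius, nBits = fp@nBits))
}

#' Predict actives in an unscreened library
#'
#' Featurizes the library with the model's fingerprint configuration,
#' removes compounds that were in the training set, and returns predicted
#' probabilities sorted descending (ties broken by compound id).
#'
#' @param model an \linkS4class{ActivityModel}.
#' @param library a \linkS4class{CompoundLibrary} or a
#'   \linkS4class{FingerprintMatrix} already computed with the model's
#'   configuration.
#' @param threshold decision threshold (default: the model's stored
#'   threshold).
#' @return data.frame: \code{compound_id}, \code{probability},
#'   \code{predicted_active}.
#' @export
predictActives <- function(model, library, threshold = NULL) {
  stopifnot(is(model, "ActivityModel"))
  if (is.null(threshold)) threshold <- model@config$threshold
  fp <- if (is(library, "FingerprintMatrix")) {
    if (library@radius != model@fpConfig$radius ||
        library@nBits != model@fpConfig$nBits)
      stop("fingerprint configuration mismatch with the model", call. = FALSE)
    library
  } else {
    morganFingerprints(library, radius = model@fpConfig$radius,
                       nBits = model@fpConfig$nBits, quiet = TRUE)
  }
  keep <- !(fp@ids %in% model@trainingIds)
  if (!any(keep))
    return(data.frame(compound_id = character(), probability = numeric(),
                      predicted_active = logical()))
  bits <- fp@bits[keep, , drop = FALSE]
  colnames(bits) <- paste0("X", seq_len(ncol(bits)))
  prob <- predict(model@forest, data.frame(bits),
                  num.threads = 1L)$predictions[, "active"]
  out <- data.frame(compound_id = fp@ids[keep], probability = prob,
                    predicted_active = prob >= threshold)
  out[order(-out$probability, out$compound_id), , drop = FALSE]
}

#' Persist / restore an activity model
#'
#' The model is written as a directory archive: the forest serialized by
#' ranger plus a JSON config. (Kept simple: a versioned RDS for the forest
#' and a sidecar JSON describing configuration.)
#'
#' @param model an \linkS4class{ActivityModel}.
#' @param path directory to write.
#' @return \code{readActivityModel}: the restored model.
#' @export
writeActivityModel <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model@forest, file.path(path, "forest.rds"))
  jsonlite::write_json(
    list(version = 1L, config = model@config, cvMetrics = model@cvMetrics,
         trainingIds = model@trainingIds, fpConfig = model@fpConfig),
    file.path(path, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeActivityModel
#' @export
readActivityModel <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  new("ActivityModel", forest = readRDS(file.path(path, "forest.rds")),
      config = as.list(meta$config), cvMetrics = as.list(meta$cvMetrics),
      trainingIds = as.character(meta$trainingIds),
      fpConfig = as.list(meta$fpConfig))
}
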