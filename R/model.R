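# Linear SVM fallback classifier. Labels follow the three-class annotation
# scheme {positive, suspected, negative}; "suspected" is merged into
# "positive" before the split, so the fitted model is binary. The split is
# stratified 80/20 under the caller's seed; the feature spec is built on the
# training portion only, and held-out metrics come from the untouched 20%.

#' Train the snippet text model
#'
#' @param snippets snippet data.frame ([extract_snippets()] columns).
#' @param labels character vector, one of `"positive"`, `"suspected"`,
#'   `"negative"` per snippet; `"suspected"` is merged into `"positive"`.
#' @param split_fraction training fraction (default 0.8).
#' @param seed integer seed controlling the stratified split.
#' @param min_document_frequency vocabulary document-frequency floor.
#' @param spec optional pre-built [build_feature_spec()]; when supplied it is
#'   used as-is (no refit on the training portion).
#' @param cost SVM regularization constant (default 1, the library default).
#' @return An object of class `opioid_text_model`: the feature spec, the
#'   fitted linear SVM, the seed, the split indices (`train_idx`,
#'   `test_idx`), and the four held-out metrics
#'   (sensitivity/specificity/ppv/accuracy).
#' @export
train_text_model <- function(snippets, labels, split_fraction = 0.8,
                             seed = 1L, min_document_frequency = 2L,
                             spec = NULL, cost = 1) {
  stopifnot(nrow(snippets) == length(labels),
            split_fraction > 0, split_fraction < 1)
  bad <- !labels %in% c("positive", "suspected", "negative")
  if (any(bad)) stop("unknown label(s): ", paste(unique(labels[bad]), collapse = ", "))
  y <- ifelse(labels == "negative", "negative", "positive")
  if (length(unique(y)) < 2L)
    stop("training corpus contains a single class ('", unique(y),
         "'); both classes are required")
  if (min(table(y)) < 2L)
    stop("need at least 2 examples per class")

  set.seed(as.integer(seed))
  train_idx <- sort(unlist(lapply(split(seq_along(y), y), function(idx) {
    k <- min(length(idx) - 1L, max(1L, round(split_fraction * length(idx))))
    sample(idx, k)
  }), use.names = FALSE))
  test_idx <- setdiff(seq_along(y), train_idx)

  if (is.null(spec))
    spec <- build_feature_spec(snippets$text[train_idx],
                               min_document_frequency = min_document_frequency)
  x_train <- featurize(snippets[train_idx, , drop = FALSE], spec)
  fit <- e1071::svm(x = x_train,
                    y = factor(y[train_idx], levels = c("negative", "positive")),
                    kernel = "linear", cost = cost, scale = FALSE)

  model <- structure(
    list(spec = spec, svm = fit, seed = as.integer(seed), cost = cost,
         split_fraction = split_fraction,
         train_idx = train_idx, test_idx = test_idx, metrics = NULL),
    class = "opioid_text_model")
  pred <- predict(model, snippets[test_idx, , drop = FALSE])
  model$metrics <- classification_metrics(
    confusion_counts(y[test_idx], as.character(pred)))
  model
}

#' Predict snippet labels with a trained text model
#'
#' @param object an [train_text_model()] result.
#' @param snippets snippet data.frame to classify.
#' @param ... unused.
#' @return factor of `"positive"`/`"negative"`, one per snippet.
#' @export
predict.opioid_text_model <- function(object, snippets, ...) {
  if (is.null(object$svm)) stop("model has not been trained")
  if (nrow(snippets) == 0L)
    return(factor(character(), levels = c("negative", "positive")))
  stats::predict(object$svm, featurize(snippets, object$spec))
}

#' @export
print.opioid_text_model <- function(x, ...) {
  cat("Snippet text model (linear SVM, cost ", x$cost, ", seed ", x$seed,
      ")\n", sep = "")
  print(x$spec)
  cat("Split: ", length(x$train_idx), " train / ", length(x$test_idx),
      " held out\n", sep = "")
  if (!is.null(x$metrics)) {
    cat("Held-out metrics:\n")
    print(round(x$metrics, 4))
  }
  invisible(x)
}

#' Persist / restore a trained text model
#'
#' The model is saved as a binary artifact plus a JSON sidecar
#' (`<path>.json`) recording the feature spec, seed, split sizes and
#' held-out metrics for inspection without loading the binary.
#'
#' @param model an `opioid_text_model`.
#' @param path file path for the binary artifact.
#' @return `path`, invisibly (`save_text_model`); the model
#'   (`load_text_model`).
#' @export
save_text_model <- function(model, path) {
  stopifnot(inherits(model, "opioid_text_model"))
  saveRDS(model, path)
  sidecar <- list(
    format_version = 1L,
    seed = model$seed, cost = model$cost,
    split_fraction = model$split_fraction,
    n_train = length(model$train_idx), n_test = length(model$test_idx),
    unigram_vocab = model$spec$unigram_vocab,
    bigram_vocab = model$spec$bigram_vocab,
    include_position = model$spec$include_position,
    min_document_frequency = model$spec$min_document_frequency,
    held_out_metrics = as.list(model$metrics))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_text_model
#' @export
load_text_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "opioid_text_model"))
    stop("file does not contain an opioid_text_model: ", path)
  model
}
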