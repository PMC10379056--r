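#' Bagged random-forest classifier configuration
#'
#' @param n_trees number of bagged trees (default 100).
#' @param seed integer seed.
#' @param export_trees keep readable per-tree split text in the model.
#' @param mtry variables tried per split; `NULL` = `sqrt(p)` default.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(n_trees = 100L, seed = 1L,
                              export_trees = FALSE, mtry = NULL) {
  if (!is.numeric(n_trees) || n_trees < 1L)
    stop("n_trees must be a positive integer")
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed),
                 export_trees = isTRUE(export_trees), mtry = mtry),
            class = "classifier_config")
}

# one-hot encoder fitted on training levels; unseen levels at predict time
# collapse into an explicit "__unseen__" indicator per variable
fit_onehot <- function(data, columns) {
  levels_of <- lapply(columns, function(nm) sort(unique(as.character(data[[nm]]))))
  names(levels_of) <- columns
  encode <- function(newdata) {
    mats <- lapply(columns, function(nm) {
      v <- as.character(newdata[[nm]])
      levs <- levels_of[[nm]]
      m <- matrix(0L, nrow = length(v), ncol = length(levs) + 1L,
                  dimnames = list(NULL, paste0(nm, "=", c(levs, "__unseen__"))))
      known <- v %in% levs
      if (any(known)) m[cbind(which(known), match(v[known], levs))] <- 1L
      if (any(!known)) m[cbind(which(!known), length(levs) + 1L)] <- 1L
      m
    })
    do.call(cbind, mats)
  }
  list(levels = levels_of, encode = encode)
}

#' Train a bagged random forest on a categorical feature table
#'
#' Categorical features are one-hot encoded (portable across forest
#' implementations; unseen levels at prediction time map to a dedicated
#' indicator rather than erroring).  The forest is `n_trees` bagged trees;
#' refitting with the same seed reproduces identical predictions.
#'
#' @param train a [feature_table()].
#' @param config a [classifier_config()].
#' @return A `domain_forest` model: the fitted forest, the one-hot
#'   encoder, class levels and config.
#' @export
train_random_forest <- function(train, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  cc <- ft_class(train)
  stopifnot(!is.null(cc))
  y <- droplevels(train[[cc]])
  if (nlevels(y) < 2L) stop("training data has a single class")
  cols <- setdiff(names(train), cc)
  enc <- fit_onehot(train, cols)
  X <- enc$encode(train)
  set.seed(config$seed)
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(X)))) else config$mtry
  fit <- randomForest::randomForest(x = X, y = y, ntree = config$n_trees,
                                    mtry = mtry)
  trees <- NULL
  if (config$export_trees) {
    trees <- lapply(seq_len(config$n_trees), function(k)
      randomForest::getTree(fit, k, labelVar = TRUE))
  }
  structure(list(forest = fit, encoder = enc, classes = levels(y),
                 class_column = cc, feature_columns = cols,
                 config = config, trees = trees),
            class = "domain_forest")
}

#' @export
print.domain_forest <- function(x, ...) {
  cat(sprintf("domain_forest: %d trees, %d classes (%s), %d one-hot inputs\n",
              x$config$n_trees, length(x$classes),
              paste(utils::head(x$classes, 4), collapse = ","),
              length(unlist(x$encoder$levels)) + length(x$encoder$levels)))
  invisible(x)
}

#' Export the forest's trees as readable text
#' @param model a `domain_forest` trained with `export_trees = TRUE`.
#' @return character vector, one block per tree.
#' @export
export_tree_text <- function(model) {
  stopifnot(inherits(model, "domain_forest"))
  if (is.null(model$trees))
    stop("model was trained without export_trees = TRUE")
  vapply(seq_along(model$trees), function(k) {
    tr <- model$trees[[k]]
    paste0("tree ", k, "\n",
           paste(utils::capture.output(print(tr)), collapse = "\n"))
  }, "")
}

#' @export
predict.domain_forest <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  X <- object$encoder$encode(newdata)
  if (type == "class") {
    # argmax of class probabilities; ties break to the lexicographically
    # smallest class label
    p <- stats::predict(object$forest, X, type = "prob")
    cls <- colnames(p)[apply(p, 1L, which.max)]
    factor(cls, levels = object$classes)
  } else {
    stats::predict(object$forest, X, type = "prob")
  }
}

compute_metrics <- function(truth, pred, prob, classes) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  cm <- base::table(truth = truth, predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(cm[cl, ]), stringsAsFactors = FALSE)
  }))
  list(accuracy = acc, confusion = cm, per_class = per_class,
       class_distribution = prob)
}

#' Evaluate the classification protocol under an evaluation scheme
#'
#' Runs the full leak-free protocol: for each train/test split of the
#' scheme, numeric columns are converted to categoricals with conversions
#' fitted on the training fold only, the training fold only is rebalanced,
#' a forest is trained, and the held-out fold is predicted.  Reports
#' accuracy, per-class precision/recall/F1, the confusion matrix, and the
#' per-instance class-probability distribution table (rows sum to 1).
#'
#' @param table a [feature_table()]; character columns are used as-is and
#'   numeric-convertible columns may be declared in `conversions`.
#' @param scheme `"cv10"`, `"split66"` or `"holdout"`.
#' @param config a [classifier_config()].
#' @param balance_method `"none"`, `"resample"` or `"spread_subsample"`.
#' @param conversions named list column -> list(method =, k =) describing
#'   how to convert that numeric column per training fold.
#' @param seed integer seed driving the split and balancing.
#' @return An `evaluation_report`.
#' @export
evaluate_scheme <- function(table, scheme = c("cv10", "split66", "holdout"),
                            config = classifier_config(),
                            balance_method = c("none", "resample",
                                               "spread_subsample"),
                            conversions = list(), seed = 1L) {
  scheme <- match.arg(scheme)
  balance_method <- match.arg(balance_method)
  cc <- ft_class(table)
  stopifnot(!is.null(cc))
  splits <- split_scheme(table, scheme, seed = seed)
  classes <- levels(droplevels(table[[cc]]))
  all_pred <- character(nrow(table))
  all_prob <- matrix(NA_real_, nrow(table), length(classes),
                     dimnames = list(NULL, classes))
  tested <- logical(nrow(table))
  fold_conversions <- list()
  for (fi in seq_along(splits)) {
    sp <- splits[[fi]]
    tr <- table[sp$train, , drop = FALSE]
    te <- table[sp$test, , drop = FALSE]
    # fit categorical conversions inside the training fold only
    if (length(conversions)) {
      fitted <- list()
      for (nm in names(conversions)) {
        cv <- conversions[[nm]]
        conv <- to_categorical(as.numeric(tr[[nm]]),
                               method = cv$method %||% "direct",
                               k = cv$k %||% 2L, seed = seed + fi)
        tr[[nm]] <- conv$labels
        te[[nm]] <- conv$assign(as.numeric(te[[nm]]))
        fitted[[nm]] <- conv
      }
      fold_conversions[[fi]] <- fitted
    }
    tr <- feature_table(as.data.frame(tr), cc)
    if (balance_method != "none")
      tr <- balance(tr, balance_method, seed = seed + fi)
    model <- train_random_forest(tr, config)
    prob <- predict(model, te, type = "prob")
    full <- matrix(0, nrow(te), length(classes),
                   dimnames = list(NULL, classes))
    full[, colnames(prob)] <- prob
    pred <- colnames(full)[apply(full, 1L, which.max)]
    all_pred[sp$test] <- pred
    all_prob[sp$test, ] <- full
    tested[sp$test] <- TRUE
  }
  truth <- as.character(table[[cc]])[tested]
  m <- compute_metrics(truth, all_pred[tested], all_prob[tested, , drop = FALSE],
                       classes)
  structure(list(scheme = scheme, accuracy = m$accuracy,
                 per_class = m$per_class, confusion = m$confusion,
                 class_distribution = m$class_distribution,
                 n_tested = sum(tested),
                 fold_conversions = fold_conversions,
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report [%s]: accuracy %.3f over %d tested instances\n",
              x$scheme, x$accuracy, x$n_tested))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the summary metrics and the per-instance class-probability
#' distribution as TSV text (deterministic byte-for-byte under a fixed
#' seed).
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @export
write_evaluation_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("scheme\t%s", report$scheme), con)
  writeLines(sprintf("accuracy\t%.10f", report$accuracy), con)
  writeLines(sprintf("n_tested\t%d", report$n_tested), con)
  writeLines("", con)
  pc <- report$per_class
  writeLines(paste(names(pc), collapse = "\t"), con)
  for (i in seq_len(nrow(pc)))
    writeLines(paste(c(pc$class[i],
                       sprintf("%.10f", c(pc$precision[i], pc$recall[i],
                                          pc$f1[i])),
                       pc$support[i]), collapse = "\t"), con)
  writeLines("", con)
  writeLines(paste(c("instance", colnames(report$class_distribution)),
                   collapse = "\t"), con)
  cd <- report$class_distribution
  for (i in seq_len(nrow(cd)))
    writeLines(paste(c(i, sprintf("%.10f", cd[i, ])), collapse = "\t"), con)
  invisible(path)
}
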