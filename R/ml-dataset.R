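#' Construct a mixed categorical feature table
#'
#' The common currency of the prediction pipeline: a data.frame of named
#' categorical feature columns plus one declared class column, with
#' optional per-column provenance (which feature module produced it).
#'
#' @param data data.frame; all columns are coerced to character except the
#'   class column, which becomes a factor.
#' @param class_column name of the class column.
#' @param provenance optional named character vector column -> source
#'   module.
#' @return A `feature_table` (data.frame subclass with attributes
#'   `class_column` and `provenance`).
#' @export
feature_table <- function(data, class_column, provenance = NULL) {
  stopifnot(is.data.frame(data), class_column %in% names(data))
  if (anyNA(data[[class_column]]))
    stop("class column must have no missing values")
  for (nm in setdiff(names(data), class_column))
    data[[nm]] <- as.character(data[[nm]])
  data[[class_column]] <- factor(as.character(data[[class_column]]))
  structure(data, class = c("feature_table", "data.frame"),
            class_column = class_column, provenance = provenance)
}

ft_class <- function(table) attr(table, "class_column")

#' @export
print.feature_table <- function(x, ...) {
  cc <- ft_class(x)
  cat(sprintf("feature_table: %d instances, %d features, class '%s' (%d levels)\n",
              nrow(x), ncol(x) - 1L, cc, nlevels(x[[cc]])))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Bisect a feature table on LLPS-associated Pfams
#'
#' Splits instances into an LLPS table (at least one Pfam associated with
#' phase separation) and a non-LLPS table; the partition is exhaustive and
#' exclusive.
#'
#' @param table a [feature_table()] (or data.frame) with a `pfams` column
#'   of comma-separated Pfam lists.
#' @param llps_pfams non-empty character vector of LLPS-associated Pfams.
#' @param pfam_column name of the Pfam list column.
#' @return list with `llps` and `non_llps` tables.
#' @export
bisect_llps <- function(table, llps_pfams, pfam_column = "pfams") {
  if (length(llps_pfams) == 0L) stop("llps_pfams set must be non-empty")
  stopifnot(pfam_column %in% names(table))
  has <- vapply(strsplit(as.character(table[[pfam_column]]), ",", fixed = TRUE),
                function(p) any(p %in% llps_pfams), logical(1))
  list(llps = table[has, , drop = FALSE],
       non_llps = table[!has, , drop = FALSE])
}

#' Convert a numeric array variable into a categorical column
#'
#' Numeric feature arrays become categorical variables either by direct
#' mapping (each distinct value one category) or by clustering: k-means,
#' a Gaussian-mixture EM fit, or a density-based 1-d valley cut.  Cluster
#' memberships are the category values; labels are `"cluster_0"`,
#' `"cluster_1"`, ... in order of descending cluster size, so the labels
#' are stable across refits.  Stochastic methods are deterministic under a
#' fixed seed.
#'
#' @param values numeric vector.
#' @param method `"direct"`, `"kmeans"`, `"em"` or `"density"`.
#' @param k number of clusters (kmeans/em).
#' @param seed integer seed for stochastic methods.
#' @return A `categorical_conversion`: list with `method`, `labels`
#'   (character vector parallel to `values`), and `assign(newdata)` for
#'   applying the fitted conversion to new values.
#' @importFrom mclust Mclust mclustBIC
#' @export
to_categorical <- function(values, method = c("direct", "kmeans", "em",
                                              "density"),
                           k = 2L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (method == "direct") {
    labs <- as.character(values)
    res <- list(method = method,
                labels = labs,
                assign = function(newdata) as.character(newdata))
    return(structure(res, class = "categorical_conversion"))
  }
  nd <- length(unique(values))
  if (method %in% c("kmeans", "em") && k > nd)
    stop(sprintf("k = %d exceeds the %d distinct values", k, nd))
  centers <- switch(method,
    kmeans = {
      set.seed(seed)
      fit <- stats::kmeans(values, centers = k, nstart = 10L)
      as.numeric(fit$centers)
    },
    em = {
      set.seed(seed)
      fit <- Mclust(values, G = k, verbose = FALSE)
      as.numeric(fit$parameters$mean)
    },
    density = {
      # valley cut on a kernel density estimate
      d <- stats::density(values)
      ys <- d$y
      valleys <- which(diff(sign(diff(ys))) == 2) + 1L
      cuts <- d$x[valleys]
      cuts <- cuts[cuts > min(values) & cuts < max(values)]
      brks <- c(-Inf, cuts, Inf)
      mids <- vapply(seq_len(length(brks) - 1L), function(i) {
        inb <- values > brks[i] & values <= brks[i + 1L]
        if (any(inb)) mean(values[inb]) else NA_real_
      }, 0)
      mids[!is.na(mids)]
    })
  nearest <- function(v) vapply(v, function(x) which.min(abs(x - centers)), 0L)
  raw <- nearest(values)
  sizes <- table(factor(raw, levels = seq_along(centers)))
  rank_by_size <- order(-as.integer(sizes), seq_along(centers))
  relabel <- integer(length(centers))
  relabel[rank_by_size] <- seq_along(centers) - 1L
  labs <- paste0("cluster_", relabel[raw])
  res <- list(method = method, centers = centers, relabel = relabel,
              labels = labs,
              assign = function(newdata)
                paste0("cluster_", relabel[nearest(newdata)]))
  structure(res, class = "categorical_conversion")
}

#' Remove duplicate rows and singleton classes
#'
#' Produces the non-redundant dataset: exact duplicate rows collapse to
#' one, and (optionally) classes left with a single instance are removed
#' -- small classes cannot be stratified.  Removal counts are recorded in
#' the `removed` attribute.
#'
#' @param table a [feature_table()].
#' @param drop_duplicates collapse duplicated full rows.
#' @param drop_singleton_classes remove classes with exactly one instance.
#' @return the reduced `feature_table`.
#' @export
prepare_dataset <- function(table, drop_duplicates = TRUE,
                            drop_singleton_classes = FALSE) {
  cc <- ft_class(table)
  stopifnot(!is.null(cc))
  n0 <- nrow(table)
  if (drop_duplicates) table <- table[!duplicated(as.data.frame(table)), ,
                                      drop = FALSE]
  n_dup <- n0 - nrow(table)
  n_singleton_classes <- 0L
  if (drop_singleton_classes) {
    tab <- base::table(as.character(table[[cc]]))
    singles <- names(tab)[tab == 1L]
    n_singleton_classes <- length(singles)
    if (length(singles) == length(tab))
      stop("all classes are singletons; nothing would remain")
    table <- table[!as.character(table[[cc]]) %in% singles, , drop = FALSE]
  }
  table[[cc]] <- droplevels(table[[cc]])
  out <- feature_table(as.data.frame(table), cc, attr(table, "provenance"))
  attr(out, "removed") <- list(duplicates = n_dup,
                               singleton_classes = n_singleton_classes)
  out
}

#' Rebalance class frequencies in a training table
#'
#' `resample` draws a stratified bootstrap whose class mass is pushed
#' toward uniform (bias-to-uniform 1, sample size 100% by default);
#' `spread_subsample` downsamples majority classes so no class exceeds
#' `max_spread` times the minority class size (spread 1 equalizes all
#' classes to the minority count).  Balancing is meant for training folds
#' only; never apply it to test data.
#'
#' @param table a [feature_table()].
#' @param method `"resample"` or `"spread_subsample"`.
#' @param seed integer seed.
#' @param max_spread maximum majority/minority ratio for
#'   `spread_subsample`.
#' @param size_fraction total sample size of `resample` as a fraction of
#'   the input size.
#' @param bias_to_uniform 0 = keep the input distribution, 1 = uniform.
#' @return the rebalanced `feature_table`.
#' @export
balance <- function(table, method = c("resample", "spread_subsample"),
                    seed = 1L, max_spread = 1, size_fraction = 1,
                    bias_to_uniform = 1) {
  method <- match.arg(method)
  cc <- ft_class(table)
  stopifnot(!is.null(cc))
  cls <- as.character(table[[cc]])
  tab <- base::table(cls)
  if (any(tab == 0L) || nrow(table) == 0L) stop("empty class in table")
  set.seed(seed)
  idx <- if (method == "spread_subsample") {
    cap <- ceiling(max_spread * min(tab))
    unlist(lapply(names(tab), function(cl) {
      i <- which(cls == cl)
      if (length(i) > cap) sort(sample(i, cap)) else i
    }))
  } else {
    n_out <- round(size_fraction * nrow(table))
    k <- length(tab)
    orig_p <- as.numeric(tab) / sum(tab)
    target_p <- (1 - bias_to_uniform) * orig_p + bias_to_uniform / k
    n_per <- round(target_p * n_out)
    unlist(lapply(seq_along(tab), function(j) {
      i <- which(cls == names(tab)[j])
      sample(i, n_per[j], replace = TRUE)
    }))
  }
  out <- table[sort(idx), , drop = FALSE]
  feature_table(as.data.frame(out), cc, attr(table, "provenance"))
}

#' Stratified train/test splits
#'
#' `cv10` builds stratified 10-fold cross-validation folds (every instance
#' is tested exactly once; class sizes per fold within 1 of proportional);
#' `split66` a single stratified 66% train / 34% test split; `holdout` a
#' stratified split persisted as disjoint train and test index sets (for
#' saving to separate files).
#'
#' @param table a [feature_table()].
#' @param scheme `"cv10"`, `"split66"` or `"holdout"`.
#' @param seed integer seed.
#' @param train_fraction train share for `split66`/`holdout`.
#' @param folds fold count for `cv10`.
#' @return list of elements with `train` and `test` integer index vectors
#'   (one element per fold; a single element for the split schemes).
#' @export
split_scheme <- function(table, scheme = c("cv10", "split66", "holdout"),
                         seed = 1L, train_fraction = 0.66, folds = 10L) {
  scheme <- match.arg(scheme)
  cc <- ft_class(table)
  stopifnot(!is.null(cc))
  cls <- as.character(table[[cc]])
  tab <- base::table(cls)
  if (any(tab < 2L))
    stop("classes with a single instance cannot be stratified; ",
         "run prepare_dataset(drop_singleton_classes = TRUE) first")
  set.seed(seed)
  if (scheme == "cv10") {
    fold_of <- integer(nrow(table))
    for (cl in names(tab)) {
      i <- sample(which(cls == cl))
      fold_of[i] <- rep_len(seq_len(folds), length(i))
    }
    lapply(seq_len(folds), function(f)
      list(train = which(fold_of != f), test = which(fold_of == f)))
  } else {
    test_idx <- unlist(lapply(names(tab), function(cl) {
      i <- sample(which(cls == cl))
      n_train <- round(train_fraction * length(i))
      i[seq_len(length(i)) > n_train]
    }))
    test_idx <- sort(test_idx)
    list(list(train = setdiff(seq_len(nrow(table)), test_idx),
              test = test_idx))
  }
}
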