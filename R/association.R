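#' Factor analysis of mixed data
#'
#' Joint ordination of continuous and categorical variables: continuous
#' columns are standardized (population scaling); each categorical column
#' is indicator-coded, every indicator divided by the square root of its
#' level frequency and centered.  Principal dimensions come from the
#' spectral decomposition of the resulting matrix with uniform row
#' weights, so the eigenvalue sum equals the total inertia
#' `#continuous + sum(levels - 1)`, and an all-continuous input reduces
#' exactly to standardized PCA.  Constant variables carry no inertia and
#' are dropped with a warning.
#'
#' @param table data.frame of numeric and categorical columns.
#' @param ndim number of principal dimensions to retain.
#' @return A `famd_result`: `eigenvalues`, `row_coords`, `row_cos2`,
#'   per-column `var_coords`, `var_contrib` (percent, sums to 100 per
#'   dimension), `var_cos2`, `total_inertia`, and the column metadata.
#' @export
famd <- function(table, ndim = 5L) {
  stopifnot(is.data.frame(table), ncol(table) >= 2L)
  n <- nrow(table)
  is_num <- vapply(table, is.numeric, logical(1))
  blocks <- list(); meta <- list()
  for (nm in names(table)) {
    x <- table[[nm]]
    if (is_num[[nm]]) {
      s <- stats::sd(x) * sqrt((n - 1) / n)
      if (s == 0) { warning(sprintf("dropping constant variable '%s'", nm)); next }
      z <- (x - mean(x)) / s
      blocks[[nm]] <- matrix(z, ncol = 1, dimnames = list(NULL, nm))
      meta[[nm]] <- list(type = "continuous", inertia = 1)
    } else {
      f <- factor(as.character(x))
      if (nlevels(f) < 2L) { warning(sprintf("dropping constant variable '%s'", nm)); next }
      ind <- stats::model.matrix(~ f - 1)
      colnames(ind) <- paste0(nm, "=", levels(f))
      p <- colMeans(ind)
      z <- sweep(ind, 2, sqrt(p), "/")
      z <- sweep(z, 2, colMeans(z), "-")
      blocks[[nm]] <- z
      meta[[nm]] <- list(type = "categorical", inertia = nlevels(f) - 1)
    }
  }
  if (length(blocks) < 2L) stop("fewer than 2 usable variables")
  M <- do.call(cbind, blocks)
  col_var <- rep(names(blocks), vapply(blocks, ncol, 0L))
  total_inertia <- sum(vapply(meta, `[[`, 0, "inertia"))
  sv <- svd(M / sqrt(n))
  pos <- sv$d^2 > 1e-12
  ndim <- min(ndim, sum(pos))
  eig <- sv$d^2
  dims <- seq_len(ndim)
  row_coords <- M %*% sv$v[, dims, drop = FALSE]
  colnames(row_coords) <- paste0("Dim", dims)
  row_d2 <- rowSums(M^2)
  row_cos2 <- sweep(row_coords^2, 1, pmax(row_d2, .Machine$double.eps), "/")
  col_coords <- sweep(sv$v[, dims, drop = FALSE], 2, sv$d[dims], "*")
  rownames(col_coords) <- colnames(M)
  colnames(col_coords) <- paste0("Dim", dims)
  # column contribution (% of dimension inertia); aggregate per variable
  col_contrib <- sweep(sv$v[, dims, drop = FALSE]^2 * 100, 2, 1, "*")
  var_contrib <- rowsum(col_contrib, col_var)
  colnames(var_contrib) <- paste0("Dim", dims)
  col_var_tot <- colSums(M^2) / n  # inertia per column
  col_cos2 <- sweep(col_coords^2, 1, pmax(col_var_tot, .Machine$double.eps), "/")
  structure(list(eigenvalues = eig[seq_len(sum(pos))],
                 total_inertia = total_inertia,
                 row_coords = row_coords, row_cos2 = row_cos2,
                 var_coords = col_coords, var_contrib = var_contrib,
                 var_cos2 = col_cos2,
                 variables = names(blocks),
                 variable_types = vapply(meta, `[[`, "", "type"),
                 column_variable = col_var, n = n),
            class = "famd_result")
}

#' @export
print.famd_result <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("FAMD of %d rows, %d variables; total inertia %.2f\n",
              x$n, length(x$variables), x$total_inertia))
  pct <- 100 * x$eigenvalues[seq_len(k)] / x$total_inertia
  cat("eigenvalues:", paste(sprintf("%.3f (%.1f%%)",
                                    x$eigenvalues[seq_len(k)], pct),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Write FAMD coordinates as TSV for external plotting
#' @param result a `famd_result`.
#' @param path output file.
#' @param what `"variables"` or `"rows"`.
#' @export
write_famd_tsv <- function(result, path, what = c("variables", "rows")) {
  what <- match.arg(what)
  m <- if (what == "variables") result$var_coords else result$row_coords
  df <- data.frame(id = if (is.null(rownames(m))) seq_len(nrow(m))
                        else rownames(m),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Correlation ratio (categorical explains numeric)
#'
#' Square root of the between-group sum of squares over the total sum of
#' squares of `y` grouped by `g`; lies in `[0, 1]`.
#'
#' @param g categorical grouping vector.
#' @param y numeric response.
#' @return the correlation ratio eta.
#' @export
correlation_ratio <- function(g, y) {
  g <- factor(as.character(g))
  keep <- !is.na(y) & !is.na(g)
  g <- droplevels(g[keep]); y <- y[keep]
  tot <- sum((y - mean(y))^2)
  if (tot == 0) return(0)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  sqrt(sum(ns * (means - mean(y))^2) / tot)
}

#' Cramer's V between two categorical vectors
#'
#' Classic chi-square based V (no continuity correction); the
#' bias-corrected variant of Bergsma is available via
#' `bias_correction = TRUE`.
#'
#' @param x,y categorical vectors.
#' @param bias_correction apply the small-sample bias correction.
#' @return V in `[0, 1]`.
#' @export
cramers_v <- function(x, y, bias_correction = FALSE) {
  tab <- base::table(as.character(x), as.character(y))
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  n <- sum(tab)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  phi2 <- as.numeric(chi2) / n
  r <- nrow(tab); c <- ncol(tab)
  if (bias_correction) {
    phi2 <- max(0, phi2 - (r - 1) * (c - 1) / (n - 1))
    r <- r - (r - 1)^2 / (n - 1)
    c <- c - (c - 1)^2 / (n - 1)
  }
  den <- min(r - 1, c - 1)
  if (den <= 0) return(0)
  min(1, sqrt(phi2 / den))
}

#' Mixed-type association matrix
#'
#' Variable-by-variable association: Pearson's r for numeric-numeric
#' pairs (in `[-1, 1]`), the correlation ratio for categorical-numeric
#' pairs (in `[0, 1]`, oriented: the categorical variable explains the
#' numeric one; the value is stored symmetrically), and Cramer's V for
#' categorical-categorical pairs (in `[0, 1]`).  Diagonal entries are 1.
#'
#' @param table data.frame of numeric and categorical columns.
#' @param bias_correction passed to [cramers_v()].
#' @return numeric matrix with an attribute `types` naming each column's
#'   type.
#' @export
association_matrix <- function(table, bias_correction = FALSE) {
  stopifnot(is.data.frame(table), ncol(table) >= 1L)
  for (nm in names(table))
    if (all(is.na(table[[nm]]))) stop(sprintf("column '%s' is all-missing", nm))
  is_num <- vapply(table, is.numeric, logical(1))
  p <- ncol(table)
  M <- matrix(1, p, p, dimnames = list(names(table), names(table)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    x <- table[[i]]; y <- table[[j]]
    v <- if (is_num[i] && is_num[j]) {
      stats::cor(x, y, use = "complete.obs")
    } else if (!is_num[i] && !is_num[j]) {
      cramers_v(x, y, bias_correction)
    } else if (is_num[i]) {
      correlation_ratio(y, x)
    } else {
      correlation_ratio(x, y)
    }
    M[i, j] <- v; M[j, i] <- v
  }
  attr(M, "types") <- ifelse(is_num, "numeric", "categorical")
  M
}

#' Report strongly associated variable pairs
#'
#' Screening helper over [association_matrix()]: the variable pairs whose
#' association exceeds the threshold (default 0.6).
#'
#' @param M an association matrix.
#' @param threshold reporting threshold.
#' @return data.frame of pairs (var1, var2, association).
#' @export
high_associations <- function(M, threshold = 0.6) {
  idx <- which(upper.tri(M) & abs(M) > threshold, arr.ind = TRUE)
  df <- data.frame(var1 = rownames(M)[idx[, 1]], var2 = colnames(M)[idx[, 2]],
                   association = M[idx], stringsAsFactors = FALSE)
  df[order(-abs(df$association)), , drop = FALSE]
}

#' Greedy hotspot-style association rules
#'
#' Grows a best-first rule tree toward a target class: at each node every
#' `(variable = level)` extension is scored by its confidence
#' `P(class = target | conditions)`; the top `branching` extensions that
#' keep support (the fraction of target-class instances covered) at or
#' above `min_support` and strictly improve the parent's confidence are
#' expanded, down to `max_depth` conditions.
#'
#' @param table a [feature_table()] (or data.frame + `class_column`).
#' @param target_class the class level the rules point to.
#' @param min_support minimal covered fraction of the target-class mass
#'   (default 0.3).
#' @param max_depth maximal number of conjunctive conditions (default 3).
#' @param branching children expanded per node (default 3).
#' @param class_column class column name when `table` is a plain
#'   data.frame.
#' @return A `hotspot_rules` object: data.frame of rules with `path`,
#'   `depth`, `confidence`, `support`, `n_covered`.
#' @export
hotspot_rules <- function(table, target_class, min_support = 0.3,
                          max_depth = 3L, branching = 3L,
                          class_column = NULL) {
  cc <- class_column %||% ft_class(table)
  stopifnot(!is.null(cc), cc %in% names(table))
  stopifnot(min_support > 0, min_support <= 1)
  cls <- as.character(table[[cc]])
  if (!target_class %in% cls) stop("target class not present in the table")
  n_target <- sum(cls == target_class)
  vars <- setdiff(names(table), cc)
  root_conf <- n_target / length(cls)
  rules <- list()
  add_rule <- function(path, depth, conf, supp, ncov)
    rules[[length(rules) + 1L]] <<- data.frame(
      path = path, depth = depth, confidence = conf, support = supp,
      n_covered = ncov, stringsAsFactors = FALSE)
  add_rule("(root)", 0L, root_conf, 1, length(cls))

  grow <- function(rows, conds, conf_parent, depth) {
    if (depth >= max_depth) return()
    cand <- list()
    for (v in setdiff(vars, vapply(conds, `[[`, "", "var"))) {
      for (lev in unique(as.character(table[rows, v]))) {
        sel <- rows[as.character(table[rows, v]) == lev]
        ncov_t <- sum(cls[sel] == target_class)
        supp <- ncov_t / n_target
        conf <- if (length(sel)) ncov_t / length(sel) else 0
        if (supp >= min_support && conf > conf_parent)
          cand[[length(cand) + 1L]] <- list(var = v, lev = lev, rows = sel,
                                            conf = conf, supp = supp)
      }
    }
    if (length(cand) == 0L) return()
    ord <- order(-vapply(cand, `[[`, 0, "conf"),
                 vapply(cand, `[[`, "", "var"),
                 vapply(cand, `[[`, "", "lev"))
    for (ci in utils::head(ord, branching)) {
      ch <- cand[[ci]]
      nconds <- c(conds, list(list(var = ch$var, lev = ch$lev)))
      path <- paste(vapply(nconds, function(cn)
        paste0(cn$var, "=", cn$lev), ""), collapse = " & ")
      add_rule(path, depth + 1L, ch$conf, ch$supp, length(ch$rows))
      grow(ch$rows, nconds, ch$conf, depth + 1L)
    }
  }
  if (root_conf < min_support) {
    warning("target class frequency below min_support; only the root is returned")
  } else {
    grow(seq_along(cls), list(), root_conf, 0L)
  }
  out <- do.call(rbind, rules)
  structure(list(rules = out, target_class = target_class,
                 min_support = min_support, max_depth = max_depth,
                 branching = branching),
            class = "hotspot_rules")
}

#' @export
print.hotspot_rules <- function(x, ...) {
  cat(sprintf("hotspot rules -> class '%s' (%d rules, min support %.2f)\n",
              x$target_class, nrow(x$rules), x$min_support))
  print(x$rules, row.names = FALSE)
  invisible(x)
}
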