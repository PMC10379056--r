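mk_table <- function(n = 40, k = 2, seed = 1) {
  set.seed(seed)
  feature_table(data.frame(
    f1 = sample(letters[1:3], n, TRUE),
    f2 = sample(letters[1:3], n, TRUE),
    class = sample(paste0("c", seq_len(k)), n, TRUE)), "class")
}

test_that("LLPS bisection is an exhaustive, exclusive partition", {
  df <- data.frame(id = 1:5,
                   pfams = c("PF_1,PF_2", "PF_3", "PF_2", "PF_4,PF_5", "PF_9"),
                   class = "x")
  parts <- bisect_llps(df, c("PF_2", "PF_9"))
  expect_equal(nrow(parts$llps) + nrow(parts$non_llps), nrow(df))
  expect_equal(parts$llps$id, c(1, 3, 5))
  expect_length(intersect(parts$llps$id, parts$non_llps$id), 0L)
  expect_error(bisect_llps(df, character()), "non-empty")
})

test_that("categorical conversion maps, clusters, and rejects bad k", {
  direct <- to_categorical(c(0, 1, 0, 1), "direct")
  expect_equal(direct$labels, c("0", "1", "0", "1"))
  km <- to_categorical(c(0, 0, 0, 10, 10, 10), "kmeans", k = 2, seed = 5)
  expect_length(unique(km$labels[1:3]), 1L)
  expect_length(unique(km$labels[4:6]), 1L)
  expect_false(km$labels[1] == km$labels[4])
  # labels are cluster_0.. by descending size
  km2 <- to_categorical(c(0, 0, 0, 0, 10, 10), "kmeans", k = 2, seed = 5)
  expect_equal(km2$labels[1], "cluster_0")
  expect_equal(km2$labels[5], "cluster_1")
  # fitted conversion applies to new data
  expect_equal(km$assign(c(-1, 11)), km$labels[c(1, 4)])
  expect_error(to_categorical(c(1, 2, 3), "kmeans", k = 7), "exceeds")
  em <- to_categorical(c(rnorm(30), rnorm(30, 12)), "em", k = 2, seed = 5)
  expect_length(unique(em$labels), 2L)
  dens <- to_categorical(c(rep(0, 20) + rnorm(20, sd = .1),
                           rep(8, 20) + rnorm(20, sd = .1)), "density")
  expect_gte(length(unique(dens$labels)), 2L)
})

test_that("dataset preparation removes duplicates and singleton classes", {
  set.seed(71)
  # 20 classes of which 14 are singletons
  sizes <- c(rep(1, 14), c(5, 4, 6, 3, 2, 7))
  cls <- rep(paste0("k", seq_along(sizes)), sizes)
  df <- data.frame(f = as.character(seq_along(cls)), class = cls)
  ft <- feature_table(df, "class")
  out <- prepare_dataset(ft, drop_duplicates = FALSE,
                         drop_singleton_classes = TRUE)
  expect_equal(nlevels(out$class), 6L)
  expect_equal(attr(out, "removed")$singleton_classes, 14L)
  # duplicate rows collapse
  dup <- feature_table(rbind(df, df[1, ]), "class")
  out2 <- prepare_dataset(dup, drop_duplicates = TRUE)
  expect_equal(attr(out2, "removed")$duplicates, 1L)
  # idempotence
  expect_equal(nrow(prepare_dataset(out2)), nrow(out2))
  all_single <- feature_table(data.frame(f = "a", class = c("x", "y")),
                              "class")
  expect_error(prepare_dataset(all_single, drop_singleton_classes = TRUE),
               "singleton")
})

test_that("spread subsampling equalizes and resampling is reproducible", {
  set.seed(73)
  df <- data.frame(f = sample(letters, 100, TRUE),
                   class = rep(c("A", "B"), c(90, 10)))
  ft <- feature_table(df, "class")
  ss <- balance(ft, "spread_subsample", seed = 3, max_spread = 1)
  expect_equal(unname(c(table(ss$class))), c(10L, 10L))
  # already balanced input is unchanged
  bal <- feature_table(df[c(1:10, 91:100), ], "class")
  expect_equal(nrow(balance(bal, "spread_subsample", seed = 3)), 20L)
  rs1 <- balance(ft, "resample", seed = 9)
  rs2 <- balance(ft, "resample", seed = 9)
  expect_identical(as.data.frame(rs1), as.data.frame(rs2))
  expect_equal(nrow(rs1), 100L)
  tab <- table(rs1$class)
  expect_lt(abs(tab[["A"]] - tab[["B"]]), 10)  # pushed toward uniform
})

test_that("splits stratify: 66/34 shares and cv folds test each instance once", {
  ft <- mk_table(n = 100, k = 2, seed = 5)
  sp <- split_scheme(ft, "split66", seed = 2)[[1]]
  expect_equal(length(sp$train), 66L)
  expect_equal(length(sp$test), 34L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  cv <- split_scheme(ft, "cv10", seed = 2)
  tested <- sort(unlist(lapply(cv, `[[`, "test")))
  expect_equal(tested, 1:100)
  # class proportions preserved within 1 per fold
  cls <- as.character(ft$class)
  for (f in cv) {
    for (cl in unique(cls)) {
      expected <- sum(cls == cl) / 10
      got <- sum(cls[f$test] == cl)
      expect_lte(abs(got - expected), 1)
    }
  }
  single <- feature_table(data.frame(f = letters[1:3],
                                     class = c("a", "a", "b")), "class")
  expect_error(split_scheme(single, "cv10"), "prepare_dataset")
})

test_that("forests are deterministic under a seed and fit separable data", {
  tab <- signal_study_table(n = 300, seed = 11)
  cfg <- classifier_config(n_trees = 50, seed = 4)
  m1 <- train_random_forest(tab, cfg)
  m2 <- train_random_forest(tab, cfg)
  expect_identical(predict(m1, tab), predict(m2, tab))
  train_acc <- mean(predict(m1, tab) == tab$class)
  expect_gt(train_acc, 0.95)
  expect_error(classifier_config(n_trees = 0), "positive")
  one_class <- feature_table(data.frame(f = letters[1:5], class = "x"),
                             "class")
  expect_error(train_random_forest(one_class, cfg), "single class")
})

test_that("tree export produces readable split text", {
  tab <- mk_table(n = 60, k = 2, seed = 8)
  m <- train_random_forest(tab, classifier_config(n_trees = 3, seed = 1,
                                                  export_trees = TRUE))
  txt <- export_tree_text(m)
  expect_length(txt, 3L)
  expect_match(txt[1], "tree 1")
  m2 <- train_random_forest(tab, classifier_config(n_trees = 3, seed = 1))
  expect_error(export_tree_text(m2), "export_trees")
})

test_that("evaluation reports have coherent probabilities and confusion margins", {
  tab <- signal_study_table(n = 200, seed = 13)
  rep <- evaluate_scheme(tab, "split66", classifier_config(n_trees = 30,
                                                           seed = 2),
                         seed = 2)
  expect_true(all(abs(rowSums(rep$class_distribution) - 1) < 1e-9))
  expect_equal(sum(rep$confusion), rep$n_tested)
  expect_equal(unname(rowSums(rep$confusion)),
               unname(vapply(colnames(rep$confusion), function(cl)
                 sum(as.character(tab$class)[
                   split_scheme(tab, "split66", seed = 2)[[1]]$test] == cl),
                 0)))
  # perfect classifier on its own training set
  m <- train_random_forest(tab, classifier_config(n_trees = 50, seed = 2))
  expect_gt(mean(predict(m, tab) == tab$class), 0.97)
})

test_that("unseen category levels at predict time map to the unseen bucket", {
  tab <- mk_table(n = 60, k = 2, seed = 9)
  m <- train_random_forest(tab, classifier_config(n_trees = 10, seed = 1))
  new <- data.frame(f1 = "zzz", f2 = "a")
  enc <- m$encoder$encode(new)
  expect_equal(unname(enc[1, "f1=__unseen__"]), 1L)
  expect_s3_class(predict(m, new), "factor")  # prediction still possible
})

test_that("categorical conversions are fitted inside each training fold only", {
  set.seed(77)
  df <- data.frame(x = c(rnorm(100, 0), rnorm(100, 10)),
                   class = rep(c("lo", "hi"), each = 100))
  ft <- feature_table(df, "class")
  ft$x <- df$x  # keep numeric for conversion
  rep <- evaluate_scheme(ft, "cv10", classifier_config(n_trees = 20, seed = 3),
                         conversions = list(x = list(method = "kmeans", k = 2)),
                         seed = 3)
  # one fitted conversion per fold, each trained on fold-sized data
  expect_length(rep$fold_conversions, 10L)
  centers <- t(vapply(rep$fold_conversions, function(f)
    sort(f$x$centers), numeric(2)))
  expect_gt(nrow(unique(round(centers, 6))), 1L)  # per-fold fits differ
  expect_gt(rep$accuracy, 0.9)
})

test_that("the full protocol is deterministic end to end", {
  tab <- signal_study_table(n = 150, seed = 17)
  r1 <- evaluate_scheme(tab, "cv10", classifier_config(n_trees = 20, seed = 5),
                        balance_method = "spread_subsample", seed = 5)
  r2 <- evaluate_scheme(tab, "cv10", classifier_config(n_trees = 20, seed = 5),
                        balance_method = "spread_subsample", seed = 5)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_evaluation_report(r1, f1)
  write_evaluation_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
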