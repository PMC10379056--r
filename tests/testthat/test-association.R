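test_that("FAMD satisfies its inertia and contribution identities", {
  set.seed(81)
  df <- data.frame(x = rnorm(60), y = rnorm(60),
                   g = sample(letters[1:3], 60, TRUE),
                   h = sample(c("u", "v"), 60, TRUE))
  res <- famd(df, ndim = 4)
  # eigenvalue sum = total inertia = 2 continuous + (3-1) + (2-1)
  expect_equal(res$total_inertia, 5)
  expect_equal(sum(res$eigenvalues), 5, tolerance = 1e-10)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_true(all(res$eigenvalues >= -1e-12))
  # contributions sum to 100% per dimension
  expect_equal(unname(colSums(res$var_contrib)), rep(100, 4),
               tolerance = 1e-9)
  # cos2 within [0,1], row cos2 sums <= 1 over retained dims
  expect_true(all(res$row_cos2 >= -1e-12 & res$row_cos2 <= 1 + 1e-12))
  expect_true(all(rowSums(res$row_cos2) <= 1 + 1e-9))
})

test_that("all-continuous FAMD equals standardized PCA within 1e-8", {
  set.seed(83)
  n <- 50
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  res <- famd(df, ndim = 3)
  # oracle: PCA of population-standardized data
  Z <- scale(as.matrix(df))
  Z <- sweep(Z, 2, sqrt((n - 1) / n), "/")   # population scaling
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  eig_oracle <- pc$sdev^2 * (n - 1) / n
  expect_equal(res$eigenvalues, eig_oracle, tolerance = 1e-8)
  for (k in 1:3) {
    a <- res$row_coords[, k]; b <- pc$x[, k]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)  # sign-free
  }
})

test_that("duplicated continuous variables coincide on the first dimension", {
  set.seed(87)
  x <- rnorm(40)
  df <- data.frame(a = x, b = x, c = rnorm(40))
  res <- famd(df, ndim = 3)
  expect_gte(res$eigenvalues[1], 2 - 1e-8)  # the shared variance
  expect_equal(res$var_coords["a", 1], res$var_coords["b", 1],
               tolerance = 1e-8)
  expect_warning(famd(data.frame(k = rep(1, 10), x = rnorm(10),
                                 y = rnorm(10))), "constant")
})

test_that("the association matrix dispatches measures by type", {
  set.seed(89)
  n <- 300
  x <- rnorm(n)
  df <- data.frame(x = x, y = x, z = rnorm(n),
                   g = sample(c("a", "b"), n, TRUE))
  M <- association_matrix(df)
  expect_equal(unname(diag(M)), rep(1, 4))
  expect_equal(M["x", "y"], 1)                      # y = x
  expect_equal(M["x", "z"], cor(x, df$z))           # plain Pearson
  expect_true(M["g", "x"] >= 0 && M["g", "x"] <= 1) # correlation ratio
  expect_equal(M, t(M))
  expect_error(association_matrix(data.frame(a = NA_real_, b = 1)),
               "all-missing")
})

test_that("correlation ratio and Cramer's V behave on known structures", {
  g <- rep(c("a", "b"), each = 50)
  y <- c(rnorm(50, 0, .1), rnorm(50, 10, .1))
  expect_gt(correlation_ratio(g, y), 0.99)
  expect_equal(correlation_ratio(rep("a", 20), rnorm(20)), 0)
  x <- rep(c("p", "q"), 50)
  expect_gt(cramers_v(x, x), 0.99)
  # independent simulated categoricals stay near zero
  set.seed(91)
  a <- sample(letters[1:4], 2000, TRUE)
  b <- sample(letters[1:4], 2000, TRUE)
  expect_lt(cramers_v(a, b), 0.1)
})

test_that("high-association screening respects the reporting threshold", {
  set.seed(93)
  x <- rnorm(100)
  df <- data.frame(x = x, y = x + rnorm(100, sd = .1), z = rnorm(100))
  hi <- high_associations(association_matrix(df), threshold = 0.6)
  expect_equal(sort(c(hi$var1[1], hi$var2[1])), c("x", "y"))
  expect_true(all(abs(hi$association) > 0.6))
})

planted_table <- function(n = 400, seed = 95) {
  set.seed(seed)
  df <- data.frame(F1 = sample(c("a", "x"), n, TRUE, prob = c(0.7, 0.3)),
                   F2 = sample(c("b", "y"), n, TRUE, prob = c(0.7, 0.3)),
                   F3 = sample(c("m", "n"), n, TRUE))
  planted <- df$F1 == "a" & df$F2 == "b"
  cls <- ifelse(planted & runif(n) < 0.95, "c_target", "c_other")
  feature_table(cbind(df, class = cls), "class")
}

test_that("hotspot rules recover a planted conjunctive rule at depth 2", {
  tab <- planted_table()
  hs <- hotspot_rules(tab, "c_target", min_support = 0.3, max_depth = 3,
                      branching = 3)
  r <- hs$rules
  deep <- r[r$depth == 2L, ]
  hit <- grepl("F1=a", deep$path) & grepl("F2=b", deep$path)
  expect_true(any(hit))
  expect_gt(max(deep$confidence[hit]), 0.9)
  # children strictly improve confidence along each path
  for (i in which(r$depth == 2L)) {
    parent_path <- sub(" & [^&]+$", "", r$path[i])
    parent <- r[r$path == parent_path | (parent_path == r$path[i] & r$depth == 0), ]
    if (nrow(parent)) expect_gt(r$confidence[i], max(parent$confidence))
  }
})

test_that("degenerate supports behave: full support keeps only the root", {
  tab <- planted_table()
  root_only <- suppressWarnings(hotspot_rules(tab, "c_target",
                                              min_support = 1.0))
  expect_equal(nrow(root_only$rules), 1L)
  expect_equal(root_only$rules$path, "(root)")
  expect_error(hotspot_rules(tab, "no_such_class"), "not present")
})

test_that("uniform noise yields no rule far above the root confidence", {
  set.seed(97)
  n <- 500
  tab <- feature_table(data.frame(
    F1 = sample(letters[1:3], n, TRUE), F2 = sample(letters[1:3], n, TRUE),
    F3 = sample(letters[1:3], n, TRUE),
    class = sample(c("t", "o"), n, TRUE)), "class")
  hs <- hotspot_rules(tab, "t", min_support = 0.3)
  root_conf <- hs$rules$confidence[hs$rules$depth == 0]
  expect_true(all(hs$rules$confidence <= root_conf + 0.1))
})
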