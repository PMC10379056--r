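test_that("fragment splitting honours the gap-3 boundary exactly", {
  expect_equal(split_fragments(c(3, 4, 5, 9)), list(c(3L, 4L, 5L, 9L)))
  expect_equal(split_fragments(c(3, 4, 5, 10)), list(c(3L, 4L, 5L), 10L))
  expect_equal(split_fragments(7), list(7L))
  expect_equal(split_fragments(integer()), list())
  expect_error(split_fragments(c(5, 3)), "sorted")
  expect_error(split_fragments(c(3, 3)), "sorted")
})

test_that("fragments agree with a brute-force gap scan and rebuild the input", {
  set.seed(31)
  for (i in 1:300) {
    pos <- sort(sample(1:80, sample(1:20, 1)))
    g <- sample(0:6, 1)
    mine <- split_fragments(pos, g)
    oracle <- oracle_fragments(pos, g)
    expect_equal(lapply(mine, as.integer), lapply(oracle, as.integer))
    expect_equal(unlist(mine), pos)
  }
})

test_that("fragment count never increases as the gap tolerance grows", {
  set.seed(37)
  for (i in 1:50) {
    pos <- sort(sample(1:120, 25))
    n_frag <- vapply(0:8, function(g) length(split_fragments(pos, g)), 0L)
    expect_true(all(diff(n_frag) <= 0))
  }
})

make_entry <- function(pair, arch, s1, s2, kind = "DDI", pv = NULL)
  list(domain_pair = pair, architecture = arch, side1 = s1, side2 = s2,
       kind = kind, protcad_value = pv)

test_that("non-redundant and redundant clusters separate by repeated members", {
  e <- list(
    make_entry(c("PF_a", "PF_b"), c("PF_a", "PF_b"), c(1, 2, 3), c(5, 6), pv = 2),
    make_entry(c("PF_a", "PF_b"), c("PF_a", "PF_b", "PF_a"), c(1, 2), c(9), pv = 3),
    make_entry(c("PF_a", "PF_b"), c("PF_b", "PF_a"), c(4), c(7, 8), pv = 1))
  cmp <- compare_interface_clusters(e)
  expect_equal(cmp$n_nonredundant, 2L)
  expect_equal(cmp$n_redundant, 1L)
  expect_length(cmp$nonredundant, 13L)
  expect_length(cmp$redundant, 13L)
  expect_equal(cmp$nonredundant$membership_size, 2L)
  expect_error(compare_interface_clusters(list(
    make_entry(c("PF_a", "PF_b"), c("PF_a", "PF_b"), 1, 2),
    make_entry(c("PF_a", "PF_c"), c("PF_a", "PF_c"), 1, 2))),
    "same unordered domain pair")
})

test_that("identical clusters give F = 0 and p = 1; lone clusters skip ANOVA", {
  same <- function(arch) make_entry(c("PF_a", "PF_b"), arch,
                                    c(1, 2, 3), c(10, 11), pv = 2)
  cmp <- compare_interface_clusters(list(
    same(c("PF_a", "PF_b")), same(c("PF_a", "PF_b")),
    same(c("PF_a", "PF_b", "PF_a")), same(c("PF_a", "PF_b", "PF_a"))))
  # n_domains differs by construction between architectures; all other
  # measures are identical across clusters
  others <- cmp$anova[cmp$anova$measure != "n_domains", ]
  expect_true(all(others$F == 0))
  expect_true(all(others$p == 1))
  lone <- compare_interface_clusters(list(same(c("PF_a", "PF_b"))))
  expect_equal(lone$n_redundant, 0L)
  expect_null(lone$redundant)
  expect_true(all(!lone$anova$applicable))
})

test_that("cluster ANOVA matches the textbook formula to 1e-9", {
  set.seed(41)
  for (rep in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    # vary interface sizes so total_aa differs between clusters
    mk <- function(arch, mu) {
      n_aa <- max(2, round(stats::rnorm(1, mu, 3)))
      make_entry(c("PF_a", "PF_b"), arch,
                 sort(sample(1:200, n_aa)), sort(sample(1:200, n_aa)),
                 pv = sample(1:6, 1))
    }
    entries <- c(replicate(n1, mk(c("PF_a", "PF_b"), 20), simplify = FALSE),
                 replicate(n2, mk(c("PF_a", "PF_b", "PF_a"), 30), simplify = FALSE))
    cmp <- compare_interface_clusters(entries)
    for (ms in c("total_aa", "protcad_value", "n_fragments")) {
      row <- cmp$anova[cmp$anova$measure == ms, ]
      if (!row$applicable || row$F == 0) next
      y <- vapply(entries, function(e) {
        frags <- c(split_fragments(e$side1), split_fragments(e$side2))
        switch(ms, total_aa = sum(lengths(frags)),
               protcad_value = e$protcad_value,
               n_fragments = length(frags))
      }, 0)
      g <- rep(c("NR", "R"), c(n1, n2))
      ora <- oracle_anova(y, g)
      expect_equal(row$F, ora$F, tolerance = 1e-9)
      expect_equal(row$p, ora$p, tolerance = 1e-9)
    }
  }
})

test_that("clearly separated clusters reach p < 0.001", {
  set.seed(43)
  mk <- function(arch, mu) {
    n_aa <- max(2, round(stats::rnorm(1, mu, 1)))
    make_entry(c("PF_a", "PF_b"), arch, sort(sample(1:500, n_aa)),
               sort(sample(1:500, n_aa)))
  }
  entries <- c(replicate(30, mk(c("PF_a", "PF_b"), 10), simplify = FALSE),
               replicate(30, mk(c("PF_a", "PF_b", "PF_a"), 60), simplify = FALSE))
  cmp <- compare_interface_clusters(entries)
  expect_lt(cmp$anova$p[cmp$anova$measure == "total_aa"], 0.001)
})

test_that("domain and interdomain regions tile the protein exactly", {
  reg <- map_features_to_regions(100, data.frame(
    pfam = c("PF_x", "PF_y"), start = c(10, 60), end = c(40, 90)))
  spans <- do.call(rbind, lapply(reg, function(r)
    data.frame(type = r$region_type, start = r$start, end = r$end)))
  inter <- spans[spans$type == "interdomain", ]
  expect_equal(Map(c, inter$start, inter$end),
               list(c(1, 9), c(41, 59), c(91, 100)))
  # exact tiling: every position covered once
  cov <- integer(100)
  for (r in reg) cov[r$start:r$end] <- cov[r$start:r$end] + 1L
  expect_true(all(cov == 1L))
})

test_that("positional features assign by containment; globals attach everywhere", {
  sites <- data.frame(position = c(25, 50), feature = c("phospho", "phospho"))
  reg <- map_features_to_regions(100, data.frame(
    pfam = c("PF_x", "PF_y"), start = c(10, 60), end = c(40, 90)),
    global_features = list(gravy = -0.3), sites = sites)
  in_dom <- Filter(function(r) r$region_type == "domain" && r$start == 10, reg)[[1]]
  expect_equal(in_dom$sites$position, 25)
  mid <- Filter(function(r) r$region_type == "interdomain" && r$start == 41,
                reg)[[1]]
  expect_equal(mid$sites$position, 50)
  expect_true(all(vapply(reg, function(r) identical(r$global$gravy, -0.3),
                         logical(1))))
  expect_error(map_features_to_regions(100, data.frame(
    pfam = "PF_x", start = 10, end = 40),
    sites = data.frame(position = 150, feature = "p")), "beyond")
})

test_that("overlapping domain annotations keep the longer span", {
  reg <- map_features_to_regions(60, data.frame(
    pfam = c("PF_long", "PF_short"), start = c(10, 30), end = c(45, 40)))
  doms <- Filter(function(r) r$region_type == "domain", reg)
  expect_length(doms, 1L)
  expect_equal(doms[[1]]$pfam, "PF_long")
  expect_equal(nrow(attr(reg, "discarded")), 1L)
})

test_that("tiling holds over randomized fixture proteins", {
  set.seed(47)
  for (i in 1:40) {
    L <- sample(50:300, 1)
    n_dom <- sample(0:4, 1)
    doms <- NULL
    if (n_dom > 0) {
      # build non-overlapping spans
      cuts <- sort(sample(seq_len(L - 1), min(2 * n_dom, L - 2)))
      if (length(cuts) >= 2) {
        starts <- cuts[seq(1, length(cuts) - 1, by = 2)]
        ends <- cuts[seq(2, length(cuts), by = 2)]
        doms <- data.frame(pfam = paste0("PF_", seq_along(starts)),
                           start = starts, end = ends)
      }
    }
    reg <- map_features_to_regions(L, doms)
    cov <- integer(L)
    for (r in reg) cov[r$start:r$end] <- cov[r$start:r$end] + 1L
    expect_true(all(cov == 1L))
  }
})

test_that("clan pools union partner clans with singleton pass-through", {
  edges <- data.frame(a = c("PR_1", "PR_2", "PR_3"),
                      b = c("PR_2", "PR_3", "PR_1"))
  pf <- list(PR_1 = c("PF_a"), PR_2 = c("PF_a", "PF_b"), PR_3 = c("PF_c"))
  clans <- c(PF_a = "CL_x", PF_b = "CL_x")
  expect_equal(clan_pool("PR_1", edges, pf, clans), c("CL_x", "PF_c"))
  expect_equal(clan_pool("PR_9", edges, pf, clans), character())
  no_map <- clan_pool("PR_1", edges, pf)
  expect_setequal(no_map, c("PF_a", "PF_b", "PF_c"))
})
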