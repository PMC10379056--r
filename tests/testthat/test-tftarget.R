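test_that("motif-type marginals are both margins of the incidence matrix", {
  tfs <- list(list(tf_id = "TF_1", motifs = c("M1", "M2")),
              list(tf_id = "TF_2", motifs = "M1"),
              list(tf_id = "TF_3", motifs = character()))
  m <- count_motif_types(tfs)
  expect_equal(m$per_tf, c(TF_1 = 2L, TF_2 = 1L, TF_3 = 0L))
  expect_equal(m$per_motif, c(M1 = 2L, M2 = 1L))
  empty <- count_motif_types(list())
  expect_length(empty$per_tf, 0L)
  expect_length(empty$per_motif, 0L)
})

simple_model <- function(gene_id = "G_1", chrom = "chr1", strand = "+",
                         start = 5000L, end = 7000L, features = NULL) {
  if (is.null(features))
    features <- data.frame(
      type = c("exon", "exon", "CDS", "CDS"),
      start = c(5000L, 6200L, 5100L, 6200L),
      end = c(5800L, 7000L, 5800L, 6800L))
  list(gene_id = gene_id, chrom = chrom, strand = strand, start = start,
       end = end, features = features)
}

test_that("gene models expand into introns, inferred UTRs and strand-aware flanks", {
  fi <- gene_feature_intervals(list(simple_model()), 2000L, 1500L)
  intron <- fi[fi$type == "intron", ]
  expect_equal(c(intron$start, intron$end), c(5800L, 6200L))
  utr <- fi[fi$type == "UTR", ]
  expect_setequal(utr$start, c(5000L, 6800L))  # exon minus CDS
  expect_true("G_1" %in% attr(fi, "inferred_utr"))
  up <- fi[fi$type == "upstream", ]
  expect_equal(c(up$start, up$end), c(3000L, 5000L))
  dn <- fi[fi$type == "downstream", ]
  expect_equal(c(dn$start, dn$end), c(7000L, 8500L))
  # minus strand flips the flanks
  rev <- gene_feature_intervals(list(simple_model(strand = "-")), 2000L, 1500L)
  expect_equal(rev[rev$type == "upstream", c("start", "end")],
               data.frame(start = 7000L, end = 9000L),
               ignore_attr = TRUE)
})

test_that("half-open boundaries: position end belongs to the next interval", {
  model <- simple_model(features = data.frame(
    type = c("exon", "exon"), start = c(5000L, 6200L), end = c(5800L, 7000L)))
  # site ending exactly at exon start does not overlap the exon
  s0 <- data.frame(chrom = "chr1", start = 4990L, end = 5000L)
  r0 <- map_sites_to_features(s0, list(model))
  expect_false("exon" %in% r0$overlaps$type)
  expect_true("upstream" %in% r0$overlaps$type)
  # site straddling the exon/intron junction hits both
  s1 <- data.frame(chrom = "chr1", start = 5795L, end = 5805L)
  r1 <- map_sites_to_features(s1, list(model))
  expect_setequal(r1$overlaps$type, c("exon", "intron"))
  # single-base site at the first intron position hits the intron only
  s2 <- data.frame(chrom = "chr1", start = 5800L, end = 5801L)
  r2 <- map_sites_to_features(s2, list(model))
  expect_equal(r2$overlaps$type, "intron")
  expect_error(map_sites_to_features(
    data.frame(chrom = "chr1", start = 10L, end = 10L), list(model)),
    "start < end")
})

test_that("unknown chromosomes go to the unmapped bucket", {
  r <- map_sites_to_features(
    data.frame(chrom = c("chr1", "chrUn"), start = c(5100L, 10L),
               end = c(5110L, 20L)), list(simple_model()))
  expect_equal(nrow(r$unmapped), 1L)
  expect_equal(r$unmapped$chrom, "chrUn")
})

test_that("interval mapping equals the naive all-pairs oracle on random fixtures", {
  set.seed(61)
  for (rep in 1:25) {
    n_genes <- sample(2:5, 1)
    models <- lapply(seq_len(n_genes), function(g) {
      st <- sample(seq(2000L, 50000L, by = 100L), 1)
      len <- sample(seq(600L, 2400L, by = 200L), 1)
      e1e <- st + round(len * 0.4); e2s <- e1e + round(len * 0.2)
      simple_model(gene_id = paste0("G_", g),
                   chrom = sample(c("chr1", "chr2"), 1),
                   strand = sample(c("+", "-"), 1),
                   start = st, end = st + len,
                   features = data.frame(
                     type = c("exon", "exon"),
                     start = c(st, e2s), end = c(e1e, st + len)))
    })
    n_sites <- 40L
    sites <- data.frame(
      chrom = sample(c("chr1", "chr2"), n_sites, replace = TRUE),
      start = sample(0:55000, n_sites))
    sites$end <- sites$start + sample(1:30, n_sites, replace = TRUE)
    res <- map_sites_to_features(sites, models)
    feats <- gene_feature_intervals(models)
    oracle <- oracle_overlaps(sites, feats)
    expect_equal(sort_overlaps(res$overlaps), sort_overlaps(oracle))
    # counts reproducible from the raw overlap list
    if (nrow(res$counts)) {
      recount <- stats::aggregate(list(count = rep(1L, nrow(res$overlaps))),
                                  by = list(gene_id = res$overlaps$gene_id,
                                            type = res$overlaps$type),
                                  FUN = sum)
      recount <- recount[order(recount$gene_id, recount$type), ]
      expect_equal(res$counts$count, recount$count)
    }
  }
})

test_that("counts are additive over site-file partitions", {
  set.seed(67)
  models <- list(simple_model())
  sites <- data.frame(chrom = "chr1", start = sample(3000:8000, 30))
  sites$end <- sites$start + 10L
  whole <- map_sites_to_features(sites, models)
  half <- sample(30, 15)
  c1 <- map_sites_to_features(sites[half, ], models)$counts
  c2 <- map_sites_to_features(sites[-half, ], models)$counts
  merged <- stats::aggregate(count ~ gene_id + type, data = rbind(c1, c2),
                             FUN = sum)
  merged <- merged[order(merged$gene_id, merged$type), ]
  expect_equal(merged$count, whole$counts$count)
})

test_that("BED and GFF3 readers convert to the internal half-open convention", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t110\tTF_1\t0\t+", bed)
  sites <- read_bed_sites(bed)
  expect_equal(sites$start, 100L)
  expect_equal(sites$end, 110L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1001\t3000\t.\t+\t.\tID=G_1",
               "chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tID=G_1.e1;Parent=G_1",
               "chr1\tsrc\texon\t2001\t3000\t.\t+\t.\tID=G_1.e2;Parent=G_1"),
             gff)
  models <- read_gff3_genes(gff)
  expect_length(models, 1L)
  expect_equal(models[[1]]$start, 1000L)  # 1-based closed -> 0-based half-open
  expect_equal(models[[1]]$end, 3000L)
  ex <- models[[1]]$features[models[[1]]$features$type == "exon", ]
  expect_equal(ex$start, c(1000L, 2000L))
  expect_equal(ex$end, c(1500L, 3000L))
})
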