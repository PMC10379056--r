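#' Configuration for the synthetic fixture generator
#'
#' The generator emits miniature, schema-conformant snapshots of every
#' input table the feature modules read, with internally consistent
#' identifier namespaces (PF_ for Pfam domains, PR_ proteins, TF_
#' transcription factors, G_ genes) so join errors are obvious.  All
#' randomness flows through the single mandatory seed.
#'
#' @param seed mandatory integer seed.
#' @param n_proteins,n_pfams,n_tfs,n_genes table sizes.
#' @param n_condensates how many condensate terms from the vocabulary are
#'   in play.
#' @param class_fractions optional named numeric vector of class relative
#'   frequencies for labeled tables (tiny-class regimes included).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed, n_proteins = 50L, n_pfams = 20L,
                           n_tfs = 10L, n_genes = 15L, n_condensates = 8L,
                           class_fractions = NULL) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  if (n_pfams < 2L) stop("n_pfams must be at least 2 when domains are generated")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 n_pfams = as.integer(n_pfams), n_tfs = as.integer(n_tfs),
                 n_genes = as.integer(n_genes),
                 n_condensates = as.integer(n_condensates),
                 class_fractions = class_fractions),
            class = "fixture_config")
}

rand_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes assemblies.tsv, interfaces.tsv, llps.tsv, gopo.gaf, tfs.tsv,
#' ppi.tsv, sites.bed, genes.gff3, proteins.fasta and a manifest.tsv with
#' md5 checksums into `dir`.  Deterministic: the same config (same seed)
#' produces byte-identical files.  Every identifier referenced across
#' files exists in its defining file.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory tables and file paths.
#' @export
generate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pfams <- sprintf("PF_%03d", seq_len(config$n_pfams))
  prots <- sprintf("PR_%03d", seq_len(config$n_proteins))
  tfs <- sprintf("TF_%02d", seq_len(config$n_tfs))
  genes <- sprintf("G_%03d", seq_len(config$n_genes))
  vocab <- condensate_vocabulary()[seq_len(config$n_condensates)]

  # proteins: sequence + 1..4 domains each
  prot_len <- sample(80:200, config$n_proteins, replace = TRUE)
  seqs <- vapply(prot_len, rand_seq, "", alphabet = aa20)
  prot_pfams <- lapply(seq_len(config$n_proteins), function(i)
    sample(pfams, sample(1:4, 1), replace = FALSE))

  # assemblies
  sym_pool <- c("C1", "C1", "C2", "C3", "D2", "D3")
  n_asm <- config$n_proteins
  asm <- data.frame(
    group_id = sprintf("GRP_%03d", seq_len(n_asm)),
    protein_id = prots,
    pfam_architecture = vapply(prot_pfams, paste, "", collapse = ","),
    stoichiometry = vapply(seq_len(n_asm), function(i) {
      nch <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
      paste0(vapply(seq_len(nch), function(j)
        paste0(LETTERS[j],
               sample(c("", "2", "4"), 1, prob = c(0.5, 0.4, 0.1))), ""),
        collapse = "")
    }, ""),
    symmetry = sample(sym_pool, n_asm, replace = TRUE),
    obligacy = sample(c("obligate", "moderate", "transient", "unknown"),
                      n_asm, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
    stringsAsFactors = FALSE)

  # interfaces: same-pair entries, NR and redundant architectures
  n_int <- 30L
  int_pairs <- t(replicate(n_int, sample(pfams, 2)))
  interfaces <- data.frame(
    pair = paste(pmin(int_pairs[, 1], int_pairs[, 2]),
                 pmax(int_pairs[, 1], int_pairs[, 2]), sep = "|"),
    architecture = vapply(seq_len(n_int), function(i) {
      base_arch <- c(int_pairs[i, 1], int_pairs[i, 2])
      if (stats::runif(1) < 0.4) base_arch <- c(base_arch, int_pairs[i, 1])
      paste(base_arch, collapse = ",")
    }, ""),
    side1 = vapply(seq_len(n_int), function(i)
      paste(sort(sample(1:60, sample(4:10, 1))), collapse = ","), ""),
    side2 = vapply(seq_len(n_int), function(i)
      paste(sort(sample(1:60, sample(4:10, 1))), collapse = ","), ""),
    kind = sample(c("DDI", "DMI"), n_int, replace = TRUE, prob = c(0.8, 0.2)),
    protcad_value = sample(1:6, n_int, replace = TRUE),
    stringsAsFactors = FALSE)

  # LLPS annotations: ~60% of proteins are LLPS factors
  is_llps <- stats::runif(config$n_proteins) < 0.6
  llps <- data.frame(
    protein_id = prots[is_llps],
    condensates = vapply(which(is_llps), function(i)
      paste(sample(vocab, sample(1:3, 1)), collapse = ","), ""),
    functional_type = sample(c("client", "regulator", "scaffold"),
                             sum(is_llps), replace = TRUE),
    pfams = vapply(prot_pfams[is_llps], paste, "", collapse = ","),
    stringsAsFactors = FALSE)

  # GO/PO annotations (GAF)
  go_terms <- sprintf("GO:%07d", sample(1000:99999, 25))
  term_names <- c("signal transduction", "response to light",
                  "response to stress", "transcription activator activity",
                  "suppressor of silencing", "cell communication",
                  "ribosome biogenesis", "flower development",
                  "protein folding", "transport")
  quals <- c("part_of", "acts_upstream_of_negative_effect", "enables",
             "involved_in")
  n_ann <- 3L * config$n_genes
  gaf_rows <- data.frame(
    db = "FIX", gene_id = sample(genes, n_ann, replace = TRUE),
    symbol = "", qualifier = sample(quals, n_ann, replace = TRUE),
    term = sample(go_terms, n_ann, replace = TRUE),
    reference = "FIX:0001", evidence = "IEA", with = "",
    aspect = sample(c("P", "F", "C", "A", "G"), n_ann, replace = TRUE,
                    prob = c(0.4, 0.2, 0.1, 0.15, 0.15)),
    name = sample(term_names, n_ann, replace = TRUE),
    synonym = "", type = "protein", taxon = "taxon:3702",
    date = "20230101", assigned_by = "FIX",
    stringsAsFactors = FALSE)

  # TFs: subset of proteins with DBD sequences and IUPAC motifs
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  motif_pool <- sprintf("M_%02d", 1:8)
  tf_prot <- sample(prots, config$n_tfs)
  tfs_df <- data.frame(
    tf_id = tfs, protein_id = tf_prot,
    family = sample(c("bZIP", "MYB", "WRKY", "bHLH"), config$n_tfs,
                    replace = TRUE),
    dbd_sequence = vapply(rep(40L, config$n_tfs), rand_seq, "",
                          alphabet = aa20),
    motifs = vapply(seq_len(config$n_tfs), function(i)
      paste(sample(motif_pool, sample(1:3, 1)), collapse = ","), ""),
    consensus = vapply(rep(8L, config$n_tfs), rand_seq, "",
                       alphabet = iupac),
    stringsAsFactors = FALSE)

  # PPI edges among proteins
  n_edges <- 2L * config$n_proteins
  ppi <- unique(data.frame(
    a = sample(prots, n_edges, replace = TRUE),
    b = sample(prots, n_edges, replace = TRUE),
    stringsAsFactors = FALSE))
  ppi <- ppi[ppi$a != ppi$b, , drop = FALSE]

  # gene models on two chromosomes + TF binding sites
  chrom_of <- sample(c("chr1", "chr2"), config$n_genes, replace = TRUE)
  gene_start <- sample(seq(5000L, 90000L, by = 500L), config$n_genes)
  gene_len <- sample(seq(900L, 3000L, by = 100L), config$n_genes,
                     replace = TRUE)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gff_lines <- c("##gff-version 3")
  for (i in seq_len(config$n_genes)) {
    g0 <- gene_start[i]; g1 <- g0 + gene_len[i]
    # two exons with one intron; CDS inside exons
    e1_end <- g0 + round(gene_len[i] * 0.4)
    e2_start <- e1_end + round(gene_len[i] * 0.2)
    gff_lines <- c(gff_lines,
      sprintf("%s\tfix\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom_of[i],
              g0 + 1L, g1, strand[i], genes[i]),
      sprintf("%s\tfix\texon\t%d\t%d\t.\t%s\t.\tID=%s.e1;Parent=%s",
              chrom_of[i], g0 + 1L, e1_end, strand[i], genes[i], genes[i]),
      sprintf("%s\tfix\texon\t%d\t%d\t.\t%s\t.\tID=%s.e2;Parent=%s",
              chrom_of[i], e2_start + 1L, g1, strand[i], genes[i], genes[i]),
      sprintf("%s\tfix\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c1;Parent=%s",
              chrom_of[i], g0 + 101L, e1_end, strand[i], genes[i], genes[i]),
      sprintf("%s\tfix\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c2;Parent=%s",
              chrom_of[i], e2_start + 1L, g1 - 100L, strand[i], genes[i],
              genes[i]))
  }
  n_sites <- 60L
  site_gene <- sample(seq_len(config$n_genes), n_sites, replace = TRUE)
  site_start <- vapply(site_gene, function(gi) {
    lo <- max(0L, gene_start[gi] - 2500L)
    hi <- gene_start[gi] + gene_len[gi] + 2000L
    sample(seq(lo, hi), 1)
  }, 0L)
  sites <- data.frame(chrom = chrom_of[site_gene], start = site_start,
                      end = site_start + sample(8:15, n_sites, replace = TRUE),
                      tf_id = sample(tfs, n_sites, replace = TRUE),
                      score = 0L,
                      strand = sample(c("+", "-"), n_sites, replace = TRUE),
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]

  # ---- write files ----
  wt <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    assemblies = wt(asm, "assemblies.tsv"),
    interfaces = wt(interfaces, "interfaces.tsv"),
    llps = wt(llps, "llps.tsv"),
    tfs = wt(tfs_df, "tfs.tsv"),
    ppi = wt(ppi, "ppi.tsv"))
  gaf_path <- file.path(dir, "gopo.gaf")
  writeLines(c("!gaf-version: 2.2",
               apply(gaf_rows, 1, paste, collapse = "\t")), gaf_path)
  paths["gopo"] <- gaf_path
  bed_path <- file.path(dir, "sites.bed")
  utils::write.table(sites, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths["sites"] <- bed_path
  gff_path <- file.path(dir, "genes.gff3")
  writeLines(gff_lines, gff_path)
  paths["genes"] <- gff_path
  fa_path <- file.path(dir, "proteins.fasta")
  writeLines(as.vector(rbind(paste0(">", prots), seqs)), fa_path)
  paths["proteins"] <- fa_path
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  wt(manifest, "manifest.tsv")
  paths["manifest"] <- file.path(dir, "manifest.tsv")

  invisible(list(paths = paths, assemblies = asm, interfaces = interfaces,
                 llps = llps, gaf = gaf_rows, tfs = tfs_df, ppi = ppi,
                 sites = sites, proteins = data.frame(
                   protein_id = prots, length = prot_len, sequence = seqs,
                   pfams = vapply(prot_pfams, paste, "", collapse = ","),
                   stringsAsFactors = FALSE),
                 config = config))
}

#' Verify a bundle's manifest checksums
#' @param dir bundle directory.
#' @return TRUE invisibly; stops on mismatch.
#' @export
verify_bundle <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  cur <- tools::md5sum(file.path(dir, man$file))
  bad <- man$file[unname(cur) != man$md5]
  if (length(bad)) stop("checksum mismatch: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Generate a labeled feature table with injected class-feature dependence
#'
#' Features are sampled independently and uniformly over their levels;
#' the class of each instance is then drawn from a multinomial whose
#' per-class log-odds receive a shift of `effect * max_shift` for every
#' signal entry `(class, feature, level)` matched by the instance.
#' Strength 0 gives exact class-feature independence; stacking entries
#' lets planted dependences reach near-deterministic Bayes accuracy.
#'
#' @param n number of instances.
#' @param features named list: feature name -> character vector of levels.
#' @param classes character vector of class labels.
#' @param signal data.frame with columns `class`, `feature`, `level`,
#'   `effect` (each effect in `[0, 1]`).
#' @param seed integer seed.
#' @param max_shift log-odds shift at effect 1 (default 8).
#' @param class_column name of the class column in the result.
#' @return a [feature_table()] with attribute `bayes_accuracy` (the exact
#'   accuracy of the Bayes classifier of the generating model).
#' @export
inject_signal <- function(n, features, classes, signal, seed,
                          max_shift = 8, class_column = "class") {
  stopifnot(is.list(features), !is.null(names(features)), length(classes) >= 2L)
  if (nrow(signal) > 0) {
    stopifnot(all(c("class", "feature", "level", "effect") %in% names(signal)))
    if (any(!signal$feature %in% names(features)))
      stop("signal references unknown feature: ",
           paste(setdiff(signal$feature, names(features)), collapse = ", "))
    if (any(!signal$class %in% classes))
      stop("signal references unknown class")
    if (any(signal$effect < 0 | signal$effect > 1))
      stop("effect strengths must lie in [0, 1]")
  }
  set.seed(seed)
  df <- as.data.frame(lapply(features, function(lv)
    sample(lv, n, replace = TRUE)), stringsAsFactors = FALSE)
  logits <- matrix(0, n, length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(nrow(signal))) {
    hit <- df[[signal$feature[i]]] == signal$level[i]
    logits[hit, signal$class[i]] <- logits[hit, signal$class[i]] +
      signal$effect[i] * max_shift
  }
  prob <- exp(logits)
  prob <- prob / rowSums(prob)
  cls <- vapply(seq_len(n), function(i)
    sample(classes, 1, prob = prob[i, ]), "")
  df[[class_column]] <- cls
  out <- feature_table(df, class_column)
  # exact Bayes accuracy of the generating model: enumerate feature cells
  cells <- expand.grid(features, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cell_w <- rep(1 / nrow(cells), nrow(cells))
  bayes <- 0
  for (ci in seq_len(nrow(cells))) {
    lg <- stats::setNames(numeric(length(classes)), classes)
    for (i in seq_len(nrow(signal)))
      if (cells[ci, signal$feature[i]] == signal$level[i])
        lg[signal$class[i]] <- lg[signal$class[i]] +
          signal$effect[i] * max_shift
    p <- exp(lg) / sum(exp(lg))
    bayes <- bayes + cell_w[ci] * max(p)
  }
  attr(out, "bayes_accuracy") <- bayes
  out
}

#' The planted-dependence study table
#'
#' Convenience wrapper reproducing the package's reference prediction
#' fixture: 4 classes, 3 informative binary features whose planted
#' log-odds shifts make the class nearly a deterministic function of the
#' first two features (the third reinforces weakly), plus 5 uninformative
#' 4-level noise features.
#'
#' @param n instances (default 600).
#' @param seed integer seed.
#' @param effect effect strength of the planted entries (default 1).
#' @return a labeled [feature_table()] (see [inject_signal()]).
#' @export
signal_study_table <- function(n = 600L, seed = 1L, effect = 1) {
  features <- c(
    list(f1 = c("a", "b"), f2 = c("a", "b"), f3 = c("a", "b")),
    stats::setNames(rep(list(c("u", "v", "w", "x")), 5),
                    paste0("noise", 1:5)))
  classes <- paste0("c", 1:4)
  signal <- rbind(
    data.frame(class = c("c1", "c2"), feature = "f1", level = "a",
               effect = effect, stringsAsFactors = FALSE),
    data.frame(class = c("c3", "c4"), feature = "f1", level = "b",
               effect = effect, stringsAsFactors = FALSE),
    data.frame(class = c("c1", "c3"), feature = "f2", level = "a",
               effect = effect, stringsAsFactors = FALSE),
    data.frame(class = c("c2", "c4"), feature = "f2", level = "b",
               effect = effect, stringsAsFactors = FALSE),
    data.frame(class = c("c1", "c4"), feature = "f3",
               level = c("a", "b"), effect = 0.125 * effect,
               stringsAsFactors = FALSE))
  inject_signal(n, features, classes, signal, seed = seed)
}
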