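#' Motif-type incidence marginals of a TF set
#'
#' Both marginals of the TF x motif-type incidence matrix: how many motif
#' types each TF binds, and how many TFs bind each motif type.
#'
#' @param tfs list; each element a list with `tf_id` and `motifs`
#'   (character vector of motif-type identifiers).
#' @return list with `per_tf` (named integer vector) and `per_motif`
#'   (named integer vector).
#' @export
count_motif_types <- function(tfs) {
  if (length(tfs) == 0L)
    return(list(per_tf = stats::setNames(integer(), character()),
                per_motif = stats::setNames(integer(), character())))
  per_tf <- stats::setNames(
    vapply(tfs, function(t) length(unique(t$motifs)), 0L),
    vapply(tfs, `[[`, "", "tf_id"))
  pairs <- do.call(rbind, lapply(tfs, function(t)
    if (length(t$motifs)) data.frame(tf = t$tf_id, motif = unique(t$motifs),
                                     stringsAsFactors = FALSE)))
  per_motif <- if (is.null(pairs)) stats::setNames(integer(), character())
               else {
                 tb <- table(pairs$motif)
                 stats::setNames(as.integer(tb), names(tb))
               }
  list(per_tf = per_tf, per_motif = per_motif)
}

#' Derive typed feature intervals from gene models
#'
#' Expands each gene model into typed intervals (internally 0-based
#' half-open): exons, CDSs, UTRs, introns, and strand-aware upstream/
#' downstream windows.  Introns are the exon complement within the gene
#' span; UTRs absent from a model are inferred as exon minus CDS (logged
#' via the `inferred_utr` attribute).  Upstream means 5' of the
#' transcription start, respecting strand.
#'
#' @param models list of gene models; each a list with `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (gene span, 0-based
#'   half-open), and `features`: data.frame with `type`
#'   (`exon`/`CDS`/`UTR`), `start`, `end` (0-based half-open).
#' @param upstream_bp,downstream_bp flanking window widths (bp).
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `type`,
#'   `start`, `end` (0-based half-open).
#' @export
gene_feature_intervals <- function(models, upstream_bp = 2000L,
                                   downstream_bp = 2000L) {
  stopifnot(upstream_bp > 0L, downstream_bp > 0L)
  inferred <- character()
  rows <- lapply(models, function(m) {
    fk <- m$features
    if (is.null(fk)) fk <- data.frame(type = character(), start = integer(),
                                      end = integer(), stringsAsFactors = FALSE)
    ex <- fk[fk$type == "exon", , drop = FALSE]
    cds <- fk[fk$type == "CDS", , drop = FALSE]
    utr <- fk[fk$type == "UTR", , drop = FALSE]
    out <- list()
    add <- function(type, start, end) {
      if (length(start) && any(end > start))
        out[[length(out) + 1L]] <<- data.frame(
          gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
          type = type, start = start[end > start], end = end[end > start],
          stringsAsFactors = FALSE)
    }
    add("exon", ex$start, ex$end)
    add("CDS", cds$start, cds$end)
    # introns: gene span minus exons
    if (nrow(ex) > 0L) {
      exi <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      gaps <- IRanges::setdiff(IRanges::IRanges(m$start + 1L, m$end), exi)
      add("intron", IRanges::start(gaps) - 1L, IRanges::end(gaps))
    }
    if (nrow(utr) > 0L) {
      add("UTR", utr$start, utr$end)
    } else if (nrow(ex) > 0L && nrow(cds) > 0L) {
      exi <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      cdi <- IRanges::reduce(IRanges::IRanges(cds$start + 1L, cds$end))
      ut <- IRanges::setdiff(exi, cdi)
      if (length(ut)) {
        inferred <<- c(inferred, m$gene_id)
        add("UTR", IRanges::start(ut) - 1L, IRanges::end(ut))
      }
    }
    if (identical(m$strand, "-")) {
      add("upstream", m$end, m$end + upstream_bp)
      add("downstream", max(0L, m$start - downstream_bp), m$start)
    } else {
      add("upstream", max(0L, m$start - upstream_bp), m$start)
      add("downstream", m$end, m$end + downstream_bp)
    }
    if (length(out) == 0L) NULL else do.call(rbind, out)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), type = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  attr(res, "inferred_utr") <- unique(inferred)
  res
}

#' Map binding sites onto gene feature intervals
#'
#' Bedmap-style counting: a site increments every feature interval it
#' overlaps by at least 1 bp; a site may hit several features and several
#' genes.  All coordinates are 0-based half-open, so adjacent intervals
#' share no position and zero-length overlaps never count.  Sites on
#' chromosomes absent from the models land in the `unmapped` report.
#'
#' @param sites data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), optional `strand`, `tf_id`.
#' @param models list of gene models (see [gene_feature_intervals()]).
#' @param upstream_bp,downstream_bp flanking window widths.
#' @return A `feature_binding_counts`: list with `counts` (data.frame
#'   gene_id/type/count), `overlaps` (raw site-feature hit list) and
#'   `unmapped` (site rows on unknown chromosomes).
#' @export
map_sites_to_features <- function(sites, models, upstream_bp = 2000L,
                                  downstream_bp = 2000L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(sites)))
  if (nrow(sites) > 0L && any(sites$start >= sites$end))
    stop("sites must satisfy start < end (0-based half-open)")
  feats <- gene_feature_intervals(models, upstream_bp, downstream_bp)
  known <- unique(feats$chrom)
  unmapped <- sites[!sites$chrom %in% known, , drop = FALSE]
  idx_known <- which(sites$chrom %in% known)
  s <- sites[idx_known, , drop = FALSE]
  overlaps <- NULL
  if (nrow(s) > 0L && nrow(feats) > 0L) {
    # 0-based half-open [start,end) -> 1-based closed [start+1, end]
    q <- GenomicRanges::GRanges(s$chrom,
                                IRanges::IRanges(s$start + 1L, s$end))
    r <- GenomicRanges::GRanges(feats$chrom,
                                IRanges::IRanges(feats$start + 1L, feats$end))
    ov <- GenomicRanges::findOverlaps(q, r, minoverlap = 1L,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      overlaps <- data.frame(
        site = idx_known[S4Vectors::queryHits(ov)],
        chrom = s$chrom[S4Vectors::queryHits(ov)],
        site_start = s$start[S4Vectors::queryHits(ov)],
        site_end = s$end[S4Vectors::queryHits(ov)],
        tf_id = if ("tf_id" %in% names(s))
          s$tf_id[S4Vectors::queryHits(ov)] else NA_character_,
        gene_id = feats$gene_id[S4Vectors::subjectHits(ov)],
        type = feats$type[S4Vectors::subjectHits(ov)],
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(overlaps))
    overlaps <- data.frame(site = integer(), chrom = character(),
                           site_start = integer(), site_end = integer(),
                           tf_id = character(), gene_id = character(),
                           type = character(), stringsAsFactors = FALSE)
  counts <- if (nrow(overlaps) > 0L) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(overlaps))),
                            by = list(gene_id = overlaps$gene_id,
                                      type = overlaps$type), FUN = sum)
    agg[order(agg$gene_id, agg$type), , drop = FALSE]
  } else {
    data.frame(gene_id = character(), type = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, overlaps = overlaps, unmapped = unmapped),
            class = "feature_binding_counts")
}

#' @export
print.feature_binding_counts <- function(x, ...) {
  cat(sprintf("feature binding counts: %d site-feature overlaps, %d unmapped sites\n",
              nrow(x$overlaps), nrow(x$unmapped)))
  if (nrow(x$counts)) print(utils::head(x$counts, 10), row.names = FALSE)
  invisible(x)
}

#' Read a BED file of binding sites
#'
#' BED is 0-based half-open; columns chrom/start/end[/name/score/strand],
#' with the name column used as the TF identifier.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `tf_id`, `strand`.
#' @export
read_bed_sites <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$tf_id <- if (ncol(df) >= 4) df[[4]] else NA_character_
  df$strand <- if (ncol(df) >= 6) df[[6]] else "*"
  df[, c("chrom", "start", "end", "tf_id", "strand")]
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `exon`, `CDS` and UTR records (GFF3 is 1-based closed;
#' converted to the internal 0-based half-open convention).  Child
#' features attach to genes via the `Parent`/`ID` attributes' gene stem.
#'
#' @param path GFF3 file.
#' @return list of gene models (see [gene_feature_intervals()]).
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  recs <- lapply(f, function(x) {
    attrs <- x[9]
    get_attr <- function(key) {
      m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    list(chrom = x[1], type = x[3],
         start = as.integer(x[4]) - 1L,  # to 0-based half-open
         end = as.integer(x[5]),
         strand = x[7], id = get_attr("ID"), parent = get_attr("Parent"))
  })
  types <- vapply(recs, `[[`, "", "type")
  genes <- recs[types == "gene"]
  kids <- recs[types %in% c("exon", "CDS", "five_prime_UTR",
                            "three_prime_UTR", "UTR")]
  lapply(genes, function(g) {
    stem <- g$id
    mine <- Filter(function(k) !is.na(k$parent) &&
                     (k$parent == stem || startsWith(k$parent, paste0(stem, "."))),
                   kids)
    feats <- if (length(mine))
      data.frame(
        type = vapply(mine, function(k)
          if (k$type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")) "UTR"
          else k$type, ""),
        start = vapply(mine, `[[`, 0L, "start"),
        end = vapply(mine, `[[`, 0L, "end"),
        stringsAsFactors = FALSE)
    else data.frame(type = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
    list(gene_id = g$id, chrom = g$chrom, strand = g$strand,
         start = g$start, end = g$end, features = feats)
  })
}
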