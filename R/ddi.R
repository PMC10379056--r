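#' Split interface residue positions into gap-limited fragments
#'
#' An interface fragment is a maximal run of listed residue positions with
#' no internal gap larger than `max_gap` missing residues: a break is
#' placed between consecutive positions p < q whenever `q - p - 1 >
#' max_gap`.  With the default `max_gap = 3`, positions 5 and 9 (gap 3)
#' stay together while 5 and 10 (gap 4) split.
#'
#' @param positions strictly increasing integer vector of 1-based residue
#'   positions.
#' @param max_gap largest tolerated number of missing residues between
#'   consecutive interface positions.
#' @return list of integer vectors (the fragments, in order).
#' @examples
#' split_fragments(c(3, 4, 5, 9))   # one fragment
#' split_fragments(c(3, 4, 5, 10))  # two fragments
#' @export
split_fragments <- function(positions, max_gap = 3L) {
  stopifnot(is.numeric(positions), max_gap >= 0)
  if (length(positions) == 0L) return(list())
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be sorted, strictly increasing (no duplicates)")
  gaps <- diff(positions) - 1L
  grp <- cumsum(c(0L, gaps > max_gap))
  unname(split(positions, grp))
}

# per-entry interface measurements used in cluster comparison
interface_entry_measures <- function(entry, max_gap = 3L) {
  arch <- entry$architecture
  frags <- c(split_fragments(entry$side1, max_gap),
             split_fragments(entry$side2, max_gap))
  flen <- lengths(frags)
  c(n_domains = length(arch),
    n_motifs = as.numeric(identical(entry$kind, "DMI")),
    n_fragments = length(frags),
    total_aa = sum(flen),
    mean_fragment_aa = if (length(flen)) mean(flen) else 0,
    max_fragment_aa = if (length(flen)) max(flen) else 0,
    protcad_value = if (!is.null(entry$protcad_value)) entry$protcad_value else NA_real_)
}

#' Compare non-redundant vs redundant interface clusters
#'
#' Entries sharing the same unordered domain pair are split into a
#' non-redundant cluster (architectures in which each member domain occurs
#' once, e.g. Dom1-Dom2) and a redundant cluster (any member domain
#' repeated, e.g. Dom1-Dom2-Dom1).  For each cluster the function computes
#' 13 named summary values over per-entry interface measurements (counts of
#' interacting domains and motifs, fragment amino-acid statistics, the
#' maximum assembly-symmetry value, cluster means/SDs and membership
#' sizes), and a one-way ANOVA per measurement across the two clusters.
#' ANOVA is applied regardless of normality: the magnitude of the
#' between-cluster difference is what is reported, and each p-value
#' carries a normality caveat flag.
#'
#' @param entries list of interface entries; each a list with fields
#'   `domain_pair` (character 2-vector, unordered), `architecture`
#'   (character vector of member domains of the parent entry), `side1`,
#'   `side2` (increasing 1-based positions), `kind` (`"DDI"`/`"DMI"`), and
#'   optional `protcad_value`.
#' @param max_gap fragment gap threshold, see [split_fragments()].
#' @return An `interface_comparison`: list with `pair`, per-cluster `values`
#'   (13 each), `anova` (data.frame measure/F/p/applicable), and sizes.
#' @export
compare_interface_clusters <- function(entries, max_gap = 3L) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  pairs <- lapply(entries, function(e) sort(e$domain_pair))
  if (length(unique(vapply(pairs, paste, "", collapse = "|"))) != 1L)
    stop("all entries must share the same unordered domain pair")
  redundant <- vapply(entries, function(e)
    any(table(e$architecture[e$architecture %in% e$domain_pair]) > 1L),
    logical(1))
  nr_m <- lapply(entries[!redundant], interface_entry_measures, max_gap = max_gap)
  rd_m <- lapply(entries[redundant], interface_entry_measures, max_gap = max_gap)

  cluster_values <- function(ms) {
    if (length(ms) == 0L) return(NULL)
    M <- do.call(rbind, ms)
    list(membership_size = nrow(M),
         mean_n_domains = mean(M[, "n_domains"]),
         n_motif_entries = sum(M[, "n_motifs"]),
         mean_n_fragments = mean(M[, "n_fragments"]),
         sd_n_fragments = if (nrow(M) > 1) stats::sd(M[, "n_fragments"]) else 0,
         mean_total_aa = mean(M[, "total_aa"]),
         sd_total_aa = if (nrow(M) > 1) stats::sd(M[, "total_aa"]) else 0,
         mean_fragment_aa = mean(M[, "mean_fragment_aa"]),
         sd_fragment_aa = if (nrow(M) > 1) stats::sd(M[, "mean_fragment_aa"]) else 0,
         max_fragment_aa = max(M[, "max_fragment_aa"]),
         max_protcad_value = if (all(is.na(M[, "protcad_value"]))) NA_real_
                             else max(M[, "protcad_value"], na.rm = TRUE),
         mean_protcad_value = if (all(is.na(M[, "protcad_value"]))) NA_real_
                              else mean(M[, "protcad_value"], na.rm = TRUE),
         total_fragments = sum(M[, "n_fragments"]))
  }
  nr_v <- cluster_values(nr_m)
  rd_v <- cluster_values(rd_m)
  stopifnot(is.null(nr_v) || length(nr_v) == 13L,
            is.null(rd_v) || length(rd_v) == 13L)

  measures <- c("n_domains", "n_motifs", "n_fragments", "total_aa",
                "mean_fragment_aa", "max_fragment_aa", "protcad_value")
  applicable <- length(nr_m) >= 1L && length(rd_m) >= 1L &&
    (length(nr_m) + length(rd_m)) >= 3L
  anova_tab <- do.call(rbind, lapply(measures, function(ms) {
    if (!applicable)
      return(data.frame(measure = ms, F = NA_real_, p = NA_real_,
                        applicable = FALSE, stringsAsFactors = FALSE))
    y <- c(vapply(nr_m, `[[`, 0, ms), vapply(rd_m, `[[`, 0, ms))
    g <- factor(rep(c("NR", "R"), c(length(nr_m), length(rd_m))))
    keep <- !is.na(y)
    if (sum(keep) < 3L || length(unique(g[keep])) < 2L)
      return(data.frame(measure = ms, F = NA_real_, p = NA_real_,
                        applicable = FALSE, stringsAsFactors = FALSE))
    if (stats::var(y[keep]) == 0) {
      # degenerate: clusters identical in this measure -> no effect
      return(data.frame(measure = ms, F = 0, p = 1, applicable = TRUE,
                        stringsAsFactors = FALSE))
    }
    within_var <- tapply(y[keep], g[keep], stats::var)
    if (all(within_var[!is.na(within_var)] == 0)) {
      # perfect separation: all variance is between clusters
      return(data.frame(measure = ms, F = Inf, p = 0, applicable = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::anova(stats::lm(y[keep] ~ g[keep]))
    data.frame(measure = ms, F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
               applicable = TRUE, stringsAsFactors = FALSE)
  }))
  attr(anova_tab, "normality_caveat") <- TRUE
  structure(list(pair = pairs[[1]],
                 nonredundant = nr_v, redundant = rd_v,
                 n_nonredundant = length(nr_m), n_redundant = length(rd_m),
                 anova = anova_tab),
            class = "interface_comparison")
}

#' @export
print.interface_comparison <- function(x, ...) {
  cat(sprintf("interface comparison %s-%s: NR n=%d, redundant n=%d\n",
              x$pair[1], x$pair[2], x$n_nonredundant, x$n_redundant))
  if (any(x$anova$applicable))
    print(x$anova[x$anova$applicable, c("measure", "F", "p")], row.names = FALSE)
  else cat("  ANOVA not applicable (a cluster is empty or too small)\n")
  invisible(x)
}

#' Map protein-level and positional features onto domain/interdomain regions
#'
#' Regions tile the protein exactly: the declared domain spans plus the
#' complementary interdomain spans cover positions 1..L with no overlap.
#' Position-borne features (PTM sites, glycosylation sites) are assigned to
#' the region containing their position; protein-global features (GRAVY,
#' pI, subcellular location, ...) are attached to every region flagged as
#' protein-level.  Overlapping domain annotations are resolved by keeping
#' the longer span (ties: the earlier start); discarded spans are recorded
#' in the `discarded` attribute.
#'
#' @param protein_length integer protein length L.
#' @param domains data.frame with columns `pfam`, `start`, `end` (1-based
#'   inclusive).
#' @param global_features named list of protein-level feature values
#'   (optional).
#' @param sites data.frame with columns `position`, `feature` (optional
#'   positional features such as PTMs).
#' @return list of region annotations; each has `region_type`
#'   (`"domain"`/`"interdomain"`), `pfam` (NA for interdomain), `start`,
#'   `end`, `sites` (data.frame subset) and `global` (the protein-level
#'   features).
#' @export
map_features_to_regions <- function(protein_length, domains,
                                    global_features = list(),
                                    sites = NULL) {
  stopifnot(protein_length >= 1L)
  discarded <- NULL
  if (is.null(domains) || nrow(domains) == 0L) {
    doms <- data.frame(pfam = character(), start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("pfam", "start", "end") %in% names(domains)))
    if (any(domains$start < 1L) || any(domains$end > protein_length) ||
        any(domains$start > domains$end))
      stop("domain spans must satisfy 1 <= start <= end <= protein_length")
    doms <- domains[order(-(domains$end - domains$start + 1L), domains$start), ,
                    drop = FALSE]
    keep <- logical(nrow(doms))
    occupied <- integer(0)
    for (i in seq_len(nrow(doms))) {
      span <- doms$start[i]:doms$end[i]
      if (length(intersect(span, occupied)) == 0L) {
        keep[i] <- TRUE
        occupied <- c(occupied, span)
      }
    }
    discarded <- doms[!keep, , drop = FALSE]
    doms <- doms[keep, , drop = FALSE]
    doms <- doms[order(doms$start), , drop = FALSE]
  }
  # complement of domain spans
  regions <- list()
  add_region <- function(type, pfam, start, end) {
    regions[[length(regions) + 1L]] <<- list(region_type = type, pfam = pfam,
                                             start = start, end = end)
  }
  cursor <- 1L
  for (i in seq_len(nrow(doms))) {
    if (doms$start[i] > cursor)
      add_region("interdomain", NA_character_, cursor, doms$start[i] - 1L)
    add_region("domain", doms$pfam[i], doms$start[i], doms$end[i])
    cursor <- doms$end[i] + 1L
  }
  if (cursor <= protein_length)
    add_region("interdomain", NA_character_, cursor, protein_length)

  if (!is.null(sites) && nrow(sites) > 0L) {
    stopifnot(all(c("position", "feature") %in% names(sites)))
    if (any(sites$position < 1L) || any(sites$position > protein_length))
      stop("site position beyond protein length")
  }
  out <- lapply(regions, function(r) {
    r$global <- global_features
    r$sites <- if (!is.null(sites) && nrow(sites) > 0L)
      sites[sites$position >= r$start & sites$position <= r$end, , drop = FALSE]
    else
      data.frame(position = integer(), feature = character(),
                 stringsAsFactors = FALSE)
    r
  })
  attr(out, "discarded") <- discarded
  out
}

#' Clan pool of a protein's interaction partners
#'
#' Collects the Pfam domains carried by every interaction partner of a
#' protein and maps them to their Pfam clans; the pool is the union of the
#' clans.  Pfams without a clan mapping pass through as singleton
#' pseudo-clans (their own identifier).  A protein absent from the edge
#' list has an empty pool.
#'
#' @param protein_id protein identifier.
#' @param ppi_edges data.frame with columns `a`, `b` (undirected edges).
#' @param protein_pfams named list: protein id -> character vector of
#'   Pfams.
#' @param pfam_clan_map named character vector Pfam -> clan (may be
#'   partial).
#' @return character vector of clans (sorted, unique).
#' @export
clan_pool <- function(protein_id, ppi_edges, protein_pfams,
                      pfam_clan_map = character()) {
  stopifnot(all(c("a", "b") %in% names(ppi_edges)))
  partners <- unique(c(ppi_edges$b[ppi_edges$a == protein_id],
                       ppi_edges$a[ppi_edges$b == protein_id]))
  partners <- setdiff(partners, protein_id)
  if (length(partners) == 0L) return(character())
  pfams <- unique(unlist(protein_pfams[partners], use.names = FALSE))
  if (length(pfams) == 0L) return(character())
  clans <- ifelse(pfams %in% names(pfam_clan_map),
                  unname(pfam_clan_map[pfams]), pfams)
  sort(unique(clans))
}

#' Read interface entries from TSV
#'
#' Columns: `pair` (`"PF_a|PF_b"`), `architecture` (comma list),
#' `side1`, `side2` (comma lists of positions), `kind`, optional
#' `protcad_value`.
#'
#' @param path TSV file.
#' @return list of interface entries (see [compare_interface_clusters()]).
#' @export
read_interfaces_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair", "architecture", "side1", "side2", "kind")
  if (!all(need %in% names(df)))
    stop("interface table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    list(domain_pair = strsplit(df$pair[i], "|", fixed = TRUE)[[1]],
         architecture = strsplit(df$architecture[i], ",", fixed = TRUE)[[1]],
         side1 = as.integer(strsplit(df$side1[i], ",", fixed = TRUE)[[1]]),
         side2 = as.integer(strsplit(df$side2[i], ",", fixed = TRUE)[[1]]),
         kind = df$kind[i],
         protcad_value = if ("protcad_value" %in% names(df))
           df$protcad_value[i] else NULL)
  })
}
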