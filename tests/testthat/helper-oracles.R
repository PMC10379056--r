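# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (simple loops) so they cannot share a defect with the
# implementation paths they check.

# all length-3 windows of a string, counted one by one
oracle_trimer_counts <- function(letters_str) {
  L <- nchar(letters_str)
  out <- list()
  if (L >= 3) {
    for (i in seq_len(L - 2)) {
      t <- substr(letters_str, i, i + 2)
      out[[t]] <- (out[[t]] %||% 0) + 1
    }
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# gap scan: walk the positions, break when more than max_gap missing
oracle_fragments <- function(positions, max_gap = 3) {
  if (length(positions) == 0) return(list())
  frags <- list(positions[1])
  for (p in positions[-1]) {
    last <- frags[[length(frags)]]
    if (p - last[length(last)] - 1 > max_gap)
      frags[[length(frags) + 1]] <- p
    else
      frags[[length(frags)]] <- c(last, p)
  }
  frags
}

# textbook one-way ANOVA from group sums
oracle_anova <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  groups <- unique(g)
  ssb <- sum(vapply(groups, function(gr)
    sum(g == gr) * (mean(y[g == gr]) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(gr)
    sum((y[g == gr] - mean(y[g == gr]))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# naive all-pairs interval overlap on 0-based half-open coordinates
oracle_overlaps <- function(sites, feats) {
  hits <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(feats))) {
      if (sites$chrom[i] == feats$chrom[j] &&
          min(sites$end[i], feats$end[j]) -
            max(sites$start[i], feats$start[j]) >= 1) {
        hits[[length(hits) + 1]] <- data.frame(
          site = i, gene_id = feats$gene_id[j], type = feats$type[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(site = integer(), gene_id = character(),
                      type = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# random reduced-alphabet sequence
rand_letters <- function(n, groups) paste(sample(groups, n, replace = TRUE),
                                          collapse = "")

# canonical sort of an overlap table, for set comparison
sort_overlaps <- function(df) {
  df <- df[order(df$site, df$gene_id, df$type), c("site", "gene_id", "type")]
  rownames(df) <- NULL
  df
}
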