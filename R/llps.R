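#' Biomolecular condensate vocabulary
#'
#' The ~40 condensate terms recognised by the LLPS annotation layer,
#' normalized to snake_case tokens.  "others" is retained as a real
#' category.
#'
#' @return character vector of 40 tokens.
#' @export
condensate_vocabulary <- function() {
  c("balbiani_bodies", "cajal_bodies", "centrosome_spindle_pole_bodies",
    "chromatin", "chromatoid_bodies", "cleavage_bodies", "ddx1_bodies",
    "dna_damage_foci", "droplets", "gemini_of_cajal_bodies",
    "germ_plasm_polar_granules", "histone_locus_bodies", "insulator_bodies",
    "microtubules", "mitochondrial_rna_granules", "neuronal_granules",
    "nuage", "nuclear_pore_complexes", "nuclear_speckles",
    "nuclear_stress_bodies", "nucleoli", "opt_domains", "others",
    "paraspeckles", "p_bodies", "pcg_bodies", "pericentriolar_matrices",
    "perinucleolar_compartments", "p_granules", "pml_nuclear_bodies",
    "post_synaptic_density", "pyrenoid_matrices", "receptor_clusters",
    "sam68_nuclear_bodies", "sirna_bodies", "spindle_apparatuses",
    "sponge_bodies", "stress_granules", "tam_bodies", "u_bodies")
}

#' Normalize a condensate term to its vocabulary token
#' @param term free-text condensate name.
#' @return snake_case token.
#' @export
normalize_condensate <- function(term) {
  t <- tolower(trimws(term))
  t <- gsub("[^a-z0-9]+", "_", t)
  gsub("^_+|_+$", "", t)
}

llps_functional_types <- c("client", "regulator", "scaffold")

#' Canonical LLPS-type key of a condensate set
#'
#' Proteins are typed by the set of condensates they associate with; the
#' key is the sorted, "|"-joined set so that identical sets give identical
#' keys regardless of input order.
#'
#' @param condensates character vector of condensate terms (free text or
#'   tokens).
#' @param vocabulary permitted tokens; defaults to
#'   [condensate_vocabulary()].
#' @return single string key.
#' @examples
#' llps_type_key(c("nucleoli", "Cajal bodies"))  # "cajal_bodies|nucleoli"
#' @export
llps_type_key <- function(condensates, vocabulary = condensate_vocabulary()) {
  if (length(condensates) == 0L)
    stop("an LLPS-annotated protein must have a non-empty condensate set")
  toks <- vapply(condensates, normalize_condensate, "")
  bad <- setdiff(toks, vocabulary)
  if (length(bad))
    stop(sprintf("unknown condensate term(s): %s; vocabulary: %s",
                 paste(bad, collapse = ", "),
                 paste(vocabulary, collapse = ", ")))
  paste(sort(unique(toks)), collapse = "|")
}

#' Frequency matrices of domains, functional types or domain dimers per
#' LLPS type
#'
#' Counts, per LLPS-type key, how often each unit occurs over an annotated
#' protein set.  Units are Pfam domains (`mode = "domain"`), LLPS
#' functional types (`"functional_type"`), or unordered within-protein
#' Pfam pairs (`"dimer"`).  Dimer mode enumerates all unordered pairs of
#' distinct domain occurrences in a protein: a protein with n distinct
#' Pfams contributes n(n-1)/2 pairs, and a self-pair PF_a-PF_a is counted
#' only when PF_a occurs at least twice in the protein.  Counting is
#' additive over proteins.
#'
#' @param proteins list; each element a list with `protein_id`, `pfams`
#'   (character vector, possibly with repeats), `condensates`, and
#'   `functional_type`.
#' @param mode `"domain"`, `"functional_type"` or `"dimer"`.
#' @return matrix (unit x LLPS-type key) of counts.
#' @export
count_type_frequencies <- function(proteins,
                                   mode = c("domain", "functional_type",
                                            "dimer")) {
  mode <- match.arg(mode)
  rows <- list()
  for (p in proteins) {
    key <- llps_type_key(p$condensates)
    units <- switch(mode,
      domain = unique(p$pfams),
      functional_type = {
        ft <- p$functional_type
        if (is.null(ft) || is.na(ft)) character() else ft
      },
      dimer = {
        pf <- p$pfams
        if (length(pf) < 2L) character()
        else {
          cmb <- utils::combn(sort(pf), 2L)
          keys <- paste(cmb[1, ], cmb[2, ], sep = "--")
          unique_pairs <- unique(keys)
          # distinct-domain pairs once; self-pairs only via real repeats
          unique_pairs
        }
      })
    for (u in units)
      rows[[length(rows) + 1L]] <- c(unit = u, key = key)
  }
  if (length(rows) == 0L)
    return(matrix(0, 0, 0))
  df <- do.call(rbind.data.frame, c(lapply(rows, as.list),
                                    list(stringsAsFactors = FALSE)))
  tab <- table(df$unit, df$key)
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Partial match of a protein against larger molecules
#'
#' Flags proteins whose full Pfam set is contained in the strictly larger
#' Pfam set of some candidate molecule (hetero-oligomers and multi-gene
#' factors), and reports the Pfam count of the largest such candidate.
#'
#' @param pfams the protein's Pfam set.
#' @param larger_molecules list of character vectors (candidate Pfam sets).
#' @return list with `matched` (logical) and `n_pfam_of_match` (integer;
#'   0 when unmatched).
#' @export
partial_match_larger <- function(pfams, larger_molecules) {
  pf <- unique(pfams)
  best <- 0L
  for (cand in larger_molecules) {
    cu <- unique(cand)
    if (length(cu) > length(pf) && all(pf %in% cu))
      best <- max(best, length(cu))
  }
  list(matched = best > 0L, n_pfam_of_match = best)
}

#' The 13 special domain-property flags
#' @return character vector of the flag names.
#' @export
special_flag_names <- function() {
  c("rna_binding_domain", "dna_binding_domain", "dmi", "low_complexity",
    "disordered_region", "repeat", "coiled_coil", "phosphorylation_site",
    "active_site",
    # configurable evidence-driven slots (defaults; see vignette)
    "transmembrane_helix", "signal_peptide", "domain_linker",
    "glycosylation")
}

#' Build the special-flag vector of a protein
#'
#' Each of the 13 flags is true iff any domain of the protein carries the
#' corresponding property in the evidence tables.  A missing evidence
#' table makes its flag `NA` ("unknown", ternary), never silently false.
#'
#' @param pfams the protein's Pfam domains.
#' @param evidence named list: flag name -> character vector of Pfams
#'   carrying the property (a flag absent from the list becomes `NA`).
#' @param flags flag names, [special_flag_names()] by default.
#' @return named logical vector of length 13 (with possible NAs).
#' @export
build_special_flags <- function(pfams, evidence, flags = special_flag_names()) {
  stopifnot(length(flags) == 13L)
  out <- stats::setNames(rep(NA, length(flags)), flags)
  for (f in flags) {
    if (!is.null(evidence[[f]]))
      out[f] <- any(pfams %in% evidence[[f]])
  }
  out
}

#' Read protein LLPS annotations from TSV
#'
#' Columns: `protein_id`, `condensates` (comma list), `functional_type`,
#' `pfams` (comma list).
#'
#' @param path TSV file.
#' @return list of annotated proteins (see [count_type_frequencies()]).
#' @export
read_llps_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "condensates", "functional_type", "pfams")
  if (!all(need %in% names(df)))
    stop("LLPS table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    list(protein_id = df$protein_id[i],
         condensates = strsplit(df$condensates[i], ",", fixed = TRUE)[[1]],
         functional_type = df$functional_type[i],
         pfams = strsplit(df$pfams[i], ",", fixed = TRUE)[[1]]))
}
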