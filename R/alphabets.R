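#' Reduced sequence alphabets
#'
#' An `alphabet_spec` describes a total map from an input residue alphabet
#' onto a small set of single-letter groups.  The shipped protein alphabet
#' collapses the 20 canonical amino acids into five groups by side-chain
#' polarity and charge; the shipped DNA alphabet collapses the 15 IUPAC
#' nucleotide codes into four groups separating G, non-G ambiguity codes
#' that include G, codes that exclude G, and the fully ambiguous N.
#'
#' @param name identifier for the alphabet.
#' @param mapping named character vector: names are input letters, values
#'   are single uppercase group letters.
#' @param group_order character vector giving the canonical ordering of the
#'   group letters; must contain every distinct group exactly once.
#' @return An object of class `alphabet_spec`.
#' @examples
#' spec <- protein_alphabet()
#' encode_protein("RKST", spec)
#' @export
alphabet_spec <- function(name, mapping, group_order) {
  stopifnot(is.character(mapping), length(mapping) > 0, !is.null(names(mapping)))
  groups <- unique(unname(mapping))
  if (!all(nchar(unname(mapping)) == 1L) || !all(unname(mapping) == toupper(unname(mapping))))
    stop("group letters must be single uppercase characters")
  if (!setequal(group_order, groups) || anyDuplicated(group_order))
    stop("group_order must contain every group letter exactly once")
  structure(list(name = name, mapping = mapping,
                 group_order = as.character(group_order)),
            class = "alphabet_spec")
}

#' @export
print.alphabet_spec <- function(x, ...) {
  cat(sprintf("alphabet_spec '%s': %d input letters -> %d groups (%s)\n",
              x$name, length(x$mapping), length(x$group_order),
              paste(x$group_order, collapse = ",")))
  invisible(x)
}

#' @rdname alphabet_spec
#' @details
#' `protein_alphabet()` groups: P = R,K,S,T (positive or polar uncharged);
#' N = D,E,N,Q (negative or polar uncharged); H = A,V,I,L,M (hydrophobic);
#' R = F,W,Y (ring structures); S = C,G,P,H (special properties).
#' Group memberships are a modelling choice: for proteins where cysteine,
#' glycine, histidine or proline deserve their own groups, supply a custom
#' spec via [alphabet_spec()].
#' @export
protein_alphabet <- function() {
  m <- c(R = "P", K = "P", S = "P", T = "P",
         D = "N", E = "N", N = "N", Q = "N",
         A = "H", V = "H", I = "H", L = "H", M = "H",
         F = "R", W = "R", Y = "R",
         C = "S", G = "S", P = "S", H = "S")
  alphabet_spec("protein5", m, c("P", "N", "H", "R", "S"))
}

#' @rdname alphabet_spec
#' @details
#' `dna_alphabet()` groups: G = G; Z = R,S,K,B,D,V (ambiguity codes that can
#' be G); X = A,C,T,Y,W,M,H (bases and codes that are never G); N = N.
#' @export
dna_alphabet <- function() {
  m <- c(G = "G",
         R = "Z", S = "Z", K = "Z", B = "Z", D = "Z", V = "Z",
         A = "X", C = "X", T = "X", Y = "X", W = "X", M = "X", H = "X",
         N = "N")
  alphabet_spec("dna4", m, c("G", "Z", "X", "N"))
}

encode_with_spec <- function(seq, spec, what) {
  stopifnot(inherits(spec, "alphabet_spec"), is.character(seq), length(seq) == 1L)
  if (is.na(seq)) stop("sequence is NA")
  s <- toupper(seq)
  if (nchar(s) == 0L)
    return(structure(list(source_id = NA_character_, letters = "", spec = spec$name),
                     class = "reduced_sequence"))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- unname(spec$mapping[chars])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unknown %s letter '%s' at position %d (alphabet '%s')",
                 what, chars[bad], bad, spec$name))
  }
  structure(list(source_id = NA_character_,
                 letters = paste(out, collapse = ""),
                 spec = spec$name),
            class = "reduced_sequence")
}

#' Encode sequences in a reduced group alphabet
#'
#' Position-wise substitution of each residue by its group letter; length is
#' preserved and unknown letters raise an error naming the offending
#' position (no silent skipping).
#'
#' @param seq a single character string (amino acids or IUPAC DNA).
#' @param spec an [alphabet_spec()]; defaults to the shipped table.
#' @return A `reduced_sequence` object with fields `letters` and `spec`.
#' @examples
#' encode_protein("ENAGDTEAPT")$letters  # "NNHSNPNHSP"
#' encode_dna("GATC")$letters            # "GXXX"
#' @export
encode_protein <- function(seq, spec = protein_alphabet()) {
  encode_with_spec(seq, spec, "amino-acid")
}

#' @rdname encode_protein
#' @export
encode_dna <- function(seq, spec = dna_alphabet()) {
  encode_with_spec(seq, spec, "nucleotide")
}

#' @export
print.reduced_sequence <- function(x, ...) {
  cat(sprintf("reduced_sequence [%s] length %d: %s\n", x$spec,
              nchar(x$letters),
              if (nchar(x$letters) > 60) paste0(substr(x$letters, 1, 60), "...")
              else x$letters))
  invisible(x)
}

#' Trimer frequency profile of a reduced sequence
#'
#' Counts every length-3 window (step 1) of the group-letter sequence.  A
#' sequence of length L has `max(0, L - 2)` windows.  The densified vector
#' enumerates all `|groups|^3` trimers in lexicographic order over
#' `group_order` (125 for the 5-letter protein alphabet, 64 for the
#' 4-letter DNA alphabet).
#'
#' @param rs a `reduced_sequence` (or a plain string over the group
#'   alphabet).
#' @param spec the [alphabet_spec()] whose `group_order` defines the trimer
#'   universe.
#' @param normalize divide counts by the total window count (when > 0).
#' @return A `trimer_vector`: named numeric vector over all trimers
#'   (attribute `total` = number of windows).
#' @examples
#' tv <- trimer_frequencies(encode_protein("ENAGDTEAPT"))
#' attr(tv, "total")  # 8
#' @export
trimer_frequencies <- function(rs, spec = protein_alphabet(), normalize = FALSE) {
  letters_str <- if (inherits(rs, "reduced_sequence")) rs$letters else as.character(rs)
  universe <- trimer_universe(spec)
  counts <- stats::setNames(numeric(length(universe)), universe)
  L <- nchar(letters_str)
  n_win <- max(0L, L - 2L)
  if (n_win > 0L) {
    chars <- strsplit(letters_str, "", fixed = TRUE)[[1]]
    if (!all(chars %in% spec$group_order))
      stop("sequence contains letters outside the group alphabet")
    tri <- paste0(chars[seq_len(n_win)], chars[seq_len(n_win) + 1L],
                  chars[seq_len(n_win) + 2L])
    tab <- table(tri)
    counts[names(tab)] <- as.numeric(tab)
  }
  if (normalize && n_win > 0L) counts <- counts / n_win
  structure(counts, total = n_win, normalized = normalize && n_win > 0L,
            class = c("trimer_vector", "numeric"))
}

#' All trimers of an alphabet, lexicographic over group_order
#' @param spec an [alphabet_spec()].
#' @return character vector of length `length(group_order)^3`.
#' @export
trimer_universe <- function(spec) {
  g <- spec$group_order
  grid <- expand.grid(c3 = g, c2 = g, c1 = g,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(grid$c1, grid$c2, grid$c3)
}

#' Mean trimer profile over a set of member sequences
#'
#' Builds a motif-level profile for a conserved-sequence family (such as a
#' nucleotide-binding motif with several member sequences): each member is
#' encoded, its trimer vector normalized, and the profile is the mean of the
#' per-member normalized vectors (aggregation is a parameter).
#'
#' @param seqs character vector of member sequences.
#' @param spec an [alphabet_spec()].
#' @param encoder encoding function, [encode_protein()] by default.
#' @param aggregate `"mean"` (default) or `"sum"` of per-member normalized
#'   vectors.
#' @return named numeric profile vector over the trimer universe.
#' @export
motif_trimer_profile <- function(seqs, spec = protein_alphabet(),
                                 encoder = encode_protein,
                                 aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(seqs) >= 1)
  vecs <- vapply(seqs, function(s)
    as.numeric(trimer_frequencies(encoder(s, spec), spec, normalize = TRUE)),
    numeric(length(spec$group_order)^3))
  prof <- if (aggregate == "mean") rowMeans(vecs) else rowSums(vecs)
  stats::setNames(prof, trimer_universe(spec))
}

#' Nucleotide-containing ligand moiety groups
#'
#' The 24 nucleotide-containing ligands recognised by conserved
#' ligand-binding sequence profiles are grouped by their moiety composition
#' into 11 codes built from the letters R (ribose/ribitol), B (nucleobase),
#' P (phosphate), F (flavin), N (nicotinamide), S (sulfur), T (thiamine/
#' thiazole) and O (other moiety).  The shipped assignment follows standard
#' moiety decomposition of each cofactor and is fully overridable.
#'
#' @return named character vector: ligand name -> group code.
#' @examples
#' default_ligand_groups()[["NAD(H)"]]  # "RBPN"
#' @export
default_ligand_groups <- function() {
  c("AMP" = "RBP", "ADP" = "RBP", "ATP" = "RBP",
    "GMP" = "RBP", "GDP" = "RBP", "GTP" = "RBP", "CTP" = "RBP",
    "cAMP" = "RBP", "cGMP" = "RBP", "c-di-AMP" = "RBP", "c-di-GMP" = "RBP",
    "PAP" = "RBP",
    "CoA" = "RBPS", "Acetyl-CoA" = "RBPS",
    "FAD(H)" = "RBPF",
    "NAD(H)" = "RBPN", "NADP" = "RBPN",
    "PPS" = "RBPSO",
    "SAM" = "RBSO",
    "FMN" = "RPF",
    "F-420" = "RPFO",
    "PLP" = "OP",
    "ThPP" = "TP",
    "THD" = "TOP")
}

#' The 11 permitted ligand group codes
#' @export
ligand_group_codes <- function() {
  c("RBP", "RBPF", "RBPN", "RBPS", "RBPSO", "RBSO",
    "TOP", "OP", "TP", "RPF", "RPFO")
}

#' Look up the moiety group of a ligand
#'
#' @param ligand ligand name (exact match against the map's names).
#' @param map named vector ligand -> group code; defaults to
#'   [default_ligand_groups()].
#' @return the group code (one of [ligand_group_codes()]).
#' @export
ligand_group <- function(ligand, map = default_ligand_groups()) {
  stopifnot(is.character(ligand), length(ligand) == 1L)
  if (!all(map %in% ligand_group_codes()))
    stop("map contains group codes outside the 11 permitted codes")
  if (!ligand %in% names(map))
    stop(sprintf("unmapped ligand '%s'; known ligands: %s", ligand,
                 paste(sort(names(map)), collapse = ", ")))
  unname(map[[ligand]])
}

#' Write trimer vectors as TSV
#'
#' Long format with columns `id`, `trimer`, `count`, `freq`.
#'
#' @param vectors named list of `trimer_vector`s (names become `id`).
#' @param path output file.
#' @param keep_zero keep zero-count trimers (default drops them).
#' @export
write_trimer_tsv <- function(vectors, path, keep_zero = FALSE) {
  stopifnot(is.list(vectors), !is.null(names(vectors)))
  rows <- lapply(names(vectors), function(id) {
    v <- vectors[[id]]
    tot <- attr(v, "total")
    cnt <- as.numeric(v)
    if (isTRUE(attr(v, "normalized"))) cnt <- cnt * tot
    keep <- if (keep_zero) seq_along(cnt) else which(cnt > 0)
    data.frame(id = id, trimer = names(v)[keep], count = cnt[keep],
               freq = if (tot > 0) cnt[keep] / tot else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param type `"protein"` or `"dna"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
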