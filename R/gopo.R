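#' Category lexicon for GO/PO annotation records
#'
#' Annotation records are assigned to five categories (GO analyses,
#' signaling pathways, gene associations, PO anatomy genes, PO temporal
#' genes) via four kinds of subcategory lists: signaling-pathway words, 34
#' major GO analysis terms, regulatory-role words, and the original
#' database qualifiers.  The shipped word lists are editable defaults (the
#' 34-term list is populated from a generic GO slim); supply your own via
#' the arguments.
#'
#' @param signaling_words signaling-pathway word list.
#' @param go_major_terms exactly 34 major GO analysis terms.
#' @param regulatory_words regulatory-role words.
#' @return A `category_lexicon` object.
#' @export
category_lexicon <- function(signaling_words = default_signaling_words(),
                             go_major_terms = default_go_major_terms(),
                             regulatory_words = default_regulatory_words()) {
  norm <- function(x) unique(tolower(trimws(x)))
  go_major_terms <- norm(go_major_terms)
  if (length(go_major_terms) != 34L)
    stop("the GO major-term list must have exactly 34 entries")
  structure(list(signaling = norm(signaling_words),
                 go_major = go_major_terms,
                 regulatory = norm(regulatory_words)),
            class = "category_lexicon")
}

#' @rdname category_lexicon
#' @export
default_signaling_words <- function() {
  c("hormone", "auxin", "abscisic acid", "gibberellin", "cytokinin",
    "ethylene", "jasmonic acid", "salicylic acid", "brassinosteroid",
    "response to light", "light signaling", "photomorphogenesis",
    "osmosensing", "osmotic stress", "signal transduction",
    "signaling pathway", "kinase cascade", "phosphorelay",
    "calcium signaling", "second messenger")
}

#' @rdname category_lexicon
#' @export
default_go_major_terms <- function() {
  c("cell communication", "response to abiotic stimulus",
    "response to biotic stimulus", "response to stress",
    "response to chemical", "signal transduction",
    "transcription", "translation", "dna repair", "dna replication",
    "cell cycle", "cell division", "cell differentiation",
    "cell death", "transport", "protein transport", "lipid metabolism",
    "carbohydrate metabolism", "amino acid metabolism",
    "secondary metabolism", "photosynthesis", "respiration",
    "protein folding", "protein modification", "proteolysis",
    "rna processing", "ribosome biogenesis", "chromatin organization",
    "cytoskeleton organization", "membrane organization",
    "development", "reproduction", "flower development",
    "embryo development")
}

#' @rdname category_lexicon
#' @export
default_regulatory_words <- function() {
  c("enhancer", "suppressor", "chaperon", "chaperone", "activator",
    "repressor", "inhibitor", "regulator", "modulator", "cofactor")
}

# case-insensitive whole-word match of any list entry inside text
match_words <- function(text, words) {
  if (is.na(text) || nchar(text) == 0L) return(character())
  hits <- vapply(words, function(w)
    grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", w), "\\b"),
          text, ignore.case = TRUE, perl = TRUE),
    logical(1))
  words[hits]
}

#' Assign one annotation record to categories
#'
#' Matches the record's term name and qualifier against each subcategory
#' list (case-insensitive, whole-word); the original-attribute subcategory
#' matches the qualifier verbatim.  PO records additionally hit their
#' anatomy/temporal category directly.
#'
#' @param record list with fields `gene_id`, `aspect` (`"GO"`,
#'   `"PO-anatomy"`, `"PO-temporal"`), `term_name`, `qualifier`.
#' @param lexicon a [category_lexicon()].
#' @return data.frame of (category, subcategory) hits (0 rows when none).
#' @export
assign_categories <- function(record, lexicon) {
  stopifnot(inherits(lexicon, "category_lexicon"))
  text <- paste(record$term_name,
                gsub("_", " ", record$qualifier %||% ""), sep = " ")
  hits <- list()
  add <- function(category, subcategory) {
    hits[[length(hits) + 1L]] <<- data.frame(category = category,
                                             subcategory = subcategory,
                                             stringsAsFactors = FALSE)
  }
  for (w in match_words(text, lexicon$signaling))
    add("signaling_pathways", w)
  for (w in match_words(text, lexicon$go_major))
    add("go_analyses", w)
  for (w in match_words(text, lexicon$regulatory))
    add("gene_associations", w)
  q <- record$qualifier %||% ""
  if (!is.na(q) && nchar(q) > 0L)
    add("original_attribute", q)
  asp <- record$aspect %||% "GO"
  if (identical(asp, "PO-anatomy")) add("po_anatomy_genes", "po_anatomy")
  if (identical(asp, "PO-temporal")) add("po_temporal_genes", "po_temporal")
  if (length(hits) == 0L)
    return(data.frame(category = character(), subcategory = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' The 10 category-frequency features
#' @return character vector of feature names.
#' @export
category_feature_names <- function() {
  c("n_go_records", "n_po_anatomy_records", "n_po_temporal_records",
    "n_signaling_hits", "n_go_major_hits", "n_regulatory_hits",
    "n_original_attribute_hits", "n_distinct_go_terms",
    "n_distinct_po_terms", "n_total_hits")
}

#' Category frequency vector of one gene
#'
#' Aggregates the (category, subcategory) hits of a gene's annotation
#' records into 10 named frequency features.  Duplicate records count
#' twice (frequency semantics) unless `dedupe = TRUE`.
#'
#' @param gene_id gene identifier.
#' @param records list of annotation records (see [assign_categories()]);
#'   records for other genes are ignored.
#' @param lexicon a [category_lexicon()].
#' @param dedupe drop identical duplicate records first.
#' @param normalize divide by the record count (rates instead of counts).
#' @return named numeric vector of length 10.
#' @export
category_frequency_vector <- function(gene_id, records, lexicon,
                                      dedupe = FALSE, normalize = FALSE) {
  recs <- Filter(function(r) identical(r$gene_id, gene_id), records)
  if (dedupe && length(recs) > 1L) {
    keys <- vapply(recs, function(r)
      paste(r$aspect %||% "", r$term %||% "", r$term_name %||% "",
            r$qualifier %||% "", sep = "\r"), "")
    recs <- recs[!duplicated(keys)]
  }
  v <- stats::setNames(numeric(10), category_feature_names())
  if (length(recs) == 0L) return(v)
  allhits <- do.call(rbind, lapply(recs, assign_categories, lexicon = lexicon))
  asp <- vapply(recs, function(r) r$aspect %||% "GO", "")
  v["n_go_records"] <- sum(asp == "GO")
  v["n_po_anatomy_records"] <- sum(asp == "PO-anatomy")
  v["n_po_temporal_records"] <- sum(asp == "PO-temporal")
  v["n_signaling_hits"] <- sum(allhits$category == "signaling_pathways")
  v["n_go_major_hits"] <- sum(allhits$category == "go_analyses")
  v["n_regulatory_hits"] <- sum(allhits$category == "gene_associations")
  v["n_original_attribute_hits"] <- sum(allhits$category == "original_attribute")
  terms <- vapply(recs, function(r) r$term %||% NA_character_, "")
  v["n_distinct_go_terms"] <- length(unique(terms[asp == "GO" & !is.na(terms)]))
  v["n_distinct_po_terms"] <- length(unique(terms[asp != "GO" & !is.na(terms)]))
  v["n_total_hits"] <- nrow(allhits)
  if (normalize) v <- v / length(recs)
  v
}

#' Read a GAF 2.x gene-association file
#'
#' Minimal reader for the 17-column GAF layout ("!" comment lines
#' skipped).  The aspect column (13: `P`/`F`/`C` for GO; `A`/`G` used here
#' for PO anatomy/temporal) maps to the internal aspects.
#'
#' @param path GAF file.
#' @return list of annotation records.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lapply(fields, function(f) {
    f <- c(f, rep("", max(0, 17 - length(f))))
    aspect <- switch(f[9], P = "GO", F = "GO", C = "GO",
                     A = "PO-anatomy", G = "PO-temporal", "GO")
    list(gene_id = f[2], aspect = aspect, term = f[5],
         term_name = f[10], qualifier = f[4], evidence = f[7])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
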