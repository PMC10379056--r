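#' Assemble a per-protein feature table from a fixture bundle
#'
#' Joins the module outputs of a generated (or schema-compatible) snapshot
#' directory into one mixed categorical [feature_table()]: the assembly
#' taxonomy from the oligomerization module, phase-separation membership
#' and functional type from the condensate annotations, and domain counts.
#' The declared class column is the assembly state (`monomer` / `single` /
#' `oligomer`), leaving the remaining variables as predictors.
#'
#' @param dir bundle directory (see [generate_bundle()]).
#' @param class_column which derived column to declare as the class:
#'   `"assembly_state"` (default) or `"oligomer_label"`.
#' @return a [feature_table()] with one row per protein.
#' @export
bundle_feature_table <- function(dir, class_column = c("assembly_state",
                                                       "oligomer_label")) {
  class_column <- match.arg(class_column)
  asm <- read_assembly_tsv(file.path(dir, "assemblies.tsv"))
  stopifnot("protein_id" %in% names(asm))
  llps <- read_llps_tsv(file.path(dir, "llps.tsv"))
  llps_ids <- vapply(llps, `[[`, "", "protein_id")
  rows <- lapply(seq_len(nrow(asm)), function(i) {
    cl <- classify_cluster(asm$stoichiometry[i], asm$symmetry[i])
    lab <- compose_oligomer_label(asm[i, , drop = FALSE])$label
    j <- match(asm$protein_id[i], llps_ids)
    pfams <- strsplit(asm$pfam_architecture[i], ",", fixed = TRUE)[[1]]
    data.frame(
      protein_id = asm$protein_id[i],
      assembly_state = cl$state,
      oligomer_label = lab,
      composition = cl$composition,
      obligacy = if ("obligacy" %in% names(asm)) asm$obligacy[i] else "unknown",
      is_llps = if (is.na(j)) "no" else "yes",
      functional_type = if (is.na(j)) "none" else llps[[j]]$functional_type,
      n_pfams = as.character(length(pfams)),
      n_condensates = if (is.na(j)) "0"
                      else as.character(length(llps[[j]]$condensates)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  drop <- if (class_column == "assembly_state") "oligomer_label"
          else "assembly_state"
  df <- df[, setdiff(names(df), c(drop, "protein_id")), drop = FALSE]
  feature_table(df, class_column,
                provenance = c(composition = "oligomer",
                               obligacy = "oligomer",
                               is_llps = "llps", functional_type = "llps",
                               n_pfams = "llps", n_condensates = "llps"))
}
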