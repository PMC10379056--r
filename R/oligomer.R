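#' Parse an assembly stoichiometry string
#'
#' Stoichiometry strings such as `"A2BC"` list chain letters with optional
#' copy counts (omitted count = 1).  The grammar is `([A-Z][0-9]*)+`.
#'
#' @param s stoichiometry string.
#' @return named integer vector: chain letter -> copy count.
#' @examples
#' parse_stoichiometry("A2BC")  # c(A = 2, B = 1, C = 1)
#' @export
parse_stoichiometry <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (is.na(s) || nchar(s) == 0L) stop("empty stoichiometry string")
  m <- gregexpr("[A-Z][0-9]*", s)[[1]]
  toks <- regmatches(s, gregexpr("[A-Z][0-9]*", s))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (m[1] != 1L || covered != nchar(s)) {
    # first position not matched by the grammar
    bad <- setdiff(seq_len(nchar(s)),
                   unlist(mapply(function(st, len) seq(st, st + len - 1),
                                 as.integer(m), attr(m, "match.length"),
                                 SIMPLIFY = FALSE)))
    stop(sprintf("malformed stoichiometry '%s' at offset %d", s,
                 if (length(bad)) min(bad) else 1L))
  }
  letters_ <- substr(toks, 1, 1)
  counts <- ifelse(nchar(toks) > 1L, as.integer(substring(toks, 2)), 1L)
  if (anyDuplicated(letters_))
    stop(sprintf("malformed stoichiometry '%s': repeated chain letter", s))
  stats::setNames(as.integer(counts), letters_)
}

#' Numeric order of a point-group symmetry token
#'
#' The symmetry number is read as the integer suffix of the point-group
#' token (C1 -> 1, C2 -> 2, D3 -> 3).  Dihedral groups contain twice as
#' many subunits as their rotational order; set `dihedral_double = TRUE`
#' to count subunits (D3 -> 6) instead of rotational order.
#'
#' @param symmetry point-group token, e.g. `"C1"`, `"C2"`, `"D3"`.
#' @param dihedral_double double the suffix for D groups.
#' @return integer symmetry order.
#' @export
symmetry_order <- function(symmetry, dihedral_double = FALSE) {
  stopifnot(is.character(symmetry))
  ok <- grepl("^[A-Z][0-9]*$", symmetry)
  if (!all(ok)) stop(sprintf("malformed symmetry token '%s'", symmetry[!ok][1]))
  n <- suppressWarnings(as.integer(sub("^[A-Z]", "", symmetry)))
  n[is.na(n)] <- 1L
  if (dihedral_double) {
    d <- substr(symmetry, 1, 1) == "D"
    n[d] <- n[d] * 2L
  }
  n
}

#' Classify one assembly cluster
#'
#' Composition is `homo` when the stoichiometry uses a single chain letter
#' (one distinct sequence) and `hetero` otherwise.  The assembly state is
#' `oligomer` when the symmetry order is 2 or higher (e.g. C2, D3);
#' among C1 clusters, `monomer` when a single chain copy is present
#' (C1-A1) and `single` when multiple chains assemble without symmetry
#' (e.g. C1-A2BC).
#'
#' @param stoichiometry stoichiometry string (see [parse_stoichiometry()]).
#' @param symmetry point-group token.
#' @return list with `composition` (`"homo"`/`"hetero"`) and `state`
#'   (`"monomer"`/`"single"`/`"oligomer"`).
#' @examples
#' classify_cluster("A1", "C1")    # homo monomer (the CMA case)
#' classify_cluster("A2BC", "C1")  # hetero single
#' classify_cluster("A6", "D3")    # homo oligomer
#' @export
classify_cluster <- function(stoichiometry, symmetry) {
  st <- parse_stoichiometry(stoichiometry)
  ord <- symmetry_order(symmetry)
  composition <- if (length(st) == 1L) "homo" else "hetero"
  state <- if (ord >= 2L) "oligomer"
           else if (sum(st) == 1L) "monomer"
           else "single"
  list(composition = composition, state = state)
}

obligacy_levels <- c("obligate", "moderate", "transient", "unknown")
state_levels <- c("monomer", "single", "oligomer")

#' Compose the oligomerization-type label for a protein or group
#'
#' Aggregates the classified assembly clusters observed for one protein (or
#' one Pfam-architecture group) into a single composite label.  The grammar
#' is deterministic and permutation-invariant:
#'
#' * `"CMA"` when every cluster is the homo C1-A1 case (a crystallographic
#'   monomer);
#' * `"C1_<obligacy>_hetero_single"` when every cluster is C1 and a hetero
#'   assembly is present (molecules from multiple sequences without
#'   symmetry);
#' * otherwise `<composition>` (`homo`, `hetero`, or `homo_hetero` when
#'   both are observed) followed by one token per distinct observed
#'   (obligacy, state) pair.  Pairs are ordered monomer < single <
#'   oligomer, then obligate < moderate < transient < unknown; monomer and
#'   single pairs render as `obligacy_state` and oligomer pairs as
#'   `state_obligacy`, reproducing composites such as
#'   `homo_obligate_monomer_oligomer_moderate`.
#'
#' @param clusters data.frame with columns `stoichiometry`, `symmetry`,
#'   `obligacy` (one of obligate/moderate/transient/unknown; missing values
#'   become `"unknown"`, never silently coerced to a real class).
#' @return An `oligomer_label` object: list with `label` and `components`.
#' @examples
#' cl <- data.frame(stoichiometry = c("A1", "A2"), symmetry = c("C1", "C2"),
#'                  obligacy = c("obligate", "moderate"))
#' compose_oligomer_label(cl)$label  # "homo_obligate_monomer_oligomer_moderate"
#' @export
compose_oligomer_label <- function(clusters) {
  if (is.null(clusters) || nrow(clusters) == 0L)
    stop("empty cluster list: at least one assembly cluster is required")
  stopifnot(all(c("stoichiometry", "symmetry") %in% names(clusters)))
  obl <- if ("obligacy" %in% names(clusters)) as.character(clusters$obligacy)
         else rep("unknown", nrow(clusters))
  obl[is.na(obl) | !obl %in% obligacy_levels] <- "unknown"
  cls <- lapply(seq_len(nrow(clusters)), function(i)
    classify_cluster(clusters$stoichiometry[i], clusters$symmetry[i]))
  comp <- vapply(cls, `[[`, "", "composition")
  state <- vapply(cls, `[[`, "", "state")
  ords <- symmetry_order(as.character(clusters$symmetry))

  components <- list(
    compositions = sort(unique(comp)),
    pairs = unique(data.frame(obligacy = obl, state = state,
                              stringsAsFactors = FALSE)))

  if (all(comp == "homo" & state == "monomer")) {
    return(structure(list(label = "CMA", components = components),
                     class = "oligomer_label"))
  }
  if (all(ords == 1L) && any(comp == "hetero")) {
    o <- obligacy_levels[min(match(obl, obligacy_levels))]
    return(structure(list(label = paste0("C1_", o, "_hetero_single"),
                          components = components),
                     class = "oligomer_label"))
  }
  comp_part <- if (all(comp == "homo")) "homo"
               else if (all(comp == "hetero")) "hetero"
               else "homo_hetero"
  pr <- components$pairs
  pr <- pr[order(match(pr$state, state_levels),
                 match(pr$obligacy, obligacy_levels)), , drop = FALSE]
  toks <- ifelse(pr$state == "oligomer",
                 paste(pr$state, pr$obligacy, sep = "_"),
                 paste(pr$obligacy, pr$state, sep = "_"))
  structure(list(label = paste(c(comp_part, toks), collapse = "_"),
                 components = components),
            class = "oligomer_label")
}

#' @export
print.oligomer_label <- function(x, ...) {
  cat("oligomer label:", x$label, "\n")
  invisible(x)
}

#' Parse a composite oligomerization label back into components
#'
#' Inverse of [compose_oligomer_label()]'s grammar; every emitted label
#' round-trips.
#'
#' @param label composite label string.
#' @return list with `compositions` and a data.frame `pairs`.
#' @export
parse_oligomer_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label == "CMA")
    return(list(compositions = "homo",
                pairs = data.frame(obligacy = NA_character_, state = "monomer",
                                   stringsAsFactors = FALSE)))
  toks <- strsplit(label, "_", fixed = TRUE)[[1]]
  if (toks[1] == "C1") {
    return(list(compositions = "hetero",
                pairs = data.frame(obligacy = toks[2], state = "single",
                                   stringsAsFactors = FALSE)))
  }
  i <- 1L
  comps <- character()
  while (i <= length(toks) && toks[i] %in% c("homo", "hetero")) {
    comps <- c(comps, toks[i]); i <- i + 1L
  }
  if (length(comps) == 0L) stop(sprintf("unparseable label '%s'", label))
  pairs <- list()
  while (i < length(toks)) {
    a <- toks[i]; b <- toks[i + 1L]
    if (a == "oligomer" && b %in% obligacy_levels) {
      pairs[[length(pairs) + 1L]] <- c(obligacy = b, state = a)
    } else if (a %in% obligacy_levels && b %in% state_levels) {
      pairs[[length(pairs) + 1L]] <- c(obligacy = a, state = b)
    } else stop(sprintf("unparseable label '%s' near '%s_%s'", label, a, b))
    i <- i + 2L
  }
  list(compositions = comps,
       pairs = do.call(rbind.data.frame,
                       c(lapply(pairs, function(p)
                         data.frame(obligacy = p[["obligacy"]],
                                    state = p[["state"]],
                                    stringsAsFactors = FALSE)),
                         list(stringsAsFactors = FALSE))))
}

#' Aggregate assembly clusters into the 19 reduced feature variables
#'
#' Reduces the raw per-cluster assembly table for one protein/group into a
#' fixed vector of 19 named features (counts, maxima and means over the
#' cluster set, plus the composite oligomerization label).  The aggregation
#' recipe is configuration-driven; the default recipe is documented in the
#' package vignette.
#'
#' @param clusters data.frame of assembly clusters (columns `stoichiometry`,
#'   `symmetry`, optional `obligacy`).
#' @param dihedral_double passed to [symmetry_order()].
#' @return named list of exactly 19 feature values.
#' @export
derive_protcad_features <- function(clusters, dihedral_double = FALSE) {
  if (is.null(clusters) || nrow(clusters) == 0L)
    stop("empty cluster table")
  stopifnot(all(c("stoichiometry", "symmetry") %in% names(clusters)))
  obl <- if ("obligacy" %in% names(clusters)) as.character(clusters$obligacy)
         else rep("unknown", nrow(clusters))
  obl[is.na(obl) | !obl %in% obligacy_levels] <- "unknown"
  cls <- lapply(seq_len(nrow(clusters)), function(i)
    classify_cluster(clusters$stoichiometry[i], clusters$symmetry[i]))
  comp <- vapply(cls, `[[`, "", "composition")
  state <- vapply(cls, `[[`, "", "state")
  sto <- lapply(as.character(clusters$stoichiometry), parse_stoichiometry)
  ords <- symmetry_order(as.character(clusters$symmetry), dihedral_double)
  copies <- vapply(sto, sum, 0L)
  lab <- compose_oligomer_label(clusters)
  out <- list(
    n_clusters = nrow(clusters),
    max_symmetry_order = max(ords),
    mean_symmetry_order = mean(ords),
    n_homo = sum(comp == "homo"),
    n_hetero = sum(comp == "hetero"),
    n_monomer = sum(state == "monomer"),
    n_single = sum(state == "single"),
    n_oligomer = sum(state == "oligomer"),
    n_obligate = sum(obl == "obligate"),
    n_moderate = sum(obl == "moderate"),
    n_transient = sum(obl == "transient"),
    n_unknown_obligacy = sum(obl == "unknown"),
    max_total_copies = max(copies),
    mean_total_copies = mean(copies),
    max_distinct_chains = max(lengths(sto)),
    n_distinct_stoichiometries = length(unique(as.character(clusters$stoichiometry))),
    n_distinct_symmetries = length(unique(as.character(clusters$symmetry))),
    has_dihedral = any(substr(as.character(clusters$symmetry), 1, 1) == "D"),
    oligomer_label = lab$label)
  stopifnot(length(out) == 19L)
  out
}

#' Read an assembly cluster table from TSV
#'
#' Expected columns: `group_id`, `pfam_architecture`, `stoichiometry`,
#' `symmetry`, `obligacy` (extra raw columns are kept).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_assembly_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_id", "stoichiometry", "symmetry")
  if (!all(need %in% names(df)))
    stop("assembly table must have columns: ", paste(need, collapse = ", "))
  df
}
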