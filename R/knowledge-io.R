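#' Directed background regulatory network
#'
#' A `background_network` holds the directed protein regulatory graph that the
#' whole pipeline operates on: regulator -> target edges collected from curated
#' pathway knowledge, optionally annotated with the pathway each edge came
#' from. Self-loops are dropped (with a count), duplicate edges collapsed, and
#' every edge endpoint becomes a node.
#'
#' @param edges A data frame with character columns `regulator` and `target`,
#'   and optionally `pathway_id`.
#' @param nodes Optional character vector of additional isolated nodes to keep
#'   (e.g. proteins declared in a document but not part of any relation).
#'
#' @return An object of class `background_network` with fields `nodes` (sorted
#'   character vector), `edges` (tibble `regulator`, `target`),
#'   `edge_pathways` (tibble `regulator`, `target`, `pathway_id`), `graph`
#'   (directed [igraph::graph]), and attribute `n_self_loops_dropped`.
#' @export
#' @examples
#' bg <- background_network(data.frame(regulator = "A", target = "B"))
#' bg$edges
background_network <- function(edges, nodes = character()) {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0 && length(nodes) == 0) {
    abort("background network is empty: no edges and no nodes")
  }
  if (!all(c("regulator", "target") %in% names(edges))) {
    abort("`edges` must have columns 'regulator' and 'target'")
  }
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (anyNA(edges$regulator) || anyNA(edges$target)) {
    abort("edge endpoints must not be missing")
  }
  self <- edges$regulator == edges$target
  n_self <- sum(self)
  if (n_self > 0) {
    warn(sprintf("dropped %d self-loop edge(s)", n_self))
    edges <- edges[!self, , drop = FALSE]
  }
  edge_pathways <- if ("pathway_id" %in% names(edges)) {
    edges |>
      filter(!is.na(.data$pathway_id), .data$pathway_id != "") |>
      distinct(.data$regulator, .data$target, .data$pathway_id) |>
      arrange(.data$regulator, .data$target, .data$pathway_id)
  } else {
    tibble(regulator = character(), target = character(),
           pathway_id = character())
  }
  edges <- edges |>
    distinct(.data$regulator, .data$target) |>
    arrange(.data$regulator, .data$target)
  all_nodes <- sort(unique(c(edges$regulator, edges$target,
                             as.character(nodes))))
  graph <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  structure(
    list(nodes = all_nodes, edges = edges, edge_pathways = edge_pathways,
         graph = graph),
    n_self_loops_dropped = n_self,
    class = "background_network"
  )
}

#' @export
print.background_network <- function(x, ...) {
  cat(sprintf("<background_network> %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
format.background_network <- function(x, ...) {
  sprintf("<background_network: %d nodes, %d edges>",
          length(x$nodes), nrow(x$edges))
}

#' Tidy a background network into its edge list
#'
#' @param x A [background_network()].
#' @param ... Unused.
#' @return A tibble with columns `regulator` and `target`.
#' @export
tidy.background_network <- function(x, ...) x$edges

#' Read a directed edge list into a background network
#'
#' Expects tab-separated columns `regulator`, `target` and optionally
#' `pathway_id`; lines starting with `#` are comments. A header row is
#' detected by name and otherwise assumed absent.
#'
#' @param path Path to a TSV edge list.
#' @return A [background_network()].
#' @export
read_background_network <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty edge list: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- identical(tolower(fields[[1]][1]), "regulator")
  start <- if (has_header) 2L else 1L
  if (start > length(fields)) abort(sprintf("edge list has no data rows: %s", path))
  rows <- fields[start:length(fields)]
  bad <- which(vapply(rows, length, 1L) < 2L)
  if (length(bad) > 0) {
    abort(sprintf("malformed edge-list row at line %d of %s (need >= 2 fields)",
                  bad[1] + start - 1L, path))
  }
  edges <- tibble(
    regulator = vapply(rows, `[[`, "", 1L),
    target = vapply(rows, `[[`, "", 2L),
    pathway_id = vapply(rows, function(f) if (length(f) >= 3) f[[3]] else NA_character_, "")
  )
  background_network(edges)
}

#' Write a background network to disk
#'
#' @param net A [background_network()].
#' @param path Output path.
#' @param format `"tsv"` for a tab-separated edge list (round-trips through
#'   [read_background_network()]) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_background_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "background_network"))
  if (format == "tsv") {
    edges <- net$edges
    if (nrow(net$edge_pathways) > 0) {
      pw <- net$edge_pathways |>
        group_by(.data$regulator, .data$target) |>
        summarise(pathway_id = paste(sort(.data$pathway_id), collapse = ";"),
                  .groups = "drop")
      edges <- left_join(edges, pw, by = c("regulator", "target"))
    }
    readr::write_tsv(edges, path)
  } else {
    igraph::write_graph(net$graph, path, format = "graphml")
  }
  invisible(path)
}

#' Parse a KGML-style pathway XML document into a background network
#'
#' Consumes the pathway XML dialect in which `<entry>` elements declare
#' proteins/genes (attributes `id`, `name`, `type`) and `<relation>` elements
#' declare directed interactions (`entry1` -> `entry2`). Entries whose `name`
#' attribute lists several identifiers are treated as groups of proteins and
#' expand combinatorially: a relation between two entries becomes one directed
#' edge per (name1, name2) pair. Relation subtypes and compound entries are
#' ignored.
#'
#' @param x Path to an XML file, or a length-1 character of XML text.
#' @return A [background_network()].
#' @export
read_kgml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) abort(sprintf("not parseable as XML: %s",
                                                    conditionMessage(e))))
  entries <- xml2::xml_find_all(doc, ".//entry")
  keep <- xml2::xml_attr(entries, "type") %in% c("protein", "gene")
  entries <- entries[keep]
  ids <- xml2::xml_attr(entries, "id")
  names_by_id <- setNames(
    strsplit(trimws(xml2::xml_attr(entries, "name")), "\\s+"), ids)
  relations <- xml2::xml_find_all(doc, ".//relation")
  edge_list <- vector("list", length(relations))
  for (i in seq_along(relations)) {
    e1 <- xml2::xml_attr(relations[[i]], "entry1")
    e2 <- xml2::xml_attr(relations[[i]], "entry2")
    if (is.na(e1) || is.na(e2) ||
        !e1 %in% names(names_by_id) || !e2 %in% names(names_by_id)) {
      abort(sprintf(
        "relation %d references unknown or non-protein entry (entry1=%s, entry2=%s)",
        i, e1 %||% "<missing>", e2 %||% "<missing>"))
    }
    eg <- expand.grid(regulator = names_by_id[[e1]],
                      target = names_by_id[[e2]],
                      stringsAsFactors = FALSE)
    edge_list[[i]] <- tibble(regulator = eg$regulator, target = eg$target)
  }
  edges <- bind_rows(edge_list)
  if (nrow(edges) == 0) {
    edges <- tibble(regulator = character(), target = character())
  }
  background_network(edges, nodes = unique(unlist(names_by_id)))
}

#' Pathway collection with class and exclusion metadata
#'
#' Combines a gene-set (GMT) source with a category table assigning each
#' pathway a class (`metabolic`, `signaling` or `other`), a free-text
#' subcategory (e.g. `"carbohydrate metabolism"`), and an exclusion flag for
#' disease pathways and global overview maps that should not enter enrichment.
#'
#' @param sets A tibble as returned by [read_gene_sets()]: columns
#'   `pathway_id`, `name`, `members` (list of character vectors).
#' @param categories A data frame with columns `pathway_id`, `class`,
#'   `subcategory`, `excluded`. Pathways without a category row default to
#'   class `"other"`, `excluded = FALSE`, with a warning.
#' @return An object of class `pathway_collection`: a tibble with columns
#'   `pathway_id`, `name`, `members`, `class`, `subcategory`, `excluded`.
#' @export
pathway_collection <- function(sets, categories = NULL) {
  sets <- as_tibble(sets)
  if (anyDuplicated(sets$pathway_id)) {
    dup <- unique(sets$pathway_id[duplicated(sets$pathway_id)])
    abort(sprintf("duplicate pathway id(s): %s", paste(dup, collapse = ", ")))
  }
  if (is.null(categories)) {
    categories <- tibble(pathway_id = character(), class = character(),
                         subcategory = character(), excluded = logical())
  }
  categories <- as_tibble(categories)
  if (anyDuplicated(categories$pathway_id)) {
    abort("duplicate pathway id(s) in category table")
  }
  bad_class <- setdiff(unique(categories$class),
                       c("metabolic", "signaling", "other"))
  if (length(bad_class) > 0) {
    abort(sprintf("unknown pathway class(es): %s", paste(bad_class, collapse = ", ")))
  }
  out <- left_join(sets, categories, by = "pathway_id")
  missing_cat <- is.na(out$class)
  if (any(missing_cat)) {
    warn(sprintf("%d pathway(s) lack a category row; defaulting to class 'other'",
                 sum(missing_cat)))
    out$class[missing_cat] <- "other"
    out$subcategory[missing_cat] <- "uncategorized"
    out$excluded[missing_cat] <- FALSE
  }
  out$excluded <- as.logical(out$excluded)
  empty <- !out$excluded & lengths(out$members) == 0
  if (any(empty)) {
    abort(sprintf("non-excluded pathway(s) with no members: %s",
                  paste(out$pathway_id[empty], collapse = ", ")))
  }
  class(out) <- c("pathway_collection", class(out))
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: `id<TAB>name<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `pathway_id`, `name`, `members` (list column).
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  tibble(
    pathway_id = vapply(fields, `[[`, "", 1L),
    name = vapply(fields, `[[`, "", 2L),
    members = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Read pathways (GMT plus category table)
#'
#' @param gmt_path Path to a GMT file ([read_gene_sets()]).
#' @param category_path Path to a TSV with header `pathway_id`, `class`,
#'   `subcategory`, `excluded`; may be `NULL`.
#' @return A [pathway_collection()].
#' @export
read_pathways <- function(gmt_path, category_path = NULL) {
  sets <- read_gene_sets(gmt_path)
  categories <- NULL
  if (!is.null(category_path)) {
    categories <- readr::read_tsv(category_path, show_col_types = FALSE,
                                  col_types = readr::cols(
                                    pathway_id = "c", class = "c",
                                    subcategory = "c", excluded = "l"))
  }
  pathway_collection(sets, categories)
}

#' Per-tissue protein abundance table
#'
#' Rows are proteins, replicate columns are strictly positive intensities;
#' each replicate column is labelled `control` or `case`. Positivity is
#' required because differential calling works on log2 intensities.
#'
#' @param x A data frame whose first column (`protein`) holds unique protein
#'   ids and whose remaining columns are replicate intensities.
#' @param groups Named character vector mapping every replicate column to
#'   `"control"` or `"case"`.
#' @param tissue Tissue identifier.
#' @return An `abundance_table`: a tibble with attributes `tissue` and
#'   `groups`.
#' @export
abundance_table <- function(x, groups, tissue) {
  x <- as_tibble(x)
  if (names(x)[1] != "protein") names(x)[1] <- "protein"
  x$protein <- as.character(x$protein)
  if (anyDuplicated(x$protein)) abort("duplicate protein ids in abundance table")
  reps <- setdiff(names(x), "protein")
  if (length(reps) == 0) abort("abundance table has no replicate columns")
  missing_lab <- setdiff(reps, names(groups))
  if (length(missing_lab) > 0) {
    abort(sprintf("replicate column(s) without group label: %s",
                  paste(missing_lab, collapse = ", ")))
  }
  groups <- groups[reps]
  if (!all(groups %in% c("control", "case"))) {
    abort("group labels must be 'control' or 'case'")
  }
  if (sum(groups == "control") < 2 || sum(groups == "case") < 2) {
    abort("need at least 2 replicates per group")
  }
  for (r in reps) {
    v <- x[[r]]
    if (!is.numeric(v)) abort(sprintf("replicate column '%s' is not numeric", r))
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-positive intensity for protein '%s' in column '%s'",
                    x$protein[bad[1]], r))
    }
  }
  structure(x, tissue = tissue, groups = groups,
            class = c("abundance_table", class(x)))
}

#' Read a per-tissue abundance TSV
#'
#' @param path TSV with header; first column protein ids, remaining columns
#'   replicate intensities.
#' @param groups Named character vector mapping replicate columns to
#'   `"control"`/`"case"`. If `NULL`, columns whose names start with `control`
#'   or `case` are labelled automatically.
#' @param tissue Tissue id; defaults to the file name without extension.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, groups = NULL, tissue = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (is.null(tissue)) {
    tissue <- sub("\\.[^.]*$", "", basename(path))
    tissue <- sub("^abundance_", "", tissue)
  }
  if (is.null(groups)) {
    reps <- setdiff(names(x), names(x)[1])
    g <- ifelse(grepl("^control", reps), "control",
                ifelse(grepl("^case", reps), "case", NA))
    if (anyNA(g)) {
      abort("cannot infer group labels from column names; pass `groups`")
    }
    groups <- setNames(g, reps)
  }
  abundance_table(x, groups, tissue)
}

#' Tissue-by-protein expression atlas
#'
#' Used for the low-expression exclusion filter: a protein whose expression in
#' one modeled tissue is more than `fold` times lower than in some other
#' tissue is excluded as a ligand there. Missing cells are kept as `NA`
#' ("unknown"), never coerced to zero, so that atlas-absent proteins are
#' exempt from the filter rather than silently deleted.
#'
#' @param x A data frame: first column protein ids, remaining columns one per
#'   tissue, non-negative numeric (NA = missing).
#' @return An `expression_atlas`: tibble with attribute `tissues`.
#' @export
expression_atlas <- function(x) {
  x <- as_tibble(x)
  if (names(x)[1] != "protein") names(x)[1] <- "protein"
  x$protein <- as.character(x$protein)
  if (anyDuplicated(x$protein)) abort("duplicate protein row in atlas")
  tissues <- setdiff(names(x), "protein")
  for (t in tissues) {
    v <- x[[t]]
    if (!is.numeric(v)) abort(sprintf("atlas column '%s' is not numeric", t))
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("negative expression value in tissue '%s'", t))
    }
  }
  structure(x, tissues = tissues, class = c("expression_atlas", class(x)))
}

#' Read an expression atlas TSV
#'
#' @param path TSV with header: protein id column then one column per tissue.
#' @return An [expression_atlas()].
#' @export
read_expression_atlas <- function(path) {
  expression_atlas(readr::read_tsv(path, show_col_types = FALSE))
}

#' Look up atlas expression values
#'
#' @param atlas An [expression_atlas()].
#' @param protein Protein id.
#' @param tissue Tissue id (must be an atlas column).
#' @return The expression level, or `NA` if the protein is absent or the cell
#'   is missing.
#' @export
atlas_value <- function(atlas, protein, tissue) {
  if (!tissue %in% attr(atlas, "tissues")) {
    abort(sprintf("tissue '%s' not in atlas", tissue))
  }
  i <- match(protein, atlas$protein)
  if (is.na(i)) return(NA_real_)
  as.numeric(atlas[[tissue]][i])
}

#' Read a secreted-protein catalog
#'
#' @param path TSV/one-per-line text of protein ids; a header line named
#'   `protein` is skipped; `#` comments allowed.
#' @return A sorted character vector of unique ids.
#' @export
read_secreted_catalog <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines <- lines[nzchar(lines)]
  lines <- lines[lines != "protein"]
  sort(unique(lines))
}

#' Read per-protein EC-number annotation
#'
#' @param path TSV with header columns `protein` and `ec`; `ec` holds
#'   semicolon-separated EC numbers (possibly empty).
#' @return A tibble with columns `protein` and `ec` (list of character
#'   vectors).
#' @export
read_ec_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(protein = "c", ec = "c"))
  ec <- lapply(x$ec, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  })
  pat <- "^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9n-]+$"
  bad <- which(vapply(ec, function(e) length(e) > 0 && !all(grepl(pat, e)), TRUE))
  if (length(bad) > 0) {
    abort(sprintf("malformed EC number for protein '%s'", x$protein[bad[1]]))
  }
  tibble(protein = x$protein, ec = ec)
}
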