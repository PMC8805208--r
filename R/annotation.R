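#' Classify proteins as metabolic enzymes, signaling proteins, or other
#'
#' A protein is a *metabolic enzyme* when it carries an EC number, is a member
#' of at least one pathway, and every (non-excluded) pathway containing it is
#' metabolic — this deliberately excludes kinases that sit on signaling
#' pathways. It is a *signaling protein* when it maps to at least one
#' signaling pathway and to no metabolic pathway. Everything else is `other`.
#' Excluded (disease/overview) pathways never count toward membership.
#'
#' @param proteins Character vector of protein ids to classify.
#' @param ec A tibble as from [read_ec_annotation()] (`protein`, `ec` list
#'   column), or a character vector of EC-bearing protein ids.
#' @param pathways A [pathway_collection()].
#' @return A tibble with columns `protein`, `role`, `has_ec`,
#'   `n_metabolic_pathways`, `n_signaling_pathways`, `n_other_pathways`.
#' @export
classify_proteins <- function(proteins, ec, pathways) {
  stopifnot(inherits(pathways, "pathway_collection"))
  ec_ids <- if (is.data.frame(ec)) {
    ec$protein[lengths(ec$ec) > 0]
  } else {
    as.character(ec)
  }
  active <- pathways[!pathways$excluded, , drop = FALSE]
  membership <- tidyr::unnest(
    tibble(class = active$class, protein = active$members),
    "protein")
  counts <- membership |>
    filter(.data$protein %in% proteins) |>
    count(.data$protein, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("metabolic", "signaling", "other")) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  out <- tibble(protein = as.character(proteins)) |>
    left_join(counts, by = "protein") |>
    mutate(dplyr::across(c("metabolic", "signaling", "other"),
                         ~ tidyr::replace_na(.x, 0L)),
           has_ec = .data$protein %in% ec_ids)
  out$role <- with(out, ifelse(
    has_ec & metabolic > 0 & signaling == 0 & other == 0, "metabolic_enzyme",
    ifelse(signaling > 0 & metabolic == 0, "signaling_protein", "other")))
  out |>
    select("protein", "role", "has_ec",
           n_metabolic_pathways = "metabolic",
           n_signaling_pathways = "signaling",
           n_other_pathways = "other")
}

#' Label network edges by the roles of their endpoints
#'
#' An edge is *metabolic-involved* when at least one endpoint is a metabolic
#' enzyme, and *signaling-involved* when at least one endpoint is a signaling
#' protein; an edge may carry both labels (no precedence is imposed), and an
#' exclusive counting where mixed edges count only as metabolic-involved is
#' returned alongside for comparison.
#'
#' @param net A [tissue_network()] or an undirected igraph.
#' @param roles A tibble from [classify_proteins()] covering all network
#'   nodes.
#' @return A list with `edges` (tibble `from`, `to`, `metabolic_involved`,
#'   `signaling_involved`) and `fractions` (named numeric:
#'   `metabolic_involved`, `signaling_involved`, plus `metabolic_exclusive`,
#'   `signaling_exclusive` where mixed edges count as metabolic only). With
#'   zero edges, `fractions` is `NULL`.
#' @export
classify_edges <- function(net, roles) {
  g <- if (inherits(net, "tissue_network")) net$graph else net
  el <- igraph::as_edgelist(g)
  role_of <- setNames(roles$role, roles$protein)
  nodes <- igraph::V(g)$name
  missing <- setdiff(nodes, names(role_of))
  if (length(missing) > 0) {
    abort(sprintf("roles missing for node(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (nrow(el) == 0) {
    return(list(edges = tibble(from = character(), to = character(),
                               metabolic_involved = logical(),
                               signaling_involved = logical()),
                fractions = NULL))
  }
  r1 <- role_of[el[, 1]]; r2 <- role_of[el[, 2]]
  met <- r1 == "metabolic_enzyme" | r2 == "metabolic_enzyme"
  sig <- r1 == "signaling_protein" | r2 == "signaling_protein"
  edges <- tibble(from = el[, 1], to = el[, 2],
                  metabolic_involved = unname(met),
                  signaling_involved = unname(sig))
  n <- nrow(edges)
  fractions <- c(metabolic_involved = sum(met) / n,
                 signaling_involved = sum(sig) / n,
                 metabolic_exclusive = sum(met) / n,
                 signaling_exclusive = sum(sig & !met) / n)
  list(edges = edges, fractions = fractions)
}

#' Partition a detected protein pool into secreted and non-secreted
#'
#' Any detected protein not in the secreted catalog is non-secreted.
#'
#' @param detected Character vector of detected protein ids.
#' @param catalog Character vector of secreted protein ids (the secretome
#'   catalog).
#' @return A list with sorted character vectors `secreted` and `non_secreted`;
#'   an exact bipartition of `detected`.
#' @export
secreted_partition <- function(detected, catalog) {
  detected <- unique(as.character(detected))
  list(secreted = sort(intersect(detected, catalog)),
       non_secreted = sort(setdiff(detected, catalog)))
}
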