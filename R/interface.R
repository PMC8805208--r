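#' Drop candidates that are low-expressed in a tissue
#'
#' A protein is excluded from a tissue when its expression there is more than
#' `fold` times lower than in at least one other atlas tissue, i.e. when
#' `max(expr in other tissues) > fold * expr(tissue)`. This guards the
#' interface against attributing a secreted signal to a tissue that barely
#' expresses the protein. Proteins absent from the atlas (or with a missing
#' cell in `tissue`) are retained with a warning: unknown is not low.
#'
#' @param candidates Character vector of protein ids.
#' @param tissue Tissue id (must be an atlas column).
#' @param atlas An [expression_atlas()].
#' @param fold Exclusion fold (default 10, strict `>`).
#' @return The retained subset of `candidates` (original order).
#' @export
filter_low_expression <- function(candidates, tissue, atlas, fold = 10) {
  if (fold <= 0) abort("fold must be positive")
  stopifnot(inherits(atlas, "expression_atlas"))
  tissues <- attr(atlas, "tissues")
  if (!tissue %in% tissues) abort(sprintf("tissue '%s' not in atlas", tissue))
  others <- setdiff(tissues, tissue)
  keep <- vapply(candidates, function(p) {
    i <- match(p, atlas$protein)
    if (is.na(i)) return(NA)
    own <- as.numeric(atlas[[tissue]][i])
    if (is.na(own)) return(NA)
    other_vals <- as.numeric(unlist(atlas[i, others, drop = FALSE]))
    other_vals <- other_vals[!is.na(other_vals)]
    if (length(other_vals) == 0) return(TRUE)
    !(max(other_vals) > fold * own)
  }, TRUE)
  if (anyNA(keep)) {
    warn(sprintf(
      "%d candidate(s) missing from the atlas retained unfiltered",
      sum(is.na(keep))))
    keep[is.na(keep)] <- TRUE
  }
  candidates[keep]
}

#' Find directed cross-tissue ligand-receptor edges from one source tissue
#'
#' Ligands are the source tissue's secreted DEPs that survive the
#' low-expression filter. For each ligand, every directed background edge
#' `ligand -> r` with `r` non-secreted yields a cross-tissue edge to each
#' other tissue whose core network contains `r` (optionally restricted to
#' receptors that are themselves DEPs of the target tissue). Same-tissue
#' (autocrine) edges are never emitted.
#'
#' @param source_dep The source tissue's `dep_table`.
#' @param networks Named list (tissue -> `tissue_network`) of candidate
#'   target tissues; the source tissue is skipped if present.
#' @param background A [background_network()].
#' @param catalog Secreted-protein catalog (character vector).
#' @param atlas An [expression_atlas()]; `NULL` disables the filter.
#' @param fold Low-expression fold (default 10).
#' @param receptor_dep Require receptors to be DEPs of the target tissue
#'   (default `FALSE`; needs `dep_tables`).
#' @param dep_tables Named list of `dep_table`s, only consulted when
#'   `receptor_dep = TRUE`.
#' @return A tibble `source_tissue`, `ligand`, `target_tissue`, `receptor`.
#' @export
find_cross_edges <- function(source_dep, networks, background, catalog,
                             atlas = NULL, fold = 10, receptor_dep = FALSE,
                             dep_tables = NULL) {
  stopifnot(inherits(source_dep, "dep_table"),
            inherits(background, "background_network"))
  src <- source_dep$tissue
  targets <- networks[setdiff(names(networks), src)]
  ligands <- intersect(dep_proteins(source_dep), catalog)
  if (!is.null(atlas) && length(ligands) > 0 &&
      src %in% attr(atlas, "tissues")) {
    ligands <- filter_low_expression(ligands, src, atlas, fold)
  }
  empty <- tibble(source_tissue = character(), ligand = character(),
                  target_tissue = character(), receptor = character())
  if (length(ligands) == 0 || length(targets) == 0) return(empty)
  edges <- background$edges
  cand <- edges[edges$regulator %in% ligands &
                  !edges$target %in% catalog, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  out <- purrr::imap(targets, function(net, tis) {
    nodes <- igraph::V(net$graph)$name
    hit <- cand[cand$target %in% nodes, , drop = FALSE]
    if (receptor_dep) {
      if (is.null(dep_tables) || is.null(dep_tables[[tis]])) {
        abort("receptor_dep = TRUE requires `dep_tables` for target tissues")
      }
      hit <- hit[hit$target %in% dep_proteins(dep_tables[[tis]]), ,
                 drop = FALSE]
    }
    tibble(source_tissue = src, ligand = hit$regulator,
           target_tissue = tis, receptor = hit$target)
  })
  bind_rows(out) |>
    distinct() |>
    arrange(.data$source_tissue, .data$ligand, .data$target_tissue,
            .data$receptor)
}

#' Upstream regulator pairs of ligands within the source tissue
#'
#' All directed background edges `u -> s` where `s` is a ligand and `u` is a
#' DEP of the source tissue (and `u != s`).
#'
#' @param ligands Character vector of ligand ids.
#' @param source_dep The source tissue's `dep_table`.
#' @param background A [background_network()].
#' @return A tibble `tissue`, `regulator`, `ligand`.
#' @export
upstream_pairs <- function(ligands, source_dep, background) {
  deps <- dep_proteins(source_dep)
  edges <- background$edges
  hit <- edges[edges$target %in% ligands & edges$regulator %in% deps &
                 edges$regulator != edges$target, , drop = FALSE]
  tibble(tissue = source_dep$tissue, regulator = hit$regulator,
         ligand = hit$target) |>
    distinct() |>
    arrange(.data$regulator, .data$ligand)
}

#' Downstream effector pairs of receptors within their own tissue
#'
#' All directed background edges `r -> d` where `r` is a receptor of a given
#' tissue and `d` is a DEP of that same tissue (`d != r`).
#'
#' @param receptors Named list: tissue -> character vector of receptor ids.
#' @param dep_tables Named list of `dep_table`s covering those tissues.
#' @param background A [background_network()].
#' @return A tibble `tissue`, `receptor`, `effector`.
#' @export
downstream_pairs <- function(receptors, dep_tables, background) {
  edges <- background$edges
  out <- purrr::imap(receptors, function(recs, tis) {
    deps <- dep_proteins(dep_tables[[tis]])
    hit <- edges[edges$regulator %in% recs & edges$target %in% deps &
                   edges$regulator != edges$target, , drop = FALSE]
    tibble(tissue = tis, receptor = hit$regulator, effector = hit$target)
  })
  bind_rows(out) |>
    distinct() |>
    arrange(.data$tissue, .data$receptor, .data$effector)
}

#' Build the cross-tissue crosstalk interface
#'
#' Unions [find_cross_edges()] over every tissue as source, then attaches the
#' intra-tissue regulatory context: upstream (regulator DEP -> ligand) pairs
#' for ligands that actually emit at least one cross edge, and downstream
#' (receptor -> effector DEP) pairs for every receptor. Together these
#' inter- and intra-tissue connections constitute the crosstalk interface.
#'
#' @param dep_tables Named list (tissue -> `dep_table`), length >= 2.
#' @param networks Named list (tissue -> `tissue_network`) for the same
#'   tissues.
#' @param background A [background_network()].
#' @param catalog Secreted-protein catalog (character vector).
#' @param atlas An [expression_atlas()] or `NULL`.
#' @param fold Low-expression fold (default 10).
#' @param receptor_dep Require receptors to be DEPs of their tissue.
#' @return A `crosstalk_interface`: list of tibbles `cross_edges`
#'   (`source_tissue`, `ligand`, `target_tissue`, `receptor`),
#'   `upstream_pairs` (`tissue`, `regulator`, `ligand`), `downstream_pairs`
#'   (`tissue`, `receptor`, `effector`).
#' @export
build_interface <- function(dep_tables, networks, background, catalog,
                            atlas = NULL, fold = 10, receptor_dep = FALSE) {
  if (length(dep_tables) < 2) abort("need >= 2 tissues")
  tissues <- names(dep_tables)
  stopifnot(!is.null(tissues), all(tissues %in% names(networks)))
  cross <- bind_rows(lapply(tissues, function(src) {
    find_cross_edges(dep_tables[[src]], networks, background, catalog,
                     atlas = atlas, fold = fold,
                     receptor_dep = receptor_dep, dep_tables = dep_tables)
  })) |>
    arrange(.data$source_tissue, .data$ligand, .data$target_tissue,
            .data$receptor)
  up <- bind_rows(lapply(tissues, function(src) {
    lig <- unique(cross$ligand[cross$source_tissue == src])
    if (length(lig) == 0) {
      return(tibble(tissue = character(), regulator = character(),
                    ligand = character()))
    }
    upstream_pairs(lig, dep_tables[[src]], background)
  }))
  recs <- split(cross$receptor, cross$target_tissue)
  recs <- lapply(recs, unique)
  down <- if (length(recs) > 0) {
    downstream_pairs(recs, dep_tables, background)
  } else {
    tibble(tissue = character(), receptor = character(),
           effector = character())
  }
  structure(list(cross_edges = cross, upstream_pairs = up,
                 downstream_pairs = down, tissues = tissues,
                 receptor_dep = receptor_dep),
            class = "crosstalk_interface")
}

#' @export
print.crosstalk_interface <- function(x, ...) {
  cat(sprintf(
    "<crosstalk_interface> %d cross edge(s), %d upstream pair(s), %d downstream pair(s) across %d tissues\n",
    nrow(x$cross_edges), nrow(x$upstream_pairs), nrow(x$downstream_pairs),
    length(x$tissues)))
  invisible(x)
}

#' Tidy an interface into one long edge table
#'
#' @param x A `crosstalk_interface`.
#' @param ... Unused.
#' @return A tibble with columns `role` (`cross`/`upstream`/`downstream`),
#'   `source_tissue`, `source_protein`, `target_tissue`, `target_protein`.
#' @export
tidy.crosstalk_interface <- function(x, ...) {
  bind_rows(
    x$cross_edges |>
      mutate(role = "cross") |>
      select("role", "source_tissue", source_protein = "ligand",
             "target_tissue", target_protein = "receptor"),
    x$upstream_pairs |>
      mutate(role = "upstream", source_tissue = .data$tissue,
             target_tissue = .data$tissue) |>
      select("role", "source_tissue", source_protein = "regulator",
             "target_tissue", target_protein = "ligand"),
    x$downstream_pairs |>
      mutate(role = "downstream", source_tissue = .data$tissue,
             target_tissue = .data$tissue) |>
      select("role", "source_tissue", source_protein = "receptor",
             "target_tissue", target_protein = "effector"))
}

#' One-row interface summary
#'
#' @param x A `crosstalk_interface`.
#' @param ... Unused.
#' @return Counts of edges, ligands and receptors.
#' @export
glance.crosstalk_interface <- function(x, ...) {
  tibble(n_cross = nrow(x$cross_edges),
         n_upstream = nrow(x$upstream_pairs),
         n_downstream = nrow(x$downstream_pairs),
         n_ligands = dplyr::n_distinct(x$cross_edges$ligand),
         n_receptors = dplyr::n_distinct(
           paste(x$cross_edges$target_tissue, x$cross_edges$receptor)))
}

#' Export an interface
#'
#' @param x A `crosstalk_interface`.
#' @param path Output path.
#' @param format `"tsv"` long table or `"graphml"` of the full interface
#'   graph (vertices named `tissue:protein`).
#' @return `path`, invisibly.
#' @export
write_interface <- function(x, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  long <- tidy(x)
  if (format == "tsv") {
    readr::write_tsv(long, path)
  } else {
    edges <- tibble(
      from = paste(long$source_tissue, long$source_protein, sep = ":"),
      to = paste(long$target_tissue, long$target_protein, sep = ":"),
      role = long$role)
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Diagram of the crosstalk interface
#'
#' @param object A `crosstalk_interface`.
#' @param ... Unused.
#' @return A ggplot laying proteins out in per-tissue columns with directed
#'   segments for cross, upstream and downstream connections.
#' @export
autoplot.crosstalk_interface <- function(object, ...) {
  long <- tidy(object)
  if (nrow(long) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "Empty interface"))
  }
  nodes <- dplyr::bind_rows(
    long |> select(tissue = "source_tissue", protein = "source_protein"),
    long |> select(tissue = "target_tissue", protein = "target_protein")) |>
    distinct() |>
    arrange(.data$tissue, .data$protein) |>
    group_by(.data$tissue) |>
    mutate(y = row_number()) |>
    ungroup() |>
    mutate(x = match(.data$tissue, sort(unique(.data$tissue))))
  seg <- long |>
    left_join(nodes, by = c(source_tissue = "tissue",
                            source_protein = "protein")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes, by = c(target_tissue = "tissue",
                            target_protein = "protein")) |>
    rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$role),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), alpha = 0.7) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$protein),
                       hjust = -0.2, size = 3) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(sort(unique(nodes$tissue))),
      labels = sort(unique(nodes$tissue)),
      limits = c(0.5, length(unique(nodes$tissue)) + 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "connection") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
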