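#' Build the seed net of a tissue
#'
#' Seeds (a tissue's DEPs) are looked up in the background regulatory graph;
#' the seed net is the undirected subgraph induced by the seeds present in
#' the background plus all their direct neighbors (edge direction is ignored
#' from here on — core networks are undirected). Seeds absent from the
#' background are counted and dropped with a warning.
#'
#' @param seeds Character vector of seed protein ids.
#' @param background A [background_network()] (or an undirected igraph, used
#'   internally).
#' @return An undirected simple igraph whose vertices carry a `name`
#'   attribute.
#' @export
build_seed_net <- function(seeds, background) {
  und <- as_undirected_background(background)
  if (igraph::vcount(und) == 0) abort("background network is empty")
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, igraph::V(und)$name)
  n_missing <- length(seeds) - length(present)
  if (n_missing > 0) {
    warn(sprintf("%d seed(s) absent from the background network were dropped",
                 n_missing))
  }
  if (length(present) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  nb <- igraph::adjacent_vertices(und, present, mode = "all")
  nodes <- sort(unique(c(present, unlist(lapply(nb, names)))))
  igraph::induced_subgraph(und, nodes)
}

as_undirected_background <- function(background) {
  if (inherits(background, "background_network")) {
    g <- igraph::as_undirected(background$graph, mode = "collapse")
    # vertices sorted at construction; keep that order for determinism
    g
  } else if (igraph::is_igraph(background)) {
    if (igraph::is_directed(background)) {
      igraph::as_undirected(background, mode = "collapse")
    } else background
  } else {
    abort("`background` must be a background_network or an igraph")
  }
}

#' Simplify a seed net into a union of Steiner trees
#'
#' Each connected component holding at least one terminal (DEP) is reduced to
#' an approximate minimum Steiner tree over that component's terminals with
#' unit edge weights, pruning branches made of non-terminal connectors while
#' keeping the nodes that bridge terminals. Components without terminals are
#' dropped; all per-component trees are retained and unioned. The
#' approximation is the classical metric-closure construction (terminal
#' distance graph -> minimum spanning tree -> shortest-path expansion ->
#' re-MST -> prune non-terminal leaves), which is within 2x of the optimum;
#' components with at most `exact_max` nodes are solved exactly by exhaustive
#' search over connector subsets.
#'
#' @param seed_net Undirected igraph (typically from [build_seed_net()]).
#' @param terminals Character vector of terminal node names; must all exist
#'   in `seed_net`.
#' @param exact_max Solve components with at most this many nodes exactly
#'   (default 0 = always use the approximation).
#' @return An undirected igraph: a forest, one tree per kept component
#'   (single-terminal components contribute an isolated terminal vertex).
#' @export
steiner_simplify <- function(seed_net, terminals, exact_max = 0) {
  terminals <- unique(as.character(terminals))
  vnames <- igraph::V(seed_net)$name
  if (length(setdiff(terminals, vnames)) > 0) {
    abort("terminals must be a subset of seed-net nodes")
  }
  if (length(terminals) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  comp <- igraph::components(seed_net)
  membership <- comp$membership
  keep_comps <- unique(membership[terminals])
  edge_frames <- list()
  iso_nodes <- character()
  for (ci in sort(keep_comps)) {
    cnodes <- sort(names(membership)[membership == ci])
    term_c <- intersect(cnodes, terminals)
    if (length(term_c) == 1) {
      iso_nodes <- c(iso_nodes, term_c)
      next
    }
    sub <- igraph::induced_subgraph(seed_net, cnodes)
    tree <- if (exact_max > 0 && length(cnodes) <= exact_max) {
      steiner_exact(sub, term_c)
    } else {
      steiner_kmb(sub, term_c)
    }
    edge_frames[[length(edge_frames) + 1]] <- tree
  }
  edges <- bind_rows(edge_frames)
  all_nodes <- sort(unique(c(iso_nodes, edges$from, edges$to)))
  if (length(all_nodes) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE))
}

# metric-closure 2-approximation on one connected component; returns an edge
# tibble (from, to) of a tree spanning all terminals
steiner_kmb <- function(sub, terms) {
  terms <- sort(terms)
  d <- igraph::distances(sub, v = terms, to = terms)
  # complete terminal graph; Kruskal with (weight, endpoint) lexicographic order
  pairs <- utils::combn(terms, 2)
  w <- d[cbind(pairs[1, ], pairs[2, ])]
  ord <- order(w, pairs[1, ], pairs[2, ])
  parent <- seq_along(terms)
  names(parent) <- terms
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  mst_pairs <- list()
  for (j in ord) {
    a <- match(pairs[1, j], terms); b <- match(pairs[2, j], terms)
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      mst_pairs[[length(mst_pairs) + 1]] <- c(pairs[1, j], pairs[2, j])
      if (length(mst_pairs) == length(terms) - 1) break
    }
  }
  # expand each metric edge into one shortest path in the component
  eids <- integer()
  for (pr in mst_pairs) {
    sp <- igraph::shortest_paths(sub, from = pr[1], to = pr[2],
                                 output = "epath")$epath[[1]]
    eids <- union(eids, as.integer(sp))
  }
  H <- igraph::subgraph_from_edges(sub, eids, delete.vertices = TRUE)
  # spanning tree of the expansion, then prune non-terminal leaves
  Tg <- igraph::mst(H)
  repeat {
    deg <- igraph::degree(Tg)
    leaves <- names(deg)[deg <= 1 & !names(deg) %in% terms]
    if (length(leaves) == 0) break
    Tg <- igraph::delete_vertices(Tg, leaves)
  }
  el <- igraph::as_edgelist(Tg)
  tibble(from = el[, 1], to = el[, 2])
}

# exact minimum Steiner tree by exhaustive search over connector subsets;
# feasible for small components only
steiner_exact <- function(sub, terms) {
  terms <- sort(terms)
  others <- sort(setdiff(igraph::V(sub)$name, terms))
  for (k in 0:length(others)) {
    combos <- if (k == 0) list(character()) else
      utils::combn(others, k, simplify = FALSE)
    for (extra in combos) {
      nodes <- c(terms, extra)
      g2 <- igraph::induced_subgraph(sub, nodes)
      if (igraph::vcount(g2) > 0 && igraph::is_connected(g2)) {
        el <- igraph::as_edgelist(igraph::mst(g2))
        return(tibble(from = el[, 1], to = el[, 2]))
      }
    }
  }
  abort("component not connected over terminals")  # unreachable on components
}

#' Topology statistics of an undirected graph
#'
#' `connected_nodes` counts vertices of degree >= 1; `density` is
#' `2E / (N (N - 1))` over those connected nodes (0 when fewer than two), or
#' the literal edge-based variant `E / (E (E - 1) / 2)` when
#' `density = "literal"`.
#'
#' @param graph Undirected igraph.
#' @param density Density convention: `"nodes"` (default) or `"literal"`.
#' @return A tibble with columns `connected_nodes`, `edges`, `density`.
#' @export
network_stats <- function(graph, density = c("nodes", "literal")) {
  density <- match.arg(density)
  deg <- igraph::degree(graph)
  n <- sum(deg >= 1)
  e <- igraph::ecount(graph)
  dens <- if (density == "nodes") {
    if (n >= 2) 2 * e / (n * (n - 1)) else 0
  } else {
    if (e >= 2) e / (e * (e - 1) / 2) else 0
  }
  tibble(connected_nodes = as.integer(n), edges = as.integer(e),
         density = dens)
}

#' Build a tissue-specific core network
#'
#' Runs the full construction for one tissue: DEPs become seed nodes, the
#' seed net is their background neighborhood, and the per-component Steiner
#' simplification cuts non-DEP branches while keeping bridging connectors.
#'
#' @param deps A `dep_table` (its DEPs are the seeds) or a character vector
#'   of seed protein ids.
#' @param background A [background_network()].
#' @param tissue Tissue id; defaults to the dep_table's tissue.
#' @param exact_max Passed to [steiner_simplify()].
#' @return A `tissue_network`: list with fields `tissue`, `graph` (the union
#'   of Steiner trees), `seeds` (terminals retained in the graph),
#'   `steiner_nodes` (non-seed connectors), `stats` (from
#'   [network_stats()]), and `n_seeds_requested`.
#' @export
build_tissue_network <- function(deps, background, tissue = NULL,
                                 exact_max = 0) {
  seeds <- if (inherits(deps, "dep_table")) dep_proteins(deps) else
    unique(as.character(deps))
  if (is.null(tissue)) {
    tissue <- if (inherits(deps, "dep_table")) deps$tissue else "tissue"
  }
  und <- as_undirected_background(background)
  seed_net <- build_seed_net(seeds, und)
  terminals <- intersect(seeds, igraph::V(seed_net)$name)
  graph <- steiner_simplify(seed_net, terminals, exact_max = exact_max)
  nodes <- igraph::V(graph)$name
  structure(
    list(tissue = tissue, graph = graph,
         seeds = sort(intersect(terminals, nodes)),
         steiner_nodes = sort(setdiff(nodes, terminals)),
         stats = network_stats(graph),
         n_seeds_requested = length(seeds)),
    class = "tissue_network")
}

#' @export
print.tissue_network <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<tissue_network> '%s': %d nodes (%d seeds, %d connectors), %d edges, density %.4f\n",
    x$tissue, length(igraph::V(x$graph)), length(x$seeds),
    length(x$steiner_nodes), s$edges, s$density))
  invisible(x)
}

#' Tidy a tissue network into its edge list
#'
#' @param x A `tissue_network`.
#' @param ... Unused.
#' @return A tibble `tissue`, `from`, `to`.
#' @export
tidy.tissue_network <- function(x, ...) {
  el <- igraph::as_edgelist(x$graph)
  tibble(tissue = x$tissue,
         from = if (nrow(el)) el[, 1] else character(),
         to = if (nrow(el)) el[, 2] else character())
}

#' One-row topology summary of a tissue network
#'
#' @param x A `tissue_network`.
#' @param ... Unused.
#' @return A tibble with tissue id, node/seed counts and topology statistics.
#' @export
glance.tissue_network <- function(x, ...) {
  dplyr::bind_cols(
    tibble(tissue = x$tissue, n_nodes = length(igraph::V(x$graph)),
           n_seeds = length(x$seeds), n_steiner = length(x$steiner_nodes)),
    x$stats)
}

#' Export a tissue network
#'
#' @param x A `tissue_network`.
#' @param path Output path.
#' @param format `"graphml"` (nodes carry `is_seed`) or `"tsv"` edge list.
#' @return `path`, invisibly.
#' @export
write_tissue_network <- function(x, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tidy(x), path)
  } else {
    g <- x$graph
    igraph::V(g)$is_seed <- igraph::V(g)$name %in% x$seeds
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Validate a tissue network against random seed resamplings
#'
#' Draws `n_null` protein sets of size `n_seeds` uniformly without
#' replacement from the background nodes, runs the identical seed-net +
#' Steiner construction on each, and compares the observed connected-node
#' count, edge count and density to the null mean and sd via Z scores. The
#' network is considered validated when all three |Z| exceed `z_threshold`
#' (2.33, i.e. one-sided p < 0.01). Fully reproducible from `rng_seed`.
#'
#' @param observed A `tissue_network`.
#' @param background A [background_network()].
#' @param n_seeds Null seed-set size; defaults to the number of seeds
#'   requested for the observed network (the tissue's DEP count).
#' @param n_null Number of random networks (default 100).
#' @param z_threshold |Z| threshold (default 2.33).
#' @param rng_seed Integer seed for the null draws.
#' @param exact_max Passed through to [steiner_simplify()].
#' @return A `randomization_report`: list with `metrics` (tibble `metric`,
#'   `observed`, `null_mean`, `null_sd`, `z`), `passed`, `n_null`,
#'   `z_threshold`, `reason` (when not passed).
#' @export
randomize_validate <- function(observed, background,
                               n_seeds = observed$n_seeds_requested,
                               n_null = 100, z_threshold = 2.33,
                               rng_seed = 1, exact_max = 0) {
  stopifnot(inherits(observed, "tissue_network"))
  und <- as_undirected_background(background)
  nodes <- igraph::V(und)$name
  if (n_seeds > length(nodes)) {
    abort("n_seeds exceeds background node count")
  }
  null_stats <- withr::with_seed(rng_seed, {
    purrr::map(seq_len(n_null), function(i) {
      rs <- sample(nodes, n_seeds)
      sn <- suppressWarnings(build_seed_net(rs, und))
      term <- intersect(rs, igraph::V(sn)$name)
      g <- steiner_simplify(sn, term, exact_max = exact_max)
      network_stats(g)
    })
  })
  null_df <- bind_rows(null_stats)
  obs <- observed$stats
  metrics <- tibble(
    metric = c("connected_nodes", "edges", "density"),
    observed = as.numeric(c(obs$connected_nodes, obs$edges, obs$density)),
    null_mean = vapply(null_df, mean, 1)[c("connected_nodes", "edges", "density")],
    null_sd = vapply(null_df, sd, 1)[c("connected_nodes", "edges", "density")])
  metrics$z <- ifelse(metrics$null_sd > 0,
                      (metrics$observed - metrics$null_mean) / metrics$null_sd,
                      NA_real_)
  degenerate <- any(is.na(metrics$z))
  passed <- !degenerate && all(abs(metrics$z) > z_threshold)
  reason <- if (degenerate) {
    sprintf("null sd is zero for metric(s): %s",
            paste(metrics$metric[is.na(metrics$z)], collapse = ", "))
  } else if (!passed) {
    sprintf("|Z| <= %.2f for metric(s): %s", z_threshold,
            paste(metrics$metric[abs(metrics$z) <= z_threshold], collapse = ", "))
  } else NA_character_
  structure(list(metrics = metrics, passed = passed, n_null = n_null,
                 z_threshold = z_threshold, rng_seed = rng_seed,
                 reason = reason, null_draws = null_df),
            class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf("<randomization_report> n_null = %d, |Z| threshold = %.2f, %s\n",
              x$n_null, x$z_threshold,
              if (x$passed) "PASSED" else sprintf("NOT passed (%s)", x$reason)))
  print(x$metrics)
  invisible(x)
}

#' Tidy the per-metric randomization comparison
#'
#' @param x A `randomization_report`.
#' @param ... Unused.
#' @return The metric tibble (`metric`, `observed`, `null_mean`, `null_sd`,
#'   `z`).
#' @export
tidy.randomization_report <- function(x, ...) x$metrics

#' One-row summary of a randomization validation
#'
#' @param x A `randomization_report`.
#' @param ... Unused.
#' @return A tibble with `passed`, `n_null`, `z_threshold`, `min_abs_z`.
#' @export
glance.randomization_report <- function(x, ...) {
  tibble(passed = x$passed, n_null = x$n_null, z_threshold = x$z_threshold,
         min_abs_z = suppressWarnings(min(abs(x$metrics$z))))
}

#' Observed-vs-null plot of a randomization validation
#'
#' @param object A `randomization_report`.
#' @param ... Unused.
#' @return A ggplot: null distributions per metric with the observed value
#'   marked.
#' @export
autoplot.randomization_report <- function(object, ...) {
  nulls <- object$null_draws |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value")
  obs <- object$metrics |> select("metric", "observed")
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "#c0392b") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "null draws",
                  title = sprintf("Observed vs %d random networks",
                                  object$n_null)) +
    ggplot2::theme_minimal()
}
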