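# Shared fixture builders and independent oracles.

# pathway collection from a compact description:
# specs = list(list(id, class, members, subcategory?, excluded?))
make_pathways <- function(specs) {
  sets <- tibble::tibble(
    pathway_id = vapply(specs, `[[`, "", "id"),
    name = vapply(specs, function(s) s$name %||% s$id, ""),
    members = lapply(specs, `[[`, "members"))
  categories <- tibble::tibble(
    pathway_id = sets$pathway_id,
    class = vapply(specs, function(s) s$class %||% "other", ""),
    subcategory = vapply(specs, function(s) s$subcategory %||% "misc", ""),
    excluded = vapply(specs, function(s) isTRUE(s$excluded), TRUE))
  pathway_collection(sets, categories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic abundance table with a known DEP set: DEPs get a clean
# 4-fold shift on fixed jittered replicates, everything else is identical
# between groups (p = 1, fold change 1)
make_abundance <- function(tissue, detected, deps = character(),
                           l2fc = 2) {
  base <- c(5, 5.1, 4.9)
  rows <- lapply(detected, function(p) {
    shift <- if (p %in% deps) l2fc else 0
    c(2^base, 2^(base + shift))
  })
  m <- do.call(rbind, rows)
  df <- data.frame(protein = detected, m)
  names(df) <- c("protein", "c1", "c2", "c3", "t1", "t2", "t3")
  abundance_table(df, groups = c(c1 = "control", c2 = "control",
                                 c3 = "control", t1 = "case", t2 = "case",
                                 t3 = "case"), tissue = tissue)
}

make_dep_table <- function(tissue, detected, deps = character()) {
  call_deps(make_abundance(tissue, detected, deps))
}

# exhaustive enumeration oracle for the hypergeometric upper tail:
# count draws of size n from 1:N with >= k members of 1:K
hyper_oracle <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(if (k > 0) 0 else 1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# independent brute-force minimum Steiner tree size (edge count) on a
# connected graph given as a 2-column edge matrix of integer vertex ids;
# elementary reachability, no package code
steiner_optimum_edges <- function(edges, n_nodes, terminals) {
  adj <- lapply(seq_len(n_nodes), function(i) integer())
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  connected_over <- function(nodes) {
    keep <- logical(n_nodes); keep[nodes] <- TRUE
    seen <- logical(n_nodes)
    queue <- nodes[1]; seen[queue] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (keep[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    all(seen[nodes])
  }
  others <- setdiff(seq_len(n_nodes), terminals)
  for (extra in 0:length(others)) {
    combos <- if (extra == 0) list(integer()) else
      utils::combn(others, extra, simplify = FALSE)
    for (cs in combos) {
      nodes <- c(terminals, cs)
      if (connected_over(nodes)) return(length(nodes) - 1L)
    }
  }
  stop("terminals not connected")
}

# random connected undirected graph as an igraph with vertex names v1..vn
random_connected_graph <- function(n, p) {
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    edges <- which(m, arr.ind = TRUE)
    # ensure a random spanning path so the graph is connected
    perm <- sample(n)
    path <- cbind(perm[-n], perm[-1])
    all_edges <- rbind(edges, path)
    g <- igraph::graph_from_edgelist(
      matrix(paste0("v", all_edges), ncol = 2), directed = FALSE)
    g <- igraph::simplify(g)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) return(g)
  }
}

# tiny two/three-tissue knowledge bundle with one hand-planted crosstalk
# axis: u -> s (source), s -> r (cross), r -> d (target)
toy_interface_bundle <- function(three_tissues = FALSE) {
  edges <- tibble::tibble(
    regulator = c("u", "s", "r", "x1", "x2"),
    target    = c("s", "r", "d", "x2", "x3"))
  background <- background_network(edges)
  dep_A <- make_dep_table("A", c("u", "s", "n1", "n2"), deps = c("u", "s"))
  dep_B <- make_dep_table("B", c("r", "d", "n3"), deps = c("r", "d"))
  deps <- list(A = dep_A, B = dep_B)
  networks <- list(
    A = suppressWarnings(build_tissue_network(dep_A, background)),
    B = suppressWarnings(build_tissue_network(dep_B, background)))
  if (three_tissues) {
    dep_C <- make_dep_table("C", c("r", "d", "n4"), deps = c("r", "d"))
    deps$C <- dep_C
    networks$C <- suppressWarnings(build_tissue_network(dep_C, background))
  }
  atlas_df <- tibble::tibble(protein = c("u", "s", "r", "d"),
                             A = c(5, 20, 5, 5), B = c(5, 0.5, 5, 5))
  if (three_tissues) atlas_df$C <- c(5, 0.5, 5, 5)
  atlas <- expression_atlas(atlas_df)
  list(background = background, deps = deps, networks = networks,
       atlas = atlas, catalog = "s")
}
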