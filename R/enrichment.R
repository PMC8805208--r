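#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing `k` or more members of a category of size
#' `K` in a draw of size `n` from a universe of size `N`:
#' `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`.
#'
#' @param N Universe (background) size.
#' @param K Category size in the universe.
#' @param n Draw (query) size.
#' @param k Observed hits; may be a vector.
#' @return Probability in (0, 1]; `k = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 4)  # 5/210
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || any(k > pmin(K, n))) {
    abort("hypergeometric bounds violated: need K <= N, n <= N, k <= min(K, n)")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: each p is scaled by m/rank and the right-to-left
#' running minimum is taken, capped at 1; input order is preserved.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) abort("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation of a query set in pathways
#'
#' Tests every non-excluded pathway with at least one member in the
#' background. Pathway memberships are intersected with the background before
#' counting, so the background acts as the sampling frame (typically the
#' tissue's detected proteins intersected with the annotation universe).
#' Results are sorted ascending by FDR, then p, with ties broken by pathway
#' id for reproducibility.
#'
#' @param query Character vector of protein ids; must be a subset of
#'   `background`.
#' @param pathways A [pathway_collection()].
#' @param background Character vector: the sampling frame.
#' @param fdr_cut Significance cutoff on BH-adjusted p (default 0.05).
#' @return An `enrichment_result`: tibble with columns `pathway_id`, `name`,
#'   `class`, `subcategory`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `significant`.
#' @export
enrich <- function(query, pathways, background, fdr_cut = 0.05) {
  stopifnot(inherits(pathways, "pathway_collection"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    abort(sprintf("query protein(s) not in background: %s",
                  paste(head(stray, 10), collapse = ", ")))
  }
  active <- pathways[!pathways$excluded, , drop = FALSE]
  members_bg <- lapply(active$members, intersect, background)
  keep <- lengths(members_bg) > 0
  active <- active[keep, , drop = FALSE]
  members_bg <- members_bg[keep]
  N <- length(background)
  n <- length(query)
  K <- lengths(members_bg)
  k <- vapply(members_bg, function(m) length(intersect(m, query)), 1L)
  p <- if (nrow(active) > 0) {
    mapply(function(K_i, k_i) hypergeom_upper_tail(N, K_i, n, k_i), K, k)
  } else numeric()
  fdr <- if (length(p) > 0) bh_fdr(p) else numeric()
  out <- tibble(pathway_id = active$pathway_id, name = active$name,
                class = active$class, subcategory = active$subcategory,
                k = as.integer(k), K = as.integer(K), n = n, N = N,
                p_value = as.numeric(p), fdr = as.numeric(fdr),
                significant = fdr < fdr_cut) |>
    arrange(.data$fdr, .data$p_value, .data$pathway_id)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Overlap of top-k enriched terms across tissues
#'
#' Takes the first `k` terms of each tissue's enrichment (assumed sorted by
#' fdr then p; ties at the rank-k boundary are broken lexicographically by
#' pathway id) and returns the term-by-tissue incidence.
#'
#' @param results_by_tissue Named list of `enrichment_result` tibbles.
#' @param k Number of top terms per tissue (default 20).
#' @return A tibble with columns `pathway_id`, `tissues` (list of tissue
#'   ids), `n_tissues`.
#' @export
top_terms_overlap <- function(results_by_tissue, k = 20) {
  if (k <= 0) abort("k must be positive")
  tops <- purrr::imap(results_by_tissue, function(res, tis) {
    res |>
      arrange(.data$fdr, .data$p_value, .data$pathway_id) |>
      slice_head(n = k) |>
      mutate(tissue = tis) |>
      select("pathway_id", "tissue")
  })
  bind_rows(tops) |>
    group_by(.data$pathway_id) |>
    summarise(tissues = list(sort(unique(.data$tissue))), .groups = "drop") |>
    mutate(n_tissues = lengths(.data$tissues)) |>
    arrange(dplyr::desc(.data$n_tissues), .data$pathway_id)
}

#' Dot plot of enrichment results
#'
#' @param object An `enrichment_result`.
#' @param top Number of terms to display (default 20).
#' @param ... Unused.
#' @return A ggplot object: terms vs -log10 FDR, sized by hit count and
#'   coloured by pathway class.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  d <- object |>
    arrange(.data$fdr, .data$p_value, .data$pathway_id) |>
    slice_head(n = top) |>
    mutate(name = factor(.data$name, levels = rev(unique(.data$name))))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$fdr), y = .data$name,
                                  size = .data$k, colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10] ~ FDR), y = NULL,
                  size = "hits", colour = "class") +
    ggplot2::theme_minimal()
}
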