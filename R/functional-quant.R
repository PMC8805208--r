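#' Assemble upstream/downstream process sets from an interface
#'
#' Per tissue, the *upstream* process set is the union of that tissue's
#' ligands (secreted DEPs emitting cross edges) and their upstream regulator
#' DEPs; the *downstream* set is the union of the receptors located in that
#' tissue and their downstream effector DEPs. Each set is tested for pathway
#' over-representation with [enrich()]; the significant terms (FDR < cut)
#' are kept as the set's enriched processes. The enrichment background is
#' the tissue's detected pool extended by the set's own proteins (receptors
#' and connectors need not have been quantified).
#'
#' @param interface A `crosstalk_interface`.
#' @param dep_tables Named list of `dep_table`s.
#' @param pathways A [pathway_collection()].
#' @param backgrounds Optional named list (tissue -> character vector)
#'   overriding the per-tissue enrichment background; defaults to each
#'   tissue's detected pool.
#' @param fdr_cut Enrichment significance cutoff (default 0.05).
#' @return A `process_set_list`: tibble with columns `tissue`, `side`
#'   (`upstream`/`downstream`), `proteins` (list), `n_proteins`, `enriched`
#'   (list of significant `enrichment_result` rows), `n_enriched`.
#' @export
assemble_process_sets <- function(interface, dep_tables, pathways,
                                  backgrounds = NULL, fdr_cut = 0.05) {
  stopifnot(inherits(interface, "crosstalk_interface"))
  tissues <- interface$tissues
  if (is.null(backgrounds)) {
    backgrounds <- lapply(dep_tables, function(d) d$detected)
  }
  rows <- purrr::map(tissues, function(tis) {
    upstream <- sort(unique(c(
      interface$cross_edges$ligand[interface$cross_edges$source_tissue == tis],
      interface$upstream_pairs$regulator[interface$upstream_pairs$tissue == tis])))
    downstream <- sort(unique(c(
      interface$cross_edges$receptor[interface$cross_edges$target_tissue == tis],
      interface$downstream_pairs$effector[interface$downstream_pairs$tissue == tis])))
    purrr::map2(list(upstream, downstream), c("upstream", "downstream"),
                function(prot, side) {
      enriched <- if (length(prot) == 0) {
        NULL
      } else {
        bg <- sort(unique(c(backgrounds[[tis]], prot)))
        res <- enrich(prot, pathways, bg, fdr_cut = fdr_cut)
        res[res$significant, , drop = FALSE]
      }
      n_enr <- if (is.null(enriched)) 0L else nrow(enriched)
      tibble(tissue = tis, side = side, proteins = list(prot),
             n_proteins = length(prot), enriched = list(enriched),
             n_enriched = n_enr)
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  class(out) <- c("process_set_list", class(out))
  out
}

#' Fraction of enriched pathways that are metabolic
#'
#' @param enriched An `enrichment_result` tibble (typically the significant
#'   set of one process set), or `NULL`.
#' @param pathways A [pathway_collection()] used to resolve classes when the
#'   `class` column is absent.
#' @return A number in \[0, 1\], or `NA` when there are no enriched pathways
#'   (empty sets are excluded from downstream averaging).
#' @export
metabolic_proportion <- function(enriched, pathways = NULL) {
  if (is.null(enriched) || nrow(enriched) == 0) return(NA_real_)
  cls <- if ("class" %in% names(enriched)) {
    enriched$class
  } else {
    stopifnot(!is.null(pathways))
    pathways$class[match(enriched$pathway_id, pathways$pathway_id)]
  }
  mean(cls == "metabolic")
}

#' Metabolic share of the background pathway universe
#'
#' Counts over non-excluded ("basic") pathways only.
#'
#' @param pathways A [pathway_collection()].
#' @return A list with `metabolic`, `total`, `proportion`.
#' @export
background_metabolic_proportion <- function(pathways) {
  stopifnot(inherits(pathways, "pathway_collection"))
  basic <- pathways[!pathways$excluded, , drop = FALSE]
  total <- nrow(basic)
  if (total == 0) abort("no non-excluded pathways in collection")
  metabolic <- sum(basic$class == "metabolic")
  list(metabolic = metabolic, total = total,
       proportion = metabolic / total)
}

#' One-sample z-test on a set of proportions
#'
#' Tests whether the mean of per-set proportions differs from a reference
#' proportion `p0`, using the sample standard deviation:
#' `z = (mean - p0) / (sd / sqrt(n))`, two-sided normal p-value, and a 95%
#' confidence interval `mean +/- 1.96 sd / sqrt(n)`.
#'
#' @param proportions Numeric vector (length >= 2, non-zero spread).
#' @param p0 Reference proportion.
#' @return A `one_sample_z`: list with `mean_prop`, `ci_low`, `ci_high`,
#'   `p0`, `z`, `p_value`, `n`, `sd`.
#' @export
#' @examples
#' one_sample_z(c(0.5, 0.7, 0.9), 0.37)  # z ~ 2.858
one_sample_z <- function(proportions, p0) {
  proportions <- proportions[!is.na(proportions)]
  n <- length(proportions)
  if (n < 2) abort("insufficient spread: need >= 2 non-missing proportions")
  s <- sd(proportions)
  if (s == 0) abort("insufficient spread: zero standard deviation")
  m <- mean(proportions)
  se <- s / sqrt(n)
  z <- (m - p0) / se
  structure(list(mean_prop = m, ci_low = m - 1.96 * se,
                 ci_high = m + 1.96 * se, p0 = p0, z = z,
                 p_value = 2 * pnorm(-abs(z)), n = n, sd = s),
            class = "one_sample_z")
}

#' @export
print.one_sample_z <- function(x, ...) {
  cat(sprintf(
    "One-sample z-test: mean %.4f (95%% CI %.4f-%.4f) vs p0 = %.4f; z = %.3f, p = %.3g, n = %d\n",
    x$mean_prop, x$ci_low, x$ci_high, x$p0, x$z, x$p_value, x$n))
  invisible(x)
}

#' Tidy a one-sample z-test
#'
#' @param x A `one_sample_z`.
#' @param ... Unused.
#' @return A one-row tibble of the estimate, CI, z, p and n.
#' @export
tidy.one_sample_z <- function(x, ...) {
  tibble(mean_prop = x$mean_prop, ci_low = x$ci_low, ci_high = x$ci_high,
         p0 = x$p0, z = x$z, p_value = x$p_value, n = x$n)
}

#' Dominant subcategory of a process set's enriched pathways
#'
#' The subcategory (e.g. "carbohydrate metabolism") holding the plurality of
#' the set's enriched pathways; ties return all tied names. Optionally
#' weights each pathway by `-log10(p)` instead of counting.
#'
#' @param enriched An `enrichment_result` tibble (significant rows), or one
#'   row of a `process_set_list` via its `enriched` element; `NULL`/empty
#'   yields `character(0)`.
#' @param weighted Weight pathways by `-log10(p_value)` (default `FALSE`).
#' @return Character vector of dominant subcategory name(s); empty when
#'   there is no enrichment.
#' @export
dominant_category <- function(enriched, weighted = FALSE) {
  if (is.null(enriched) || nrow(enriched) == 0) return(character())
  w <- if (weighted) -log10(enriched$p_value) else rep(1, nrow(enriched))
  tot <- tapply(w, enriched$subcategory, sum)
  sort(names(tot)[tot == max(tot)])
}

#' Functionally quantify a crosstalk interface
#'
#' Runs the full functional summary: assembles upstream/downstream process
#' sets, computes each non-empty set's metabolic proportion, compares their
#' mean against the background metabolic proportion with a one-sample
#' z-test (skipped with a reason when fewer than two non-empty sets exist or
#' the proportions have no spread), and names the dominant upstream
#' subcategory for every directed tissue pair that carries cross edges.
#'
#' @param interface A `crosstalk_interface`.
#' @param dep_tables Named list of `dep_table`s.
#' @param pathways A [pathway_collection()].
#' @param backgrounds,fdr_cut Passed to [assemble_process_sets()].
#' @return A `functional_summary`: list with `process_sets`, `proportions`
#'   (tibble `tissue`, `side`, `n_enriched`, `metabolic_proportion`),
#'   `background` (from [background_metabolic_proportion()]), `z_test`
#'   (`one_sample_z` or `NULL`), `z_note`, `dominant_upstream` (tibble
#'   `source_tissue`, `target_tissue`, `dominant` list column).
#' @export
quantify_interface <- function(interface, dep_tables, pathways,
                               backgrounds = NULL, fdr_cut = 0.05) {
  sets <- assemble_process_sets(interface, dep_tables, pathways,
                                backgrounds = backgrounds, fdr_cut = fdr_cut)
  props <- sets |>
    mutate(metabolic_proportion =
             vapply(.data$enriched, metabolic_proportion, 1)) |>
    select("tissue", "side", "n_enriched", "metabolic_proportion")
  bg <- background_metabolic_proportion(pathways)
  obs <- props$metabolic_proportion[!is.na(props$metabolic_proportion)]
  z_test <- NULL
  z_note <- NA_character_
  if (length(obs) < 2) {
    z_note <- "fewer than 2 process sets with enriched pathways"
  } else if (sd(obs) == 0) {
    z_note <- "no spread among process-set proportions"
  } else {
    z_test <- one_sample_z(obs, bg$proportion)
  }
  pairs <- distinct(interface$cross_edges,
                    .data$source_tissue, .data$target_tissue)
  dominant <- pairs |>
    mutate(dominant = purrr::map(.data$source_tissue, function(src) {
      enr <- sets$enriched[sets$tissue == src & sets$side == "upstream"][[1]]
      dominant_category(enr)
    }))
  structure(list(process_sets = sets, proportions = props, background = bg,
                 z_test = z_test, z_note = z_note,
                 dominant_upstream = dominant),
            class = "functional_summary")
}

#' @export
print.functional_summary <- function(x, ...) {
  cat("<functional_summary>\n")
  print(x$proportions)
  cat(sprintf("background: %d/%d metabolic (%.2f%%)\n", x$background$metabolic,
              x$background$total, 100 * x$background$proportion))
  if (!is.null(x$z_test)) print(x$z_test) else
    cat(sprintf("z-test skipped: %s\n", x$z_note))
  invisible(x)
}

#' Tidy the per-set metabolic proportions of a functional summary
#'
#' @param x A `functional_summary`.
#' @param ... Unused.
#' @return The proportions tibble.
#' @export
tidy.functional_summary <- function(x, ...) x$proportions

#' One-row overview of a functional summary
#'
#' @param x A `functional_summary`.
#' @param ... Unused.
#' @return A tibble with the mean metabolic proportion, its CI and z-test
#'   results (NA when the test was skipped), and the background proportion.
#' @export
glance.functional_summary <- function(x, ...) {
  zt <- x$z_test
  tibble(
    mean_metabolic_proportion =
      mean(x$proportions$metabolic_proportion, na.rm = TRUE),
    n_sets = sum(!is.na(x$proportions$metabolic_proportion)),
    background_proportion = x$background$proportion,
    z = if (is.null(zt)) NA_real_ else zt$z,
    p_value = if (is.null(zt)) NA_real_ else zt$p_value,
    ci_low = if (is.null(zt)) NA_real_ else zt$ci_low,
    ci_high = if (is.null(zt)) NA_real_ else zt$ci_high)
}

#' Export a functional summary
#'
#' Writes a JSON summary (per-set proportions, background, z-test, dominant
#' upstream categories) and, optionally, a flat TSV of enriched pathways per
#' process set.
#'
#' @param x A `functional_summary`.
#' @param json_path Path for the JSON summary.
#' @param tsv_path Optional path for the flat enriched-pathway TSV.
#' @return `json_path`, invisibly.
#' @export
write_functional_summary <- function(x, json_path, tsv_path = NULL) {
  zt <- x$z_test
  payload <- list(
    proportions = x$proportions,
    background = x$background,
    z_test = if (is.null(zt)) NULL else unclass(zt),
    z_note = if (is.na(x$z_note)) NULL else x$z_note,
    dominant_upstream = x$dominant_upstream)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(tsv_path)) {
    flat <- x$process_sets |>
      mutate(enriched = purrr::map(.data$enriched, function(e) {
        if (is.null(e)) tibble() else as_tibble(e)
      })) |>
      select("tissue", "side", "enriched") |>
      tidyr::unnest("enriched")
    readr::write_tsv(flat, tsv_path)
  }
  invisible(json_path)
}
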