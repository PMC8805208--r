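#' Pipeline run configuration
#'
#' Collects every input path and threshold of the pipeline. Defaults are the
#' canonical analysis values: fold-change gates 1.2 / 0.83, raw p < 0.05 for
#' DEP calling, FDR < 0.05 for enrichment, |Z| > 2.33 against 100 random
#' networks, and the 10-fold low-expression exclusion.
#'
#' @param abundance Named list (tissue -> path) or character vector of
#'   abundance TSV paths (tissue inferred from file names when unnamed).
#' @param background Path to the background edge list TSV.
#' @param gmt Path to the pathway GMT file.
#' @param categories Path to the pathway category TSV (or `NULL`).
#' @param secreted Path to the secreted catalog.
#' @param atlas Path to the expression atlas TSV (or `NULL` to disable the
#'   low-expression filter).
#' @param ec Path to the EC annotation TSV (or `NULL`).
#' @param fc_up,fc_down,alpha DEP thresholds (defaults 1.2, 0.83, 0.05).
#' @param fdr Enrichment FDR cutoff (default 0.05).
#' @param z_threshold Randomization |Z| threshold (default 2.33).
#' @param fold Low-expression exclusion fold (default 10).
#' @param n_null Number of random networks (default 100).
#' @param receptor_dep Require receptors to be DEPs (default FALSE).
#' @param rng_seed Seed for all randomness (default 1).
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(abundance, background, gmt, categories = NULL,
                       secreted, atlas = NULL, ec = NULL,
                       fc_up = 1.2, fc_down = 0.83, alpha = 0.05,
                       fdr = 0.05, z_threshold = 2.33, fold = 10,
                       n_null = 100, receptor_dep = FALSE, rng_seed = 1,
                       out_dir = "tissuetalk_results") {
  abundance <- as.list(abundance)
  if (is.null(names(abundance)) || any(!nzchar(names(abundance)))) {
    names(abundance) <- vapply(abundance, function(p) {
      sub("^abundance_", "", sub("\\.[^.]*$", "", basename(p)))
    }, "")
  }
  structure(list(
    abundance = abundance, background = background, gmt = gmt,
    categories = categories, secreted = secreted, atlas = atlas, ec = ec,
    fc_up = fc_up, fc_down = fc_down, alpha = alpha, fdr = fdr,
    z_threshold = z_threshold, fold = fold, n_null = n_null,
    receptor_dep = receptor_dep, rng_seed = rng_seed, out_dir = out_dir),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML mirrors [run_config()] field-for-field and round-trips
#' unchanged.
#'
#' @param path YAML path.
#' @return [read_run_config()]: a `run_config`; [write_run_config()]:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @param config A `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

load_inputs <- function(config) {
  list(
    background = read_background_network(config$background),
    pathways = read_pathways(config$gmt, config$categories),
    secreted = read_secreted_catalog(config$secreted),
    atlas = if (is.null(config$atlas)) NULL else
      read_expression_atlas(config$atlas),
    ec = if (is.null(config$ec)) NULL else read_ec_annotation(config$ec),
    abundance = purrr::imap(config$abundance, function(p, tis) {
      read_abundance(p, tissue = tis)
    }))
}

#' Validate every configured input without running the analysis
#'
#' Runs each loader in check mode and reports per-input status: `ok`,
#' `warning` (e.g. dropped self-loops, pathways lacking category rows) or
#' `error`, with messages. Problems are report content, not conditions.
#'
#' @param config A `run_config`.
#' @return A tibble with columns `input`, `status`, `message`.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  items <- c(
    list(background = function() read_background_network(config$background),
         pathways = function() read_pathways(config$gmt, config$categories),
         secreted = function() read_secreted_catalog(config$secreted)),
    if (!is.null(config$atlas))
      list(atlas = function() read_expression_atlas(config$atlas)),
    if (!is.null(config$ec))
      list(ec = function() read_ec_annotation(config$ec)),
    purrr::imap(config$abundance, function(p, tis) {
      force(p); force(tis)
      function() read_abundance(p, tissue = tis)
    }))
  rows <- purrr::imap(items, function(f, nm) {
    msgs <- character()
    res <- tryCatch(
      withCallingHandlers(
        { f(); "ok" },
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        msgs <<- c(msgs, conditionMessage(e))
        "error"
      })
    status <- if (res == "error") "error" else
      if (length(msgs) > 0) "warning" else "ok"
    tibble(input = nm, status = status,
           message = paste(msgs, collapse = "; "))
  })
  bind_rows(rows)
}

#' Run the full crosstalk pipeline
#'
#' Stages: differential calling per tissue -> tissue-specific core networks
#' -> randomization validation -> cross-tissue interface -> functional
#' quantification. Every stage's export is written under
#' `config$out_dir`, together with a machine-readable `run_report.json`
#' (package version, seed, thresholds, per-stage counts). All randomness
#' derives from `config$rng_seed`.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `deps`, `networks`, `randomization`,
#'   `interface`, `summary`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_inputs(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tissues <- names(inputs$abundance)

  deps <- purrr::map(inputs$abundance, function(ab) {
    call_deps(ab, fc_up = config$fc_up, fc_down = config$fc_down,
              alpha = config$alpha)
  })
  for (tis in tissues) {
    write_dep_table(deps[[tis]], file.path(out, sprintf("deps_%s.tsv", tis)))
  }

  networks <- purrr::map(deps, function(d) {
    suppressWarnings(build_tissue_network(d, inputs$background))
  })
  for (tis in tissues) {
    write_tissue_network(networks[[tis]],
                         file.path(out, sprintf("network_%s.graphml", tis)))
    write_tissue_network(networks[[tis]],
                         file.path(out, sprintf("network_%s_edges.tsv", tis)),
                         format = "tsv")
  }

  randomization <- purrr::imap(networks, function(net, tis) {
    rep <- randomize_validate(
      net, inputs$background, n_null = config$n_null,
      z_threshold = config$z_threshold,
      rng_seed = config$rng_seed + match(tis, tissues))
    jsonlite::write_json(
      list(tissue = tis, metrics = rep$metrics, passed = rep$passed,
           n_null = rep$n_null, z_threshold = rep$z_threshold,
           reason = if (is.na(rep$reason)) NULL else rep$reason),
      file.path(out, sprintf("randomization_%s.json", tis)),
      auto_unbox = TRUE, digits = NA)
    rep
  })

  interface <- suppressWarnings(build_interface(
    deps, networks, inputs$background, inputs$secreted,
    atlas = inputs$atlas, fold = config$fold,
    receptor_dep = config$receptor_dep))
  write_interface(interface, file.path(out, "interface.tsv"))
  write_interface(interface, file.path(out, "interface.graphml"),
                  format = "graphml")

  summary <- quantify_interface(interface, deps, inputs$pathways,
                                fdr_cut = config$fdr)
  write_functional_summary(summary, file.path(out, "functional_summary.json"),
                           file.path(out, "enriched_pathways.tsv"))

  report <- list(
    package = "tissuetalk",
    version = as.character(utils::packageVersion("tissuetalk")),
    rng_seed = config$rng_seed,
    thresholds = config[c("fc_up", "fc_down", "alpha", "fdr", "z_threshold",
                          "fold", "n_null", "receptor_dep")],
    stages = list(
      differential = lapply(deps, function(d) as.list(glance(d))),
      networks = lapply(networks, function(n) as.list(glance(n))),
      randomization = lapply(randomization, function(r)
        list(passed = r$passed,
             min_abs_z = suppressWarnings(min(abs(r$metrics$z))))),
      interface = as.list(glance(interface)),
      functional = as.list(glance(summary))))
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(deps = deps, networks = networks,
                 randomization = randomization, interface = interface,
                 summary = summary, report = report))
}
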