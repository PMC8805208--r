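#' Specification of a synthetic multi-tissue fixture
#'
#' Describes a complete self-consistent input bundle: a directed background
#' regulatory network (Erdős–Rényi by default, with all planted crosstalk
#' edges overlaid), a pathway collection with metabolic/signaling/other
#' classes, a secreted catalog, EC annotation, a tissue expression atlas, and
#' per-tissue replicate abundance tables with planted DEPs. The defaults
#' mirror the structure of the study design the package targets: three
#' insulin-sensitive tissues, three replicates per group, planted
#' differential proteins at linear fold change 2 with log2 replicate noise
#' sd 0.1, and one planted secreted-ligand -> receptor crosstalk axis per
#' ordered tissue pair around the cycle.
#'
#' Each planted axis is a chain `regulator -> ligand` (source tissue),
#' `ligand -> receptor` (cross-tissue), `receptor -> effector` (target
#' tissue), with the ligand secreted and highly expressed in its source
#' tissue, and all four proteins planted as DEPs of their tissue. Axis
#' proteins take part in no other background edges, and extra secreted
#' proteins are drawn from non-differential proteins, so the planted axes
#' are exactly the true cross-tissue edges — recovery tests are
#' non-circular.
#'
#' @param n_proteins Number of proteins (default 160).
#' @param n_pathways Number of basic pathways (default 40; two excluded
#'   disease/overview pathways are added on top).
#' @param metabolic_fraction Fraction of basic pathways labelled metabolic
#'   (default 0.35; remainder split between signaling and other).
#' @param n_tissues Number of tissues (default 3).
#' @param n_replicates_per_group Replicates per group (default 3).
#' @param planted_axes Tibble with columns `source_tissue`, `regulator`,
#'   `ligand`, `receptor`, `effector`, `target_tissue`; `NULL` (default)
#'   plants one axis per ordered tissue pair around the cycle using reserved
#'   protein ids.
#' @param n_extra_deps Additional planted DEPs per tissue beyond axis
#'   proteins (default 12).
#' @param n_secreted_extra Non-differential secreted proteins added to the
#'   catalog (default 10).
#' @param edge_prob Erdős–Rényi directed edge probability among non-axis
#'   proteins (default 0.02).
#' @param dep_fold_change Planted linear fold change (default 2).
#' @param log2_noise_sd Replicate noise sd on the log2 scale (default 0.1).
#' @param rng_seed Integer seed; the whole bundle is reproducible from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 160, n_pathways = 40,
                         metabolic_fraction = 0.35, n_tissues = 3,
                         n_replicates_per_group = 3, planted_axes = NULL,
                         n_extra_deps = 12, n_secreted_extra = 10,
                         edge_prob = 0.02, dep_fold_change = 2,
                         log2_noise_sd = 0.1, rng_seed = 1) {
  stopifnot(n_proteins >= 20, n_tissues >= 1, n_replicates_per_group >= 2,
            dep_fold_change > 0, log2_noise_sd >= 0,
            metabolic_fraction >= 0, metabolic_fraction <= 1)
  tissues <- fixture_tissues(n_tissues)
  if (is.null(planted_axes)) {
    planted_axes <- default_planted_axes(tissues, n_proteins)
  } else {
    planted_axes <- as_tibble(planted_axes)
  }
  axis_prot <- axis_proteins(planted_axes)
  if (length(axis_prot) > 0 &&
      any(!axis_prot %in% protein_ids(n_proteins))) {
    abort("planted axis proteins exceed n_proteins")
  }
  for (i in seq_len(nrow(planted_axes))) {
    ax <- unlist(planted_axes[i, c("regulator", "ligand", "receptor",
                                   "effector")])
    if (anyDuplicated(ax)) abort("axis proteins must be pairwise distinct")
  }
  structure(list(
    n_proteins = n_proteins, n_pathways = n_pathways,
    metabolic_fraction = metabolic_fraction, n_tissues = n_tissues,
    tissues = tissues, n_replicates_per_group = n_replicates_per_group,
    planted_axes = planted_axes, n_extra_deps = n_extra_deps,
    n_secreted_extra = n_secreted_extra, edge_prob = edge_prob,
    dep_fold_change = dep_fold_change, log2_noise_sd = log2_noise_sd,
    rng_seed = rng_seed), class = "fixture_spec")
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))

fixture_tissues <- function(n) {
  base <- c("adipose", "liver", "muscle")
  if (n <= 3) base[seq_len(n)] else c(base, sprintf("tissue%02d", 4:n))
}

default_planted_axes <- function(tissues, n_proteins) {
  n <- length(tissues)
  if (n < 2) {
    return(tibble(source_tissue = character(), regulator = character(),
                  ligand = character(), receptor = character(),
                  effector = character(), target_tissue = character()))
  }
  ids <- protein_ids(n_proteins)
  k <- seq_len(n)
  tibble(
    source_tissue = tissues[k],
    regulator = ids[4 * (k - 1) + 1],
    ligand = ids[4 * (k - 1) + 2],
    receptor = ids[4 * (k - 1) + 3],
    effector = ids[4 * (k - 1) + 4],
    target_tissue = tissues[c(k[-1], k[1])])
}

axis_proteins <- function(axes) {
  unique(c(axes$regulator, axes$ligand, axes$receptor, axes$effector))
}

#' Planted DEP assignment of a fixture
#'
#' Axis proteins are DEPs (upregulated) of their home tissue: regulator and
#' ligand in the source tissue, receptor and effector in the target tissue.
#' `n_extra_deps` additional proteins per tissue are drawn (reproducibly)
#' from the non-axis pool with alternating up/down directions.
#'
#' @param spec A [fixture_spec()].
#' @return Named list: tissue -> named character vector (protein -> "up" /
#'   "down").
#' @export
planted_dep_assignment <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  axes <- spec$planted_axes
  assign <- setNames(
    lapply(spec$tissues, function(t) character()), spec$tissues)
  add <- function(tis, prot, dir) {
    cur <- assign[[tis]]
    cur[prot] <- dir
    assign[[tis]] <<- cur
  }
  for (i in seq_len(nrow(axes))) {
    add(axes$source_tissue[i], axes$regulator[i], "up")
    add(axes$source_tissue[i], axes$ligand[i], "up")
    add(axes$target_tissue[i], axes$receptor[i], "up")
    add(axes$target_tissue[i], axes$effector[i], "up")
  }
  pool <- setdiff(protein_ids(spec$n_proteins), axis_proteins(axes))
  withr::with_seed(spec$rng_seed + 1L, {
    for (tis in spec$tissues) {
      extra <- sample(pool, min(spec$n_extra_deps, length(pool)))
      dirs <- rep(c("up", "down"), length.out = length(extra))
      for (j in seq_along(extra)) add(tis, extra[j], dirs[j])
    }
  })
  assign
}

#' Generate the knowledge side of a synthetic fixture
#'
#' Builds the background network (random directed edges among non-axis
#' proteins plus the planted axis chains), the pathway collection, the
#' secreted catalog (planted ligands plus non-differential extras), EC
#' annotation (every member of a metabolic pathway carries an EC number),
#' and the expression atlas (ligands high in their source tissue and more
#' than 10-fold lower elsewhere, so the low-expression filter is exercised
#' in both directions via additional low-expressed secreted decoys).
#'
#' @param spec A [fixture_spec()].
#' @return A list with `background`, `pathways`, `secreted`, `ec`, `atlas`,
#'   `dep_assignment`, `spec`.
#' @export
generate_background <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ids <- protein_ids(spec$n_proteins)
  axes <- spec$planted_axes
  ax <- axis_proteins(axes)
  free <- setdiff(ids, ax)
  dep_assignment <- planted_dep_assignment(spec)
  all_deps <- unique(unlist(lapply(dep_assignment, names)))

  withr::with_seed(spec$rng_seed, {
    nf <- length(free)
    pair_idx <- which(matrix(runif(nf * nf), nf, nf) < spec$edge_prob,
                      arr.ind = TRUE)
    pair_idx <- pair_idx[pair_idx[, 1] != pair_idx[, 2], , drop = FALSE]
    edges <- tibble(regulator = free[pair_idx[, 1]],
                    target = free[pair_idx[, 2]])
    axis_edges <- bind_rows(
      tibble(regulator = axes$regulator, target = axes$ligand),
      tibble(regulator = axes$ligand, target = axes$receptor),
      tibble(regulator = axes$receptor, target = axes$effector))
    background <- background_network(bind_rows(edges, axis_edges),
                                     nodes = ids)

    n_met <- round(spec$n_pathways * spec$metabolic_fraction)
    n_sig <- floor((spec$n_pathways - n_met) / 2)
    n_oth <- spec$n_pathways - n_met - n_sig
    classes <- c(rep("metabolic", n_met), rep("signaling", n_sig),
                 rep("other", n_oth))
    sub_of <- function(cl) switch(cl,
      metabolic = sample(c("carbohydrate metabolism", "lipid metabolism",
                           "amino acid metabolism"), 1),
      signaling = "signal transduction",
      other = "cellular processes")
    basic <- tibble(
      pathway_id = sprintf("pw%03d", seq_len(spec$n_pathways)),
      name = sprintf("pathway %03d", seq_len(spec$n_pathways)),
      members = lapply(seq_len(spec$n_pathways), function(i)
        sort(sample(ids, sample(8:20, 1)))),
      class = classes,
      subcategory = vapply(classes, sub_of, ""),
      excluded = FALSE)
    excluded <- tibble(
      pathway_id = c("pw900", "pw901"),
      name = c("disease pathway (excluded)", "global map (excluded)"),
      members = list(sort(sample(ids, 25)), sort(sample(ids, 40))),
      class = c("other", "other"),
      subcategory = c("human disease", "overview"),
      excluded = TRUE)
    sets <- bind_rows(basic, excluded)
    pathways <- pathway_collection(sets[, c("pathway_id", "name", "members")],
                                   sets[, c("pathway_id", "class",
                                            "subcategory", "excluded")])

    secretable <- setdiff(free, all_deps)
    extra_secreted <- sort(sample(secretable,
                                  min(spec$n_secreted_extra,
                                      length(secretable))))
    secreted <- sort(unique(c(axes$ligand, extra_secreted)))

    met_members <- unique(unlist(basic$members[basic$class == "metabolic"]))
    ec <- tibble(
      protein = ids,
      ec = lapply(ids, function(p) {
        if (p %in% met_members) {
          sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1),
                  sample(1:9, 1), sample(1:99, 1))
        } else character()
      }))

    atlas_m <- matrix(round(runif(spec$n_proteins * spec$n_tissues, 1, 10), 2),
                      nrow = spec$n_proteins,
                      dimnames = list(ids, spec$tissues))
    for (i in seq_len(nrow(axes))) {
      atlas_m[axes$ligand[i], ] <- 0.5
      atlas_m[axes$ligand[i], axes$source_tissue[i]] <- 20
    }
    # low-expressed secreted decoys: high everywhere except the first tissue
    decoys <- head(extra_secreted, 2)
    for (p in decoys) {
      atlas_m[p, ] <- 5
      atlas_m[p, spec$tissues[1]] <- 0.1
    }
    atlas <- expression_atlas(
      tibble(protein = ids) |>
        dplyr::bind_cols(as_tibble(atlas_m)))

    list(background = background, pathways = pathways, secreted = secreted,
         ec = ec, atlas = atlas, dep_assignment = dep_assignment,
         spec = spec)
  })
}

#' Generate per-tissue replicate abundance tables
#'
#' Log2 intensities are a per-protein baseline plus a group offset of
#' `+/- log2(dep_fold_change)` for planted DEPs (sign by direction) plus
#' Gaussian noise with sd `log2_noise_sd`; linear intensities are the
#' exponentials, hence strictly positive.
#'
#' @param spec A [fixture_spec()].
#' @param dep_assignment As from [planted_dep_assignment()]; defaults to the
#'   spec's own assignment.
#' @return Named list: tissue -> [abundance_table()].
#' @export
generate_abundance <- function(spec, dep_assignment = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(dep_assignment)) dep_assignment <- planted_dep_assignment(spec)
  ids <- protein_ids(spec$n_proteins)
  nrep <- spec$n_replicates_per_group
  cols <- c(paste0("control_", seq_len(nrep)), paste0("case_", seq_len(nrep)))
  groups <- setNames(rep(c("control", "case"), each = nrep), cols)
  withr::with_seed(spec$rng_seed + 2L, {
    tabs <- lapply(spec$tissues, function(tis) {
      baseline <- runif(length(ids), 4, 10)
      offset <- numeric(length(ids))
      planted <- dep_assignment[[tis]]
      idx <- match(names(planted), ids)
      offset[idx] <- ifelse(planted == "up", 1, -1) * log2(spec$dep_fold_change)
      m <- matrix(rep(baseline, 2 * nrep), ncol = 2 * nrep,
                  dimnames = list(ids, cols))
      m[, (nrep + 1):(2 * nrep)] <- m[, (nrep + 1):(2 * nrep)] + offset
      if (spec$log2_noise_sd > 0) {
        m <- m + matrix(rnorm(length(m), sd = spec$log2_noise_sd),
                        nrow = nrow(m))
      }
      abundance_table(
        dplyr::bind_cols(tibble(protein = ids), as_tibble(2^m)),
        groups = groups, tissue = tis)
    })
    setNames(tabs, spec$tissues)
  })
}

#' Generate a full in-memory fixture
#'
#' @param spec A [fixture_spec()].
#' @return A list combining [generate_background()] output with
#'   `abundance` (named list of [abundance_table()]s).
#' @export
generate_fixture <- function(spec) {
  bundle <- generate_background(spec)
  bundle$abundance <- generate_abundance(spec, bundle$dep_assignment)
  bundle
}

#' Write a complete fixture bundle to disk
#'
#' Writes every external-interface file consumed by the loaders — background
#' edge list, GMT gene sets, pathway category table, secreted catalog,
#' expression atlas, EC annotation, one abundance TSV per tissue — plus a
#' pipeline config (`config.yaml`) and a JSON manifest recording the planted
#' truths (axes and DEP assignment) for scoring.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `files`, `planted_axes`,
#'   `dep_assignment`, `rng_seed`).
#' @export
generate_fixture_bundle <- function(spec, out_dir) {
  bundle <- generate_fixture(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory: %s", out_dir))
  p <- function(f) file.path(out_dir, f)

  write_background_network(bundle$background, p("background_edges.tsv"))
  gmt <- vapply(seq_len(nrow(bundle$pathways)), function(i) {
    paste(c(bundle$pathways$pathway_id[i], bundle$pathways$name[i],
            bundle$pathways$members[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(gmt, p("pathways.gmt"))
  readr::write_tsv(
    as_tibble(bundle$pathways)[, c("pathway_id", "class", "subcategory",
                                   "excluded")],
    p("pathway_categories.tsv"))
  readr::write_lines(c("protein", bundle$secreted), p("secreted.tsv"))
  readr::write_tsv(as_tibble(bundle$atlas), p("atlas.tsv"))
  readr::write_tsv(
    tibble(protein = bundle$ec$protein,
           ec = vapply(bundle$ec$ec, paste, "", collapse = ";")),
    p("ec.tsv"))
  ab_files <- character()
  for (tis in names(bundle$abundance)) {
    f <- sprintf("abundance_%s.tsv", tis)
    readr::write_tsv(as_tibble(bundle$abundance[[tis]]), p(f))
    ab_files[tis] <- f
  }
  config <- run_config(
    abundance = as.list(file.path(out_dir, ab_files)),
    background = p("background_edges.tsv"),
    gmt = p("pathways.gmt"),
    categories = p("pathway_categories.tsv"),
    secreted = p("secreted.tsv"),
    atlas = p("atlas.tsv"),
    ec = p("ec.tsv"),
    rng_seed = spec$rng_seed,
    out_dir = file.path(out_dir, "results"))
  write_run_config(config, p("config.yaml"))
  manifest <- list(
    files = c(list(background = "background_edges.tsv",
                   gmt = "pathways.gmt",
                   categories = "pathway_categories.tsv",
                   secreted = "secreted.tsv", atlas = "atlas.tsv",
                   ec = "ec.tsv", config = "config.yaml"),
              abundance = list(as.list(ab_files))),
    planted_axes = bundle$planted_axes %||% spec$planted_axes,
    dep_assignment = lapply(bundle$dep_assignment, as.list),
    rng_seed = spec$rng_seed)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
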