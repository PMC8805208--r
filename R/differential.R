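#' Call differentially expressed proteins (DEPs) in one tissue
#'
#' For each protein the fold change is the ratio of geometric group means,
#' `2^(mean(log2 case) - mean(log2 control))`, and the p-value comes from a
#' two-sided two-sample t-test on the log2 intensities (pooled variance by
#' default, matching the classical Student test; Welch behind
#' `var_equal = FALSE`). A protein is a DEP when `fold_change >= fc_up` or
#' `fold_change <= fc_down` (both inclusive) and `p_value < alpha`. No
#' multiple-testing correction is applied at this stage; correction enters
#' later, in pathway enrichment.
#'
#' Proteins with zero within-group variance in both groups and equal group
#' means have no defined t statistic; they are flagged `untestable` with
#' `p_value = NA` and `is_dep = FALSE`. With zero variance but unequal means
#' the evidence is taken as conclusive (`p_value = 0`).
#'
#' @param x An [abundance_table()].
#' @param fc_up,fc_down Inclusive linear fold-change gates (defaults 1.2 and
#'   0.83); must satisfy `fc_down < 1 < fc_up`.
#' @param alpha Raw p-value cutoff (default 0.05, strict inequality).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch otherwise.
#' @return A `dep_table`: list with fields `tissue`, `records` (tibble
#'   `protein`, `log2fc`, `fold_change`, `p_value`, `direction`, `is_dep`,
#'   `untestable`) and `detected` (the full quantified protein set).
#' @export
#' @examples
#' tab <- abundance_table(
#'   data.frame(protein = c("P1", "P2"),
#'              c1 = c(2, 4), c2 = c(2.1, 4.1), c3 = c(1.9, 3.9),
#'              t1 = c(4, 4), t2 = c(4.2, 4.1), t3 = c(3.8, 3.9)),
#'   groups = c(c1 = "control", c2 = "control", c3 = "control",
#'              t1 = "case", t2 = "case", t3 = "case"),
#'   tissue = "liver")
#' tidy(call_deps(tab))
call_deps <- function(x, fc_up = 1.2, fc_down = 0.83, alpha = 0.05,
                      var_equal = TRUE) {
  stopifnot(inherits(x, "abundance_table"))
  if (!(fc_down < 1 && 1 < fc_up)) abort("need fc_down < 1 < fc_up")
  groups <- attr(x, "groups")
  con_cols <- names(groups)[groups == "control"]
  case_cols <- names(groups)[groups == "case"]
  m <- log2(as.matrix(x[, c(con_cols, case_cols), drop = FALSE]))
  rownames(m) <- x$protein
  is_con <- c(rep(TRUE, length(con_cols)), rep(FALSE, length(case_cols)))

  one <- function(row) {
    con <- row[is_con]; cas <- row[!is_con]
    l2fc <- mean(cas) - mean(con)
    if (sd(con) == 0 && sd(cas) == 0) {
      p <- if (mean(cas) == mean(con)) NA_real_ else 0
      return(c(l2fc, p))
    }
    p <- tryCatch(
      t.test(cas, con, var.equal = var_equal)$p.value,
      error = function(e) NA_real_)
    c(l2fc, p)
  }
  res <- t(apply(m, 1L, one))
  l2fc <- unname(res[, 1])
  p <- unname(res[, 2])
  fc <- 2^l2fc
  untestable <- is.na(p)
  # inclusive gates, robust to representation error in 2^log2(x)
  eps <- 1e-12
  dep <- !untestable & (fc >= fc_up * (1 - eps) | fc <= fc_down * (1 + eps)) &
    p < alpha
  direction <- ifelse(!dep, "none", ifelse(fc > 1, "up", "down"))
  records <- tibble(
    protein = x$protein, log2fc = l2fc, fold_change = fc, p_value = p,
    direction = direction, is_dep = dep, untestable = untestable)
  new_dep_table(attr(x, "tissue"), records, x$protein)
}

new_dep_table <- function(tissue, records, detected) {
  stopifnot(all(records$protein %in% detected), !anyDuplicated(records$protein))
  structure(list(tissue = tissue, records = records,
                 detected = sort(unique(detected))),
            class = "dep_table")
}

#' @export
print.dep_table <- function(x, ...) {
  cat(sprintf("<dep_table> tissue '%s': %d detected, %d DEPs (%d up, %d down)\n",
              x$tissue, length(x$detected), sum(x$records$is_dep),
              sum(x$records$direction == "up"),
              sum(x$records$direction == "down")))
  invisible(x)
}

#' Tidy per-protein differential results
#'
#' @param x A `dep_table` from [call_deps()].
#' @param ... Unused.
#' @return A tibble with a leading `tissue` column followed by the per-protein
#'   records.
#' @export
tidy.dep_table <- function(x, ...) {
  dplyr::bind_cols(tibble(tissue = x$tissue), x$records)
}

#' One-row summary of a differential analysis
#'
#' @param x A `dep_table`.
#' @param ... Unused.
#' @return A tibble with counts of detected, DEP, up- and downregulated
#'   proteins.
#' @export
glance.dep_table <- function(x, ...) {
  tibble(tissue = x$tissue, n_detected = length(x$detected),
         n_dep = sum(x$records$is_dep),
         n_up = sum(x$records$direction == "up"),
         n_down = sum(x$records$direction == "down"),
         n_untestable = sum(x$records$untestable))
}

#' DEP protein ids of a dep_table
#'
#' @param x A `dep_table`.
#' @return Character vector of DEP protein ids (sorted).
#' @export
dep_proteins <- function(x) {
  stopifnot(inherits(x, "dep_table"))
  sort(x$records$protein[x$records$is_dep])
}

#' Write a dep_table to TSV
#'
#' @param x A `dep_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dep_table <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}

#' Count proteins differential in every tissue with a consistent direction
#'
#' A protein contributes only if it is a DEP in every table and its direction
#' (up/down) is identical across all of them.
#'
#' @param tables A list of `dep_table` objects (>= 2).
#' @return Non-negative integer count.
#' @export
count_consistent_overlap <- function(tables) {
  if (length(tables) < 2) abort("need >= 2 tables")
  dirs <- lapply(tables, function(t) {
    r <- t$records[t$records$is_dep, c("protein", "direction")]
    setNames(r$direction, r$protein)
  })
  shared <- Reduce(intersect, lapply(dirs, names))
  if (length(shared) == 0) return(0L)
  sum(vapply(shared, function(p) {
    length(unique(vapply(dirs, `[[`, "", p))) == 1L
  }, TRUE))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1. The table is
#' `rbind(c(a, b), c(c, d))`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A list with `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_2x2(30, 70, 10, 90)  # statistic 12.5
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate table: zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Compare differential rates inside vs outside a protein partition
#'
#' Builds the 2x2 table (DEP vs non-DEP) x (in partition vs out) over the
#' detected pool and tests it with [chi_square_2x2()]. Used to ask whether
#' e.g. secreted proteins are differential more often than non-secreted ones.
#'
#' @param dep A `dep_table`.
#' @param partition Character vector of protein ids; must be a subset of
#'   `dep$detected`, non-empty, and a proper subset.
#' @return A list with `rate_in`, `rate_out`, `statistic`, `p_value`, and the
#'   underlying `table`.
#' @export
differential_rate_test <- function(dep, partition) {
  stopifnot(inherits(dep, "dep_table"))
  partition <- unique(partition)
  extra <- setdiff(partition, dep$detected)
  if (length(extra) > 0) {
    abort(sprintf("partition not a subset of detected: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  if (length(partition) == 0 || length(partition) == length(dep$detected)) {
    abort("degenerate table: partition empty or equal to detected pool")
  }
  deps <- dep_proteins(dep)
  in_dep <- length(intersect(partition, deps))
  in_non <- length(partition) - in_dep
  out_size <- length(dep$detected) - length(partition)
  out_dep <- length(deps) - in_dep
  out_non <- out_size - out_dep
  res <- chi_square_2x2(in_dep, in_non, out_dep, out_non)
  list(rate_in = in_dep / length(partition), rate_out = out_dep / out_size,
       statistic = res$statistic, p_value = res$p_value,
       table = matrix(c(in_dep, in_non, out_dep, out_non), nrow = 2,
                      byrow = TRUE,
                      dimnames = list(c("in", "out"), c("dep", "non_dep"))))
}

#' Volcano plot of a differential analysis
#'
#' @param object A `dep_table`.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change vs -log10 p, DEPs coloured by
#'   direction.
#' @export
autoplot.dep_table <- function(object, ...) {
  d <- tidy(object) |> filter(!.data$untestable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = expression(-log[10] ~ p),
                  title = sprintf("Differential proteins: %s", object$tissue)) +
    ggplot2::theme_minimal()
}
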