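test_that("edge lists load into deduplicated directed graphs without self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tB", "B\tC"), f)
  bg <- read_background_network(f)
  expect_setequal(bg$nodes, c("A", "B", "C"))
  expect_equal(nrow(bg$edges), 2)
  expect_true(igraph::is_directed(bg$graph))

  writeLines(c("A\tB", "A\tB"), f)
  expect_equal(nrow(read_background_network(f)$edges), 1)

  writeLines("A\tA", f)
  expect_warning(bg2 <- read_background_network(f), "self-loop")
  expect_equal(nrow(bg2$edges), 0)
  expect_equal(attr(bg2, "n_self_loops_dropped"), 1)
})

test_that("malformed or empty edge lists raise informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "lonely"), f)
  expect_error(read_background_network(f), "line 2")
  writeLines(character(), f)
  expect_error(read_background_network(f), "empty")
})

kgml_doc <- function(body) {
  paste0('<?xml version="1.0"?><pathway name="test">', body, "</pathway>")
}

test_that("KGML subset parsing turns relations into directed edges", {
  doc <- kgml_doc(paste0(
    '<entry id="1" name="P1" type="protein"/>',
    '<entry id="2" name="P2" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>'))
  bg <- read_kgml(doc)
  expect_equal(bg$edges, tibble::tibble(regulator = "P1", target = "P2"))
})

test_that("multi-name entries expand combinatorially", {
  doc <- kgml_doc(paste0(
    '<entry id="1" name="P1 P2" type="protein"/>',
    '<entry id="2" name="P3" type="protein"/>',
    '<relation entry1="1" entry2="2"/>'))
  bg <- read_kgml(doc)
  expect_equal(bg$edges,
               tibble::tibble(regulator = c("P1", "P2"),
                              target = c("P3", "P3")))
})

test_that("relation-free documents, bad XML and dangling relations are handled", {
  bg <- read_kgml(kgml_doc('<entry id="1" name="P1" type="protein"/>'))
  expect_equal(bg$nodes, "P1")
  expect_equal(nrow(bg$edges), 0)

  expect_error(read_kgml("this is not xml <<<"), "XML")
  expect_error(
    read_kgml(kgml_doc(paste0('<entry id="1" name="P1" type="protein"/>',
                              '<relation entry1="1" entry2="99"/>'))),
    "relation 1")
})

test_that("GMT plus category table builds a pathway collection", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  cat_f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pw1\tglycolysis\tA\tB\tC", gmt)
  writeLines(c("pathway_id\tclass\tsubcategory\texcluded",
               "pw1\tmetabolic\tcarbohydrate metabolism\tFALSE"), cat_f)
  pw <- read_pathways(gmt, cat_f)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$class, "metabolic")
  expect_setequal(pw$members[[1]], c("A", "B", "C"))

  # excluded pathways are retained but flagged
  writeLines(c("pathway_id\tclass\tsubcategory\texcluded",
               "pw1\tother\thuman disease\tTRUE"), cat_f)
  pw2 <- read_pathways(gmt, cat_f)
  expect_true(pw2$excluded)

  # missing category rows default to 'other' with a warning
  expect_warning(pw3 <- read_pathways(gmt, NULL), "category")
  expect_equal(pw3$class, "other")
  expect_false(pw3$excluded)

  writeLines(c("pw1\ta\tA", "pw1\tb\tB"), gmt)
  expect_error(read_pathways(gmt, NULL), "duplicate")
  writeLines("pw1\tonly-name", gmt)
  expect_error(read_pathways(gmt, NULL), "fewer than 3")
})

test_that("abundance tables validate groups and positivity", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(protein = c("P1", "P2"),
                   control_1 = c(1, 2), control_2 = c(1.1, 2.1),
                   control_3 = c(0.9, 1.9),
                   case_1 = c(2, 4), case_2 = c(2.2, 4.2),
                   case_3 = c(1.8, 3.8))
  readr::write_tsv(df, f)
  ab <- read_abundance(f, tissue = "liver")
  expect_s3_class(ab, "abundance_table")
  expect_equal(attr(ab, "tissue"), "liver")
  expect_equal(unname(attr(ab, "groups")),
               rep(c("control", "case"), each = 3))

  df_bad <- df; df_bad$control_2[1] <- 0
  expect_error(abundance_table(df_bad, attr(ab, "groups"), "liver"),
               "non-positive intensity.*P1.*control_2")
  expect_error(abundance_table(df, attr(ab, "groups")[-6], "liver"),
               "without group label")
  expect_error(abundance_table(df[, 1:4],
                               attr(ab, "groups")[1:3], "liver"),
               "2 replicates per group")
})

test_that("expression atlas keeps missing cells missing and rejects negatives", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tadipose\tliver\tmuscle", "P1\t1\t12\t5",
               "P2\t\t3\t4"), f)
  atlas <- read_expression_atlas(f)
  expect_equal(atlas_value(atlas, "P1", "adipose"), 1)
  expect_equal(atlas_value(atlas, "P1", "liver"), 12)
  expect_equal(atlas_value(atlas, "P1", "muscle"), 5)
  expect_true(is.na(atlas_value(atlas, "P2", "adipose")))
  expect_true(is.na(atlas_value(atlas, "P9", "liver")))
  expect_error(atlas_value(atlas, "P1", "brain"), "not in atlas")

  writeLines(c("protein\ta\tb", "P1\t-1\t2"), f)
  expect_error(read_expression_atlas(f), "negative")
  writeLines(c("protein\ta", "P1\t1", "P1\t2"), f)
  expect_error(read_expression_atlas(f), "duplicate")
})

test_that("EC annotation parses dotted numbers and flags malformed ones", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tec", "P1\t2.7.1.1;1.1.1.1", "P2\t"), f)
  ec <- read_ec_annotation(f)
  expect_equal(ec$ec[[1]], c("2.7.1.1", "1.1.1.1"))
  expect_length(ec$ec[[2]], 0)
  writeLines(c("protein\tec", "P1\tnot-an-ec"), f)
  expect_error(read_ec_annotation(f), "malformed EC.*P1")
})

test_that("background networks round-trip through edge-list text", {
  bg <- background_network(
    tibble::tibble(regulator = c("A", "B", "C"), target = c("B", "C", "A"),
                   pathway_id = c("pw1", "pw1", NA)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_background_network(bg, f)
  bg2 <- read_background_network(f)
  expect_identical(bg$nodes, bg2$nodes)
  expect_identical(bg$edges, bg2$edges)
})

test_that("KGML parsing then export equals direct edge-list loading", {
  doc <- kgml_doc(paste0(
    '<entry id="1" name="P1 P2" type="protein"/>',
    '<entry id="2" name="P3" type="protein"/>',
    '<entry id="3" name="P4" type="gene"/>',
    '<relation entry1="1" entry2="2"/>',
    '<relation entry1="2" entry2="3"/>'))
  bg <- read_kgml(doc)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_background_network(bg, f)
  bg2 <- read_background_network(f)
  expect_identical(bg$edges, bg2$edges)
  # loaders are pure: same bytes in, same parsed content out
  bg3 <- read_background_network(f)
  expect_identical(bg3$edges, bg2$edges)
  expect_identical(bg3$nodes, bg2$nodes)
  expect_identical(bg3$edge_pathways, bg2$edge_pathways)
})
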