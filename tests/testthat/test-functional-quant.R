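test_that("process sets union ligands with regulators and receptors with effectors", {
  b <- toy_interface_bundle()
  iface <- suppressWarnings(build_interface(
    b$deps, b$networks, b$background, b$catalog, atlas = b$atlas))
  pw <- make_pathways(list(
    list(id = "pwA", class = "metabolic", members = c("u", "s", "n1"),
         subcategory = "carbohydrate metabolism"),
    list(id = "pwB", class = "signaling", members = c("x1", "x2", "n3"))))
  # widen the sampling frame with undetected filler proteins so the planted
  # 2-of-3 overlap is actually significant at the default FDR cut
  fillers <- sprintf("f%02d", 1:40)
  bgs <- list(A = c(b$deps$A$detected, fillers),
              B = c(b$deps$B$detected, fillers))
  sets <- assemble_process_sets(iface, b$deps, pw, backgrounds = bgs)
  upA <- sets[sets$tissue == "A" & sets$side == "upstream", ]
  expect_setequal(upA$proteins[[1]], c("u", "s"))
  downB <- sets[sets$tissue == "B" & sets$side == "downstream", ]
  expect_setequal(downB$proteins[[1]], c("r", "d"))
  # tissue receiving nothing has an empty downstream set and no enrichment
  downA <- sets[sets$tissue == "A" & sets$side == "downstream", ]
  expect_equal(downA$n_proteins, 0L)
  expect_equal(downA$n_enriched, 0L)

  # planted enrichment: upstream proteins {u, s} both in pwA of size 3;
  # background = detected(A) + receptors = {n1, n2, s, u} ... pwA members
  # within background = {u, s, n1}; p = P(X >= 2 | N, K = 3, n = 2)
  enrA <- upA$enriched[[1]]
  expect_equal(nrow(enrA), 1)
  N <- enrA$N; K <- enrA$K
  expect_equal(enrA$p_value, hyper_oracle(N, K, 2, 2), tolerance = 1e-12)
})

test_that("metabolic proportion counts enriched metabolic pathways", {
  enr <- tibble::tibble(pathway_id = c("a", "b", "c"),
                        class = c("metabolic", "metabolic", "signaling"))
  expect_equal(metabolic_proportion(enr), 2 / 3)
  expect_equal(metabolic_proportion(enr[3, ]), 0)
  expect_true(is.na(metabolic_proportion(enr[0, ])))
  expect_true(is.na(metabolic_proportion(NULL)))
})

test_that("background metabolic proportion counts basic pathways only", {
  mk <- function(n_met, n_other, n_excl = 0) {
    specs <- c(
      lapply(seq_len(n_met), function(i)
        list(id = sprintf("m%03d", i), class = "metabolic", members = "P1")),
      lapply(seq_len(n_other), function(i)
        list(id = sprintf("o%03d", i), class = "other", members = "P1")),
      lapply(seq_len(n_excl), function(i)
        list(id = sprintf("x%03d", i), class = "metabolic", members = "P1",
             excluded = TRUE)))
    make_pathways(specs)
  }
  bp <- background_metabolic_proportion(mk(91, 152, 5))
  expect_equal(bp$metabolic, 91)
  expect_equal(bp$total, 243)
  expect_equal(round(100 * bp$proportion, 2), 37.45)
  expect_equal(background_metabolic_proportion(mk(3, 0))$proportion, 1)
  expect_error(background_metabolic_proportion(mk(0, 0, 2)), "no non-excluded")
})

test_that("the one-sample z-test matches the hand-derived example", {
  zt <- one_sample_z(c(0.5, 0.7, 0.9), 0.37)
  expect_equal(zt$mean_prop, 0.7)
  expect_equal(zt$sd, 0.2)
  expect_equal(zt$z, (0.7 - 0.37) / (0.2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(zt$z, 2.858, tolerance = 1e-3)
  expect_equal(zt$ci_low, 0.7 - 1.96 * 0.2 / sqrt(3), tolerance = 1e-12)
  expect_equal(tidy(zt)$p_value, 2 * pnorm(-abs(zt$z)))

  expect_error(one_sample_z(c(0.5, 0.5), 0.5), "insufficient spread")
  expect_error(one_sample_z(0.5, 0.4), "insufficient spread")
  expect_equal(one_sample_z(c(0.2, 0.6), 0.4)$z, 0)
})

test_that("the z statistic is order-invariant and sign-equivariant", {
  withr::with_seed(19, {
    for (i in 1:10) {
      props <- runif(5)
      p0 <- runif(1)
      z1 <- one_sample_z(props, p0)$z
      expect_equal(one_sample_z(sample(props), p0)$z, z1, tolerance = 1e-12)
      expect_equal(one_sample_z(1 - props, 1 - p0)$z, -z1, tolerance = 1e-12)
    }
  })
})

test_that("dominant category is a plurality with ties reported in full", {
  enr <- tibble::tibble(
    pathway_id = c("a", "b", "c"),
    subcategory = c("carbohydrate metabolism", "carbohydrate metabolism",
                    "lipid metabolism"),
    p_value = c(0.001, 0.01, 0.0001))
  expect_equal(dominant_category(enr), "carbohydrate metabolism")
  expect_setequal(dominant_category(enr[c(1, 3), ]),
                  c("carbohydrate metabolism", "lipid metabolism"))
  expect_equal(dominant_category(NULL), character())
  # weighting by -log10 p can flip the plurality
  expect_equal(dominant_category(enr[c(1, 3), ], weighted = TRUE),
               "lipid metabolism")
})

test_that("interface quantification rejects the background when upstream sets are metabolic", {
  # a fixture whose interface proteins all sit in metabolic pathways while
  # the pathway universe is mostly non-metabolic
  b <- toy_interface_bundle(three_tissues = TRUE)
  pw_specs <- c(
    list(list(id = "met_up", class = "metabolic",
              members = c("u", "s", "n1"),
              subcategory = "carbohydrate metabolism"),
         list(id = "met_down", class = "metabolic",
              members = c("r", "d", "n3"),
              subcategory = "lipid metabolism")),
    lapply(1:8, function(i)
      list(id = sprintf("sig%02d", i), class = "signaling",
           members = c("x1", "x2", "x3"))))
  pw <- make_pathways(pw_specs)
  fillers <- sprintf("f%02d", 1:40)
  bgs <- lapply(b$deps, function(d) c(d$detected, fillers))
  fs <- quantify_interface(
    suppressWarnings(build_interface(b$deps, b$networks, b$background,
                                     b$catalog, atlas = b$atlas)),
    b$deps, pw, backgrounds = bgs)
  expect_s3_class(fs, "functional_summary")
  props <- fs$proportions$metabolic_proportion
  expect_true(all(props[!is.na(props)] == 1))
  expect_equal(fs$background$proportion, 0.2)
  if (!is.null(fs$z_test)) {
    expect_gt(fs$z_test$z, 0)
  } else {
    # identical proportions give zero spread; the summary says so
    expect_match(fs$z_note, "spread|enriched")
  }
  dom <- fs$dominant_upstream
  expect_true(all(vapply(
    dom$dominant[dom$source_tissue == "A"],
    function(d) identical(d, "carbohydrate metabolism"), TRUE)))
})

test_that("functional summaries serialize to JSON and TSV", {
  b <- toy_interface_bundle()
  pw <- make_pathways(list(
    list(id = "pwA", class = "metabolic", members = c("u", "s", "n1"))))
  fs <- quantify_interface(
    suppressWarnings(build_interface(b$deps, b$networks, b$background,
                                     b$catalog, atlas = b$atlas)),
    b$deps, pw)
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_functional_summary(fs, jf, tf)
  parsed <- jsonlite::read_json(jf)
  expect_true(!is.null(parsed$background$total))
  expect_true(file.exists(tf))
  g <- glance(fs)
  expect_true(is.finite(g$mean_metabolic_proportion) ||
                is.na(g$mean_metabolic_proportion))
})
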