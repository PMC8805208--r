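test_that("the low-expression filter excludes by the max of other tissues", {
  atlas <- expression_atlas(tibble::tibble(
    protein = c("hi_other", "ok", "absent_cell"),
    t1 = c(1, 1, NA), t2 = c(12, 9, 3), t3 = c(5, 2, 4)))
  expect_equal(filter_low_expression(c("hi_other", "ok"), "t1", atlas),
               "ok")  # 12 > 10*1 excludes; 9 <= 10*1 retains
  expect_warning(
    keep <- filter_low_expression(c("ok", "absent_cell", "unknown"), "t1",
                                  atlas),
    "missing from the atlas")
  expect_setequal(keep, c("ok", "absent_cell", "unknown"))
  expect_error(filter_low_expression("ok", "t1", atlas, fold = 0), "positive")
  expect_error(filter_low_expression("ok", "t9", atlas), "not in atlas")
})

test_that("cross edges require a secreted DEP, a directed edge, and network presence", {
  b <- toy_interface_bundle()
  edges <- find_cross_edges(b$deps$A, b$networks, b$background, b$catalog,
                            atlas = b$atlas)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$ligand, "s")
  expect_equal(edges$receptor, "r")
  expect_equal(edges$target_tissue, "B")

  # receptor secreted -> no edge
  expect_equal(nrow(find_cross_edges(b$deps$A, b$networks, b$background,
                                     c("s", "r"), atlas = b$atlas)), 0)
  # receptor absent from the target network -> no edge
  nets2 <- b$networks
  nets2$B <- suppressWarnings(build_tissue_network(
    make_dep_table("B", c("x1", "x3"), deps = c("x1", "x3")),
    b$background, tissue = "B"))
  expect_equal(nrow(find_cross_edges(b$deps$A, nets2, b$background,
                                     b$catalog, atlas = b$atlas)), 0)
  # ligand removed by the 10x filter -> no edge
  atlas_lo <- expression_atlas(tibble::tibble(
    protein = "s", A = 1, B = 20))
  expect_equal(nrow(find_cross_edges(b$deps$A, b$networks, b$background,
                                     b$catalog, atlas = atlas_lo)), 0)
})

test_that("upstream pairs follow edge direction and DEP status", {
  b <- toy_interface_bundle()
  up <- upstream_pairs("s", b$deps$A, b$background)
  expect_equal(up, tibble::tibble(tissue = "A", regulator = "u",
                                  ligand = "s"))
  # reversed direction only: s -> r is not an upstream pair for r's side
  expect_equal(nrow(upstream_pairs("u", b$deps$A, b$background)), 0)
  # non-DEP regulator is dropped
  dep_noU <- make_dep_table("A", c("u", "s", "n1"), deps = "s")
  expect_equal(nrow(upstream_pairs("s", dep_noU, b$background)), 0)
})

test_that("downstream pairs stay within the receptor's own tissue", {
  b <- toy_interface_bundle()
  down <- downstream_pairs(list(B = "r"), b$deps, b$background)
  expect_equal(down, tibble::tibble(tissue = "B", receptor = "r",
                                    effector = "d"))
  # d differential only in another tissue does not count
  dep_B_noD <- make_dep_table("B", c("r", "d", "n3"), deps = "r")
  expect_equal(nrow(downstream_pairs(list(B = "r"),
                                     list(A = b$deps$A, B = dep_B_noD),
                                     b$background)), 0)
  expect_equal(nrow(downstream_pairs(list(B = "d"), b$deps, b$background)),
               0)  # no outgoing background edges from d
})

test_that("the assembled interface recovers the hand-planted axis exactly", {
  b <- toy_interface_bundle()
  iface <- suppressWarnings(build_interface(
    b$deps, b$networks, b$background, b$catalog, atlas = b$atlas))
  expect_equal(nrow(iface$cross_edges), 1)
  expect_equal(nrow(iface$upstream_pairs), 1)
  expect_equal(nrow(iface$downstream_pairs), 1)
  expect_equal(iface$cross_edges$ligand, "s")
  expect_equal(iface$upstream_pairs$regulator, "u")
  expect_equal(iface$downstream_pairs$effector, "d")
  long <- tidy(iface)
  expect_setequal(long$role, c("cross", "upstream", "downstream"))
  expect_equal(glance(iface)$n_ligands, 1L)

  # no secreted proteins anywhere -> empty interface
  empty <- suppressWarnings(build_interface(
    b$deps, b$networks, b$background, character(), atlas = b$atlas))
  expect_equal(nrow(empty$cross_edges), 0)
  expect_equal(nrow(empty$upstream_pairs), 0)
  expect_equal(nrow(empty$downstream_pairs), 0)
  expect_error(build_interface(b$deps["A"], b$networks, b$background,
                               b$catalog), ">= 2")
})

test_that("a ligand fans out to every target network containing its receptor", {
  b <- toy_interface_bundle(three_tissues = TRUE)
  iface <- suppressWarnings(build_interface(
    b$deps, b$networks, b$background, b$catalog, atlas = b$atlas))
  cross_from_A <- iface$cross_edges[iface$cross_edges$source_tissue == "A", ]
  expect_equal(nrow(cross_from_A), 2)  # B and C both hold r
  expect_setequal(cross_from_A$target_tissue, c("B", "C"))
  expect_equal(unique(cross_from_A$ligand), "s")
})

test_that("removing a ligand from the catalog ablates its edges and upstream pairs", {
  b <- toy_interface_bundle()
  with_s <- suppressWarnings(build_interface(
    b$deps, b$networks, b$background, b$catalog, atlas = b$atlas))
  without_s <- suppressWarnings(build_interface(
    b$deps, b$networks, b$background, setdiff(b$catalog, "s"),
    atlas = b$atlas))
  expect_gt(nrow(with_s$cross_edges), 0)
  expect_equal(nrow(without_s$cross_edges), 0)
  expect_equal(nrow(without_s$upstream_pairs), 0)
})

test_that("receptor-DEP mode restricts receptors to differential proteins", {
  b <- toy_interface_bundle()
  dep_B_nonDiffR <- make_dep_table("B", c("r", "d", "n3"), deps = "d")
  nets <- list(A = b$networks$A,
               B = suppressWarnings(build_tissue_network(
                 c("d", "r"), b$background, tissue = "B")))
  deps <- list(A = b$deps$A, B = dep_B_nonDiffR)
  lax <- suppressWarnings(build_interface(
    deps, nets, b$background, b$catalog, atlas = b$atlas))
  strict <- suppressWarnings(build_interface(
    deps, nets, b$background, b$catalog, atlas = b$atlas,
    receptor_dep = TRUE))
  expect_equal(nrow(lax$cross_edges), 1)
  expect_equal(nrow(strict$cross_edges), 0)
})

test_that("every cross edge of a synthetic build satisfies the structural invariants", {
  spec <- fixture_spec(rng_seed = 77)
  bundle <- generate_fixture(spec)
  deps <- purrr::map(bundle$abundance, call_deps)
  nets <- purrr::map(deps, function(d)
    suppressWarnings(build_tissue_network(d, bundle$background)))
  iface <- suppressWarnings(build_interface(
    deps, nets, bundle$background, bundle$secreted, atlas = bundle$atlas))
  ce <- iface$cross_edges
  expect_gt(nrow(ce), 0)
  expect_true(all(ce$source_tissue != ce$target_tissue))
  expect_true(all(ce$ligand %in% bundle$secreted))
  expect_true(all(!ce$receptor %in% bundle$secreted))
  edge_key <- paste(bundle$background$edges$regulator,
                    bundle$background$edges$target)
  expect_true(all(paste(ce$ligand, ce$receptor) %in% edge_key))
  for (i in seq_len(nrow(ce))) {
    expect_true(ce$receptor[i] %in%
                  igraph::V(nets[[ce$target_tissue[i]]]$graph)$name)
  }
  # every upstream pair's ligand emits a cross edge; every downstream
  # receptor receives one
  expect_true(all(iface$upstream_pairs$ligand %in% ce$ligand))
  expect_true(all(iface$downstream_pairs$receptor %in% ce$receptor))
})
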