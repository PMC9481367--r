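# Reactome-dialect parsing, DAG layerization, sub-hierarchy selection.

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("parse_relations filters by species keyword and tolerates empty input", {
  f <- write_lines_tmp(c("R-HSA-A\tR-HSA-B", "R-HSA-A\tR-HSA-C", "R-MMU-X\tR-MMU-Y"))
  dag <- parse_relations(f)
  expect_setequal(dag$nodes, c("R-HSA-A", "R-HSA-B", "R-HSA-C"))
  expect_equal(nrow(dag$edges), 2)

  empty <- parse_relations(write_lines_tmp(character(0)))
  expect_length(empty$nodes, 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("parse_relations raises structured errors on malformed lines and cycles", {
  expect_error(parse_relations(write_lines_tmp(c("R-HSA-A\tR-HSA-B", "only-one-field"))),
               class = "pathnn_parse_error")
  f <- write_lines_tmp(c("R-HSA-A\tR-HSA-B", "R-HSA-A\tR-HSA-C", "R-HSA-B\tR-HSA-A"))
  expect_error(parse_relations(f), class = "pathnn_structural_error")
})

test_that("parse_gmt deduplicates genes and rejects bad lines", {
  f <- write_lines_tmp("P1\tdesc\tTP53\tJAK2\tTP53")
  gs <- parse_gmt(f)
  expect_setequal(gs$entries$P1$genes, c("TP53", "JAK2"))

  expect_error(parse_gmt(write_lines_tmp(c("P1\tdesc\tTP53", "P1\tother\tJAK2"))),
               regexp = "duplicate", class = "pathnn_parse_error")
  expect_error(parse_gmt(write_lines_tmp("P1\tdesc")), class = "pathnn_parse_error")
})

test_that("parse_gmt reproduces the generator's manifest exactly", {
  f <- small_fixture()
  expect_setequal(names(f$gs$entries), names(f$fx$hierarchy$gene_sets))
  for (id in names(f$gs$entries))
    expect_setequal(f$gs$entries[[id]]$genes, f$fx$hierarchy$gene_sets[[id]])
})

test_that("assign_layers places chains and diamonds by longest path", {
  chain <- parse_relations(write_lines_tmp(c("R-HSA-A\tR-HSA-B", "R-HSA-B\tR-HSA-C")))
  expect_equal(assign_layers(chain)$layers,
               list("R-HSA-A", "R-HSA-B", "R-HSA-C"))

  diamond <- parse_relations(write_lines_tmp(
    c("R-HSA-A\tR-HSA-B", "R-HSA-A\tR-HSA-C", "R-HSA-B\tR-HSA-D", "R-HSA-C\tR-HSA-D")))
  h <- assign_layers(diamond)
  expect_equal(h$layers, list("R-HSA-A", c("R-HSA-B", "R-HSA-C"), "R-HSA-D"))
  expect_length(h$copies, 0)
  expect_error(assign_layers(structure(list(nodes = character(),
                                            edges = data.frame(parent = character(),
                                                               child = character())),
                                       class = "pathway_dag")),
               class = "pathnn_structural_error")
})

test_that("skip-level edges are realized through copy chains; adjacency invariant holds", {
  # A->B->C->D plus skip edge A->D (gap 3: copies of D at layers 2 and 3)
  dag <- parse_relations(write_lines_tmp(
    c("R-HSA-A\tR-HSA-B", "R-HSA-B\tR-HSA-C", "R-HSA-C\tR-HSA-D", "R-HSA-A\tR-HSA-D")))
  h <- assign_layers(dag)
  expect_length(h$copies, 2)
  expect_true(all(h$copies == "R-HSA-D"))
  expect_true(all(h$node_layer[h$edges$child] == h$node_layer[h$edges$parent] + 1L))

  # generated fixture: one chain per planted cross edge
  f <- small_fixture()
  cross <- f$fx$hierarchy$cross_edges
  expect_equal(length(unique(sub("::copy\\d+$", "", names(f$hier$copies)))),
               nrow(cross))
  expect_true(all(f$hier$node_layer[f$hier$edges$child] ==
                  f$hier$node_layer[f$hier$edges$parent] + 1L))
})

test_that("select_sublayers reverses layer order and builds the diamond adjacency", {
  diamond <- parse_relations(write_lines_tmp(
    c("R-HSA-A\tR-HSA-B", "R-HSA-A\tR-HSA-C", "R-HSA-B\tR-HSA-D", "R-HSA-C\tR-HSA-D")))
  h <- assign_layers(diamond)
  gs <- parse_gmt(write_lines_tmp(c("R-HSA-B\tdesc\tg1", "R-HSA-C\tdesc\tg1\tg2")))
  sel <- select_sublayers(h, gs, k = 2)
  expect_equal(sel$pathway_layers$P1, c("R-HSA-B", "R-HSA-C"))  # DAG layer 2 first
  expect_equal(sel$pathway_layers$P2, "R-HSA-A")
  expect_equal(sel$gene_list, c("g1", "g2"))
  A <- as.matrix(sel$masks$A)
  expect_equal(A["R-HSA-B", ], c(g1 = 1, g2 = 0))
  expect_equal(A["R-HSA-C", ], c(g1 = 1, g2 = 1))
  expect_equal(as.vector(as.matrix(sel$masks$M2)), c(1, 1))
})

test_that("select_sublayers validates k and prunes gene-less nodes", {
  f <- small_fixture()
  expect_error(select_sublayers(f$hier, f$gs, k = 0), class = "pathnn_config_error")
  expect_error(select_sublayers(f$hier, f$gs, k = 99), class = "pathnn_config_error")

  # drop one P1 node's gene annotation: it must be pruned with a warning
  victim <- resolve <- f$sel$pathway_layers$P1[1]
  if (victim %in% names(f$hier$copies)) resolve <- f$hier$copies[[victim]]
  gs2 <- f$gs
  gs2$entries[[resolve]] <- NULL
  expect_warning(sel2 <- select_sublayers(f$hier, gs2, k = 4), regexp = "pruning")
  expect_false(victim %in% sel2$pathway_layers$P1)
})

test_that("masks are binary with no all-zero rows; nnz(A) matches gene-set sizes", {
  f <- small_fixture()
  for (m in f$sel$masks) {
    expect_true(all(m@x == 1))
    expect_true(all(Matrix::rowSums(m) > 0))
  }
  expected_nnz <- sum(vapply(f$sel$pathway_layers$P1, function(id) {
    g <- f$gs$entries[[if (id %in% names(f$sel$copies)) f$sel$copies[[id]] else id]]$genes
    length(intersect(unique(g), f$sel$gene_list))
  }, 0L))
  expect_equal(Matrix::nnzero(f$sel$masks$A), expected_nnz)
})

test_that("selection is deterministic and round-trips through disk byte-identically", {
  f <- small_fixture()
  sel2 <- suppressWarnings(select_sublayers(f$hier, f$gs, k = 4))
  d1 <- tempfile(); d2 <- tempfile()
  write_hierarchy(f$sel, d1)
  write_hierarchy(sel2, d2)
  for (fn in list.files(d1))
    expect_identical(readLines(file.path(d1, fn)), readLines(file.path(d2, fn)))

  back <- read_hierarchy(d1)
  expect_identical(back$gene_list, f$sel$gene_list)
  expect_identical(back$pathway_layers, f$sel$pathway_layers)
  for (nm in names(f$sel$masks))
    expect_true(all(back$masks[[nm]] == f$sel$masks[[nm]]))
})

test_that("pathway-name file parses", {
  f <- small_fixture()
  nm <- parse_pathway_names(file.path(f$dir, "names.tsv"))
  expect_true(all(c("id", "name", "species") %in% names(nm)))
  expect_true(all(f$fx$hierarchy$pathways$id %in% nm$id))
})
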