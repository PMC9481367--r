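# Difference-from-reference contribution propagation, ranking, Sankey export.

test_that("reference activations are a plain forward pass on the reference", {
  sel <- random_selected_hierarchy(41, n_genes = 3, sizes = c(3, 2))
  model <- init_model(sel, list(seed = 41))
  ref0 <- reference_activations(model)            # zero input, zero biases
  for (h in ref0$hidden) expect_true(all(h == 0))
  expect_true(all(ref0$head_p == 0.5))
  expect_equal(ref0$combined, 0.5)

  # nonzero biases: references equal an ordinary forward pass on x0
  for (i in seq_along(model$layers)) model$layers[[i]]$b[] <- 0.3
  x0 <- rep(c(1, 0, 0), 3)
  ref <- reference_activations(model, x0)
  fw <- forward(model, matrix(x0, 1))
  for (i in seq_along(ref$hidden))
    expect_equal(ref$hidden[[i]], fw$hidden[[i]][1, ])
  expect_equal(ref$head_p, fw$head_p[1, ])
})

test_that("x0 = x gives delta-t = 0 and zero contributions", {
  f <- small_fixture()
  model <- small_trained()$model
  x <- f$prep$features[3, ]
  rep <- deeplift_scores(model, matrix(x, 1), x0 = x)
  expect_equal(rep$delta_t, 0)
  for (lc in rep$layer_contrib) expect_true(all(abs(lc) < 1e-12))
})

test_that("summation-to-delta holds at every layer and the input for the final-head target", {
  f <- small_fixture()
  model <- small_trained()$model
  X <- f$prep$features[1:40, ]
  rep <- deeplift_scores(model, X)
  for (lc in rep$layer_contrib)
    expect_lt(max(abs(rowSums(lc) - rep$delta_t)), 1e-5)
  expect_lt(max(abs(rowSums(rep$input_contrib) - rep$delta_t)), 1e-5)
})

test_that("combined-target attribution satisfies summation-to-delta at the gene and input layers", {
  f <- small_fixture()
  model <- small_trained()$model
  X <- f$prep$features[1:20, ]
  rep <- deeplift_scores(model, X, target = "combined")
  expect_lt(max(abs(rowSums(rep$layer_contrib$genes) - rep$delta_t)), 1e-5)
  expect_lt(max(abs(rowSums(rep$input_contrib) - rep$delta_t)), 1e-5)
  expect_equal(rep$delta_t,
               forward(model, X)$combined - reference_activations(model)$combined)
})

test_that("single-path contributions equal delta-t and match brute-force perturbation", {
  model <- single_path_model(k = 4, w = 0.8, b = 0.1)
  x <- c(1, 0, 0)
  rep <- deeplift_scores(model, matrix(x, 1))
  # one node per layer: that node carries the whole delta
  for (lc in rep$layer_contrib)
    expect_equal(unname(lc[1, 1]), rep$delta_t, tolerance = 1e-10)
  # brute force: delta of the final head between x and the reference
  p_x <- forward(model, matrix(x, 1))$head_p[1, 5]
  p_0 <- forward(model, matrix(0, 1, 3))$head_p[1, 5]
  expect_equal(rep$delta_t, p_x - p_0, tolerance = 1e-12)
  # monotone path: the active input feature gets the full (positive) credit
  expect_equal(unname(rep$input_contrib[1, 1]), rep$delta_t, tolerance = 1e-10)
  expect_true(all(rep$input_contrib[1, -1] == 0))
})

test_that("attribution sign agrees with single-node perturbation on small models", {
  for (seed in c(51, 52, 53)) {
    sel <- random_selected_hierarchy(seed, n_genes = 3, sizes = c(3, 2))
    model <- init_model(sel, list(seed = seed))
    # monotone paths: make every weight non-negative
    for (i in seq_along(model$layers)) {
      model$layers[[i]]$W <- abs(model$layers[[i]]$W)
      model$heads[[i]]$u <- abs(model$heads[[i]]$u)
    }
    set.seed(seed)
    x <- rbinom(9, 1, 0.6)
    rep <- deeplift_scores(model, matrix(x, 1))
    # flipping input feature j to the reference removes its contribution
    for (j in which(x == 1)) {
      xr <- x; xr[j] <- 0
      d <- forward(model, matrix(x, 1))$head_p[1, 3] -
           forward(model, matrix(xr, 1))$head_p[1, 3]
      if (abs(d) > 1e-8 && abs(rep$input_contrib[1, j]) > 1e-8)
        expect_equal(unname(sign(rep$input_contrib[1, j])), sign(d))
    }
  }
})

test_that("rank_nodes orders by absolute aggregate with lexicographic ties", {
  rep <- structure(list(aggregate = list(genes = c(a = 0.5, b = -0.9, c = 0.1))),
                   class = "attribution_report")
  r <- rank_nodes(rep, "genes")
  expect_equal(r$node, c("b", "a", "c"))
  expect_equal(r$rank, 1:3)
  # equal-magnitude opposite scores cancel to zero and rank last
  rep2 <- structure(list(aggregate = list(genes = c(a = 0, b = -0.2, c = 0.4))),
                    class = "attribution_report")
  expect_equal(rank_nodes(rep2, "genes")$node[3], "a")
  expect_error(rank_nodes(rep, "nope"), class = "pathnn_config_error")
})

test_that("ranking is invariant to sample order", {
  f <- small_fixture()
  model <- small_trained()$model
  X <- f$prep$features[1:30, ]
  r1 <- rank_nodes(deeplift_scores(model, X), "genes")
  r2 <- rank_nodes(deeplift_scores(model, X[rev(seq_len(30)), ]), "genes")
  expect_equal(r1$node, r2$node)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
})

test_that("sankey export retains top-k nodes and the right links", {
  f <- small_fixture()
  model <- small_trained()$model
  rep <- deeplift_scores(model, f$prep$features[1:30, ])
  sk <- export_sankey(model, rep, top_k = 3)
  for (layer in c("genes", "P1", "P2", "P3", "P4"))
    expect_equal(sum(sk$nodes$layer == layer), min(3, length(model$node_ids[[layer]])))
  expect_true(all(c("mutation", "amplification", "deletion", "output") %in% sk$nodes$id))
  expect_true(all(sk$links$value >= 0))
  expect_error(export_sankey(model, rep, top_k = 0), class = "pathnn_config_error")

  # top_k = layer size: pathway-pathway link count equals mask nnz
  skall <- export_sankey(model, rep, top_k = max(lengths(model$node_ids)))
  n_pp <- sum(vapply(2:5, function(i) Matrix::nnzero(model$layers[[i]]$M), 0))
  gene_layer_nodes <- sk <- NULL
  pp_links <- 0
  expect_equal(
    sum(vapply(seq_len(nrow(skall$links)), function(r)
      !(skall$links$source[r] %in% c("mutation", "amplification", "deletion")) &&
        skall$links$target[r] != "output", logical(1))),
    n_pp)

  d <- tempfile(fileext = ".json")
  export_sankey(model, rep, top_k = 3, path = d)
  js <- jsonlite::read_json(d, simplifyVector = TRUE)
  expect_true(all(c("nodes", "links") %in% names(js)))
})

test_that("feature-type aggregates split the input contributions", {
  f <- small_fixture()
  model <- small_trained()$model
  rep <- deeplift_scores(model, f$prep$features[1:30, ])
  expect_named(rep$feature_type, c("mutation", "amplification", "deletion"))
  expect_equal(sum(rep$feature_type), sum(rep$input_contrib), tolerance = 1e-10)
})

test_that("ranked tables are written per layer", {
  f <- small_fixture()
  model <- small_trained()$model
  rep <- deeplift_scores(model, f$prep$features[1:10, ])
  d <- tempfile()
  write_rankings(rep, d, parse_pathway_names(file.path(f$dir, "names.tsv")))
  expect_setequal(list.files(d),
                  paste0("ranking_", c("genes", "P1", "P2", "P3", "P4"), ".tsv"))
  tab <- utils::read.delim(file.path(d, "ranking_P1.tsv"))
  expect_equal(names(tab), c("node", "name", "score", "rank"))
  expect_equal(tab$rank, seq_len(nrow(tab)))
})
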