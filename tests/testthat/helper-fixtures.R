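# Shared fixtures, built in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small synthetic world (hierarchy files + cohort) used across modules.
small_fixture <- function() {
  cached("small", function() {
    man <- fixture_manifest(seed = 101L, n_samples = 300L)
    dir <- file.path(tempdir(), "pathnn-small-fixture")
    fx <- simulate_fixtures(man, dir)
    dag <- parse_relations(file.path(dir, "relations.tsv"))
    hier <- assign_layers(dag)
    gs <- parse_gmt(file.path(dir, "pathways.gmt"))
    sel <- suppressWarnings(select_sublayers(hier, gs, k = 4))
    prep <- suppressMessages(prepare_cohort(fx$cohort$mutation, fx$cohort$cnv,
                                            fx$cohort$clinical, sel, seed = 101L))
    list(manifest = man, dir = dir, fx = fx, dag = dag, hier = hier, gs = gs,
         sel = sel, prep = prep)
  })
}

# A model trained on the small fixture (no dropout: deterministic surface
# for the attribution tests).
small_trained <- function() {
  cached("trained", function() {
    f <- small_fixture()
    model <- init_model(f$sel, list(seed = 5L, dropout = rep(0, 5)))
    res <- train_model(model, f$prep$features, f$prep$labels, f$prep$split,
                       training_config(epochs = 120, base_learning_rate = 0.01,
                                       seed = 5L))
    res
  })
}

# Hand-made selected hierarchy with random (but never all-zero-row) masks,
# for toy-model property tests.
random_selected_hierarchy <- function(seed, n_genes = 3, sizes = c(3, 2)) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  layer_ids <- lapply(seq_along(sizes), function(j) sprintf("L%d_%02d", j, seq_len(sizes[j])))
  rand_mask <- function(rows, cols) {
    m <- matrix(rbinom(length(rows) * length(cols), 1, 0.6),
                length(rows), length(cols), dimnames = list(rows, cols))
    for (r in which(rowSums(m) == 0)) m[r, sample.int(length(cols), 1)] <- 1
    Matrix::Matrix(m, sparse = TRUE)
  }
  masks <- list(A = rand_mask(layer_ids[[1]], genes))
  if (length(sizes) > 1) for (j in 2:length(sizes))
    masks[[paste0("M", j)]] <- rand_mask(layer_ids[[j]], layer_ids[[j - 1]])
  structure(list(pathway_layers = setNames(layer_ids, paste0("P", seq_along(sizes))),
                 gene_list = genes, masks = masks, copies = character(0),
                 pruned = character(0), k = length(sizes)),
            class = "selected_hierarchy")
}

# Straight-through reimplementation of the forward pass with explicit loops
# over nodes and incoming edges: the independent dense oracle.
dense_forward_oracle <- function(model, X) {
  n <- nrow(X)
  inp <- X
  L <- length(model$layers)
  head_p <- matrix(0, n, L)
  for (i in seq_len(L)) {
    ly <- model$layers[[i]]
    Wz <- ly$W
    Wz[ly$M == 0] <- 0  # dense weights with zeros written at masked positions
    h <- matrix(0, n, nrow(Wz))
    for (s in seq_len(n)) for (r in seq_len(nrow(Wz))) {
      acc <- ly$b[r]
      for (c in seq_len(ncol(Wz))) acc <- acc + Wz[r, c] * inp[s, c]
      h[s, r] <- tanh(acc)
    }
    for (s in seq_len(n))
      head_p[s, i] <- 1 / (1 + exp(-(sum(h[s, ] * model$heads[[i]]$u) + model$heads[[i]]$c)))
    inp <- h
  }
  list(head_p = head_p,
       combined = as.vector(head_p %*% model$head_weights))
}

# A single-path model: one gene -> one node per pathway layer, every
# unmasked weight set to `w`, biases `b`. Closed-form oracle: nested tanh.
single_path_model <- function(k = 4, w = 1, b = 0) {
  genes <- "gA"
  layer_ids <- lapply(seq_len(k), function(j) paste0("P", j, "_1"))
  masks <- list(A = Matrix::Matrix(matrix(1, 1, 1, dimnames = list(layer_ids[[1]], genes)),
                                   sparse = TRUE))
  if (k > 1) for (j in 2:k)
    masks[[paste0("M", j)]] <- Matrix::Matrix(
      matrix(1, 1, 1, dimnames = list(layer_ids[[j]], layer_ids[[j - 1]])), sparse = TRUE)
  sel <- structure(list(pathway_layers = setNames(layer_ids, paste0("P", seq_len(k))),
                        gene_list = genes, masks = masks, copies = character(0),
                        pruned = character(0), k = k),
                   class = "selected_hierarchy")
  model <- init_model(sel, list(seed = 1, dropout = rep(0, k + 1)))
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$W <- model$layers[[i]]$M * w
    model$layers[[i]]$b[] <- b
    model$heads[[i]]$u[] <- w
    model$heads[[i]]$c <- b
  }
  model
}
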