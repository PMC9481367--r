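# The network core: a diagonal gene layer, mask-constrained pathway layers,
# tanh activations, per-layer single-unit sigmoid output heads, the forward
# pass and parameter counting. Every layer computes y = f((W * M) x + b)
# where M is the binary connectivity mask; entries with M = 0 never
# influence outputs and never receive gradient.

default_model_config <- function(k) {
  list(n_features_per_gene = 3L,
       dropout = c(0.5, rep(0.1, k)),  # after gene layer, after each pathway layer
       head_weights = rep(1 / (k + 1), k + 1),
       seed = 1L)
}

#' Initialize a pathway-structured sparse model
#'
#' Builds the layer stack from a selected hierarchy: a diagonal gene layer
#' (each gene node sees only its own per-gene feature block), one masked
#' linear layer per pathway layer, and a single-unit sigmoid head on every
#' hidden layer. Unmasked weights are drawn from a seeded symmetric uniform
#' scaled by the unmasked fan-in of each target node; masked entries are 0
#' and stay frozen.
#'
#' @param hierarchy a `selected_hierarchy`.
#' @param config optional list overriding `n_features_per_gene`, `dropout`
#'   (vector, one rate per hidden layer), `head_weights` (convex), `seed`.
#' @return class `sparse_model`.
#' @export
init_model <- function(hierarchy, config = list()) {
  k <- hierarchy$k
  cfg <- utils::modifyList(default_model_config(k), config)
  if (length(cfg$dropout) != k + 1) config_error("dropout needs one rate per hidden layer")
  set.seed(cfg$seed)
  G <- length(hierarchy$gene_list)
  fpg <- cfg$n_features_per_gene
  layers <- list()

  # gene layer: diagonal-block mask, G x (fpg * G)
  M0 <- matrix(0, G, fpg * G,
               dimnames = list(hierarchy$gene_list, NULL))
  for (f in seq_len(fpg)) M0[cbind(seq_len(G), fpg * (seq_len(G) - 1L) + f)] <- 1
  layers[[1]] <- new_layer(M0, "h0_genes", cfg$dropout[1])

  for (j in seq_len(k)) {
    m <- hierarchy$masks[[if (j == 1) "A" else paste0("M", j)]]
    if (j == 1 && !identical(colnames(m), hierarchy$gene_list))
      structural_error("gene->pathway mask columns do not match the gene list")
    layers[[j + 1]] <- new_layer(as.matrix(m), paste0("h", j, "_P", j), cfg$dropout[j + 1])
  }
  heads <- lapply(layers, function(l) {
    s <- nrow(l$W)
    list(u = runif(s, -sqrt(6 / s), sqrt(6 / s)), c = 0)
  })
  hw <- cfg$head_weights
  if (length(hw) != length(heads) || any(hw < 0) || abs(sum(hw) - 1) > 1e-8)
    config_error("head_weights must be convex with one weight per hidden layer")
  structure(list(layers = layers, heads = heads, head_weights = hw,
                 gene_list = hierarchy$gene_list,
                 node_ids = c(list(genes = hierarchy$gene_list),
                              hierarchy$pathway_layers),
                 n_features_per_gene = fpg, config = cfg, k = k),
            class = "sparse_model")
}

new_layer <- function(M, name, dropout) {
  M <- (as.matrix(M) != 0) * 1
  fan_in <- pmax(rowSums(M), 1)
  scale <- sqrt(6 / fan_in)
  W <- matrix(runif(length(M), -1, 1), nrow(M), ncol(M)) * scale * M
  list(W = W, b = numeric(nrow(M)), M = M, activation = "tanh",
       dropout = dropout, name = name)
}

#' Forward pass
#'
#' Evaluates every hidden layer (tanh, so node values stay in \[-1, 1\]) and
#' every sigmoid head. In training mode, inverted dropout is applied to each
#' hidden layer's output before it feeds the next layer; heads always read
#' the undropped activation. Evaluation mode is deterministic.
#'
#' @param model a `sparse_model`.
#' @param X numeric matrix, samples x (features per gene * genes), or a
#'   single feature row.
#' @param train_mode apply dropout (default FALSE).
#' @return list: `hidden` (list of samples x nodes activation matrices),
#'   `pre` (pre-activations), `head_z`, `head_p` (samples x heads),
#'   `combined` (convex head combination, the model probability),
#'   `drop_masks` (training mode only).
#' @export
forward <- function(model, X, train_mode = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!all(is.finite(X))) validation_error("non-finite values in the input")
  if (ncol(X) != ncol(model$layers[[1]]$W))
    structural_error(sprintf("input has %d columns; model expects %d",
                             ncol(X), ncol(model$layers[[1]]$W)))
  n <- nrow(X)
  L <- length(model$layers)
  hidden <- pre <- drop_masks <- vector("list", L)
  head_z <- head_p <- matrix(0, n, L)
  inp <- X
  for (i in seq_len(L)) {
    ly <- model$layers[[i]]
    Weff <- ly$W * ly$M
    a <- tcrossprod(inp, Weff) + matrix(ly$b, n, length(ly$b), byrow = TRUE)
    h <- tanh(a)
    pre[[i]] <- a
    colnames(h) <- rownames(Weff)
    hidden[[i]] <- h
    head_z[, i] <- as.vector(h %*% model$heads[[i]]$u) + model$heads[[i]]$c
    head_p[, i] <- plogis(head_z[, i])
    if (train_mode && ly$dropout > 0) {
      keep <- matrix(rbinom(length(h), 1, 1 - ly$dropout), n) / (1 - ly$dropout)
      drop_masks[[i]] <- keep
      inp <- h * keep
    } else {
      inp <- h
    }
  }
  list(hidden = hidden, pre = pre, head_z = head_z, head_p = head_p,
       combined = combine_heads(head_p, model$head_weights),
       drop_masks = drop_masks)
}

#' Combine per-layer head probabilities
#'
#' Convex (default uniform) combination of the per-layer sigmoid heads.
#' @param head_probs matrix samples x heads (or a vector of head values).
#' @param head_weights convex weights, one per head.
#' @return numeric vector of combined probabilities.
#' @export
combine_heads <- function(head_probs, head_weights = NULL) {
  if (is.null(dim(head_probs))) head_probs <- matrix(head_probs, nrow = 1)
  H <- ncol(head_probs)
  head_weights <- head_weights %||% rep(1 / H, H)
  if (length(head_weights) != H) config_error("one weight per head required")
  if (any(head_weights < 0) || abs(sum(head_weights) - 1) > 1e-8)
    config_error("head weights must be convex")
  as.vector(head_probs %*% head_weights)
}

#' Predict with a trained model
#' @param object a `sparse_model`; @param X feature matrix; @param ... unused.
#' @return vector of combined probabilities of the positive (non-LTS) class.
#' @export
predict.sparse_model <- function(object, X, ...) forward(object, X)$combined

#' Count trainable parameters of the sparse model
#'
#' Per masked layer: nnz(M) weights plus one bias per target node; per head:
#' source size + 1. The dense-equivalent total applies
#' `w_l = n_l * (n_{l-1} + 1)` to the same node counts.
#'
#' @param model a `sparse_model`.
#' @return class `param_count_report`: data.frame `layers` (layer, type,
#'   output_size, params), `total`, `dense_total`, `ratio`.
#' @export
count_sparse_params <- function(model) {
  rows <- lapply(seq_along(model$layers), function(i) {
    ly <- model$layers[[i]]
    data.frame(layer = ly$name, type = if (i == 1) "diagonal" else "sparse",
               output_size = nrow(ly$W),
               params = sum(ly$M != 0) + length(ly$b))
  })
  hrows <- lapply(seq_along(model$heads), function(i)
    data.frame(layer = sprintf("o_linear%d", i), type = "head", output_size = 1L,
               params = length(model$heads[[i]]$u) + 1L))
  tab <- do.call(rbind, c(rows, hrows))
  sizes <- c(ncol(model$layers[[1]]$W), vapply(model$layers, function(l) nrow(l$W), 0L), 1L)
  dense <- count_dense_params(sizes)
  structure(list(layers = tab, total = sum(tab$params), dense_total = dense,
                 ratio = sum(tab$params) / dense),
            class = "param_count_report")
}

#' Parameter counts from an architecture manifest
#'
#' Counts parameters without materializing a model: useful for published
#' architecture dimensions. `mask_nnz` gives the nonzeros of the gene->P1
#' adjacency and each pathway mask, in layer order.
#'
#' @param n_genes gene-layer size.
#' @param pathway_sizes node counts of the pathway layers, in network order.
#' @param mask_nnz nonzero counts of the masks (length = number of pathway layers).
#' @param n_features_per_gene input features per gene (default 3).
#' @return class `param_count_report`.
#' @export
count_params_manifest <- function(n_genes, pathway_sizes, mask_nnz,
                                  n_features_per_gene = 3L) {
  stopifnot(length(mask_nnz) == length(pathway_sizes))
  sizes <- c(n_genes, pathway_sizes)
  rows <- data.frame(
    layer = c("h0_genes", paste0("h", seq_along(pathway_sizes), "_P", seq_along(pathway_sizes)),
              sprintf("o_linear%d", seq_along(sizes))),
    type = c("diagonal", rep("sparse", length(pathway_sizes)), rep("head", length(sizes))),
    output_size = c(sizes, rep(1L, length(sizes))),
    params = c(n_features_per_gene * n_genes + n_genes,
               mask_nnz + pathway_sizes,
               sizes + 1L))
  dense <- count_dense_params(c(n_features_per_gene * n_genes, sizes, 1L))
  structure(list(layers = rows, total = sum(rows$params), dense_total = dense,
                 ratio = sum(rows$params) / dense),
            class = "param_count_report")
}

#' Dense-equivalent parameter count
#'
#' For layer sizes `n_0, n_1, ..., n_L`, a fully connected network has
#' `sum_l n_l * (n_{l-1} + 1)` weights (weights plus biases).
#'
#' @param node_counts integer vector of layer sizes, input first.
#' @return total parameter count (double, to avoid integer overflow).
#' @export
count_dense_params <- function(node_counts) {
  if (length(node_counts) < 2) config_error("need at least two layer sizes")
  if (any(node_counts <= 0)) config_error("layer sizes must be positive")
  n <- as.numeric(node_counts)
  sum(n[-1] * (n[-length(n)] + 1))
}

#' @export
print.param_count_report <- function(x, ...) {
  print(x$layers, row.names = FALSE)
  cat(sprintf("Total (sparse): %s\nDense equivalent: %s\nRatio: %.3g\n",
              format(x$total, big.mark = ","),
              format(x$dense_total, big.mark = ","), x$ratio))
  invisible(x)
}

#' @export
print.sparse_model <- function(x, ...) {
  cat(sprintf("Pathway-structured sparse model: %d genes, %d pathway layers\n",
              length(x$gene_list), x$k))
  for (ly in x$layers)
    cat(sprintf("  %s: %d nodes, %d unmasked weights\n", ly$name, nrow(ly$W), sum(ly$M != 0)))
  invisible(x)
}

#' Serialize a model to a directory
#'
#' Writes a JSON architecture manifest, masks as sparse triplet text and all
#' weights/biases/heads as full-precision text; [load_model()] reproduces
#' the model bit-exactly.
#'
#' @param model a `sparse_model`; @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    k = model$k, n_features_per_gene = model$n_features_per_gene,
    gene_list = model$gene_list, node_ids = model$node_ids,
    head_weights = model$head_weights,
    layers = lapply(model$layers, function(l)
      list(name = l$name, rows = nrow(l$W), cols = ncol(l$W),
           activation = l$activation, dropout = l$dropout)),
    config = model$config)
  jsonlite::write_json(manifest, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    nz <- which(ly$M != 0, arr.ind = TRUE)
    nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
    writeLines(paste(nz[, 1], nz[, 2], format_full(ly$W[nz]), sep = "\t"),
               file.path(dir, sprintf("layer%d_weights.tsv", i)))
    writeLines(format_full(ly$b), file.path(dir, sprintf("layer%d_bias.tsv", i)))
    writeLines(c(format_full(model$heads[[i]]$c), format_full(model$heads[[i]]$u)),
               file.path(dir, sprintf("head%d.tsv", i)))
  }
  invisible(dir)
}

#' Load a model written by [save_model()]
#' @param dir model directory.
#' @return a `sparse_model`, bit-identical to the saved one.
#' @export
load_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "architecture.json"), simplifyVector = TRUE)
  layers <- list()
  heads <- list()
  for (i in seq_along(man$layers$name)) {
    li <- lapply(man$layers, `[[`, i)
    trip <- strsplit(readLines(file.path(dir, sprintf("layer%d_weights.tsv", i))), "\t")
    r <- as.integer(vapply(trip, `[[`, "", 1))
    c <- as.integer(vapply(trip, `[[`, "", 2))
    w <- as.numeric(vapply(trip, `[[`, "", 3))
    W <- M <- matrix(0, li$rows, li$cols)
    M[cbind(r, c)] <- 1
    W[cbind(r, c)] <- w
    rownames(W) <- rownames(M) <- as.character(man$node_ids[[i]])
    if (i > 1) colnames(W) <- colnames(M) <- as.character(man$node_ids[[i - 1]])
    layers[[i]] <- list(W = W, b = as.numeric(readLines(file.path(dir, sprintf("layer%d_bias.tsv", i)))),
                        M = M, activation = li$activation, dropout = li$dropout,
                        name = li$name)
    hv <- as.numeric(readLines(file.path(dir, sprintf("head%d.tsv", i))))
    heads[[i]] <- list(u = hv[-1], c = hv[1])
  }
  structure(list(layers = layers, heads = heads,
                 head_weights = as.numeric(man$head_weights),
                 gene_list = as.character(man$gene_list),
                 node_ids = lapply(man$node_ids, as.character),
                 n_features_per_gene = as.integer(man$n_features_per_gene),
                 config = man$config, k = as.integer(man$k)),
            class = "sparse_model")
}
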