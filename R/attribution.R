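# Difference-from-reference (DeepLIFT-style) contribution propagation over
# the trained sparse model: the linear rule across the masked affine maps
# and the rescale rule across tanh/sigmoid nonlinearities. Because the
# rescale multiplier is the exact finite-difference ratio delta(out) /
# delta(in) at each node, propagated contributions at any layer that
# separates the target from the input sum exactly to the target's
# difference-from-reference delta-t.

#' Reference activations
#'
#' Runs a deterministic evaluation-mode forward pass on the reference input
#' (default: the all-zero "no alteration" profile) and records every node's
#' activation, head values, and the combined output.
#'
#' @param model a `sparse_model`.
#' @param x0 reference feature row; `NULL` for all-zeros.
#' @return list: `hidden` (per-layer activation vectors), `pre`, `head_z`,
#'   `head_p`, `combined`.
#' @export
reference_activations <- function(model, x0 = NULL) {
  f <- ncol(model$layers[[1]]$W)
  x0 <- x0 %||% numeric(f)
  if (!all(is.finite(x0))) validation_error("non-finite reference input")
  fw <- forward(model, matrix(x0, nrow = 1))
  list(hidden = lapply(fw$hidden, function(h) h[1, ]),
       pre = lapply(fw$pre, function(a) a[1, ]),
       head_z = fw$head_z[1, ], head_p = fw$head_p[1, ],
       combined = fw$combined[1])
}

# Rescale multiplier delta(f(a))/delta(a) with the removable singularity at
# delta(a) ~ 0 replaced by the derivative of f at the reference.
rescale_mult <- function(d_out, d_in, deriv_ref, tol = 1e-9) {
  m <- d_out / d_in
  sing <- abs(d_in) < tol
  m[sing] <- deriv_ref[sing]
  m
}

#' DeepLIFT contribution scores
#'
#' Propagates the difference-from-reference of the target output back
#' through the network. The target is by default the final (deepest) head,
#' for which every hidden layer is a separating cut and the per-layer
#' contributions sum exactly to `delta_t = t - t0`; `target = "combined"`
#' attributes the convex head combination instead (summation-to-delta then
#' holds at the input and gene layers, where all heads are downstream, but
#' not at later layers, which earlier heads bypass).
#'
#' @param model a trained `sparse_model`.
#' @param X samples x features matrix.
#' @param x0 reference input (`NULL` = all-zeros).
#' @param target `"final"` (default), `"combined"`, or `"head"` with
#'   `head_index`.
#' @param head_index head to attribute when `target = "head"`.
#' @return class `attribution_report`: `layer_contrib` (named list
#'   `genes`, `P1`, ... of samples x nodes contribution matrices),
#'   `input_contrib` (samples x features), `delta_t` (per sample),
#'   `aggregate` (per-layer signed sums over samples),
#'   `feature_type` (aggregate input contribution of the mutation /
#'   amplification / deletion blocks), `target`, `reference`.
#' @export
deeplift_scores <- function(model, X, x0 = NULL, target = c("final", "combined", "head"),
                            head_index = NULL) {
  target <- match.arg(target)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  L <- length(model$layers)
  if (target == "head") {
    stopifnot(!is.null(head_index), head_index >= 1, head_index <= L)
  } else if (target == "final") head_index <- L
  ref <- reference_activations(model, x0)
  fw <- forward(model, X)
  n <- nrow(X)
  f <- ncol(model$layers[[1]]$W)
  x0v <- x0 %||% numeric(f)
  dX <- X - matrix(x0v, n, f, byrow = TRUE)
  dH <- lapply(seq_len(L), function(i)
    fw$hidden[[i]] - matrix(ref$hidden[[i]], n, length(ref$hidden[[i]]), byrow = TRUE))
  dA <- lapply(seq_len(L), function(i)
    fw$pre[[i]] - matrix(ref$pre[[i]], n, length(ref$pre[[i]]), byrow = TRUE))
  dZ <- fw$head_z - matrix(ref$head_z, n, L, byrow = TRUE)
  dP <- fw$head_p - matrix(ref$head_p, n, L, byrow = TRUE)

  hw <- switch(target,
               combined = model$head_weights,
               final = as.numeric(seq_len(L) == L),
               head = as.numeric(seq_len(L) == head_index))
  delta_t <- as.vector(dP %*% hw)
  # per-head multiplier onto the head pre-activation z_j
  sig_ref <- ref$head_p * (1 - ref$head_p)
  mZ <- vapply(seq_len(L), function(j)
    hw[j] * rescale_mult(dP[, j], dZ[, j], rep(sig_ref[j], n)), numeric(n))
  mZ <- matrix(mZ, n, L)

  layer_contrib <- vector("list", L)
  mH_next <- NULL
  for (i in L:1) {
    mH <- tcrossprod(mZ[, i], model$heads[[i]]$u)   # head path
    if (!is.null(mH_next)) mH <- mH + mH_next
    colnames(mH) <- colnames(fw$hidden[[i]])
    layer_contrib[[i]] <- mH * dH[[i]]
    tanh_ref <- 1 - tanh(ref$pre[[i]])^2
    mA <- mH * rescale_mult(dH[[i]], dA[[i]],
                            matrix(tanh_ref, n, length(tanh_ref), byrow = TRUE))
    Weff <- model$layers[[i]]$W * model$layers[[i]]$M
    mH_next <- mA %*% Weff
  }
  input_contrib <- mH_next * dX
  colnames(input_contrib) <- colnames(model$layers[[1]]$W) %||%
    paste0(rep(model$gene_list, each = model$n_features_per_gene),
           c("_mut", "_amp", "_del"))
  names(layer_contrib) <- names(model$node_ids)

  fpg <- model$n_features_per_gene
  type_cols <- split(seq_len(f), rep(seq_len(fpg), times = f / fpg))
  feature_type <- vapply(type_cols, function(cols) sum(input_contrib[, cols]), 0)
  names(feature_type) <- c("mutation", "amplification", "deletion")[seq_len(fpg)]

  structure(list(layer_contrib = layer_contrib, input_contrib = input_contrib,
                 delta_t = delta_t,
                 aggregate = lapply(layer_contrib, colSums),
                 feature_type = feature_type,
                 target = target, head_index = head_index,
                 reference = ref, x0 = x0v),
            class = "attribution_report")
}

#' Rank nodes of a layer by aggregate contribution
#'
#' Aggregate score = signed sum of per-sample contributions; ranking is by
#' absolute aggregate, descending, ties broken lexicographically by node id.
#'
#' @param report an `attribution_report`.
#' @param layer layer name (`"genes"`, `"P1"`, ...) or index.
#' @return data.frame `node`, `score`, `rank`.
#' @export
rank_nodes <- function(report, layer) {
  if (is.numeric(layer)) layer <- names(report$aggregate)[layer]
  if (!layer %in% names(report$aggregate))
    config_error(sprintf("unknown layer '%s'", layer))
  s <- report$aggregate[[layer]]
  o <- order(-abs(s), names(s))
  data.frame(node = names(s)[o], score = unname(s[o]), rank = seq_along(s))
}

#' Export a Sankey diagram of the attributed network
#'
#' Emits the top-k nodes per layer (by absolute aggregate contribution) with
#' their scores and per-layer normalized color weights, the retained edges
#' among them weighted by `|W * M|`, input feature-type nodes, and the
#' output node, as a JSON-ready list `{nodes, links}`.
#'
#' @param model a `sparse_model`.
#' @param report an `attribution_report` for that model.
#' @param top_k nodes kept per layer.
#' @param path optional path to write the JSON document.
#' @return list with data.frames `nodes` and `links`, invisibly when written.
#' @export
export_sankey <- function(model, report, top_k = 10, path = NULL) {
  if (top_k < 1) config_error("top_k must be >= 1")
  L <- length(model$layers)
  keep <- lapply(seq_len(L), function(i) {
    r <- rank_nodes(report, i)
    r$node[seq_len(min(top_k, nrow(r)))]
  })
  layer_names <- names(report$aggregate)
  nodes <- do.call(rbind, lapply(seq_len(L), function(i) {
    s <- report$aggregate[[i]][keep[[i]]]
    data.frame(id = names(s), layer = layer_names[i], score = unname(s),
               color_weight = if (max(abs(s)) > 0) abs(s) / max(abs(s)) else 0,
               stringsAsFactors = FALSE)
  }))
  ft <- report$feature_type
  nodes <- rbind(nodes,
                 data.frame(id = names(ft), layer = "features", score = unname(ft),
                            color_weight = if (max(abs(ft)) > 0) abs(ft) / max(abs(ft)) else 0,
                            stringsAsFactors = FALSE),
                 data.frame(id = "output", layer = "output", score = sum(report$delta_t),
                            color_weight = 1, stringsAsFactors = FALSE))
  links <- list()
  # feature types -> retained genes, weighted by |gene-layer weights|
  W0 <- abs(model$layers[[1]]$W * model$layers[[1]]$M)
  fpg <- model$n_features_per_gene
  for (g in keep[[1]]) {
    gi <- match(g, model$gene_list)
    w <- W0[gi, fpg * (gi - 1) + seq_len(fpg)]
    links[[length(links) + 1]] <- data.frame(
      source = names(ft), target = g, value = unname(w), stringsAsFactors = FALSE)
  }
  for (i in 2:L) {
    Weff <- abs(model$layers[[i]]$W * model$layers[[i]]$M)
    sub <- Weff[keep[[i]], keep[[i - 1]], drop = FALSE]
    nz <- which(sub != 0, arr.ind = TRUE)
    if (nrow(nz))  # flow runs lower layer -> upper layer
      links[[length(links) + 1]] <- data.frame(
        source = colnames(sub)[nz[, 2]], target = rownames(sub)[nz[, 1]],
        value = sub[nz], stringsAsFactors = FALSE)
  }
  uL <- abs(model$heads[[L]]$u)
  names(uL) <- model$node_ids[[L]]
  links[[length(links) + 1]] <- data.frame(
    source = keep[[L]], target = "output", value = unname(uL[keep[[L]]]),
    stringsAsFactors = FALSE)
  links <- do.call(rbind, links)
  out <- list(nodes = nodes, links = links)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Write per-layer ranked node tables
#'
#' One TSV per layer: node id, display name (if provided), aggregate score,
#' rank.
#'
#' @param report an `attribution_report`.
#' @param dir output directory.
#' @param names_table optional data.frame `id`, `name` (see
#'   [parse_pathway_names()]).
#' @return `dir`, invisibly.
#' @export
write_rankings <- function(report, dir, names_table = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(report$aggregate)) {
    r <- rank_nodes(report, layer)
    r$name <- if (is.null(names_table)) r$node else
      names_table$name[match(r$node, names_table$id)]
    utils::write.table(r[, c("node", "name", "score", "rank")],
                       file.path(dir, paste0("ranking_", layer, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
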