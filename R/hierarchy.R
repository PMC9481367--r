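# Pathway hierarchy: Reactome-dialect readers, DAG layerization, and the
# selected sub-hierarchy that blueprints the sparse network.

#' Parse a pathway parent-child relation file
#'
#' Reads a two-column tab-separated file (parent-id TAB child-id, one edge per
#' line) in the dialect of `ReactomePathwaysRelation.txt` and keeps only edges
#' where both endpoints contain the species keyword (default `"HSA"`, the
#' human Reactome ids). Leaf ids that never appear as parents are still nodes.
#'
#' @param path path to the relation TSV.
#' @param species keyword that both endpoint ids must contain.
#' @return an object of class `pathway_dag`: `nodes` (character),
#'   `edges` (data.frame with columns `parent`, `child`), `species`.
#' @export
parse_relations <- function(path, species = "HSA") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(structure(list(nodes = character(),
                          edges = data.frame(parent = character(), child = character(),
                                             stringsAsFactors = FALSE),
                          species = species),
                     class = "pathway_dag"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    parse_error(sprintf("%s: line %d does not have exactly 2 tab-separated fields", path, bad[1]))
  parent <- vapply(parts, `[[`, "", 1)
  child <- vapply(parts, `[[`, "", 2)
  keep <- grepl(species, parent, fixed = TRUE) & grepl(species, child, fixed = TRUE)
  parent <- parent[keep]; child <- child[keep]
  if (any(parent == child))
    structural_error(sprintf("self-edge on node %s", parent[which(parent == child)[1]]))
  edges <- unique(data.frame(parent = parent, child = child, stringsAsFactors = FALSE))
  dag <- structure(list(nodes = sort(unique(c(edges$parent, edges$child))),
                        edges = edges, species = species),
                   class = "pathway_dag")
  check_acyclic(dag)  # raises a structural error naming an offending edge
  dag
}

# Kahn's algorithm; returns nodes in topological order or raises on a cycle.
topo_sort <- function(dag) {
  nodes <- dag$nodes
  if (length(nodes) == 0) return(character())
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(dag$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  kids <- split(dag$edges$child, dag$edges$parent)
  queue <- sort(names(indeg)[indeg == 0])
  out <- character(0)
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    out <- c(out, n)
    for (c in kids[[n]] %||% character()) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- sort(c(queue, c))
    }
  }
  if (length(out) < length(nodes)) {
    remaining <- setdiff(nodes, out)
    e <- dag$edges[dag$edges$parent %in% remaining & dag$edges$child %in% remaining, ]
    structural_error(sprintf("cycle detected involving edge %s -> %s",
                             e$parent[1], e$child[1]))
  }
  out
}

check_acyclic <- function(dag) invisible(topo_sort(dag))

#' Parse a GMT gene-set file
#'
#' Tab-separated lines: pathway id, description, then member gene symbols.
#' Duplicate gene symbols within a line are deduplicated; empty trailing
#' fields are dropped.
#'
#' @param path path to the GMT file.
#' @return class `pathway_gene_sets`: `entries`, a named list of
#'   `list(name = <description>, genes = <character vector>)`.
#' @export
parse_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  entries <- list()
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      parse_error(sprintf("%s: line %d has fewer than 3 fields (id, description, genes...)", path, ln))
    id <- fields[1]
    if (id %in% names(entries))
      parse_error(sprintf("%s: line %d duplicates pathway id %s", path, ln, id))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      parse_error(sprintf("%s: line %d has an empty gene set", path, ln))
    entries[[id]] <- list(name = fields[2], genes = genes)
  }
  structure(list(entries = entries), class = "pathway_gene_sets")
}

#' Parse a pathway-name file
#'
#' Three tab-separated columns: pathway id, display name, species.
#'
#' @param path path to the names TSV.
#' @return data.frame with columns `id`, `name`, `species`.
#' @export
parse_pathway_names <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    parse_error(sprintf("%s: line %d does not have 3 tab-separated fields", path, bad[1]))
  data.frame(id = vapply(parts, `[[`, "", 1),
             name = vapply(parts, `[[`, "", 2),
             species = vapply(parts, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Assign depth layers to a pathway DAG
#'
#' Roots (in-degree 0) form layer 1 and each node is placed at one plus the
#' length of its longest path from any root. An edge that skips layers
#' (child more than one layer below its parent) is realized by a chain of
#' pass-through copies of the child at the intermediate layers, so that every
#' retained edge connects adjacent layers. Copy ids are
#' `<original>::copy<layer>` and are recorded in `copies`.
#'
#' @param dag a `pathway_dag`.
#' @return class `layered_hierarchy`: `layers` (list of sorted node-id
#'   vectors, layer 1 = roots), `node_layer` (named integer), `copies`
#'   (named character, copy id -> original id), `edges` (data.frame of
#'   realized adjacent-layer edges `parent`, `child`).
#' @export
assign_layers <- function(dag) {
  if (length(dag$nodes) == 0) structural_error("cannot layerize an empty DAG")
  order <- topo_sort(dag)
  parents <- split(dag$edges$parent, dag$edges$child)
  depth <- setNames(integer(length(order)), order)
  for (n in order) {
    ps <- parents[[n]] %||% character()
    depth[n] <- if (length(ps) == 0) 1L else max(depth[ps]) + 1L
  }
  copies <- character(0)
  edges <- data.frame(parent = character(), child = character(), stringsAsFactors = FALSE)
  add_edge <- function(p, c) edges[nrow(edges) + 1L, ] <<- c(p, c)
  copy_id <- function(orig, layer) paste0(orig, "::copy", layer)
  for (r in seq_len(nrow(dag$edges))) {
    p <- dag$edges$parent[r]; c <- dag$edges$child[r]
    gap <- depth[c] - depth[p]
    if (gap == 1L) {
      add_edge(p, c)
    } else {
      # hoist copies of the child to the intermediate layers
      lvls <- (depth[p] + 1L):(depth[c] - 1L)
      ids <- copy_id(c, lvls)
      for (k in seq_along(lvls)) {
        if (!(ids[k] %in% names(copies))) {
          copies[ids[k]] <- c
          depth[ids[k]] <- lvls[k]
        }
      }
      chain <- c(p, ids, c)
      for (k in seq_len(length(chain) - 1L)) add_edge(chain[k], chain[k + 1L])
    }
  }
  edges <- unique(edges)
  layers <- lapply(seq_len(max(depth)), function(l) sort(names(depth)[depth == l]))
  stopifnot(all(depth[edges$child] == depth[edges$parent] + 1L))
  structure(list(layers = layers, node_layer = depth, copies = copies, edges = edges),
            class = "layered_hierarchy")
}

resolve_copy <- function(id, copies) {
  if (id %in% names(copies)) unname(copies[id]) else id
}

#' Select the k-layer sub-hierarchy and build its connectivity masks
#'
#' Keeps DAG layers `1..k` and reverses their order for the network: the
#' deepest retained DAG layer becomes pathway layer 1 (closest to the genes)
#' and the root layer becomes pathway layer k, because the outputs of child
#' pathways serve as inputs of their parents. Pathway-layer-1 nodes take
#' their gene sets from `gene_sets` (copies resolve to their original's
#' set); nodes without genes, and nodes left without any input after that,
#' are pruned bottom-up so that no mask row is all-zero.
#'
#' @param h a `layered_hierarchy`.
#' @param gene_sets a `pathway_gene_sets`.
#' @param k number of pathway layers to retain (default 4).
#' @return class `selected_hierarchy`: `pathway_layers` (named list
#'   `P1..Pk` of node ids in network order), `gene_list` (sorted union of
#'   pathway-layer-1 gene sets), `masks` (named list: `A` = gene->P1
#'   adjacency, then `M2..Mk` pathway masks; rows = target layer, columns =
#'   source layer), `copies`, `pruned`, `k`.
#' @export
select_sublayers <- function(h, gene_sets, k = 4L) {
  k <- as.integer(k)
  if (k < 1L || k > length(h$layers))
    config_error(sprintf("k = %d outside 1..%d (hierarchy depth)", k, length(h$layers)))
  # network layer j corresponds to DAG layer k - j + 1
  net_layers <- lapply(seq_len(k), function(j) h$layers[[k - j + 1L]])
  pruned <- character(0)

  p1 <- net_layers[[1L]]
  sets <- lapply(p1, function(id) {
    e <- gene_sets$entries[[resolve_copy(id, h$copies)]]
    if (is.null(e)) character() else sort(e$genes)
  })
  names(sets) <- p1
  empty <- p1[lengths(sets) == 0]
  if (length(empty)) {
    warning(sprintf("pruning %d pathway-layer-1 node(s) with no annotated genes", length(empty)))
    pruned <- c(pruned, empty)
    net_layers[[1L]] <- setdiff(p1, empty)
    sets <- sets[net_layers[[1L]]]
  }
  if (length(net_layers[[1L]]) == 0)
    structural_error("no pathway-layer-1 node has annotated genes")

  # bottom-up prune: a node above layer 1 must keep >= 1 retained child below
  for (j in 2:k) {
    if (k < 2) break
    below <- net_layers[[j - 1L]]
    keep <- vapply(net_layers[[j]], function(n) {
      any(h$edges$parent == n & h$edges$child %in% below)
    }, logical(1))
    if (any(!keep)) {
      pruned <- c(pruned, net_layers[[j]][!keep])
      net_layers[[j]] <- net_layers[[j]][keep]
    }
    if (length(net_layers[[j]]) == 0)
      structural_error(sprintf("pathway layer %d empty after pruning", j))
  }

  gene_list <- sort(unique(unlist(sets, use.names = FALSE)))
  a_links <- data.frame(
    r = rep(names(sets), lengths(sets)),
    c = unlist(sets, use.names = FALSE), stringsAsFactors = FALSE)
  masks <- list(A = mask_matrix(net_layers[[1L]], gene_list, a_links))
  if (k >= 2) for (j in 2:k) {
    e <- h$edges[h$edges$parent %in% net_layers[[j]] &
                 h$edges$child %in% net_layers[[j - 1L]], ]
    masks[[paste0("M", j)]] <- mask_matrix(net_layers[[j]], net_layers[[j - 1L]],
                                           data.frame(r = e$parent, c = e$child))
  }
  for (m in masks) stopifnot(all(Matrix::rowSums(m) > 0))
  used <- unlist(net_layers, use.names = FALSE)
  structure(list(pathway_layers = setNames(net_layers, paste0("P", seq_len(k))),
                 gene_list = gene_list, masks = masks,
                 copies = h$copies[names(h$copies) %in% used],
                 pruned = pruned, k = k),
            class = "selected_hierarchy")
}

#' Write a selected hierarchy to a directory
#'
#' Emits `layers.json` (ordered node ids per layer, gene list, copies) and
#' one sparse triplet file per mask (`A.tsv`, `M2.tsv`, ...; row-id TAB
#' col-id per nonzero). [read_hierarchy()] reproduces identical masks.
#'
#' @param sel a `selected_hierarchy`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_hierarchy <- function(sel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(k = sel$k, pathway_layers = sel$pathway_layers,
         gene_list = sel$gene_list, copies = as.list(sel$copies),
         pruned = sel$pruned),
    file.path(dir, "layers.json"), auto_unbox = FALSE, pretty = TRUE)
  for (nm in names(sel$masks))
    write_mask_triplets(sel$masks[[nm]], file.path(dir, paste0(nm, ".tsv")))
  invisible(dir)
}

#' Read a selected hierarchy written by [write_hierarchy()]
#' @param dir directory containing `layers.json` and the mask triplet files.
#' @return a `selected_hierarchy`.
#' @export
read_hierarchy <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "layers.json"), simplifyVector = TRUE)
  k <- as.integer(meta$k)
  layers <- lapply(meta$pathway_layers, as.character)
  gene_list <- as.character(meta$gene_list)
  masks <- list(A = read_mask_triplets(file.path(dir, "A.tsv"), layers[[1]], gene_list))
  if (k >= 2) for (j in 2:k)
    masks[[paste0("M", j)]] <- read_mask_triplets(file.path(dir, paste0("M", j, ".tsv")),
                                                  layers[[j]], layers[[j - 1L]])
  copies <- unlist(meta$copies) %||% character(0)
  if (length(copies) == 0) copies <- character(0)
  structure(list(pathway_layers = setNames(layers, paste0("P", seq_len(k))),
                 gene_list = gene_list, masks = masks, copies = copies,
                 pruned = as.character(meta$pruned %||% character(0)), k = k),
            class = "selected_hierarchy")
}

#' @export
print.selected_hierarchy <- function(x, ...) {
  cat(sprintf("Selected pathway hierarchy: %d pathway layers, %d genes\n",
              x$k, length(x$gene_list)))
  for (j in seq_len(x$k))
    cat(sprintf("  P%d: %d nodes, mask nnz %d\n", j, length(x$pathway_layers[[j]]),
                Matrix::nnzero(x$masks[[if (j == 1) "A" else paste0("M", j)]])))
  invisible(x)
}
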