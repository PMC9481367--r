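# Synthetic fixtures: a toy pathway hierarchy written in the Reactome file
# dialects and a cohort with planted gene-outcome signal, so that the whole
# pipeline is testable without any download.

#' Describe a synthetic fixture
#'
#' The manifest fully determines the generated hierarchy and cohort given its
#' seed. Defaults describe a small but structurally complete world: a
#' two-root, depth-5, binary-branching pathway tree (62 pathways) with a few
#' level-skipping cross edges (these exercise the copy-chain logic), five
#' genes per leaf pathway drawn from a 100-gene universe, and a cohort whose
#' outcome follows a logistic model over a handful of recurrently altered
#' driver genes. Background alteration rates (mutation 0.05, amplification /
#' deletion 0.02) are order-of-magnitude realistic for exome-scale binary
#' calls; planted driver genes are altered at elevated rates (mutation 0.30,
#' CNV 0.15), the frequency scale of TP53-class drivers. The class balance
#' defaults to 80% poor-prognosis (non-LTS), matching a heavily imbalanced
#' survival cohort.
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param roots,depth,branching,genes_per_leaf,gene_pool hierarchy shape.
#' @param n_cross_edges number of level-skipping edges added to the tree.
#' @param n_samples labeled cohort size.
#' @param class_balance target fraction of positive (non-LTS, label 1) samples.
#' @param censor_frac extra samples, as a fraction of `n_samples`, censored
#'   before the survival horizon (alive, < 60 months); these must be excluded
#'   by labeling.
#' @param n_signal_genes number of planted driver genes.
#' @param effect_mut,effect_amp,effect_del log-odds increments per altered
#'   feature of a planted gene.
#' @param rate_mut,rate_amp,rate_del background per-gene alteration rates.
#' @param signal_rate_mut,signal_rate_amp,signal_rate_del alteration rates of
#'   the planted genes.
#' @return class `fixture_manifest` (a list of the above).
#' @export
fixture_manifest <- function(seed = 1L,
                             roots = 2L, depth = 5L, branching = 2L,
                             genes_per_leaf = 5L, gene_pool = 100L,
                             n_cross_edges = 3L,
                             n_samples = 1000L, class_balance = 0.8,
                             censor_frac = 0.1,
                             n_signal_genes = 3L,
                             effect_mut = 3, effect_amp = 2, effect_del = 2,
                             rate_mut = 0.05, rate_amp = 0.02, rate_del = 0.02,
                             signal_rate_mut = 0.30, signal_rate_amp = 0.15,
                             signal_rate_del = 0.15) {
  m <- as.list(environment())
  rates <- unlist(m[grep("rate|balance|frac", names(m))])
  if (any(rates < 0 | rates > 1)) config_error("all rates/fractions must be in [0,1]")
  n_nodes <- roots * (branching^depth - 1) / (branching - 1)
  if (n_nodes > 1e4) config_error(sprintf("hierarchy would have %d nodes; fixtures stay tiny", n_nodes))
  if (depth < 5) config_error("depth must be >= 5 so a 4-pathway-layer selection plus leaves is exercised")
  structure(m, class = "fixture_manifest")
}

#' Generate a toy pathway hierarchy in the Reactome dialects
#'
#' Writes a rooted tree plus level-skipping cross edges as a GMT file (every
#' pathway annotated with the union of its descendant leaves' genes), a
#' two-column parent-child relation TSV (including two non-human decoy edges
#' that the species filter must drop) and a three-column names TSV.
#'
#' @param manifest a [fixture_manifest()].
#' @param out_dir directory to write `pathways.gmt`, `relations.tsv`,
#'   `names.tsv` into; `NULL` for in-memory only.
#' @return list with the ground truth: `pathways` (data.frame id/depth),
#'   `edges` (tree + cross edges), `cross_edges`, `gene_sets` (named list),
#'   `gene_universe`, and `files` (paths, if written).
#' @export
generate_hierarchy <- function(manifest, out_dir = NULL) {
  set.seed(manifest$seed)
  b <- manifest$branching
  # breadth-first ids per depth level
  ids <- list()
  counter <- 0L
  new_ids <- function(n) {
    out <- sprintf("R-HSA-%06d", counter + seq_len(n))
    counter <<- counter + n
    out
  }
  ids[[1]] <- new_ids(manifest$roots)
  edges <- data.frame(parent = character(), child = character(), stringsAsFactors = FALSE)
  for (d in 2:manifest$depth) {
    ids[[d]] <- new_ids(length(ids[[d - 1]]) * b)
    edges <- rbind(edges, data.frame(parent = rep(ids[[d - 1]], each = b),
                                     child = ids[[d]], stringsAsFactors = FALSE))
  }
  depth_of <- setNames(rep(seq_along(ids), lengths(ids)), unlist(ids))

  # level-skipping cross edges with distinct children (one copy chain each)
  cross <- data.frame(parent = character(), child = character(), stringsAsFactors = FALSE)
  if (manifest$n_cross_edges > 0) {
    used_children <- character(0)
    while (nrow(cross) < manifest$n_cross_edges) {
      dp <- sample.int(manifest$depth - 2L, 1L)
      cand_d <- (dp + 2L):manifest$depth
      dc <- cand_d[sample.int(length(cand_d), 1L)]
      p <- ids[[dp]][sample.int(length(ids[[dp]]), 1L)]
      cand_c <- setdiff(ids[[dc]], used_children)
      c <- cand_c[sample.int(length(cand_c), 1L)]
      used_children <- c(used_children, c)
      cross <- rbind(cross, data.frame(parent = p, child = c, stringsAsFactors = FALSE))
    }
  }
  all_edges <- rbind(edges, cross)

  genes <- sprintf("G%04d", seq_len(manifest$gene_pool))
  leaves <- ids[[manifest$depth]]
  leaf_sets <- setNames(lapply(leaves, function(.) sort(sample(genes, manifest$genes_per_leaf))),
                        leaves)
  # gene set of an internal pathway = union over its descendant leaves (tree edges)
  kids <- split(edges$child, edges$parent)
  gene_sets <- leaf_sets
  for (d in rev(seq_len(manifest$depth - 1L))) {
    for (n in ids[[d]])
      gene_sets[[n]] <- sort(unique(unlist(gene_sets[kids[[n]]], use.names = FALSE)))
  }
  gene_sets <- gene_sets[order(names(gene_sets))]

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gmt <- file.path(out_dir, "pathways.gmt")
    writeLines(vapply(names(gene_sets), function(id)
      paste(c(id, paste0("Synthetic pathway ", id), gene_sets[[id]]), collapse = "\t"),
      ""), gmt)
    rel <- file.path(out_dir, "relations.tsv")
    decoy <- data.frame(parent = c("R-MMU-000001", "R-MMU-000001"),
                        child = c("R-MMU-000002", "R-MMU-000003"),
                        stringsAsFactors = FALSE)
    rel_edges <- rbind(all_edges, decoy)
    writeLines(paste(rel_edges$parent, rel_edges$child, sep = "\t"), rel)
    nm <- file.path(out_dir, "names.tsv")
    writeLines(paste(names(gene_sets), paste0("Synthetic pathway ", names(gene_sets)),
                     "Homo sapiens", sep = "\t"), nm)
    files <- list(gmt = gmt, relations = rel, names = nm)
  }
  list(pathways = data.frame(id = names(depth_of), depth = unname(depth_of),
                             stringsAsFactors = FALSE),
       edges = all_edges, tree_edges = edges, cross_edges = cross,
       gene_sets = gene_sets, gene_universe = genes, files = files)
}

#' Generate a synthetic cohort with planted gene-outcome signal
#'
#' Per sample, background alterations are drawn independently per gene at the
#' manifest rates; the planted driver genes are altered at their elevated
#' rates. The binary outcome follows a logistic model whose logit is
#' intercept + sum(effect x feature) over the planted genes; the intercept is
#' solved by bisection so the expected positive rate equals the manifest's
#' class balance. Survival months are synthesized consistently with the
#' label (label 1: died before 60 months; label 0: lived past 60 months),
#' plus a block of censored samples (alive, < 60 months) that labeling must
#' exclude.
#'
#' @param manifest a [fixture_manifest()].
#' @param hierarchy result of [generate_hierarchy()] (supplies the gene universe).
#' @param out_dir directory to write `mutations.tsv`, `cnv.tsv`,
#'   `clinical.csv`, `truth.json` into; `NULL` for in-memory only.
#' @return list: `mutation` and `cnv` (gene x sample matrices), `clinical`
#'   (data.frame sample/months/status), `labels` (named 0/1 vector over the
#'   labelable samples), `truth` (signal genes, effects, intercept), `files`.
#' @export
generate_cohort <- function(manifest, hierarchy, out_dir = NULL) {
  set.seed(manifest$seed + 1L)
  genes <- hierarchy$gene_universe
  G <- length(genes)
  n_cens <- round(manifest$censor_frac * manifest$n_samples)
  n <- manifest$n_samples + n_cens
  samples <- sprintf("S%04d", seq_len(n))

  # plant signal only in genes covered by some leaf gene set: a gene absent
  # from the hierarchy cannot enter the network and tests nothing
  covered <- sort(unique(unlist(hierarchy$gene_sets, use.names = FALSE)))
  signal <- sort(sample(covered, manifest$n_signal_genes))
  rmut <- ifelse(genes %in% signal, manifest$signal_rate_mut, manifest$rate_mut)
  ramp <- ifelse(genes %in% signal, manifest$signal_rate_amp, manifest$rate_amp)
  rdel <- ifelse(genes %in% signal, manifest$signal_rate_del, manifest$rate_del)

  mutation <- matrix(rbinom(G * n, 1L, rep(rmut, times = n)), G, n,
                     dimnames = list(genes, samples))
  # CNV on the five-level scale: amp (+2) / del (-2) draws are exclusive;
  # low-level gains/losses (+1/-1) occur at a fixed background 5% each.
  u <- matrix(runif(G * n), G, n)
  cnv <- matrix(0L, G, n, dimnames = list(genes, samples))
  pa <- rep(ramp, times = n); pd <- rep(rdel, times = n)
  cnv[u < pa] <- 2L
  cnv[u >= pa & u < pa + pd] <- -2L
  rest <- u >= pa + pd
  v <- matrix(runif(G * n), G, n)
  cnv[rest & v < 0.05] <- 1L
  cnv[rest & v >= 0.05 & v < 0.10] <- -1L

  eff <- manifest$effect_mut * mutation[signal, , drop = FALSE] +
    manifest$effect_amp * (cnv[signal, , drop = FALSE] == 2L) +
    manifest$effect_del * (cnv[signal, , drop = FALSE] == -2L)
  score <- colSums(eff)
  f <- function(b0) mean(plogis(b0 + score)) - manifest$class_balance
  intercept <- stats::uniroot(f, c(-30, 30))$root
  y <- rbinom(n, 1L, plogis(intercept + score))

  censored <- samples[seq_len(n_cens) + manifest$n_samples]
  months <- numeric(n); status <- character(n)
  pos <- y == 1L & !(samples %in% censored)
  neg <- y == 0L & !(samples %in% censored)
  months[pos] <- runif(sum(pos), 1, 59); status[pos] <- "dead"
  months[neg] <- runif(sum(neg), 61, 120)
  status[neg] <- ifelse(runif(sum(neg)) < 0.7, "alive", "dead")  # LTS regardless of status
  cens_idx <- samples %in% censored
  months[cens_idx] <- runif(sum(cens_idx), 1, 59); status[cens_idx] <- "alive"
  clinical <- data.frame(sample = samples, months = round(months, 1),
                         status = status, stringsAsFactors = FALSE)
  labels <- setNames(y[!cens_idx], samples[!cens_idx])

  truth <- list(signal_genes = signal, intercept = intercept,
                effects = c(mut = manifest$effect_mut, amp = manifest$effect_amp,
                            del = manifest$effect_del),
                class_balance = manifest$class_balance,
                censored = censored)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(mutation = file.path(out_dir, "mutations.tsv"),
                  cnv = file.path(out_dir, "cnv.tsv"),
                  clinical = file.path(out_dir, "clinical.csv"),
                  truth = file.path(out_dir, "truth.json"))
    write_gene_sample_matrix(mutation, files$mutation)
    write_gene_sample_matrix(cnv, files$cnv)
    utils::write.csv(clinical, files$clinical, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA)
  }
  list(mutation = mutation, cnv = cnv, clinical = clinical, labels = labels,
       truth = truth, files = files)
}

#' Generate the full fixture set on disk
#'
#' Convenience wrapper: hierarchy files plus cohort files plus the manifest
#' as JSON ground truth, all under one directory.
#'
#' @param manifest a [fixture_manifest()].
#' @param out_dir output directory.
#' @return list with `hierarchy` and `cohort` ground-truth objects.
#' @export
simulate_fixtures <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hier <- generate_hierarchy(manifest, out_dir)
  cohort <- generate_cohort(manifest, hier, out_dir)
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(hierarchy = hier, cohort = cohort))
}
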