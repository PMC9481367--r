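# Cohort features: mutation/CNV/clinical readers, binary encoding, survival
# labeling, feature assembly and the stratified train/validation/test split.

#' Read a gene x sample matrix from TSV
#'
#' First column = gene symbol, remaining columns = samples (header row).
#' @param path path to the TSV.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_gene_sample_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

write_gene_sample_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read MAF-lite mutation records
#'
#' Tab-separated with a header containing at least `sample` and `gene`
#' columns (a `variant_class` column is carried through if present).
#' @param path path to the TSV.
#' @return data.frame of records.
#' @export
read_maf_lite <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("sample", "gene") %in% names(df)))
    parse_error(sprintf("%s: MAF-lite needs 'sample' and 'gene' columns", path))
  df
}

#' Read a clinical survival table
#'
#' CSV with columns `sample`, `months`, `status`.
#' @param path path to the CSV.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("sample", "months", "status") %in% names(df)))
    parse_error(sprintf("%s: clinical table needs sample, months, status columns", path))
  df
}

#' Binarize mutation data per gene and sample
#'
#' Entry is 1 iff the sample has at least one mutation record for the gene.
#' Accepts either MAF-lite records (data.frame with `sample`, `gene`) or a
#' gene x sample count matrix. Gene symbols not in `genes` are dropped with a
#' logged count.
#'
#' @param mutations MAF-lite data.frame or numeric gene x sample matrix.
#' @param genes ordered gene symbols (the hierarchy gene list).
#' @param samples ordered sample ids.
#' @return binary gene x sample matrix over exactly `genes` x `samples`.
#' @export
binarize_mutations <- function(mutations, genes, samples) {
  out <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (is.data.frame(mutations)) {
    rec <- mutations[mutations$sample %in% samples, , drop = FALSE]
    unmatched <- setdiff(unique(rec$gene), genes)
    if (length(unmatched))
      message(sprintf("binarize_mutations: dropping %d gene symbol(s) not in the hierarchy gene list",
                      length(unmatched)))
    rec <- rec[rec$gene %in% genes, , drop = FALSE]
    if (nrow(rec)) out[cbind(rec$gene, rec$sample)] <- 1
  } else {
    m <- as.matrix(mutations)
    unmatched <- setdiff(rownames(m), genes)
    if (length(unmatched))
      message(sprintf("binarize_mutations: dropping %d gene symbol(s) not in the hierarchy gene list",
                      length(unmatched)))
    common_g <- intersect(genes, rownames(m))
    common_s <- intersect(samples, colnames(m))
    out[common_g, common_s] <- (m[common_g, common_s, drop = FALSE] >= 1) * 1
  }
  out
}

#' Encode GISTIC-style CNV calls as amplification / deletion indicators
#'
#' Deep deletion (-2) and high-level amplification (+2) become 1 in the
#' respective output; -1, 0 and 1 yield (0, 0). Values outside the
#' five-level scale raise a validation error naming the offending
#' gene/sample.
#'
#' @param cnv gene x sample matrix with values in \{-2,-1,0,1,2\}.
#' @return list with binary matrices `amp` and `del` of the same shape.
#' @export
encode_cnv <- function(cnv) {
  cnv <- as.matrix(cnv)
  bad <- which(matrix(!(cnv %in% c(-2, -1, 0, 1, 2)), nrow(cnv)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    validation_error(sprintf("CNV value %s for gene %s, sample %s is not on the -2..2 scale",
                             format(cnv[bad[1, , drop = FALSE]]),
                             rownames(cnv)[bad[1, 1]] %||% bad[1, 1],
                             colnames(cnv)[bad[1, 2]] %||% bad[1, 2]))
  list(amp = (cnv == 2) * 1, del = (cnv == -2) * 1)
}

#' Label samples for long-term vs short-term survival
#'
#' Long-term survival (LTS, label 0): more than `horizon_months` months,
#' independent of vital status. Short-term (non-LTS, label 1 — the positive,
#' poor-prognosis class): died before the horizon. Samples censored before
#' the horizon (alive, months < horizon) fit neither definition and are
#' excluded. Exactly-at-horizon months are assigned LTS.
#'
#' @param clinical data.frame with `sample`, `months`, `status` (alive/dead,
#'   case-insensitive).
#' @param horizon_months survival horizon (default 60).
#' @return named integer vector of labels (0 = LTS, 1 = non-LTS) over the
#'   labelable samples; excluded sample ids in `attr(, "excluded")`.
#' @export
label_survival <- function(clinical, horizon_months = 60) {
  months <- suppressWarnings(as.numeric(clinical$months))
  status <- tolower(trimws(as.character(clinical$status)))
  id <- as.character(clinical$sample)
  invalid <- is.na(months) | !(status %in% c("alive", "dead"))
  if (any(invalid))
    warning(sprintf("excluding %d sample(s) with missing months or status", sum(invalid)))
  if (any(months < 0, na.rm = TRUE)) validation_error("negative survival months")
  lab <- rep(NA_integer_, nrow(clinical))
  lab[!invalid & months >= horizon_months] <- 0L
  lab[!invalid & months < horizon_months & status == "dead"] <- 1L
  excluded <- id[is.na(lab)]
  out <- setNames(lab[!is.na(lab)], id[!is.na(lab)])
  attr(out, "excluded") <- excluded
  out
}

#' Assemble the model feature matrix
#'
#' Interleaves the three binary per-gene indicator matrices into the network
#' input layout: for each gene in `gene_list` order, a (mutation,
#' amplification, deletion) column block. Samples missing from a matrix are
#' imputed as all-zero with a message.
#'
#' @param mut,amp,del binary gene x sample matrices.
#' @param gene_list ordered gene symbols (the hierarchy gene list).
#' @param samples ordered sample ids.
#' @return samples x (3 * genes) binary matrix; column names
#'   `<gene>_mut`, `<gene>_amp`, `<gene>_del`; `attr(, "gene_list")` set.
#' @export
assemble_features <- function(mut, amp, del, gene_list, samples) {
  if (length(gene_list) == 0) config_error("empty gene_list")
  if (!identical(dim(amp), dim(del)) || !identical(rownames(amp), rownames(del)))
    validation_error("amp and del matrices must share the same gene/sample index")
  pick <- function(m, what) {
    missing_s <- setdiff(samples, colnames(m))
    if (length(missing_s))
      message(sprintf("assemble_features: imputing %d sample(s) absent from the %s matrix as all-zero",
                      length(missing_s), what))
    missing_g <- setdiff(gene_list, rownames(m))
    if (length(missing_g))
      message(sprintf("assemble_features: imputing %d gene(s) absent from the %s matrix as all-zero",
                      length(missing_g), what))
    out <- matrix(0, length(gene_list), length(samples),
                  dimnames = list(gene_list, samples))
    cg <- intersect(gene_list, rownames(m)); cs <- intersect(samples, colnames(m))
    out[cg, cs] <- m[cg, cs, drop = FALSE]
    out
  }
  mut <- pick(mut, "mutation"); amp <- pick(amp, "amplification"); del <- pick(del, "deletion")
  if (!all(c(mut, amp, del) %in% c(0, 1)))
    validation_error("feature values must be binary")
  G <- length(gene_list)
  X <- matrix(0, length(samples), 3L * G,
              dimnames = list(samples, paste0(rep(gene_list, each = 3),
                                              c("_mut", "_amp", "_del"))))
  X[, seq(1, 3 * G, by = 3)] <- t(mut)
  X[, seq(2, 3 * G, by = 3)] <- t(amp)
  X[, seq(3, 3 * G, by = 3)] <- t(del)
  attr(X, "gene_list") <- gene_list
  X
}

#' Stratified train/validation/test split
#'
#' Global validation and test sizes are `floor(fraction * N)` with the
#' remainder assigned to training; within that, per-class counts follow
#' largest-remainder proportional allocation, so class proportions are
#' preserved within one sample per stratum. Deterministic given the seed.
#'
#' @param labels named 0/1 vector (see [label_survival()]).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return list with `train`, `validation`, `test` sample-id vectors plus the
#'   fractions and seed.
#' @export
split_dataset <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  N <- length(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) config_error("need at least one sample of each class")
  if (any(table(labels) < 3))
    warning("a class has fewer than 3 samples; stratification degenerates")
  n_val <- floor(fractions[2] * N)
  n_test <- floor(fractions[3] * N)
  allocate <- function(total) {
    quota <- total * as.numeric(table(labels)[as.character(classes)]) / N
    base <- floor(quota)
    rem <- total - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    setNames(base, classes)
  }
  a_val <- allocate(n_val); a_test <- allocate(n_test)
  set.seed(seed)
  val <- test <- train <- character(0)
  for (cl in classes) {
    ids <- sample(names(labels)[labels == cl])
    cl <- as.character(cl)
    val <- c(val, ids[seq_len(a_val[cl])])
    test <- c(test, ids[a_val[cl] + seq_len(a_test[cl])])
    used <- a_val[cl] + a_test[cl]
    if (used < length(ids)) train <- c(train, ids[(used + 1):length(ids)])
  }
  list(train = sort(train), validation = sort(val), test = sort(test),
       fractions = fractions, seed = seed)
}

#' One-call preparation from raw inputs to model-ready data
#'
#' Convenience composition of [binarize_mutations()], [encode_cnv()],
#' [label_survival()], [assemble_features()] and [split_dataset()] against a
#' selected hierarchy's gene list.
#'
#' @param mutations MAF-lite data.frame or gene x sample matrix.
#' @param cnv gene x sample matrix on the -2..2 scale.
#' @param clinical data.frame sample/months/status.
#' @param hierarchy a `selected_hierarchy`.
#' @param horizon_months survival horizon (default 60).
#' @param fractions,seed passed to [split_dataset()].
#' @return list: `features` (labeled samples x 3 genes), `labels`, `split`.
#' @export
prepare_cohort <- function(mutations, cnv, clinical, hierarchy,
                           horizon_months = 60, fractions = c(0.8, 0.1, 0.1),
                           seed = 1L) {
  labels <- label_survival(clinical, horizon_months)
  samples <- names(labels)
  mut <- binarize_mutations(mutations, hierarchy$gene_list, samples)
  enc <- encode_cnv(cnv)
  X <- assemble_features(mut, enc$amp, enc$del, hierarchy$gene_list, samples)
  split <- split_dataset(labels, fractions, seed)
  list(features = X, labels = labels, split = split)
}
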