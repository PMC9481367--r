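# Feature encoding, survival labeling, assembly, splitting.

test_that("binarize_mutations applies the at-least-one rule from records and matrices", {
  rec <- data.frame(sample = c("s1", "s1"), gene = c("TP53", "TP53"))
  m <- binarize_mutations(rec, c("TP53", "JAK2"), "s1")
  expect_equal(m[, "s1"], c(TP53 = 1, JAK2 = 0))

  empty <- binarize_mutations(data.frame(sample = character(), gene = character()),
                              c("TP53", "JAK2"), c("s1", "s2"))
  expect_true(all(empty == 0))

  counts <- matrix(c(0, 3), 2, 1, dimnames = list(c("TP53", "JAK2"), "s1"))
  expect_equal(binarize_mutations(counts, c("TP53", "JAK2"), "s1")[, 1],
               c(TP53 = 0, JAK2 = 1))
  expect_message(binarize_mutations(data.frame(sample = "s1", gene = "NOPE"),
                                    "TP53", "s1"), regexp = "dropping")
})

test_that("binarized fixture matrix equals the generator's planted truth", {
  f <- small_fixture()
  genes <- rownames(f$fx$cohort$mutation)
  samples <- colnames(f$fx$cohort$mutation)
  m <- binarize_mutations(f$fx$cohort$mutation, genes, samples)
  expect_equal(unname(m), unname((f$fx$cohort$mutation >= 1) * 1))
})

test_that("encode_cnv keeps only extreme calls and validates the scale", {
  cnv <- matrix(c(2, -2, 1, -1, 0, 2), 2, 3,
                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  enc <- encode_cnv(cnv)
  expect_equal(enc$amp["g1", ], c(s1 = 1, s2 = 0, s3 = 0))
  expect_equal(enc$del["g2", ], c(s1 = 1, s2 = 0, s3 = 0))
  expect_equal(enc$amp["g2", "s3"], 1)
  expect_true(all(enc$amp[cnv %in% c(-1, 0, 1)] == 0))
  expect_true(all(enc$del[cnv %in% c(-1, 0, 1)] == 0))

  zeros <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  encz <- encode_cnv(zeros)
  expect_true(all(encz$amp == 0) && all(encz$del == 0))

  bad <- cnv; bad["g1", "s2"] <- 3
  expect_error(encode_cnv(bad), regexp = "g1.*s2", class = "pathnn_validation_error")
})

test_that("label_survival implements the 60-month horizon with censor exclusion", {
  clin <- data.frame(sample = c("a", "b", "c", "d", "e"),
                     months = c(72, 40, 40, 60, NA),
                     status = c("dead", "dead", "alive", "alive", "dead"))
  lab <- suppressWarnings(label_survival(clin))
  expect_equal(lab[["a"]], 0)                 # > horizon, independent of status
  expect_equal(lab[["b"]], 1)                 # died before horizon
  expect_false("c" %in% names(lab))           # censored before horizon
  expect_equal(lab[["d"]], 0)                 # boundary goes to LTS
  expect_setequal(attr(lab, "excluded"), c("c", "e"))
  # partition: no sample is both labeled and excluded
  expect_length(intersect(names(lab), attr(lab, "excluded")), 0)
  # configurable horizon
  lab90 <- label_survival(data.frame(sample = "a", months = 72, status = "dead"),
                          horizon_months = 90)
  expect_equal(lab90[["a"]], 1)
})

test_that("assemble_features interleaves per-gene blocks and validates inputs", {
  gs <- c("gA", "gB")
  mk <- function(v) matrix(v, 2, 1, dimnames = list(gs, "s1"))
  X <- assemble_features(mk(c(1, 0)), mk(c(0, 1)), mk(c(0, 0)), gs, "s1")
  expect_equal(unname(X["s1", ]), c(1, 0, 0, 0, 1, 0))
  expect_equal(colnames(X), c("gA_mut", "gA_amp", "gA_del", "gB_mut", "gB_amp", "gB_del"))
  expect_equal(ncol(X), 3 * length(gs))
  expect_error(assemble_features(mk(0), mk(0), mk(0), character(0), "s1"),
               class = "pathnn_config_error")
  # absent samples imputed as zero, with a message
  expect_message(X2 <- assemble_features(mk(c(1, 0)), mk(c(0, 1)), mk(c(0, 0)),
                                         gs, c("s1", "s2")), regexp = "imputing")
  expect_true(all(X2["s2", ] == 0))
})

test_that("split_dataset follows floor-plus-remainder sizing with stratification", {
  lab <- setNames(rep(c(0, 1), each = 5), paste0("s", 1:10))
  sp <- split_dataset(lab, seed = 3)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 8L, validation = 1L, test = 1L))
  expect_setequal(c(sp$train, sp$validation, sp$test), names(lab))

  # N = 225 with the paper-shaped 183/42 imbalance: 181/22/22
  lab225 <- setNames(c(rep(1, 183), rep(0, 42)), sprintf("t%03d", 1:225))
  sp225 <- split_dataset(lab225, seed = 1)
  expect_equal(lengths(sp225[c("train", "validation", "test")]),
               c(train = 181L, validation = 22L, test = 22L))
  # stratified: class proportion preserved within 1 sample per partition
  for (part in c("validation", "test"))
    expect_equal(sum(lab225[sp225[[part]]] == 0), 4)

  expect_identical(split_dataset(lab225, seed = 9), split_dataset(lab225, seed = 9))
  expect_false(identical(split_dataset(lab225, seed = 9)$train,
                         split_dataset(lab225, seed = 10)$train))
  expect_error(split_dataset(setNames(rep(1, 5), paste0("s", 1:5))),
               class = "pathnn_config_error")
})

test_that("prepared fixture features are binary with the right shape and labels", {
  f <- small_fixture()
  X <- f$prep$features
  expect_true(all(X %in% c(0, 1)))
  expect_equal(ncol(X), 3 * length(f$sel$gene_list))
  expect_setequal(rownames(X), names(f$prep$labels))
  # censored fixture samples are excluded from the labeled cohort
  expect_length(intersect(names(f$prep$labels), f$fx$cohort$truth$censored), 0)
  # labels agree with the generator's planted outcome
  expect_equal(as.numeric(f$prep$labels),
               as.numeric(f$fx$cohort$labels[names(f$prep$labels)]))
})

test_that("file readers round-trip the fixture inputs", {
  f <- small_fixture()
  mut <- read_gene_sample_matrix(file.path(f$dir, "mutations.tsv"))
  expect_equal(mut, f$fx$cohort$mutation)
  clin <- read_clinical(file.path(f$dir, "clinical.csv"))
  expect_equal(clin$sample, f$fx$cohort$clinical$sample)
  maf <- tempfile()
  writeLines(c("sample\tgene\tvariant_class", "s1\tTP53\tMissense_Mutation"), maf)
  expect_equal(read_maf_lite(maf)$gene, "TP53")
})
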