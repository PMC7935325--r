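write_tsv_fixture <- function(lines, env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(lines, f)
  f
}

meta_fixture <- function(ids, groups, env = parent.frame()) {
  write_tsv_fixture(c("sample_id\tgroup",
                      paste(ids, groups, sep = "\t")), env = env)
}

test_that("expression TSV write/read round trip is exact", {
  m <- toy_matrix(matrix(c(pi, exp(1), sqrt(2), 1/3, 2/7, 1e-8), 3, 2),
                  groups = c("control", "case"))
  dir <- withr::local_tempdir()
  write_expression(m, file.path(dir, "e.tsv"), file.path(dir, "m.tsv"))
  m2 <- read_expression(file.path(dir, "e.tsv"), file.path(dir, "m.tsv"))
  expect_identical(dim(m2$values), dim(m$values))
  expect_equal(m2$values, m$values, tolerance = 0)
  expect_identical(m2$group, m$group)
})

test_that("duplicate gene IDs are reported by name", {
  e <- write_tsv_fixture(c("gene_id\ts1\ts2",
                           "LCK\t1\t2", "LCK\t3\t4", "CD2\t5\t6"))
  md <- meta_fixture(c("s1", "s2"), c("control", "case"))
  expect_error(read_expression(e, md), "LCK")
})

test_that("a sample missing from the metadata is an error", {
  e <- write_tsv_fixture(c("gene_id\ts1\ts2", "A\t1\t2"))
  md <- meta_fixture("s1", "control")
  expect_error(read_expression(e, md), "s2")
})

test_that("genes with missing cells are dropped with a warning", {
  e <- write_tsv_fixture(c("gene_id\ts1\ts2",
                           "A\t1\t2", "B\tNA\t4", "C\t5\t6"))
  md <- meta_fixture(c("s1", "s2"), c("control", "case"))
  expect_warning(m <- read_expression(e, md), "missing")
  expect_identical(gene_ids(m), c("A", "C"))
})

test_that("log2_transform computes log2 and rejects nonpositive values", {
  m <- toy_matrix(cbind(c(8, 2), c(1, 4), c(32, 16)),
                  groups = c("control", "control", "case"))
  out <- log2_transform(m)
  expect_equal(out$values[1, ], c(s01 = 3, s02 = 0, s03 = 5))
  expect_equal(unname(out$values[, 3]), c(5, 4))
  m$values[2, 1] <- -1
  expect_error(log2_transform(m), "g02.*s01")
})

test_that("quantile normalization matches the mean-of-sorted-columns rule", {
  m <- toy_matrix(cbind(c(2, 4, 6), c(9, 1, 5)), groups = c("control", "case"))
  out <- quantile_normalize(m)
  expect_equal(unname(out$values[, 1]), c(1.5, 4.5, 7.5))
  expect_equal(unname(out$values[, 2]), c(7.5, 1.5, 4.5))
  # all columns share the same sorted vector and hence the same mean
  expect_equal(apply(out$values, 2, sort), cbind(s01 = c(1.5, 4.5, 7.5),
                                                 s02 = c(1.5, 4.5, 7.5)))
  expect_equal(colMeans(out$values)[[1]], colMeans(out$values)[[2]])
})

test_that("quantile normalization is idempotent and keeps fixed points", {
  set.seed(42)
  m <- toy_matrix(matrix(rnorm(60, 8), 10, 6),
                  groups = rep(c("control", "case"), each = 3))
  once <- quantile_normalize(m)
  twice <- quantile_normalize(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  same <- toy_matrix(cbind(c(1, 5, 3), c(1, 5, 3)),
                     groups = c("control", "case"))
  expect_equal(quantile_normalize(same)$values, same$values)
  single <- toy_matrix(matrix(1:3, 3, 1), groups = "control")
  expect_error(quantile_normalize(single), ">=2 samples")
})

test_that("collapse_probes keeps the max-mean probe per gene", {
  m <- toy_matrix(rbind(c(5, 5), c(7, 7), c(1, 3)),
                  groups = c("control", "case"),
                  genes = c("p1", "p2", "p3"))
  out <- collapse_probes(m, c(p1 = "G", p2 = "G"))
  expect_identical(gene_ids(out), "G")
  expect_equal(unname(out$values[1, ]), c(7, 7))  # p2 has the higher mean
  # one-to-one mapping relabels without touching values
  out2 <- collapse_probes(m, c(p1 = "A", p2 = "B", p3 = "C"))
  expect_identical(gene_ids(out2), c("A", "B", "C"))
  expect_equal(unname(out2$values), unname(m$values))
  # unmapped probes are dropped; gene count equals distinct mapped genes
  out3 <- collapse_probes(m, c(p1 = "G", p2 = "G", p3 = "H"))
  expect_setequal(gene_ids(out3), c("G", "H"))
  expect_error(collapse_probes(m, character(0)), "empty")
})

test_that("max-mean ties are broken by lexicographic probe ID", {
  m <- toy_matrix(rbind(c(4, 4), c(4, 4)), groups = c("control", "case"),
                  genes = c("pB", "pA"))
  out <- collapse_probes(m, c(pB = "G", pA = "G"))
  expect_equal(unname(out$values[1, ]), c(4, 4))
  # reconstruct which probe won via a marker
  m2 <- toy_matrix(rbind(c(4, 4.0), c(4.0, 4)), groups = c("control", "case"),
                   genes = c("pB", "pA"))
  m2$values["pA", ] <- c(8, 0)   # same mean, different profile
  out2 <- collapse_probes(m2, c(pB = "G", pA = "G"))
  expect_equal(unname(out2$values[1, ]), c(8, 0))  # pA < pB lexicographically
})

test_that("balanced subsampling keeps all controls and samples cases once", {
  set.seed(9)
  vals <- matrix(rnorm(10 * 53, 8), 10, 53)
  m <- toy_matrix(vals, groups = rep(c("control", "case"), c(18, 35)))
  out <- balanced_subsample(m, seed = 4)
  expect_equal(sum(out$group == "control"), 18)
  expect_equal(sum(out$group == "case"), 18)
  expect_false(anyDuplicated(sample_ids(out)) > 0)
  expect_identical(sample_ids(balanced_subsample(m, seed = 4)),
                   sample_ids(out))
  expect_false(identical(sample_ids(balanced_subsample(m, seed = 5)),
                         sample_ids(out)))
  # equal group sizes: everything retained
  m2 <- toy_matrix(vals[, 1:36], groups = rep(c("control", "case"), each = 18))
  expect_identical(sample_ids(balanced_subsample(m2, 1)), sample_ids(m2))
  # more controls than cases is an error
  m3 <- toy_matrix(vals[, 1:20], groups = rep(c("control", "case"), c(15, 5)))
  expect_error(balanced_subsample(m3, 1), "fewer cases")
})

test_that("group selection by outcome works and validates", {
  vals <- matrix(rnorm(8), 2, 4,
                 dimnames = list(c("a", "b"), sprintf("s%d", 1:4)))
  m <- expr_matrix(vals, group = c("control", "case", "case", "case"),
                   outcome = c(NA, "survivor", "nonsurvivor", "survivor"))
  expect_identical(sample_ids(select_group(m, "survivor")), c("s2", "s4"))
  expect_identical(sample_ids(select_group(m, "nonsurvivor")), "s3")
  expect_error(select_group(expr_matrix(vals, rep("case", 4)), "survivor"),
               "outcome")
})
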