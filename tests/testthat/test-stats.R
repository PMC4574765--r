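test_that("datasets validate their two-group structure", {
  ds <- tiny_dataset()
  expect_identical(ds$reference, "A")
  expect_identical(ds$case, "B")
  vals <- ds$values
  expect_error(expression_dataset(vals, c(s1 = "A", s2 = "A", s3 = "B"), "A"),
               "s4")
  expect_error(expression_dataset(vals, setNames(rep("A", 4), colnames(vals)), "A"),
               "two group labels")
  expect_error(expression_dataset(vals, c(s1 = "A", s2 = "B", s3 = "B", s4 = "B"), "A"),
               "fewer than 2")
  bad <- vals; rownames(bad) <- c("g", "g")
  expect_error(expression_dataset(bad, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"), "A"),
               "duplicate gene id: g")
})

test_that("written datasets reload identically", {
  sim <- generate_dataset(n_genes = 30, n_per_group = 4, n_de = 5, seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  ds <- load_dataset(paths[["matrix"]], paths[["design"]], "low")
  expect_equal(ds$values, sim$dataset$values)
  expect_identical(ds$groups, sim$dataset$groups)
  expect_identical(ds$reference, "low")
  # design missing a sample column names the offender
  design <- read.table(paths[["design"]], sep = "\t")
  broken <- file.path(dir, "broken-design.tsv")
  write.table(design[-1, ], broken, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(load_dataset(paths[["matrix"]], broken, "low"),
               design[1, 1])
})

test_that("mean fold change is the difference of group means on the log2 scale", {
  ds <- tiny_dataset()
  # gB constant across groups -> 0; gA: mean(5,7) - mean(1,3) = 4
  fc <- mean_log2_fold_change(ds, c("gA", "gB", "ghost"))
  expect_equal(unname(fc), c(4, 0, NA))
  expect_named(fc, c("gA", "gB", "ghost"))
  expect_length(mean_log2_fold_change(ds, character()), 0)
  expect_equal(unname(mean_log2_fold_change(ds, "gA", linear = TRUE)), 16)
  # a planted 1-unit shift is recovered exactly
  vals <- matrix(c(1, 2, 2, 3), nrow = 1,
                 dimnames = list("g", paste0("s", 1:4)))
  ds2 <- expression_dataset(vals, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"), "A")
  expect_equal(unname(mean_log2_fold_change(ds2, "g")), 1)
})

test_that("per-sample fold change centers on the reference-group mean", {
  ds <- tiny_dataset()
  # gA: reference {1,3} (mean 2), case {5,7} -> {-1, +1, +3, +5}
  psfc <- per_sample_fold_change(ds, "gA")
  expect_equal(unname(psfc), c(-1, 1, 3, 5))
  expect_identical(names(psfc), ds$sample_ids)
  expect_equal(unname(per_sample_fold_change(ds, "gB")), rep(0, 4))
  expect_equal(mean(psfc[ds$groups == "A"]), 0)
  expect_error(per_sample_fold_change(ds, "ghost"), "not found")
})

test_that("the Welch t-test matches the closed form and its conventions", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  r2 <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  o <- welch_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$t_stat, o$t_stat, tolerance = 1e-12)
  expect_equal(r2$p_value, o$p_value, tolerance = 1e-12)
  # group swap negates t, preserves p
  r3 <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r3$t_stat, -r2$t_stat)
  expect_equal(r3$p_value, r2$p_value)
  # degenerate zero-variance conventions
  expect_equal(two_sample_t(c(0, 0), c(1, 1))$p_value, 0)
  expect_equal(two_sample_t(c(2, 2), c(2, 2)),
               list(t_stat = 0, p_value = 1))
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  # pooled-variance variant agrees with stats::t.test(var.equal = TRUE)
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(2.0, 2.5, 6.1, 3.3, 4.4)
  ht <- t.test(x, y, var.equal = TRUE)
  rp <- two_sample_t(x, y, var_equal = TRUE)
  expect_equal(rp$t_stat, unname(ht$statistic))
  expect_equal(rp$p_value, ht$p.value)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_adjust(numeric()), numeric())
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-14)
    expect_true(all(q >= p & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("dataset-wide differential expression is consistent and order-equivariant", {
  sim <- generate_dataset(n_genes = 60, n_per_group = 5, n_de = 10, seed = 5)
  ds <- sim$dataset
  de <- differential_expression(ds)
  expect_identical(de$gene_id, ds$gene_ids)
  expect_equal(de$log2_fc, unname(mean_log2_fold_change(ds, ds$gene_ids)))
  expect_equal(de$q_value, bh_adjust(de$p_value))
  expect_true(all(de$q_value >= de$p_value & de$q_value <= 1))
  # permuting gene order permutes, but does not change, the statistics
  set.seed(1); perm <- sample(nrow(ds$values))
  ds_perm <- expression_dataset(ds$values[perm, ], ds$groups, ds$reference)
  de_perm <- differential_expression(ds_perm)
  expect_equal(de_perm[match(de$gene_id, de_perm$gene_id), ], de,
               ignore_attr = TRUE)
  # single-gene dataset: BH with n = 1 leaves p untouched
  one <- expression_dataset(ds$values[1, , drop = FALSE], ds$groups, ds$reference)
  de1 <- differential_expression(one)
  expect_equal(de1$q_value, de1$p_value)
})

test_that("raw expression returns full rows and null markers", {
  ds <- tiny_dataset()
  rows <- raw_expression(ds, c("gA", "ghost"))
  expect_identical(rows$gA, ds$values["gA", ])
  expect_length(rows$gA, length(ds$sample_ids))
  expect_null(rows$ghost)
})
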