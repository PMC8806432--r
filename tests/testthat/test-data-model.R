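test_that("expression TSV write/read round-trips the object", {
  vals <- matrix(c(0.5, 1.25, 2, 0, 3.75, 10.125), nrow = 3,
                 dimnames = list(c("LNC1", "LNC2", "GENE1"),
                                 c("S1", "S2")))
  expr <- expression_matrix(vals, c("tumor", "normal"),
                            data.frame(gene_id = rownames(vals),
                                       biotype = c("lncRNA", "lncRNA", "mRNA"),
                                       immune_flag = c(FALSE, FALSE, TRUE)))
  d <- withr::local_tempdir()
  p <- file.path(d, c("e.tsv", "g.tsv", "s.tsv"))
  write_expression(expr, p[1], p[2], p[3])
  back <- read_expression(p[1], p[2], p[3])
  expect_identical(back$values, expr$values)
  expect_identical(back$sample_group, expr$sample_group)
  expect_equal(back$gene_meta, expr$gene_meta)
})

test_that("validation rejects duplicate ids and bad values, naming them", {
  vals <- matrix(1:4, 2, dimnames = list(c("A", "A"), c("S1", "S2")))
  meta <- data.frame(gene_id = c("A", "A"), biotype = "lncRNA",
                     immune_flag = FALSE)
  expect_error(expression_matrix(vals, c("tumor", "tumor"), meta),
               "duplicated gene id.*A")
  vals2 <- matrix(c(1, -2, 3, 4), 2,
                  dimnames = list(c("A", "B"), c("S1", "S2")))
  meta2 <- data.frame(gene_id = c("A", "B"), biotype = "lncRNA",
                      immune_flag = FALSE)
  expect_error(expression_matrix(vals2, c("tumor", "tumor"), meta2),
               "negative expression at gene 'B', sample 'S1'")
})

test_that("a simulated matrix carries the requested gene counts", {
  spec <- simulation_spec(n_tumor = 20, n_normal = 5, n_lncRNA = 132,
                          n_mRNA = 30, n_immune_genes = 10, n_irlnc = 8,
                          n_de = 4,
                          planted_pairs = data.frame(a = 1L, b = 2L,
                                                     beta = 1),
                          seed = 3L)
  co <- simulate_cohort(spec)
  expect_length(lncRNA_ids(co$expr), 132)
  expect_equal(dim(co$expr), c(162L, 25L))
})

test_that("patient filtering excludes follow-up <= 30 days and duplicates", {
  surv <- survival_table(c("a", "b", "c", "d"), c(10, 30, 31, 400),
                         c(1, 1, 0, 1))
  kept <- suppressMessages(filter_patients(surv))
  expect_identical(kept$patient_id, c("c", "d"))
  expect_identical(attr(kept, "n_short_followup"), 2L)

  # idempotent, and identity when nothing is filterable
  again <- suppressMessages(filter_patients(kept))
  expect_equal(as.data.frame(again), as.data.frame(kept),
               ignore_attr = TRUE)

  dup <- survival_table(c("a", "b", "b", "c", "d"),
                        c(100, 200, 999, 300, 400), c(1, 0, 1, 1, 0))
  out <- suppressMessages(filter_patients(dup))
  expect_equal(nrow(out), 4)
  expect_equal(out$time[out$patient_id == "b"], 200)  # first occurrence kept
  expect_error(suppressMessages(
    filter_patients(survival_table("a", 5, 1))), "no patients remain")
})

test_that("survival and pair tables round-trip through TSV", {
  surv <- survival_table(c("p1", "p2"), c(100.5, 400), c(1, 0),
                         age = c(60, 70), gender = c("male", "female"),
                         grade = c("G1", "G2"), stage = c("I", "IV"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_survival(surv, f)
  expect_equal(as.data.frame(read_survival(f)), as.data.frame(surv))

  X <- matrix(c(5, 1, 1, 5, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  pm <- build_pair_matrix(X)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pm, f2)
  back <- read_pairs(f2)
  expect_identical(unname(back$P), unname(pm$P))
  expect_equal(back$freq1, unname(pm$freq1))
})

test_that("config validation enforces threshold ranges", {
  expect_error(pipeline_config(pair_low = 0.9, pair_high = 0.8))
  expect_error(pipeline_config(corr_p = 0))
  cfg <- pipeline_config(seed = 5)
  expect_s3_class(cfg, "pairsig_config")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("corr_r: 0.5", "seed: 9"), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$corr_r, 0.5)
  expect_equal(cfg2$seed, 9L)
  writeLines("nonsense_key: 1", f)
  expect_error(read_config(f), "unknown config key")
})
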