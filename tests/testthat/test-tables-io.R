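test_that("abundance TSV round-trips through read/write", {
  tab <- rand_paired_table(3, 1, seed = 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, tf)
  back <- read_abundance_table(tf, "counts")
  expect_identical(dim(back), c(3L, 2L))
  expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
  expect_identical(table_unit(back), "counts")

  pct <- to_relative(tab)
  write_abundance_table(pct, tf)
  back <- read_abundance_table(tf, "percent")
  expect_equal(unclass(back), unclass(pct), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("malformed tables are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts1", "a\t1\t2", "b\t3\t4"), tf)
  expect_error(read_abundance_table(tf, "counts"), "duplicate sample")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\t2", "a\t3\t4"), tf)
  expect_error(read_abundance_table(tf, "counts"), "duplicate taxon")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\t-2", "b\t3\t4"), tf)
  expect_error(read_abundance_table(tf, "counts"), "negative")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\tx", "b\t3\t4"), tf)
  expect_error(read_abundance_table(tf, "counts"), "non-numeric")
})

test_that("percent tables renormalize near 100 and reject drift beyond 0.5", {
  m <- matrix(c(49.9, 50.0, 60, 40), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- abundance_table(m, "percent")
  expect_equal(colSums(tab), c(s1 = 100, s2 = 100), tolerance = 1e-9)
  m[1, 1] <- 40
  expect_error(abundance_table(m, "percent"), "sums to")
})

test_that("to_relative produces percent columns summing to 100", {
  m <- matrix(c(2, 2, 1, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  rel <- to_relative(abundance_table(m, "counts"))
  expect_equal(unname(unclass(rel)[, "s1"]), c(50, 50))
  expect_equal(unname(unclass(rel)[, "s2"]), c(25, 75))

  tab <- rand_paired_table(50, 5, seed = 2)
  expect_equal(unname(colSums(to_relative(tab))), rep(100, 10),
               tolerance = 1e-9)

  m0 <- matrix(c(1, 1, 0, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(to_relative(abundance_table(m0, "counts")), "s2")
})

test_that("rank normalization uses ascending average ranks over n", {
  m <- rbind(x = c(5, 1, 3), y = c(2, 2, 7))
  colnames(m) <- c("s1", "s2", "s3")
  rk <- rank_normalize(abundance_table(m, "counts"))
  expect_equal(unname(rk["x", ]), c(1, 1 / 3, 2 / 3))
  expect_equal(unname(rk["y", ]), c(0.5, 0.5, 1))
  expect_error(rank_normalize(abundance_table(m[, 1, drop = FALSE],
                                              "counts")), ">=2 samples")
})

test_that("rank normalization matches a brute-force oracle and is invariant
           under strictly monotone transforms", {
  set.seed(9)
  for (i in 1:20) {
    v <- sample(0:5, 12, replace = TRUE)
    m <- matrix(v, 1, dimnames = list("t", sprintf("s%02d", 1:12)))
    rk <- rank_normalize(abundance_table(m, "counts"))
    # oracle: sort, assign average rank per tie group, divide by n
    oracle <- vapply(v, function(a) mean(which(sort(v) == a)), numeric(1))
    expect_equal(unname(rk[1, ]), oracle / 12)
    m2 <- matrix(exp(v) + 3, 1, dimnames = dimnames(m))
    expect_equal(rank_normalize(abundance_table(m2, "counts"))[1, ], rk[1, ])
  }
})

test_that("relative contribution pools counts within a class", {
  m <- matrix(c(30, 70, 10, 90, 30, 70), 2,
              dimnames = list(c("A", "B"), c("S01V1", "S02N1", "S03N1")))
  tab <- abundance_table(m, "counts")
  meta <- paired_meta(tab)
  expect_equal(relative_contribution(tab, meta, "lesional"),
               c(A = 30, B = 70))
  # two equal-depth non-lesional samples with A at 10% and 30% pool to 20%
  expect_equal(relative_contribution(tab, meta, "non_lesional")[["A"]], 20)

  tab2 <- rand_paired_table(40, 6, seed = 3)
  expect_equal(sum(relative_contribution(tab2, paired_meta(tab2),
                                         "lesional")), 100)
  expect_error(relative_contribution(tab, meta[meta$klass == "lesional", ],
                                     "non_lesional"), "no samples")
})

test_that("a single-sample class reproduces that sample's percentages", {
  tab <- rand_paired_table(25, 1, seed = 4)
  pct <- to_relative(tab)
  meta <- paired_meta(tab)
  contrib <- relative_contribution(tab, meta, "lesional")
  expect_equal(contrib, unclass(pct)[, "S01V1"])
})

test_that("sample ids decode subject, site and class", {
  meta <- parse_sample_ids(c("A1N1", "A1V1", "X10V3"))
  expect_equal(meta$subject_id, c("A1", "A1", "X10"))
  expect_equal(meta$klass, c("non_lesional", "lesional", "lesional"))
  expect_equal(meta$site_tag, c("N1", "V1", "V3"))
  expect_error(parse_sample_ids("sample7"), "unparseable")
})

test_that("metadata and annotations validate their vocabularies", {
  expect_error(sample_meta("s1", "a", "N1", "healthy"), "invalid class")
  expect_error(sample_meta(c("s1", "s1"), c("a", "a"), c("N1", "V1"),
                           c("lesional", "lesional")), "duplicate")
  ann <- data.frame(taxon_id = c("t1", "t2"), phylum = c("Firmicutes", ""),
                    gram_nature = c("positive", ""))
  out <- taxon_annotations(ann)
  expect_true(is.na(out$phylum[2]))
  ann$gram_nature <- c("positive", "purple")
  expect_error(taxon_annotations(ann), "vocabulary")
})
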