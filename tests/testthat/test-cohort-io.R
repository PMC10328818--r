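test_that("count table round-trips through TSV with depths recomputed", {
  ct <- tiny_count_table()
  expect_equal(unname(ct$depths), c(5, 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  ct2 <- read_count_table(f)
  expect_equal(ct2$counts, ct$counts)
  expect_equal(ct2$taxa$taxon_id, ct$taxa$taxon_id)
})

test_that("malformed count input is rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_error(read_count_table(f), "parse error|empty")
  writeLines(c("taxon_id\trank\ts1", "g1\tgenus\t-3"), f)
  expect_error(read_count_table(f), "negative")
  writeLines(c("taxon_id\trank\ts1", "g1\tgenus\tabc"), f)
  expect_error(read_count_table(f), "row 1")
  writeLines(c("wrong\trank\ts1", "g1\tgenus\t2"), f)
  expect_error(read_count_table(f), "sentinel")
  expect_error(count_table(rbind(1, 2),
                           data.frame(taxon_id = c("a", "a"), rank = "genus"),
                           "s1"),
               "duplicate")
})

test_that("sparse triplet format reconstructs the dense table", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\trank\tsample_id\tcount",
               "g1\tgenus\ts1\t1", "g1\tgenus\ts2\t2",
               "g2\tgenus\ts2\t3", "g3\tgenus\ts1\t4"), f)
  ct <- read_count_table(f, format = "triplet")
  expect_equal(ct$counts["g1", ], c(s1 = 1, s2 = 2))
  expect_equal(ct$counts["g2", "s1"], 0)
  expect_equal(unname(ct$depths), c(5, 5))
})

test_that("depth filter applies the age-specific cutoffs strictly", {
  ct <- count_table(matrix(c(2999, 3000, 4999, 5000), 1),
                    data.frame(taxon_id = "g1", rank = "genus"),
                    sprintf("s%d", 1:4))
  md <- tiny_metadata(4)
  md$timepoint <- c("3w", "3m", "12m", "12m")
  res <- filter_samples_by_depth(ct, md)
  expect_equal(res$removed$sample_id, c("s1", "s3"))
  expect_equal(res$counts$sample_ids, c("s2", "s4"))
  expect_equal(res$metadata$sample_id, c("s2", "s4"))
  # all above cutoff -> identity
  ct2 <- count_table(matrix(c(6000, 6000), 1),
                     data.frame(taxon_id = "g1", rank = "genus"),
                     c("s1", "s2"))
  res2 <- filter_samples_by_depth(ct2, tiny_metadata(2))
  expect_equal(res2$counts$sample_ids, c("s1", "s2"))
  expect_equal(nrow(res2$removed), 0)
})

test_that("unknown-annotation filter removes samples strictly over the cutoff", {
  counts <- rbind(c(75, 80, 100), c(25, 20, 0))
  ct <- count_table(counts,
                    data.frame(taxon_id = c("g1", "unknown_1"),
                               rank = c("genus", "unknown")),
                    c("s1", "s2", "s3"))
  res <- filter_unknown_fraction(ct, 0.20)
  # 25% unknown -> excluded; exactly 20% -> retained (strict "over")
  expect_equal(res$removed_samples, "s1")
  expect_equal(res$counts$sample_ids, c("s2", "s3"))
  expect_equal(res$counts$taxa$taxon_id, "g1")
  # no unknown taxa -> identity
  ct2 <- tiny_count_table()
  res2 <- filter_unknown_fraction(ct2)
  expect_equal(res2$counts$counts, ct2$counts)
})

test_that("variable screening marks but never removes", {
  n <- 120
  df <- data.frame(
    sample_id = sprintf("s%03d", 1:n), subject_id = sprintf("i%03d", 1:n),
    family_id = sprintf("f%03d", 1:n), role = "infant", timepoint = "3w",
    imbal = c(rep("big", 112), rep("tiny1", 5), rep("tiny2", 3)),
    holey = c(rep(NA, 100), rnorm(20)),
    good = rep(c("u", "v"), 60))
  md <- sample_metadata(df, data.frame(
    name = c("imbal", "holey", "good"),
    type = c("categorical", "numeric", "categorical"),
    role = "biological", levels = NA))
  scr <- screen_variables(md, min_group = 10, max_missing = 0.75)
  ex <- md_exclusions(scr)
  expect_setequal(ex$variable, c("imbal", "holey"))
  expect_true(grepl("missing", ex$reason[ex$variable == "holey"]))
  expect_equal(nrow(scr), n)                     # no samples removed
  v <- md_variables(scr)
  expect_false(v$excluded[v$name == "good"])
  expect_true(all(v$excluded[v$name %in% c("imbal", "holey")]))
})

test_that("three-class delivery variable partitions samples and rejects CS without antibiotics", {
  md <- tiny_metadata(4)
  md$delivery_mode <- c("CS", "VD", "VD", NA)
  md$intrapartum_ab <- c("yes", "yes", "no", "no")
  md2 <- derive_delivery3(md)
  expect_equal(md2$delivery3, c("CS+AB", "VD+AB", "VD-AB", NA))
  expect_equal(sum(table(md2$delivery3)), 3)     # levels partition non-missing
  md$intrapartum_ab[1] <- "no"
  expect_error(derive_delivery3(md), "validation")
})

test_that("distance matrix TSV round-trip is exact at 12 digits and validates", {
  set.seed(5)
  y <- matrix(runif(12), 3)
  d <- as.matrix(dist(y)); dimnames(d) <- list(paste0("s", 1:3), paste0("s", 1:3))
  dm <- dist_matrix(d, method = "aitchison")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, f)
  dm2 <- read_distance_matrix(f)
  expect_equal(dm2$values, dm$values, tolerance = 1e-12)
  expect_equal(dm2$method, "aitchison")
  expect_equal(dm2$sample_ids, dm$sample_ids)
  # nonzero diagonal / asymmetry rejected
  bad <- d; bad[1, 1] <- 0.5
  expect_error(dist_matrix(bad), "diagonal")
  bad2 <- d; bad2[1, 2] <- bad2[1, 2] + 1e-6
  expect_error(dist_matrix(bad2), "asymmetric")
})

test_that("metadata round-trips with its YAML declaration sidecar", {
  md <- tiny_metadata(6)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".yml")
  write_metadata(md, f1, f2)
  md2 <- read_metadata(f1, f2)
  expect_equal(md2$sample_id, md$sample_id)
  expect_equal(md_variables(md2)$name, md_variables(md)$name)
  expect_equal(md_variables(md2)$type, md_variables(md)$type)
})
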