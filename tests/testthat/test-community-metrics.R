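test_that("aggregation sums within family and drops unannotated taxa", {
  ct <- count_table(rbind(c(3, 1), c(4, 2), c(5, 9)),
                    data.frame(taxon_id = c("g1", "g2", "g3"),
                               rank = "genus",
                               family = c("FamA", "FamA", NA)),
                    c("s1", "s2"))
  expect_warning(fam <- aggregate_taxa(ct, "family"), "lack family")
  expect_equal(unname(fam$counts["FamA", ]), c(7, 3))
  expect_equal(nrow(fam$counts), 1)
  # genus-level aggregation = identity minus unknowns
  ct2 <- tiny_count_table()
  expect_equal(aggregate_taxa(ct2, "genus")$counts, ct2$counts)
})

test_that("relative abundances sum to one and reject zero-depth samples", {
  ct <- tiny_count_table(rbind(c(1, 1), c(3, 0)), genera = c("a", "b")[1:2])
  p <- relative_abundance(ct)
  expect_equal(unname(p[, 1]), c(0.25, 0.75))
  expect_equal(unname(colSums(p)), c(1, 1), tolerance = 1e-12)
  ct0 <- count_table(rbind(c(1, 0), c(1, 0)),
                     data.frame(taxon_id = c("a", "b"), rank = "genus"),
                     c("s1", "s2"))
  expect_error(relative_abundance(ct0), "zero-depth")
})

test_that("rarefaction is an exact-depth deterministic single draw", {
  set.seed(99)
  ct <- count_table(matrix(rpois(60, 30), 6),
                    data.frame(taxon_id = paste0("g", 1:6), rank = "genus"),
                    paste0("s", 1:10))
  r1 <- rarefy_counts(ct, 100, seed = 11)
  r2 <- rarefy_counts(ct, 100, seed = 11)
  expect_identical(r1$counts, r2$counts)
  expect_true(all(r1$depths == 100))
  expect_true(all(r1$counts <= ct$counts))
  # depth equal to a sample's own depth leaves it unchanged
  dmin <- min(ct$depths)
  r3 <- rarefy_counts(ct, dmin, seed = 1)
  j <- which.min(ct$depths)
  expect_equal(r3$counts[, j], ct$counts[, j])
  expect_error(rarefy_counts(ct, max(ct$depths) + 1), "exceeds")
})

test_that("rarefaction preserves expected proportions", {
  ct <- count_table(matrix(c(600, 300, 100), 3),
                    data.frame(taxon_id = paste0("g", 1:3), rank = "genus"),
                    "s1")
  props <- sapply(1:400, function(s)
    rarefy_counts(ct, 200, seed = s)$counts[, 1] / 200)
  p0 <- c(0.6, 0.3, 0.1)
  se <- sqrt(p0 * (1 - p0) / 200) / sqrt(400)
  expect_true(all(abs(rowMeans(props) - p0) < 3 * se + 1e-9))
})

test_that("alpha panel matches closed forms and brute force", {
  # uniform four taxa: shannon = ln 4, pielou = 1
  ct <- count_table(matrix(c(5, 5, 5, 5), 4),
                    data.frame(taxon_id = paste0("g", 1:4), rank = "genus"),
                    "s1")
  ap <- alpha_panel(ct, depth = 20, seed = 1)
  expect_equal(ap$shannon, log(4), tolerance = 1e-12)
  expect_equal(ap$pielou, 1, tolerance = 1e-12)
  # no singletons or doubletons: chao1 equals observed richness
  ct2 <- count_table(matrix(c(5, 5, 5), 3),
                     data.frame(taxon_id = paste0("g", 1:3), rank = "genus"),
                     "s1")
  expect_equal(alpha_panel(ct2, 15, 1)$chao1, 3)
  # hand-derived case: counts (1,1,2)
  ct3 <- count_table(matrix(c(1, 1, 2), 3),
                     data.frame(taxon_id = paste0("g", 1:3), rank = "genus"),
                     "s1")
  ap3 <- alpha_panel(ct3, 4, 1)
  expect_equal(ap3$shannon, 1.0397208, tolerance = 1e-6)
  expect_equal(ap3$chao1, 3.5)
  # brute-force agreement on 100 random samples
  set.seed(123)
  m <- matrix(rpois(100 * 30, 3), 30)
  colnames(m) <- sprintf("r%03d", 1:100)
  ctr <- count_table(m, data.frame(taxon_id = paste0("g", 1:30),
                                   rank = "genus"), colnames(m))
  ctr <- ct_subset(ctr, samples = ctr$sample_ids[ctr$depths > 0])
  d <- min(ctr$depths)
  app <- alpha_panel(ctr, d, seed = 3)
  raref <- rarefy_counts(ctr, d, seed = 3)
  for (j in seq_along(app$sample_id)) {
    x <- raref$counts[, j]
    expect_equal(app$shannon[j], bf_shannon(x), tolerance = 1e-10)
    expect_equal(app$chao1[j], bf_chao1(x), tolerance = 1e-10)
    if (sum(x > 0) >= 2)
      expect_equal(app$pielou[j], bf_pielou(x), tolerance = 1e-10)
    expect_equal(app$rarity_lms[j], bf_skew(log1p(x)), tolerance = 1e-10)
  }
  # single observed taxon: pielou undefined, not an error
  ct1 <- count_table(matrix(4, 1),
                     data.frame(taxon_id = "g1", rank = "genus"), "s1")
  expect_true(is.na(alpha_panel(ct1, 4, 1)$pielou))
})

test_that("Bray-Curtis identities hold in both spaces", {
  p <- cbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1))
  rownames(p) <- paste0("t", 1:3)
  dm <- bray_curtis(p)
  expect_equal(dm$values["a", "b"], 0)
  expect_equal(dm$values["a", "c"], 1)            # disjoint supports
  expect_true(all(dm$values >= 0 & dm$values <= 1))
  expect_equal(dm$values, t(dm$values))
  # count-space hand example: x=(6,2), y=(2,2) -> 1 - 2(2+2)/(8+4) = 1/3
  cm <- cbind(x = c(6, 2), y = c(2, 2))
  expect_equal(bray_curtis(cm, space = "count")$values["x", "y"], 1 / 3,
               tolerance = 1e-12)
  # proportion-space value differs (depths differ) and follows 1 - sum(min)
  pm <- sweep(cm, 2, colSums(cm), "/")
  expect_equal(bray_curtis(pm)$values["x", "y"],
               1 - sum(pmin(pm[, 1], pm[, 2])), tolerance = 1e-12)
})

test_that("Aitchison distance is CLR-Euclidean with scale invariance in the limit", {
  x <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(aitchison(x, 1)$values["a", "b"], 0)
  # CLR of equal counts is all zeros
  expect_equal(max(abs(clr_transform(matrix(7, 4, 1), 0))), 0)
  # CLR columns are mean-centred
  set.seed(1)
  y <- matrix(rpois(30, 20) + 1, 5)
  expect_lt(max(abs(colMeans(clr_transform(y, 1)))), 1e-10)
  # scaling one sample by 10 vanishes as pseudocount -> 0 (zero-free)
  z <- cbind(a = c(3, 5, 9), b = 10 * c(3, 5, 9))
  colnames(z) <- c("a", "b")
  expect_lt(aitchison(z, 1e-6)$values["a", "b"], 1e-4)
  # triangle inequality (Euclidean geometry)
  w <- matrix(rpois(15, 10) + 1, 5)
  colnames(w) <- paste0("s", 1:3)
  dv <- aitchison(w, 1)$values
  expect_lte(dv[1, 3], dv[1, 2] + dv[2, 3] + 1e-12)
})

test_that("Pearson distance spans [0,2] with exact endpoints", {
  p <- cbind(a = c(0.9, 0.1), b = c(0.9, 0.1), c = c(0.1, 0.9))
  dm <- pearson_distance(p)
  expect_equal(dm$values["a", "b"], 0)
  expect_equal(dm$values["a", "c"], 2)
  set.seed(4)
  q <- matrix(runif(40), 8)
  colnames(q) <- paste0("s", 1:5)
  dq <- pearson_distance(q)$values
  expect_true(all(dq >= 0 & dq <= 2))
  expect_error(pearson_distance(cbind(a = c(1, 1), b = c(1, 2))),
               "zero-variance")
})
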