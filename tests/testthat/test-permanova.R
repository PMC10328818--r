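test_that("Gower centring reproduces the total-SS identity", {
  # all-zero distances
  z <- matrix(0, 3, 3); dimnames(z) <- list(paste0("s", 1:3), paste0("s", 1:3))
  G0 <- gower_center(dist_matrix(z, method = "generic"))
  expect_equal(max(abs(G0)), 0)
  # two tight pairs at distance 1: SS_total = 4/4 = 1
  d <- matrix(1, 4, 4); d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0; dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  G <- gower_center(dist_matrix(d, method = "generic"))
  expect_equal(sum(diag(G)), 1, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(G))), 1e-10)
  # trace identity on random matrices
  for (s in 1:5) {
    set.seed(s)
    y <- matrix(rnorm(8 * 3), 8)
    dd <- as.matrix(dist(y))
    dimnames(dd) <- list(paste0("s", 1:8), paste0("s", 1:8))
    Gr <- gower_center(dist_matrix(dd, method = "euclidean"))
    expect_equal(sum(diag(Gr)), sum(dd[upper.tri(dd)]^2) / 8,
                 tolerance = 1e-10)
  }
})

test_that("two separated pairs give R2 = 1 and intercept-only leaves all SS residual", {
  d <- matrix(1, 4, 4); d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0; dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  md <- tiny_metadata(4)
  md$grp <- c("a", "a", "b", "b")
  fit <- fit_permanova(dist_matrix(d, method = "generic"), md, "grp", B = 0)
  expect_equal(fit$R2[1], 1, tolerance = 1e-10)
  expect_equal(fit$SS[fit$term == "Residual"], 0, tolerance = 1e-10)
  fit0 <- fit_permanova(dist_matrix(d, method = "generic"), md,
                        character(0), B = 0)
  expect_equal(fit0$SS[fit0$term == "Residual"], attr(fit0, "SS_total"))
})

test_that("sequential SS matches adonis2 and decomposes exactly", {
  skip_if_not_installed("vegan")
  set.seed(21)
  n <- 25
  md <- tiny_metadata(n)
  md$grp <- sample(c("a", "b", "c"), n, TRUE)
  md$x <- rnorm(n)
  y <- matrix(rnorm(n * 4), n)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(md$sample_id, md$sample_id)
  dm <- dist_matrix(d, method = "euclidean")
  fit <- fit_permanova(dm, md, c("x", "grp"), B = 0)
  ad <- vegan::adonis2(stats::as.dist(d) ~ x + grp, data = md,
                       permutations = 2, by = "terms")
  expect_equal(fit$SS, ad$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(fit$F[1:2], ad$F[1:2], tolerance = 1e-8)
  expect_equal(sum(fit$SS), attr(fit, "SS_total"), tolerance = 1e-8)
  # total model SS is invariant under candidate reordering
  fit2 <- fit_permanova(dm, md, c("grp", "x"), B = 0)
  expect_equal(sum(fit2$SS[1:2]), sum(fit$SS[1:2]), tolerance = 1e-10)
})

test_that("single-factor R2 equals coordinate-wise ANOVA eta-squared", {
  for (s in 1:10) {
    set.seed(s)
    n <- 18
    g <- factor(sample(c("a", "b", "c"), n, TRUE))
    y <- matrix(rnorm(n * 3), n)
    if (nlevels(droplevels(g)) < 2) next
    d <- as.matrix(dist(y))
    ids <- sprintf("s%d", 1:n)
    dimnames(d) <- list(ids, ids)
    md <- tiny_metadata(n)
    md$grp <- as.character(g)
    fit <- fit_permanova(dist_matrix(d, method = "euclidean"), md, "grp",
                         B = 0)
    sst <- sum(scale(y, scale = FALSE)^2)
    ssb <- sum(sapply(seq_len(ncol(y)), function(j) {
      a <- stats::anova(stats::lm(y[, j] ~ g)); a$`Sum Sq`[1]
    }))
    expect_equal(fit$R2[1], ssb / sst, tolerance = 1e-8)
  }
})

test_that("permutation p equals exhaustive enumeration on small n", {
  set.seed(8)
  n <- 6
  md <- tiny_metadata(n)
  md$grp <- c("a", "a", "a", "b", "b", "b")
  y <- matrix(rnorm(n * 2), n)
  d <- as.matrix(dist(y)); dimnames(d) <- list(md$sample_id, md$sample_id)
  dm <- dist_matrix(d, method = "euclidean")
  perms <- all_perms(n)
  ident <- which(apply(perms, 1, function(p) all(p == seq_len(n))))
  fit <- fit_permanova(dm, md, "grp", B = 0,
                       perm_matrix = perms[-ident, , drop = FALSE])
  # independent oracle: enumerate F over all relabellings from raw distances
  f_obs <- bf_onefactor_F(d, md$grp)
  fs <- apply(perms, 1, function(p) bf_onefactor_F(d, md$grp[p]))
  p_exact <- mean(fs >= f_obs - 1e-12)
  expect_equal(fit$p[1], p_exact, tolerance = 1e-12)
  expect_equal(fit$F[1], f_obs, tolerance = 1e-10)
})

test_that("aliased and rank-deficient designs are handled with zero df", {
  md <- tiny_metadata(12)
  md$copy <- md$grp
  md2 <- sample_metadata(as.data.frame(md), rbind(
    md_variables(md),
    data.frame(name = "copy", type = "categorical", role = "biological",
               levels = "a,b")))
  set.seed(2)
  y <- matrix(rnorm(24), 12)
  d <- as.matrix(dist(y)); dimnames(d) <- list(md$sample_id, md$sample_id)
  expect_warning(
    fit <- fit_permanova(dist_matrix(d, method = "euclidean"), md2,
                         c("grp", "copy"), B = 19),
    "aliased")
  expect_equal(fit$df[fit$term == "copy"], 0)
  expect_equal(fit$SS[fit$term == "copy"], 0)
  expect_true(is.na(fit$p[fit$term == "copy"]))
})

test_that("confounder-first screening reports the candidate after adjustment", {
  cfg <- cohort_config(n_families = 80, timepoints = c("3w", "6w"), seed = 3)
  sim <- quiet(simulate_cohort(cfg, demo_truth()))
  ids <- sim$metadata$sample_id[sim$metadata$timepoint == "3w"]
  dm <- community_distance(ct_subset(sim$counts, samples = ids))
  fit <- quiet(screen_variable(dm, sim$metadata, "delivery3",
                               c("batch", "reads"), B = 99, seed = 1))
  expect_equal(fit$term[1:2], c("batch", "reads"))
  expect_equal(fit$term[3], "delivery3")
  expect_lt(fit$p[3], 0.05)          # planted large effect is detected
  expect_error(screen_variable(dm, sim$metadata, "batch", c("batch", "reads")),
               "confounder")
})

test_that("permdisp matches betadisper distances and flags planted dispersion", {
  skip_if_not_installed("vegan")
  set.seed(31)
  n <- 40
  y <- matrix(rnorm(n * 3, sd = rep(c(1, 2), each = n / 2)), n)
  md <- tiny_metadata(n)
  md$grp <- rep(c("a", "b"), each = n / 2)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(md$sample_id, md$sample_id)
  pd <- permdisp(dist_matrix(d, method = "euclidean"), md, "grp",
                 B = 199, seed = 1)
  bd <- vegan::betadisper(stats::as.dist(d), md$grp, type = "centroid")
  expect_equal(unname(pd$distances), unname(bd$distances), tolerance = 1e-8)
  expect_true(pd$uneven)             # doubled spread must be flagged
  # degenerate identical points: non-significant with warning
  dz <- matrix(0, 4, 4); dimnames(dz) <- list(paste0("s", 1:4),
                                              paste0("s", 1:4))
  mdz <- tiny_metadata(4); mdz$grp <- c("a", "a", "b", "b")
  expect_warning(
    pz <- permdisp(dist_matrix(dz, method = "generic"), mdz, "grp", B = 19),
    "degenerate")
  expect_false(pz$uneven)
})

test_that("within-batch similarity test counts pairs correctly and detects planted batches", {
  # two batches of two samples: 2 within pairs, 4 between pairs
  md <- tiny_metadata(4)
  md$batch <- c("b1", "b1", "b2", "b2")
  set.seed(6)
  y <- matrix(rnorm(8), 4)
  d <- as.matrix(dist(y)); dimnames(d) <- list(md$sample_id, md$sample_id)
  r <- within_batch_similarity_test(dist_matrix(d, method = "euclidean"),
                                    md, "batch")
  expect_equal(r$n_within, 2)
  expect_equal(r$n_between, 4)
  # planted batch effect: within-batch median below between-batch median
  cfg <- cohort_config(n_families = 120, timepoints = c("3w", "6w"),
                       batch_size = 30, seed = 9)
  tr <- synthetic_truth(batch_sd = 1.2)
  sim <- quiet(simulate_cohort(cfg, tr))
  ids <- sim$metadata$sample_id[sim$metadata$timepoint == "3w"]
  dm <- community_distance(ct_subset(sim$counts, samples = ids))
  rb <- within_batch_similarity_test(dm, sim$metadata, "batch",
                                     role = "infant", timepoint = "3w")
  expect_lt(rb$median_within, rb$median_between)
  expect_lt(rb$p, 0.05)
})
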