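test_that("BH adjustment matches hand arithmetic and brute force", {
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(7)
  for (k in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_fdr(p), bf_bh(p), tolerance = 1e-12)
  }
})

test_that("screen_all applies within-timepoint FDR and the dual rule", {
  cfg <- cohort_config(n_families = 120, timepoints = c("3w", "12m"),
                       seed = 23)
  sim <- quiet(simulate_cohort(cfg, demo_truth()))
  md <- screen_variables(sim$metadata)
  dms <- list()
  for (tp in c("3w", "12m")) {
    ids <- md$sample_id[md$timepoint == tp]
    dms[[tp]] <- community_distance(ct_subset(sim$counts, samples = ids))
  }
  rep_ <- quiet(screen_all(dms, md, c("delivery3", "parity", "platform"),
                           c("batch", "reads"), B = 99, seed = 1,
                           dispersion = FALSE))
  expect_s3_class(rep_, "screen_report")
  expect_equal(nrow(rep_), 6)
  # q within each timepoint reproduces bh_fdr of the stored p
  for (tp in c("3w", "12m")) {
    i <- rep_$timepoint == tp
    expect_equal(rep_$q[i], bh_fdr(rep_$p[i]))
  }
  # flags are a pure function of stored p and q
  expect_equal(rep_$significant,
               !is.na(rep_$p) & rep_$p < 0.05 & rep_$q < 0.1)
  # planted large early delivery effect detected at 3w
  expect_true(rep_$significant[rep_$timepoint == "3w" &
                                 rep_$variable == "delivery3"])
  # one variable, one timepoint -> q = p
  rep1 <- quiet(screen_all(dms["3w"], md, "parity", c("batch", "reads"),
                           B = 99, seed = 2, dispersion = FALSE))
  expect_equal(rep1$q, rep1$p)
})

test_that("interaction screen admits planted interactions and refuses aliased ones", {
  n <- 240
  md <- tiny_metadata(n)
  set.seed(41)
  md$a <- sample(c("a1", "a2"), n, TRUE)
  md$b <- sample(c("b1", "b2"), n, TRUE)
  md$konst <- "same"
  md2 <- sample_metadata(as.data.frame(md), data.frame(
    name = c("a", "b", "konst"), type = "categorical", role = "biological",
    levels = NA))
  # centred pure interaction: +shift on concordant cells, none on discordant,
  # leaving both margins flat
  y <- matrix(rnorm(n * 4, sd = 0.6), n)
  conc <- (md$a == "a2") == (md$b == "b2")
  y[conc, 1:2] <- y[conc, 1:2] + 1.2
  d <- as.matrix(dist(y)); dimnames(d) <- list(md$sample_id, md$sample_id)
  dm <- dist_matrix(d, method = "euclidean")
  r <- screen_interaction(dm, md2, "a", "b", B = 99, seed = 1)
  expect_true(r$admitted)
  mains <- r$fit$R2[match(c("a", "b"), r$fit$term)]
  expect_gt(r$R2, max(mains))        # interaction dominates its mains
  expect_error(quiet(screen_interaction(dm, md2, "a", "konst", B = 19)),
               "aliased")
})

test_that("stratified screening recovers stratum-specific effects and skips tiny strata", {
  n <- 300
  md <- tiny_metadata(n)
  set.seed(43)
  md$strat <- sample(c("A", "B"), n, TRUE)
  md$v <- sample(c("x", "y"), n, TRUE)
  md2 <- sample_metadata(as.data.frame(md), data.frame(
    name = c("strat", "v"), type = "categorical", role = "biological",
    levels = NA))
  y <- matrix(rnorm(n * 3, sd = 0.7), n)
  inA <- md$strat == "A" & md$v == "y"
  y[inA, 1] <- y[inA, 1] + 1.5       # effect only inside stratum A
  d <- as.matrix(dist(y)); dimnames(d) <- list(md$sample_id, md$sample_id)
  dm <- dist_matrix(d, method = "euclidean")
  r <- stratified_screen(dm, md2, "v", "strat", B = 199, seed = 1)
  expect_lt(r$p[r$stratum == "A"], 0.05)
  expect_gt(r$p[r$stratum == "B"], 0.05)
  # single-level stratifier reduces to the unstratified screen
  md2$strat <- "A"
  r1 <- stratified_screen(dm, md2, "v", "strat", B = 99, seed = 2)
  f1 <- quiet(screen_variable(dm, md2, "v", B = 99, seed = 2))
  expect_equal(r1$R2[1], f1$R2[match("v", f1$term)], tolerance = 1e-12)
  # tiny stratum skipped with reason
  md3 <- md2
  md3$strat <- c(rep("A", n - 3), rep("Z", 3))
  r2 <- stratified_screen(dm, md3, "v", "strat", B = 19, seed = 1)
  expect_match(r2$note[r2$stratum == "Z"], "skipped")
})

test_that("symmetric uncertainty matches hand-computed plug-in values", {
  x <- rep(c("a", "b"), 20)
  expect_equal(symmetric_uncertainty(x, x), 1)
  # exactly independent uniform 2x2 -> 0
  xx <- rep(c("a", "a", "b", "b"), 5)
  yy <- rep(c("u", "v", "u", "v"), 5)
  expect_equal(symmetric_uncertainty(xx, yy), 0)
  # dependent 2x2 table [[2,1],[1,2]] scaled up to n >= 10
  x2 <- rep(c("a", "a", "a", "b", "b", "b"), 2)
  y2 <- rep(c("u", "u", "v", "u", "v", "v"), 2)
  # hand plug-in: H(X)=H(Y)=ln 2; H(X,Y) = -2*(1/3 ln 1/3) - 2*(1/6 ln 1/6)
  hxy <- -(2 * (1 / 3) * log(1 / 3) + 2 * (1 / 6) * log(1 / 6))
  su_hand <- 2 * (2 * log(2) - hxy) / (2 * log(2))
  expect_equal(symmetric_uncertainty(x2, y2), su_hand, tolerance = 1e-10)
  # symmetry and range
  expect_equal(symmetric_uncertainty(x2, y2), symmetric_uncertainty(y2, x2))
  set.seed(3)
  a <- sample(c("p", "q", "r"), 60, TRUE); b <- rnorm(60)
  su <- symmetric_uncertainty(a, b)
  expect_true(su >= 0 && su <= 1)
  # constant variable -> undefined
  expect_true(is.na(symmetric_uncertainty(rep("k", 20), rep(c("a", "b"), 10))))
})

test_that("spearman matrix flags |rho| strictly above 0.3", {
  md <- data.frame(u = 1:20, v = (1:20)^2, w = 20:1)
  r <- spearman_matrix(md, c("u", "v", "w"))
  expect_equal(r$rho[r$var1 == "u" & r$var2 == "v"], 1)
  expect_equal(r$rho[r$var1 == "u" & r$var2 == "w"], -1)
  expect_true(all(r$fair))
  # boundary: rho = 0.29... not flagged
  set.seed(9)
  repeat {
    a <- rnorm(50); b <- 0.3 * a + rnorm(50)
    rho <- cor(a, b, method = "spearman")
    if (abs(rho) < 0.3 && abs(rho) > 0.2) break
  }
  r2 <- spearman_matrix(data.frame(a = a, b = b), c("a", "b"))
  expect_false(r2$fair)
})

test_that("family-dyad comparison counts pairs and detects planted similarity", {
  # two families -> 2 within pairs and 2 between pairs
  md <- data.frame(sample_id = c("i1", "i2", "m1", "m2"),
                   subject_id = c("i1", "i2", "m1", "m2"),
                   family_id = c("f1", "f2", "f1", "f2"),
                   role = c("infant", "infant", "mother", "mother"),
                   timepoint = c("3w", "3w", "parental", "parental"))
  set.seed(2)
  y <- matrix(rnorm(8), 4)
  d <- as.matrix(dist(y)); dimnames(d) <- list(md$sample_id, md$sample_id)
  r <- family_dyad_analysis(dist_matrix(d, method = "euclidean"), md,
                            "mother-infant", "3w", min_families = 2)
  expect_equal(r$n_within, 2)
  expect_equal(r$n_between, 2)
  # planted family component: within-family distances smaller
  cfg <- cohort_config(n_families = 80, timepoints = c("3w", "6w"),
                       include_parents = TRUE, seed = 29)
  sim <- quiet(simulate_cohort(cfg, synthetic_truth(sigma_family = 0.8,
                                                    sigma_subject = 0.4)))
  dm <- community_distance(sim$counts)
  rr <- family_dyad_analysis(dm, sim$metadata, "mother-infant", "3w")
  expect_lt(rr$median_within, rr$median_between)
  expect_lt(rr$p, 0.05)
  expect_error(family_dyad_analysis(dm, sim$metadata, "mother-infant", "3w",
                                    min_families = 1e6), "insufficient")
})
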