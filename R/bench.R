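### Simulation benchmarks: each function re-runs a piece of the analysis on
### generated data with known truth and returns the headline quantities the
### acceptance checks assert. Shared by the test suite and
### scripts/acceptance.R so both always measure the same thing.

#' Engine-vs-ANOVA oracle agreement on Euclidean distances
#'
#' Random single-factor instances where PERMANOVA R2 has a closed classical
#' counterpart: coordinate-wise ANOVA eta-squared summed over coordinates.
#' Also compares the permutation p-value against exhaustive enumeration over
#' all n! relabellings for n = 6 and n = 7.
#'
#' @param n_instances number of random instances (default 50).
#' @param seed RNG seed.
#' @return list with `max_r2_diff` and `max_p_diff`.
#' @export
bench_oracle_equivalence <- function(n_instances = 50, seed = 1L) {
  max_r2 <- 0
  for (i in seq_len(n_instances)) {
    set.seed(seed + i)
    n <- sample(12:25, 1)
    g <- factor(sample(letters[1:3], n, TRUE))
    if (nlevels(droplevels(g)) < 2) g[1:2] <- c("a", "b")
    y <- matrix(stats::rnorm(n * 4), n)
    d <- as.matrix(stats::dist(y))
    ids <- sprintf("s%03d", seq_len(n))
    dimnames(d) <- list(ids, ids)
    md <- data.frame(sample_id = ids, grp = as.character(g))
    fit <- fit_permanova(dist_matrix(d, method = "euclidean"), md, "grp",
                         B = 0)
    sst <- sum(scale(y, scale = FALSE)^2)
    ssb <- sum(vapply(seq_len(ncol(y)), function(j) {
      a <- stats::anova(stats::lm(y[, j] ~ g)); a$`Sum Sq`[1]
    }, numeric(1)))
    max_r2 <- max(max_r2, abs(fit$R2[1] - ssb / sst))
  }
  # exact enumeration on n = 6 and n = 7
  perm_all <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- perm_all(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k)
      cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))))
  }
  bf_F <- function(d, g) {
    n <- length(g)
    ss_t <- sum(d[upper.tri(d)]^2) / n
    ss_w <- 0
    for (lev in unique(g)) {
      i <- which(g == lev)
      if (length(i) > 1)
        ss_w <- ss_w + sum(d[i, i][upper.tri(d[i, i])]^2) / length(i)
    }
    a <- length(unique(g))
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  max_p <- 0
  for (n in c(6L, 7L)) {
    set.seed(seed + 1000 + n)
    g <- rep(c("a", "b"), length.out = n)
    y <- matrix(stats::rnorm(n * 2), n)
    d <- as.matrix(stats::dist(y))
    ids <- sprintf("s%d", seq_len(n)); dimnames(d) <- list(ids, ids)
    perms <- perm_all(n)
    ident <- which(apply(perms, 1, function(p) all(p == seq_len(n))))
    md <- data.frame(sample_id = ids, grp = g)
    fit <- fit_permanova(dist_matrix(d, method = "euclidean"), md, "grp",
                         B = 0, perm_matrix = perms[-ident, , drop = FALSE])
    fs <- apply(perms, 1, function(p) bf_F(d, g[p]))
    p_exact <- mean(fs >= bf_F(d, g) - 1e-12)
    max_p <- max(max_p, abs(fit$p[1] - p_exact))
  }
  list(max_r2_diff = max_r2, max_p_diff = max_p)
}

# one null community set: samples from a common Dirichlet-multinomial
null_community_dm <- function(n, n_taxa = 40, concentration = 30,
                              depth = 5000) {
  base <- exp(seq(log(0.2), log(0.001), length.out = n_taxa))
  base <- base / sum(base)
  alpha <- base * concentration
  gam <- matrix(stats::rgamma(n_taxa * n, shape = alpha), n_taxa, n)
  pr <- sweep(gam, 2, colSums(gam), "/")
  cnt <- vapply(seq_len(n), function(j)
    stats::rmultinom(1, depth, pr[, j])[, 1], numeric(n_taxa))
  p <- sweep(cnt, 2, pmax(colSums(cnt), 1), "/")
  colnames(p) <- sprintf("s%04d", seq_len(n))
  bray_curtis(p)
}

#' Type-I error of the permutation test on null communities
#'
#' Communities drawn from one shared Dirichlet-multinomial composition, a
#' random binary label, Bray-Curtis distances, permutation p at B
#' permutations; returns the rejection rate at alpha.
#'
#' @param n_sims simulations (default 1000).
#' @param n samples per simulation (default 40).
#' @param B permutations (default 199).
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rate`, `se` (binomial SE at the nominal level), `n_sims`.
#' @export
bench_type1 <- function(n_sims = 1000, n = 40, B = 199, alpha = 0.05,
                        seed = 1L) {
  rej <- 0L
  for (s in seq_len(n_sims)) {
    set.seed(seed * 7 + s)
    dm <- null_community_dm(n)
    md <- data.frame(sample_id = dm$sample_ids,
                     grp = sample(c("a", "b"), n, TRUE))
    if (length(unique(md$grp)) < 2) md$grp[1:2] <- c("a", "b")
    fit <- fit_permanova(dm, md, "grp", B = B, seed = seed * 11 + s)
    if (!is.na(fit$p[1]) && fit$p[1] < alpha) rej <- rej + 1L
  }
  list(rate = rej / n_sims, se = sqrt(alpha * (1 - alpha) / n_sims),
       n_sims = n_sims)
}

#' Recovered R2 per planted tier against the frozen expectation
#'
#' Simulates fresh cohorts under [tier_truth()] at the default study scale
#' (300 families, two sampling ages), screens each tier-carrying variable on
#' genus Bray-Curtis distances, and compares the recovered R2 to the frozen
#' Monte-Carlo expectation shipped in `extdata/expected_r2_tiers.tsv`.
#'
#' @param n_rep replicate cohorts to average (default 3).
#' @param seed RNG seed.
#' @return data.frame per (variable, tier, timepoint): recovered mean/sd,
#'   frozen mean/sd, and `within_tol` at 3 combined SDs.
#' @export
bench_tier_recovery <- function(n_rep = 3, seed = 1L) {
  frozen <- utils::read.delim(system.file("extdata",
                                          "expected_r2_tiers.tsv",
                                          package = "microvarpart"))
  truth <- tier_truth()
  vars <- vapply(truth$effects, `[[`, "", "variable")
  tiers <- vapply(truth$effects, `[[`, "", "tier")
  acc <- list()
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_families = 300, timepoints = c("3w", "12m"),
                         seed = substream_seed(seed, paste0("tier", r)))
    sim <- simulate_cohort(cfg, truth)
    for (tp in cfg$timepoints) {
      ids <- sim$metadata$sample_id[sim$metadata$timepoint == tp]
      dm <- community_distance(ct_subset(sim$counts, samples = ids))
      for (i in seq_along(vars)) {
        fit <- fit_permanova(dm, sim$metadata, vars[i], B = 0)
        acc[[length(acc) + 1]] <- data.frame(
          variable = vars[i], tier = tiers[i], timepoint = tp, rep = r,
          r2 = fit$R2[fit$term == vars[i]])
      }
    }
  }
  df <- do.call(rbind, acc)
  agg <- stats::aggregate(r2 ~ variable + tier + timepoint, df, function(x)
    c(mean = mean(x), sd = stats::sd(x)))
  out <- data.frame(variable = agg$variable, tier = agg$tier,
                    timepoint = agg$timepoint,
                    recovered_mean = agg$r2[, "mean"],
                    recovered_sd = ifelse(is.na(agg$r2[, "sd"]), 0,
                                          agg$r2[, "sd"]))
  key <- paste(out$variable, out$timepoint)
  fkey <- paste(frozen$variable, frozen$timepoint)
  out$frozen_mean <- frozen$r2_mean[match(key, fkey)]
  out$frozen_sd <- frozen$r2_sd[match(key, fkey)]
  tol <- 3 * sqrt(out$frozen_sd^2 + out$recovered_sd^2 + 1e-6)
  out$within_tol <- abs(out$recovered_mean - out$frozen_mean) <= tol
  out
}

#' AICc backward-selection recovery on planted candidate sets
#'
#' Each replicate simulates a 300-subject single-age cohort with three true
#' medium-tier terms (the three-class delivery variable, defecation
#' frequency, breastfeeding) and seven null six-level survey covariates
#' (stool-colour-like multi-level classes), then runs
#' the confounder-anchored backward selection and scores which candidates
#' survive.
#'
#' @param n_rep replicates (default 100).
#' @param seed RNG seed.
#' @return list with `true_recovery` (fraction of replicates retaining all
#'   three true terms), `median_null_retained`, `mean_null_retained`, and the
#'   per-replicate table.
#' @export
bench_selection <- function(n_rep = 100, seed = 1L) {
  true_terms <- c("delivery3", "defecation_freq", "breastfeeding")
  nulls <- sprintf("null%d", 1:7)
  truth <- synthetic_truth(list(
    planted_effect("delivery3", "medium", level = "CS+AB",
                   taxa = c("Bacteroides", "Parabacteroides",
                            "Bifidobacterium", "Escherichia", "Klebsiella",
                            "Enterococcus")),
    planted_effect("defecation_freq", "medium", level = "high",
                   taxa = c("Akkermansia", "Collinsella", "Eggerthella",
                            "Haemophilus", "Clostridium_sensu_stricto",
                            "Lactobacillus")),
    planted_effect("breastfeeding", "medium", level = "no",
                   taxa = c("Blautia", "Veillonella", "Streptococcus",
                            "Sutterella", "Faecalibacterium",
                            "Ruminococcus"))),
    sigma_subject = 0.8, batch_sd = 0.5)
  rows <- list()
  for (r in seq_len(n_rep)) {
    s <- substream_seed(seed, paste0("sel", r))
    cfg <- cohort_config(n_families = 300, timepoints = c("3w", "6w"),
                         missing_visit_prob = 0, seed = s)
    sim <- simulate_cohort(cfg, truth)
    md <- as.data.frame(sim$metadata)
    set.seed(s + 1L)
    for (v in nulls) md[[v]] <- sample(letters[1:6], nrow(md), TRUE)
    vt <- rbind(md_variables(sim$metadata),
                data.frame(name = nulls, type = "categorical",
                           role = "biological", levels = NA))
    md <- sample_metadata(md, vt)
    ids <- md$sample_id[md$timepoint == "3w"]
    dm <- community_distance(ct_subset(sim$counts, samples = ids))
    tr <- suppressWarnings(backward_select(
      dm, md, c(true_terms, nulls), c("batch", "reads"), B = 0, seed = s))
    rows[[r]] <- data.frame(
      rep = r,
      true_kept = sum(true_terms %in% tr$final_terms),
      null_kept = sum(nulls %in% tr$final_terms))
  }
  tab <- do.call(rbind, rows)
  list(true_recovery = mean(tab$true_kept == length(true_terms)),
       median_null_retained = stats::median(tab$null_kept),
       mean_null_retained = mean(tab$null_kept),
       table = tab)
}

#' Differential-abundance cascade recovery, calibration and offset invariance
#'
#' Planted two-fold (log 2) effects on six moderately abundant early-life
#' genera against the parity
#' indicator at 200 subjects: measures the fraction of planted taxa that are
#' significant with the correct sign, the empirical false-discovery
#' proportion under a null relabelling, and the maximal coefficient shift
#' when all depths are doubled.
#'
#' @param n_rep replicates (default 20).
#' @param seed RNG seed.
#' @return list with `sign_recovery`, `null_fdp`, `max_depth_shift`.
#' @export
bench_da <- function(n_rep = 20, seed = 1L) {
  taxa <- c("Veillonella", "Streptococcus", "Clostridium_sensu_stricto",
            "Lactobacillus", "Klebsiella", "Haemophilus")
  truth <- synthetic_truth(list(
    planted_effect("parity", NA, lfc = log(2), level = "nulliparous",
                   taxa = taxa)), sigma_subject = 0.4)
  hit <- 0L; tot <- 0L
  null_sig <- 0L; null_tot <- 0L
  max_shift <- 0
  for (r in seq_len(n_rep)) {
    s <- substream_seed(seed, paste0("da", r))
    cfg <- cohort_config(n_families = 200, timepoints = c("3w", "6w"),
                         missing_visit_prob = 0, concentration = 100,
                         seed = s)
    sim <- simulate_cohort(cfg, truth)
    ids <- sim$metadata$sample_id[sim$metadata$timepoint == "3w"]
    ct <- aggregate_taxa(ct_subset(sim$counts, samples = ids), "genus")
    res <- suppressWarnings(fit_da(ct, sim$metadata, "parity",
                                   adjust = "batch",
                                   reference = "multiparous"))
    sh <- sim$truth$realized[[1]]$shift_by_timepoint[, 1]
    planted <- sim$truth$panel$taxon_id[sh != 0]
    sgn <- sign(sh[sh != 0])
    for (i in seq_along(planted)) {
      row <- res[res$taxon == planted[i], ]
      if (!nrow(row)) next
      tot <- tot + 1L
      if (isTRUE(row$significant[1]) &&
          sign(row$estimate[1]) == sgn[i]) hit <- hit + 1L
    }
    # null relabelling on the same cohort
    mdn <- as.data.frame(sim$metadata)
    set.seed(s + 2L)
    mdn$parity <- sample(mdn$parity)
    mdn <- sample_metadata(mdn, md_variables(sim$metadata))
    resn <- suppressWarnings(fit_da(ct, mdn, "parity", adjust = "batch",
                                    reference = "multiparous"))
    null_sig <- null_sig + sum(resn$significant, na.rm = TRUE)
    null_tot <- null_tot + sum(resn$family != "unfit")
    if (r == 1) {
      ct2 <- count_table(ct$counts * 2, ct$taxa, ct$sample_ids)
      res2 <- suppressWarnings(fit_da(ct2, sim$metadata, "parity",
                                      adjust = "batch",
                                      reference = "multiparous"))
      shared <- intersect(res$taxon, res2$taxon)
      max_shift <- max(abs(res$estimate[match(shared, res$taxon)] -
                             res2$estimate[match(shared, res2$taxon)]))
    }
  }
  list(sign_recovery = hit / tot, null_fdp = null_sig / max(null_tot, 1),
       max_depth_shift = max_shift)
}

#' Family-dyad similarity: power under planted transmission, calibration
#' under independence
#'
#' @param n_rep replicates per arm (default 25).
#' @param n_families families per cohort (default 100).
#' @param seed RNG seed.
#' @return list with `power` (planted family component, p < 0.05 rate) and
#'   `null_rate` (independent families).
#' @export
bench_dyads <- function(n_rep = 25, n_families = 100, seed = 1L) {
  run_arm <- function(sigma_family, tag) {
    hits <- 0L
    for (r in seq_len(n_rep)) {
      cfg <- cohort_config(n_families = n_families,
                           timepoints = c("3w", "6w"),
                           include_parents = TRUE,
                           seed = substream_seed(seed, paste0(tag, r)))
      sim <- simulate_cohort(cfg, synthetic_truth(
        sigma_family = sigma_family, sigma_subject = 0.5))
      md <- sim$metadata
      keep <- md$sample_id[md$role == "mother" |
                             (md$role == "infant" & md$timepoint == "3w")]
      dm <- community_distance(ct_subset(sim$counts, samples = keep))
      res <- family_dyad_analysis(dm, md, "mother-infant", "3w")
      if (res$p < 0.05) hits <- hits + 1L
    }
    hits / n_rep
  }
  list(power = run_arm(0.8, "fam"), null_rate = run_arm(0, "nullfam"))
}

#' PERMDISP calibration and power against doubled Dirichlet dispersion
#'
#' Two groups sharing one mean composition; under the alternative one group's
#' Dirichlet concentration is halved (doubling its compositional dispersion).
#'
#' @param n_rep_power,n_rep_null replicates per arm (default 40 power,
#'   100 calibration).
#' @param n_per_group samples per group (default 100).
#' @param B permutations (default 199).
#' @param seed RNG seed.
#' @return list with `type1` and `power`.
#' @export
bench_permdisp <- function(n_rep_power = 40, n_rep_null = 100,
                           n_per_group = 100, B = 199, seed = 1L) {
  draw_group <- function(n, concentration, s) {
    set.seed(s)
    base <- exp(seq(log(0.2), log(0.001), length.out = 40))
    base <- base / sum(base)
    gam <- matrix(stats::rgamma(40 * n, shape = base * concentration),
                  40, n)
    pr <- sweep(gam, 2, colSums(gam), "/")
    vapply(seq_len(n), function(j) stats::rmultinom(1, 8000, pr[, j])[, 1],
           numeric(40))
  }
  run <- function(c2, n_rep, tag) {
    hits <- 0L
    for (r in seq_len(n_rep)) {
      s <- substream_seed(seed, paste0(tag, r))
      cnt <- cbind(draw_group(n_per_group, 30, s),
                   draw_group(n_per_group, c2, s + 1L))
      colnames(cnt) <- sprintf("s%03d", seq_len(2 * n_per_group))
      p <- sweep(cnt, 2, colSums(cnt), "/")
      dm <- bray_curtis(p)
      md <- data.frame(sample_id = colnames(cnt),
                       grp = rep(c("a", "b"), each = n_per_group))
      res <- permdisp(dm, md, "grp", B = B, seed = s)
      if (isTRUE(res$uneven)) hits <- hits + 1L
    }
    hits / n_rep
  }
  list(type1 = run(30, n_rep_null, "disp0"),
       power = run(15, n_rep_power, "disp1"))
}
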