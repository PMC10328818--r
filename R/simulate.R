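### Dirichlet-multinomial longitudinal cohort simulator with planted,
### known-magnitude covariate effects. The composition model is log-linear:
### baseline age trajectory per genus + subject and family random intercepts
### + planted covariate log-fold-changes + multiplicative batch effects,
### softmaxed to proportions, Dirichlet-perturbed, and sampled multinomially
### at a log-normal read depth.

tp_levels <- function() c("3w", "6w", "3m", "6m", "9m", "12m", "18m", "24m")

tp_age <- function(tp) {
  a <- c("3w" = 0.06, "6w" = 0.12, "3m" = 0.25, "6m" = 0.5, "9m" = 0.75,
         "12m" = 1, "18m" = 1.5, "24m" = 2, "parental" = 2)
  unname(a[tp])
}

# fixed genus panel: (name, family, log-abundance at birth, at two years)
default_taxon_panel <- function() {
  tab <- rbind(
    c("Bifidobacterium", "Bifidobacteriaceae", 3.5, 2.0),
    c("Bacteroides", "Bacteroidaceae", 1.5, 3.0),
    c("Escherichia", "Enterobacteriaceae", 2.5, 0.5),
    c("Veillonella", "Veillonellaceae", 1.8, 1.0),
    c("Streptococcus", "Streptococcaceae", 2.0, 1.0),
    c("Clostridium_sensu_stricto", "Clostridiaceae", 1.0, 1.5),
    c("Lactobacillus", "Lactobacillaceae", 1.2, 0.5),
    c("Akkermansia", "Akkermansiaceae", -1.0, 1.0),
    c("Blautia", "Lachnospiraceae", 0.0, 2.5),
    c("Faecalibacterium", "Ruminococcaceae", -1.5, 2.5),
    c("Ruminococcus", "Ruminococcaceae", -1.0, 2.0),
    c("Collinsella", "Coriobacteriaceae", 0.0, 1.0),
    c("Parabacteroides", "Tannerellaceae", 0.5, 1.5),
    c("Haemophilus", "Pasteurellaceae", 0.8, 0.2),
    c("Klebsiella", "Enterobacteriaceae", 1.0, 0.0),
    c("Enterococcus", "Enterococcaceae", 1.0, 0.2),
    c("Staphylococcus", "Staphylococcaceae", 1.5, -0.5),
    c("Sutterella", "Sutterellaceae", -0.5, 0.5),
    c("Eggerthella", "Eggerthellaceae", -0.3, 0.3),
    c("Alistipes", "Rikenellaceae", -1.5, 1.0))
  data.frame(taxon_id = tab[, 1], family = tab[, 2],
             base_early = as.numeric(tab[, 3]),
             base_late = as.numeric(tab[, 4]))
}

#' Generator configuration for the synthetic cohort
#'
#' Defaults emulate a longitudinal infant birth cohort at desk scale:
#' eight infant sampling ages from three weeks to two years with roughly six
#' visits kept per infant, parental spot samples, log-normal read depths
#' around a 16.8k median, and DNA-extraction batches of 80 samples filled in
#' chronological order across two sequencing platforms.
#'
#' @param n_families number of families (default 300).
#' @param timepoints infant sampling ages.
#' @param n_taxa number of genera (>= 20; the first 20 are a named panel
#'   with realistic age trajectories, the rest a rank-abundance tail).
#' @param n_unknown extra taxa carrying "unknown" annotation.
#' @param concentration Dirichlet concentration governing sample-to-sample
#'   overdispersion (larger = less noise; default 50).
#' @param depth_meanlog,depth_sdlog log-normal read-depth parameters
#'   (default log(16800), 0.6).
#' @param missing_visit_prob probability a scheduled infant visit is skipped
#'   (default 0.25, giving ~6 of 8 visits).
#' @param include_parents draw parental spot samples?
#' @param parent_prob inclusion probability for mother and father samples.
#' @param batch_size DNA-extraction batch size (default 80).
#' @param miseq_from fraction of batches after which the platform switches
#'   from HiSeq to MiSeq (default 0.6).
#' @param seed base seed; every component draws from a named substream.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 300, timepoints = tp_levels(),
                          n_taxa = 60, n_unknown = 2, concentration = 50,
                          depth_meanlog = log(16800), depth_sdlog = 0.6,
                          missing_visit_prob = 0.25,
                          include_parents = FALSE,
                          parent_prob = c(mother = 0.73, father = 0.57),
                          batch_size = 80, miseq_from = 0.6, seed = 1L) {
  stopifnot(n_families >= 2, length(timepoints) >= 2, n_taxa >= 20,
            concentration > 0, missing_visit_prob >= 0,
            missing_visit_prob <= 1, all(parent_prob >= 0 & parent_prob <= 1))
  structure(as.list(environment()), class = "cohort_config")
}

tier_lfc <- function(tier) {
  # log-fold-change magnitudes per variance-fraction tier, calibrated once
  # by expected_r2() simulation under the default configuration: the induced
  # Bray-Curtis R2 lands near 1% (small; the detectability floor above the
  # null df/(n-1) baseline at 300 subjects), 2% (medium) and 6% (large)
  c(none = 0, small = 0.35, medium = 0.6, large = 0.9)[[tier]]
}

#' One planted covariate effect
#'
#' @param variable metadata variable carrying the effect.
#' @param tier "none", "small", "medium" or "large" (mapped to a declared
#'   log-fold-change magnitude), or NA when `lfc` is given directly.
#' @param taxa taxa carrying the effect (names or count; default 8).
#' @param level affected level of a categorical variable (other non-reference
#'   levels get half the shift); ignored for numeric variables.
#' @param timepoints ages at which the effect is active (default all).
#' @param decay multiplier applied per successive timepoint (1 = constant).
#' @param lfc optional explicit log-fold-change magnitude.
#' @export
planted_effect <- function(variable, tier = "medium", taxa = 8, level = NULL,
                           timepoints = NULL, decay = 1, lfc = NULL) {
  list(variable = variable, tier = tier,
       lfc = lfc %||% tier_lfc(tier), taxa = taxa, level = level,
       timepoints = timepoints, decay = decay)
}

#' Ground-truth description of the planted structure
#'
#' @param effects list of [planted_effect()]s.
#' @param sigma_subject subject random-intercept SD on the log scale
#'   (default 0.8; drives the within-subject similarity a pooled model
#'   attributes to individual identity).
#' @param sigma_family family random-intercept SD shared by all members of a
#'   family (default 0; set positive to plant parent-infant similarity).
#' @param batch_sd SD of the multiplicative (log-scale) batch effect applied
#'   to a random 20% taxon subset per extraction batch (default 0).
#' @param sibling_flip_prob probability the older-siblings indicator
#'   disagrees with parity (default 0.02; keeps the pair nearly collinear).
#' @export
synthetic_truth <- function(effects = list(), sigma_subject = 0.8,
                            sigma_family = 0, batch_sd = 0,
                            sibling_flip_prob = 0.02) {
  structure(list(effects = effects, sigma_subject = sigma_subject,
                 sigma_family = sigma_family, batch_sd = batch_sd,
                 sibling_flip_prob = sibling_flip_prob),
            class = "synthetic_truth")
}

#' The packaged demo truth: batch, delivery, parity and stool effects
#'
#' Large three-class delivery effect decaying with age, medium batch effect,
#' small-to-medium parity effect, medium defecation-frequency effect and a
#' numeric stool-consistency effect, over a strong subject random intercept.
#' @export
demo_truth <- function() {
  synthetic_truth(
    effects = list(
      planted_effect("delivery3", "large", taxa = c(
        "Bacteroides", "Parabacteroides", "Bifidobacterium", "Escherichia",
        "Klebsiella", "Enterococcus", "Staphylococcus", "Veillonella"),
        level = "CS+AB", decay = 0.6),
      planted_effect("parity", "small", taxa = c(
        "Bacteroides", "Faecalibacterium", "Lactobacillus", "Sutterella",
        "Bifidobacterium", "Alistipes", "Collinsella", "Salmonella")[1:7],
        level = "nulliparous"),
      planted_effect("defecation_freq", "medium", taxa = c(
        "Akkermansia", "Bacteroides", "Bifidobacterium", "Collinsella",
        "Eggerthella", "Lactobacillus", "Clostridium_sensu_stricto",
        "Haemophilus", "Klebsiella"), level = "high"),
      planted_effect("stool_consistency", "small", taxa = c(
        "Bacteroides", "Streptococcus", "Haemophilus", "Blautia"))),
    sigma_subject = 0.8, batch_sd = 1.0)
}

#' Tier-calibration truth: one planted effect per variance tier
#'
#' Four covariates carry disjoint taxon sets at the four effect tiers
#' (none, small, medium, large); used to measure how faithfully screening
#' recovers a known variance-fraction ordering.
#' @export
tier_truth <- function() {
  synthetic_truth(list(
    planted_effect("breastfeeding", "none", level = "no",
                   taxa = c("Alistipes", "Staphylococcus")),
    planted_effect("parity", "small", level = "nulliparous",
                   taxa = c("Blautia", "Veillonella", "Streptococcus",
                            "Sutterella", "Faecalibacterium",
                            "Ruminococcus")),
    planted_effect("defecation_freq", "medium", level = "high",
                   taxa = c("Akkermansia", "Collinsella", "Eggerthella",
                            "Haemophilus", "Clostridium_sensu_stricto",
                            "Lactobacillus")),
    planted_effect("delivery3", "large", level = "CS+AB",
                   taxa = c("Bacteroides", "Parabacteroides",
                            "Bifidobacterium", "Escherichia", "Klebsiella",
                            "Enterococcus"))),
    sigma_subject = 0.8)
}

draw_covariates <- function(cfg, truth, seed) {
  set.seed(seed)
  nf <- cfg$n_families
  delivery_mode <- ifelse(stats::runif(nf) < 0.16, "CS", "VD")
  intrapartum_ab <- ifelse(delivery_mode == "CS", "yes",
                           ifelse(stats::runif(nf) < 0.23, "yes", "no"))
  parity <- ifelse(stats::runif(nf) < 0.51, "multiparous", "nulliparous")
  flip <- stats::runif(nf) < truth$sibling_flip_prob
  older_siblings <- ifelse(xor(parity == "multiparous", flip), "yes", "no")
  data.frame(family_id = sprintf("F%04d", seq_len(nf)),
             delivery_mode = delivery_mode, intrapartum_ab = intrapartum_ab,
             parity = parity, older_siblings = older_siblings)
}

# per-sample age-dependent covariates
draw_visit_covariates <- function(tp, n, seed) {
  set.seed(seed)
  age <- tp_age(tp)
  bf_prob <- stats::approx(c(0, 0.25, 0.5, 0.75, 1, 1.5, 2),
                           c(0.96, 0.95, 0.90, 0.80, 0.67, 0.40, 0.20),
                           xout = min(age, 2), rule = 2)$y
  breastfeeding <- ifelse(stats::runif(n) < bf_prob, "yes", "no")
  # defecation frequency: 3 classes, newborns skewed high
  ph <- max(0.15, 0.55 - 0.25 * age); pl <- min(0.5, 0.15 + 0.2 * age)
  u <- stats::runif(n)
  defecation_freq <- ifelse(u < ph, "high", ifelse(u < ph + (1 - ph - pl),
                                                   "mid", "low"))
  stool_consistency <- pmin(7, pmax(1, round(
    stats::rnorm(n, mean = 6 - 1.6 * min(age, 2), sd = 1))))
  data.frame(breastfeeding = breastfeeding,
             defecation_freq = defecation_freq,
             stool_consistency = stool_consistency)
}

effect_shift <- function(eff, taxa_ids, tp_index, tps) {
  # signed per-taxon lfc vector for one effect at one timepoint
  shift <- numeric(length(taxa_ids))
  sel <- if (is.character(eff$taxa)) match(intersect(eff$taxa, taxa_ids),
                                           taxa_ids)
  else seq_len(min(eff$taxa, length(taxa_ids)))
  sel <- sel[!is.na(sel)]
  if (!length(sel)) stop("planted effect names no taxa in the panel: ",
                         eff$variable)
  sgn <- rep_len(c(-1, 1), length(sel))
  active <- is.null(eff$timepoints) || tps[tp_index] %in% eff$timepoints
  if (!active) return(shift)
  mag <- eff$lfc * eff$decay^(tp_index - 1)
  shift[sel] <- sgn * mag
  shift
}

#' Simulate a longitudinal cohort with planted effects
#'
#' @param cfg [cohort_config()].
#' @param truth [synthetic_truth()].
#' @return list with `counts` (count_table), `metadata` (sample_metadata) and
#'   `truth` (input truth augmented with the taxon panel, the per-effect
#'   affected-taxa/sign realisation, and the seed).
#' @export
simulate_cohort <- function(cfg, truth = synthetic_truth()) {
  panel <- default_taxon_panel()
  extra <- cfg$n_taxa - nrow(panel)
  if (extra > 0) {
    filler <- data.frame(
      taxon_id = sprintf("Genus_%03d", seq_len(extra) + nrow(panel)),
      family = sprintf("Family_%02d", (seq_len(extra) %% 12) + 1),
      base_early = seq(-0.5, -3, length.out = extra),
      base_late = seq(-0.5, -3, length.out = extra))
    panel <- rbind(panel, filler)
  }
  taxa <- data.frame(taxon_id = panel$taxon_id, rank = "genus",
                     family = panel$family)
  if (cfg$n_unknown > 0)
    taxa <- rbind(taxa, data.frame(
      taxon_id = sprintf("unknown_%02d", seq_len(cfg$n_unknown)),
      rank = "unknown", family = NA))
  nt <- nrow(taxa)
  ntk <- nrow(panel)

  fam <- draw_covariates(cfg, truth, substream_seed(cfg$seed, "covariates"))
  tps <- cfg$timepoints

  # visit schedule
  set.seed(substream_seed(cfg$seed, "visits"))
  visits <- expand.grid(family = seq_len(cfg$n_families),
                        tp = seq_along(tps), KEEP.OUT.ATTRS = FALSE)
  visits <- visits[stats::runif(nrow(visits)) >= cfg$missing_visit_prob, ]
  rows <- data.frame(
    family = visits$family, role = "infant", tp = tps[visits$tp],
    tp_index = visits$tp)
  if (cfg$include_parents) {
    set.seed(substream_seed(cfg$seed, "parents"))
    for (pr in c("mother", "father")) {
      inc <- stats::runif(cfg$n_families) < cfg$parent_prob[[pr]]
      rows <- rbind(rows, data.frame(family = which(inc), role = pr,
                                     tp = "parental", tp_index = NA))
    }
  }
  n <- nrow(rows)
  rows$subject_id <- ifelse(rows$role == "infant",
                            sprintf("I%04d", rows$family),
                            sprintf("%s%04d", toupper(substr(rows$role, 1, 1)),
                                    rows$family))
  rows$sample_id <- sprintf("S%05d", seq_len(n))
  rows$family_id <- fam$family_id[rows$family]

  # visit-level covariates (infants only)
  set.seed(substream_seed(cfg$seed, "visit_covariates"))
  rows$breastfeeding <- NA_character_
  rows$defecation_freq <- NA_character_
  rows$stool_consistency <- NA_real_
  for (t in seq_along(tps)) {
    i <- which(rows$role == "infant" & rows$tp_index == t)
    if (!length(i)) next
    vc <- draw_visit_covariates(tps[t], length(i),
                                substream_seed(cfg$seed,
                                               paste0("visit_", tps[t])))
    rows$breastfeeding[i] <- vc$breastfeeding
    rows$defecation_freq[i] <- vc$defecation_freq
    rows$stool_consistency[i] <- vc$stool_consistency
  }
  # parents get a lab Bristol score too
  ip <- which(rows$role != "infant")
  if (length(ip)) {
    set.seed(substream_seed(cfg$seed, "parent_stool"))
    rows$stool_consistency[ip] <- pmin(7, pmax(1, round(
      stats::rnorm(length(ip), 3.8, 1))))
  }

  # technical variables: extraction batches fill chronologically
  ord <- order(ifelse(is.na(rows$tp_index), 99L, rows$tp_index), rows$family)
  batch_no <- integer(n)
  batch_no[ord] <- (seq_len(n) - 1L) %/% cfg$batch_size + 1L
  n_batches <- max(batch_no)
  rows$batch <- sprintf("B%03d", batch_no)
  rows$platform <- ifelse(batch_no <= ceiling(n_batches * cfg$miseq_from),
                          "HiSeq", "MiSeq")
  set.seed(substream_seed(cfg$seed, "depths"))
  rows$reads <- pmax(1000, round(stats::rlnorm(n, cfg$depth_meanlog,
                                               cfg$depth_sdlog)))

  # random effects
  set.seed(substream_seed(cfg$seed, "subject_effects"))
  subj_ids <- unique(rows$subject_id)
  subj_eff <- matrix(stats::rnorm(length(subj_ids) * ntk, 0,
                                  truth$sigma_subject),
                     length(subj_ids), ntk, dimnames = list(subj_ids, NULL))
  set.seed(substream_seed(cfg$seed, "family_effects"))
  fam_eff <- matrix(stats::rnorm(cfg$n_families * ntk, 0,
                                 truth$sigma_family),
                    cfg$n_families, ntk)
  set.seed(substream_seed(cfg$seed, "batch_effects"))
  n_aff <- max(1L, round(0.2 * ntk))
  batch_eff <- matrix(0, n_batches, ntk)
  for (b in seq_len(n_batches)) {
    aff <- sample.int(ntk, n_aff)
    batch_eff[b, aff] <- stats::rnorm(n_aff, 0, truth$batch_sd)
  }

  # merge family covariates onto samples
  md <- cbind(rows[, c("sample_id", "subject_id", "family_id", "role")],
              timepoint = rows$tp,
              fam[rows$family, c("delivery_mode", "intrapartum_ab", "parity",
                                 "older_siblings")],
              rows[, c("breastfeeding", "defecation_freq",
                       "stool_consistency", "batch", "platform", "reads")])
  rownames(md) <- NULL
  # parents: infant-specific exposures do not apply
  md$delivery_mode[md$role != "infant"] <- NA
  md$intrapartum_ab[md$role != "infant"] <- NA
  md$breastfeeding[md$role != "infant"] <- NA
  md$defecation_freq[md$role != "infant"] <- NA

  variables <- data.frame(
    name = c("delivery_mode", "intrapartum_ab", "parity", "older_siblings",
             "breastfeeding", "defecation_freq", "stool_consistency",
             "batch", "platform", "reads"),
    type = c("categorical", "categorical", "categorical", "categorical",
             "categorical", "categorical", "numeric",
             "categorical", "categorical", "numeric"),
    role = c("biological", "biological", "biological", "biological",
             "biological", "biological", "biological",
             "confounder", "technical", "confounder"),
    levels = c("CS,VD", "yes,no", "multiparous,nulliparous", "yes,no",
               "yes,no", "low,mid,high", NA, NA, "HiSeq,MiSeq", NA))
  smd <- sample_metadata(md, variables)
  smd <- derive_delivery3(smd)

  # realize effect shifts (sign pattern per effect, fixed across timepoints)
  shifts <- lapply(truth$effects, function(eff)
    vapply(seq_along(tps), function(t)
      effect_shift(eff, panel$taxon_id, t, tps), numeric(ntk)))

  # compositions
  set.seed(substream_seed(cfg$seed, "composition"))
  counts <- matrix(0, nt, n)
  age_w <- ifelse(is.na(rows$tp_index), 1,
                  pmin(tp_age(rows$tp) / 2, 1))
  subj_row <- match(rows$subject_id, subj_ids)
  batch_row <- batch_no
  for (i in seq_len(n)) {
    w <- age_w[i]
    eta <- panel$base_early * (1 - w) + panel$base_late * w
    eta <- eta + subj_eff[subj_row[i], ] + fam_eff[rows$family[i], ] +
      batch_eff[batch_row[i], ]
    for (e in seq_along(truth$effects)) {
      eff <- truth$effects[[e]]
      x <- smd[[eff$variable]][i]
      if (is.na(x) || is.na(rows$tp_index[i])) next
      sh <- shifts[[e]][, rows$tp_index[i]]
      vtype <- md_variables(smd)$type[match(eff$variable,
                                            md_variables(smd)$name)]
      if (identical(vtype, "numeric") || is.numeric(x)) {
        eta <- eta + sh * (as.numeric(x) - 4) / 2
      } else if (!is.null(eff$level)) {
        lev <- as.character(x)
        if (lev == eff$level) eta <- eta + sh
        else if (lev != ref_level_of(eff, smd, i)) eta <- eta + 0.5 * sh
      } else {
        # first declared level acts as reference; others get the shift
        eta <- eta + sh * (x != smd[[eff$variable]][which(!is.na(
          smd[[eff$variable]]))[1]])
      }
    }
    pr <- exp(eta - max(eta))
    pr <- pr / sum(pr)
    alpha <- pr * cfg$concentration
    gam <- stats::rgamma(ntk, shape = alpha, rate = 1)
    if (sum(gam) == 0) gam[which.max(pr)] <- 1
    pi_full <- c(gam / sum(gam) * (1 - 0.01 * cfg$n_unknown),
                 rep(0.01, cfg$n_unknown))
    pi_full <- pi_full / sum(pi_full)
    counts[, i] <- stats::rmultinom(1, rows$reads[i], pi_full)
  }
  ct <- count_table(counts, taxa, rows$sample_id)
  # metadata reads = realized depth (post-hoc, like processed read counts)
  smd$reads <- unname(ct$depths)

  truth$panel <- panel
  truth$realized <- lapply(seq_along(truth$effects), function(e) {
    eff <- truth$effects[[e]]
    list(variable = eff$variable, tier = eff$tier,
         shift_by_timepoint = shifts[[e]],
         taxa = panel$taxon_id[which(rowSums(abs(shifts[[e]])) > 0)])
  })
  truth$seed <- cfg$seed
  list(counts = ct, metadata = smd, truth = truth)
}

ref_level_of <- function(eff, md, i) {
  # reference = "more standard" level per variable; defaults used by the
  # differential-abundance contrasts as well
  refs <- c(delivery3 = "VD-AB", delivery_mode = "VD", intrapartum_ab = "no",
            parity = "multiparous", older_siblings = "no",
            breastfeeding = "yes", defecation_freq = "low")
  unname(refs[eff$variable] %||% "")
}

#' Monte-Carlo expected PERMANOVA R2 of each planted effect
#'
#' Simulates `n_mc` replicate cohorts at effectively noise-free depth (fixed
#' deep reads) and, per timepoint and planted variable, runs the sequential
#' PERMANOVA engine on genus-level Bray-Curtis distances with no confounders,
#' returning the mean and SD of the recovered R2. These are the recovery
#' targets the acceptance simulations are compared against.
#'
#' @param truth [synthetic_truth()].
#' @param cfg [cohort_config()].
#' @param n_mc number of replicate cohorts (default 5).
#' @return data.frame (variable, tier, timepoint, r2_mean, r2_sd, n_mc).
#' @export
expected_r2 <- function(truth, cfg, n_mc = 5) {
  cfg$depth_meanlog <- log(2e5); cfg$depth_sdlog <- 0
  vars <- vapply(truth$effects, `[[`, "", "variable")
  out <- list()
  for (m in seq_len(n_mc)) {
    cfg$seed <- substream_seed(cfg$seed, paste0("mc", m))
    sim <- simulate_cohort(cfg, truth)
    inf <- sim$metadata[sim$metadata$role == "infant", ]
    for (tp in cfg$timepoints) {
      ids <- inf$sample_id[inf$timepoint == tp]
      if (length(ids) < 20) next
      dmt <- community_distance(ct_subset(sim$counts, samples = ids))
      for (v in unique(vars)) {
        fit <- fit_permanova(dmt, sim$metadata, v, B = 0)
        out[[length(out) + 1]] <- data.frame(
          variable = v,
          tier = truth$effects[[match(v, vars)]]$tier,
          timepoint = tp, rep = m, r2 = fit$R2[fit$term == v])
      }
    }
  }
  df <- do.call(rbind, out)
  agg <- stats::aggregate(r2 ~ variable + tier + timepoint, df,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  data.frame(variable = agg$variable, tier = agg$tier,
             timepoint = agg$timepoint,
             r2_mean = agg$r2[, "mean"],
             r2_sd = ifelse(is.na(agg$r2[, "sd"]), 0, agg$r2[, "sd"]),
             n_mc = n_mc)
}
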