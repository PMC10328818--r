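#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p vector of p-values in [0,1]; NAs pass through.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen every candidate variable at every timepoint
#'
#' For each timepoint (one sample role), runs the confounder-adjusted
#' sequential PERMANOVA for each variable, the beta-dispersion check for
#' categorical variables, and applies BH-FDR within the timepoint's variable
#' family. The dual significance rule is raw p < 0.05 AND q < 0.1.
#'
#' @param dms named list of dist_matrix, one per timepoint.
#' @param md sample_metadata (screened; excluded variables are skipped with a
#'   logged reason).
#' @param variables candidate variable names.
#' @param confounders technical confounder terms placed first.
#' @param B permutations.
#' @param seed RNG base seed.
#' @param role sample role the screen applies to (default "infant").
#' @param dispersion also run [permdisp()] for categoricals?
#' @return data.frame of class `screen_report`: one row per
#'   (timepoint, variable) with df, R2, F, p, q, significant, dispersion_p,
#'   uneven_dispersion, n.
#' @export
screen_all <- function(dms, md, variables, confounders = character(),
                       B = 999, seed = 1L, role = "infant",
                       dispersion = TRUE) {
  vtab <- md_variables(md)
  rows <- list()
  for (tp in names(dms)) {
    dmt <- dms[[tp]]
    res <- list()
    for (v in variables) {
      fit <- tryCatch(
        screen_variable(dmt, md, v, confounders,
                        B = B, seed = substream_seed(seed,
                                                     paste(tp, v))),
        error = function(e) e)
      if (inherits(fit, "error")) {
        res[[v]] <- data.frame(timepoint = tp, variable = v, df = NA,
                               R2 = NA, F = NA, p = NA, n = NA,
                               note = conditionMessage(fit))
        next
      }
      i <- match(v, fit$term)
      disp_p <- NA_real_
      if (dispersion && !is.null(vtab) &&
          vtab$type[match(v, vtab$name)] == "categorical") {
        dsp <- tryCatch(
          permdisp(dmt, md, v, B = B,
                   seed = substream_seed(seed, paste("disp", tp, v))),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(dsp)) disp_p <- dsp$p
      }
      res[[v]] <- data.frame(timepoint = tp, variable = v, df = fit$df[i],
                             R2 = fit$R2[i], F = fit$F[i], p = fit$p[i],
                             n = attr(fit, "n"), note = "",
                             dispersion_p = disp_p)
    }
    tpdf <- do.call(rbind, lapply(res, function(d) {
      if (!"dispersion_p" %in% names(d)) d$dispersion_p <- NA_real_
      d
    }))
    tpdf$q <- bh_fdr(tpdf$p)
    rows[[tp]] <- tpdf
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- !is.na(out$p) & out$p < 0.05 & out$q < 0.1
  out$uneven_dispersion <- !is.na(out$dispersion_p) & out$dispersion_p < 0.05
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Interaction screen for a variable pair
#'
#' Fits `(confounders..., var1, var2, var1:var2)` and reports the
#' interaction's sequential R2 and permutation p; the interaction is admitted
#' as a cumulative-model candidate iff p < 0.05.
#'
#' @inheritParams fit_permanova
#' @param var1,var2 main-effect variable names.
#' @return list with the full `fit`, and the interaction's `R2`, `p`,
#'   `admitted` flag.
#' @export
screen_interaction <- function(dm, md, var1, var2,
                               confounders = character(), B = 999,
                               seed = 1L) {
  ia <- paste0(var1, ":", var2)
  fit <- fit_permanova(dm, md, c(confounders, var1, var2, ia), confounders,
                       B = B, seed = seed)
  i <- match(ia, fit$term)
  if (fit$df[i] == 0) stop("interaction aliased (zero df); refused")
  list(fit = fit, R2 = fit$R2[i], p = fit$p[i],
       admitted = !is.na(fit$p[i]) && fit$p[i] < 0.05)
}

#' Stratified screening of one variable
#'
#' Runs the confounder-adjusted screen independently inside each level of a
#' stratifier (e.g. the three-class delivery variable). Strata too small for
#' the design are skipped with a reason. Raw per-stratum p-values are
#' reported (no cross-stratum FDR).
#'
#' @inheritParams screen_variable
#' @param stratifier categorical stratification variable.
#' @param min_n minimal stratum size; default total model df + 5.
#' @return data.frame (stratum, n, df, R2, F, p, note).
#' @export
stratified_screen <- function(dm, md, variable, stratifier,
                              confounders = character(), B = 999,
                              seed = 1L, min_n = NULL) {
  md <- as.data.frame_keep(md)
  s <- md[[stratifier]][match(dm$sample_ids, md$sample_id)]
  out <- list()
  for (lev in sort(unique(stats::na.omit(s)))) {
    ids <- dm$sample_ids[!is.na(s) & s == lev]
    des_df <- tryCatch({
      sub <- md[md$sample_id %in% ids, , drop = FALSE]
      d <- build_design(md_reindex(md, match(ids, md$sample_id)),
                        c(confounders, variable))
      ncol(d$X)
    }, error = function(e) NA_integer_)
    thr <- min_n %||% (if (is.na(des_df)) 5 else des_df + 5)
    if (length(ids) < thr || is.na(des_df)) {
      out[[lev]] <- data.frame(stratum = lev, n = length(ids), df = NA,
                               R2 = NA, F = NA, p = NA,
                               note = sprintf("skipped: n=%d < %d",
                                              length(ids), thr))
      next
    }
    fit <- tryCatch(
      screen_variable(dm_subset(dm, ids), md, variable, confounders,
                      B = B, seed = substream_seed(seed, lev),
                      check_usable = FALSE),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out[[lev]] <- data.frame(stratum = lev, n = length(ids), df = NA,
                               R2 = NA, F = NA, p = NA,
                               note = conditionMessage(fit))
      next
    }
    i <- match(variable, fit$term)
    out[[lev]] <- data.frame(stratum = lev, n = attr(fit, "n"),
                             df = fit$df[i], R2 = fit$R2[i], F = fit$F[i],
                             p = fit$p[i], note = "")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- covariate-redundancy diagnostics --------------------------------------

entropy_nats <- function(x) {
  p <- table(x); p <- p / sum(p)
  -sum(p * log(p))
}

#' Symmetric uncertainty between two covariates
#'
#' Normalised mutual information, `2 MI(X,Y) / (H(X) + H(Y))`, with plug-in
#' entropies in nats. Numeric variables are discretised to equal-frequency
#' bins (default `ceiling(n^(1/3))`). SU is 1 for identical variables and 0
#' exactly when the empirical MI vanishes; it is undefined (NA) when either
#' variable is constant.
#'
#' @param x,y vectors (categorical or numeric); pairwise-complete
#'   observations are used.
#' @param bins bin count for numeric variables (default `ceiling(n^(1/3))`).
#' @return value in [0,1], or NA.
#' @export
symmetric_uncertainty <- function(x, y, bins = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need >= 10 pairwise-complete observations")
  disc <- function(v) {
    if (!is.numeric(v)) return(as.character(v))
    b <- bins %||% ceiling(n^(1 / 3))
    qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = b + 1)))
    if (length(qs) < 2) return(rep("c1", length(v)))
    as.character(cut(v, qs, include.lowest = TRUE))
  }
  xd <- disc(x); yd <- disc(y)
  hx <- entropy_nats(xd); hy <- entropy_nats(yd)
  if (hx == 0 || hy == 0) return(NA_real_)
  hxy <- entropy_nats(paste(xd, yd, sep = "\r"))
  mi <- max(0, hx + hy - hxy)
  2 * mi / (hx + hy)
}

#' Pairwise Spearman correlations with "fair" flags
#'
#' Rank correlation with average ties on pairwise-complete observations;
#' pairs with |rho| strictly above 0.3 are flagged as fairly correlated.
#'
#' @param md sample_metadata or data.frame.
#' @param variables numeric variable names.
#' @return data.frame (var1, var2, rho, n, fair), one row per unordered pair.
#' @export
spearman_matrix <- function(md, variables) {
  md <- as.data.frame(md)
  out <- list()
  for (i in seq_along(variables)) for (j in seq_len(i - 1L)) {
    x <- as.numeric(md[[variables[i]]]); y <- as.numeric(md[[variables[j]]])
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    out[[length(out) + 1]] <- data.frame(
      var1 = variables[j], var2 = variables[i], rho = rho, n = sum(ok),
      fair = !is.na(rho) && abs(rho) > 0.3)
  }
  do.call(rbind, out)
}

#' Within- versus between-family dyad distances
#'
#' Compares the distance between each infant and its own parent (or between
#' the two parents) against the distances between that infant and every other
#' family's corresponding parent, with an unpaired Wilcoxon rank-sum test.
#'
#' @param dm dist_matrix covering infants at `timepoint` and parental spot
#'   samples.
#' @param md sample_metadata.
#' @param dyad "mother-infant", "father-infant" or "mother-father".
#' @param timepoint infant sampling age (ignored for mother-father).
#' @param min_families minimal number of complete dyads (default 5).
#' @return list with `statistic`, `p`, `median_within`, `median_between`,
#'   `n_within`, `n_between`.
#' @export
family_dyad_analysis <- function(dm, md, dyad = c("mother-infant",
                                                  "father-infant",
                                                  "mother-father"),
                                 timepoint = NULL, min_families = 5) {
  dyad <- match.arg(dyad)
  md <- as.data.frame_keep(md)
  parts <- strsplit(dyad, "-")[[1]]
  pick <- function(role, tp = NULL) {
    sel <- md$role == role & md$sample_id %in% dm$sample_ids
    if (!is.null(tp) && role == "infant") sel <- sel & md$timepoint == tp
    md[sel, c("sample_id", "family_id")]
  }
  a <- pick(parts[1]); b <- pick(parts[2], timepoint)
  fams <- intersect(a$family_id, b$family_id)
  if (length(fams) < min_families)
    stop("insufficient dyads: ", length(fams), " complete families")
  a <- a[a$family_id %in% fams, ][match(fams, a$family_id[a$family_id %in%
                                                            fams]), ]
  a <- a[!duplicated(a$family_id), ]
  b <- b[!duplicated(b$family_id), ]
  a <- a[match(fams, a$family_id), ]; b <- b[match(fams, b$family_id), ]
  D <- dm$values[match(a$sample_id, dm$sample_ids),
                 match(b$sample_id, dm$sample_ids), drop = FALSE]
  within <- diag(D)
  between <- c(D[row(D) != col(D)])
  wt <- stats::wilcox.test(within, between, exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_within = stats::median(within),
       median_between = stats::median(between),
       n_within = length(within), n_between = length(between))
}
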