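#' Gower-centre a distance matrix
#'
#' Forms `A = -d^2/2` and double-centres it, `G = (I - J/n) A (I - J/n)`.
#' The trace of G is the total sum of squares of the distance model,
#' `sum_{i<j} d_ij^2 / n`.
#'
#' @param dm dist_matrix or square numeric matrix of distances.
#' @return symmetric matrix G with zero row sums.
#' @export
gower_center <- function(dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$values else as.matrix(dm)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  a - outer(rm_, rm_, "+") + mean(a)
}

# Treatment-coded design matrix for an ordered term list.
# Returns X (with intercept), the assign vector (0 = intercept, k = k-th
# term), and the rows retained after missing-value removal.
build_design <- function(md, terms, ref_levels = NULL) {
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(vars, names(md))
  if (length(miss)) stop("variables absent from metadata: ",
                         paste(miss, collapse = ", "))
  vtab <- md_variables(md)
  data <- as.data.frame(md)[, vars, drop = FALSE]
  keep <- stats::complete.cases(data)
  data <- data[keep, , drop = FALSE]
  for (v in vars) {
    type <- if (!is.null(vtab) && v %in% vtab$name)
      vtab$type[match(v, vtab$name)]
    else if (is.numeric(data[[v]])) "numeric" else "categorical"
    if (type == "categorical") {
      f <- factor(data[[v]])
      ref <- ref_levels[[v]]
      if (!is.null(ref) && ref %in% levels(f)) f <- stats::relevel(f, ref)
      # a single observed level is constant: keep the term but let it alias
      # with the intercept (zero df) instead of crashing the contrasts
      data[[v]] <- if (nlevels(f) < 2) 0 else f
    } else data[[v]] <- as.numeric(data[[v]])
  }
  if (length(terms) == 0) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X, assign = 0L, keep = keep, data = data))
  }
  tm <- stats::terms(stats::reformulate(terms), keep.order = TRUE)
  X <- stats::model.matrix(tm, data)
  list(X = X, assign = attr(X, "assign"), keep = keep, data = data)
}

#' Distance-based PERMANOVA with sequential (Type I) sums of squares
#'
#' Fits the ordered term list to a Gower-centred distance matrix. Each term's
#' SS is the increase in `tr(H G H)` when the term's columns join the
#' cumulative hat projector, so the decomposition is sequential: confounders
#' placed first absorb shared variance before any candidate is assessed.
#' Pseudo-F is tested by unrestricted permutation of sample identities
#' (joint row/column permutation of the distance matrix), all term statistics
#' recomputed per permutation; p-values use the `(1 + #exceed)/(1 + B)`
#' convention.
#'
#' @param dm dist_matrix (or square distance matrix with dimnames).
#' @param md sample_metadata (or data.frame with a `sample_id` column).
#' @param terms character vector of model terms in entry order; interactions
#'   as "a:b".
#' @param confounders subset of `terms` forced to the front (added if absent).
#' @param B number of permutations (0 skips inference).
#' @param seed permutation RNG seed.
#' @param ref_levels named list of reference levels for categorical terms.
#' @param perm_matrix optional integer matrix, one permutation of `1:n` per
#'   row, used instead of random draws (pass every non-identity permutation
#'   for an exact test on small n).
#' @return object of class `permanova_result`: data.frame with one row per
#'   term plus a Residual row (term, df, SS, R2, F, p, aliased), and
#'   attributes `n`, `B`, `seed`, `SS_total`, `dropped_samples`.
#' @export
fit_permanova <- function(dm, md, terms, confounders = character(),
                          B = 999, seed = 1L, ref_levels = NULL,
                          perm_matrix = NULL) {
  if (!inherits(dm, "dist_matrix"))
    dm <- dist_matrix(as.matrix(dm), method = "generic")
  md <- as.data.frame_keep(md)
  idx <- match(dm$sample_ids, md$sample_id)
  if (anyNA(idx)) stop("distance matrix samples missing from metadata")
  md <- md_reindex(md, idx)
  terms <- c(confounders, setdiff(terms, confounders))
  des <- build_design(md, terms)
  dropped <- dm$sample_ids[!des$keep]
  if (length(dropped))
    msg("fit_permanova: dropped %d sample(s) with missing design values",
        length(dropped))
  ids <- dm$sample_ids[des$keep]
  n <- length(ids)
  K <- length(terms)
  p_model <- ncol(des$X)
  if (n < p_model + 2) stop("too few samples (", n, ") for ", p_model,
                            " design columns")
  G <- gower_center(dm_subset(dm, ids))
  ss_total <- sum(diag(G))

  # cumulative orthonormal bases and per-term hat increments
  H <- vector("list", K + 1L)      # H[[k+1]] = projector onto first k terms
  ranks <- integer(K + 1L)
  for (k in 0:K) {
    Xk <- des$X[, des$assign <= k, drop = FALSE]
    qrk <- qr(Xk)
    r <- qrk$rank
    Q <- qr.Q(qrk)[, seq_len(r), drop = FALSE]
    H[[k + 1L]] <- tcrossprod(Q)
    ranks[k + 1L] <- r
  }
  df_term <- diff(ranks)
  aliased <- df_term == 0L
  if (any(aliased))
    warning("aliased term(s) with zero df: ",
            paste(terms[aliased], collapse = ", "))
  df_res <- n - ranks[K + 1L]

  trGH <- vapply(H, function(h) sum(G * h), numeric(1))
  ss_term <- diff(trGH)
  ss_term[abs(ss_term) < 1e-12] <- 0
  ss_res <- ss_total - trGH[K + 1L]
  f_obs <- ifelse(df_term > 0,
                  (ss_term / df_term) / (ss_res / df_res), NA_real_)

  p_perm <- rep(NA_real_, K)
  if (!is.null(perm_matrix)) B <- nrow(perm_matrix)
  if (B > 0 && K > 0 && df_res > 0 && ss_res > 0) {
    set.seed(seed)
    exceed <- numeric(K)
    for (b in seq_len(B)) {
      p <- if (is.null(perm_matrix)) sample.int(n) else perm_matrix[b, ]
      Gp <- G[p, p]
      trp <- vapply(H, function(h) sum(Gp * h), numeric(1))
      ssp <- diff(trp)
      ssrp <- ss_total - trp[K + 1L]
      fp <- ifelse(df_term > 0, (ssp / df_term) / (ssrp / df_res), -Inf)
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
    p_perm <- ifelse(df_term > 0, (1 + exceed) / (1 + B), NA_real_)
  }

  res <- data.frame(
    term = c(terms, "Residual"),
    df = c(df_term, df_res),
    SS = c(ss_term, ss_res),
    R2 = c(ss_term, ss_res) / ss_total,
    F = c(f_obs, NA_real_),
    p = c(p_perm, NA_real_),
    aliased = c(aliased, FALSE),
    row.names = NULL)
  structure(res, class = c("permanova_result", "data.frame"),
            n = n, B = B, seed = seed, SS_total = ss_total,
            confounders = confounders, dropped_samples = dropped)
}

as.data.frame_keep <- function(md) {
  if (!"sample_id" %in% names(md)) stop("metadata needs a sample_id column")
  md
}

md_reindex <- function(md, idx) {
  out <- md[idx, , drop = FALSE]
  attr(out, "variables") <- attr(md, "variables")
  class(out) <- class(md)
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS), n = %d, B = %d permutations\n",
              attr(x, "n"), attr(x, "B")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Screen one candidate variable after technical confounders
#'
#' Fits `(confounders..., variable)` and reports the candidate's sequential
#' R2 and permutation p after the confounders have absorbed their share.
#'
#' @inheritParams fit_permanova
#' @param variable candidate variable name.
#' @param check_usable honour [screen_variables()] exclusions for the scope
#'   spanned by `dm`?
#' @return permanova_result; the candidate is the last non-residual row.
#' @export
screen_variable <- function(dm, md, variable, confounders = character(),
                            B = 999, seed = 1L, ref_levels = NULL,
                            check_usable = TRUE) {
  if (variable %in% confounders) stop("variable is itself a confounder")
  if (check_usable && !is.null(md_exclusions(md))) {
    ids <- dm$sample_ids
    sub <- md[md$sample_id %in% ids, , drop = FALSE]
    scopes <- unique(sub[, c("role", "timepoint")])
    ok <- any(vapply(seq_len(nrow(scopes)), function(i)
      variable_usable(md, variable, scopes$role[i], scopes$timepoint[i]),
      logical(1)))
    if (!ok) stop("variable '", variable,
                  "' excluded by screening in this scope: ",
                  paste(md_exclusions(md)$reason[
                    md_exclusions(md)$variable == variable][1]))
  }
  fit_permanova(dm, md, c(confounders, variable), confounders,
                B = B, seed = seed, ref_levels = ref_levels)
}

#' Beta-dispersion homogeneity test (PERMDISP)
#'
#' Principal-coordinate embedding of the distance matrix keeping every axis;
#' each sample's squared distance to its group centroid is the sum of squared
#' coordinate differences over positive-eigenvalue axes minus the sum over
#' negative-eigenvalue axes (floored at zero before the square root), the
#' standard correction for semi-metric distances such as Bray-Curtis. A
#' one-way F on the centroid distances is tested by permuting group labels.
#'
#' @param dm dist_matrix.
#' @param md sample_metadata.
#' @param variable categorical grouping variable.
#' @param B permutations.
#' @param seed RNG seed.
#' @return list with `distances` (per-sample centroid distance), `F`, `p`,
#'   `uneven` flag (p < 0.05), `groups`.
#' @export
permdisp <- function(dm, md, variable, B = 999, seed = 1L) {
  md <- as.data.frame_keep(md)
  g0 <- md[[variable]][match(dm$sample_ids, md$sample_id)]
  keep <- !is.na(g0)
  dmk <- dm_subset(dm, dm$sample_ids[keep])
  g <- factor(as.character(md[[variable]][match(dmk$sample_ids,
                                                md$sample_id)]))
  sizes <- table(g)
  if (any(sizes < 2)) {
    warning("dropping level(s) with a single sample: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep2 <- g %in% names(sizes)[sizes >= 2]
    dmk <- dm_subset(dmk, dmk$sample_ids[keep2])
    g <- droplevels(g[keep2])
  }
  if (nlevels(g) < 2) stop("need >= 2 non-empty levels")
  G <- gower_center(dmk)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  use <- abs(eig$values) > tol
  lam <- eig$values[use]
  coords <- eig$vectors[, use, drop = FALSE] %*% diag(sqrt(abs(lam)),
                                                      sum(use))
  pos <- lam > 0
  dist_to_centroid <- function(grp) {
    z <- numeric(length(grp))
    for (lev in levels(grp)) {
      i <- which(grp == lev)
      cen <- colMeans(coords[i, , drop = FALSE])
      d2 <- sweep(coords[i, , drop = FALSE], 2, cen)^2
      zsq <- rowSums(d2[, pos, drop = FALSE]) -
        rowSums(d2[, !pos, drop = FALSE])
      z[i] <- sqrt(pmax(zsq, 0))
    }
    z
  }
  z <- dist_to_centroid(g)
  f_stat <- function(z, grp) {
    gm <- mean(z)
    ng <- tabulate(grp)
    mns <- tapply(z, grp, mean)
    ssb <- sum(ng * (mns - gm)^2)
    ssw <- sum((z - mns[as.integer(grp)])^2)
    dfb <- nlevels(grp) - 1L; dfw <- length(z) - nlevels(grp)
    if (ssw <= 1e-14) return(NA_real_)
    (ssb / dfb) / (ssw / dfw)
  }
  f_obs <- f_stat(z, g)
  if (is.na(f_obs)) {
    warning("degenerate dispersion (all centroid distances equal); ",
            "reported non-significant")
    return(list(distances = stats::setNames(z, dmk$sample_ids), F = NA_real_,
                p = NA_real_, uneven = FALSE, groups = g))
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(B)) {
    gp <- g[sample.int(length(g))]
    zp <- dist_to_centroid(gp)
    fp <- f_stat(zp, gp)
    if (!is.na(fp) && fp >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + B)
  list(distances = stats::setNames(z, dmk$sample_ids), F = f_obs, p = p,
       uneven = p < 0.05, groups = g)
}

#' Within- versus between-batch community similarity
#'
#' Within a stratum (one sample role and timepoint), compares the multiset of
#' pairwise distances between samples sharing an extraction batch against
#' pairs from different batches, with an unpaired Wilcoxon rank-sum test.
#' Lower within-batch distances indicate a batch effect.
#'
#' @param dm dist_matrix.
#' @param md sample_metadata.
#' @param batch_variable batch column name.
#' @param role,timepoint stratum selectors (NULL = use every sample in `dm`).
#' @return list with `statistic`, `p`, `median_within`, `median_between`,
#'   `n_within`, `n_between`.
#' @export
within_batch_similarity_test <- function(dm, md, batch_variable = "batch",
                                         role = NULL, timepoint = NULL) {
  md <- as.data.frame_keep(md)
  sel <- md$sample_id %in% dm$sample_ids
  if (!is.null(role)) sel <- sel & md$role == role
  if (!is.null(timepoint)) sel <- sel & md$timepoint == timepoint
  ids <- md$sample_id[sel]
  b <- md[[batch_variable]][sel]
  ok <- !is.na(b)
  ids <- ids[ok]; b <- b[ok]
  if (length(ids) < 4) stop("too few samples in stratum")
  dmk <- dm_subset(dm, ids)
  b <- b[match(dmk$sample_ids, ids)]
  n <- length(b)
  same <- outer(b, b, "==")
  ut <- upper.tri(same)
  within <- dmk$values[ut][same[ut]]
  between <- dmk$values[ut][!same[ut]]
  if (!length(within)) stop("no within-batch pairs in stratum")
  if (!length(between)) stop("no between-batch pairs in stratum")
  wt <- stats::wilcox.test(within, between, exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_within = stats::median(within),
       median_between = stats::median(between),
       n_within = length(within), n_between = length(between))
}
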