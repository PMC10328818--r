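#' Prevalence filter for per-taxon testing
#'
#' Retains taxa detected (nonzero) in strictly more than `threshold` of the
#' samples.
#'
#' @param ct count_table.
#' @param threshold prevalence fraction (default 0.10).
#' @return character vector of retained taxon ids.
#' @export
prevalence_filter <- function(ct, threshold = 0.10) {
  prev <- rowMeans(ct$counts > 0)
  ct$taxa$taxon_id[prev > threshold]
}

# one taxon's fit through the NB -> Poisson -> quasi-Poisson -> GLS cascade
fit_one_taxon <- function(y, data, form, reads) {
  diag_ <- list(family = NA_character_, nb_converged = NA,
                poisson_ratio = NA_real_)
  out <- NULL
  nb <- tryCatch(suppressWarnings(
    MASS::glm.nb(stats::as.formula(paste("y ~", form,
                                         "+ offset(log(reads))")),
                 data = cbind(data, y = y, reads = reads),
                 control = stats::glm.control(maxit = 50))),
    error = function(e) NULL)
  nb_ok <- !is.null(nb) && isTRUE(nb$converged) &&
    is.finite(nb$theta) && nb$theta > 1e-3 && nb$theta < 1e5
  diag_$nb_converged <- nb_ok
  if (nb_ok) {
    out <- nb; diag_$family <- "NB"
  } else {
    po <- tryCatch(suppressWarnings(
      stats::glm(stats::as.formula(paste("y ~", form,
                                         "+ offset(log(reads))")),
                 family = stats::poisson(),
                 data = cbind(data, y = y, reads = reads))),
      error = function(e) NULL)
    if (!is.null(po) && isTRUE(po$converged)) {
      ratio <- sum(stats::residuals(po, "pearson")^2) / po$df.residual
      diag_$poisson_ratio <- ratio
      if (ratio > 1.5) {
        qp <- tryCatch(suppressWarnings(
          stats::glm(stats::as.formula(paste("y ~", form,
                                             "+ offset(log(reads))")),
                     family = stats::quasipoisson(),
                     data = cbind(data, y = y, reads = reads))),
          error = function(e) NULL)
        if (!is.null(qp) && isTRUE(qp$converged)) {
          out <- qp; diag_$family <- "quasi-Poisson"
        }
      } else {
        out <- po; diag_$family <- "Poisson"
      }
    }
  }
  if (is.null(out)) {
    # last resort: GLS on log relative abundance with a scale-aware
    # pseudo-abundance (half the minimum nonzero relative abundance)
    rel <- y / reads
    nz <- rel[rel > 0]
    pseudo <- if (length(nz)) min(nz) / 2 else 0.5 / max(reads)
    gls_fit <- tryCatch(suppressWarnings(
      nlme::gls(stats::as.formula(paste("lrel ~", form)),
                data = cbind(data, lrel = log(rel + pseudo)))),
      error = function(e) NULL)
    if (!is.null(gls_fit)) {
      out <- gls_fit; diag_$family <- "GLS"
    }
  }
  list(fit = out, diagnostics = diag_)
}

#' Differential abundance against a covariate via a model-fit cascade
#'
#' Per retained taxon, fits a negative-binomial log-linear model
#' `count ~ covariate (+ adjust)` with log read depth as offset. On NB
#' failure (non-convergence or a dispersion estimate at the boundary) the
#' taxon falls back to Poisson; an overdispersed Poisson fit (Pearson
#' chi-square per residual df > 1.5) is refit as quasi-Poisson; if no count
#' model fits, generalised least squares on log relative abundance is used.
#' Wald p-values per non-reference level; BH-FDR across taxa within each
#' contrast; the dual rule (p < 0.05 and q < 0.1) flags significance.
#'
#' @param ct genus-level count_table.
#' @param md sample_metadata.
#' @param covariate covariate of interest.
#' @param adjust optional adjustment variable (e.g. extraction batch), or
#'   NULL.
#' @param reference reference level for a categorical covariate (default:
#'   first level alphabetically).
#' @param threshold prevalence threshold (default 0.10).
#' @param min_n minimal non-missing samples (default 20).
#' @return data.frame of class `da_result`: taxon, contrast, family,
#'   estimate (log fold-change vs reference), se, p, q, prevalence,
#'   significant, plus cascade diagnostics.
#' @export
fit_da <- function(ct, md, covariate, adjust = NULL, reference = NULL,
                   threshold = 0.10, min_n = 20) {
  md <- as.data.frame_keep(md)
  idx <- match(ct$sample_ids, md$sample_id)
  x <- md[[covariate]][idx]
  ok <- !is.na(x)
  if (!is.null(adjust)) ok <- ok & !is.na(md[[adjust]][idx])
  if (sum(ok) < min_n) stop("fewer than ", min_n,
                            " samples with non-missing covariate")
  ct <- ct_subset(ct, samples = ct$sample_ids[ok])
  idx <- match(ct$sample_ids, md$sample_id)
  x <- md[[covariate]][idx]
  vtab <- md_variables(md)
  categorical <- if (!is.null(vtab) && covariate %in% vtab$name)
    vtab$type[match(covariate, vtab$name)] == "categorical"
  else !is.numeric(x)
  if (categorical) {
    x <- factor(x)
    if (length(levels(x)) < 2) stop("covariate is constant")
    if (!is.null(reference)) x <- stats::relevel(x, reference)
  } else {
    x <- as.numeric(x)
    if (stats::var(x) == 0) stop("covariate is constant")
  }
  data <- data.frame(xvar = x)
  form <- "xvar"
  if (!is.null(adjust)) {
    data$adj <- factor(md[[adjust]][idx])
    if (nlevels(data$adj) > 1) form <- "xvar + adj"
  }
  reads <- ct$depths
  keep_taxa <- prevalence_filter(ct, threshold)
  rows <- list()
  for (tx in keep_taxa) {
    y <- ct$counts[match(tx, ct$taxa$taxon_id), ]
    f <- fit_one_taxon(y, data, form, reads)
    prev <- mean(y > 0)
    if (is.null(f$fit)) {
      rows[[tx]] <- data.frame(taxon = tx, contrast = NA, family = "unfit",
                               estimate = NA, se = NA, p = NA,
                               prevalence = prev,
                               nb_converged = f$diagnostics$nb_converged,
                               poisson_ratio = f$diagnostics$poisson_ratio)
      next
    }
    cf <- if (inherits(f$fit, "gls")) {
      s <- summary(f$fit)$tTable
      data.frame(name = rownames(s), est = s[, "Value"],
                 se = s[, "Std.Error"], row.names = NULL)
    } else {
      s <- summary(f$fit)$coefficients
      data.frame(name = rownames(s), est = s[, 1], se = s[, 2],
                 row.names = NULL)
    }
    want <- grep("^xvar", cf$name)
    for (w in want) {
      contrast <- if (categorical)
        paste0(sub("^xvar", "", cf$name[w]), " vs ",
               levels(x)[1])
      else covariate
      z <- cf$est[w] / cf$se[w]
      rows[[paste(tx, w)]] <- data.frame(
        taxon = tx, contrast = contrast, family = f$diagnostics$family,
        estimate = cf$est[w], se = cf$se[w],
        p = 2 * stats::pnorm(-abs(z)), prevalence = prev,
        nb_converged = f$diagnostics$nb_converged,
        poisson_ratio = f$diagnostics$poisson_ratio)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  for (ctr in unique(stats::na.omit(out$contrast))) {
    i <- which(!is.na(out$contrast) & out$contrast == ctr &
                 out$family != "unfit")
    out$q[i] <- bh_fdr(out$p[i])
  }
  out$significant <- !is.na(out$p) & out$p < 0.05 & !is.na(out$q) &
    out$q < 0.1
  attr(out, "covariate") <- covariate
  attr(out, "reference") <- if (categorical) levels(x)[1] else NA
  class(out) <- c("da_result", "data.frame")
  out
}

#' Signed significance table across timepoints
#'
#' Long-format table for heatmap rendering: per taxon and timepoint, the sign
#' of the coefficient gated by the dual significance rule, plus the
#' log-fold-change itself.
#'
#' @param results named list of [fit_da()] results, one per timepoint, all
#'   with the same contrast structure.
#' @return data.frame (taxon, timepoint, contrast, direction, lfc).
#' @export
da_direction_table <- function(results) {
  out <- list()
  for (tp in names(results)) {
    r <- results[[tp]]
    r <- r[!is.na(r$contrast) & r$family != "unfit", , drop = FALSE]
    if (!nrow(r)) next
    out[[tp]] <- data.frame(taxon = r$taxon, timepoint = tp,
                            contrast = r$contrast,
                            direction = sign(r$estimate) * r$significant,
                            lfc = r$estimate)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
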