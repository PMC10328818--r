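#' Small-sample corrected Akaike criterion for distance models
#'
#' Default form is the standard least-squares AICc,
#' `2k + n*ln(RSS/n) + 2k(k+1)/(n-k-1)`, with RSS the residual sum of squares
#' of the distance model and k the number of design-matrix columns including
#' the intercept (aliased columns excluded). A "literal" variant,
#' `2k + n + ln(RSS/n) + 2k(k+1)/(n-k-1)`, is selectable; it replaces the
#' multiplicative coupling of n and fit quality by an additive one and is
#' kept only for comparability.
#'
#' @param n number of samples.
#' @param k number of model parameters (design columns incl. intercept).
#' @param rss residual sum of squares (> 0).
#' @param form "standard" or "literal".
#' @return AICc value.
#' @export
aicc <- function(n, k, rss, form = c("standard", "literal")) {
  form <- match.arg(form)
  if (n <= k + 1) stop("n must exceed k + 1 (correction term singular)")
  if (rss <= 0) stop("rss must be positive")
  corr <- 2 * k * (k + 1) / (n - k - 1)
  if (form == "standard") 2 * k + n * log(rss / n) + corr
  else 2 * k + n + log(rss / n) + corr
}

# residual SS and parameter count of one distance model
model_rss <- function(G, md, terms, ref_levels = NULL) {
  des <- build_design(md, terms, ref_levels)
  qrx <- qr(des$X)
  r <- qrx$rank
  Q <- qr.Q(qrx)[, seq_len(r), drop = FALSE]
  ss_total <- sum(diag(G))
  rss <- ss_total - sum(Q * (G %*% Q))
  list(rss = max(rss, 1e-12), k = r, n = nrow(des$X))
}

interactions_of <- function(terms) terms[grepl(":", terms, fixed = TRUE)]

droppable_terms <- function(candidates) {
  ints <- interactions_of(candidates)
  parents <- unique(unlist(strsplit(ints, ":", fixed = TRUE)))
  c(ints, setdiff(candidates, c(ints, parents)))
}

#' Backward elimination of cumulative PERMANOVA terms under AICc
#'
#' Starts from the full model (confounders + candidates, interactions last),
#' and at each step evaluates the removal of every droppable term — an
#' interaction before its main effects, a main only once no retained
#' interaction references it. The single removal with the lowest AICc is
#' accepted if it improves the criterion by at least `min_improvement` (2
#' units); otherwise selection stops. Confounders are never droppable.
#' Permutation p-values are computed only for the initial and final models.
#'
#' @inheritParams fit_permanova
#' @param candidates candidate terms (mains and admitted "a:b" interactions).
#' @param min_improvement required AICc drop to accept a removal (default 2).
#' @param form AICc form, see [aicc()].
#' @return list of class `selection_trace`: `steps` data.frame (step, action,
#'   term, k, n, rss, aicc), `final_terms`, `final_fit` (permanova_result),
#'   `initial_fit`, `form`.
#' @export
backward_select <- function(dm, md, candidates, confounders = character(),
                            B = 999, seed = 1L, min_improvement = 2,
                            form = "standard", ref_levels = NULL) {
  if (!length(candidates)) {
    fit <- fit_permanova(dm, md, confounders, confounders, B = B, seed = seed,
                         ref_levels = ref_levels)
    return(structure(list(steps = data.frame(), final_terms = confounders,
                          final_fit = fit, initial_fit = fit, form = form),
                     class = "selection_trace"))
  }
  terms_all <- c(confounders, candidates)
  init <- fit_permanova(dm, md, terms_all, confounders, B = B, seed = seed,
                        ref_levels = ref_levels)
  aliased <- init$term[init$aliased & init$term %in% candidates]
  if (length(aliased)) {
    warning("dropping aliased candidate(s) with zero df: ",
            paste(aliased, collapse = ", "))
    candidates <- setdiff(candidates, aliased)
  }
  # complete-case data fixed across the whole selection
  des <- build_design(md_reindex(md, match(dm$sample_ids, md$sample_id)),
                      unique(c(confounders, candidates)))
  ids <- dm$sample_ids[des$keep]
  mdk <- md_reindex(md, match(ids, md$sample_id))
  G <- gower_center(dm_subset(dm, ids))

  cur <- candidates
  m0 <- model_rss(G, mdk, c(confounders, cur), ref_levels)
  cur_aicc <- aicc(m0$n, m0$k, m0$rss, form)
  steps <- list()
  steps[[1]] <- data.frame(step = 0L, action = "start", term = "",
                           k = m0$k, n = m0$n, rss = m0$rss,
                           aicc = cur_aicc)
  repeat {
    dr <- droppable_terms(cur)
    if (!length(dr)) break
    cand_fits <- lapply(dr, function(t) {
      reduced <- setdiff(cur, t)
      m <- model_rss(G, mdk, c(confounders, reduced), ref_levels)
      c(aicc = aicc(m$n, m$k, m$rss, form), k = m$k, rss = m$rss)
    })
    av <- vapply(cand_fits, `[[`, 0, "aicc")
    best <- min(av)
    if (cur_aicc - best < min_improvement) break
    tied <- which(av <= best + 1e-9)
    if (length(tied) > 1) {
      # prefer the largest-df removal (smallest reduced k), then by name
      ks <- vapply(cand_fits[tied], `[[`, 0, "k")
      tied <- tied[ks == min(ks)]
      tied <- tied[order(dr[tied])]
    }
    pick <- tied[1]
    cur <- setdiff(cur, dr[pick])
    cur_aicc <- av[pick]
    steps[[length(steps) + 1]] <- data.frame(
      step = length(steps) - 0L, action = "drop", term = dr[pick],
      k = cand_fits[[pick]][["k"]], n = m0$n,
      rss = cand_fits[[pick]][["rss"]], aicc = cur_aicc)
  }
  steps[[length(steps) + 1]] <- {
    m <- model_rss(G, mdk, c(confounders, cur), ref_levels)
    data.frame(step = length(steps), action = "stop", term = "",
               k = m$k, n = m$n, rss = m$rss, aicc = cur_aicc)
  }
  final <- fit_permanova(dm, md, c(confounders, cur), confounders,
                         B = B, seed = seed, ref_levels = ref_levels)
  structure(list(steps = do.call(rbind, steps),
                 final_terms = c(confounders, cur),
                 final_fit = final, initial_fit = init, form = form),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("AICc backward selection (", x$form, " form)\n", sep = "")
  print.data.frame(x$steps, digits = 5, row.names = FALSE)
  cat("final terms:", paste(x$final_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Pooled all-timepoint model with subject identity and age
#'
#' One sequential fit on the distance matrix over every infant sample:
#' read-depth confounder first, then subject identity, sampling age, and the
#' remaining variables. Subject identity is categorical (subjects with a
#' single sample contribute df and are permitted, with a note); age is the
#' timepoint label.
#'
#' @inheritParams fit_permanova
#' @param terms additional variables after subject and age.
#' @param confounders confounder terms (default "reads").
#' @param subject,age column names for subject identity and sampling age.
#' @return permanova_result.
#' @export
pooled_model <- function(dm, md, terms = character(),
                         confounders = "reads", subject = "subject_id",
                         age = "timepoint", B = 199, seed = 1L) {
  md <- as.data.frame_keep(md)
  sub <- md[match(dm$sample_ids, md$sample_id), ]
  if (length(unique(sub[[age]])) < 2)
    stop("age term needs >= 2 timepoints (df 0); refused")
  ones <- names(which(table(sub[[subject]]) == 1))
  if (length(ones))
    msg("pooled_model: %d subject(s) contribute a single sample",
        length(ones))
  md2 <- md
  md2[[subject]] <- as.character(md2[[subject]])
  md2[[age]] <- as.character(md2[[age]])
  v <- attr(md, "variables")
  if (!is.null(v)) {
    for (nm in c(subject, age)) if (!nm %in% v$name) {
      add <- v[1, , drop = FALSE]
      add$name <- nm; add$type <- "categorical"; add$role <- "biological"
      add$levels <- NA
      v <- rbind(v, add)
    }
    attr(md2, "variables") <- v
  }
  fit_permanova(dm, md2, c(confounders, subject, age, terms), confounders,
                B = B, seed = seed)
}
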