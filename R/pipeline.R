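#' Run configuration for the full analysis graph
#'
#' @param out_dir output directory.
#' @param rank taxonomic rank for distances (default "genus").
#' @param distance distance method (default "bray_curtis").
#' @param confounders technical confounders, placed first in every adjusted
#'   model (default extraction batch and processed reads).
#' @param B permutations (default 199 for the orchestrated run).
#' @param seed base seed.
#' @param p_threshold,q_threshold dual significance rule (0.05 / 0.1).
#' @param prevalence DA prevalence threshold (0.10).
#' @param aicc_improvement required AICc improvement (2).
#' @param depth_cutoff_early,depth_cutoff_late read-depth QC cutoffs
#'   (3000 / 5000).
#' @param max_unknown unknown-annotation sample cutoff (0.20).
#' @export
run_config <- function(out_dir, rank = "genus", distance = "bray_curtis",
                       confounders = c("batch", "reads"), B = 199,
                       seed = 1L, p_threshold = 0.05, q_threshold = 0.1,
                       prevalence = 0.10, aicc_improvement = 2,
                       depth_cutoff_early = 3000, depth_cutoff_late = 5000,
                       max_unknown = 0.20) {
  stopifnot(p_threshold > 0, q_threshold > 0, prevalence > 0,
            aicc_improvement > 0)
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(cfg) {
  # hash the analysis parameters, not the output location
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  s <- paste(vapply(cfg, function(x) paste(format(x), collapse = ","), ""),
             collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 968742591
  sprintf("%09d", h)
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Execute the full variance-partitioning analysis graph
#'
#' QC filters, genus aggregation, per-timepoint distances, unadjusted
#' technical-variable screen, confounder-adjusted biological screen with
#' dispersion flags, interaction screen over significant pairs, stratified
#' parity analysis, AICc cumulative models per timepoint, the pooled
#' all-timepoint model, the alpha-diversity panel, differential abundance,
#' and family-dyad distances. Every table lands in `cfg$out_dir` with a
#' manifest recording the seed and a config hash.
#'
#' @param ct count_table (raw, genus rows, may contain unknown taxa).
#' @param md sample_metadata.
#' @param cfg [run_config()].
#' @param stages subset of stage names to run (default all).
#' @return invisibly, the output directory.
#' @export
run_full <- function(ct, md, cfg, stages = NULL) {
  all_stages <- c("qc", "distances", "screen_technical", "screen_biological",
                  "interactions", "stratified", "cumulative", "pooled",
                  "diversity", "da", "dyads")
  stages <- stages %||% all_stages
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("config_hash\t%s", config_hash(cfg)),
                sprintf("seed\t%d", cfg$seed),
                sprintf("B\t%d", cfg$B),
                sprintf("stages\t%s", paste(stages, collapse = ",")))
  writeLines(manifest, file.path(cfg$out_dir, "manifest.tsv"))

  stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    msg("[stage %s]", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }

  # --- qc -------------------------------------------------------------------
  qc <- stage("qc", {
    f1 <- filter_samples_by_depth(ct, md, cfg$depth_cutoff_early,
                                  cfg$depth_cutoff_late)
    f2 <- filter_unknown_fraction(f1$counts, cfg$max_unknown)
    keep <- f2$counts$sample_ids
    md2 <- screen_variables(md_subset(f1$metadata,
                                      f1$metadata$sample_id %in% keep))
    write_tsv(data.frame(
      sample_id = c(f1$removed$sample_id, f2$removed_samples),
      reason = c(rep("low_depth", nrow(f1$removed)),
                 rep("unknown_fraction", length(f2$removed_samples)))),
      cfg$out_dir, "qc_removed_samples.tsv")
    write_tsv(md_exclusions(md2), cfg$out_dir, "qc_excluded_variables.tsv")
    list(ct = f2$counts, md = md2)
  })
  if (is.null(qc)) qc <- list(ct = ct, md = screen_variables(md))
  ctq <- aggregate_taxa(qc$ct, cfg$rank)
  mdq <- qc$md
  infant_tps <- intersect(tp_levels(), unique(mdq$timepoint))

  dms <- stage("distances", {
    dms <- list()
    for (tp in infant_tps) {
      ids <- mdq$sample_id[mdq$role == "infant" & mdq$timepoint == tp]
      ids <- intersect(ids, ctq$sample_ids)
      if (length(ids) < 10) next
      dms[[tp]] <- community_distance(ct_subset(qc$ct, samples = ids),
                                      cfg$distance, cfg$rank)
    }
    dms
  })
  if (is.null(dms)) stop("distance stage required downstream")

  tech_vars <- setdiff(md_vars_by_role(mdq, "technical"), cfg$confounders)
  bio_vars <- setdiff(md_vars_by_role(mdq, "biological"),
                      c("delivery_mode", "intrapartum_ab"))

  rep_tech <- stage("screen_technical", {
    r <- screen_all(dms, mdq, c(tech_vars, cfg$confounders),
                    confounders = character(), B = cfg$B, seed = cfg$seed)
    write_tsv(r, cfg$out_dir, "screen_technical.tsv")
    r
  })

  rep_bio <- stage("screen_biological", {
    r <- screen_all(dms, mdq, bio_vars, cfg$confounders,
                    B = cfg$B, seed = cfg$seed)
    write_tsv(r, cfg$out_dir, "screen_biological.tsv")
    r
  })

  admitted <- stage("interactions", {
    ia <- list()
    if (!is.null(rep_bio)) {
      sig_by_tp <- split(rep_bio$variable[rep_bio$significant],
                         rep_bio$timepoint[rep_bio$significant])
      for (tp in names(sig_by_tp)) {
        vs <- unique(sig_by_tp[[tp]])
        if (length(vs) < 2) next
        for (i in seq_along(vs)) for (j in seq_len(i - 1)) {
          r <- tryCatch(screen_interaction(dms[[tp]], mdq, vs[j], vs[i],
                                           cfg$confounders, B = cfg$B,
                                           seed = cfg$seed),
                        error = function(e) NULL)
          if (!is.null(r))
            ia[[length(ia) + 1]] <- data.frame(
              timepoint = tp, interaction = paste0(vs[j], ":", vs[i]),
              R2 = r$R2, p = r$p, admitted = r$admitted)
        }
      }
    }
    iadf <- if (length(ia)) do.call(rbind, ia) else
      data.frame(timepoint = character(), interaction = character(),
                 R2 = numeric(), p = numeric(), admitted = logical())
    write_tsv(iadf, cfg$out_dir, "interactions.tsv")
    iadf
  })

  stage("stratified", {
    out <- list()
    for (tp in names(dms)) {
      r <- tryCatch(stratified_screen(dms[[tp]], mdq, "parity", "delivery3",
                                      cfg$confounders, B = cfg$B,
                                      seed = cfg$seed),
                    error = function(e) NULL)
      if (!is.null(r)) out[[tp]] <- cbind(timepoint = tp, r)
    }
    if (length(out))
      write_tsv(do.call(rbind, out), cfg$out_dir, "stratified_parity.tsv")
  })

  stage("cumulative", {
    out <- list()
    for (tp in names(dms)) {
      cand <- unique(rep_bio$variable[rep_bio$significant &
                                        rep_bio$timepoint == tp])
      if (!is.null(admitted) && nrow(admitted))
        cand <- c(cand, admitted$interaction[admitted$admitted &
                                               admitted$timepoint == tp])
      if (!length(cand)) next
      tr <- backward_select(dms[[tp]], mdq, cand, cfg$confounders,
                            B = cfg$B, seed = cfg$seed,
                            min_improvement = cfg$aicc_improvement)
      ff <- tr$final_fit
      out[[tp]] <- data.frame(timepoint = tp, term = ff$term, df = ff$df,
                              SS = ff$SS, R2 = ff$R2, F = ff$F, p = ff$p)
      write_tsv(tr$steps, cfg$out_dir,
                sprintf("cumulative_trace_%s.tsv", tp))
    }
    if (length(out))
      write_tsv(do.call(rbind, out), cfg$out_dir, "cumulative_models.tsv")
  })

  stage("pooled", {
    ids <- mdq$sample_id[mdq$role == "infant"]
    ids <- intersect(ids, ctq$sample_ids)
    dm_all <- community_distance(ct_subset(qc$ct, samples = ids),
                                 cfg$distance, cfg$rank)
    extra <- unique(rep_bio$variable[rep_bio$significant])
    extra <- extra[vapply(extra, function(v)
      !any(is.na(mdq[[v]][match(ids, mdq$sample_id)])), logical(1))]
    pf <- pooled_model(dm_all, mdq, extra, confounders = "reads",
                       B = cfg$B, seed = cfg$seed)
    write_tsv(as.data.frame(pf), cfg$out_dir, "pooled_model.tsv")
  })

  stage("diversity", {
    ap <- alpha_panel(ctq, seed = cfg$seed)
    write_tsv(ap, cfg$out_dir, "alpha_panel.tsv")
  })

  stage("da", {
    out <- list()
    for (tp in names(dms)) {
      ids <- mdq$sample_id[mdq$role == "infant" & mdq$timepoint == tp]
      ids <- intersect(ids, ctq$sample_ids)
      r <- tryCatch(fit_da(ct_subset(ctq, samples = ids), mdq, "delivery3",
                           adjust = "batch", reference = "VD-AB",
                           threshold = cfg$prevalence),
                    error = function(e) NULL)
      if (!is.null(r)) out[[tp]] <- r
    }
    if (length(out)) {
      write_tsv(da_direction_table(out), cfg$out_dir,
                "da_delivery_directions.tsv")
      long <- do.call(rbind, lapply(names(out), function(tp)
        cbind(timepoint = tp, as.data.frame(out[[tp]]))))
      write_tsv(long, cfg$out_dir, "da_delivery.tsv")
    }
  })

  stage("dyads", {
    if (any(mdq$role != "infant")) {
      ids <- ctq$sample_ids
      dm_all <- community_distance(ct_subset(qc$ct, samples = ids),
                                   cfg$distance, cfg$rank)
      out <- list()
      for (tp in names(dms)) for (dy in c("mother-infant", "father-infant")) {
        r <- tryCatch(family_dyad_analysis(dm_all, mdq, dy, tp),
                      error = function(e) NULL)
        if (!is.null(r))
          out[[paste(dy, tp)]] <- data.frame(
            dyad = dy, timepoint = tp, p = r$p,
            median_within = r$median_within,
            median_between = r$median_between)
      }
      if (length(out))
        write_tsv(do.call(rbind, out), cfg$out_dir, "family_dyads.tsv")
    }
  })

  invisible(cfg$out_dir)
}
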