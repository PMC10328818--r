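#' Per-sample metadata with declared variable types and roles
#'
#' A data.frame with one row per sample and mandatory columns `sample_id`,
#' `subject_id`, `family_id`, `role` (infant/mother/father), `timepoint`,
#' plus covariate columns. A variable-declaration table travels with it as an
#' attribute: each covariate has a `type` (categorical/numeric), a `role`
#' (biological/technical/confounder) and, for categoricals, its level set.
#' Missing values are an explicit `NA`, never zero.
#'
#' @param df data.frame of samples.
#' @param variables data.frame with columns `name`, `type`
#'   ("categorical"/"numeric"), `role` ("biological"/"technical"/"confounder")
#'   and optional `levels` (comma-separated). Variables absent from the table
#'   are treated as identifiers, not covariates.
#' @return object of class `sample_metadata` (a data.frame).
#' @export
sample_metadata <- function(df, variables) {
  need <- c("sample_id", "subject_id", "family_id", "role", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  stopifnot(all(c("name", "type", "role") %in% names(variables)))
  bad <- setdiff(variables$name, names(df))
  if (length(bad)) stop("declared variables absent from metadata: ",
                        paste(bad, collapse = ", "))
  for (v in variables$name[variables$type == "categorical"])
    df[[v]] <- as.character(df[[v]])
  attr(df, "variables") <- variables
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Variable declarations of a sample_metadata
#' @param md sample_metadata.
#' @return the declaration data.frame.
#' @export
md_variables <- function(md) attr(md, "variables")

#' Names of variables with a given role
#' @param md sample_metadata.
#' @param role one of "biological", "technical", "confounder", or "any".
#' @param include_excluded keep variables marked excluded by
#'   [screen_variables()]?
#' @export
md_vars_by_role <- function(md, role = "any", include_excluded = FALSE) {
  v <- md_variables(md)
  keep <- if (role == "any") rep(TRUE, nrow(v)) else v$role == role
  if (!include_excluded && !is.null(v$excluded)) keep <- keep & !v$excluded
  v$name[keep]
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("sample_metadata: %d samples, %d declared variables\n",
              nrow(x), nrow(md_variables(x))))
  NextMethod()
}

md_subset <- function(md, keep) {
  out <- md[keep, , drop = FALSE]
  attr(out, "variables") <- md_variables(md)
  class(out) <- class(md)
  out
}

#' Read metadata TSV plus its variable-declaration sidecar
#'
#' The sidecar is YAML: a list of entries `name`, `type`, `role`, optional
#' `levels`.
#'
#' @param path metadata TSV (one row per sample).
#' @param decl_path YAML sidecar path.
#' @return [sample_metadata()]
#' @export
read_metadata <- function(path, decl_path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  decl <- yaml::read_yaml(decl_path)
  variables <- do.call(rbind, lapply(decl, function(d)
    data.frame(name = d$name, type = d$type, role = d$role,
               levels = if (is.null(d$levels)) NA_character_ else
                 paste(d$levels, collapse = ","))))
  sample_metadata(df, variables)
}

#' Write metadata TSV and YAML variable declarations
#' @param md sample_metadata.
#' @param path metadata TSV destination.
#' @param decl_path YAML sidecar destination.
#' @export
write_metadata <- function(md, path, decl_path) {
  utils::write.table(as.data.frame(md), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  v <- md_variables(md)
  decl <- lapply(seq_len(nrow(v)), function(i) {
    d <- list(name = v$name[i], type = v$type[i], role = v$role[i])
    if (!is.na(v$levels[i] %||% NA)) d$levels <- strsplit(v$levels[i], ",")[[1]]
    d
  })
  yaml::write_yaml(decl, decl_path)
  invisible(path)
}

# ---- sample QC -------------------------------------------------------------

#' Age-specific read-depth filter
#'
#' Removes samples whose read depth falls below the cutoff for their sampling
#' age: an early cutoff for samples collected at three months or before and a
#' higher cutoff for all later (and parental) samples. A sample is removed
#' when its depth is strictly below its cutoff.
#'
#' @param ct count_table.
#' @param md sample_metadata covering the same samples.
#' @param cutoff_early reads cutoff for early timepoints (default 3000).
#' @param cutoff_late reads cutoff for the rest (default 5000).
#' @param early_timepoints labels mapped to the early cutoff
#'   (default 3w, 6w, 3m).
#' @return list with filtered `counts`, `metadata`, and a `removed` log
#'   data.frame (sample_id, depth, cutoff).
#' @export
filter_samples_by_depth <- function(ct, md, cutoff_early = 3000,
                                    cutoff_late = 5000,
                                    early_timepoints = c("3w", "6w", "3m")) {
  tp <- md$timepoint[match(ct$sample_ids, md$sample_id)]
  if (anyNA(tp)) stop("samples missing from metadata: ",
                      paste(ct$sample_ids[is.na(tp)], collapse = ", "))
  known <- c(early_timepoints, unique(md$timepoint))
  cut <- ifelse(tp %in% early_timepoints, cutoff_early, cutoff_late)
  drop <- ct$depths < cut
  removed <- data.frame(sample_id = ct$sample_ids[drop],
                        depth = unname(ct$depths[drop]),
                        cutoff = cut[drop])
  keep_ids <- ct$sample_ids[!drop]
  list(counts = ct_subset(ct, samples = keep_ids),
       metadata = md_subset(md, md$sample_id %in% keep_ids),
       removed = removed)
}

#' Exclude unknown annotations and poorly annotated samples
#'
#' Samples whose read fraction carried by unknown-annotated taxa is strictly
#' greater than `max_unknown` (computed before any taxa are dropped) are
#' excluded; then all unknown-annotated taxon rows are removed from the table.
#'
#' @param ct count_table; taxa with `rank == "unknown"` or taxon ids matching
#'   "unknown" (case-insensitive) count as unannotated.
#' @param max_unknown maximal tolerated unknown read fraction (default 0.20).
#' @return list with `counts` (filtered count_table) and `removed_samples`.
#' @export
filter_unknown_fraction <- function(ct, max_unknown = 0.20) {
  unk <- ct$taxa$rank == "unknown" |
    grepl("^unknown", ct$taxa$taxon_id, ignore.case = TRUE)
  frac <- if (any(unk))
    colSums(ct$counts[unk, , drop = FALSE]) / pmax(ct$depths, 1)
  else rep(0, ncol(ct$counts))
  drop_s <- frac > max_unknown   # strictly "over"
  out <- ct_subset(ct,
                   samples = ct$sample_ids[!drop_s],
                   taxa = ct$taxa$taxon_id[!unk])
  list(counts = out, removed_samples = ct$sample_ids[drop_s])
}

# ---- variable screening ----------------------------------------------------

#' Screen covariates for usable group sizes and missingness
#'
#' Within each scope (sample role x timepoint), marks categorical variables
#' excluded when all but one level have strictly fewer than `min_group`
#' samples, and any variable excluded when its missingness is strictly above
#' `max_missing`. Variables are only marked, never removed; samples are
#' untouched. Scope-level exclusions are recorded in the `exclusions` log;
#' a variable's global `excluded` flag is set when it is excluded in every
#' scope in which it was observed.
#'
#' @param md sample_metadata.
#' @param min_group minimal level size (default 10).
#' @param max_missing maximal missing fraction (default 0.75).
#' @return sample_metadata with an `excluded` column added to the variable
#'   declarations and an `exclusions` attribute (scope-level log).
#' @export
screen_variables <- function(md, min_group = 10, max_missing = 0.75) {
  v <- md_variables(md)
  scopes <- unique(md[, c("role", "timepoint")])
  log <- list()
  excluded_everywhere <- stats::setNames(rep(TRUE, nrow(v)), v$name)
  observed <- stats::setNames(rep(FALSE, nrow(v)), v$name)
  for (s in seq_len(nrow(scopes))) {
    idx <- md$role == scopes$role[s] & md$timepoint == scopes$timepoint[s]
    n <- sum(idx)
    if (n == 0) next
    for (i in seq_len(nrow(v))) {
      x <- md[[v$name[i]]][idx]
      if (all(is.na(x))) next
      observed[v$name[i]] <- TRUE
      reason <- NULL
      fmiss <- mean(is.na(x))
      if (fmiss > max_missing)
        reason <- sprintf("missingness %.2f > %.2f", fmiss, max_missing)
      if (is.null(reason) && v$type[i] == "categorical") {
        sizes <- sort(table(x), decreasing = TRUE)
        if (length(sizes) >= 2 && all(sizes[-1] < min_group))
          reason <- sprintf("all but one level with <%d samples", min_group)
        if (length(sizes) == 1) reason <- "single observed level"
      }
      if (!is.null(reason))
        log[[length(log) + 1]] <- data.frame(
          variable = v$name[i], role = scopes$role[s],
          timepoint = scopes$timepoint[s], reason = reason)
      else excluded_everywhere[v$name[i]] <- FALSE
    }
  }
  v$excluded <- excluded_everywhere & observed
  attr(md, "variables") <- v
  attr(md, "exclusions") <- if (length(log)) do.call(rbind, log) else
    data.frame(variable = character(), role = character(),
               timepoint = character(), reason = character())
  md
}

#' Variable exclusion log of a screened metadata
#' @param md sample_metadata after [screen_variables()].
#' @export
md_exclusions <- function(md) attr(md, "exclusions")

#' Is a variable usable within a scope?
#' @param md screened sample_metadata.
#' @param variable variable name.
#' @param role,timepoint scope.
#' @export
variable_usable <- function(md, variable, role, timepoint) {
  ex <- md_exclusions(md)
  if (is.null(ex)) return(TRUE)
  !any(ex$variable == variable & ex$role == role & ex$timepoint == timepoint)
}

#' Combine birth mode and intrapartum antibiotics into a three-class variable
#'
#' C-section deliveries always involve intrapartum antibiotic prophylaxis in
#' this design, so the crossing collapses to three classes: CS+AB, VD+AB,
#' VD-AB. A C-section without antibiotics is rejected as a data error.
#'
#' @param md sample_metadata with categorical `delivery_mode` (CS/VD) and
#'   `intrapartum_ab` (yes/no).
#' @param name name of the derived variable (default "delivery3").
#' @return sample_metadata with the new confounder-free categorical variable
#'   declared as biological.
#' @export
derive_delivery3 <- function(md, name = "delivery3") {
  dm <- md$delivery_mode; ab <- md$intrapartum_ab
  if (is.null(dm) || is.null(ab))
    stop("delivery_mode and intrapartum_ab required")
  bad <- which(dm == "CS" & ab == "no")
  if (length(bad)) stop("validation error: C-section without intrapartum ",
                        "antibiotics at sample ", md$sample_id[bad[1]])
  lev <- ifelse(is.na(dm) | is.na(ab), NA_character_,
                ifelse(dm == "CS", "CS+AB",
                       ifelse(ab == "yes", "VD+AB", "VD-AB")))
  md[[name]] <- lev
  v <- md_variables(md)
  if (!name %in% v$name) {
    add <- data.frame(name = name, type = "categorical", role = "biological",
                      levels = "CS+AB,VD+AB,VD-AB")
    for (extra in setdiff(names(v), names(add))) add[[extra]] <- FALSE
    v <- rbind(v, add[, names(v), drop = FALSE])
  }
  attr(md, "variables") <- v
  md
}
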