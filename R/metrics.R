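#' Aggregate counts to a taxonomic rank
#'
#' Sums counts within genus or family. Unknown annotations are removed. At
#' family rank, taxa lacking a family annotation are dropped with a warning.
#'
#' @param ct count_table with genus-level rows and a `family` lineage column.
#' @param rank "genus" or "family".
#' @return count_table aggregated at `rank`.
#' @export
aggregate_taxa <- function(ct, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  unk <- ct$taxa$rank == "unknown" |
    grepl("^unknown", ct$taxa$taxon_id, ignore.case = TRUE)
  ct <- ct_subset(ct, taxa = ct$taxa$taxon_id[!unk])
  if (rank == "genus") return(ct)
  if (!"family" %in% names(ct$taxa))
    stop("rank 'family' absent from taxon annotations")
  fam <- ct$taxa$family
  has <- !is.na(fam) & fam != "" & !grepl("^unknown", fam, ignore.case = TRUE)
  if (any(!has))
    warning(sum(!has), " taxa lack family annotation; dropped at family rank")
  ct <- ct_subset(ct, taxa = ct$taxa$taxon_id[has])
  fam <- ct$taxa$family
  m <- rowsum(ct$counts, group = fam, reorder = FALSE)
  count_table(m, data.frame(taxon_id = rownames(m), rank = "family"),
              ct$sample_ids)
}

#' Relative abundances (proportions) per sample
#' @param ct count_table with all depths > 0.
#' @return matrix of proportions; columns sum to 1.
#' @export
relative_abundance <- function(ct) {
  if (any(ct$depths <= 0)) stop("zero-depth sample(s): ",
    paste(ct$sample_ids[ct$depths <= 0], collapse = ", "))
  sweep(ct$counts, 2, ct$depths, "/")
}

#' Rarefy every sample to a common depth
#'
#' A single subsample without replacement per sample, deterministic under the
#' seed (vegan's hypergeometric subsampler does the draw).
#'
#' @param ct count_table.
#' @param depth target depth; must not exceed any sample's depth.
#' @param seed RNG seed.
#' @return count_table with all depths equal to `depth`.
#' @export
rarefy_counts <- function(ct, depth = min(ct$depths), seed = 1L) {
  short <- ct$depths < depth
  if (any(short)) stop("depth ", depth, " exceeds sample depth for: ",
                       paste(ct$sample_ids[short], collapse = ", "))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # rrarefy warns when integer counts look like a single community; the
  # input here is validated upstream
  m <- t(suppressWarnings(vegan::rrarefy(t(ct$counts), depth)))
  out <- count_table(m, ct$taxa, ct$sample_ids)
  attr(out, "rarefaction") <- list(depth = depth, seed = seed)
  out
}

sample_skewness <- function(x) {
  # third standardized moment with the unbiased-variance (n-1) denominator
  n <- length(x); m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  sum((x - m)^3) / n / s^3
}

chao1_bc <- function(x) {
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Alpha-diversity panel after rarefaction
#'
#' Computes, per sample, Shannon diversity (nats), bias-corrected Chao1
#' richness, observed richness, Pielou evenness, and a rarity index defined
#' as the sample skewness of log(1+x) over all taxa (zeros included). All
#' indices are computed on a single rarefied draw at `depth`.
#'
#' @param ct genus-aggregated count_table.
#' @param depth rarefaction depth (default: smallest sample depth).
#' @param seed rarefaction seed.
#' @return data.frame (sample_id, shannon, chao1, observed_richness, pielou,
#'   rarity_lms) with the depth and seed as attributes. Pielou is `NA` when a
#'   sample has fewer than two observed taxa.
#' @export
alpha_panel <- function(ct, depth = min(ct$depths), seed = 1L) {
  r <- rarefy_counts(ct, depth, seed)
  x <- r$counts
  sh <- vegan::diversity(t(x), index = "shannon")
  s_obs <- colSums(x > 0)
  pielou <- ifelse(s_obs >= 2, sh / log(s_obs), NA_real_)
  out <- data.frame(
    sample_id = r$sample_ids,
    shannon = unname(sh),
    chao1 = apply(x, 2, chao1_bc),
    observed_richness = unname(s_obs),
    pielou = unname(pielou),
    rarity_lms = apply(log1p(x), 2, sample_skewness),
    row.names = NULL)
  attr(out, "rarefaction") <- list(depth = depth, seed = seed)
  out
}

# ---- beta-diversity distances ---------------------------------------------

#' Bray-Curtis dissimilarity
#'
#' Quantitative Bray-Curtis, `1 - 2*sum(min(x_i, y_i)) / (sum x + sum y)`.
#' The default operates on relative abundances (columns summing to 1), where
#' the expression reduces to `1 - sum(min(p_i, q_i))`; `space = "count"`
#' applies the same formula to raw counts, which differs when depths differ.
#'
#' @param x proportion matrix (taxa x samples, columns sum to 1) or, with
#'   `space = "count"`, a raw count matrix or count_table.
#' @param space "proportion" or "count".
#' @return [dist_matrix()] with method "bray_curtis".
#' @export
bray_curtis <- function(x, space = c("proportion", "count")) {
  space <- match.arg(space)
  if (inherits(x, "count_table")) x <- x$counts
  if (any(x < 0)) stop("negative abundances")
  if (space == "proportion") {
    cs <- colSums(x)
    if (max(abs(cs - 1)) > 1e-8) stop("columns must sum to 1 in proportion space")
  }
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  diag(d) <- 0
  dist_matrix(d, colnames(x), "bray_curtis")
}

#' Aitchison distance (Euclidean on centred log-ratios)
#'
#' @param ct count_table (or count matrix).
#' @param pseudocount added to all counts before the log-ratio transform
#'   (default 1).
#' @return dist_matrix with method "aitchison".
#' @export
aitchison <- function(ct, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  x <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  lx <- log(x + pseudocount)
  clr <- sweep(lx, 2, colMeans(lx), "-")
  d <- as.matrix(stats::dist(t(clr)))
  diag(d) <- 0
  dist_matrix(d, colnames(x), "aitchison")
}

#' Centred log-ratio transform
#' @param x count or proportion matrix, taxa in rows.
#' @param pseudocount added before logging.
#' @return matrix with zero column means.
#' @export
clr_transform <- function(x, pseudocount = 0) {
  lx <- log(x + pseudocount)
  sweep(lx, 2, colMeans(lx), "-")
}

#' Pearson correlation distance between samples
#'
#' `d = 1 - r` with r the Pearson correlation of two samples' abundance
#' profiles across taxa; range 0 to 2.
#'
#' @param p abundance matrix, taxa in rows.
#' @return dist_matrix with method "pearson".
#' @export
pearson_distance <- function(p) {
  if (inherits(p, "count_table")) p <- p$counts
  if (nrow(p) < 2) stop("need at least two taxa")
  v <- apply(p, 2, stats::var)
  if (any(v == 0)) stop("zero-variance sample profile(s): ",
                        paste(colnames(p)[v == 0], collapse = ", "))
  d <- 1 - stats::cor(p)
  d[d < 0] <- 0
  diag(d) <- 0
  dist_matrix(d, colnames(p), "pearson")
}

#' Compute the study's distance of choice from counts
#'
#' Aggregates to `rank`, converts to relative abundances where the method
#' asks for them, and returns the distance matrix.
#'
#' @param ct count_table.
#' @param method "bray_curtis", "aitchison" or "pearson".
#' @param rank aggregation rank.
#' @param pseudocount for aitchison.
#' @export
community_distance <- function(ct, method = c("bray_curtis", "aitchison",
                                              "pearson"),
                               rank = "genus", pseudocount = 1) {
  method <- match.arg(method)
  ct <- aggregate_taxa(ct, rank)
  switch(method,
         bray_curtis = bray_curtis(relative_abundance(ct)),
         aitchison = aitchison(ct, pseudocount),
         pearson = pearson_distance(relative_abundance(ct)))
}
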