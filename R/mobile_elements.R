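#' Transposase (or other category) gene density per Mbp
#'
#' Insertion-sequence load is the field's first-order measure of a
#' replicon's plasticity: giant linear plasmids typically carry an order of
#' magnitude more transposase genes per Mbp than their host chromosome.
#'
#' @param features Feature data frame ([feature_table()] columns).
#' @param replicon A [replicon], or an integer length in bp.
#' @param category Feature category to count (default `"transposase"`).
#' @param replicon_id Replicon name when `replicon` is a bare length.
#' @return Data frame with `replicon_id`, `category`, `count`,
#'   `length_bp`, `density_per_mbp` (unrounded) and `density_rounded`
#'   (1 decimal, for display).
#' @examples
#' fts <- feature_table("chr", c(10, 500), c(100, 900),
#'                      product = "IS5 family transposase")
#' transposase_density(fts, 1e6, replicon_id = "chr")  # 2 per Mbp
#' @export
transposase_density <- function(features, replicon,
                                category = "transposase",
                                replicon_id = NULL) {
  if (inherits(replicon, "replicon")) {
    len <- replicon$length
    rid <- replicon$id
  } else {
    len <- as.numeric(replicon)
    rid <- if (is.null(replicon_id)) NA_character_ else replicon_id
  }
  if (is.na(len) || len <= 0) stop("replicon length must be positive")
  fts <- features[is.na(features$replicon_id) | is.na(rid) |
                    features$replicon_id == rid, , drop = FALSE]
  count <- sum(fts$kind == "CDS" & fts$category == category)
  dens <- count / (len / 1e6)
  data.frame(replicon_id = rid, category = category, count = count,
             length_bp = len, density_per_mbp = dens,
             density_rounded = round(dens, 1))
}

feature_ranges <- function(features, category = NULL, kind = "CDS") {
  fts <- features
  if (!is.null(kind)) fts <- fts[fts$kind == kind, , drop = FALSE]
  if (!is.null(category))
    fts <- fts[fts$category == category, , drop = FALSE]
  IRanges::IRanges(start = fts$start, end = fts$end)
}

#' Distance from breakpoints to the nearest feature of a category
#'
#' Zero for a breakpoint inside a feature interval; otherwise the gap to
#' the nearest feature edge. Breakpoints can come from rearrangement
#' events or from contig-junction coordinates of a fragmented assembly.
#'
#' @param breakpoints Integer positions (1-based bp).
#' @param features Feature data frame.
#' @param category Target category (default `"transposase"`).
#' @return Integer vector of distances, one per breakpoint.
#' @export
breakpoint_feature_distance <- function(breakpoints, features,
                                        category = "transposase") {
  fr <- feature_ranges(features, category)
  if (length(fr) == 0L)
    stop("no CDS features of category '", category,
         "': distance undefined")
  bp <- IRanges::IRanges(start = as.integer(breakpoints),
                         width = 1L)
  point_feature_distance(bp, fr)
}

# 0 inside a feature; otherwise the base-count difference to the nearest
# feature edge (a point one base left of a feature is at distance 1, not
# the 0 that IRanges gap counting would give)
point_feature_distance <- function(bp, fr) {
  hits <- IRanges::distanceToNearest(bp, fr)
  d <- rep(NA_integer_, length(bp))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  inside <- IRanges::overlapsAny(bp, fr)
  ifelse(inside, 0L, d + 1L)
}

#' Permutation test for breakpoint proximity to a feature category
#'
#' Observed statistic: mean distance from the breakpoints to the nearest
#' feature of the category. Null: the same statistic for equally many
#' positions drawn uniformly over the replicon, `n_perm` times. One-sided
#' p-value with a +1 pseudo-count, p = (1 + #{null <= observed}) /
#' (n_perm + 1), so small distances (breakpoints falling at mobile
#' elements) give small p. Irregular feature intervals make an analytic
#' null impractical; Monte Carlo makes the qualitative claim "junctions
#' sit at transposase genes" a calibrated test.
#'
#' @param breakpoints Integer positions.
#' @param features Feature data frame.
#' @param replicon_length Length of the replicon the positions live on.
#' @param category Target category (default `"transposase"`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed; results are bit-for-bit reproducible given it.
#' @return Object of class `enrichment_result`: list with `observed_stat`,
#'   `null_stats`, `p_value`, `n_perm`, `seed`.
#' @export
breakpoint_enrichment_test <- function(breakpoints, features,
                                       replicon_length,
                                       category = "transposase",
                                       n_perm = 10000, seed = 1) {
  stopifnot(length(breakpoints) >= 1L, replicon_length >= 1)
  obs <- mean(breakpoint_feature_distance(breakpoints, features, category))
  m <- length(breakpoints)
  fr <- feature_ranges(features, category)
  null_stats <- withr::with_seed(seed, {
    pos <- sample.int(replicon_length, n_perm * m, replace = TRUE)
    bp <- IRanges::IRanges(start = pos, width = 1L)
    colMeans(matrix(point_feature_distance(bp, fr), nrow = m))
  })
  p <- (1 + sum(null_stats <= obs)) / (n_perm + 1)
  structure(list(observed_stat = obs, null_stats = null_stats,
                 p_value = p, n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> observed mean distance %.1f bp, null mean %.1f bp, p = %.4g (%d permutations, seed %d)\n",
    x$observed_stat, mean(x$null_stats), x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Replicon summary (general-features table row)
#'
#' Length, GC%, CDS count, median CDS length and per-category counts — the
#' row format of a genome report's general-features table. The median uses
#' the lower-middle convention for even counts (ties are not averaged), so
#' the reported value is always an actual CDS length.
#'
#' @param replicon A [replicon].
#' @param features Feature data frame.
#' @return One-row data frame with `replicon_id`, `length_bp`,
#'   `gc_percent`, `cds_count`, `median_cds_bp`, `transposase`,
#'   `transcriptional_regulator`, `hypothetical`.
#' @export
replicon_summary <- function(replicon, features) {
  cds <- features[features$kind == "CDS" &
                    features$replicon_id == replicon$id, , drop = FALSE]
  lens <- sort(cds$end - cds$start + 1L)
  med <- if (length(lens) == 0L) NA_integer_
         else lens[ceiling(length(lens) / 2)]
  cnt <- function(cat) sum(cds$category == cat)
  data.frame(replicon_id = replicon$id,
             length_bp = replicon$length,
             gc_percent = round(100 * gc_content(replicon), 1),
             cds_count = nrow(cds),
             median_cds_bp = med,
             transposase = cnt("transposase"),
             transcriptional_regulator = cnt("transcriptional_regulator"),
             hypothetical = cnt("hypothetical"))
}
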