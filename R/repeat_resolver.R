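#' Segment a coverage track into constant-depth regions
#'
#' Median-filter smoothing followed by binary segmentation (within-segment
#' squared-deviation cost with a BIC-style penalty), then merging of
#' segments shorter than `min_segment_bp` into their more similar
#' neighbour. The procedure is deterministic given the track. Its target
#' signal is the hallmark of an assembler-collapsed terminal inverted
#' repeat: a long end-anchored region at twice the depth of the rest of the
#' contig.
#'
#' @param track A [coverage_track].
#' @param min_segment_bp Shortest segment reported (default 5000).
#' @param smooth_window_bp Median filter window (default 1000).
#' @return Data frame with columns `start`, `end` (1-based inclusive,
#'   contiguous and exhaustive over the contig) and `mean_depth` (mean of
#'   the raw, unsmoothed track over the segment).
#' @export
segment_coverage <- function(track, min_segment_bp = 5000,
                             smooth_window_bp = 1000) {
  x <- track$depth
  n <- length(x)
  if (n < 2L * min_segment_bp)
    stop("track too short to segment: ", n, " bp < 2 * ", min_segment_bp)
  k <- min(smooth_window_bp, n - 1L)
  if (k %% 2L == 0L) k <- k + 1L
  sm <- stats::runmed(x, k, endrule = "median")

  # noise scale from per-base first differences of the raw track; the
  # penalty stops splitting once gains fall to noise scale
  sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
  pen <- max(sigma2, 1e-9) * 10 * log(n)

  s1 <- c(0, cumsum(sm))
  s2 <- c(0, cumsum(sm^2))
  seg_sse <- function(l, r) {
    s <- s1[r + 1L] - s1[l]
    (s2[r + 1L] - s2[l]) - s * s / (r - l + 1L)
  }
  cuts <- integer(0)  # each cut t: boundary between t and t+1
  recurse <- function(l, r) {
    if (r - l + 1L < 4L) return(invisible())
    t <- l:(r - 1L)
    nl <- t - l + 1L; nr <- r - t
    Sl <- s1[t + 1L] - s1[l]; Ql <- s2[t + 1L] - s2[l]
    Sr <- s1[r + 1L] - s1[t + 1L]; Qr <- s2[r + 1L] - s2[t + 1L]
    cost <- (Ql - Sl^2 / nl) + (Qr - Sr^2 / nr)
    best <- which.min(cost)
    gain <- seg_sse(l, r) - cost[best]
    if (gain > pen) {
      tb <- t[best]
      cuts <<- c(cuts, tb)
      recurse(l, tb)
      recurse(tb + 1L, r)
    }
    invisible()
  }
  recurse(1L, n)
  cuts <- sort(cuts)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)

  # merge short segments into the neighbour with the closer mean
  repeat {
    widths <- ends - starts + 1L
    if (length(starts) <= 1L || all(widths >= min_segment_bp)) break
    i <- which(widths < min_segment_bp)[which.min(widths[widths <
                                                           min_segment_bp])]
    mean_of <- function(j) mean(x[starts[j]:ends[j]])
    into <- if (i == 1L) 2L
            else if (i == length(starts)) i - 1L
            else if (abs(mean_of(i - 1L) - mean_of(i)) <=
                     abs(mean_of(i + 1L) - mean_of(i))) i - 1L else i + 1L
    lo <- min(i, into); hi <- max(i, into)
    starts <- starts[-hi]
    ends <- ends[-lo]
  }
  data.frame(start = starts, end = ends,
             mean_depth = vapply(seq_along(starts), function(j)
               mean(x[starts[j]:ends[j]]), numeric(1)))
}

#' Call a collapsed terminal inverted repeat from coverage segments
#'
#' When an assembler collapses the two copies of a long terminal inverted
#' repeat, the single reported copy (the "arm", length R) attracts the
#' reads of both copies and shows ~2x the depth of the unique central
#' region (length C); the true plasmid length is 2R + C. The call scans
#' end-anchored segment runs from both contig ends, computes the
#' length-weighted mean depth of the candidate arm against the remainder,
#' and accepts the boundary whose ratio falls inside `ratio_band`, choosing
#' the candidate closest to the band centre when several qualify. No-call
#' (returns `NULL`) when no ratio is in band or the candidate arm would
#' cover the whole contig.
#'
#' @param segments Segment data frame from [segment_coverage()].
#' @param ratio_band Accepted arm/central depth ratio interval
#'   (default `c(1.6, 2.4)`, an operational "about twice").
#' @param contig_id Contig name carried into the call.
#' @return An object of class `collapsed_repeat_call` (list with
#'   `contig_id`, `arm_start`, `arm_end`, `central_start`, `central_end`,
#'   `arm_side`, `R`, `C`, `baseline_depth`, `depth_ratio`,
#'   `reconstructed_length`), or `NULL` for no-call.
#' @export
call_collapsed_repeat <- function(segments, ratio_band = c(1.6, 2.4),
                                  contig_id = NA_character_) {
  stopifnot(nrow(segments) >= 1L)
  n <- nrow(segments)
  if (n < 2L) return(NULL)
  w <- segments$end - segments$start + 1L
  tot <- sum(w * segments$mean_depth)
  W <- sum(w)
  cand <- list()
  for (j in seq_len(n - 1L)) {
    # left-anchored arm = segments 1..j
    aw <- sum(w[1:j]); am <- sum(w[1:j] * segments$mean_depth[1:j]) / aw
    rm_ <- (tot - am * aw) / (W - aw)
    if (rm_ > 0)
      cand[[length(cand) + 1L]] <- list(side = "left", j = j,
                                        ratio = am / rm_)
    # right-anchored arm = segments (j+1)..n
    k <- j + 1L
    aw2 <- sum(w[k:n]); am2 <- sum(w[k:n] * segments$mean_depth[k:n]) / aw2
    rm2 <- (tot - am2 * aw2) / (W - aw2)
    if (rm2 > 0)
      cand[[length(cand) + 1L]] <- list(side = "right", j = k,
                                        ratio = am2 / rm2)
  }
  ok <- Filter(function(c.) c. $ratio >= ratio_band[1] &&
                 c.$ratio <= ratio_band[2], cand)
  if (length(ok) == 0L) return(NULL)
  centre <- mean(ratio_band)
  pick <- ok[[which.min(vapply(ok, function(c.) abs(c.$ratio - centre),
                               numeric(1)))]]
  if (pick$side == "left") {
    arm_start <- segments$start[1]; arm_end <- segments$end[pick$j]
    central_start <- segments$start[pick$j + 1L]
    central_end <- segments$end[n]
  } else {
    arm_start <- segments$start[pick$j]; arm_end <- segments$end[n]
    central_start <- segments$start[1]
    central_end <- segments$end[pick$j - 1L]
  }
  R <- arm_end - arm_start + 1L
  C <- central_end - central_start + 1L
  central_idx <- if (pick$side == "left") (pick$j + 1L):n
                 else 1:(pick$j - 1L)
  baseline <- sum(w[central_idx] * segments$mean_depth[central_idx]) /
    sum(w[central_idx])
  structure(list(contig_id = contig_id,
                 arm_start = arm_start, arm_end = arm_end,
                 central_start = central_start, central_end = central_end,
                 arm_side = pick$side, R = R, C = C,
                 baseline_depth = baseline, depth_ratio = pick$ratio,
                 reconstructed_length = 2L * R + C),
            class = "collapsed_repeat_call")
}

#' @export
print.collapsed_repeat_call <- function(x, ...) {
  cat(sprintf(
    "<collapsed_repeat_call> %s: %s arm %s-%s (R=%s), central %s-%s (C=%s), ratio %.2f, full length %s bp\n",
    x$contig_id, x$arm_side,
    format(x$arm_start, big.mark = ","), format(x$arm_end, big.mark = ","),
    format(x$R, big.mark = ","),
    format(x$central_start, big.mark = ","),
    format(x$central_end, big.mark = ","), format(x$C, big.mark = ","),
    x$depth_ratio, format(x$reconstructed_length, big.mark = ",")))
  invisible(x)
}

#' Full plasmid length from a collapsed contig
#'
#' With a unique central region of length C on a collapsed contig of length
#' L, the duplicated arm has length R = L - C and the full plasmid is
#' 2R + C bases. Monotone increasing in L, decreasing in C.
#'
#' @param contig_length Collapsed contig length (bp).
#' @param central Either the central-region length C (scalar) or a 1-based
#'   inclusive interval `c(start, end)` on the contig.
#' @return Integer full length 2R + C.
#' @examples
#' reconstruct_full_length(100, 20)              # 180
#' reconstruct_full_length(189563, 22563)        # 356563
#' @export
reconstruct_full_length <- function(contig_length, central) {
  C <- if (length(central) == 2L) central[2] - central[1] + 1 else central
  if (C > contig_length)
    stop("central region (", C, " bp) exceeds contig length (",
         contig_length, " bp)")
  if (C < 0) stop("negative central length")
  as.integer(2 * (contig_length - C) + C)
}

#' Expand a collapsed contig to the full inverted-repeat plasmid
#'
#' For a left-anchored arm the collapsed contig is arm + central; the full
#' plasmid is arm + central + reverse-complement(arm), so its first R bases
#' equal the reverse complement of its last R bases (the defining identity
#' of a terminal inverted repeat). `arm_side = "right"` handles the
#' central + arm orientation symmetrically.
#'
#' @param sequence Collapsed contig sequence (character scalar or
#'   [replicon]).
#' @param arm_interval,central_interval 1-based inclusive intervals that
#'   must partition the contig, the arm touching the stated end.
#' @param arm_side `"left"` or `"right"`.
#' @return Character scalar, the full plasmid sequence of length 2R + C.
#' @examples
#' expand_collapsed_sequence("ACGTT", c(1, 3), c(4, 5))  # "ACGTTCGT"
#' @export
expand_collapsed_sequence <- function(sequence, arm_interval,
                                      central_interval,
                                      arm_side = c("left", "right")) {
  arm_side <- match.arg(arm_side)
  if (inherits(sequence, "replicon")) sequence <- sequence$sequence
  L <- nchar(sequence)
  ai <- as.integer(arm_interval)
  empty_central <- is.null(central_interval) ||
    central_interval[1] > central_interval[2]
  ci <- if (empty_central) NULL else as.integer(central_interval)
  partition_ok <- if (empty_central)
    ai[1] == 1L && ai[2] == L
  else if (arm_side == "left")
    ai[1] == 1L && ci[2] == L && ci[1] == ai[2] + 1L
  else
    ci[1] == 1L && ai[2] == L && ai[1] == ci[2] + 1L
  if (!partition_ok)
    stop("arm and central intervals must partition the contig with the ",
         "arm touching the ", arm_side, " end")
  arm <- substr(sequence, ai[1], ai[2])
  central <- if (empty_central) "" else substr(sequence, ci[1], ci[2])
  if (arm_side == "left")
    paste0(arm, central, revcomp(arm))
  else
    paste0(revcomp(arm), central, arm)
}
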