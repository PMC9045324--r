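#' Find unique k-mer anchors between two sequences
#'
#' Anchors are maximal exact matches seeded by k-mers that occur exactly
#' once in sequence A (top strand) and exactly once in sequence B (counting
#' both strands). Matches are found forward and against the reverse
#' complement of B, and overlapping seed matches on the same diagonal are
#' merged into maximal exact matches. Unique-k-mer seeding makes the dot
#' plot of two near-identical ~300-kb plasmids essentially noise-free:
#' at k = 21 a random shared k-mer is vanishingly improbable, and repeated
#' elements (transposase cassettes) are excluded automatically because
#' their k-mers are not unique.
#'
#' @param seq_a,seq_b Character scalars or [replicon]s.
#' @param k K-mer size (default 21).
#' @return Data frame with columns `pos_a`, `pos_b` (1-based start of the
#'   match on each top strand), `length`, `orientation` (`"forward"` or
#'   `"reverse"`), sorted by `pos_a`. For reverse anchors the A-strand
#'   match equals the reverse complement of B at `[pos_b, pos_b+length-1]`.
#' @export
find_anchors <- function(seq_a, seq_b, k = 21) {
  if (inherits(seq_a, "replicon")) seq_a <- seq_a$sequence
  if (inherits(seq_b, "replicon")) seq_b <- seq_b$sequence
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na < k || nb < k)
    stop("k = ", k, " exceeds a sequence length (", na, ", ", nb, ")")

  ka <- substring(seq_a, 1:(na - k + 1L), k:na)
  kb <- substring(seq_b, 1:(nb - k + 1L), k:nb)
  kbr <- substring(revcomp(seq_b), 1:(nb - k + 1L), k:nb)

  # unique-occurrence masks
  okA <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  allb <- c(kb, kbr)
  dupB <- duplicated(allb) | duplicated(allb, fromLast = TRUE)
  okBf <- !dupB[seq_along(kb)]
  okBr <- !dupB[length(kb) + seq_along(kbr)]

  jf <- match(ka, kb)
  jr <- match(ka, kbr)
  fwd <- which(okA & !is.na(jf) & okBf[ifelse(is.na(jf), 1L, jf)])
  rev_ <- which(okA & !is.na(jr) & okBr[ifelse(is.na(jr), 1L, jr)])

  merge_diag <- function(i, j, k) {
    # merge seed matches on a shared diagonal whose starts are <= k apart
    if (length(i) == 0L)
      return(data.frame(pos_a = integer(0), pos_b = integer(0),
                        length = integer(0)))
    d <- i - j
    o <- order(d, i)
    i <- i[o]; j <- j[o]; d <- d[o]
    new_run <- c(TRUE, diff(d) != 0L | diff(i) > k)
    run <- cumsum(new_run)
    first <- !duplicated(run)
    last <- !duplicated(run, fromLast = TRUE)
    data.frame(pos_a = i[first], pos_b = j[first],
               length = i[last] - i[first] + k)
  }

  f <- merge_diag(fwd, jf[fwd], k)
  f$orientation <- rep("forward", nrow(f))
  r <- merge_diag(rev_, jr[rev_], k)
  # map reverse matches from revcomp(B) coordinates back to B top strand:
  # a match of length L starting at j in revcomp(B) covers B bases
  # [nb - j - L + 2, nb - j + 1]
  if (nrow(r) > 0L)
    r$pos_b <- nb - r$pos_b - r$length + 2L
  r$orientation <- rep("reverse", nrow(r))
  out <- rbind(f, r)
  out <- out[order(out$pos_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain anchors into synteny blocks
#'
#' Anchors are clustered greedily along sequence A into runs that are
#' collinear, consistently oriented, and separated by at most `max_gap` on
#' both sequences; runs spanning less than `min_block` on A are dropped.
#' Per-block identity is computed exactly: anchored bases count as matches,
#' and the unanchored gaps between consecutive anchors are globally aligned
#' (Needleman-Wunsch via [Biostrings::pairwiseAlignment()]); gaps larger
#' than `max_align_gap` are counted as fully unaligned rather than aligned.
#'
#' @param anchors Anchor data frame from [find_anchors()].
#' @param seq_a,seq_b The two sequences (needed for gap alignment).
#' @param max_gap Maximum within-block gap on either sequence (default
#'   5000 bp).
#' @param min_block Minimum block span on A (default 500 bp).
#' @param max_align_gap Largest gap pair aligned base-by-base
#'   (default 2000 bp).
#' @return Data frame of blocks (`a_start`, `a_end`, `b_start`, `b_end`,
#'   1-based inclusive; `orientation`; `identity`; `n_anchors`) with the
#'   member anchors of each block in `attr(, "members")`.
#' @export
chain_blocks <- function(anchors, seq_a, seq_b, max_gap = 5000,
                         min_block = 500, max_align_gap = 2000) {
  if (inherits(seq_a, "replicon")) seq_a <- seq_a$sequence
  if (inherits(seq_b, "replicon")) seq_b <- seq_b$sequence
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), identity = numeric(0),
                      n_anchors = integer(0))
  if (is.null(anchors) || nrow(anchors) == 0L) {
    attr(empty, "members") <- list()
    return(empty)
  }
  n <- nrow(anchors)
  block_id <- integer(n)
  cur <- 1L
  block_id[1] <- cur
  prev <- 1L  # last anchor appended to the current block
  for (i in seq_len(n)[-1]) {
    pa_end <- anchors$pos_a[prev] + anchors$length[prev] - 1L
    gap_a <- anchors$pos_a[i] - pa_end - 1L
    same_orient <- anchors$orientation[i] == anchors$orientation[prev]
    compatible <- FALSE
    if (same_orient && gap_a <= max_gap && gap_a >= -anchors$length[prev]) {
      if (anchors$orientation[i] == "forward") {
        pb_end <- anchors$pos_b[prev] + anchors$length[prev] - 1L
        gap_b <- anchors$pos_b[i] - pb_end - 1L
        compatible <- anchors$pos_b[i] > anchors$pos_b[prev] &&
          gap_b <= max_gap
      } else {
        # reverse blocks walk leftward on B as A advances
        gap_b <- anchors$pos_b[prev] -
          (anchors$pos_b[i] + anchors$length[i] - 1L) - 1L
        compatible <- anchors$pos_b[i] < anchors$pos_b[prev] &&
          gap_b <= max_gap
      }
    }
    if (!compatible) cur <- cur + 1L
    block_id[i] <- cur
    prev <- i
  }

  members <- split(anchors, block_id)
  rows <- lapply(members, function(m) {
    a_start <- min(m$pos_a)
    a_end <- max(m$pos_a + m$length - 1L)
    b_start <- min(m$pos_b)
    b_end <- max(m$pos_b + m$length - 1L)
    idn <- block_identity(m, seq_a, seq_b, max_align_gap)
    data.frame(a_start = a_start, a_end = a_end, b_start = b_start,
               b_end = b_end, orientation = m$orientation[1],
               identity = idn, n_anchors = nrow(m))
  })
  blocks <- do.call(rbind, rows)
  keep <- (blocks$a_end - blocks$a_start + 1L) >= min_block
  blocks <- blocks[keep, , drop = FALSE]
  members <- members[keep]
  o <- order(blocks$a_start)
  blocks <- blocks[o, , drop = FALSE]
  rownames(blocks) <- NULL
  attr(blocks, "members") <- members[o]
  blocks
}

# identity over a block: anchored bases are matches; gaps between
# consecutive anchors are aligned (or counted unaligned when too large)
block_identity <- function(m, seq_a, seq_b, max_align_gap) {
  matches <- sum(m$length)
  columns <- sum(m$length)
  if (nrow(m) > 1L) {
    for (i in seq_len(nrow(m) - 1L)) {
      g <- anchor_gap_sequences(m[i, ], m[i + 1L, ], seq_a, seq_b)
      la <- nchar(g$a); lb <- nchar(g$b)
      if (la == 0L && lb == 0L) next
      if (la == 0L || lb == 0L || max(la, lb) > max_align_gap) {
        columns <- columns + max(la, lb)
      } else {
        al <- Biostrings::pairwiseAlignment(g$a, g$b, type = "global")
        matches <- matches + Biostrings::nmatch(al)
        columns <- columns + Biostrings::nchar(al)
      }
    }
  }
  matches / columns
}

# gap sequences between two consecutive anchors of one block, as compared
# strings (for reverse blocks the B gap is reverse-complemented so it reads
# in A orientation); also returns B-strand coordinates of the B gap
anchor_gap_sequences <- function(m1, m2, seq_a, seq_b) {
  a_from <- m1$pos_a + m1$length
  a_to <- m2$pos_a - 1L
  ga <- if (a_to >= a_from) substr(seq_a, a_from, a_to) else ""
  if (m1$orientation == "forward") {
    b_from <- m1$pos_b + m1$length
    b_to <- m2$pos_b - 1L
    gb <- if (b_to >= b_from) substr(seq_b, b_from, b_to) else ""
    list(a = ga, b = gb, a_from = a_from, b_from = b_from, b_to = b_to,
         b_forward = TRUE)
  } else {
    b_from <- m2$pos_b + m2$length
    b_to <- m1$pos_b - 1L
    gb <- if (b_to >= b_from) revcomp(substr(seq_b, b_from, b_to)) else ""
    list(a = ga, b = gb, a_from = a_from, b_from = b_from, b_to = b_to,
         b_forward = FALSE)
  }
}

#' Export anchors as a dot-plot coordinate table
#'
#' Writes a TSV of (pos_a, pos_b, length, orientation): forward anchors
#' form the main diagonal, reverse anchors anti-diagonal segments, as in a
#' classic genome-vs-genome dot plot.
#'
#' @param anchors Anchor data frame from [find_anchors()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_dotplot <- function(anchors, path) {
  writeLines(tool_header(c("pos_a", "pos_b", "length", "orientation")),
             path)
  if (!is.null(anchors) && nrow(anchors) > 0L)
    suppressWarnings(write.table(
      anchors[, c("pos_a", "pos_b", "length", "orientation")], path,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
      append = TRUE))
  invisible(path)
}
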