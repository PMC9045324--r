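#' Classify rearrangement events between two replicons
#'
#' Interprets the synteny-block layout of a reference (A) versus a derived
#' (B) replicon. Blocks are ordered along A; a longest-increasing chain of
#' B positions defines the collinear backbone, and differences become
#' typed events:
#' * gap present only in B -> `insertion` (locus is a point on A; the
#'   reported `position` is the 1-based B coordinate of the first inserted
#'   base);
#' * gap present only in A -> `deletion`;
#' * reverse-orientation block -> `inversion`;
#' * block out of the collinear backbone -> `translocation` (its span is
#'   excluded from the flanking gap arithmetic so the move is not
#'   double-reported as deletion + insertion);
#' * block whose A interval substantially overlaps an earlier block's ->
#'   `duplication`.
#' Gaps shorter than `min_event` are left to [call_snps()].
#'
#' @param blocks Block data frame from [chain_blocks()].
#' @param len_a,len_b Sequence lengths (used for terminal gaps).
#' @param min_event Smallest gap reported as an event rather than an indel
#'   SNP call (default 50 bp).
#' @return Data frame with columns `type`, `a_locus`, `b_start`, `b_end`,
#'   `length`, `position` (1-based; `position` is the B coordinate of the
#'   first inserted base for insertions, `NA` otherwise).
#' @export
classify_events <- function(blocks, len_a, len_b, min_event = 50) {
  ev <- data.frame(type = character(0), a_locus = integer(0),
                   b_start = integer(0), b_end = integer(0),
                   length = integer(0), position = integer(0))
  if (nrow(blocks) == 0L) return(ev)
  blocks <- blocks[order(blocks$a_start), , drop = FALSE]
  n <- nrow(blocks)

  # duplications: a block re-using A territory already covered
  dup <- rep(FALSE, n)
  if (n > 1L) {
    for (i in 2:n) {
      for (j in 1:(i - 1L)) {
        ov <- min(blocks$a_end[i], blocks$a_end[j]) -
          max(blocks$a_start[i], blocks$a_start[j]) + 1L
        w <- blocks$a_end[i] - blocks$a_start[i] + 1L
        if (ov >= 0.5 * w) { dup[i] <- TRUE; break }
      }
    }
  }

  # collinear backbone: longest chain (by A-span) of non-duplicated blocks
  # with increasing B position
  idx <- which(!dup)
  bs <- blocks$b_start[idx]
  wspan <- blocks$a_end[idx] - blocks$a_start[idx] + 1L
  m <- length(idx)
  best <- wspan
  prev <- rep(NA_integer_, m)
  if (m > 1L) {
    for (i in 2:m) {
      for (j in 1:(i - 1L)) {
        if (bs[j] < bs[i] && best[j] + wspan[i] > best[i]) {
          best[i] <- best[j] + wspan[i]
          prev[i] <- j
        }
      }
    }
  }
  chain <- integer(0)
  if (m > 0L) {
    i <- which.max(best)
    while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  }
  backbone <- idx[chain]
  moved <- setdiff(seq_len(n), c(backbone, which(dup)))

  add <- function(type, a_locus, b_start, b_end, length, position = NA) {
    ev <<- rbind(ev, data.frame(type = type, a_locus = as.integer(a_locus),
                                b_start = as.integer(b_start),
                                b_end = as.integer(b_end),
                                length = as.integer(length),
                                position = as.integer(position)))
  }

  for (i in which(dup))
    add("duplication", blocks$a_start[i], blocks$b_start[i],
        blocks$b_end[i], blocks$a_end[i] - blocks$a_start[i] + 1L)
  for (i in moved)
    add("translocation", blocks$a_start[i], blocks$b_start[i],
        blocks$b_end[i], blocks$a_end[i] - blocks$a_start[i] + 1L,
        position = blocks$b_start[i])
  for (i in backbone)
    if (blocks$orientation[i] == "reverse")
      add("inversion", blocks$a_start[i], blocks$b_start[i],
          blocks$b_end[i], blocks$a_end[i] - blocks$a_start[i] + 1L)

  # bases of a gap explained by moved/duplicated blocks do not count as
  # deleted/inserted material
  covered <- function(from, to, starts, ends) {
    if (to < from) return(0L)
    s <- pmax(starts, from); e <- pmin(ends, to)
    sum(pmax(0L, e - s + 1L))
  }
  gap_pairs <- cbind(c(NA, backbone), c(backbone, NA))
  for (r in seq_len(nrow(gap_pairs))) {
    i <- gap_pairs[r, 1]; j <- gap_pairs[r, 2]
    a_from <- if (is.na(i)) 1L else blocks$a_end[i] + 1L
    a_to <- if (is.na(j)) len_a else blocks$a_start[j] - 1L
    b_from <- if (is.na(i)) 1L else blocks$b_end[i] + 1L
    b_to <- if (is.na(j)) len_b else blocks$b_start[j] - 1L
    gap_a <- max(0L, a_to - a_from + 1L) -
      covered(a_from, a_to, blocks$a_start[moved], blocks$a_end[moved])
    gap_b <- max(0L, b_to - b_from + 1L) -
      covered(b_from, b_to, blocks$b_start[c(moved, which(dup))],
              blocks$b_end[c(moved, which(dup))])
    if (gap_b >= min_event && gap_a < min_event)
      add("insertion", a_locus = a_from - 1L, b_start = b_from,
          b_end = b_to, length = gap_b, position = b_from)
    else if (gap_a >= min_event && gap_b < min_event)
      add("deletion", a_locus = a_from, b_start = b_from, b_end = b_from,
          length = gap_a)
    else if (gap_a >= min_event && gap_b >= min_event) {
      add("deletion", a_locus = a_from, b_start = b_from, b_end = b_from,
          length = gap_a)
      add("insertion", a_locus = a_from - 1L, b_start = b_from,
          b_end = b_to, length = gap_b, position = b_from)
    }
  }

  # indels large enough to be events but small enough (< max_gap) not to
  # break a block live between consecutive anchors inside a block
  members <- attr(blocks, "members")
  if (!is.null(members)) {
    for (bi in seq_len(n)) {
      m <- members[[bi]]
      if (is.null(m) || nrow(m) < 2L) next
      for (i in seq_len(nrow(m) - 1L)) {
        g <- anchor_gap_coords(m[i, ], m[i + 1L, ])
        gap_a <- max(0L, g$a_to - g$a_from + 1L) -
          covered(g$a_from, g$a_to, blocks$a_start[moved],
                  blocks$a_end[moved])
        gap_b <- max(0L, g$b_to - g$b_from + 1L) -
          covered(g$b_from, g$b_to,
                  blocks$b_start[c(moved, which(dup))],
                  blocks$b_end[c(moved, which(dup))])
        if (gap_b >= min_event && gap_a < min_event)
          add("insertion", a_locus = g$a_from - 1L, b_start = g$b_from,
              b_end = g$b_to, length = gap_b - gap_a,
              position = g$b_from)
        else if (gap_a >= min_event && gap_b < min_event)
          add("deletion", a_locus = g$a_from, b_start = g$b_from,
              b_end = g$b_from, length = gap_a - gap_b)
      }
    }
  }
  ev <- ev[order(ev$a_locus), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# coordinates of the unanchored gap between two consecutive block anchors
anchor_gap_coords <- function(m1, m2) {
  a_from <- m1$pos_a + m1$length
  a_to <- m2$pos_a - 1L
  if (m1$orientation == "forward")
    list(a_from = a_from, a_to = a_to,
         b_from = m1$pos_b + m1$length, b_to = m2$pos_b - 1L,
         b_forward = TRUE)
  else
    list(a_from = a_from, a_to = a_to,
         b_from = m2$pos_b + m2$length, b_to = m1$pos_b - 1L,
         b_forward = FALSE)
}

#' Call SNPs and short indels within near-identical synteny blocks
#'
#' Walks the unanchored gaps between consecutive anchors of each block with
#' identity above `min_identity`, aligns them globally, and reports
#' substitution columns as SNPs and alignment gaps shorter than
#' `max_indel` as indel calls. Coordinates are 1-based on each replicon's
#' top strand; for reverse blocks the alternate allele is reported in
#' reference (A) orientation.
#'
#' @param blocks Block data frame from [chain_blocks()] (with its
#'   `members` attribute).
#' @param seq_a,seq_b The two sequences.
#' @param min_identity Blocks below this identity are skipped
#'   (default 0.9).
#' @param max_indel Indels up to this length are SNP-level calls; larger
#'   differences belong to [classify_events()] (default 50 bp).
#' @return Data frame with columns `pos_a`, `pos_b`, `ref`, `alt`, `type`
#'   (`"substitution"`, `"insertion"`, `"deletion"`). For indels `ref`/
#'   `alt` hold the indel sequence and `"-"`; `pos_a`/`pos_b` give the
#'   first affected base.
#' @export
call_snps <- function(blocks, seq_a, seq_b, min_identity = 0.9,
                      max_indel = 50) {
  if (inherits(seq_a, "replicon")) seq_a <- seq_a$sequence
  if (inherits(seq_b, "replicon")) seq_b <- seq_b$sequence
  members <- attr(blocks, "members")
  out <- list()
  use <- which(blocks$identity > min_identity)
  for (bi in use) {
    m <- members[[bi]]
    if (nrow(m) < 2L) next
    for (i in seq_len(nrow(m) - 1L)) {
      g <- anchor_gap_sequences(m[i, ], m[i + 1L, ], seq_a, seq_b)
      la <- nchar(g$a); lb <- nchar(g$b)
      if (la == 0L && lb == 0L) next
      if (max(la, lb) > max_indel) next  # event-scale: classify_events()
      out[[length(out) + 1L]] <- align_gap_calls(g, la, lb)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pos_a = integer(0), pos_b = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$pos_a), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# SNP/indel calls from one anchor gap (already orientation-normalised)
align_gap_calls <- function(g, la, lb) {
  calls <- data.frame(pos_a = integer(0), pos_b = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0))
  b_coord <- function(off) {
    # offset (1-based) within the gap, in A orientation -> B top strand
    if (g$b_forward) g$b_from + off - 1L else g$b_to - off + 1L
  }
  if (la == lb && la >= 1L) {
    ca <- strsplit(g$a, "")[[1]]
    cb <- strsplit(g$b, "")[[1]]
    mm <- which(ca != cb)
    for (p in mm)
      calls <- rbind(calls, data.frame(
        pos_a = g$a_from + p - 1L, pos_b = b_coord(p),
        ref = ca[p], alt = cb[p], type = "substitution"))
    return(calls)
  }
  if (la == 0L) {
    return(data.frame(pos_a = g$a_from - 1L, pos_b = b_coord(1L),
                      ref = "-", alt = g$b, type = "insertion"))
  }
  if (lb == 0L) {
    return(data.frame(pos_a = g$a_from, pos_b = b_coord(1L),
                      ref = g$a, alt = "-", type = "deletion"))
  }
  al <- Biostrings::pairwiseAlignment(g$a, g$b, type = "global")
  # substitutions
  mt <- Biostrings::mismatchTable(al)
  if (nrow(mt) > 0L) {
    for (r in seq_len(nrow(mt)))
      calls <- rbind(calls, data.frame(
        pos_a = g$a_from + mt$PatternStart[r] - 1L,
        pos_b = b_coord(mt$SubjectStart[r]),
        ref = as.character(mt$PatternSubstring[r]),
        alt = as.character(mt$SubjectSubstring[r]),
        type = "substitution"))
  }
  # deletions in B = gaps in subject (insertions relative to pattern)
  del <- Biostrings::deletion(al)[[1]]
  if (length(del) > 0L) {
    for (r in seq_along(del)) {
      st <- BiocGenerics::start(del)[r]; w <- BiocGenerics::width(del)[r]
      calls <- rbind(calls, data.frame(
        pos_a = g$a_from + st - 1L, pos_b = b_coord(max(1L, st - 1L)),
        ref = substr(g$a, st, st + w - 1L), alt = "-", type = "deletion"))
    }
  }
  ins <- Biostrings::insertion(al)[[1]]
  if (length(ins) > 0L) {
    for (r in seq_along(ins)) {
      st <- BiocGenerics::start(ins)[r]; w <- BiocGenerics::width(ins)[r]
      calls <- rbind(calls, data.frame(
        pos_a = g$a_from + st - 1L, pos_b = b_coord(st),
        ref = "-", alt = substr(g$b, st, st + w - 1L), type = "insertion"))
    }
  }
  calls
}

#' Classify the coding effect of a SNP or short indel
#'
#' Looks up the CDS overlapping the call on the reference, rebuilds the
#' affected codon before and after the change (strand-aware, standard
#' bacterial/plastid translation), and classifies: `synonymous`,
#' `missense`, `nonsense` (premature stop gained), `frameshift` (indel
#' length not divisible by 3), `indel_inframe`, or `intergenic` when no
#' CDS overlaps.
#'
#' @param call One row of the [call_snps()] output (or a list with
#'   `pos_a`, `ref`, `alt`, `type`).
#' @param features Feature data frame for the reference replicon.
#' @param seq_a Reference sequence.
#' @return Character scalar, the effect.
#' @export
classify_snp_effect <- function(call, features, seq_a) {
  if (inherits(seq_a, "replicon")) seq_a <- seq_a$sequence
  pos <- as.integer(call$pos_a)
  cds <- features[features$kind == "CDS" & features$start <= pos &
                    features$end >= pos, , drop = FALSE]
  if (nrow(cds) == 0L) return("intergenic")
  cds <- cds[1, ]

  if (call$type %in% c("insertion", "deletion")) {
    len <- nchar(if (call$type == "insertion") call$alt else call$ref)
    return(if (len %% 3L == 0L) "indel_inframe" else "frameshift")
  }

  cds_len <- cds$end - cds$start + 1L
  if (cds_len %% 3L != 0L)
    warning("CDS length not divisible by 3 at ", cds$start, "..", cds$end,
            "; using the annotated frame start")
  # codon index from the annotated frame start on the coding strand
  offset <- if (cds$strand == "+") pos - cds$start else cds$end - pos
  codon_i <- offset %/% 3L
  if (cds$strand == "+") {
    c_start <- cds$start + 3L * codon_i
    codon_ref <- substr(seq_a, c_start, c_start + 2L)
    within <- pos - c_start + 1L
    codon_alt <- codon_ref
    substr(codon_alt, within, within) <- toupper(call$alt)
  } else {
    c_end <- cds$end - 3L * codon_i
    codon_fwd <- substr(seq_a, c_end - 2L, c_end)
    within_fwd <- pos - (c_end - 2L) + 1L
    codon_alt_fwd <- codon_fwd
    substr(codon_alt_fwd, within_fwd, within_fwd) <- toupper(call$alt)
    codon_ref <- revcomp(codon_fwd)
    codon_alt <- revcomp(codon_alt_fwd)
  }
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(codon_ref), no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(codon_alt), no.init.codon = TRUE))
  if (aa_alt == aa_ref) "synonymous"
  else if (aa_alt == "*" && aa_ref != "*") "nonsense"
  else "missense"
}

#' Compare two replicons end to end
#'
#' Convenience wrapper running [find_anchors()], [chain_blocks()],
#' [classify_events()] and [call_snps()] with shared parameters.
#'
#' @param ref,query [replicon]s or character sequences (reference = A,
#'   derived = B).
#' @param k Anchor k-mer size.
#' @param max_gap,min_block Chaining parameters, see [chain_blocks()].
#' @param min_event Indel/event size boundary, see [classify_events()].
#' @return List with `anchors`, `blocks`, `events`, `snps`.
#' @export
compare_replicons <- function(ref, query, k = 21, max_gap = 5000,
                              min_block = 500, min_event = 50) {
  sa <- if (inherits(ref, "replicon")) ref$sequence else ref
  sb <- if (inherits(query, "replicon")) query$sequence else query
  anchors <- find_anchors(sa, sb, k = k)
  blocks <- chain_blocks(anchors, sa, sb, max_gap = max_gap,
                         min_block = min_block)
  events <- classify_events(blocks, nchar(sa), nchar(sb),
                            min_event = min_event)
  snps <- call_snps(blocks, sa, sb, max_indel = min_event)
  list(anchors = anchors, blocks = blocks, events = events, snps = snps)
}
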