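#' Restriction enzymes
#'
#' A restriction enzyme is a (possibly ambiguous) IUPAC recognition site
#' with the cut offset on the top strand, counted in bases from the 5' end
#' of the site. The built-in table ships the rare cutters used to validate
#' high-GC linear assemblies on pulsed-field gels: their AT-rich sites are
#' scarce in a ~70% GC genome, so digests yield few, large fragments.
#'
#' @param name Enzyme name.
#' @param site IUPAC DNA recognition site.
#' @param cut_offset Integer in `[0, nchar(site)]`.
#' @return Object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("DraI")          # built-in: TTT^AAA
#' restriction_enzyme("EcoRI", "GAATTC", 1)
#' @export
restriction_enzyme <- function(name, site = NULL, cut_offset = NULL) {
  builtin <- list(
    DraI = list(site = "TTTAAA", cut_offset = 3L),
    AseI = list(site = "ATTAAT", cut_offset = 2L),
    BfrI = list(site = "CTTAAG", cut_offset = 1L),
    XbaI = list(site = "TCTAGA", cut_offset = 1L)
  )
  if (is.null(site)) {
    if (!name %in% names(builtin))
      stop("unknown enzyme '", name, "'; built-ins are ",
           paste(names(builtin), collapse = ", "),
           " - supply site and cut_offset for others")
    site <- builtin[[name]]$site
    cut_offset <- builtin[[name]]$cut_offset
  }
  site <- toupper(site)
  stopifnot(nchar(site) > 0L,
            all(strsplit(site, "")[[1]] %in% IUPAC_LETTERS))
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie in [0, ", nchar(site), "]")
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s: %s^%s\n", x$name,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1, nchar(x$site))))
  invisible(x)
}

is_palindromic_site <- function(site) {
  identical(site, revcomp(site))
}

#' Find restriction cut positions
#'
#' Scans the top strand with IUPAC-aware matching; for non-palindromic
#' sites the bottom strand is scanned as well and its cuts mapped back to
#' top-strand coordinates (palindromic sites are counted once). Circular
#' replicons are scanned across the origin. Sequence N bases never match:
#' ambiguity in the *site* is honoured, ambiguity in a draft *assembly* is
#' treated conservatively.
#'
#' @param replicon A [replicon].
#' @param enzyme A [restriction_enzyme] (or a built-in enzyme name).
#' @return Sorted unique integer cut positions, each the length of the
#'   sequence prefix left of the cut (0 < cut < length for linear;
#'   0 <= cut < length for circular).
#' @examples
#' find_sites(replicon("x", "AAATTTAAACCC"), "DraI")  # 6
#' @export
find_sites <- function(replicon, enzyme) {
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  seq <- replicon$sequence
  L <- replicon$length
  w <- nchar(enzyme$site)
  circular <- replicon$topology == "circular"
  subject <- if (circular && L >= w)
    paste0(seq, substr(seq, 1L, w - 1L)) else seq
  if (nchar(subject) < w) return(integer(0))

  # fixed = "subject": IUPAC codes in the site are expanded, assembly bases
  # are literal, so N in the sequence matches nothing (except a literal N
  # in a user-supplied site).
  starts0 <- Biostrings::start(Biostrings::matchPattern(
    enzyme$site, Biostrings::DNAString(subject), fixed = "subject")) - 1L
  cuts <- starts0 + enzyme$cut_offset

  if (!is_palindromic_site(enzyme$site)) {
    rc_starts0 <- Biostrings::start(Biostrings::matchPattern(
      revcomp(enzyme$site), Biostrings::DNAString(subject),
      fixed = "subject")) - 1L
    # a bottom-strand site whose revcomp starts at s cuts the top strand
    # w - offset bases into the match
    cuts <- c(cuts, rc_starts0 + (w - enzyme$cut_offset))
  }
  if (circular) {
    cuts <- cuts %% L
  } else {
    cuts <- cuts[cuts > 0L & cuts < L]
  }
  sort(unique(as.integer(cuts)))
}

#' Digest one replicon
#'
#' A linear replicon with n distinct interior cuts yields n + 1 fragments
#' (the two telomeric ends are fragment boundaries); a circular replicon
#' yields n fragments, or a single full-length fragment when uncut.
#' Fragment lengths always sum exactly to the replicon length.
#'
#' @inheritParams find_sites
#' @return A `fragment_set`: data frame with columns `replicon_id`,
#'   `enzyme`, `fragment_bp`, `topology`.
#' @export
digest_replicon <- function(replicon, enzyme) {
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  cuts <- find_sites(replicon, enzyme)
  L <- replicon$length
  if (replicon$topology == "linear") {
    frags <- diff(c(0L, cuts, L))
  } else if (length(cuts) == 0L) {
    frags <- L
  } else {
    frags <- diff(c(cuts, cuts[1] + L))
  }
  fragment_set(replicon$id, enzyme$name, frags, replicon$topology)
}

fragment_set <- function(replicon_id, enzyme, fragment_bp, topology) {
  n <- length(fragment_bp)
  df <- data.frame(replicon_id = rep_len(as.character(replicon_id),
                                         length.out = n),
                   enzyme = rep_len(as.character(enzyme), length.out = n),
                   fragment_bp = as.integer(fragment_bp),
                   topology = rep_len(as.character(topology),
                                      length.out = n),
                   stringsAsFactors = FALSE)
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' Digest a whole genome
#'
#' The multiset union of per-replicon digests: what a total-DNA digest
#' loaded in one gel lane contains.
#'
#' @param replicons List of [replicon] objects.
#' @inheritParams find_sites
#' @return A `fragment_set` over all replicons.
#' @export
digest_genome <- function(replicons, enzyme) {
  if (inherits(replicons, "replicon")) replicons <- list(replicons)
  stopifnot(length(replicons) >= 1L)
  out <- do.call(rbind, lapply(replicons, digest_replicon, enzyme = enzyme))
  class(out) <- c("fragment_set", "data.frame")
  rownames(out) <- NULL
  out
}

#' Pulsed-field gel model
#'
#' Captures the two facts of a PFGE run that matter for matching an in
#' silico digest to a gel photograph: fragments below a run-dependent size
#' cutoff run off (or out of) the gel, and migration distance is linear in
#' log10(size) within the resolvable range.
#'
#' @param min_visible_bp Smallest fragment that shows as a band
#'   (default 30000, typical of runs resolving 50 kb - 1 Mb).
#' @param a,b Migration calibration: position = a - b * log10(size_bp).
#' @param range_bp Resolvable size range `c(lo, hi)`; sizes outside are
#'   compressed at the gel limit.
#' @return Object of class `gel_model`.
#' @export
gel_model <- function(min_visible_bp = 30000, a = 140, b = 20,
                      range_bp = c(30000, 10e6)) {
  stopifnot(b > 0, min_visible_bp >= 0, range_bp[1] < range_bp[2])
  structure(list(min_visible_bp = min_visible_bp, a = a, b = b,
                 range_bp = range_bp),
            class = "gel_model")
}

#' Visible fragments under a gel model
#'
#' @param fragments A `fragment_set`.
#' @param gel A [gel_model].
#' @return The `fragment_set` restricted to fragments >= `min_visible_bp`,
#'   with attribute `n_removed` counting the dropped small fragments.
#' @export
visible_fragments <- function(fragments, gel = gel_model()) {
  keep <- fragments$fragment_bp >= gel$min_visible_bp
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Gel migration position of a fragment
#'
#' @param size_bp Fragment size(s) in bp.
#' @param gel A [gel_model].
#' @return Data frame with `size_bp`, `position` (a - b*log10(size),
#'   monotonically decreasing in size) and `compressed` (TRUE when the size
#'   is outside the resolvable range and the position is clamped to the gel
#'   limit).
#' @export
migration_position <- function(size_bp, gel = gel_model()) {
  stopifnot(all(size_bp > 0))
  clamped <- pmin(pmax(size_bp, gel$range_bp[1]), gel$range_bp[2])
  data.frame(size_bp = size_bp,
             position = gel$a - gel$b * log10(clamped),
             compressed = size_bp < gel$range_bp[1] |
               size_bp > gel$range_bp[2])
}

#' Match predicted fragments to observed gel bands
#'
#' One-to-one assignment of visible predicted fragments to observed band
#' sizes, maximising the number of matches under a relative-error cap and,
#' among maximum-cardinality assignments, minimising total relative error
#' (dynamic programme over the two size-sorted lists). Predicted fragments
#' so close in size that they co-migrate as a single band (pairwise within
#' `rel_tol`) may share one observed band; such fragments are reported in
#' the same co-migration group rather than as unmatched.
#'
#' @param predicted A `fragment_set` (all fragments; visibility filtering
#'   happens internally).
#' @param observed Numeric vector of observed band sizes (bp).
#' @param gel A [gel_model].
#' @param rel_tol Relative size tolerance for a match, |p - o| / o
#'   (default 0.05, reflecting PFGE sizing error on large bands).
#' @return Object of class `band_match_report`: list with `matches` (data
#'   frame: predicted_bp, observed_bp, rel_error, comigration_group),
#'   `unmatched_predicted_visible`, `unmatched_observed`, `rel_tol`,
#'   `n_invisible`.
#' @export
match_bands <- function(predicted, observed, gel = gel_model(),
                        rel_tol = 0.05) {
  stopifnot(all(observed > 0))
  vis <- visible_fragments(predicted, gel)
  p <- sort(vis$fragment_bp)
  o <- sort(observed)
  np <- length(p); no <- length(o)

  ok <- function(pp, oo) abs(pp - oo) / oo <= rel_tol

  # DP over sorted lists; objective lexicographic (matches, -total error).
  # Compatibility windows are intervals on both sorted lists, so a
  # non-crossing assignment attains maximum cardinality.
  M <- matrix(0L, np + 1L, no + 1L)
  E <- matrix(0, np + 1L, no + 1L)
  for (i in seq_len(np)) {
    for (j in seq_len(no)) {
      best_m <- M[i, j + 1L]; best_e <- E[i, j + 1L]
      if (M[i + 1L, j] > best_m ||
          (M[i + 1L, j] == best_m && E[i + 1L, j] < best_e)) {
        best_m <- M[i + 1L, j]; best_e <- E[i + 1L, j]
      }
      if (ok(p[i], o[j])) {
        cand_m <- M[i, j] + 1L
        cand_e <- E[i, j] + abs(p[i] - o[j]) / o[j]
        if (cand_m > best_m || (cand_m == best_m && cand_e < best_e)) {
          best_m <- cand_m; best_e <- cand_e
        }
      }
      M[i + 1L, j + 1L] <- best_m
      E[i + 1L, j + 1L] <- best_e
    }
  }
  # trace back
  pi_match <- integer(0); oj_match <- integer(0)
  i <- np; j <- no
  while (i > 0L && j > 0L) {
    if (ok(p[i], o[j]) &&
        M[i + 1L, j + 1L] == M[i, j] + 1L &&
        abs(E[i + 1L, j + 1L] - (E[i, j] + abs(p[i] - o[j]) / o[j])) <
          1e-12) {
      pi_match <- c(i, pi_match); oj_match <- c(j, oj_match)
      i <- i - 1L; j <- j - 1L
    } else if (M[i + 1L, j + 1L] == M[i, j + 1L] &&
               E[i + 1L, j + 1L] == E[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }

  matched_p <- rep(FALSE, np)
  matched_p[pi_match] <- TRUE
  matches <- data.frame(predicted_bp = p[pi_match],
                        observed_bp = o[oj_match],
                        rel_error = abs(p[pi_match] - o[oj_match]) /
                          o[oj_match],
                        comigration_group = seq_along(pi_match))

  # co-migration: an unmatched predicted fragment within rel_tol of a
  # matched fragment's band (and of that fragment) shares the band
  if (np > 0L && nrow(matches) > 0L) {
    for (i in which(!matched_p)) {
      cand <- which(ok(p[i], matches$observed_bp) &
                      abs(p[i] - matches$predicted_bp) /
                      matches$predicted_bp <= rel_tol)
      if (length(cand) > 0L) {
        k <- cand[which.min(abs(p[i] - matches$observed_bp[cand]))]
        matches <- rbind(matches, data.frame(
          predicted_bp = p[i], observed_bp = matches$observed_bp[k],
          rel_error = abs(p[i] - matches$observed_bp[k]) /
            matches$observed_bp[k],
          comigration_group = matches$comigration_group[k]))
        matched_p[i] <- TRUE
      }
    }
  }
  matches <- matches[order(matches$predicted_bp, decreasing = TRUE), ]
  rownames(matches) <- NULL

  structure(list(
    matches = matches,
    unmatched_predicted_visible = p[!matched_p],
    unmatched_observed = if (length(oj_match) > 0L) o[-oj_match] else o,
    rel_tol = rel_tol,
    n_invisible = attr(vis, "n_removed")
  ), class = "band_match_report")
}

#' @export
print.band_match_report <- function(x, ...) {
  cat(sprintf(
    "<band_match_report> %d matched (%d bands), %d predicted unmatched, %d observed unmatched, %d below visibility\n",
    nrow(x$matches), length(unique(x$matches$comigration_group)),
    length(x$unmatched_predicted_visible), length(x$unmatched_observed),
    x$n_invisible))
  invisible(x)
}

#' Write a fragment set as TSV
#'
#' @param fragments A `fragment_set`.
#' @param path Output path.
#' @export
write_fragments_tsv <- function(fragments, path) {
  writeLines(tool_header(c("replicon_id", "enzyme", "fragment_bp")), path)
  suppressWarnings(write.table(
    fragments[, c("replicon_id", "enzyme", "fragment_bp")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    append = TRUE))
  invisible(path)
}
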