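#' Simulation configuration
#'
#' Bundles every knob of the synthetic-replicon generator into one
#' serializable object. Defaults describe the system the package targets:
#' a ~70% GC linear replicon, transposase/regulator/hypothetical CDS
#' cassettes, 40x long-read coverage with +/-15% multiplicative noise, and
#' gel observations with 2% sizing error and a 30-kb visibility cutoff.
#'
#' @param seed Integer master seed.
#' @param length Replicon length (bp).
#' @param gc_target Fraction of G+C bases (default 0.72).
#' @param cassettes Data frame (`category`, `count`, `length`, optional
#'   `window_start`, `window_end`) of CDS cassettes to plant.
#' @param events Data frame of rearrangement events (see [apply_events()]).
#' @param coverage List `(baseline_depth, noise)`.
#' @param gel List `(enzyme, size_error, min_visible)`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, length = 300000, gc_target = 0.72,
                       cassettes = NULL, events = NULL,
                       coverage = list(baseline_depth = 40, noise = 0.15),
                       gel = list(enzyme = "DraI", size_error = 0.02,
                                  min_visible = 30000)) {
  cfg <- list(seed = as.integer(seed), length = as.integer(length),
              gc_target = gc_target, cassettes = cassettes,
              events = events, coverage = coverage, gel = gel)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- character(0)
  if (!is.finite(cfg$length) || cfg$length <= 0) bad <- c(bad, "length")
  if (cfg$gc_target < 0 || cfg$gc_target > 1) bad <- c(bad, "gc_target")
  if (cfg$coverage$noise < 0 || cfg$coverage$noise > 1)
    bad <- c(bad, "coverage$noise")
  if (cfg$coverage$baseline_depth <= 0) bad <- c(bad, "baseline_depth")
  if (cfg$gel$size_error < 0 || cfg$gel$size_error > 1)
    bad <- c(bad, "gel$size_error")
  if (length(bad) > 0L)
    stop("invalid sim_config field(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read / write a simulation config as YAML
#' @param cfg A [sim_config].
#' @param path File path.
#' @export
write_sim_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$cassettes <- if (!is.null(cfg$cassettes)) as.list(cfg$cassettes)
  lst$events <- if (!is.null(cfg$events)) as.list(cfg$events)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$cassettes))
    lst$cassettes <- as.data.frame(lst$cassettes)
  if (!is.null(lst$events)) lst$events <- as.data.frame(lst$events)
  do.call(sim_config, lst)
}

#' Generate a random linear replicon
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc_target/2 and
#' P(A) = P(T) = (1 - gc_target)/2 — no dinucleotide or codon structure,
#' which is sufficient for digestion and anchoring statistics at high GC.
#' Deterministic given the seed.
#'
#' @param length Replicon length (bp).
#' @param gc_target Target GC fraction.
#' @param seed Integer seed.
#' @param id Replicon id.
#' @return A [replicon] (topology linear).
#' @export
generate_replicon <- function(length, gc_target = 0.72, seed = 1,
                              id = "sim") {
  stopifnot(length > 0, gc_target >= 0, gc_target <= 1)
  seq <- withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
                    (1 - gc_target) / 2)),
    collapse = ""))
  replicon(id, seq, "linear")
}

cassette_products <- list(
  transposase = c("IS5 family transposase",
                  "IS481 family transposase",
                  "Mu transposase domain-containing protein",
                  "IS630 family transposase"),
  transcriptional_regulator = c("GntR family transcriptional regulator",
                                "TetR/AcrR family transcriptional regulator",
                                "DeoR transcriptional regulator"),
  hypothetical = "hypothetical protein",
  other = c("DUF4232 domain-containing protein",
            "ABC transporter ATP-binding protein")
)

#' Plant annotated CDS cassettes on a replicon
#'
#' Places non-overlapping CDS features with category-typical product
#' strings (so that [classify_feature()] recovers each planted category
#' exactly). Placement is uniform within the optional window columns, with
#' bounded retries; an impossible packing errors out.
#'
#' @param replicon A [replicon].
#' @param spec Data frame with columns `category`, `count`, `length` and
#'   optional `window_start`, `window_end`.
#' @param seed Integer seed.
#' @param max_tries Placement retries per cassette (default 1000).
#' @return Feature data frame of the planted cassettes (strand alternates
#'   deterministically), sorted by start.
#' @export
plant_cassettes <- function(replicon, spec, seed = 1, max_tries = 1000) {
  if (is.null(spec) || nrow(spec) == 0L)
    return(feature_table(character(), integer(), integer(),
                         character(), character(), character()))
  withr::with_seed(seed, {
    placed_start <- integer(0); placed_end <- integer(0)
    rows <- list()
    for (r in seq_len(nrow(spec))) {
      cat_ <- spec$category[r]
      len <- spec$length[r]
      lo <- if ("window_start" %in% names(spec) &&
                !is.na(spec$window_start[r])) spec$window_start[r] else 1L
      hi <- if ("window_end" %in% names(spec) &&
                !is.na(spec$window_end[r])) spec$window_end[r]
            else replicon$length
      for (i in seq_len(spec$count[r])) {
        ok <- FALSE
        for (t in seq_len(max_tries)) {
          s <- lo + sample.int(hi - len + 2L - lo, 1L) - 1L
          e <- s + len - 1L
          if (!any(s <= placed_end & e >= placed_start)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("cannot place a ", len, "-bp ", cat_, " cassette without ",
               "overlap after ", max_tries, " tries")
        placed_start <- c(placed_start, s); placed_end <- c(placed_end, e)
        prods <- cassette_products[[cat_]]
        rows[[length(rows) + 1L]] <- data.frame(
          replicon_id = replicon$id, start = s, end = e,
          strand = if (length(rows) %% 2L == 0L) "+" else "-",
          kind = "CDS", product = sample(prods, 1L))
      }
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$start), ]
    feature_table(df$replicon_id, df$start, df$end, df$strand, df$kind,
                  df$product, replicon_length = replicon$length)
  })
}

#' Apply rearrangement events to a replicon
#'
#' Applies substitutions, insertions, deletions, inversions and
#' translocations at stated (or `NA` = uniformly sampled) loci on the
#' original coordinate system; event footprints must not overlap. Returns
#' the derived replicon together with a truth table carrying both original
#' (A) and derived (B) coordinates of every event, exact by construction,
#' so a rearrangement mapper's calls can be scored without re-deriving
#' anything. Derived length = original + sum(insertions) -
#' sum(deletions), exactly.
#'
#' @param replicon A [replicon] (the reference, A).
#' @param events Data frame with columns `type` (substitution, insertion,
#'   deletion, inversion, translocation), `locus` (1-based start on A; for
#'   insertions the new material lands after `locus`), `length`, optional
#'   `dest` (translocations: insert after this A position), optional
#'   `donor_start` (insertions copied from A itself, which leaves the
#'   material in two copies as a chromosomal repeat would), optional `seq`
#'   (explicit insertion material, e.g. copied from a different replicon;
#'   otherwise the material is sampled).
#' @param seed Integer seed (for sampled insertion material and
#'   substitution alleles).
#' @param id Id of the derived replicon.
#' @return List with `replicon` (derived) and `truth` (data frame `type`,
#'   `a_locus`, `b_position`, `length`).
#' @export
apply_events <- function(replicon, events, seed = 1,
                         id = paste0(replicon$id, "_derived")) {
  seq_a <- replicon$sequence
  L <- replicon$length
  if (is.null(events) || nrow(events) == 0L)
    return(list(replicon = replicon(id, seq_a, replicon$topology),
                truth = data.frame(type = character(0),
                                   a_locus = integer(0),
                                   b_position = integer(0),
                                   length = integer(0))))
  ev <- events
  ev$length <- as.integer(ev$length)
  if (!"dest" %in% names(ev)) ev$dest <- NA_integer_
  if (!"donor_start" %in% names(ev)) ev$donor_start <- NA_integer_
  if (!"seq" %in% names(ev)) ev$seq <- NA_character_

  withr::with_seed(seed, {
    # footprint on A: [locus, locus+length-1] for deletion/inversion/
    # translocation source; a point for insertions/substitutions
    foot_end <- function(e)
      ifelse(e$type %in% c("deletion", "inversion", "translocation"),
             e$locus + e$length - 1L,
             ifelse(e$type == "substitution", e$locus, e$locus))
    # sample any NA loci away from existing footprints
    for (r in which(is.na(ev$locus))) {
      for (t in 1:1000) {
        ev$locus[r] <- sample.int(L - ev$length[r], 1L)
        if (!any(overlaps_row(ev, r, foot_end))) break
        ev$locus[r] <- NA_integer_
      }
      if (is.na(ev$locus[r])) stop("cannot place sampled event ", r)
    }
    fe <- foot_end(ev)
    o <- order(ev$locus)
    if (any(ev$locus[o][-1] <= fe[o][-nrow(ev)]))
      stop("overlapping events")
    tr_dest <- ev$dest[!is.na(ev$dest)]
    if (any(vapply(tr_dest, function(d)
      any(d >= ev$locus & d <= fe), logical(1))))
      stop("translocation destination inside another event footprint")

    # expand translocations into an unlinked cut + paste
    ops <- list()   # each: list(kind, at, len, seq) acting on A coords
    truth <- list()
    for (r in seq_len(nrow(ev))) {
      e <- ev[r, ]
      if (e$type == "substitution") {
        old <- substr(seq_a, e$locus, e$locus)
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        ops[[length(ops) + 1L]] <- list(kind = "sub", at = e$locus,
                                        len = 1L, seq = new)
        truth[[length(truth) + 1L]] <- data.frame(
          type = "substitution", a_locus = e$locus, b_position = NA,
          length = 1L, ref = old, alt = new)
      } else if (e$type == "insertion") {
        insseq <- if (!is.na(e$seq)) {
          if (nchar(e$seq) != e$length)
            stop("insertion seq length disagrees with the length column")
          toupper(e$seq)
        } else if (!is.na(e$donor_start))
          substr(seq_a, e$donor_start, e$donor_start + e$length - 1L)
        else paste(sample(c("A", "C", "G", "T"), e$length, replace = TRUE,
                          prob = c(0.14, 0.36, 0.36, 0.14)),
                   collapse = "")
        ops[[length(ops) + 1L]] <- list(kind = "ins", at = e$locus,
                                        len = e$length, seq = insseq)
        truth[[length(truth) + 1L]] <- data.frame(
          type = "insertion", a_locus = e$locus, b_position = NA,
          length = e$length, ref = "", alt = "")
      } else if (e$type == "deletion") {
        ops[[length(ops) + 1L]] <- list(kind = "del", at = e$locus,
                                        len = e$length)
        truth[[length(truth) + 1L]] <- data.frame(
          type = "deletion", a_locus = e$locus, b_position = NA,
          length = e$length, ref = "", alt = "")
      } else if (e$type == "inversion") {
        ops[[length(ops) + 1L]] <- list(kind = "inv", at = e$locus,
                                        len = e$length)
        truth[[length(truth) + 1L]] <- data.frame(
          type = "inversion", a_locus = e$locus, b_position = NA,
          length = e$length, ref = "", alt = "")
      } else if (e$type == "translocation") {
        moved <- substr(seq_a, e$locus, e$locus + e$length - 1L)
        ops[[length(ops) + 1L]] <- list(kind = "del", at = e$locus,
                                        len = e$length)
        ops[[length(ops) + 1L]] <- list(kind = "ins", at = e$dest,
                                        len = e$length, seq = moved)
        truth[[length(truth) + 1L]] <- data.frame(
          type = "translocation", a_locus = e$locus, b_position = NA,
          length = e$length, ref = "", alt = "")
      } else stop("unknown event type: ", e$type)
    }

    # apply right-to-left so A coordinates stay valid
    at <- vapply(ops, function(o) o$at, numeric(1))
    seq_b <- seq_a
    for (i in order(at, decreasing = TRUE)) {
      op <- ops[[i]]
      if (op$kind == "sub") {
        substr(seq_b, op$at, op$at) <- op$seq
      } else if (op$kind == "ins") {
        seq_b <- paste0(substr(seq_b, 1L, op$at), op$seq,
                        substr(seq_b, op$at + 1L, nchar(seq_b)))
      } else if (op$kind == "del") {
        seq_b <- paste0(substr(seq_b, 1L, op$at - 1L),
                        substr(seq_b, op$at + op$len, nchar(seq_b)))
      } else if (op$kind == "inv") {
        substr(seq_b, op$at, op$at + op$len - 1L) <-
          revcomp(substr(seq_b, op$at, op$at + op$len - 1L))
      }
    }

    # derived (B) coordinate of an A position: shift by indels to its left
    shift_at <- function(p) {
      s <- 0L
      for (op in ops) {
        if (op$kind == "ins" && op$at < p) s <- s + op$len
        if (op$kind == "del" && (op$at + op$len - 1L) < p) s <- s - op$len
      }
      s
    }
    truth <- do.call(rbind, truth)
    truth$b_position <- NA_integer_
    for (r in seq_len(nrow(truth))) {
      tt <- truth$type[r]
      if (tt == "insertion") {
        truth$b_position[r] <-
          truth$a_locus[r] + shift_at(truth$a_locus[r] + 1L) -
          truth$length[r] + 1L
        # shift_at counts this insertion itself for p > locus; first
        # inserted base sits right after the shifted locus
      } else if (tt == "translocation") {
        d <- ev$dest[ev$type == "translocation" &
                       ev$locus == truth$a_locus[r]][1]
        truth$b_position[r] <- d + shift_at(d + 1L) - truth$length[r] + 1L
      } else if (tt == "deletion") {
        truth$b_position[r] <- truth$a_locus[r] + shift_at(truth$a_locus[r])
      } else {
        truth$b_position[r] <- truth$a_locus[r] + shift_at(truth$a_locus[r])
      }
    }
    list(replicon = replicon(id, seq_b, replicon$topology), truth = truth)
  })
}

overlaps_row <- function(ev, r, foot_end) {
  fe <- foot_end(ev)
  s <- ev$locus; e <- fe
  i <- seq_len(nrow(ev)) != r & !is.na(s)
  s[r] <= e[i] & e[r] >= s[i]
}

#' Build a terminal-inverted-repeat plasmid and its collapsed contig
#'
#' The full plasmid is arm + central + reverse-complement(arm) (length
#' 2R + C); the collapsed contig is arm + central, the form an assembler
#' reports when it cannot separate the two repeat copies. Arm and central
#' are taken as the leading R + C bases of the supplied replicon.
#'
#' @param replicon Source [replicon] (length >= R + C).
#' @param R Arm length (bp, > 0).
#' @param C Central-region length (bp, >= 0).
#' @return List with `full` ([replicon], 2R + C bp), `collapsed`
#'   ([replicon], R + C bp) and `truth` (list `R`, `C`,
#'   `arm_interval`, `central_interval` on the collapsed contig).
#' @export
make_inverted_repeat_plasmid <- function(replicon, R, C) {
  R <- as.integer(R); C <- as.integer(C)
  if (R <= 0L) stop("arm length R must be positive")
  if (C < 0L) stop("negative central length")
  if (R + C > replicon$length)
    stop("R + C exceeds the source replicon length")
  arm <- substr(replicon$sequence, 1L, R)
  central <- if (C > 0L) substr(replicon$sequence, R + 1L, R + C) else ""
  full <- paste0(arm, central, revcomp(arm))
  collapsed <- paste0(arm, central)
  list(full = replicon(paste0(replicon$id, "_full"), full, "linear"),
       collapsed = replicon(paste0(replicon$id, "_collapsed"), collapsed,
                            "linear"),
       truth = list(R = R, C = C, arm_interval = c(1L, R),
                    central_interval = if (C > 0L) c(R + 1L, R + C)
                                       else NULL))
}

#' Simulate a coverage track over a collapsed contig
#'
#' Expected depth is `2 * baseline` over the collapsed arm (both repeat
#' copies map there) and `baseline` over the central region; realized
#' depth multiplies the expectation by (1 + uniform(-noise, +noise)) per
#' base. Seeded and deterministic.
#'
#' @param contig_length Collapsed contig length (bp).
#' @param arm_interval 1-based inclusive arm interval (or `NULL` for a
#'   flat track).
#' @param baseline Baseline depth (> 0, default 40).
#' @param noise Multiplicative noise half-width (default 0.15).
#' @param seed Integer seed.
#' @param id Contig id.
#' @return A [coverage_track].
#' @export
simulate_coverage <- function(contig_length, arm_interval, baseline = 40,
                              noise = 0.15, seed = 1, id = "sim") {
  stopifnot(baseline > 0, noise >= 0, noise < 1)
  expected <- rep(baseline, contig_length)
  if (!is.null(arm_interval))
    expected[arm_interval[1]:arm_interval[2]] <- 2 * baseline
  depth <- withr::with_seed(seed,
    expected * (1 + runif(contig_length, -noise, noise)))
  coverage_track(id, depth)
}

#' Simulate an observed gel band list from a predicted digest
#'
#' Drops fragments below the visibility cutoff, perturbs each surviving
#' size multiplicatively by (1 + Normal(0, size_error)) — the sizing error
#' of reading band positions off a pulsed-field gel — and optionally
#' merges bands that co-migrate within the gel's resolution.
#'
#' @param fragments A `fragment_set` (or integer sizes).
#' @param size_error Multiplicative sizing error SD (default 0.02).
#' @param min_visible Visibility cutoff (bp, default 30000).
#' @param merge_within Relative resolution below which adjacent bands
#'   merge into one (default 0, no merging).
#' @param seed Integer seed.
#' @return Numeric vector of observed band sizes, sorted decreasing.
#' @export
simulate_gel_observation <- function(fragments, size_error = 0.02,
                                     min_visible = 30000,
                                     merge_within = 0, seed = 1) {
  sizes <- if (is.data.frame(fragments)) fragments$fragment_bp
           else as.numeric(fragments)
  sizes <- sizes[sizes >= min_visible]
  if (length(sizes) == 0L) return(numeric(0))
  obs <- withr::with_seed(seed,
    sizes * (1 + rnorm(length(sizes), 0, size_error)))
  obs <- sort(obs, decreasing = TRUE)
  if (merge_within > 0 && length(obs) > 1L) {
    merged <- list()
    grp <- obs[1]
    for (x in obs[-1]) {
      if ((grp[length(grp)] - x) / x <= merge_within) grp <- c(grp, x)
      else { merged[[length(merged) + 1L]] <- mean(grp); grp <- x }
    }
    merged[[length(merged) + 1L]] <- mean(grp)
    obs <- unlist(merged)
  }
  obs
}
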