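#' Load replicons from FASTA or GenBank
#'
#' FASTA records carry no topology, so they default to linear (the replicons
#' this package targets are linear chromosomes and linear plasmids) with a
#' warning; use `topology=` to silence it. GenBank flat files state topology
#' on the LOCUS line and it is read from there.
#'
#' @param path File path.
#' @param format `"fasta"` or `"genbank"`.
#' @param topology Optional override applied to every record (silences the
#'   FASTA default warning).
#' @return A list of [replicon] objects, named by id.
#' @export
load_replicons <- function(path, format = c("fasta", "genbank"),
                           topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e)
                       stop("cannot parse FASTA '", path, "': ",
                            conditionMessage(e)))
    if (length(seqs) == 0L) stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    topo <- topology
    if (is.null(topo)) {
      warning("FASTA carries no topology; defaulting all records to linear")
      topo <- "linear"
    }
    reps <- Map(function(id, s) replicon(id, as.character(s), topo),
                ids, as.character(seqs))
  } else {
    recs <- parse_genbank(path)
    if (length(recs) == 0L) stop("no records in GenBank file: ", path)
    reps <- lapply(recs, function(r) {
      topo <- if (!is.null(topology)) topology else r$topology
      replicon(r$id, r$sequence, topo)
    })
    names(reps) <- vapply(reps, function(r) r$id, character(1))
  }
  reps
}

#' Write replicons to FASTA
#'
#' @param replicons A list of [replicon] objects.
#' @param path Output path.
#' @export
write_replicons <- function(replicons, path) {
  if (inherits(replicons, "replicon")) replicons <- list(replicons)
  seqs <- Biostrings::DNAStringSet(
    setNames(vapply(replicons, function(r) r$sequence, character(1)),
             vapply(replicons, function(r) r$id, character(1))))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Load annotated features from GenBank or GFF3
#'
#' Every CDS row gets a `category` from the keyword rules
#' ([classify_feature()]); non-CDS features are retained with their kind.
#'
#' @param path File path.
#' @param format `"genbank"` or `"gff3"`.
#' @param rules Keyword rules, default [default_keyword_rules()].
#' @param replicon_lengths Optional named vector of replicon lengths used to
#'   check coordinates.
#' @return A feature data frame (see [feature_table()]).
#' @export
load_features <- function(path, format = c("genbank", "gff3"),
                          rules = default_keyword_rules(),
                          replicon_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genbank") {
    recs <- parse_genbank(path)
    rows <- do.call(rbind, lapply(recs, function(r) r$features))
    if (is.null(rows) || nrow(rows) == 0L)
      return(feature_table(character(), integer(), integer(),
                           character(), character(), character(), rules))
    df <- feature_table(rows$replicon_id, rows$start, rows$end, rows$strand,
                        rows$kind, rows$product, rules)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    product <- if ("product" %in% names(S4Vectors::mcols(gr)))
      as.character(S4Vectors::mcols(gr)$product) else rep("", length(gr))
    df <- feature_table(as.character(GenomicRanges::seqnames(gr)),
                        BiocGenerics::start(gr), BiocGenerics::end(gr),
                        as.character(BiocGenerics::strand(gr)),
                        as.character(S4Vectors::mcols(gr)$type),
                        product, rules)
    df$strand[!df$strand %in% c("+", "-")] <- "+"
  }
  if (!is.null(replicon_lengths)) {
    for (i in seq_len(nrow(df))) {
      L <- replicon_lengths[[df$replicon_id[i]]]
      if (!is.null(L) && df$end[i] > L)
        stop("feature out of bounds on ", df$replicon_id[i], ": ",
             df$product[i], " ends at ", df$end[i], " > ", L)
    }
  }
  df
}

#' Load a per-base coverage track
#'
#' bedGraph intervals are 0-based half-open and must be sorted, contiguous
#' and non-overlapping; they are expanded to one depth value per base. The
#' TSV form has two columns, 1-based position and depth, contiguous from
#' position 1.
#'
#' @param path File path.
#' @param format `"bedgraph"` or `"tsv"`.
#' @param replicon_id For TSV input (which carries no name); defaults to the
#'   file stem.
#' @return A [coverage_track].
#' @export
load_coverage <- function(path, format = c("bedgraph", "tsv"),
                          replicon_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) stop("empty bedGraph: ", path)
    chroms <- as.character(GenomicRanges::seqnames(gr))
    if (length(unique(chroms)) > 1L)
      stop("bedGraph covers more than one contig; split it first")
    start <- BiocGenerics::start(gr)   # 1-based after import
    end <- BiocGenerics::end(gr)
    o <- order(start)
    start <- start[o]; end <- end[o]
    score <- S4Vectors::mcols(gr)$score[o]
    if (start[1] != 1L)
      stop("coverage does not start at the first base (first interval ",
           "starts at ", start[1], ")")
    if (length(start) > 1L) {
      gap <- which(start[-1] != end[-length(end)] + 1L)
      if (length(gap) > 0L)
        stop("gap or overlap in bedGraph after interval ending at ",
             end[gap[1]])
    }
    depth <- rep(score, end - start + 1L)
    coverage_track(if (is.null(replicon_id)) chroms[1] else replicon_id,
                   depth)
  } else {
    df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#")
    if (ncol(df) < 2L) stop("coverage TSV needs columns position, depth")
    pos <- as.integer(df[[1]])
    if (!identical(pos, seq_along(pos)))
      stop("coverage TSV positions must be contiguous from 1")
    coverage_track(
      if (is.null(replicon_id)) tools::file_path_sans_ext(basename(path))
      else replicon_id,
      as.numeric(df[[2]]))
  }
}

tool_header <- function(columns) {
  paste0("# replicontools ",
         as.character(utils::packageVersion("replicontools")),
         "\n# ", paste(columns, collapse = "\t"))
}

#' Write / read a feature table as TSV
#'
#' The writer emits a commented header naming columns and tool version; a
#' write-then-read round trip reproduces the table field for field.
#'
#' @param features Feature data frame.
#' @param path File path.
#' @export
write_feature_tsv <- function(features, path) {
  writeLines(tool_header(names(features)), path)
  suppressWarnings(write.table(features, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE,
                               append = TRUE))
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  cols <- strsplit(sub("^# ", "", hdr[2]), "\t", fixed = TRUE)[[1]]
  df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                   col.names = cols, stringsAsFactors = FALSE,
                   colClasses = c(replicon_id = "character",
                                  start = "integer", end = "integer",
                                  strand = "character", kind = "character",
                                  product = "character",
                                  category = "character")[cols])
  df
}

# ---------------------------------------------------------------------------
# Minimal GenBank flat-file parser: LOCUS topology, FEATURES (key, location,
# /product), ORIGIN sequence. Handles complement() and collapses join() to
# its envelope with a warning. Enough for assembly records; not a general
# GenBank reader.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  rec_start <- grep("^LOCUS", lines)
  if (length(rec_start) == 0L) stop("no LOCUS line: not a GenBank file")
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  lapply(seq_along(rec_start), function(i)
    parse_genbank_record(lines[rec_start[i]:rec_end[i]]))
}

parse_genbank_record <- function(lines) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  id <- locus[2]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L)
    stop("GenBank record '", id, "' has no ORIGIN sequence block")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L)
    stop("GenBank record '", id, "': empty ORIGIN block")

  features <- parse_genbank_features(lines, id, origin_at[1])
  list(id = id, topology = topology, sequence = sequence,
       features = features)
}

parse_genbank_features <- function(lines, id, origin_at) {
  feat_at <- grep("^FEATURES", lines)
  empty <- data.frame(replicon_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      kind = character(), product = character(),
                      stringsAsFactors = FALSE)
  if (length(feat_at) == 0L) return(empty)
  block <- lines[(feat_at[1] + 1L):(origin_at - 1L)]
  # feature headers sit at column 6; qualifiers/continuations at column 22
  hdr <- grep("^ {5}\\S", block)
  if (length(hdr) == 0L) return(empty)
  hdr_end <- c(hdr[-1] - 1L, length(block))
  rows <- lapply(seq_along(hdr), function(i) {
    chunk <- block[hdr[i]:hdr_end[i]]
    head_parts <- strsplit(trimws(chunk[1]), "\\s+")[[1]]
    kind <- head_parts[1]
    loc <- paste(head_parts[-1], collapse = "")
    j <- 2L
    # location may continue over lines until the first qualifier
    while (j <= length(chunk) && !grepl("^\\s+/", chunk[j])) {
      loc <- paste0(loc, trimws(chunk[j])); j <- j + 1L
    }
    if (kind == "source") return(NULL)
    strand <- if (grepl("complement", loc)) "-" else "+"
    if (grepl("^join|^complement\\(join", loc))
      warning("join() location collapsed to its envelope for a ", kind,
              " on ", id)
    nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 1L) return(NULL)
    qual <- paste(trimws(chunk[j:length(chunk)]), collapse = " ")
    product <- ""
    m <- regmatches(qual, regexpr('/product="[^"]*"', qual))
    if (length(m) == 1L)
      product <- sub('/product="', "", sub('"$', "", m))
    data.frame(replicon_id = id, start = as.integer(min(nums)),
               end = as.integer(max(nums)), strand = strand, kind = kind,
               product = product, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}
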