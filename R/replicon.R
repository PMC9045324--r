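#' Construct a replicon
#'
#' A replicon is a named DNA sequence with an explicit topology. Topology is
#' never inferred from the sequence: linear chromosomes and giant linear
#' plasmids of actinomycetes are represented exactly like circular replicons
#' except for this flag, and every downstream operation (digestion, coverage
#' segmentation, comparison) consults it.
#'
#' @param id Character scalar, the replicon name.
#' @param sequence Character scalar, DNA over the IUPAC alphabet. Lower case
#'   input is upper-cased.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `replicon`: a list with elements `id`,
#'   `sequence`, `topology` and `length`.
#' @examples
#' rep <- replicon("p1", "ACGTACGTACGT", "linear")
#' rep$length
#' @export
replicon <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("replicon '", id, "': empty sequence")
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]),
                 IUPAC_LETTERS)
  if (length(bad) > 0L)
    stop("replicon '", id, "': illegal characters outside the IUPAC ",
         "alphabet: ", paste(bad, collapse = ", "))
  structure(
    list(id = id, sequence = sequence, topology = topology,
         length = nchar(sequence)),
    class = "replicon"
  )
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s\n",
              x$id, format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' @export
length.replicon <- function(x) x$length

#' Default product-keyword classification rules
#'
#' Ordered case-insensitive substring rules mapping CDS product strings to
#' the categories used in plasmid summary tables: transposases,
#' transcriptional regulators and hypothetical proteins. The first matching
#' rule wins; a product matching no rule is classified `other`. The rule
#' order matters: "GntR family transcriptional regulator" must hit the
#' regulator rule even though annotations are free text.
#'
#' @return A list of `(category, patterns)` pairs, class `keyword_rules`.
#' @seealso [classify_feature()]
#' @export
default_keyword_rules <- function() {
  structure(
    list(
      list(category = "transposase",
           patterns = c("transposase")),
      list(category = "transcriptional_regulator",
           patterns = c("transcriptional regulator", "regulator")),
      list(category = "hypothetical",
           patterns = c("hypothetical protein"))
    ),
    class = "keyword_rules"
  )
}

#' Classify a CDS product string
#'
#' Deterministic, case-insensitive substring matching against an ordered
#' rule table; the first rule with any matching pattern assigns the
#' category, and unmatched products fall through to `"other"`.
#'
#' @param product Character vector of product strings (free annotation
#'   text). `NA` is treated as an empty string.
#' @param rules A `keyword_rules` object; defaults to
#'   [default_keyword_rules()].
#' @return Character vector of categories, one per product.
#' @examples
#' classify_feature("IS5 family transposase")
#' classify_feature("GntR family transcriptional regulator")
#' classify_feature("hypothetical protein")
#' @export
classify_feature <- function(product, rules = default_keyword_rules()) {
  product <- ifelse(is.na(product), "", product)
  low <- tolower(product)
  out <- rep("other", length(low))
  unset <- rep(TRUE, length(low))
  for (rule in rules) {
    hit <- rep(FALSE, length(low))
    for (p in rule$patterns)
      hit <- hit | grepl(tolower(p), low, fixed = TRUE)
    out[unset & hit] <- rule$category
    unset <- unset & !hit
  }
  out
}

#' Build a feature table
#'
#' Features are held in an ordinary data frame (one row per feature) with
#' 1-based inclusive coordinates, the convention of GenBank flat files and
#' of every coordinate printed in genome reports.
#'
#' @param replicon_id,start,end,strand,kind,product Vectors, recycled to a
#'   common length.
#' @param rules Keyword rules used to derive the `category` column for CDS
#'   rows; non-CDS rows get category `other`.
#' @param replicon_length Optional; when given, coordinates are checked
#'   against it.
#' @return A data frame with columns `replicon_id`, `start`, `end`,
#'   `strand`, `kind`, `product`, `category`.
#' @export
feature_table <- function(replicon_id, start, end, strand = "+",
                          kind = "CDS", product = "",
                          rules = default_keyword_rules(),
                          replicon_length = NULL) {
  df <- data.frame(replicon_id = replicon_id, start = as.integer(start),
                   end = as.integer(end), strand = strand, kind = kind,
                   product = product, stringsAsFactors = FALSE)
  bad <- which(df$start < 1L | df$end < df$start)
  if (length(bad) > 0L)
    stop("invalid coordinates for feature row(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (!is.null(replicon_length)) {
    oob <- which(df$end > replicon_length)
    if (length(oob) > 0L)
      stop("feature out of replicon bounds: row ", oob[1], " (",
           df$product[oob[1]], ", end ", df$end[oob[1]], " > ",
           replicon_length, ")")
  }
  df$category <- ifelse(df$kind == "CDS",
                        classify_feature(df$product, rules), "other")
  no_prod <- df$kind == "CDS" & (is.na(df$product) | df$product == "")
  if (any(no_prod))
    warning(sum(no_prod), " CDS feature(s) have no product; category set ",
            "to 'other'")
  df
}

#' GC content of a DNA sequence
#'
#' Fraction (G + C) / (non-N bases). N bases count in neither numerator nor
#' denominator, so draft assemblies with gap runs are not diluted.
#'
#' @param sequence Character scalar (or a `replicon`).
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("GGCC")  # 1
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(sequence) {
  if (inherits(sequence, "replicon")) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(sequence))
  denom <- sum(f[c("A", "C", "G", "T")])
  if (denom == 0L)
    stop("GC content undefined: sequence contains no unambiguous A/C/G/T ",
         "bases")
  unname((f[["G"]] + f[["C"]]) / denom)
}

#' Per-base coverage track
#'
#' @param replicon_id Character scalar.
#' @param depth Numeric vector, one non-negative value per base (position 1
#'   is the first base).
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(replicon_id, depth) {
  depth <- as.numeric(depth)
  if (any(is.na(depth)) || any(depth < 0))
    stop("coverage depths must be non-negative and non-missing")
  structure(list(replicon_id = replicon_id, depth = depth),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %s bp, mean depth %.1f\n",
              x$replicon_id, format(length(x$depth), big.mark = ","),
              mean(x$depth)))
  invisible(x)
}

# Reverse complement of a plain character sequence (IUPAC-aware).
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
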