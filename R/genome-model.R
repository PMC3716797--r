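#' @importFrom methods is
#' @importFrom stats setNames
NULL

FEATURE_KINDS <- c("CDS", "gene", "tRNA", "rRNA", "tmRNA", "misc")
ANNOTATION_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "tmRNA")

#' Genomic interval on a possibly circular sequence
#'
#' Coordinates are 0-based half-open: `start` is the first base covered,
#' `end` is one past the last. On a circular sequence an interval may span
#' the origin, in which case `wraps = TRUE` and `start > end` is permitted;
#' the covered length is then `(L - start) + end`.
#'
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp).
#' @param wraps Does the interval cross the origin of a circular sequence?
#' @return An object of class `gb_interval`.
#' @export
gb_interval <- function(start, end, wraps = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start < 0L) stop("interval start must be >= 0")
  if (!wraps && start >= end) stop("non-wrapping interval requires start < end")
  structure(list(start = start, end = end, wraps = isTRUE(wraps)),
            class = "gb_interval")
}

#' Length of an interval on a sequence of length L
#' @param iv A [gb_interval()].
#' @param L Sequence length in bp.
#' @return Integer length in bp (always >= 1 for valid intervals).
#' @export
interval_length <- function(iv, L) {
  if (iv$wraps) (L - iv$start) + iv$end else iv$end - iv$start
}

#' Annotated feature
#'
#' One annotated element of a genome: a coding sequence, gene, structural
#' RNA, or miscellaneous span. The location is an ordered list of intervals
#' (multi-interval locations arise from `join(...)` annotations).
#'
#' @param kind One of `r paste(FEATURE_KINDS, collapse = ", ")`.
#' @param name Gene symbol (or `NA` when unnamed).
#' @param location A [gb_interval()] or list of them.
#' @param strand `"+"` or `"-"`.
#' @param qualifiers Named character vector of free-form qualifiers
#'   (product, anticodon, note, ...).
#' @return An object of class `gb_feature`.
#' @export
gb_feature <- function(kind, name = NA_character_, location, strand = "+",
                       qualifiers = character()) {
  kind <- match.arg(kind, FEATURE_KINDS)
  if (is(location, "gb_interval")) location <- list(location)
  stopifnot(length(location) >= 1L,
            all(vapply(location, function(x) is(x, "gb_interval"), logical(1))))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(kind = kind, name = as.character(name), location = location,
                 strand = strand, qualifiers = qualifiers),
            class = "gb_feature")
}

#' Total span of a feature in bp
#' @inheritParams interval_length
#' @param feature A [gb_feature()].
#' @export
feature_length <- function(feature, L) {
  sum(vapply(feature$location, interval_length, numeric(1), L = L))
}

#' Annotated genome record
#'
#' An in-memory genome: sequence, topology and features. This is the object
#' every pipeline stage consumes. Sequences are stored uppercase; lowercase
#' input is folded at construction.
#'
#' @param id Accession-like identifier.
#' @param sequence Nucleotide string over the IUPAC alphabet.
#' @param topology `"circular"` or `"linear"`.
#' @param features List of [gb_feature()] objects.
#' @param organism Organism name.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, topology = c("circular", "linear"),
                          features = list(), organism = NA_character_) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  rec <- structure(list(id = as.character(id), sequence = sequence,
                        topology = topology, features = features,
                        organism = as.character(organism)),
                   class = "genome_record")
  validate_genome_record(rec)
  rec
}

#' Sequence length of a record
#' @param record A [genome_record()].
#' @export
genome_length <- function(record) nchar(record$sequence)

#' Validate a genome record's invariants
#'
#' Checks that every feature location lies within the sequence, that wrapped
#' intervals occur only on circular records, and warns when a CDS span is not
#' a multiple of 3 (annotated partialness aside, this usually flags a
#' transcription error rather than a real pseudogene).
#'
#' @param record A [genome_record()].
#' @return The record, invisibly; errors on violated invariants.
#' @export
validate_genome_record <- function(record) {
  L <- genome_length(record)
  bad <- setdiff(unique(strsplit(record$sequence, "", fixed = TRUE)[[1]]),
                 strsplit("ACGTNRYSWKMBDHV", "", fixed = TRUE)[[1]])
  if (length(bad) > 0L)
    stop("sequence of ", record$id, " contains non-IUPAC characters: ",
         paste(bad, collapse = " "))
  for (f in record$features) {
    for (iv in f$location) {
      if (iv$wraps && record$topology == "linear")
        stop("feature ", f$name, " wraps the origin of linear record ", record$id)
      if (iv$start < 0L || iv$start >= L || iv$end < 0L || iv$end > L ||
          (!iv$wraps && iv$end > L))
        stop("feature ", ifelse(is.na(f$name), f$kind, f$name),
             " lies outside [0, ", L, ") in record ", record$id)
    }
    if (f$kind == "CDS") {
      partial <- any(grepl("[<>]", f$qualifiers)) ||
        isTRUE(attr(f, "partial"))
      if (!partial && feature_length(f, L) %% 3L != 0L)
        warning("CDS ", f$name, " in ", record$id,
                " has length not a multiple of 3", call. = FALSE)
    }
  }
  invisible(record)
}

# Unroll an interval into 1-based closed IRanges pieces on [1, L].
.interval_pieces <- function(iv, L) {
  if (iv$wraps) {
    IRanges::IRanges(start = c(iv$start + 1L, 1L), end = c(L, iv$end))
  } else {
    IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  }
}

#' Length of the union of feature spans
#'
#' Computes the number of base pairs covered by at least one feature of the
#' requested kinds, resolving overlaps and origin-spanning locations on the
#' circle. This is the quantity behind the intergenic-space statistic:
#' intergenic bp = L minus this union.
#'
#' @param record A [genome_record()].
#' @param kinds Character vector of feature kinds to include.
#' @return Covered length in bp, between 0 and `genome_length(record)`.
#' @export
feature_span_union <- function(record, kinds = ANNOTATION_KINDS) {
  stopifnot(length(kinds) >= 1L)
  L <- genome_length(record)
  keep <- Filter(function(f) f$kind %in% kinds, record$features)
  if (length(keep) == 0L) return(0L)
  pieces <- do.call(c, unlist(lapply(keep, function(f) {
    for (iv in f$location) {
      if (iv$start >= L || iv$end > L)
        stop("feature ", ifelse(is.na(f$name), f$kind, f$name),
             " has coordinates outside the sequence")
    }
    lapply(f$location, .interval_pieces, L = L)
  }), recursive = FALSE))
  sum(IRanges::width(IRanges::reduce(pieces)))
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s), %d bp, %d features\n",
              x$id, x$topology, genome_length(x), length(x$features)))
  kinds <- vapply(x$features, `[[`, character(1), "kind")
  if (length(kinds)) {
    tab <- table(kinds)
    cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.gb_feature <- function(x, ...) {
  loc <- paste(vapply(x$location, function(iv)
    sprintf("[%d,%d)%s", iv$start, iv$end, if (iv$wraps) "~" else ""),
    character(1)), collapse = ",")
  cat(sprintf("<gb_feature> %s %s %s strand %s\n",
              x$kind, ifelse(is.na(x$name), "(unnamed)", x$name), loc, x$strand))
  invisible(x)
}

# Reverse complement for plain character sequences (IUPAC-aware).
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Extract the nucleotide sequence covered by a feature, strand-corrected
# (5'->3' on the coding strand).
feature_sequence <- function(record, feature) {
  L <- genome_length(record)
  parts <- vapply(feature$location, function(iv) {
    if (iv$wraps) {
      paste0(substr(record$sequence, iv$start + 1L, L),
             substr(record$sequence, 1L, iv$end))
    } else {
      substr(record$sequence, iv$start + 1L, iv$end)
    }
  }, character(1))
  s <- paste(parts, collapse = "")
  if (feature$strand == "-") revcomp(s) else s
}
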