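#' Read a GenBank flat file
#'
#' Parses the subset of the GenBank flat-file grammar that annotated genome
#' records use: the LOCUS line (name, length, circular/linear topology), the
#' ORGANISM line, the FEATURES table with `join(...)`/`complement(...)`
#' locations and multi-line qualifiers, and the ORIGIN sequence block.
#' Header blocks other than these are carried along as opaque text and
#' re-emitted by [write_genbank()].
#'
#' Coordinates are converted from GenBank 1-based inclusive to the package's
#' 0-based half-open convention at this boundary. On circular records a
#' two-part `join(x..L,1..y)` is collapsed into a single origin-spanning
#' interval. The feature symbol is taken from the `gene` qualifier when
#' present, else `locus_tag`, else `product`. Feature keys outside
#' gene/CDS/tRNA/rRNA/tmRNA are retained as kind `misc` (the `source`
#' meta-feature is dropped).
#'
#' @param path Path to a GenBank flat file.
#' @return A [genome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)[1]
  if (is.na(locus_i)) stop("GenBank format error: no LOCUS line in ", path)
  locus <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  id <- locus[2]
  bp_i <- match("bp", locus)
  declared_len <- suppressWarnings(as.integer(locus[bp_i - 1L]))
  topology <- if ("circular" %in% locus) "circular" else "linear"

  feat_i <- grep("^FEATURES", lines)[1]
  origin_i <- grep("^ORIGIN", lines)[1]
  if (is.na(origin_i)) stop("GenBank format error: no ORIGIN section in ", path)
  end_i <- grep("^//", lines)[1]
  if (is.na(end_i)) end_i <- length(lines) + 1L

  org_i <- grep("^\\s{2,}ORGANISM", lines)
  organism <- if (length(org_i)) trimws(sub("^\\s+ORGANISM\\s+", "", lines[org_i[1]]))
              else NA_character_

  header <- if (!is.na(feat_i) && feat_i > locus_i + 1L)
    lines[(locus_i + 1L):(feat_i - 1L)] else character()

  seq <- toupper(gsub("[^A-Za-z]", "",
                      paste(lines[(origin_i + 1L):(end_i - 1L)], collapse = "")))
  L <- nchar(seq)
  if (!is.na(declared_len) && declared_len != L)
    warning("LOCUS length ", declared_len, " != ORIGIN length ", L,
            " in ", path, call. = FALSE)

  features <- list()
  if (!is.na(feat_i)) {
    flines <- lines[(feat_i + 1L):(origin_i - 1L)]
    features <- .parse_feature_table(flines, L, topology)
  }

  rec <- genome_record(id = id, sequence = seq, topology = topology,
                       features = features, organism = organism)
  attr(rec, "gb_header") <- header
  rec
}

.parse_feature_table <- function(flines, L, topology) {
  # A feature begins with a key in column 6; continuation/qualifier lines
  # are indented to column 22.
  starts <- grep("^ {5}\\S", flines)
  features <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    j <- if (k < length(starts)) starts[k + 1L] - 1L else length(flines)
    key <- sub("^ {5}(\\S+).*$", "\\1", flines[i])
    block <- flines[i:j]
    # split location (lines before first qualifier) from qualifiers
    body <- c(sub("^ {5}\\S+\\s*", "", block[1]),
              if (length(block) > 1L) trimws(block[-1]) else character())
    qual_start <- which(startsWith(body, "/"))[1]
    loc_str <- paste(body[seq_len(ifelse(is.na(qual_start),
                                         length(body), qual_start - 1L))],
                     collapse = "")
    quals <- if (!is.na(qual_start)) .parse_qualifiers(body[qual_start:length(body)])
             else character()
    if (key == "source") next
    kind <- if (key %in% ANNOTATION_KINDS) key else "misc"
    loc <- .parse_location(loc_str, L, topology)
    name <- if ("gene" %in% names(quals)) quals[["gene"]]
            else if ("locus_tag" %in% names(quals)) quals[["locus_tag"]]
            else if ("product" %in% names(quals)) quals[["product"]]
            else NA_character_
    f <- gb_feature(kind = kind, name = name, location = loc$intervals,
                    strand = loc$strand, qualifiers = quals)
    attr(f, "partial") <- loc$partial
    attr(f, "source_key") <- key
    features[[length(features) + 1L]] <- f
  }
  features
}

.parse_qualifiers <- function(qlines) {
  # Merge continuation lines (those not starting with "/") into the
  # preceding qualifier, then split at the first "=".
  merged <- character()
  for (ln in qlines) {
    if (startsWith(ln, "/") || length(merged) == 0L) {
      merged <- c(merged, ln)
    } else {
      sep <- if (grepl("^/translation=", merged[length(merged)])) "" else " "
      merged[length(merged)] <- paste(merged[length(merged)], ln, sep = sep)
    }
  }
  keys <- sub("^/([^=]+)(=.*)?$", "\\1", merged)
  vals <- ifelse(grepl("=", merged),
                 gsub('^"|"$', "", sub("^/[^=]+=", "", merged)),
                 "")
  setNames(vals, keys)
}

.parse_location <- function(loc_str, L, topology) {
  s <- gsub("\\s", "", loc_str)
  strand <- "+"
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) s <- sub("^join\\((.*)\\)$", "\\1", s)
  if (grepl("complement\\(", s)) {
    # join(complement(..),..) variant: strip inner complements, flag minus
    strand <- "-"
    s <- gsub("complement\\(([^)]*)\\)", "\\1", s)
  }
  partial <- grepl("[<>]", s)
  s <- gsub("[<>]", "", s)
  pieces <- strsplit(s, ",", fixed = TRUE)[[1]]
  ivs <- lapply(pieces, function(p) {
    ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    if (any(is.na(ab)) || ab[1] < 1L || ab[2] > L)
      stop("coordinate error: location '", loc_str,
           "' outside declared length ", L)
    gb_interval(ab[1] - 1L, ab[2])     # 1-based inclusive -> 0-based half-open
  })
  # collapse a piece ending at L followed by a piece starting at 1 into one
  # origin-spanning interval (circular records only)
  if (topology == "circular" && length(ivs) >= 2L) {
    out <- list()
    i <- 1L
    while (i <= length(ivs)) {
      a <- ivs[[i]]
      if (i < length(ivs) && !a$wraps && a$end == L &&
          ivs[[i + 1L]]$start == 0L && !ivs[[i + 1L]]$wraps) {
        out[[length(out) + 1L]] <- gb_interval(a$start, ivs[[i + 1L]]$end,
                                               wraps = TRUE)
        i <- i + 2L
      } else {
        out[[length(out) + 1L]] <- a
        i <- i + 1L
      }
    }
    ivs <- out
  }
  list(intervals = ivs, strand = strand, partial = partial)
}

.format_location <- function(feature, L) {
  parts <- unlist(lapply(feature$location, function(iv) {
    if (iv$wraps) {
      c(sprintf("%d..%d", iv$start + 1L, L), sprintf("%d..%d", 1L, iv$end))
    } else {
      sprintf("%d..%d", iv$start + 1L, iv$end)
    }
  }))
  s <- if (length(parts) > 1L) sprintf("join(%s)", paste(parts, collapse = ","))
       else parts
  if (feature$strand == "-") s <- sprintf("complement(%s)", s)
  s
}

#' Write a GenBank flat file
#'
#' Emits a record in GenBank flat-file form readable by [read_genbank()]
#' (and by standard GenBank parsers): 1-based inclusive coordinates,
#' origin-spanning features as `join(x..L,1..y)`, minus strand as
#' `complement(...)`, sequence in 60-base ORIGIN lines. Output is
#' deterministic, so a read/write cycle is byte-stable.
#'
#' @param record A [genome_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  validate_genome_record(record)
  L <- genome_length(record)
  if (record$topology == "linear")
    for (f in record$features)
      for (iv in f$location)
        if (iv$wraps) stop("linear record ", record$id,
                           " contains an origin-spanning feature")
  con <- file(path, open = "wt")
  on.exit(close(con))
  topo <- if (record$topology == "circular") "circular" else "linear  "
  writeLines(sprintf("LOCUS       %-16s %10d bp    DNA     %s UNA 01-JAN-2000",
                     record$id, L, topo), con)
  header <- attr(record, "gb_header")
  if (is.null(header)) {
    header <- c(sprintf("DEFINITION  %s.", record$id),
                sprintf("SOURCE      %s",
                        ifelse(is.na(record$organism), "synthetic construct",
                               record$organism)),
                sprintf("  ORGANISM  %s",
                        ifelse(is.na(record$organism), "synthetic construct",
                               record$organism)))
  }
  writeLines(header, con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (f in record$features) {
    key <- attr(f, "source_key")
    if (is.null(key)) key <- if (f$kind == "misc") "misc_feature" else f$kind
    writeLines(sprintf("     %-16s%s", key, .format_location(f, L)), con)
    quals <- f$qualifiers
    if (!is.na(f$name) && !"gene" %in% names(quals))
      quals <- c(setNames(f$name, "gene"), quals)
    for (qi in seq_along(quals)) {
      k <- names(quals)[qi]; v <- quals[[qi]]
      q <- if (nzchar(v)) sprintf("/%s=\"%s\"", k, v) else sprintf("/%s", k)
      writeLines(paste0(strrep(" ", 21), q), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
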