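#' ORF search parameters
#'
#' Defaults follow common practice for plastid annotation: start codons ATG
#' and GTG, a 90 bp minimum, standard genetic code. TTG can be admitted as an
#' additional start via `use_extended = TRUE`. `min_length` counts the full
#' span including the stop codon by default; set
#' `include_stop_in_length = FALSE` to apply the threshold to the coding part
#' only (the counting convention differs between annotation tools, so both
#' are available).
#'
#' @param start_codons Character vector of start trinucleotides.
#' @param extended_start_codons Additional starts admitted when
#'   `use_extended` is `TRUE`.
#' @param use_extended Include the extended start codons?
#' @param min_length Minimum ORF length in bp.
#' @param include_stop_in_length Does `min_length` count the stop codon?
#' @param counting_mode `"longest_per_stop"` (one call per stop, anchored at
#'   the 5'-most qualifying start) or `"all_starts"` (one call per start).
#' @return An object of class `orf_params`.
#' @export
orf_params <- function(start_codons = c("ATG", "GTG"),
                       extended_start_codons = "TTG",
                       use_extended = FALSE,
                       min_length = 90L,
                       include_stop_in_length = TRUE,
                       counting_mode = c("longest_per_stop", "all_starts")) {
  counting_mode <- match.arg(counting_mode)
  starts <- toupper(start_codons)
  if (use_extended) starts <- union(starts, toupper(extended_start_codons))
  stopifnot(min_length >= 3L,
            all(nchar(starts) == 3L),
            all(strsplit(paste(starts, collapse = ""), "")[[1]] %in%
                  c("A", "C", "G", "T")))
  structure(list(start_codons = starts, min_length = as.integer(min_length),
                 include_stop_in_length = isTRUE(include_stop_in_length),
                 counting_mode = counting_mode),
            class = "orf_params")
}

STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

# codon strings at 0-based offsets 0..(nchar(s)-3)
.codons_at <- function(s) {
  n <- nchar(s)
  if (n < 3L) return(character())
  substring(s, 1:(n - 2L), 3:n)
}

#' Find open reading frames on a genome
#'
#' Scans both strands in all frames. On circular records the scan continues
#' across the origin, so an ORF may wrap (reported with an origin-spanning
#' interval); ORF length is capped at the genome length. Codons containing
#' ambiguity codes never match a start or a stop. In `longest_per_stop` mode
#' exactly one call is reported per (strand, stop position), anchored at the
#' 5'-most qualifying start; `all_starts` reports every qualifying start.
#'
#' @param record A [genome_record()].
#' @param params An [orf_params()].
#' @return A data frame of class `orf_calls`, one row per ORF, sorted by
#'   plus-strand start coordinate: `start`, `end` (0-based half-open on the
#'   plus strand), `wraps`, `strand`, `frame` (plus-strand start mod 3),
#'   `start_codon`, `length` (bp, including the stop codon).
#' @export
find_orfs <- function(record, params = orf_params()) {
  validate_genome_record(record)
  L <- genome_length(record)
  if (L < 3L) stop("sequence shorter than one codon")
  circular <- record$topology == "circular"
  rows <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") record$sequence else revcomp(record$sequence)
    D <- if (circular) paste0(S, S) else S
    cod <- .codons_at(D)
    nq <- length(cod)                      # codon offsets 0..nq-1
    is_stop <- cod %in% STOP_CODONS
    is_start <- cod %in% params$start_codons
    # next in-frame stop at or after each offset, per offset residue class
    next_stop <- rep(NA_integer_, nq)
    for (r in 0:2) {
      if (r > nq - 1L) next
      idx <- seq.int(r, nq - 1L, by = 3L)
      ns <- NA_integer_
      for (t in rev(seq_along(idx))) {
        q <- idx[t]
        if (is_stop[q + 1L]) ns <- q
        next_stop[q + 1L] <- ns
      }
    }
    p_max <- min(L, nq) - 1L
    cand_p <- which(is_start[seq_len(p_max + 1L)]) - 1L
    if (length(cand_p) == 0L) next
    q <- next_stop[cand_p + 1L]
    len <- q - cand_p + 3L
    keep <- !is.na(q) & len <= L
    core_len <- if (params$include_stop_in_length) len else len - 3L
    keep <- keep & core_len >= params$min_length
    cand_p <- cand_p[keep]; q <- q[keep]; len <- len[keep]
    if (length(cand_p) == 0L) next
    if (params$counting_mode == "longest_per_stop") {
      ord <- order(q %% L, -len)
      first <- !duplicated((q %% L)[ord])
      sel <- ord[first]
      cand_p <- cand_p[sel]; q <- q[sel]; len <- len[sel]
    }
    for (i in seq_along(cand_p)) {
      p <- cand_p[i]; l <- len[i]
      if (strand == "+") {
        s_abs <- p; e_abs <- p + l
      } else {
        s_abs <- L - p - l; e_abs <- L - p
        if (s_abs < 0L) { s_abs <- s_abs + L; e_abs <- e_abs + L }
      }
      wraps <- e_abs > L
      rows[[length(rows) + 1L]] <- data.frame(
        start = s_abs, end = if (wraps) e_abs - L else e_abs, wraps = wraps,
        strand = strand, frame = s_abs %% 3L,
        start_codon = substr(D, p + 1L, p + 3L), length = l,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), wraps = logical(),
               strand = character(), frame = integer(),
               start_codon = character(), length = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand, out$length), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("orf_calls", class(out))
  out
}

#' Translate a nucleotide sequence
#'
#' Standard-table translation via the [Biostrings::GENETIC_CODE] lookup.
#' Stops render as `*` (internal stops are permitted; the caller validates).
#' Codons containing ambiguity codes render as `X`. Initiator recoding is
#' not applied: GTG/TTG starts translate as V/L.
#'
#' @param nt Nucleotide string; length must be a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_dna <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  cods <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Extract the nucleotide sequence of an ORF call
#' @param record The [genome_record()] the calls came from.
#' @param call One row of an `orf_calls` data frame.
#' @return The ORF sequence 5'->3' on its coding strand.
#' @export
orf_sequence <- function(record, call) {
  iv <- gb_interval(call$start, call$end, wraps = call$wraps)
  feature_sequence(record, gb_feature("misc", location = iv,
                                      strand = call$strand))
}
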