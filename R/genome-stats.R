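# Round half away from zero at one decimal; reporting-time only, internal
# arithmetic stays unrounded.
round1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

.base_counts <- function(seq) {
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  setNames(as.integer(tab[c("A", "C", "G", "T")]), c("A", "C", "G", "T"))
}

#' G+C content of a sequence
#'
#' 100 x (G + C) / (A + C + G + T). Ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @param seq Nucleotide string.
#' @return Percentage (unrounded).
#' @export
gc_content <- function(seq) {
  stopifnot(nchar(seq) > 0L)
  counts <- .base_counts(toupper(seq))
  counts[is.na(counts)] <- 0L
  denom <- sum(counts)
  if (denom == 0L) stop("sequence has no unambiguous bases; G+C undefined")
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

#' Intergenic fraction of a genome
#'
#' Percentage of the genome not covered by any gene or RNA annotation:
#' 100 x (L - union of gene/CDS/tRNA/rRNA/tmRNA spans) / L. The kind set is
#' configurable for sensitivity to the annotation-class convention.
#'
#' @param record A [genome_record()].
#' @param kinds Feature kinds whose spans count as "annotated".
#' @return Percentage (unrounded).
#' @export
intergenic_fraction <- function(record, kinds = ANNOTATION_KINDS) {
  L <- genome_length(record)
  100 * (L - feature_span_union(record, kinds)) / L
}

# protein-coding features: CDS where present, else gene features that are
# not RNA genes (records annotated with `gene` only)
.coding_features <- function(record) {
  cds <- Filter(function(f) f$kind == "CDS", record$features)
  if (length(cds)) return(cds)
  Filter(function(f) f$kind == "gene" && !grepl("^(trn|rrn|ssra)", f$name,
                                                ignore.case = TRUE),
         record$features)
}

#' Start-codon usage of protein-coding features
#'
#' Extracts the strand-corrected first codon of every protein-coding feature
#' and reports the percentage starting with ATG, GTG, TTG, and an `others`
#' bucket. Percentages are rounded half-away-from-zero to one decimal.
#'
#' @param record A [genome_record()].
#' @return Named numeric vector `c(ATG=, GTG=, TTG=, others=)`.
#' @export
start_codon_usage <- function(record) {
  feats <- .coding_features(record)
  if (length(feats) == 0L) stop("record has no protein-coding features")
  L <- genome_length(record)
  first <- character()
  for (f in feats) {
    if (feature_length(f, L) < 3) {
      warning("feature ", f$name, " shorter than one codon; skipped",
              call. = FALSE)
      next
    }
    first <- c(first, substr(feature_sequence(record, f), 1L, 3L))
  }
  n <- length(first)
  named <- c("ATG", "GTG", "TTG")
  pct <- vapply(named, function(cod) 100 * sum(first == cod) / n, numeric(1))
  out <- c(pct, others = 100 * sum(!first %in% named) / n)
  round1(out)
}

# rRNA features within `gap` bp of each other (on the circle) form one operon
.count_rrna_operons <- function(record, gap = 5000L) {
  rr <- Filter(function(f) f$kind == "rRNA", record$features)
  if (length(rr) == 0L) return(0L)
  L <- genome_length(record)
  spans <- do.call(rbind, lapply(rr, function(f) {
    iv <- f$location[[1]]
    if (iv$wraps) c(iv$start, iv$end + L) else c(iv$start, iv$end)
  }))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  k <- 1L
  for (i in seq_len(nrow(spans) - 1L)) {
    if (spans[i + 1L, 1] - spans[i, 2] > gap) k <- k + 1L
  }
  # close the circle: if last and first clusters touch around the origin,
  # merge them
  if (k > 1L && record$topology == "circular") {
    wrap_gap <- (spans[1L, 1] + L) - spans[nrow(spans), 2]
    if (wrap_gap <= gap) k <- k - 1L
  }
  k
}

#' Per-genome summary statistics
#'
#' Size, G+C%, intergenic space, protein-coding gene / tRNA counts, rRNA
#' operon count (rRNA features clustered at a 5 kb gap), and start-codon
#' usage — the standard characterization row for an organelle genome.
#'
#' @param record A [genome_record()].
#' @return An object of class `genome_summary` (a list).
#' @export
genome_summary <- function(record) {
  n_coding <- length(.coding_features(record))
  usage <- if (n_coding > 0) start_codon_usage(record)
           else c(ATG = NA_real_, GTG = NA_real_, TTG = NA_real_,
                  others = NA_real_)
  structure(list(
    id = record$id,
    organism = record$organism,
    size_bp = genome_length(record),
    gc_percent = round1(gc_content(record$sequence)),
    intergenic_percent = round1(intergenic_fraction(record)),
    n_protein_genes = n_coding,
    n_trna = sum(vapply(record$features, `[[`, character(1), "kind") == "tRNA"),
    n_rrna_operons = .count_rrna_operons(record),
    start_codon_usage = usage
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("<genome_summary> %s: %d bp, GC %.1f%%, intergenic %.1f%%\n",
              x$id, x$size_bp, x$gc_percent, x$intergenic_percent))
  cat(sprintf("  %d protein genes, %d tRNAs, %d rRNA operon(s); ATG %.1f%%\n",
              x$n_protein_genes, x$n_trna, x$n_rrna_operons,
              x$start_codon_usage[["ATG"]]))
  invisible(x)
}

#' Genome-characteristics table for a set of genomes
#'
#' One column per genome (input order preserved), rows for each summary
#' statistic — the conventional layout for comparing organelle genomes.
#'
#' @param records List of [genome_record()] objects.
#' @return A [report_table()].
#' @export
summary_table <- function(records) {
  sums <- lapply(records, genome_summary)
  ids <- vapply(sums, `[[`, character(1), "id")
  stat_names <- c("size_bp", "gc_percent", "intergenic_percent",
                  "n_protein_genes", "n_trna", "n_rrna_operons",
                  "start_ATG_pct", "start_GTG_pct", "start_TTG_pct",
                  "start_others_pct")
  grab <- function(s) c(s$size_bp, s$gc_percent, s$intergenic_percent,
                        s$n_protein_genes, s$n_trna, s$n_rrna_operons,
                        s$start_codon_usage)
  df <- data.frame(statistic = stat_names,
                   stringsAsFactors = FALSE)
  for (i in seq_along(sums)) df[[ids[i]]] <- unname(grab(sums[[i]]))
  report_table(df, "Genome characteristics")
}
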