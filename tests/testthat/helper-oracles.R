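# Independent oracles and small builders used across the suite. These
# deliberately use naive algorithms (bitmaps, position-wise scans, exhaustive
# enumeration) so they share no code path with the implementation.

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# record with random features (possibly wrapping) for union/intergenic tests
random_record <- function(L = 1000L, n_features = 10L, topology = "circular",
                          kinds = c("CDS", "tRNA", "rRNA")) {
  feats <- lapply(seq_len(n_features), function(i) {
    len <- sample.int(max(2L, L %/% 4L), 1L)
    s <- sample.int(L, 1L) - 1L
    e <- s + len
    iv <- if (e > L && topology == "circular") gb_interval(s, e - L, wraps = TRUE)
          else gb_interval(s %% max(1L, (L - len)), s %% max(1L, (L - len)) + len)
    gb_feature(sample(kinds, 1L), paste0("f", i), iv,
               sample(c("+", "-"), 1L))
  })
  suppressWarnings(genome_record(paste0("R", sample.int(1e6, 1L)),
                                 random_dna(L), topology, feats))
}

# position-by-position boolean-mask union length
bitmap_union <- function(record, kinds) {
  L <- genome_length(record)
  mask <- logical(L)
  for (f in record$features) {
    if (!f$kind %in% kinds) next
    for (iv in f$location) {
      pos <- if (iv$wraps) c(seq_len(iv$end), (iv$start + 1L):L)
             else (iv$start + 1L):iv$end
      mask[pos] <- TRUE
    }
  }
  sum(mask)
}

# rotate the origin of a circular record by `off` bp (features remapped)
rotate_record <- function(record, off) {
  L <- genome_length(record)
  off <- off %% L
  if (off == 0L) return(record)
  seq2 <- paste0(substr(record$sequence, off + 1L, L),
                 substr(record$sequence, 1L, off))
  feats <- lapply(record$features, function(f) {
    f$location <- lapply(f$location, function(iv) {
      len <- interval_length(iv, L)
      s <- (iv$start - off) %% L
      e <- s + len
      if (e > L) gb_interval(s, e - L, wraps = TRUE) else gb_interval(s, e)
    })
    f
  })
  suppressWarnings(genome_record(record$id, seq2, record$topology, feats,
                                 record$organism))
}

rc_chr <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# naive position-wise ORF scan: enumerate every (strand, start, next in-frame
# stop) tuple and filter by the same published rules
orf_scan_oracle <- function(record, starts = c("ATG", "GTG"),
                            min_length = 90L, include_stop = TRUE,
                            mode = "longest_per_stop") {
  stops <- c("TAA", "TAG", "TGA")
  L <- genome_length(record)
  circular <- record$topology == "circular"
  out <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") record$sequence else rc_chr(record$sequence)
    D <- if (circular) paste0(S, S) else S
    codon <- function(q) substr(D, q + 1L, q + 3L)
    p_hi <- if (circular) L - 1L else L - 3L
    for (p in 0:p_hi) {
      if (!codon(p) %in% starts) next
      k <- 1L
      len <- NA_integer_
      while (p + 3L * k + 2L <= nchar(D) - 1L && 3L * k + 3L <= L) {
        if (codon(p + 3L * k) %in% stops) { len <- 3L * k + 3L; break }
        k <- k + 1L
      }
      if (is.na(len)) next
      eff <- if (include_stop) len else len - 3L
      if (eff < min_length) next
      out[[length(out) + 1L]] <- data.frame(
        strand = strand, p = p, len = len,
        stop_pos = (p + len - 3L) %% L, start_codon = codon(p),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(data.frame())
  df <- do.call(rbind, out)
  if (mode == "longest_per_stop") {
    df <- df[order(df$strand, df$stop_pos, -df$len), , drop = FALSE]
    df <- df[!duplicated(df[, c("strand", "stop_pos")]), , drop = FALSE]
  }
  # convert strand coordinates to plus-strand starts for comparison
  df$plus_start <- ifelse(df$strand == "+", df$p, (L - df$p - df$len) %% L)
  df[order(df$plus_start, df$strand, df$len), , drop = FALSE]
}

# canonical comparable form of find_orfs() output
orf_call_key <- function(calls) {
  k <- sprintf("%s:%d:%d:%s", calls$strand, calls$start, calls$length,
               calls$start_codon)
  sort(k)
}
orf_oracle_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(sprintf("%s:%d:%d:%s", df$strand, df$plus_start, df$len,
               df$start_codon))
}

# exhaustive presence-signature partition over all 2^k species subsets
signature_partition_oracle <- function(sets, clades) {
  species <- names(sets)
  universe <- sort(unique(unlist(sets)))
  blocks <- list()
  for (gene in universe) {
    present <- sort(species[vapply(sets, function(s) gene %in% s, logical(1))])
    label <- if (length(present) == length(species)) "core"
    else {
      lab <- NA_character_
      for (cl in names(clades))
        if (setequal(present, clades[[cl]])) { lab <- paste0("clade:", cl); break }
      if (!is.na(lab)) lab
      else if (length(present) == 1L) paste0("unique:", present)
      else paste0("other:", paste(present, collapse = "+"))
    }
    blocks[[label]] <- c(blocks[[label]], gene)
  }
  blocks
}

# random signed circular order over markers 1..n
random_signed_order <- function(n) {
  perm <- sample.int(n)
  signs <- sample(c(1L, -1L), n, replace = TRUE)
  signed_gene_order(list(perm * signs), shapes = "circular")
}

# independent translation oracle: hard-coded codon table lookup
codon_table_oracle <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  # first base slowest, third base fastest (matches the aas string above)
  cods <- c(sapply(bases, function(b1) sapply(bases, function(b2)
    paste0(b1, b2, bases))))
  setNames(aas, cods)
})

translate_oracle <- function(nt) {
  n <- nchar(nt)
  cods <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  paste(unname(codon_table_oracle[cods]), collapse = "")
}
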