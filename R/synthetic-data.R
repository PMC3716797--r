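CANONICAL_ISOACCEPTORS <- c(
  "trnA(GGC)", "trnA(TGC)", "trnC(GCA)", "trnD(GTC)", "trnE(TTC)",
  "trnF(GAA)", "trnG(GCC)", "trnG(TCC)", "trnH(GTG)", "trnI(GAT)",
  "trnK(TTT)", "trnL(CAA)", "trnL(GAG)", "trnL(TAA)", "trnL(TAG)",
  "trnM(CAT)", "trnN(GTT)", "trnP(TGG)", "trnQ(TTG)", "trnR(ACG)",
  "trnR(CCG)", "trnR(CCT)", "trnR(TCT)", "trnS(CGA)", "trnS(GCT)",
  "trnS(GGA)", "trnS(TGA)", "trnT(GGT)", "trnT(TGT)", "trnV(GAC)",
  "trnV(TAC)", "trnW(CCA)", "trnY(GTA)")

#' Simulation parameters for plastid-like genomes
#'
#' Defaults emulate the composition of red algal plastid genomes: circular
#' DNA in the 150-192 kb range, G+C near 0.29-0.38, ~200 densely packed
#' single-exon genes, ~29 tRNAs, one rRNA operon, 9-18% intergenic space,
#' and start-codon proportions near 88/6/6 ATG/GTG/TTG.
#'
#' @param genome_length Genome size in bp.
#' @param gc_target Target G+C fraction.
#' @param n_genes Number of protein-coding genes.
#' @param n_trna Number of tRNA genes.
#' @param intergenic_target Target intergenic fraction.
#' @param start_codon_props Named proportions for planted start codons.
#' @param seed Integer seed fixing all downstream randomness.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(genome_length = 180000L, gc_target = 0.31,
                       n_genes = 200L, n_trna = 29L,
                       intergenic_target = 0.15,
                       start_codon_props = c(ATG = 0.88, GTG = 0.06,
                                             TTG = 0.06),
                       seed = 1L) {
  stopifnot(gc_target > 0, gc_target < 1,
            intergenic_target >= 0, intergenic_target < 1,
            n_genes >= 0L, n_trna >= 0L,
            abs(sum(start_codon_props) - 1) < 1e-9)
  structure(list(genome_length = as.integer(genome_length),
                 gc_target = gc_target, n_genes = as.integer(n_genes),
                 n_trna = as.integer(n_trna),
                 intergenic_target = intergenic_target,
                 start_codon_props = start_codon_props,
                 seed = as.integer(seed)),
            class = "sim_params")
}

TRNA_LEN <- 72L
RRNA_SPEC <- c(rrs = 1500L, rrl = 2900L, rrf = 120L)

.random_seq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random coding sequence: planted start codon, no internal in-frame stop,
# random stop codon
.random_gene_seq <- function(len, gc, start_codon) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  body <- .random_seq(len - 6L, gc)
  cods <- substring(body, seq(1L, len - 6L, 3L), seq(3L, len - 6L, 3L))
  bad <- which(cods %in% STOP_CODONS)
  while (length(bad)) {
    for (i in bad) {
      repeat {
        cod <- .random_seq(3L, gc)
        if (!cod %in% STOP_CODONS) break
      }
      cods[i] <- cod
    }
    bad <- which(cods %in% STOP_CODONS)
  }
  paste0(start_codon, paste(cods, collapse = ""),
         sample(STOP_CODONS, 1L))
}

# Layout: the editable intermediate between simulation and sequence. One
# element per gene/tRNA/rRNA, in genome order around the circle, each with
# its coding-strand sequence, plus one intergenic gap length per slot
# (following the element in that slot).
.build_record <- function(id, layout, params, organism = "synthetic construct") {
  elements <- layout$elements
  gaps <- layout$gaps
  stopifnot(length(elements) == length(gaps))
  seq_parts <- character()
  features <- list()
  pos <- 0L
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    len <- nchar(el$seq)
    plus_seq <- if (el$strand == "-") revcomp(el$seq) else el$seq
    seq_parts <- c(seq_parts, plus_seq)
    quals <- switch(el$type,
      gene = c(gene = el$name),
      tRNA = c(gene = sub("\\(.*$", "", el$name), product = el$name),
      rRNA = c(gene = el$name))
    kind <- switch(el$type, gene = "CDS", tRNA = "tRNA", rRNA = "rRNA")
    f <- gb_feature(kind, name = unname(quals[["gene"]]),
                    location = gb_interval(pos, pos + len),
                    strand = el$strand, qualifiers = quals)
    attr(f, "source_key") <- kind
    features[[length(features) + 1L]] <- f
    pos <- pos + len
    gap_gc <- if (!is.null(layout$gap_gc)) layout$gap_gc else params$gc_target
    gapseq <- .random_seq(gaps[i], gap_gc)
    seq_parts <- c(seq_parts, gapseq)
    pos <- pos + gaps[i]
  }
  genome_record(id = id, sequence = paste(seq_parts, collapse = ""),
                topology = "circular", features = features,
                organism = organism)
}

.layout_gene_names <- function(layout) {
  vapply(Filter(function(e) e$type == "gene", layout$elements),
         `[[`, character(1), "name")
}

# signed order of gene markers in a layout, restricted to `markers`
.layout_marker_order <- function(layout, markers) {
  keep <- Filter(function(e) e$type == "gene" && e$name %in% markers,
                 layout$elements)
  ids <- match(vapply(keep, `[[`, character(1), "name"), markers)
  signs <- ifelse(vapply(keep, `[[`, character(1), "strand") == "+", 1L, -1L)
  signed_gene_order(list(ids * signs), shapes = "circular",
                    marker_names = markers)
}

#' Simulate an ancestral plastid-like genome
#'
#' Generates a circular annotated genome under [sim_params()]: gene names
#' drawn without replacement from the bundled master pool of real plastid
#' symbols, planted start codons, stop-free coding interiors, one rRNA
#' operon, tRNAs with canonical isoacceptor labels, and i.i.d. intergenic
#' spacers at the target G+C. Fully reproducible from the seed.
#'
#' @param params A [sim_params()].
#' @return List with `record` (a [genome_record()]) and `truth` (a
#'   `sim_truth` list: the layout, the gene table, planted proportions, and
#'   the parameters — sufficient to recompute every expected pipeline output
#'   without re-simulation).
#' @export
simulate_ancestor <- function(params = sim_params()) {
  set.seed(params$seed)
  L <- params$genome_length
  pool <- load_gene_pool()
  if (params$n_genes > length(pool))
    stop("parameter error: n_genes exceeds the master pool size (",
         length(pool), ")")
  gene_names <- if (params$n_genes > 0L) sample(pool, params$n_genes)
                else character()
  trna_labels <- sample(CANONICAL_ISOACCEPTORS, params$n_trna,
                        replace = params$n_trna > length(CANONICAL_ISOACCEPTORS))
  use_rrna <- L >= 20000L
  rrna_total <- if (use_rrna) sum(RRNA_SPEC) else 0L
  coding_target <- round(L * (1 - params$intergenic_target))
  gene_total <- coding_target - params$n_trna * TRNA_LEN - rrna_total
  gene_total <- 3L * (gene_total %/% 3L)   # keep codon arithmetic exact
  if (params$n_genes > 0L && gene_total < 99L * params$n_genes)
    stop("parameter error: genes do not fit in the genome at the requested ",
         "intergenic fraction")

  gene_lens <- integer()
  if (params$n_genes > 0L) {
    mean_len <- gene_total / params$n_genes
    raw <- runif(params$n_genes, 0.4 * mean_len, 1.6 * mean_len)
    gene_lens <- pmax(99L, 3L * round(raw / 3))
    # nudge lengths (in codons) until the genic total is exact
    diff <- gene_total - sum(gene_lens)
    step <- 3L * sign(diff)
    while (diff != 0L) {
      i <- sample.int(params$n_genes, 1L)
      if (gene_lens[i] + step >= 99L) {
        gene_lens[i] <- gene_lens[i] + step
        diff <- diff - step
      }
    }
  }
  starts <- sample(names(params$start_codon_props),
                   params$n_genes, replace = TRUE,
                   prob = params$start_codon_props)

  elements <- c(
    lapply(seq_len(params$n_genes), function(i) list(
      type = "gene", name = gene_names[i],
      strand = sample(c("+", "-"), 1L),
      seq = .random_gene_seq(gene_lens[i], params$gc_target, starts[i]),
      start_codon = starts[i])),
    lapply(trna_labels, function(lab) list(
      type = "tRNA", name = lab, strand = sample(c("+", "-"), 1L),
      seq = .random_seq(TRNA_LEN, params$gc_target)))
  )
  elements <- elements[sample.int(length(elements))]
  if (use_rrna) {
    op_strand <- sample(c("+", "-"), 1L)
    operon <- lapply(names(RRNA_SPEC), function(nm) list(
      type = "rRNA", name = nm, strand = op_strand,
      seq = .random_seq(RRNA_SPEC[[nm]], params$gc_target)))
    at <- if (length(elements)) sample.int(length(elements) + 1L, 1L) else 1L
    elements <- append(elements, operon, after = at - 1L)
  }
  n_el <- length(elements)
  total_gap <- L - coding_target + (coding_target -
    sum(vapply(elements, function(e) nchar(e$seq), integer(1))))
  gaps <- if (n_el > 0L) {
    u <- runif(n_el)
    g <- floor(total_gap * u / sum(u))
    rem <- total_gap - sum(g)
    if (rem > 0L) {
      bump <- sample.int(n_el, rem, replace = rem > n_el)
      for (i in bump) g[i] <- g[i] + 1L
    }
    as.integer(g)
  } else integer()
  # keep the rRNA operon clustered: internal operon gaps capped at 100 bp
  if (use_rrna && n_el >= 3L) {
    rr_idx <- which(vapply(elements, `[[`, character(1), "type") == "rRNA")
    for (i in rr_idx[-length(rr_idx)]) {
      excess <- gaps[i] - 100L
      if (excess > 0L) {
        gaps[i] <- 100L
        j <- if (n_el > 3L) setdiff(seq_len(n_el), rr_idx)[1] else i
        gaps[j] <- gaps[j] + excess
      }
    }
  }
  # coding interiors avoid stop codons, which biases their G+C slightly above
  # target; compensate by tuning the intergenic spacer composition so the
  # whole genome lands on gc_target
  gap_gc <- params$gc_target
  total_gap_len <- sum(gaps)
  if (total_gap_len > 0L && n_el > 0L) {
    genic <- paste(vapply(elements, `[[`, character(1), "seq"), collapse = "")
    genic_gc <- sum(strsplit(genic, "", fixed = TRUE)[[1]] %in% c("G", "C"))
    gap_gc <- min(1, max(0, (params$gc_target * L - genic_gc) / total_gap_len))
  }
  layout <- list(elements = elements, gaps = gaps, gap_gc = gap_gc)
  record <- if (n_el > 0L) .build_record("SIMANC", layout, params)
            else genome_record("SIMANC", .random_seq(L, params$gc_target),
                               topology = "circular")
  truth <- structure(list(
    params = params, layout = layout,
    genes = data.frame(
      name = vapply(Filter(function(e) e$type == "gene", elements),
                    `[[`, character(1), "name"),
      strand = vapply(Filter(function(e) e$type == "gene", elements),
                      `[[`, character(1), "strand"),
      start_codon = vapply(Filter(function(e) e$type == "gene", elements),
                           `[[`, character(1), "start_codon"),
      stringsAsFactors = FALSE),
    trna_labels = trna_labels,
    planted_start_props = params$start_codon_props,
    edits = list()
  ), class = "sim_truth")
  list(record = record, truth = truth)
}

#' Evolve a simulated genome by inversions, losses and gains
#'
#' Applies `inversions` random contiguous segment inversions (order reversal
#' plus strand flip — each is exactly one DCJ operation), `losses` random
#' gene removals, and `gains` insertions of unused pool genes, to a genome
#' produced by [simulate_ancestor()] or a previous [evolve_genome()] call.
#' Every edit is recorded in the returned truth.
#'
#' @param parent List with `record` and `truth` as returned by
#'   [simulate_ancestor()].
#' @param edits Named vector/list with `inversions`, `losses`, `gains`.
#' @param seed Integer seed for this branch.
#' @param id Identifier for the child record.
#' @param gain_pool Optional character vector restricting which gene names a
#'   gain may introduce. [make_clade()] uses this to keep gains globally
#'   unique across branches, so that every gene shared by two leaves
#'   descends from a single position in their common ancestor and the
#'   planted inversion count remains an exact upper bound on the DCJ
#'   distance between them.
#' @return List with `record` and `truth` for the child.
#' @export
evolve_genome <- function(parent, edits = c(inversions = 0L, losses = 0L,
                                            gains = 0L),
                          seed = 1L, id = "SIMCHILD", gain_pool = NULL) {
  set.seed(seed)
  edits <- as.list(edits)
  for (k in c("inversions", "losses", "gains"))
    if (is.null(edits[[k]])) edits[[k]] <- 0L
  layout <- parent$truth$layout
  params <- parent$truth$params
  applied <- list()

  n_el <- length(layout$elements)
  for (i in seq_len(edits$inversions)) {
    se <- sort(sample.int(n_el, 2L))
    idx <- se[1]:se[2]
    seg <- rev(layout$elements[idx])
    seg <- lapply(seg, function(e) {
      e$strand <- if (e$strand == "+") "-" else "+"
      e
    })
    layout$elements[idx] <- seg
    layout$gaps[idx] <- rev(layout$gaps[idx])
    applied[[length(applied) + 1L]] <- list(op = "inversion", from = se[1],
                                            to = se[2])
  }

  gene_idx <- which(vapply(layout$elements, `[[`, character(1), "type") ==
                      "gene")
  if (edits$losses > length(gene_idx))
    stop("parameter error: losses exceed the gene count")
  if (edits$losses > 0L) {
    drop <- sample(gene_idx, edits$losses)
    lost <- vapply(layout$elements[drop], `[[`, character(1), "name")
    layout$elements <- layout$elements[-drop]
    layout$gaps <- layout$gaps[-drop]
    applied[[length(applied) + 1L]] <- list(op = "loss", genes = lost)
  }

  if (edits$gains > 0L) {
    pool <- setdiff(if (is.null(gain_pool)) load_gene_pool() else gain_pool,
                    .layout_gene_names(layout))
    if (edits$gains > length(pool))
      stop("parameter error: gains exceed the unused pool")
    gained <- sample(pool, edits$gains)
    for (nm in gained) {
      len <- 3L * sample(33:400, 1L)
      sc <- sample(names(params$start_codon_props), 1L,
                   prob = params$start_codon_props)
      el <- list(type = "gene", name = nm, strand = sample(c("+", "-"), 1L),
                 seq = .random_gene_seq(len, params$gc_target, sc),
                 start_codon = sc)
      at <- sample.int(length(layout$elements) + 1L, 1L)
      layout$elements <- append(layout$elements, list(el), after = at - 1L)
      gap <- if (length(layout$gaps)) round(mean(layout$gaps)) else 100L
      layout$gaps <- append(layout$gaps, as.integer(gap), after = at - 1L)
    }
    applied[[length(applied) + 1L]] <- list(op = "gain", genes = gained)
  }

  record <- .build_record(id, layout, params)
  is_gene <- vapply(layout$elements, `[[`, character(1), "type") == "gene"
  truth <- parent$truth
  truth$layout <- layout
  truth$genes <- data.frame(
    name = vapply(layout$elements[is_gene], `[[`, character(1), "name"),
    strand = vapply(layout$elements[is_gene], `[[`, character(1), "strand"),
    start_codon = vapply(layout$elements[is_gene], `[[`, character(1),
                         "start_codon"),
    stringsAsFactors = FALSE)
  truth$edits <- c(parent$truth$edits,
                   list(list(branch_seed = seed, requested = edits,
                             applied = applied)))
  list(record = record, truth = truth)
}

#' Ground-truth signed marker order of a simulated genome
#'
#' @param truth A `sim_truth`.
#' @param markers Character vector of marker (gene) names defining the
#'   shared alphabet; defaults to all genes in the genome.
#' @return A [signed_gene_order()].
#' @export
truth_marker_order <- function(truth, markers = sort(truth$genes$name)) {
  .layout_marker_order(truth$layout, markers)
}

#' Simulate a clade of related genomes down a tree
#'
#' Evolves an ancestor down a nested tree, applying per-branch edit counts,
#' and returns the leaf genomes with per-leaf truth plus clade-level truth
#' (the true core set and pairwise inversion-count bounds on the DCJ
#' distance). Optional alias noise renames genes in the *annotations* (not
#' the truth) using a synonym table, for exercising harmonization.
#'
#' @param params A [sim_params()] for the ancestor.
#' @param tree Nested list: each node is `list(name=, edits=c(inversions=,
#'   losses=, gains=), children=list(...))`; nodes without children are
#'   leaves. Root edits are ignored (the root is the ancestor).
#' @param aliases Optional [synonym_table()] for alias noise.
#' @param alias_rate Probability that an aliasable gene name is replaced by
#'   a non-canonical alias in a leaf's annotation.
#' @return List with `genomes` (named list of records), `truths` (named list
#'   of `sim_truth`), `core` (true core gene set), `pair_inversions` (matrix
#'   of summed inversion counts along the tree path between leaves), and
#'   `ancestor`.
#' @export
make_clade <- function(params, tree, aliases = NULL, alias_rate = 0) {
  anc <- simulate_ancestor(params)
  leaves <- list()
  paths <- list()   # per-leaf named vector: branch label -> inversions
  counter <- 0L
  # names never used anywhere in the clade so far; gains draw from (and
  # deplete) this shared pool, keeping every gain unique across branches
  avail <- setdiff(load_gene_pool(), anc$truth$genes$name)
  walk <- function(node, genome, path) {
    counter <<- counter + 1L
    label <- if (!is.null(node$name)) node$name else paste0("node", counter)
    if (!is.null(node$edits)) {
      branch_seed <- (params$seed * 131L + counter * 7919L) %% 2147483647L
      genome <- evolve_genome(genome, node$edits, seed = branch_seed,
                              id = label, gain_pool = avail)
      last <- genome$truth$edits[[length(genome$truth$edits)]]
      for (ap in last$applied)
        if (ap$op == "gain") avail <<- setdiff(avail, ap$genes)
      ed <- as.list(node$edits)
      path <- c(path, setNames(ifelse(is.null(ed$inversions), 0L,
                                      ed$inversions), label))
    }
    if (is.null(node$children) || length(node$children) == 0L) {
      leaves[[label]] <<- genome
      paths[[label]] <<- path
    } else {
      for (child in node$children) walk(child, genome, path)
    }
  }
  walk(tree, anc, c(root = 0L))
  if (length(leaves) < 2L) stop("tree must have at least two leaves")

  genomes <- lapply(leaves, function(g) g$record)
  truths <- lapply(leaves, function(g) g$truth)

  if (!is.null(aliases) && alias_rate > 0) {
    set.seed((params$seed * 977L) %% 2147483647L)
    inverse <- list()  # canonical -> non-canonical aliases
    for (g in aliases$groups) {
      canon <- if (!is.na(g$canonical)) g$canonical else sort(g$aliases)[1]
      inverse[[canon]] <- setdiff(g$aliases, canon)
    }
    for (nm in names(genomes)) {
      rec <- genomes[[nm]]
      for (fi in seq_along(rec$features)) {
        f <- rec$features[[fi]]
        alts <- inverse[[f$name]]
        if (f$kind == "CDS" && !is.null(alts) && length(alts) &&
            runif(1) < alias_rate) {
          alias <- sample(alts, 1L)
          rec$features[[fi]]$name <- alias
          rec$features[[fi]]$qualifiers[["gene"]] <- alias
        }
      }
      genomes[[nm]] <- rec
    }
  }

  sets <- lapply(truths, function(t) sort(unique(t$genes$name)))
  core <- Reduce(intersect, sets)
  nms <- names(leaves)
  pair <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i == j) next
    pa <- paths[[nms[i]]]; pb <- paths[[nms[j]]]
    shared_pre <- intersect(names(pa), names(pb))
    # path between leaves = branches in exactly one root-path
    pair[i, j] <- sum(pa[setdiff(names(pa), shared_pre)]) +
      sum(pb[setdiff(names(pb), shared_pre)])
  }
  list(genomes = genomes, truths = truths, core = core,
       per_leaf_sets = sets, pair_inversions = pair, ancestor = anc)
}
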