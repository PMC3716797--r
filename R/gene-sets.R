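#' Gene-name synonym table
#'
#' Groups of spellings that denote the same gene. A group may carry a curated
#' canonical name (the preferred symbol); groups without one are resolved at
#' harmonization time by majority vote across species. Alias groups must be
#' pairwise disjoint, and every canonical name belongs to its own group.
#'
#' @param curated Named list: canonical name -> character vector of aliases.
#' @param uncurated List of character vectors, each one alias group with no
#'   curated canonical.
#' @return An object of class `synonym_table`.
#' @export
synonym_table <- function(curated = list(), uncurated = list()) {
  groups <- c(
    lapply(seq_along(curated), function(i)
      list(canonical = names(curated)[i],
           aliases = union(names(curated)[i], curated[[i]]))),
    lapply(uncurated, function(g)
      list(canonical = NA_character_, aliases = unique(g)))
  )
  all_aliases <- unlist(lapply(groups, `[[`, "aliases"))
  dup <- unique(all_aliases[duplicated(all_aliases)])
  if (length(dup))
    stop("alias(es) present in more than one group: ",
         paste(dup, collapse = ", "))
  structure(list(groups = groups), class = "synonym_table")
}

#' Read a synonym table from a two-column TSV
#'
#' Columns `alias` and `canonical`. A canonical value beginning with `~`
#' defines an uncurated group: all aliases sharing the same `~label` are
#' grouped, and the canonical spelling is elected by majority at
#' harmonization time.
#'
#' @param path TSV path.
#' @return A [synonym_table()].
#' @export
read_synonym_table <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("alias", "canonical") %in% names(df)))
  uncur <- df[startsWith(df$canonical, "~"), , drop = FALSE]
  cur <- df[!startsWith(df$canonical, "~"), , drop = FALSE]
  synonym_table(
    curated = if (nrow(cur)) split(cur$alias, cur$canonical) else list(),
    uncurated = if (nrow(uncur)) unname(split(uncur$alias, uncur$canonical))
                else list()
  )
}

#' The bundled plastid gene synonym table
#' @return A [synonym_table()] seeded with common plastid symbol aliases.
#' @export
default_synonym_table <- function() {
  read_synonym_table(system.file("extdata", "gene_synonyms.tsv",
                                 package = "plastidcomp", mustWork = TRUE))
}

#' Harmonize gene names across species
#'
#' Replaces every name by its group's canonical form. For groups without a
#' curated canonical, the spelling used by the largest number of species is
#' elected (ties broken lexicographically). Duplicate names within a species
#' collapse to one set element.
#'
#' @param per_species_names Named list: species -> character vector of names.
#' @param synonyms A [synonym_table()].
#' @return Named list: species -> sorted character vector (a set) of
#'   canonical names.
#' @export
harmonize <- function(per_species_names, synonyms = synonym_table()) {
  map <- harmonize_map(per_species_names, synonyms)
  lapply(per_species_names, function(nm) {
    out <- ifelse(nm %in% names(map), map[nm], nm)
    sort(unique(out))
  })
}

#' Alias-to-canonical mapping for a concrete set of species
#'
#' The name-wise mapping [harmonize()] applies: curated groups map to their
#' canonical; uncurated groups elect the spelling used by the most species
#' (ties lexicographic).
#'
#' @inheritParams harmonize
#' @return Named character vector: alias -> canonical.
#' @export
harmonize_map <- function(per_species_names, synonyms = synonym_table()) {
  out <- character()
  for (g in synonyms$groups) {
    canon <- if (!is.na(g$canonical)) {
      g$canonical
    } else {
      # majority election: one vote per species per spelling used
      votes <- table(unlist(lapply(per_species_names, function(nm)
        intersect(unique(nm), g$aliases))))
      if (length(votes) == 0L) sort(g$aliases)[1]
      else sort(names(votes)[votes == max(votes)])[1]
    }
    out[g$aliases] <- canon
  }
  out
}

#' Partition gene content by presence signature
#'
#' Computes, for every gene in the union of the harmonized per-species sets,
#' its exact presence signature across species, and groups genes into
#' disjoint blocks: `core` (present in all species), one block per named
#' clade (present in exactly that clade's species and absent elsewhere),
#' `unique:<species>`, and a residual `other:<signature>` block per
#' remaining signature. Together the blocks tile the union exactly.
#'
#' @param harmonized Named list: species -> character vector (set) of names.
#' @param groups Named list: clade label -> character vector of species.
#' @return An object of class `gene_set_partition` with elements `species`,
#'   `blocks` (named list of gene vectors) and `counts`.
#' @export
partition_sets <- function(harmonized, groups = list()) {
  species <- names(harmonized)
  if (length(species) < 2L) stop("need at least two species")
  for (lab in names(groups)) {
    unknown <- setdiff(groups[[lab]], species)
    if (length(unknown))
      stop("clade '", lab, "' references unknown species: ",
           paste(unknown, collapse = ", "))
  }
  harmonized <- lapply(harmonized, unique)
  universe <- sort(unique(unlist(harmonized)))
  pres <- vapply(species, function(sp) universe %in% harmonized[[sp]],
                 logical(length(universe)))
  if (length(universe) == 1L) pres <- matrix(pres, nrow = 1L,
                                             dimnames = list(NULL, species))
  block_of <- character(length(universe))
  for (i in seq_along(universe)) {
    present <- species[pres[i, ]]
    if (length(present) == length(species)) { block_of[i] <- "core"; next }
    matched <- FALSE
    for (lab in names(groups)) {
      if (setequal(present, groups[[lab]])) {
        block_of[i] <- paste0("clade:", lab); matched <- TRUE; break
      }
    }
    if (matched) next
    if (length(present) == 1L) { block_of[i] <- paste0("unique:", present); next }
    block_of[i] <- paste0("other:", paste(sort(present), collapse = "+"))
  }
  blocks <- split(universe, block_of)
  structure(list(species = species, groups = groups, blocks = blocks,
                 counts = vapply(blocks, length, integer(1))),
            class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat("<gene_set_partition>", length(x$species), "species,",
      sum(x$counts), "genes\n")
  for (b in names(x$blocks))
    cat(sprintf("  %-40s %d\n", b, x$counts[[b]]))
  invisible(x)
}

# normalize an isoacceptor label to trnX(NNN); returns NA when unparsable
.parse_isoacceptor <- function(label) {
  m <- regmatches(label,
                  regexec("trn([A-Za-z])\\s*\\(([A-Za-z]{3})\\)", label))[[1]]
  if (length(m) == 3L) sprintf("trn%s(%s)", toupper(m[2]), toupper(m[3]))
  else NA_character_
}

#' tRNA isoacceptor copy-number matrix
#'
#' Builds a species x isoacceptor count matrix. Input is either a list of
#' [genome_record()] objects (isoacceptor keys parsed as `trnX(NNN)` from the
#' feature name, `product` or `note` qualifier; unparsable labels are kept
#' verbatim with a warning) or a data frame whose first column is the species
#' and remaining columns are per-isoacceptor counts.
#'
#' @param x List of records, or a data frame of transcribed rows.
#' @return Integer matrix, rows = species, columns = isoacceptors.
#' @export
trna_matrix <- function(x) {
  if (is.data.frame(x)) {
    m <- as.matrix(x[, -1, drop = FALSE])
    m[is.na(m)] <- 0
    storage.mode(m) <- "integer"
    rownames(m) <- x[[1]]
    return(m)
  }
  stopifnot(is.list(x), length(x) >= 1L)
  per_species <- lapply(x, function(rec) {
    feats <- Filter(function(f) f$kind == "tRNA", rec$features)
    keys <- vapply(feats, function(f) {
      cands <- c(f$name, f$qualifiers[c("product", "note")])
      cands <- cands[!is.na(cands)]
      for (cand in cands) {
        k <- .parse_isoacceptor(cand)
        if (!is.na(k)) return(k)
      }
      warning("unparsable tRNA isoacceptor label '", cands[1],
              "' in ", rec$id, call. = FALSE)
      cands[1]
    }, character(1))
    table(keys)
  })
  cols <- sort(unique(unlist(lapply(per_species, names))))
  m <- matrix(0L, nrow = length(x), ncol = length(cols),
              dimnames = list(vapply(x, `[[`, character(1), "id"), cols))
  for (i in seq_along(per_species))
    m[i, names(per_species[[i]])] <- as.integer(per_species[[i]])
  m
}

#' Presence difference between two tRNA repertoires
#'
#' Number of isoacceptor columns whose presence (count > 0) differs between
#' two species. Symmetric; zero iff the presence vectors are identical.
#'
#' @param m A matrix from [trna_matrix()].
#' @param a,b Row names (species) to compare.
#' @return Non-negative integer.
#' @export
trna_repertoire_difference <- function(m, a, b) {
  stopifnot(a %in% rownames(m), b %in% rownames(m))
  sum((m[a, ] > 0) != (m[b, ] > 0))
}

#' Curated red-algal plastid gene-sharing table
#'
#' The 233 protein-coding genes of the *Grateloupia taiwanensis* plastid
#' genome, each with its category and a sharing flag across six red algal
#' plastid genomes: `all` (all six), `eurhodophytina` (the four
#' Eurhodophytina genomes), `florideophyceae` (the two florideophytes),
#' `other` (present in *G. taiwanensis* and some other subset), `unique`
#' (*G. taiwanensis* only). Flags whose published formatting was ambiguous
#' were completed by curation to match the published category totals
#' (140 / 21 / 5 / 35); see the fixture file header.
#'
#' @return Data frame with columns `gene`, `category`, `sharing`.
#' @export
load_gene_sharing <- function() {
  read_tsv(system.file("extdata", "red_algal_gene_sharing.tsv",
                       package = "plastidcomp", mustWork = TRUE))
}

RED_ALGAL_SPECIES <- c("G_taiwanensis", "G_tenuistipitata", "P_purpurea",
                       "P_yezoensis", "C_merolae", "C_caldarium")

RED_ALGAL_CLADES <- list(
  Eurhodophytina = c("G_taiwanensis", "G_tenuistipitata", "P_purpurea",
                     "P_yezoensis"),
  Florideophyceae = c("G_taiwanensis", "G_tenuistipitata")
)

#' Per-species gene sets implied by the sharing table
#'
#' Expands the sharing flags of [load_gene_sharing()] into per-species gene
#' name sets for the six genomes (the `other` flag is expanded as presence in
#' *G. taiwanensis* plus the two Bangiophyceae, a curated placeholder
#' signature that keeps those genes out of the named blocks).
#'
#' @param sharing Data frame from [load_gene_sharing()].
#' @return Named list: species -> character vector of gene names.
#' @export
gene_presence_from_sharing <- function(sharing = load_gene_sharing()) {
  members <- list(
    all = RED_ALGAL_SPECIES,
    eurhodophytina = RED_ALGAL_CLADES$Eurhodophytina,
    florideophyceae = RED_ALGAL_CLADES$Florideophyceae,
    other = c("G_taiwanensis", "P_purpurea", "P_yezoensis"),
    unique = "G_taiwanensis"
  )
  bad <- setdiff(unique(sharing$sharing), names(members))
  if (length(bad)) stop("unknown sharing flag(s): ", paste(bad, collapse = ", "))
  sets <- setNames(vector("list", length(RED_ALGAL_SPECIES)),
                   RED_ALGAL_SPECIES)
  for (sp in RED_ALGAL_SPECIES) sets[[sp]] <- character()
  for (i in seq_len(nrow(sharing))) {
    for (sp in members[[sharing$sharing[i]]])
      sets[[sp]] <- c(sets[[sp]], sharing$gene[i])
  }
  lapply(sets, sort)
}

#' Transcribed red-algal plastid tRNA matrix
#'
#' Species x isoacceptor copy counts for the six red algal plastid genomes,
#' transcribed from published annotations. Anticodon strings are preserved
#' exactly as printed (the source gives them 3'-5', the reverse of the usual
#' convention; they are not reverse-complemented here).
#'
#' @return Integer matrix via [trna_matrix()].
#' @export
load_trna_table <- function() {
  trna_matrix(read_tsv(system.file("extdata", "red_algal_trna_matrix.tsv",
                                   package = "plastidcomp", mustWork = TRUE)))
}

#' Master pool of plastid gene symbols
#'
#' Real plastid gene symbols used by the synthetic-genome generator when
#' naming simulated genes.
#'
#' @return Character vector of gene symbols.
#' @export
load_gene_pool <- function() {
  readLines(system.file("extdata", "plastid_gene_pool.txt",
                        package = "plastidcomp", mustWork = TRUE))
}
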