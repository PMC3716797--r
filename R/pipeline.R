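#' Run the full comparative report
#'
#' Orchestrates the pipeline over a set of annotated genomes and writes
#' machine-readable reports to `out_dir`:
#' \describe{
#'   \item{summary.tsv}{per-genome characteristics ([summary_table()])}
#'   \item{gene_partition.tsv}{core/clade-shared/unique gene-content blocks
#'     ([partition_sets()]) with membership}
#'   \item{trna_matrix.tsv}{tRNA isoacceptor copy-number matrix
#'     ([trna_matrix()])}
#'   \item{dcj_matrix.tsv}{all-pairs DCJ distances over shared single-copy
#'     gene orders ([dcj_distance()])}
#' }
#' plus `run.log` (versions, seed, parameter toggles) and `MANIFEST`
#' marking each stage done/skipped/failed. No arithmetic happens here;
#' every number is produced by exactly one module operation. With a single
#' input genome the comparison stages are skipped with a logged notice.
#'
#' @param genomes Named list of [genome_record()] objects, or a named
#'   character vector of GenBank file paths.
#' @param out_dir Output directory (created if needed).
#' @param clades Named list: clade label -> character vector of genome names.
#' @param synonyms A [synonym_table()] for harmonization.
#' @param orf Optional [orf_params()]; when supplied an `orfs_<name>.tsv`
#'   report is written per genome.
#' @param intergenic_kinds Feature kinds counted as annotated for the
#'   intergenic statistic.
#' @return Invisibly, a list with per-stage status (`"done"`, `"skipped"`,
#'   or `"failed: <message>"`) and the computed objects.
#' @export
run_report <- function(genomes, out_dir, clades = list(),
                       synonyms = synonym_table(), orf = NULL,
                       intergenic_kinds = ANNOTATION_KINDS) {
  if (is.character(genomes)) {
    paths <- genomes
    if (is.null(names(paths)))
      names(paths) <- sub("\\.[^.]+$", "", basename(paths))
    genomes <- lapply(paths, read_genbank)
  }
  stopifnot(length(genomes) >= 1L, !is.null(names(genomes)),
            !anyDuplicated(names(genomes)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("plastidcomp %s | R %s",
       as.character(utils::packageVersion("plastidcomp")),
       paste(R.version$major, R.version$minor, sep = "."))
  logf("genomes: %s", paste(names(genomes), collapse = ", "))
  logf("clades: %s", if (length(clades))
    paste(vapply(names(clades), function(l) paste0(l, "={",
      paste(clades[[l]], collapse = ","), "}"), character(1)),
      collapse = "; ") else "(none)")
  logf("intergenic kinds: %s", paste(intergenic_kinds, collapse = ","))

  status <- list()
  results <- list()
  stage <- function(name, run) {
    status[[name]] <<- tryCatch({
      results[[name]] <<- run()
      logf("stage %s: done", name)
      "done"
    }, error = function(e) {
      logf("stage %s: FAILED (%s)", name, conditionMessage(e))
      paste0("failed: ", conditionMessage(e))
    })
  }

  for (i in seq_along(genomes)) genomes[[i]]$id <- names(genomes)[i]

  stage("stats", function() {
    tbl <- summary_table(genomes)
    write_tsv(tbl, file.path(out_dir, "summary.tsv"))
    tbl
  })

  if (!is.null(orf)) {
    stage("orfs", function() {
      out <- lapply(names(genomes), function(nm) {
        calls <- find_orfs(genomes[[nm]], orf)
        write_tsv(report_table(as.data.frame(calls),
                               paste("ORF calls for", nm)),
                  file.path(out_dir, paste0("orfs_", nm, ".tsv")))
        calls
      })
      logf("orf params: starts=%s min_length=%d mode=%s include_stop=%s",
           paste(orf$start_codons, collapse = ","), orf$min_length,
           orf$counting_mode, orf$include_stop_in_length)
      setNames(out, names(genomes))
    })
  }

  if (length(genomes) < 2L) {
    logf("single genome input: comparison stages skipped")
    status$genes <- status$trnas <- status$dcj <- "skipped"
  } else {
    stage("genes", function() {
      per_species <- lapply(genomes, function(rec) {
        feats <- Filter(function(f) f$kind == "CDS" && !is.na(f$name),
                        rec$features)
        if (length(feats) == 0L)
          feats <- Filter(function(f) f$kind == "gene" && !is.na(f$name),
                          rec$features)
        vapply(feats, `[[`, character(1), "name")
      })
      part <- partition_sets(harmonize(per_species, synonyms), clades)
      df <- data.frame(
        block = names(part$blocks),
        n = unname(part$counts),
        genes = vapply(part$blocks, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
      write_tsv(report_table(df, "Gene-content partition"),
                file.path(out_dir, "gene_partition.tsv"))
      part
    })

    stage("trnas", function() {
      m <- trna_matrix(genomes)
      df <- data.frame(species = rownames(m), as.data.frame(m),
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(report_table(df, "tRNA isoacceptor copy numbers"),
                file.path(out_dir, "trna_matrix.tsv"))
      m
    })

    stage("dcj", function() {
      nms <- names(genomes)
      d <- matrix(NA_integer_, length(nms), length(nms),
                  dimnames = list(nms, nms))
      diag(d) <- 0L
      for (i in seq_along(nms)) for (j in seq_along(nms)) {
        if (j <= i) next
        dd <- tryCatch({
          ords <- shared_marker_orders(genomes[[i]], genomes[[j]], synonyms)
          dcj_distance(ords$a, ords$b)
        }, error = function(e) {
          logf("dcj %s vs %s: %s", nms[i], nms[j], conditionMessage(e))
          NA_integer_
        })
        d[i, j] <- d[j, i] <- dd
      }
      df <- data.frame(species = rownames(d), as.data.frame(d),
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(report_table(df, "Pairwise DCJ distances"),
                file.path(out_dir, "dcj_matrix.tsv"))
      d
    })
  }

  manifest <- vapply(names(status), function(nm)
    sprintf("%s\t%s", nm, status[[nm]]), character(1))
  writeLines(c("stage\tstatus", manifest), file.path(out_dir, "MANIFEST"))
  invisible(list(status = status, results = results))
}
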