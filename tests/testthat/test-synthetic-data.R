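small_params <- function(seed = 1, ...) {
  sim_params(genome_length = 30000, n_genes = 30, n_trna = 6, seed = seed, ...)
}

test_that("the generator honours its composition contract", {
  sim <- simulate_ancestor(sim_params(seed = 1))
  expect_equal(genome_length(sim$record), 180000)
  gc <- gc_content(sim$record$sequence)
  expect_gte(gc, 30); expect_lte(gc, 32)      # target 0.31 +- 0.01
  ig <- intergenic_fraction(sim$record)
  expect_lt(abs(ig / 100 - 0.15), 0.03)
  expect_equal(sum(vapply(sim$record$features, `[[`, character(1),
                          "kind") == "CDS"), 200)
  expect_equal(sum(vapply(sim$record$features, `[[`, character(1),
                          "kind") == "tRNA"), 29)
})

test_that("a gene-free, RNA-free simulation is all intergenic", {
  sim <- simulate_ancestor(sim_params(genome_length = 10000, n_genes = 0,
                                      n_trna = 0, seed = 2))
  expect_equal(intergenic_fraction(sim$record), 100)
  expect_length(sim$record$features, 0)
})

test_that("the same seed is byte-identical and seeds differ", {
  p1 <- withr::local_tempfile(fileext = ".gb")
  p2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(simulate_ancestor(small_params(5))$record, p1)
  write_genbank(simulate_ancestor(small_params(5))$record, p2)
  expect_identical(readLines(p1), readLines(p2))
  other <- simulate_ancestor(small_params(6))$record
  expect_false(identical(other$sequence,
                         simulate_ancestor(small_params(5))$record$sequence))
})

test_that("infeasible packing is a parameter error", {
  expect_error(simulate_ancestor(sim_params(genome_length = 5000,
                                            n_genes = 60, n_trna = 0,
                                            seed = 1)),
               "parameter error")
})

test_that("zero edits leave the DCJ distance at zero, one inversion at one", {
  anc <- simulate_ancestor(small_params(3))
  same <- evolve_genome(anc, c(inversions = 0, losses = 0, gains = 0),
                        seed = 4, id = "SAME")
  mk <- sort(anc$truth$genes$name)
  expect_equal(dcj_distance(truth_marker_order(anc$truth, mk),
                            truth_marker_order(same$truth, mk)), 0)
  one <- evolve_genome(anc, c(inversions = 1), seed = 5, id = "ONE")
  expect_equal(dcj_distance(truth_marker_order(anc$truth, mk),
                            truth_marker_order(one$truth, mk)), 1)
})

test_that("k inversions bound the DCJ distance over many seeds", {
  anc <- evolve_seeds_anc <- simulate_ancestor(small_params(8))
  mk <- sort(anc$truth$genes$name)
  oa <- truth_marker_order(anc$truth, mk)
  for (seed in 1:50) {
    k <- sample(2:5, 1)
    child <- evolve_genome(anc, c(inversions = k), seed = seed, id = "X")
    d <- dcj_distance(oa, truth_marker_order(child$truth, mk))
    expect_lte(d, k)
  }
})

test_that("losses and gains are recorded and respected", {
  anc <- simulate_ancestor(small_params(12))
  child <- evolve_genome(anc, c(inversions = 0, losses = 3, gains = 2),
                         seed = 13, id = "LG")
  expect_equal(nrow(child$truth$genes), nrow(anc$truth$genes) - 1)
  ed <- child$truth$edits[[length(child$truth$edits)]]
  ops <- vapply(ed$applied, `[[`, character(1), "op")
  lost <- unlist(lapply(ed$applied[ops == "loss"], `[[`, "genes"))
  gained <- unlist(lapply(ed$applied[ops == "gain"], `[[`, "genes"))
  expect_length(lost, 3)
  expect_length(gained, 2)
  expect_false(any(lost %in% child$truth$genes$name))
  expect_true(all(gained %in% child$truth$genes$name))
  expect_error(evolve_genome(anc, c(losses = 1000), seed = 1),
               "parameter error")
})

test_that("a two-leaf clade with no edits is all-core", {
  tree <- list(name = "root", children = list(
    list(name = "L1", edits = c(inversions = 0, losses = 0, gains = 0)),
    list(name = "L2", edits = c(inversions = 0, losses = 0, gains = 0))))
  clade <- make_clade(small_params(21), tree)
  sets <- lapply(clade$genomes, function(rec)
    vapply(Filter(function(f) f$kind == "CDS", rec$features),
           `[[`, character(1), "name"))
  part <- partition_sets(lapply(sets, unique))
  expect_equal(length(part$blocks$core), 30)
  expect_equal(sum(part$counts), 30)
})

test_that("clade truth matches the pipeline partition with planted losses", {
  tree <- list(name = "root", children = list(
    list(name = "cladeA", edits = c(inversions = 2, losses = 2, gains = 0),
         children = list(
           list(name = "s1", edits = c(inversions = 1, losses = 2, gains = 1)),
           list(name = "s2", edits = c(inversions = 2, losses = 1, gains = 0)))),
    list(name = "s3", edits = c(inversions = 3, losses = 3, gains = 2))))
  clade <- make_clade(small_params(31), tree)
  expect_setequal(names(clade$genomes), c("s1", "s2", "s3"))
  # pipeline-recovered sets equal the truth sets
  sets <- lapply(clade$genomes, function(rec)
    sort(unique(vapply(Filter(function(f) f$kind == "CDS", rec$features),
                       `[[`, character(1), "name"))))
  expect_equal(sets[order(names(sets))],
               clade$per_leaf_sets[order(names(clade$per_leaf_sets))])
  part <- partition_sets(sets)
  expect_equal(sort(part$blocks$core), sort(clade$core))
  # DCJ bounded by summed inversions along the tree path
  for (pair in list(c("s1", "s2"), c("s1", "s3"), c("s2", "s3"))) {
    ords <- shared_marker_orders(clade$genomes[[pair[1]]],
                                 clade$genomes[[pair[2]]])
    d <- dcj_distance(ords$a, ords$b)
    expect_lte(d, clade$pair_inversions[pair[1], pair[2]])
  }
})

test_that("alias noise is reversed by harmonization before partitioning", {
  syn <- synonym_table(curated = list(ycf24 = "sufB", odpA = "pdhA",
                                      tufA = "tuf", groEL = "groL"))
  tree <- list(name = "root", children = list(
    list(name = "a1", edits = c(inversions = 1, losses = 1, gains = 0)),
    list(name = "a2", edits = c(inversions = 1, losses = 1, gains = 0))))
  clade <- make_clade(small_params(41), tree, aliases = syn, alias_rate = 1)
  raw_sets <- lapply(clade$genomes, function(rec)
    unique(vapply(Filter(function(f) f$kind == "CDS", rec$features),
                  `[[`, character(1), "name")))
  harmonized <- harmonize(raw_sets, syn)
  expect_equal(lapply(harmonized, sort),
               clade$per_leaf_sets[names(harmonized)])
})
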