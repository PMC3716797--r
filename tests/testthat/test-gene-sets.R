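test_that("harmonize elects the majority spelling with lexicographic ties", {
  syn <- synonym_table(uncurated = list(c("rbcL", "rbcl")))
  out <- harmonize(list(A = "rbcL", B = "rbcl"), syn)
  expect_equal(out$A, "rbcL")   # 1-1 tie -> lexicographic winner
  expect_equal(out$B, "rbcL")

  out2 <- harmonize(list(A = "rbcl", B = "rbcl", C = "rbcL"), syn)
  expect_equal(unique(unlist(out2)), "rbcl")  # majority wins over case

  cur <- synonym_table(curated = list(ycf24 = "sufB"))
  out3 <- harmonize(list(A = c("sufB", "psbA"), B = "ycf24"), cur)
  expect_equal(out3$A, c("psbA", "ycf24"))
  expect_equal(out3$B, "ycf24")
})

test_that("harmonize is the identity on already-canonical names", {
  nm <- list(A = c("psbA", "rbcL"), B = c("atpA", "psbA", "psbA"))
  out <- harmonize(nm, default_synonym_table())
  expect_equal(out$A, sort(unique(nm$A)))
  expect_equal(out$B, sort(unique(nm$B)))
})

test_that("synonym tables reject overlapping alias groups", {
  expect_error(synonym_table(curated = list(a = "x", b = "x")), "more than one")
  syn <- synonym_table(curated = list(a = "x"), uncurated = list(c("y", "z")))
  expect_length(syn$groups, 2)
})

test_that("partition of identical sets is all-core", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g1", "g2", "g3"))
  part <- partition_sets(sets)
  expect_equal(part$blocks$core, c("g1", "g2", "g3"))
  expect_equal(sum(part$counts), 3)
})

test_that("partition blocks tile the union and match exhaustive enumeration", {
  set.seed(123)
  species <- c("w", "x", "y", "z")
  clades <- list(front = c("w", "x"), back = c("y", "z"))
  for (rep in 1:15) {
    universe <- paste0("g", 1:30)
    sets <- setNames(lapply(species, function(s)
      sort(sample(universe, sample(5:25, 1)))), species)
    part <- partition_sets(sets, clades)
    oracle <- signature_partition_oracle(sets, clades)
    expect_setequal(names(part$blocks), names(oracle))
    for (b in names(oracle)) expect_equal(part$blocks[[b]], sort(oracle[[b]]))
    # disjoint and exhaustive
    all_genes <- unname(unlist(part$blocks))
    expect_equal(sort(all_genes), sort(unique(unlist(sets))))
    expect_false(anyDuplicated(all_genes) > 0)
    expect_lte(length(part$blocks$core), min(lengths(sets)))
  }
})

test_that("partition is invariant under species and gene-list permutation", {
  set.seed(4)
  sets <- list(A = sample(paste0("g", 1:20), 12),
               B = sample(paste0("g", 1:20), 15),
               C = sample(paste0("g", 1:20), 9))
  p1 <- partition_sets(sets, list(pair = c("A", "C")))
  p2 <- partition_sets(rev(lapply(sets, sample)), list(pair = c("A", "C")))
  expect_equal(p1$blocks[order(names(p1$blocks))],
               p2$blocks[order(names(p2$blocks))])
})

test_that("clades referencing unknown species are configuration errors", {
  sets <- list(A = "g1", B = "g2")
  expect_error(partition_sets(sets, list(cl = c("A", "Q"))), "unknown species")
})

test_that("the curated sharing fixture reproduces the published block sizes", {
  sharing <- load_gene_sharing()
  expect_equal(nrow(sharing), 233)
  expect_false(anyDuplicated(sharing$gene) > 0)
  sets <- gene_presence_from_sharing(sharing)
  part <- partition_sets(harmonize(sets, default_synonym_table()),
                         plastidcomp:::RED_ALGAL_CLADES)
  expect_equal(length(part$blocks$core), 140)
  expect_equal(length(part$blocks[["clade:Eurhodophytina"]]), 21)
  expect_equal(length(part$blocks[["clade:Florideophyceae"]]), 5)
  expect_equal(length(part$blocks[["unique:G_taiwanensis"]]), 35)
  expect_equal(length(sets$G_taiwanensis), 233)
})

test_that("tRNA matrices are built from annotations with parsed isoacceptors", {
  seq <- random_dna(1000)
  mk <- function(label, s) {
    gb_feature("tRNA", sub("\\(.*$", "", label), gb_interval(s, s + 72), "+",
               qualifiers = c(product = label))
  }
  rec <- genome_record("t1", seq, "circular",
                       list(mk("trnA(TGC)", 0), mk("trnM(CAT)", 100),
                            mk("trnM(CAT)", 200)))
  m <- trna_matrix(list(rec))
  expect_equal(ncol(m), 2)
  expect_equal(sum(m), 3)
  expect_equal(m["t1", "trnM(CAT)"], 2)
  rec2 <- genome_record("t2", seq, "circular",
                        list(mk("trnA(TGC)", 0)))
  m2 <- trna_matrix(list(rec, rec2))
  expect_equal(rowSums(m2), c(t1 = 3, t2 = 1))
  expect_equal(trna_repertoire_difference(m2, "t1", "t2"), 1)
})

test_that("the transcribed tRNA table has the published row sums and ordering", {
  m <- load_trna_table()
  expect_equal(sum(m["G_taiwanensis", ]), 29)
  expect_equal(sum(m["P_purpurea", ]), 37)
  expect_equal(sum(m["G_tenuistipitata", ]), 29)
  expect_equal(sum(m["P_yezoensis", ]), 38)
  # florideophytes and cyanidiophytes closer to each other than to bangiophytes
  expect_lt(trna_repertoire_difference(m, "G_taiwanensis", "C_caldarium"),
            trna_repertoire_difference(m, "G_taiwanensis", "P_purpurea"))
})

test_that("repertoire difference is a presence-vector semimetric", {
  m <- load_trna_table()
  sp <- rownames(m)
  for (a in sp) expect_equal(trna_repertoire_difference(m, a, a), 0)
  for (i in 1:5) {
    ab <- sample(sp, 2)
    expect_equal(trna_repertoire_difference(m, ab[1], ab[2]),
                 trna_repertoire_difference(m, ab[2], ab[1]))
  }
  expect_equal(trna_repertoire_difference(m, "G_taiwanensis",
                                          "G_tenuistipitata"), 0)
})
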