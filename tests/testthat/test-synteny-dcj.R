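circ <- function(...) signed_gene_order(list(c(...)), shapes = "circular")

test_that("identical circular orders are at distance zero", {
  a <- circ(1, 2, 3, -4, 5)
  expect_equal(dcj_distance(a, a), 0)
  g <- adjacency_graph(a, a)
  expect_equal(g$N, 5)
  expect_equal(g$C, 5)   # identical single circles: one cycle per adjacency
  expect_equal(g$I, 0)
})

test_that("a single inversion is one DCJ operation", {
  a <- circ(1, 2, 3, 4, 5)
  b <- circ(1, -3, -2, 4, 5)   # segment [2,3] inverted
  expect_equal(dcj_distance(a, b), 1)
  expect_equal(dcj_distance_bruteforce(a, b), 1)
})

test_that("distance agrees with the BFS oracle on random circular orders", {
  set.seed(2024)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    a <- random_signed_order(n)
    b <- random_signed_order(n)
    expect_equal(dcj_distance(a, b), dcj_distance_bruteforce(a, b),
                 info = sprintf("rep %d: a=%s b=%s", rep,
                                paste(a$chromosomes[[1]], collapse = ","),
                                paste(b$chromosomes[[1]], collapse = ",")))
  }
})

test_that("distance satisfies the metric axioms on sampled triples", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    a <- random_signed_order(n)
    b <- random_signed_order(n)
    c_ <- random_signed_order(n)
    expect_equal(dcj_distance(a, b), dcj_distance(b, a))
    expect_gte(dcj_distance(a, b), 0)
    expect_lte(dcj_distance(a, c_),
               dcj_distance(a, b) + dcj_distance(b, c_))
    expect_equal(dcj_distance(a, a), 0)
  }
})

test_that("distance is invariant under rotation and reflection of a circle", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    a <- random_signed_order(n)
    b <- random_signed_order(n)
    d0 <- dcj_distance(a, b)
    v <- b$chromosomes[[1]]
    rot <- signed_gene_order(list(c(v[-(1:2)], v[1:2])), shapes = "circular")
    expect_equal(dcj_distance(a, rot), d0)
    refl <- signed_gene_order(list(rev(-v)), shapes = "circular")
    expect_equal(dcj_distance(a, refl), d0)
  }
})

test_that("marker-set mismatches are reported with the symmetric difference", {
  a <- circ(1, 2, 3)
  b <- circ(1, 2, 4)
  expect_error(dcj_distance(a, b), "3, 4")
  expect_error(signed_gene_order(list(c(1, 2, 2))), "more than once")
})

test_that("shared_marker_orders keeps single-copy shared genes in order", {
  seq <- random_dna(3000)
  mk <- function(nm, s, strand = "+")
    gb_feature("CDS", nm, gb_interval(s, s + 300), strand,
               qualifiers = c(gene = nm))
  a <- genome_record("A", seq, "circular",
                     list(mk("g1", 0), mk("g2", 400), mk("g3", 900, "-")))
  b <- genome_record("B", seq, "circular",
                     list(mk("g1", 0), mk("g2", 400), mk("g3", 900, "-")))
  ords <- shared_marker_orders(a, b)
  expect_equal(ords$a$chromosomes, ords$b$chromosomes)
  expect_equal(dcj_distance(ords$a, ords$b), 0)

  # duplicated gene in one genome is excluded from both orders
  b2 <- genome_record("B2", seq, "circular",
                      list(mk("g1", 0), mk("g2", 400), mk("g3", 900, "-"),
                           mk("g2", 1500), mk("g4", 2000)))
  a2 <- genome_record("A2", seq, "circular",
                      list(mk("g1", 0), mk("g2", 400), mk("g3", 900, "-"),
                           mk("g4", 2000)))
  ords2 <- shared_marker_orders(a2, b2)
  expect_false("g2" %in% ords2$a$marker_names)
  expect_setequal(ords2$a$marker_names, c("g1", "g3", "g4"))

  # fewer than three shared single-copy markers is an input error
  tiny_a <- genome_record("TA", seq, "circular", list(mk("g1", 0), mk("g2", 400)))
  tiny_b <- genome_record("TB", seq, "circular", list(mk("g1", 0), mk("g2", 400)))
  expect_error(shared_marker_orders(tiny_a, tiny_b), "insufficient")
})

test_that("marker orders recover the generator's recorded ground truth", {
  sim <- simulate_ancestor(sim_params(genome_length = 25000, n_genes = 20,
                                      n_trna = 4, seed = 9))
  child <- evolve_genome(sim, c(inversions = 2, losses = 2, gains = 1),
                         seed = 10, id = "KID")
  shared <- sort(intersect(sim$truth$genes$name, child$truth$genes$name))
  ords <- shared_marker_orders(sim$record, child$record)
  expect_equal(ords$a$marker_names, shared)
  truth_a <- truth_marker_order(sim$truth, shared)
  truth_b <- truth_marker_order(child$truth, shared)
  expect_equal(ords$a$chromosomes, truth_a$chromosomes)
  expect_equal(ords$b$chromosomes, truth_b$chromosomes)
})

test_that("linear chromosomes and telomere moves agree with the BFS oracle", {
  lin <- function(...) signed_gene_order(list(c(...)), shapes = "linear")
  circ_ <- function(...) signed_gene_order(list(c(...)), shapes = "circular")
  expect_equal(dcj_distance(lin(1, 2, 3), lin(1, 2, 3)), 0)
  expect_equal(dcj_distance(lin(1, 2, 3), lin(1, -2, 3)), 1)  # one inversion
  expect_equal(dcj_distance(lin(1, 2, 3), circ_(1, 2, 3)), 1) # circularization
  set.seed(808)
  for (rep in 1:30) {
    n <- sample(3:5, 1)
    sh <- sample(c("linear", "circular"), 2, replace = TRUE)
    a <- signed_gene_order(list(sample.int(n) *
                                  sample(c(1L, -1L), n, replace = TRUE)),
                           shapes = sh[1])
    b <- signed_gene_order(list(sample.int(n) *
                                  sample(c(1L, -1L), n, replace = TRUE)),
                           shapes = sh[2])
    g <- adjacency_graph(a, b)
    expect_equal(g$I %% 2, 0)   # odd paths pair up across telomeres
    expect_equal(dcj_distance(a, b), dcj_distance_bruteforce(a, b),
                 info = sprintf("shapes %s/%s", sh[1], sh[2]))
  }
})

test_that("bruteforce oracle refuses oversized inputs", {
  a <- random_signed_order(9)
  expect_error(dcj_distance_bruteforce(a, a, max_n = 8), "exceeds")
})
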