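# Fixture: a small two-branch ontology with a hand-chosen corpus so IC
# values have known closed forms.
ic_fixture <- function() {
  g <- ontology_graph(
    data.frame(id = c("R", "A", "B", "A1", "A2", "B1"),
               name = c("R", "A", "B", "A1", "A2", "B1"),
               namespace = "biological_process"),
    data.frame(child = c("A", "B", "A1", "A2", "B1"),
               parent = c("R", "R", "A", "A", "B"),
               relation = "is_a"))
  rec <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g1", "g2", "g3", "g4"),
    term = c("A1", "A1", "A2", "B1", "R", "R", "R", "R"),
    evidence = "IDA", stringsAsFactors = FALSE)
  anns <- annotation_set(rec, g)
  list(graph = g, ic = information_content(anns, g))
}

test_that("information content follows descendant-inclusive frequencies", {
  f <- ic_fixture()
  # corpus: 4 genes; A covers g1,g2,g3 -> p = 3/4; A1 covers g1,g2 -> 1/2
  expect_equal(ic_value(f$ic, "R"), 0)
  expect_equal(ic_value(f$ic, "A"), -log(3 / 4))
  expect_equal(ic_value(f$ic, "A1"), log(2))
  expect_equal(ic_value(f$ic, "B"), log(4))     # one gene of four
  expect_error(ic_value(f$ic, "Zzz"), "no information content")
})

test_that("unannotated terms carry no IC and lookups fail explicitly", {
  g <- ontology_graph(
    data.frame(id = c("R", "A", "Leaf"), name = c("R", "A", "Leaf"),
               namespace = "biological_process"),
    data.frame(child = c("A", "Leaf"), parent = c("R", "A"),
               relation = "is_a"))
  anns <- annotation_set(
    data.frame(gene = "g1", term = "A", evidence = "IDA"), g)
  ic <- information_content(anns, g)
  expect_false("Leaf" %in% names(ic$ic))
  expect_error(ic_value(ic, "Leaf"), "Leaf")
})

test_that("IC is anti-monotone along edges on random corpora", {
  for (seed in 1:25) {
    d <- random_dag_corpus(seed)
    e <- d$graph$edges
    for (i in seq_len(nrow(e))) {
      ic_c <- d$ic$ic[e$child[i]]; ic_p <- d$ic$ic[e$parent[i]]
      if (!is.na(ic_c) && !is.na(ic_p)) {
        expect_gte(ic_c, ic_p - 1e-12)
      }
    }
  }
})

test_that("Resnik similarity matches the brute-force ancestor enumeration", {
  f <- ic_fixture()
  expect_equal(resnik_similarity(f$ic, f$graph, "A1", "A1"),
               ic_value(f$ic, "A1"))
  expect_equal(resnik_similarity(f$ic, f$graph, "A1", "B1"), 0)  # via root
  expect_equal(resnik_similarity(f$ic, f$graph, "A1", "A2"),
               ic_value(f$ic, "A"))
  n_checked <- 0L
  for (seed in 1:40) {
    d <- random_dag_corpus(seed)
    terms <- names(d$ic$ic)
    set.seed(seed)
    for (rep in 1:6) {
      t12 <- sample(terms, 2, replace = TRUE)
      got <- resnik_similarity(d$ic, d$graph, t12[1], t12[2])
      expect_equal(got, brute_resnik(d$ic, d$graph, t12[1], t12[2]))
      expect_lte(got, min(ic_value(d$ic, t12[1]), ic_value(d$ic, t12[2])) + 1e-12)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("Resnik equals the smaller IC when one term is an ancestor of the other", {
  for (seed in 1:10) {
    d <- random_dag_corpus(seed)
    terms <- names(d$ic$ic)
    for (t in terms) {
      anc <- intersect(reflexive_ancestors(d$graph, t), terms)
      a <- anc[length(anc)]
      expect_equal(resnik_similarity(d$ic, d$graph, t, a), ic_value(d$ic, a))
    }
  }
})

test_that("cross-namespace Resnik is rejected", {
  g <- ontology_graph(
    data.frame(id = c("B0", "M0"), name = c("B0", "M0"),
               namespace = c("biological_process", "molecular_function")),
    data.frame(child = character(0), parent = character(0),
               relation = character(0)))
  anns <- annotation_set(
    data.frame(gene = c("g1", "g1"), term = c("B0", "M0"), evidence = "IDA"), g)
  ic <- information_content(anns, g)
  expect_error(resnik_similarity(ic, g, "B0", "M0"), "namespace")
})

test_that("optimal assignment equals the exhaustive oracle on random profiles", {
  f <- ic_fixture()
  # single-term profiles: plain Resnik
  expect_equal(optimal_assignment_similarity("A1", "B1", f$ic, f$graph),
               resnik_similarity(f$ic, f$graph, "A1", "B1"))
  n_checked <- 0L
  for (seed in 1:40) {
    d <- random_dag_corpus(seed, n_terms = 14L, n_records = 35L)
    terms <- names(d$ic$ic)
    set.seed(seed + 500)
    for (rep in 1:6) {
      p1 <- sample(terms, sample(1:min(6, length(terms)), 1))
      p2 <- sample(terms, sample(1:min(6, length(terms)), 1))
      got <- optimal_assignment_similarity(p1, p2, d$ic, d$graph)
      sym <- optimal_assignment_similarity(p2, p1, d$ic, d$graph)
      expect_equal(got, sym)
      p1 <- sort(unique(p1)); p2 <- sort(unique(p2))
      small <- if (length(p1) <= length(p2)) p1 else p2
      large <- if (length(p1) <= length(p2)) p2 else p1
      w <- outer(small, large,
                 Vectorize(function(x, y) resnik_similarity(d$ic, d$graph, x, y)))
      expect_equal(got, brute_assignment(w) / length(small))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("identical profiles score the mean of their term ICs when diagonals dominate", {
  f <- ic_fixture()
  # resnik(A1,A1)=ln 2 and resnik(B1,B1)=ln 4 dominate the cross terms
  expect_equal(
    optimal_assignment_similarity(c("A1", "B1"), c("A1", "B1"), f$ic, f$graph),
    (ic_value(f$ic, "A1") + ic_value(f$ic, "B1")) / 2)
})

test_that("profile similarity matrix is symmetric, unit-diagonal and in [0,1]", {
  for (seed in 1:10) {
    d <- random_dag_corpus(seed, n_terms = 14L, n_genes = 12L, n_records = 40L)
    terms <- names(d$ic$ic)
    terms <- terms[d$ic$ic > 0]
    if (length(terms) < 4) next
    set.seed(seed)
    profiles <- lapply(1:6, function(i) sample(terms, sample(1:3, 1)))
    names(profiles) <- sprintf("p%02d", 1:6)
    ps <- profile_similarity_matrix(profiles, d$ic, d$graph)
    m <- ps$matrix
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 6))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("identical profiles give similarity 1; root-only profiles are rejected", {
  f <- ic_fixture()
  ps <- profile_similarity_matrix(
    list(x = c("A1", "A2"), y = c("A1", "A2"), z = "B1"), f$ic, f$graph)
  expect_equal(ps$matrix["x", "y"], 1)
  expect_lt(ps$matrix["x", "z"], 0.3)    # disjoint deep branches
  expect_error(
    profile_similarity_matrix(list(x = "R", y = "A1"), f$ic, f$graph),
    "zero self-similarity")
})
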