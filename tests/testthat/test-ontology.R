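test_that("parse_obo builds the graph, drops obsolete terms and foreign relations", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0002", "name: a", "namespace: biological_process",
    "is_a: GO:0001 ! root", "",
    "[Term]", "id: GO:0003", "name: gone", "namespace: biological_process",
    "is_a: GO:0001", "is_obsolete: true", "",
    "[Term]", "id: GO:0004", "name: b", "namespace: biological_process",
    "alt_id: GO:9004",
    "is_a: GO:0002", "relationship: regulates GO:0001", "")
  g <- parse_obo(obo)
  expect_setequal(g$terms$id, c("GO:0001", "GO:0002", "GO:0004"))
  expect_equal(nrow(g$edges), 2L)           # regulates edge omitted
  expect_false("GO:0003" %in% g$terms$id)   # obsolete absent
  expect_equal(unname(g$roots), "GO:0001")
  expect_equal(unname(g$alt_ids["GO:9004"]), "GO:0004")
})

test_that("parse_obo fails on cycles, dangling parents and empty input", {
  base <- c("[Term]", "id: GO:0001", "name: r", "namespace: biological_process")
  cyc <- c(base, "is_a: GO:0002", "",
           "[Term]", "id: GO:0002", "name: x", "namespace: biological_process",
           "is_a: GO:0001")
  expect_error(parse_obo(cyc), "cycle")
  dangling <- c(base, "", "[Term]", "id: GO:0002", "name: x",
                "namespace: biological_process", "is_a: GO:9999")
  expect_error(parse_obo(dangling), "unknown parent")
  expect_error(parse_obo(c("format-version: 1.2")), "no \\[Term\\]")
})

test_that("shipped organelle OBO file reproduces the in-code example graph", {
  path <- system.file("extdata", "organelle_example.obo", package = "funcdiv")
  g <- parse_obo(path)
  ref <- organelle_example_graph()
  expect_setequal(g$terms$id, ref$terms$id)
  expect_equal(g$depth[order(names(g$depth))],
               ref$depth[order(names(ref$depth))])
})

test_that("parse_gaf keeps evidence codes, drops NOT rows, resolves alt ids", {
  g <- parse_obo(system.file("extdata", "organelle_example.obo",
                             package = "funcdiv"))
  gaf_line <- function(gene, qual, term, ev) {
    paste(c("DB", gene, gene, qual, term, "REF", ev, "", "C", "", "",
            "protein", "taxon:3702", "20090604", "TAIR"), collapse = "\t")
  }
  gaf <- c("!gaf-version: 2.1",
           gaf_line("geneA", "", "CC:0005", "IDA"),
           gaf_line("geneB", "", "CC:0004", "IEA"),
           gaf_line("geneC", "NOT", "CC:0002", "IDA"),
           gaf_line("geneD", "", "CC:9003", "TAS"))   # alt id -> CC:0003
  anns <- parse_gaf(gaf, g)
  expect_equal(nrow(anns$records), 3L)
  expect_setequal(anns$records$evidence, c("IDA", "IEA", "TAS"))
  expect_false("geneC" %in% anns$records$gene)
  expect_equal(anns$records$term[anns$records$gene == "geneD"], "CC:0003")
  expect_error(parse_gaf(c("a\tb\tc"), g), "malformed GAF line 1")
  expect_error(parse_gaf("!only comments", g), "no annotation lines")
})

test_that("reflexive ancestors include the term and match the walking oracle", {
  g <- organelle_example_graph()
  expect_equal(reflexive_ancestors(g, "CC:0000"), "CC:0000")
  expect_setequal(reflexive_ancestors(g, "CC:0001"), c("CC:0001", "CC:0000"))
  env <- reflexive_ancestors(g, "CC:0005")
  expect_true(all(c("CC:0002", "CC:0003") %in% env))
  expect_error(reflexive_ancestors(g, "CC:9999"), "unknown term")
  for (seed in 1:20) {
    d <- random_dag_corpus(seed)
    for (t in sample(d$graph$terms$id, 5)) {
      expect_setequal(reflexive_ancestors(d$graph, t),
                      walk_ancestors(d$graph, t))
    }
  }
})

test_that("ancestor sets shrink along child-to-parent edges", {
  for (seed in 1:10) {
    d <- random_dag_corpus(seed)
    e <- d$graph$edges
    for (i in seq_len(nrow(e))) {
      expect_true(all(reflexive_ancestors(d$graph, e$parent[i]) %in%
                        reflexive_ancestors(d$graph, e$child[i])))
    }
  }
})

test_that("term depth is the BFS shortest-path distance", {
  g <- organelle_example_graph()
  expect_equal(term_depth(g, "CC:0000"), 0L)
  expect_equal(term_depth(g, "CC:0001"), 1L)
  expect_equal(term_depth(g, "CC:0004"), 3L)
  # diamond with a 2-edge and a 3-edge path: depth is the minimum
  dia <- ontology_graph(
    data.frame(id = c("R", "A", "B", "X"), name = c("R", "A", "B", "X"),
               namespace = "biological_process"),
    data.frame(child = c("A", "B", "X", "X"),
               parent = c("R", "A", "B", "R"),
               relation = "is_a"))
  expect_equal(term_depth(dia, "X"), 1L)
  dia2 <- ontology_graph(
    data.frame(id = c("R", "A", "B", "X"), name = c("R", "A", "B", "X"),
               namespace = "biological_process"),
    data.frame(child = c("A", "B", "X", "X"),
               parent = c("R", "A", "B", "A"),
               relation = c("is_a", "is_a", "part_of", "is_a")))
  expect_equal(term_depth(dia2, "X"), 2L)
  for (seed in 1:10) {
    d <- random_dag_corpus(seed)
    for (t in d$graph$terms$id) {
      expect_equal(term_depth(d$graph, t), bfs_depth(d$graph, t))
    }
    e <- d$graph$edges
    expect_true(all(d$graph$depth[e$child] <= d$graph$depth[e$parent] + 1L))
  }
})

test_that("most specific shared terms reproduce the organelle worked example", {
  g <- organelle_example_graph()
  envelope <- term_by_name(g, "organelle envelope")
  imbo <- term_by_name(g, "intracellular membrane-bound organelle")
  shared <- most_specific_shared_terms(g, envelope, imbo)
  expect_setequal(shared,
                  c(term_by_name(g, "membrane-bound organelle"),
                    term_by_name(g, "intracellular organelle")))
  expect_equal(most_specific_shared_terms(g, "CC:0004", "CC:0004"), "CC:0004")
  # only common ancestor is the root: empty at min_depth 1
  two_leaf <- ontology_graph(
    data.frame(id = c("R", "L1", "L2"), name = c("R", "L1", "L2"),
               namespace = "biological_process"),
    data.frame(child = c("L1", "L2"), parent = "R", relation = "is_a"))
  expect_length(most_specific_shared_terms(two_leaf, "L1", "L2", 1L), 0L)
  expect_equal(most_specific_shared_terms(two_leaf, "L1", "L2", 0L), "R")
  expect_error(most_specific_shared_terms(g, character(0), "CC:0004"),
               "empty term set")
})

test_that("shared-term output is an antichain and symmetric in its inputs", {
  for (seed in 1:20) {
    d <- random_dag_corpus(seed)
    ids <- d$graph$terms$id
    set.seed(seed + 1000)
    A <- sample(ids, 3); B <- sample(ids, 3)
    s1 <- most_specific_shared_terms(d$graph, A, B)
    s2 <- most_specific_shared_terms(d$graph, B, A)
    expect_identical(s1, s2)
    for (x in s1) {
      others <- setdiff(s1, x)
      anc <- reflexive_ancestors(d$graph, x)
      expect_false(any(others %in% setdiff(anc, x)))
    }
  }
})

test_that("pair filtering applies the evidence and shared-function stages", {
  g <- organelle_example_graph()
  rec <- data.frame(
    gene = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    term = c("CC:0005", "CC:0004",        # pair a: shared mbo+io
             "CC:0002", "CC:0002",        # pair b: same depth-2 term
             "CC:0001", "CC:0001",        # pair c: IEA-only gene c2
             "CC:0002", "CC:0003"),       # pair d: shared only organelle
    evidence = c("IDA", "IDA", "IDA", "TAS", "IDA", "IEA", "IMP", "IDA"),
    stringsAsFactors = FALSE)
  anns <- annotation_set(rec, g)
  pairs <- data.frame(gene1 = c("a1", "b1", "c1", "d1"),
                      gene2 = c("a2", "b2", "c2", "d2"))
  fil <- filter_pairs(pairs, anns, g)
  f <- fil$funnel
  expect_equal(f$n_input, 4L)
  expect_equal(f$dropped_evidence, 1L)            # pair c: c2 only IEA
  expect_equal(unname(f$n_retained["cellular_component"]), 3L)
  expect_equal(fil$profiles$cellular_component[["b1|b2"]], "CC:0002")
  expect_setequal(fil$profiles$cellular_component[["a1|a2"]],
                  c("CC:0002", "CC:0003"))
  # depth >= 1 keeps "organelle" (depth 1) for pair d
  expect_equal(fil$profiles$cellular_component[["d1|d2"]], "CC:0001")
  # min_depth 2 drops pair d from the namespace
  fil2 <- filter_pairs(pairs, anns, g, min_depth = 2L)
  expect_null(fil2$profiles$cellular_component[["d1|d2"]])
  # drop counts are consistent with input minus output
  expect_equal(f$dropped_evidence +
                 unname(f$dropped_no_shared["cellular_component"]),
               f$n_input - unname(f$n_retained["cellular_component"]))
  # a gene absent from the annotation index drops its pair at stage 1
  fil3 <- filter_pairs(rbind(pairs, data.frame(gene1 = "zz", gene2 = "a1")),
                       anns, g)
  expect_equal(fil3$funnel$dropped_evidence, 2L)
})
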