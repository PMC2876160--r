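small_config <- function(...) {
  simulation_config(n_families = 3L, pairs_per_family = 8L,
                    terms_per_namespace = 120L, ...)
}

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config()
  g1 <- simulate_ontology(cfg, 4); g2 <- simulate_ontology(cfg, 4)
  expect_identical(g1$edges, g2$edges)
  g3 <- simulate_ontology(cfg, 5)
  expect_false(identical(g1$edges, g3$edges))
  a1 <- simulate_annotated_pairs(g1, cfg, 6)
  a2 <- simulate_annotated_pairs(g1, cfg, 6)
  expect_identical(a1$annotations$records, a2$annotations$records)
  expect_identical(a1$truth, a2$truth)
  o1 <- simulate_omega(a1$truth, cfg, 7)
  expect_identical(o1, simulate_omega(a1$truth, cfg, 7))
  l1 <- simulate_layout(a1$pairs$gene1, cfg, 8)
  expect_identical(l1, simulate_layout(a1$pairs$gene1, cfg, 8))
  s1 <- simulate_cds_pair(60, 3, 2, seed = 9)
  expect_identical(s1, simulate_cds_pair(60, 3, 2, seed = 9))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(iea_fraction = 1.4), "probabilities")
  expect_error(simulation_config(omega_bounds = c(0, 2.5)), "omega bounds")
  expect_error(simulation_config(family_omega_means = c(1, 1, 1, 1, 1, 1)),
               "truncation bounds")
})

test_that("simulated ontologies are valid DAGs with non-ancestral deep anchors", {
  cfg <- small_config()
  g <- simulate_ontology(cfg, 12)        # construction validates acyclicity
  expect_length(g$roots, 3L)
  anchors <- attr(g, "anchors")
  for (ns in colnames(anchors)) {
    for (k in seq_len(nrow(anchors))) {
      expect_gte(term_depth(g, anchors[k, ns]), 3L)
      others <- anchors[-k, ns]
      expect_false(any(others %in% reflexive_ancestors(g, anchors[k, ns])))
    }
    # every anchor has descendants to annotate from
    fam <- attr(g, "family_terms")[[ns]]
    expect_true(all(lengths(fam) >= 1L))
  }
})

test_that("zero part_of fraction yields a pure is_a ontology", {
  cfg <- small_config(part_of_fraction = 0)
  g <- simulate_ontology(cfg, 3)
  expect_setequal(unique(g$edges$relation), "is_a")
})

test_that("IEA fraction 0 keeps all pairs; IEA fraction 1 drops them all", {
  cfg0 <- small_config(iea_fraction = 0)
  g <- simulate_ontology(cfg0, 2)
  ap0 <- simulate_annotated_pairs(g, cfg0, 3)
  fil0 <- filter_pairs(ap0$pairs, ap0$annotations, g)
  expect_equal(fil0$funnel$dropped_evidence, 0L)
  cfg1 <- small_config(iea_fraction = 1)
  ap1 <- simulate_annotated_pairs(g, cfg1, 3)
  fil1 <- filter_pairs(ap1$pairs, ap1$annotations, g)
  expect_equal(fil1$funnel$n_after_evidence, 0L)
})

test_that("within-family profile similarity exceeds the between-family average", {
  for (seed in c(2, 13)) {
    cfg <- small_config()
    study <- simulate_study(cfg, seed)
    fil <- filter_pairs(study$pairs, study$annotations, study$graph)
    rec <- study$annotations$records
    corpus <- annotation_set(rec[!(rec$evidence %in% c("IEA", "ND")), ],
                             study$graph)
    ic <- information_content(corpus, study$graph)
    sim <- profile_similarity_matrix(fil$profiles$biological_process, ic,
                                     study$graph)
    truth <- study$truth[sim$ids]
    same <- outer(truth, truth, "==") & upper.tri(sim$matrix)
    diff <- outer(truth, truth, "!=") & upper.tri(sim$matrix)
    expect_gt(mean(sim$matrix[same]), mean(sim$matrix[diff]))
  }
})

test_that("omega draws follow the family means and truncation bounds", {
  cfg <- small_config(omega_sd = 0)
  truth <- setNames(rep(1:3, each = 5), sprintf("p%02d", 1:15))
  om <- simulate_omega(truth, cfg, 4)
  expect_equal(unname(om), cfg$family_omega_means[truth], tolerance = 1e-12)
  cfg2 <- small_config(omega_sd = 0.3)
  om2 <- simulate_omega(truth, cfg2, 4)
  expect_true(all(om2 >= cfg2$omega_bounds[1] & om2 <= cfg2$omega_bounds[2]))
})

test_that("two distant family means give a decisive ANOVA", {
  cfg <- simulation_config(n_families = 2L, pairs_per_family = 30L,
                           family_omega_means = c(0.05, 0.35),
                           omega_sd = 0.05)
  truth <- setNames(rep(1:2, each = 30), sprintf("p%02d", 1:60))
  om <- simulate_omega(truth, cfg, 8)
  tab <- one_way_anova(om, truth)
  expect_lt(tab$p[1], 1e-6)
})

test_that("CDS pairs carry exactly the requested substitution structure", {
  sp0 <- simulate_cds_pair(50, 0, 0, seed = 1)
  expect_equal(sp0$cds1, sp0$cds2)
  est0 <- ng86_divergence(list(codons1 = funcdiv:::split_codons(sp0$cds1),
                               codons2 = funcdiv:::split_codons(sp0$cds2)))
  expect_equal(est0$dN, 0); expect_equal(est0$dS, 0)
  sp_syn <- simulate_cds_pair(80, 6, 0, seed = 2)
  expect_equal(sp_syn$protein1, sp_syn$protein2)   # synonymous changes only
  est_syn <- ng86_divergence(list(codons1 = funcdiv:::split_codons(sp_syn$cds1),
                                  codons2 = funcdiv:::split_codons(sp_syn$cds2)))
  expect_equal(est_syn$dN, 0)
  expect_gt(est_syn$dS, 0)
  # one change per codon: counting recovers Sd + Nd exactly
  sp <- simulate_cds_pair(300, 5, 5, seed = 3)
  est <- ng86_divergence(list(codons1 = funcdiv:::split_codons(sp$cds1),
                              codons2 = funcdiv:::split_codons(sp$cds2)))
  expect_equal(est$Sd + est$Nd, 10)
  expect_equal(est$Sd, 5); expect_equal(est$Nd, 5)
  expect_error(simulate_cds_pair(5, 4, 4, seed = 1), "exceed")
})

test_that("no stop codons ever appear in simulated coding sequences", {
  for (seed in 1:10) {
    sp <- simulate_cds_pair(100, 10, 10, seed = seed)
    expect_false(grepl("\\*", sp$protein1))
    expect_false(grepl("\\*", sp$protein2))
  }
})

test_that("genome layout places genes within bounds; planted correlation is recovered", {
  cfg <- small_config()
  genes <- sprintf("g%03d", 1:200)
  lay <- simulate_layout(genes, cfg, 6)
  expect_true(all(lay$layout$start >= 0 &
                    lay$layout$end <= cfg$chromosome_length))
  expect_true(all(lay$layout$centromere_distance >= 0))
  # null: no location effect
  sig <- setNames(runif(200), genes)
  ct <- pearson_correlation(lay$layout$centromere_distance, sig[genes])
  expect_gt(ct$p, 0.001)
  # planted rho = 0.9 at n = 500
  cfg2 <- small_config(location_effect = 0.9)
  genes2 <- sprintf("h%03d", 1:500)
  set.seed(10); sig2 <- setNames(runif(500), genes2)
  lay2 <- simulate_layout(genes2, cfg2, 7, signal = sig2)
  ct2 <- pearson_correlation(lay2$layout$centromere_distance, sig2[genes2])
  expect_gt(ct2$r, 0.7)
  expect_error(simulate_layout(sprintf("x%06d", 1:2e5),
                               small_config(n_chromosomes = 1L,
                                            chromosome_length = 1e5), 1),
               "capacity")
})

test_that("a full synthetic study passes every upstream validator", {
  study <- simulate_study(small_config(), seed = 3)
  # graph validated at construction; annotations resolvable by design
  expect_s3_class(study$graph, "ontology_graph")
  expect_true(all(c(study$pairs$gene1, study$pairs$gene2) %in%
                    names(study$annotations$by_gene)))
  expect_setequal(names(study$truth), study$pairs$pair_id)
  # CDS translate cleanly to their proteins
  for (g in sample(names(study$cds), 10)) {
    expect_equal(
      paste(funcdiv:::translate_codons(funcdiv:::split_codons(study$cds[[g]])),
            collapse = ""),
      study$proteins[[g]])
  }
  expect_setequal(study$layout$gene,
                  c(study$pairs$gene1, study$pairs$gene2))
})
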