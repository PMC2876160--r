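# Synthetic-study generator: a layered random ontology with planted family
# anchor terms, annotation corpora with an electronically-annotated
# fraction, duplicate pairs organized into functional families,
# group-dependent omega values, diverged CDS pairs with controlled
# substitution counts, and a genome layout. Every generator is a pure
# function of (config, seed).

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: three namespaces of 300
#' terms each, six planted functional families of 30 duplicate pairs,
#' family omega means spread over [0.03, 0.45] (SD 0.06, truncated to
#' [0, 0.8]), 300-codon coding sequences receiving 30 synonymous
#' substitutions plus a nonsynonymous count scaled to the pair's omega, a
#' 10% electronically-annotated gene fraction, and five 30-Mb chromosomes
#' with central centromeres.
#'
#' @param n_families number of planted functional families.
#' @param pairs_per_family duplicate pairs per family.
#' @param terms_per_namespace ontology size per namespace.
#' @param layer_fractions fractions of non-root terms per depth layer.
#' @param part_of_fraction probability a term gets a second (part_of)
#'   parent.
#' @param family_attach_prob probability a deep term is attached inside a
#'   family subtree rather than freely.
#' @param iea_fraction fraction of genes annotated only electronically
#'   (evidence code IEA).
#' @param terms_per_gene range (min, max) of family-pool terms per gene.
#' @param family_pool_size number of anchor-descendant terms forming each
#'   family's annotation pool.
#' @param family_omega_means per-family omega means (length `n_families`).
#' @param omega_sd within-family omega standard deviation.
#' @param omega_bounds truncation bounds for omega.
#' @param n_codons CDS length in codons.
#' @param syn_subs synonymous substitutions per pair.
#' @param ns_site_ratio assumed nonsynonymous/synonymous site ratio used to
#'   convert a pair's omega into its nonsynonymous substitution count.
#' @param multiple_prob per-family probability that a pair is a "multiple"
#'   duplicate (recycled to `n_families`).
#' @param n_chromosomes,chromosome_length genome layout.
#' @param location_effect planted correlation between centromere distance
#'   and omega (0 = none).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 6L,
                              pairs_per_family = 30L,
                              terms_per_namespace = 300L,
                              layer_fractions = c(0.03, 0.10, 0.17, 0.30, 0.40),
                              part_of_fraction = 0.2,
                              family_attach_prob = 0.8,
                              iea_fraction = 0.1,
                              terms_per_gene = c(2L, 4L),
                              family_pool_size = 8L,
                              family_omega_means = NULL,
                              omega_sd = 0.06,
                              omega_bounds = c(0, 0.8),
                              n_codons = 300L,
                              syn_subs = 30L,
                              ns_site_ratio = 3,
                              multiple_prob = seq(0.1, 0.6, length.out = n_families),
                              n_chromosomes = 5L,
                              chromosome_length = 3e7,
                              location_effect = 0) {
  if (is.null(family_omega_means)) {
    family_omega_means <- seq(0.03, 0.45, length.out = n_families)
  }
  cfg <- list(n_families = as.integer(n_families),
              pairs_per_family = as.integer(pairs_per_family),
              terms_per_namespace = as.integer(terms_per_namespace),
              layer_fractions = layer_fractions,
              part_of_fraction = part_of_fraction,
              family_attach_prob = family_attach_prob,
              iea_fraction = iea_fraction,
              terms_per_gene = as.integer(terms_per_gene),
              family_pool_size = as.integer(family_pool_size),
              family_omega_means = family_omega_means,
              omega_sd = omega_sd,
              omega_bounds = omega_bounds,
              n_codons = as.integer(n_codons),
              syn_subs = as.integer(syn_subs),
              ns_site_ratio = ns_site_ratio,
              multiple_prob = rep_len(multiple_prob, n_families),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = chromosome_length,
              location_effect = location_effect)
  probs <- c(cfg$part_of_fraction, cfg$family_attach_prob, cfg$iea_fraction,
             cfg$multiple_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$omega_bounds[1] < 0 || cfg$omega_bounds[2] >= 2) {
    stopf("omega bounds must lie within [0, 2)")
  }
  if (any(cfg$family_omega_means < cfg$omega_bounds[1] |
          cfg$family_omega_means > cfg$omega_bounds[2])) {
    stopf("family omega means outside truncation bounds")
  }
  if (cfg$n_families < 1L || cfg$pairs_per_family < 1L) {
    stopf("need at least one family and one pair per family")
  }
  if (abs(sum(cfg$layer_fractions) - 1) > 1e-9) {
    stopf("layer fractions must sum to 1")
  }
  class(cfg) <- "simulation_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a layered random ontology with family anchors
#'
#' Builds, per namespace, a rooted DAG by layered random attachment: each
#' non-root term takes one `is_a` parent from the previous layer and, with
#' probability `part_of_fraction`, a second `part_of` parent. The K family
#' anchor terms sit at depth 3 (same layer, hence pairwise non-ancestral);
#' deeper terms attach inside one family's subtree with probability
#' `family_attach_prob`, giving each anchor a dedicated descendant pool, and
#' second parents are restricted to the same subtree or to depth <= 2 so
#' family branches stay separated.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return an [ontology_graph()] with attributes `anchors` (matrix: family x
#'   namespace of anchor term ids) and `family_terms` (per namespace, per
#'   family: anchor plus descendants).
#' @export
simulate_ontology <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  K <- config$n_families
  nspaces <- c("biological_process", "molecular_function", "cellular_component")
  prefix <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  with_seed(seed, {
    all_terms <- list(); all_edges <- list()
    anchors <- matrix("", K, length(nspaces),
                      dimnames = list(NULL, nspaces))
    family_terms <- setNames(vector("list", length(nspaces)), nspaces)
    for (ns in nspaces) {
      n <- config$terms_per_namespace
      sizes <- pmax(1L, round(config$layer_fractions * (n - 1L)))
      sizes[length(sizes)] <- (n - 1L) - sum(sizes[-length(sizes)])
      if (sizes[3] < K) stopf("layer 3 too small for %d family anchors", K)
      ids <- sprintf("%s:%04d", prefix[[ns]], seq_len(n))
      root <- ids[1]
      layer <- c(0L, rep(seq_along(sizes), sizes))
      names(layer) <- ids
      # anchors: first K terms of layer 3
      l3 <- ids[layer == 3L]
      anchor_ids <- l3[seq_len(K)]
      anchors[, ns] <- anchor_ids
      fam_of <- setNames(rep(NA_integer_, n), ids)
      fam_of[anchor_ids] <- seq_len(K)
      # all family anchors hang from one shared "hub" parent, emulating the
      # broad general terms of real ontologies; the hub's gene coverage then
      # spans every family, so the parent-child enrichment statistic can
      # single out the anchor subtrees rather than their shallow ancestors
      hub <- ids[layer == 2L][1]
      child <- character(0); parent <- character(0); relation <- character(0)
      for (i in seq(2L, n)) {
        t <- ids[i]; ly <- layer[[t]]
        prev <- if (t %in% anchor_ids) hub else ids[layer == ly - 1L]
        if (ly >= 4L && runif(1) < config$family_attach_prob) {
          fam <- sample.int(K, 1L)
          cand <- prev[!is.na(fam_of[prev]) & fam_of[prev] == fam]
          if (length(cand) == 0L) {
            # family has no member in the previous layer: attach under the
            # anchor itself (depth may exceed the layer index slightly)
            cand <- anchor_ids[fam]
          }
          p1 <- cand[sample.int(length(cand), 1L)]
          fam_of[t] <- fam
        } else {
          p1 <- prev[sample.int(length(prev), 1L)]
          if (ly >= 4L && !is.na(fam_of[p1])) fam_of[t] <- fam_of[p1]
        }
        child <- c(child, t); parent <- c(parent, p1)
        relation <- c(relation, "is_a")
        if (!(t %in% anchor_ids) && runif(1) < config$part_of_fraction) {
          # anchors keep a single layer-2 parent so their depth stays >= 3
          # second parent: same family subtree or a shallow general term
          if (!is.na(fam_of[t])) {
            cand <- ids[layer < ly & layer >= 1L &
                          (is.na(fam_of[ids]) & layer[ids] <= 2L |
                             (!is.na(fam_of[ids]) & fam_of[ids] == fam_of[t]))]
          } else {
            cand <- ids[layer < ly & layer >= 1L & is.na(fam_of[ids])]
          }
          cand <- setdiff(cand, p1)
          if (length(cand)) {
            p2 <- cand[sample.int(length(cand), 1L)]
            child <- c(child, t); parent <- c(parent, p2)
            relation <- c(relation, "part_of")
          }
        }
      }
      all_terms[[ns]] <- data.frame(
        id = ids, name = paste("term", ids), namespace = ns,
        stringsAsFactors = FALSE)
      all_edges[[ns]] <- data.frame(child = child, parent = parent,
                                    relation = relation,
                                    stringsAsFactors = FALSE)
      family_terms[[ns]] <- lapply(seq_len(K), function(k) {
        ids[!is.na(fam_of) & fam_of == k]
      })
    }
    graph <- ontology_graph(do.call(rbind, all_terms),
                            do.call(rbind, all_edges))
    attr(graph, "anchors") <- anchors
    attr(graph, "family_terms") <- family_terms
    graph
  })
}

#' Simulate annotated duplicate pairs with planted families
#'
#' Each family's pairs draw their annotations from a family-specific pool of
#' anchor descendants, in every namespace: both genes of a pair share a core
#' term (so their shared-function profile is nonempty and family-specific)
#' plus extra pool terms. Within-family profiles overlap heavily;
#' between-family overlap exists only through shallow common ancestors. A
#' configurable fraction of genes receives only IEA evidence, exercising the
#' evidence filter; copy-number classes are drawn per family.
#'
#' @param graph a [simulate_ontology()] result (with anchor attributes).
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `annotations` ([annotation_set()]), `pairs`
#'   (data.frame gene1, gene2, pair_id, copy_number_class), and `truth`
#'   (named integer vector pair_id -> family).
#' @export
simulate_annotated_pairs <- function(graph, config = simulation_config(),
                                     seed = 1L) {
  anchors <- attr(graph, "anchors")
  family_terms <- attr(graph, "family_terms")
  if (is.null(anchors)) stopf("graph carries no family anchors")
  K <- config$n_families
  npairs <- config$pairs_per_family
  curated_codes <- c("IDA", "IMP", "IGI", "TAS")
  with_seed(seed, {
    pools <- lapply(names(family_terms), function(ns) {
      lapply(seq_len(K), function(k) {
        fam <- family_terms[[ns]][[k]]
        if (length(fam) == 0L) stopf("family %d anchor has no descendants", k)
        deep <- setdiff(fam, anchors[k, ns])
        pool_n <- min(config$family_pool_size, length(deep))
        if (pool_n == 0L) fam else deep[sample.int(length(deep), pool_n)]
      })
    })
    names(pools) <- names(family_terms)
    genes <- character(0); terms <- character(0); evid <- character(0)
    g1s <- character(0); g2s <- character(0); fams <- integer(0)
    copy <- character(0)
    idx <- 0L
    for (k in seq_len(K)) {
      # the electronically-annotated fraction is exact per family: an IEA
      # gene slot count of round(fraction * genes), placed at random
      n_slots <- 2L * npairs
      n_iea <- round(config$iea_fraction * n_slots)
      iea_slots <- rep(FALSE, n_slots)
      if (n_iea > 0L) iea_slots[sample.int(n_slots, n_iea)] <- TRUE
      for (p in seq_len(npairs)) {
        idx <- idx + 1L
        gA <- sprintf("g%04da", idx); gB <- sprintf("g%04db", idx)
        iea_A <- iea_slots[2L * p - 1L]
        iea_B <- iea_slots[2L * p]
        for (ns in names(pools)) {
          pool <- pools[[ns]][[k]]
          core <- pool[sample.int(length(pool), 1L)]
          for (g in c(gA, gB)) {
            extra_n <- sample(seq(config$terms_per_gene[1],
                                  config$terms_per_gene[2]), 1L) - 1L
            extra_n <- min(extra_n, length(pool) - 1L)
            extra <- if (extra_n > 0L) {
              setdiff(pool, core)[sample.int(length(pool) - 1L, extra_n)]
            } else character(0)
            tset <- c(core, extra)
            iea <- if (g == gA) iea_A else iea_B
            ev <- if (iea) rep("IEA", length(tset)) else {
              curated_codes[sample.int(length(curated_codes), length(tset),
                                       replace = TRUE)]
            }
            genes <- c(genes, rep(g, length(tset)))
            terms <- c(terms, tset)
            evid <- c(evid, ev)
          }
        }
        g1s <- c(g1s, gA); g2s <- c(g2s, gB)
        fams <- c(fams, k)
        copy <- c(copy, if (runif(1) < config$multiple_prob[k]) "multiple"
                  else "single")
      }
    }
    pairs <- make_pairs(g1s, g2s, copy)
    truth <- setNames(fams, pair_key(g1s, g2s))
    anns <- annotation_set(
      data.frame(gene = genes, term = terms, evidence = evid,
                 stringsAsFactors = FALSE), graph)
    list(annotations = anns, pairs = pairs, truth = truth)
  })
}

#' Simulate per-pair omega values with family-dependent means
#'
#' Omega is drawn from a normal distribution with the pair's family mean and
#' the configured SD, truncated by rejection to the configured bounds.
#'
#' @param truth named integer vector pair_id -> family.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return named numeric vector pair_id -> omega.
#' @export
simulate_omega <- function(truth, config = simulation_config(), seed = 1L) {
  means <- config$family_omega_means
  if (any(means < config$omega_bounds[1] | means > config$omega_bounds[2])) {
    stopf("family omega mean outside truncation bounds")
  }
  with_seed(seed, {
    vapply(names(truth), function(pid) {
      mu <- means[truth[[pid]]]
      repeat {
        x <- rnorm(1, mu, config$omega_sd)
        if (x >= config$omega_bounds[1] && x <= config$omega_bounds[2]) {
          return(x)
        }
      }
    }, numeric(1))
  })
}

# single-base mutations of a codon, annotated synonymous/nonsynonymous
codon_neighbors <- function(codon) {
  gc <- genetic_code()
  nt <- strsplit(codon, "")[[1]]
  out <- character(0); syn <- logical(0)
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), nt[pos])) {
      mut <- nt; mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (gc[mutc] == "*") next
      out <- c(out, mutc)
      syn <- c(syn, gc[mutc] == gc[codon])
    }
  }
  list(codon = out, synonymous = syn)
}

#' Simulate a diverged coding-sequence pair with controlled substitutions
#'
#' Draws a random sense-codon ancestor and applies exactly `n_syn`
#' synonymous and `n_nonsyn` nonsynonymous single-base changes to the second
#' copy, at distinct codon positions, never creating stop codons. With one
#' change per codon the counting estimator recovers the planted difference
#' counts exactly.
#'
#' @param n_codons sequence length in codons.
#' @param n_syn,n_nonsyn substitution counts (`n_syn + n_nonsyn <=
#'   n_codons`).
#' @param seed integer seed.
#' @param max_tries resampling attempts for infeasible codons.
#' @return list with `cds1`, `cds2`, `protein1`, `protein2`, and `truth`
#'   (`n_syn`, `n_nonsyn`).
#' @export
simulate_cds_pair <- function(n_codons, n_syn, n_nonsyn, seed = 1L,
                              max_tries = 100L) {
  if (n_syn + n_nonsyn > n_codons) {
    stopf("requested %d substitutions exceed %d codons", n_syn + n_nonsyn,
          n_codons)
  }
  sense <- sense_codons()
  with_seed(seed, {
    anc <- sense[sample.int(length(sense), n_codons, replace = TRUE)]
    target <- sample.int(n_codons, n_syn + n_nonsyn)
    syn_pos <- target[seq_len(n_syn)]
    non_pos <- target[n_syn + seq_len(n_nonsyn)]
    der <- anc
    for (i in syn_pos) {
      tries <- 0L
      repeat {
        nb <- codon_neighbors(der[i])
        cand <- nb$codon[nb$synonymous]
        if (length(cand)) {
          der[i] <- cand[sample.int(length(cand), 1L)]
          break
        }
        tries <- tries + 1L
        if (tries > max_tries) stopf("cannot place synonymous change")
        # codon (e.g. ATG/TGG) has no synonymous neighbor: redraw ancestor
        anc[i] <- sense[sample.int(length(sense), 1L)]
        der[i] <- anc[i]
      }
    }
    for (i in non_pos) {
      nb <- codon_neighbors(der[i])
      cand <- nb$codon[!nb$synonymous]
      # every sense codon has at least one nonsynonymous sense neighbor
      der[i] <- cand[sample.int(length(cand), 1L)]
    }
    list(cds1 = paste(anc, collapse = ""),
         cds2 = paste(der, collapse = ""),
         protein1 = paste(translate_codons(anc), collapse = ""),
         protein2 = paste(translate_codons(der), collapse = ""),
         truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn))
  })
}

#' Simulate a genome layout for the location analysis
#'
#' Genes are placed uniformly on equal-length chromosomes with central
#' centromeres. An optional planted correlation couples a gene's centromere
#' distance to a supplied per-gene signal (e.g. its pair's omega) via a
#' Gaussian copula.
#'
#' @param genes character vector of gene identifiers.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param signal optional named numeric vector (gene -> value) used when
#'   `config$location_effect` is nonzero.
#' @return list with `layout` (data.frame gene, chromosome, start, end,
#'   midpoint, centromere_distance) and `centromeres` (data.frame
#'   chromosome, position).
#' @export
simulate_layout <- function(genes, config = simulation_config(), seed = 1L,
                            signal = NULL) {
  n <- length(genes)
  gene_len <- 2000
  capacity <- config$n_chromosomes * (config$chromosome_length - gene_len)
  if (n * gene_len > capacity) stopf("gene count exceeds placeable capacity")
  with_seed(seed, {
    chrom <- sample.int(config$n_chromosomes, n, replace = TRUE)
    start <- floor(runif(n, 1, config$chromosome_length - gene_len))
    centromere <- rep(config$chromosome_length / 2, config$n_chromosomes)
    mid <- start + gene_len / 2
    dist <- abs(mid - centromere[chrom])
    rho <- config$location_effect
    if (rho != 0) {
      if (is.null(signal)) stopf("location_effect set but no signal supplied")
      s <- signal[genes]
      z <- rho * scale(s)[, 1] + sqrt(1 - rho^2) * rnorm(n)
      # reassign distances so their ranks follow the coupled latent variable
      dist <- sort(dist)[rank(z, ties.method = "first")]
      # reposition midpoints consistently with the planted distances
      side <- sample(c(-1, 1), n, replace = TRUE)
      mid <- centromere[chrom] + side * dist
      mid <- pmin(pmax(mid, gene_len / 2 + 1),
                  config$chromosome_length - gene_len / 2)
      dist <- abs(mid - centromere[chrom])
      start <- mid - gene_len / 2
    }
    list(layout = data.frame(gene = genes, chromosome = chrom,
                             start = start, end = start + gene_len,
                             midpoint = mid, centromere_distance = dist,
                             stringsAsFactors = FALSE),
         centromeres = data.frame(chromosome = seq_len(config$n_chromosomes),
                                  position = centromere))
  })
}

#' Simulate a complete synthetic study
#'
#' Composes the ontology, annotations, duplicate pairs, omega truth, coding
#' sequences (substitution counts scaled to each pair's omega), and genome
#' layout into one object with full ground truth.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; all sub-generators derive their seeds from it.
#' @return list of class `synthetic_study`: `graph`, `annotations`, `pairs`,
#'   `truth`, `omega`, `proteins`, `cds`, `layout`, `centromeres`,
#'   `config`, `seed`.
#' @export
simulate_study <- function(config = simulation_config(), seed = 1L) {
  seeds <- with_seed(seed, sample.int(1e7, 5))
  graph <- simulate_ontology(config, seeds[1])
  ap <- simulate_annotated_pairs(graph, config, seeds[2])
  omega <- simulate_omega(ap$truth, config, seeds[3])
  n_nonsyn <- round(omega * config$syn_subs * config$ns_site_ratio)
  n_nonsyn[n_nonsyn < 0] <- 0
  proteins <- character(0); cds <- character(0)
  for (i in seq_len(nrow(ap$pairs))) {
    pid <- ap$pairs$pair_id[i]
    sp <- simulate_cds_pair(config$n_codons, config$syn_subs,
                            n_nonsyn[[pid]],
                            seed = seeds[4] + i)
    proteins[ap$pairs$gene1[i]] <- sp$protein1
    proteins[ap$pairs$gene2[i]] <- sp$protein2
    cds[ap$pairs$gene1[i]] <- sp$cds1
    cds[ap$pairs$gene2[i]] <- sp$cds2
  }
  genes <- c(ap$pairs$gene1, ap$pairs$gene2)
  signal <- setNames(rep(omega[ap$pairs$pair_id], 2), genes)
  lay <- simulate_layout(genes, config, seeds[5], signal = signal)
  structure(list(graph = graph, annotations = ap$annotations,
                 pairs = ap$pairs, truth = ap$truth, omega = omega,
                 proteins = proteins, cds = cds,
                 layout = lay$layout, centromeres = lay$centromeres,
                 config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d pairs in %d families, seed %d\n",
              nrow(x$pairs), x$config$n_families, x$seed))
  invisible(x)
}
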