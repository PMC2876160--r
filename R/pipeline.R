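# End-to-end orchestration: filter -> profiles -> similarity -> cluster ->
# dN/dS -> ANOVA/Tukey -> enrichment -> report, per namespace, with
# deterministic on-disk outputs.

#' Pipeline configuration
#'
#' Validates the analysis parameters. Exactly one of `min_size` (bottom-up
#' minimum-size tree cut) or `height` (fixed-height cut) must be given.
#' Inputs are supplied either as a [simulate_study()] object (`study`) or as
#' file paths (`obo`, `gaf`, `pairs`, plus `proteins`/`cds` FASTA or an
#' `omega_table` TSV).
#'
#' @param study optional `synthetic_study` supplying all inputs in memory.
#' @param obo,gaf,pairs,proteins,cds,omega_table,layout input file paths
#'   (ignored when `study` is given).
#' @param namespaces namespaces to analyze.
#' @param min_depth minimum shared-function depth (default 1).
#' @param evidence_blacklist non-curated evidence codes.
#' @param min_size,height cluster cut parameters (choose one).
#' @param alpha familywise error rate for Tukey HSD.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(study = NULL, obo = NULL, gaf = NULL,
                            pairs = NULL, proteins = NULL, cds = NULL,
                            omega_table = NULL, layout = NULL,
                            namespaces = "biological_process",
                            min_depth = 1L,
                            evidence_blacklist = c("IEA", "ND"),
                            min_size = 20L, height = NULL,
                            alpha = 0.05, out_dir = NULL) {
  if (!is.null(min_size) && !is.null(height)) {
    stopf("choose exactly one of min_size or height")
  }
  if (is.null(min_size) && is.null(height)) {
    stopf("one of min_size or height must be set")
  }
  if (is.null(study)) {
    for (f in c(obo, gaf, pairs)) {
      if (is.null(f) || !file.exists(f)) {
        stopf("input file missing: ontology, annotations and pairs are required")
      }
    }
    if (is.null(omega_table) && (is.null(proteins) || is.null(cds))) {
      stopf("supply either protein+CDS FASTA files or an omega table")
    }
  } else if (!inherits(study, "synthetic_study")) {
    stopf("study must be a synthetic_study object")
  }
  structure(list(study = study, obo = obo, gaf = gaf, pairs = pairs,
                 proteins = proteins, cds = cds, omega_table = omega_table,
                 layout = layout, namespaces = namespaces,
                 min_depth = min_depth,
                 evidence_blacklist = evidence_blacklist,
                 min_size = min_size, height = height, alpha = alpha,
                 out_dir = out_dir),
            class = "pipeline_config")
}

read_fasta_named <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

load_inputs <- function(config) {
  if (!is.null(config$study)) {
    s <- config$study
    return(list(graph = s$graph, annotations = s$annotations,
                pairs = s$pairs, proteins = s$proteins, cds = s$cds,
                omega_table = NULL, layout = s$layout))
  }
  graph <- parse_obo(config$obo)
  list(graph = graph,
       annotations = parse_gaf(config$gaf, graph),
       pairs = read_pair_list(config$pairs),
       proteins = if (!is.null(config$proteins)) read_fasta_named(config$proteins),
       cds = if (!is.null(config$cds)) read_fasta_named(config$cds),
       omega_table = if (!is.null(config$omega_table))
         import_divergence_table(config$omega_table),
       layout = if (!is.null(config$layout)) read_tsv(config$layout))
}

#' Run the full functional-divergence analysis
#'
#' Executes, per namespace: evidence and shared-function filtering,
#' information content, profile similarity, Ward clustering with the
#' configured cut, per-pair dN/dS (an imported omega table takes precedence
#' over sequence-based estimation), the omega histogram, one-way ANOVA and
#' Tukey HSD across functional groups, a two-way ANOVA with copy-number
#' class when available, the centromere-distance correlation when a layout
#' is available, and parent-child union enrichment. With `out_dir` set,
#' every stage writes a provenance-stamped TSV; identical configurations
#' reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`: `funnel`, `divergence`, `histogram`,
#'   `location`, and per-namespace entries with `groups`, `anova`, `tukey`,
#'   `extreme_groups`, `two_way`, `enrichment`, `tree`, `similarity`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_inputs(config)
  graph <- inputs$graph
  filtered <- filter_pairs(inputs$pairs, inputs$annotations, graph,
                           evidence_blacklist = config$evidence_blacklist,
                           min_depth = config$min_depth)
  if (nrow(filtered$pairs) == 0L) {
    stopf("no pairs survive the evidence filter (funnel: %d -> 0)",
          filtered$funnel$n_input)
  }
  # evidence-filtered corpus feeds IC and enrichment
  rec <- inputs$annotations$records
  rec <- rec[!(rec$evidence %in% config$evidence_blacklist), , drop = FALSE]
  corpus <- annotation_set(rec, graph)
  ic <- information_content(corpus, graph)

  # omega per pair: imported table takes precedence over NG86 from sequences
  if (!is.null(inputs$omega_table)) {
    div <- inputs$omega_table
  } else {
    div <- pair_divergence(filtered$pairs, inputs$proteins, inputs$cds)
  }
  omega <- setNames(div$omega, div$pair_id)
  n_unusable <- sum(is.na(omega) | nzchar(div$flags))
  hist <- omega_histogram(omega[is.finite(omega)])

  location <- NULL
  if (!is.null(inputs$layout)) {
    lay <- inputs$layout
    gene_pairs <- rbind(
      data.frame(gene = filtered$pairs$gene1, pair_id = filtered$pairs$pair_id),
      data.frame(gene = filtered$pairs$gene2, pair_id = filtered$pairs$pair_id))
    d <- lay$centromere_distance[match(gene_pairs$gene, lay$gene)]
    w <- omega[gene_pairs$pair_id]
    location <- pearson_correlation(d, w)
  }

  report <- list(funnel = filtered$funnel, divergence = div,
                 histogram = hist, location = location,
                 omega_excluded = n_unusable,
                 namespaces = list(), config = config)
  for (ns in config$namespaces) {
    prof <- filtered$profiles[[ns]]
    if (length(prof) < 2L) {
      warnf("namespace %s has <2 profiled pairs; skipped", ns)
      next
    }
    sim <- profile_similarity_matrix(prof, ic, graph)
    tree <- ward_linkage(similarity_to_distance(sim))
    groups <- if (!is.null(config$min_size)) {
      cut_by_min_size(tree, config$min_size)
    } else {
      cut_by_height(tree, config$height)
    }
    w <- omega[groups$pair_id]
    ok <- is.finite(w)
    anova_tab <- one_way_anova(w[ok], groups$group[ok])
    tukey <- tukey_hsd(w[ok], groups$group[ok], alpha = config$alpha)
    two_way <- NULL
    if (!is.null(filtered$pairs$copy_number_class)) {
      cls <- filtered$pairs$copy_number_class[
        match(groups$pair_id, filtered$pairs$pair_id)]
      if (length(unique(cls[ok])) > 1L && length(unique(groups$group[ok])) > 1L) {
        two_way <- two_way_anova(w[ok], groups$group[ok], cls[ok])
      }
    }
    population <- unique(c(filtered$pairs$gene1, filtered$pairs$gene2))
    enr <- enrich_groups(groups, corpus, graph, population, ns)
    report$namespaces[[ns]] <- list(
      groups = groups, n_groups = length(unique(groups$group)),
      similarity = sim, tree = tree, anova = anova_tab, tukey = tukey,
      extreme_groups = extreme_groups(tukey), two_way = two_way,
      enrichment = enr)
  }
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  f <- x$funnel
  cat(sprintf("run_report: %d pairs -> %d curated", f$n_input,
              f$n_after_evidence))
  cat("\n")
  for (ns in names(x$namespaces)) {
    r <- x$namespaces[[ns]]
    cat(sprintf("  %s: %d pairs, %d groups, ANOVA F=%.2f p=%.3g, extremes: %s\n",
                ns, nrow(r$groups), r$n_groups, r$anova$F[1], r$anova$p[1],
                if (length(r$extreme_groups))
                  paste(r$extreme_groups, collapse = ",") else "none"))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  prov <- c(sprintf("funcdiv %s", as.character(utils::packageVersion("funcdiv"))),
            sprintf("config_hash=%s", config_hash(
              cfg[setdiff(names(cfg), c("study", "out_dir"))])))
  write_tsv(report$divergence, file.path(out_dir, "divergence.tsv"), prov)
  hist_df <- data.frame(bin_lo = report$histogram$edges[-length(report$histogram$edges)],
                        bin_hi = report$histogram$edges[-1],
                        count = report$histogram$counts)
  write_tsv(hist_df, file.path(out_dir, "omega_histogram.tsv"), prov)
  jsonlite::write_json(report$funnel, file.path(out_dir, "funnel.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (ns in names(report$namespaces)) {
    r <- report$namespaces[[ns]]
    tag <- function(name) file.path(out_dir, sprintf("%s_%s.tsv", ns, name))
    write_tsv(r$groups, tag("groups"), prov)
    write_tsv(as.data.frame(r$anova), tag("anova"), prov)
    write_tsv(r$tukey$groups, tag("tukey_means"), prov)
    write_tsv(r$tukey$pairs, tag("tukey_pairs"), prov)
    if (!is.null(r$two_way)) write_tsv(as.data.frame(r$two_way), tag("two_way_anova"), prov)
    write_tsv(r$enrichment$records, tag("enrichment"), prov)
    write_tsv(r$enrichment$top, tag("enrichment_top"), prov)
    writeLines(dendrogram_newick(r$tree),
               file.path(out_dir, sprintf("%s_tree.nwk", ns)))
  }
  if (!is.null(report$location)) {
    jsonlite::write_json(unclass(report$location),
                         file.path(out_dir, "location_correlation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Sensitivity of the group analysis to clustering parameters
#'
#' Re-runs the clustering tail (cut -> ANOVA) on a cached similarity tree
#' for each requested parameter value, reporting group counts and ANOVA
#' p-values so the robustness of the group effect can be judged.
#'
#' @param report a [run_pipeline()] result (supplies the cached tree and
#'   omega values).
#' @param namespace which analyzed namespace to scan.
#' @param heights numeric vector of fixed cut heights (may be empty).
#' @param min_sizes integer vector of minimum group sizes (may be empty).
#' @return data.frame with columns `parameter`, `value`, `n_groups`,
#'   `anova_F`, `anova_p`.
#' @export
sensitivity_scan <- function(report, namespace = NULL, heights = numeric(0),
                             min_sizes = integer(0)) {
  stopifnot(inherits(report, "run_report"))
  if (length(heights) + length(min_sizes) == 0L) {
    stopf("supply at least one height or min_size")
  }
  namespace <- namespace %||% names(report$namespaces)[1]
  r <- report$namespaces[[namespace]]
  if (is.null(r)) stopf("namespace %s was not analyzed; run the pipeline first",
                        namespace)
  omega <- setNames(report$divergence$omega, report$divergence$pair_id)
  scan_one <- function(parameter, value, groups) {
    w <- omega[groups$pair_id]
    ok <- is.finite(w)
    at <- tryCatch(one_way_anova(w[ok], groups$group[ok]),
                   error = function(e) NULL)
    data.frame(parameter = parameter, value = value,
               n_groups = length(unique(groups$group)),
               anova_F = if (is.null(at)) NA_real_ else at$F[1],
               anova_p = if (is.null(at)) NA_real_ else at$p[1],
               stringsAsFactors = FALSE)
  }
  rows <- c(
    lapply(heights, function(h) scan_one("height", h, cut_by_height(r$tree, h))),
    lapply(min_sizes, function(m) scan_one("min_size", m,
                                           cut_by_min_size(r$tree, m))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
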