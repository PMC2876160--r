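# Codon-level divergence estimation for duplicate gene pairs:
# global protein alignment -> codon back-translation -> counting estimator
# (synonymous/nonsynonymous site and difference counts with Jukes-Cantor
# multiple-hit correction).

.funcdiv_cache <- new.env(parent = emptyenv())

genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

blosum62_matrix <- function() {
  if (is.null(.funcdiv_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    # unknown residue X is scored 0 against everything
    m["X", ] <- 0L; m[, "X"] <- 0L
    .funcdiv_cache$blosum62 <- m
  }
  .funcdiv_cache$blosum62
}

#' Global protein alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' with BLOSUM62 scoring and affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`, end gaps included). The unknown residue `X`
#' is scored 0 against every residue.
#'
#' @param seq1,seq2 nonempty amino-acid strings (standard alphabet, `X`
#'   allowed).
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @return object of class `protein_alignment`: list with gapped strings
#'   `aln1`, `aln2` and the alignment `score`.
#' @export
global_protein_align <- function(seq1, seq2, gap_open = 10, gap_extend = 0.5) {
  for (s in list(seq1, seq2)) {
    if (!is.character(s) || length(s) != 1L || nchar(s) == 0L) {
      stopf("protein sequences must be nonempty strings")
    }
  }
  allowed <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
               "S","T","W","Y","V","X")
  for (nm in c("seq1", "seq2")) {
    s <- strsplit(get(nm), "")[[1]]
    bad <- which(!(s %in% allowed))
    if (length(bad)) {
      stopf("illegal residue '%s' at position %d of %s", s[bad[1]], bad[1], nm)
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  aln1 <- as.character(Biostrings::alignedPattern(pa))
  aln2 <- as.character(Biostrings::alignedSubject(pa))
  out <- list(aln1 = unname(aln1), aln2 = unname(aln2),
              score = Biostrings::score(pa))
  class(out) <- "protein_alignment"
  stopifnot(nchar(out$aln1) == nchar(out$aln2),
            gsub("-", "", out$aln1, fixed = TRUE) == seq1,
            gsub("-", "", out$aln2, fixed = TRUE) == seq2)
  out
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: length %d, score %.2f\n",
              nchar(x$aln1), x$score))
  invisible(x)
}

strip_terminal_stop <- function(cds) {
  if (nchar(cds) %% 3 == 0L && nchar(cds) >= 3L) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!is.na(genetic_code()[last]) && genetic_code()[last] == "*") {
      return(substr(cds, 1L, nchar(cds) - 3L))
    }
  }
  cds
}

split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3 != 0L) stopf("sequence length %d not a multiple of 3", n)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Expands each protein alignment column into a codon column: residues map
#' to their codons, protein gaps become `---`. Terminal stop codons on the
#' CDS inputs are stripped before validation. Each CDS must be exactly three
#' times its protein's length and translate to it codon by codon under the
#' standard genetic code; an internal stop or a translation mismatch is an
#' error naming the codon index.
#'
#' @param alignment a [global_protein_align()] result.
#' @param cds1,cds2 nucleotide strings for the two aligned proteins.
#' @return object of class `codon_alignment`: list with gapped nucleotide
#'   strings `nt1`, `nt2` (lengths a multiple of 3) and codon vectors
#'   `codons1`, `codons2` (gap codons as `"---"`).
#' @export
backtranslate_alignment <- function(alignment, cds1, cds2) {
  stopifnot(inherits(alignment, "protein_alignment"))
  prot <- list(gsub("-", "", alignment$aln1, fixed = TRUE),
               gsub("-", "", alignment$aln2, fixed = TRUE))
  cds <- list(toupper(strip_terminal_stop(cds1)),
              toupper(strip_terminal_stop(cds2)))
  codon_rows <- vector("list", 2L)
  for (k in 1:2) {
    if (nchar(cds[[k]]) != 3L * nchar(prot[[k]])) {
      stopf("cds%d length %d does not match protein length %d x 3",
            k, nchar(cds[[k]]), nchar(prot[[k]]))
    }
    codons <- split_codons(cds[[k]])
    aa <- translate_codons(codons)
    target <- strsplit(prot[[k]], "")[[1]]
    # ambiguous codons (with N etc.) translate to NA; they are tolerated
    # here and excluded later by the estimator
    known <- !is.na(aa)
    if (any(aa[known] == "*")) {
      stopf("internal stop codon at codon %d of cds%d", which(aa == "*")[1], k)
    }
    mismatch <- known & aa != target & target != "X"
    if (any(mismatch)) {
      stopf("cds%d translation disagrees with protein at codon %d",
            k, which(mismatch)[1])
    }
    codon_rows[[k]] <- codons
  }
  expand <- function(aln, codons) {
    cols <- strsplit(aln, "")[[1]]
    out <- character(length(cols)); i <- 0L
    for (j in seq_along(cols)) {
      if (cols[j] == "-") out[j] <- "---"
      else { i <- i + 1L; out[j] <- codons[i] }
    }
    out
  }
  c1 <- expand(alignment$aln1, codon_rows[[1]])
  c2 <- expand(alignment$aln2, codon_rows[[2]])
  out <- list(nt1 = paste(c1, collapse = ""), nt2 = paste(c2, collapse = ""),
              codons1 = c1, codons2 = c2)
  class(out) <- "codon_alignment"
  out
}

# --- NG86 counting tables -------------------------------------------------

# Fraction of the three possible single-base changes at each codon position
# that are synonymous; changes creating a stop codon count as nonsynonymous
# so that synonymous + nonsynonymous sites always total 3 per codon.
syn_site_table <- function() {
  if (!is.null(.funcdiv_cache$syn_sites)) return(.funcdiv_cache$syn_sites)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  sense <- sense_codons()
  tab <- setNames(numeric(length(sense)), sense)
  for (codon in sense) {
    s <- 0
    nt <- strsplit(codon, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, nt[pos])) {
        mut <- nt; mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (gc[mutc] != "*" && gc[mutc] == gc[codon]) s <- s + 1 / 3
      }
    }
    tab[codon] <- s
  }
  .funcdiv_cache$syn_sites <- tab
  tab
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons over all minimal substitution paths (orderings of the differing
# positions), each path weighted equally; paths passing through a stop
# codon are excluded (if all are blocked, all paths are used and the
# comparison flagged via the "stop_paths" attribute downstream).
codon_path_diffs <- function(c1, c2) {
  gc <- genetic_code()
  p1 <- strsplit(c1, "")[[1]]; p2 <- strsplit(c2, "")[[1]]
  diffpos <- which(p1 != p2)
  nd <- length(diffpos)
  if (nd == 0L) return(c(sd = 0, nd = 0, blocked = 0))
  perms <- if (nd == 1L) list(diffpos) else {
    if (nd == 2L) list(diffpos, rev(diffpos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(o) diffpos[o])
    }
  }
  walk <- function(order) {
    cur <- p1; sd <- 0; nd_ <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- p2[pos]
      a1 <- gc[paste(cur, collapse = "")]
      a2 <- gc[paste(nxt, collapse = "")]
      if (a2 == "*" || a1 == "*") return(NULL)   # path through a stop
      if (a1 == a2) sd <- sd + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd, nd_)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, logical(1))
  blocked <- 0
  if (!any(ok)) {
    # every path crosses a stop; fall back to unrestricted averaging
    blocked <- 1
    res <- lapply(perms, function(order) {
      cur <- p1; sd <- 0; nd_ <- 0
      for (pos in order) {
        nxt <- cur; nxt[pos] <- p2[pos]
        a1 <- gc[paste(cur, collapse = "")]; a2 <- gc[paste(nxt, collapse = "")]
        if (!is.na(a1) && !is.na(a2) && a1 == a2 && a1 != "*") sd <- sd + 1
        else nd_ <- nd_ + 1
        cur <- nxt
      }
      c(sd, nd_)
    })
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(sd = mean(m[, 1]), nd = mean(m[, 2]), blocked = blocked)
}

codon_pair_table <- function() {
  if (!is.null(.funcdiv_cache$pair_tab)) return(.funcdiv_cache$pair_tab)
  sense <- sense_codons()
  key <- function(a, b) paste(a, b)
  sd <- new.env(parent = emptyenv())
  .funcdiv_cache$pair_tab <- sd
  sd
}

codon_pair_diffs <- function(c1, c2) {
  tab <- codon_pair_table()
  k <- paste(c1, c2)
  v <- tab[[k]]
  if (is.null(v)) {
    v <- codon_path_diffs(c1, c2)
    assign(k, v, envir = tab)
    assign(paste(c2, c1), v, envir = tab)   # symmetric
  }
  v
}

#' Counting-method divergence estimate from a codon alignment
#'
#' Nei-Gojobori style estimator. Synonymous site counts per codon are the
#' summed fractions of single-base changes that are synonymous (stop-creating
#' changes count as nonsynonymous), averaged between the two rows over the
#' compared codons; `N = 3L - S`. Differences between unequal codons are
#' partitioned into synonymous and nonsynonymous by averaging over all
#' minimal substitution paths with equal weights, excluding paths through
#' stop codons. Proportions `pS = Sd/S`, `pN = Nd/N` receive the
#' Jukes-Cantor correction `d = -(3/4) ln(1 - (4/3) p)`. Codon columns with
#' gaps or ambiguous bases are excluded pairwise.
#'
#' @param alignment a [backtranslate_alignment()] result (or any list with
#'   `codons1`, `codons2`).
#' @return object of class `divergence_estimate`: list with `dN`, `dS`,
#'   `omega`, site counts `N`, `S`, difference counts `Nd`, `Sd`, the number
#'   of compared codons `L`, and `flags` (character vector; may contain
#'   `"omega_undefined"`, `"saturated_dS"`, `"saturated_dN"`,
#'   `"stop_blocked_paths"`).
#' @export
ng86_divergence <- function(alignment) {
  c1 <- alignment$codons1; c2 <- alignment$codons2
  stopifnot(length(c1) == length(c2))
  sense <- sense_codons()
  ok <- c1 %in% sense & c2 %in% sense
  if (!any(ok)) stopf("no comparable codon columns (all gapped or ambiguous)")
  c1 <- c1[ok]; c2 <- c2[ok]
  L <- length(c1)
  st <- syn_site_table()
  S <- (sum(st[c1]) + sum(st[c2])) / 2
  N <- 3 * L - S
  Sd <- 0; Nd <- 0; blocked <- 0
  neq <- which(c1 != c2)
  for (i in neq) {
    v <- codon_pair_diffs(c1[i], c2[i])
    Sd <- Sd + v[["sd"]]; Nd <- Nd + v[["nd"]]; blocked <- blocked + v[["blocked"]]
  }
  flags <- character(0)
  if (blocked > 0) flags <- c(flags, "stop_blocked_paths")
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    if (p == 0) return(0)
    -0.75 * log(1 - 4 * p / 3)
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jc(pS); dN <- jc(pN)
  if (is.na(dS)) flags <- c(flags, "saturated_dS")
  if (is.na(dN)) flags <- c(flags, "saturated_dN")
  omega <- NA_real_
  if (!is.na(dN) && !is.na(dS)) {
    if (dS > 0) omega <- dN / dS else flags <- c(flags, "omega_undefined")
  }
  structure(list(dN = dN, dS = dS, omega = omega, N = N, S = S,
                 Nd = Nd, Sd = Sd, L = L, flags = flags),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("divergence_estimate: dN=%.4f dS=%.4f omega=%s (L=%d)%s\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega), x$L,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Per-pair divergence from protein and CDS sequences
#'
#' Convenience wrapper running alignment, back-translation and the counting
#' estimator for a table of pairs.
#'
#' @param pairs data.frame with `gene1`, `gene2` columns.
#' @param proteins,cds named character vectors of sequences indexed by gene
#'   identifier.
#' @return data.frame with one row per pair: gene1, gene2, pair_id, dN, dS,
#'   omega, N, S, Nd, Sd, flags (comma-joined).
#' @export
pair_divergence <- function(pairs, proteins, cds) {
  missing <- setdiff(c(pairs$gene1, pairs$gene2), names(proteins))
  if (length(missing)) stopf("no protein sequence for gene %s", missing[1])
  missing <- setdiff(c(pairs$gene1, pairs$gene2), names(cds))
  if (length(missing)) stopf("no CDS for gene %s", missing[1])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    aln <- global_protein_align(proteins[[g1]], proteins[[g2]])
    ca <- backtranslate_alignment(aln, cds[[g1]], cds[[g2]])
    est <- ng86_divergence(ca)
    data.frame(gene1 = g1, gene2 = g2, pair_id = pair_key(g1, g2),
               dN = est$dN, dS = est$dS, omega = est$omega,
               N = est$N, S = est$S, Nd = est$Nd, Sd = est$Sd,
               flags = paste(est$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Import an externally computed divergence table
#'
#' Accepts dN/dS values computed outside the package (e.g. by a
#' maximum-likelihood codon model) so that real-data runs are not tied to
#' the built-in counting estimator. Pairs are canonically ordered, omega is
#' derived, and rows with `dS <= 0` are flagged.
#'
#' @param path TSV path or character vector of lines with columns
#'   `gene1`, `gene2`, `dN`, `dS`.
#' @return data.frame with gene1, gene2, pair_id, dN, dS, omega, flags.
#' @export
import_divergence_table <- function(path) {
  df <- if (length(path) == 1L && file.exists(path)) read_tsv(path) else {
    read.delim(text = paste(path, collapse = "\n"), sep = "\t",
               stringsAsFactors = FALSE)
  }
  need <- c("gene1", "gene2", "dN", "dS")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("divergence table missing column: %s", miss[1])
  for (col in c("dN", "dS")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) stopf("non-numeric %s value in row %d", col, bad[1])
    df[[col]] <- v
  }
  swap <- df$gene1 > df$gene2
  tmp <- df$gene1[swap]; df$gene1[swap] <- df$gene2[swap]; df$gene2[swap] <- tmp
  df$pair_id <- paste(df$gene1, df$gene2, sep = "|")
  df$omega <- ifelse(df$dS > 0, df$dN / df$dS, NA_real_)
  df$flags <- ifelse(df$dS > 0, "", "omega_undefined")
  df[c("gene1", "gene2", "pair_id", "dN", "dS", "omega", "flags")]
}
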