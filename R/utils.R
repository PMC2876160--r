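#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov anova lm cor.test pf ptukey qtukey phyper rnorm runif
#'   setNames cophenetic as.dist cutree deviance df.residual p.adjust sd var
#'   complete.cases
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Canonical unordered pair identifier
#'
#' Orders the two gene identifiers lexicographically and joins them, so the
#' same physical duplicate pair always maps to one key regardless of input
#' order.
#'
#' @param gene1,gene2 character vectors of gene identifiers (recycled
#'   together).
#' @return character vector of canonical pair keys.
#' @export
pair_key <- function(gene1, gene2) {
  swap <- gene1 > gene2
  a <- ifelse(swap, gene2, gene1)
  b <- ifelse(swap, gene1, gene2)
  paste(a, b, sep = "|")
}

# Deterministic 32-bit FNV-1a hash of a character scalar; used to stamp
# output files with a configuration fingerprint without a digest dependency.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor into the low 16 bits (bytes never touch the high half)
    lo <- h %% 65536
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply in split halves to stay within exact doubles
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a32(paste(deparse(config, control = "all"), collapse = "\n"))
}

# Writes a data.frame as TSV with a provenance comment header. Numeric
# columns are formatted with full precision so identical inputs give
# byte-identical files.
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (line in provenance) writeLines(paste0("# ", line), con)
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
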