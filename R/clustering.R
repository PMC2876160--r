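# Ward hierarchical clustering of duplicate pairs by functional similarity,
# and the two tree cuts used to define functional groups.

#' Convert a similarity matrix to a distance matrix
#'
#' `d(i,j) = 1 - s(i,j)` with the zero diagonal preserved. Input must be
#' symmetric within 1e-9 with a unit diagonal and entries in `[0, 1]`.
#'
#' @param sim a [profile_similarity_matrix()] result, or a plain numeric
#'   matrix with the same properties.
#' @return symmetric numeric matrix with zero diagonal, dimnames preserved.
#' @export
similarity_to_distance <- function(sim) {
  m <- if (inherits(sim, "profile_similarity")) sim$matrix else as.matrix(sim)
  if (nrow(m) != ncol(m)) stopf("similarity matrix must be square")
  if (max(abs(m - t(m))) > 1e-9) stopf("similarity matrix is asymmetric")
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stopf("similarity entries outside [0, 1]")
  }
  if (max(abs(diag(m) - 1)) > 1e-9) stopf("similarity diagonal must be 1")
  d <- 1 - m
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative merging under Ward's minimum-variance criterion, computed
#' by Lance-Williams updates on `d^2 / 2` so that each merge height equals
#' the increase in within-cluster sum of squares (two singletons at distance
#' `d` merge at height `d^2 / 2`). Ties are broken deterministically by the
#' smallest, then second-smallest, active cluster index. The naive O(n^3)
#' scan is used: problem sizes here are a few thousand leaves at most.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal (from
#'   [similarity_to_distance()]); rownames are the leaf labels.
#' @return an object of classes `funcdiv_dendrogram` and `hclust` (merge,
#'   height, order, labels), usable with [stats::cutree()] and
#'   [stats::cophenetic()].
#' @export
ward_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stopf("need at least two leaves")
  if (!all(is.finite(d))) stopf("non-finite distance entries")
  if (max(abs(d - t(d))) > 1e-9) stopf("distance matrix is asymmetric")
  labels <- rownames(d) %||% as.character(seq_len(n))

  e <- d^2 / 2                       # Ward merge cost between singletons
  size <- rep(1L, n)
  # cluster id bookkeeping in hclust convention: negatives are leaves,
  # positives are merge step numbers
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- c(NA_integer_, NA_integer_); best_v <- Inf
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[(ii + 1L):length(act)]
      vals <- e[i, js]
      jbest <- which.min(vals)       # first minimum: smallest second index
      if (vals[jbest] < best_v) {
        best_v <- vals[jbest]
        best <- c(i, js[jbest])
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_v
    ni <- size[i]; nj <- size[j]
    ks <- act[act != i & act != j]
    if (length(ks)) {
      nk <- size[ks]
      e[i, ks] <- ((ni + nk) * e[i, ks] + (nj + nk) * e[j, ks] - nk * best_v) /
        (ni + nj + nk)
      e[ks, i] <- e[i, ks]
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    id[i] <- step
  }

  order <- dendrogram_order(merge)
  out <- list(merge = merge, height = height, order = order,
              labels = labels, method = "ward", call = match.call(),
              dist.method = "1 - similarity")
  class(out) <- c("funcdiv_dendrogram", "hclust")
  out
}

# leaf ordering by left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  n <- nrow(merge) + 1L
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

# leaf index sets per internal node
node_members <- function(tree) {
  n1 <- nrow(tree$merge)
  members <- vector("list", n1)
  for (k in seq_len(n1)) {
    kids <- tree$merge[k, ]
    members[[k]] <- unlist(lapply(kids, function(x) {
      if (x < 0L) -x else members[[x]]
    }))
  }
  members
}

group_frame <- function(tree, assignment, heights) {
  data.frame(pair_id = tree$labels,
             group = assignment,
             height = heights[assignment],
             stringsAsFactors = FALSE)
}

#' Cut a dendrogram into groups with a minimum size
#'
#' Bottom-up cut: each leaf belongs to its lowest ancestor whose subtree
#' reaches `min_size` leaves. Leaves sharing that node, minus leaves already
#' claimed by a qualifying descendant, form a candidate group. A candidate
#' still below `min_size` (stragglers above an already-claimed core) is
#' absorbed into the most recently emitted group inside that node's subtree
#' — the topologically nearest established group — rather than carried to
#' the root; such absorptions are counted in the `residual_absorbed`
#' attribute. The result always partitions the leaves with every group of at
#' least `min_size` members whenever the tree has that many leaves.
#'
#' @param tree a [ward_linkage()] dendrogram.
#' @param min_size minimum group size (default 20).
#' @return data.frame with columns `pair_id`, `group` (integer labels in
#'   order of emission), `height` (defining node height; 0 for singleton
#'   groups at `min_size` 1). Attribute `sizes` gives group sizes.
#' @export
cut_by_min_size <- function(tree, min_size = 20L) {
  stopifnot(inherits(tree, "hclust"), min_size >= 1L)
  n <- length(tree$labels)
  if (min_size > n) {
    warnf("min_size %d exceeds leaf count %d: returning a single group",
          min_size, n)
    return(group_frame(tree, rep(1L, n), c(`1` = max(tree$height))))
  }
  if (min_size == 1L) {
    g <- seq_len(n)
    return(data.frame(pair_id = tree$labels, group = g, height = 0,
                      stringsAsFactors = FALSE))
  }
  members <- node_members(tree)
  claimed <- rep(FALSE, n)
  assignment <- rep(NA_integer_, n)
  # most recently emitted group inside each node's subtree (0 = none)
  last_group <- integer(nrow(tree$merge))
  last_step <- integer(nrow(tree$merge))   # merge step of that emission
  gheights <- numeric(0)
  next_group <- 0L
  absorbed <- 0L
  for (k in seq_along(members)) {       # merge steps are bottom-up
    kids <- tree$merge[k, ]
    inherited <- c(0L, 0L); inh_step <- c(0L, 0L)
    for (c in 1:2) {
      if (kids[c] > 0L) {
        inherited[c] <- last_group[kids[c]]
        inh_step[c] <- last_step[kids[c]]
      }
    }
    pick <- which.max(inh_step)
    last_group[k] <- inherited[pick]
    last_step[k] <- inh_step[pick]
    mem <- members[[k]]
    if (length(mem) < min_size) next
    cand <- mem[!claimed[mem]]
    if (length(cand) >= min_size) {
      next_group <- next_group + 1L
      assignment[cand] <- next_group
      gheights[next_group] <- tree$height[k]
      claimed[cand] <- TRUE
      last_group[k] <- next_group
      last_step[k] <- k
    } else if (length(cand) > 0L) {
      # stragglers above a claimed core: absorb into the nearest
      # (most recently) emitted group of this subtree, which exists
      # because the node qualifies yet some of its leaves are claimed
      assignment[cand] <- last_group[k]
      claimed[cand] <- TRUE
      absorbed <- absorbed + length(cand)
    }
  }
  out <- group_frame(tree, assignment, gheights)
  attr(out, "sizes") <- table(out$group)
  attr(out, "residual_absorbed") <- absorbed
  out
}

#' Cut a dendrogram at a fixed height
#'
#' Groups are the maximal subtrees whose merge height is at most `h`;
#' singleton groups are allowed.
#'
#' @param tree a [ward_linkage()] dendrogram.
#' @param h non-negative cut height.
#' @return data.frame with columns `pair_id`, `group`, `height` (highest
#'   merge inside the group; 0 for singletons).
#' @export
cut_by_height <- function(tree, h) {
  stopifnot(inherits(tree, "hclust"), h >= 0)
  cl <- stats::cutree(tree, h = h)
  members <- node_members(tree)
  gh <- setNames(rep(0, length(unique(cl))), sort(unique(cl)))
  for (k in seq_along(members)) {
    if (tree$height[k] <= h) {
      g <- unique(cl[members[[k]]])
      stopifnot(length(g) == 1L)
      gh[as.character(g)] <- max(gh[as.character(g)], tree$height[k])
    }
  }
  data.frame(pair_id = tree$labels, group = unname(cl),
             height = unname(gh[as.character(cl)]),
             stringsAsFactors = FALSE)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are the height differences between a node and its parent,
#' so leaf-to-root path lengths equal merge heights.
#'
#' @param tree a [ward_linkage()] dendrogram.
#' @return single Newick string (terminated by `;`).
#' @export
dendrogram_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  fmt <- function(node, parent_h) {
    if (node < 0L) {
      sprintf("%s:%.6g", tree$labels[-node], parent_h)
    } else {
      h <- tree$height[node]
      sprintf("(%s,%s):%.6g",
              fmt(tree$merge[node, 1L], h), fmt(tree$merge[node, 2L], h),
              parent_h - h)
    }
  }
  root <- nrow(tree$merge)
  paste0("(", fmt(tree$merge[root, 1L], tree$height[root]), ",",
         fmt(tree$merge[root, 2L], tree$height[root]), ");")
}
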