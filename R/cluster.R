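#' Two-fold change filter
#'
#' Keeps proteins whose abundance departs from their own mean by at least
#' two-fold (|log2 ratio| >= threshold, inclusive) in at least one time
#' point. Operates on row-mean-normalized values.
#'
#' @param x an [AbundanceExperiment] with state `"row_mean_normalized"` or
#'   a numeric matrix of log2 ratios.
#' @param threshold minimum absolute log2 ratio (default 1 = two-fold).
#' @return The retained subset, same class as the input.
#' @export
twofoldFilter <- function(x, threshold = 1) {
  a <- if (is(x, "AbundanceExperiment")) abundanceValues(x) else x
  mx <- suppressWarnings(apply(abs(a), 1, max, na.rm = TRUE))
  keep <- is.finite(mx) & mx >= threshold
  if (is(x, "AbundanceExperiment")) x[keep, ] else a[keep, , drop = FALSE]
}

#' Average-linkage hierarchical clustering of protein trajectories
#'
#' Agglomerative clustering of protein rows under correlation distance
#' (`1 - Pearson r`, the conventional metric for expression profiles) or
#' Euclidean distance, with average linkage. Rows with zero variance have
#' no defined correlation and are excluded with a warning.
#'
#' @param x an [AbundanceExperiment] or numeric matrix (proteins in rows).
#' @param distance `"pearson"` (default) or `"euclidean"`.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `hclust` with protein ids as labels.
#' @export
hclusterProteins <- function(x, distance = c("pearson", "euclidean"),
                             linkage = "average") {
  distance <- match.arg(distance)
  a <- if (is(x, "AbundanceExperiment")) abundanceValues(x) else x
  stopIfNot(nrow(a) >= 2, "need at least 2 rows to cluster")
  stopIfNot(all(rowSums(!is.na(a)) > 0), "all-missing rows are not allowed")
  if (distance == "pearson") {
    v <- apply(a, 1, function(r) var(r[!is.na(r)]))
    if (any(v == 0 | is.na(v))) {
      warning(sum(v == 0 | is.na(v)),
              " zero-variance row(s) excluded from clustering")
      a <- a[!(v == 0 | is.na(v)), , drop = FALSE]
    }
    r <- suppressWarnings(cor(t(a), use = "pairwise.complete.obs"))
    stopIfNot(!anyNA(r), "undefined pairwise correlations; filter rows first")
    d <- as.dist(1 - r)
  } else {
    d <- dist(a)
    stopIfNot(!anyNA(d), "undefined pairwise distances; filter rows first")
  }
  hclust(d, method = linkage)
}

# leaves (label indices) under a merge-tree node; node > 0 indexes a merge
# row, node < 0 a leaf
leavesUnder <- function(merge, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    if (nd < 0) out <- c(out, -nd)
    else stack <- c(stack, merge[nd, ])
  }
  out
}

# nodes reached `depth` levels below the root (leaves close early)
nodesAtDepth <- function(merge, depth) {
  root <- nrow(merge)
  level <- root
  for (i in seq_len(depth)) {
    nxt <- integer(0)
    for (nd in level)
      nxt <- c(nxt, if (nd > 0) merge[nd, ] else nd)
    level <- nxt
  }
  level
}

#' Extract clusters at a dendrogram node depth
#'
#' Descends a fixed number of levels from the root of the merge tree (root
#' = depth 0); every node reached at that depth, or leaf reached earlier,
#' is one cluster. Clusters larger than `subsetThreshold` are re-cut at
#' `subsetDepth` (counted from the root) and reported as sub-clusters
#' (labels `"k.1"`, `"k.2"`, ...). This is the cluster-extraction rule that
#' yields, e.g., eight clusters at node depth three on a near-balanced
#' trajectory tree, with large clusters subset at node depth five.
#'
#' @param tree an `hclust` object (see [hclusterProteins()]).
#' @param depth node depth of the main cut (default 3).
#' @param subsetThreshold cluster size above which the cluster is re-cut
#'   (default 500); `Inf` disables subsetting.
#' @param subsetDepth node depth of the re-cut, relative to the root
#'   (default 5).
#' @return data.frame with columns `protein`, `cluster` (label, numbered in
#'   dendrogram order), `nodeDepth` (depth the cluster's node was reached
#'   at). Labels partition the clustered proteins; the cut is
#'   deterministic.
#' @export
cutByNodeDepth <- function(tree, depth = 3, subsetThreshold = 500,
                           subsetDepth = 5) {
  stopIfNot(inherits(tree, "hclust"), "tree must be an hclust object")
  checkScalarNumber(depth, "depth", lower = 0, integer = TRUE)
  merge <- tree$merge
  labels <- tree$labels %||% as.character(seq_len(nrow(merge) + 1))
  nodes <- nodesAtDepth(merge, depth)
  memb <- lapply(nodes, leavesUnder, merge = merge)
  nodeDepth <- rep(depth, length(nodes))
  # order clusters along the dendrogram
  ord <- order(vapply(memb, function(m) min(match(m, tree$order)), numeric(1)))
  nodes <- nodes[ord]; memb <- memb[ord]
  out <- data.frame(protein = character(0), cluster = character(0),
                    nodeDepth = integer(0))
  subNodes <- NULL
  for (i in seq_along(nodes)) {
    if (length(memb[[i]]) > subsetThreshold && subsetDepth > depth) {
      if (is.null(subNodes)) subNodes <- nodesAtDepth(merge, subsetDepth)
      inside <- subNodes[vapply(subNodes, function(nd)
        all(leavesUnder(merge, nd) %in% memb[[i]]), logical(1))]
      sm <- lapply(inside, leavesUnder, merge = merge)
      sord <- order(vapply(sm, function(m) min(match(m, tree$order)),
                           numeric(1)))
      sm <- sm[sord]
      for (j in seq_along(sm))
        out <- rbind(out, data.frame(protein = labels[sm[[j]]],
                                     cluster = paste0(i, ".", j),
                                     nodeDepth = subsetDepth))
    } else {
      out <- rbind(out, data.frame(protein = labels[memb[[i]]],
                                   cluster = as.character(i),
                                   nodeDepth = depth))
    }
  }
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test for one protein set
#'
#' For every term, tests whether the cluster contains more term members
#' than expected by drawing `|cluster|` proteins from the universe without
#' replacement (one-sided upper-tail hypergeometric), with
#' Benjamini-Hochberg adjustment across terms. The universe defaults to the
#' detected proteome, the standard background for over-representation
#' analysis.
#'
#' @param cluster character vector of protein ids (must be contained in
#'   `universe`).
#' @param annotations named list mapping terms to protein-id vectors (e.g.
#'   from [readGmt()]); terms are intersected with the universe.
#' @param universe character vector of background protein ids.
#' @param fdr FDR level for the `enriched` flag (default 0.05).
#' @return data.frame with columns `term`, `overlap`, `clusterSize`,
#'   `termSize`, `universeSize`, `p`, `q`, `enriched`, sorted by p.
#' @export
enrichTerms <- function(cluster, annotations, universe, fdr = 0.05) {
  universe <- unique(universe)
  stopIfNot(length(universe) > 0, "empty universe")
  cluster <- unique(cluster)
  stopIfNot(all(cluster %in% universe), "cluster must be a subset of universe")
  N <- length(universe); n <- length(cluster)
  res <- lapply(names(annotations), function(tm) {
    term <- intersect(unique(annotations[[tm]]), universe)
    K <- length(term)
    k <- length(intersect(term, cluster))
    p <- if (K == 0) NA_real_ else phyper(k - 1, K, N - K, n,
                                          lower.tail = FALSE)
    data.frame(term = tm, overlap = k, clusterSize = n, termSize = K,
               universeSize = N, p = p)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out$enriched <- !is.na(out$q) & out$q < fdr
  out[order(out$p), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: tab-separated lines `name`, `description`,
#'   members...
#' @return Named list of character member vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stopIfNot(all(lengths(parts) >= 3), "GMT lines need name, description and members")
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[`, character(1), 1))
}

#' Export a dendrogram as Newick
#'
#' @param tree an `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @importFrom ape as.phylo write.tree
#' @export
writeNewick <- function(tree, path) {
  write.tree(as.phylo(tree), file = path)
  invisible(path)
}
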