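#' Presence/absence matrix of mutations across sectors
#'
#' A mutation is called present in a sector when its alternate read count
#' reaches `min_alt` (a Mutect-like detection rule; the default of 3
#' supporting reads mimics sequencing detection limits). Mutations detected
#' in no sector are dropped with a warning.
#'
#' @param mt A [mutation_table()], or a ready binary matrix (sectors in
#'   columns are transposed to the sectors-in-rows orientation used here).
#' @param min_alt Minimum alt reads for presence (default 3).
#' @return Binary matrix, sectors x mutations, of class `presence_matrix`.
#' @export
presence_matrix <- function(mt, min_alt = 3L) {
  if (inherits(mt, "mutation_table")) {
    if (!nrow(mt$variants)) stop("mutation table is empty")
    m <- t(mt$alt_count >= min_alt) * 1L
    rownames(m) <- mt$sectors
    colnames(m) <- mt$variants$mutation_id
  } else {
    m <- as.matrix(mt) * 1L
    if (!all(m %in% c(0L, 1L))) stop("presence matrix must be binary")
  }
  empty <- colSums(m) == 0L
  if (any(empty)) {
    warning(sum(empty), " mutation(s) detected in no sector were dropped")
    m <- m[, !empty, drop = FALSE]
  }
  if (!ncol(m)) stop("no mutation detected in any sector")
  structure(m, class = c("presence_matrix", class(m)))
}

#' Pairwise Hamming distances between sectors
#'
#' `d(i, j)` is the unnormalized count of mutations whose presence differs
#' between sectors i and j (counts, not proportions, so branch lengths are
#' in mutation units).
#'
#' @param pm A [presence_matrix()] (sectors x mutations, binary).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
hamming_distances <- function(pm) {
  m <- unclass(pm)
  if (nrow(m) < 2L) stop("need at least 2 sectors")
  # |xi - xj| summed over columns == xi(1-xj) + xj(1-xi) summed
  ones <- tcrossprod(m, 1 - m)
  d <- ones + t(ones)
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative estimated
#' branch lengths are clamped to zero and the number clamped is recorded in
#' the `"clamped"` attribute. The result is unrooted.
#'
#' @param dm Symmetric distance matrix (or `dist`) with sector labels.
#' @return An unrooted `phylo` tree; leaf labels are the sector ids.
#' @export
nj_tree <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("S", seq_len(n))
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    warning("only 2 taxa: returning the trivial single-edge tree")
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2L),
                         edge.length = rep(d[1L, 2L] / 2, 2L),
                         tip.label = rownames(d), Nnode = 1L),
                    class = "phylo")
    attr(tr, "clamped") <- 0L
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

# star tree used for degenerate bootstrap replicates (all sectors identical)
star_tree <- function(labels) {
  n <- length(labels)
  tr <- ape::stree(n)
  tr$tip.label <- labels
  tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' Mutation-resampling bootstrap and majority-rule consensus
#'
#' Each replicate resamples mutation columns of the presence matrix with
#' replacement, recomputes Hamming distances and the neighbour-joining tree;
#' split supports are the fraction of replicate trees containing each
#' bipartition, and the consensus keeps splits above the majority threshold.
#' When the number of mutations m satisfies `m^m <= max_exhaustive` the
#' bootstrap distribution is enumerated exactly over all `m^m` equally
#' likely resamples instead of sampled (removing seed sensitivity from
#' small cases).
#'
#' @param pm A [presence_matrix()] with at least 3 sectors.
#' @param n_replicates Number of bootstrap replicates (default 100, the
#'   field's convention).
#' @param seed Integer seed for the resampling stream.
#' @param method `"auto"` (default: exhaustive when cheap), `"resample"`, or
#'   `"exhaustive"`.
#' @param max_exhaustive Enumeration budget for `"auto"`/`"exhaustive"`.
#' @param consensus_p Majority-rule threshold (splits with support strictly
#'   above this fraction enter the consensus; default 0.5).
#' @return Object of class `sector_boot`: list with `consensus` (a `phylo`
#'   whose internal node labels hold supports in `[0, 1]`), `supports`
#'   (data.frame: one row per observed split with its support), `trees`
#'   (the replicate trees), `n_replicates`, and `method`.
#' @export
bootstrap_consensus <- function(pm, n_replicates = 100L, seed = 1L,
                                method = c("auto", "resample", "exhaustive"),
                                max_exhaustive = 4000L, consensus_p = 0.5) {
  method <- match.arg(method)
  m <- unclass(pm)
  if (nrow(m) < 3L) stop("need at least 3 sectors")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  nmut <- ncol(m)
  exhaustive <- switch(method,
    exhaustive = TRUE,
    resample = FALSE,
    auto = nmut^nmut <= max_exhaustive)
  if (exhaustive && nmut^nmut > max_exhaustive)
    stop("exhaustive enumeration needs m^m <= max_exhaustive (m = ", nmut, ")")

  rep_tree <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    d <- hamming_distances(sub)
    if (all(d == 0)) star_tree(rownames(m)) else nj_tree(d)
  }
  if (exhaustive) {
    idx <- as.matrix(expand.grid(rep(list(seq_len(nmut)), nmut)))
    trees <- apply(idx, 1L, rep_tree, simplify = FALSE)
  } else {
    set.seed(derive_seed(seed, "bootstrap"))
    trees <- lapply(seq_len(n_replicates), function(i)
      rep_tree(sample.int(nmut, nmut, replace = TRUE)))
  }
  class(trees) <- "multiPhylo"
  nrep <- length(trees)

  pp <- ape::prop.part(trees)
  labs <- attr(pp, "labels")
  split_key <- function(tips) {
    # canonical key: the side not containing the first label, sorted
    side <- sort(labs[tips])
    if (labs[1L] %in% side) side <- sort(setdiff(labs, side))
    paste(side, collapse = "|")
  }
  keys <- vapply(pp, split_key, "")
  counts <- tapply(attr(pp, "number"), keys, sum)  # same unrooted split can
  # surface as either rooted clade across replicates; sum the two spellings
  sizes <- lengths(strsplit(names(counts), "|", fixed = TRUE))
  supports <- data.frame(split = names(counts), size = sizes,
                         support = as.numeric(counts) / nrep,
                         stringsAsFactors = FALSE)
  # keep non-trivial bipartitions only (both sides of size >= 2)
  supports <- supports[supports$size >= 2L & supports$size <= length(labs) - 2L, ,
                       drop = FALSE]
  supports <- supports[order(-supports$support, supports$split), ]
  rownames(supports) <- NULL

  cons <- ape::consensus(trees, p = consensus_p, check.labels = TRUE)
  nodefreq <- ape::prop.clades(cons, part = pp, rooted = FALSE)
  nodefreq[is.na(nodefreq)] <- 0
  cons$node.label <- formatC(nodefreq / nrep, digits = 3, format = "g")
  structure(list(consensus = cons, supports = supports, trees = trees,
                 n_replicates = nrep,
                 method = if (exhaustive) "exhaustive" else "resample"),
            class = "sector_boot")
}

#' @export
print.sector_boot <- function(x, ...) {
  cat("Bootstrap consensus over ", x$n_replicates, " replicates (",
      x$method, ")\n", sep = "")
  cat("Non-trivial splits observed:\n")
  print(utils::head(x$supports, 10L))
  invisible(x)
}

#' @export
plot.sector_boot <- function(x, ...) {
  ape::plot.phylo(x$consensus, ...)
  ape::nodelabels(x$consensus$node.label, frame = "none", adj = c(1.1, -0.3))
  invisible(x)
}

#' Bootstrap support of one bipartition
#'
#' @param boot A [bootstrap_consensus()] result.
#' @param tips Character vector: the sector ids on one side of the split.
#' @return Support in `[0, 1]` (0 if the split was never observed).
#' @export
split_support <- function(boot, tips) {
  labs <- boot$consensus$tip.label
  if (!all(tips %in% labs)) stop("unknown sector id in tips")
  side <- sort(tips)
  if (labs[1L] %in% side) side <- sort(setdiff(labs, side))
  key <- paste(side, collapse = "|")
  hit <- boot$supports$support[boot$supports$split == key]
  if (length(hit)) hit[1L] else 0
}

#' Write a tree to a newick file
#'
#' Branch lengths and support labels (internal node labels) survive a
#' round-trip through [read_tree()].
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path Path to a newick file.
#' @return A `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.tree(path)
}
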