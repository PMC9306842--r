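#' @importFrom ape read.tree read.nexus write.tree is.rooted Ntip
#'   node.depth.edgelength keep.tip
NULL

#' Node heights above the tips
#'
#' Heights are measured from the tips (tips at 0) towards the root, the
#' scale on which MCC-tree tools report node heights and on which all GMYC
#' thresholds in this package are expressed.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, indexed like `ape` node
#'   numbers (tips first).
#' @export
node_heights <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

#' Validate and canonicalise an ultrametric tree
#'
#' Checks rootedness and ultrametricity within a tolerance, snaps tips to
#' exactly height 0, and breaks tied internal node heights (including
#' zero-length internal branches) by a deterministic tiny jitter so that
#' all waiting times in the branching schedule are strictly positive and
#' event order is reproducible.
#'
#' Ties are ordered by (number of descendant tips, smallest descendant tip
#' label): a parent always has more descendants than its child, so it is
#' jittered further from the tips and strict parent-above-child ordering is
#' restored.
#'
#' @param tree an `ape::phylo`.
#' @param epsilon ultrametricity tolerance as a fraction of tree depth
#'   (default `1e-6`).
#' @param delta jitter applied to tied heights, as a fraction of depth.
#' @return the canonicalised `phylo`, with attribute `"heights"`.
#' @export
as_ultrametric <- function(tree, epsilon = 1e-6, delta = 1e-9) {
  if (!inherits(tree, "phylo"))
    stop_gmyc("expected an ape 'phylo' tree", class = "validation_error")
  if (is.null(tree$edge.length))
    stop_gmyc("tree has no branch lengths", class = "validation_error")
  if (!ape::is.rooted(tree))
    stop_gmyc("tree is not rooted", class = "validation_error")
  ntip <- ape::Ntip(tree)
  if (ntip < 2L)
    stop_gmyc("tree must have at least 2 tips", class = "validation_error")
  if (anyDuplicated(tree$tip.label))
    stop_gmyc("duplicate tip labels", class = "validation_error")
  if (!ape::is.binary(tree))
    stop_gmyc("tree must be fully bifurcating (use ape::multi2di first)",
              class = "validation_error")
  h <- node_heights(tree)
  depth <- max(h)
  tip_dev <- abs(h[seq_len(ntip)])
  if (max(tip_dev) > epsilon * depth) {
    worst <- which.max(tip_dev)
    stop_gmyc("tree is not ultrametric: tip '", tree$tip.label[worst],
              "' deviates by ", format(tip_dev[worst]),
              " (tolerance ", format(epsilon * depth), ")",
              class = "ultrametric_error")
  }
  # snap tips to exactly 0 by absorbing the deviation into terminal edges
  term <- tree$edge[, 2] <= ntip
  tree$edge.length[term] <- tree$edge.length[term] + h[tree$edge[term, 2]]
  h[seq_len(ntip)] <- 0

  # deterministic jitter of tied internal node heights
  int_idx <- (ntip + 1L):(ntip + tree$Nnode)
  hi <- h[int_idx]
  if (anyDuplicated(signif(hi, 12))) {
    ndesc <- sapply(int_idx, function(v) length(tips_under(tree, v)))
    minlab <- sapply(int_idx, function(v) min(tree$tip.label[tips_under(tree, v)]))
    key <- order(hi, ndesc, minlab)
    hs <- hi[key]
    dj <- delta * depth
    for (i in seq_along(hs)[-1]) {
      if (hs[i] <= hs[i - 1]) hs[i] <- hs[i - 1] + dj
    }
    hi[key] <- hs
    h[int_idx] <- hi
    # rebuild edge lengths from adjusted heights
    tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
    if (any(tree$edge.length <= 0))
      stop_gmyc("could not resolve tied node heights", class = "validation_error")
  }
  attr(tree, "heights") <- h
  tree
}

# tip indices under node v (v may itself be a tip)
tips_under <- function(tree, v) {
  ntip <- ape::Ntip(tree)
  if (v <= ntip) return(v)
  out <- integer(0)
  stack <- v
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    u <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(u)]]
    tips <- kids[kids <= ntip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Read ultrametric trees from newick or NEXUS files
#'
#' NEXUS translate tables are honoured by the underlying `ape` reader.
#' Every tree is validated with [as_ultrametric()]. MCC-tree files contain
#' a single tree; posterior files may contain many, so the caller chooses.
#'
#' @param path file path.
#' @param format `"newick"` or `"nexus"`.
#' @param epsilon ultrametricity tolerance (fraction of depth).
#' @param all if `FALSE` (default) only the first tree is returned (in a
#'   length-one list); if `TRUE`, all trees.
#' @return a list of canonicalised `phylo` objects.
#' @export
read_trees <- function(path, format = c("newick", "nexus"),
                       epsilon = 1e-6, all = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_gmyc("no such file: ", path, class = "io_error")
  trees <- switch(format,
                  newick = ape::read.tree(path),
                  nexus  = ape::read.nexus(path))
  if (is.null(trees))
    stop_gmyc("no trees parsed from ", path, class = "empty_input_error")
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!all) trees <- trees[1L]
  lapply(trees, as_ultrametric, epsilon = epsilon)
}

#' Cross-check tree tips against a group map
#'
#' Fails fast, listing every tip label absent from the group map and every
#' mapped sample absent from the tree.
#'
#' @param tree a `phylo`.
#' @param groups a [group_map()].
#' @param require_all_samples also require every mapped sample to be a tip.
#' @return `TRUE`, invisibly, on success.
#' @export
check_tip_groups <- function(tree, groups, require_all_samples = FALSE) {
  missing_tips <- setdiff(tree$tip.label, names(groups))
  if (length(missing_tips))
    stop_gmyc("tips missing from group map: ",
              paste(missing_tips, collapse = ", "),
              class = "crosscheck_error")
  if (require_all_samples) {
    extra <- setdiff(names(groups), tree$tip.label)
    if (length(extra))
      stop_gmyc("mapped samples missing from tree: ",
                paste(extra, collapse = ", "),
                class = "crosscheck_error")
  }
  invisible(TRUE)
}
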