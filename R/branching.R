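#' Partition tips into putative species at a time threshold
#'
#' Every maximal subtree whose root node height is at or below the
#' threshold `T` forms one species; a tip whose parent node lies above the
#' threshold is a singleton species. Species are ordered canonically by
#' their smallest tip label and numbered 1..K.
#'
#' @param tree a `phylo`, ideally canonicalised with [as_ultrametric()].
#' @param threshold time on the tip-referenced height scale, in
#'   `[0, depth]`.
#' @return an object of class `species_partition`: a list of character
#'   vectors of tip labels.
#' @export
threshold_partition <- function(tree, threshold) {
  h <- attr(tree, "heights") %||% node_heights(tree)
  depth <- max(h)
  if (threshold < 0 || threshold > depth)
    stop_gmyc("threshold must lie in [0, depth = ", format(depth), "]",
              class = "validation_error")
  roots <- species_roots(tree, h, threshold)
  species <- lapply(roots, function(v) sort(tree$tip.label[tips_under(tree, v)]))
  new_partition(species)
}

new_partition <- function(species) {
  species <- lapply(species, sort)
  species <- species[order(vapply(species, `[`, "", 1L))]
  if (any(lengths(species) == 0L))
    stop_gmyc("species sets must be non-empty", class = "validation_error")
  tips <- unlist(species)
  if (anyDuplicated(tips))
    stop_gmyc("species sets are not disjoint", class = "validation_error")
  structure(species, class = "species_partition")
}

#' Build a species partition from explicit tip sets
#'
#' @param species list of character vectors of tip names (disjoint,
#'   non-empty); canonical ordering is applied.
#' @return a `species_partition`.
#' @export
species_partition <- function(species) new_partition(species)

#' @export
print.species_partition <- function(x, ...) {
  cnt <- entity_counts(x)
  cat("SpeciesPartition:", cnt[["entities"]], "species (",
      cnt[["clusters"]], "clusters,", cnt[["singletons"]], "singletons ) over",
      length(unlist(x)), "tips\n")
  invisible(x)
}

#' Tip-to-species assignment table
#' @param partition a `species_partition`.
#' @return data.frame with columns `sample_name`, `gmyc_species_id`.
#' @export
partition_table <- function(partition) {
  data.frame(sample_name = unlist(partition),
             gmyc_species_id = rep(seq_along(partition), lengths(partition)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# node indices (tips or internal) that are maximal with height <= T
species_roots <- function(tree, h, threshold) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent[root] <- root # so h[parent[.]] is well-defined at the root
  nodes <- seq_len(ntip + tree$Nnode)
  is_root_sp <- (h[nodes] <= threshold) &
    (nodes == root | h[parent[nodes]] > threshold)
  which(is_root_sp)
}

#' Branching-event schedule of an ultrametric tree
#'
#' Lists the branching events of the tree from the root towards the tips,
#' together with the waiting time below each event and the lineage state
#' during that waiting interval. The root split is the first event; the
#' final interval runs from the youngest internal node down to the tips.
#'
#' With a threshold, each event is classed as `diversification` (node
#' height above the threshold) or `coalescent` (at or below), and the state
#' tracks the number of species-level lineages `k` (each delimited species
#' counts as one species lineage from the present back to its speciation
#' event) and the number of within-species gene lineages `n_j` of each
#' species.
#'
#' @param tree a `phylo` (canonicalised with [as_ultrametric()] if needed).
#' @param threshold optional time threshold in `[0, depth]`; `NULL` gives a
#'   single-class schedule tracking only the total lineage count.
#' @return an object of class `branching_schedule`: a list with `events`
#'   (data.frame: `height`, `x`, `n_total`, and when classified `class`,
#'   `k`, `species`), `pairs` (data.frame `interval`, `pairs` listing
#'   `n_j (n_j - 1)` for every species with two or more lineages in that
#'   interval), `partition`, `threshold`, `depth`, `n_tips`.
#' @export
branching_events <- function(tree, threshold = NULL) {
  if (is.null(attr(tree, "heights"))) tree <- as_ultrametric(tree)
  h <- attr(tree, "heights")
  ntip <- ape::Ntip(tree)
  depth <- max(h)
  int_nodes <- (ntip + 1L):(ntip + tree$Nnode)
  ord <- int_nodes[order(h[int_nodes], decreasing = TRUE)]
  hs <- h[ord]
  m <- length(ord)
  x <- c(hs[-1L], 0) * -1 + hs # h_i - h_{i+1}, last interval ends at tips
  ev <- data.frame(node = ord, height = hs, x = x,
                   n_total = seq_len(m) + 1L)

  if (is.null(threshold)) {
    sched <- list(events = ev, pairs = NULL, partition = NULL,
                  threshold = NULL, depth = depth, n_tips = ntip)
    class(sched) <- "branching_schedule"
    return(sched)
  }

  if (threshold < 0 || threshold > depth)
    stop_gmyc("threshold must lie in [0, depth = ", format(depth), "]",
              class = "validation_error")
  roots <- species_roots(tree, h, threshold)
  # canonical species order (by smallest tip label) so that event species
  # ids agree with the returned partition
  minlab <- vapply(roots,
                   function(v) min(tree$tip.label[tips_under(tree, v)]), "")
  roots <- roots[order(minlab)]
  # species id of every node at or below a species root
  sp_of <- integer(ntip + tree$Nnode)
  for (i in seq_along(roots)) {
    r <- roots[i]
    sp_of[r] <- i
    if (r > ntip) {
      desc <- c(tips_under(tree, r), internal_under(tree, r))
      sp_of[desc] <- i
    }
  }
  ev$class <- ifelse(ev$height > threshold, "diversification", "coalescent")
  ev$species <- ifelse(ev$class == "coalescent", sp_of[ev$node], NA_integer_)

  # walk root -> tips: k species lineages, n_j gene lineages per species
  k <- 1L
  nper <- rep(1L, length(roots))
  kvec <- integer(m)
  pair_int <- integer(0)
  pair_val <- numeric(0)
  for (i in seq_len(m)) {
    if (ev$class[i] == "diversification") {
      k <- k + 1L
    } else {
      s <- ev$species[i]
      nper[s] <- nper[s] + 1L
    }
    kvec[i] <- k
    multi <- which(nper >= 2L)
    if (length(multi)) {
      pair_int <- c(pair_int, rep.int(i, length(multi)))
      pair_val <- c(pair_val, nper[multi] * (nper[multi] - 1))
    }
  }
  ev$k <- kvec
  species <- lapply(roots, function(v) sort(tree$tip.label[tips_under(tree, v)]))
  sched <- list(events = ev,
                pairs = data.frame(interval = pair_int, pairs = pair_val),
                partition = new_partition(species),
                threshold = threshold, depth = depth, n_tips = ntip)
  class(sched) <- "branching_schedule"
  sched
}

internal_under <- function(tree, v) {
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  stack <- v
  while (length(stack)) {
    u <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(u)]]
    ints <- kids[kids > ntip]
    out <- c(out, ints)
    stack <- c(stack, ints)
  }
  out
}

#' @export
print.branching_schedule <- function(x, ...) {
  cat("BranchingSchedule:", nrow(x$events), "intervals,", x$n_tips,
      "tips, depth", format(x$depth), "\n")
  if (!is.null(x$threshold))
    cat("  classified at threshold", format(x$threshold), "->",
        length(x$partition), "species\n")
  invisible(x)
}
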