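# ---- synthetic-data generators -------------------------------------------
# Ground-truth scaffolding for the pipeline: Yule species trees, Kingman
# coalescent gene trees grafted inside them, JC69 sequences, and the fixed
# hand-built 16-tip illustration fixture used by the concordance tests.

# recursive newick emitter for a parent-pointer node table
# parent: integer (0 for root); time: distance from root (increasing toward
# tips); label: tip labels (NA for internal nodes)
newick_from_nodes <- function(parent, time, label) {
  children <- split(seq_along(parent), parent)
  emit <- function(v) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) return(label[v])
    inner <- vapply(kids, function(k)
      paste0(emit(k), sprintf(":%.12g", time[k] - time[v])), "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  root <- which(parent == 0L)
  paste0(emit(root), ";")
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Forward construction: starting from the root split with two lineages,
#' the waiting time at `k` lineages is exponential with rate `k * lambda`;
#' at each event a uniformly chosen lineage splits. After reaching `n`
#' lineages a final exponential waiting time at rate `n * lambda` runs
#' down to the present, so the expected root depth is
#' `sum_{k=2}^{n} 1 / (k lambda)`.
#'
#' @param n_species number of tips (`>= 1`).
#' @param speciation_rate per-lineage birth rate `lambda > 0`.
#' @param seed integer seed; the tree (its newick string) is deterministic
#'   per seed.
#' @return an ultrametric `phylo` with tips `sp01, sp02, ...` and heights
#'   attached; a degenerate single-tip `phylo` for `n_species = 1`.
#' @export
simulate_species_tree <- function(n_species, speciation_rate = 1, seed = 1L) {
  stopifnot(n_species >= 1, speciation_rate > 0)
  set.seed(seed)
  lab <- sprintf("sp%02d", seq_len(n_species))
  if (n_species == 1L) {
    depth <- stats::rexp(1, speciation_rate)
    tr <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = lab,
               edge.length = depth, Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "heights") <- stats::setNames(c(0, depth), NULL)
    return(tr)
  }
  waits <- stats::rexp(n_species - 1L, rate = (2:n_species) * speciation_rate)
  depth <- sum(waits)
  split_times <- cumsum(waits)[seq_len(max(0L, n_species - 2L))]

  parent <- 0L          # node table: root only
  time <- 0
  active <- c(1L, 1L)   # open lineages, each recorded by its parent node
  for (s in split_times) {
    u <- sample.int(length(active), 1L)
    parent <- c(parent, active[u])
    time <- c(time, s)
    v <- length(parent)
    active <- c(active[-u], v, v)
  }
  for (i in seq_along(active)) {
    parent <- c(parent, active[i])
    time <- c(time, depth)
  }
  label <- c(rep(NA_character_, n_species - 1L), lab)
  tree <- ape::read.tree(text = newick_from_nodes(parent, time, label))
  as_ultrametric(tree)
}

#' Simulate a coalescent-within-species gene tree with true labels
#'
#' Within each species, its samples coalesce under a Kingman coalescent
#' with expected pairwise coalescence depth `coalescent_scale *
#' depth(species_tree)`; lineages surviving at a species-tree node are
#' handed to the ancestral branch where the coalescent continues, and any
#' lineages surviving above the species-tree root coalesce there. The
#' output is ultrametric; small `coalescent_scale` gives species-monophyly
#' with shallow tip clusters below deep interspecific divergences -- the
#' regime the GMYC model assumes.
#'
#' @param species_tree an ultrametric `phylo` (e.g. from
#'   [simulate_species_tree()]).
#' @param samples_per_species integer scalar or vector along the species
#'   tree tips; use 1 for chosen species to create singletons.
#' @param coalescent_scale expected within-species pairwise coalescence
#'   depth relative to the species-tree depth (`> 0`).
#' @param seed integer seed.
#' @return a `truth_set`: list with `tree` (gene tree, heights attached),
#'   `groups` (a [group_map()] of true species labels) and
#'   `true_partition` (the [species_partition()] induced by the labels).
#' @export
simulate_gene_tree <- function(species_tree, samples_per_species = 5L,
                               coalescent_scale = 0.02, seed = 1L) {
  stopifnot(coalescent_scale > 0)
  set.seed(seed)
  sp_lab <- species_tree$tip.label
  nsp <- length(sp_lab)
  nsam <- rep_len(as.integer(samples_per_species), nsp)
  stopifnot(all(nsam >= 1L))
  h <- attr(species_tree, "heights") %||% node_heights(species_tree)
  depth <- max(h)
  theta <- coalescent_scale * depth

  # pools of open gene lineages per current species-tree edge, each lineage
  # a newick fragment plus the height of its top
  merge_pool <- function(pool, from, until) {
    t_cur <- from
    while (length(pool$frag) >= 2L) {
      n <- length(pool$frag)
      t_cur <- t_cur + stats::rexp(1, rate = choose(n, 2) / theta)
      if (t_cur > until) break
      pick <- sample.int(n, 2L)
      a <- pick[1]; b <- pick[2]
      frag <- paste0("(", pool$frag[a], sprintf(":%.12g", t_cur - pool$top[a]),
                     ",", pool$frag[b], sprintf(":%.12g", t_cur - pool$top[b]),
                     ")")
      pool$frag <- c(pool$frag[-pick], frag)
      pool$top <- c(pool$top[-pick], t_cur)
    }
    pool
  }

  ntip <- nsp
  if (nsp == 1L) {
    samples <- paste0(sp_lab, "_", seq_len(nsam[1]))
    pool <- list(frag = samples, top = rep(0, nsam[1]))
    if (length(pool$frag) == 1L) {
      # single sample of a single species: degenerate one-tip gene tree
      stop_gmyc("need at least 2 samples in total", class = "validation_error")
    }
    pool <- merge_pool(pool, 0, Inf)
    tree <- ape::read.tree(text = paste0(pool$frag, ";"))
    tree <- as_ultrametric(tree)
    groups <- group_map(samples, rep(sp_lab, nsam[1]))
    return(new_truth_set(tree, groups))
  }

  parent <- integer(ntip + species_tree$Nnode)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  pools <- vector("list", ntip + species_tree$Nnode)
  for (i in seq_len(nsp)) {
    samples <- paste0(sp_lab[i], "_", seq_len(nsam[i]))
    pools[[i]] <- merge_pool(list(frag = samples, top = rep(0, nsam[i])),
                             from = 0, until = h[parent[i]])
    # lineages stop at the parent node height, survivors hand over there
    pools[[i]]$top <- pools[[i]]$top
  }
  int_nodes <- (ntip + 1L):(ntip + species_tree$Nnode)
  root <- ntip + 1L
  for (v in int_nodes[order(h[int_nodes])]) {
    kids <- species_tree$edge[species_tree$edge[, 1] == v, 2]
    pool <- list(frag = c(pools[[kids[1]]]$frag, pools[[kids[2]]]$frag),
                 top = c(pools[[kids[1]]]$top, pools[[kids[2]]]$top))
    until <- if (v == root) Inf else h[parent[v]]
    pools[[v]] <- merge_pool(pool, from = h[v], until = until)
  }
  final <- pools[[root]]
  stopifnot(length(final$frag) == 1L)
  tree <- as_ultrametric(ape::read.tree(text = paste0(final$frag, ";")))
  groups <- group_map(paste0(rep(sp_lab, nsam),
                             "_",
                             unlist(lapply(nsam, seq_len))),
                      rep(sp_lab, nsam))
  new_truth_set(tree, groups)
}

new_truth_set <- function(tree, groups) {
  part <- species_partition(split(names(groups),
                                  as.character(unclass(groups))))
  structure(list(tree = tree, groups = groups, true_partition = part),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("TruthSet:", ape::Ntip(x$tree), "tips,",
      length(x$true_partition), "true species\n")
  invisible(x)
}

#' The 16-tip illustration fixture
#'
#' A fixed, byte-stable ultrametric tree of 16 samples in 8 user groups
#' whose threshold partition at the designed threshold (T = 1) has six
#' GMYC species realising one three-group merge, one group split in two,
#' one exact match, one singleton, and one merge involving a
#' dataset-singleton group -- the canonical worked example for the
#' concordance metrics.
#'
#' @return list with `truth` (a `truth_set` whose `groups` are the 8 user
#'   groups), `imposed_partition` (the 6-species delimitation),
#'   `threshold` (the designed T).
#' @export
figure1_fixture <- function() {
  nwk <- paste0(
    "((((sp1_1:0.2,sp1_2:0.2):0.4,((sp2_1:0.2,sp2_2:0.2):0.25,",
    "(sp3_1:0.15,sp3_2:0.15):0.3):0.15):1.8,(((spA_1:0.3,spA_2:0.3):1.2,",
    "(spA_3:0.25,spA_4:0.25):1.25):0.5,(spZ_1:0.35,spZ_2:0.35):1.65):0.4)",
    ":0.6,(((spY_1:0.2,spY_2:0.2):0.3,spW_1:0.5):1.3,spB_1:1.8):1.2);")
  tree <- as_ultrametric(ape::read.tree(text = nwk))
  samples <- tree$tip.label
  groups <- group_map(samples, sub("_[0-9]+$", "", samples))
  truth <- structure(list(tree = tree, groups = groups,
                          true_partition = species_partition(
                            split(names(groups),
                                  as.character(unclass(groups))))),
                     class = "truth_set")
  imposed <- threshold_partition(tree, 1.0)
  list(truth = truth, imposed_partition = imposed, threshold = 1.0)
}

#' Simulate a JC69 alignment along a tree
#'
#' @param tree a `phylo` with branch lengths (time units).
#' @param length number of sites (`>= 1`).
#' @param mutation_rate substitutions per site per unit time; 0 yields
#'   identical sequences.
#' @param seed integer seed.
#' @return a [gmyc_alignment()] with one record per tip.
#' @export
simulate_sequences <- function(tree, length = 500L, mutation_rate = 1,
                               seed = 1L) {
  stopifnot(length >= 1, mutation_rate >= 0)
  set.seed(seed)
  if (mutation_rate == 0) {
    root <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
    seqs <- stats::setNames(rep(root, ape::Ntip(tree)), tree$tip.label)
    return(gmyc_alignment(seqs))
  }
  dat <- phangorn::simSeq(tree, l = length, rate = mutation_rate)
  mat <- as.character(dat)
  seqs <- stats::setNames(toupper(apply(mat, 1L, paste, collapse = "")),
                          rownames(mat))
  gmyc_alignment(seqs[tree$tip.label])
}
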