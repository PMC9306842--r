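# shared fixtures and independent oracles, built in code at test time

# random alignment of unambiguous bases
make_alignment <- function(n, len, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
  names(seqs) <- sprintf("s%04d", seq_len(n))
  gmyc_alignment(seqs)
}

# random ultrametric tree (coalescent shape) with heights attached
random_tree <- function(n, seed) {
  set.seed(seed)
  as_ultrametric(ape::rcoal(n))
}

# clean truth set: interspecific divergences at least `ratio` times the
# expected within-species pairwise coalescence depth, by construction
sim_clean <- function(n_species, samples, seed, ratio = 20) {
  sp <- simulate_species_tree(n_species, 1, seed)
  h <- attr(sp, "heights")
  hint <- h[(n_species + 1L):(n_species + sp$Nnode)]
  scale <- min(hint) / (ratio * max(h))
  simulate_gene_tree(sp, samples, scale, seed = derive_seed(seed, 1L))
}

# random partition + group map over n samples (for metric algebra checks)
random_partition_and_groups <- function(n, seed) {
  set.seed(seed)
  samples <- sprintf("x%03d", seq_len(n))
  n_groups <- sample(1:max(1, n %/% 2), 1)
  gm <- group_map(samples, paste0("g", sample.int(n_groups, n, replace = TRUE)))
  n_sp <- sample(1:n, 1)
  assign_sp <- sample.int(n_sp, n, replace = TRUE)
  part <- species_partition(split(samples, assign_sp))
  list(partition = part, groups = gm)
}

# ---- independent GMYC likelihood oracle ----------------------------------
# Interval states computed by edge-crossing counts and a closed formula for
# the species-lineage count, not by the package's incremental event walk.
oracle_states <- function(tree, threshold) {
  h <- attr(tree, "heights")
  ntip <- ape::Ntip(tree)
  int_nodes <- (ntip + 1L):(ntip + tree$Nnode)
  hs <- sort(h[int_nodes], decreasing = TRUE)
  bounds <- c(hs, 0)
  div_heights <- h[int_nodes][h[int_nodes] > threshold]
  # species roots: maximal nodes with height <= threshold
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent[ntip + 1L] <- ntip + 1L
  all_nodes <- seq_len(ntip + tree$Nnode)
  roots <- all_nodes[h[all_nodes] <= threshold &
                     (all_nodes == ntip + 1L | h[parent[all_nodes]] > threshold)]
  desc_sets <- lapply(roots, function(r) {
    if (r <= ntip) r else unlist(phangorn::Descendants(tree, r, "all"))
  })
  # include the species root itself as a possible edge child
  desc_sets <- mapply(function(s, r) unique(c(s, r)), desc_sets, roots,
                      SIMPLIFY = FALSE)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    t_mid <- (bounds[i] + bounds[i + 1L]) / 2
    crossing <- which(h[tree$edge[, 1]] > t_mid & h[tree$edge[, 2]] < t_mid)
    kids <- tree$edge[crossing, 2]
    nj <- vapply(desc_sets, function(s) sum(kids %in% s), 0L)
    ev_height <- bounds[i]
    list(x = bounds[i] - bounds[i + 1L],
         k = 1L + sum(div_heights > t_mid),
         nj = nj,
         event_class = if (ev_height > threshold) "diversification"
                       else "coalescent")
  })
}

oracle_loglik <- function(tree, threshold, lambda_div, lambda_coal,
                          p_div, p_coal) {
  st <- oracle_states(tree, threshold)
  ll <- 0
  for (s in st) {
    pairs <- s$nj * (s$nj - 1)
    F_coal <- sum(pairs[pairs > 0]^p_coal)
    F_div <- s$k^p_div
    b <- lambda_div * F_div + lambda_coal * F_coal
    rho <- if (s$event_class == "diversification") lambda_div * F_div
           else lambda_coal * F_coal
    if (rho <= 0) return(-Inf)
    ll <- ll + log(rho) - b * s$x
  }
  ll
}

# profile log-likelihood at fixed exponents, oracle version (lambda = m/E)
oracle_profile <- function(tree, threshold, p_div, p_coal) {
  st <- oracle_states(tree, threshold)
  acc <- list(div = c(m = 0, E = 0, lf = 0), coal = c(m = 0, E = 0, lf = 0))
  for (s in st) {
    pairs <- s$nj * (s$nj - 1)
    F_coal <- sum(pairs[pairs > 0]^p_coal)
    F_div <- s$k^p_div
    cls <- if (s$event_class == "diversification") "div" else "coal"
    Fe <- if (cls == "div") F_div else F_coal
    if (Fe <= 0) return(-Inf)
    acc$div[["E"]] <- acc$div[["E"]] + F_div * s$x
    acc$coal[["E"]] <- acc$coal[["E"]] + F_coal * s$x
    acc[[cls]][["m"]] <- acc[[cls]][["m"]] + 1
    acc[[cls]][["lf"]] <- acc[[cls]][["lf"]] + log(Fe)
  }
  ll <- 0
  for (cls in c("div", "coal")) {
    m <- acc[[cls]][["m"]]; E <- acc[[cls]][["E"]]
    if (m > 0) ll <- ll + m * log(m / E) + acc[[cls]][["lf"]] - m
  }
  ll
}

# exhaustive fit: every candidate threshold x refined exponent grid
oracle_fit <- function(tree) {
  h <- attr(tree, "heights")
  ntip <- ape::Ntip(tree)
  hi <- sort(unique(h[(ntip + 1L):(ntip + tree$Nnode)]))
  cands <- c(hi[1] / 2,
             if (length(hi) > 1) (hi[-1] + hi[-length(hi)]) / 2,
             max(hi))
  refine <- function(fun, grid) {
    vals <- vapply(grid, fun, 0)
    grid[which.max(vals)]
  }
  best <- -Inf
  best_T <- NA
  for (Tc in cands) {
    # separable in the two exponents: refine each on a nested grid
    f_d <- function(p) oracle_profile(tree, Tc, p, 1)
    f_c <- function(p) oracle_profile(tree, Tc, 1, p)
    pd <- refine(f_d, seq(0, 10, by = 0.25))
    pd <- refine(f_d, seq(max(0, pd - 0.25), min(10, pd + 0.25), by = 0.005))
    pd <- refine(f_d, seq(max(0, pd - 0.005), min(10, pd + 0.005),
                          by = 0.0001))
    pc <- refine(f_c, seq(0, 10, by = 0.25))
    pc <- refine(f_c, seq(max(0, pc - 0.25), min(10, pc + 0.25), by = 0.005))
    pc <- refine(f_c, seq(max(0, pc - 0.005), min(10, pc + 0.005),
                          by = 0.0001))
    ll <- oracle_profile(tree, Tc, pd, pc)
    if (ll > best) { best <- ll; best_T <- Tc }
  }
  list(logL = best, threshold = best_T)
}
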