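#' GMYC fit configuration
#'
#' @param p_bounds bounds for the branching-rate exponents (both classes
#'   and the null), default `c(0, 10)`.
#' @param df degrees of freedom for the likelihood-ratio test; 3 by default
#'   (two extra rate-class parameters plus the threshold), 2 is the other
#'   convention in use.
#' @param grid_points number of coarse grid points used to bracket each
#'   1-D exponent profile before local refinement.
#' @return a list of class `gmyc_config`.
#' @export
gmyc_config <- function(p_bounds = c(0, 10), df = 3, grid_points = 21L) {
  stopifnot(length(p_bounds) == 2L, p_bounds[1] >= 0,
            p_bounds[2] > p_bounds[1], df >= 1, grid_points >= 5L)
  structure(list(p_bounds = p_bounds, df = df,
                 grid_points = as.integer(grid_points)),
            class = "gmyc_config")
}

#' Branching rate of one lineage class
#'
#' The per-interval rate contribution of a single class:
#' `lambda * (n (n - 1))^p` for a coalescent class with `n` gene lineages
#' (zero when `n < 2`: no pair available to coalesce) and `lambda * k^p`
#' for a diversification class with `k` species lineages.
#'
#' @param n lineage count (gene lineages for `"coalescent"`, species
#'   lineages for `"diversification"`).
#' @param lambda rate parameter, `> 0`.
#' @param p dimensionless exponent.
#' @param class `"coalescent"` or `"diversification"`.
#' @return the rate, a non-negative number.
#' @export
single_class_rate <- function(n, lambda, p,
                              class = c("coalescent", "diversification")) {
  class <- match.arg(class)
  f <- switch(class, coalescent = pow0(n * (n - 1), p),
              diversification = pow0(n, p))
  lambda * f
}

# per-interval class state factors for a classified schedule:
#   F_div[i]  = k_i^p_div
#   F_coal[i] = sum_j (n_ij (n_ij - 1))^p_coal   (0 when no species has >= 2)
schedule_factors <- function(schedule, p_div, p_coal) {
  ev <- schedule$events
  if (is.null(ev$class))
    stop_gmyc("schedule is not classified by a threshold",
              class = "validation_error")
  F_div <- pow0(ev$k, p_div)
  F_coal <- numeric(nrow(ev))
  pr <- schedule$pairs
  if (!is.null(pr) && nrow(pr)) {
    w <- rowsum(pow0(pr$pairs, p_coal), pr$interval)
    F_coal[as.integer(rownames(w))] <- w[, 1]
  }
  list(div = F_div, coal = F_coal)
}

#' GMYC log-likelihood of a classified schedule
#'
#' The composite branching process has total rate
#' `b_i = lambda_div * k_i^p_div + lambda_coal * sum_j (n_ij (n_ij-1))^p_coal`
#' in interval `i`; each interval contributes `log(rho_i) - b_i * x_i`,
#' where `rho_i` is the rate component of the class of the event the
#' interval belongs to. The log-likelihood is `-Inf` whenever an observed
#' event has zero class rate.
#'
#' @param schedule a classified [branching_events()] schedule.
#' @param params list with `lambda_div`, `lambda_coal`, `p_div`, `p_coal`.
#' @return the log-likelihood (possibly `-Inf`).
#' @export
gmyc_log_likelihood <- function(schedule, params) {
  f <- schedule_factors(schedule, params$p_div, params$p_coal)
  ev <- schedule$events
  b <- params$lambda_div * f$div + params$lambda_coal * f$coal
  is_div <- ev$class == "diversification"
  rho <- ifelse(is_div, params$lambda_div * f$div,
                params$lambda_coal * f$coal)
  if (any(rho <= 0)) return(-Inf)
  sum(log(rho) - b * ev$x)
}

#' Analytic profile of the class rates
#'
#' For fixed exponents the likelihood is maximised in each `lambda` by
#' `lambda_hat = m_class / E_class`, the event count of the class divided
#' by its accumulated exposure `sum_i F_class,i x_i`. A class with no
#' events gets `lambda_hat = 0` and contributes only exposure.
#'
#' @param schedule a classified schedule.
#' @param p_div,p_coal exponents.
#' @return list with `lambda_div`, `lambda_coal`, `logL`.
#' @export
profile_lambdas <- function(schedule, p_div, p_coal) {
  f <- schedule_factors(schedule, p_div, p_coal)
  ev <- schedule$events
  is_div <- ev$class == "diversification"
  out <- list()
  ll <- 0
  for (cls in c("div", "coal")) {
    sel <- if (cls == "div") is_div else !is_div
    Fc <- f[[cls]]
    m <- sum(sel)
    E <- sum(Fc * ev$x)
    if (m == 0L) {
      lam <- 0
    } else {
      if (E <= 0)
        stop_gmyc("class '", cls, "' has events but zero exposure",
                  class = "degenerate_error")
      if (any(Fc[sel] <= 0)) return(list(lambda_div = NA_real_,
                                         lambda_coal = NA_real_,
                                         logL = -Inf))
      lam <- m / E
      ll <- ll + m * log(lam) + sum(log(Fc[sel])) - m
    }
    out[[paste0("lambda_", if (cls == "div") "div" else "coal")]] <- lam
  }
  out$logL <- ll
  out
}

# 1-D maximisation of a profile log-likelihood in the exponent: coarse grid
# bracket, then golden-section refinement. Deterministic and bounded.
maximise_exponent <- function(fun, bounds, grid_points) {
  grid <- seq(bounds[1], bounds[2], length.out = grid_points)
  vals <- vapply(grid, fun, 0)
  best <- which.max(vals)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(fun, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  if (opt$objective >= vals[best]) {
    list(p = opt$maximum, value = opt$objective)
  } else {
    list(p = grid[best], value = vals[best])
  }
}

# profile log-likelihood terms of one class as a function of its exponent;
# the two classes are variationally independent, so each exponent can be
# profiled separately.
class_profile_fun <- function(schedule, cls) {
  ev <- schedule$events
  is_div <- ev$class == "diversification"
  sel <- if (cls == "div") is_div else !is_div
  m <- sum(sel)
  x <- ev$x
  if (cls == "div") {
    state <- ev$k
    factor_fun <- function(p) pow0(state, p)
  } else {
    pr <- schedule$pairs
    nint <- nrow(ev)
    factor_fun <- function(p) {
      Fc <- numeric(nint)
      if (!is.null(pr) && nrow(pr)) {
        w <- rowsum(pow0(pr$pairs, p), pr$interval)
        Fc[as.integer(rownames(w))] <- w[, 1]
      }
      Fc
    }
  }
  function(p) {
    if (m == 0L) return(0)
    Fc <- factor_fun(p)
    E <- sum(Fc * x)
    if (E <= 0 || any(Fc[sel] <= 0)) return(-Inf)
    m * log(m / E) + sum(log(Fc[sel])) - m
  }
}

#' Fit the one-class null model
#'
#' The null has a single branching-rate class over all nodes with rate
#' `lambda0 * (n_i (n_i - 1))^p0`, `n_i` the total lineage count. `lambda0`
#' is profiled analytically; `p0` is maximised within bounds.
#'
#' @param schedule an unclassified (single-class) [branching_events()]
#'   schedule.
#' @param config a [gmyc_config()].
#' @return list with `lambda0`, `p0`, `logL`.
#' @export
fit_null <- function(schedule, config = gmyc_config()) {
  ev <- schedule$events
  m <- nrow(ev)
  pairs <- ev$n_total * (ev$n_total - 1)
  gfun <- function(p0) {
    Fc <- pow0(pairs, p0)
    E <- sum(Fc * ev$x)
    if (E <= 0) return(-Inf)
    m * log(m / E) + sum(log(Fc)) - m
  }
  if (m == 1L) {
    warning("degenerate single-event schedule: p0 fixed at 1")
    p0 <- 1
    val <- gfun(p0)
  } else {
    opt <- maximise_exponent(gfun, config$p_bounds, config$grid_points)
    p0 <- opt$p
    val <- opt$value
  }
  Fc <- pow0(pairs, p0)
  list(lambda0 = m / sum(Fc * ev$x), p0 = p0, logL = val)
}

#' Likelihood-ratio test for the threshold model
#'
#' `LR = max(0, 2 (logL - null_logL))`, compared against a chi-square
#' upper tail with `df` degrees of freedom. The p-value is reported, never
#' auto-thresholded.
#'
#' @param logL alternative (threshold model) maximum log-likelihood.
#' @param null_logL null maximum log-likelihood.
#' @param df chi-square degrees of freedom (default 3).
#' @return list with `LR` and `p_value`.
#' @export
likelihood_ratio_test <- function(logL, null_logL, df = 3) {
  if (logL < null_logL - 1e-6)
    warning("alternative log-likelihood below null beyond tolerance")
  LR <- max(0, 2 * (logL - null_logL))
  list(LR = LR, p_value = stats::pchisq(LR, df = df, lower.tail = FALSE))
}

#' Entities, clusters and singletons of a partition
#'
#' Entities are all delimited species; singletons those with exactly one
#' sample; clusters those with two or more (entities minus singletons).
#'
#' @param partition a `species_partition`.
#' @return named integer vector `entities`, `clusters`, `singletons`.
#' @export
entity_counts <- function(partition) {
  sizes <- lengths(partition)
  entities <- length(sizes)
  singletons <- sum(sizes == 1L)
  c(entities = entities, clusters = entities - singletons,
    singletons = singletons)
}

# candidate thresholds: midpoints between consecutive distinct internal
# node heights, plus the two boundary partitions (all singletons at the
# bottom, one species at the root). The likelihood is piecewise constant
# in T between node heights, so midpoints avoid tie ambiguity.
candidate_thresholds <- function(tree) {
  h <- attr(tree, "heights") %||% node_heights(tree)
  ntip <- ape::Ntip(tree)
  hi <- sort(unique(h[(ntip + 1L):(ntip + tree$Nnode)]))
  cand <- hi[1] / 2
  if (length(hi) > 1L)
    cand <- c(cand, (hi[-1] + hi[-length(hi)]) / 2)
  c(cand, max(hi))
}

#' Fit the single-threshold GMYC model
#'
#' Scans all candidate thresholds (midpoints between consecutive distinct
#' node heights plus both boundary partitions); at each, the two exponents
#' are maximised within bounds with both rates profiled analytically. Ties
#' in log-likelihood between thresholds are resolved deterministically
#' towards fewer species (the older threshold). The fit is compared to the
#' one-class null with a likelihood-ratio test.
#'
#' @param tree a `phylo` with at least 3 tips (canonicalised internally).
#' @param config a [gmyc_config()].
#' @return an object of class `gmyc_fit`: list with `params`
#'   (`lambda_div`, `lambda_coal`, `p_div`, `p_coal`, `threshold`), `logL`,
#'   `null_logL`, `null_params`, `LR`, `p_value`, `df`, `partition`,
#'   `threshold_profile` (data.frame `threshold`, `logL`, `n_species`),
#'   `n_entities`, `n_clusters`, `n_singletons`, and the canonicalised
#'   `tree`.
#' @export
fit_single_threshold <- function(tree, config = gmyc_config()) {
  if (is.null(attr(tree, "heights"))) tree <- as_ultrametric(tree)
  if (ape::Ntip(tree) < 3L)
    stop_gmyc("need at least 3 tips to fit the threshold model",
              class = "validation_error")
  cands <- candidate_thresholds(tree)
  profile <- data.frame(threshold = cands, logL = NA_real_,
                        n_species = NA_integer_)
  fits <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    sched <- branching_events(tree, cands[i])
    g_div <- class_profile_fun(sched, "div")
    g_coal <- class_profile_fun(sched, "coal")
    o_div <- maximise_exponent(g_div, config$p_bounds, config$grid_points)
    o_coal <- maximise_exponent(g_coal, config$p_bounds, config$grid_points)
    prof <- profile_lambdas(sched, o_div$p, o_coal$p)
    profile$logL[i] <- prof$logL
    profile$n_species[i] <- length(sched$partition)
    fits[[i]] <- list(schedule = sched, p_div = o_div$p, p_coal = o_coal$p,
                      lambda_div = prof$lambda_div,
                      lambda_coal = prof$lambda_coal, logL = prof$logL)
  }
  # argmax with ties broken towards the larger threshold (fewer species)
  ord <- order(profile$threshold, decreasing = TRUE)
  best <- ord[1]
  for (i in ord) if (profile$logL[i] > profile$logL[best] + 1e-9) best <- i
  bf <- fits[[best]]

  null <- fit_null(branching_events(tree), config)
  lrt <- likelihood_ratio_test(bf$logL, null$logL, df = config$df)
  cnt <- entity_counts(bf$schedule$partition)
  structure(list(
    params = list(lambda_div = bf$lambda_div, lambda_coal = bf$lambda_coal,
                  p_div = bf$p_div, p_coal = bf$p_coal,
                  threshold = cands[best]),
    logL = bf$logL, null_logL = null$logL,
    null_params = null[c("lambda0", "p0")],
    LR = lrt$LR, p_value = lrt$p_value, df = config$df,
    partition = bf$schedule$partition,
    threshold_profile = profile,
    n_entities = cnt[["entities"]], n_clusters = cnt[["clusters"]],
    n_singletons = cnt[["singletons"]],
    tree = tree), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("Single-threshold GMYC fit\n")
  cat("  tips:", ape::Ntip(x$tree),
      " threshold T =", format(x$params$threshold, digits = 4), "\n")
  cat("  logL =", format(x$logL, digits = 6),
      " null logL =", format(x$null_logL, digits = 6), "\n")
  cat("  LR =", format(x$LR, digits = 4),
      " df =", x$df,
      " p =", format(x$p_value, digits = 3), "\n")
  cat("  entities:", x$n_entities, " clusters:", x$n_clusters,
      " singletons:", x$n_singletons, "\n")
  invisible(x)
}

#' Akaike-weight support for species-defining nodes
#'
#' Each candidate threshold model receives an Akaike weight computed from
#' its profile log-likelihood (all candidates share the same parameter
#' count, so weights reduce to normalised relative likelihoods). The
#' support of an internal node is the summed weight of all candidate
#' models in which that node is a species-defining node (the root of one
#' delimited species).
#'
#' @param tree the canonicalised tree of the fit.
#' @param threshold_profile the `threshold_profile` of a [fit_single_threshold()]
#'   fit (data.frame with `threshold` and `logL`).
#' @return data.frame with `node` (ape node number) and `support` in
#'   `[0, 1]`.
#' @export
node_support <- function(tree, threshold_profile) {
  if (is.null(attr(tree, "heights"))) tree <- as_ultrametric(tree)
  h <- attr(tree, "heights")
  ntip <- ape::Ntip(tree)
  w <- exp(threshold_profile$logL - max(threshold_profile$logL))
  w <- w / sum(w)
  int_nodes <- (ntip + 1L):(ntip + tree$Nnode)
  support <- stats::setNames(numeric(length(int_nodes)), int_nodes)
  for (i in seq_len(nrow(threshold_profile))) {
    roots <- species_roots(tree, h, threshold_profile$threshold[i])
    roots <- roots[roots > ntip]
    support[as.character(roots)] <- support[as.character(roots)] + w[i]
  }
  data.frame(node = int_nodes, support = as.numeric(support),
             row.names = NULL)
}
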