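#' Classify each GMYC species against user-predefined groups
#'
#' The scoring unit is the GMYC species. A species of one sample is a
#' `singleton` (even when it coincides with a one-sample user group). A
#' multi-sample species containing two or more user groups is a merge:
#' `merge_II` when at least one constituent group is represented by a
#' single sample in the analysed (possibly subsampled) data set, otherwise
#' `merge_I`; both carry match flag `"n"`. A multi-sample species pure for
#' one group is flagged `"y"`: a `split` when that group also occurs in
#' another GMYC species, an `exact` match when it occurs nowhere else.
#'
#' @param partition a `species_partition`.
#' @param groups a [group_map()] covering every tip of the partition.
#' @return data.frame with one row per GMYC species: `species_id`, `size`,
#'   `n_groups`, `groups_present` (comma-collapsed labels), `category`,
#'   `match_flag`.
#' @export
classify_species <- function(partition, groups) {
  tips <- unlist(partition)
  missing <- setdiff(tips, names(groups))
  if (length(missing))
    stop_gmyc("tips missing from group map: ",
              paste(missing, collapse = ", "), class = "crosscheck_error")
  gm <- unclass(groups)[tips]
  dataset_group_sizes <- table(gm)
  sp_groups <- lapply(partition, function(s) unique(unname(unclass(groups)[s])))
  # in how many GMYC species does each group occur (singletons included)
  occ <- table(unlist(sp_groups))

  n_sp <- length(partition)
  category <- character(n_sp)
  flag <- character(n_sp)
  for (i in seq_len(n_sp)) {
    size <- length(partition[[i]])
    gs <- sp_groups[[i]]
    if (size == 1L) {
      category[i] <- "singleton"; flag[i] <- "singleton"
    } else if (length(gs) >= 2L) {
      has_dataset_singleton <- any(dataset_group_sizes[gs] == 1L)
      category[i] <- if (has_dataset_singleton) "merge_II" else "merge_I"
      flag[i] <- "n"
    } else {
      category[i] <- if (occ[[gs]] >= 2L) "split" else "exact"
      flag[i] <- "y"
    }
  }
  data.frame(species_id = seq_len(n_sp),
             size = lengths(partition),
             n_groups = lengths(sp_groups),
             groups_present = vapply(sp_groups,
                                     function(g) paste(sort(g), collapse = ","),
                                     ""),
             category = category, match_flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall percentage match
#'
#' `m_i = 100 (y + s) / (y + n + s)` including singletons and
#' `m_e = 100 y / (y + n)` excluding them, where `y`, `n` and `s` count
#' GMYC species flagged match, merge and singleton respectively.
#'
#' @param y,n,s counts of y-flagged, n-flagged and singleton species.
#' @param include_singletons logical; include singletons in the score.
#' @return percentage (full precision); `NA` with a warning for the
#'   excluding form when `y + n = 0`.
#' @export
percentage_match <- function(y, n, s, include_singletons = TRUE) {
  if (include_singletons) {
    if (y + n + s < 1) stop_gmyc("no species to score", class = "empty_input_error")
    100 * (y + s) / (y + n + s)
  } else {
    if (y + n == 0) {
      warning("percentage match excluding singletons undefined (y + n = 0)")
      return(NA_real_)
    }
    100 * y / (y + n)
  }
}

#' Splitting ratio
#'
#' Ratio of the number of GMYC species to the number of user-defined
#' groups; values above 1 suggest user under-splitting, below 1 user
#' over-splitting.
#'
#' @param n_species number of GMYC species (entities).
#' @param n_singletons number of singleton species among them.
#' @param n_groups number of user-defined groups.
#' @param include_singletons logical.
#' @return the ratio at full precision.
#' @export
splitting_ratio <- function(n_species, n_singletons, n_groups,
                            include_singletons = TRUE) {
  stopifnot(n_groups >= 1, n_singletons <= n_species)
  if (include_singletons) n_species / n_groups
  else (n_species - n_singletons) / n_groups
}

#' Percentage of singleton GMYC species
#'
#' @param n_singletons number of singleton species.
#' @param n_species total number of GMYC species.
#' @return percentage at full precision.
#' @export
singleton_percentage <- function(n_singletons, n_species) {
  stopifnot(n_species >= 1)
  100 * n_singletons / n_species
}

#' Per-group oversplit factor
#'
#' For each user group, the number of distinct GMYC species containing at
#' least one of its samples. Singleton species count towards the factor by
#' default (a group split into a pair plus a singleton has factor 2).
#'
#' @param partition a `species_partition`.
#' @param groups a [group_map()].
#' @param include_singleton_species count singleton GMYC species (default
#'   `TRUE`).
#' @return named integer vector, one entry per group present in the data.
#' @export
per_group_split_factor <- function(partition, groups,
                                   include_singleton_species = TRUE) {
  tips <- unlist(partition)
  missing <- setdiff(tips, names(groups))
  if (length(missing))
    stop_gmyc("tips missing from group map: ",
              paste(missing, collapse = ", "), class = "crosscheck_error")
  keep <- if (include_singleton_species) seq_along(partition)
          else which(lengths(partition) >= 2L)
  all_groups <- sort(unique(unname(unclass(groups)[tips])))
  fac <- stats::setNames(integer(length(all_groups)), all_groups)
  for (i in keep) {
    gs <- unique(unname(unclass(groups)[partition[[i]]]))
    fac[gs] <- fac[gs] + 1L
  }
  fac
}

#' All concordance metrics of one GMYC run
#'
#' Aggregates [classify_species()] into the full per-run metric set: y/n/
#' singleton counts, percentage matches including and excluding
#' singletons, splitting ratios, singleton percentage, merge records,
#' exact-match groups and incidence, per-group split factors, and the
#' per-sample match table.
#'
#' @param partition a `species_partition`.
#' @param groups a [group_map()].
#' @return an object of class `run_metrics`.
#' @export
run_metrics <- function(partition, groups) {
  cls <- classify_species(partition, groups)
  y <- sum(cls$match_flag == "y")
  n <- sum(cls$match_flag == "n")
  s <- sum(cls$match_flag == "singleton")
  tips <- unlist(partition)
  groups_in_data <- sort(unique(unname(unclass(groups)[tips])))
  n_groups <- length(groups_in_data)
  exact_groups <- sort(unique(cls$groups_present[cls$category == "exact"]))
  merges <- cls[cls$category %in% c("merge_I", "merge_II"),
                c("species_id", "groups_present", "category")]
  names(merges)[3] <- "merge_type"
  cnt <- entity_counts(partition)

  tip_species <- rep(seq_along(partition), lengths(partition))
  match_table <- data.frame(
    sample_name = tips,
    gmyc_species_id = tip_species,
    user_group = unname(unclass(groups)[tips]),
    match = cls$match_flag[tip_species],
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    y_count = y, n_count = n, singleton_count = s,
    n_species = cnt[["entities"]], n_clusters = cnt[["clusters"]],
    n_groups = n_groups,
    m_incl = percentage_match(y, n, s, TRUE),
    m_excl = percentage_match(y, n, s, FALSE),
    sr_incl = splitting_ratio(cnt[["entities"]], cnt[["singletons"]],
                              n_groups, TRUE),
    sr_excl = splitting_ratio(cnt[["entities"]], cnt[["singletons"]],
                              n_groups, FALSE),
    singleton_pct = singleton_percentage(cnt[["singletons"]],
                                         cnt[["entities"]]),
    exact_groups = exact_groups,
    exact_match_incidence = 100 * length(exact_groups) / n_groups,
    merges = merges,
    split_factors = per_group_split_factor(partition, groups),
    classification = cls,
    match_table = match_table), class = "run_metrics")
}

#' @export
print.run_metrics <- function(x, ...) {
  cat("GMYC concordance metrics (", x$n_species, "species vs",
      x$n_groups, "groups )\n")
  cat("  y =", x$y_count, " n =", x$n_count,
      " singletons =", x$singleton_count, "\n")
  cat("  match incl/excl singletons:",
      paste0(round_half_up(x$m_incl), "% / ",
             round_half_up(x$m_excl), "%"), "\n")
  cat("  splitting ratio incl/excl:",
      paste0(round_half_up(x$sr_incl, 2), " / ",
             round_half_up(x$sr_excl, 2)), "\n")
  cat("  singletons:", paste0(round_half_up(x$singleton_pct), "%"),
      " exact-match incidence:",
      paste0(round_half_up(x$exact_match_incidence), "%"), "\n")
  invisible(x)
}

#' Per-group exact-match scores across runs
#'
#' `score(g) = 100 * (#runs in which g is an exact match) / (#runs)`.
#'
#' @param runs list of [run_metrics()] objects.
#' @param all_groups character vector of groups to report; defaults to the
#'   union of groups seen across runs.
#' @return named numeric vector of percentages.
#' @export
exact_match_scores <- function(runs, all_groups = NULL) {
  if (length(runs) < 1L)
    stop_gmyc("need at least one run", class = "empty_input_error")
  if (is.null(all_groups))
    all_groups <- sort(unique(unlist(lapply(runs, function(r)
      r$classification$groups_present))))
  counts <- stats::setNames(numeric(length(all_groups)), all_groups)
  for (r in runs) {
    hit <- intersect(all_groups, r$exact_groups)
    counts[hit] <- counts[hit] + 1
  }
  100 * counts / length(runs)
}
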