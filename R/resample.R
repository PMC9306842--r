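#' Resampling configuration
#'
#' @param fraction proportion of records to keep, in `(0, 1]`. The subset
#'   size is the ceiling of `fraction * n_records`, so 50% of 500 records
#'   gives exactly 250 and the size never drops below one.
#' @param n_replicates number of independent replicates.
#' @param base_seed integer base seed; each replicate uses
#'   [derive_seed()]`(base_seed, replicate_index)`.
#' @param ensure_representation if `TRUE`, every predefined group present
#'   in the source is guaranteed at least one representative in every
#'   replicate (requires `group_map`).
#' @param group_map a [group_map()] or `NULL`.
#' @return a list of class `resample_config`.
#' @export
resample_config <- function(fraction, n_replicates = 10L, base_seed = 1L,
                            ensure_representation = FALSE,
                            group_map = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_gmyc("fraction must lie in (0, 1]", class = "validation_error")
  if (n_replicates < 1L)
    stop_gmyc("n_replicates must be >= 1", class = "validation_error")
  if (ensure_representation && is.null(group_map))
    stop_gmyc("ensure_representation requires a group_map",
              class = "validation_error")
  structure(list(fraction = fraction,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 ensure_representation = isTRUE(ensure_representation),
                 group_map = group_map),
            class = "resample_config")
}

#' Draw one subsample of an alignment
#'
#' Records are drawn uniformly without replacement. With group
#' representation enforced the draw is two-phase: first one uniform
#' representative per group present in the source, then the remaining
#' slots uniformly from the rest. Output record order always matches the
#' source order.
#'
#' @param aln a [gmyc_alignment()].
#' @param cfg a [resample_config()].
#' @param replicate_index 0-based replicate index, `< n_replicates`.
#' @return a [gmyc_alignment()] with `ceiling(fraction * n_records)`
#'   records.
#' @export
draw_subsample <- function(aln, cfg, replicate_index = 0L) {
  if (replicate_index < 0L || replicate_index >= cfg$n_replicates)
    stop_gmyc("replicate_index out of range", class = "validation_error")
  nm <- names(aln)
  n <- length(nm)
  target <- as.integer(ceiling(cfg$fraction * n))
  seed <- derive_seed(cfg$base_seed, replicate_index)

  if (cfg$ensure_representation) {
    gm <- cfg$group_map
    missing <- setdiff(nm, names(gm))
    if (length(missing))
      stop_gmyc("records missing from group map: ",
                paste(missing, collapse = ", "), class = "crosscheck_error")
    grp <- unname(unclass(gm)[nm])
    n_groups <- length(unique(grp))
    if (target < n_groups)
      stop_gmyc("target size ", target, " cannot represent ", n_groups,
                " groups", class = "representation_error")
    set.seed(seed)
    reps <- vapply(split(seq_len(n), grp),
                   function(ix) if (length(ix) == 1L) ix else sample(ix, 1L),
                   0L)
    pool <- setdiff(seq_len(n), reps)
    fill <- if (target - length(reps) > 0L)
      sample_exact(pool, target - length(reps)) else integer(0)
    keep <- sort(c(unname(reps), fill))
  } else {
    set.seed(seed)
    keep <- sort(sample_exact(seq_len(n), target))
  }
  aln[keep]
}

# sample() with the n == 1 surprise removed
sample_exact <- function(pool, size) {
  if (length(pool) == 1L) return(if (size >= 1L) pool else integer(0))
  sample(pool, size)
}

#' Generate and write a full replicate set
#'
#' Writes `n_replicates` FASTA files named
#' `subset_{fraction}_{rep:03d}.fasta` plus a provenance manifest
#' (`manifest.csv`: fraction, replicate, seed, record count, source
#' checksum). The same base seed yields byte-identical outputs.
#'
#' @param aln a [gmyc_alignment()].
#' @param cfg a [resample_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with `files`, `seeds`, `manifest`,
#'   `replicates` (the alignments).
#' @export
generate_replicates <- function(aln, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_gmyc("cannot create output directory ", out_dir, class = "io_error")
  src <- tempfile(fileext = ".fasta")
  on.exit(unlink(src))
  write_alignment(aln, src)
  checksum <- unname(tools::md5sum(src))

  idx <- seq_len(cfg$n_replicates) - 1L
  files <- file.path(out_dir, sprintf("subset_%s_%03d.fasta",
                                      format(cfg$fraction), idx))
  seeds <- vapply(idx, function(i) derive_seed(cfg$base_seed, i), 0L)
  reps <- vector("list", cfg$n_replicates)
  for (i in idx) {
    sub <- draw_subsample(aln, cfg, i)
    write_alignment(sub, files[i + 1L])
    reps[[i + 1L]] <- sub
  }
  manifest <- data.frame(fraction = cfg$fraction, replicate = idx,
                         seed = seeds,
                         n_records = lengths(reps),
                         file = basename(files),
                         source_md5 = checksum,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(files = files, seeds = seeds, manifest = manifest,
                 replicates = reps))
}
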