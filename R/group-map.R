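#' Construct a group map
#'
#' A group map assigns each sample (sequence/tip name) to one predefined
#' group label, e.g. a morphospecies or ecotype. Labels are kept verbatim
#' and are case-sensitive.
#'
#' @param samples character vector of unique sample names.
#' @param groups character vector of group labels, same length.
#' @return a named character vector of class `group_map` (names = samples,
#'   values = group labels).
#' @export
group_map <- function(samples, groups) {
  samples <- trimws(as.character(samples))
  groups <- trimws(as.character(groups))
  if (length(samples) != length(groups))
    stop_gmyc("samples and groups differ in length", class = "validation_error")
  if (length(samples) == 0L)
    stop_gmyc("empty group map", class = "empty_input_error")
  if (anyDuplicated(samples))
    stop_gmyc("duplicated sample names: ",
              paste(unique(samples[duplicated(samples)]), collapse = ", "),
              class = "validation_error")
  if (any(!nzchar(groups)))
    stop_gmyc("empty group labels are not allowed", class = "validation_error")
  structure(stats::setNames(groups, samples), class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat("GroupMap:", length(x), "samples in", length(unique(unclass(x))),
      "groups\n")
  invisible(x)
}

#' @export
`[.group_map` <- function(x, i) {
  structure(unclass(x)[i], class = "group_map")
}

#' Distinct group labels of a group map
#' @param gm a [group_map()].
#' @return character vector of distinct labels, in order of first appearance.
#' @export
group_labels <- function(gm) unique(as.character(unclass(gm)))

#' Read a group map from CSV
#'
#' The file must be comma-separated UTF-8 with a header row and columns
#' `sample_name` and `group` (in that order or found by name). Surrounding
#' whitespace is stripped; labels are otherwise preserved verbatim.
#'
#' @param path CSV file path.
#' @return a [group_map()].
#' @export
read_group_map <- function(path) {
  if (!file.exists(path))
    stop_gmyc("no such file: ", path, class = "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("sample_name", "group")
  if (!all(need %in% names(df)))
    stop_gmyc("group CSV must have columns 'sample_name' and 'group'; found: ",
              paste(names(df), collapse = ", "), class = "schema_error")
  group_map(df$sample_name, df$group)
}

#' Write a group map to CSV
#' @param gm a [group_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(gm, path) {
  utils::write.csv(data.frame(sample_name = names(gm),
                              group = as.character(unclass(gm)),
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
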