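#' Read an aligned FASTA file
#'
#' Reads a multiple-sequence alignment in FASTA format and validates that
#' all records have equal length.
#'
#' @param path FASTA file path.
#' @return character matrix (samples x sites), upper case, rownames = record
#'   ids.
#' @export
read_alignment <- function(path) {
  stopifnot(file.exists(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty alignment: ", path)
  len <- lengths(dna)
  if (length(unique(len)) != 1L) {
    bad <- names(dna)[len != len[1L]]
    stop("ragged alignment in ", path, ": record(s) ",
         paste(bad, collapse = ", "), " differ in length from the first")
  }
  aln <- toupper(do.call(rbind, as.character(dna)))
  rownames(aln) <- names(dna)
  aln
}

#' Write an alignment to FASTA
#'
#' Deterministic plain-text writer: one header line and one sequence line
#' per record, in row order.
#'
#' @param alignment character matrix (samples x sites).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  aln <- .as_alignment(alignment)
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1L, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Reads a tab-separated table with columns `sample`, `population`,
#' `group`, `latitude`, `longitude` and validates it: unique sample ids,
#' finite coordinates, non-empty populations, every population assigned to
#' a group.
#'
#' @param path TSV file path.
#' @return validated data.frame of class `population_map`.
#' @export
read_popmap <- function(path) {
  stopifnot(file.exists(path))
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_popmap(pm)
}

#' Validate a population map
#'
#' @param pop_map data.frame with columns `sample`, `population`, `group`,
#'   `latitude`, `longitude`.
#' @return the validated data.frame, classed `population_map`.
#' @export
validate_popmap <- function(pop_map) {
  need <- c("sample", "population", "group", "latitude", "longitude")
  missing_cols <- setdiff(need, names(pop_map))
  if (length(missing_cols) > 0L)
    stop("popmap lacks column(s): ", paste(missing_cols, collapse = ", "))
  dup <- pop_map$sample[duplicated(pop_map$sample)]
  if (length(dup) > 0L)
    stop("duplicate sample id(s) in popmap: ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(pop_map$latitude)) || !all(is.finite(pop_map$longitude)))
    stop("popmap coordinates must be finite")
  grp <- unique(pop_map[, c("population", "group")])
  if (anyDuplicated(grp$population))
    stop("population(s) assigned to more than one group: ",
         paste(grp$population[duplicated(grp$population)], collapse = ", "))
  class(pop_map) <- c("population_map", "data.frame")
  pop_map
}

#' Write a population map to TSV
#'
#' @param pop_map a population map data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pop_map, path) {
  utils::write.table(pop_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# check that every alignment row is mapped; returns popmap subset in
# alignment order
.match_popmap <- function(alignment, pop_map) {
  ids <- rownames(alignment)
  missing_ids <- setdiff(ids, pop_map$sample)
  if (length(missing_ids) > 0L)
    stop("sample(s) missing from popmap: ", paste(missing_ids, collapse = ", "))
  pop_map[match(ids, pop_map$sample), , drop = FALSE]
}
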