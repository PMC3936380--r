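# internal helpers shared across modules

# set RNG reproducibly when a seed is supplied; NULL leaves the stream alone
.seed_rng <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# alignment = character matrix, rows = samples, cols = sites, upper case
.as_alignment <- function(x) {
  if (inherits(x, "DNAbin")) x <- as.character(as.matrix(x))
  if (is.list(x) && !is.data.frame(x)) {
    len <- lengths(x)
    if (length(unique(len)) != 1L)
      stop("ragged alignment: records ",
           paste(names(x)[len != len[1L]], collapse = ", "),
           " differ in length from the first record")
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || !is.character(x))
    stop("alignment must be a character matrix (samples x sites)")
  if (nrow(x) == 0L) stop("empty alignment")
  x <- toupper(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  x
}

.GAP_CHARS <- c("-", "N", "?")

# integer coding of an alignment: A,C,G,T -> 1..4, gap/ambiguous -> NA,
# or 5 for gaps when fifth_state
.encode_alignment <- function(aln, gap_mode = c("missing", "fifth_state")) {
  gap_mode <- match.arg(gap_mode)
  aln <- .as_alignment(aln)
  code <- matrix(NA_integer_, nrow(aln), ncol(aln),
                 dimnames = list(rownames(aln), NULL))
  for (i in seq_len(4L)) code[aln == c("A", "C", "G", "T")[i]] <- i
  if (gap_mode == "fifth_state") code[aln == "-"] <- 5L
  code
}

#' Pairwise sequence differences
#'
#' Counts (or proportions) of differing sites for every pair of sequences in
#' an alignment.  Under `gap_mode = "missing"` any site where either sequence
#' of a pair carries a gap (or ambiguity) is excluded from that comparison
#' (pairwise deletion); under `"fifth_state"` the gap symbol is a fifth
#' character state and gap/base mismatches count as differences.
#'
#' @param alignment character matrix (samples x sites), `DNAbin`, or list of
#'   equal-length character vectors.
#' @param gap_mode `"missing"` or `"fifth_state"`.
#' @param proportion if `TRUE` return per-pair proportion of differing sites
#'   among compared sites instead of raw counts.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_differences <- function(alignment,
                                 gap_mode = c("missing", "fifth_state"),
                                 proportion = FALSE) {
  gap_mode <- match.arg(gap_mode)
  code <- .encode_alignment(alignment, gap_mode)
  n <- nrow(code)
  d <- matrix(0, n, n, dimnames = list(rownames(code), rownames(code)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]
    for (j in (i + 1L):n) {
      xj <- code[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      ndiff <- sum(xi[ok] != xj[ok])
      val <- if (proportion) {
        if (any(ok)) ndiff / sum(ok) else 0
      } else ndiff
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

# segregating sites: columns with >= 2 distinct non-missing states
.segregating_sites <- function(aln, gap_mode = "missing") {
  code <- .encode_alignment(aln, gap_mode)
  sum(apply(code, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L))
}

# harmonic mean
.hmean <- function(x) length(x) / sum(1 / x)
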