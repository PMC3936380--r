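#' Collapse aligned sequences into haplotypes
#'
#' Groups sequences that are identical under the chosen gap handling.
#' Under `gap_mode = "missing"`, sites where either sequence of a pair
#' carries a gap (or ambiguity) are ignored in the identity comparison, so
#' a sequence matches a haplotype when it agrees at every mutually resolved
#' site; because that relation is not transitive, sequences are assigned
#' greedily to the first matching haplotype in input order (the convention
#' of standard haplotype collapsers).  Under `"fifth_state"`, `-` is a
#' distinct character state and haplotypes are exact string classes.
#'
#' @param alignment character matrix (samples x sites), `DNAbin`, or list
#'   of equal-length character vectors.
#' @param gap_mode `"fifth_state"` (default) or `"missing"`.
#' @param pop_map optional population map (see [validate_popmap()]); when
#'   supplied, haplotype counts are tabulated per population, otherwise in
#'   a single column `all`.
#' @return object of class `haplotype_table`: list with `sequences` (named
#'   character vector of representative sequences), `assignment` (sample ->
#'   haplotype id), `counts` (haplotype x population integer matrix) and
#'   `gap_mode`.
#' @export
collapse_haplotypes <- function(alignment,
                                gap_mode = c("fifth_state", "missing"),
                                pop_map = NULL) {
  gap_mode <- match.arg(gap_mode)
  aln <- .as_alignment(alignment)
  if (nrow(aln) == 0L) stop("empty alignment")
  code <- .encode_alignment(aln, gap_mode)
  n <- nrow(aln)
  rep_idx <- integer(0)          # row index of each haplotype representative
  assign_idx <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (h in seq_along(rep_idx)) {
      a <- code[rep_idx[h], ]
      b <- code[i, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(a[ok] != b[ok])) { hit <- h; break }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      hit <- length(rep_idx)
    }
    assign_idx[i] <- hit
  }
  hap_ids <- paste0("H", seq_along(rep_idx))
  sequences <- stats::setNames(apply(aln[rep_idx, , drop = FALSE], 1L,
                                     paste0, collapse = ""), hap_ids)
  assignment <- stats::setNames(hap_ids[assign_idx], rownames(aln))
  if (!is.null(pop_map)) {
    pm <- .match_popmap(aln, pop_map)
    pops <- unique(pm$population)
    counts <- table(factor(hap_ids[assign_idx], levels = hap_ids),
                    factor(pm$population, levels = pops))
  } else {
    counts <- table(factor(hap_ids[assign_idx], levels = hap_ids),
                    rep("all", n))
  }
  counts <- matrix(as.integer(counts), nrow = length(hap_ids),
                   dimnames = list(hap_ids, colnames(counts)))
  structure(list(sequences = sequences, assignment = assignment,
                 counts = counts, gap_mode = gap_mode),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(length(x$sequences), "haplotypes among", sum(x$counts),
      "sequences (gaps as", if (x$gap_mode == "missing") "missing data"
      else "fifth state", ")\n")
  print(x$counts)
  invisible(x)
}

#' Pairwise mutational distances between haplotypes
#'
#' Mismatch counts between haplotype representative sequences, under the
#' table's own gap handling.
#'
#' @param haplotypes a [collapse_haplotypes()] result.
#' @return symmetric integer matrix (haplotype x haplotype).
#' @export
haplotype_distances <- function(haplotypes) {
  stopifnot(inherits(haplotypes, "haplotype_table"))
  aln <- do.call(rbind, strsplit(haplotypes$sequences, ""))
  rownames(aln) <- names(haplotypes$sequences)
  pairwise_differences(aln, gap_mode = haplotypes$gap_mode)
}

# probability that all j observed differences between two sequences of
# length m are single mutations, under a Poisson multiple-hit model with a
# Jukes-Cantor state chain.  lambda solves the JC relation
# (3/4)(1 - exp(-4 lambda / 3)) = j/m; the probability a differing site is
# parsimonious is P(exactly one hit) / P(site differs).
.parsimony_probability <- function(j, m) {
  q <- j / m
  if (q <= 0) return(1)
  # beyond the JC saturation point the divergence estimate is capped at
  # the largest estimable value, keeping the probability positive (and
  # vanishingly small) for every step count
  q <- min(q, 0.75 * (1 - 1e-6))
  lambda <- -(3 / 4) * log(1 - 4 * q / 3)
  p_site <- (lambda * exp(-lambda)) / q
  p_site^j
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps at which two haplotypes may be
#' connected while the probability that the connection is non-homoplasious
#' (every observed difference arose from a single mutation) still exceeds
#' the confidence level.  The probability is computed under a Poisson
#' multiple-hit model on a finite Jukes-Cantor locus; at 95% confidence
#' and 1417 bp the limit is 14 steps.
#'
#' @param locus_length alignment length in sites (>= 1).
#' @param confidence confidence level in (0, 1); default 0.95.
#' @return integer number of steps (>= 1).
#' @export
parsimony_connection_limit <- function(locus_length, confidence = 0.95) {
  stopifnot(.is_count(locus_length))
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1)
    stop("confidence must lie strictly between 0 and 1")
  limit <- 0L
  for (j in seq_len(locus_length)) {
    if (.parsimony_probability(j, locus_length) > confidence) limit <- j
    else break
  }
  max(limit, 1L)
}

#' Build a statistical-parsimony haplotype network
#'
#' Connects haplotypes whose mutational distance does not exceed the
#' connection limit, by minimum-spanning construction ordered by pairwise
#' distance.  Multi-step connections pass through inferred (unsampled)
#' intermediate nodes, one per extra step.  When alternative equal-length
#' connections would close a loop, the edge whose endpoints have the
#' higher total haplotype frequency is retained (a simplified frequency
#' criterion) and the discarded alternatives are reported.
#'
#' @param haplotypes a [collapse_haplotypes()] result.
#' @param limit connection limit in steps; default
#'   [parsimony_connection_limit()] at 95% for the locus length.
#' @return object of class `parsimony_network`: list with `graph` (an
#'   `igraph` graph whose nodes are haplotypes and intermediates, all
#'   edges one mutational step), `connections` (data.frame of accepted
#'   haplotype-pair connections with step counts), `discarded` (equal-cost
#'   alternatives skipped to avoid loops), `components` (haplotype ->
#'   component id), `limit` and `frequencies`.
#' @export
build_network <- function(haplotypes,
                          limit = parsimony_connection_limit(nchar(haplotypes$sequences[[1L]]))) {
  stopifnot(inherits(haplotypes, "haplotype_table"), .is_count(limit))
  d <- haplotype_distances(haplotypes)
  hap_ids <- rownames(d)
  freq <- rowSums(haplotypes$counts)[hap_ids]
  H <- length(hap_ids)
  if (H == 1L) {
    g <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(hap_ids, kind = "haplotype", frequency = freq)
    return(structure(list(graph = g,
                          connections = data.frame(),
                          discarded = data.frame(),
                          components = stats::setNames(1L, hap_ids),
                          limit = limit, frequencies = freq),
                     class = "parsimony_network"))
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pd <- d[pairs]
  keep <- pd <= limit & pd > 0
  pairs <- pairs[keep, , drop = FALSE]
  pd <- pd[keep]
  pf <- freq[pairs[, 1L]] + freq[pairs[, 2L]]
  ord <- order(pd, -pf)
  # union-find over haplotypes
  parent <- seq_len(H)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  conns <- list()
  disc <- list()
  for (k in ord) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      conns[[length(conns) + 1L]] <-
        data.frame(from = hap_ids[i], to = hap_ids[j], steps = pd[k],
                   stringsAsFactors = FALSE)
    } else {
      disc[[length(disc) + 1L]] <-
        data.frame(from = hap_ids[i], to = hap_ids[j], steps = pd[k],
                   stringsAsFactors = FALSE)
    }
  }
  connections <- if (length(conns)) do.call(rbind, conns) else
    data.frame(from = character(0), to = character(0), steps = numeric(0))
  # identical-distance alternatives that were skipped are the ambiguous
  # loops; longer skipped pairs are just redundant paths
  discarded <- if (length(disc)) do.call(rbind, disc) else
    data.frame(from = character(0), to = character(0), steps = numeric(0))

  # expand multi-step connections through anonymous intermediates
  edges <- character(0)
  inter <- character(0)
  for (r in seq_len(nrow(connections))) {
    a <- connections$from[r]; b <- connections$to[r]
    st <- connections$steps[r]
    if (st == 1) {
      edges <- c(edges, a, b)
    } else {
      mids <- paste0(a, ".", b, ".m", seq_len(st - 1L))
      inter <- c(inter, mids)
      chain <- c(a, mids, b)
      for (q in seq_len(length(chain) - 1L))
        edges <- c(edges, chain[q], chain[q + 1L])
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(hap_ids, kind = "haplotype",
                     frequency = unname(freq)) +
    igraph::vertices(inter, kind = "intermediate", frequency = 0)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership[hap_ids]
  structure(list(graph = g, connections = connections,
                 discarded = discarded, components = comp,
                 limit = limit, frequencies = freq),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  ncomp <- length(unique(x$components))
  cat("Parsimony network:", length(x$frequencies), "haplotypes,",
      nrow(x$connections), "connections,", ncomp,
      if (ncomp == 1L) "component" else "components",
      "(limit", x$limit, "steps)\n")
  if (nrow(x$discarded) > 0L)
    cat(nrow(x$discarded), "equal-cost alternative connection(s) discarded\n")
  invisible(x)
}

#' Write a network edge list to TSV
#'
#' Writes all single-step edges (`node1`, `node2`, `steps = 1`), including
#' those through inferred intermediates.
#'
#' @param network a [build_network()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "parsimony_network"))
  el <- igraph::as_edgelist(network$graph)
  df <- data.frame(node1 = el[, 1L], node2 = el[, 2L], steps = 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
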