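#' Pairwise distance matrix between sequences
#'
#' `model = "raw"` gives mismatch counts (pairwise deletion of gaps under
#' `gap_mode = "missing"`).  `model = "tamura_nei"` gives TN93-corrected
#' distances multiplied by the alignment length, so both models are on the
#' scale of substitution counts; if the TN93 transformation is undefined
#' for the data (e.g. zero base frequencies), raw distances are returned
#' with a warning.
#'
#' @param alignment character matrix (samples x sites) or compatible input.
#' @param model `"raw"` (default) or `"tamura_nei"`.
#' @param gap_mode gap handling for raw distances.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(alignment, model = c("raw", "tamura_nei"),
                                     gap_mode = c("missing", "fifth_state")) {
  model <- match.arg(model)
  gap_mode <- match.arg(gap_mode)
  aln <- .as_alignment(alignment)
  if (model == "raw")
    return(pairwise_differences(aln, gap_mode = gap_mode))
  dna <- ape::as.DNAbin(tolower(aln))
  d <- suppressWarnings(ape::dist.dna(dna, model = "TN93",
                                      pairwise.deletion = TRUE))
  d <- as.matrix(d) * ncol(aln)
  if (any(!is.finite(d))) {
    warning("TN93 distance undefined for this alignment; falling back to raw")
    return(pairwise_differences(aln, gap_mode = gap_mode))
  }
  dimnames(d) <- list(rownames(aln), rownames(aln))
  d
}

# Excoffier-Smouse-Quattro sums of squares and variance components from a
# matrix of squared distances.  pop: character vector per sample; group:
# named map population -> group, or NULL for a two-level analysis.
.amova_components <- function(d2, pop, group = NULL) {
  d2 <- as.matrix(d2)
  N <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  n_p <- as.numeric(table(factor(pop, levels = pops)))
  pair_sum <- function(rows) {
    if (length(rows) < 2L) return(0)
    sum(d2[rows, rows]) / 2
  }
  ss_total <- pair_sum(seq_len(N)) / N
  ss_wp <- sum(vapply(pops, function(p)
    pair_sum(which(pop == p)) / sum(pop == p), numeric(1L)))

  if (is.null(group)) {
    df_a <- P - 1L
    df_b <- N - P
    ss_a <- ss_total - ss_wp
    ms_a <- ss_a / df_a
    ms_b <- ss_wp / df_b
    n_prime <- (N - sum(n_p^2) / N) / df_a
    sigma_b <- ms_b
    sigma_a <- (ms_a - ms_b) / n_prime
    total <- sigma_a + sigma_b
    fst <- if (total > 0) sigma_a / total else NA_real_
    tab <- data.frame(
      source = c("Among populations", "Within populations", "Total"),
      df = c(df_a, df_b, df_a + df_b),
      SS = c(ss_a, ss_wp, ss_total),
      variance = c(sigma_a, sigma_b, total),
      percent = 100 * c(sigma_a, sigma_b, total) / total,
      stringsAsFactors = FALSE)
    return(list(table = tab,
                indices = c(F_ST = fst),
                sigma = c(a = sigma_a, b = sigma_b, total = total)))
  }

  grp_of_pop <- group[pops]
  if (anyNA(grp_of_pop)) stop("grouping must cover every population")
  groups <- unique(grp_of_pop)
  G <- length(groups)
  if (G < 2L) stop("grouping defines a single group; omit it for a two-level analysis")
  grp <- grp_of_pop[match(pop, pops)]
  N_g <- as.numeric(table(factor(grp, levels = groups)))
  ss_wg <- sum(vapply(groups, function(g)
    pair_sum(which(grp == g)) / sum(grp == g), numeric(1L)))
  ss_a <- ss_total - ss_wg          # among groups
  ss_b <- ss_wg - ss_wp             # among populations within groups
  df_a <- G - 1L
  df_b <- P - G
  df_c <- N - P
  ms_a <- ss_a / df_a
  ms_b <- if (df_b > 0L) ss_b / df_b else 0
  ms_c <- ss_wp / df_c
  # unequal-sample-size coefficients for the expected mean squares
  sum_np2_over_Ng <- sum(vapply(groups, function(g) {
    idx <- grp_of_pop == g
    sum(n_p[idx]^2) / sum(n_p[idx])
  }, numeric(1L)))
  n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / df_a
  n3 <- (N - sum(N_g^2) / N) / df_a
  sigma_c <- ms_c
  # with every population its own group there is no among-populations-
  # within-groups stratum and the design collapses to two levels
  sigma_b <- if (df_b > 0L) {
    n1 <- (N - sum_np2_over_Ng) / df_b
    (ms_b - sigma_c) / n1
  } else 0
  sigma_a <- (ms_a - sigma_c - n2 * sigma_b) / n3
  total <- sigma_a + sigma_b + sigma_c
  ind <- c(F_CT = if (total > 0) sigma_a / total else NA_real_,
           F_SC = if ((sigma_b + sigma_c) > 0) sigma_b / (sigma_b + sigma_c) else NA_real_,
           F_ST = if (total > 0) (sigma_a + sigma_b) / total else NA_real_)
  tab <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations", "Total"),
    df = c(df_a, df_b, df_c, N - 1L),
    SS = c(ss_a, ss_b, ss_wp, ss_total),
    variance = c(sigma_a, sigma_b, sigma_c, total),
    percent = 100 * c(sigma_a, sigma_b, sigma_c, total) / total,
    stringsAsFactors = FALSE)
  list(table = tab, indices = ind,
       sigma = c(a = sigma_a, b = sigma_b, c = sigma_c, total = total))
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical partition of molecular variance from a matrix of pairwise
#' differences (treated as squared distances, the molecular-variance
#' convention): among groups, among populations within groups, and within
#' populations, with variance components obtained by equating observed and
#' expected mean squares under unequal sample sizes, and fixation indices
#' `F_CT = sigma_a / sigma_T`, `F_SC = sigma_b / (sigma_b + sigma_c)`,
#' `F_ST = (sigma_a + sigma_b) / sigma_T`.  Without a grouping a two-level
#' analysis (among/within populations) is returned.  Permutation p-values
#' use the scheme appropriate to each index: individuals among populations
#' anywhere (`F_ST`), individuals among populations within their group
#' (`F_SC`), and whole populations among groups (`F_CT`).
#'
#' @param d square matrix of pairwise differences between samples (e.g.
#'   [pairwise_distance_matrix()]).
#' @param pop_map population map covering the rownames of `d`, or a
#'   character vector of population labels in row order.
#' @param grouping optional named character vector population -> group (or
#'   `NULL`).  When the popmap has a `group` column and `grouping` is
#'   `TRUE`, that column is used.
#' @param n_perm permutations for the significance tests (0 to skip).
#' @param seed optional integer seed.
#' @return object of class `amova_result`: list with `table` (df, SS,
#'   variance components, percent of variation), `indices`, `p_values` and
#'   `n_permutations`.
#' @export
amova <- function(d, pop_map, grouping = NULL, n_perm = 0L, seed = NULL) {
  .seed_rng(seed)
  d <- as.matrix(d)
  if (is.data.frame(pop_map) || inherits(pop_map, "population_map")) {
    pm <- pop_map[match(rownames(d), pop_map$sample), , drop = FALSE]
    if (anyNA(pm$sample)) stop("samples in d missing from popmap")
    pop <- pm$population
    if (isTRUE(grouping))
      grouping <- stats::setNames(pm$group, pm$population)[unique(pm$population)]
  } else {
    pop <- as.character(pop_map)
    stopifnot(length(pop) == nrow(d))
  }
  if (length(unique(pop)) < 2L) stop("need at least 2 populations")
  if (is.logical(grouping) && !grouping) grouping <- NULL
  res <- .amova_components(d, pop, grouping)
  p_values <- NULL
  if (n_perm > 0L) {
    p_values <- .amova_permutation(d, pop, grouping, res$indices, n_perm)
  }
  structure(list(table = res$table, indices = res$indices,
                 p_values = p_values, n_permutations = n_perm,
                 grouping = grouping),
            class = "amova_result")
}

# permutation p-values: (count >= observed + 1) / (n + 1)
.amova_permutation <- function(d, pop, grouping, observed, n_perm) {
  pops <- unique(pop)
  out <- stats::setNames(rep(NA_real_, length(observed)), names(observed))
  count <- stats::setNames(rep(0L, length(observed)), names(observed))
  for (r in seq_len(n_perm)) {
    if (is.null(grouping)) {
      perm_pop <- sample(pop)
      ind <- .amova_components(d, perm_pop, NULL)$indices
      if (is.finite(ind[["F_ST"]]) && ind[["F_ST"]] >= observed[["F_ST"]])
        count[["F_ST"]] <- count[["F_ST"]] + 1L
    } else {
      grp <- grouping[pop]
      # F_ST: individuals among populations across the whole system
      ind <- .amova_components(d, sample(pop), grouping)$indices
      if (is.finite(ind[["F_ST"]]) && ind[["F_ST"]] >= observed[["F_ST"]])
        count[["F_ST"]] <- count[["F_ST"]] + 1L
      # F_SC: individuals among populations within groups
      perm_pop <- pop
      for (g in unique(grp)) {
        idx <- which(grp == g)
        perm_pop[idx] <- sample(pop[idx])
      }
      ind <- .amova_components(d, perm_pop, grouping)$indices
      if (is.finite(ind[["F_SC"]]) && ind[["F_SC"]] >= observed[["F_SC"]])
        count[["F_SC"]] <- count[["F_SC"]] + 1L
      # F_CT: whole populations among groups
      perm_grouping <- stats::setNames(sample(grouping[pops]), pops)
      ind <- tryCatch(.amova_components(d, pop, perm_grouping)$indices,
                      error = function(e) NULL)
      if (!is.null(ind) && is.finite(ind[["F_CT"]]) &&
          ind[["F_CT"]] >= observed[["F_CT"]])
        count[["F_CT"]] <- count[["F_CT"]] + 1L
    }
  }
  (count + 1L) / (n_perm + 1L)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Analysis of molecular variance\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 3)
  tab$variance <- round(tab$variance, 5)
  tab$percent <- round(tab$percent, 2)
  print(tab, row.names = FALSE)
  cat("Fixation indices:",
      paste(sprintf("%s = %.4f", names(x$indices), x$indices), collapse = ", "),
      "\n")
  if (!is.null(x$p_values))
    cat("Permutation P:",
        paste(sprintf("%s: %.4g", names(x$p_values), x$p_values), collapse = ", "),
        sprintf("(%d permutations)\n", x$n_permutations))
  invisible(x)
}
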