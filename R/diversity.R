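#' Haplotype (gene) diversity
#'
#' Nei's unbiased gene diversity `h = n/(n-1) (1 - sum p_i^2)` from
#' haplotype counts.
#'
#' @param counts non-negative integer vector of haplotype counts.
#' @return `h` in `[0, 1]`; `NA` (with a warning) when fewer than two
#'   sequences are available.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) {
    warning("haplotype diversity undefined for n < 2")
    return(NA_real_)
  }
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity
#'
#' Mean pairwise proportion of differing sites over all sequence pairs,
#' with pairwise deletion of gap-containing comparisons under
#' `gap_mode = "missing"`.
#'
#' @param alignment character matrix (samples x sites) or compatible input.
#' @param gap_mode `"missing"` (default) or `"fifth_state"`.
#' @return nucleotide diversity per site (>= 0).
#' @export
nucleotide_diversity <- function(alignment, gap_mode = c("missing", "fifth_state")) {
  gap_mode <- match.arg(gap_mode)
  aln <- .as_alignment(alignment)
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  d <- pairwise_differences(aln, gap_mode = gap_mode, proportion = TRUE)
  mean(d[upper.tri(d)])
}

#' Per-population diversity table
#'
#' Sample size, haplotype diversity and nucleotide diversity for each
#' population.
#'
#' @param alignment character matrix (samples x sites).
#' @param pop_map population map covering every sample.
#' @param gap_mode gap handling for both haplotype identity and nucleotide
#'   diversity.
#' @return data.frame with columns `population`, `n`, `h`, `pi`.
#' @export
population_diversity <- function(alignment, pop_map,
                                 gap_mode = c("fifth_state", "missing")) {
  gap_mode <- match.arg(gap_mode)
  aln <- .as_alignment(alignment)
  pm <- .match_popmap(aln, pop_map)
  ht <- collapse_haplotypes(aln, gap_mode = gap_mode, pop_map = pm)
  pops <- colnames(ht$counts)
  out <- data.frame(population = pops,
                    n = colSums(ht$counts),
                    h = NA_real_, pi = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_along(pops)) {
    rows <- pm$population == pops[k]
    out$h[k] <- if (sum(rows) >= 2)
      suppressWarnings(haplotype_diversity(ht$counts[, k])) else NA_real_
    out$pi[k] <- if (sum(rows) >= 2)
      nucleotide_diversity(aln[rows, , drop = FALSE],
                           gap_mode = if (gap_mode == "fifth_state") "fifth_state" else "missing")
      else NA_real_
  }
  out
}

#' Pairwise Phi-ST between populations
#'
#' For every population pair, computes Phi-ST as a two-population AMOVA on
#' the pairwise-difference matrix, with a permutation test that reshuffles
#' individuals between the two populations.
#'
#' @param d square matrix of pairwise differences between samples (treated
#'   as squared distances, as in molecular-variance analysis).
#' @param pop_map population map covering every sample (rownames of `d`).
#' @param n_perm permutations per pair (default 1000).
#' @param seed optional integer seed.
#' @return list with matrices `fst` (Phi-ST values) and `p` (permutation
#'   p-values); populations with fewer than two samples are dropped with a
#'   warning.
#' @export
pairwise_fst <- function(d, pop_map, n_perm = 1000L, seed = NULL) {
  .seed_rng(seed)
  d <- as.matrix(d)
  pm <- pop_map[match(rownames(d), pop_map$sample), , drop = FALSE]
  if (anyNA(pm$sample)) stop("samples in d missing from popmap")
  sizes <- table(pm$population)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0L) {
    warning("population(s) with n < 2 excluded: ", paste(small, collapse = ", "))
    keep <- pm$population %in% names(sizes)[sizes >= 2]
    d <- d[keep, keep, drop = FALSE]
    pm <- pm[keep, , drop = FALSE]
  }
  pops <- unique(pm$population)
  P <- length(pops)
  if (P < 2L) stop("need at least 2 populations with n >= 2")
  fst <- p <- matrix(0, P, P, dimnames = list(pops, pops))
  for (a in seq_len(P - 1L)) {
    for (b in (a + 1L):P) {
      rows <- pm$population %in% pops[c(a, b)]
      dd <- d[rows, rows, drop = FALSE]
      labels <- pm$population[rows]
      obs <- .phi_st_two_pop(dd, labels)
      exceed <- 0L
      for (r in seq_len(n_perm)) {
        perm <- sample(labels)
        if (.phi_st_two_pop(dd, perm) >= obs) exceed <- exceed + 1L
      }
      fst[a, b] <- fst[b, a] <- obs
      p[a, b] <- p[b, a] <- (exceed + 1L) / (n_perm + 1L)
    }
  }
  list(fst = fst, p = p)
}

# Phi-ST from a two-level AMOVA on one pair of populations
.phi_st_two_pop <- function(d, labels) {
  res <- .amova_components(d, labels, group = NULL)
  res$indices[["F_ST"]]
}

#' Pons-Petit differentiation for unordered and ordered haplotypes
#'
#' Estimates within- and total-population diversity for unordered
#' haplotypes (`hS`, `hT`, identity distance) and ordered haplotypes
#' (`vS`, `vT`, weighted by mutational distances), with the
#' differentiation coefficients `G_ST = 1 - hS/hT` and
#' `N_ST = 1 - vS/vT`.  Small-sample corrections follow the
#' Pons-Petit/Nei-Chesser estimators: per-population diversities use
#' `n/(n-1)` debiasing, populations are weighted equally, and the total
#' diversity adds `hS/(n_harmonic K)`.  Standard errors are obtained by
#' delete-one-population jackknife.  The phylogeographic-signal test
#' permutes haplotype identities on the distance matrix (rows/columns
#' shuffled jointly), recomputing `N_ST` each time; the one-sided p-value
#' is the fraction of permutations with `N_ST - G_ST` at least the
#' observed difference (with add-one correction).
#'
#' @param counts haplotype x population matrix of non-negative counts.
#' @param distances symmetric haplotype distance matrix with zero
#'   diagonal, e.g. [haplotype_distances()] or network step counts.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return object of class `permut_result`: list with `hS`, `hT`, `vS`,
#'   `vT`, `GST`, `NST`, their jackknife standard errors (`se`),
#'   `p_value`, `n_permutations` and a `flags` character vector.
#' @export
pons_petit <- function(counts, distances, n_perm = 1000L, seed = NULL) {
  .seed_rng(seed)
  counts <- as.matrix(counts)
  distances <- as.matrix(distances)
  H <- nrow(counts)
  stopifnot(nrow(distances) == H, ncol(distances) == H)
  if (max(abs(distances - t(distances))) > 1e-12 || any(diag(distances) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  keep <- colSums(counts) >= 2
  if (!all(keep)) {
    warning("population(s) with n < 2 excluded: ",
            paste(colnames(counts)[!keep], collapse = ", "))
    counts <- counts[, keep, drop = FALSE]
  }
  K <- ncol(counts)
  if (K < 2L) stop("need at least 2 populations")

  est <- .pons_petit_estimates(counts, distances)
  flags <- character(0)
  if (!is.finite(est$GST)) flags <- c(flags, "GST undefined (hT = 0)")
  if (!is.finite(est$NST)) flags <- c(flags, "NST undefined (vT = 0)")
  if (any(unlist(est[c("GST", "NST")]) < 0, na.rm = TRUE))
    flags <- c(flags, "negative differentiation estimate")

  # delete-one-population jackknife SEs
  jk <- matrix(NA_real_, K, 6L,
               dimnames = list(NULL, c("hS", "hT", "vS", "vT", "GST", "NST")))
  if (K > 2L) {
    for (k in seq_len(K)) {
      e <- .pons_petit_estimates(counts[, -k, drop = FALSE], distances)
      jk[k, ] <- unlist(e[colnames(jk)])
    }
    se <- apply(jk, 2L, function(x)
      sqrt((K - 1) / K * sum((x - mean(x))^2)))
  } else {
    se <- stats::setNames(rep(NA_real_, 6L), colnames(jk))
  }

  obs_delta <- est$NST - est$GST
  p_value <- NA_real_
  if (is.finite(obs_delta) && n_perm > 0L) {
    exceed <- 0L
    for (r in seq_len(n_perm)) {
      perm <- sample.int(H)
      e <- .pons_petit_estimates(counts, distances[perm, perm, drop = FALSE])
      if ((e$NST - e$GST) >= obs_delta) exceed <- exceed + 1L
    }
    p_value <- (exceed + 1L) / (n_perm + 1L)
  }
  structure(c(est, list(se = se, p_value = p_value,
                        n_permutations = n_perm, flags = flags)),
            class = "permut_result")
}

# core Pons-Petit estimators for a counts matrix and distance matrix
.pons_petit_estimates <- function(counts, distances) {
  n_k <- colSums(counts)
  K <- ncol(counts)
  p <- sweep(counts, 2L, n_k, "/")
  corr <- n_k / (n_k - 1)
  h_k <- corr * (1 - colSums(p^2))
  v_k <- corr * diag(t(p) %*% distances %*% p)
  hS <- mean(h_k)
  vS <- mean(v_k)
  pbar <- rowMeans(p)
  nh <- .hmean(n_k)
  hT <- 1 - sum(pbar^2) + hS / (nh * K)
  vT <- drop(pbar %*% distances %*% pbar) + vS / (nh * K)
  GST <- if (hT > 0) 1 - hS / hT else NA_real_
  NST <- if (vT > 0) 1 - vS / vT else NA_real_
  list(hS = hS, hT = hT, vS = vS, vT = vT, GST = GST, NST = NST)
}

#' @export
print.permut_result <- function(x, ...) {
  fmt <- function(v, s) sprintf("%.4f (SE %.4f)", v,
                                if (is.finite(s)) s else NA)
  cat("Pons-Petit diversity and differentiation\n")
  cat("  hS =", fmt(x$hS, x$se[["hS"]]), "  hT =", fmt(x$hT, x$se[["hT"]]), "\n")
  cat("  vS =", fmt(x$vS, x$se[["vS"]]), "  vT =", fmt(x$vT, x$se[["vT"]]), "\n")
  cat(sprintf("  GST = %.4f   NST = %.4f\n", x$GST, x$NST))
  cat(sprintf("  one-sided P(NST > GST) = %.4g (%d permutations)\n",
              x$p_value, x$n_permutations))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
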