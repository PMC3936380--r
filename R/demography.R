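# single-deme coalescent in mutational time units: mutations accrue at
# rate 1 per lineage per unit time, pairs coalesce at rate 2/theta(s).
# theta(s) = theta1 for s < tau/2 (present epoch) and theta0 beyond, which
# reproduces the sudden-expansion model; constant size is tau = Inf.
# Returns branch lengths and the tip set below each branch.
.sim_coal_branches <- function(n, theta1 = 1, theta0 = theta1, tau = Inf) {
  stopifnot(n >= 2L)
  active_tips <- lapply(seq_len(n), identity)
  birth <- rep(0, n)
  lengths <- numeric(2L * n - 2L)
  tipsets <- vector("list", 2L * n - 2L)
  nb <- 0L
  s <- 0
  boundary <- tau / 2
  while (length(active_tips) > 1L) {
    k <- length(active_tips)
    th <- if (s < boundary) theta1 else theta0
    w <- rexp(1L, k * (k - 1L) / th)
    if (s < boundary && s + w > boundary) {
      # crossing the size change: restart the (memoryless) wait there
      s <- boundary
      next
    }
    s <- s + w
    pair <- sample.int(k, 2L)
    for (x in pair) {
      nb <- nb + 1L
      lengths[nb] <- s - birth[x]
      tipsets[[nb]] <- active_tips[[x]]
    }
    merged <- c(active_tips[[pair[1L]]], active_tips[[pair[2L]]])
    keep <- setdiff(seq_len(k), pair)
    active_tips <- c(active_tips[keep], list(merged))
    birth <- c(birth[keep], s)
  }
  list(lengths = lengths[seq_len(nb)], tipsets = tipsets[seq_len(nb)], n = n)
}

# pairwise-difference matrix from simulated branches: mutations per branch
# are Poisson(length) (or a fixed total S spread multinomially), and a
# mutation on a branch separates the tips below it from the rest
.branch_mutations <- function(br, S_fixed = NULL) {
  if (is.null(S_fixed)) {
    rpois(length(br$lengths), br$lengths)
  } else {
    as.integer(stats::rmultinom(1L, S_fixed, prob = br$lengths))
  }
}

.pair_diffs_from_branches <- function(br, muts) {
  n <- br$n
  d <- matrix(0, n, n)
  for (b in which(muts > 0L)) {
    inside <- br$tipsets[[b]]
    outside <- setdiff(seq_len(n), inside)
    d[inside, outside] <- d[inside, outside] + muts[b]
  }
  d + t(d)
}

# Tajima's standard constants
.tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D neutrality test
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants, where `pi` is the mean number of pairwise differences and
#' `S` the number of segregating sites.  The p-value is the proportion of
#' neutral constant-size coalescent simulations (conditioned on `S`
#' mutations placed on the genealogy) with `D` at most the observed value,
#' so small p indicates a significant negative `D` (excess of rare
#' variants, as under population growth).
#'
#' @param alignment character matrix (samples x sites) or compatible input.
#' @param n_sim coalescent simulations for the p-value (default 1000; 0
#'   skips it).
#' @param gap_mode gap handling for differences and segregating sites.
#' @param seed optional integer seed.
#' @return list with `D`, `p_value`, `n`, `S`, `pi` and `flags`.
#' @export
tajimas_d <- function(alignment, n_sim = 1000L,
                      gap_mode = c("missing", "fifth_state"), seed = NULL) {
  gap_mode <- match.arg(gap_mode)
  .seed_rng(seed)
  aln <- .as_alignment(alignment)
  n <- nrow(aln)
  if (n < 4L) stop("Tajima's D needs at least 4 sequences")
  S <- .segregating_sites(aln, gap_mode)
  dd <- pairwise_differences(aln, gap_mode = gap_mode)
  pi_hat <- mean(dd[upper.tri(dd)])
  if (S == 0L) {
    return(list(D = NA_real_, p_value = NA_real_, n = n, S = 0L, pi = pi_hat,
                flags = "undefined: no segregating sites"))
  }
  cst <- .tajima_constants(n)
  D <- (pi_hat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  p <- NA_real_
  if (n_sim > 0L) {
    npairs <- n * (n - 1) / 2
    d_sim <- vapply(seq_len(n_sim), function(r) {
      br <- .sim_coal_branches(n)
      m <- .branch_mutations(br, S_fixed = S)
      sizes <- lengths(br$tipsets)
      pi_s <- sum(m * sizes * (n - sizes)) / npairs
      (pi_s - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    }, numeric(1L))
    p <- mean(d_sim <= D)
  }
  list(D = D, p_value = p, n = n, S = S, pi = pi_hat, flags = character(0))
}

# log unsigned Stirling numbers of the first kind, row n: |S(n, k)|,
# k = 1..n, via the recurrence in log space
.log_stirling_row <- function(n) {
  ls <- c(0, rep(-Inf, n - 1L))              # row 1: |S(1,1)| = 1
  if (n == 1L) return(ls)
  for (m in 2L:n) {
    new <- rep(-Inf, n)
    for (k in seq_len(m)) {
      terms <- c(if (k > 1L) ls[k - 1L] else -Inf,
                 log(m - 1) + ls[k])
      mx <- max(terms)
      new[k] <- if (is.finite(mx)) mx + log(sum(exp(terms - mx))) else -Inf
    }
    ls <- new
  }
  ls
}

# log Ewens sampling probabilities P(K = k | theta), k = 1..n
.log_ewens_pk <- function(n, theta) {
  ls <- .log_stirling_row(n)
  log_rising <- sum(log(theta + 0:(n - 1L)))
  ls + seq_len(n) * log(theta) - log_rising
}

.logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fu's Fs statistic
#'
#' `S' = P(K >= k_observed | theta)` under the Ewens sampling
#' distribution, `P(K = k) = |S(n, k)| theta^k / theta_(n)` with unsigned
#' Stirling numbers of the first kind and the rising factorial, evaluated
#' in log space; `Fs = ln(S' / (1 - S'))`.  Large negative values (an
#' excess of haplotypes relative to the pairwise diversity) indicate
#' population growth.  The optional p-value simulates `K` under the Ewens
#' distribution at the same `theta` and reports the proportion of
#' simulated `Fs` at most the observed.
#'
#' @param n sample size (>= 2).
#' @param k_observed observed number of distinct haplotypes (1..n).
#' @param theta_pi diversity estimate (mean pairwise differences; > 0).
#' @param n_sim simulations for the p-value (0 skips it).
#' @param seed optional integer seed.
#' @return list with `Fs`, `S_prime`, `p_value`, `n`, `k`, `theta` and
#'   `flags` (non-empty when `S'` is numerically 0 or 1 and `Fs` is
#'   infinite).
#' @export
fus_fs <- function(n, k_observed, theta_pi, n_sim = 0L, seed = NULL) {
  stopifnot(.is_count(n), n >= 2, .is_count(k_observed),
            k_observed >= 1, k_observed <= n)
  if (!is.numeric(theta_pi) || theta_pi <= 0)
    stop("theta_pi must be positive")
  .seed_rng(seed)
  lpk <- .log_ewens_pk(n, theta_pi)
  log_up <- .logsumexp(lpk[k_observed:n])          # log S'
  log_down <- if (k_observed > 1L) .logsumexp(lpk[1:(k_observed - 1L)]) else -Inf
  Fs <- log_up - log_down
  S_prime <- exp(log_up)
  flags <- character(0)
  if (!is.finite(Fs))
    flags <- sprintf("S' numerically %s; Fs unbounded", format(round(S_prime)))
  p <- NA_real_
  if (n_sim > 0L) {
    # Ewens K by the sequential (Hoppe urn) construction
    pr_new <- theta_pi / (theta_pi + seq_len(n - 1L))
    fs_sim <- vapply(seq_len(n_sim), function(r) {
      k_sim <- 1L + sum(runif(n - 1L) < pr_new)
      up <- .logsumexp(lpk[k_sim:n])
      dn <- if (k_sim > 1L) .logsumexp(lpk[1:(k_sim - 1L)]) else -Inf
      up - dn
    }, numeric(1L))
    p <- mean(fs_sim <= Fs)
  }
  list(Fs = Fs, S_prime = S_prime, p_value = p, n = n, k = k_observed,
       theta = theta_pi, flags = flags)
}

#' Expected mismatch distribution under sudden expansion
#'
#' The expected relative frequencies of pairwise difference counts
#' `i = 0, 1, ...` for a population that changed scaled diversity from
#' `theta0` to `theta1` at mutational time `tau` before present:
#' `F_i = Fhat_i(theta1) + exp(-tau (theta1 + 1) / theta1) *
#' sum_j tau^j / j! (Fhat_{i-j}(theta0) - Fhat_{i-j}(theta1))`, where
#' `Fhat_i(theta) = theta^i / (theta + 1)^{i+1}` is the equilibrium
#' distribution.  The full distribution over `i = 0..Inf` sums to one;
#' any finite support is a truncation.
#'
#' @param i vector of non-negative integer difference counts.
#' @param tau expansion time in mutational units (>= 0).
#' @param theta0 pre-expansion diversity (>= 0).
#' @param theta1 post-expansion diversity (>= theta0 in the expansion
#'   model; not enforced so the fitter can explore).
#' @return numeric vector of expected frequencies.
#' @export
mismatch_expected <- function(i, tau, theta0, theta1) {
  stopifnot(all(i >= 0), tau >= 0, theta0 >= 0, theta1 >= 0)
  eq <- function(j, th) if (th == 0) as.numeric(j == 0) else
    exp(j * log(th) - (j + 1) * log(th + 1))
  imax <- max(i)
  j <- 0:imax
  f1 <- eq(j, theta1)
  f0 <- eq(j, theta0)
  log_pref <- -tau * (theta1 + 1) / max(theta1, .Machine$double.eps)
  pois <- if (tau == 0) c(exp(log_pref), rep(0, imax)) else
    exp(log_pref + j * log(tau) - lgamma(j + 1))
  # convolution sum_{k<=i} pois_k (f0_{i-k} - f1_{i-k})
  out <- f1
  diff0 <- f0 - f1
  for (ii in j) out[ii + 1L] <- f1[ii + 1L] +
    sum(pois[1:(ii + 1L)] * rev(diff0[1:(ii + 1L)]))
  out[i + 1L]
}

#' Harpending's raggedness of a mismatch distribution
#'
#' Sum of squared successive differences of the relative frequencies;
#' smooth (expansion-like) distributions have small values.
#'
#' @param f numeric vector of relative frequencies.
#' @return raggedness index.
#' @export
raggedness <- function(f) {
  stopifnot(is.numeric(f), length(f) >= 2L)
  sum(diff(f)^2)
}

# least-squares fit of (tau, theta0, theta1) to an observed mismatch
# distribution; multiple moment-based restarts, optimization on log scale
.fit_mismatch <- function(f_obs) {
  support <- seq_along(f_obs) - 1L
  mean_d <- sum(support * f_obs)
  ssd_of <- function(par) {
    tau <- exp(par[1L]); th0 <- exp(par[2L]); th1 <- th0 + exp(par[3L])
    sum((f_obs - mismatch_expected(support, tau, th0, th1))^2)
  }
  starts <- list(c(log(max(mean_d, 0.1)), log(0.05), log(max(10 * mean_d, 5))),
                 c(log(max(mean_d / 2, 0.1)), log(0.5), log(max(mean_d, 1))),
                 c(log(max(2 * mean_d, 0.2)), log(0.01), log(50)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(stats::optim(st, ssd_of, method = "Nelder-Mead",
                                 control = list(maxit = 400)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  par <- best$par
  list(tau = exp(par[1L]), theta0 = exp(par[2L]),
       theta1 = exp(par[2L]) + exp(par[3L]), ssd = best$value)
}

#' Mismatch-distribution analysis under the sudden-expansion model
#'
#' Fits the sudden-expansion parameters (`tau`, `theta0`, `theta1`) to the
#' observed distribution of pairwise difference counts by nonlinear least
#' squares on the sum of squared deviations (SSD), and assesses
#' goodness-of-fit of the expansion model by parametric bootstrap:
#' coalescent datasets are simulated under the fitted expansion, refit,
#' and `p_SSD` (and `p_Hri` for the raggedness index) is the proportion of
#' simulated statistics at least as large as the observed.  Small p
#' rejects the sudden-expansion model.
#'
#' @param alignment character matrix (samples x sites) or compatible input.
#' @param n_bootstrap parametric bootstrap replicates (default 1000; the
#'   conventional reporting default is 10000).
#' @param gap_mode gap handling for the pairwise differences.
#' @param seed optional integer seed.
#' @return object of class `mismatch_result`: list with `tau`, `theta0`,
#'   `theta1`, `observed` and `expected` (relative frequency vectors over
#'   0..max differences), `SSD`, `Hri`, `p_SSD`, `p_Hri`, `n_bootstrap`.
#' @export
mismatch_fit <- function(alignment, n_bootstrap = 1000L,
                         gap_mode = c("missing", "fifth_state"), seed = NULL) {
  gap_mode <- match.arg(gap_mode)
  .seed_rng(seed)
  aln <- .as_alignment(alignment)
  n <- nrow(aln)
  if (n < 3L) stop("mismatch analysis needs at least 3 sequences")
  dd <- pairwise_differences(aln, gap_mode = gap_mode)
  diffs <- dd[upper.tri(dd)]
  dmax <- max(diffs)
  if (dmax == 0) {
    obs <- 1
    names(obs) <- "0"
    return(structure(list(tau = 0, theta0 = 0, theta1 = 0,
                          observed = obs, expected = obs,
                          SSD = 0, Hri = NA_real_, p_SSD = 1, p_Hri = NA_real_,
                          n_bootstrap = 0L),
                     class = "mismatch_result"))
  }
  f_obs <- tabulate(diffs + 1L, nbins = dmax + 1L) / length(diffs)
  names(f_obs) <- 0:dmax
  fit <- .fit_mismatch(f_obs)
  expected <- mismatch_expected(0:dmax, fit$tau, fit$theta0, fit$theta1)
  ssd_obs <- fit$ssd
  hri_obs <- raggedness(f_obs)
  p_ssd <- p_hri <- NA_real_
  if (n_bootstrap > 0L) {
    ssd_sim <- hri_sim <- numeric(n_bootstrap)
    for (r in seq_len(n_bootstrap)) {
      br <- .sim_coal_branches(n, theta1 = fit$theta1, theta0 = fit$theta0,
                               tau = fit$tau)
      dsim <- .pair_diffs_from_branches(br, .branch_mutations(br))
      ds <- dsim[upper.tri(dsim)]
      fm <- tabulate(ds + 1L, nbins = max(ds) + 1L) / length(ds)
      if (length(fm) < 2L) fm <- c(fm, 0)
      ssd_sim[r] <- .fit_mismatch(fm)$ssd
      hri_sim[r] <- raggedness(fm)
    }
    p_ssd <- (sum(ssd_sim >= ssd_obs) + 1L) / (n_bootstrap + 1L)
    p_hri <- (sum(hri_sim >= hri_obs) + 1L) / (n_bootstrap + 1L)
  }
  structure(list(tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 observed = f_obs, expected = expected,
                 SSD = ssd_obs, Hri = hri_obs,
                 p_SSD = p_ssd, p_Hri = p_hri,
                 n_bootstrap = n_bootstrap),
            class = "mismatch_result")
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat(sprintf("Sudden-expansion mismatch fit: tau = %.3f, theta0 = %.4f, theta1 = %.3f\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f (p = %.4g), raggedness = %.5f (p = %.4g), %d bootstrap replicates\n",
              x$SSD, x$p_SSD, x$Hri, x$p_Hri, x$n_bootstrap))
  invisible(x)
}
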