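#' Neighborhood graph of populations by Delaunay triangulation
#'
#' Computes the Delaunay adjacency of population coordinates by the
#' empty-circumcircle criterion (brute force over triangles; adequate for
#' the tens of populations typical of a phylogeographic survey).
#' Collinear layouts fall back to chain adjacency along the transect, and
#' a disconnected result (possible after degeneracies) is repaired by
#' adding the nearest-neighbor edge between components, with a warning.
#'
#' @param coords numeric matrix (populations x 2, e.g. longitude/latitude)
#'   with rownames.
#' @return symmetric logical adjacency matrix.
#' @export
delaunay_adjacency <- function(coords) {
  coords <- as.matrix(coords)
  P <- nrow(coords)
  stopifnot(P >= 2L, ncol(coords) == 2L, all(is.finite(coords)))
  if (is.null(rownames(coords))) rownames(coords) <- paste0("P", seq_len(P))
  adj <- matrix(FALSE, P, P, dimnames = list(rownames(coords), rownames(coords)))
  if (P == 2L) {
    adj[1L, 2L] <- adj[2L, 1L] <- TRUE
    return(adj)
  }
  centered <- sweep(coords, 2L, colMeans(coords))
  sv <- svd(centered)$d
  scale_len <- max(sv[1L], .Machine$double.eps)
  if (sv[2L] / scale_len < 1e-9) {
    # collinear: chain along the principal axis
    proj <- centered %*% svd(centered)$v[, 1L]
    ord <- order(proj)
    for (i in seq_len(P - 1L))
      adj[ord[i], ord[i + 1L]] <- adj[ord[i + 1L], ord[i]] <- TRUE
    return(adj)
  }
  tol <- 1e-9 * scale_len^2
  for (tri in utils::combn(P, 3L, simplify = FALSE)) {
    a <- coords[tri[1L], ]; b <- coords[tri[2L], ]; c <- coords[tri[3L], ]
    den <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
                  c[1L] * (a[2L] - b[2L]))
    if (abs(den) < tol) next                    # degenerate triangle
    ux <- ((sum(a^2)) * (b[2L] - c[2L]) + (sum(b^2)) * (c[2L] - a[2L]) +
             (sum(c^2)) * (a[2L] - b[2L])) / den
    uy <- ((sum(a^2)) * (c[1L] - b[1L]) + (sum(b^2)) * (a[1L] - c[1L]) +
             (sum(c^2)) * (b[1L] - a[1L])) / den
    r2 <- sum((a - c(ux, uy))^2)
    others <- setdiff(seq_len(P), tri)
    d2 <- (coords[others, 1L] - ux)^2 + (coords[others, 2L] - uy)^2
    if (all(d2 > r2 * (1 - 1e-9))) {
      adj[tri[1L], tri[2L]] <- adj[tri[2L], tri[1L]] <- TRUE
      adj[tri[1L], tri[3L]] <- adj[tri[3L], tri[1L]] <- TRUE
      adj[tri[2L], tri[3L]] <- adj[tri[3L], tri[2L]] <- TRUE
    }
  }
  # repair disconnection if degeneracies left isolated parts
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    warning("adjacency graph disconnected; joining components by nearest edge")
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    first <- which(comp$membership == 1L)
    rest <- which(comp$membership != 1L)
    for (i in first) for (j in rest) {
      dd <- sum((coords[i, ] - coords[j, ])^2)
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    adj[best[1L], best[2L]] <- adj[best[2L], best[1L]] <- TRUE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
  }
  adj
}

# population-pair sums of squared distances: diagonal = within-population
# pair sum, off-diagonal = full cross sum (each unordered pair once)
.pop_pair_sums <- function(d2, pop, pops) {
  P <- length(pops)
  W <- matrix(0, P, P, dimnames = list(pops, pops))
  idx <- split(seq_along(pop), factor(pop, levels = pops))
  for (p in seq_len(P)) {
    W[p, p] <- sum(d2[idx[[p]], idx[[p]]]) / 2
    if (p < P) for (q in (p + 1L):P) {
      W[p, q] <- W[q, p] <- sum(d2[idx[[p]], idx[[q]]])
    }
  }
  W
}

# F_CT of a grouping evaluated from precomputed population-pair sums
.phi_ct_fast <- function(assign, W, n_p, ss_total, ss_wp, N) {
  G <- max(assign)
  P <- length(assign)
  ss_wg <- 0
  sum_np2_over_Ng <- 0
  N_g <- numeric(G)
  for (g in seq_len(G)) {
    S <- which(assign == g)
    Ng <- sum(n_p[S])
    if (Ng == 0) return(NA_real_)
    N_g[g] <- Ng
    Wg <- W[S, S, drop = FALSE]
    ss_wg <- ss_wg + (sum(Wg) + sum(diag(Wg))) / 2 / Ng
    sum_np2_over_Ng <- sum_np2_over_Ng + sum(n_p[S]^2) / Ng
  }
  df_a <- G - 1L; df_b <- P - G; df_c <- N - P
  if (df_b <= 0L) return(NA_real_)
  ss_a <- ss_total - ss_wg
  ss_b <- ss_wg - ss_wp
  ms_a <- ss_a / df_a; ms_b <- ss_b / df_b; ms_c <- ss_wp / df_c
  n1 <- (N - sum_np2_over_Ng) / df_b
  n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / df_a
  n3 <- (N - sum(N_g^2) / N) / df_a
  sigma_c <- ms_c
  sigma_b <- (ms_b - sigma_c) / n1
  sigma_a <- (ms_a - sigma_c - n2 * sigma_b) / n3
  total <- sigma_a + sigma_b + sigma_c
  if (total <= 0) return(NA_real_)
  sigma_a / total
}

# is the set S connected under adjacency?
.is_connected_subset <- function(S, adj) {
  if (length(S) <= 1L) return(TRUE)
  seen <- S[1L]
  frontier <- S[1L]
  while (length(frontier) > 0L) {
    nb <- which(rowSums(adj[, frontier, drop = FALSE]) > 0)
    nb <- setdiff(intersect(nb, S), seen)
    seen <- c(seen, nb)
    frontier <- nb
  }
  length(seen) == length(S)
}

# random contiguous K-partition: grow regions from K random seeds
.random_contiguous_partition <- function(adj, K) {
  P <- nrow(adj)
  assign <- integer(P)
  seeds <- sample.int(P, K)
  assign[seeds] <- seq_len(K)
  while (any(assign == 0L)) {
    unas <- which(assign == 0L)
    cand <- unas[vapply(unas, function(p) any(assign[adj[p, ]] > 0L), TRUE)]
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    gs <- unique(assign[adj[p, ]])
    gs <- gs[gs > 0L]
    assign[p] <- if (length(gs) == 1L) gs else sample(gs, 1L)
  }
  assign
}

#' Spatial analysis of molecular variance (SAMOVA)
#'
#' Searches for the partition of populations into `K` geographically
#' contiguous groups that maximizes the among-group fixation index
#' `F_CT`, by simulated annealing on the population neighborhood graph:
#' starting from a random contiguous partition, single populations are
#' moved to adjacent groups (keeping every group non-empty and
#' contiguous), improvements are always accepted and worsening moves with
#' probability `exp(delta / temperature)` under geometric cooling.  The
#' best assignment over `n_runs` independent runs is returned.
#'
#' @param d square matrix of pairwise differences between samples.
#' @param pop_map population map covering the rownames of `d`.
#' @param K number of groups (`2 <= K <` number of populations).
#' @param coords optional populations x 2 coordinate matrix (rownames =
#'   populations); default: per-population mean longitude/latitude from
#'   the popmap.
#' @param n_runs independent annealing runs (default 100).
#' @param n_steps proposals per run (default 1000).
#' @param seed optional integer seed.
#' @return object of class `samova_result`: list with `K`, `assignment`
#'   (named population -> group index), `phi_ct`, `trajectory` (best
#'   `F_CT` per run), `n_runs`, `adjacency`.
#' @export
samova <- function(d, pop_map, K, coords = NULL, n_runs = 100L,
                   n_steps = 1000L, seed = NULL) {
  .seed_rng(seed)
  d <- as.matrix(d)
  pm <- pop_map[match(rownames(d), pop_map$sample), , drop = FALSE]
  if (anyNA(pm$sample)) stop("samples in d missing from popmap")
  pop <- pm$population
  pops <- unique(pop)
  P <- length(pops)
  if (!.is_count(K) || K < 2L || K >= P)
    stop("K must satisfy 2 <= K < number of populations (", P, ")")
  if (is.null(coords)) {
    coords <- cbind(
      lon = tapply(pm$longitude, factor(pop, levels = pops), mean),
      lat = tapply(pm$latitude, factor(pop, levels = pops), mean))
    rownames(coords) <- pops
  }
  adj <- delaunay_adjacency(coords[pops, , drop = FALSE])
  n_p <- as.numeric(table(factor(pop, levels = pops)))
  N <- nrow(d)
  W <- .pop_pair_sums(d, pop, pops)
  ss_total <- (sum(W) + sum(diag(W))) / 2 / N
  ss_wp <- sum(diag(W) / n_p)
  eval_phi <- function(assign) .phi_ct_fast(assign, W, n_p, ss_total, ss_wp, N)

  best_phi <- -Inf
  best_assign <- NULL
  trajectory <- numeric(n_runs)

  propose <- function(assign) {
    # movable populations: adjacent to another group, leaving their own
    # group non-empty and contiguous
    cand <- list()
    for (p in sample.int(P)) {
      g <- assign[p]
      nb_groups <- setdiff(unique(assign[adj[p, ]]), g)
      if (length(nb_groups) == 0L) next
      rest <- setdiff(which(assign == g), p)
      if (length(rest) == 0L || !.is_connected_subset(rest, adj)) next
      return(list(p = p, to = if (length(nb_groups) == 1L) nb_groups
                  else sample(nb_groups, 1L)))
    }
    NULL
  }

  for (run in seq_len(n_runs)) {
    assign <- .random_contiguous_partition(adj, K)
    phi <- eval_phi(assign)
    if (!is.finite(phi)) phi <- -1
    # calibrate the initial temperature to accept ~half of average
    # worsening moves
    deltas <- numeric(0)
    for (i in seq_len(20L)) {
      mv <- propose(assign)
      if (is.null(mv)) break
      alt <- assign; alt[mv$p] <- mv$to
      phi_alt <- eval_phi(alt)
      if (is.finite(phi_alt)) deltas <- c(deltas, abs(phi_alt - phi))
    }
    temp <- if (length(deltas) && mean(deltas) > 0) mean(deltas) / log(2) else 0.01
    run_best <- phi
    run_best_assign <- assign
    cool_every <- max(1L, ceiling(n_steps / 50L))
    for (step in seq_len(n_steps)) {
      mv <- propose(assign)
      if (is.null(mv)) break
      alt <- assign; alt[mv$p] <- mv$to
      phi_alt <- eval_phi(alt)
      if (!is.finite(phi_alt)) next
      delta <- phi_alt - phi
      if (delta >= 0 || runif(1L) < exp(delta / temp)) {
        assign <- alt; phi <- phi_alt
        if (phi > run_best) { run_best <- phi; run_best_assign <- assign }
      }
      if (step %% cool_every == 0L) temp <- temp * 0.9
    }
    trajectory[run] <- run_best
    if (run_best > best_phi) {
      best_phi <- run_best
      best_assign <- run_best_assign
    }
  }
  structure(list(K = K,
                 assignment = stats::setNames(best_assign, pops),
                 phi_ct = best_phi,
                 trajectory = trajectory,
                 n_runs = n_runs,
                 adjacency = adj),
            class = "samova_result")
}

#' @export
print.samova_result <- function(x, ...) {
  cat("SAMOVA: K =", x$K, " F_CT =", round(x$phi_ct, 4), "\n")
  for (g in sort(unique(x$assignment)))
    cat("  group", g, ":", paste(names(x$assignment)[x$assignment == g],
                                 collapse = ", "), "\n")
  invisible(x)
}
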