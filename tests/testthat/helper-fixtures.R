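# shared fixtures, built in code

# tiny alignment as a character matrix from a vector of strings
aln_from_strings <- function(x, ids = paste0("s", seq_along(x))) {
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- ids
  toupper(m)
}

# popmap for samples split evenly over populations, groups optional
toy_popmap <- function(samples, populations, groups = NULL,
                       lon = NULL, lat = NULL) {
  pops <- unique(populations)
  if (is.null(groups)) groups <- rep("g1", length(populations))
  if (is.null(lon)) lon <- match(populations, pops)
  if (is.null(lat)) lat <- rep(0, length(samples))
  validate_popmap(data.frame(sample = samples, population = populations,
                             group = groups, latitude = lat, longitude = lon,
                             stringsAsFactors = FALSE))
}

# random toy dataset for AMOVA-style checks: samples carry integer "types"
# and distance = |type difference| squared-scale mismatch
random_toy_distances <- function(n_pops, n_per_pop, n_types = 4L) {
  n <- n_pops * n_per_pop
  type <- sample.int(n_types, n, replace = TRUE)
  d <- outer(type, type, function(a, b) as.numeric(a != b) * (1 + (a + b) %% 3))
  diag(d) <- 0
  d <- (d + t(d)) / 2
  rownames(d) <- colnames(d) <- sprintf("s%02d", seq_len(n))
  list(d = d, pop = rep(sprintf("P%d", seq_len(n_pops)), each = n_per_pop))
}

# brute-force AMOVA oracle: builds the hierarchical ANOVA table from
# explicit squared-distance sums with scalar loops (independent of the
# package's matrix implementation)
oracle_amova <- function(d2, pop, grouping = NULL) {
  n <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  n_p <- sapply(pops, function(p) sum(pop == p))
  sum_pairs <- function(idx) {
    s <- 0
    if (length(idx) >= 2) {
      for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b)
        s <- s + d2[idx[a], idx[b]]
    }
    s
  }
  ss_tot <- sum_pairs(seq_len(n)) / n
  ss_wp <- 0
  for (p in pops) ss_wp <- ss_wp + sum_pairs(which(pop == p)) / sum(pop == p)
  if (is.null(grouping)) {
    df_a <- P - 1; df_b <- n - P
    ss_a <- ss_tot - ss_wp
    nc <- (n - sum(n_p^2) / n) / df_a
    sb <- ss_wp / df_b
    sa <- (ss_a / df_a - sb) / nc
    return(list(sigma = c(a = sa, b = sb), F_ST = sa / (sa + sb)))
  }
  grp <- grouping[pop]
  groups <- unique(grp)
  G <- length(groups)
  N_g <- sapply(groups, function(g) sum(grp == g))
  ss_wg <- 0
  for (g in groups) ss_wg <- ss_wg + sum_pairs(which(grp == g)) / sum(grp == g)
  ss_a <- ss_tot - ss_wg
  ss_b <- ss_wg - ss_wp
  df_a <- G - 1; df_b <- P - G; df_c <- n - P
  s_np2_Ng <- 0
  for (g in groups) {
    idx <- names(grouping)[grouping == g]
    s_np2_Ng <- s_np2_Ng + sum(n_p[pops %in% idx]^2) / sum(n_p[pops %in% idx])
  }
  n1 <- (n - s_np2_Ng) / df_b
  n2 <- (s_np2_Ng - sum(n_p^2) / n) / df_a
  n3 <- (n - sum(N_g^2) / n) / df_a
  sc <- ss_wp / df_c
  sb <- (ss_b / df_b - sc) / n1
  sa <- (ss_a / df_a - sc - n2 * sb) / n3
  tot <- sa + sb + sc
  list(sigma = c(a = sa, b = sb, c = sc),
       F_CT = sa / tot, F_SC = sb / (sb + sc), F_ST = (sa + sb) / tot)
}

# exhaustive Fitch oracle: minimum label changes over all interior
# assignments of a rooted binary tree
oracle_fitch <- function(tree, demes) {
  demes <- demes[tree$tip.label]
  lev <- unique(demes)
  L <- length(lev)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  tip_state <- match(demes, lev)
  combos <- as.matrix(expand.grid(rep(list(seq_len(L)), nint)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    state <- c(tip_state, combos[r, ])
    ch <- sum(state[tree$edge[, 1]] != state[tree$edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# exhaustive contiguous-bipartition search for the SAMOVA oracle, using
# the full amova() computation (a different code path from the annealer)
oracle_best_bipartition <- function(d, pop_map, adj) {
  pops <- rownames(adj)
  P <- length(pops)
  connected <- function(S) {
    if (length(S) <= 1) return(TRUE)
    seen <- S[1]; frontier <- S[1]
    while (length(frontier)) {
      nb <- setdiff(intersect(which(rowSums(adj[, frontier, drop = FALSE]) > 0), S), seen)
      seen <- c(seen, nb); frontier <- nb
    }
    length(seen) == length(S)
  }
  best <- -Inf; best_set <- NULL
  for (mask in 1:(2^(P - 1) - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(P) - 1)) > 0)
    Sc <- setdiff(seq_len(P), S)
    if (!connected(S) || !connected(Sc)) next
    grouping <- stats::setNames(ifelse(seq_len(P) %in% S, "A", "B"), pops)
    fct <- amova(d, pop_map, grouping)$indices[["F_CT"]]
    if (is.finite(fct) && fct > best) { best <- fct; best_set <- S }
  }
  list(phi_ct = best, set = best_set)
}
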