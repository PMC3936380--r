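# default sampling design: 19 populations, 2-14 samples each, 160 in total
.default_samples <- function(n_pops) {
  base <- c(14, 12, 12, 12, 10, 10, 10, 10, 8, 8, 8, 8, 8, 8, 6, 6, 4, 4, 2)
  if (n_pops == 19L) return(base)
  pmin(14L, pmax(2L, rep_len(base, n_pops)))
}

#' Configuration for synthetic chloroplast sequence data
#'
#' Describes the sampling design and demographic history used by
#' [simulate_sequences()]: haploid samples spread over populations, which
#' belong to geographic groups; each group is one panmictic deme of the
#' structured coalescent.  Defaults emulate a survey of a cloud-forest
#' tree: 19 populations of 2-14 samples (160 total) in two groups split by
#' a barrier, a 1417-bp non-recombining locus, substitution rate 1.59e-9
#' per site per year, generation time 34 years, deme size 10,000 gene
#' copies and a 1.8-Myr-old split -- a regime that yields on the order of
#' ten segregating sites and strong private-haplotype structure.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop integer vector of per-population sample counts.
#' @param group_of_pop character/factor of length `n_pops` assigning each
#'   population to a group (deme).
#' @param locus_length locus length in bp.
#' @param mu_site_year substitution rate per site per year.
#' @param gen_time_years generation time in years.
#' @param deme_sizes named numeric vector of deme sizes (gene copies), one
#'   per group.
#' @param split_times_years split times in years, oldest first, strictly
#'   decreasing; group `i + 1` joins group 1 at the `i`-th time.
#' @param migration per-generation lineage migration probability between
#'   groups, in `[0, 1)`.
#' @param indel_rate_rel indel rate relative to the substitution rate;
#'   each indel deletes a run of 1-3 bp.
#' @param barrier_gap extra spacing inserted between consecutive groups on
#'   the (linear) population transect, so spatial contiguity is meaningful.
#' @param seed integer seed used by [simulate_sequences()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 19L,
                       samples_per_pop = NULL,
                       group_of_pop = NULL,
                       locus_length = 1417L,
                       mu_site_year = 1.59e-9,
                       gen_time_years = 34,
                       deme_sizes = NULL,
                       split_times_years = 1.8e6,
                       migration = 0,
                       indel_rate_rel = 0.05,
                       barrier_gap = 2,
                       seed = 1L) {
  stopifnot(.is_count(n_pops), .is_count(locus_length),
            mu_site_year >= 0, gen_time_years > 0,
            indel_rate_rel >= 0, migration >= 0, migration < 1)
  if (is.null(samples_per_pop)) samples_per_pop <- .default_samples(n_pops)
  samples_per_pop <- as.integer(samples_per_pop)
  if (length(samples_per_pop) != n_pops || any(samples_per_pop < 1L))
    stop("samples_per_pop must give a positive count for each population")
  if (is.null(group_of_pop))
    group_of_pop <- ifelse(seq_len(n_pops) <= ceiling(n_pops * 10 / 19),
                           "north", "south")
  group_of_pop <- as.character(group_of_pop)
  if (length(group_of_pop) != n_pops)
    stop("group_of_pop must label every population")
  groups <- unique(group_of_pop)
  if (is.null(deme_sizes))
    deme_sizes <- stats::setNames(rep(10000, length(groups)), groups)
  if (!setequal(names(deme_sizes), groups))
    stop("deme_sizes names must match the group labels")
  if (any(deme_sizes <= 0)) stop("deme sizes must be positive")
  if (length(groups) > 1L) {
    if (length(split_times_years) != length(groups) - 1L)
      stop("need one split time per group beyond the first")
    if (any(split_times_years <= 0) ||
        any(diff(split_times_years) >= 0 & length(split_times_years) > 1L))
      stop("split times must be positive and strictly decreasing toward the present")
  }
  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 group_of_pop = group_of_pop, locus_length = locus_length,
                 mu_site_year = mu_site_year, gen_time_years = gen_time_years,
                 deme_sizes = deme_sizes,
                 split_times_years = split_times_years,
                 migration = migration, indel_rate_rel = indel_rate_rel,
                 barrier_gap = barrier_gap, seed = seed),
            class = "sim_config")
}

# deme model implied by a sim_config: one deme per group, caterpillar joins
.model_from_config <- function(config) {
  groups <- unique(config$group_of_pop)
  nsamp <- vapply(groups, function(g)
    sum(config$samples_per_pop[config$group_of_pop == g]), integer(1L))
  joins <- NULL
  if (length(groups) > 1L) {
    t_gen <- years_to_generations(config$split_times_years,
                                  config$gen_time_years)
    # oldest split first in the config: group 2 splits earliest, later
    # groups split progressively more recently
    joins <- data.frame(time = t_gen,
                        from = groups[seq_along(t_gen) + 1L],
                        to = groups[1L],
                        size = config$deme_sizes[[groups[1L]]])
    joins <- joins[order(joins$time), , drop = FALSE]
  }
  population_model(deme_sizes = config$deme_sizes,
                   samples_per_deme = stats::setNames(nsamp, groups),
                   joins = joins, migration = config$migration)
}

#' Simulate an aligned sequence dataset with population structure
#'
#' Draws a genealogy from the structured coalescent implied by the
#' configuration, then evolves a `locus_length`-bp sequence down the tree
#' under a finite-sites Jukes-Cantor substitution process (multiple hits
#' possible) with substitutions placed as Poisson events proportional to
#' branch length, plus a low-rate deletion process producing 1-3 bp gap
#' runs.  Identical seeds give identical datasets.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return object of class `synthetic_dataset`: a list with `alignment`
#'   (character matrix, rows = samples), `pop_map` (data.frame with
#'   `sample`, `population`, `group`, `latitude`, `longitude`),
#'   `genealogy` (`phylo`, branch lengths in generations, tips = samples)
#'   and `truth` (the configuration).
#' @export
simulate_sequences <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .seed_rng(seed)
  model <- .model_from_config(config)
  tree <- simulate_genealogy(model)

  # assign tips (grouped by deme, in order) to populations within the deme
  groups <- unique(config$group_of_pop)
  pops <- sprintf("P%02d", seq_len(config$n_pops))
  sample_pop <- character(0)
  for (g in groups) {
    idx <- which(config$group_of_pop == g)
    sample_pop <- c(sample_pop, rep(pops[idx], config$samples_per_pop[idx]))
  }
  n <- length(sample_pop)
  sample_id <- sprintf("%s_i%02d", sample_pop,
                       unlist(lapply(table(factor(sample_pop, levels = unique(sample_pop))), seq_len)))
  # genealogy tips are ordered deme by deme exactly like sample_pop
  old_demes <- attr(tree, "demes")
  tree$tip.label <- sample_id
  attr(tree, "demes") <- stats::setNames(unname(old_demes), sample_id)

  aln <- .evolve_sequences(tree, config)
  rownames(aln) <- sample_id

  # populations on a linear transect with a barrier gap between groups
  grp_of <- config$group_of_pop
  lon <- numeric(config$n_pops)
  pos <- 0
  for (i in seq_len(config$n_pops)) {
    if (i > 1L && grp_of[i] != grp_of[i - 1L]) pos <- pos + config$barrier_gap
    pos <- pos + 1
    lon[i] <- pos
  }
  pop_map <- data.frame(sample = sample_id,
                        population = sample_pop,
                        group = grp_of[match(sample_pop, pops)],
                        latitude = 0,
                        longitude = lon[match(sample_pop, pops)],
                        stringsAsFactors = FALSE)
  structure(list(alignment = aln, pop_map = pop_map, genealogy = tree,
                 truth = config),
            class = "synthetic_dataset")
}

# evolve sequences down the tree: finite-sites JC substitutions + deletions
.evolve_sequences <- function(tree, config) {
  L <- config$locus_length
  mu_gen <- config$mu_site_year * config$gen_time_years
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample(bases, L, replace = TRUE)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; chi <- tr$edge[e, 2L]
    s <- seqs[[par]]
    lam <- mu_gen * L * tr$edge.length[e]
    nsub <- rpois(1L, lam)
    if (nsub > 0L) {
      sites <- sample.int(L, nsub, replace = TRUE)
      for (k in seq_len(nsub)) {
        cur <- s[sites[k]]
        if (cur != "-") s[sites[k]] <- sample(setdiff(bases, cur), 1L)
      }
    }
    nind <- rpois(1L, lam * config$indel_rate_rel)
    if (nind > 0L) {
      for (k in seq_len(nind)) {
        start <- sample.int(L, 1L)
        len <- sample.int(3L, 1L)
        s[start:min(L, start + len - 1L)] <- "-"
      }
    }
    seqs[[chi]] <- s
  }
  do.call(rbind, seqs[seq_len(ntip)])
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$alignment), "samples x",
      ncol(x$alignment), "sites;",
      length(unique(x$pop_map$population)), "populations in",
      length(unique(x$pop_map$group)), "group(s)\n")
  cat("Segregating sites:", .segregating_sites(x$alignment), "\n")
  invisible(x)
}

#' Configuration for synthetic niche/occurrence data
#'
#' Describes two lineages occupying multivariate normal environmental
#' niches inside (possibly broader) background environments, emulating the
#' inputs of a background-corrected niche divergence test.
#'
#' @param n_occurrences occurrence points per lineage (>= 3).
#' @param n_background background points per lineage.
#' @param env_dim number of environmental variables (columns `BIO1..`).
#' @param lineage_means 2 x `env_dim` matrix of lineage niche means.
#' @param lineage_cov list of two covariance matrices (symmetric PSD).
#' @param background_means 2 x `env_dim` matrix of background means.
#' @param background_cov list of two covariance matrices (symmetric PSD).
#' @param lineages character vector of two lineage names.
#' @param seed integer seed for [simulate_niche_data()].
#' @return object of class `niche_sim_config`.
#' @export
niche_sim_config <- function(n_occurrences = 100L,
                             n_background = 1000L,
                             env_dim = 10L,
                             lineage_means = NULL,
                             lineage_cov = NULL,
                             background_means = NULL,
                             background_cov = NULL,
                             lineages = c("north", "south"),
                             seed = 1L) {
  stopifnot(.is_count(env_dim), .is_count(n_background))
  if (!.is_count(n_occurrences) || n_occurrences < 3L)
    stop("n_occurrences must be an integer >= 3")
  if (is.null(lineage_means)) {
    lineage_means <- matrix(0, 2L, env_dim)
    lineage_means[1L, 1L] <- 1
    lineage_means[2L, 1L] <- -1
  }
  if (is.null(background_means)) background_means <- matrix(0, 2L, env_dim)
  if (is.null(lineage_cov)) lineage_cov <- list(diag(env_dim), diag(env_dim))
  if (is.null(background_cov))
    background_cov <- list(4 * diag(env_dim), 4 * diag(env_dim))
  check_cov <- function(S, what) {
    S <- as.matrix(S)
    if (nrow(S) != env_dim || ncol(S) != env_dim ||
        max(abs(S - t(S))) > 1e-8 ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(what, " covariance must be a symmetric PSD ", env_dim, "x",
           env_dim, " matrix")
    S
  }
  lineage_cov <- lapply(lineage_cov, check_cov, what = "lineage")
  background_cov <- lapply(background_cov, check_cov, what = "background")
  stopifnot(nrow(lineage_means) == 2L, ncol(lineage_means) == env_dim,
            nrow(background_means) == 2L, ncol(background_means) == env_dim,
            length(lineages) == 2L)
  structure(list(n_occurrences = n_occurrences, n_background = n_background,
                 env_dim = env_dim, lineage_means = lineage_means,
                 lineage_cov = lineage_cov,
                 background_means = background_means,
                 background_cov = background_cov,
                 lineages = lineages, seed = seed),
            class = "niche_sim_config")
}

#' Simulate occurrence and background environmental tables
#'
#' Draws occurrence rows from each lineage's environmental distribution
#' and background rows from the corresponding background distribution
#' (multivariate normal).  Geographic coordinates are generated around
#' lineage-specific centres so that minimum-convex-polygon utilities can
#' be exercised; they carry no information beyond lineage identity.
#'
#' @param config a [niche_sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with data.frames `occurrence` and `background`, each with
#'   columns `lineage`, `lon`, `lat`, `BIO1..BIOk`.
#' @export
simulate_niche_data <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "niche_sim_config"))
  .seed_rng(seed)
  k <- config$env_dim
  bio <- paste0("BIO", seq_len(k))
  centre <- list(c(0, 0), c(10, 0))
  draw <- function(n, mean, cov, lineage, ctr) {
    env <- MASS::mvrnorm(n, mu = mean, Sigma = cov)
    env <- matrix(env, ncol = k, dimnames = list(NULL, bio))
    data.frame(lineage = lineage,
               lon = ctr[1L] + stats::rnorm(n),
               lat = ctr[2L] + stats::rnorm(n),
               env, stringsAsFactors = FALSE)
  }
  occ <- rbind(
    draw(config$n_occurrences, config$lineage_means[1L, ],
         config$lineage_cov[[1L]], config$lineages[1L], centre[[1L]]),
    draw(config$n_occurrences, config$lineage_means[2L, ],
         config$lineage_cov[[2L]], config$lineages[2L], centre[[2L]]))
  bg <- rbind(
    draw(config$n_background, config$background_means[1L, ],
         config$background_cov[[1L]], config$lineages[1L], centre[[1L]]),
    draw(config$n_background, config$background_means[2L, ],
         config$background_cov[[2L]], config$lineages[2L], centre[[2L]]))
  list(occurrence = occ, background = bg)
}
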