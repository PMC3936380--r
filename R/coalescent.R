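#' Define a population (deme) history for coalescent simulation
#'
#' A deme model consists of present-day demes with sizes in gene copies,
#' sample sizes per deme, and a series of join events going back in time.
#' A join at time `t` (generations before present) moves all lineages of
#' deme `from` into deme `to` and resets the size of `to` (the ancestral
#' size).  Sizes are gene-copy counts: for a haploid, uniparentally
#' inherited locus the pairwise coalescence rate within a deme of size `N`
#' is `1/N` per pair per generation.
#'
#' @param deme_sizes named numeric vector of present deme sizes (> 0),
#'   gene copies.
#' @param samples_per_deme named integer vector of sample counts (>= 0),
#'   same names as `deme_sizes`.
#' @param joins `NULL` or a data.frame with columns `time` (positive
#'   generations, forming a consistent history), `from`, `to` (deme names)
#'   and `size` (ancestral size of `to` after the join).
#' @param migration per-lineage migration probability per generation to any
#'   other active deme (scalar in `[0, 1)`), divided uniformly among
#'   destinations.  Default 0 (pure isolation).
#' @param label optional scenario label.
#' @return object of class `population_model`.
#' @export
population_model <- function(deme_sizes, samples_per_deme, joins = NULL,
                             migration = 0, label = NULL) {
  if (is.null(names(deme_sizes)) || is.null(names(samples_per_deme)))
    stop("deme_sizes and samples_per_deme must be named")
  if (!setequal(names(deme_sizes), names(samples_per_deme)))
    stop("deme_sizes and samples_per_deme must cover the same demes")
  samples_per_deme <- samples_per_deme[names(deme_sizes)]
  stopifnot(all(deme_sizes > 0), all(samples_per_deme >= 0),
            all(samples_per_deme == round(samples_per_deme)))
  if (!is.numeric(migration) || length(migration) != 1L ||
      migration < 0 || migration >= 1)
    stop("migration must be a scalar in [0, 1)")
  if (!is.null(joins)) {
    joins <- as.data.frame(joins)
    stopifnot(all(c("time", "from", "to", "size") %in% names(joins)))
    if (any(joins$time <= 0)) stop("join times must be positive")
    if (any(joins$size <= 0)) stop("ancestral sizes must be positive")
    joins <- joins[order(joins$time), , drop = FALSE]
    if (!all(c(joins$from, joins$to) %in% names(deme_sizes)))
      stop("joins refer to unknown demes")
    # walking back in time every deme must eventually merge into one
    active <- names(deme_sizes)
    for (i in seq_len(nrow(joins))) {
      if (!(joins$from[i] %in% active) || !(joins$to[i] %in% active))
        stop("join ", i, " refers to a deme already merged away")
      active <- setdiff(active, joins$from[i])
    }
    if (length(active) != 1L && sum(samples_per_deme > 0) > 1L)
      stop("history must end with a single ancestral deme")
  } else if (sum(samples_per_deme > 0) > 1L) {
    stop("multiple sampled demes require join events to share an ancestor")
  }
  structure(list(deme_sizes = deme_sizes,
                 samples_per_deme = samples_per_deme,
                 joins = joins, migration = migration, label = label),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model", if (!is.null(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  demes:", paste(sprintf("%s (N=%g, n=%d)", names(x$deme_sizes),
                                x$deme_sizes, x$samples_per_deme),
                        collapse = ", "), "\n")
  if (!is.null(x$joins))
    for (i in seq_len(nrow(x$joins)))
      cat(sprintf("  t=%g: %s -> %s (ancestral N=%g)\n", x$joins$time[i],
                  x$joins$from[i], x$joins$to[i], x$joins$size[i]))
  if (x$migration > 0) cat("  migration:", x$migration, "per lineage per generation\n")
  invisible(x)
}

# core event-driven structured coalescent.
# track = "tree": record merges and return them; track = "s": only carry
# deme-set bitmasks and return the Fitch sorting-event count.
.coalesce_core <- function(model, track = c("tree", "s")) {
  track <- match.arg(track)
  demes <- names(model$deme_sizes)
  sizes <- model$deme_sizes
  nsamp <- model$samples_per_deme
  n <- sum(nsamp)
  if (n < 2L) stop("need at least 2 samples in total")
  joins <- model$joins
  njoin <- if (is.null(joins)) 0L else nrow(joins)

  lin_deme <- rep(match(names(nsamp), demes), nsamp)   # current location
  lin_id <- seq_len(n)
  if (track == "s") {
    lin_mask <- bitwShiftL(1L, rep(match(names(nsamp), demes), nsamp) - 1L)
    s_count <- 0L
  } else {
    m_c1 <- m_c2 <- integer(n - 1L)
    m_t <- numeric(n - 1L)
  }
  nmerge <- 0L
  t_now <- 0
  join_i <- 1L
  active <- rep(TRUE, length(demes))
  mig <- model$migration

  while (length(lin_id) > 1L) {
    k <- tabulate(lin_deme, nbins = length(demes))
    coal_rate <- ifelse(active & k > 1L, k * (k - 1L) / 2 / sizes, 0)
    mig_rate <- if (mig > 0 && sum(active) > 1L) mig * length(lin_id) else 0
    total <- sum(coal_rate) + mig_rate
    t_next_join <- if (join_i <= njoin) joins$time[join_i] else Inf
    dt <- if (total > 0) rexp(1L, total) else Inf
    if (t_now + dt >= t_next_join) {
      # apply the join: lineages of `from` relocate into `to`
      t_now <- t_next_join
      fi <- match(joins$from[join_i], demes)
      ti <- match(joins$to[join_i], demes)
      lin_deme[lin_deme == fi] <- ti
      sizes[ti] <- joins$size[join_i]
      active[fi] <- FALSE
      join_i <- join_i + 1L
      next
    }
    if (!is.finite(dt))
      stop("coalescent cannot complete: isolated lineages with no remaining joins")
    t_now <- t_now + dt
    if (runif(1L) < mig_rate / total) {
      li <- sample.int(length(lin_id), 1L)
      dest <- which(active)
      dest <- dest[dest != lin_deme[li]]
      lin_deme[li] <- if (length(dest) == 1L) dest else sample(dest, 1L)
    } else {
      d <- sample.int(length(demes), 1L, prob = coal_rate)
      pair <- sample(which(lin_deme == d), 2L)
      nmerge <- nmerge + 1L
      if (track == "s") {
        overlap <- bitwAnd(lin_mask[pair[1L]], lin_mask[pair[2L]])
        if (overlap > 0L) {
          lin_mask[pair[1L]] <- overlap
        } else {
          lin_mask[pair[1L]] <- bitwOr(lin_mask[pair[1L]], lin_mask[pair[2L]])
          s_count <- s_count + 1L
        }
        lin_deme <- lin_deme[-pair[2L]]
        lin_mask <- lin_mask[-pair[2L]]
        lin_id <- lin_id[-pair[2L]]
      } else {
        m_c1[nmerge] <- lin_id[pair[1L]]
        m_c2[nmerge] <- lin_id[pair[2L]]
        m_t[nmerge] <- t_now
        lin_id[pair[1L]] <- n + nmerge
        lin_deme <- lin_deme[-pair[2L]]
        lin_id <- lin_id[-pair[2L]]
      }
    }
  }
  if (track == "s") return(s_count)
  list(c1 = m_c1, c2 = m_c2, time = m_t, n = n)
}

#' Simulate a gene genealogy under a deme model
#'
#' Draws one genealogy from the structured coalescent defined by a
#' [population_model()]: within each deme, pairs of lineages coalesce at
#' rate `1/N` per pair per generation (continuous-time exponential
#' waiting), lineages are pooled at join events, and, if the model allows
#' it, lineages migrate between active demes.
#'
#' @param model a [population_model()].
#' @param seed optional integer seed.
#' @return an `ape` `phylo` tree with branch lengths in generations; tip
#'   labels are `"<deme>_<i>"` and the attribute `"demes"` carries a named
#'   character vector mapping tip label to sampling deme.
#' @export
simulate_genealogy <- function(model, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  .seed_rng(seed)
  res <- .coalesce_core(model, track = "tree")
  n <- res$n
  nmerge <- n - 1L
  # ape wants root = n + 1; merges are in time order so the last is the root
  remap <- function(id) ifelse(id <= n, id, n + (nmerge - (id - n) + 1L))
  height <- c(rep(0, n), res$time)   # height by original id
  parent <- remap(n + seq_len(nmerge))
  edge <- rbind(cbind(parent, remap(res$c1)), cbind(parent, remap(res$c2)))
  child_orig <- c(res$c1, res$c2)
  edge_len <- rep(res$time, 2L) - height[child_orig]
  demes <- rep(names(model$samples_per_deme), model$samples_per_deme)
  tip_lab <- paste0(demes, "_", unlist(lapply(model$samples_per_deme, seq_len)))
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = tip_lab, Nnode = nmerge),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "demes") <- stats::setNames(demes, tip_lab)
  tr
}

#' Minimum number of sorting events on a gene tree (Slatkin-Maddison s)
#'
#' Computes the minimum number of deme-label state changes required to
#' explain the distribution of tip labels on a rooted tree, by Fitch
#' parsimony (post-order union/intersection pass with unordered states).
#' Small values indicate concordance between the gene tree and the
#' population subdivision; branch lengths are ignored.
#'
#' @param tree a rooted (preferably binary) `phylo` tree.
#' @param demes named character vector mapping tip labels to deme labels,
#'   or a vector in tip order.  Defaults to the `"demes"` attribute left by
#'   [simulate_genealogy()].
#' @return integer count of sorting events (0 when all tips share a label).
#' @export
s_statistic <- function(tree, demes = attr(tree, "demes")) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(demes)) stop("no deme labels supplied")
  labs <- tree$tip.label
  if (!is.null(names(demes))) {
    if (!all(labs %in% names(demes)))
      stop("unlabeled tips: ", paste(setdiff(labs, names(demes)), collapse = ", "))
    demes <- demes[labs]
  } else if (length(demes) != length(labs)) {
    stop("demes must be named or match the number of tips")
  }
  if (anyNA(demes)) stop("unlabeled tip (NA deme)")
  lev <- unique(demes)
  if (length(lev) > 30L) stop("more than 30 deme labels not supported")
  ntip <- length(labs)
  tr <- ape::reorder.phylo(tree, "postorder")
  state <- integer(ntip + tr$Nnode)
  state[seq_len(ntip)] <- bitwShiftL(1L, match(demes, lev) - 1L)
  changes <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]
    chi <- tr$edge[e, 2L]
    if (state[par] == 0L) {
      state[par] <- state[chi]
    } else {
      overlap <- bitwAnd(state[par], state[chi])
      if (overlap > 0L) {
        state[par] <- overlap
      } else {
        state[par] <- bitwOr(state[par], state[chi])
        changes <- changes + 1L
      }
    }
  }
  changes
}

#' Two-refugia scenario preset
#'
#' Two demes of size `Ne` each, isolated (no migration) since `t_years`,
#' merging into an ancestral deme of size `Ne`.
#'
#' @param Ne deme size in gene copies.
#' @param t_years isolation time in years before present.
#' @param generation_time_years generation time used to convert years to
#'   generations.
#' @param samples_per_deme named integer vector of sample sizes for the two
#'   demes.
#' @param label scenario label.
#' @return a [population_model()].
#' @export
scenario_two_refugia <- function(Ne, t_years, generation_time_years,
                                 samples_per_deme, label = "two_refugia") {
  stopifnot(length(samples_per_deme) == 2L, !is.null(names(samples_per_deme)))
  d <- names(samples_per_deme)
  t_gen <- years_to_generations(t_years, generation_time_years)
  population_model(
    deme_sizes = stats::setNames(c(Ne, Ne), d),
    samples_per_deme = samples_per_deme,
    joins = data.frame(time = t_gen, from = d[1L], to = d[2L], size = Ne),
    label = label)
}

#' Single-refuge fragmentation scenario preset
#'
#' A single panmictic deme of size `Ne` that fragmented `t_years` ago into
#' two demes of size `Ne / 2` each (total size conserved).
#'
#' @inheritParams scenario_two_refugia
#' @return a [population_model()].
#' @export
scenario_fragmentation <- function(Ne, t_years, generation_time_years,
                                   samples_per_deme, label = "fragmentation") {
  stopifnot(length(samples_per_deme) == 2L, !is.null(names(samples_per_deme)))
  d <- names(samples_per_deme)
  t_gen <- years_to_generations(t_years, generation_time_years)
  population_model(
    deme_sizes = stats::setNames(c(Ne / 2, Ne / 2), d),
    samples_per_deme = samples_per_deme,
    joins = data.frame(time = t_gen, from = d[1L], to = d[2L], size = Ne),
    label = label)
}

#' Test refugial scenarios against an observed genealogy
#'
#' For each candidate scenario, simulates `n_sims` gene genealogies under
#' the structured coalescent, records the distribution of the
#' Slatkin-Maddison `s` statistic, and compares the observed `s` with the
#' central 95% of the simulated distribution (empirical 2.5th/97.5th
#' percentiles with linear interpolation).  A scenario is rejected when the
#' observed value falls outside that interval (`tail = "two"`), or above
#' the 95th percentile only (`tail = "upper"`).
#'
#' @param observed observed genealogy (`phylo`) with deme labels, or an
#'   integer observed `s` value.
#' @param scenarios a [population_model()] or list of them.
#' @param demes tip-to-deme labels for `observed` (see [s_statistic()]);
#'   ignored when `observed` is already an `s` value.
#' @param n_sims simulated genealogies per scenario (default 1000).
#' @param tail `"two"` (central 95% interval) or `"upper"`.
#' @param seed optional integer seed.
#' @return data.frame of class `refugia_test` with one row per scenario:
#'   `scenario`, `s_observed`, `q2.5`, `q97.5`, `n_sims`, `decision`; the
#'   simulated values are attached as attribute `"s_simulated"` (a list).
#' @export
refugia_test <- function(observed, scenarios, demes = NULL, n_sims = 1000L,
                         tail = c("two", "upper"), seed = NULL) {
  tail <- match.arg(tail)
  .seed_rng(seed)
  if (inherits(scenarios, "population_model")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, TRUE, "population_model")))
  if (inherits(observed, "phylo")) {
    if (is.null(demes)) demes <- attr(observed, "demes")
    s_obs <- s_statistic(observed, demes)
    obs_labels <- unique(if (!is.null(names(demes))) demes[observed$tip.label] else demes)
  } else {
    stopifnot(is.numeric(observed), length(observed) == 1L, observed >= 0)
    s_obs <- as.integer(observed)
    obs_labels <- NULL
  }
  out <- vector("list", length(scenarios))
  sims_all <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    if (!is.null(obs_labels)) {
      sampled <- names(sc$samples_per_deme)[sc$samples_per_deme > 0]
      missing_demes <- setdiff(sampled, obs_labels)
      if (length(missing_demes) > 0L)
        stop("scenario deme(s) absent from observed labels: ",
             paste(missing_demes, collapse = ", "))
    }
    s_sim <- vapply(seq_len(n_sims), function(k) .coalesce_core(sc, "s"),
                    integer(1L))
    qs <- quantile(s_sim, c(0.025, 0.975), names = FALSE)
    reject <- if (tail == "two") (s_obs < qs[1L] || s_obs > qs[2L])
              else s_obs > quantile(s_sim, 0.95, names = FALSE)
    lab <- if (!is.null(sc$label)) sc$label else paste0("scenario", i)
    out[[i]] <- data.frame(scenario = lab, s_observed = s_obs,
                           q2.5 = qs[1L], q97.5 = qs[2L],
                           n_sims = n_sims,
                           decision = if (reject) "reject" else "fail_to_reject",
                           stringsAsFactors = FALSE)
    sims_all[[i]] <- s_sim
  }
  res <- do.call(rbind, out)
  names(sims_all) <- res$scenario
  attr(res, "s_simulated") <- sims_all
  class(res) <- c("refugia_test", "data.frame")
  res
}
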