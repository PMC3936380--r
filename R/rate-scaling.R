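#' Average generation time of an iteroparous perennial
#'
#' Computes the approximate average generation time
#' `T = a + s / (1 - s)`, where `a` is the age at first reproduction in
#' years and `s` the annual adult survival rate.  For a long-lived tree
#' maturing at 25 years, survival 0.9 gives T = 34 y and survival 0.99
#' gives T = 124 y.
#'
#' @param a age at maturity in years (> 0).
#' @param s_adult annual adult survival probability in `[0, 1)`.
#' @return generation time in years.
#' @export
generation_time <- function(a, s_adult) {
  stopifnot(is.numeric(a), is.numeric(s_adult), a > 0)
  if (any(s_adult < 0 | s_adult >= 1))
    stop("s_adult must lie in [0, 1); survival of 1 gives a divergent generation time")
  a + s_adult / (1 - s_adult)
}

#' Per-lineage substitution rate from net divergence and crown age
#'
#' Converts a between-clade sequence divergence per site (Dxy) and a crown
#' divergence time into a per-lineage substitution rate: the divergence is
#' split between the two lineages (Dxy / 2) and divided by twice the
#' divergence time, i.e. `rate_per_myr = (dxy / 2) / (2 * t_div_ma)`.
#'
#' @param dxy between-clade divergence, substitutions per site (>= 0).
#' @param t_div_ma crown divergence time in millions of years (> 0).
#' @return list with `dxy`, `t_div_ma`, `per_lineage_divergence` (dxy/2),
#'   `rate_per_myr` and `rate_per_year` (= rate_per_myr / 1e6).
#' @export
substitution_rate_from_divergence <- function(dxy, t_div_ma) {
  stopifnot(is.numeric(dxy), is.numeric(t_div_ma), dxy >= 0)
  if (t_div_ma <= 0) stop("t_div_ma must be positive")
  per_lineage <- dxy / 2
  rate_myr <- per_lineage / (2 * t_div_ma)
  list(dxy = dxy, t_div_ma = t_div_ma,
       per_lineage_divergence = per_lineage,
       rate_per_myr = rate_myr,
       rate_per_year = rate_myr / 1e6)
}

#' Scale a mutation-scaled divergence time to years
#'
#' Isolation-with-migration samplers report the splitting time as
#' `t_raw = t * u_locus`, mutation-scaled by the per-locus rate.  The time
#' in years is recovered as `t_raw / (mu_site_year * locus_length)`.
#'
#' @param t_raw mutation-scaled time parameter (> 0).
#' @param mu_site_year substitution rate per site per year (> 0).
#' @param locus_length locus length in base pairs (> 0).
#' @return time in years.
#' @export
scale_ima_time <- function(t_raw, mu_site_year, locus_length) {
  stopifnot(is.numeric(t_raw), is.numeric(mu_site_year), is.numeric(locus_length))
  if (any(mu_site_year <= 0) || any(locus_length <= 0))
    stop("mutation rate and locus length must be positive")
  if (any(t_raw < 0)) stop("t_raw must be non-negative")
  t_raw / (mu_site_year * locus_length)
}

#' Scale mutation-scaled population sizes and migration rates
#'
#' Converts mutation-scaled size parameters `q = inheritance_scalar * Ne *
#' u_locus * g` and migration parameters to demographic units:
#' `Ne = q / (inheritance_scalar * mu_site_year * locus_length *
#' generation_time_years)` and the population migration rate
#' `Nm = q * m / inheritance_scalar`.  For a haploid, uniparentally
#' inherited organellar locus the conventional inheritance scalar is 2
#' (q = 2 * Ne * u); it is a parameter, never assumed.
#'
#' @param q mutation-scaled size parameter(s) (> 0).
#' @param m mutation-scaled migration parameter(s) (>= 0); optional.
#' @param mu_site_year substitution rate per site per year.
#' @param locus_length locus length in bp.
#' @param generation_time_years generation time in years.
#' @param inheritance_scalar ploidy/inheritance scalar (default 2).
#' @return list with `Ne` (effective sizes, gene copies) and, when `m` is
#'   supplied, `Nm` (migrants per generation).
#' @export
scale_ima_popsize_and_migration <- function(q, m = NULL, mu_site_year,
                                            locus_length,
                                            generation_time_years,
                                            inheritance_scalar = 2) {
  stopifnot(all(q > 0), mu_site_year > 0, locus_length > 0,
            generation_time_years > 0, inheritance_scalar > 0)
  mu_locus_gen <- mu_site_year * locus_length * generation_time_years
  Ne <- q / (inheritance_scalar * mu_locus_gen)
  out <- list(Ne = Ne)
  if (!is.null(m)) {
    stopifnot(all(m >= 0))
    out$Nm <- q * m / inheritance_scalar
  }
  out
}

#' Convert absolute time to coalescent time
#'
#' @param years time in years (>= 0).
#' @param generation_time_years generation time in years (> 0).
#' @return time in generations.
#' @export
years_to_generations <- function(years, generation_time_years) {
  stopifnot(is.numeric(years), all(years >= 0))
  if (any(generation_time_years <= 0)) stop("generation time must be positive")
  years / generation_time_years
}
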