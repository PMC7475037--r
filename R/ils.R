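## Incomplete-lineage-sorting test for a shared haplotype length.
##
## Under ILS, a haplotype segment shared between the modern human and
## archaic lineages descends from their common ancestor and has been
## exposed to recombination along both branches.  The expected length of
## such a shared tract is L = 1 / (r * t), with r the local recombination
## rate per bp per generation and t the summed branch lengths in
## generations.  Measuring the tract from a focal point, the extents to the
## left and to the right are independent exponentials with mean L, so the
## total tract length follows a Gamma(shape 2, scale L) distribution; the
## probability that an ILS tract is at least as long as the observed
## haplotype is the Gamma survival function (1 + m/L) * exp(-m/L).

#' Parameters of the ILS haplotype-length test
#'
#' Defaults are the emulated locus: a 56.2 kb haplotype, deCODE local
#' recombination rate 0.87 cM/Mb, 25-year generations, and conservative
#' branch lengths of 200 ky (modern human) and 100 ky (archaic).
#'
#' @param m_bp observed haplotype length in bp.
#' @param r_cM_per_Mb local recombination rate (centimorgan per megabase).
#' @param gen_time_years generation time in years.
#' @param t_modern_years,t_archaic_years branch lengths in years.
#' @return a validated list of class `ILSParams`.
#' @export
ils_params <- function(m_bp = 56200,
                       r_cM_per_Mb = 0.87,
                       gen_time_years = 25,
                       t_modern_years = 200000,
                       t_archaic_years = 100000) {
  for (nm in c("m_bp", "r_cM_per_Mb", "gen_time_years", "t_modern_years",
               "t_archaic_years")) {
    stopifnot_positive(get(nm), nm)
  }
  structure(
    list(m_bp = m_bp, r_cM_per_Mb = r_cM_per_Mb,
         gen_time_years = gen_time_years,
         t_modern_years = t_modern_years,
         t_archaic_years = t_archaic_years),
    class = "ILSParams"
  )
}

#' Expected length of an ILS-shared tract
#'
#' `L = 1 / (r * t)` with `r = r_cM_per_Mb * 1e-8` Morgans per bp and
#' `t = (t_modern_years + t_archaic_years) / gen_time_years` generations.
#'
#' @param params an [ils_params()].
#' @return expected tract length in bp.
#' @examples
#' expected_tract_length(ils_params())  # ~9578.5 bp
#' @export
expected_tract_length <- function(params) {
  stopifnot(inherits(params, "ILSParams"))
  r_per_bp <- params$r_cM_per_Mb * 1e-8
  t_gen <- (params$t_modern_years + params$t_archaic_years) /
    params$gen_time_years
  1 / (r_per_bp * t_gen)
}

#' Probability that an ILS tract is at least the observed length
#'
#' With `L = expected_tract_length(params)` and `x = m_bp / L`, returns the
#' Gamma(shape 2, scale L) survival function `(1 + x) * exp(-x)`: the tract
#' is modelled as the sum of two independent exponential extents (left and
#' right of a focal point), each with mean `L`.  A small value means a
#' haplotype of this length is unlikely to be shared through incomplete
#' lineage sorting and supports introgression instead.
#'
#' @param params an [ils_params()].
#' @return probability in (0, 1].
#' @examples
#' round(ils_probability(ils_params()), 2)  # 0.02 at the default locus
#' @export
ils_probability <- function(params) {
  stopifnot(inherits(params, "ILSParams"))
  x <- params$m_bp / expected_tract_length(params)
  ## identical to stats::pgamma(x, shape = 2, lower.tail = FALSE)
  (1 + x) * exp(-x)
}

#' Sensitivity of the ILS probability to branch lengths
#'
#' The branch lengths are the least constrained inputs (deliberately chosen
#' as conservative lower estimates, since overestimated branches understate
#' the ILS probability); this helper evaluates the probability over a grid.
#'
#' @param params baseline [ils_params()].
#' @param modern_grid,archaic_grid branch lengths (years) to evaluate.
#' @return data.frame: t_modern_years, t_archaic_years, expected_length_bp,
#'   probability.
#' @export
ils_sensitivity <- function(params,
                            modern_grid = seq(150000, 350000, by = 50000),
                            archaic_grid = seq(80000, 140000, by = 20000)) {
  stopifnot(inherits(params, "ILSParams"))
  grid <- expand.grid(t_modern_years = modern_grid,
                      t_archaic_years = archaic_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- ils_params(params$m_bp, params$r_cM_per_Mb, params$gen_time_years,
                    grid$t_modern_years[i], grid$t_archaic_years[i])
    c(expected_length_bp = expected_tract_length(p),
      probability = ils_probability(p))
  })
  cbind(grid, do.call(rbind, res))
}
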