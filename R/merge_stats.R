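#' Statistics configuration
#'
#' @param u Instability factor entering the refinement weights
#'   `w = 1/(sigma^2 + (u * Fo^2)^2)`; dimensionless, default 0.01.
#' @param obs_threshold Multiplier on sigma in the observed-reflection
#'   criterion `I > obs_threshold * sigma(I)`; default 3.
#' @return An object of class `"stats_config"`.
#' @export
stats_config <- function(u = 0.01, obs_threshold = 3) {
  if (u < 0) stop("u must be non-negative")
  if (!(obs_threshold > 0)) stop("obs_threshold must be positive")
  structure(list(u = u, obs_threshold = obs_threshold), class = "stats_config")
}

#' Merge symmetry-equivalent measurements
#'
#' Each unique reflection gets the unweighted mean of its member
#' intensities and a merged e.s.u. propagated from the (corrected)
#' per-measurement e.s.u.'s, `sqrt(sum(sigma'^2))/n` — the standard error
#' of the mean under independent errors. The merged intensity does not
#' depend on the error model; only the e.s.u. and hence the observed flag
#' do. Optionally the scatter-based standard error of the mean
#' (`sample_std/sqrt(n)`) is used where it exceeds the propagated value.
#'
#' @param groups An [group_equivalents()] result, typically after
#'   [apply_error_model()] (the `sigma_adj` column is used when present).
#' @param config A [stats_config()].
#' @param use_scatter Take `max(propagated, scatter-based)` as merged e.s.u.
#' @return A data frame of class `"merged_reflections"`: canonical `h`,
#'   `k`, `l`, `intensity`, `sigma`, `n`, `observed`.
#' @export
merge_groups <- function(groups, config = stats_config(), use_scatter = FALSE) {
  stopifnot(inherits(groups, "esu_groups"))
  m <- groups$measurements
  g <- groups$groups
  if (nrow(g) == 0L) stop("no groups to merge")
  sig <- if (!is.null(m$sigma_adj)) m$sigma_adj else m$sigma
  if (any(sig <= 0)) stop("non-positive e.s.u.'s: cannot merge")
  ssq <- as.numeric(tapply(sig^2, m$group, sum))
  merged_sig <- sqrt(ssq) / g$n
  if (use_scatter) {
    scatter <- ifelse(g$n >= 2, g$sample_std / sqrt(g$n), 0)
    merged_sig <- pmax(merged_sig, scatter)
  }
  out <- data.frame(h = g$h, k = g$k, l = g$l,
                    intensity = g$mean_intensity, sigma = merged_sig,
                    n = g$n,
                    observed = g$mean_intensity > config$obs_threshold * merged_sig)
  class(out) <- c("merged_reflections", "data.frame")
  out
}

#' Internal merging residual R_int
#'
#' `R_int = 100 * sum |I_hl - <I>_h| / sum I_hl` over all measurements
#' belonging to groups with n >= 2. Invariant under global intensity
#' scaling.
#'
#' @param groups An [group_equivalents()] result with at least one n >= 2
#'   group.
#' @return R_int in percent.
#' @examples
#' # a single pair (4, 6): |4-5| + |6-5| over 10 -> 20%
#' @export
r_int <- function(groups) {
  stopifnot(inherits(groups, "esu_groups"))
  m <- groups$measurements
  g <- groups$groups
  multi <- g$n[m$group] >= 2L
  if (!any(multi)) stop("R_int needs at least one multiply measured reflection")
  num <- sum(abs(m$intensity[multi] - g$mean_intensity[m$group][multi]))
  den <- sum(m$intensity[multi])
  if (den <= 0) stop("non-positive intensity sum: R_int undefined")
  100 * num / den
}

#' Refinement residuals R(obs), wR(all) and goodness of fit
#'
#' Given observed and calculated squared structure-factor magnitudes:
#' `R_obs = 100 * sum||Fo| - |Fc|| / sum|Fo|` over observed reflections only
#' (`Fo2 > obs_threshold * sigma`), with `|F| = sqrt(max(F2, 0))`;
#' `wR_all = 100 * sqrt(sum w (Fo2 - Fc2)^2 / sum w Fo2^2)` over all
#' reflections; `GOF = sqrt(sum w (Fo2 - Fc2)^2 / (N - n_par))`; weights
#' `w = 1/(sigma^2 + (u * Fo2)^2)` with instability factor `u`.
#'
#' @param fo2,fc2 Observed and calculated F^2, equal lengths.
#' @param sigma E.s.u.'s of `fo2`, positive.
#' @param n_par Number of refined parameters (for the GOF denominator).
#' @param config A [stats_config()].
#' @return A list with `r_obs` (percent), `wr_all` (percent), `gof`,
#'   `n_obs`, `n_all`.
#' @export
r_factors <- function(fo2, fc2, sigma, n_par = 0, config = stats_config()) {
  n <- length(fo2)
  if (length(fc2) != n || length(sigma) != n) stop("fo2, fc2 and sigma must have equal length")
  if (any(sigma <= 0)) stop("sigma must be positive")
  obs <- fo2 > config$obs_threshold * sigma
  fo <- sqrt(pmax(fo2, 0)); fc <- sqrt(pmax(fc2, 0))
  r_obs <- if (any(obs) && sum(fo[obs]) > 0)
    100 * sum(abs(fo[obs] - fc[obs])) / sum(fo[obs]) else NA_real_
  w <- 1 / (sigma^2 + (config$u * fo2)^2)
  wr_all <- 100 * sqrt(sum(w * (fo2 - fc2)^2) / sum(w * fo2^2))
  if (n <= n_par) stop("goodness of fit undefined: no degrees of freedom")
  gof <- sqrt(sum(w * (fo2 - fc2)^2) / (n - n_par))
  list(r_obs = r_obs, wr_all = wr_all, gof = gof, n_obs = sum(obs), n_all = n)
}

#' Multiplicity histogram
#'
#' Counts of unique reflections by multiplicity n.
#'
#' @param groups An [group_equivalents()] result.
#' @return Named integer vector mapping n to the number of groups.
#' @export
multiplicity_histogram <- function(groups) {
  stopifnot(inherits(groups, "esu_groups"))
  if (nrow(groups$groups) == 0L) stop("no groups")
  tab <- table(groups$groups$n)
  stats::setNames(as.integer(tab), names(tab))
}
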