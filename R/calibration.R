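#' Calibration configuration
#'
#' Tuning knobs of the normal-probability-plot calibration and the iterative
#' outlier rejection.
#'
#' @param reference_mode Reference-intensity mode overriding the model
#'   default (`"inclusive_mean"` for model 2, `"max"` for model 3); one of
#'   `"inclusive_mean"`, `"exclusive_mean"`, `"weighted_mean"`, `"max"`.
#' @param tukey_k Tukey fence multiplier k, `> 0`. 1.5 is the classic rule.
#' @param plotting_position Rule mapping rank i of N to a CDF value:
#'   `"centered"` for (i - 0.5)/N, `"expected"` for i/(N + 1).
#' @param init Starting [error_model_params()], or `NULL` (default) for
#'   data-driven initial values: a restricted-maximum-likelihood estimate of
#'   the corrected-variance composition from the within-group residuals, a
#'   consistent starting point that places the simplex in the right valley
#'   of the misfit surface (the quantile misfit is nearly flat along a
#'   s_fac-vs-s_B ridge when counting variances are close to proportional to
#'   intensity, so a good start matters more than the final polish).
#' @param tol_d Relative convergence tolerance on the plot misfit D.
#' @param tol_param Relative convergence tolerance on the parameters.
#' @param max_supercycles Cap on re-sorting supercycles per fit.
#' @param max_outlier_iters Cap on fit/reject alternations.
#' @param allow_negative Allow `s_b`/`s_add` to go negative during fitting.
#' @param seed Integer seed recorded in run manifests.
#' @return An object of class `"calibration_config"`.
#' @export
calibration_config <- function(reference_mode = NULL, tukey_k = 1.5,
                               plotting_position = c("centered", "expected"),
                               init = NULL,
                               tol_d = 1e-7, tol_param = 1e-6,
                               max_supercycles = 12L, max_outlier_iters = 12L,
                               allow_negative = FALSE, seed = 1L) {
  plotting_position <- match.arg(plotting_position)
  if (!(tukey_k > 0)) stop("tukey_k must be positive")
  if (max_supercycles < 1L || max_outlier_iters < 1L) stop("iteration caps must be >= 1")
  if (!is.null(reference_mode))
    reference_mode <- match.arg(reference_mode,
                                c("inclusive_mean", "exclusive_mean", "weighted_mean", "max"))
  structure(list(reference_mode = reference_mode, tukey_k = tukey_k,
                 plotting_position = plotting_position, init = init,
                 tol_d = tol_d, tol_param = tol_param,
                 max_supercycles = as.integer(max_supercycles),
                 max_outlier_iters = as.integer(max_outlier_iters),
                 allow_negative = allow_negative, seed = as.integer(seed)),
            class = "calibration_config")
}

# per-measurement reference intensities over the non-excluded members of each
# group, plus the mask of measurements usable in the plot (>= 2 active members)
.reference_vector <- function(m, mode, exclude = NULL, sigma = NULL) {
  if (is.null(exclude)) exclude <- rep(FALSE, nrow(m))
  act <- !exclude
  gid <- m$group
  ng <- max(gid)
  n_act <- tabulate(gid[act], ng)
  sum_act <- rep(0, ng)
  tmp <- tapply(m$intensity[act], gid[act], sum)
  sum_act[as.integer(names(tmp))] <- tmp
  iref <- switch(mode,
    inclusive_mean = (sum_act / pmax(n_act, 1))[gid],
    exclusive_mean = {
      v <- (sum_act[gid] - ifelse(act, m$intensity, 0)) /
           pmax(n_act[gid] - act, 1)
      v[n_act[gid] - act < 1] <- NA_real_
      v
    },
    weighted_mean = {
      if (is.null(sigma)) stop("weighted_mean reference needs current e.s.u.'s")
      w <- ifelse(act, 1 / sigma^2, 0)
      sw <- rep(0, ng); swi <- rep(0, ng)
      t1 <- tapply(w, gid, sum); sw[as.integer(names(t1))] <- t1
      t2 <- tapply(w * m$intensity, gid, sum); swi[as.integer(names(t2))] <- t2
      (swi / pmax(sw, .Machine$double.xmin))[gid]
    },
    max = {
      mx <- rep(-Inf, ng)
      tmx <- tapply(m$intensity[act], gid[act], max)
      mx[as.integer(names(tmx))] <- tmx
      mx[gid]
    },
    stop("unknown reference mode: ", mode))
  list(iref = iref, usable = act & n_act[gid] >= 2L)
}

#' Reference intensity of a group member
#'
#' The intensity against which a measurement's deviation is normalized:
#' the unweighted mean over all members including the measurement itself
#' (`"inclusive_mean"`, the package default), the mean excluding it
#' (`"exclusive_mean"`, undefined for n = 1), the inverse-variance-weighted
#' mean (`"weighted_mean"`), or the largest member intensity (`"max"`).
#'
#' @param intensities Member intensities of one group.
#' @param member Index of the measurement in question (needed for
#'   `exclusive_mean`).
#' @param mode Reference mode (see above).
#' @param sigmas Current e.s.u.'s, needed for `weighted_mean`.
#' @return The reference intensity; `NA` for `exclusive_mean` on n = 1.
#' @examples
#' reference_intensity(c(4, 6), mode = "max")  # 6
#' @export
reference_intensity <- function(intensities, member = 1L,
                                mode = c("inclusive_mean", "exclusive_mean",
                                         "weighted_mean", "max"),
                                sigmas = NULL) {
  mode <- match.arg(mode)
  if (length(intensities) == 0L) stop("empty group")
  switch(mode,
    inclusive_mean = mean(intensities),
    exclusive_mean = if (length(intensities) < 2L) NA_real_
                     else mean(intensities[-member]),
    weighted_mean = {
      if (is.null(sigmas)) stop("weighted_mean needs e.s.u.'s")
      sum(intensities / sigmas^2) / sum(1 / sigmas^2)
    },
    max = max(intensities))
}

#' Normalized deviations
#'
#' `delta = (I - I_ref) / sigma'` per measurement; if the e.s.u.'s describe
#' the scatter correctly these follow a standard normal distribution.
#' Measurements in groups with a single (active) member get delta = 0 by the
#' inclusive-mean convention and are excluded from plot construction.
#'
#' @param groups An [group_equivalents()] result.
#' @param sigma Per-measurement e.s.u.'s; defaults to the `sigma_adj` column
#'   when present, else the counting-statistics `sigma`.
#' @param mode Reference mode, see [reference_intensity()].
#' @return Numeric vector of deltas aligned with `groups$measurements`,
#'   with logical attribute `"usable"` marking members of multi-measurement
#'   groups (the ones that enter normal-probability plots).
#' @export
normalized_deviations <- function(groups, sigma = NULL, mode = "inclusive_mean") {
  stopifnot(inherits(groups, "esu_groups"))
  m <- groups$measurements
  if (is.null(sigma))
    sigma <- if (!is.null(m$sigma_adj)) m$sigma_adj else m$sigma
  rv <- .reference_vector(m, mode, sigma = sigma)
  delta <- rep(0, nrow(m))
  u <- rv$usable
  if (any(u)) {
    if (any(sigma[u] <= 0)) stop("non-positive e.s.u. among multiply measured reflections")
    delta[u] <- (m$intensity[u] - rv$iref[u]) / sigma[u]
  }
  attr(delta, "usable") <- u
  delta
}

#' Theoretical standard-normal quantiles
#'
#' Expected values of the order statistics of a standard-normal sample of
#' size N: `qnorm(p_i)` at plotting positions `p_i = (i - 0.5)/N`
#' (`"centered"`, default) or `p_i = i/(N + 1)` (`"expected"`). The sequence
#' is strictly increasing and antisymmetric, `q_i = -q_{N+1-i}`.
#'
#' @param n Sample size N, `>= 1`.
#' @param rule Plotting-position rule.
#' @return Numeric vector of length `n`.
#' @examples
#' theoretical_quantiles(3)  # -0.967, 0, 0.967
#' @export
theoretical_quantiles <- function(n, rule = c("centered", "expected")) {
  rule <- match.arg(rule)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  i <- seq_len(n)
  p <- if (rule == "centered") (i - 0.5) / n else i / (n + 1)
  stats::qnorm(p)
}

# Working arrays for one calibration pass. The numerator reference of the
# normalized deviation is always a mean (the group maximum enters only the
# corrected-sigma formula, mode "max"), computed over non-excluded members;
# only members of groups with >= 2 active measurements are usable.
.prep_calib <- function(m, mode, exclude = NULL) {
  if (is.null(exclude)) exclude <- rep(FALSE, nrow(m))
  act <- !exclude
  gid <- m$group
  ng <- max(gid)
  n_act <- tabulate(gid[act], ng)
  usable <- act & n_act[gid] >= 2L
  idx <- which(usable)
  gid_u <- match(gid[idx], sort(unique(gid[idx])))   # contiguous 1..G
  sumI <- rowsum(m$intensity[idx], gid_u)[, 1]
  maxI <- as.numeric(tapply(m$intensity[idx], gid_u, max))
  n_u <- tabulate(gid_u)[gid_u]
  list(idx = idx, gid = gid_u, n = n_u,
       I = m$intensity[idx], s0 = m$sigma[idx],
       mean_ref = sumI[gid_u] / n_u,
       excl_ref = (sumI[gid_u] - m$intensity[idx]) / (n_u - 1L),
       max_ref = maxI[gid_u],
       group_ids_orig = m$group[idx])
}

# The corrected variance is optimized in the decoupled composition
# sigma'^2 = u * sigma0^2 + v * max(I_ref, 0) + w * I_ref^2 with
# u = s_fac^2, v = s_fac^2 s_B, w = (s_fac s_add)^2: a bijection for u > 0
# that removes the multiplicative coupling between s_fac and the other two
# parameters (a curved valley the simplex tracks poorly in the original
# coordinates).
.p2uvw <- function(p) c(p[1]^2, p[1]^2 * p[2], (p[1] * p[3])^2)
.uvw2p <- function(u) c(sqrt(u[1]), u[2] / u[1], sqrt(pmax(u[3], 0) / u[1]))

# Standardized deviations z_l = delta_l / c_l at composition uvw. delta uses
# the mode's numerator mean; sigma' uses the mode's reference intensity
# (group max for mode "max", the mean otherwise). c_l is the exact null
# standard deviation of delta_l for independent Gaussian errors with sds
# sigma'_j:
#   inclusive mean:  c^2 = 1 - 2/n + (sum_j sigma_j'^2) / (n^2 sigma_l'^2)
#   exclusive mean:  c^2 = 1 + (sum_{j!=l} sigma_j'^2) / ((n-1)^2 sigma_l'^2)
#   weighted mean:   c^2 = 1 - 1 / (sigma_l'^2 sum_j sigma_j'^-2)
# At n = 2 with equal sigmas the inclusive form gives c = 1/sqrt(2), the
# familiar +-0.707 signature of reflection pairs.
.std_deviations <- function(pc, uvw, mode) {
  sig_ref <- if (mode == "max") pc$max_ref else
             if (mode == "exclusive_mean") pc$excl_ref else pc$mean_ref
  v <- uvw[1] * pc$s0^2 + uvw[2] * pmax(sig_ref, 0) + uvw[3] * sig_ref^2
  sig <- sqrt(pmax(v, .Machine$double.xmin))
  s2 <- sig^2
  gs <- rowsum(s2, pc$gid)[, 1][pc$gid]
  n <- pc$n
  if (mode == "exclusive_mean") {
    num_ref <- pc$excl_ref
    c2 <- 1 + (gs - s2) / ((n - 1L)^2 * s2)
  } else if (mode == "weighted_mean") {
    w <- 1 / s2
    gw <- rowsum(w, pc$gid)[, 1][pc$gid]
    gwi <- rowsum(w * pc$I, pc$gid)[, 1][pc$gid]
    num_ref <- gwi / gw
    c2 <- pmax(1 - 1 / (s2 * gw), 1e-6)
  } else {
    num_ref <- pc$mean_ref
    c2 <- 1 - 2 / n + gs / (n^2 * s2)
  }
  (pc$I - num_ref) / (sig * sqrt(c2))
}

# One normal-probability-plot fit at fixed outlier exclusion.
# Supercycles: fix the ordering of the standardized deviations, minimize
# D = sum((z_i - q_i)^2) against the fixed quantiles by Nelder-Mead over
# (s_fac, s_B, s_add), re-sort, repeat until D, the parameters and the
# ordering stabilize. Re-sorting can only decrease D (rearrangement
# inequality), so D is non-increasing over accepted steps.
.fit_npp <- function(groups, mode, cfg, exclude = NULL) {
  m <- groups$measurements
  pc <- .prep_calib(m, mode, exclude)
  if (length(pc$idx) == 0L) stop("no multiply measured reflections to calibrate against")
  lower <- if (cfg$allow_negative) c(1e-10, -Inf, -Inf) else c(1e-10, 0, 0)
  N <- length(pc$idx)
  q <- theoretical_quantiles(N, cfg$plotting_position)
  if (!is.null(exclude) && any(exclude)) {
    # surviving deviations are a fence-censored sample: match them against
    # the quantiles of the normal truncated at the nominal Tukey fence
    # (z = qnorm(.75)*(1+2k)), not of a complete normal — otherwise the fit
    # deflates the tail sigmas to stretch the censored extremes and each
    # rejection pass flags more points than the last
    alpha <- stats::pnorm(stats::qnorm(0.75) * (1 + 2 * cfg$tukey_k),
                          lower.tail = FALSE)
    i <- seq_len(N)
    p <- if (cfg$plotting_position == "centered") (i - 0.5) / N else i / (N + 1)
    q <- stats::qnorm(alpha + p * (1 - 2 * alpha))
  }
  s02m <- stats::median(pc$s0^2)
  Im <- stats::median(pmax(abs(pc$mean_ref), 1))
  parscale <- c(0.25, 0.25 * s02m / Im, 0.25 * s02m / Im^2)

  z_of <- function(uvw) .std_deviations(pc, pmax(uvw, lower), mode)
  objective <- function(uvw, ord) {
    pen <- sum((pmin(uvw - lower, 0) / parscale)^2)
    z <- z_of(uvw)
    sum((z[ord] - q)^2) + 1e6 * pen
  }
  run_supercycles <- function(uvw) {
    ord <- order(z_of(uvw))
    D <- sum((z_of(uvw)[ord] - q)^2)
    converged <- FALSE
    sc <- 0L
    rel_dd <- Inf
    while (sc < cfg$max_supercycles) {
      sc <- sc + 1L
      opt <- stats::optim(uvw, objective, ord = ord, method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-12,
                                         parscale = parscale))
      new_uvw <- pmax(opt$par, lower)
      new_ord <- order(z_of(new_uvw))
      new_D <- sum((z_of(new_uvw)[new_ord] - q)^2)
      rel_dd <- abs(D - new_D) / max(new_D, 1)
      uvw <- new_uvw; ord <- new_ord; D <- new_D
      # convergence is judged through D alone: ties among near-equal
      # deviations can swap order indefinitely, and the simplex restart
      # jitters the parameters along the flat valley without moving D
      if (rel_dd <= cfg$tol_d) { converged <- TRUE; break }
    }
    # each re-sort keeps unlocking micro-improvements far below the plot's
    # statistical noise; D stationary to 0.1% per cycle counts as converged
    if (!converged && rel_dd <= 1e-3) converged <- TRUE
    list(uvw = uvw, D = D, sc = sc, converged = converged)
  }

  start <- if (!is.null(cfg$init)) {
    .p2uvw(c(cfg$init$s_fac, cfg$init$s_b, cfg$init$s_add))
  } else {
    # restricted-maximum-likelihood start: maximize the profile likelihood
    # of the within-group residuals under independent Gaussian errors with
    # variances u*sigma0^2 + v*max(I_ref,0) + w*I_ref^2 (the group mean is
    # profiled out; the 0.5*log(sum of weights) term is the REML adjustment
    # for estimating it). A consistent estimate that places the simplex in
    # the right valley of the misfit surface.
    tryCatch({
      sig_ref <- if (mode == "max") pc$max_ref else pc$mean_ref
      X1 <- pc$s0^2; X2 <- pmax(sig_ref, 0); X3 <- sig_ref^2
      nll <- function(uvw) {
        uvw <- pmax(uvw, c(1e-10, 0, 0))
        s2 <- uvw[1] * X1 + uvw[2] * X2 + uvw[3] * X3
        w <- 1 / s2
        W <- rowsum(w, pc$gid)[, 1]
        mu <- rowsum(w * pc$I, pc$gid)[, 1] / W
        r <- pc$I - mu[pc$gid]
        0.5 * sum(log(s2) + w * r^2) + 0.5 * sum(log(W))
      }
      pmax(stats::optim(c(1, 0, 0), nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10,
                                       parscale = parscale))$par,
           c(1e-10, lower[2:3]))
    }, error = function(e) c(1, 0, 0))
  }

  best <- run_supercycles(start)
  uvw <- best$uvw
  par <- .uvw2p(uvw)
  zs <- sort(z_of(uvw))
  fit_line <- stats::lsfit(q, zs)$coefficients
  list(params = error_model_params(par[1], par[2], par[3],
                                   allow_negative = cfg$allow_negative),
       deltas_sorted = zs, quantiles = q, D = best$D,
       intercept = unname(fit_line[1]), slope = unname(fit_line[2]),
       n_supercycles = best$sc, converged = best$converged, usable_idx = pc$idx)
}

#' Fit the three-parameter error model by normal-plot linearization
#'
#' Optimizes (s_fac, s_B, s_add) so that the sorted normalized deviations
#' track the theoretical standard-normal quantiles, minimizing the misfit
#' `D = sum((delta_i - q_i)^2)` with a derivative-free simplex. After each
#' minimization the deviations are re-sorted and the supercycle repeated
#' until D, the parameters and the ordering stabilize. Measurements flagged
#' in `exclude` and members of groups left with fewer than two active
#' measurements are omitted from the plot.
#'
#' The deviations entering D are standardized: the plain delta of a member
#' of an n-fold group is Gaussian with standard deviation below 1 even when
#' the e.s.u.'s are perfect, because the empirical reference mean is
#' correlated with the measurement (exactly 1/sqrt(2) at n = 2 — the
#' constant steps reflection pairs produce in normal plots). Each delta is
#' therefore divided by its exact null scale before being matched to the
#' quantiles; otherwise low-redundancy data would bias every fitted
#' parameter downward and the minimum would not sit at the generating
#' parameters.
#'
#' @param groups An [group_equivalents()] result.
#' @param mode Reference-intensity mode for the corrected e.s.u.:
#'   `"inclusive_mean"` is the mean-referenced model (model 2), `"max"` the
#'   maximum-referenced one (model 3; the group maximum enters only the
#'   sigma correction — deviations are always measured from a mean);
#'   `"exclusive_mean"` and `"weighted_mean"` are available for comparison.
#' @param config A [calibration_config()].
#' @param exclude Optional logical vector flagging measurements (e.g.
#'   outliers) to leave out of the fit.
#' @return A list with the fitted `params`, `deltas_sorted`, `quantiles`,
#'   misfit `D`, normal-plot `slope` and `intercept`, `n_supercycles` and
#'   `converged`.
#' @export
fit_error_model <- function(groups, mode = c("inclusive_mean", "max",
                                             "exclusive_mean", "weighted_mean"),
                            config = calibration_config(), exclude = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(groups, "esu_groups"))
  if (all(groups$groups$n < 2L))
    stop("no multiply measured reflections: cannot calibrate an error model")
  .fit_npp(groups, mode, config, exclude)
}

#' Tukey-fence outlier flags
#'
#' Flags values outside `[Q1 - k * IQR, Q3 + k * IQR]`, with quartiles by
#' linear interpolation of the order statistics (type 7). For symmetry-
#' equivalent pairs (groups of exactly two measurements among the supplied
#' values) a flagged member drags its partner along: with only two
#' equivalents there is no telling which of the two is wrong.
#'
#' @param deltas Numeric vector (normalized deviations).
#' @param k Fence multiplier, `> 0`.
#' @param group_id Optional integer group ids aligned with `deltas`,
#'   enabling the pair rule.
#' @return Logical vector of flags. Fewer than 4 values yield no flags and
#'   a warning.
#' @examples
#' tukey_outliers(c(1:9, 100))  # only 100 flagged
#' @export
tukey_outliers <- function(deltas, k = 1.5, group_id = NULL) {
  if (!(k > 0)) stop("k must be positive")
  n <- length(deltas)
  if (n < 4L) {
    warning("fewer than 4 values: no outlier flags assigned")
    return(rep(FALSE, n))
  }
  qs <- stats::quantile(deltas, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  flags <- deltas < qs[1] - k * iqr | deltas > qs[2] + k * iqr
  if (!is.null(group_id)) {
    sz <- table(group_id)
    pair_ids <- as.integer(names(sz)[sz == 2L])
    hit <- unique(group_id[flags])
    drag <- group_id %in% intersect(pair_ids, hit)
    flags <- flags | drag
  }
  flags
}

#' Calibrate an intensity error model
#'
#' The package's main fitting function. Alternates normal-probability-plot
#' refinement of (s_fac, s_B, s_add) with Tukey-fence outlier rejection:
#' the first rejection pass screens the deviations of the uncorrected data,
#' each fit excludes the current outliers, the fitted parameters are then
#' applied to all measurements and the fences re-evaluated, until the
#' parameters and the outlier set stop changing. Model 2 corrects each
#' e.s.u. using the group mean intensity as reference; model 3 uses the
#' group maximum instead, which avoids inflating the e.s.u.'s of strong
#' reflections when the spread among equivalents is large — the regime
#' typical of electron diffraction data. Deviations are standardized by
#' their exact null scale before entering the misfit and the fences; see
#' [fit_error_model()].
#'
#' @param groups An [group_equivalents()] result; at least one group must
#'   have n >= 2.
#' @param model 2 (mean reference) or 3 (maximum reference).
#' @param config A [calibration_config()]; `config$reference_mode` overrides
#'   the model's default reference.
#'
#' @return An object of class `"esu_calibration"` with components `params`
#'   ([error_model_params()]), `model`, `mode`, `deltas_sorted`, `quantiles`,
#'   `D`, `slope`, `intercept`, `outlier_flags` (per measurement),
#'   `n_supercycles`, `n_outlier_iters`, `converged`, `n_measurements`,
#'   `n_used`, `config` and the `groups` calibrated against. Methods:
#'   `print`, `summary`, `coef`, `plot`, `predict`, `residuals`.
#' @seealso [apply_error_model()] to stamp the fitted e.s.u.'s onto the
#'   measurements, [merge_groups()] to average equivalents afterwards.
#' @examples
#' spec <- synthetic_spec(n_groups = 300, seed = 7)
#' sim <- simulate_reflections(spec)
#' g <- group_equivalents(sim$measurements, symmetry_setting(operators = list(diag(3)),
#'                                                           add_friedel = FALSE))
#' fit <- esu_calibrate(g, model = 3)
#' coef(fit)
#' @export
esu_calibrate <- function(groups, model = 3, config = calibration_config()) {
  stopifnot(inherits(groups, "esu_groups"))
  model <- as.integer(model)
  if (!model %in% c(2L, 3L)) stop("calibration is defined for models 2 and 3")
  mode <- if (!is.null(config$reference_mode)) config$reference_mode
          else if (model == 2L) "inclusive_mean" else "max"
  m <- groups$measurements
  pc_all <- .prep_calib(m, mode)
  s02m_all <- stats::median(pc_all$s0^2)
  im_all <- stats::median(pmax(abs(pc_all$mean_ref), 1))

  flag_from_z <- function(z) {
    f <- rep(FALSE, nrow(m))
    if (length(pc_all$idx) >= 4L)
      f[pc_all$idx] <- tukey_outliers(z, config$tukey_k, pc_all$group_ids_orig)
    f
  }
  # first rejection pass screens the uncorrected data (identity parameters)
  flags <- flag_from_z(.std_deviations(pc_all, c(1, 0, 0), mode))

  fit <- NULL
  it <- 0L
  outer_converged <- FALSE
  prev_par <- if (is.null(config$init)) c(1, 0, 0)
              else c(config$init$s_fac, config$init$s_b, config$init$s_add)
  cfg_it <- config
  while (it < config$max_outlier_iters) {
    it <- it + 1L
    fit <- .fit_npp(groups, mode, cfg_it, exclude = flags)
    cfg_it$init <- fit$params   # warm-start subsequent refits
    p <- fit$params
    # re-evaluate the fences on all measurements with the fitted correction
    z_all <- .std_deviations(pc_all, .p2uvw(c(p$s_fac, p$s_b, p$s_add)), mode)
    new_flags <- flag_from_z(z_all)
    par <- c(p$s_fac, p$s_b, p$s_add)
    # parameter stability on the corrected-variance scale: changes are
    # weighted by the typical size of the term they multiply, so a
    # physically negligible shuffle between s_B (counts) and s_fac does not
    # read as movement
    du <- abs(.p2uvw(par) - .p2uvw(prev_par))
    denom <- sum(.p2uvw(prev_par) * c(s02m_all, im_all, im_all^2))
    dpar <- sum(du * c(s02m_all, im_all, im_all^2)) / max(denom, s02m_all * 1e-6)
    prev_par <- par
    # the iteration ends when the parameters settle and the number of
    # identified outliers stops changing (after several passes, a count
    # oscillating by a measurement or two around the fences counts as stable)
    slack <- if (it >= 3L) max(1L, as.integer(2e-3 * length(pc_all$idx))) else 0L
    if (abs(sum(new_flags) - sum(flags)) <= slack && dpar <= 1e-2) {
      flags <- new_flags
      outer_converged <- TRUE
      break
    }
    flags <- new_flags
  }

  structure(list(params = fit$params, model = model, mode = mode,
                 deltas_sorted = fit$deltas_sorted, quantiles = fit$quantiles,
                 D = fit$D, slope = fit$slope, intercept = fit$intercept,
                 outlier_flags = flags,
                 n_supercycles = fit$n_supercycles, n_outlier_iters = it,
                 converged = fit$converged && outer_converged,
                 n_measurements = nrow(m), n_used = length(fit$deltas_sorted),
                 config = config, groups = groups, call = match.call()),
            class = "esu_calibration")
}

#' @export
print.esu_calibration <- function(x, ...) {
  cat(sprintf("Error-model calibration (model %d, %s reference)\n", x$model, x$mode))
  cat(sprintf("  s_fac = %.6g, s_B = %.6g, s_add = %.6g\n",
              x$params$s_fac, x$params$s_b, x$params$s_add))
  cat(sprintf("  normal plot: slope %.4f, intercept %.4f, D = %.4g (N = %d)\n",
              x$slope, x$intercept, x$D, x$n_used))
  cat(sprintf("  outliers: %d of %d measurements; %s after %d supercycle(s), %d rejection pass(es)\n",
              sum(x$outlier_flags), x$n_measurements,
              if (x$converged) "converged" else "NOT converged",
              x$n_supercycles, x$n_outlier_iters))
  invisible(x)
}

#' @export
coef.esu_calibration <- function(object, ...) {
  c(s_fac = object$params$s_fac, s_B = object$params$s_b, s_add = object$params$s_add)
}

#' @export
summary.esu_calibration <- function(object, ...) {
  g <- object$groups$groups
  structure(list(fit = object,
                 multiplicity = table(g$n),
                 n_groups = nrow(g),
                 outlier_fraction = mean(object$outlier_flags)),
            class = "summary.esu_calibration")
}

#' @export
print.summary.esu_calibration <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d unique reflections; outlier fraction %.2f%%\n",
              x$n_groups, 100 * x$outlier_fraction))
  cat("  multiplicity:",
      paste(sprintf("n=%s:%d", names(x$multiplicity), as.integer(x$multiplicity)),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
residuals.esu_calibration <- function(object, ...) {
  object$deltas_sorted - object$quantiles
}

#' Corrected e.s.u.'s from a calibration
#'
#' Applies the fitted three-parameter correction to (new) grouped
#' measurements, returning the adjusted per-measurement e.s.u.'s.
#'
#' @param object An [esu_calibrate()] fit.
#' @param groups An [group_equivalents()] result; defaults to the data the
#'   model was calibrated on.
#' @param ... Unused.
#' @return Numeric vector of corrected e.s.u.'s aligned with
#'   `groups$measurements`.
#' @export
predict.esu_calibration <- function(object, groups = object$groups, ...) {
  g <- apply_error_model(groups, object$model, object$params)
  g$measurements$sigma_adj
}

#' Normal probability plot of a calibration
#'
#' Sorted normalized deviations against theoretical standard-normal
#' quantiles; the dashed identity line is the ideal, the solid line the
#' least-squares fit whose slope and intercept the calibration reports.
#'
#' @param x An [esu_calibrate()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.esu_calibration <- function(x, ...) {
  graphics::plot(x$quantiles, x$deltas_sorted,
                 xlab = "theoretical quantile", ylab = "normalized deviation",
                 main = sprintf("Normal probability plot (model %d)", x$model),
                 pch = 20, cex = 0.4, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}
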