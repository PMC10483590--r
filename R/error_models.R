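#' Error-model correction parameters
#'
#' The SDFAC/SDB/SDADD triple inflating counting-statistics variances:
#' `s_fac` is a dimensionless overall scale (errors independent of the
#' intensity, e.g. gain uncertainty), `s_b` (counts) accounts for errors
#' proportional to the intensity such as instrument instabilities, and
#' `s_add` (dimensionless) is a fractional term with no direct physical
#' meaning, included for flexibility of the fit.
#'
#' @param s_fac Scale factor, `> 0`.
#' @param s_b Intensity-proportional term in counts, `>= 0` unless
#'   `allow_negative`.
#' @param s_add Fractional term, `>= 0` unless `allow_negative`.
#' @param allow_negative Relax the non-negativity of `s_b` and `s_add`
#'   (positivity of every corrected variance is then checked at application
#'   time instead).
#' @return An object of class `"error_model_params"`.
#' @examples
#' error_model_params(1, 0, 0)  # identity correction
#' @export
error_model_params <- function(s_fac = 1, s_b = 0, s_add = 0, allow_negative = FALSE) {
  if (!(s_fac > 0)) stop("s_fac must be positive")
  if (!allow_negative && (s_b < 0 || s_add < 0))
    stop("s_b and s_add must be non-negative (set allow_negative to relax)")
  structure(list(s_fac = s_fac, s_b = s_b, s_add = s_add), class = "error_model_params")
}

#' @export
print.error_model_params <- function(x, ...) {
  cat(sprintf("s_fac = %.6g, s_B = %.6g, s_add = %.6g\n", x$s_fac, x$s_b, x$s_add))
  invisible(x)
}

#' Sample standard deviation of equivalent intensities
#'
#' The Bessel-corrected sample standard deviation
#' `sqrt(sum((x - mean(x))^2) / (n - 1))` used as the common e.s.u. of all
#' members of a multiply measured reflection. Requires n >= 2; singly
#' measured reflections must use the binned lookup table instead.
#'
#' @param values Numeric vector of n >= 2 equivalent intensities.
#' @return The sample standard deviation.
#' @export
sample_std <- function(values) {
  if (length(values) < 2L)
    stop("sample_std requires at least two measurements; use the lookup table for n = 1")
  stats::sd(values)
}

#' Binned e.s.u. lookup table for singly measured reflections
#'
#' Unique reflections with n >= 2 are sorted by mean intensity into ten
#' equal-count bins (the remainder of N mod 10 spread one-per-bin from the
#' highest bin downward) and into resolution bins of width 0.2 1/angstrom
#' anchored at d* = 0. Each cell stores the arithmetic mean of the sample
#' standard deviations of its member reflections; a singly measured
#' reflection is assigned the value of its (intensity, resolution) cell.
#'
#' @param groups An [group_equivalents()] result whose measurements carry
#'   `d_star` values.
#' @param res_bin_width Resolution bin width in 1/angstrom.
#' @return An object of class `"esu_lookup"` with intensity `breaks`, the
#'   resolution bin width, and the cell matrix (`NA` for empty cells).
#' @export
build_esu_lookup <- function(groups, res_bin_width = 0.2) {
  stopifnot(inherits(groups, "esu_groups"))
  g <- groups$groups[groups$groups$n >= 2, , drop = FALSE]
  if (nrow(g) == 0L) stop("all reflections have n = 1: sample-deviation model inapplicable")
  if (anyNA(g$d_star)) stop("d* values required to build the lookup table")
  N <- nrow(g)
  ord <- order(g$mean_intensity)
  g <- g[ord, , drop = FALSE]
  nb <- min(10L, N)
  base <- N %/% nb
  sizes <- rep(base, nb)
  r <- N %% nb
  if (r > 0) sizes[(nb - r + 1L):nb] <- sizes[(nb - r + 1L):nb] + 1L
  ibin <- rep(seq_len(nb), times = sizes)
  # breaks halfway between adjacent sorted intensities at each bin boundary
  cuts <- cumsum(sizes)[-nb]
  breaks <- c(-Inf, (g$mean_intensity[cuts] + g$mean_intensity[cuts + 1L]) / 2, Inf)
  rbin <- pmax(1L, floor(g$d_star / res_bin_width) + 1L)
  nr <- max(rbin)
  cell <- matrix(NA_real_, nb, nr)
  cnt <- matrix(0L, nb, nr)
  for (i in seq_len(N)) {
    a <- ibin[i]; b <- rbin[i]
    cnt[a, b] <- cnt[a, b] + 1L
    cell[a, b] <- if (cnt[a, b] == 1L) g$sample_std[i] else
      cell[a, b] + (g$sample_std[i] - cell[a, b]) / cnt[a, b]
  }
  structure(list(breaks = breaks, res_bin_width = res_bin_width,
                 cell = cell, n_reflections = N),
            class = "esu_lookup")
}

# cell value for (intensity, d*); nearest non-empty resolution bin in the
# same intensity row as fallback, then the overall table mean
.lookup_esu <- function(table, intensity, dstar) {
  a <- findInterval(intensity, table$breaks, all.inside = TRUE)
  nr <- ncol(table$cell)
  b <- pmin(nr, pmax(1L, floor(dstar / table$res_bin_width) + 1L))
  out <- table$cell[cbind(a, b)]
  miss <- which(is.na(out))
  for (i in miss) {
    row <- table$cell[a[i], ]
    ok <- which(!is.na(row))
    if (length(ok)) {
      out[i] <- row[ok[which.min(abs(ok - b[i]))]]
    } else {
      out[i] <- mean(table$cell, na.rm = TRUE)
    }
  }
  out
}

#' Assign sample-deviation e.s.u.'s (model 1)
#'
#' Every member of a group with n >= 2 receives the group's sample standard
#' deviation as its e.s.u.; singly measured reflections receive the mean
#' e.s.u. of their (intensity, resolution) lookup cell.
#'
#' @param groups An [group_equivalents()] result.
#' @param table An [build_esu_lookup()] table; built on the fly when `NULL`.
#' @return Numeric vector of e.s.u.'s aligned with `groups$measurements`.
#' @export
model1_assign <- function(groups, table = NULL) {
  stopifnot(inherits(groups, "esu_groups"))
  if (is.null(table)) table <- build_esu_lookup(groups)
  m <- groups$measurements
  g <- groups$groups
  out <- g$sample_std[m$group]
  single <- which(g$n[m$group] == 1L)
  if (length(single)) {
    if (is.null(m$d_star) || anyNA(m$d_star[single]))
      stop("d* values required to assign lookup e.s.u.'s to n = 1 reflections")
    out[single] <- .lookup_esu(table, m$intensity[single], m$d_star[single])
  }
  out
}

#' Three-parameter corrected e.s.u.
#'
#' `sigma' = s_fac * sqrt(sigma^2 + s_B * max(I_ref, 0) + (s_add * I_ref)^2)`.
#' The reference intensity `I_ref` is the group mean (model 2) or the group
#' maximum (model 3); a negative reference contributes nothing to the linear
#' term so that the corrected variance stays positive for
#' background-subtracted intensities that undershoot zero.
#'
#' @param sigma Counting-statistics e.s.u.(s), `>= 0`.
#' @param i_ref Reference intensity (counts), may be negative.
#' @param params An [error_model_params()].
#' @return Corrected e.s.u.(s), vectorized over `sigma` and `i_ref`.
#' @examples
#' corrected_sigma(1, 6, error_model_params(1, 1, 0))  # sqrt(7)
#' @export
corrected_sigma <- function(sigma, i_ref, params) {
  stopifnot(inherits(params, "error_model_params"))
  if (any(sigma < 0)) stop("sigma must be non-negative")
  v <- sigma^2 + params$s_b * pmax(i_ref, 0) + (params$s_add * i_ref)^2
  if (any(sigma > 0 & v <= 0))
    stop("parameters yield non-positive corrected variance")
  params$s_fac * sqrt(pmax(v, 0))
}

#' Apply an error model to grouped measurements
#'
#' Model 0 leaves the counting-statistics e.s.u.'s unchanged; model 1
#' replaces them by group sample standard deviations with the binned lookup
#' for n = 1; models 2 and 3 apply the three-parameter correction with the
#' group mean, respectively the group maximum, as reference intensity.
#' Intensities are never modified.
#'
#' @param groups An [group_equivalents()] result.
#' @param model Integer 0, 1, 2 or 3.
#' @param params [error_model_params()], required for models 2 and 3
#'   (typically `coef()` of an [esu_calibrate()] fit).
#' @param table Optional [build_esu_lookup()] table for model 1.
#' @return `groups` with an added/updated `sigma_adj` column in
#'   `$measurements` holding the adjusted per-measurement e.s.u.'s.
#' @export
apply_error_model <- function(groups, model, params = NULL, table = NULL) {
  stopifnot(inherits(groups, "esu_groups"))
  model <- as.integer(model)
  if (!model %in% 0:3) stop("model must be 0, 1, 2 or 3")
  m <- groups$measurements
  g <- groups$groups
  sig <- switch(as.character(model),
    "0" = m$sigma,
    "1" = model1_assign(groups, table),
    "2" = ,
    "3" = {
      if (is.null(params)) stop("models 2 and 3 require error-model parameters")
      iref <- if (model == 2L) g$mean_intensity[m$group] else g$max_intensity[m$group]
      corrected_sigma(m$sigma, iref, params)
    })
  groups$measurements$sigma_adj <- sig
  groups
}
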