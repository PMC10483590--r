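# Rotational subgroups of the 11 Laue classes, acting on Miller indices.
# The class name selects the proper-rotation part; Friedel inversion is
# toggled separately so that unmerged Friedel pairs can be kept apart.

.mat <- function(...) matrix(c(...), 3, 3, byrow = TRUE)

.laue_generators <- function(class) {
  id  <- diag(3)
  r2z <- diag(c(-1, -1, 1))
  r2y <- diag(c(-1, 1, -1))
  r2x <- diag(c(1, -1, -1))
  r4z <- .mat(0, -1, 0,  1, 0, 0,  0, 0, 1)       # (h,k,l) -> (-k,h,l)
  r3z <- .mat(0, 1, 0,  -1, -1, 0,  0, 0, 1)      # hexagonal 3-fold: (h,k,l) -> (k,-h-k,l)
  r2d <- .mat(0, 1, 0,  1, 0, 0,  0, 0, -1)       # 2-fold along [110] (hex): (h,k,l) -> (k,h,-l)
  r3c <- .mat(0, 1, 0,  0, 0, 1,  1, 0, 0)        # cubic body-diagonal: (h,k,l) -> (k,l,h)
  switch(class,
    "-1"    = list(id),
    "2/m"   = list(r2y),                          # unique axis b
    "mmm"   = list(r2x, r2y, r2z),
    "4/m"   = list(r4z),
    "4/mmm" = list(r4z, r2x),
    "-3"    = list(r3z),
    "-3m"   = list(r3z, r2d),                     # -3m1 setting
    "6/m"   = list(r3z, r2z),
    "6/mmm" = list(r3z, r2z, r2d),
    "m-3"   = list(r2z, r2y, r3c),
    "m-3m"  = list(r2z, r2y, r3c, r4z),
    stop("unknown Laue class: ", class)
  )
}

.group_closure <- function(gens) {
  key <- function(m) paste(as.integer(round(m)), collapse = ",")
  ops <- list(diag(3))
  names(ops) <- key(diag(3))
  queue <- gens
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    for (o in ops) {
      for (p in list(g %*% o, o %*% g)) {
        kk <- key(p)
        if (is.null(ops[[kk]])) {
          ops[[kk]] <- round(p)
          queue <- c(queue, list(round(p)))
        }
      }
    }
    if (length(ops) > 96) stop("operator set does not close: not a finite group")
  }
  unname(ops)
}

#' Laue-class rotation operators
#'
#' Returns the proper-rotation operators (3x3 integer matrices acting on
#' Miller index columns) of one of the 11 Laue classes, generated by closure
#' from canonical generators. The inversion that completes the Laue group is
#' handled separately through `add_friedel` in [symmetry_setting()].
#' Conventions: `2/m` uses unique axis b; trigonal and hexagonal classes use
#' hexagonal axes; `-3m` is the -3m1 setting. Other settings can be supplied
#' as an explicit operator list to [symmetry_setting()].
#'
#' @param class One of `"-1"`, `"2/m"`, `"mmm"`, `"4/m"`, `"4/mmm"`, `"-3"`,
#'   `"-3m"`, `"6/m"`, `"6/mmm"`, `"m-3"`, `"m-3m"`.
#' @return A list of 3x3 integer matrices containing the identity and closed
#'   under composition.
#' @export
laue_operators <- function(class) {
  .group_closure(.laue_generators(class))
}

#' Symmetry setting for equivalence grouping
#'
#' Bundles the operator set that defines which reflections are considered
#' symmetry-equivalent. Either a Laue-class name or an explicit list of 3x3
#' integer rotation matrices may be given. With `add_friedel = TRUE` (the
#' default, matching the common practice of adding a centre of symmetry when
#' averaging) the inversion is composed with every operator, so Friedel
#' mates h,k,l and -h,-k,-l fall in the same group.
#'
#' @param laue_class Laue-class name (see [laue_operators()]), or `NULL` if
#'   `operators` is given.
#' @param operators Optional explicit list of 3x3 integer matrices; must
#'   contain the identity after closure.
#' @param add_friedel Logical; include the inversion.
#'
#' @return An object of class `"symmetry_setting"` with elements `operators`
#'   (the full closed set actually applied, inversion included if requested),
#'   `laue_class` and `add_friedel`.
#' @examples
#' symmetry_setting("mmm")
#' symmetry_setting(operators = list(diag(3)), add_friedel = FALSE)
#' @export
symmetry_setting <- function(laue_class = NULL, operators = NULL, add_friedel = TRUE) {
  if (is.null(operators)) {
    if (is.null(laue_class)) stop("either 'laue_class' or 'operators' must be given")
    ops <- laue_operators(laue_class)
  } else {
    if (length(operators) == 0L) stop("empty operator set")
    ok <- vapply(operators, function(m) is.matrix(m) && all(dim(m) == 3) &&
                   all(abs(m - round(m)) < 1e-9) && abs(abs(det(m)) - 1) < 1e-9, logical(1))
    if (!all(ok)) stop("operators must be 3x3 integer matrices with |det| = 1")
    ops <- .group_closure(lapply(operators, round))
  }
  if (isTRUE(add_friedel))
    ops <- .group_closure(c(ops, list(-diag(3))))
  structure(list(operators = ops,
                 laue_class = if (is.null(laue_class)) NA_character_ else laue_class,
                 add_friedel = isTRUE(add_friedel)),
            class = "symmetry_setting")
}

#' @export
print.symmetry_setting <- function(x, ...) {
  cat(sprintf("Symmetry setting: %s (%d operators%s)\n",
              if (is.na(x$laue_class)) "custom operators" else paste("Laue", x$laue_class),
              length(x$operators),
              if (x$add_friedel) ", Friedel inversion included" else ""))
  invisible(x)
}

# canonical representative: lexicographically greatest orbit member
# (compare h, then k, then l)
.canonicalize <- function(hkl, ops) {
  n <- nrow(hkl)
  best <- matrix(-Inf, n, 3)
  for (op in ops) {
    cand <- hkl %*% t(op)
    newer <- (cand[, 1] > best[, 1]) |
             (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
             (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] & cand[, 3] > best[, 3])
    best[newer, ] <- cand[newer, , drop = FALSE]
  }
  storage.mode(best) <- "integer"
  best
}

#' Group measurements into symmetry-equivalence classes
#'
#' Partitions unmerged measurements into groups of symmetry-equivalent
#' reflections: two measurements share a group iff an operator of the
#' setting (including Friedel inversion when enabled) maps one index onto
#' the other. The orbit representative is the lexicographically greatest
#' equivalent index, which makes the partition independent of input order.
#' Per-group multiplicity n, the unweighted mean intensity, the maximum
#' intensity and the Bessel-corrected sample standard deviation (NA for
#' n = 1) are derived. If a `cell` is supplied, per-measurement d* values
#' are computed (overriding any existing `d_star` column).
#'
#' @param measurements Data frame with columns `h`, `k`, `l`, `intensity`,
#'   `sigma` (e.g. from [read_hkl()] or [simulate_reflections()]).
#' @param sym A [symmetry_setting()].
#' @param cell Optional [unit_cell()] used to compute d*.
#'
#' @return An object of class `"esu_groups"`: a list with
#'   \describe{
#'     \item{measurements}{the input rows plus `group` (integer id) and,
#'       when available, `d_star`;}
#'     \item{groups}{one row per unique reflection: canonical `h`, `k`, `l`,
#'       `n`, `mean_intensity`, `max_intensity`, `sample_std`, `d_star`
#'       (mean of member d*);}
#'     \item{sym}{the symmetry setting used.}
#'   }
#' @export
group_equivalents <- function(measurements, sym, cell = NULL) {
  if (!is.data.frame(measurements) || nrow(measurements) == 0L)
    stop("'measurements' must be a non-empty data frame")
  if (!inherits(sym, "symmetry_setting")) stop("'sym' must be a symmetry_setting")
  m <- as.data.frame(measurements)
  hkl <- cbind(m$h, m$k, m$l)
  if (any(rowSums(abs(hkl)) == 0))
    stop("hkl = (0,0,0) is not a real reflection")
  if (!is.null(cell)) m$d_star <- d_star(cell, hkl)

  can <- .canonicalize(hkl, sym$operators)
  keys <- paste(can[, 1], can[, 2], can[, 3], sep = ",")
  # deterministic group order: sort canonical indices lexicographically
  ord_keys <- unique(keys[order(can[, 1], can[, 2], can[, 3])])
  gid <- match(keys, ord_keys)
  m$group <- gid

  ng <- length(ord_keys)
  n_g <- tabulate(gid, ng)
  mean_g <- as.numeric(tapply(m$intensity, gid, mean))
  max_g <- as.numeric(tapply(m$intensity, gid, max))
  sd_g <- as.numeric(tapply(m$intensity, gid, function(x) if (length(x) >= 2) stats::sd(x) else NA_real_))
  ds_g <- if (!is.null(m$d_star)) as.numeric(tapply(m$d_star, gid, mean)) else rep(NA_real_, ng)
  first <- match(seq_len(ng), gid)
  groups <- data.frame(h = can[first, 1], k = can[first, 2], l = can[first, 3],
                       n = n_g, mean_intensity = mean_g, max_intensity = max_g,
                       sample_std = sd_g, d_star = ds_g)

  structure(list(measurements = m, groups = groups, sym = sym),
            class = "esu_groups")
}

#' @export
print.esu_groups <- function(x, ...) {
  cat(sprintf("Reflection groups: %d measurements in %d unique reflections\n",
              nrow(x$measurements), nrow(x$groups)))
  tab <- table(x$groups$n)
  cat("multiplicity:", paste(sprintf("n=%s:%d", names(tab), as.integer(tab)), collapse = "  "), "\n")
  invisible(x)
}
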