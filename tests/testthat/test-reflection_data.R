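test_that("fixed-width and free hkl records parse, sigma <= 0 is rejected", {
  f <- write_tmp_lines(c("   1   2   3  100.00    5.00",
                         "  -1  -5  -9  250.50   12.10",
                         "   1   2   3   10.00    0.00"))
  expect_message(m <- read_hkl(f, "shelx_fixed"), "rejected")
  expect_equal(nrow(m), 2L)
  expect_equal(unlist(m[1, c("h", "k", "l")], use.names = FALSE), c(1L, 2L, 3L))
  expect_equal(m$intensity, c(100, 250.5))
  expect_equal(attr(m, "n_rejected"), 1L)

  f2 <- write_tmp_lines("-1 -5 -9 250.5 12.1 7 extra_col")
  m2 <- read_hkl(f2, "free")
  expect_equal(unlist(m2[1, c("h", "k", "l")], use.names = FALSE), c(-1L, -5L, -9L))
  expect_equal(m2$sigma, 12.1)
  expect_equal(m2$frame, 7L)
})

test_that("malformed, empty and terminator-only files error clearly", {
  bad <- write_tmp_lines(c("1 2 3 5.0 1.0", "1 2 notanumber 5 1"))
  expect_error(read_hkl(bad, "free"), "line 2")
  empty <- write_tmp_lines(character(0))
  expect_error(read_hkl(empty, "free"), "empty")
  term <- write_tmp_lines("   0   0   0    0.00    0.00")
  expect_error(read_hkl(term, "shelx_fixed"), "no reflection")
})

test_that("write then read round-trips indices exactly and values to print precision", {
  x <- data.frame(h = c(1L, -3L), k = c(2L, 0L), l = c(3L, 5L),
                  intensity = c(123.456, -7.891), sigma = c(4.567, 2.345),
                  frame = c(NA_integer_, NA_integer_))
  for (d in c("shelx_fixed", "free")) {
    p <- tempfile(fileext = ".hkl")
    write_hkl(x, p, d)
    y <- read_hkl(p, d)
    expect_equal(y[c("h", "k", "l")], x[c("h", "k", "l")])
    expect_true(all(abs(y$intensity - x$intensity) <= 0.01))
    expect_true(all(abs(y$sigma - x$sigma) <= 0.01))
  }
  expect_error(write_hkl(x[0, ], tempfile()), "empty")

  merged <- data.frame(h = 1L, k = 2L, l = 3L, intensity = 10, sigma = 1, n = 4L)
  p <- tempfile(fileext = ".hkl")
  write_hkl(merged, p, "free")
  toks <- strsplit(trimws(readLines(p)), "[[:space:]]+")[[1]]
  expect_equal(as.integer(toks[6]), 4L)  # multiplicity kept as trailing column
})

test_that("d_star matches closed forms and rejects degenerate cells", {
  expect_equal(d_star(unit_cell(10, 10, 10), c(1, 0, 0)), 0.1)
  expect_equal(d_star(unit_cell(7, 9, 11), c(0, 0, 0)), 0)
  # orthorhombic zeolite cell: (0,0,2) -> 2/c
  nat <- unit_cell(18.2872, 18.6661, 6.6222)
  expect_equal(d_star(nat, c(0, 0, 2)), 2 / 6.6222, tolerance = 1e-12)
  expect_equal(d_star(nat, c(0, 0, 2)), 0.30202, tolerance = 1e-4)

  set.seed(4)
  for (i in 1:20) {
    abc <- runif(3, 3, 40)
    cell <- unit_cell(abc[1], abc[2], abc[3])
    hkl <- sample(-9:9, 3, replace = TRUE)
    expect_equal(d_star(cell, hkl),
                 sqrt(sum((hkl / abc)^2)), tolerance = 1e-12)
  }
  expect_error(unit_cell(1, 1, 1, alpha = 0), "angles")
  expect_error(unit_cell(-1, 1, 1), "positive")
  # alpha + beta + gamma geometry that cannot close a cell
  expect_error(unit_cell(1, 1, 1, alpha = 179, beta = 179, gamma = 179))
})

test_that("Laue operator tables have the right group orders and close", {
  orders <- c("-1" = 1, "2/m" = 2, "mmm" = 4, "4/m" = 4, "4/mmm" = 8,
              "-3" = 3, "-3m" = 6, "6/m" = 6, "6/mmm" = 12,
              "m-3" = 12, "m-3m" = 24)
  for (cl in names(orders)) {
    ops <- laue_operators(cl)
    expect_length(ops, orders[[cl]])
    # closure under composition
    key <- function(m) paste(as.integer(m), collapse = ",")
    keys <- vapply(ops, key, "")
    for (a in ops[seq_len(min(4, length(ops)))])
      for (b in ops)
        expect_true(key(a %*% b) %in% keys)
  }
})

test_that("symmetry equivalence grouping follows the operator set and Friedel flag", {
  mk <- function(hkls) data.frame(h = hkls[, 1], k = hkls[, 2], l = hkls[, 3],
                                  intensity = seq_len(nrow(hkls)), sigma = 1)
  # mmm with Friedel: mirror-related indices merge
  g <- group_equivalents(mk(rbind(c(1, 2, 3), c(-1, 2, 3))), symmetry_setting("mmm"))
  expect_equal(nrow(g$groups), 1L)
  # Laue -1: Friedel mates split or merge with the flag
  pair <- mk(rbind(c(1, 2, 3), c(-1, -2, -3)))
  g_off <- group_equivalents(pair, symmetry_setting("-1", add_friedel = FALSE))
  g_on <- group_equivalents(pair, symmetry_setting("-1", add_friedel = TRUE))
  expect_equal(nrow(g_off$groups), 2L)
  expect_equal(nrow(g_on$groups), 1L)
  # full orbit: all eight sign combinations of (1,2,3) under mmm + Friedel
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  orbit <- t(t(signs) * c(1, 2, 3))
  g8 <- group_equivalents(mk(orbit), symmetry_setting("mmm"))
  expect_equal(nrow(g8$groups), 1L)
  expect_equal(g8$groups$n, 8L)
  # canonical representative is the lexicographically greatest member
  expect_equal(unlist(g8$groups[1, c("h", "k", "l")], use.names = FALSE), c(1L, 2L, 3L))
})

test_that("grouping conserves counts, ignores input order, and is idempotent", {
  set.seed(11)
  hkl <- cbind(sample(1:4, 60, TRUE), sample(0:3, 60, TRUE), sample(1:3, 60, TRUE))
  m <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                  intensity = rnorm(60, 100, 10), sigma = runif(60, 1, 2))
  sym <- symmetry_setting("mmm")
  g <- group_equivalents(m, sym)
  expect_equal(sum(g$groups$n), nrow(m))
  expect_true(all(g$groups$mean_intensity <= g$groups$max_intensity + 1e-12))
  expect_true(all(g$groups$sample_std[g$groups$n >= 2] >= 0))

  perm <- sample(nrow(m))
  g2 <- group_equivalents(m[perm, ], sym)
  key <- function(gr) sort(paste(gr$h, gr$k, gr$l, gr$n))
  expect_equal(key(g2$groups), key(g$groups))

  g3 <- group_equivalents(g$measurements[names(m)], sym)
  expect_equal(key(g3$groups), key(g$groups))

  expect_error(symmetry_setting(operators = list()), "empty")
  expect_error(group_equivalents(data.frame(h = 0L, k = 0L, l = 0L,
                                            intensity = 1, sigma = 1), sym),
               "0,0,0|not a real", ignore.case = TRUE)
})
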