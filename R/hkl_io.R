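#' Read an unmerged reflection file
#'
#' Reads reflection records (h, k, l, intensity, sigma, optional frame id)
#' from a SHELX-style fixed-width file (`3I4, 2F8.2`, optional trailing `I4`
#' batch/frame column) or a free whitespace-delimited file with columns
#' h k l I sigma \[frame\]; extra trailing columns are ignored in the free
#' dialect. A trailing all-zero `0 0 0` record (the conventional HKLF
#' terminator) ends the file. Records with sigma <= 0 are dropped and the
#' number dropped reported via a message and the `"n_rejected"` attribute;
#' counting-statistics uncertainties must be strictly positive. Negative
#' intensities are legal: background subtraction can undershoot.
#'
#' @param path Path to the reflection file.
#' @param dialect `"shelx_fixed"` or `"free"`.
#'
#' @return A data frame with columns `h`, `k`, `l`, `intensity`, `sigma`,
#'   `frame` (NA when absent), in file order, with attribute `n_rejected`.
#' @seealso [write_hkl()]
#' @export
read_hkl <- function(path, dialect = c("shelx_fixed", "free")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty reflection file: ", path)

  parse_fail <- function(i) stop("malformed record at line ", i, " of ", path)
  n <- length(lines)
  h <- k <- l <- integer(n); I <- s <- numeric(n); fr <- rep(NA_integer_, n)

  if (dialect == "shelx_fixed") {
    for (i in seq_len(n)) {
      ln <- lines[[i]]
      if (nchar(ln) < 28L) parse_fail(i)
      v <- suppressWarnings(c(as.numeric(substr(ln, 1, 4)),
                              as.numeric(substr(ln, 5, 8)),
                              as.numeric(substr(ln, 9, 12)),
                              as.numeric(substr(ln, 13, 20)),
                              as.numeric(substr(ln, 21, 28))))
      if (anyNA(v)) parse_fail(i)
      h[i] <- as.integer(v[1]); k[i] <- as.integer(v[2]); l[i] <- as.integer(v[3])
      I[i] <- v[4]; s[i] <- v[5]
      if (nchar(ln) >= 29L) {
        f <- suppressWarnings(as.integer(substr(ln, 29, 32)))
        if (!is.na(f)) fr[i] <- f
      }
    }
  } else {
    for (i in seq_len(n)) {
      tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
      if (length(tok) < 5L) parse_fail(i)
      v <- suppressWarnings(as.numeric(tok[1:5]))
      if (anyNA(v)) parse_fail(i)
      h[i] <- as.integer(v[1]); k[i] <- as.integer(v[2]); l[i] <- as.integer(v[3])
      I[i] <- v[4]; s[i] <- v[5]
      if (length(tok) >= 6L) {
        f <- suppressWarnings(as.integer(tok[6]))
        if (!is.na(f)) fr[i] <- f
      }
    }
  }

  # conventional terminator record
  term <- h == 0L & k == 0L & l == 0L & I == 0 & s == 0
  if (any(term)) {
    first <- which(term)[1]
    keep0 <- seq_len(first - 1L)
  } else keep0 <- seq_len(n)
  h <- h[keep0]; k <- k[keep0]; l <- l[keep0]; I <- I[keep0]; s <- s[keep0]; fr <- fr[keep0]
  if (length(h) == 0L) stop("no reflection records in ", path)

  bad <- s <= 0
  if (any(bad))
    message(sum(bad), " record(s) with sigma <= 0 rejected from ", basename(path))
  out <- data.frame(h = h[!bad], k = k[!bad], l = l[!bad],
                    intensity = I[!bad], sigma = s[!bad], frame = fr[!bad])
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a reflection file
#'
#' Writes measurements or merged reflections in the fixed `3I4, 2F8.2`
#' SHELX-style layout or as free whitespace-separated columns. Merged
#' records (those carrying an `n` multiplicity column) get `n` appended as
#' an extra integer column in either dialect. Round-tripping through
#' [read_hkl()] reproduces indices exactly and intensities/sigmas to the
#' printed precision (0.01 for the fixed dialect).
#'
#' @param x Data frame with columns `h`, `k`, `l`, `intensity`, `sigma` and
#'   optionally `frame` or `n`.
#' @param path Output path.
#' @param dialect `"shelx_fixed"` or `"free"`.
#'
#' @return Invisibly, `path`.
#' @export
write_hkl <- function(x, path, dialect = c("shelx_fixed", "free")) {
  dialect <- match.arg(dialect)
  if (!is.data.frame(x) || nrow(x) == 0L) stop("nothing to write: empty record set")
  need <- c("h", "k", "l", "intensity", "sigma")
  if (!all(need %in% names(x))) stop("records must have columns h, k, l, intensity, sigma")
  extra <- if ("n" %in% names(x)) as.integer(x$n)
           else if ("frame" %in% names(x) && any(!is.na(x$frame))) as.integer(x$frame)
           else NULL
  if (dialect == "shelx_fixed") {
    body <- sprintf("%4d%4d%4d%8.2f%8.2f", x$h, x$k, x$l, x$intensity, x$sigma)
    if (!is.null(extra)) body <- paste0(body, sprintf("%4d", ifelse(is.na(extra), 0L, extra)))
  } else {
    body <- sprintf("%d %d %d %.6g %.6g", x$h, x$k, x$l, x$intensity, x$sigma)
    if (!is.null(extra)) body <- paste(body, ifelse(is.na(extra), 0L, extra))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(body, con)
  invisible(path)
}
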