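# shared fixtures: everything is generated in code at test time

# expensive fits computed once and reused across related expectations
.acceptance_cache <- new.env(parent = emptyenv())

# P1-like setting: identity only, no Friedel pairing — groups are defined by
# identical index triples, which is what the synthetic generator emits
identity_sym <- function() {
  symmetry_setting(operators = list(diag(3)), add_friedel = FALSE)
}

# groups object from explicit member intensity vectors (one hkl per group)
make_groups <- function(member_intensities, sigmas = NULL, d_star = NULL) {
  ng <- length(member_intensities)
  rows <- do.call(rbind, lapply(seq_len(ng), function(i) {
    I <- member_intensities[[i]]
    data.frame(h = i, k = 0L, l = 1L, intensity = I,
               sigma = if (is.null(sigmas)) rep(1, length(I)) else sigmas[[i]],
               frame = NA_integer_,
               d_star = if (is.null(d_star)) 0.5 else d_star[[i]])
  }))
  group_equivalents(rows, identity_sym())
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".hkl")
  writeLines(lines, f)
  f
}
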