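# Shared fixtures, built once per test session.

# Compact helix + ligand complex used by most unit tests; the full-size
# default fixture is reserved for the acceptance-level checks.
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_fixture(fixture_config(sequence = "AEKLLSAMVETIKGA",
                                            n_starts = 2L, seed = 11L))
    cache
  }
})

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture(fixture_config(seed = 42L))
    cache
  }
})

# tiny structure with named protons at chosen coordinates
proton_structure <- function(xyz, names = paste0("H", seq_len(nrow(xyz))),
                             chain = "A", resno = 1L) {
  nmr_structure(data.frame(chain = chain, resno = resno, resname = "GLY",
                           atname = names, x = xyz[, 1L], y = xyz[, 2L],
                           z = xyz[, 3L], stringsAsFactors = FALSE))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  set_coords(s, sweep(coords(s) %*% t(R), 2L, t, "+"))
}
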