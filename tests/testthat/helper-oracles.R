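# Brute-force periodic-geometry oracles used to cross-check the
# minimum-image arithmetic, plus small fixture builders.

# distance between p and q considering all 27 periodic images explicitly
image_dist_oracle <- function(p, q, box) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  best <- Inf
  for (i in seq_len(nrow(shifts))) {
    d <- sqrt(sum((p - (q + shifts[i, ] * box))^2))
    if (d < best) best <- d
  }
  best
}

# exhaustive neighbor scan: indices of oxygens within r of `p` (strict)
neighbors_oracle <- function(p, opos, box, r) {
  which(vapply(seq_len(nrow(opos)), function(i)
    image_dist_oracle(p, opos[i, ], box), numeric(1)) < r)
}

# one ideal water at `center`, O-H 0.9572 A, H-O-H 104.52 deg, in-plane
ideal_water <- function(center = c(0, 0, 0)) {
  oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(center,
        center + c(oh * sin(half), oh * cos(half), 0),
        center + c(-oh * sin(half), oh * cos(half), 0))
}

# frame with waters at the given O positions (ideal geometry, no rotation)
frame_from_o_positions <- function(opos, box, time_ps = 0) {
  xyz <- do.call(rbind, lapply(seq_len(nrow(opos)), function(i)
    ideal_water(opos[i, ])))
  hdo_frame(rep(c("O", "H", "H"), nrow(opos)), xyz, box, time_ps)
}

# synthetic RDF with analytically placed extrema: peaks at 2.8, 4.5, 6.8 A
# and minima at 3.4, 5.6, 7.8 A on a 1.0 baseline
shelly_rdf <- function(dr = 0.05, r_max = 10) {
  r <- seq(dr / 2, r_max - dr / 2, by = dr)
  g <- 1 +
    2.0 * exp(-(r - 2.8)^2 / 0.05) - 0.60 * exp(-(r - 3.4)^2 / 0.05) +
    0.5 * exp(-(r - 4.5)^2 / 0.10) - 0.25 * exp(-(r - 5.6)^2 / 0.10) +
    0.2 * exp(-(r - 6.8)^2 / 0.20) - 0.10 * exp(-(r - 7.8)^2 / 0.20)
  out <- data.frame(r = r, g = pmax(g, 0))
  attr(out, "dr") <- dr
  class(out) <- c("hdo_rdf", "data.frame")
  out
}

# a cluster object with prescribed first-shell radii, for the mock map
synthetic_cluster <- function(r_first, r1 = 3.4, deuterium = "h1",
                              time_ps = 0) {
  structure(list(probe_xyz = ideal_water(), probe_elements = c("O", "H", "H"),
                 deuterium = deuterium,
                 env_xyz = lapply(r_first, function(r) ideal_water(c(r, 0, 0))),
                 r_oo = r_first, n_first_shell = sum(r_first < r1),
                 r1 = r1, time_ps = time_ps),
            class = "hdo_cluster")
}
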