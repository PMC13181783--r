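test_that("a single intact water is perceived", {
  fr <- hdo_frame(c("O", "H", "H"), ideal_water(), 20)
  w <- perceive_waters(fr)
  expect_equal(nrow(w), 1)
  expect_equal(w$o, 1)
  expect_setequal(c(w$h1, w$h2), 2:3)
})

test_that("perception matches brute-force nearest-oxygen assignment on a random box", {
  fr <- generate_water_box(100, 14.5, seed = 7)
  w <- perceive_waters(fr)
  o_idx <- which(fr$elements == "O")
  for (h in which(fr$elements == "H")) {
    d <- vapply(o_idx, function(o)
      image_dist_oracle(fr$xyz[h, ], fr$xyz[o, ], fr$box), numeric(1))
    o_star <- o_idx[which.min(d)]
    row <- which(w$h1 == h | w$h2 == h)
    expect_equal(w$o[row], o_star)
  }
})

test_that("degenerate frames are rejected with the offending atom named", {
  lone_o <- hdo_frame(c("O", "H", "H", "O"),
                      rbind(ideal_water(), c(5, 5, 5)), 20)
  expect_error(perceive_waters(lone_o), "index 4")
  stray_h <- hdo_frame(c("O", "H", "H", "H"),
                       rbind(ideal_water(), c(5, 5, 5)), 20)
  expect_error(perceive_waters(stray_h), "index 4")
  ion <- hdo_frame(c("O", "H", "H", "Na"),
                   rbind(ideal_water(), c(5, 5, 5)), 20)
  expect_error(perceive_waters(ion), "non-water")
  expect_error(perceive_waters(hdo_frame(c("O", "H", "H"), ideal_water(), 20),
                               oh_cutoff = 2), "0.5, 1.5")
})

test_that("water splits across the periodic boundary are still perceived", {
  # O at the corner, hydrogens wrapped to the far side of the box
  box <- c(10, 10, 10)
  xyz <- ideal_water(c(0.1, 0.1, 0.1))
  xyz[2, ] <- xyz[2, ] %% box
  xyz[3, ] <- xyz[3, ] + box  # image shifted a full box
  fr <- hdo_frame(c("O", "H", "H"), xyz, box)
  expect_equal(nrow(perceive_waters(fr)), 1)
})

test_that("RDF of a single pair puts all weight in the separation bin", {
  fr <- frame_from_o_positions(rbind(c(1, 1, 1), c(1, 1, 4.13)), c(30, 30, 30))
  w <- perceive_waters(fr)
  rdf <- compute_rdf(fr, w, r_max = 10, dr = 0.05)
  occupied <- rdf$r[rdf$g > 0]
  expect_length(occupied, 1)
  expect_lt(abs(occupied - 3.13), 0.05)
})

test_that("RDF of a homogeneous random box converges to one", {
  # oxygen positions uniform at bulk-like density; Poisson reference g = 1
  set.seed(42)
  box <- 22
  n <- 160
  frames <- lapply(1:12, function(i) {
    opos <- matrix(runif(3 * n, 0, box), ncol = 3)
    frame_from_o_positions(opos, c(box, box, box))
  })
  # waters table built directly: overlapping Poisson points are fine for the
  # O-O histogram but would not parse as intact molecules
  w <- data.frame(o = seq(1, 3 * n, by = 3))
  w$h1 <- w$o + 1L
  w$h2 <- w$o + 2L
  # bins wide enough that the per-bin Poisson noise sits under the 5% band
  rdf <- compute_rdf(frames, w, r_max = 10, dr = 0.5)
  far <- rdf$r > 2
  expect_true(all(abs(rdf$g[far] - 1) < 0.05))
})

test_that("RDF first peak of a simple-cubic lattice sits at the spacing", {
  a <- 3.1
  grid <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) * a
  fr <- frame_from_o_positions(grid, rep(4 * a, 3))
  w <- perceive_waters(fr)
  rdf <- compute_rdf(fr, w, r_max = 4 * a / 2 - 0.1, dr = 0.05)
  first_peak <- rdf$r[which(rdf$g > 0)[1]]
  expect_lt(abs(first_peak - a), 0.05)
})

test_that("r_max beyond half the box is rejected", {
  fr <- frame_from_o_positions(rbind(c(1, 1, 1), c(4, 4, 4)), c(12, 12, 12))
  w <- perceive_waters(fr)
  expect_error(compute_rdf(fr, w, r_max = 6), "half the smallest box")
})

test_that("shell cutoffs are located at the constructed minima", {
  rdf <- shelly_rdf()
  cuts <- locate_shell_cutoffs(rdf)
  expect_lt(abs(cuts$r1 - 3.4), 2 * attr(rdf, "dr"))
  expect_lt(abs(cuts$r3 - 7.8), 2 * attr(rdf, "dr"))
  expect_lt(cuts$r1, cuts$r3)
})

test_that("featureless g(r) raises a no-shell-structure error", {
  r <- seq(0.025, 10, by = 0.05)
  mono <- data.frame(r = r, g = r / 10)
  class(mono) <- c("hdo_rdf", "data.frame")
  expect_error(locate_shell_cutoffs(mono), "no shell structure")
})

test_that("cluster of an isolated probe is the probe alone", {
  fr <- frame_from_o_positions(matrix(c(5, 5, 5), 1), c(40, 40, 40))
  w <- perceive_waters(fr)
  cl <- carve_cluster(fr, w, probe_spec(1), list(r1 = 3.4, r3 = 7.8),
                      mode = "radius")
  expect_length(cl$env_xyz, 0)
  expect_equal(cl$n_first_shell, 0)
})

test_that("radius-mode membership equals the exhaustive periodic-image oracle", {
  cuts <- list(r1 = 3.4, r3 = 5.6)
  for (seed in 1:5) {
    fr <- generate_water_box(60, 12.3, seed = seed)
    w <- perceive_waters(fr)
    cl <- carve_cluster(fr, w, probe_spec(1), cuts, mode = "radius")
    opos <- fr$xyz[w$o, , drop = FALSE]
    expected <- setdiff(neighbors_oracle(opos[1, ], opos, fr$box, cuts$r3), 1)
    expect_setequal(cl$env_rows, expected)
    expect_equal(cl$n_first_shell,
                 length(setdiff(neighbors_oracle(opos[1, ], opos, fr$box,
                                                 cuts$r1), 1)))
  }
})

test_that("a neighbor across the boundary is unwrapped next to the probe", {
  box <- c(10, 10, 10)
  opos <- rbind(c(0.5, 0.5, 0.5), c(9.8, 0.5, 0.5))  # 2.7 A across the face
  fr <- frame_from_o_positions(opos, box)
  w <- perceive_waters(fr)
  cl <- carve_cluster(fr, w, probe_spec(1), list(r1 = 3.4, r3 = 6),
                      mode = "radius")
  expect_length(cl$env_xyz, 1)
  env_o <- cl$env_xyz[[1]][1, ]
  expect_equal(env_o, c(-0.2, 0.5, 0.5), tolerance = 1e-9)
  expect_lt(sqrt(sum((env_o - cl$probe_xyz[1, ])^2)), 3)
})

test_that("cluster size is non-decreasing in the cutoff radius", {
  fr <- generate_water_box(80, 13.4, seed = 13)
  w <- perceive_waters(fr)
  sizes <- vapply(seq(3, 6.5, by = 0.5), function(r3)
    length(carve_cluster(fr, w, probe_spec(1), list(r1 = 3.4, r3 = r3),
                         mode = "radius")$env_xyz), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("nearest-n mode returns exactly n waters and rejects impossible n", {
  fr <- generate_water_box(40, 11, seed = 5)
  w <- perceive_waters(fr)
  cl <- carve_cluster(fr, w, probe_spec(1), list(r1 = 3.4, r3 = 6), n = 29)
  expect_length(cl$env_xyz, 29)
  expect_error(carve_cluster(fr, w, probe_spec(1), list(r1 = 3.4, r3 = 6),
                             n = 40), "available")
})

test_that("first-shell counting is strict at the cutoff and matches the oracle", {
  # four neighbors at 2.8 A and one exactly at the cutoff
  opos <- rbind(c(10, 10, 10),
                c(12.8, 10, 10), c(7.2, 10, 10), c(10, 12.8, 10),
                c(10, 7.2, 10), c(10, 10, 13.4))
  fr <- frame_from_o_positions(opos, c(40, 40, 40))
  w <- perceive_waters(fr)
  expect_equal(count_first_shell(fr, w, probe_spec(1), r1 = 3.4), 4)
  for (seed in 1:10) {
    frr <- generate_water_box(50, 12, seed = 100 + seed)
    ww <- perceive_waters(frr)
    opos <- frr$xyz[ww$o, , drop = FALSE]
    expect_equal(count_first_shell(frr, ww, probe_spec(1), 3.4),
                 length(setdiff(neighbors_oracle(opos[1, ], opos, frr$box,
                                                 3.4), 1)))
  }
})

test_that("first-shell count agrees with the cluster's own coordination", {
  for (seed in 1:5) {
    fr <- generate_water_box(60, 12.3, seed = 200 + seed)
    w <- perceive_waters(fr)
    cl <- carve_cluster(fr, w, probe_spec(1), list(r1 = 3.4, r3 = 5.6),
                        mode = "radius")
    expect_equal(cl$n_first_shell,
                 count_first_shell(fr, w, probe_spec(1), 3.4))
  }
})

test_that("snapshot schedules have the exact bookkeeping", {
  sched <- snapshot_schedule(12, 50, 50)
  expect_equal(nrow(sched), 12000)
  expect_equal(nrow(snapshot_schedule(1, 1, 50)), 20)
  expect_equal(nrow(snapshot_schedule(1, 0.48, 48)), 10)
  expect_warning(s <- snapshot_schedule(1, 1, 300), "truncated")
  expect_equal(nrow(s), 3)
  expect_error(snapshot_schedule(0, 50, 50), "positive")
  # per-replica times are stride, 2 stride, ... usable_length
  one <- snapshot_schedule(2, 1, 100)
  expect_equal(one$time_ps[one$replica == 1], seq(0.1, 1, by = 0.1))
})
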