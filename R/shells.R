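#' Perceive water molecules in a frame
#'
#' Assigns every hydrogen to its nearest oxygen under the minimum-image
#' convention, requiring the O-H distance to fall below `oh_cutoff`. The
#' frame must contain only O and H atoms; each oxygen must end up with
#' exactly two hydrogens.
#'
#' @param frame an [hdo_frame].
#' @param oh_cutoff O-H bonding cutoff in Angstrom; must lie in (0.5, 1.5).
#'   Default 1.25 Å, generous enough for flexible water models.
#' @return data.frame with columns `o`, `h1`, `h2`: 1-based atom indices of
#'   each water's oxygen and two hydrogens.
#' @export
perceive_waters <- function(frame, oh_cutoff = 1.25) {
  stopifnot(inherits(frame, "hdo_frame"))
  if (oh_cutoff <= 0.5 || oh_cutoff >= 1.5)
    stop("`oh_cutoff` must lie in (0.5, 1.5) Angstrom")
  el <- frame$elements
  bad <- which(!el %in% c("O", "H"))
  if (length(bad))
    stop("frame contains non-water species at atom index ", bad[1],
         " (element ", el[bad[1]], ")")
  o_idx <- which(el == "O")
  h_idx <- which(el == "H")
  if (!length(o_idx))
    stop("frame contains no oxygen atoms")
  assigned <- integer(length(h_idx))
  for (j in seq_along(h_idx)) {
    d <- min_image_dist(frame$xyz[h_idx[j], ], frame$xyz[o_idx, , drop = FALSE],
                        frame$box)
    k <- which.min(d)
    if (d[k] >= oh_cutoff)
      stop("hydrogen at atom index ", h_idx[j],
           " has no oxygen within the bonding cutoff (nearest at ",
           sprintf("%.3f", d[k]), " A)")
    assigned[j] <- o_idx[k]
  }
  waters <- data.frame(o = o_idx, h1 = NA_integer_, h2 = NA_integer_)
  for (i in seq_along(o_idx)) {
    hs <- h_idx[assigned == o_idx[i]]
    if (length(hs) != 2L)
      stop("oxygen at atom index ", o_idx[i], " has ", length(hs),
           " assigned hydrogens (expected 2)")
    waters$h1[i] <- hs[1]
    waters$h2[i] <- hs[2]
  }
  waters
}

#' Specify the HDO probe
#'
#' Marks one perceived water as the probe and one of its two hydrogens as
#' the deuterium site.
#'
#' @param water_index row index of the probe in the water table returned by
#'   [perceive_waters()].
#' @param deuterium which hydrogen carries the deuterium mass: `"h1"` or
#'   `"h2"`.
#' @return An object of class `hdo_probe`.
#' @export
probe_spec <- function(water_index, deuterium = c("h1", "h2")) {
  deuterium <- match.arg(deuterium)
  if (!is.numeric(water_index) || water_index < 1)
    stop("`water_index` must be a positive water row index")
  structure(list(water = as.integer(water_index), deuterium = deuterium),
            class = "hdo_probe")
}

#' Oxygen-oxygen radial distribution function
#'
#' Accumulates the O-O pair histogram over frames under the minimum-image
#' convention and normalizes by the ideal-gas shell count at the frames'
#' mean oxygen density, so that g(r) tends to 1 at large r for homogeneous
#' input.
#'
#' @param frames list of [hdo_frame] objects.
#' @param waters water table from [perceive_waters()] (same topology for all
#'   frames).
#' @param r_max histogram range (Å); must be below half the smallest box
#'   length so minimum-image distances are valid.
#' @param dr bin width (Å). Default 0.05.
#' @return data.frame of class `hdo_rdf` with columns `r` (bin centers) and
#'   `g`; attributes `dr` and `pair` record the binning and pair type.
#' @export
compute_rdf <- function(frames, waters, r_max, dr = 0.05) {
  if (inherits(frames, "hdo_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L, dr > 0)
  min_box <- min(vapply(frames, function(f) min(f$box), numeric(1)))
  if (r_max >= min_box / 2)
    stop("`r_max` must be below half the smallest box length (",
         sprintf("%.2f", min_box / 2), " A) for the minimum image to be valid")
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + dr)
  counts <- numeric(length(edges) - 1L)
  dens <- numeric(length(frames))
  n_o <- nrow(waters)
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    opos <- fr$xyz[waters$o, , drop = FALSE]
    d <- min_image_pdist(opos, fr$box)
    d <- d[d < r_max]
    counts <- counts + tabulate(findInterval(d, edges), nbins = length(counts))
    dens[fi] <- n_o / prod(fr$box)
  }
  rho <- mean(dens)
  shell_vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  # ideal count per bin for all N(N-1)/2 pairs, averaged over frames
  ideal <- length(frames) * n_o * (n_o - 1) / 2 * shell_vol * rho / n_o
  g <- ifelse(ideal > 0, counts / ideal, 0)
  out <- data.frame(r = (edges[-1L] + edges[-length(edges)]) / 2, g = g)
  attr(out, "dr") <- dr
  attr(out, "pair") <- "O-O"
  class(out) <- c("hdo_rdf", "data.frame")
  out
}

#' Locate solvation-shell cutoffs from an RDF
#'
#' Smooths g(r) with a centered moving average, then takes the first local
#' minimum after the first smoothed maximum as the first-shell cutoff and
#' the third such minimum as the cluster radius (the outer edge of the
#' third solvation shell).
#'
#' @param rdf RDF table from [compute_rdf()] (columns `r`, `g`).
#' @param smoothing_window moving-average window in bins (odd; default 5).
#' @return list of class `hdo_cutoffs` with elements `r1` and `r3`
#'   (Angstrom, bin centers).
#' @export
locate_shell_cutoffs <- function(rdf, smoothing_window = 5) {
  g <- rdf$g
  r <- rdf$r
  w <- as.integer(smoothing_window)
  if (w < 1L) stop("`smoothing_window` must be >= 1 bin")
  if (w %% 2L == 0L) w <- w + 1L
  gs <- stats::filter(g, rep(1 / w, w), sides = 2)
  gs <- as.numeric(gs)
  # edges keep raw values so extrema near the boundary are not lost
  gs[is.na(gs)] <- g[is.na(gs)]
  n <- length(gs)
  interior <- 2:(n - 1L)
  is_max <- interior[gs[interior] > gs[interior - 1L] & gs[interior] >= gs[interior + 1L]]
  is_min <- interior[gs[interior] < gs[interior - 1L] & gs[interior] <= gs[interior + 1L]]
  if (length(is_max) < 3L || !length(is_min))
    stop("no shell structure: fewer than three local maxima in the smoothed g(r)")
  minima_after <- function(max_pos) {
    cand <- is_min[is_min > max_pos]
    if (!length(cand)) NA_integer_ else cand[1L]
  }
  m1 <- minima_after(is_max[1L])
  m3 <- minima_after(is_max[3L])
  if (is.na(m1) || is.na(m3))
    stop("no shell structure: missing minimum after a shell peak")
  structure(list(r1 = r[m1], r3 = r[m3]), class = "hdo_cutoffs")
}

# Re-centers a whole molecule next to the probe oxygen: first makes the
# molecule whole (H wrapped around its own O), then shifts the molecule by
# the lattice vector that brings its O into the minimum image of the probe.
unwrap_molecule <- function(frame, water_row, ref_o_pos) {
  box <- frame$box
  o <- frame$xyz[water_row$o, ]
  h1 <- o + min_image_disp(frame$xyz[water_row$h1, , drop = FALSE],
                           matrix(o, 1), box)
  h2 <- o + min_image_disp(frame$xyz[water_row$h2, , drop = FALSE],
                           matrix(o, 1), box)
  shift <- -box * round((o - ref_o_pos) / box)
  rbind(o + shift, h1 + shift, h2 + shift)
}

#' Carve a probe-centered solvation cluster
#'
#' Extracts the probe water and its environment from a frame, unwrapping
#' coordinates around the probe oxygen so the cluster is spatially
#' contiguous (no molecule split across the periodic boundary). Two
#' selection modes: `"radius"` keeps every water whose O-O minimum-image
#' distance to the probe oxygen is strictly below the third-shell cutoff;
#' `"nearest_n"` keeps exactly the `n` nearest waters, which yields a fixed
#' cluster size for reproducible engine inputs (default `n = 30`).
#'
#' @param frame an [hdo_frame].
#' @param waters water table from [perceive_waters()].
#' @param probe an `hdo_probe` from [probe_spec()].
#' @param cutoffs an `hdo_cutoffs` from [locate_shell_cutoffs()] (or a list
#'   with `r1`, `r3`).
#' @param mode `"nearest_n"` (default) or `"radius"`.
#' @param n number of environment waters in `nearest_n` mode. Default 29,
#'   i.e. a 30-molecule cluster including the probe.
#' @return An object of class `hdo_cluster`: probe elements/coordinates
#'   (rows O, H1, H2), environment coordinates per molecule, the O-O
#'   distances `r_oo` of the environment to the probe, the first-shell
#'   coordination count `n_first_shell` (strict `< r1`), and the frame time
#'   stamp.
#' @export
carve_cluster <- function(frame, waters, probe, cutoffs,
                          mode = c("nearest_n", "radius"), n = 29) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "hdo_frame"), inherits(probe, "hdo_probe"))
  if (probe$water > nrow(waters))
    stop("probe water index ", probe$water, " not present in the frame")
  prow <- waters[probe$water, ]
  opos <- frame$xyz[waters$o, , drop = FALSE]
  p_o <- opos[probe$water, ]
  d <- min_image_dist(p_o, opos, frame$box)
  d[probe$water] <- Inf
  env_rows <- if (mode == "radius") {
    which(d < cutoffs$r3)
  } else {
    if (n > nrow(waters) - 1L)
      stop("requested ", n, " environment waters but only ",
           nrow(waters) - 1L, " are available")
    order(d)[seq_len(n)]
  }
  env_rows <- env_rows[order(d[env_rows])]
  probe_xyz <- unwrap_molecule(frame, prow, p_o)
  env <- lapply(env_rows, function(i) unwrap_molecule(frame, waters[i, ], p_o))
  structure(
    list(probe_xyz = probe_xyz,
         probe_elements = c("O", "H", "H"),
         deuterium = probe$deuterium,
         env_xyz = env,
         env_rows = env_rows,
         r_oo = d[env_rows],
         n_first_shell = sum(d[env_rows] < cutoffs$r1),
         r1 = cutoffs$r1,
         time_ps = frame$time_ps),
    class = "hdo_cluster")
}

#' @export
print.hdo_cluster <- function(x, ...) {
  cat(sprintf(paste0("<hdo_cluster> probe + %d waters, first shell n = %d, ",
                     "t = %.4f ps\n"),
              length(x$env_xyz), x$n_first_shell, x$time_ps))
  invisible(x)
}

#' Count waters in the probe's first solvation shell
#'
#' Counts environment waters whose O-O minimum-image distance to the probe
#' oxygen is strictly less than `r1`; a neighbor at exactly `r1` is
#' excluded.
#'
#' @inheritParams carve_cluster
#' @param r1 first-shell cutoff (Å), typically the first RDF minimum.
#' @return integer coordination count.
#' @export
count_first_shell <- function(frame, waters, probe, r1) {
  stopifnot(r1 > 0)
  opos <- frame$xyz[waters$o, , drop = FALSE]
  d <- min_image_dist(opos[probe$water, ], opos, frame$box)
  d[probe$water] <- Inf
  sum(d < r1)
}

#' Snapshot extraction schedule
#'
#' Builds the (replica, time) grid at which snapshots are pulled from the
#' production trajectories: per replica, times `stride, 2 stride, ...` up to
#' the usable trajectory length.
#'
#' @param replicas number of independent replicas.
#' @param usable_length_ps usable trajectory length per replica (ps).
#' @param stride_fs snapshot spacing (fs). If it does not divide the usable
#'   length the schedule is truncated with a warning.
#' @return data.frame with columns `replica` and `time_ps`; 12 replicas of
#'   50 ps at a 50 fs stride give 12,000 rows.
#' @export
snapshot_schedule <- function(replicas, usable_length_ps, stride_fs) {
  if (replicas < 1 || usable_length_ps <= 0 || stride_fs <= 0)
    stop("all schedule arguments must be positive")
  total_fs <- usable_length_ps * 1000
  n_per <- floor(total_fs / stride_fs + 1e-9)
  if (abs(n_per * stride_fs - total_fs) > 1e-6 * stride_fs)
    warning("stride does not divide the usable length; schedule truncated to ",
            n_per, " snapshots per replica")
  data.frame(
    replica = rep(seq_len(replicas), each = n_per),
    time_ps = rep(seq_len(n_per) * stride_fs / 1000, times = replicas))
}
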