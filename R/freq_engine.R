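#' Build a frequency-calculation input from a cluster
#'
#' Assembles the deck contract for the external engine: probe atoms first
#' (O, H, H), every environment atom frozen, and a single isotope mass
#' override of 2.014 amu on the probe hydrogen designated as deuterium. The
#' engine is expected to optimize only the free (probe) atoms and then
#' compute their harmonic frequencies with the environment held at the
#' sampled geometry.
#'
#' @param cluster an `hdo_cluster` from [carve_cluster()].
#' @param charge,multiplicity electronic state passed through to the engine.
#' @return An object of class `hdo_engine_input` with fields `elements`,
#'   `xyz`, `frozen` (1-based indices of all environment atoms),
#'   `mass_override` (index + mass), `charge`, `multiplicity`, `time_ps`.
#' @export
build_engine_input <- function(cluster, charge = 0, multiplicity = 1) {
  stopifnot(inherits(cluster, "hdo_cluster"))
  env_xyz <- if (length(cluster$env_xyz)) do.call(rbind, cluster$env_xyz) else
    matrix(numeric(0), ncol = 3L)
  xyz <- rbind(cluster$probe_xyz, env_xyz)
  n_env <- nrow(env_xyz)
  elements <- c("O", "H", "H", rep(c("O", "H", "H"), n_env / 3L))
  d_index <- if (cluster$deuterium == "h1") 2L else 3L
  structure(
    list(elements = elements, xyz = xyz,
         frozen = if (n_env) 3L + seq_len(n_env) else integer(0),
         mass_override = list(index = d_index, mass = 2.014),
         charge = charge, multiplicity = multiplicity,
         n_first_shell = cluster$n_first_shell,
         r1 = cluster$r1,
         time_ps = cluster$time_ps),
    class = "hdo_engine_input")
}

#' Write an engine deck (coordinates + control block)
#'
#' Emits XYZ coordinates followed by an xtb-style control block: a `$fix`
#' group listing the frozen atoms (1-based, comma-separated ranges) and an
#' isotope override for the deuterium.
#'
#' @param input an `hdo_engine_input`.
#' @param path output file path.
#' @export
write_engine_deck <- function(input, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(input$elements)), con)
  writeLines(sprintf("charge=%d mult=%d t= %.6f", input$charge,
                     input$multiplicity, input$time_ps), con)
  writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", input$elements,
                     input$xyz[, 1], input$xyz[, 2], input$xyz[, 3]), con)
  if (length(input$frozen)) {
    writeLines("$fix", con)
    writeLines(paste0("  atoms: ", paste(input$frozen, collapse = ",")), con)
    writeLines("$end", con)
  }
  writeLines("$isotope", con)
  writeLines(sprintf("  mass: %d,%.3f", input$mass_override$index,
                     input$mass_override$mass), con)
  writeLines("$end", con)
  invisible(path)
}

#' Parse a vibrational-frequency output table
#'
#' Understands two dialects: a plain two-column table of
#' `frequency_cm1 intensity` pairs (comment lines starting with `#`
#' ignored), and g98-style blocks where `Frequencies --` and `IR Inten --`
#' lines each carry up to three values.
#'
#' @param path path to the engine output file.
#' @return data.frame with columns `freq_cm1` and `intensity`.
#' @export
parse_frequency_output <- function(path) {
  lines <- readLines(path)
  fl <- grep("Frequencies\\s*--", lines, value = TRUE)
  if (length(fl)) {
    il <- grep("IR Inten\\s*--", lines, value = TRUE)
    grab <- function(x) as.numeric(unlist(strsplit(trimws(
      sub(".*--", "", x)), "\\s+")))
    freq <- unlist(lapply(fl, grab))
    inten <- unlist(lapply(il, grab))
    if (length(freq) != length(inten))
      stop("g98-style output: frequency and intensity counts differ")
    return(data.frame(freq_cm1 = freq, intensity = inten))
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (is.null(vals) || ncol(vals) < 2L)
    stop("unrecognized frequency output format: ", path)
  data.frame(freq_cm1 = vals[, 1], intensity = vals[, 2])
}

#' Default parameters of the deterministic mock frequency map
#'
#' The mock engine replaces the semiempirical calculation in tests and dry
#' runs. Its gas-phase-like base frequencies and per-neighbor redshift
#' slopes mimic water solvatochromism: each first-shell neighbor pulls the
#' stretches down (20 cm^-1 per neighbor for OD, 25 for OH) and barely
#' moves the bend (1 cm^-1), and a short-range distance term
#' `c * exp(-r / lambda)` adds a smooth geometry dependence with a 0.5 Å
#' decay length, the steepness typical of hydrogen-bond frequency maps.
#'
#' @return named list of map coefficients.
#' @export
mock_map_params <- function() {
  list(
    base   = c(bend = 1355, OD = 2600, OH = 3530),   # cm^-1
    slope  = c(bend = 1,    OD = 20,   OH = 25),     # cm^-1 per neighbor
    decay_c = c(bend = 2,   OD = 30,   OH = 35),     # cm^-1 at r = 0
    lambda = 0.5,                                    # Angstrom
    intensity0 = c(bend = 30, OD = 60, OH = 45),
    intensity_slope = c(bend = 2, OD = 8, OH = 6),
    low_modes = c(82, 214, 356)                      # pseudo-librations
  )
}

#' Deterministic mock frequency engine
#'
#' Maps a cluster to the three HDO mode frequencies without any electronic
#' structure: `w_mode = base - slope * n1 - sum_j c * exp(-r_j / lambda)`
#' over the first-shell neighbors j (O-O distance `r_j < r1`), with
#' intensities a positive affine function of the coordination count. The
#' map is fully deterministic given the cluster geometry and reproduces the
#' qualitative solvatochromic redshift of real water: more first-shell
#' neighbors means lower stretch frequencies.
#'
#' @param cluster an `hdo_cluster`.
#' @param map_params coefficient list as from [mock_map_params()].
#' @return An `hdo_engine_result`: data.frame of raw `freq_cm1`/`intensity`
#'   rows (including low-frequency pseudo-modes of the constrained probe),
#'   a `converged` flag (always `TRUE`), and the snapshot time stamp.
#' @export
mock_frequency_map <- function(cluster, map_params = mock_map_params()) {
  stopifnot(inherits(cluster, "hdo_cluster"))
  p <- map_params
  first <- cluster$r_oo[cluster$r_oo < cluster$r1]
  n1 <- length(first)
  decay <- if (n1) sum(exp(-first / p$lambda)) else 0
  freqs <- p$base - p$slope * n1 - p$decay_c * decay
  inten <- p$intensity0 + p$intensity_slope * n1
  modes <- data.frame(
    freq_cm1 = c(p$low_modes, unname(freqs[c("bend", "OD", "OH")])),
    intensity = c(rep(5, length(p$low_modes)),
                  unname(inten[c("bend", "OD", "OH")])))
  engine_result(modes, converged = TRUE, time_ps = cluster$time_ps,
                n_first_shell = n1)
}

#' Construct an engine result
#'
#' @param modes data.frame with columns `freq_cm1`, `intensity`.
#' @param converged logical convergence flag; non-converged snapshots are
#'   kept but excluded from observables downstream.
#' @param time_ps snapshot time stamp (ps).
#' @param replica replica label.
#' @param n_first_shell first-shell coordination count carried through for
#'   the coordination-resolved analysis.
#' @return An object of class `hdo_engine_result`.
#' @export
engine_result <- function(modes, converged = TRUE, time_ps = 0, replica = 1L,
                          n_first_shell = NA_integer_) {
  stopifnot(is.data.frame(modes),
            all(c("freq_cm1", "intensity") %in% names(modes)))
  if (nrow(modes) && any(modes$intensity < 0))
    stop("intensities must be non-negative")
  structure(list(modes = modes, converged = isTRUE(converged),
                 time_ps = time_ps, replica = replica,
                 n_first_shell = n_first_shell),
            class = "hdo_engine_result")
}

#' Run the frequency engine on one input
#'
#' Dispatches an engine input to an adapter function. The adapter contract:
#' it receives the `hdo_engine_input`, performs a constrained optimization
#' of the free atoms followed by harmonic frequencies of those atoms, and
#' returns an `hdo_engine_result`. The built-in [mock_adapter()] satisfies
#' the contract deterministically.
#'
#' @param input an `hdo_engine_input` (or, for the mock adapter, an
#'   `hdo_cluster`).
#' @param adapter function implementing the engine contract.
#' @return an `hdo_engine_result`.
#' @export
run_engine <- function(input, adapter = mock_adapter()) {
  if (!is.function(adapter)) stop("`adapter` must be a function")
  res <- adapter(input)
  if (!inherits(res, "hdo_engine_result"))
    stop("adapter did not return an engine result")
  res
}

#' Mock engine adapter
#'
#' Wraps [mock_frequency_map()] in the adapter contract; accepts either a
#' cluster (used directly) or an engine input built from one (the cluster
#' geometry is reconstructed from the deck).
#'
#' @param map_params coefficients forwarded to the map.
#' @return adapter function for [run_engine()].
#' @export
mock_adapter <- function(map_params = mock_map_params()) {
  function(input) {
    if (inherits(input, "hdo_cluster"))
      return(mock_frequency_map(input, map_params))
    if (!inherits(input, "hdo_engine_input"))
      stop("mock adapter expects a cluster or an engine input")
    # rebuild first-shell radii from the deck: probe O is atom 1, environment
    # oxygens every third frozen atom
    env_o <- input$xyz[input$elements == "O", , drop = FALSE][-1L, , drop = FALSE]
    r <- if (nrow(env_o)) sqrt(rowSums(sweep(env_o, 2L, input$xyz[1L, ])^2)) else
      numeric(0)
    cl <- structure(list(probe_xyz = input$xyz[1:3, , drop = FALSE],
                         r_oo = r, r1 = input$r1 %||% 3.4,
                         n_first_shell = input$n_first_shell,
                         time_ps = input$time_ps),
                    class = "hdo_cluster")
    mock_frequency_map(cl, map_params)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default frequency windows for HDO mode assignment
#'
#' Disjoint intervals (closed on the left) bracketing the three HDO modes
#' with wide margins: bend \[1100, 1800), OD stretch \[1800, 2900), OH
#' stretch \[2900, 4200) cm^-1.
#'
#' @return named list of `c(lower, upper)` intervals.
#' @export
default_mode_windows <- function() {
  list(bend = c(1100, 1800), OD = c(1800, 2900), OH = c(2900, 4200))
}

#' Assign engine modes to the HDO bend, OD and OH stretches
#'
#' Low-frequency pseudo-translations/rotations of the constrained probe are
#' discarded; within each window the single candidate is taken, or the most
#' intense one if several fall inside (the snapshot is then flagged).
#'
#' @param result an `hdo_engine_result`.
#' @param windows per-mode frequency intervals as from
#'   [default_mode_windows()]; must be disjoint.
#' @return data.frame with one row per mode: `mode`, `freq_cm1`,
#'   `intensity`, `flagged` (multiple candidates in the window).
#' @export
assign_probe_modes <- function(result, windows = default_mode_windows()) {
  stopifnot(inherits(result, "hdo_engine_result"))
  iv <- do.call(rbind, windows)
  if (any(iv[order(iv[, 1]), 2][-nrow(iv)] > iv[order(iv[, 1]), 1][-1L]))
    stop("mode windows must be disjoint")
  out <- lapply(names(windows), function(m) {
    w <- windows[[m]]
    cand <- result$modes[result$modes$freq_cm1 >= w[1] &
                           result$modes$freq_cm1 < w[2], , drop = FALSE]
    if (!nrow(cand))
      stop("no frequency in the ", m, " window [", w[1], ", ", w[2],
           ") for snapshot at t = ", result$time_ps, " ps")
    pick <- cand[which.max(cand$intensity), ]
    data.frame(mode = m, freq_cm1 = pick$freq_cm1, intensity = pick$intensity,
               flagged = nrow(cand) > 1L)
  })
  do.call(rbind, out)
}
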