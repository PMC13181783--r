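#' Read a multi-frame XYZ trajectory
#'
#' Reads the plain XYZ dialect used throughout this package: each frame is an
#' atom count line, a comment line carrying the orthorhombic box lengths as
#' three whitespace-separated numbers (optionally followed by `t=<ps>`), and
#' one `element x y z` line per atom, coordinates in Angstrom.
#'
#' @param path path to the `.xyz` file.
#' @param dt_ps frame spacing in ps used to assign time stamps when the
#'   comment line carries no `t=` field. Default 0 stamps all frames with
#'   their frame index times `dt_ps`.
#' @return list of [hdo_frame] objects.
#' @seealso [write_xyz()], [read_pdb_frames()]
#' @export
read_xyz_frames <- function(path, dt_ps = 0) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L)
      stop("malformed XYZ: expected an atom count at line ", i)
    if (i + 1L + nat > length(lines))
      stop("malformed XYZ: truncated frame starting at line ", i)
    comment <- lines[i + 1L]
    toks <- strsplit(trimws(comment), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(toks))
    if (sum(!is.na(nums)) < 3L)
      stop("XYZ comment line must carry three box lengths: frame at line ", i)
    box <- nums[!is.na(nums)][1:3]
    tmatch <- regmatches(comment, regexpr("t=\\s*([0-9.eE+-]+)", comment))
    t_ps <- if (length(tmatch)) {
      as.numeric(sub("t=\\s*", "", tmatch))
    } else {
      fidx * dt_ps
    }
    body <- do.call(rbind, strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+"))
    frames[[length(frames) + 1L]] <- hdo_frame(
      elements = body[, 1L],
      xyz = matrix(as.numeric(body[, 2:4]), ncol = 3L),
      box = box, time_ps = t_ps)
    i <- i + 2L + nat
    fidx <- fidx + 1L
  }
  frames
}

#' Write frames (or a carved cluster) to an XYZ file
#'
#' @param frames a single [hdo_frame] or a list of them.
#' @param path output path.
#' @param digits coordinate precision (decimal places). Default 6.
#' @export
write_xyz <- function(frames, path, digits = 6) {
  if (inherits(frames, "hdo_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%-2s %%14.%df %%14.%df %%14.%df", digits, digits, digits)
  for (fr in frames) {
    writeLines(as.character(nrow(fr$xyz)), con)
    writeLines(sprintf("%.6f %.6f %.6f t= %.6f", fr$box[1], fr$box[2],
                       fr$box[3], fr$time_ps), con)
    writeLines(sprintf(fmt, fr$elements, fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]),
               con)
  }
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Minimal PDB reader for water boxes: takes the box from the `CRYST1`
#' record (orthorhombic cell assumed; angles must be 90 degrees) and splits
#' frames on `MODEL`/`ENDMDL`. Element symbols come from the atom-name
#' column.
#'
#' @param path path to the PDB file.
#' @param dt_ps frame spacing in ps used to stamp consecutive models.
#' @return list of [hdo_frame] objects.
#' @export
read_pdb_frames <- function(path, dt_ps = 0) {
  lines <- readLines(path)
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cry)) stop("PDB file has no CRYST1 record; box unknown")
  box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                      substr(cry[1], 25, 33)))
  ang <- as.numeric(c(substr(cry[1], 34, 40), substr(cry[1], 41, 47),
                      substr(cry[1], 48, 54)))
  if (any(abs(ang - 90) > 1e-3))
    stop("only orthorhombic cells are supported (CRYST1 angles must be 90)")
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
  frames <- list()
  for (m in sort(unique(model_id[is_atom]))) {
    rec <- lines[is_atom & model_id == m]
    el <- trimws(substr(rec, 77, 78))
    fallback <- !nzchar(el)
    el[fallback] <- gsub("[0-9 ]", "", substr(rec[fallback], 13, 14))
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
    xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
    frames[[length(frames) + 1L]] <- hdo_frame(
      elements = el, xyz = xyz, box = box,
      time_ps = (length(frames)) * dt_ps)
  }
  frames
}
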