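#' Write a filament configuration as XYZ
#'
#' One-frame XYZ with coordinates in Angstrom; the comment line carries
#' optional metadata.
#'
#' @param config a [filament_conf()].
#' @param file path.
#' @param comment comment-line text.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(config, file, comment = "filament") {
  pos <- conf_coords(as_conf_matrix(config), units = "angstrom")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), comment), con)
  writeLines(sprintf("C %14.6f %14.6f %14.6f", pos[, 1], pos[, 2], pos[, 3]), con)
  invisible(file)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj a `cg_trajectory`.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  nf <- dim(traj$frames)[3]
  n <- dim(traj$frames)[1]
  for (f in seq_len(nf)) {
    pos <- traj$frames[, , f] * 10
    writeLines(c(as.character(n),
                 sprintf("t= %.6f ns phase= %s", traj$times[f],
                         as.character(traj$phase[f]))), con)
    writeLines(sprintf("C %14.6f %14.6f %14.6f", pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(file)
}

#' Read a multi-frame XYZ trajectory
#' @param file path written by [write_trajectory_xyz()] (Angstrom).
#' @return list with `frames` (n x 3 x nf array, nm), `times`, `phase`.
#' @export
read_trajectory_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list(); times <- numeric(0); phase <- character(0)
  q <- 1L
  while (q <= length(lines)) {
    n <- as.integer(lines[q])
    hdr <- strsplit(trimws(lines[q + 1L]), "\\s+")[[1]]
    times <- c(times, suppressWarnings(as.numeric(hdr[2])))
    phase <- c(phase, if (length(hdr) >= 5) hdr[5] else NA_character_)
    block <- lines[(q + 2L):(q + 1L + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), function(w)
      as.numeric(w[2:4])))
    frames[[length(frames) + 1L]] <- m / 10
    q <- q + 2L + n
  }
  list(frames = array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames))),
       times = times, phase = phase)
}

#' Write subunit centroids as CSV
#' @param config a [filament_conf()].
#' @param file path; columns index, x, y, z (Angstrom).
#' @return `file`, invisibly.
#' @export
write_centroid_csv <- function(config, file) {
  pos <- conf_coords(as_conf_matrix(config), units = "angstrom")
  utils::write.csv(data.frame(index = seq_len(nrow(pos)) - 1L,
                              x = pos[, 1], y = pos[, 2], z = pos[, 3]),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read 3D marker/centroid points from CSV
#'
#' Accepts columns named x, y, z (case-insensitive; extra columns are
#' ignored) in Angstrom or nm.
#'
#' @param file CSV path.
#' @param units `"angstrom"` (default, matching marker exports) or `"nm"`.
#' @return m x 3 matrix in nm.
#' @export
read_markers_csv <- function(file, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  d <- utils::read.csv(file)
  names(d) <- tolower(names(d))
  if (!all(c("x", "y", "z") %in% names(d)))
    stop("CSV must contain x, y, z columns")
  m <- as.matrix(d[, c("x", "y", "z")])
  if (units == "angstrom") m <- m / 10
  m
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored; values are parsed as numbers where possible.
#'
#' @param file path.
#' @return named list.
#' @export
read_config_file <- function(file) {
  lines <- readLines(file)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
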