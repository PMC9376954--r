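#' Write frames in GRO dialect
#'
#' Writes one frame or a whole trajectory as (multi-frame) GROMACS GRO text:
#' title line carrying the time stamp (`t=` in ps, the GRO convention),
#' atom count, fixed-width atom records (positions in nm to 0.001 nm,
#' velocities in nm/ps to 0.0001 when present), and the cubic box line.
#' Bead kinds are encoded in the atom-name column (`B`, `S`, `TN`, `TC`).
#'
#' @param x A `cg_frame` or `cg_trajectory`.
#' @param topology A `cg_topology` (atom names, residue numbering).
#' @param path Output path.
#' @param wrap Wrap coordinates into the box before writing.
#' @export
write_gro <- function(x, topology, path, wrap = FALSE) {
  frames <- if (inherits(x, "cg_trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  b <- topology$beads
  resnum <- cumsum(c(TRUE, diff(b$chain * 10000L + b$residue) != 0))
  for (fr in frames) {
    if (wrap) fr <- wrap_frame(fr)
    writeLines(sprintf("two-bead peptide frame, t= %.5f", fr$time * 1000),
               con)
    writeLines(sprintf("%5d", nrow(fr$pos)), con)
    has_v <- !is.null(fr$vel)
    for (i in seq_len(nrow(fr$pos))) {
      rec <- sprintf("%5dPEP  %5s%5d%8.3f%8.3f%8.3f",
                     resnum[i] %% 100000L, b$kind[i], i %% 100000L,
                     fr$pos[i, 1], fr$pos[i, 2], fr$pos[i, 3])
      if (has_v)
        rec <- paste0(rec, sprintf("%8.4f%8.4f%8.4f", fr$vel[i, 1],
                                   fr$vel[i, 2], fr$vel[i, 3]))
      writeLines(rec, con)
    }
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$L, fr$L, fr$L), con)
  }
  invisible(path)
}

#' Read GRO-dialect frames
#'
#' Reads one or more concatenated GRO frames. The time stamp is taken from
#' a `t=` field on the title line when present (ps, converted to ns).
#'
#' @param path GRO file.
#' @return A list of `cg_frame`s (length 1 for a single-frame file), with
#'   attribute `kinds` (atom-name column).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(n)) stop("malformed GRO: bad atom count at line ", i + 1)
    if (i + 1 + n + 1 > length(lines))
      stop("malformed GRO: truncated frame starting at line ", i)
    at <- lines[(i + 2):(i + 1 + n)]
    kinds <- trimws(substr(at, 11, 15))
    px <- as.numeric(substr(at, 21, 28))
    py <- as.numeric(substr(at, 29, 36))
    pz <- as.numeric(substr(at, 37, 44))
    if (anyNA(px) || anyNA(py) || anyNA(pz))
      stop("malformed GRO: bad coordinate field near line ", i + 2)
    vel <- NULL
    if (nchar(at[1]) >= 68) {
      vx <- as.numeric(substr(at, 45, 52))
      vy <- as.numeric(substr(at, 53, 60))
      vz <- as.numeric(substr(at, 61, 68))
      if (!anyNA(vx)) vel <- cbind(vx, vy, vz)
    }
    box <- as.numeric(strsplit(trimws(lines[i + n + 2]), "\\s+")[[1]])
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time_ns <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) / 1000 else 0
    fr <- cg_frame(cbind(px, py, pz), L = box[1], velocities = vel,
                   time = time_ns)
    attr(fr, "kinds") <- kinds
    frames[[length(frames) + 1]] <- fr
    i <- i + n + 3
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Write frames in XYZ dialect
#'
#' Extended XYZ text with coordinates in nm; the comment line must carry
#' the box edge as `L=<nm>` and optionally `t=<ns>`. Bead kinds go in the
#' atom-name column.
#'
#' @inheritParams write_gro
#' @export
write_xyz <- function(x, topology, path) {
  frames <- if (inherits(x, "cg_trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  kinds <- topology$beads$kind
  for (fr in frames) {
    writeLines(sprintf("%d", nrow(fr$pos)), con)
    writeLines(sprintf("L=%.6f t=%.6f", fr$L, fr$time), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", kinds, fr$pos[, 1],
                       fr$pos[, 2], fr$pos[, 3]), con)
  }
  invisible(path)
}

#' Read XYZ-dialect frames
#'
#' @param path XYZ file with `L=` on every comment line (coordinates nm).
#' @return A list of `cg_frame`s with attribute `kinds`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: bad atom count at line ", i)
    comment <- lines[i + 1]
    Lm <- regmatches(comment, regexpr("L=\\s*[-0-9.eE+]+", comment))
    if (!length(Lm))
      stop("XYZ comment line must carry the box edge as 'L=<nm>' (line ",
           i + 1, ")")
    L <- as.numeric(sub("L=\\s*", "", Lm))
    tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else 0
    rec <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    bad <- which(lengths(rec) < 4)
    if (length(bad))
      stop("malformed XYZ record at line ", i + 1 + bad[1])
    kinds <- vapply(rec, `[[`, "", 1)
    pos <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    fr <- cg_frame(pos, L = L, time = time)
    attr(fr, "kinds") <- kinds
    frames[[length(frames) + 1]] <- fr
    i <- i + n + 2
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Write a run metadata log
#'
#' Sidecar text log for a simulation or analysis run: settings, seeds, and
#' the package version, as flat `key = value` lines.
#'
#' @param path Output path.
#' @param ... Named values to log.
#' @export
write_run_log <- function(path, ...) {
  vals <- list(...)
  lines <- c(sprintf("package_version = %s",
                     as.character(utils::packageVersion("fibrilsim"))),
             sprintf("date = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(vals), function(k)
               sprintf("%s = %s", k, paste(format(vals[[k]]), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
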