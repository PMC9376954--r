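#' Default run configuration with provenance tags
#'
#' Collects every tunable of the toolkit in one flat list. Each entry is
#' tagged with its provenance: `"reference"` for values fixed by the model
#' protocol (force-field constants, 303 K, 15 fs, 0.17 ps, 35 nm box,
#' 5.5 A cluster cutoff, 0.8-2.4 nm neighbor shell), `"assumption"` for
#' package defaults the protocol leaves open (combination rule, nonbonded
#' truncation scheme, bead mass, insertion floor, phase boundaries, fit
#' weights). [show_assumptions()] lists the latter.
#'
#' @return A `run_config` list; each element has `value` and `provenance`.
#' @export
run_config <- function() {
  e <- function(value, provenance, note = "")
    list(value = value, provenance = provenance, note = note)
  structure(list(
    sigma_SS = e(0.41, "assumption", "mid-range of the 0.37-0.45 nm scan"),
    r0_BS = e(0.55, "assumption", "mid-range of the 0.40-0.70 nm scan"),
    dt_fs = e(15, "reference"),
    temperature_K = e(303, "reference"),
    tau_ps = e(0.17, "reference"),
    box_L_nm = e(35, "reference"),
    cluster_cutoff_nm = e(0.55, "reference"),
    cbb_shell_nm = e(c(0.8, 2.4), "reference"),
    nonbonded_cutoff_nm = e(1.2, "assumption", "with potential shift to zero"),
    nonbonded_shift = e(TRUE, "assumption"),
    sigma_combine = e("arithmetic", "assumption", "sigma_BS combination rule"),
    angle_form = e("cosine", "assumption", "MARTINI cosine-harmonic"),
    repulsive_form = e("lj12", "assumption", "WCA available as switch"),
    bead_mass_amu = e(72, "assumption", "MARTINI-standard bead mass"),
    insertion_floor_nm = e(0.5, "assumption", "monomer placement"),
    overlap_floor_nm = e(0.05, "assumption", "overlap flagging"),
    terminal_beads_in_contacts = e(TRUE, "assumption",
                                   "all bead kinds enter the cluster rule"),
    phase_boundaries = e("fitted to fixtures", "assumption",
                         "see phase_boundaries()"),
    kinetics_V_nm3 = e(35^3, "reference"),
    kinetics_N = e(72, "reference"),
    fit_weights = e("equal per curve per point", "assumption")
  ), class = "run_config")
}

#' List assumption-tagged configuration defaults
#'
#' @param config A [run_config()].
#' @return Data frame of the entries whose provenance is `"assumption"`.
#' @export
show_assumptions <- function(config = run_config()) {
  rows <- lapply(names(config), function(k) {
    en <- config[[k]]
    if (!identical(en$provenance, "assumption")) return(NULL)
    data.frame(parameter = k,
               value = paste(format(en$value), collapse = " "),
               note = en$note)
  })
  do.call(rbind, rows)
}

#' Write a run configuration to a flat key-value file
#'
#' @param config A [run_config()].
#' @param path Output path. Round-trips losslessly through
#'   [read_config()].
#' @export
write_config <- function(config, path) {
  lines <- unlist(lapply(names(config), function(k) {
    en <- config[[k]]
    sprintf("%s = %s | %s | %s", k,
            paste(format(en$value, digits = 17), collapse = ","),
            en$provenance, en$note)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' @param path File written by [write_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  proto <- run_config()
  for (ln in lines) {
    k <- trimws(sub("=.*", "", ln))
    rest <- strsplit(sub("^[^=]*=", "", ln), "|", fixed = TRUE)[[1]]
    raw <- trimws(rest[1])
    vals <- strsplit(raw, ",", fixed = TRUE)[[1]]
    value <- suppressWarnings(as.numeric(vals))
    if (anyNA(value)) {
      value <- if (all(vals %in% c("TRUE", "FALSE"))) as.logical(vals)
               else trimws(vals)
    }
    out[[k]] <- list(value = value,
                     provenance = trimws(rest[2]),
                     note = if (length(rest) >= 3) trimws(rest[3]) else "")
  }
  structure(out, class = "run_config")
}
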