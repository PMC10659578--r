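# CSV dialects. Every writer puts a "# provenance:" JSON comment on the
# first line; readers skip comments, validate numeric content and report
# offending line numbers. Values survive a write/read round trip to 1e-12
# (17 significant digits).

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

provenance_line <- function(provenance) {
  paste0("# provenance: ",
         jsonlite::toJSON(provenance %||% list(), auto_unbox = TRUE, digits = NA))
}

read_provenance <- function(lines) {
  pl <- grep("^# provenance:", lines, value = TRUE)
  if (length(pl) == 0) return(NULL)
  tryCatch(jsonlite::fromJSON(sub("^# provenance:\\s*", "", pl[1])),
           error = function(e) NULL)
}

read_csv_checked <- function(path, expect_first = NULL) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) < 2) stopf("'%s': no data rows found.", path)
  header <- strsplit(lines[body_idx[1]], ",", fixed = TRUE)[[1]]
  if (!is.null(expect_first) && header[1] != expect_first) {
    stopf("'%s': expected first column '%s', found '%s' (line %d).",
          path, expect_first, header[1], body_idx[1])
  }
  rows <- lapply(body_idx[-1], function(i) {
    cells <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(cells) != length(header)) {
      stopf("'%s' line %d: %d cells but %d columns in the header.",
            path, i, length(cells), length(header))
    }
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) | cells == "")
    if (length(bad) > 0) {
      stopf("'%s' line %d, column %d ('%s'): non-numeric or missing cell.",
            path, i, bad[1], header[bad[1]])
    }
    vals
  })
  m <- do.call(rbind, rows)
  colnames(m) <- header
  list(matrix = m, header = header, provenance = read_provenance(lines))
}

write_csv_block <- function(path, header, m, provenance) {
  lines <- c(provenance_line(provenance),
             paste(header, collapse = ","),
             apply(m, 1, function(r) paste(fmt_num(r), collapse = ",")))
  writeLines(lines, path)
}

#' Read and write single-wavelength time courses
#'
#' Two-column CSV (`time_s`, `absorbance`) with a `# provenance:` comment
#' line. Reading validates strictly increasing time and numeric cells,
#' reporting line numbers on failure.
#'
#' @param tc A `heme_timecourse` (or data frame with `time_s`,
#'   `absorbance`).
#' @param path File path.
#' @return `read_timecourse()` returns a `heme_timecourse` with the
#'   provenance attribute restored; `write_timecourse()` returns `path`
#'   invisibly.
#' @export
write_timecourse <- function(tc, path) {
  write_csv_block(path, c("time_s", "absorbance"),
                  cbind(tc$time_s, tc$absorbance), attr(tc, "provenance"))
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  got <- read_csv_checked(path, expect_first = "time_s")
  tt <- got$matrix[, 1]
  if (any(diff(tt) <= 0)) {
    bad <- which(diff(tt) <= 0)[1]
    stopf("'%s': time is not strictly increasing at data row %d.", path, bad + 1L)
  }
  new_timecourse(tt, got$matrix[, 2], provenance = got$provenance)
}

#' Read and write rapid-scan matrices
#'
#' Dialect: first header cell `time_s`, remaining header cells the
#' wavelengths in nm; one row per time point; `# provenance:` comment first.
#'
#' @param dataset A `rapid_scan`.
#' @param path File path.
#' @return `read_rapid_scan()` returns a `rapid_scan` (conditions reduced to
#'   what provenance carries); `write_rapid_scan()` returns `path`
#'   invisibly.
#' @export
write_rapid_scan <- function(dataset, path) {
  prov <- dataset$provenance %||% list()
  prov$dead_time_s <- prov$dead_time_s %||% dataset$conditions$dead_time_s
  write_csv_block(path, c("time_s", fmt_num(dataset$grid_nm)),
                  cbind(dataset$time_s, dataset$absorbance), prov)
  invisible(path)
}

#' @rdname write_rapid_scan
#' @export
read_rapid_scan <- function(path) {
  got <- read_csv_checked(path, expect_first = "time_s")
  tt <- got$matrix[, 1]
  if (any(diff(tt) <= 0)) stopf("'%s': time is not strictly increasing.", path)
  grid <- suppressWarnings(as.numeric(got$header[-1]))
  if (anyNA(grid)) stopf("'%s': wavelength headers must be numeric.", path)
  prov <- got$provenance
  dead <- prov$dead_time_s %||% 0
  cond <- experiment_conditions(
    enzyme_uM = prov$enzyme_uM %||% 1,
    dead_time_s = dead)
  structure(list(time_s = tt, grid_nm = grid,
                 absorbance = unname(got$matrix[, -1, drop = FALSE]),
                 conditions = cond, provenance = prov),
            class = "rapid_scan")
}

#' Read and write titration tables
#'
#' Two-column CSV (`substrate_uM`, `k_obs`) with provenance comment.
#'
#' @param tt A `titration` tibble.
#' @param path File path.
#' @return `read_titration()` returns a `titration` tibble.
#' @export
write_titration <- function(tt, path) {
  write_csv_block(path, c("substrate_uM", "k_obs"),
                  cbind(tt$substrate_uM, tt$k_obs), attr(tt, "provenance"))
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  got <- read_csv_checked(path, expect_first = "substrate_uM")
  out <- tibble(substrate_uM = got$matrix[, 1], k_obs = got$matrix[, 2])
  attr(out, "provenance") <- got$provenance
  class(out) <- c("titration", class(out))
  out
}

#' Read and write species libraries
#'
#' CSV with `wavelength_nm` first and one absorptivity column per species.
#'
#' @param library A [species_library()].
#' @param path File path.
#' @return `read_species_library()` returns a `species_library` (redox
#'   states restored from provenance when present).
#' @export
write_species_library <- function(library, path) {
  write_csv_block(path, c("wavelength_nm", library_species(library)),
                  as.matrix(library),
                  list(redox_states = as.list(attr(library, "redox_states"))))
  invisible(path)
}

#' @rdname write_species_library
#' @export
read_species_library <- function(path) {
  got <- read_csv_checked(path, expect_first = "wavelength_nm")
  states <- got$provenance$redox_states
  specs <- lapply(got$header[-1], function(nm) {
    s <- tibble(wavelength_nm = got$matrix[, 1],
                epsilon = got$matrix[, nm])
    attr(s, "name") <- nm
    attr(s, "redox_state") <- (states[[nm]] %||% "other")
    class(s) <- c("species_spectrum", class(s))
    s
  })
  species_library(specs)
}

#' Write a concentration trajectory
#'
#' CSV with `time_s` first and one concentration column per species.
#'
#' @param traj A `concentration_trajectory`.
#' @param path File path.
#' @return `path`, invisibly; `read_trajectory()` returns the tibble.
#' @export
write_trajectory <- function(traj, path) {
  write_csv_block(path, names(traj), as.matrix(traj), NULL)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  got <- read_csv_checked(path, expect_first = "time_s")
  out <- as_tibble(as.data.frame(got$matrix))
  class(out) <- c("concentration_trajectory", class(out))
  out
}
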