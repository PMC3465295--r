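#' Read and write the standard CSV schemas
#'
#' Mass-at-age series (`animal_id,age_yr,mass_kg`), feeding records
#' (`animal_id,age_start_yr,age_end_yr,mass_start_kg,mass_end_kg,
#' food_wet_kg`), energy assays (`sample_id,dry_fraction,
#' energy_kj_per_g_dm`) and population grids (`age_yr,N,mass_kg,
#' F_t_per_yr,Q_t_per_yr,B_t`). Readers validate the header and basic
#' invariants; writers emit plain comma-separated text without row names.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return the validated data frame (readers); the path, invisibly
#'   (writers).
#' @name leatherback_io
NULL

read_checked <- function(path, cols) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(cols %in% names(d))) {
    stop("expected columns ", paste(cols, collapse = ","), " in ", path)
  }
  d[cols]
}

#' @rdname leatherback_io
#' @export
read_mass_series <- function(path) {
  d <- read_checked(path, c("animal_id", "age_yr", "mass_kg"))
  if (any(d$age_yr < 0)) stop("negative ages in mass series")
  if (any(d$mass_kg <= 0)) stop("non-positive masses in mass series")
  if (any(unlist(tapply(d$age_yr, d$animal_id, function(a) diff(a) <= 0)))) {
    stop("per-animal ages must be strictly increasing")
  }
  d
}

#' @rdname leatherback_io
#' @export
write_mass_series <- function(x, path) {
  utils::write.csv(x[c("animal_id", "age_yr", "mass_kg")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname leatherback_io
#' @export
read_feeding_records <- function(path) {
  cols <- c("animal_id", "age_start_yr", "age_end_yr", "mass_start_kg",
            "mass_end_kg", "food_wet_kg")
  d <- read_checked(path, cols)
  if (any(d$age_end_yr <= d$age_start_yr)) {
    stop("feeding intervals must have end > start")
  }
  if (any(d$food_wet_kg < 0)) stop("negative food masses")
  if (any(d$mass_start_kg <= 0 | d$mass_end_kg <= 0)) {
    stop("non-positive masses in feeding records")
  }
  d
}

#' @rdname leatherback_io
#' @export
write_feeding_records <- function(x, path) {
  cols <- c("animal_id", "age_start_yr", "age_end_yr", "mass_start_kg",
            "mass_end_kg", "food_wet_kg")
  utils::write.csv(x[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname leatherback_io
#' @export
read_energy_assays <- function(path) {
  d <- read_checked(path, c("sample_id", "dry_fraction",
                            "energy_kj_per_g_dm"))
  if (any(d$dry_fraction <= 0 | d$dry_fraction >= 1)) {
    stop("dry fractions must lie in (0, 1)")
  }
  if (any(d$energy_kj_per_g_dm <= 0)) stop("non-positive energy densities")
  d
}

#' @rdname leatherback_io
#' @export
write_energy_assays <- function(x, path) {
  utils::write.csv(x[c("sample_id", "dry_fraction", "energy_kj_per_g_dm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname leatherback_io
#' @export
write_population_grid <- function(x, path) {
  stopifnot(inherits(x, "population_grid"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Flat key-value configuration files
#'
#' A minimal sectioned `key = value` format (INI style):
#' `[section]` headers, one `key = value` per line, `#` comments.
#' Values are parsed as numeric vectors when possible (space-separated),
#' otherwise kept as strings. `write_config()` is the inverse.
#'
#' @param path file path.
#' @param config named list of sections, each a named list of values.
#' @return named list of sections (reader); the path, invisibly (writer).
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("key before any [section] in ", path)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
      out[[section]][[key]] <- if (!anyNA(num)) num else val
    } else {
      stop("unparseable config line: ", ln)
    }
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (section in names(config)) {
    lines <- c(lines, sprintf("[%s]", section))
    for (key in names(config[[section]])) {
      val <- config[[section]][[key]]
      lines <- c(lines, sprintf("%s = %s", key,
                                paste(format(val, digits = 15),
                                      collapse = " ")))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialise growth parameters to and from a config section
#'
#' Writes a `[growth]` section with keys
#' `w_inf_kg, k_per_yr, t0_yr, b, a`; the reader reconstructs a
#' [growth_params()] object.
#'
#' @param p a [growth_params()] object.
#' @param config a config list from [read_config()].
#' @return a config list fragment, or a [growth_params()] object.
#' @export
growth_params_to_config <- function(p) {
  stopifnot(inherits(p, "growth_params"))
  list(growth = list(w_inf_kg = p$w_inf, k_per_yr = p$k, t0_yr = p$t0,
                     b = p$b, a = p$a))
}

#' @rdname growth_params_to_config
#' @export
growth_params_from_config <- function(config) {
  g <- config$growth
  if (is.null(g)) stop("no [growth] section")
  growth_params(w_inf = g$w_inf_kg, k = g$k_per_yr, t0 = g$t0_yr,
                b = g$b, a = g$a)
}
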