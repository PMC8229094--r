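# YAML/JSON run configuration with explicit units at the file boundary.

UNIT_FACTORS <- c(
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9,
  "T" = 1, "mT" = 1e-3,
  "Am2" = 1, "fAm2" = 1e-15,
  "m3/s" = 1, "mL/min" = 1e-6 / 60, "mL/s" = 1e-6,
  "Pa s" = 1, "mPa s" = 1e-3,
  "kg/m3" = 1, "A/m" = 1, "s" = 1
)

#' Parse a physical quantity with unit to SI
#'
#' Accepts a bare number (taken as SI) or a string like `"1.0 mm"`,
#' `"22 mT"`, `"10 fAm2"`, `"1 mL/min"`.
#'
#' @param x numeric or string.
#' @return Numeric value in SI units.
#' @export
#' @examples
#' parse_quantity("1.0 mm")   # 1e-3
#' parse_quantity("10 fAm2")  # 1e-14
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  if (length(x) > 1) return(vapply(x, parse_quantity, numeric(1), USE.NAMES = FALSE))
  x <- trimws(x)
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*(.*)$", x))[[1]]
  if (length(m) != 3 || m[2] == "") abort(paste0("cannot parse quantity '", x, "'"))
  val <- suppressWarnings(as.numeric(m[2]))
  if (is.na(val)) abort(paste0("cannot parse quantity '", x, "'"))
  unit <- trimws(m[3])
  if (unit == "") return(val)
  if (!unit %in% names(UNIT_FACTORS)) {
    abort(paste0("unknown unit '", unit, "' in '", x, "'"))
  }
  val * UNIT_FACTORS[[unit]]
}

check_keys <- function(x, allowed, where, errors) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    errors <- c(errors, paste0("unknown key(s) in ", where, ": ",
                               paste(bad, collapse = ", ")))
  }
  errors
}

config_array <- function(a, errors) {
  errors <- check_keys(a, c("pattern", "element_width", "heights", "height",
                            "grade", "Br", "span", "phase"), "array", errors)
  pattern <- a$pattern
  if (is.null(pattern)) {
    errors <- c(errors, "array: missing required key 'pattern'")
    return(list(arr = NULL, errors = errors))
  }
  Br <- if (!is.null(a$Br)) parse_quantity(a$Br)
        else if (!is.null(a$grade)) grade_remanence(a$grade)
        else 1.45
  w <- parse_quantity(a$element_width %||% "1 mm")
  span <- if (!is.null(a$span)) parse_quantity(a$span) else c(-10e-3, 60e-3)
  phase <- as.integer(a$phase %||% 0L)
  if (w <= 0) {
    errors <- c(errors, "array: element_width must be positive")
    return(list(arr = NULL, errors = errors))
  }
  arr <- tryCatch({
    if (pattern == "halbach") {
      hs <- parse_quantity(a$heights %||% c("2.75 mm", "2 mm"))
      if (length(hs) == 1) hs <- rep(hs, 2)
      halbach_array(w, hs[1], hs[2], Br = Br, span = span, phase = phase)
    } else if (pattern == "alternating") {
      h <- parse_quantity(a$height %||% a$heights %||% "2.375 mm")
      alternating_array(w, h[1], Br = Br, span = span, phase = phase)
    } else {
      errors <- c(errors, paste0("array: unknown pattern '", pattern, "'"))
      NULL
    }
  }, error = function(e) {
    errors <<- c(errors, paste0("array: ", conditionMessage(e)))
    NULL
  })
  list(arr = arr, errors = errors)
}

#' Load a run configuration
#'
#' Reads a YAML (or `.json`) configuration, validates it against the schema
#' (unknown keys, missing array pattern and non-positive dimensions are
#' collected and reported together) and fills defaults: an empty
#' configuration describes the reference system (800-um channel at
#' 1 mL/min, optimized 1-mm Halbach array, 10 fAm^2 arctangent cell).
#' Quantities may be strings with units (see [parse_quantity()]).
#'
#' @param path file path, or a list already parsed.
#' @return A list of class `run_config` with `channel`, `fluid`, `arrays`
#'   (named list), `cell`, `sim`.
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  errors <- character()
  errors <- check_keys(raw, c("channel", "fluid", "array", "arrays", "cell",
                              "sim"), "config", errors)

  ch <- raw$channel %||% list()
  errors <- check_keys(ch, c("preset", "height", "width", "length", "wall",
                             "flow_rate"), "channel", errors)
  channel <- tryCatch({
    if (!is.null(ch$preset)) {
      ibidi_channel(as.numeric(ch$preset),
                    flow_rate = parse_quantity(ch$flow_rate %||% "1 mL/min"))
    } else {
      flow_channel(height = parse_quantity(ch$height %||% "800 um"),
                   width = parse_quantity(ch$width %||% "5 mm"),
                   length = parse_quantity(ch$length %||% "50 mm"),
                   wall = parse_quantity(ch$wall %||% "200 um"),
                   flow_rate = parse_quantity(ch$flow_rate %||% "1 mL/min"))
    }
  }, error = function(e) { errors <<- c(errors, paste0("channel: ", conditionMessage(e))); NULL })

  fl <- raw$fluid %||% list()
  errors <- check_keys(fl, c("viscosity", "density"), "fluid", errors)
  fluid <- tryCatch(
    fluid_medium(viscosity = parse_quantity(fl$viscosity %||% "0.89 mPa s"),
                 density = parse_quantity(fl$density %||% 1000)),
    error = function(e) { errors <<- c(errors, paste0("fluid: ", conditionMessage(e))); NULL })

  cl <- raw$cell %||% list()
  errors <- check_keys(cl, c("radius", "density", "magnetization"), "cell", errors)
  mg <- cl$magnetization %||% list()
  errors <- check_keys(mg, c("variant", "m_s", "Bs"), "cell$magnetization", errors)
  cell <- tryCatch(
    cell_model(radius = parse_quantity(cl$radius %||% "5 um"),
               density = parse_quantity(cl$density %||% 1077),
               magnetization = magnetization_model(
                 variant = mg$variant %||% "arctan",
                 m_s = parse_quantity(mg$m_s %||% "10 fAm2"),
                 Bs = parse_quantity(mg$Bs %||% "22 mT"))),
    error = function(e) { errors <<- c(errors, paste0("cell: ", conditionMessage(e))); NULL })

  sm <- raw$sim %||% list()
  errors <- check_keys(sm, c("n_cells", "rtol", "atol", "max_transit_factor",
                             "capture_standoff", "use_grid"), "sim", errors)
  sim <- tryCatch(
    sim_config(n_cells = sm$n_cells %||% 500,
               rtol = sm$rtol %||% 1e-6, atol = sm$atol %||% 1e-9,
               max_transit_factor = sm$max_transit_factor %||% 20,
               capture_standoff = if (!is.null(sm$capture_standoff))
                 parse_quantity(sm$capture_standoff),
               use_grid = sm$use_grid %||% TRUE),
    error = function(e) { errors <<- c(errors, paste0("sim: ", conditionMessage(e))); NULL })

  arr_specs <- if (!is.null(raw$arrays)) raw$arrays else list(array = raw$array %||% list(pattern = "halbach"))
  arrays <- list()
  for (nm in names(arr_specs)) {
    ca <- config_array(arr_specs[[nm]], errors)
    errors <- ca$errors
    arrays[[nm]] <- ca$arr
  }

  if (length(errors)) {
    abort(paste0("invalid configuration:\n  ",
                 paste(errors, collapse = "\n  ")))
  }
  structure(list(channel = channel, fluid = fluid, arrays = arrays,
                 cell = cell, sim = sim),
            class = "run_config")
}

#' Canonical (SI numeric) form of a run configuration
#'
#' @param config a `run_config`.
#' @return A plain list with all quantities as SI numbers; suitable for
#'   [save_config()] and hashing.
#' @export
config_to_list <- function(config) {
  arr_list <- lapply(config$arrays, function(a) {
    out <- list(pattern = a$pattern, element_width = a$element_width,
                Br = a$Br, span = as.numeric(a$span),
                phase = as.integer(a$phase))
    if (a$pattern == "halbach") out$heights <- as.numeric(a$heights)
    else out$height <- as.numeric(a$heights[[1]])
    out
  })
  list(
    channel = config$channel[c("height", "width", "length", "wall", "flow_rate")],
    fluid = config$fluid[c("viscosity", "density")],
    cell = list(radius = config$cell$radius, density = config$cell$density,
                magnetization = list(variant = config$cell$magnetization$variant,
                                     m_s = config$cell$magnetization$m_s,
                                     Bs = config$cell$magnetization$Bs)),
    sim = config$sim[c("n_cells", "rtol", "atol", "max_transit_factor",
                       "use_grid")],
    arrays = arr_list
  )
}

#' Write a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly. `load_config(save_config(x, p))` reproduces
#'   `x` (round-trip identity on the SI values).
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(x$channel)
  print(x$cell)
  for (nm in names(x$arrays)) { cat(nm, ": "); print(x$arrays[[nm]]) }
  invisible(x)
}
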