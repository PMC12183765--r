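#' Read and write XYZ coordinate files
#'
#' Plain XYZ: an atom count line, a comment line, then one
#' `label x y z` row per particle (nm). `write_xyz` can append frames to
#' build a multi-frame trajectory.
#'
#' @param positions n x 3 matrix (nm).
#' @param labels Particle-type labels for the element column.
#' @param file Path.
#' @param comment Comment-line text.
#' @param append Append a frame instead of overwriting.
#' @return `write_xyz`: the path, invisibly. `read_xyz`: a list of frames,
#'   each `list(positions, labels, comment)`.
#' @export
write_xyz <- function(positions, labels, file, comment = "", append = FALSE) {
  positions <- as.matrix(positions)
  lines <- c(sprintf("%d", nrow(positions)), comment,
             sprintf("%-6s %14.8f %14.8f %14.8f", labels,
                     positions[, 1], positions[, 2], positions[, 3]))
  if (append) {
    cat(lines, file = file, sep = "\n", append = TRUE)
  } else {
    writeLines(lines, file)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop(sprintf("bad XYZ atom count at line %d", i))
    comment <- lines[i + 1L]
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    labels <- vapply(parts, `[`, character(1), 1L)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(positions = coords, labels = labels,
                                          comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' Write / read an energy-record stream as CSV
#'
#' Columns: time (ps), V_R, V_1..V_N, w_1..w_N, s. Offsets and temperature
#' travel in a JSON side-channel column-comment-free way: they are written
#' into a companion `<file>.meta.json`.
#'
#' @param records Record data frame from [run_re_eds()].
#' @param file CSV path.
#' @return `write_energy_records`: the path, invisibly;
#'   `read_energy_records`: the data frame with `offsets` and `temperature`
#'   attributes restored when the meta file exists.
#' @export
write_energy_records <- function(records, file) {
  data.table::fwrite(records, file)
  meta <- list(offsets = attr(records, "offsets"),
               temperature = attr(records, "temperature"))
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_energy_records
#' @export
read_energy_records <- function(file) {
  df <- as.data.frame(data.table::fread(file))
  meta_path <- paste0(file, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(df, "offsets") <- meta$offsets
    attr(df, "temperature") <- meta$temperature
  }
  df
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' One document with sections `system`, `states`, `eds`, `replicas`,
#' `pipeline`, `output`. Validation reports the exact path of the offending
#' entry. The `system` section may either inline coordinates or point to an
#' XYZ file (`coordinates: file.xyz`).
#'
#' @param path Config file (.yaml/.yml or .json).
#' @return Validated config list.
#' @export
read_reeds_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_reeds_config(cfg)
}

validate_reeds_config <- function(cfg) {
  fail <- function(path, msg) stop(sprintf("config %s: %s", path, msg), call. = FALSE)
  need <- function(x, path) if (is.null(x)) fail(path, "missing required entry") else x
  num <- function(x, path, min = -Inf, max = Inf) {
    x <- need(x, path)
    if (!is.numeric(x)) fail(path, "must be numeric")
    if (any(x < min | x > max)) fail(path, sprintf("must be in [%g, %g]", min, max))
    x
  }
  need(cfg$system, "system")
  need(cfg$states, "states")
  if (!is.null(cfg$eds)) {
    if (!is.null(cfg$eds$s)) num(cfg$eds$s, "eds.s", min = 1e-7, max = 1)
    if (!is.null(cfg$eds$temperature)) num(cfg$eds$temperature, "eds.temperature", min = 1e-6)
  }
  if (!is.null(cfg$replicas) && !is.null(cfg$replicas$s_values)) {
    sv <- num(cfg$replicas$s_values, "replicas.s_values", min = 1e-7, max = 1)
    if (length(sv) > 1 && any(diff(sv) >= 0)) fail("replicas.s_values", "must be strictly descending")
  }
  if (!is.null(cfg$pipeline)) {
    for (f in c("explore_steps", "opt_steps", "prod_steps")) {
      if (!is.null(cfg$pipeline[[f]])) num(cfg$pipeline[[f]], paste0("pipeline.", f), min = 1)
    }
  }
  cfg
}

#' Write a stage manifest
#'
#' Every pipeline stage records its inputs hash, parameters and outputs as a
#' JSON manifest, so stages can be audited and resumed.
#'
#' @param manifest Named list.
#' @param file Output JSON path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, file) {
  manifest$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(file)
}
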