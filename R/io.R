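# Tabular I/O: rate tables, titration tables and flat YAML configs.
# All CSV outputs begin with '#'-prefixed provenance headers; readers skip
# them.

pkg_version <- function() {
  as.character(utils::packageVersion("cypsom"))
}

config_hash <- function(config) {
  # hash the scientific configuration only: where outputs land and how
  # chatty the run is must not change the recorded identity
  config <- config[setdiff(names(config), c("out_dir", "verbosity"))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(seed = NULL, config = NULL) {
  h <- paste0("# cypsom ", pkg_version())
  if (!is.null(config)) h <- c(h, paste0("# config_hash: ", config_hash(config)))
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  h
}

write_csv_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# strict numeric CSV reader that reports the 1-based file line number of
# the first malformed row
read_numeric_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop_io(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop_input(paste("empty input file:", path))
  lineno <- which(keep)
  header <- strsplit(trimws(lines[lineno[1]]), ",")[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0)
    stop_input(paste0(path, ": missing required columns: ",
                      paste(missing_cols, collapse = ", ")))
  data_idx <- lineno[-1]
  if (length(data_idx) == 0) stop_input(paste("no data rows in", path))
  rows <- lapply(data_idx, function(i) {
    fields <- strsplit(lines[i], ",")[[1]]
    if (length(fields) != length(header))
      stop_input(sprintf("%s: line %d has %d fields, expected %d",
                         path, i, length(fields), length(header)))
    vals <- suppressWarnings(as.numeric(gsub('^"|"$', "", trimws(fields))))
    bad <- which(is.na(vals) & !(trimws(fields) %in% c("NA", '"NA"', "")))
    if (length(bad) > 0)
      stop_input(sprintf("%s: line %d: non-numeric value in column %s",
                         path, i, sQuote(header[bad[1]])))
    vals
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- header
  df[, intersect(c(required, optional), header), drop = FALSE]
}

#' Read a kinetic rate table
#'
#' Expects a CSV with header `s_um,x_um,v1oh,v4oh` and an optional `sd`
#' column; `#`-prefixed comment lines are skipped.  Malformed rows are
#' reported with their file line number.
#'
#' @param path Path to the CSV file.
#' @return Data frame with the rate-table columns.
#' @export
read_rate_csv <- function(path) {
  df <- read_numeric_csv(path, required = c("s_um", "x_um", "v1oh", "v4oh"),
                         optional = c("sd", "replicate"))
  validate_rate_dataset(df)
  df
}

#' Write a kinetic rate table with a provenance header
#'
#' @param data Rate data frame (`s_um,x_um,v1oh,v4oh[,sd]`).
#' @param path Output path.
#' @param seed,config Optional provenance fields recorded in the header.
#' @export
write_rate_csv <- function(data, path, seed = NULL, config = NULL) {
  keep <- intersect(c("s_um", "x_um", "v1oh", "v4oh", "sd", "replicate"),
                    names(data))
  write_csv_with_header(data[, keep, drop = FALSE], path,
                        provenance_header(seed, config))
}

#' Read a spin-shift titration table
#'
#' Expects a CSV with header `ligand_um,response` (comment lines skipped).
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `ligand_um` and `response`.
#' @export
read_titration_csv <- function(path) {
  read_numeric_csv(path, required = c("ligand_um", "response"))
}

#' Write a titration table with a provenance header
#'
#' @param curve Titration data frame (`ligand_um,response`).
#' @param path Output path.
#' @param seed,config Optional provenance fields recorded in the header.
#' @export
write_titration_csv <- function(curve, path, seed = NULL, config = NULL) {
  write_csv_with_header(curve[, c("ligand_um", "response")], path,
                        provenance_header(seed, config))
}

# --- flat YAML-style configs ------------------------------------------------

# sentinels: kd_allo_x = "disabled" and kd_prod_x = "nobind" map to Inf
.sentinel_map <- c(kd_allo_x = "disabled", kd_prod_x = "nobind")

#' Serialise occupancy-model parameters to a flat config list
#'
#' @param params An [occupancy_params()] object.
#' @return Named list with every field; disabled binding modes are spelled
#'   `"disabled"` (effector/allosteric) and `"nobind"`
#'   (effector/productive).
#' @export
params_to_config <- function(params) {
  validate_occupancy_params(params)
  out <- unclass(params)
  for (f in names(.sentinel_map)) {
    if (!is.finite(out[[f]])) out[[f]] <- unname(.sentinel_map[f])
  }
  out
}

#' Build occupancy-model parameters from a flat config list
#'
#' @param config Named list (or YAML-loaded section) naming
#'   [occupancy_params()] fields; sentinels `"disabled"`/`"nobind"` are
#'   accepted for the effector dissociation constants.
#' @return An [occupancy_params()] object.
#' @export
config_to_params <- function(config) {
  if (!is.list(config)) stop_config("params config must be a named list")
  defaults <- formals(occupancy_params)
  unknown <- setdiff(names(config), .par_fields)
  if (length(unknown) > 0)
    stop_config(paste("unknown parameter fields:",
                      paste(unknown, collapse = ", ")))
  args <- list()
  for (f in names(config)) {
    v <- config[[f]]
    if (is.character(v)) {
      if (v %in% c("disabled", "nobind", "Inf", ".inf")) v <- Inf
      else {
        v <- suppressWarnings(as.numeric(v))
        if (is.na(v)) stop_config(paste("non-numeric value for", f))
      }
    }
    args[[f]] <- v
  }
  do.call(occupancy_params, args)
}

#' Read / write a run configuration
#'
#' Configurations are flat YAML files; the `params` (or `init`) block uses
#' the [params_to_config()] spelling, including the `disabled`/`nobind`
#' sentinels.
#'
#' @param path Path to the YAML file.
#' @return `read_config()`: the configuration as a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io(paste("config not found:", path))
  tryCatch(yaml::read_yaml(path),
           error = function(e) stop_config(paste("cannot parse config:",
                                                 conditionMessage(e))))
}

#' @rdname read_config
#' @param config Named list to serialise.
#' @export
write_config <- function(config, path) {
  # full double precision so numeric designs survive the round trip
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}
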