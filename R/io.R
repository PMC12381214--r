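#' Write a collection of force curves to TSV with a JSON sidecar
#'
#' Curves go into one long TSV (`curve_id`, `extension_nm`, `force_pN`);
#' acquisition metadata (pulling speed, spring constant, experiment) goes
#' into `<path>.json`. The round trip through [read_force_curves()] is
#' lossless.
#'
#' @param curves List of [force_curve()] objects (or one).
#' @param path Path of the TSV file to write.
#' @return `path`, invisibly.
#' @export
write_force_curves <- function(curves, path) {
  if (inherits(curves, "force_curve")) curves <- list(curves)
  tab <- do.call(rbind, lapply(curves, function(cv) data.frame(
    curve_id = cv$curve_id, extension_nm = cv$extension,
    force_pN = cv$force, stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- lapply(curves, function(cv) list(
    curve_id = cv$curve_id, experiment_id = cv$experiment_id,
    pulling_speed_nm_s = cv$pulling_speed,
    spring_constant_N_m = cv$spring_constant))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read force curves written by [write_force_curves()]
#'
#' @param path TSV path; the `<path>.json` sidecar must exist.
#' @return List of [force_curve()] objects (possibly empty, with a
#'   warning for an empty file). Non-numeric rows abort with the
#'   offending line number.
#' @export
read_force_curves <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty curve file: ", path)
    return(list())
  }
  for (col in c("extension_nm", "force_pN")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column %s at line %d of %s",
                   col, bad[1] + 1L, path))  # +1 for the header line
    raw[[col]] <- num
  }
  meta_by_id <- stats::setNames(meta, vapply(meta, `[[`, "", "curve_id"))
  lapply(split(raw, raw$curve_id), function(d) {
    m <- meta_by_id[[d$curve_id[1]]]
    if (is.null(m)) stop("no metadata for curve ", d$curve_id[1])
    force_curve(d$extension_nm, d$force_pN, m$pulling_speed_nm_s,
                m$spring_constant_N_m, m$curve_id, m$experiment_id)
  })
}

#' Write rupture or lifetime records as CSV
#'
#' Column names carry explicit unit suffixes; list columns (intermediate
#' increments) are serialised as semicolon-joined strings.
#'
#' @param records Data.frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  rec <- as.data.frame(records)
  for (col in names(rec)) {
    if (is.list(rec[[col]]))
      rec[[col]] <- vapply(rec[[col]], paste, "", collapse = ";")
  }
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a run configuration with provenance
#'
#' Collects arbitrary named parameters plus the master seed; the
#' configuration hash changes iff any parameter changes, and stochastic
#' outputs should embed (seed, hash) so a run can be reproduced exactly.
#'
#' @param ... Named parameters.
#' @param master_seed Integer master seed.
#' @return List of class `run_config` with a `provenance` block
#'   (package version, config hash, master seed).
#' @export
run_config <- function(..., master_seed = 1) {
  params <- list(...)
  if (length(params) && (is.null(names(params)) || any(names(params) == "")))
    stop("all configuration parameters must be named")
  cfg <- list(params = params, master_seed = master_seed)
  cfg$provenance <- list(
    package_version = as.character(utils::packageVersion("catchbond")),
    config_hash = config_hash(cfg),
    master_seed = master_seed
  )
  class(cfg) <- "run_config"
  cfg
}

#' Hash a configuration object
#'
#' 32-bit FNV-1a over the canonical (alphabetically sorted, fully
#' unboxed) JSON serialisation of the parameters and seed.
#'
#' @param cfg A `run_config` or plain list.
#' @return Hash as an 8-character hex string.
#' @export
config_hash <- function(cfg) {
  core <- if (inherits(cfg, "run_config") || !is.null(cfg$params))
    list(params = cfg$params, master_seed = cfg$master_seed) else cfg
  js <- as.character(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  bytes <- utf8ToInt(js)
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits; keep h in double
    # precision (it exceeds the signed 32-bit range bitwXor handles)
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # FNV prime 16777619, modulo 2^32; split the multiply so every
    # intermediate stays inside exact double-precision integer range
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a run configuration (with provenance) to JSON
#'
#' @param cfg A `run_config`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON, verifying its hash
#'
#' @param path JSON path.
#' @return A `run_config`; unknown top-level keys or a hash mismatch are
#'   hard errors.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(raw), c("params", "master_seed", "provenance"))
  if (length(extra))
    stop("unknown keys in config: ", paste(extra, collapse = ", "))
  cfg <- structure(raw, class = "run_config")
  if (!identical(config_hash(cfg), raw$provenance$config_hash))
    stop("config hash mismatch: file edited after writing?")
  cfg
}
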