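# Serialization: trajectories, record tables, run configurations.
# Text outputs carry a one-line JSON provenance header ("# provenance: ...")
# with the full parameter set, solver settings, seed and package version,
# so any result file can be traced back to the run that produced it.

.provenance <- function(params = NULL, config = NULL, dbs = NULL,
                        extra = list()) {
  prov <- c(list(package = "dbsnet",
                 version = as.character(utils::packageVersion("dbsnet"))),
            extra)
  if (!is.null(params))
    prov$params <- list(w = as.list(params$w), ext = params$ext,
                        tau_ms = as.list(params$tau_s * 1000),
                        sigmoid = unclass(params$sigmoid))
  if (!is.null(config)) {
    cf <- unclass(config)
    cf$initial_state <- if (is.null(cf$initial_state)) NULL else
      as.list(cf$initial_state)
    prov$config <- cf
  }
  if (!is.null(dbs)) prov$dbs <- unclass(dbs)
  jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA, null = "null")
}

# Full-precision numeric formatting so CSV round trips are exact.
.format_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write / read a trajectory as CSV
#'
#' Columns \code{time_s, Cx, Th, nRT, DCN, GPe, GPi, STN}; a commented
#' provenance header records parameters, solver settings and package
#' version.  \code{read_trajectory} returns a plain data frame (the
#' provenance JSON, if present, in attribute \code{"provenance"}).
#'
#' @param traj a \code{wc_trajectory}.
#' @param path output file.
#' @return \code{write_trajectory} returns \code{path} invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "wc_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ",
                    .provenance(traj$params, traj$config, traj$dbs)), con)
  df <- .format_df(as.data.frame(traj))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (startsWith(first, "# provenance: "))
    attr(df, "provenance") <-
      jsonlite::fromJSON(sub("^# provenance: ", "", first))
  df
}

#' Write / read sweep record tables
#'
#' \code{format = "csv"} writes a commented provenance header followed by
#' the table at full precision, so \code{read_records(write_records(x))}
#' reproduces the values exactly.  \code{format = "feather"} writes the
#' Arrow/Feather binary tabular format (requires the \code{arrow} package)
#' for large surveys.
#'
#' @param records a \code{sweep_records} data frame.
#' @param path output file.
#' @param format \code{"csv"} or \code{"feather"}.
#' @param seed optional seed recorded in the provenance header.
#' @return \code{write_records} returns \code{path} invisibly;
#'   \code{read_records} returns the records data frame.
#' @export
write_records <- function(records, path, format = c("csv", "feather"),
                          seed = NULL) {
  format <- match.arg(format)
  meta <- attr(records, "meta")
  prov_extra <- list(sweep_kind = attr(records, "sweep_kind"))
  if (!is.null(meta)) prov_extra$meta <- meta
  if (!is.null(seed)) prov_extra$seed <- seed
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for feather output",
           call. = FALSE)
    df <- as.data.frame(records)
    attr(df, "dbsnet_provenance") <- as.character(.provenance(extra = prov_extra))
    arrow::write_feather(df, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", .provenance(extra = prov_extra)), con)
  write.csv(.format_df(as.data.frame(records)), con,
            row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path, format = c("csv", "feather")) {
  format <- match.arg(format)
  if (format == "feather") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for feather input",
           call. = FALSE)
    df <- as.data.frame(arrow::read_feather(path))
  } else {
    first <- readLines(path, n = 1L)
    df <- read.csv(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
    # all-NA columns come back as logical; restore the schema types
    for (nm in c("dbs_amplitude", "dbs_frequency", "dominant_frequency",
                 "baseline_frequency"))
      if (nm %in% names(df)) df[[nm]] <- as.numeric(df[[nm]])
    if ("dbs_target" %in% names(df))
      df$dbs_target <- as.character(df$dbs_target)
    if (startsWith(first, "# provenance: ")) {
      prov <- jsonlite::fromJSON(sub("^# provenance: ", "", first))
      attr(df, "sweep_kind") <- prov$sweep_kind
      attr(df, "provenance") <- prov
    }
  }
  class(df) <- c("sweep_records", "data.frame")
  df
}

# Recognized configuration keys (nested blocks validated separately).
.CONFIG_KEYS <- list(
  top = c("preset", WEIGHT_NAMES, "ext", "tau_ms", "sigmoid", "simulation",
          "dbs", "spectral", "bands"),
  sigmoid = c("theta_e", "b_e", "theta_i", "b_i", "k_e", "k_i"),
  simulation = c("duration", "dt_output", "integrator", "rtol", "atol",
                 "hmax", "seed", "init_policy"),
  dbs = c("target", "amplitude", "frequency", "n_max", "onset", "waveform"),
  spectral = c("analysis_window", "n_segments", "overlap", "resolution",
               "min_freq", "peak_floor_factor", "subharmonic_ratio"),
  bands = c("tremor", "beta", "gamma"))

.check_keys <- function(x, block) {
  bad <- setdiff(names(x), .CONFIG_KEYS[[block]])
  if (length(bad))
    stop(sprintf("unknown %s key%s: %s",
                 if (block == "top") "configuration" else
                   paste0("'", block, "'"),
                 if (length(bad) > 1) "s" else "",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
}

#' Load a run configuration
#'
#' Reads a flat YAML or JSON configuration (dialect chosen by file
#' extension) and resolves it into validated package objects.  A
#' \code{preset} key seeds the parameter set; individual keys
#' \code{w1..w11}, \code{ext}, \code{tau_ms} and a \code{sigmoid} block
#' override it.  Optional blocks \code{simulation}, \code{dbs},
#' \code{spectral} and \code{bands} map onto \code{\link{sim_config}},
#' \code{\link{dbs_spec}}, \code{\link{spectral_settings}} and
#' \code{\link{band_table}}.  Unknown keys are rejected by name; weights
#' must be non-negative magnitudes (signed weights are refused by
#' \code{\link{wc_params}}).
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return A list with elements \code{params}, \code{sim}, \code{dbs}
#'   (possibly \code{NULL}), \code{spectral} and \code{bands}.
#' @examples
#' cfg <- load_config(system.file("extdata", "example-config.yaml",
#'                                package = "dbsnet"))
#' cfg$params$w[["w7"]]  # preset value overridden to 22
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
             error = function(e)
               stop("malformed JSON in ", path, ": ", conditionMessage(e),
                    call. = FALSE))
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e)
               stop("malformed YAML in ", path, ": ", conditionMessage(e),
                    call. = FALSE))
  }
  if (!is.list(raw)) stop("configuration must be a key-value mapping",
                          call. = FALSE)
  .check_keys(raw, "top")

  base <- if (!is.null(raw$preset)) wc_preset(raw$preset) else NULL
  w <- if (is.null(base)) setNames(rep(NA_real_, 11), WEIGHT_NAMES) else
    base$w
  for (nm in WEIGHT_NAMES)
    if (!is.null(raw[[nm]])) w[[nm]] <- as.numeric(raw[[nm]])
  if (anyNA(w))
    stop("incomplete parameter set: provide a 'preset' or all of w1..w11",
         call. = FALSE)
  ext <- if (!is.null(raw$ext)) as.numeric(raw$ext) else
    if (!is.null(base)) base$ext else
      stop("missing 'ext' (and no preset given)", call. = FALSE)
  tau_ms <- if (!is.null(raw$tau_ms)) as.numeric(raw$tau_ms) else
    if (!is.null(base)) base$tau_s * 1000 else 10
  sigmoid <- if (!is.null(raw$sigmoid)) {
    .check_keys(raw$sigmoid, "sigmoid")
    do.call(sigmoid_params, raw$sigmoid)
  } else sigmoid_params()
  params <- wc_params(w, ext, tau_ms = tau_ms, sigmoid = sigmoid)

  sim <- if (!is.null(raw$simulation)) {
    .check_keys(raw$simulation, "simulation")
    do.call(sim_config, raw$simulation)
  } else sim_config()

  dbs <- if (!is.null(raw$dbs)) {
    .check_keys(raw$dbs, "dbs")
    do.call(dbs_spec, raw$dbs)
  } else NULL

  spectral <- if (!is.null(raw$spectral)) {
    .check_keys(raw$spectral, "spectral")
    do.call(spectral_settings, raw$spectral)
  } else spectral_settings()

  bands <- if (!is.null(raw$bands)) {
    .check_keys(raw$bands, "bands")
    do.call(band_table, raw$bands)
  } else band_table()

  list(params = params, sim = sim, dbs = dbs, spectral = spectral,
       bands = bands)
}

#' Write a resolved run configuration
#'
#' Serializes a configuration list (as returned by \code{\link{load_config}},
#' or assembled from package objects) back to YAML or JSON, such that
#' \code{load_config(write_config(cfg, path))} resolves to the same
#' objects.
#'
#' @param cfg list with elements \code{params} (required), and optionally
#'   \code{sim}, \code{dbs}, \code{spectral}, \code{bands}.
#' @param path output file (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg$params, "wc_params"))
  out <- c(as.list(cfg$params$w),
           list(ext = cfg$params$ext,
                tau_ms = unname(cfg$params$tau_s * 1000),
                sigmoid = unclass(cfg$params$sigmoid)))
  if (!is.null(cfg$sim)) {
    s <- unclass(cfg$sim)
    s$initial_state <- NULL  # reconstructed from policy + seed
    out$simulation <- s[!vapply(s, is.null, logical(1))]
  }
  if (!is.null(cfg$dbs)) out$dbs <- unclass(cfg$dbs)
  if (!is.null(cfg$spectral)) out$spectral <- unclass(cfg$spectral)
  if (!is.null(cfg$bands)) out$bands <- cfg$bands
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a PSD as CSV
#'
#' @param psd a \code{\link{power_spectrum}} result, or a named list of
#'   them (one per population) as stored in a spectral summary.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_psd <- function(psd, path) {
  if (inherits(psd, "wc_psd")) psd <- list(power = psd)
  stopifnot(all(vapply(psd, inherits, logical(1), "wc_psd")))
  df <- data.frame(frequency_hz = psd[[1]]$freq)
  for (nm in names(psd)) df[[nm]] <- psd[[nm]]$power
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", .provenance()), con)
  write.csv(.format_df(df), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
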