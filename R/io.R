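SESSION_SCHEMA_VERSION <- "1.0"

# FNV-1a hash of a character scalar, reported as 8 hex digits; used to
# stamp every result table with the configuration that produced it
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  # 32-bit arithmetic carried in doubles, split into 16-bit halves: both
  # bitwXor and plain multiplication break past the integer range
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Hash an experiment configuration
#'
#' Deterministic 8-hex-digit digest of the JSON serialization of any
#' configuration list; recorded in report bundles so every table can be
#' traced to the run that produced it.
#'
#' @param config Any serializable list.
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  fnv1a_hash(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)))
}

session_table <- function(session, session_id = "session1") {
  cbind(data.frame(session_id = session_id), session$samples,
        as.data.frame(session$counts))
}

#' Save / load a synthetic session
#'
#' A session round-trips through two plain-text files in `dir`:
#' `samples.tsv` (one row per sample: session id, trial id, time,
#' condition, all kinematic/force/muscle covariates, then one integer
#' column per neuron) and `meta.json` (schema version, config, geometry,
#' ground-truth neurons, events, seed). Counts reload identically;
#' floating-point signals reload to within 1e-12 relative error.
#'
#' @param session A `synthetic_session`.
#' @param dir Output directory (created if needed).
#' @param session_id Identifier written into the table.
#' @return `dir`, invisibly.
#' @export
save_session <- function(session, dir, session_id = "session1") {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- session_table(session, session_id)
  utils::write.table(format(tab, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     file.path(dir, "samples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    task = session$task,
    session_id = session_id,
    rng_seed = session$rng_seed,
    sim_dt = session$sim_dt,
    n_neurons = ncol(session$counts),
    neuron_ids = colnames(session$counts),
    config = unclass(session$config),
    geometry = unclass(session$geometry),
    neurons = lapply(session$neurons, unclass),
    events = session$events)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' @rdname save_session
#' @export
load_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  tab_path <- file.path(dir, "samples.tsv")
  if (!file.exists(meta_path) || !file.exists(tab_path)) {
    stop_invalid("no saved session at '%s'", dir)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  if (!identical(meta$schema_version, SESSION_SCHEMA_VERSION)) {
    stop_invalid("session schema version mismatch: file '%s' vs supported '%s'",
                 meta$schema_version %||% "?", SESSION_SCHEMA_VERSION)
  }
  tab <- utils::read.table(tab_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("session_id", "trial_id", "t", "condition",
                unlist(kinematic_cols, use.names = FALSE))
  missing <- setdiff(required, colnames(tab))
  if (length(missing)) {
    stop_invalid("session table missing column(s): %s",
                 paste(missing, collapse = ", "))
  }
  neuron_ids <- meta$neuron_ids
  counts <- as.matrix(tab[, neuron_ids, drop = FALSE])
  storage.mode(counts) <- "integer"
  samples <- tab[, setdiff(colnames(tab), c("session_id", neuron_ids))]
  neurons <- lapply(meta$neurons, function(n) {
    ground_truth_neuron(n$neuron_id, n$covariate_set, n$intercept,
                        n$coefficients %||% numeric(0),
                        n$active_gain, n$passive_gain)
  })
  geometry <- arm_geometry(meta$geometry$upper_arm_length,
                           meta$geometry$forearm_length,
                           meta$geometry$shoulder_origin,
                           meta$geometry$elbow_bend_sign)
  cfg <- meta$config
  cfg$workspaces <- lapply(cfg$workspaces, function(w) {
    list(center = as.numeric(w$center), side = w$side)
  })
  config <- do.call(task_config, cfg)
  events <- do.call(rbind, lapply(meta$events, function(e) {
    as.data.frame(lapply(e, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  structure(
    list(samples = samples, counts = counts,
         events = events, neurons = neurons,
         geometry = geometry, config = config, sim_dt = meta$sim_dt,
         rng_seed = meta$rng_seed, task = meta$task),
    class = "synthetic_session")
}

#' Save / load a report bundle
#'
#' Each result table of the bundle is written as one TSV under `dir`;
#' run metadata (seed, config hash, package version) goes to
#' `report_meta.json`. Tables reload to identical values.
#'
#' @param bundle A `report_bundle` from an experiment runner.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables)) {
    utils::write.table(format(bundle$tables[[nm]], digits = 17,
                              scientific = FALSE, trim = TRUE),
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(bundle$meta, file.path(dir, "report_meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname save_report
#' @export
load_report <- function(dir) {
  meta_path <- file.path(dir, "report_meta.json")
  if (!file.exists(meta_path)) stop_invalid("no report at '%s'", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tables <- lapply(files, utils::read.table, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(tables) <- sub("\\.tsv$", "", basename(files))
  structure(list(tables = tables, meta = meta), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Report bundle (%s, config %s): %s\n",
              x$meta$experiment %||% "experiment",
              x$meta$config_hash %||% "?",
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}
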