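#' Read and write expression time-course TSV files
#'
#' The on-disk format is a TSV with a `gene_id` column followed by one
#' column per sample named `ZT<t>_rep<k>` (e.g. `ZT4_rep1`). Writing then
#' reading a [timecourse] reproduces it exactly. CSV input is accepted on
#' read (detected from the extension).
#'
#' @param path file path.
#' @return `read_timecourse` returns a [timecourse];
#'   `write_timecourse` returns `path` invisibly.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no data rows in ", path)
  if (names(df)[1] != "gene_id")
    stop("malformed header: first column must be 'gene_id', found '", names(df)[1], "'")
  sample_cols <- names(df)[-1]
  ok <- grepl("^ZT[0-9]+(\\.[0-9]+)?_rep[0-9]+$", sample_cols)
  if (any(!ok))
    stop("malformed sample column name(s): ",
         paste(sample_cols[!ok], collapse = ", "),
         " (expected ZT<t>_rep<k>)")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad[1] + 1]]))))[1]
    stop("non-numeric value in column '", sample_cols[bad[1]],
         "', row ", badrow)
  }
  zt <- as.numeric(sub("^ZT([0-9.]+)_rep[0-9]+$", "\\1", sample_cols))
  rep_idx <- as.integer(sub("^ZT[0-9.]+_rep([0-9]+)$", "\\1", sample_cols))
  rownames(vals) <- df$gene_id
  timecourse(vals, sample_zt = zt, replicate_index = rep_idx,
             gene_ids = df$gene_id)
}

#' @rdname read_timecourse
#' @param x a [timecourse].
#' @export
write_timecourse <- function(x, path) {
  stopifnot(inherits(x, "timecourse"))
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write luminescence trace TSV files
#'
#' Two columns: `t_h` (hours since synchronization) and `counts`.
#'
#' @param path file path.
#' @return `read_trace` returns a [luminescence_trace];
#'   `write_trace` returns `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("t_h", "counts") %in% names(df)))
    stop("trace file needs columns t_h and counts")
  luminescence_trace(df$t_h, df$counts)
}

#' @rdname read_trace
#' @param trace a [luminescence_trace].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "luminescence_trace"))
  utils::write.table(data.frame(t_h = trace$t, counts = trace$counts),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write void-event TSV files
#'
#' Events carry either a time stamp (`t_h`) and `volume_ul`, or the raw
#' aVSOP measurements `position_cm` and `area_cm2` (convert with
#' [stain_to_event()]). Optional columns (`subject`, `day`, ...) pass
#' through. The recording-start ZT is stored in a `# start_zt=` comment
#' line so a round trip preserves the time origin.
#'
#' @param path file path.
#' @return `read_void_events` returns the events data frame with attribute
#'   `start_zt`; `write_void_events` returns `path` invisibly.
#' @export
read_void_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  first <- readLines(path, n = 1)
  start_zt <- NULL
  if (grepl("^#\\s*start_zt=", first))
    start_zt <- as.numeric(sub("^#\\s*start_zt=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!("t_h" %in% names(df) || "position_cm" %in% names(df)))
    stop("void-event file needs a t_h or position_cm column")
  if (!is.null(start_zt)) attr(df, "start_zt") <- start_zt
  df
}

#' @rdname read_void_events
#' @param events data frame of events (attribute `start_zt` honored).
#' @export
write_void_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  start_zt <- attr(events, "start_zt")
  if (!is.null(start_zt)) writeLines(paste0("# start_zt=", start_zt), con)
  utils::write.table(as.data.frame(events), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# nested list of recognized configuration keys and their defaults
default_run_config <- function() {
  list(seed = NULL,
       rhythm = list(maxcorr_min = 0.85, fold_min = 1.5, period_h = 24),
       trace = list(window_h = 24, min_separation_h = 18,
                    transient_exclude_h = 12),
       micturition = list(paper_speed_cm_h = 10, reference_bin = "ZT6",
                          bin_centers = c(14, 22, 6), bin_half_width_h = 4),
       stats = list(posthoc = "sidak", alpha = 0.05),
       input = NULL, output = NULL)
}

#' Read a run configuration (YAML or JSON)
#'
#' Loads analysis settings, fills unset keys from the package defaults, and
#' rejects unknown keys outright — a misspelled threshold should fail loudly
#' rather than silently fall back to a default.
#'
#' @param path YAML file path (JSON is a subset of YAML and also parses), or
#'   `NULL` for the pure defaults.
#' @return A nested named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  merge_checked <- function(def, usr, prefix = "") {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown) > 0)
      stop("unknown config key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    for (k in names(usr)) {
      if (is.list(def[[k]]) && is.list(usr[[k]])) {
        def[[k]] <- merge_checked(def[[k]], usr[[k]], paste0(prefix, k, "."))
      } else {
        def[[k]] <- usr[[k]]
      }
    }
    def
  }
  merge_checked(defaults, user)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package version next to a run's
#' outputs so any deterministic stage can be reproduced bit for bit.
#'
#' @param config configuration list (as from [read_run_config()]).
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(
    package = "bladderclock",
    version = as.character(utils::packageVersion("bladderclock")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
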