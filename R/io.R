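fmt12 <- function(x) formatC(x, digits = 12, format = "g")

#' Write time-course data as tidy TSV
#'
#' Long format, one row per (time, band, replicate): columns `time_s`,
#' `band_length`, `fraction`, `condition`, `replicate`. Long format is
#' preferred over wide because band sets vary across assays (7/10-mer
#' stability lanes vs 10–19-mer elongation lanes). Numbers carry 12
#' significant digits, so a write/read round trip is exact to ~1e-12.
#'
#' @param x a `replicate_set` or single `observed_timecourse`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse_table <- function(x, path) {
  if (inherits(x, "observed_timecourse")) x <- list(replicates = list(x))
  rows <- do.call(rbind, lapply(x$replicates, function(otc) {
    lens <- as.integer(rownames(otc$bands))
    data.frame(time_s = rep(otc$times, each = length(lens)),
               band_length = rep(lens, length(otc$times)),
               fraction = as.numeric(otc$bands),
               condition = otc$condition,
               replicate = otc$replicate)
  }))
  out <- data.frame(time_s = fmt12(rows$time_s),
                    band_length = rows$band_length,
                    fraction = fmt12(rows$fraction),
                    condition = rows$condition,
                    replicate = rows$replicate)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tidy time-course TSV into a replicate set
#'
#' Validates the schema at load: required columns, band lengths within
#' 7–19, fractions within \[0, 1\] (offending row numbers are reported),
#' nonnegative times, uniqueness of (time, band, condition, replicate), and
#' a shared time grid and band set across replicates.
#'
#' @param path TSV file written by [write_timecourse_table()] or of the same
#'   dialect.
#' @param tol_sum tolerance on per-time band-fraction totals above 1
#'   (noisy experimental fractions need not sum below 1 exactly).
#' @return a `replicate_set` (scenario field `NULL` for external data).
#' @export
read_timecourse_table <- function(path, tol_sum = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("time_s", "band_length", "fraction", "condition", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(df$fraction < 0 | df$fraction > 1)
  if (length(bad)) {
    stop("validation error: fraction outside [0, 1] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(df$time_s < 0)) {
    stop("validation error: negative time_s", call. = FALSE)
  }
  if (!all(df$band_length %in% 7:19)) {
    stop("validation error: band_length outside 7..19", call. = FALSE)
  }
  key <- paste(df$time_s, df$band_length, df$condition, df$replicate)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("validation error: duplicate (time, band, condition, replicate) at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }

  reps <- split(df, list(df$condition, df$replicate), drop = TRUE)
  grids <- lapply(reps, function(g) sort(unique(g$time_s)))
  bandsets <- lapply(reps, function(g) sort(unique(g$band_length)))
  if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1L ||
      length(unique(vapply(bandsets, paste, "", collapse = ","))) != 1L) {
    stop("validation error: replicates must share time grid and band set",
         call. = FALSE)
  }
  times <- grids[[1]]
  lens <- bandsets[[1]]
  replicates <- lapply(reps, function(g) {
    bands <- matrix(NA_real_, length(lens), length(times),
                    dimnames = list(as.character(lens), NULL))
    bands[cbind(match(g$band_length, lens), match(g$time_s, times))] <-
      g$fraction
    if (anyNA(bands)) {
      stop("validation error: incomplete band grid for condition ",
           g$condition[1], " replicate ", g$replicate[1], call. = FALSE)
    }
    new_observed_timecourse(times, bands, g$condition[1],
                            as.integer(g$replicate[1]), tol_sum = tol_sum)
  })
  names(replicates) <- NULL
  structure(list(replicates = replicates, scenario = NULL, seed = NA),
            class = "replicate_set")
}

#' Read stability-lane TSV
#'
#' Long format with columns `time_s`, `band` (7 or 10), `signal`,
#' `condition`, `replicate`, as consumed by [analyze_stability()].
#'
#' @param path TSV file path.
#' @return validated data frame of lanes.
#' @export
read_stability_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("time_s", "band", "signal", "condition", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$band %in% c(7, 10))) {
    stop("validation error: band must be 7 or 10", call. = FALSE)
  }
  if (any(df$signal < 0)) {
    stop("validation error: negative signal", call. = FALSE)
  }
  df
}

#' Write stability lanes as tidy TSV
#'
#' @param lanes data frame from [simulate_stability()] or of the same shape.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stability_table <- function(lanes, path) {
  out <- lanes
  out$time_s <- fmt12(out$time_s)
  out$signal <- fmt12(out$signal)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

serialize_result <- function(obj) {
  if (inherits(obj, "aggregated_fit")) {
    list(type = "aggregated_fit", scheme_id = obj$scheme_id, n = obj$n,
         mean = as.list(obj$mean), sd = as.list(obj$sd),
         replicate_ssr = vapply(obj$fits, `[[`, 0, "ssr"))
  } else if (inherits(obj, "fit_result")) {
    list(type = "fit_result", scheme_id = obj$scheme_id,
         params = as.list(obj$params), ssr = obj$ssr,
         n_obs = obj$n_obs, n_params = obj$n_params,
         convergence = obj$convergence)
  } else if (inherits(obj, "model_comparison")) {
    list(type = "model_comparison",
         aicc = as.list(obj$aicc), delta_aicc = as.list(obj$delta_aicc),
         preferred = obj$preferred, tie = obj$tie,
         ssr = lapply(obj$fits, `[[`, "ssr"))
  } else if (inherits(obj, "kinetic_summary")) {
    c(list(type = "kinetic_summary"), unclass(obj))
  } else if (inherits(obj, "stability_analysis")) {
    list(type = "stability_analysis",
         max_abs_diff = obj$contrast$max_abs_diff,
         unaffected = obj$contrast$unaffected)
  } else NULL
}

#' Write analysis results and a run manifest to a directory
#'
#' Dispatches on object class: fits, comparisons and summaries go to JSON;
#' `replicate_set`/`observed_timecourse` objects and stability lane tables
#' go to tidy TSV. A `manifest.json` records the written files, a config
#' hash, the seed and package version. Payload files are byte-identical
#' across re-runs with identical inputs (only the manifest carries a
#' timestamp).
#'
#' @param objects named list of result objects.
#' @param out_dir output directory (created if needed).
#' @param config optional [fit_config()] recorded (hashed) in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return invisible character vector of written file paths (the manifest
#'   last); an empty object list writes nothing and returns an empty
#'   manifest.
#' @export
write_results <- function(objects, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(objects))
  if (length(objects) && (is.null(names(objects)) ||
                          any(!nzchar(names(objects))))) {
    stop("objects must be named", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  written <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    js <- serialize_result(obj)
    if (!is.null(js)) {
      p <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(js, p, auto_unbox = TRUE, digits = 12,
                           pretty = TRUE, na = "null")
      written <- c(written, p)
    } else if (inherits(obj, "replicate_set") ||
               inherits(obj, "observed_timecourse")) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write_timecourse_table(obj, p)
      written <- c(written, p)
    } else if (is.data.frame(obj) && all(c("band", "signal") %in% names(obj))) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write_stability_table(obj, p)
      written <- c(written, p)
    } else {
      stop("don't know how to serialize object '", nm, "' of class ",
           paste(class(obj), collapse = "/"), call. = FALSE)
    }
  }
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile()
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  manifest <- list(
    files = as.list(basename(written)),
    config_md5 = cfg_hash,
    seed = seed,
    package_version = as.character(utils::packageVersion("polkin")),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(c(written, mp))
}
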