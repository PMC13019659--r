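# On-disk path archive: one subdirectory per archived path holding a
# plain-text trajectory plus a JSON sidecar, and JSONL event logs.

ARCHIVE_SCHEMA <- "poretis-archive-v1"

#' Write a path archive to a directory tree
#'
#' Each archived path gets a subdirectory `path_<k>` with
#' `trajectory.csv` (frame columns plus the order-parameter series, with
#' a schema-versioned header comment) and `path.json` (ensemble, cycle,
#' weight, status, order-parameter extrema, length, duration,
#' generation).  An `archive.json` index records the schema and the
#' interface set.
#'
#' @param archive `path_archive` from [run_sampler()] (run with
#'   `store_lambdas = TRUE`; frames are written when present).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_archive <- function(archive, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(schema = ARCHIVE_SCHEMA,
         interfaces = archive$interfaces$lambdas,
         timestep = archive$timestep,
         n_paths = length(archive$records)),
    file.path(dir, "archive.json"), auto_unbox = TRUE, digits = NA)
  for (k in seq_along(archive$records)) {
    rec <- archive$records[[k]]
    sub <- file.path(dir, sprintf("path_%06d", k))
    dir.create(sub, showWarnings = FALSE)
    jsonlite::write_json(
      list(schema = ARCHIVE_SCHEMA, ensemble = rec$ensemble,
           cycle = rec$cycle, weight = rec$weight, status = rec$status,
           lmax = rec$lmax, lmin = rec$lmin, n_frames = rec$n_frames,
           duration = rec$duration, generation = rec$generation),
      file.path(sub, "path.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(rec$lambdas)) {
      df <- data.frame(lambda = rec$lambdas)
      if (!is.null(rec$frames) && is.matrix(rec$frames)) {
        fr <- as.data.frame(rec$frames)
        names(fr) <- paste0("q", seq_len(ncol(fr)))
        df <- cbind(fr, df)
      }
      con <- file(file.path(sub, "trajectory.csv"), "w")
      writeLines(paste0("# ", ARCHIVE_SCHEMA), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
  }
  invisible(dir)
}

#' Read a path archive from a directory tree
#'
#' @param dir directory written by [write_archive()].
#' @return A `path_archive`.
#' @export
read_archive <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "archive.json"),
                             simplifyVector = TRUE)
  if (!identical(idx$schema, ARCHIVE_SCHEMA))
    stop("unrecognised archive schema: ", idx$schema)
  subs <- sort(list.dirs(dir, recursive = FALSE))
  records <- vector("list", length(subs))
  for (k in seq_along(subs)) {
    meta <- jsonlite::read_json(file.path(subs[k], "path.json"),
                                simplifyVector = TRUE)
    rec <- list(ensemble = meta$ensemble, cycle = meta$cycle,
                weight = meta$weight, status = meta$status,
                lmax = meta$lmax, lmin = meta$lmin,
                n_frames = meta$n_frames, duration = meta$duration,
                generation = meta$generation, lambdas = NULL,
                frames = NULL)
    traj <- file.path(subs[k], "trajectory.csv")
    if (file.exists(traj)) {
      df <- utils::read.csv(traj, comment.char = "#")
      rec$lambdas <- df$lambda
      qc <- grep("^q", names(df))
      if (length(qc) > 0) rec$frames <- as.matrix(df[, qc, drop = FALSE])
    }
    records[[k]] <- rec
  }
  structure(list(records = records,
                 interfaces = interface_set(idx$interfaces),
                 timestep = idx$timestep),
            class = "path_archive")
}

#' Write / read a JSONL event log
#'
#' One JSON object per line; used for the move log and the
#' initialisation rounds log.
#'
#' @param df data.frame (or list of records).
#' @param path file path.
#' @return `path` / a data.frame.
#' @export
write_jsonl <- function(df, path) {
  if (is.data.frame(df))
    df <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  con <- file(path, "w")
  for (rec in df)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  close(con)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write CV records as tidy CSV
#'
#' @param cv_records data.frame from [cv_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(cv_records, path) {
  con <- file(path, "w")
  writeLines("# poretis-cv-v1", con)
  utils::write.csv(cv_records, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_cv_csv
#' @export
read_cv_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
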