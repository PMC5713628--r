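# Filename-metadata parsing, parallel per-image execution with temp-file
# results, aggregation into an SQLite store, and tabular export.
#
# Concurrency model: each image is processed in its own process with no
# shared mutable state; workers write one JSON temp file per image and the
# SQLite file is touched only by the single aggregator process after all
# image processing is complete.

#' Restricted metadata vocabulary
#'
#' The terms a filename template may use. Extensible: pass additional
#' terms via `extra` when building a template.
#' @export
metadata_vocabulary <- c("plantbarcode", "timestamp", "measurementlabel",
                         "camera", "imgtype", "zoom", "lifter", "gain",
                         "exposure", "frame", "id", "other")

#' Build a filename-metadata template
#'
#' @param terms character vector of vocabulary terms, in filename order;
#'   `"other"` may repeat, all other terms must be unique
#' @param delimiter nonempty field delimiter (default `"_"`)
#' @param timestamp_format `strptime` format for the `timestamp` field
#' @param extra additional vocabulary terms allowed beyond the builtin set
#' @return a `metadata_template`
#' @export
metadata_template <- function(terms, delimiter = "_",
                              timestamp_format = "%Y-%m-%d",
                              extra = character()) {
  vocab <- c(metadata_vocabulary, extra)
  bad <- setdiff(terms, vocab)
  if (length(bad)) stop("unknown metadata term(s): ", paste(bad, collapse = ", "))
  dup <- terms[duplicated(terms) & terms != "other"]
  if (length(dup)) stop("duplicated metadata term(s): ", paste(unique(dup), collapse = ", "))
  if (!nzchar(delimiter)) stop("delimiter must be nonempty")
  structure(list(terms = terms, delimiter = delimiter,
                 timestamp_format = timestamp_format),
            class = "metadata_template")
}

#' Parse filename metadata against a template
#'
#' Splits the filename (extension stripped) on the template delimiter and
#' maps fields to terms positionally; the timestamp field is validated
#' against the template's format. A field-count mismatch is a skip signal:
#' the function warns and returns `NULL`, and the pipeline runner counts
#' the file as skipped.
#'
#' @param filename file name or path
#' @param template a `metadata_template`
#' @return named list term -> value, or `NULL` on mismatch
#' @export
parse_filename <- function(filename, template) {
  stopifnot(inherits(template, "metadata_template"))
  stem <- tools::file_path_sans_ext(basename(filename))
  fields <- strsplit(stem, template$delimiter, fixed = TRUE)[[1]]
  if (length(fields) != length(template$terms)) {
    warning(sprintf("filename '%s' has %d field(s) but the template expects %d; skipping",
                    basename(filename), length(fields), length(template$terms)))
    return(NULL)
  }
  meta <- as.list(fields)
  names(meta) <- template$terms
  if ("timestamp" %in% template$terms) {
    ts <- strptime(meta$timestamp, template$timestamp_format, tz = "UTC")
    if (is.na(ts)) {
      warning(sprintf("filename '%s': timestamp '%s' does not match format '%s'; skipping",
                      basename(filename), meta$timestamp, template$timestamp_format))
      return(NULL)
    }
    meta$timestamp <- format(ts, "%Y-%m-%d %H:%M:%S")
  }
  meta
}

# One image's work unit: run the user pipeline, write a JSON temp file.
process_one_image <- function(path, pipeline_fun, meta, tmp_dir) {
  out <- file.path(tmp_dir, paste0(basename(path), ".json"))
  rec <- tryCatch({
    feats <- pipeline_fun(path)
    if (is.null(names(feats)) || anyNA(suppressWarnings(as.numeric(feats))))
      stop("pipeline must return a named numeric vector of features")
    list(image = path, status = "ok", metadata = meta,
         features = as.list(as.numeric(feats)) |> stats::setNames(names(feats)))
  }, error = function(e) {
    list(image = path, status = "failed", metadata = meta,
         error = conditionMessage(e))
  })
  jsonlite::write_json(rec, out, auto_unbox = TRUE, digits = NA, null = "null")
  out
}

#' Run a single-image pipeline over a directory in parallel
#'
#' Every image whose filename parses against the template is processed
#' independently (one process per task, no shared state): the pipeline
#' function reads one image path and returns one named numeric feature
#' vector, which is written to a per-image temp file. Only after all
#' images complete are the temp files aggregated into the SQLite store, so
#' database content is identical for any worker count. A failing image is
#' recorded as failed and the run continues.
#'
#' @param pipeline a function `(image_path) -> named numeric vector`, or
#'   the path of an R script that defines a function named `pipeline`
#' @param image_dir directory of input images (png/tif/tiff/jpg/jpeg)
#' @param template a `metadata_template` for the filenames
#' @param n_workers parallel worker processes (default 1)
#' @param db path of the SQLite results database (created or appended)
#' @return run summary: `processed`, `skipped`, `failed` counts, `run_id`,
#'   and `db`
#' @export
run_parallel <- function(pipeline, image_dir, template, n_workers = 1, db) {
  stopifnot(inherits(template, "metadata_template"))
  if (is.character(pipeline)) {
    script <- pipeline
    if (!file.exists(script)) stop("pipeline script not found: ", script)
    env <- new.env(parent = globalenv())
    sys.source(script, envir = env)
    if (!is.function(env$pipeline))
      stop("pipeline script must define a function named 'pipeline'")
    pipeline_fun <- env$pipeline
  } else {
    pipeline_fun <- match.fun(pipeline)
  }
  files <- list.files(image_dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  metas <- lapply(files, function(f)
    withCallingHandlers(parse_filename(f, template),
                        warning = function(w) invokeRestart("muffleWarning")))
  ok <- !vapply(metas, is.null, logical(1))
  skipped <- sum(!ok)
  files <- files[ok]; metas <- metas[ok]
  tmp_dir <- tempfile("phenokit_run_")
  dir.create(tmp_dir)
  on.exit(unlink(tmp_dir, recursive = TRUE), add = TRUE)
  worker <- function(i) process_one_image(files[i], pipeline_fun, metas[[i]], tmp_dir)
  tmp_files <- if (n_workers > 1 && .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(seq_along(files), worker, mc.cores = n_workers))
  } else {
    vapply(seq_along(files), worker, character(1))
  }
  agg <- aggregate_results(tmp_files, db,
                           pipeline_name = if (is.character(pipeline)) pipeline else "function",
                           template_str = paste(template$terms, collapse = template$delimiter))
  list(processed = agg$processed, skipped = skipped, failed = agg$failed,
       run_id = agg$run_id, db = db)
}

db_init <- function(con) {
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS runinfo (
      run_id INTEGER PRIMARY KEY, run_at TEXT, pipeline TEXT, template TEXT)")
  DBI::dbExecute(con, paste0(
    "CREATE TABLE IF NOT EXISTS metadata (
      run_id INTEGER, image_id INTEGER, image TEXT, ",
    paste(metadata_vocabulary, "TEXT", collapse = ", "), ")"))
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS features (
      run_id INTEGER, image_id INTEGER, trait TEXT, value REAL)")
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS failures (
      run_id INTEGER, image TEXT, error TEXT)")
}

#' Aggregate per-image temp files into the SQLite store
#'
#' Appends one metadata row per successfully processed image and one
#' features row per (image, trait) pair under a fresh run id; prior runs'
#' rows are never touched. The single fixed three-table schema (runinfo,
#' metadata, features) holds any camera system — unknown metadata terms
#' simply stay empty.
#'
#' @param temp_files character vector of per-image JSON result files
#' @param db SQLite database path
#' @param pipeline_name,template_str recorded in `runinfo`
#' @return list with `run_id`, `processed`, `failed`
#' @export
aggregate_results <- function(temp_files, db, pipeline_name = "", template_str = "") {
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  db_init(con)
  run_id <- (DBI::dbGetQuery(con, "SELECT COALESCE(MAX(run_id), 0) AS m FROM runinfo")$m) + 1L
  DBI::dbExecute(con,
    "INSERT INTO runinfo VALUES (:r, :t, :p, :tp)",
    params = list(r = run_id, t = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  p = pipeline_name, tp = template_str))
  processed <- 0L; failed <- 0L; image_id <- 0L
  for (tf in sort(temp_files)) {
    rec <- tryCatch(jsonlite::read_json(tf), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$status)) {
      failed <- failed + 1L
      DBI::dbExecute(con, "INSERT INTO failures VALUES (:r, :i, :e)",
                     params = list(r = run_id, i = tf, e = "malformed result file"))
      next
    }
    if (!identical(rec$status, "ok")) {
      failed <- failed + 1L
      DBI::dbExecute(con, "INSERT INTO failures VALUES (:r, :i, :e)",
                     params = list(r = run_id, i = rec$image,
                                   e = rec$error %||% "unknown error"))
      next
    }
    processed <- processed + 1L
    image_id <- image_id + 1L
    meta <- rec$metadata
    vals <- vapply(metadata_vocabulary, function(t)
      as.character(meta[[t]] %||% ""), character(1))
    DBI::dbExecute(con, paste0(
      "INSERT INTO metadata VALUES (", paste(rep("?", 3 + length(vals)), collapse = ","), ")"),
      params = c(list(run_id, image_id, rec$image), as.list(unname(vals))))
    for (trait in names(rec$features)) {
      DBI::dbExecute(con, "INSERT INTO features VALUES (:r, :i, :t, :v)",
                     params = list(r = run_id, i = image_id, t = trait,
                                   v = as.numeric(rec$features[[trait]])))
    }
  }
  list(run_id = run_id, processed = processed, failed = failed)
}

#' Export the results database to a tab-delimited table
#'
#' Wide format, one row per image: image path, the metadata columns, then
#' one column per trait (alphabetical). Traits an image lacks are left
#' empty. The export is deterministic: re-exporting an unchanged database
#' is byte-identical.
#'
#' @param db SQLite database path
#' @param out output TSV path
#' @param run_id restrict to one run (default: all runs)
#' @return `out`, invisibly
#' @export
export_table <- function(db, out, run_id = NULL) {
  if (!file.exists(db)) stop("database not found: ", db)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  db_init(con)
  where <- if (is.null(run_id)) "" else sprintf(" WHERE run_id = %d", as.integer(run_id))
  meta <- DBI::dbGetQuery(con, paste0("SELECT * FROM metadata", where,
                                      " ORDER BY run_id, image_id"))
  feats <- DBI::dbGetQuery(con, paste0("SELECT * FROM features", where))
  traits <- sort(unique(feats$trait))
  for (tr in traits) {
    col <- rep("", nrow(meta))
    sub <- feats[feats$trait == tr, ]
    key_meta <- paste(meta$run_id, meta$image_id)
    key_sub <- paste(sub$run_id, sub$image_id)
    hit <- match(key_meta, key_sub)
    col[!is.na(hit)] <- vapply(sub$value[hit[!is.na(hit)]], function(v)
      format(v, digits = 15, trim = TRUE, scientific = FALSE), character(1))
    meta[[tr]] <- col
  }
  utils::write.table(meta, out, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(out)
}
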