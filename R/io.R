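# XYZ, JSON-lines event store, and run-manifest I/O.

write_xyz_frame <- function(coords, tags, comment, path, append) {
  n <- nrow(coords)
  lines <- c(as.character(n), comment,
             sprintf("%s %.6f %.6f %.6f", tags, coords[, 1], coords[, 2],
                     coords[, 3]))
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a multi-frame XYZ trajectory
#'
#' Standard XYZ blocks (atom count, comment line carrying the time stamp in
#' \eqn{t_{LJ}} units, then one `tag x y z` line per particle at six
#' decimals). Coordinates round-trip exactly at the written precision
#' through [read_trajectory()].
#'
#' @param frames A list of `N x 3` coordinate matrices (or
#'   [system_state()] objects, whose bead positions and times are used).
#' @param path Output path.
#' @param times Time stamps, one per frame (taken from states when
#'   omitted).
#' @param tags Element tag(s) per particle (recycled), default `"C"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path, times = NULL, tags = "C") {
  if (length(frames) == 0) {
    abort("need at least one frame", class = "crowdpore_data_error")
  }
  if (inherits(frames, "system_state")) frames <- list(frames)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (inherits(fr, "system_state")) {
      tm <- fr$time
      fr <- fr$positions
    } else {
      tm <- if (!is.null(times)) times[i] else NA_real_
    }
    fr <- unname(as.matrix(fr))
    write_xyz_frame(fr, rep_len(tags, nrow(fr)),
                    sprintf("t = %s t_LJ", format(tm, digits = 10)),
                    path, append = i > 1)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path Path written by [write_trajectory()] (or any standard XYZ).
#' @return A list of frames, each a list with `positions` (`N x 3`
#'   matrix), `tags` (character) and `comment`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    tags <- vapply(parts, `[[`, "", 1)
    coords <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                     ncol = 3, byrow = TRUE)
    frames[[length(frames) + 1]] <- list(positions = coords, tags = tags,
                                         comment = comment)
    i <- i + 2 + n
  }
  frames
}

#' Serialise translocation events as JSON lines
#'
#' One JSON record per attempt, holding the scalar outcome fields and the
#' per-bead arrays (entry/exit times, beads-in-channel counts, gyration
#' tensor components). The store is plain text, appendable, and is the
#' checkpoint format of [run_ensemble()].
#'
#' @param ens An `ensemble_result` or `translocation_event` tibble.
#' @param path Output path.
#' @param append Append to an existing store.
#' @return `path`, invisibly.
#' @export
write_events <- function(ens, path, append = FALSE) {
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ens))) {
    rec <- list(
      run = ens$run[i], success = ens$success[i],
      failure_mode = ens$failure_mode[i], tau = ens$tau[i],
      n_steps = ens$n_steps[i],
      entry_times = ens$entry_times[[i]],
      exit_times = ens$exit_times[[i]],
      exit_order_times = ens$exit_order_times[[i]],
      n_in_at_exit = ens$n_in_at_exit[[i]],
      gyr_whole = as.numeric(ens$gyr_whole[[i]]),
      gyr_out = as.numeric(ens$gyr_out[[i]])
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' Read a JSON-lines event store
#'
#' @param path Path written by [write_events()].
#' @return An `ensemble_result`-shaped tibble (without parameters
#'   attached).
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    abort("event store is empty", class = "crowdpore_data_error")
  }
  recs <- purrr::map(lines, ~ jsonlite::fromJSON(.x, simplifyVector = TRUE))
  num <- function(v) { # JSON nulls inside arrays come back as list elements
    if (is.list(v)) {
      v <- vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
                  numeric(1))
    }
    as.numeric(v)
  }
  out <- dplyr::bind_rows(purrr::map(recs, function(r) {
    nbead <- length(r$entry_times)
    tibble(
      run = as.integer(r$run), success = isTRUE(r$success),
      failure_mode = r$failure_mode %||% "none",
      tau = if (is.null(r$tau)) NA_real_ else as.numeric(r$tau),
      n_steps = as.numeric(r$n_steps),
      entry_times = list(num(r$entry_times)),
      exit_times = list(num(r$exit_times)),
      exit_order_times = list(num(r$exit_order_times)),
      n_in_at_exit = list(as.integer(num(r$n_in_at_exit))),
      gyr_whole = list(matrix(num(r$gyr_whole), nrow = nbead)),
      gyr_out = list(matrix(num(r$gyr_out), nrow = nbead))
    )
  }))
  class(out) <- c("ensemble_result", class(tibble()))
  out
}

#' Write a run manifest
#'
#' Provenance record for a simulation output: full parameter set, a hash
#' of it, package version and R version.
#'
#' @param params A [sim_params()] object.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(params, path, extra = list()) {
  m <- c(list(
    package = "crowdpore",
    version = as.character(utils::packageVersion("crowdpore")),
    r_version = R.version.string,
    config = unclass(params),
    config_hash = rlang::hash(unclass(params)),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(m)
}
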