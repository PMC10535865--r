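# Schema-validated readers and writers for the tabular formats used by
# the pipeline. Every reader checks the header and cell types and names
# the offending column / file line in its errors; write-then-read is the
# identity on canonical files.

read_table_checked <- function(path, columns, numeric_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  if (file.size(path) == 0) stop(what, " file is empty: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!nrow(df)) stop(what, " file has a header but no rows: ", path)
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop(sprintf("%s file %s: missing column(s) %s (header must be `%s`)",
                 what, path, paste(missing, collapse = ", "),
                 paste(columns, collapse = ",")))
  }
  extra <- setdiff(names(df), columns)
  if (length(extra)) {
    stop(sprintf("%s file %s: unknown column(s) %s", what, path,
                 paste(extra, collapse = ", ")))
  }
  df <- df[columns]
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & !df[[cc]] %in% c("NA", ""))
    if (length(bad)) {
      stop(sprintf("%s file %s: non-numeric `%s` at line %s", what, path,
                   cc, paste(bad + 1L, collapse = ", ")))
    }
    df[[cc]] <- v
  }
  df
}

#' Read / write a fluorescence trace CSV
#'
#' Canonical trace files have the header `time_s,intensity`. Assay
#' events may be supplied as a second CSV with header `event,time_s`
#' (events `drug_added`, `steady_window_start`, `steady_window_end`,
#' `triton`) or attached later.
#'
#' @param path trace CSV path.
#' @param events_path optional events CSV path.
#' @return a [fluorescence_trace()].
#' @export
read_trace_csv <- function(path, events_path = NULL) {
  df <- read_table_checked(path, c("time_s", "intensity"),
                           c("time_s", "intensity"), "trace")
  events <- list()
  if (!is.null(events_path)) {
    ev <- read_table_checked(events_path, c("event", "time_s"),
                             "time_s", "events")
    get1 <- function(nm) {
      i <- which(ev$event == nm)
      if (length(i)) ev$time_s[i[1]] else NULL
    }
    events$drug_added <- get1("drug_added")
    ws <- get1("steady_window_start")
    we <- get1("steady_window_end")
    if (!is.null(ws) && !is.null(we)) {
      events$steady_state_window <- c(ws, we)
    }
    events$permeabilization <- get1("triton")
    events <- events[!vapply(events, is.null, logical(1))]
  }
  fluorescence_trace(df$time_s, df$intensity, events)
}

#' @rdname read_trace_csv
#' @param trace a [fluorescence_trace()] to write.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  utils::write.csv(data.frame(time_s = trace$times,
                              intensity = trace$intensities),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dose-response CSV
#'
#' Header: `dose,unit,replicate,viability_pct`.
#'
#' @param path CSV path.
#' @return data.frame with columns `dose`, `unit`, `replicate`,
#'   `viability` ready for [fit_dose_response()].
#' @export
read_dose_response_csv <- function(path) {
  df <- read_table_checked(path, c("dose", "unit", "replicate",
                                   "viability_pct"),
                           c("dose", "viability_pct"), "dose-response")
  if (length(unique(df$unit)) > 1) {
    stop("dose-response file ", path, " mixes dose units: ",
         paste(unique(df$unit), collapse = ", "))
  }
  data.frame(dose = df$dose, unit = df$unit, replicate = df$replicate,
             viability = df$viability_pct)
}

#' Read a qPCR Ct table
#'
#' Header: `sample,gene,ct`.
#'
#' @param path CSV path.
#' @return data.frame `sample`/`gene`/`ct`.
#' @export
read_qpcr_csv <- function(path) {
  read_table_checked(path, c("sample", "gene", "ct"), "ct", "qPCR")
}

#' Read per-frame MM-GBSA component energies
#'
#' Header: `replica,frame,e_vdw,e_elect,g_polar,g_nonpolar`.
#'
#' @param path CSV path.
#' @return data.frame ready for [mmgbsa_summarize()].
#' @export
read_energy_csv <- function(path) {
  read_table_checked(path,
                     c("replica", "frame", "e_vdw", "e_elect", "g_polar",
                       "g_nonpolar"),
                     c("frame", "e_vdw", "e_elect", "g_polar",
                       "g_nonpolar"), "energy")
}

#' Read a per-residue decomposition table
#'
#' Header: `residue,energy`.
#'
#' @param path CSV path.
#' @return data.frame ready for [decompose_filter()].
#' @export
read_decomposition_csv <- function(path) {
  read_table_checked(path, c("residue", "energy"), "energy",
                     "decomposition")
}

#' Read trajectory coordinates and donor/acceptor annotations from CSV
#'
#' Coordinates: header `frame,serial,name,resname,resid,x,y,z`, one row
#' per atom per frame with an identical atom roster in every frame.
#' Annotations: header `serial,role` with role `donor`, `acceptor` or
#' `hydrogen-of:<serial>`.
#'
#' @param path coordinates CSV path.
#' @param annotations_path optional annotations CSV path.
#' @return a [trajectory()].
#' @export
read_trajectory_csv <- function(path, annotations_path = NULL) {
  df <- read_table_checked(path,
                           c("frame", "serial", "name", "resname", "resid",
                             "x", "y", "z"),
                           c("frame", "serial", "resid", "x", "y", "z"),
                           "trajectory")
  frames <- sort(unique(df$frame))
  df <- df[order(df$frame, df$serial), ]
  first <- df[df$frame == frames[1], ]
  n <- nrow(first)
  if (nrow(df) != n * length(frames)) {
    stop("trajectory file ", path, ": atom roster differs across frames")
  }
  coords <- array(NA_real_, c(n, 3, length(frames)))
  for (k in seq_along(frames)) {
    fr <- df[df$frame == frames[k], ]
    if (!identical(fr$serial, first$serial)) {
      stop("trajectory file ", path, ": atom roster differs across frames")
    }
    coords[, , k] <- as.matrix(fr[, c("x", "y", "z")])
  }
  atoms <- data.frame(serial = first$serial, name = first$name,
                      residue = paste0(first$resname,
                                       ifelse(is.na(first$resid), "",
                                              first$resid)),
                      role = NA_character_, parent = NA_integer_)
  if (!is.null(annotations_path)) {
    ann <- read_annotation_csv(annotations_path)
    atoms <- apply_annotations(atoms, ann)
  }
  trajectory(atoms, coords)
}

#' @rdname read_trajectory_csv
#' @param annotations_path,path CSV paths.
#' @export
read_annotation_csv <- function(path) {
  read_table_checked(path, c("serial", "role"), "serial", "annotation")
}

#' Write a trajectory to the canonical coordinates CSV
#'
#' @param traj a [trajectory()].
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  res <- traj$atoms$residue
  resid <- suppressWarnings(as.integer(sub("^\\D*", "", res)))
  resname <- sub("\\d+$", "", res)
  rows <- do.call(rbind, lapply(seq_len(traj$n_frames), function(f) {
    xyz <- frame_coords(traj, f)
    data.frame(frame = f, serial = traj$atoms$serial,
               name = traj$atoms$name, resname = resname, resid = resid,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
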