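#' Read marker trajectories from disk
#'
#' The canonical on-disk dialect is "wide CSV": a `frame` column plus one
#' `<label>_x,<label>_y,<label>_z` triple per marker, in millimetres.
#' Missing samples may be encoded as empty cells, as a `NaN`/`NA` token, or
#' as a numeric sentinel value (some capture systems export e.g. -99999 for
#' occluded markers). An optional leading comment line `# frame_rate=<Hz>`
#' carries the sampling rate; otherwise `frame_rate` must be supplied.
#'
#' TRC (tab-delimited mocap text, read-only) is also supported. C3D is a
#' binary container this package does not parse; requesting it raises an
#' error pointing at the supported dialects.
#'
#' @param path file to read.
#' @param dialect one of `"wide_csv"`, `"trc"`.
#' @param frame_rate sampling rate in Hz used when the file does not carry
#'   one (wide CSV without a `# frame_rate=` line).
#' @param na_sentinel optional numeric value to additionally treat as
#'   missing (applied to whole samples where all three coordinates equal it,
#'   or per coordinate).
#' @return a [mocap_traj()].
#' @export
read_trajectories <- function(path, dialect = c("wide_csv", "trc", "c3d"),
                              frame_rate = NULL, na_sentinel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect,
    wide_csv = read_wide_csv(path, frame_rate, na_sentinel),
    trc = read_trc(path, na_sentinel),
    c3d = stop("C3D is a binary dialect this package does not parse; ",
               "export to wide CSV or TRC instead", call. = FALSE)
  )
}

read_wide_csv <- function(path, frame_rate, na_sentinel) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*frame_rate\\s*=", first)) {
    fr <- as.numeric(sub("^#\\s*frame_rate\\s*=\\s*", "", first))
    if (is.finite(fr)) frame_rate <- fr
  }
  if (is.null(frame_rate)) frame_rate <- 100
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        na.strings = c("", "NA", "NaN", "nan"))
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  cols <- names(df)
  if (!"frame" %in% cols) stop("wide CSV must have a `frame` column", call. = FALSE)
  coord_cols <- setdiff(cols, "frame")
  bad <- coord_cols[!grepl("_[xyz]$", coord_cols)]
  if (length(bad) > 0) {
    stop("column not of the form <label>_x/_y/_z: ", bad[1], call. = FALSE)
  }
  labels <- unique(sub("_[xyz]$", "", coord_cols))
  for (lab in labels) {
    triple <- paste0(lab, "_", c("x", "y", "z"))
    missing_cols <- setdiff(triple, coord_cols)
    if (length(missing_cols) > 0) {
      stop("incomplete coordinate triple for marker `", lab,
           "`: missing column ", missing_cols[1], call. = FALSE)
    }
  }
  counts <- table(sub("_[xyz]$", "", coord_cols))
  if (any(counts > 3)) {
    stop("duplicate marker label: ", names(counts)[counts > 3][1], call. = FALSE)
  }
  nf <- nrow(df)
  pos <- array(NA_real_, dim = c(nf, length(labels), 3L))
  for (j in seq_along(labels)) {
    for (k in 1:3) {
      v <- as.numeric(df[[paste0(labels[j], "_", c("x", "y", "z")[k])]])
      if (!is.null(na_sentinel)) v[v == na_sentinel] <- NA_real_
      pos[, j, k] <- v
    }
  }
  mocap_traj(pos, labels = labels, frame_rate = frame_rate,
             start_frame = as.integer(df$frame[1]))
}

# Minimal TRC reader: standard 5 header lines, then Frame#/Time + X/Y/Z
# triples per marker. Tab-delimited.
read_trc <- function(path, na_sentinel) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop("truncated TRC file: ", path, call. = FALSE)
  hdr_keys <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  rate_idx <- match("DataRate", hdr_keys)
  if (is.na(rate_idx)) stop("TRC header lacks DataRate", call. = FALSE)
  frame_rate <- as.numeric(hdr_vals[rate_idx])
  marker_row <- strsplit(lines[4], "\t")[[1]]
  labels <- marker_row[-(1:2)]
  labels <- labels[labels != ""]
  if (anyDuplicated(labels)) {
    stop("duplicate marker label: ", labels[duplicated(labels)][1], call. = FALSE)
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  rows <- strsplit(data_lines, "\t")
  ncol_expect <- 2L + 3L * length(labels)
  nf <- length(rows)
  pos <- array(NA_real_, dim = c(nf, length(labels), 3L))
  start_frame <- suppressWarnings(as.integer(rows[[1]][1]))
  for (i in seq_len(nf)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    length(v) <- ncol_expect
    for (j in seq_along(labels)) {
      pos[i, j, ] <- v[2L + (j - 1L) * 3L + 1:3]
    }
  }
  if (!is.null(na_sentinel)) pos[pos == na_sentinel] <- NA_real_
  mocap_traj(pos, labels = labels, frame_rate = frame_rate,
             start_frame = if (is.na(start_frame)) 1L else start_frame)
}

#' Write marker trajectories as wide CSV
#'
#' Writes the lossless wide-CSV dialect: a `# frame_rate=` comment line, a
#' `frame` column, and one x/y/z column triple per marker. Coordinates are
#' printed with 17 significant digits so that reading the file back yields
#' bit-identical doubles; invalid samples become empty cells.
#'
#' @param set a [mocap_traj()].
#' @param path output file.
#' @param dialect only `"wide_csv"` is supported for writing.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(set, path, dialect = "wide_csv") {
  if (!identical(dialect, "wide_csv")) {
    stop("only the wide_csv dialect is writable", call. = FALSE)
  }
  if (length(set$labels) == 0L) stop("trajectory set has no markers", call. = FALSE)
  header <- c("frame", as.vector(t(outer(set$labels, c("_x", "_y", "_z"), paste0))))
  nf <- n_frames(set)
  cols <- vector("list", length(header))
  cols[[1]] <- as.character(frame_numbers(set))
  idx <- 2L
  for (j in seq_along(set$labels)) {
    for (k in 1:3) {
      v <- set$positions[, j, k]
      s <- ifelse(is.na(v), "", sprintf("%.17g", v))
      cols[[idx]] <- s
      idx <- idx + 1L
    }
  }
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(sprintf("# frame_rate=%.17g", set$frame_rate),
               paste(header, collapse = ","), body), path)
  invisible(path)
}
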