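# Plain-text motion-capture formats: TRC (marker trajectories, millimetres,
# tab-separated) and MOT/STO (coordinate time series, rotations in degrees).

#' Write a motion sequence to a TRC file
#'
#' Positions are written in millimetres in the usual tab-separated TRC dialect
#' (two header lines of metadata, marker-name line, X/Y/Z sub-header).
#'
#' @param seq a [motion_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(seq, path) {
  pos <- seq$positions * 1000
  n <- dim(pos)[1]; m <- dim(pos)[2]
  rate <- seq$rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%.2f\t%.2f\t%d\t%d\tmm\t%.2f\t1\t%d",
                     rate, rate, n, m, rate, n), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(seq$marker_names, "", ""))),
                   collapse = "\t"), con)
  xyz <- paste0(rep(c("X", "Y", "Z"), m), rep(seq_len(m), each = 3))
  writeLines(paste(c("", "", xyz), collapse = "\t"), con)
  flat <- matrix(aperm(pos, c(1, 3, 2)), nrow = n)  # frames x (3*m), xyz fastest
  times <- (seq_len(n) - 1) / rate
  body <- apply(cbind(seq_len(n), times, flat), 1, function(r)
    paste(c(sprintf("%d", r[1]), sprintf("%.8f", r[-1])), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a TRC file into a motion sequence
#'
#' @param path TRC file path.
#' @param meta optional [subject_meta()] to attach.
#' @param movement_class movement label to attach.
#' @return a [motion_sequence()] (positions in metres).
#' @export
read_trc <- function(path, meta = NULL, movement_class = "freestyle") {
  lines <- readLines(path)
  hdr <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(hdr[1])
  n <- as.integer(hdr[3]); m <- as.integer(hdr[4])
  units <- hdr[5]
  names_line <- strsplit(lines[4], "\t")[[1]]
  mnames <- names_line[-(1:2)]
  mnames <- mnames[mnames != ""][seq_len(m)]
  dat <- utils::read.table(text = lines[6:(5 + n)], sep = "\t")
  flat <- as.matrix(dat[, 3:(2 + 3 * m)])
  fac <- if (identical(units, "mm")) 1e-3 else 1
  pos <- aperm(array(flat, dim = c(n, 3, m)), c(1, 3, 2)) * fac
  dimnames(pos) <- list(NULL, mnames, c("x", "y", "z"))
  if (is.null(meta)) meta <- subject_meta("unknown", 1.75, 75, 1.0)
  motion_sequence(rate = rate, positions = pos, meta = meta,
                  movement_class = movement_class)
}

#' Write a joint trajectory to a MOT/STO file
#'
#' Rotational coordinates are converted to degrees (the `inDegrees=yes`
#' dialect); translations stay in metres.
#'
#' @param traj a [joint_trajectory()].
#' @param path output file path.
#' @param rot_coords names of rotational coordinates; defaults to every
#'   coordinate not named like a translation (`*_tx/_ty/_tz`).
#' @return `path`, invisibly.
#' @export
write_mot <- function(traj, path, rot_coords = NULL) {
  if (is.null(rot_coords))
    rot_coords <- traj$coordinates[!grepl("_t[xyz]$", traj$coordinates)]
  vals <- traj$values
  for (nm in intersect(rot_coords, colnames(vals)))
    vals[, nm] <- rad2deg(vals[, nm])
  n <- nrow(vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(basename(path), "version=1",
               sprintf("nRows=%d", n),
               sprintf("nColumns=%d", ncol(vals) + 1),
               "inDegrees=yes", "endheader"), con)
  writeLines(paste(c("time", colnames(vals)), collapse = "\t"), con)
  times <- (seq_len(n) - 1) / traj$rate
  writeLines(apply(cbind(times, vals), 1, function(r)
    paste(sprintf("%.8f", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a MOT/STO file into a joint trajectory
#'
#' @param path file path.
#' @return a [joint_trajectory()] (rotations converted back to radians when
#'   the header declares degrees).
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "endheader")[1]
  in_deg <- any(grepl("inDegrees\\s*=\\s*yes", lines[1:end]))
  hdr <- strsplit(lines[end + 1], "\t")[[1]]
  dat <- utils::read.table(text = lines[(end + 2):length(lines)], sep = "\t")
  colnames(dat) <- hdr
  times <- dat[[1]]
  rate <- if (length(times) > 1) 1 / stats::median(diff(times)) else 1
  vals <- as.matrix(dat[, -1, drop = FALSE])
  if (in_deg) {
    rot <- colnames(vals)[!grepl("_t[xyz]$", colnames(vals))]
    for (nm in rot) vals[, nm] <- deg2rad(vals[, nm])
  }
  joint_trajectory(rate, colnames(vals), vals)
}

#' Write a corpus to a directory container
#'
#' One TRC file per sequence plus a JSON index with subject metadata and
#' provenance.
#'
#' @param corpus a `mocap_corpus`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- list()
  for (id in names(corpus$sequences)) {
    s <- corpus$sequences[[id]]
    write_trc(s, file.path(dir, paste0(id, ".trc")))
    pv <- attr(s, "provenance")
    index[[id]] <- list(file = paste0(id, ".trc"), provenance = pv,
                        meta = unclass(s$meta),
                        movement_class = s$movement_class)
  }
  jsonlite::write_json(list(subjects = corpus$subjects, index = index),
                       file.path(dir, "corpus.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a corpus directory container
#'
#' @param dir directory written by [write_corpus()].
#' @return a `mocap_corpus`.
#' @export
read_corpus <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "corpus.json"))
  sequences <- list()
  for (id in names(idx$index)) {
    e <- idx$index[[id]]
    meta <- subject_meta(e$meta$subject_id, e$meta$height, e$meta$mass,
                         e$meta$scale_factor)
    s <- read_trc(file.path(dir, e$file), meta = meta,
                  movement_class = e$movement_class)
    attr(s, "provenance") <- e$provenance
    sequences[[id]] <- s
  }
  subjects <- do.call(rbind, lapply(idx$subjects, as.data.frame))
  structure(list(sequences = sequences, subjects = subjects),
            class = "mocap_corpus")
}
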