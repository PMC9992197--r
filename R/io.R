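#' Recording container on disk
#'
#' A recording is persisted as a directory with three members mirroring a
#' hierarchical scientific container:
#' \describe{
#'   \item{meta.yaml}{rate (Hz), n_channels, n_samples, byte order,
#'     annotations.}
#'   \item{sensors.csv}{sensor_id, pos_x/y/z (m), ori_x/y/z.}
#'   \item{data.bin}{channels x samples float64, little-endian,
#'     column-major in sample-major order (all channels of sample 1,
#'     then sample 2, ...).}
#' }
#'
#' @param recording a [Recording-class]. @param dir container directory.
#' @return `readRecording` returns a [Recording-class].
#' @export
writeRecording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- sensorArray(recording)
  yaml::write_yaml(list(
    rate = samplingRate(recording),
    n_channels = nrow(recordingData(recording)),
    n_samples = ncol(recordingData(recording)),
    byte_order = "little",
    annotations = annotations(recording)), file.path(dir, "meta.yaml"))
  utils::write.csv(data.frame(
    sensor_id = sensorIds(arr),
    pos_x = sensorPositions(arr)[, 1], pos_y = sensorPositions(arr)[, 2],
    pos_z = sensorPositions(arr)[, 3],
    ori_x = sensorOrientations(arr)[, 1],
    ori_y = sensorOrientations(arr)[, 2],
    ori_z = sensorOrientations(arr)[, 3]),
    file.path(dir, "sensors.csv"), row.names = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recordingData(recording)), con, size = 8,
           endian = "little")
  invisible(dir)
}

#' @rdname writeRecording
#' @export
readRecording <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  sens <- utils::read.csv(file.path(dir, "sensors.csv"))
  arr <- new("SensorArray",
             sensorIds = as.character(sens$sensor_id),
             positions = unname(as.matrix(sens[, c("pos_x", "pos_y", "pos_z")])),
             orientations = unname(as.matrix(sens[, c("ori_x", "ori_y",
                                                      "ori_z")])))
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  d <- readBin(con, what = "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  ann <- meta$annotations
  if (is.null(ann)) ann <- list()
  new("Recording", array = arr,
      data = matrix(d, meta$n_channels, meta$n_samples),
      rate = meta$rate, annotations = ann)
}

#' Write a cohort to disk with a checksum manifest
#'
#' Writes each recording container, the empty room, the clinical manifest
#' CSV, the design YAML and a `files.csv` listing every written file with
#' its md5 checksum.
#'
#' @param cohort list as returned by [simulateCohort()].
#' @param design the [CohortDesign-class] that produced it.
#' @param dir output directory.
#' @return invisible path of the checksum manifest.
#' @export
writeCohort <- function(cohort, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCohortDesign(design, file.path(dir, "design.yaml"))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  writeRecording(cohort$emptyRoom, file.path(dir, "empty_room"))
  for (id in names(cohort$recordings))
    writeRecording(cohort$recordings[[id]], file.path(dir, id))
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(dir, "files.csv"))
  utils::write.csv(data.frame(
    file = sub(paste0("^", dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files))),
    file.path(dir, "files.csv"), row.names = FALSE)
  invisible(file.path(dir, "files.csv"))
}
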