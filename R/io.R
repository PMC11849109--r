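# File-format glue: NIfTI volumes via RNifti, tables as CSV.

#' Write a numeric array as NIfTI
#'
#' @param x 3-D or 4-D numeric/logical array.
#' @param path Output path (".nii" or ".nii.gz").
#' @param voxelSizeMm Isotropic voxel size in mm.
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path, voxelSizeMm = 1) {
  img <- RNifti::asNifti(x * 1)
  RNifti::pixdim(img) <- rep(voxelSizeMm, length(dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
readVolume <- function(path) {
  x <- RNifti::readNifti(path)
  array(as.numeric(x), dim(x))
}

#' Read a respiratory trace from CSV
#'
#' Expects columns \code{time} (seconds, uniformly sampled) and
#' \code{percent}.
#'
#' @param path CSV file path.
#' @return A \code{\link{respiratoryTrace}}.
#' @export
readRespTraceCsv <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("time", "percent") %in% names(x)))
  dt <- diff(x$time)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  respiratoryTrace(x$percent, samplingHz = 1 / stats::median(dt))
}

#' Write a respiratory trace to CSV
#'
#' @param trace A \code{\link{respiratoryTrace}}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeRespTraceCsv <- function(trace, path) {
  n <- length(o2Samples(trace))
  utils::write.csv(data.frame(time = (seq_len(n) - 1) / samplingRate(trace),
                              percent = o2Samples(trace)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write the per-subject inputs of a simulated cohort to disk
#'
#' For each subject: the 4-D ASL difference signals, M0, ASL mask,
#' parcellation, susceptibility map, brain mask and vein seed labels as
#' NIfTI; the respiratory trace as CSV.  A cohort-level CSV holds the
#' covariates, and a truth CSV the generating per-territory values.
#'
#' @param cohort A \code{\link{CohortTruth}}.
#' @param dir Output directory (created if needed).
#' @param schedule An \code{\link{acquisitionSchedule}}.
#' @param ... Passed to \code{\link{simulateSubjectInputs}}.
#' @return The directory, invisibly.
#' @export
writeCohortInputs <- function(cohort, dir, schedule = defaultSchedule(),
                              ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohortSubjects(cohort),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(cohortTruth(cohort),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  sch <- data.frame(tau = labelDurations(schedule),
                    pld = postLabelDelays(schedule))
  utils::write.csv(sch, file.path(dir, "schedule.csv"), row.names = FALSE)
  for (id in cohortSubjects(cohort)$subject) {
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    inp <- simulateSubjectInputs(cohort, id, schedule, ...)
    writeVolume(inp$asl, file.path(sdir, "asl.nii.gz"))
    writeVolume(inp$m0, file.path(sdir, "m0.nii.gz"))
    writeVolume(inp$aslMask, file.path(sdir, "asl_mask.nii.gz"))
    writeVolume(inp$parcellation, file.path(sdir, "parcellation.nii.gz"))
    writeVolume(inp$chi, file.path(sdir, "chi.nii.gz"))
    writeVolume(inp$brainMask, file.path(sdir, "brain_mask.nii.gz"))
    seedLabels <- array(0L, dim(inp$chi))
    for (k in seq_along(inp$veinSeeds))
      seedLabels[inp$veinSeeds[[k]]] <- k
    writeVolume(seedLabels, file.path(sdir, "vein_seeds.nii.gz"))
    writeRespTraceCsv(inp$respTrace, file.path(sdir, "resp_trace.csv"))
  }
  invisible(dir)
}

#' Read one subject's pipeline inputs from disk
#'
#' Inverse of the per-subject layout written by
#' \code{\link{writeCohortInputs}}.
#'
#' @param dir Cohort directory.
#' @param subject Subject identifier (subdirectory name).
#' @return Named list of pipeline inputs for \code{\link{runSubject}}.
#' @export
readSubjectInputs <- function(dir, subject) {
  sdir <- file.path(dir, subject)
  subjects <- utils::read.csv(file.path(dir, "cohort.csv"))
  i <- match(subject, subjects$subject)
  if (is.na(i)) stop("unknown subject: ", subject)
  seedLabels <- readVolume(file.path(sdir, "vein_seeds.nii.gz"))
  seeds <- lapply(seq_along(territoryNames()),
                  function(k) array(seedLabels == k, dim(seedLabels)))
  names(seeds) <- territoryNames()
  list(subject = subject, session = 1L, hct = subjects$hct[i],
       asl = readVolume(file.path(sdir, "asl.nii.gz")),
       m0 = readVolume(file.path(sdir, "m0.nii.gz")),
       aslMask = readVolume(file.path(sdir, "asl_mask.nii.gz")) > 0.5,
       parcellation = {
         p <- readVolume(file.path(sdir, "parcellation.nii.gz"))
         array(as.integer(round(p)), dim(p))
       },
       chi = readVolume(file.path(sdir, "chi.nii.gz")),
       brainMask = readVolume(file.path(sdir, "brain_mask.nii.gz")) > 0.5,
       veinSeeds = seeds,
       respTrace = readRespTraceCsv(file.path(sdir, "resp_trace.csv")))
}

#' Read an acquisition schedule from CSV
#'
#' Expects columns \code{tau} and \code{pld} in ms.
#'
#' @param path CSV file path.
#' @return An \code{\link{acquisitionSchedule}}.
#' @export
readScheduleCsv <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("tau", "pld") %in% names(x)))
  acquisitionSchedule(x$tau, x$pld)
}
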