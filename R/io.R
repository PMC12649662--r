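#' Read a BIDS-style events table
#'
#' Tab-separated file with columns `onset`, `duration`, `trial_type`
#' (seconds, relative to run start).
#'
#' @param path Path to the events TSV.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of volumes in the run.
#' @param run_id Run identifier (defaults to the file name).
#' @return An `event_design`.
#' @export
read_events <- function(path, tr, n_volumes,
                        run_id = tools::file_path_sans_ext(basename(path))) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    stop("events file is missing column(s): ", paste(missing, collapse = ", "))
  if (any(d$duration < 0)) stop("negative duration in events file")
  if (nrow(d) > 1 && any(diff(d$onset) <= 0))
    stop("onsets must be strictly increasing")
  event_design(d$onset, d$duration, d$trial_type, tr, n_volumes, run_id)
}

#' Write a design as a BIDS-style events TSV
#' @param design An `event_design`.
#' @param path Output path.
#' @export
write_events <- function(design, path) {
  utils::write.table(
    data.frame(onset = design$onsets, duration = design$durations,
               trial_type = design$conditions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a BOLD run as 4D NIfTI (plus a label volume)
#'
#' Voxels are laid out along the first spatial axis; the TR is stored in the
#' header's temporal pixdim.
#'
#' @param run A `bold_run`.
#' @param path Output `.nii` path.
#' @param labels_path Optional path for the integer region-label volume.
#' @export
write_bold <- function(run, path, labels_path = NULL) {
  n_vox <- nrow(run$data)
  arr <- array(run$data, dim = c(n_vox, 1, 1, ncol(run$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr)
  RNifti::writeNifti(img, path)
  if (!is.null(labels_path)) {
    lab <- RNifti::asNifti(array(as.integer(run$region_labels),
                                 dim = c(n_vox, 1, 1)))
    RNifti::writeNifti(lab, labels_path)
  }
  invisible(path)
}

#' Read a 4D BOLD NIfTI into a `bold_run`
#'
#' @param path Path to a 4D NIfTI file.
#' @param labels_path Optional integer label volume on the same grid.
#' @param regions Optional named label map (name -> integer).
#' @return A `bold_run` (with empty `outlier_volumes`).
#' @export
read_bold <- function(path, labels_path = NULL, regions = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4D NIfTI file, got ", length(d), "D")
  tr <- RNifti::pixdim(img)[4]
  n_vox <- prod(d[1:3])
  data <- matrix(as.numeric(img), n_vox, d[4])
  labels <- rep(1L, n_vox)
  if (!is.null(labels_path)) {
    lab <- RNifti::readNifti(labels_path)
    if (prod(dim(lab)) != n_vox)
      stop("label volume grid does not match the BOLD grid")
    labels <- as.integer(lab)
  }
  if (is.null(regions))
    regions <- stats::setNames(sort(unique(labels)),
                               paste0("region", sort(unique(labels))))
  structure(list(data = data, tr = tr, region_labels = labels,
                 regions = regions, outlier_volumes = integer(0)),
            class = "bold_run")
}
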