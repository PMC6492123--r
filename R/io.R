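# Cine I/O as NIfTI (frames on the temporal axis, spacings in the header),
# trajectory export as plain CSV, model persistence as RDS.

#' Write a cine volume to NIfTI
#'
#' Frames go on the 4th NIfTI axis (singleton 3rd axis); pixel and frame
#' spacing are stored in `pixdim`.
#'
#' @param cine A [cine_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_cine_nifti <- function(cine, path) {
  stopifnot(inherits(cine, "cine_volume"))
  d <- dim(cine$data)
  a <- array(cine$data, c(d[1], d[2], 1, d[3]))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(cine$pixel_mm, cine$pixel_mm, 1,
                           cine$frame_ms / 1000)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cine volume from NIfTI
#'
#' Accepts `(x, y, t)` or `(x, y, 1, t)` magnitude images; negative values
#' are clipped at zero.
#'
#' @param path NIfTI file path.
#' @param rr_ms Optional R-R interval to attach.
#' @return A [cine_volume()].
#' @export
read_cine_nifti <- function(path, rr_ms = NULL) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  a <- if (length(d) == 4) array(img, c(d[1], d[2], d[4])) else
    array(img, c(d[1], d[2], if (length(d) >= 3) d[3] else 1))
  frame_ms <- if (length(d) == 4 && hdr$pixdim[5] > 0) hdr$pixdim[5] * 1000 else 1
  cine_volume(pmax(a, 0), pixel_mm = hdr$pixdim[2], frame_ms = frame_ms,
              rr_ms = rr_ms)
}

#' Export a trajectory's angles to CSV
#'
#' Long format: `frame`, `spoke`, `angle_deg`. The sample radii are implied
#' by the protocol (uniform from -0.5 up to +0.5 cycles/pixel).
#'
#' @param traj A [make_trajectory()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "radial_trajectory"))
  df <- data.frame(
    frame = rep(seq_len(traj$n_frames), ncol(traj$angles_deg)),
    spoke = rep(seq_len(ncol(traj$angles_deg)), each = traj$n_frames),
    angle_deg = as.vector(traj$angles_deg))
  df <- df[order(df$frame, df$spoke), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model
#'
#' Thin RDS wrappers kept for the command-line interface.
#'
#' @param trained A [train()] result.
#' @param path File path.
#' @return `path` (save) or the `trained_model` (load).
#' @export
save_model <- function(trained, path) {
  stopifnot(inherits(trained, "trained_model"))
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "trained_model"))
  m
}
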