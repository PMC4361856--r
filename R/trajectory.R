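#' Build a trajectory
#'
#' An ordered set of frames bound to one topology. Coordinates are in
#' Angstrom; the bilayer normal is the +z axis and z = 0 sits at the
#' membrane centre.
#'
#' @param topology an `mg_topology`.
#' @param coords a list of `n_atoms x 3` numeric matrices (one per frame) or
#'   an array of dimension `c(n_atoms, 3, n_frames)`.
#' @param box optional orthorhombic box lengths, a length-3 vector applied to
#'   every frame or an `n_frames x 3` matrix.
#' @param time optional per-frame times, ps.
#' @param stride frame stride metadata (simulation steps between frames).
#' @return an object of class `mg_trajectory`.
#' @export
mg_trajectory <- function(topology, coords, box = NULL, time = NULL,
                          stride = 1L) {
  if (is.list(coords)) {
    nf <- length(coords)
    if (nf < 1L) stop("a trajectory needs at least one frame")
    na <- nrow(coords[[1L]])
    arr <- array(NA_real_, dim = c(na, 3L, nf))
    for (i in seq_len(nf)) {
      m <- as.matrix(coords[[i]])
      if (!identical(dim(m), c(na, 3L)) && !all(dim(m) == c(na, 3L)))
        stop("all frames must share the same atom count")
      arr[, , i] <- m
    }
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1L] != n_atoms(topology))
    stop("coordinate count (", dim(coords)[1L],
         ") does not match topology atom count (", n_atoms(topology), ")")
  if (dim(coords)[3L] < 1L) stop("a trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  nf <- dim(coords)[3L]
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
    if (nrow(box) != nf) stop("box must give 3 lengths per frame")
  }
  if (!is.null(time) && length(time) != nf)
    stop("time must have one entry per frame")
  structure(list(topology = topology, coords = coords, box = box,
                 time = time, stride = as.integer(stride)),
            class = "mg_trajectory")
}

#' Number of frames
#' @param traj an `mg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one frame's coordinates
#' @param traj an `mg_trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix, Angstrom.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

#' @export
print.mg_trajectory <- function(x, ...) {
  cat("mg_trajectory:", n_frames(x), "frames x", n_atoms(x$topology),
      "atoms", if (!is.null(x$box)) "(periodic box)" else "", "\n")
  invisible(x)
}

## Subset frames, keeping topology and metadata aligned.
subset_frames <- function(traj, idx) {
  mg_trajectory(traj$topology, traj$coords[, , idx, drop = FALSE],
                box = if (!is.null(traj$box)) traj$box[idx, , drop = FALSE],
                time = if (!is.null(traj$time)) traj$time[idx],
                stride = traj$stride)
}
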