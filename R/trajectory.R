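#' Construct a trajectory
#'
#' Ordered frames of positions (and optionally velocities) over a fixed
#' topology. Velocities are required downstream by the charge-current
#' spectrum, so the engine always records them.
#'
#' @param topology the \code{particle_system} the frames refer to.
#' @param times numeric vector of frame times, ps, strictly increasing.
#' @param positions array \code{[n_frames, n_atoms, 3]}, nm.
#' @param velocities array \code{[n_frames, n_atoms, 3]}, nm/ps, or NULL.
#' @return An object of class \code{md_trajectory} with \code{dt_sample} set
#'   when frame spacing is uniform (within 1e-9 ps), otherwise NA.
#' @export
trajectory <- function(topology, times, positions, velocities = NULL) {
  if (!inherits(topology, "particle_system")) stop("topology must be a particle_system")
  times <- as.numeric(times)
  nf <- length(times)
  if (nf < 1L) stop("a trajectory needs at least one frame")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  dp <- dim(positions)
  if (length(dp) != 3L || dp[1] != nf || dp[2] != topology$n_atoms || dp[3] != 3L)
    stop("positions must be an [n_frames, n_atoms, 3] array matching topology (",
         topology$n_atoms, " atoms)")
  if (!is.null(velocities)) {
    dv <- dim(velocities)
    if (!identical(as.integer(dv), as.integer(dp)))
      stop("velocities must have the same dimensions as positions")
  }
  dt_sample <- NA_real_
  if (nf > 1L) {
    dts <- diff(times)
    if (max(dts) - min(dts) < 1e-9) dt_sample <- mean(dts)
  }
  structure(list(topology = topology, times = times, positions = positions,
                 velocities = velocities, dt_sample = dt_sample),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, t = [%g, %g] ps, dt_sample = %s ps, velocities: %s\n",
              length(x$times), x$topology$n_atoms, x$times[1],
              x$times[length(x$times)],
              ifelse(is.na(x$dt_sample), "irregular/NA", format(x$dt_sample)),
              ifelse(is.null(x$velocities), "no", "yes")))
  invisible(x)
}

#' @rdname trajectory
#' @param traj an \code{md_trajectory}.
#' @export
n_frames <- function(traj) length(traj$times)

#' Write / read the package trajectory format
#'
#' A self-describing plain-text format: a four-line header (magic, atom and
#' frame counts, velocity flag), one line of frame times (ps), then a
#' frame-major table with one \code{x y z [vx vy vz]} row per atom and frame
#' (nm, nm/ps). Velocities round-trip; coordinates reproduce well within
#' 1e-3 nm.
#'
#' @param traj an \code{md_trajectory}.
#' @param path file path.
#' @param topology the \code{particle_system} to attach on read; its atom
#'   count must match the file.
#' @return \code{read_trajectory} returns an \code{md_trajectory};
#'   \code{write_trajectory} returns \code{path} invisibly.
#' @export
write_trajectory <- function(traj, path) {
  has_vel <- !is.null(traj$velocities)
  n <- traj$topology$n_atoms
  nf <- length(traj$times)
  writeLines(c("# thzbind trajectory v1",
               paste("n_atoms", n),
               paste("n_frames", nf),
               paste("has_velocities", as.integer(has_vel)),
               paste(sprintf("%.10g", traj$times), collapse = " ")), path)
  # frame-major block: frame 1 atoms 1..n, frame 2 atoms 1..n, ...
  flat <- function(arr) {
    m <- aperm(arr, c(2L, 1L, 3L))   # atom, frame, dim
    dim(m) <- c(n * nf, 3L)
    m
  }
  block <- flat(traj$positions)
  if (has_vel) block <- cbind(block, flat(traj$velocities))
  data.table::fwrite(data.table::as.data.table(block), path, append = TRUE,
                     sep = " ", col.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, topology) {
  hdr <- readLines(path, n = 5L)
  if (length(hdr) < 5L || !startsWith(hdr[1], "# thzbind trajectory"))
    stop("not a thzbind trajectory file: ", path)
  get_hdr <- function(k, name) {
    parts <- strsplit(hdr[k], " ", fixed = TRUE)[[1]]
    if (parts[1] != name) stop("malformed header line ", k, ": expected ", name)
    as.integer(parts[2])
  }
  n <- get_hdr(2L, "n_atoms"); nf <- get_hdr(3L, "n_frames")
  has_vel <- get_hdr(4L, "has_velocities") == 1L
  if (n != topology$n_atoms)
    stop("topology has ", topology$n_atoms, " atoms but file has ", n)
  times <- scan(text = hdr[5L], quiet = TRUE)
  if (length(times) != nf) stop("times line does not match n_frames")
  block <- as.matrix(data.table::fread(path, skip = 5L, header = FALSE))
  ncols <- if (has_vel) 6L else 3L
  if (nrow(block) != n * nf || ncol(block) != ncols)
    stop("coordinate block has wrong shape (", nrow(block), " x ",
         ncol(block), ")")
  unflat <- function(cols) {
    m <- block[, cols, drop = FALSE]
    dim(m) <- c(n, nf, 3L)
    aperm(m, c(2L, 1L, 3L))
  }
  pos <- unflat(1:3)
  vel <- if (has_vel) unflat(4:6) else NULL
  trajectory(topology, times, pos, vel)
}

#' Extract the frames inside a time window
#'
#' @param traj an \code{md_trajectory}.
#' @param from,to window bounds in ps (inclusive); \code{NULL} means open.
#' @return An \code{md_trajectory} restricted to the window.
#' @export
trajectory_window <- function(traj, from = NULL, to = NULL) {
  keep <- rep(TRUE, length(traj$times))
  if (!is.null(from)) keep <- keep & traj$times >= from - 1e-12
  if (!is.null(to)) keep <- keep & traj$times <= to + 1e-12
  if (!any(keep)) stop("window contains no frames")
  trajectory(traj$topology, traj$times[keep],
             traj$positions[keep, , , drop = FALSE],
             if (!is.null(traj$velocities)) traj$velocities[keep, , , drop = FALSE])
}
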