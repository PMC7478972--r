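#' Construct a 3D swimming track
#'
#' A track is one cell's time series of positions in the laboratory frame,
#' sampled at a uniform frame interval. Positions are in micrometres, times in
#' seconds.
#'
#' @param track_id scalar identifier (coerced to character).
#' @param t numeric vector of times (s), strictly increasing and uniformly
#'   spaced.
#' @param pos numeric matrix with one row per frame and columns x, y, z (um).
#' @param validate check invariants (uniform spacing, finite coordinates).
#' @return An object of class `swim_track`.
#' @seealso [track_tangents()], [track_speeds()], [generate_swimmer_track()]
#' @export
swim_track <- function(track_id, t, pos, validate = TRUE) {
  pos <- as.matrix(pos)
  colnames(pos) <- c("x", "y", "z")
  x <- structure(list(track_id = as.character(track_id)[1],
                      t = as.numeric(t), pos = pos),
                 class = "swim_track")
  if (validate) validate_track(x)
  x
}

validate_track <- function(x) {
  if (length(x$t) != nrow(x$pos))
    stop("track times and positions differ in length")
  if (length(x$t) < 2L) stop("a track needs at least 2 frames")
  dt <- diff(x$t)
  if (any(dt <= 0)) stop("track times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9)
    stop("track times must be uniformly spaced (interpolate gaps first)")
  if (!all(is.finite(x$pos))) stop("track coordinates must be finite")
  invisible(x)
}

#' @export
print.swim_track <- function(x, ...) {
  cat(sprintf("<swim_track '%s': %d frames, %.2f s at %.1f Hz>\n",
              x$track_id, length(x$t), diff(range(x$t)),
              1 / median(diff(x$t))))
  invisible(x)
}

#' @export
as.data.frame.swim_track <- function(x, ...) {
  data.frame(track_id = x$track_id,
             frame = seq_along(x$t) - 1L,
             t_s = x$t,
             x_um = x$pos[, 1], y_um = x$pos[, 2], z_um = x$pos[, 3])
}

#' Frame interval of a track (s)
#' @param track a `swim_track`.
#' @return Scalar frame interval in seconds.
#' @export
track_dt <- function(track) median(diff(track$t))

#' Unit tangent vectors of a track
#'
#' Forward finite differences of position: the tangent at frame i points from
#' frame i to frame i+1, so tangents are undefined at the final frame.
#'
#' @param track a `swim_track`.
#' @return Matrix with `nrow(track$pos) - 1` unit rows.
#' @export
track_tangents <- function(track) {
  d <- diff(track$pos)
  len <- sqrt(rowSums(d^2))
  len[len == 0] <- NA_real_
  d / len
}

#' Instantaneous speeds of a track (um/s)
#'
#' Forward finite-difference speeds; one value per frame except the last.
#' Raw (unsmoothed) tracks carry a strong upward localization-noise bias;
#' apply [smooth_and_filter()] before interpreting speeds.
#'
#' @param track a `swim_track`.
#' @return Numeric vector of length `nrow(track$pos) - 1`.
#' @export
track_speeds <- function(track) {
  d <- diff(track$pos)
  sqrt(rowSums(d^2)) / diff(track$t)
}

#' Bundle tracks into a track set
#' @param tracks list of `swim_track` objects.
#' @return An object of class `track_set` (a list of tracks).
#' @export
track_set <- function(tracks) {
  stopifnot(all(vapply(tracks, inherits, logical(1), "swim_track")))
  names(tracks) <- vapply(tracks, function(x) x$track_id, character(1))
  structure(tracks, class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  nf <- sum(vapply(x, function(tr) length(tr$t), integer(1)))
  cat(sprintf("<track_set: %d tracks, %d frames total>\n", length(x), nf))
  invisible(x)
}

#' @export
`[.track_set` <- function(x, i) track_set(unclass(x)[i])

#' @export
as.data.frame.track_set <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}
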