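#' Accessors for the core classes
#'
#' Slot access for [DiabodySystem-class], [Trajectory-class],
#' [PMFProfile-class] and [EventSeries-class] objects.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))

#' @rdname accessors
#' @export
setMethod("beads", "DiabodySystem", function(x) x@beads)

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname accessors
#' @export
setMethod("bonds", "DiabodySystem", function(x) x@bonds)

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname accessors
#' @export
setMethod("angles", "DiabodySystem", function(x) x@angles)

#' @rdname accessors
#' @export
setGeneric("dihedrals", function(x) standardGeneric("dihedrals"))

#' @rdname accessors
#' @export
setMethod("dihedrals", "DiabodySystem", function(x) x@dihedrals)

#' @rdname accessors
#' @export
setGeneric("rigidGroups", function(x) standardGeneric("rigidGroups"))

#' @rdname accessors
#' @export
setMethod("rigidGroups", "DiabodySystem", function(x) x@rigidGroups)

#' @rdname accessors
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' @rdname accessors
#' @export
setMethod("boxDims", "DiabodySystem", function(x) x@box)

#' @rdname accessors
#' @export
setMethod("boxDims", "Trajectory", function(x) x@box)

#' @rdname accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' @rdname accessors
#' @export
setMethod("nBeads", "DiabodySystem", function(x) nrow(x@beads))

#' @rdname accessors
#' @export
setMethod("nBeads", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname accessors
#' @export
setGeneric("beadNames", function(x) standardGeneric("beadNames"))

#' @rdname accessors
#' @export
setMethod("beadNames", "DiabodySystem", function(x) x@beads$name)

#' @rdname accessors
#' @export
setMethod("beadNames", "Trajectory", function(x) x@beadNames)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' Coordinates of one frame
#'
#' @param x a [Trajectory-class].
#' @param frame frame index (default last).
#' @return an `n x 3` matrix with rownames set to the bead names.
#' @export
frameCoords <- function(x, frame = nFrames(x)) {
  stopifnot(is(x, "Trajectory"), frame >= 1, frame <= nFrames(x))
  m <- x@coords[, , frame, drop = TRUE]
  dim(m) <- c(dim(x@coords)[1], 3)
  rownames(m) <- x@beadNames
  colnames(m) <- c("x", "y", "z")
  m
}

#' Initial coordinate matrix of a system
#'
#' @param x a [DiabodySystem-class].
#' @return an `n x 3` matrix of the build coordinates.
#' @export
startCoords <- function(x) {
  stopifnot(is(x, "DiabodySystem"))
  m <- as.matrix(x@beads[, c("x", "y", "z")])
  rownames(m) <- x@beads$name
  m
}

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setMethod("events", "EventSeries", function(x) x@events)

#' PMF profile as a data.frame
#'
#' @param x a [PMFProfile-class].
#' @return data.frame with columns `cv`, `pmf`, `stderr`.
#' @export
pmfTable <- function(x) {
  stopifnot(is(x, "PMFProfile"))
  data.frame(cv = x@grid, pmf = x@pmf,
             stderr = if (length(x@stderr)) x@stderr else NA_real_)
}

#' z-coordinate time series of one bead
#'
#' Uses the high-frequency track when the bead was tracked during the run,
#' otherwise falls back to the stored frames.
#'
#' @param x a [Trajectory-class].
#' @param bead bead name.
#' @return list with `z` (numeric series) and `interval` (sampling interval).
#' @export
beadHeightSeries <- function(x, bead) {
  stopifnot(is(x, "Trajectory"))
  if (length(x@track) && bead %in% x@track$beads) {
    j <- match(bead, x@track$beads)
    return(list(z = x@track$z[, j], interval = x@track$interval))
  }
  i <- match(bead, x@beadNames)
  if (is.na(i)) stop("unknown bead: ", bead)
  list(z = x@coords[i, 3, ], interval = x@frameInterval)
}
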