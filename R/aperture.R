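#' Construct an aperture
#'
#' @param yJaws numeric(2): y-jaw positions (y1, y2) at isocenter (mm).
#' @param bankA,bankB per-leaf tip positions (mm at isocenter), one value per
#'   leaf pair; bank A is the lower-x bank.
#' @param transmission MLC transmission weight outside the opening.
#' @param geometry a [MachineGeometry-class] fixing leaf count and pitch.
#' @return an [Aperture-class].
#' @export
aperture <- function(yJaws, bankA, bankB, transmission = 0,
                     geometry = defaultGeometry()) {
  nPairs <- geometry@mlcLeafCount %/% 2L
  if (length(bankA) != nPairs || length(bankB) != nPairs)
    stop("expected ", nPairs, " leaf positions per bank, got ",
         length(bankA), " / ", length(bankB))
  obj <- new("Aperture", yJaws = as.numeric(yJaws), bankA = as.numeric(bankA),
             bankB = as.numeric(bankB), transmission = transmission)
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok)) stop("invalid aperture: ", paste(ok, collapse = "; "))
  obj
}

#' Evaluate the aperture function
#'
#' The aperture (omega) function: 1 where a point of the isocenter plane lies
#' inside the opening defined by the y-jaws and the leaf pair containing the
#' point, and the MLC transmission elsewhere (0 by default).  Points beyond
#' the fixed x-jaws are outside.  Intervals are half-open `[low, high)` so a
#' point on a shared leaf boundary belongs to exactly one leaf.
#'
#' @param aperture an [Aperture-class].
#' @param x,y coordinates at the isocenter plane (mm), vectors of equal
#'   length (or recyclable).
#' @param geometry a [MachineGeometry-class].
#' @return numeric vector of weights in `{transmission, 1}`.
#' @examples
#' ap <- makeSquareField(100)
#' apertureMask(ap, 0, 0)    # 1: open field center
#' apertureMask(ap, 0, 80)   # 0: beyond the y-jaws
#' @export
apertureMask <- function(aperture, x, y, geometry = defaultGeometry()) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  nPairs <- length(aperture@bankA)
  pitch <- geometry@mlcLeafWidth
  y0 <- -pitch * nPairs / 2                    # leaf 1 lower edge
  leaf <- floor((y - y0) / pitch) + 1          # half-open bands [low, high)
  inBank <- leaf >= 1 & leaf <= nPairs
  leafC <- pmin(pmax(leaf, 1L), nPairs)
  open <- inBank &
    y >= aperture@yJaws[1] & y < aperture@yJaws[2] &
    x >= aperture@bankA[leafC] & x < aperture@bankB[leafC] &
    x >= -geometry@fixedXJaw & x < geometry@fixedXJaw
  ifelse(open, 1, aperture@transmission)
}

#' Open area of an aperture
#'
#' Total open area A of the aperture at the isocenter plane (mm^2): for each
#' leaf pair, the overlap of its y-band with the y-jaw interval times the
#' open x-extent between the leaf tips, clipped to the fixed x-jaws.  Equals
#' the analytic width x height for rectangular fields.
#'
#' @inheritParams apertureMask
#' @return open area (mm^2).
#' @export
openArea <- function(aperture, geometry = defaultGeometry()) {
  nPairs <- length(aperture@bankA)
  pitch <- geometry@mlcLeafWidth
  y0 <- -pitch * nPairs / 2
  lo <- y0 + pitch * (seq_len(nPairs) - 1)
  hi <- lo + pitch
  dy <- pmax(0, pmin(hi, aperture@yJaws[2]) - pmax(lo, aperture@yJaws[1]))
  xa <- pmax(aperture@bankA, -geometry@fixedXJaw)
  xb <- pmin(aperture@bankB, geometry@fixedXJaw)
  dx <- pmax(0, xb - xa)
  sum(dy * dx)
}

#' Create a square (or offset square) field aperture
#'
#' Sets the y-jaws to `offsetY +/- width/2`, opens the leaf pairs whose
#' y-band intersects the field to `offsetX +/- width/2`, and parks all other
#' leaf pairs closed (zero gap) behind the y-jaws.
#'
#' @param width field width (mm at isocenter).
#' @param offsetX,offsetY field-center offset in IEC61217 x / y (mm).
#' @param transmission MLC transmission.
#' @param geometry a [MachineGeometry-class].
#' @return an [Aperture-class].
#' @examples
#' openArea(makeSquareField(100))            # 10000 mm^2
#' openArea(makeSquareField(30, offsetX = 100))
#' @export
makeSquareField <- function(width, offsetX = 0, offsetY = 0, transmission = 0,
                            geometry = defaultGeometry()) {
  if (width <= 0) stop("field width must be positive")
  lim <- geometry@fixedXJaw
  x1 <- offsetX - width / 2; x2 <- offsetX + width / 2
  y1 <- offsetY - width / 2; y2 <- offsetY + width / 2
  if (x1 < -lim - 1e-9 || x2 > lim + 1e-9 || y1 < -lim - 1e-9 || y2 > lim + 1e-9)
    stop("field exceeds the +/-", lim, " mm travel range")
  nPairs <- geometry@mlcLeafCount %/% 2L
  pitch <- geometry@mlcLeafWidth
  y0 <- -pitch * nPairs / 2
  lo <- y0 + pitch * (seq_len(nPairs) - 1)
  hi <- lo + pitch
  inField <- hi > y1 & lo < y2
  park <- min(max(offsetX, -lim), lim)   # closed pairs: zero gap, behind jaws
  bankA <- rep(park, nPairs); bankB <- rep(park, nPairs)
  bankA[inField] <- x1; bankB[inField] <- x2
  aperture(c(y1, y2), bankA, bankB, transmission, geometry)
}

#' Construct a segment
#'
#' @param aperture an [Aperture-class].
#' @param mu monitor units (> 0).
#' @param gantryAngle,collimatorAngle machine angles (degrees).
#' @return a [Segment-class].
#' @export
segment <- function(aperture, mu, gantryAngle = 0, collimatorAngle = 0) {
  obj <- new("Segment", aperture = aperture, mu = mu,
             gantryAngle = gantryAngle, collimatorAngle = collimatorAngle)
  validObject(obj)
  obj
}

setMethod("show", "Aperture", function(object) {
  gap <- object@bankB - object@bankA
  cat(sprintf("Aperture: y-jaws [%.1f, %.1f] mm, %d leaf pairs (%d open), transmission %.3g\n",
              object@yJaws[1], object@yJaws[2], length(gap), sum(gap > 0),
              object@transmission))
  cat(sprintf("  open area %.1f mm^2\n", openArea(object)))
})

setMethod("show", "Segment", function(object) {
  cat(sprintf("Segment: %.2f MU, gantry %.1f deg, open area %.1f mm^2\n",
              object@mu, object@gantryAngle, openArea(object@aperture)))
})

setMethod("show", "Beam", function(object) {
  cat(sprintf("Beam: gantry %.1f deg, %d segment(s), %.2f MU total\n",
              object@gantryAngle, length(object@segments),
              sum(vapply(object@segments, function(s) s@mu, 0))))
})

setMethod("show", "Plan", function(object) {
  nseg <- sum(vapply(object@beams, function(b) length(b@segments), 0L))
  cat(sprintf("Plan '%s' (%s): %d beam(s), %d segment(s), prescription %.1f cGy\n",
              object@name, object@quality, length(object@beams), nseg,
              object@prescriptionDose))
})
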