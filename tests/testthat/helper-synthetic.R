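# Shared fixtures: small, fast synthetic geometries used across tests.

smallGeom <- function(zPlanes = 8, ...) {
  RootGeometry(nFiles = 3, cellsPerFile = 6, zPlanes = zPlanes,
               cellDepthPlanes = 4, ...)
}

# a PlaneSegmentation built directly from a region table (for linking
# tests that never touch pixels)
makeSeg <- function(plane, label, area, crow, ccol, border = FALSE) {
  n <- length(label)
  new("PlaneSegmentation", planeIndex = as.integer(plane),
      labels = matrix(0L, 1, 1),
      table = data.frame(label = as.integer(label), area = area,
                         crow = crow, ccol = ccol,
                         border = rep_len(border, n)))
}

# tiny two-cell wall image: two rooms separated by a bright 2-px wall
twoCellImage <- function(n = 64, wallRows = 32:33, bright = 200, dim = 30) {
  img <- matrix(dim, n, n)
  img[wallRows, ] <- bright
  img
}
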