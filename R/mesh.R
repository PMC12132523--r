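#' Build a polygonal cell mesh
#'
#' Generates a jittered hexagonal tessellation of the field: cell centres on
#' a hexagonal lattice whose spacing is calibrated so the mean
#' equivalent-circle diameter of the cells equals `meanCellDiameter`, with
#' the shared cell vertices perturbed by a small Gaussian jitter so cells
#' are irregular polygons, as in an epithelial sheet. Each vertex is shared
#' by up to three cells (a tricellular junction), each edge by up to two.
#'
#' @param fieldSize numeric(1 or 2), field extent in \eqn{\mu m}.
#' @param meanCellDiameter target mean equivalent diameter, \eqn{\mu m}
#'   (default 6).
#' @param seed integer; the mesh is deterministic given the seed.
#' @param jitterFraction vertex jitter SD as a fraction of the cell diameter
#'   (default 0.07; small enough that polygons stay simple).
#' @return a [TissueMesh-class].
#' @examples
#' mesh <- buildCellMesh(c(60, 60), 6, seed = 1)
#' mesh
#' @export
buildCellMesh <- function(fieldSize, meanCellDiameter = 6, seed = 1L,
                          jitterFraction = 0.07) {
  fieldSize <- rep(as.numeric(fieldSize), length.out = 2L)
  d <- meanCellDiameter
  if (any(fieldSize < 2 * d))
    stopInvalidConfig("field must be at least twice the cell diameter")
  # hexagon of area pi (d/2)^2 has centre spacing a with area sqrt(3)/2 a^2
  a <- d * sqrt(pi / (2 * sqrt(3)))
  r <- a / sqrt(3)                      # circumradius
  dy <- a * sqrt(3) / 2
  jitterSd <- jitterFraction * d

  withr::with_seed(as.integer(seed), {
    ni <- ceiling(fieldSize[1L] / a) + 2L
    nj <- ceiling(fieldSize[2L] / dy) + 2L
    centers <- do.call(rbind, lapply(seq(-1L, nj), function(j) {
      cbind(a * (seq(-1L, ni) + 0.5 * (j %% 2L)), dy * j)
    }))
    # six corners per hexagon (pointy-top), keyed on a snapped grid so
    # shared corners dedupe exactly
    ang <- pi / 6 + (0:5) * pi / 3
    corner_dx <- r * cos(ang)
    corner_dy <- r * sin(ang)
    nC <- nrow(centers)
    cx <- rep(centers[, 1L], each = 6L) + rep(corner_dx, nC)
    cy <- rep(centers[, 2L], each = 6L) + rep(corner_dy, nC)
    key <- paste(round(cx * 1e4), round(cy * 1e4))
    uidx <- !duplicated(key)
    vid <- match(key, key[uidx])
    verts <- cbind(cx[uidx], cy[uidx])
    verts <- verts + matrix(rnorm(length(verts), 0, jitterSd), ncol = 2L)

    cells <- split(vid, rep(seq_len(nC), each = 6L))
    keep <- centers[, 1L] >= -a & centers[, 1L] <= fieldSize[1L] + a &
      centers[, 2L] >= -a & centers[, 2L] <= fieldSize[2L] + a
    cells <- unname(cells[keep])

    e1 <- unlist(cells)
    e2 <- unlist(lapply(cells, function(v) c(v[-1L], v[1L])))
    edges <- cbind(pmin(e1, e2), pmax(e1, e2))
    edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L])), , drop = FALSE]

    new("TissueMesh", vertices = verts, edges = edges, cells = cells,
        meanCellDiameter = d, fieldSize = fieldSize)
  })
}

#' Equivalent-circle diameters of mesh cells
#'
#' Shoelace polygon areas converted to equivalent-circle diameters,
#' restricted to cells fully inside the field.
#'
#' @param mesh a [TissueMesh-class].
#' @return numeric vector of diameters, \eqn{\mu m}.
#' @export
meshCellDiameters <- function(mesh) {
  inside <- vapply(mesh@cells, function(idx) {
    v <- mesh@vertices[idx, , drop = FALSE]
    all(v[, 1L] >= 0 & v[, 1L] <= mesh@fieldSize[1L] &
          v[, 2L] >= 0 & v[, 2L] <= mesh@fieldSize[2L])
  }, logical(1L))
  areas <- vapply(mesh@cells[inside], function(idx) {
    v <- mesh@vertices[idx, , drop = FALSE]
    x <- v[, 1L]; y <- v[, 2L]
    abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  }, numeric(1L))
  2 * sqrt(areas / pi)
}
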