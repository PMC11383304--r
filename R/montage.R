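#' Standard 61-channel scalp montage
#'
#' Builds a schematic International 10-10 electrode layout: 61 scalp
#' channels (the analysis grid that remains after the mastoid references
#' are removed), optionally extended with the two mastoid reference
#' channels `TP9`/`TP10`. Positions are computed from idealized spherical
#' coordinates and projected to 2-D with an azimuthal-equidistant
#' projection (vertex `Cz` at the origin, ear level at radius 0.5).
#'
#' The layout is schematic, not digitized: it preserves the relative
#' ordering and neighborhood structure of the 10-10 system, which is what
#' the adjacency-based cluster statistics and spatial smoothing consume.
#'
#' @param include_references logical; append mastoid channels `TP9`, `TP10`.
#' @return A data.frame with columns `name`, `x`, `y` (2-D projection) and
#'   attribute-free numeric 3-D coordinates in columns `X3`, `Y3`, `Z3`.
#' @export
standard_montage <- function(include_references = FALSE) {
  rows <- list(
    Fp = list(m = 72, idx = c(1, 2)),
    AF = list(m = 54, idx = c(7, 3, 4, 8)),
    F  = list(m = 36, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    FC = list(m = 18, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),  # FT7/FT8 at +-7
    C  = list(m = 0,  idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),  # T7/T8 at +-7
    CP = list(m = -18, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)), # TP7/TP8 at +-7
    P  = list(m = -36, idx = c(7, 5, 3, 1, 0, 2, 4, 6, 8)),
    PO = list(m = -54, idx = c(7, 3, 0, 4, 8)),
    O  = list(m = -72, idx = c(1, 0, 2))
  )
  name_for <- function(row, i) {
    if (i == 0) return(paste0(row, "z"))
    side7 <- c(FC = "FT", C = "T", CP = "TP")
    base <- if (i >= 7 && row %in% names(side7)) side7[[row]] else row
    if (base == "T") paste0(base, i) else paste0(base, i)
  }
  out <- list()
  for (row in names(rows)) {
    m <- rows[[row]]$m
    for (i in rows[[row]]$idx) {
      lat <- 22.5 * ceiling(i / 2)            # lateral angle magnitude
      if (i %% 2 == 1) lat <- -lat            # odd indices on the left
      nm <- name_for(row, i)
      out[[nm]] <- c(m = m, l = lat)
    }
  }
  # extra low frontal-temporal sites to complete the 61-channel grid
  out[["FT9"]] <- c(m = 18, l = -101.25)
  out[["FT10"]] <- c(m = 18, l = 101.25)
  if (include_references) {
    out[["TP9"]] <- c(m = -18, l = -101.25)
    out[["TP10"]] <- c(m = -18, l = 101.25)
  }
  ang <- do.call(rbind, out)
  m <- ang[, "m"] * pi / 180
  l <- ang[, "l"] * pi / 180
  # vertex (0,0,1) tilted forward by m about the left-right axis, then
  # rotated laterally by l about the front-back axis
  x3 <- cos(m) * sin(l)
  y3 <- sin(m)
  z3 <- cos(m) * cos(l)
  theta <- acos(pmin(pmax(z3, -1), 1))
  phi <- atan2(x3, y3)
  r <- theta / pi                          # ear level (theta = pi/2) -> 0.5
  df <- data.frame(
    name = rownames(ang),
    x = r * sin(phi),
    y = r * cos(phi),
    X3 = x3, Y3 = y3, Z3 = z3,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

#' Electrode adjacency from Delaunay triangulation
#'
#' Computes the Delaunay triangulation of the 2-D projected electrode
#' positions by the empty-circumcircle criterion and returns the symmetric
#' adjacency matrix of its edges, after pruning edges longer than
#' `prune_factor` times the median edge length (which removes spurious
#' long-range links along the convex hull).
#'
#' @param montage data.frame as returned by [standard_montage()].
#' @param prune_factor numeric; edges longer than this multiple of the
#'   median Delaunay edge length are dropped. Default 1.8.
#' @return logical adjacency matrix (channels x channels), symmetric with
#'   a `FALSE` diagonal, dimnames set to channel names.
#' @export
montage_adjacency <- function(montage, prune_factor = 1.8) {
  pts <- as.matrix(montage[, c("x", "y")])
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 electrodes for a triangulation")
  tri <- utils::combn(n, 3)
  ax <- pts[tri[1, ], 1]; ay <- pts[tri[1, ], 2]
  bx <- pts[tri[2, ], 1]; by <- pts[tri[2, ], 2]
  cx <- pts[tri[3, ], 1]; cy <- pts[tri[3, ], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  bad <- abs(d) < 1e-12
  d[bad] <- 1
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ax - ux)^2 + (ay - uy)^2
  r2[bad] <- Inf
  # a triangle is Delaunay iff no other point lies strictly inside its
  # circumcircle
  dx <- outer(ux, pts[, 1], "-")
  dy <- outer(uy, pts[, 2], "-")
  inside <- (dx^2 + dy^2) < (r2 - 1e-12)
  # points of the triangle itself sit on the circle; mask them
  for (k in 1:3) inside[cbind(seq_len(ncol(tri)), tri[k, ])] <- FALSE
  keep <- !bad & rowSums(inside) == 0
  tri <- tri[, keep, drop = FALSE]
  adj <- matrix(FALSE, n, n, dimnames = list(montage$name, montage$name))
  edges <- cbind(c(tri[1, ], tri[1, ], tri[2, ]),
                 c(tri[2, ], tri[3, ], tri[3, ]))
  len <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                       pts[edges[, 2], , drop = FALSE])^2))
  cutoff <- prune_factor * stats::median(len)
  edges <- edges[len <= cutoff, , drop = FALSE]
  adj[edges] <- TRUE
  adj[edges[, 2:1, drop = FALSE]] <- TRUE
  diag(adj) <- FALSE
  adj
}
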