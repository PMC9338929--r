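#' Neighborhood context of a spot for one cell type
#'
#' Splits the plane around the spot center into four axis-aligned 90-degree
#' sectors (angles measured counter-clockwise from the +x axis, quadrant q
#' covering (90q-90, 90q] degrees), picks the nearest neighbor spot within
#' each sector, and records that neighbor's fitted proportion of the given
#' cell type. Sectors with no spot (tissue edge) get ratio 0 and the
#' minimum distance over populated sectors, so the sampler can still point
#' there.
#'
#' @param spot spot id.
#' @param type cell type whose local ratio is wanted.
#' @param composition a \linkS4class{Composition} fitted on the spots.
#' @param coords spot coordinate data.frame (rownames = spot ids, columns
#'   x, y).
#' @return list with \code{spot}, \code{type}, \code{center} (x0, y0),
#'   \code{centerRatio}, and \code{quadrants}: a 4-row data.frame with
#'   columns \code{q}, \code{neighbor}, \code{dist}, \code{R},
#'   \code{real} (whether the sector had a spot).
#' @export
computeNeighborContext <- function(spot, type, composition, coords) {
  stopifnot(spot %in% rownames(coords))
  P <- compositionProps(composition)
  stopifnot(type %in% rownames(P))
  others <- setdiff(rownames(coords), spot)
  if (length(others) == 0) stop("spot ", spot, " has no neighbor spots")
  x0 <- coords[spot, "x"]; y0 <- coords[spot, "y"]
  dx <- coords[others, "x"] - x0
  dy <- coords[others, "y"] - y0
  d <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) * 180 / pi      # (-180, 180]
  ang <- ifelse(ang <= 0, ang + 360, ang)  # (0, 360]
  q <- pmin(ceiling(ang / 90), 4L)
  quad <- data.frame(q = 1:4, neighbor = NA_character_, dist = NA_real_,
                     R = 0, real = FALSE, stringsAsFactors = FALSE)
  for (qq in 1:4) {
    in_q <- which(q == qq)
    if (length(in_q)) {
      nn <- in_q[order(d[in_q], others[in_q])][1]
      quad$neighbor[qq] <- others[nn]
      quad$dist[qq] <- d[nn]
      quad$R[qq] <- P[type, others[nn]]
      quad$real[qq] <- TRUE
    }
  }
  dmin <- min(quad$dist, na.rm = TRUE)
  quad$dist[!quad$real] <- dmin
  list(spot = spot, type = type, center = c(x = x0, y = y0),
       centerRatio = unname(P[type, spot]), quadrants = quad)
}

# Vectorized coordinate sampler; returns one row per placed cell.
.samplePlacements <- function(ctx, n) {
  quad <- ctx$quadrants
  pq <- (quad$R + 1) / sum(quad$R + 1)
  q <- sample.int(4L, n, replace = TRUE, prob = pq)
  theta <- stats::runif(n, 90 * q - 90, 90 * q)
  dmin <- quad$dist[q]
  Rtheta <- quad$R[q]
  Rc <- ctx$centerRatio
  pLow <- (Rc + 1) / (Rc + Rtheta + 2)
  low <- stats::runif(n) < pLow
  alpha <- ifelse(low, stats::runif(n, 0, 0.5), stats::runif(n, 0.5, 1))
  x <- ctx$center[["x"]] + alpha * dmin * cos(theta * pi / 180) / 2
  y <- ctx$center[["y"]] + alpha * dmin * sin(theta * pi / 180) / 2
  data.frame(q = q, theta = theta, alpha = alpha, dmin = dmin, x = x, y = y)
}

#' Sample a coordinate for one cell inside a spot
#'
#' Draws a sector with probability proportional to the same-type neighbor
#' ratio plus one, an angle uniform within the sector, and a radius weight
#' alpha in (0, 0.5] with probability (R_center+1)/(R_center+R_theta+2)
#' (else (0.5, 1]), then offsets the spot center by
#' \code{alpha * dmin * (cos, sin)(theta) / 2}, where dmin is the distance
#' to the chosen sector's nearest neighbor. The placement therefore lies
#' within half the neighbor distance of the spot center.
#'
#' @param ctx a context from \code{\link{computeNeighborContext}}.
#' @param n number of placements to draw.
#' @return data.frame with columns \code{q}, \code{theta}, \code{alpha},
#'   \code{dmin}, \code{x}, \code{y}.
#' @export
sampleCellCoordinate <- function(ctx, n = 1) {
  stopifnot(n >= 1)
  .samplePlacements(ctx, n)
}

#' Reconstruct a single-cell atlas from spot-level data
#'
#' Places every reference cell selected by
#' \code{\link{selectSpotCells}} at a sampled coordinate within its spot's
#' neighborhood; with \code{maxCells = 1} (near-cellular platforms) the
#' coordinate sampler is bypassed and cells sit exactly at the spot
#' centers. Atlas expression is the selected reference cells' raw counts.
#'
#' @param st spot-level \linkS4class{STData} with coordinates.
#' @param composition \linkS4class{Composition} over the spots.
#' @param combinations named list (per spot) from
#'   \code{\link{selectSpotCells}}.
#' @param ref reference \linkS4class{STData}.
#' @param config a \linkS4class{RunConfig}.
#' @return a \linkS4class{CellAtlas}.
#' @export
reconstructAtlas <- function(st, composition, combinations, ref,
                             config = runConfig()) {
  stopifnot(is(st, "STData"), nrow(spatialCoords(st)) > 0)
  coords <- spatialCoords(st)
  singleCell <- config@maxCells == 1L
  rows <- list()
  cellCounter <- 0L
  for (spot in names(combinations)) {
    sel <- combinations[[spot]]
    if (length(sel$cells) == 0) next
    df <- data.frame(type = sel$types, ref_cell = sel$cells,
                     stringsAsFactors = FALSE)
    if (singleCell) {
      df$x <- coords[spot, "x"]; df$y <- coords[spot, "y"]
      df$alpha <- NA_real_; df$theta <- NA_real_
    } else {
      df$x <- NA_real_; df$y <- NA_real_
      df$alpha <- NA_real_; df$theta <- NA_real_
      for (tp in unique(df$type)) {
        idx <- which(df$type == tp)
        ctx <- computeNeighborContext(spot, tp, composition, coords)
        pl <- .samplePlacements(ctx, length(idx))
        df$x[idx] <- pl$x; df$y[idx] <- pl$y
        df$alpha[idx] <- pl$alpha; df$theta[idx] <- pl$theta
      }
    }
    df$spot <- spot
    df$cell <- paste0("cell", cellCounter + seq_len(nrow(df)))
    cellCounter <- cellCounter + nrow(df)
    rows[[spot]] <- df
  }
  placements <- do.call(rbind, rows)
  if (is.null(placements)) stop("no cells selected in any spot")
  rownames(placements) <- NULL
  placements <- placements[, c("cell", "type", "x", "y", "spot",
                               "ref_cell", "alpha", "theta")]
  cnt <- assayCounts(ref)[, placements$ref_cell, drop = FALSE]
  colnames(cnt) <- placements$cell
  expr <- STData(cnt, coords = data.frame(x = placements$x,
                                          y = placements$y,
                                          row.names = placements$cell))
  new("CellAtlas", placements = placements, expr = expr)
}

#' Build a single-cell atlas from observed single-cell ST data
#'
#' For single-cell resolution platforms no reconstruction is needed: the
#' observed cells, their assigned labels, and their measured coordinates
#' form the atlas directly.
#'
#' @param st single-cell \linkS4class{STData} with coordinates.
#' @param labels data.frame from \code{\link{assignCellLabels}} or a named
#'   character vector cell -> type.
#' @param dropUnsure drop cells labeled "unsure" (default TRUE).
#' @return a \linkS4class{CellAtlas}.
#' @export
atlasFromLabels <- function(st, labels, dropUnsure = TRUE) {
  stopifnot(is(st, "STData"), nrow(spatialCoords(st)) > 0)
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$type, labels$unit)
  } else lab <- labels
  cells <- unitNames(st)
  stopifnot(all(cells %in% names(lab)))
  lab <- lab[cells]
  keep <- if (dropUnsure) lab != "unsure" else rep(TRUE, length(lab))
  cells <- cells[keep]
  coords <- spatialCoords(st)[cells, , drop = FALSE]
  placements <- data.frame(cell = cells, type = unname(lab[cells]),
                           x = coords$x, y = coords$y, spot = cells,
                           ref_cell = cells, alpha = NA_real_,
                           theta = NA_real_, stringsAsFactors = FALSE)
  new("CellAtlas", placements = placements, expr = st[, cells])
}
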