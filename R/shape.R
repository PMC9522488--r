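#' Trace the outer boundary of a mask
#'
#' Moore-neighbour tracing of the closed 8-connected outer boundary of a
#' single-component mask, starting from the topmost-then-leftmost boundary
#' pixel and proceeding counter-clockwise (down the left flank first, in
#' screen coordinates). Deterministic; a single-pixel mask yields a
#' length-one sequence.
#'
#' @param mask Logical matrix with exactly one 8-connected component.
#' @return An `n x 2` matrix of `(row, col)` boundary pixels in traversal
#'   order (the chain is closed: the last pixel is 8-adjacent to the first).
#' @export
trace_boundary <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 1L) {
    return(matrix(pts[1L, ], 1L, 2L, dimnames = list(NULL, c("row", "col"))))
  }
  if (n_components(mask) != 1L) {
    stop("mask must have exactly one 8-connected component", call. = FALSE)
  }
  # start: topmost row, then leftmost column
  ord <- order(pts[, 1L], pts[, 2L])
  start <- pts[ord[1L], ]
  # neighbour ring, counter-clockwise in screen coordinates starting at "up"
  ring <- cbind(c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L))
  h <- nrow(mask); w <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]
  ring_index <- function(dr, dc) {
    which(ring[, 1L] == dr & ring[, 2L] == dc)
  }
  cur <- start
  back_dir <- 1L # backtrack direction: up (known background for the start pixel)
  chain <- matrix(0L, 4L * nrow(pts) + 8L, 2L)
  chain[1L, ] <- cur
  n_chain <- 1L
  first_move <- NULL
  repeat {
    found <- FALSE
    for (s in 1:8) {
      k <- ((back_dir - 1L + s - 1L) %% 8L) + 1L
      nr <- cur[1L] + ring[k, 1L]; nc <- cur[2L] + ring[k, 2L]
      if (inside(nr, nc)) {
        # new backtrack: direction from the new pixel to the last background
        # neighbour scanned before it
        prev_k <- ((k - 2L) %% 8L) + 1L
        pr <- cur[1L] + ring[prev_k, 1L]; pc <- cur[2L] + ring[prev_k, 2L]
        back_dir <- ring_index(pr - nr, pc - nc)
        cur <- c(nr, nc)
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel group (cannot happen for n > 1 connected)
    move <- c(cur, back_dir)
    if (is.null(first_move)) {
      first_move <- move
    } else if (all(move == first_move)) {
      break # Jacob's stopping criterion: same pixel entered the same way
    }
    n_chain <- n_chain + 1L
    if (n_chain > nrow(chain)) break # safety net
    chain[n_chain, ] <- cur
  }
  # drop a duplicated closing start pixel if present
  if (n_chain > 1L && all(chain[n_chain, ] == start)) n_chain <- n_chain - 1L
  out <- chain[seq_len(n_chain), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Chord-based shape descriptors of a segmented mask
#'
#' The seven geometric features of a lesion mask: pixel-count area, convex
#' area (pixel count of the rasterised convex hull of the pixel centres),
#' perimeter (sum of Euclidean steps, 1 or `sqrt(2)`, along the closed
#' traced boundary), major axis length (largest pairwise distance between
#' convex-hull vertices, i.e. the longest chord across the shape), minor
#' axis length (hull width measured perpendicular to the major-axis
#' direction), eccentricity and solidity.
#'
#' Note the axis convention: eccentricity here is `minor / major`, the
#' short-to-long chord ratio -- 1 for a circle and 0 for a line, the reverse
#' of the conic-section convention. Smooth round masses score near 1 in both
#' eccentricity and solidity; spiculated masses score markedly lower
#' solidity.
#'
#' @param mask Logical matrix with one 8-connected component and at least
#'   one `TRUE` pixel.
#' @return A one-row tibble with columns `shape_area`, `shape_convex_area`,
#'   `shape_perimeter`, `shape_major_axis`, `shape_minor_axis`,
#'   `shape_eccentricity`, `shape_solidity`.
#' @examples
#' m <- matrix(FALSE, 12, 12); m[4:9, 4:9] <- TRUE
#' shape_features(m)
#' @export
shape_features <- function(mask) {
  assert_mask(mask)
  area <- sum(mask)
  if (area == 0L) stop("mask is empty", call. = FALSE)
  pts <- which(mask, arr.ind = TRUE) # (row, col) centres
  if (area == 1L) {
    return(tibble::tibble(
      shape_area = 1, shape_convex_area = 1, shape_perimeter = 0,
      shape_major_axis = 0, shape_minor_axis = 0,
      shape_eccentricity = 0, shape_solidity = 1
    ))
  }
  boundary <- trace_boundary(mask)
  per <- if (nrow(boundary) > 1L) {
    closed <- rbind(boundary, boundary[1L, ])
    sum(sqrt(rowSums(diff(closed)^2)))
  } else 0
  x <- pts[, 2L]; y <- pts[, 1L]
  hull_idx <- grDevices::chull(x, y)
  hx <- x[hull_idx]; hy <- y[hull_idx]
  # degenerate (collinear) hull: the mask itself is the hull
  poly_area <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
  if (length(hull_idx) < 3L || poly_area == 0) {
    convex_area <- area
  } else {
    cand_x <- rep(min(x):max(x), times = max(y) - min(y) + 1L)
    cand_y <- rep(min(y):max(y), each = max(x) - min(x) + 1L)
    inside <- pracma::inpolygon(cand_x, cand_y, hx, hy, boundary = TRUE)
    convex_area <- max(sum(inside), area)
  }
  # longest chord over hull vertex pairs
  hp <- cbind(hx, hy)
  d2 <- as.matrix(stats::dist(hp))
  best <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
  major <- d2[best[1L], best[2L]]
  if (major == 0) {
    minor <- 0; ecc <- 0
  } else {
    u <- (hp[best[2L], ] - hp[best[1L], ]) / major
    perp <- c(-u[2L], u[1L])
    proj <- hp %*% perp
    minor <- max(proj) - min(proj)
    ecc <- minor / major
  }
  tibble::tibble(
    shape_area = as.numeric(area),
    shape_convex_area = as.numeric(convex_area),
    shape_perimeter = per,
    shape_major_axis = major,
    shape_minor_axis = minor,
    shape_eccentricity = ecc,
    shape_solidity = area / convex_area
  )
}
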