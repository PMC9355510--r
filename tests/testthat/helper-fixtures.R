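# Shared fixtures and independent oracles, built in code at test time.

# Build a TrackSet from coordinate vectors of a single cell.
make_track <- function(x, y, dt_h = 1 / 3, surface = flatSpec(),
                       unwrapped = TRUE, cell_id = "c1") {
  n <- length(x)
  trackSet(data.frame(cell_id = cell_id, frame = seq_len(n) - 1L,
                      time_h = (seq_len(n) - 1L) * dt_h, x_um = x, y_um = y),
           surface = surface, unwrapped = unwrapped)
}

# Combine several single-cell coordinate lists into one TrackSet.
make_tracks <- function(xs, ys, dt_h = 1 / 3, surface = flatSpec(),
                        unwrapped = TRUE) {
  dfs <- lapply(seq_along(xs), function(i) {
    n <- length(xs[[i]])
    data.frame(cell_id = sprintf("c%03d", i), frame = seq_len(n) - 1L,
               time_h = (seq_len(n) - 1L) * dt_h,
               x_um = xs[[i]], y_um = ys[[i]])
  })
  trackSet(do.call(rbind, dfs), surface = surface, unwrapped = unwrapped)
}

# Rasterize a disk: labeled matrix fixture.
raster_disk <- function(radius_px, canvas = NULL, label = 1L) {
  if (is.null(canvas)) canvas <- rep(2L * ceiling(radius_px) + 11L, 2)
  cx <- canvas[2] / 2; cy <- canvas[1] / 2
  m <- matrix(0L, canvas[1], canvas[2])
  for (i in seq_len(canvas[1])) {
    dx2 <- ((seq_len(canvas[2]) - 0.5) - cx)^2
    inside <- dx2 + ((i - 0.5) - cy)^2 <= radius_px^2
    m[i, inside] <- label
  }
  m
}

# Rasterize an axis-misalignable ellipse via the package-internal rasterizer
# is avoided here: tests that need an independent raster construct it
# directly with this plain loop (semi-axes a, b in px, rotation theta).
raster_ellipse <- function(a_px, b_px, theta = 0, canvas = NULL, label = 1L) {
  if (is.null(canvas)) canvas <- rep(2L * ceiling(a_px) + 11L, 2)
  cx <- canvas[2] / 2; cy <- canvas[1] / 2
  m <- matrix(0L, canvas[1], canvas[2])
  ct <- cos(theta); st <- sin(theta)
  for (i in seq_len(canvas[1])) {
    xd <- (seq_len(canvas[2]) - 0.5) - cx
    yd <- (i - 0.5) - cy
    u <- ct * xd + st * yd
    v <- -st * xd + ct * yd
    m[i, (u / a_px)^2 + (v / b_px)^2 <= 1] <- label
  }
  m
}

# Plus-sign fixture: two crossing bars.
raster_plus <- function(arm = 30L, width = 10L, canvas = 91L) {
  m <- matrix(0L, canvas, canvas)
  mid <- (canvas + 1L) %/% 2
  half_w <- width %/% 2
  m[(mid - half_w):(mid + half_w - 1L), (mid - arm):(mid + arm)] <- 1L
  m[(mid - arm):(mid + arm), (mid - half_w):(mid + half_w - 1L)] <- 1L
  m
}

# --- Independent convex-hull oracle ----------------------------------------
# Gift-wrapping hull + even-odd ray-cast point-in-polygon, written without
# chull()/inpolygon() so it is an independent check of the solidity path.

oracle_hull <- function(x, y) {
  n <- length(x)
  start <- which.min(x + y * 1e-9)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (n == 1L) p else setdiff(seq_len(n), p)[1]
    for (q in seq_len(n)) {
      if (q == p) next
      cr <- (x[cand] - x[p]) * (y[q] - y[p]) - (y[cand] - y[p]) * (x[q] - x[p])
      d_cand <- (x[cand] - x[p])^2 + (y[cand] - y[p])^2
      d_q <- (x[q] - x[p])^2 + (y[q] - y[p])^2
      if (cr < 0 || (abs(cr) < 1e-12 && d_q > d_cand)) cand <- q
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > n) break
  }
  cbind(x = x[hull], y = y[hull])
}

oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py)
    xin <- px < (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & xin)
    j <- i
  }
  inside
}

# On-boundary test for the hull polygon (within eps of an edge segment).
oracle_on_boundary <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  on <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    len2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / len2))
    d2 <- (ax + t * (bx - ax) - px)^2 + (ay + t * (by - ay) - py)^2
    on <- on | d2 < eps
  }
  on
}

# Solidity of a labeled object by the independent oracle.
oracle_solidity <- function(mask_matrix, label = 1L) {
  idx <- which(mask_matrix == label)
  r <- ((idx - 1L) %% nrow(mask_matrix)) + 1L
  cl <- ((idx - 1L) %/% nrow(mask_matrix)) + 1L
  xc <- cl - 0.5; yc <- r - 0.5
  poly <- oracle_hull(xc, yc)
  if (nrow(poly) < 3L) return(1)
  grid_x <- floor(min(xc)):ceiling(max(xc))
  grid_y <- floor(min(yc)):ceiling(max(yc))
  gx <- rep(grid_x, times = length(grid_y))
  gy <- rep(grid_y, each = length(grid_x))
  inside <- oracle_point_in_poly(gx, gy, poly) | oracle_on_boundary(gx, gy, poly)
  length(idx) / sum(inside)
}

# Brute-force minimal-total-distance matching for <= 7 points per side.
oracle_optimal_matching <- function(old_xy, new_xy, gate) {
  n_old <- nrow(old_xy); n_new <- nrow(new_xy)
  d <- sqrt(outer(old_xy[, 1], new_xy[, 1], "-")^2 +
            outer(old_xy[, 2], new_xy[, 2], "-")^2)
  d[d > gate] <- NA
  best <- NULL; best_cost <- Inf; best_n <- -1L
  assign_rec <- function(i, used, pairs, cost) {
    if (i > n_old) {
      np <- nrow(pairs)
      if (np > best_n || (np == best_n && cost < best_cost)) {
        best <<- pairs; best_cost <<- cost; best_n <<- np
      }
      return(invisible())
    }
    assign_rec(i + 1L, used, pairs, cost)        # leave old i unmatched
    for (j in seq_len(n_new)) {
      if (used[j] || is.na(d[i, j])) next
      used[j] <- TRUE
      assign_rec(i + 1L, used, rbind(pairs, c(i, j)), cost + d[i, j])
      used[j] <- FALSE
    }
  }
  assign_rec(1L, rep(FALSE, n_new), matrix(integer(0), ncol = 2), 0)
  list(pairs = best, cost = best_cost)
}
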