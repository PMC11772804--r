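## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so simulators are deterministic
#' given their own seed without disturbing the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Otsu threshold of an arbitrary-dimensional intensity array
#'
#' EBImage's otsu() operates on 2D grayscale frames; pooling all voxels into a
#' single-column image gives the histogram-wide threshold.
#' @noRd
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  hi <- max(v)
  if (hi <= 0) return(Inf)                      # blank input: nothing passes
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)), range = c(0, hi))
}

## Minimal union-find over integer ids 1..n (path compression, no rank).
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

#' 3D connected-component labelling of a binary array (6-connectivity)
#'
#' Labels each z-plane with EBImage::bwlabel, then merges components that
#' overlap between adjacent planes.
#' @return integer array of the same dim; 0 = background
#' @noRd
label_components_3d <- function(mask) {
  dm <- dim(mask)
  stopifnot(length(dm) == 3L)
  nz <- dm[3]
  lab <- array(0L, dm)
  offset <- 0L
  for (k in seq_len(nz)) {
    lk <- EBImage::bwlabel(matrix(as.numeric(mask[, , k] > 0), dm[1], dm[2]))
    lk <- as.integer(lk)
    n_k <- max(lk, 0L)
    pos <- lk > 0L
    lk[pos] <- lk[pos] + offset
    lab[, , k] <- lk
    offset <- offset + n_k
  }
  if (offset == 0L) return(lab)
  parent <- uf_new(offset)
  for (k in seq_len(nz - 1L)) {
    a <- lab[, , k]
    b <- lab[, , k + 1L]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (r in seq_len(nrow(pairs))) {
      parent <- uf_union(parent, pairs[r, 1L], pairs[r, 2L])
    }
  }
  root <- vapply(seq_len(offset), function(i) uf_find(parent, i), integer(1))
  ## compact to 1..n in order of first appearance (raster order of component
  ## minimum, since original labels increase in raster order within planes)
  uroot <- sort(unique(root))
  remap <- integer(offset)
  remap[uroot] <- seq_along(uroot)
  newlab <- c(0L, remap[root])[lab + 1L]
  array(newlab, dm)
}

#' Pixel-center coordinate grids for an ny x nx frame (1-based)
#' @return list(x = nx-col matrix of x coords, y = matrix of y coords)
#' @noRd
pixel_grid <- function(ny, nx) {
  list(
    x = matrix(rep(seq_len(nx), each = ny), ny, nx),
    y = matrix(rep(seq_len(ny), times = nx), ny, nx)
  )
}

#' Nearest-site assignment of every pixel to one of a set of xy sites
#'
#' Ties go to the smaller site index (strict improvement required to switch).
#' @return integer matrix [ny, nx] of site indices
#' @noRd
nearest_site_map <- function(ny, nx, site_x, site_y) {
  n <- length(site_x)
  best_d <- matrix(Inf, ny, nx)
  best_i <- matrix(0L, ny, nx)
  ## box-limited pass: each site only competes within a window of half-width h.
  ## An assignment at euclidean distance <= h is provably exact (the true
  ## nearest site would lie inside a box covering the pixel); the rest get a
  ## full scan below.
  h <- ceiling(3 * sqrt(ny * nx / n)) + 1
  for (i in seq_len(n)) {
    yi <- max(1L, floor(site_y[i] - h)):min(ny, ceiling(site_y[i] + h))
    xi <- max(1L, floor(site_x[i] - h)):min(nx, ceiling(site_x[i] + h))
    d <- outer((yi - site_y[i])^2, (xi - site_x[i])^2, `+`)
    upd <- d < best_d[yi, xi]
    if (any(upd)) {
      bd <- best_d[yi, xi]; bi <- best_i[yi, xi]
      bd[upd] <- d[upd]; bi[upd] <- i
      best_d[yi, xi] <- bd; best_i[yi, xi] <- bi
    }
  }
  left <- which(best_d > h^2 | best_i == 0L)
  if (length(left) > 0L) {
    py <- ((left - 1L) %% ny) + 1L
    px <- ((left - 1L) %/% ny) + 1L
    dfull <- (matrix(px, length(left), n) - matrix(site_x, length(left), n,
                                                   byrow = TRUE))^2 +
             (matrix(py, length(left), n) - matrix(site_y, length(left), n,
                                                   byrow = TRUE))^2
    best_i[left] <- max.col(-dfull, ties.method = "first")
  }
  best_i
}

`%||%` <- function(a, b) if (is.null(a)) b else a
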