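#' Suitability landscapes
#'
#' A `suitability_landscape` is a time-indexed stack of gridded habitat
#' suitability values in \[0, 1\] on a planar km grid, optionally with a
#' friction layer (1 = impassable) and a domain mask.  Each layer ("slice")
#' is valid on an interval of years BP; intervals are contiguous and
#' non-overlapping, and BP decreases as simulation time advances, so the
#' landscape is piecewise stationary with abrupt changes at slice boundaries.
#'
#' Grids are stored as matrices with `mat[i, j]` the cell centred at
#' `origin + (c(i, j) - 0.5) * cell_size`; `origin` is the lower-left corner
#' of cell (1, 1).
#'
#' @param suitability list of numeric matrices (one per slice), values in
#'   \[0, 1\], all the same shape.
#' @param slice_bp data frame with columns `t_start_bp`, `t_end_bp` (years BP,
#'   start > end), one row per slice, intervals contiguous.
#' @param origin numeric length-2, km coordinates of the grid corner.
#' @param cell_size cell edge length, km.
#' @param friction optional matrix in \[0, 1\] (1 = impassable), same shape.
#' @param domain_mask optional logical matrix; cells outside the mask are
#'   treated as suitability 0 and impassable.
#' @return A `suitability_landscape` object.
#' @export
landscape <- function(suitability, slice_bp, origin = c(0, 0), cell_size = 1,
                      friction = NULL, domain_mask = NULL) {
  if (!is.list(suitability) || length(suitability) == 0)
    stop("`suitability` must be a non-empty list of matrices", call. = FALSE)
  dims <- dim(suitability[[1]])
  for (m in suitability) {
    if (!is.matrix(m) || !identical(dim(m), dims))
      stop("all suitability layers must be matrices of identical shape",
           call. = FALSE)
    if (anyNA(m) || any(m < 0) || any(m > 1))
      stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  slice_bp <- tibble::as_tibble(slice_bp)
  if (!all(c("t_start_bp", "t_end_bp") %in% names(slice_bp)))
    stop("`slice_bp` needs columns t_start_bp, t_end_bp", call. = FALSE)
  if (nrow(slice_bp) != length(suitability))
    stop("one slice interval per suitability layer required", call. = FALSE)
  if (any(slice_bp$t_start_bp <= slice_bp$t_end_bp))
    stop("slice intervals must have t_start_bp > t_end_bp (years BP)",
         call. = FALSE)
  o <- order(slice_bp$t_start_bp, decreasing = TRUE)
  slice_bp <- slice_bp[o, , drop = FALSE]
  suitability <- suitability[o]
  if (nrow(slice_bp) > 1) {
    gaps <- slice_bp$t_end_bp[-nrow(slice_bp)] - slice_bp$t_start_bp[-1]
    if (any(abs(gaps) > 1e-9))
      stop("slice intervals must be contiguous (gap or overlap found)",
           call. = FALSE)
  }
  if (!is.null(friction)) {
    if (!identical(dim(friction), dims))
      stop("friction layer shape must match suitability layers", call. = FALSE)
    if (anyNA(friction) || any(friction < 0) || any(friction > 1))
      stop("friction values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(domain_mask)) {
    if (!identical(dim(domain_mask), dims))
      stop("domain mask shape must match suitability layers", call. = FALSE)
    suitability <- lapply(suitability, function(m) { m[!domain_mask] <- 0; m })
    if (is.null(friction)) friction <- matrix(0, dims[1], dims[2])
    friction[!domain_mask] <- 1
  }
  slice_bp$slice <- seq_len(nrow(slice_bp))
  structure(
    list(suitability = suitability, slice_bp = slice_bp,
         origin = as.numeric(origin), cell_size = as.numeric(cell_size),
         friction = friction, domain_mask = domain_mask,
         cache = new.env(parent = emptyenv())),
    class = "suitability_landscape")
}

#' @export
print.suitability_landscape <- function(x, ...) {
  d <- dim(x$suitability[[1]])
  cat(sprintf(
    "<suitability_landscape> %d x %d cells of %g km, %d slice(s), %g-%g BP%s\n",
    d[1], d[2], x$cell_size, length(x$suitability),
    max(x$slice_bp$t_start_bp), min(x$slice_bp$t_end_bp),
    if (is.null(x$friction)) "" else ", friction layer"))
  invisible(x)
}

#' Landscape-coupling parameters
#'
#' @param env_weight dimensionless scale of the environmental potential
#'   `V = -env_weight * s`; larger values make suitability gradients pull
#'   harder on camps.
#' @param kappa carrying-capacity coefficient, people per km^2 of fully
#'   suitable land.  The default supports ~60 people (one camp at the fission
#'   threshold) on a fully suitable foraging disc of radius 20 km.
#' @param sigma0 base Brownian noise scale, km month^-1/2.
#' @param barrier_sigma_floor minimum sigma multiplier in passable terrain.
#' @return A list of class `landscape_params`.
#' @export
landscape_params <- function(env_weight = 1, kappa = 60 / (pi * 20^2),
                             sigma0 = 0.4, barrier_sigma_floor = 0.01) {
  stopifnot(env_weight > 0, kappa > 0, sigma0 > 0,
            barrier_sigma_floor >= 0, barrier_sigma_floor < 1)
  structure(list(env_weight = env_weight, kappa = kappa, sigma0 = sigma0,
                 barrier_sigma_floor = barrier_sigma_floor),
            class = "landscape_params")
}

# index of the slice active at t_bp (last slice closed at its end)
slice_index <- function(L, t_bp) {
  sb <- L$slice_bp
  if (t_bp > max(sb$t_start_bp) || t_bp < min(sb$t_end_bp))
    stop(sprintf("time %g BP outside the covered horizon [%g, %g]",
                 t_bp, max(sb$t_start_bp), min(sb$t_end_bp)), call. = FALSE)
  i <- which(t_bp <= sb$t_start_bp & t_bp > sb$t_end_bp)
  if (length(i) == 0) i <- nrow(sb)  # t_bp == final t_end_bp
  i[1]
}

#' Interpolated suitability at positions
#'
#' Bilinear interpolation of the slice active at `t_bp`; returns 0 outside the
#' grid/domain.  Continuous within a slice, discontinuous only at slice
#' boundaries.
#'
#' @param L a [landscape()].
#' @param x,y positions, km (vectorised).
#' @param t_bp time, years BP.
#' @return numeric vector of suitability values in \[0, 1\].
#' @export
suitability_at <- function(L, x, y, t_bp) {
  g <- L$suitability[[slice_index(L, t_bp)]]
  cpp_bilinear(g, L$origin[1], L$origin[2], L$cell_size,
               as.numeric(x), as.numeric(y))
}

#' Gradient of the environmental potential
#'
#' The potential is `V(x, t) = -env_weight * s(x, t)`, so suitability maxima
#' are potential minima and the drift `-grad V` points uphill in suitability.
#' The gradient is taken by central finite differences on the bilinear
#' interpolant with step `cell_size / 2`.
#'
#' @inheritParams suitability_at
#' @param params a [landscape_params()].
#' @return matrix with one `(dV/dx, dV/dy)` row per position.
#' @export
potential_gradient <- function(L, params, x, y, t_bp) {
  g <- L$suitability[[slice_index(L, t_bp)]]
  -params$env_weight *
    cpp_grad(g, L$origin[1], L$origin[2], L$cell_size,
             as.numeric(x), as.numeric(y), L$cell_size / 2)
}

# friction at positions by containing-cell lookup; outside the grid -> 1
friction_at <- function(L, x, y) {
  if (is.null(L$friction)) {
    nx <- dim(L$suitability[[1]])[1]; ny <- dim(L$suitability[[1]])[2]
    inside <- x >= L$origin[1] & x <= L$origin[1] + nx * L$cell_size &
      y >= L$origin[2] & y <= L$origin[2] + ny * L$cell_size
    return(ifelse(inside, 0, 1))
  }
  cpp_cell_value(L$friction, L$origin[1], L$origin[2], L$cell_size,
                 as.numeric(x), as.numeric(y), outside = 1)
}

#' Friction-scaled noise amplitude
#'
#' `sigma(x) = sigma0 * (1 - friction(x))`, floored at
#' `barrier_sigma_floor * sigma0` in passable terrain and exactly 0 where
#' friction is 1 (impassable).  Without a friction layer, `sigma0` everywhere
#' inside the grid.
#'
#' @inheritParams potential_gradient
#' @return numeric vector of noise scales, km month^-1/2.
#' @export
sigma_at <- function(L, params, x, y) {
  fr <- friction_at(L, x, y)
  s <- params$sigma0 * (1 - fr)
  passable <- fr < 1
  s[passable] <- pmax(s[passable], params$barrier_sigma_floor * params$sigma0)
  s[!passable] <- 0
  s
}

#' Local carrying capacity
#'
#' Maximum number of people sustainable by foraging within radius `r1` of a
#' location: `K_t(x) = kappa * sum_{cells within r1 of x} s(cell, t) *
#' cell_area`, i.e. linear in the disc-integrated suitability.
#'
#' @inheritParams potential_gradient
#' @param r1 foraging / short-range interaction radius, km.
#' @return numeric vector, people.
#' @export
carrying_capacity <- function(L, params, x, y, t_bp, r1 = 20) {
  stopifnot(r1 > 0)
  g <- L$suitability[[slice_index(L, t_bp)]]
  cs <- L$cell_size
  nx <- nrow(g); ny <- ncol(g)
  cx <- L$origin[1] + (seq_len(nx) - 0.5) * cs
  cy <- L$origin[2] + (seq_len(ny) - 0.5) * cs
  vapply(seq_along(x), function(k) {
    ii <- which(abs(cx - x[k]) <= r1)
    jj <- which(abs(cy - y[k]) <= r1)
    if (length(ii) == 0 || length(jj) == 0) return(0)
    dd <- outer((cx[ii] - x[k])^2, (cy[jj] - y[k])^2, "+")
    sum(g[ii, jj, drop = FALSE][dd <= r1^2]) * cs^2 * params$kappa
  }, numeric(1))
}

# Precomputed carrying-capacity grid for one slice (disc convolution at cell
# centres); used by the engine, interpolated bilinearly between centres.
k_grid <- function(L, params, slice, r1) {
  key <- sprintf("k_%d_%g_%g", slice, r1, params$kappa)
  if (!is.null(L$cache[[key]])) return(L$cache[[key]])
  g <- L$suitability[[slice]]
  cs <- L$cell_size
  rad <- floor(r1 / cs)
  offs <- expand.grid(di = -rad:rad, dj = -rad:rad)
  offs <- offs[(offs$di * cs)^2 + (offs$dj * cs)^2 <= r1^2, ]
  nx <- nrow(g); ny <- ncol(g)
  K <- matrix(0, nx, ny)
  for (r in seq_len(nrow(offs))) {
    di <- offs$di[r]; dj <- offs$dj[r]
    si <- max(1, 1 - di):min(nx, nx - di)
    sj <- max(1, 1 - dj):min(ny, ny - dj)
    K[si, sj] <- K[si, sj] + g[si + di, sj + dj]
  }
  K <- K * cs^2 * params$kappa
  L$cache[[key]] <- K
  K
}

#' Sample camp positions from the suitability equilibrium
#'
#' Cells are sampled with probability proportional to their suitability at
#' `t_bp`; within a cell the position is uniform.  Zero-suitability cells are
#' never sampled.
#'
#' @inheritParams suitability_at
#' @param n number of positions.
#' @param seed optional integer; when given, sampling is deterministic and the
#'   caller's RNG state is untouched.
#' @return tibble with columns `x`, `y` (km).
#' @export
sample_equilibrium <- function(L, t_bp, n, seed = NULL) {
  g <- L$suitability[[slice_index(L, t_bp)]]
  if (sum(g) <= 0)
    stop("cannot sample positions: landscape suitability is zero everywhere",
         call. = FALSE)
  draw <- function() {
    idx <- sample.int(length(g), n, replace = TRUE, prob = as.vector(g))
    i <- (idx - 1) %% nrow(g) + 1
    j <- (idx - 1) %/% nrow(g) + 1
    tibble::tibble(
      x = L$origin[1] + (i - 1 + stats::runif(n)) * L$cell_size,
      y = L$origin[2] + (j - 1 + stats::runif(n)) * L$cell_size)
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# run expr under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic suitability landscape
#'
#' Emulates the qualitative features of palaeo-suitability projections:
#' smooth patchy fields in \[0, 1\], piecewise-constant in time with abrupt
#' changes at slice boundaries, and optional impassable barrier corridors.
#' Each slice is a squashed Gaussian random field (white noise smoothed with a
#' Gaussian kernel of the requested correlation length, then mapped through
#' the normal CDF); successive slices share an AR(1)-correlated underlying
#' field so landscapes drift rather than reshuffle completely.
#'
#' @param nx,ny grid shape, cells.
#' @param cell_size cell edge, km.
#' @param n_slices number of time slices.
#' @param smoothness spatial correlation length, km.
#' @param bp_start,bp_end covered horizon, years BP (`bp_start > bp_end`).
#' @param barrier optional barrier spec:
#'   `list(orientation = "v"|"h", at = <km>, width = <km>, gap = c(from, to))`;
#'   barrier cells get friction 1 (the optional `gap` stays open).
#' @param slice_cor AR(1) correlation of the underlying field between
#'   consecutive slices.
#' @param contrast scale applied to the standardised field before squashing;
#'   larger values push cells toward 0/1.
#' @param seed integer; the landscape is deterministic given the seed.
#' @return A [landscape()].
#' @export
synth_landscape <- function(nx = 100, ny = 100, cell_size = 5, n_slices = 10,
                            smoothness = 50, bp_start = 120000, bp_end = 0,
                            barrier = NULL, slice_cor = 0.7, contrast = 1,
                            seed = 1) {
  stopifnot(nx > 0, ny > 0, n_slices > 0, smoothness > 0, bp_start > bp_end)
  fields <- withr_seed(seed, {
    z <- smooth_field(matrix(stats::rnorm(nx * ny), nx, ny),
                      smoothness / cell_size)
    out <- vector("list", n_slices)
    out[[1]] <- z
    if (n_slices > 1) for (s in 2:n_slices) {
      innov <- smooth_field(matrix(stats::rnorm(nx * ny), nx, ny),
                            smoothness / cell_size)
      z <- slice_cor * z + sqrt(1 - slice_cor^2) * innov
      out[[s]] <- z
    }
    out
  })
  suit <- lapply(fields, function(z) {
    z <- (z - mean(z)) / stats::sd(z)
    matrix(stats::pnorm(contrast * z), nx, ny)
  })
  edges <- seq(bp_start, bp_end, length.out = n_slices + 1)
  sb <- tibble::tibble(t_start_bp = edges[-length(edges)], t_end_bp = edges[-1])
  fr <- NULL
  if (!is.null(barrier)) {
    fr <- matrix(0, nx, ny)
    fr <- apply_barrier(fr, barrier, cell_size)
    for (s in seq_along(suit)) suit[[s]][fr == 1] <- 0
  }
  landscape(suit, sb, origin = c(0, 0), cell_size = cell_size, friction = fr)
}

# mark barrier cells (friction 1) on a friction matrix
apply_barrier <- function(fr, barrier, cell_size) {
  stopifnot(barrier$orientation %in% c("v", "h"))
  nx <- nrow(fr); ny <- ncol(fr)
  ctr <- function(n) (seq_len(n) - 0.5) * cell_size
  if (barrier$orientation == "v") {
    cols <- which(abs(ctr(nx) - barrier$at) <= barrier$width / 2)
    fr[cols, ] <- 1
    if (!is.null(barrier$gap)) {
      open <- which(ctr(ny) >= barrier$gap[1] & ctr(ny) <= barrier$gap[2])
      fr[cols, open] <- 0
    }
  } else {
    rows <- which(abs(ctr(ny) - barrier$at) <= barrier$width / 2)
    fr[, rows] <- 1
    if (!is.null(barrier$gap)) {
      open <- which(ctr(nx) >= barrier$gap[1] & ctr(nx) <= barrier$gap[2])
      fr[open, rows] <- 0
    }
  }
  fr
}

# separable Gaussian smoothing (circular boundary), sd in cells; the kernel
# is truncated to the grid size when the correlation length approaches it
smooth_field <- function(z, sd_cells) {
  if (sd_cells <= 0) return(z)
  half <- max(1L, min(ceiling(3 * sd_cells),
                      floor((min(dim(z)) - 1) / 2)))
  k <- stats::dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) as.numeric(stats::filter(col, k, circular = TRUE)))
  t(apply(t(z), 2, function(row) as.numeric(stats::filter(row, k, circular = TRUE))))
}

#' Two-patch (or multi-patch) landscape
#'
#' Builds a landscape of smooth Gaussian suitability bumps on a low
#' background — the controlled geometry used in fragmentation and isolation
#' experiments.
#'
#' @inheritParams synth_landscape
#' @param centers list of `c(x, y)` km patch centres.
#' @param radius patch scale (Gaussian sd), km; recycled over patches.
#' @param peak,background suitability at the patch centre / far field.
#' @export
patch_landscape <- function(nx = 100, ny = 100, cell_size = 5, centers,
                            radius = 60, peak = 0.9, background = 0.02,
                            n_slices = 1, bp_start = 120000, bp_end = 0,
                            barrier = NULL) {
  radius <- rep_len(radius, length(centers))
  cx <- (seq_len(nx) - 0.5) * cell_size
  cy <- (seq_len(ny) - 0.5) * cell_size
  g <- matrix(background, nx, ny)
  for (p in seq_along(centers)) {
    d2 <- outer((cx - centers[[p]][1])^2, (cy - centers[[p]][2])^2, "+")
    g <- pmax(g, background + (peak - background) * exp(-d2 / (2 * radius[p]^2)))
  }
  edges <- seq(bp_start, bp_end, length.out = n_slices + 1)
  sb <- tibble::tibble(t_start_bp = edges[-length(edges)], t_end_bp = edges[-1])
  fr <- NULL
  if (!is.null(barrier)) {
    fr <- apply_barrier(matrix(0, nx, ny), barrier, cell_size)
    g[fr == 1] <- 0
  }
  landscape(rep(list(g), n_slices), sb, origin = c(0, 0),
            cell_size = cell_size, friction = fr)
}

#' Read / write landscapes as ESRI ASCII grids
#'
#' `read_landscape()` loads one ASCII grid per slice plus a time-index table
#' (columns `slice_file`, `t_start_bp`, `t_end_bp`); `write_landscape()`
#' writes a landscape back in the same format for round-tripping.
#'
#' @param time_index data frame or path to a CSV with columns `slice_file`,
#'   `t_start_bp`, `t_end_bp`.
#' @param dir directory slice files are relative to.
#' @param friction_file optional ASCII grid of friction values.
#' @return A [landscape()].
#' @export
read_landscape <- function(time_index, dir = ".", friction_file = NULL) {
  if (is.character(time_index))
    time_index <- utils::read.csv(time_index, stringsAsFactors = FALSE)
  need <- c("slice_file", "t_start_bp", "t_end_bp")
  if (!all(need %in% names(time_index)))
    stop("time index needs columns slice_file, t_start_bp, t_end_bp",
         call. = FALSE)
  if (!is.numeric(time_index$t_start_bp) || !is.numeric(time_index$t_end_bp))
    stop("time-index error: slice intervals must be numeric years BP",
         call. = FALSE)
  grids <- lapply(file.path(dir, time_index$slice_file), read_asc)
  hdr <- grids[[1]][c("origin", "cell_size")]
  for (g in grids)
    if (!isTRUE(all.equal(g$origin, hdr$origin)) ||
        !isTRUE(all.equal(g$cell_size, hdr$cell_size)) ||
        !identical(dim(g$grid), dim(grids[[1]]$grid)))
      stop("format error: rasters disagree in shape, origin or cell size",
           call. = FALSE)
  fr <- NULL
  if (!is.null(friction_file)) {
    f <- read_asc(file.path(dir, friction_file))
    if (!identical(dim(f$grid), dim(grids[[1]]$grid)))
      stop("format error: friction raster shape mismatch", call. = FALSE)
    fr <- f$grid
  }
  landscape(lapply(grids, `[[`, "grid"),
            time_index[c("t_start_bp", "t_end_bp")],
            origin = hdr$origin, cell_size = hdr$cell_size, friction = fr)
}

#' @rdname read_landscape
#' @param L a [landscape()].
#' @param stem file-name stem for the written slice grids.
#' @export
write_landscape <- function(L, dir = ".", stem = "slice") {
  files <- sprintf("%s_%02d.asc", stem, seq_along(L$suitability))
  for (s in seq_along(L$suitability))
    write_asc(L$suitability[[s]], file.path(dir, files[s]),
              L$origin, L$cell_size)
  if (!is.null(L$friction))
    write_asc(L$friction, file.path(dir, paste0(stem, "_friction.asc")),
              L$origin, L$cell_size)
  ti <- data.frame(slice_file = files,
                   t_start_bp = L$slice_bp$t_start_bp,
                   t_end_bp = L$slice_bp$t_end_bp)
  utils::write.csv(ti, file.path(dir, paste0(stem, "_index.csv")),
                   row.names = FALSE)
  invisible(file.path(dir, paste0(stem, "_index.csv")))
}

# ESRI ASCII grid reader: rows run north->south, our matrices are [x, y]
# with y increasing, hence the flip + transpose.
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  ncol_ <- hdr$ncols; nrow_ <- hdr$nrows
  if (length(vals) != ncol_ * nrow_)
    stop("format error: cell count does not match header", call. = FALSE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  if (anyNA(vals) || any(vals < 0) || any(vals > 1))
    stop("format error: raster values outside [0, 1]", call. = FALSE)
  m <- matrix(vals, nrow = nrow_, ncol = ncol_, byrow = TRUE)
  g <- t(m[nrow_:1, , drop = FALSE])  # -> [x, y], y increasing
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  list(grid = g, origin = c(x0, y0), cell_size = hdr$cellsize)
}

write_asc <- function(grid, path, origin, cell_size) {
  nx <- nrow(grid); ny <- ncol(grid)
  m <- t(grid)[ny:1, , drop = FALSE]  # back to north->south rows
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
               sprintf("xllcorner %g", origin[1]),
               sprintf("yllcorner %g", origin[2]),
               sprintf("cellsize %g", cell_size),
               "NODATA_value -9999"), con)
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
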