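# Independent brute-force oracles and small fixture builders. These are
# deliberately written with plain loops / direct formulas, independent of the
# package's accelerated code paths.

# random mask on a small grid
random_mask <- function(grid, p = 0.2, seed = 1) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  occ <- withr_seed(seed,
                    array(runif(prod(grid$shape)) < p, dim = grid$shape))
  binary_mask(grid, occ)
}

# rasterized sphere built directly (independent of make_phantom)
sphere_mask <- function(grid, center, r) {
  sh <- grid$shape; sp <- grid$spacing; or <- grid$origin
  x <- or[1] + (seq_len(sh[1]) - 1) * sp[1]
  y <- or[2] + (seq_len(sh[2]) - 1) * sp[2]
  z <- or[3] + (seq_len(sh[3]) - 1) * sp[3]
  occ <- array(FALSE, sh)
  for (k in seq_len(sh[3])) {
    dz2 <- (z[k] - center[3])^2
    occ[, , k] <- outer((x - center[1])^2, (y - center[2])^2, `+`) + dz2 <=
      r^2
  }
  binary_mask(grid, occ)
}

# brute-force exposed-face enumeration: returns data.frame of face centres
# and areas, looping over every foreground voxel and its 6 neighbours
bf_surface <- function(m) {
  occ <- m$occupancy
  dm <- dim(occ)
  sp <- m$grid$spacing
  or <- m$grid$origin
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  centers <- list(); areas <- numeric(0)
  idx <- which(occ, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    ijk <- idx[v, ]
    for (f in 1:6) {
      nb <- ijk + offs[f, ]
      outside <- any(nb < 1) || any(nb > dm)
      if (outside || !occ[nb[1], nb[2], nb[3]]) {
        axis <- which(offs[f, ] != 0)
        ctr <- or + (ijk - 1) * sp
        ctr[axis] <- ctr[axis] + offs[f, axis] * sp[axis] / 2
        centers[[length(centers) + 1L]] <- ctr
        areas <- c(areas, prod(sp[-axis]))
      }
    }
  }
  list(centers = do.call(rbind, centers), areas = areas)
}

# O(n^2) nearest-distance oracle
bf_nn <- function(from, to) {
  apply(from, 1, function(p)
    sqrt(min((to[, 1] - p[1])^2 + (to[, 2] - p[2])^2 + (to[, 3] - p[3])^2)))
}

# per-voxel vote count by explicit looping over observers
bf_vote <- function(masks) {
  acc <- array(0L, dim(masks[[1]]$occupancy))
  for (m in masks) acc <- acc + (m$occupancy * 1L)
  acc
}

# exact two-sided Mann-Whitney p by enumerating every assignment of ranks,
# using the same two-sided convention as the exact rank-sum distribution:
# 2 * min(P(U <= u), P(U >= u)), capped at 1
bf_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# barycentric point-in-triangle oracle (strictly inside / outside;
# NA within eps of an edge)
bf_in_triangle <- function(px, py, tri, eps = 1e-9) {
  x1 <- tri[1, 1]; y1 <- tri[1, 2]
  x2 <- tri[2, 1]; y2 <- tri[2, 2]
  x3 <- tri[3, 1]; y3 <- tri[3, 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
  l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
  l3 <- 1 - l1 - l2
  near_edge <- pmin(abs(l1), abs(l2), abs(l3)) < eps
  inside <- l1 > 0 & l2 > 0 & l3 > 0
  inside[near_edge] <- NA
  inside
}

# small three-group case with identical masks within each group
unanimous_case <- function(grid = voxel_grid(c(16, 16, 8)),
                           ns = c("RAD" = 3L, "GTV-" = 3L, "GTV+" = 3L)) {
  occ <- array(FALSE, grid$shape)
  occ[5:12, 5:12, 3:6] <- TRUE
  m <- binary_mask(grid, occ)
  groups <- lapply(names(ns), function(g)
    observer_set(rep(list(m), ns[[g]]),
                 sprintf("%s%d", chartr("-+", "mp", g), seq_len(ns[[g]])), g))
  names(groups) <- names(ns)
  case_study("caseX", groups)
}
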