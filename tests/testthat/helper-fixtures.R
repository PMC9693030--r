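# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small two-lung phantom shared across tests
small_phantom <- function() fixture("phantom48", function()
  make_lung_phantom(c(48, 48, 48), seed = 7))

# straight tube mask along x, radius 3 voxels, axis at y = z = 7
tube_mask <- function(n = c(40, 15, 15), r = 3, axis_yz = c(7, 7)) {
  co <- grid_coords(n)
  g <- expand.grid(x = co$x, y = co$y, z = co$z)
  array((g$y - axis_yz[1])^2 + (g$z - axis_yz[2])^2 <= r^2, n)
}

# voxelized sphere mask
sphere_mask <- function(n = 31, center = 15, r = 10) {
  co <- grid_coords(c(n, n, n))
  g <- expand.grid(x = co$x, y = co$y, z = co$z)
  array((g$x - center)^2 + (g$y - center)^2 + (g$z - center)^2 <= r^2,
        c(n, n, n))
}

# flat square mesh at height z, spanning [0,10]^2 with unit triangles
flat_square_mesh <- function(z) {
  gr <- expand.grid(x = 0:10, y = 0:10)
  V <- cbind(gr$x, gr$y, z)
  tri <- do.call(rbind, lapply(0:9, function(i)
    do.call(rbind, lapply(0:9, function(j) {
      a <- i * 11 + j + 1; b <- (i + 1) * 11 + j + 1
      rbind(c(a, b, a + 1), c(b, b + 1, a + 1))
    }))))
  structure(list(vertices = V, triangles = tri), class = "lm_mesh")
}

# independent point-to-triangle distance: min over the plane projection
# (when its barycentric coordinates are admissible) and the three edges
oracle_point_tri_dist <- function(p, a, b, cc) {
  seg_d <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / max(sum(w^2), 1e-300)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * w))^2))
  }
  n <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
         (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
         (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
  best <- min(seg_d(p, a, b), seg_d(p, b, cc), seg_d(p, cc, a))
  n2 <- sum(n^2)
  if (n2 > 0) {
    q <- p - sum((p - a) * n) / n2 * n
    # barycentric test via areas
    M <- cbind(b - a, cc - a)
    co <- tryCatch(qr.solve(crossprod(M), crossprod(M, q - a)),
                   error = function(e) NULL)
    if (!is.null(co) && co[1] >= 0 && co[2] >= 0 && sum(co) <= 1)
      best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

oracle_point_mesh_dist <- function(P, mesh) {
  V <- mesh$vertices; Fm <- mesh$triangles
  vapply(seq_len(nrow(P)), function(i) {
    min(vapply(seq_len(nrow(Fm)), function(t)
      oracle_point_tri_dist(P[i, ], V[Fm[t, 1], ], V[Fm[t, 2], ],
                            V[Fm[t, 3], ]), numeric(1)))
  }, numeric(1))
}

# brute-force symmetric mean nearest-neighbour distance between point sets
oracle_symmetric_nn <- function(A, B) {
  dmat <- as.matrix(stats::dist(rbind(A, B)))
  nA <- nrow(A)
  d_ab <- apply(dmat[seq_len(nA), nA + seq_len(nrow(B)), drop = FALSE], 1, min)
  d_ba <- apply(dmat[nA + seq_len(nrow(B)), seq_len(nA), drop = FALSE], 1, min)
  (mean(d_ab) + mean(d_ba)) / 2
}

# count 26-connected components of a logical array (for topology checks)
count_components26 <- function(m) {
  d <- dim(m)
  lab <- array(0L, d); nl <- 0L
  for (v in which(m)) {
    if (lab[v] > 0) next
    nl <- nl + 1L
    q <- v
    while (length(q)) {
      x <- q[[1]]; q <- q[-1]
      if (lab[x] > 0) next
      lab[x] <- nl
      ai <- arrayInd(x, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        p <- ai + c(dx, dy, dz)
        if (all(p >= 1 & p <= d)) {
          pi <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
          if (m[pi] && lab[pi] == 0) q <- c(q, pi)
        }
      }
    }
  }
  nl
}
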