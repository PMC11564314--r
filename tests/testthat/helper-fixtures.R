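# Geometric fixtures built in code, plus pure-R oracles kept independent of
# the package's C++ ray-casting path.

cube_mesh <- function(center = c(0, 0, 0), half = 0.5) {
  s <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- sweep(s * half, 2, center, "+")
  f <- matrix(c(1, 3, 4, 1, 4, 2, 5, 6, 8, 5, 8, 7,
                1, 2, 6, 1, 6, 5, 3, 7, 8, 3, 8, 4,
                1, 5, 7, 1, 7, 3, 2, 4, 8, 2, 8, 6), ncol = 3, byrow = TRUE)
  m <- list(vertices = v, faces = f)
  vol <- sum(v[f[, 1], 1] * (v[f[, 2], 2] * v[f[, 3], 3] - v[f[, 2], 3] * v[f[, 3], 2]) -
             v[f[, 1], 2] * (v[f[, 2], 1] * v[f[, 3], 3] - v[f[, 2], 3] * v[f[, 3], 1]) +
             v[f[, 1], 3] * (v[f[, 2], 1] * v[f[, 3], 2] - v[f[, 2], 2] * v[f[, 3], 1])) / 6
  if (vol < 0) m$faces <- m$faces[, c(1, 3, 2)]
  trimesh(m$vertices, m$faces)
}

# axis-aligned slab of thickness t (along x), large in y/z
slab_mesh <- function(thickness = 10, x0 = 0, extent = 200) {
  s <- as.matrix(expand.grid(c(x0, x0 + thickness),
                             c(-extent, extent), c(-extent, extent)))
  v <- s
  f <- matrix(c(1, 3, 4, 1, 4, 2, 5, 6, 8, 5, 8, 7,
                1, 2, 6, 1, 6, 5, 3, 7, 8, 3, 8, 4,
                1, 5, 7, 1, 7, 3, 2, 4, 8, 2, 8, 6), ncol = 3, byrow = TRUE)
  m <- trimesh(v, f, validate = FALSE)
  if (glenplan:::mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  trimesh(m$vertices, m$faces)
}

# two slabs 10 mm apart, each 5 mm thick, as one multi-component mesh
two_slab_mesh <- function() {
  a <- slab_mesh(5, x0 = 0)
  b <- slab_mesh(5, x0 = 15)
  glenplan:::merge_meshes(list(a, b))
}

# a fully anterior-posterior symmetric scapula (no version, no leans, no
# anchor offset, no dogleg)
symmetric_params <- function(...) {
  scapula_params(version_deg = 0, inclination_deg = 0,
                 corridor_cranial_deg = 0, corridor_posterior_deg = 0,
                 corridor_bend_posterior_deg = 0,
                 corridor_bend_cranial_deg = 0,
                 corridor_anchor_ap_mm = 0,
                 pillar_anterior_deg = 0, pillar_bend_caudal_deg = 0,
                 pillar_anchor_ap_mm = 0, ...)
}

# ---- independent pure-R ray/triangle and point-in-solid oracles ----

# Moller-Trumbore in R, vectorized over triangles, for one ray
r_ray_hits <- function(mesh, origin, dir) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  px <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  py <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  pz <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  det <- e1[, 1] * px + e1[, 2] * py + e1[, 3] * pz
  sx <- origin[1] - a[, 1]; sy <- origin[2] - a[, 2]; sz <- origin[3] - a[, 3]
  u <- (sx * px + sy * py + sz * pz) / det
  qx <- sy * e1[, 3] - sz * e1[, 2]
  qy <- sz * e1[, 1] - sx * e1[, 3]
  qz <- sx * e1[, 2] - sy * e1[, 1]
  vv <- (dir[1] * qx + dir[2] * qy + dir[3] * qz) / det
  t <- (e2[, 1] * qx + e2[, 2] * qy + e2[, 3] * qz) / det
  keep <- is.finite(t) & abs(det) > 1e-14 & u >= -1e-10 & vv >= -1e-10 &
    u + vv <= 1 + 1e-10 & t > 1e-9
  list(t = t[keep], comp = mesh$components[keep])
}

# point-in-union-of-solids by per-component crossing parity along a fixed
# probe direction
r_inside <- function(mesh, pts, probe = c(0.7297, 0.4621, 0.5039)) {
  probe <- probe / sqrt(sum(probe^2))
  ncomp <- max(mesh$components)
  apply(pts, 1, function(p) {
    h <- r_ray_hits(mesh, p, probe)
    any(vapply(seq_len(ncomp), function(ci)
      sum(h$comp == ci) %% 2 == 1, logical(1)))
  })
}

# marching oracle for bi-cortical length: coarse scan + bisection of each
# in/out transition, first-exit semantics (void bridging 0)
r_marching_bicortical <- function(mesh, origin, dir, max_len = 120,
                                  coarse = 0.05, tol = 0.005) {
  ts <- seq(coarse / 2, max_len, by = coarse)
  pts <- sweep(outer(ts, dir), 2, origin, "+")
  ins <- r_inside(mesh, pts)
  flips <- which(ins[-1] != ins[-length(ins)])
  refine <- function(lo, hi, state_lo) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (identical(r_inside(mesh, matrix(origin + mid * dir, 1))[1],
                    state_lo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  cross <- vapply(flips, function(i)
    refine(ts[i], ts[i + 1], ins[i]), numeric(1))
  # first-exit-after-first-entry semantics (void bridging 0)
  if (ins[1]) {
    if (!length(cross)) return(max_len)
    return(cross[1])
  }
  if (length(cross) >= 2) return(cross[2])
  if (length(cross) == 1) return(max_len)
  NA_real_
}

make_rim_scapula <- function(radius = 14.1, n = 12) {
  # rim circle in the y-z plane, tubercle on +z, body landmarks on -x side
  phi <- 2 * pi * (0:(n - 1)) / n
  rim <- lapply(phi, function(p) c(0, radius * sin(p), radius * cos(p)))
  names(rim) <- paste0("glenoid_rim_point_", seq_len(n))
  lms <- c(list(
    supraglenoid_tubercle = c(0, 0, radius + 1),
    inferior_glenoid_margin = c(0, 0, -radius),
    trigonum_spinae = c(-80, 0, 0),
    inferior_angle = c(-40, 0, -60),
    spine_confluence = c(-40, 0, 10),
    suprascapular_notch_center = c(-30, 10, 10),
    spinoglenoid_notch_center = c(-30, -10, 10)), rim)
  scapula_model(cube_mesh(half = 5), lms, validate = FALSE)
}

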