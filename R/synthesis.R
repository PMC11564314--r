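#' Parametric scapula parameters
#'
#' Parameters of the constructive synthetic scapula: an elliptical glenoid
#' disc (AP width x CC diameter) tilted by version/inclination, a tapering
#' solid vault corridor running postero-medially toward the scapular-spine
#' confluence, a thin body pillar running caudally toward the inferior
#' angle, a spine slab carrying the two nerve-notch landmarks, and small
#' marker blocks for the trigonum spinae and inferior angle. The corridor
#' and pillar directions are the anatomical features that make optimal screw
#' length depend on baseplate roll and screw angulation.
#'
#' @param ap_width glenoid anterior-posterior width (mm).
#' @param cc_diameter glenoid cranial-caudal diameter (mm); must exceed
#'   `ap_width`.
#' @param version_deg glenoid version (posterior negative), |v| <= 20.
#' @param inclination_deg glenoid inclination (superior positive).
#' @param vault_depth thickness of the glenoid disc solid (mm).
#' @param spine_corridor_length length of the vault corridor (mm).
#' @param spine_corridor_taper end/start radius ratio of the corridor.
#' @param body_plate_thickness antero-posterior thickness of the body pillar
#'   (mm).
#' @param body_plate_extent length of the body pillar (mm).
#' @param corridor_cranial_deg,corridor_posterior_deg tilt of the vault
#'   funnel axis from the inward glenoid normal (degrees; the default
#'   slight anterior lean combines with the posterior dogleg so that the
#'   spine-base segment runs posteriorly, as the spine does).
#' @param corridor_bend_posterior_deg,corridor_bend_cranial_deg dogleg of
#'   the spine-base segment relative to the funnel axis (degrees); the bend
#'   makes the corridor non-convex, so achievable screw length degrades
#'   when entry point or direction are misaligned.
#' @param corridor_anchor_ap_mm anterior-posterior offset of the corridor
#'   entrance on the glenoid face (posterior positive, mm); the roll-angle
#'   optimum rotates the superior screw hole onto this entrance.
#' @param pillar_caudal_deg,pillar_anterior_deg body-pillar axis tilt from
#'   the inward glenoid normal (degrees).
#' @param pillar_bend_caudal_deg caudal dogleg of the distal pillar
#'   segment (degrees).
#' @param pillar_anchor_ap_mm anterior-posterior offset of the pillar
#'   entrance (posterior positive, mm).
#' @param notch_positions optional list of two 3-D points (suprascapular,
#'   spinoglenoid notch centers); auto-placed on the spine slab when `NULL`.
#' @param sex `"F"` or `"M"`.
#' @param age years (carried into cohort tables; no geometric effect).
#' @return An object of class `scapula_params`.
#' @export
scapula_params <- function(ap_width = 28.2, cc_diameter = 38.0,
                           version_deg = -4.1, inclination_deg = 0,
                           vault_depth = 10, spine_corridor_length = 50,
                           spine_corridor_taper = 0.5,
                           body_plate_thickness = 6.5,
                           body_plate_extent = 48,
                           corridor_cranial_deg = 7,
                           corridor_posterior_deg = -9,
                           corridor_bend_posterior_deg = 14,
                           corridor_bend_cranial_deg = 3,
                           corridor_anchor_ap_mm = 3.2,
                           pillar_caudal_deg = 8,
                           pillar_anterior_deg = 0.7,
                           pillar_bend_caudal_deg = 4,
                           pillar_anchor_ap_mm = 0,
                           notch_positions = NULL,
                           sex = c("F", "M"), age = 73.5) {
  sex <- match.arg(sex)
  stopifnot(ap_width > 0, cc_diameter > 0, vault_depth > 0,
            spine_corridor_length > 0, body_plate_thickness > 0,
            body_plate_extent > 0, spine_corridor_taper > 0,
            spine_corridor_taper <= 1)
  if (ap_width >= cc_diameter)
    stop("ap_width must be smaller than cc_diameter")
  if (abs(version_deg) > 20) stop("|version_deg| must be <= 20")
  structure(as.list(environment()), class = "scapula_params")
}

# orthonormal basis perpendicular to unit vector d
perp_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(ref - sum(ref * d) * d)
  list(u = u, w = cross3(d, u))
}

segment_count <- function(radius, resolution) {
  n <- ceiling(2 * pi * radius / max(resolution, 0.2))
  max(24L, as.integer(4 * ceiling(n / 4)))
}

# closed elliptical cylinder: start ellipse center O in plane (u, v),
# semi-axes ru (along u) and rv (along v), extruded len along axis
mesh_ecyl <- function(O, axis, len, ru, rv, u, v, nseg) {
  phi <- 2 * pi * (seq_len(nseg) - 1) / nseg
  ring <- t(vapply(phi, function(p) O + ru * cos(p) * u + rv * sin(p) * v,
                   numeric(3)))
  top <- sweep(ring, 2, len * axis, "+")
  vs <- rbind(ring, top, O, O + len * axis)
  c0 <- 2L * nseg + 1L
  c1 <- 2L * nseg + 2L
  idx <- seq_len(nseg)
  nxt <- c(idx[-1], 1L)
  side <- rbind(cbind(idx, nxt, nseg + nxt), cbind(idx, nseg + nxt, nseg + idx))
  cap0 <- cbind(rep(c0, nseg), nxt, idx)
  cap1 <- cbind(rep(c1, nseg), nseg + idx, nseg + nxt)
  orient_part(vs, rbind(side, cap0, cap1))
}

# tapered circular corridor: start disc center A, unit axis d, radius r0 -> r1
mesh_frustum <- function(A, d, len, r0, r1, nseg) {
  b <- perp_basis(d)
  phi <- 2 * pi * (seq_len(nseg) - 1) / nseg
  ring0 <- t(vapply(phi, function(p) A + r0 * (cos(p) * b$u + sin(p) * b$w),
                    numeric(3)))
  ring1 <- t(vapply(phi, function(p) A + len * d + r1 * (cos(p) * b$u + sin(p) * b$w),
                    numeric(3)))
  vs <- rbind(ring0, ring1, A, A + len * d)
  c0 <- 2L * nseg + 1L
  c1 <- 2L * nseg + 2L
  idx <- seq_len(nseg)
  nxt <- c(idx[-1], 1L)
  side <- rbind(cbind(idx, nxt, nseg + nxt), cbind(idx, nseg + nxt, nseg + idx))
  cap0 <- cbind(rep(c0, nseg), nxt, idx)
  cap1 <- cbind(rep(c1, nseg), nseg + idx, nseg + nxt)
  orient_part(vs, rbind(side, cap0, cap1))
}

# oriented box: center, axes as 3x3 matrix (columns), half extents
mesh_obox <- function(center, axes, half) {
  s <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
  vs <- t(apply(s, 1, function(sg)
    center + axes %*% (sg * half)))
  f <- matrix(c(1, 3, 4, 1, 4, 2, 5, 6, 8, 5, 8, 7,
                1, 2, 6, 1, 6, 5, 3, 7, 8, 3, 8, 4,
                1, 5, 7, 1, 7, 3, 2, 4, 8, 2, 8, 6), ncol = 3, byrow = TRUE)
  orient_part(vs, f)
}

orient_part <- function(vertices, faces) {
  p <- list(vertices = vertices, faces = faces)
  if (mesh_volume(p) < 0) p$faces <- p$faces[, c(1, 3, 2)]
  p
}

#' Generate a synthetic scapula with analytic ground truth
#'
#' Builds the constructive-solid scapula of [scapula_params] as a
#' multi-component watertight [trimesh], emits all mandatory landmarks at
#' their construction positions, and returns the construction ground truth:
#' the exact glenoid frame, the corridor axes, and the analytic solid
#' primitives from which the optimizer's result can be verified
#' independently of the tessellated mesh (see [ground_truth_optimum]).
#'
#' @param params a [scapula_params].
#' @param mesh_resolution target circumferential edge length (mm);
#'   tessellation error falls quadratically with it. Planar walls are exact
#'   at any resolution.
#' @param case_id identifier stored in the model.
#' @return list with `model` (a [scapula_model]) and `truth` (list: `frame`,
#'   `params`, `primitives`, `superior_corridor`, `inferior_corridor`).
#' @export
generate_scapula <- function(params, mesh_resolution = 1.5,
                             case_id = "synthetic") {
  stopifnot(inherits(params, "scapula_params"))
  p <- params
  # construction body frame (landmarks are pinned so the measured frame
  # reproduces these axes exactly)
  l_b <- c(1, 0, 0); s_b <- c(0, 1, 0); n_b <- c(0, 0, 1)
  body <- list(l_b = l_b, s_b = s_b, n_b = n_b)
  O <- c(0, 0, 0)
  L <- lateral_from_vi(p$version_deg, p$inclination_deg, body)
  S_f <- unitize(s_b - sum(s_b * L) * L)
  P_f <- cross3(L, S_f)

  cc <- p$cc_diameter; ap <- p$ap_width
  # Vault corridor: a funnel behind the glenoid face narrows to a neck,
  # then the spine-base segment doglegs further posteriorly/cranially and
  # tapers into a conical tip at the confluence. The bent axis makes the
  # corridor non-convex: a straight screw reaches the confluence only when
  # its entry point and direction line up with the neck aperture, and its
  # achievable length degrades smoothly with roll/angle misalignment - the
  # phenomenon the planning protocol exploits.
  a_off <- min(max(22.5 - cc / 2, 0), cc / 4)
  A <- O + a_off * S_f + p$corridor_anchor_ap_mm * P_f
  d_sup <- unitize(-L + tan(deg2rad(p$corridor_cranial_deg)) * S_f +
                     tan(deg2rad(p$corridor_posterior_deg)) * P_f)
  d_sup2 <- unitize(d_sup +
                      tan(deg2rad(p$corridor_bend_posterior_deg)) * P_f +
                      tan(deg2rad(p$corridor_bend_cranial_deg)) * S_f)
  r0 <- min(0.32 * ap, 10)
  r_m <- max(0.33 * r0, 2.8)                  # neck radius
  r_t <- max(1.8, p$spine_corridor_taper * r_m * 1.2)
  len_c <- p$spine_corridor_length
  L1 <- 0.35 * len_c
  L2 <- len_c - L1
  tip_c <- min(3 * r_t, 0.45 * L2)
  J <- A + L1 * d_sup
  E <- J + L2 * d_sup2

  # thin body pillar (plate) toward the inferior angle, with a caudal
  # dogleg and tip of its own
  b_off <- max(cc / 2 - 4.5, 6)
  B <- O - b_off * S_f + p$pillar_anchor_ap_mm * P_f
  d_inf <- unitize(-L - tan(deg2rad(p$pillar_caudal_deg)) * S_f -
                     tan(deg2rad(p$pillar_anterior_deg)) * P_f)
  d_inf2 <- unitize(d_inf - tan(deg2rad(p$pillar_bend_caudal_deg)) * S_f)
  e_t <- unitize(P_f - sum(P_f * d_inf) * d_inf)
  e_w <- cross3(e_t, d_inf)
  e_t2 <- unitize(P_f - sum(P_f * d_inf2) * d_inf2)
  e_w2 <- cross3(e_t2, d_inf2)
  ext <- p$body_plate_extent
  thick <- p$body_plate_thickness
  X1 <- 0.4 * ext
  X2 <- ext - X1
  tip_p <- min(5 * thick / 2, 0.3 * X2)
  Jp <- B + X1 * d_inf
  pil_end <- Jp + X2 * d_inf2

  # spine slab above the corridor end; carries the notch landmarks
  slab_half <- c(20, 4, 6)
  slab_center <- c(E[1] - slab_half[1] + 5,
                   E[2] + r_t + 8 + slab_half[2], E[3])
  slab_axes <- diag(3)

  # landmark marker blocks (z = 0 pins the scapular body plane)
  ts <- c(E[1] - 25, 0, 0)
  ia <- c(pil_end[1], pil_end[2] - 8, 0)
  ts_center <- ts + c(-2.5, 0, 0)
  ia_center <- ia + c(0, -2.5, 0)

  nseg <- segment_count(max(ap, cc) / 2, mesh_resolution)
  nseg_c <- segment_count(r0, mesh_resolution)
  nseg_p <- segment_count(10, mesh_resolution)
  parts <- list(
    disc = mesh_ecyl(O, -L, p$vault_depth, cc / 2, ap / 2, S_f, P_f, nseg),
    vault_neck = mesh_frustum(A, d_sup, L1 + 0.5, r0, r_m, nseg_c),
    spine_base = mesh_frustum(J - 0.5 * d_sup2, d_sup2,
                              L2 - tip_c + 0.5, r_m, r_t, nseg_c),
    corridor_tip = mesh_frustum(E - (tip_c + 0.5) * d_sup2, d_sup2,
                                tip_c + 0.5, r_t, 0.4, nseg_c),
    pillar1 = mesh_ecyl(B, d_inf, X1 + 0.5, 10, thick / 2, e_w, e_t,
                        nseg_p),
    pillar2 = mesh_ecyl(Jp - 0.5 * d_inf2, d_inf2, X2 - tip_p + 0.5, 8,
                        thick / 2, e_w2, e_t2, nseg_p),
    pillar_tip = mesh_frustum(pil_end - (tip_p + 0.5) * d_inf2, d_inf2,
                              tip_p + 0.5, thick / 2, 0.4, nseg_c),
    slab = mesh_obox(slab_center, slab_axes, slab_half),
    ts_marker = mesh_obox(ts_center, diag(3), c(2.5, 2.5, 2.5)),
    ia_marker = mesh_obox(ia_center, diag(3), c(2.5, 2.5, 2.5)))
  mesh <- merge_meshes(parts)

  phi <- 2 * pi * (0:11) / 12
  rim <- lapply(seq_along(phi), function(k)
    O + (cc / 2) * cos(phi[k]) * S_f + (ap / 2) * sin(phi[k]) * P_f)
  names(rim) <- paste0("glenoid_rim_point_", seq_along(phi))

  if (!is.null(p$notch_positions)) {
    supra <- as.numeric(p$notch_positions[[1]])
    spino <- as.numeric(p$notch_positions[[2]])
  } else {
    y_bot <- slab_center[2] - slab_half[2]
    supra <- c(E[1] + 2, y_bot, slab_center[3] - 5)
    spino <- c(E[1] + 2, y_bot, slab_center[3] + 5)
  }

  landmarks <- c(list(
    supraglenoid_tubercle = O + (cc / 2) * S_f,
    inferior_glenoid_margin = O - (cc / 2) * S_f,
    trigonum_spinae = ts,
    inferior_angle = ia,
    spine_confluence = E,
    suprascapular_notch_center = supra,
    spinoglenoid_notch_center = spino), rim)

  model <- scapula_model(mesh, landmarks, case_id = case_id, sex = p$sex,
                         age = p$age)

  frame <- structure(list(origin = O, axis_superior = S_f,
                          axis_posterior = P_f, axis_lateral = L),
                     class = "glenoid_frame")
  primitives <- list(
    list(type = "ecyl", O = O, axis = -L, len = p$vault_depth,
         ru = cc / 2, rv = ap / 2, u = S_f, v = P_f),
    list(type = "frustum", A = A, dir = d_sup, len = L1 + 0.5,
         r0 = r0, r1 = r_m),
    list(type = "frustum", A = J - 0.5 * d_sup2, dir = d_sup2,
         len = L2 - tip_c + 0.5, r0 = r_m, r1 = r_t),
    list(type = "frustum", A = E - (tip_c + 0.5) * d_sup2, dir = d_sup2,
         len = tip_c + 0.5, r0 = r_t, r1 = 0.4),
    list(type = "ecyl", O = B, axis = d_inf, len = X1 + 0.5,
         ru = 10, rv = thick / 2, u = e_w, v = e_t),
    list(type = "ecyl", O = Jp - 0.5 * d_inf2, axis = d_inf2,
         len = X2 - tip_p + 0.5, ru = 8, rv = thick / 2, u = e_w2,
         v = e_t2),
    list(type = "frustum", A = pil_end - (tip_p + 0.5) * d_inf2,
         dir = d_inf2, len = tip_p + 0.5, r0 = thick / 2, r1 = 0.4),
    list(type = "obox", center = slab_center, axes = slab_axes,
         half = slab_half),
    list(type = "obox", center = ts_center, axes = diag(3),
         half = c(2.5, 2.5, 2.5)),
    list(type = "obox", center = ia_center, axes = diag(3),
         half = c(2.5, 2.5, 2.5)))
  truth <- list(frame = frame, params = p, primitives = primitives,
                superior_corridor = list(anchor = A, dir = d_sup,
                                         dir_spine = d_sup2, elbow = J,
                                         length = len_c, r0 = r0,
                                         r_neck = r_m, r_tip = r_t,
                                         tip_length = tip_c, end = E),
                inferior_corridor = list(anchor = B, dir = d_inf,
                                         dir_distal = d_inf2, elbow = Jp,
                                         length = ext, tip_length = tip_p,
                                         end = pil_end))
  list(model = model, truth = truth)
}

# ---- analytic ray casting against the construction primitives ----

# intervals where a*t^2 + b*t + c <= 0
quad_leq <- function(a, b, c) {
  eps <- 1e-12
  if (abs(a) < eps) {
    if (abs(b) < eps) {
      if (c <= 0) return(matrix(c(-Inf, Inf), 1)) else return(NULL)
    }
    t0 <- -c / b
    if (b > 0) return(matrix(c(-Inf, t0), 1))
    return(matrix(c(t0, Inf), 1))
  }
  disc <- b * b - 4 * a * c
  if (a > 0) {
    if (disc <= 0) return(NULL)
    r <- sqrt(disc)
    return(matrix(c((-b - r) / (2 * a), (-b + r) / (2 * a)), 1))
  }
  if (disc <= 0) return(matrix(c(-Inf, Inf), 1))
  r <- sqrt(disc)
  t1 <- (-b + r) / (2 * a); t2 <- (-b - r) / (2 * a)
  rbind(c(-Inf, t1), c(t2, Inf))
}

# interval where lo <= w + t*d <= hi
slab_leq <- function(w, d, lo, hi) {
  if (abs(d) < 1e-12) {
    if (w >= lo && w <= hi) return(c(-Inf, Inf)) else return(NULL)
  }
  t <- sort(c((lo - w) / d, (hi - w) / d))
  t
}

isect_iv <- function(a, b) {
  if (is.null(a) || is.null(b)) return(NULL)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    keep <- lo < hi
    if (any(keep)) out <- rbind(out, cbind(lo[keep], hi[keep]))
  }
  out
}

ray_prim_intervals <- function(prim, o, d) {
  if (prim$type == "obox") {
    w <- as.numeric(o - prim$center)
    iv <- matrix(c(-Inf, Inf), 1)
    for (k in 1:3) {
      ax <- prim$axes[, k]
      s <- slab_leq(sum(w * ax), sum(d * ax), -prim$half[k], prim$half[k])
      if (is.null(s)) return(NULL)
      iv <- isect_iv(iv, matrix(s, 1))
      if (is.null(iv)) return(NULL)
    }
    return(iv)
  }
  if (prim$type == "ecyl") {
    w <- as.numeric(o - prim$O)
    du <- sum(d * prim$u) / prim$ru; dv <- sum(d * prim$v) / prim$rv
    wu <- sum(w * prim$u) / prim$ru; wv <- sum(w * prim$v) / prim$rv
    q <- quad_leq(du^2 + dv^2, 2 * (wu * du + wv * dv), wu^2 + wv^2 - 1)
    if (is.null(q)) return(NULL)
    s <- slab_leq(sum(w * prim$axis), sum(d * prim$axis), 0, prim$len)
    if (is.null(s)) return(NULL)
    return(isect_iv(q, matrix(s, 1)))
  }
  if (prim$type == "frustum") {
    ax <- prim$dir
    w <- as.numeric(o - prim$A)
    wa <- sum(w * ax); da <- sum(d * ax)
    wd <- w - wa * ax; dd <- d - da * ax
    k <- (prim$r1 - prim$r0) / prim$len
    a2 <- sum(dd * dd) - (k * da)^2
    b2 <- 2 * (sum(wd * dd) - k * da * (prim$r0 + k * wa))
    c2 <- sum(wd * wd) - (prim$r0 + k * wa)^2
    q <- quad_leq(a2, b2, c2)
    if (is.null(q)) return(NULL)
    s <- slab_leq(wa, da, 0, prim$len)
    if (is.null(s)) return(NULL)
    return(isect_iv(q, matrix(s, 1)))
  }
  stop("unknown primitive type")
}

# ---- vectorized analytic intervals (one [lo, hi] pair per slot) ----

# slab helper: lo <= w + t*d <= hi for vectors w, d; returns list(lo, hi)
# with NA where the slab is missed entirely
slab_vec <- function(w, d, lo, hi) {
  par <- abs(d) < 1e-12
  t1 <- (lo - w) / d
  t2 <- (hi - w) / d
  a <- pmin(t1, t2); b <- pmax(t1, t2)
  inside <- w >= lo & w <= hi
  a[par] <- ifelse(inside[par], -Inf, NA_real_)
  b[par] <- ifelse(inside[par], Inf, NA_real_)
  list(lo = a, hi = b)
}

# solution set of a*t^2 + b*t + c <= 0 for rows with a >= 0 (vectorized);
# NA when empty. Degenerate a ~ 0 falls back to the linear/constant case.
quad_pos_vec <- function(a, b, c) {
  n <- length(a)
  lo <- rep(NA_real_, n); hi <- rep(NA_real_, n)
  quad <- a > 1e-14
  if (any(quad)) {
    disc <- b[quad]^2 - 4 * a[quad] * c[quad]
    ok <- disc > 0
    r <- sqrt(pmax(disc, 0))
    lo[quad] <- ifelse(ok, (-b[quad] - r) / (2 * a[quad]), NA_real_)
    hi[quad] <- ifelse(ok, (-b[quad] + r) / (2 * a[quad]), NA_real_)
  }
  linr <- !quad & abs(b) > 1e-14
  lo[linr] <- ifelse(b[linr] > 0, -Inf, -c[linr] / b[linr])
  hi[linr] <- ifelse(b[linr] > 0, -c[linr] / b[linr], Inf)
  con <- !quad & abs(b) <= 1e-14
  lo[con] <- ifelse(c[con] <= 0, -Inf, NA_real_)
  hi[con] <- ifelse(c[con] <= 0, Inf, NA_real_)
  list(lo = lo, hi = hi)
}

isect2 <- function(x, y) {
  lo <- pmax(x$lo, y$lo); hi <- pmin(x$hi, y$hi)
  bad <- is.na(lo) | is.na(hi) | lo >= hi
  lo[bad] <- NA_real_; hi[bad] <- NA_real_
  list(lo = lo, hi = hi)
}

# per-primitive interval slots for a batch of rays; returns list of
# list(lo, hi) vectors (length n each)
prim_intervals_vec <- function(prim, origins, dirs) {
  n <- nrow(origins)
  if (prim$type == "obox") {
    w <- sweep(origins, 2, prim$center)
    iv <- list(lo = rep(-Inf, n), hi = rep(Inf, n))
    for (k in 1:3) {
      ax <- prim$axes[, k]
      iv <- isect2(iv, slab_vec(drop(w %*% ax), drop(dirs %*% ax),
                                -prim$half[k], prim$half[k]))
    }
    return(list(iv))
  }
  if (prim$type == "ecyl") {
    w <- sweep(origins, 2, prim$O)
    du <- drop(dirs %*% prim$u) / prim$ru
    dv <- drop(dirs %*% prim$v) / prim$rv
    wu <- drop(w %*% prim$u) / prim$ru
    wv <- drop(w %*% prim$v) / prim$rv
    q <- quad_pos_vec(du^2 + dv^2, 2 * (wu * du + wv * dv),
                      wu^2 + wv^2 - 1)
    s <- slab_vec(drop(w %*% prim$axis), drop(dirs %*% prim$axis),
                  0, prim$len)
    return(list(isect2(q, s)))
  }
  if (prim$type == "frustum") {
    ax <- prim$dir
    w <- sweep(origins, 2, prim$A)
    wa <- drop(w %*% ax); da <- drop(dirs %*% ax)
    wd <- w - outer(wa, ax); dd <- dirs - outer(da, ax)
    k <- (prim$r1 - prim$r0) / prim$len
    a2 <- rowSums(dd * dd) - (k * da)^2
    b2 <- 2 * (rowSums(wd * dd) - k * da * (prim$r0 + k * wa))
    c2 <- rowSums(wd * wd) - (prim$r0 + k * wa)^2
    # the mirror cone lies beyond the apex; the slab below keeps s within
    # [0, min(len, apex)] so each sign branch leaves at most one interval
    apex <- if (abs(k) > 1e-12) -prim$r0 / k else Inf
    smax <- if (apex > 0) min(prim$len, apex) else prim$len
    s <- slab_vec(wa, da, 0, smax)
    # convex rows (a2 > 0): single interval between the roots.
    # concave/linear rows: f <= 0 holds outside the roots; keep both
    # branches as separate slots and let the slab clip them.
    s1 <- list(lo = rep(NA_real_, n), hi = rep(NA_real_, n))
    s2 <- list(lo = rep(NA_real_, n), hi = rep(NA_real_, n))
    pos <- a2 > 1e-12
    if (any(pos)) {
      q <- quad_pos_vec(a2[pos], b2[pos], c2[pos])
      s1$lo[pos] <- q$lo; s1$hi[pos] <- q$hi
    }
    if (any(!pos)) {
      idx <- which(!pos)
      a <- a2[idx]; b <- b2[idx]; c <- c2[idx]
      lin <- abs(a) <= 1e-12
      loL <- hiL <- loR <- hiR <- rep(NA_real_, length(idx))
      bl <- lin & abs(b) > 1e-12   # linear: b*t + c <= 0
      loL[bl] <- ifelse(b[bl] > 0, -Inf, -c[bl] / b[bl])
      hiL[bl] <- ifelse(b[bl] > 0, -c[bl] / b[bl], Inf)
      ba <- lin & abs(b) <= 1e-12  # constant
      loL[ba] <- ifelse(c[ba] <= 0, -Inf, NA_real_)
      hiL[ba] <- ifelse(c[ba] <= 0, Inf, NA_real_)
      cv <- !lin
      if (any(cv)) {
        disc <- b[cv]^2 - 4 * a[cv] * c[cv]
        r <- sqrt(pmax(disc, 0))
        ra <- (-b[cv] - r) / (2 * a[cv]); rb <- (-b[cv] + r) / (2 * a[cv])
        t1 <- pmin(ra, rb); t2 <- pmax(ra, rb)
        none <- disc <= 0  # f <= 0 everywhere
        loL[cv] <- -Inf
        hiL[cv] <- ifelse(none, Inf, t1)
        loR[cv] <- ifelse(none, NA_real_, t2)
        hiR[cv] <- ifelse(none, NA_real_, Inf)
      }
      s1$lo[idx] <- loL; s1$hi[idx] <- hiL
      s2$lo[idx] <- loR; s2$hi[idx] <- hiR
    }
    return(list(isect2(s1, s), isect2(s2, s)))
  }
  stop("unknown primitive type")
}

# analytic counterpart of bicortical_batch over the construction solids;
# vectorized over rays, with the same entry/chaining semantics
analytic_bicortical_batch <- function(primitives, origins, dirs,
                                      max_length = 200, void_bridge_mm = 0) {
  n <- nrow(origins)
  slots <- list()
  for (pr in primitives)
    slots <- c(slots, prim_intervals_vec(pr, origins, dirs))
  lo <- do.call(cbind, lapply(slots, `[[`, "lo"))
  hi <- do.call(cbind, lapply(slots, `[[`, "hi"))
  lo <- pmax(lo, 0)
  hi <- pmin(hi, max_length)
  dead <- is.na(lo) | is.na(hi) | hi <= lo + 1e-12
  lo[dead] <- Inf
  hi[dead] <- -Inf
  entry <- do.call(pmin, c(as.data.frame(lo), list(Inf)))
  valid <- is.finite(entry) & entry < max_length
  # fixed-point chaining: extend the corridor end across overlapping
  # intervals and voids no wider than void_bridge
  end <- ifelse(valid, entry, 0)
  for (pass in seq_len(ncol(lo))) {
    newend <- end
    for (k in seq_len(ncol(lo))) {
      reach <- lo[, k] <= newend + void_bridge_mm + 1e-9 & hi[, k] > newend
      newend <- ifelse(reach, hi[, k], newend)
    }
    if (all(abs(newend - end) < 1e-12)) break
    end <- newend
  }
  out <- matrix(0, n, 6)
  out[, 1] <- ifelse(valid, end, 0)
  out[, 2] <- origins[, 1] + dirs[, 1] * out[, 1]
  out[, 3] <- origins[, 2] + dirs[, 2] * out[, 1]
  out[, 4] <- origins[, 3] + dirs[, 3] * out[, 1]
  out[, 5] <- as.numeric(valid)
  out[, 6] <- ifelse(valid, entry, 0)
  out
}
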