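#' Search configuration for trajectory optimization
#'
#' Exhaustive grid search over the glenoid roll angle (GRA) and the screw
#' angle pairs inside the variable-angle cone, followed by one local
#' refinement pass. Grids are aligned to multiples of their step so that
#' refined and coarse lattices nest.
#'
#' @param gra_range GRA search interval (degrees).
#' @param gra_step GRA grid step (degrees).
#' @param angle_step screw-angle grid step (degrees).
#' @param refine logical; run a local refinement pass.
#' @param refine_step refinement grid step (degrees).
#' @param refine_window half-width of the refinement window (degrees).
#' @param max_length ray search horizon (mm).
#' @param void_bridge_mm widest bone void a screw may bridge (mm); 0 stops
#'   the screw at the first exit from bone.
#' @param clearance_mm added clearance around notch keep-out spheres (mm).
#' @param tie_mm superior-length differences at or below this value count
#'   as ties of the roll-angle search (default 0.5 mm: differences below
#'   the grid and tessellation resolution, and far below clinical screw
#'   increments, are not meaningful). Tied roll angles are resolved in favor of the longest
#'   inferior screw, then the smallest |GRA|.
#' @param measure_from `"baseplate"` measures screw length from the hole
#'   origin on the baseplate plane; `"bone_entry"` from the first bone
#'   entry.
#' @param gra_coupling `"joint"` re-optimizes the superior screw angles for
#'   every GRA candidate; `"nominal"` rates GRA candidates with the screws
#'   held on their nominal hole axes, then optimizes angles at the chosen
#'   GRA.
#' @param objective `"lexicographic"` (superior screw first, the default) or
#'   `"sum"` (maximize the summed length of both screws over GRA).
#' @return An object of class `search_config`.
#' @export
search_config <- function(gra_range = c(-20, 20), gra_step = 1,
                          angle_step = 1, refine = TRUE, refine_step = 0.25,
                          refine_window = 1, max_length = 200, tie_mm = 0.5,
                          void_bridge_mm = 0, clearance_mm = 2,
                          measure_from = c("baseplate", "bone_entry"),
                          gra_coupling = c("joint", "nominal"),
                          objective = c("lexicographic", "sum")) {
  measure_from <- match.arg(measure_from)
  gra_coupling <- match.arg(gra_coupling)
  objective <- match.arg(objective)
  stopifnot(gra_step > 0, angle_step > 0, gra_range[1] < gra_range[2])
  structure(as.list(environment()), class = "search_config")
}

#' Notch keep-out safety check
#'
#' A screw is notch-safe when its shaft segment (origin to
#' origin + length * direction, dilated by `screw_radius`) stays strictly
#' clear of every keep-out sphere (notch radius + `clearance_mm`). The
#' keep-out is closed: a trajectory exactly tangent to the inflated sphere
#' is unsafe.
#'
#' @param scapula a [scapula_model] (notch centers are its landmarks, radii
#'   its `keep_out_radii`).
#' @param r a [ray].
#' @param length screw length along the ray (mm).
#' @param clearance_mm clearance margin (mm).
#' @param screw_radius screw shaft radius (mm).
#' @return logical.
#' @export
check_notch_safety <- function(scapula, r, length, clearance_mm = 2,
                               screw_radius = 0) {
  for (nm in names(scapula$keep_out_radii)) {
    q <- scapula$landmarks[[nm]]
    if (is.null(q)) next
    w <- q - r$origin
    t <- min(max(sum(w * r$direction), 0), length)
    d <- vnorm(w - t * r$direction)
    if (d <= scapula$keep_out_radii[[nm]] + clearance_mm + screw_radius)
      return(FALSE)
  }
  TRUE
}

# vectorized segment-sphere clearance over candidate rows
notch_safe_rows <- function(scapula, origins, dirs, lengths, clearance,
                            screw_radius) {
  safe <- rep(TRUE, nrow(origins))
  len <- ifelse(is.finite(lengths), lengths, 0)
  for (nm in names(scapula$keep_out_radii)) {
    q <- scapula$landmarks[[nm]]
    if (is.null(q)) next
    w <- sweep(-origins, 2, q, "+")
    t <- pmin(pmax(rowSums(w * dirs), 0), len)
    dx <- w - dirs * t
    d <- sqrt(rowSums(dx^2))
    safe <- safe & (d > scapula$keep_out_radii[[nm]] + clearance +
                      screw_radius)
  }
  safe
}

# lattice of angle-grid values covering the variable-angle cone
angle_grid <- function(spec, step) {
  nom <- spec$nominal_hole_divergence
  cone <- spec$cone_half_angle
  cca <- seq(step * floor((nom - cone) / step),
             step * ceiling((nom + cone) / step), by = step)
  apa <- seq(step * floor(-cone / step), step * ceiling(cone / step),
             by = step)
  g <- expand.grid(cca = cca, apa = apa)
  g[cone_deviation(spec, g$cca, g$apa) <= cone + 1e-9, ]
}

# rotate the hole chord of a gra = 0 placement to an arbitrary roll angle
placement_at_gra <- function(pl0, gra) {
  u <- rotate_about(pl0$u_chord0, pl0$normal, -deg2rad(gra))
  pl0$u_chord <- u
  pl0$p_local <- cross3(pl0$normal, u)
  pl0$superior_hole_origin <- pl0$center + pl0$spec$hole_offset * u
  pl0$inferior_hole_origin <- pl0$center - pl0$spec$hole_offset * u
  pl0$gra_deg <- gra
  pl0
}

# evaluate candidates (gra, cca, apa) for one screw; returns the candidate
# data.frame extended with length/valid/safe/dev and exit coordinates
eval_candidates <- function(evaluator, pl0, screw, cand, scapula, spec, cfg) {
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(cand$gra, cand$cca, cand$apa), , drop = FALSE]
  origins <- matrix(0, nrow(cand), 3)
  dirs <- matrix(0, nrow(cand), 3)
  for (g in unique(cand$gra)) {
    idx <- which(cand$gra == g)
    pl <- placement_at_gra(pl0, g)
    o <- if (screw == "superior") pl$superior_hole_origin
         else pl$inferior_hole_origin
    origins[idx, ] <- matrix(o, length(idx), 3, byrow = TRUE)
    dirs[idx, ] <- screw_dirs(pl, screw, cand$cca[idx], cand$apa[idx])
  }
  res <- evaluator(origins, dirs)
  len <- ifelse(res[, 5] > 0, res[, 1], NA_real_)
  if (cfg$measure_from == "bone_entry") len <- len - res[, 6]
  cand$length <- len
  cand$valid <- res[, 5] > 0
  cand$safe <- notch_safe_rows(scapula, origins, dirs, len,
                               cfg$clearance_mm, spec$screw_diameter / 2)
  cand$dev <- cone_deviation(spec, cand$cca, cand$apa)
  cand$exit_x <- res[, 2]; cand$exit_y <- res[, 3]; cand$exit_z <- res[, 4]
  cand
}

# deterministic selection: longest screw, then smaller |GRA|, then smaller
# deviation from the nominal hole axis, then the screw's own positive
# (cranial/caudal) direction, then anterior, then row order
pick_best <- function(df) {
  ok <- df$valid & df$safe
  if (!any(ok)) return(NULL)
  d <- df[ok, , drop = FALSE]
  key_len <- round(d$length * 1e9)
  o <- order(-key_len, abs(d$gra), round(d$dev * 1e9), -d$cca, d$apa)
  d[o[1], , drop = FALSE]
}

refine_seq <- function(center, window, step, lo = -Inf, hi = Inf) {
  s <- seq(center - window, center + window, by = step)
  s[s >= lo & s <= hi]
}

screw_solution <- function(row, spec) {
  if (is.null(row))
    return(list(angles = c(cca_deg = NA_real_, apa_deg = NA_real_),
                length = NA_real_, exit_point = NULL, notch_safe = FALSE,
                corridor_valid = FALSE))
  list(angles = c(cca_deg = row$cca, apa_deg = row$apa),
       length = row$length,
       exit_point = c(row$exit_x, row$exit_y, row$exit_z),
       notch_safe = row$safe, corridor_valid = row$valid)
}

make_evaluator <- function(engine, scapula, primitives, cfg) {
  if (engine == "mesh") {
    function(origins, dirs)
      bicortical_batch(scapula$mesh, origins, dirs, cfg$max_length,
                       cfg$void_bridge_mm)
  } else {
    function(origins, dirs)
      analytic_bicortical_batch(primitives, origins, dirs, cfg$max_length,
                                cfg$void_bridge_mm)
  }
}

#' Patient-specific trajectory optimization
#'
#' Grid search reproducing the planning protocol: the baseplate is seated
#' inferiorly flush with a near-nominal tilt, then (1) the roll angle and the
#' superior screw angles are chosen jointly to maximize the bi-cortical
#' superior screw length among notch-safe candidates, and (2) with that roll
#' angle fixed, the inferior screw angles are chosen to maximize the
#' inferior bi-cortical length. Ties are broken toward smaller |GRA|, then
#' smaller deviation from the nominal hole axis, then the screw's own
#' cranial (superior screw) or caudal (inferior screw) preference. The
#' result is deterministic for fixed grids.
#'
#' @param scapula a [scapula_model].
#' @param frame a [build_glenoid_frame] result (computed when `NULL`).
#' @param spec a [metaglene_spec].
#' @param search_cfg a [search_config].
#' @param engine `"mesh"` casts rays against the triangle mesh;
#'   `"analytic"` casts against construction primitives (requires
#'   `primitives`; used to verify recovery of generator ground truth).
#' @param primitives analytic primitive list from [generate_scapula] truth.
#' @param extra_candidates optional list of full angle sets
#'   (`list(gra, s_cca, s_apa, i_cca, i_apa)`) additionally evaluated and
#'   locally refined; the incumbent is replaced only when a candidate is
#'   lexicographically better (longer superior, then longer inferior).
#' @return An object of class `case_solution`: `gra_deg`, `superior` and
#'   `inferior` screw solutions (angles, length, exit point, safety flags),
#'   `placement`, and `search_metadata`.
#' @export
optimize_case <- function(scapula, frame = NULL, spec = metaglene_spec(),
                          search_cfg = search_config(), engine = "mesh",
                          primitives = NULL, extra_candidates = list()) {
  cfg <- search_cfg
  if (is.null(frame)) frame <- build_glenoid_frame(scapula)
  evaluator <- make_evaluator(engine, scapula, primitives, cfg)
  pl0 <- place_baseplate(scapula, frame, spec, gra_deg = 0)
  pl0$u_chord0 <- pl0$u_chord
  n_eval <- 0L

  gra_grid <- seq(cfg$gra_range[1], cfg$gra_range[2], by = cfg$gra_step)
  ang <- angle_grid(spec, cfg$angle_step)

  run_sup <- function(gras, angles) {
    cand <- cbind(gra = rep(gras, each = nrow(angles)),
                  angles[rep(seq_len(nrow(angles)), length(gras)), ])
    n_eval <<- n_eval + nrow(cand)
    eval_candidates(evaluator, pl0, "superior", as.data.frame(cand),
                    scapula, spec, cfg)
  }
  run_inf <- function(gras, angles) {
    cand <- cbind(gra = rep(gras, each = nrow(angles)),
                  angles[rep(seq_len(nrow(angles)), length(gras)), ])
    n_eval <<- n_eval + nrow(cand)
    eval_candidates(evaluator, pl0, "inferior", as.data.frame(cand),
                    scapula, spec, cfg)
  }

  if (cfg$gra_coupling == "joint") {
    sup_all <- run_sup(gra_grid, ang)
    ok <- sup_all[sup_all$valid & sup_all$safe, , drop = FALSE]
    if (nrow(ok) && cfg$tie_mm > 0) {
      # roll angles whose best superior length ties the optimum compete on
      # the inferior screw, then on |GRA|
      lmax <- max(ok$length)
      tied <- sort(unique(ok$gra[ok$length >= lmax - cfg$tie_mm]))
      if (length(tied) > 1) {
        inf_all <- run_inf(tied, ang)
        iok <- inf_all[inf_all$valid & inf_all$safe, , drop = FALSE]
        ilen <- vapply(tied, function(g) {
          v <- iok$length[iok$gra == g]
          if (length(v)) max(v) else -Inf
        }, numeric(1))
        o <- order(-round(ilen * 1e9), abs(tied), tied)
        g_pick <- tied[o[1]]
      } else g_pick <- tied
      best_sup <- pick_best(ok[ok$gra == g_pick, , drop = FALSE])
    } else {
      best_sup <- pick_best(sup_all)
    }
  } else {
    nom <- data.frame(cca = spec$nominal_hole_divergence, apa = 0)
    by_gra <- pick_best(run_sup(gra_grid, nom))
    g0 <- if (is.null(by_gra)) 0 else by_gra$gra
    best_sup <- pick_best(run_sup(g0, ang))
  }

  refine_around <- function(best, which_screw) {
    if (is.null(best) || !cfg$refine) return(best)
    gras <- if (which_screw == "superior")
      refine_seq(best$gra, cfg$refine_window, cfg$refine_step,
                 cfg$gra_range[1], cfg$gra_range[2]) else best$gra
    cc <- refine_seq(best$cca, cfg$refine_window, cfg$refine_step)
    aa <- refine_seq(best$apa, cfg$refine_window, cfg$refine_step)
    angles <- expand.grid(cca = cc, apa = aa)
    angles <- angles[cone_deviation(spec, angles$cca, angles$apa) <=
                       spec$cone_half_angle + 1e-9, ]
    res <- if (which_screw == "superior") run_sup(gras, angles)
           else run_inf(gras, angles)
    cand <- pick_best(res)
    if (is.null(cand) || cand$length < best$length) best else cand
  }

  best_sup <- refine_around(best_sup, "superior")
  gra_star <- if (is.null(best_sup)) 0 else best_sup$gra

  if (cfg$objective == "sum" && !is.null(best_sup)) {
    # re-rate GRA candidates by summed length of both screws
    if (cfg$gra_coupling != "joint") sup_all <- run_sup(gra_grid, ang)
    tot <- vapply(gra_grid, function(g) {
      s <- pick_best(sup_all[sup_all$gra == g, , drop = FALSE])
      if (is.null(s)) return(-Inf)
      i <- pick_best(run_inf(g, ang))
      if (is.null(i)) return(-Inf)
      s$length + i$length
    }, numeric(1))
    if (any(is.finite(tot))) {
      g <- gra_grid[which.max(tot)]
      best_sup <- refine_around(
        pick_best(sup_all[sup_all$gra == g, , drop = FALSE]), "superior")
      gra_star <- g
    }
  }

  best_inf <- refine_around(pick_best(run_inf(gra_star, ang)), "inferior")

  sol <- list(gra_deg = gra_star, superior = screw_solution(best_sup, spec),
              inferior = screw_solution(best_inf, spec))

  for (ec in extra_candidates) {
    cand_sol <- tryCatch(
      evaluate_fixed_angles(scapula, frame, spec, ec$gra, c(ec$s_cca, ec$s_apa),
                            c(ec$i_cca, ec$i_apa), search_cfg = cfg,
                            engine = engine, primitives = primitives),
      error = function(e) NULL)
    if (is.null(cand_sol)) next
    s_new <- cand_sol$superior$length
    s_old <- sol$superior$length
    better <- isTRUE(s_new > s_old + 1e-9) ||
      (isTRUE(abs(s_new - s_old) <= 1e-9) &&
         isTRUE(cand_sol$inferior$length > sol$inferior$length + 1e-9))
    if (better) sol <- cand_sol[c("gra_deg", "superior", "inferior")]
  }

  sol$placement <- placement_at_gra(pl0, sol$gra_deg)
  sol$search_metadata <- list(evaluations = n_eval,
                              gra_step = cfg$gra_step,
                              angle_step = cfg$angle_step,
                              refine_step = if (cfg$refine) cfg$refine_step
                                            else NA_real_,
                              engine = engine)
  class(sol) <- "case_solution"
  if (!sol$superior$corridor_valid || !sol$inferior$corridor_valid ||
      !isTRUE(sol$superior$notch_safe) || !isTRUE(sol$inferior$notch_safe))
    sol$failed <- TRUE
  sol
}

#' @export
print.case_solution <- function(x, ...) {
  cat(sprintf("case_solution: GRA %.2f deg\n", x$gra_deg))
  cat(sprintf("  superior: CCA %.2f, APA %.2f deg -> %.1f mm (safe: %s)\n",
              x$superior$angles[1], x$superior$angles[2], x$superior$length,
              x$superior$notch_safe))
  cat(sprintf("  inferior: CCA %.2f, APA %.2f deg -> %.1f mm (safe: %s)\n",
              x$inferior$angles[1], x$inferior$angles[2], x$inferior$length,
              x$inferior$notch_safe))
  invisible(x)
}

#' Evaluate a fixed angle prescription on one case
#'
#' No optimization: the baseplate is placed with the given roll angle under
#' the same placement rules, both screws are evaluated at the given angles,
#' and the same bi-cortical and notch-safety definitions apply. This is the
#' evaluation primitive for the calculated-average and rounded-average
#' validation models. Angles outside the variable-angle cone are an error.
#'
#' @param scapula,frame,spec,search_cfg,engine,primitives as in
#'   [optimize_case].
#' @param gra_deg roll angle (degrees).
#' @param superior_angles,inferior_angles numeric `c(cca, apa)` (degrees).
#' @return A `case_solution` (without search metadata refinement).
#' @export
evaluate_fixed_angles <- function(scapula, frame, spec, gra_deg,
                                  superior_angles, inferior_angles,
                                  search_cfg = search_config(),
                                  engine = "mesh", primitives = NULL) {
  cfg <- search_cfg
  if (is.null(frame)) frame <- build_glenoid_frame(scapula)
  for (a in list(superior_angles, inferior_angles)) {
    dev <- cone_deviation(spec, a[1], a[2])
    if (dev > spec$cone_half_angle + 1e-9)
      stop(sprintf("angles (%.1f, %.1f) outside the variable-angle cone", a[1], a[2]))
  }
  evaluator <- make_evaluator(engine, scapula, primitives, cfg)
  pl0 <- place_baseplate(scapula, frame, spec, gra_deg = 0)
  pl0$u_chord0 <- pl0$u_chord
  sup <- eval_candidates(evaluator, pl0, "superior",
                         data.frame(gra = gra_deg, cca = superior_angles[1],
                                    apa = superior_angles[2]),
                         scapula, spec, cfg)
  inf <- eval_candidates(evaluator, pl0, "inferior",
                         data.frame(gra = gra_deg, cca = inferior_angles[1],
                                    apa = inferior_angles[2]),
                         scapula, spec, cfg)
  sol <- list(gra_deg = gra_deg,
              superior = screw_solution(sup[1, , drop = FALSE], spec),
              inferior = screw_solution(inf[1, , drop = FALSE], spec),
              placement = placement_at_gra(pl0, gra_deg),
              search_metadata = list(evaluations = 2L, engine = engine))
  class(sol) <- "case_solution"
  sol
}

#' Optimum implied by the generator's analytic geometry
#'
#' Runs the same search as [optimize_case] but measures every candidate ray
#' against the exact construction solids of [generate_scapula] instead of
#' the tessellated mesh, providing mesh-independent ground truth for
#' recovery tests.
#'
#' @param generated a `list(model, truth)` from [generate_scapula].
#' @param spec a [metaglene_spec].
#' @param search_cfg a [search_config].
#' @return A `case_solution`.
#' @export
ground_truth_optimum <- function(generated, spec = metaglene_spec(),
                                 search_cfg = search_config()) {
  optimize_case(generated$model, generated$truth$frame, spec, search_cfg,
                engine = "analytic", primitives = generated$truth$primitives)
}
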