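# Iterative posture refinement: greedy coordinate descent on the
# correspondence score, mirroring the manual few-posture iteration of the
# reverse trajectorial workflow (propose neighbouring postures, keep the
# best strictly-improving one, stop when none improves).

#' Search configuration
#'
#' @param base_posture starting [posture()]
#' @param step_deg step size per DOF in degrees (scalar or named vector)
#' @param bounds named list `c(lo, hi)` per DOF
#' @param max_iterations iteration cap
#' @param improvement_tolerance minimum score improvement (degrees) to
#'   accept a candidate
#' @return a `search_config`
#' @export
search_config <- function(base_posture, step_deg = 5,
                          bounds = DOF_BOUNDS_DEFAULT,
                          max_iterations = 50,
                          improvement_tolerance = 0) {
  if (length(step_deg) == 1)
    step_deg <- stats::setNames(rep(step_deg, length(DOF_NAMES)), DOF_NAMES)
  if (any(step_deg <= 0)) stop("step sizes must be strictly positive")
  if (improvement_tolerance < 0) stop("improvement tolerance must be >= 0")
  structure(list(base_posture = as_posture(base_posture),
                 step_deg = step_deg[DOF_NAMES], bounds = bounds,
                 max_iterations = max_iterations,
                 improvement_tolerance = improvement_tolerance),
            class = "search_config")
}

#' Enumerate neighbouring candidate postures
#'
#' Coordinate-wise +/- one step per DOF, clipped to bounds and
#' deduplicated (a DOF sitting at a bound yields a one-sided candidate).
#'
#' @param current a [posture()]
#' @param config a [search_config()]
#' @return list of postures
#' @export
enumerate_candidates <- function(current, config) {
  current <- as_posture(current)
  cands <- list()
  seen <- character()
  for (d in DOF_NAMES) {
    for (sgn in c(-1, 1)) {
      p <- unclass(current)
      b <- config$bounds[[d]]
      p[[d]] <- min(max(p[[d]] + sgn * config$step_deg[[d]], b[1]), b[2])
      key <- paste(signif(p, 12), collapse = "|")
      if (identical(unname(p[[d]]), unname(current[[d]]))) next
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1]] <- structure(p, class = "posture")
    }
  }
  cands
}

#' Evaluate one posture end-to-end
#'
#' Inverse statics, static optimization, stress trajectories at the
#' fabric lattice points, and the correspondence report against the
#' fabric field.
#'
#' @param model a `model_spec`
#' @param fabric a `fabric_field`
#' @param rois list of [spherical_roi()]
#' @param pose a [posture()]
#' @param loadcase a [load_case()]
#' @param roi_points_only evaluate stresses only at lattice points inside
#'   some ROI (faster; identical score)
#' @return list: `report` (a `correspondence_report`), `solution`, `fk`
#' @export
evaluate_posture <- function(model, fabric, rois, pose,
                             loadcase = load_case(model),
                             roi_points_only = TRUE) {
  fk <- forward_kinematics(model, pose)
  if (!fk$feasible) stop("infeasible posture: joint below ground plane")
  M <- inverse_static_moments(model, pose, loadcase)
  sol <- static_optimization(model, M, pose)
  pts <- fabric
  if (roi_points_only && "roi" %in% names(fabric))
    pts <- fabric[fabric$roi != "", , drop = FALSE]
  stress <- stress_trajectory_field(model, pose, sol, pts, loadcase)
  rep <- correspondence_score(stress, fabric, rois)
  list(report = rep, solution = sol, fk = fk, stress = stress)
}

#' Greedy posture search
#'
#' Starting from the base posture, repeatedly evaluates all candidate
#' neighbours and accepts the best strictly improving one (improvement
#' greater than the tolerance); halts when no candidate improves or the
#' iteration cap is reached.  Because several correspondence signals
#' depend on segment orientations that are sums of joint angles, the
#' score surface has diagonal valleys (e.g. hip extension vs knee
#' flexion); the proposal set therefore includes two-DOF diagonal steps
#' in addition to the single-DOF perturbations of
#' [enumerate_candidates()] (disable with `diagonal = FALSE`).  Candidate ties are broken by the smallest
#' total angular change from the current posture, then by DOF order, so
#' the result is independent of enumeration order.  The search itself is
#' deterministic; all randomness lives in fabric generation.
#'
#' @param model a `model_spec`
#' @param fabric a `fabric_field`
#' @param rois list of [spherical_roi()]
#' @param config a [search_config()]
#' @param loadcase a [load_case()]
#' @param verbose print progress
#' @return list: `posture` (solution posture), `score`, `trace`
#'   (data.frame of every evaluated posture with per-ROI deviations,
#'   overall score, iteration and accepted flag), `report`
#' @export
search_posture <- function(model, fabric, rois, config,
                           loadcase = load_case(model), diagonal = TRUE,
                           verbose = FALSE) {
  cur <- config$base_posture
  ev <- evaluate_posture(model, fabric, rois, cur, loadcase)
  if (is.na(ev$report$overall_score))
    stop("base posture not evaluable: ROI failures ",
         paste(ev$report$failed, collapse = ", "))
  trace <- list(trace_row(cur, ev$report, 0L, TRUE))
  best_rep <- ev$report

  for (it in seq_len(config$max_iterations)) {
    cands <- enumerate_candidates(cur, config)
    if (diagonal) cands <- c(cands, diagonal_candidates(cur, config))
    scores <- rep(NA_real_, length(cands))
    reps <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      e <- tryCatch(evaluate_posture(model, fabric, rois, cands[[i]],
                                     loadcase),
                    error = function(err) NULL)
      if (!is.null(e)) {
        scores[i] <- e$report$overall_score
        reps[[i]] <- e$report
      }
    }
    cur_score <- best_rep$overall_score
    improving <- which(!is.na(scores) &
                         scores < cur_score - config$improvement_tolerance -
                         1e-12)
    idx_map <- integer(length(cands))
    for (i in seq_along(cands))
      if (!is.null(reps[[i]])) {
        trace[[length(trace) + 1]] <- trace_row(cands[[i]], reps[[i]], it,
                                                FALSE)
        idx_map[i] <- length(trace)
      }
    if (length(improving) == 0) break
    # strict improvement exists: pick best score; ties by smallest total
    # angular change, then enumeration (DOF) order
    delta <- vapply(cands, function(p) sum(abs(unclass(p) - unclass(cur))),
                    0)
    ord <- improving[order(scores[improving], delta[improving], improving)]
    pick <- ord[1]
    cur <- cands[[pick]]
    best_rep <- reps[[pick]]
    trace[[idx_map[pick]]]$accepted <- TRUE
    if (verbose)
      message("iter ", it, ": score ", signif(best_rep$overall_score, 4),
              " deg")
  }
  trace_df <- do.call(rbind, trace)
  rownames(trace_df) <- NULL
  list(posture = cur, score = best_rep$overall_score, trace = trace_df,
       report = best_rep)
}

trace_row <- function(pose, rep, iteration, accepted) {
  row <- as.data.frame(as.list(unclass(pose)))
  for (k in seq_len(nrow(rep$per_roi)))
    row[[paste0("dev_", rep$per_roi$label[k])]] <- rep$per_roi$deviation[k]
  row$overall_score <- rep$overall_score
  row$iteration <- iteration
  row$accepted <- accepted
  row
}

# Two-DOF diagonal perturbations (all +/- combinations of distinct DOF
# pairs), clipped to bounds and deduplicated against the current posture.
diagonal_candidates <- function(current, config) {
  current <- as_posture(current)
  cands <- list(); seen <- character()
  nd <- length(DOF_NAMES)
  for (i in seq_len(nd - 1)) for (j in seq((i + 1), nd)) {
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      p <- unclass(current)
      for (k in c(i, j)) {
        d <- DOF_NAMES[k]; b <- config$bounds[[d]]
        sgn <- if (k == i) s1 else s2
        p[[d]] <- min(max(p[[d]] + sgn * config$step_deg[[d]], b[1]), b[2])
      }
      if (all(abs(p - unclass(current)) < 1e-12)) next
      key <- paste(signif(p, 12), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1]] <- structure(p, class = "posture")
    }
  }
  cands
}

#' Hip-articulation variant
#'
#' Moves the femur (and every structure distal to it, including distal
#' joint frames and muscle points level with or below the hip) medially
#' within the acetabulum, and adds fixed abduction / external long-axis
#' rotation offsets to evaluated postures.
#'
#' @param medial_translation metres (positive = medial)
#' @param extra_abduction degrees added to hip abduction
#' @param extra_lar degrees of additional external long-axis rotation
#' @return a `hip_variant`
#' @export
hip_variant <- function(medial_translation = 0, extra_abduction = 0,
                        extra_lar = 0) {
  structure(list(medial_translation = medial_translation,
                 extra_abduction = extra_abduction,
                 extra_lar = extra_lar), class = "hip_variant")
}

#' Apply a hip-articulation variant to a model
#'
#' @param model a `model_spec`
#' @param variant a [hip_variant()]
#' @param acetabular_width maximum admissible medial translation (m);
#'   defaults to half the femur length times 0.25 (pelvis half-width)
#' @return modified `model_spec`
#' @export
apply_hip_variant <- function(model, variant, acetabular_width = NULL) {
  if (is.null(acetabular_width))
    acetabular_width <- 0.25 * model$template$femur_length
  if (abs(variant$medial_translation) > acetabular_width)
    stop("medial translation exceeds the acetabular width (",
         signif(acetabular_width, 3), " m)")
  model$hip_medial_offset <- model$hip_medial_offset +
    variant$medial_translation
  model$extra_abduction <- model$extra_abduction + variant$extra_abduction
  model$extra_lar <- model$extra_lar + variant$extra_lar
  model
}

#' Foot-placement diagnostics for a posture
#'
#' Step width is twice the mediolateral distance between the
#' metatarsophalangeal joint and the body midline; the midline sits one
#' pelvis half-width (default a quarter femur length) medial to the hip.
#'
#' @param model a `model_spec`
#' @param pose a [posture()]
#' @param pelvis_half_width metres
#' @return list: `step_width`, `hip_height`, `step_width_ratio`
#' @export
posture_diagnostics <- function(model, pose,
                                pelvis_half_width =
                                  0.25 * model$template$femur_length) {
  fk <- forward_kinematics(model, pose)
  sw <- 2 * abs(pelvis_half_width - fk$joints$mtp[2])
  list(step_width = sw, hip_height = fk$h,
       step_width_ratio = sw / fk$h)
}
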