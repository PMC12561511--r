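#' Pipeline configuration for coarse-to-fine registration
#'
#' @param k_regions number of FPS candidate regions on the pre-operative
#'   cloud (default 25).
#' @param region_radius_factor region radius as a fraction of the
#'   intra-operative cloud's bounding-sphere radius (default 0.75); used
#'   when `region_radius` is `NULL`.
#' @param region_radius explicit region radius in mm (overrides factor).
#' @param ransac_iters RANSAC hypothesis count.
#' @param ransac_inlier_factor inlier threshold as a multiple of the
#'   target keypoints' median nearest-neighbor spacing.
#' @param min_prob minimum match probability for a correspondence.
#' @param icp_max_iters,icp_tol,icp_max_corr_dist point-to-point ICP
#'   settings (iterations, mean-residual change tolerance in mm,
#'   correspondence cutoff in mm).
#' @param icp_robust use Welsch-weighted re-estimation in the fine
#'   stage (still point-to-point; softens cross-source mismatch bias).
#' @param icp_polish,icp_polish_dist run a short symmetric-correspondence
#'   pass at this tight gate (mm) from the converged pose; cancels most
#'   nearest-sample quantization bias.
#' @param fail_rotation_deg,fail_translation_mm a coarse result beyond
#'   either bound is flagged as a registration failure.
#' @param seed RNG seed for RANSAC.
#' @export
pipeline_config <- function(k_regions = 25L,
                            region_radius_factor = 0.75,
                            region_radius = NULL,
                            ransac_iters = 5000L,
                            ransac_inlier_factor = 2,
                            min_prob = 0,
                            icp_max_iters = 100L,
                            icp_tol = 1e-6,
                            icp_max_corr_dist = 10,
                            icp_robust = TRUE,
                            icp_polish = TRUE,
                            icp_polish_dist = 1.2,
                            fail_rotation_deg = 60,
                            fail_translation_mm = 60,
                            seed = 1L) {
  structure(list(k_regions = as.integer(k_regions),
                 region_radius_factor = region_radius_factor,
                 region_radius = region_radius,
                 ransac_iters = as.integer(ransac_iters),
                 ransac_inlier_factor = ransac_inlier_factor,
                 min_prob = min_prob,
                 icp_max_iters = as.integer(icp_max_iters),
                 icp_tol = icp_tol,
                 icp_max_corr_dist = icp_max_corr_dist,
                 icp_robust = icp_robust,
                 icp_polish = icp_polish,
                 icp_polish_dist = icp_polish_dist,
                 fail_rotation_deg = fail_rotation_deg,
                 fail_translation_mm = fail_translation_mm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Robust pose from putative correspondences (RANSAC)
#'
#' Scores minimal 3-pair hypotheses by inlier count and refits the best
#' one on all its inliers by least-squares orthogonal superposition.
#' Deterministic given `seed`.
#'
#' @param correspondences data.frame from [extract_correspondences()]
#'   (uses its `src_xyz`/`tgt_xyz` attributes), or `NULL` when raw
#'   matrices are given.
#' @param src_xyz,tgt_xyz optional explicit n x 3 matched coordinates.
#' @param iters number of hypotheses.
#' @param inlier_thresh inlier residual threshold in mm.
#' @param seed RNG seed.
#' @return list with `transform` (`rigid_transform`), `inlier_count`,
#'   `inliers` (indices) and `ok`; `ok = FALSE` with fewer than 3
#'   correspondences.
#' @export
estimate_pose_ransac <- function(correspondences = NULL, src_xyz = NULL,
                                 tgt_xyz = NULL, iters = 5000L,
                                 inlier_thresh = 2, seed = 1L) {
  if (!is.null(correspondences)) {
    src_xyz <- attr(correspondences, "src_xyz")
    tgt_xyz <- attr(correspondences, "tgt_xyz")
  }
  if (is.null(src_xyz) || nrow(src_xyz) < 3L) {
    return(list(ok = FALSE, transform = identity_transform(),
                inlier_count = 0L, inliers = integer()))
  }
  res <- ransac_cpp(src_xyz, tgt_xyz, as.integer(iters), inlier_thresh,
                    as.integer(seed) %% .Machine$integer.max)
  if (!res$ok) {
    return(list(ok = FALSE, transform = identity_transform(),
                inlier_count = 0L, inliers = integer()))
  }
  list(ok = TRUE,
       transform = rigid_transform(res$rotation, res$translation),
       inlier_count = res$inlier_count,
       inliers = as.integer(res$inliers))
}

#' Point-to-point ICP refinement
#'
#' Iterates nearest-neighbor correspondence (within `max_corr_dist`) and
#' least-squares rigid re-estimation from the initial pose, stopping when
#' the mean matched residual changes by less than `tol` or after
#' `max_iters` iterations.
#'
#' @param src,tgt [point_cloud()]s; the refined transform maps `src`
#'   onto `tgt`.
#' @param init initial `rigid_transform`.
#' @param max_iters,tol,max_corr_dist see [pipeline_config()].
#' @param trim fraction of closest correspondences kept per iteration
#'   (1 = plain point-to-point ICP); trimming suppresses the tangential
#'   pull that patch boundaries exert under partial overlap.
#' @param robust re-estimate each iteration with Welsch weights scaled
#'   by the median residual, softening the influence of boundary and
#'   cross-source mismatches.
#' @param symmetric also match target points back to the source and
#'   stack both correspondence sets; this cancels most of the
#'   nearest-sample quantization bias when the two clouds sample the
#'   surface at different densities.
#' @return list with `transform`, `converged`, `residuals` (per
#'   iteration) and `had_correspondences` (FALSE when no point matched
#'   at the initial pose, in which case `init` is returned unchanged).
#' @export
icp_refine <- function(src, tgt, init = identity_transform(),
                       max_iters = 100L, tol = 1e-6, max_corr_dist = 10,
                       trim = 1.0, symmetric = FALSE, robust = FALSE) {
  stopifnot(inherits(src, "point_cloud"), inherits(tgt, "point_cloud"),
            inherits(init, "rigid_transform"))
  res <- icp_cpp(src$points, tgt$points, init$rotation, init$translation,
                 as.integer(max_iters), tol, max_corr_dist, trim, symmetric,
                 robust)
  if (!res$had_correspondences) {
    return(list(transform = init, converged = FALSE,
                had_correspondences = FALSE, residuals = numeric()))
  }
  list(transform = rigid_transform(res$rotation, res$translation),
       converged = res$converged,
       had_correspondences = TRUE,
       residuals = as.numeric(res$residuals))
}

# Match the intra-operative keypoints against one candidate region and
# estimate the pose. Returns NULL when the region is too small to encode.
.match_region <- function(intraop_kp_raw, region_cloud, model, cfg) {
  if (n_points(region_cloud) < model$config$sa_layers[[3]]$n_out) {
    return(NULL)
  }
  kp_r <- encode(region_cloud, model)
  att <- attend(intraop_kp_raw, kp_r, model)
  phi <- match_keypoints(att$src, att$tgt, model_temperature(model))
  corr <- extract_correspondences(phi, att$src, att$tgt, cfg$min_prob)
  if (nrow(corr) < 3L) {
    return(list(ok = FALSE, inlier_count = 0L, n_corr = nrow(corr)))
  }
  # threshold from the tighter of the two keypoint samplings: a loose
  # threshold lets approximately self-similar wrong alignments collect
  # as many inliers as the true one
  sp_r <- if (nrow(kp_r$coords) >= 2L) {
    median(knn_cpp(kp_r$coords, kp_r$coords, 1L, TRUE)$dist[, 1L])
  } else 1
  sp_i <- if (nrow(intraop_kp_raw$coords) >= 2L) {
    median(knn_cpp(intraop_kp_raw$coords, intraop_kp_raw$coords, 1L,
                   TRUE)$dist[, 1L])
  } else 1
  spacing <- min(sp_r, sp_i)
  pose <- estimate_pose_ransac(corr, iters = cfg$ransac_iters,
                               inlier_thresh = cfg$ransac_inlier_factor * spacing,
                               seed = cfg$seed)
  if (!pose$ok) {
    return(list(ok = FALSE, inlier_count = 0L, n_corr = nrow(corr)))
  }
  # trimmed RMS residual of inlier correspondences under the pose
  sx <- attr(corr, "src_xyz")[pose$inliers, , drop = FALSE]
  tx <- attr(corr, "tgt_xyz")[pose$inliers, , drop = FALSE]
  moved <- sweep(sx %*% t(pose$transform$rotation), 2L,
                 pose$transform$translation, "+")
  resid <- sqrt(mean(rowSums((moved - tx)^2)))
  list(ok = TRUE, transform = pose$transform,
       inlier_count = pose$inlier_count, residual = resid,
       n_corr = nrow(corr))
}

#' Coarse registration by candidate-region traversal
#'
#' Matches the intra-operative cloud against every FPS local region of
#' the pre-operative cloud (encode, attend, match, RANSAC) and selects
#' the winning region. In `oracle` mode regions are ranked by rotation
#' error against the supplied ground truth (ties: lowest translation
#' error, then lowest region index) — the evaluation protocol. In
#' `blind` mode (no ground truth needed) ranking is by RANSAC inlier
#' count, then lowest trimmed RMS residual, then lowest index.
#'
#' @param intraop intra-operative [point_cloud()] with curvature.
#' @param regions a `local_region_set` from [extract_regions()].
#' @param preop the pre-operative [point_cloud()] with curvature.
#' @param model a trained `matcher_model`.
#' @param mode `"oracle"` or `"blind"`.
#' @param T_G ground-truth `rigid_transform` (required for oracle mode).
#' @param cfg a [pipeline_config()].
#' @return A `registration_result` with the coarse transform, the
#'   selected region index and a per-region log; `failed = TRUE` when no
#'   region yields a usable pose.
#' @export
select_region <- function(intraop, regions, preop, model,
                          mode = c("oracle", "blind"), T_G = NULL,
                          cfg = pipeline_config()) {
  mode <- match.arg(mode)
  if (mode == "oracle" && is.null(T_G)) {
    stop("oracle mode requires the ground-truth transform T_G")
  }
  kp_i <- encode(intraop, model)
  log <- vector("list", length(regions$regions))
  for (ri in seq_along(regions$regions)) {
    reg_cloud <- subset_cloud(preop, regions$regions[[ri]])
    mr <- .match_region(kp_i, reg_cloud, model, cfg)
    if (is.null(mr)) {
      log[[ri]] <- list(region_index = ri, ok = FALSE, inliers = 0L,
                        residual = NA_real_, note = "region too small")
      next
    }
    if (!mr$ok) {
      log[[ri]] <- list(region_index = ri, ok = FALSE, inliers = 0L,
                        residual = NA_real_, note = "pose estimation failed")
      next
    }
    entry <- list(region_index = ri, ok = TRUE, inliers = mr$inlier_count,
                  residual = mr$residual, transform = mr$transform)
    if (!is.null(T_G)) {
      err <- registration_error(mr$transform, T_G)
      entry$e_r <- err$rotation_error_deg
      entry$e_t <- err$translation_error_mm
    }
    log[[ri]] <- entry
  }
  ok <- vapply(log, function(e) isTRUE(e$ok), TRUE)
  if (!any(ok)) {
    return(structure(list(failed = TRUE, mode = mode, per_region_log = log),
                     class = "registration_result"))
  }
  cand <- which(ok)
  if (mode == "oracle") {
    er <- vapply(log[cand], function(e) e$e_r, 1.0)
    best <- cand[order(er, cand)][1L]  # ties: lowest region index
  } else {
    inl <- vapply(log[cand], function(e) as.numeric(e$inliers), 1.0)
    res <- vapply(log[cand], function(e) e$residual, 1.0)
    best <- cand[order(-inl, res, cand)][1L]
  }
  chosen <- log[[best]]
  failed <- FALSE
  coarse_error <- NULL
  if (!is.null(T_G)) {
    coarse_error <- registration_error(chosen$transform, T_G)
    failed <- coarse_error$rotation_error_deg > cfg$fail_rotation_deg ||
      coarse_error$translation_error_mm > cfg$fail_translation_mm
  }
  structure(list(failed = failed, mode = mode,
                 coarse_transform = chosen$transform,
                 selected_region_index = best,
                 coarse_error = coarse_error,
                 per_region_log = log),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  if (isTRUE(x$failed) && is.null(x$coarse_transform)) {
    cat("<registration_result> FAILED (no region produced a pose)\n")
    return(invisible(x))
  }
  cat(sprintf("<registration_result> mode=%s region=%d%s\n", x$mode,
              x$selected_region_index,
              if (isTRUE(x$failed)) " [FLAGGED FAILED]" else ""))
  if (!is.null(x$coarse_error)) {
    cat(sprintf("  coarse: e_r = %.3f deg, e_t = %.3f mm\n",
                x$coarse_error$rotation_error_deg,
                x$coarse_error$translation_error_mm))
  }
  if (!is.null(x$fine_error)) {
    cat(sprintf("  fine:   e_r = %.3f deg, e_t = %.3f mm\n",
                x$fine_error$rotation_error_deg,
                x$fine_error$translation_error_mm))
  }
  invisible(x)
}

#' End-to-end coarse-to-fine registration
#'
#' Runs the full pipeline: density equalization of the intra-operative
#' cloud, curvature on both clouds, FPS region extraction on the
#' pre-operative cloud, coarse registration by region traversal
#' ([select_region()]), then point-to-point ICP of the intra-operative
#' cloud against the full pre-operative cloud from the coarse pose. The
#' returned transforms map the intra-operative cloud into the
#' pre-operative frame.
#'
#' @param preop,intraop [point_cloud()]s (curvature computed when
#'   absent).
#' @param model a trained `matcher_model`.
#' @param mode `"oracle"` (requires `T_G`) or `"blind"`.
#' @param T_G optional ground-truth `rigid_transform` for evaluation.
#' @param cfg a [pipeline_config()].
#' @param curv_cfg a [curvature_config()].
#' @return A `registration_result` with coarse and fine transforms,
#'   errors when ground truth was given, the per-region log and stage
#'   timings (seconds).
#' @export
register_clouds <- function(preop, intraop, model,
                            mode = c("oracle", "blind"), T_G = NULL,
                            cfg = pipeline_config(),
                            curv_cfg = curvature_config()) {
  mode <- match.arg(mode)
  timings <- c()
  t0 <- proc.time()[["elapsed"]]
  intraop_full <- intraop  # the fine stage uses every measured point
  intraop <- equalize_density(intraop, preop)
  if (is.null(preop$features)) preop <- compute_curvature(preop, curv_cfg)
  intraop <- compute_curvature(intraop, curv_cfg)  # density changed
  timings["prepare"] <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  rr <- if (is.null(cfg$region_radius)) {
    base <- cfg$region_radius_factor * bounding_radius(intraop)
    # floor at the FPS coverage distance so the union of candidate
    # regions covers the whole pre-operative surface: otherwise a small
    # exposed patch can fall between sample points and no region
    # contains the true overlap
    samp <- farthest_point_sample(preop, cfg$k_regions)
    cover <- max(knn_cpp(preop$points,
                         preop$points[samp, , drop = FALSE], 1L,
                         FALSE)$dist[, 1L])
    max(base, 1.1 * cover)
  } else cfg$region_radius
  regions <- extract_regions(preop, cfg$k_regions, rr)
  result <- select_region(intraop, regions, preop, model, mode, T_G, cfg)
  timings["coarse"] <- proc.time()[["elapsed"]] - t0
  if (isTRUE(result$failed) && is.null(result$coarse_transform)) {
    result$timings <- timings
    return(result)
  }
  t0 <- proc.time()[["elapsed"]]
  icp <- icp_refine(intraop_full, preop, result$coarse_transform,
                    cfg$icp_max_iters, cfg$icp_tol, cfg$icp_max_corr_dist,
                    robust = isTRUE(cfg$icp_robust))
  if (isTRUE(cfg$icp_polish) && icp$had_correspondences) {
    # short symmetric pass at a tight gate from the converged pose:
    # symmetrized correspondences cancel most nearest-sample
    # quantization bias once the alignment is already close
    polish <- icp_refine(intraop_full, preop, icp$transform, 60L, 1e-9,
                         cfg$icp_polish_dist, robust = isTRUE(cfg$icp_robust),
                         symmetric = TRUE)
    if (polish$had_correspondences) {
      icp$transform <- polish$transform
      icp$converged <- icp$converged && polish$converged
    }
  }
  timings["fine"] <- proc.time()[["elapsed"]] - t0
  result$fine_transform <- icp$transform
  result$icp_converged <- icp$converged
  if (!is.null(T_G)) {
    result$fine_error <- registration_error(icp$transform, T_G)
  }
  result$timings <- timings
  result$regions <- regions
  result
}
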