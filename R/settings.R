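#' Alignment settings
#'
#' Every knob of the two-stage registration.  The defaults reproduce the
#' automated comparison protocol: estimated overlap 100 % (no residual
#' trimming), 20 initial positions for the rough alignment, rough stage with
#' approximate (fast) nearest neighbours at 1 % point sampling, point-to-point
#' metric, 100 iterations; fine stage with exact nearest neighbours plus
#' normal compatibility at 100 % sampling, point-to-plane metric, 100
#' iterations.
#'
#' @param overlap_fraction fraction of accepted correspondences retained
#'   after residual trimming each fine iteration; 1 = no trimming.
#' @param n_initial_positions number of rough-alignment starting rotations.
#' @param rough_sampling fraction of source vertices used by the rough stage.
#' @param rough_iterations maximum rough-stage iterations per start.
#' @param fine_sampling fraction of source vertices used by the fine stage.
#' @param fine_iterations maximum fine-stage iterations.
#' @param normal_angle_max maximum angle (degrees) between source and target
#'   normals for a fine-stage correspondence to be accepted.
#' @param convergence_tol change in RMS residual (mm) below which iteration
#'   stops early.
#' @param approx_eps slack of the (1+eps)-approximate nearest-neighbour
#'   search used by the rough stage.
#' @param value_metric how the final mesh-to-mesh value is summarised:
#'   `"symmetric_rms"` (default), `"mean_absolute"`, `"hausdorff"` or
#'   `"one_directional"`.
#' @param agreement pair-declaration rule handed to [mutual_match()]:
#'   `"best"` (mutual rank-1, default) or `"topk"`.
#' @param seed integer seed controlling all sampling randomness.
#' @return An object of class `alignment_settings`.
#' @export
alignment_settings <- function(overlap_fraction = 1.0,
                               n_initial_positions = 20L,
                               rough_sampling = 0.01,
                               rough_iterations = 100L,
                               fine_sampling = 1.0,
                               fine_iterations = 100L,
                               normal_angle_max = 45,
                               convergence_tol = 1e-7,
                               approx_eps = 0.1,
                               value_metric = c("symmetric_rms",
                                                "mean_absolute", "hausdorff",
                                                "one_directional"),
                               agreement = c("best", "topk"),
                               seed = 1L) {
  value_metric <- match.arg(value_metric)
  agreement <- match.arg(agreement)
  s <- structure(list(overlap_fraction = overlap_fraction,
                      n_initial_positions = as.integer(n_initial_positions),
                      rough_sampling = rough_sampling,
                      rough_metric = "point_to_point",
                      rough_nn = "approximate",
                      rough_iterations = as.integer(rough_iterations),
                      fine_sampling = fine_sampling,
                      fine_metric = "point_to_plane",
                      fine_nn = "exact_normal_compatible",
                      fine_iterations = as.integer(fine_iterations),
                      normal_angle_max = normal_angle_max,
                      convergence_tol = convergence_tol,
                      approx_eps = approx_eps,
                      value_metric = value_metric,
                      agreement = agreement,
                      seed = as.integer(seed)),
                 class = "alignment_settings")
  validate_settings(s)
  s
}

validate_settings <- function(s) {
  stopifnot(s$overlap_fraction > 0, s$overlap_fraction <= 1,
            s$rough_sampling > 0, s$rough_sampling <= 1,
            s$fine_sampling > 0, s$fine_sampling <= 1,
            s$rough_iterations >= 1L, s$fine_iterations >= 1L,
            s$n_initial_positions >= 1L,
            s$normal_angle_max > 0, s$convergence_tol >= 0,
            s$approx_eps >= 0)
  invisible(s)
}

#' @export
print.alignment_settings <- function(x, ...) {
  cat("alignment_settings\n")
  cat(sprintf("  rough: point-to-point, %s NN (eps %.2g), %.3g%% sampling, %d starts, <=%d iterations\n",
              x$rough_nn, x$approx_eps, 100 * x$rough_sampling,
              x$n_initial_positions, x$rough_iterations))
  cat(sprintf("  fine:  point-to-plane, exact NN + normal compatibility (<=%g deg), %.3g%% sampling, <=%d iterations\n",
              x$normal_angle_max, 100 * x$fine_sampling, x$fine_iterations))
  cat(sprintf("  overlap %.3g%%, convergence tol %g mm, value metric %s, seed %d\n",
              100 * x$overlap_fraction, x$convergence_tol, x$value_metric,
              x$seed))
  invisible(x)
}

#' Read / write alignment settings as JSON
#'
#' Settings round-trip losslessly through a JSON config file whose defaults
#' are those of [alignment_settings()].
#'
#' @param settings an [alignment_settings()] object.
#' @param path file path.
#' @return `read_settings` returns an [alignment_settings()].
#' @export
write_settings <- function(settings, path) {
  jsonlite::write_json(unclass(settings), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_settings
#' @export
read_settings <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- alignment_settings()
  keep <- intersect(names(raw), setdiff(names(defaults),
                                        c("rough_metric", "rough_nn",
                                          "fine_metric", "fine_nn")))
  do.call(alignment_settings, raw[keep])
}
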