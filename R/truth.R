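#' Define a ground-truth trajectory
#'
#' @param species species name the trajectory belongs to.
#' @param anchor_fold intact fold at \code{anchor_time} relative to t = 0.
#' @param anchor_time anchor time in scenario clock units.
#' @param f_sol fraction of degraded mass rendered acid-soluble.
#' @param h0 hypomodified fraction during steady-state growth.
#' @param k_mod maturation rate of hypomodified tRNA (per minute).
#' @param points optional data.frame (\code{time}, \code{fold}) switching the
#'   species to piecewise-linear interpolation through these anchors. A leading
#'   (0, 1) anchor is added if absent.
#' @return a \code{\linkS4class{TruthTrajectory}}.
#' @examples
#' tr <- truthTrajectory("23S", anchor_fold = 0.75, anchor_time = 80)
#' intactFold(tr, c(0, 40, 80))
#' @export
truthTrajectory <- function(species, anchor_fold = 1, anchor_time = 80,
                            f_sol = 0.35, h0 = 0.10, k_mod = 0.1,
                            points = NULL) {
  if (is.null(points)) {
    points <- data.frame(time = numeric(), fold = numeric())
  } else {
    points <- as.data.frame(points)[, c("time", "fold")]
    if (nrow(points) == 0 || points$time[1] != 0) {
      points <- rbind(data.frame(time = 0, fold = 1), points)
    }
  }
  obj <- new("TruthTrajectory", species = species,
             anchor_fold = anchor_fold, anchor_time = anchor_time,
             f_sol = f_sol, h0 = h0, k_mod = k_mod, points = points)
  validObject(obj)
  obj
}

#' Intact labeled fold at time t
#'
#' Default geometric form \eqn{F(t) = a^{t/T}}: monotone, \eqn{F(0) = 1} and
#' \eqn{F(T) = a} exactly. If the trajectory carries piecewise-linear anchor
#' points, F interpolates linearly between them and holds the last anchor
#' value afterwards.
#'
#' @param traj a \code{\linkS4class{TruthTrajectory}}.
#' @param t time(s) >= 0, scenario clock units.
#' @return numeric vector of dimensionless folds.
#' @export
intactFold <- function(traj, t) {
  stopifnot(is(traj, "TruthTrajectory"))
  if (any(!is.finite(t)) || any(t < 0)) {
    .stopf("time must be finite and >= 0")
  }
  if (nrow(traj@points) > 0) {
    stats::approx(traj@points$time, traj@points$fold, xout = t, rule = 2)$y
  } else {
    traj@anchor_fold^(t / traj@anchor_time)
  }
}

#' Partition degraded mass between TCA-precipitable fragments and
#' acid-soluble products
#'
#' RNA degradation produces a mixture of fragments: oligomers longer than
#' roughly 16 nt stay in the TCA precipitate while mono-, di- and short
#' oligomers become acid-soluble and escape it. The split is governed by the
#' trajectory's \code{f_sol}.
#'
#' @param traj a \code{\linkS4class{TruthTrajectory}}.
#' @param mass degraded labeled mass (>= 0).
#' @return named numeric vector with components \code{tca_fragments} and
#'   \code{acid_soluble}; the two sum to \code{mass} exactly.
#' @export
degradedPartition <- function(traj, mass) {
  stopifnot(is(traj, "TruthTrajectory"))
  if (any(!is.finite(mass)) || any(mass < 0)) {
    .stopf("degraded mass must be finite and >= 0")
  }
  sol <- traj@f_sol * mass
  c(tca_fragments = mass - sol, acid_soluble = sol)
}

#' Hypomodified fraction of a tRNA pool at time t
#'
#' While synthesis is on, a constant fraction \code{h0} of the pool is newly
#' made and not yet fully modified. When stable-RNA synthesis shuts off (the
#' stringent response, or transcription inhibition), no new hypomodified
#' molecules enter and the existing ones mature at rate \code{k_mod}, so the
#' fraction decays as \eqn{h_0 e^{-k_{mod} t}}.
#'
#' @param traj a \code{\linkS4class{TruthTrajectory}}.
#' @param t time(s) >= 0 in minutes.
#' @param synthesis_on logical; is stable-RNA synthesis still running?
#' @return hypomodified fraction(s) in [0, h0].
#' @export
hypomodFraction <- function(traj, t, synthesis_on) {
  stopifnot(is(traj, "TruthTrajectory"), .is_flag(synthesis_on))
  if (any(!is.finite(t)) || any(t < 0)) {
    .stopf("time must be finite and >= 0")
  }
  if (synthesis_on) {
    rep(traj@h0, length(t))
  } else {
    traj@h0 * exp(-traj@k_mod * t)
  }
}

setMethod("show", "TruthTrajectory", function(object) {
  form <- if (nrow(object@points) > 0) {
    sprintf("piecewise-linear through %d anchors", nrow(object@points))
  } else {
    sprintf("geometric, fold %.3g at t = %.3g", object@anchor_fold,
            object@anchor_time)
  }
  cat(sprintf("TruthTrajectory '%s': %s; f_sol %.2f, h0 %.2f, k_mod %.3g\n",
              object@species, form, object@f_sol, object@h0, object@k_mod))
})

# resolve the trajectory for a species, defaulting to flat at 1; the flat
# default is shared (constructed once) since it is species-agnostic
.flatTrajCache <- new.env(parent = emptyenv())
.trajFor <- function(trajectories, species) {
  if (!is.null(trajectories[[species]])) {
    return(trajectories[[species]])
  }
  if (is.null(.flatTrajCache$flat)) {
    .flatTrajCache$flat <- truthTrajectory("flat", anchor_fold = 1)
  }
  .flatTrajCache$flat
}

#' Trajectory anchor table I/O
#'
#' Scenario ground truth is exchanged as two delimited tables: an anchor table
#' (columns \code{species}, \code{anchor_time}, \code{anchor_fold},
#' \code{f_sol}, \code{h0}, \code{k_mod}) and an optional piecewise-linear
#' points table (columns \code{species}, \code{time}, \code{fold}).
#'
#' @param anchors anchor data.frame.
#' @param points optional points data.frame.
#' @return \code{trajectoriesFromTable}: named list of
#'   \code{\linkS4class{TruthTrajectory}}. \code{trajectoriesToTable}: list
#'   with elements \code{anchors} and \code{points}.
#' @export
trajectoriesFromTable <- function(anchors, points = NULL) {
  need <- c("species", "anchor_time", "anchor_fold", "f_sol", "h0", "k_mod")
  missing <- setdiff(need, names(anchors))
  if (length(missing)) {
    .stopf("anchor table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    sp <- anchors$species[i]
    pts <- NULL
    if (!is.null(points) && nrow(points) > 0) {
      sel <- points[points$species == sp, c("time", "fold"), drop = FALSE]
      if (nrow(sel) > 0) pts <- sel
    }
    out[[sp]] <- truthTrajectory(
      sp, anchor_fold = anchors$anchor_fold[i],
      anchor_time = anchors$anchor_time[i], f_sol = anchors$f_sol[i],
      h0 = anchors$h0[i], k_mod = anchors$k_mod[i], points = pts)
  }
  out
}

#' @rdname trajectoriesFromTable
#' @param trajectories named list of \code{\linkS4class{TruthTrajectory}}.
#' @export
trajectoriesToTable <- function(trajectories) {
  anchors <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(species = tr@species, anchor_time = tr@anchor_time,
               anchor_fold = tr@anchor_fold, f_sol = tr@f_sol, h0 = tr@h0,
               k_mod = tr@k_mod, stringsAsFactors = FALSE)
  }))
  points <- do.call(rbind, lapply(trajectories, function(tr) {
    if (nrow(tr@points) == 0) return(NULL)
    data.frame(species = tr@species, time = tr@points$time,
               fold = tr@points$fold, stringsAsFactors = FALSE)
  }))
  if (is.null(points)) {
    points <- data.frame(species = character(), time = numeric(),
                         fold = numeric())
  }
  rownames(anchors) <- NULL
  rownames(points) <- NULL
  list(anchors = anchors, points = points)
}
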