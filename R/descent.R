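#' Agent policy for a view-matching descent
#'
#' Two minimal motor rules, named after the two candidate strategies for
#' trunk navigation. The *gradient* agent probes the familiarity (best
#' rotIDF mismatch against its stored views) at several azimuth offsets at
#' its current height and side-steps toward the most familiar probe. The
#' *compass* agent computes the best-matching rotation of its current view
#' against memory and side-steps so as to reduce that rotation. Both then
#' descend a fixed height increment with von Mises motor noise on the
#' lateral component; the total lateral change per step is bounded by
#' `lateral_step`.
#'
#' When the best familiarity on offer is worse than a no-signal threshold
#' (set from a pure-screen view in landmark-blocked runs), the agent has no
#' usable gradient: it side-steps uniformly at random within
#' `lateral_step`, and in blocked runs may instead escape above the screen
#' (see [run_condition()]).
#'
#' @param strategy `"gradient"` or `"compass"`.
#' @param memory list of reference panoramas from [acquire_memory()];
#'   `NULL` to let [run_condition()] acquire the default base view, or an
#'   empty `list()` for a memory-free agent that side-steps at random.
#' @param scan_offsets candidate probe azimuths relative to the current
#'   position (deg); must be symmetric about 0.
#' @param step_down height descended per step (m).
#' @param lateral_step maximum lateral movement per step (deg of trunk
#'   azimuth).
#' @param noise_kappa von Mises concentration of the lateral motor noise;
#'   `Inf` disables noise.
#' @param p_escape probability that a blocked agent with no usable signal
#'   climbs above the screen before descending for good.
#' @param metric mismatch metric passed to [rotidf()].
#' @return an object of class `trunknav_policy`.
#' @export
agent_policy <- function(strategy = c("gradient", "compass"),
                         memory = NULL,
                         scan_offsets = c(-20, -10, 10, 20),
                         step_down = 0.10,
                         lateral_step = 20,
                         noise_kappa = 50,
                         p_escape = 0.5,
                         metric = c("sad", "rms")) {
  strategy <- match.arg(strategy)
  metric <- match.arg(metric)
  if (step_down <= 0) stop("step_down must be > 0")
  if (lateral_step <= 0) stop("lateral_step must be > 0")
  if (!isTRUE(all.equal(sort(scan_offsets), sort(-scan_offsets)))) {
    stop("scan_offsets must be symmetric about 0")
  }
  structure(
    list(strategy = strategy, memory = memory, scan_offsets = scan_offsets,
         step_down = step_down, lateral_step = lateral_step,
         noise_kappa = noise_kappa, p_escape = p_escape, metric = metric),
    class = "trunknav_policy"
  )
}

#' Acquire reference view memory at a tree
#'
#' Renders the views an ant is assumed to have stored: by default a single
#' panorama at the base of the tree on its nest-facing side (trunk azimuth
#' 0, height 0).
#'
#' @param scene a [scene()] — for blocked experiments, the scene *without*
#'   the screen, since views are learned before the screen is installed.
#' @param tree_id which tree the memory belongs to.
#' @param heights acquisition heights in m (duplicates are dropped with a
#'   warning).
#' @param azimuth trunk azimuth of acquisition (deg; default 0, nest side).
#' @param offset eye clearance outside the bark (m).
#' @return a list of `trunknav_panorama`s, each tagged with its acquisition
#'   position.
#' @export
acquire_memory <- function(scene, tree_id = "foraging", heights = 0,
                           azimuth = 0, offset = 0.02) {
  if (any(heights < 0)) stop("heights must be >= 0")
  if (anyDuplicated(heights)) {
    warning("duplicate acquisition heights dropped")
    heights <- unique(heights)
  }
  purrr::map(heights, function(h) {
    p <- render_panorama(scene, trunk_viewpoint(scene, tree_id, azimuth, h,
                                                offset = offset))
    p$acquired_at <- list(azimuth = azimuth, height = h)
    p
  })
}

# familiarity + best rotation at a (rounded) trunk azimuth and height,
# memoised in `cache` because agents revisit the same positions constantly
view_match <- function(scene, tree_id, azimuth, height, memory, metric,
                       offset = 0.02, cache = NULL) {
  az <- wrap_deg(round(azimuth))
  hcm <- max(0L, as.integer(round(height * 100)))
  key <- sprintf("%s|%d|%d", tree_id, az, hcm)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  vp <- trunk_viewpoint(scene, tree_id, az, hcm / 100, offset = offset)
  cur <- render_panorama(scene, vp)
  best <- NULL
  for (mem in memory) {
    curve <- rotidf(mem, cur, metric = metric)
    if (is.null(best) || curve$best_mismatch < best$familiarity) {
      best <- list(familiarity = curve$best_mismatch,
                   best_rotation = curve$best_rotation)
    }
  }
  if (!is.null(cache)) cache[[key]] <- best
  best
}

#' Familiarity of a viewpoint given stored views
#'
#' The minimum over stored views of the best rotIDF mismatch between the
#' stored view and the current view: lower values mean a more familiar
#' place. Because panoramas are world-aligned and the rotIDF scans all
#' rotations, familiarity does not depend on the agent's heading.
#'
#' @param scene a [scene()].
#' @param viewpoint a [trunk_viewpoint()].
#' @param memory nonempty list of reference panoramas.
#' @param metric mismatch metric.
#' @return a single nonnegative mismatch value.
#' @export
familiarity <- function(scene, viewpoint, memory, metric = c("sad", "rms")) {
  metric <- match.arg(metric)
  if (length(memory) == 0) stop("memory must be nonempty")
  cur <- render_panorama(scene, viewpoint)
  min(purrr::map_dbl(memory, ~ rotidf(.x, cur, metric = metric)$best_mismatch))
}

#' Initial agent state on a trunk
#'
#' @param azimuth release azimuth (deg, 0 = nest side).
#' @param height release height (m).
#' @return an agent-state list used by [agent_step()].
#' @export
agent_state <- function(azimuth, height) {
  list(azimuth = azimuth, height = height, phase = "descend",
       escape_decided = FALSE, escape_allowed = NA, reorient_left = 0L,
       reorient_target = NULL)
}

motor_noise <- function(kappa) {
  if (!is.finite(kappa)) return(0)
  wrap_signed(rvonmises_deg(1, 0, kappa))
}

# one lateral decision; returns signed degrees before noise
lateral_intent <- function(state, policy, scene, tree_id, threshold, cache,
                           gate = TRUE) {
  ls <- policy$lateral_step
  if (length(policy$memory) == 0) {           # memory-free: random side-step
    return(list(move = runif(1, -ls, ls), signal = FALSE, random = TRUE))
  }
  if (policy$strategy == "gradient") {
    offs <- policy$scan_offsets
    fam <- purrr::map_dbl(offs, function(o) {
      view_match(scene, tree_id, state$azimuth + o, state$height,
                 policy$memory, policy$metric, cache = cache)$familiarity
    })
    if (gate && min(fam) > threshold) {
      return(list(move = runif(1, -ls, ls), signal = FALSE, random = TRUE))
    }
    cand <- offs[fam == min(fam)]
    move <- if (any(cand > 0) && any(cand < 0)) {
      0 # symmetric tie: stay
    } else {
      best <- cand[which.min(abs(cand))]
      sign(best) * min(ls, abs(best))
    }
    list(move = move, signal = TRUE, random = FALSE)
  } else {                                    # compass
    vm <- view_match(scene, tree_id, state$azimuth, state$height,
                     policy$memory, policy$metric, cache = cache)
    if (gate && vm$familiarity > threshold) {
      return(list(move = runif(1, -ls, ls), signal = FALSE, random = TRUE))
    }
    r <- wrap_signed(vm$best_rotation)
    move <- if (r == 0) 0 else -sign(r) * min(ls, abs(r))
    list(move = move, signal = TRUE, random = FALSE)
  }
}

#' Advance an agent by one step
#'
#' Applies the policy's lateral rule at the current height, then descends
#' `step_down` (or ascends, for a blocked agent escaping above the screen).
#' The total lateral change per step never exceeds `lateral_step`; height
#' clamps to 0 at the ground.
#'
#' @param state an [agent_state()].
#' @param policy an [agent_policy()] whose `memory` is set.
#' @param scene the scene the agent moves in.
#' @param tree_id the tree the agent is on.
#' @param threshold no-signal familiarity threshold (`Inf` = always signal).
#' @param escape if `TRUE` (blocked runs), an agent hitting no-signal for
#'   the first time escapes above the screen with probability `p_escape`.
#' @param ascend_to target height for an escaping agent (m).
#' @param cache optional environment memoising view matches.
#' @return the updated state.
#' @export
agent_step <- function(state, policy, scene, tree_id = "foraging",
                       threshold = Inf, escape = FALSE, ascend_to = 2.2,
                       cache = NULL) {
  ls <- policy$lateral_step

  if (state$phase == "ascend") {
    state$height <- state$height + policy$step_down
    if (state$height >= ascend_to ||
        state$height >= scene_tree(scene, tree_id)$height - policy$step_down) {
      state$phase <- "reorient"
      state$reorient_left <- as.integer(ceiling(2 * 360 / ls))
    }
    return(state)
  }

  if (state$phase == "reorient") {
    # above the screen the panorama is informative again; escaped foragers
    # scan extensively there, modelled as a full panoramic familiarity scan
    # whose best azimuth becomes the movement target
    if (is.null(state$reorient_target)) {
      scan_az <- state$azimuth + seq(0, 359, by = ls)
      fam <- purrr::map_dbl(scan_az, function(a) {
        view_match(scene, tree_id, a, state$height, policy$memory,
                   policy$metric, cache = cache)$familiarity
      })
      state$reorient_target <- scan_az[which.min(fam)]
    }
    diff <- ang_diff(state$reorient_target, state$azimuth)
    if (abs(diff) <= ls) {
      state$azimuth <- state$azimuth + diff
      state$phase <- "descend"
    } else {
      state$azimuth <- state$azimuth +
        max(-ls, min(ls, sign(diff) * ls + motor_noise(policy$noise_kappa)))
      state$reorient_left <- state$reorient_left - 1L
      if (state$reorient_left <= 0L) state$phase <- "descend"
    }
    return(state)
  }

  intent <- lateral_intent(state, policy, scene, tree_id, threshold, cache)
  if (!intent$signal && escape && !state$escape_decided &&
      length(policy$memory) > 0) {
    state$escape_decided <- TRUE
    # escape propensity: preassigned by run_condition (population fraction
    # p_escape), or an independent coin for a standalone agent
    goes_up <- if (is.na(state$escape_allowed)) runif(1) < policy$p_escape
               else state$escape_allowed
    if (goes_up) {
      state$phase <- "ascend"
      return(state)
    }
  }
  state$azimuth <- state$azimuth +
    max(-ls, min(ls, intent$move + motor_noise(policy$noise_kappa)))
  state$height <- if (state$height <= policy$step_down) 0 else
    state$height - policy$step_down
  state
}

#' Run one displacement condition
#'
#' Releases `n_agents` independent seeded agents on the trunk and lets each
#' descend to the ground under the policy. In a blocked run the scene must
#' contain the landmark screen; memory is acquired from the same scene with
#' the screen removed (views are learned before the screen goes up), a
#' no-signal threshold is precomputed as 0.9 times the familiarity of
#' inside-screen views, and agents hitting no-signal may escape above the
#' screen with probability `p_escape` before their final descent.
#'
#' @param scene a [scene()]; with its screen present when `blocked = TRUE`.
#' @param policy an [agent_policy()]. A `NULL` memory is filled with the
#'   default single base view of `tree_id`.
#' @param release_azimuth,release_height release point on the trunk (deg, m).
#' @param n_agents number of independent agents.
#' @param tree_id tree the agents descend.
#' @param blocked landmark-blocking condition flag.
#' @param seed integer seed controlling all randomness in the run.
#' @param crossing_heights heights (m) at which to record azimuth crossings.
#' @param cache optional shared environment memoising rendered view matches
#'   across conditions of the same scene/memory/metric.
#' @return a `trunknav_descent_run`: list with `paths` (tibble: agent, step,
#'   azimuth_deg unwrapped, azimuth_wrapped in (-180, 180], height_m,
#'   phase), `crossings` (tibble: agent, height_m, azimuth_deg, after the
#'   final-descent filter), and run metadata.
#' @export
run_condition <- function(scene, policy, release_azimuth, release_height = 2,
                          n_agents = 15, tree_id = "foraging",
                          blocked = FALSE, seed = 1,
                          crossing_heights = c(1, 0), cache = NULL) {
  stopifnot(inherits(policy, "trunknav_policy"))
  if (n_agents < 1) stop("n_agents must be >= 1")
  if (blocked && is.null(scene$screen)) {
    stop("blocked = TRUE requires a scene with a screen")
  }
  mem_scene <- scene
  if (blocked) mem_scene$screen <- NULL
  if (is.null(policy$memory)) {
    policy$memory <- acquire_memory(mem_scene, tree_id = tree_id)
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  threshold <- Inf
  if (blocked && length(policy$memory) > 0) {
    threshold <- 0.9 * screen_view_familiarity(scene, policy, tree_id,
                                               release_height)
  }

  agent_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1,
                                                   n_agents))
  # "half of the foragers" climb above the screen: treat p_escape as a
  # population fraction, with the identity of the escapers randomised
  n_up <- round(policy$p_escape * n_agents)
  escape_allowed <- withr::with_seed(agent_seeds[1] %% 1000000L + 1L,
                                     sample(rep(c(TRUE, FALSE),
                                                c(n_up, n_agents - n_up))))
  max_steps <- as.integer(ceiling((release_height + 5) / policy$step_down) +
                            2 * 360 / policy$lateral_step + 100)

  paths <- purrr::map_dfr(seq_len(n_agents), function(i) {
    withr::with_seed(agent_seeds[i], {
      st <- agent_state(release_azimuth, release_height)
      st$escape_allowed <- escape_allowed[i]
      rows <- vector("list", max_steps + 1)
      rows[[1]] <- tibble::tibble(step = 0L, azimuth_deg = st$azimuth,
                                  height_m = st$height, phase = st$phase)
      k <- 1L
      while (st$height > 0 && k <= max_steps) {
        st <- agent_step(st, policy, scene, tree_id = tree_id,
                         threshold = threshold, escape = blocked,
                         cache = cache)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(step = k - 1L, azimuth_deg = st$azimuth,
                                    height_m = st$height, phase = st$phase)
      }
      out <- dplyr::bind_rows(rows[seq_len(k)])
      out$agent <- i
      out
    })
  })
  paths <- dplyr::mutate(paths,
                         azimuth_wrapped = wrap_signed(.data$azimuth_deg)) |>
    dplyr::select("agent", "step", "azimuth_deg", "azimuth_wrapped",
                  "height_m", "phase")

  crossings <- paths |>
    dplyr::group_by(.data$agent) |>
    dplyr::group_modify(~ height_crossings(.x, heights = crossing_heights)) |>
    dplyr::ungroup()

  structure(
    list(paths = paths, crossings = crossings,
         release = list(azimuth = release_azimuth, height = release_height),
         n_agents = n_agents, tree_id = tree_id, blocked = blocked,
         seed = seed, threshold = threshold, policy = policy),
    class = "trunknav_descent_run"
  )
}

# familiarity of "pure screen" surroundings: inside-screen views at the four
# cardinal trunk azimuths at the release height, averaged
screen_view_familiarity <- function(scene, policy, tree_id, height) {
  mean(purrr::map_dbl(c(0, 90, 180, 270), function(a) {
    vp <- trunk_viewpoint(scene, tree_id, a, height)
    familiarity(scene, vp, policy$memory, metric = policy$metric)
  }))
}

#' @export
print.trunknav_descent_run <- function(x, ...) {
  cat(sprintf(
    "<trunknav_descent_run> %d agents released at (%g deg, %g m) on '%s'%s\n",
    x$n_agents, x$release$azimuth, x$release$height, x$tree_id,
    if (x$blocked) " [blocked]" else ""))
  invisible(x)
}

#' Circular statistics of a descent run's height crossings
#'
#' @param run a `trunknav_descent_run`.
#' @param mu0 predicted direction in deg (nest = 0).
#' @return a tibble with one summary row per crossing height (see
#'   [circ_summary_row()]).
#' @export
condition_stats <- function(run, mu0 = 0) {
  run$crossings |>
    dplyr::group_by(.data$height_m) |>
    dplyr::group_modify(~ circ_summary_row(.x$azimuth_deg, mu0 = mu0)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$height_m))
}

#' @export
autoplot.trunknav_descent_run <- function(object, ...) {
  ggplot2::ggplot(object$paths,
                  ggplot2::aes(.data$azimuth_wrapped, .data$height_m,
                               group = .data$agent)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "trunk azimuth (deg, nest side at 0; +/-180 identical)",
                  y = "height (m)")
}
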