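#' Render the standard view grid for a tree
#'
#' The imaging protocol of the study: one reference panorama at the base of
#' the tree (nest side, ground level) plus views at the four cardinal trunk
#' azimuths (0, 90, 180, 270 deg) at two heights (1 m and 1.75 m by
#' default) — nine panoramas per tree.
#'
#' @param scene a [scene()].
#' @param tree_id which tree to image.
#' @param azimuths trunk azimuths (deg).
#' @param heights heights (m).
#' @param outdir optional directory; when given, PNGs plus JSON sidecars are
#'   written and file paths recorded in the returned table.
#' @return a tibble with columns `label`, `azimuth_deg`, `height_m`,
#'   `panorama` (list-column) and, with `outdir`, `path`.
#' @export
render_view_grid <- function(scene, tree_id = "foraging",
                             azimuths = c(0, 90, 180, 270),
                             heights = c(1, 1.75), outdir = NULL) {
  grid <- dplyr::bind_rows(
    tibble::tibble(label = "base", azimuth_deg = 0, height_m = 0),
    tidyr::expand_grid(azimuth_deg = azimuths, height_m = heights) |>
      dplyr::mutate(label = sprintf("az%03d_h%.2f", .data$azimuth_deg,
                                    .data$height_m))
  )
  grid$panorama <- purrr::map2(grid$azimuth_deg, grid$height_m, function(a, h) {
    render_panorama(scene, trunk_viewpoint(scene, tree_id, a, h))
  })
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    grid$path <- purrr::map2_chr(grid$panorama, grid$label, function(p, lab) {
      f <- file.path(outdir, paste0(tree_id, "_", lab, ".png"))
      write_panorama(p, f)
      f
    })
  }
  grid
}

#' rotIDF curves of a set of test views against one reference
#'
#' Always includes the reference's self-comparison as the baseline curve.
#'
#' @param reference a `trunknav_panorama` (or PNG path).
#' @param tests named list of `trunknav_panorama`s (or PNG paths).
#' @param metric `"sad"` or `"rms"`.
#' @param outdir optional directory for per-curve CSVs and a summary JSON.
#' @return a tibble with `label`, `curve` (list-column) and the glance
#'   columns (`best_rotation`, `best_mismatch`, `valley_depth`,
#'   `clear_minimum`).
#' @export
rotidf_report <- function(reference, tests, metric = c("sad", "rms"),
                          outdir = NULL) {
  metric <- match.arg(metric)
  load_pano <- function(x) {
    if (inherits(x, "trunknav_panorama")) x else read_panorama(x)
  }
  reference <- load_pano(reference)
  tests <- purrr::map(tests, load_pano)
  all_tests <- c(list(self = reference), tests)
  out <- purrr::imap_dfr(all_tests, function(p, lab) {
    curve <- rotidf(reference, p, metric = metric)
    dplyr::bind_cols(tibble::tibble(label = lab, curve = list(curve)),
                     glance(curve))
  })
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    purrr::walk2(out$curve, out$label, function(curve, lab) {
      write_rotidf(curve, csv_path = file.path(outdir,
                                               paste0("rotidf_", lab, ".csv")))
    })
    jsonlite::write_json(
      dplyr::select(out, -"curve"),
      file.path(outdir, "rotidf_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' Run a full displacement experiment
#'
#' Executes a set of conditions (release azimuth and height, blocked or
#' not, agent strategy, sample size) on a scene and returns a results-table
#' style report: per condition and crossing height the mean vector, 95% CI,
#' Rayleigh Z and p, and V and p toward the nest direction, all
#' recomputable from the returned crossings with the circular-statistics
#' functions alone.
#'
#' @param scene a [scene()] (must include the screen if any condition is
#'   blocked); memory is always acquired with the screen removed.
#' @param conditions a tibble with columns `release_azimuth`, and optionally
#'   `release_height` (default 2 m; 1.5 m for blocked rows), `blocked`
#'   (default `FALSE`), `strategy` (default "gradient"), `n` (default 15),
#'   `tree_id` (default "foraging"; "nest" for blocked rows), `label`.
#' @param seed integer master seed; each condition derives its own seed.
#' @param crossing_heights heights at which crossings are analysed; blocked
#'   conditions additionally record 1.4 m.
#' @param ... further arguments passed to [agent_policy()].
#' @return a `trunknav_experiment`: list with `report` (tibble), `runs`
#'   (list of `trunknav_descent_run`), `crossings` (bound tibble), `seed`.
#' @export
run_experiment <- function(scene, conditions, seed = 1,
                           crossing_heights = c(1, 0), ...) {
  conditions <- tibble::as_tibble(conditions)
  n_cond <- nrow(conditions)
  fill <- function(col, default) {
    v <- if (col %in% names(conditions)) conditions[[col]] else
      rep(NA, n_cond)
    v[is.na(v)] <- default[is.na(v)]
    v
  }
  conditions$blocked <- fill("blocked", rep(FALSE, n_cond))
  conditions$strategy <- fill("strategy", rep("gradient", n_cond))
  conditions$n <- fill("n", rep(15L, n_cond))
  conditions$release_height <- fill("release_height",
                                    ifelse(conditions$blocked, 1.5, 2))
  conditions$tree_id <- fill("tree_id",
                             ifelse(conditions$blocked, "nest", "foraging"))
  if (!"label" %in% names(conditions)) {
    conditions$label <- sprintf(
      "%s_%03d%s", conditions$strategy, conditions$release_azimuth,
      ifelse(conditions$blocked, "_blocked", ""))
  }
  cond_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max - 1,
                                            n_cond + 1))
  report_seed <- cond_seeds[n_cond + 1]

  # one view-match cache per (tree, metric, screen-state); memory is the
  # default base view so runs of the same tree can share rendered matches
  caches <- new.env(parent = emptyenv())
  runs <- purrr::map(seq_len(n_cond), function(i) {
    cond <- conditions[i, ]
    pol <- agent_policy(strategy = cond$strategy, ...)
    ckey <- paste(cond$tree_id, pol$metric, cond$blocked, sep = "|")
    if (is.null(caches[[ckey]])) {
      caches[[ckey]] <- new.env(parent = emptyenv())
    }
    ch <- if (cond$blocked) sort(unique(c(1.4, crossing_heights)),
                                 decreasing = TRUE) else crossing_heights
    run_condition(scene, pol,
                  release_azimuth = cond$release_azimuth,
                  release_height = cond$release_height,
                  n_agents = cond$n, tree_id = cond$tree_id,
                  blocked = cond$blocked, seed = cond_seeds[i],
                  crossing_heights = ch, cache = caches[[ckey]])
  })
  names(runs) <- conditions$label

  # seeded so that small-sample simulated p-values reproduce run to run
  report <- withr::with_seed(report_seed, {
    purrr::map2_dfr(runs, conditions$label, function(run, lab) {
      dplyr::bind_cols(tibble::tibble(condition = lab), condition_stats(run))
    })
  })
  crossings <- purrr::map2_dfr(runs, conditions$label, function(run, lab) {
    dplyr::bind_cols(tibble::tibble(condition = lab), run$crossings)
  })

  structure(
    list(report = report, runs = runs, crossings = crossings,
         conditions = conditions, seed = seed),
    class = "trunknav_experiment"
  )
}

#' @export
print.trunknav_experiment <- function(x, ...) {
  cat("<trunknav_experiment> ", nrow(x$conditions), " conditions, seed ",
      x$seed, "\n", sep = "")
  print(report_table(x))
  invisible(x)
}

#' Results-table style report, angles rounded to 3 decimals
#'
#' @param experiment a `trunknav_experiment`.
#' @return a tibble formatted like the study's statistics table.
#' @export
report_table <- function(experiment) {
  experiment$report |>
    dplyr::mutate(dplyr::across(c("mu", "ci_minus", "ci_plus", "rayleigh_Z",
                                  "V"), ~ round(.x, 3)),
                  dplyr::across(c("rayleigh_p", "v_p"), ~ signif(.x, 3)))
}

#' Write experiment outputs and a run manifest
#'
#' Emits the report (CSV + JSON), the per-agent paths CSV, the crossings
#' CSV, and a manifest JSON recording the seed, conditions and every output
#' path.
#'
#' @param experiment a `trunknav_experiment`.
#' @param outdir output directory.
#' @return the manifest (invisibly).
#' @export
write_experiment <- function(experiment, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    report_csv = file.path(outdir, "report.csv"),
    report_json = file.path(outdir, "report.json"),
    paths_csv = file.path(outdir, "paths.csv"),
    crossings_csv = file.path(outdir, "crossings.csv"),
    manifest = file.path(outdir, "manifest.json")
  )
  rep <- report_table(experiment)
  utils::write.csv(rep, paths$report_csv, row.names = FALSE)
  jsonlite::write_json(rep, paths$report_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  all_paths <- purrr::imap_dfr(experiment$runs, function(run, lab) {
    dplyr::bind_cols(tibble::tibble(condition = lab), run$paths)
  })
  utils::write.csv(all_paths, paths$paths_csv, row.names = FALSE)
  utils::write.csv(experiment$crossings, paths$crossings_csv,
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("trunknav")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = experiment$seed,
    conditions = experiment$conditions,
    outputs = paths[names(paths) != "manifest"]
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  ok <- purrr::map_lgl(paths, file.exists)
  if (!all(ok)) stop("manifest lists missing outputs")
  invisible(manifest)
}

#' Read an experiment config (YAML/JSON)
#'
#' The config has a `conditions` list whose entries mirror the columns of
#' the `conditions` tibble of [run_experiment()], plus optional `seed`.
#'
#' @param path config file path.
#' @return a list with `conditions` (tibble) and `seed`.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  conds <- cfg$conditions
  if (!is.data.frame(conds)) conds <- purrr::map_dfr(conds, tibble::as_tibble)
  list(conditions = tibble::as_tibble(conds), seed = cfg$seed %||% 1L)
}
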