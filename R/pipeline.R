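#' Pipeline configuration
#'
#' Bundles every tunable of the image-to-statistics pipeline with its
#' default: pixel size 0.05 um/px, probability threshold 0.8, cavity cutoff
#' 5 px (fill holes larger than this), and the selection thresholds
#' (eccentricity 0.95, solidity 0.9, area 50 px). The segmentation backend is
#' either `"oracle"` (ground-truth-driven test double, requires a truth mask)
#' or `"network"` (a trained model checkpoint).
#'
#' @param pixel_size_um physical pixel size in micrometres.
#' @param prob_threshold probability threshold for class assignment.
#' @param cavity_px cavity-size cutoff in pixels.
#' @param fill_direction `"larger"` or `"smaller"`, see [fill_cavities()].
#' @param max_eccentricity,min_solidity,min_area_px selection thresholds,
#'   see [selection_criteria()].
#' @param exclude_border exclude fibers touching the image border.
#' @param backend `"oracle"` or `"network"`.
#' @param model_path checkpoint path for the network backend.
#' @param oracle_flip_rate corruption rate for the oracle backend.
#' @param tile,overlap tiling for network prediction (NULL tile = single shot).
#' @param seed seed for any stochastic step (oracle corruption).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pixel_size_um = 0.05, prob_threshold = 0.8,
                            cavity_px = 5, fill_direction = "larger",
                            max_eccentricity = 0.95, min_solidity = 0.9,
                            min_area_px = 50, exclude_border = FALSE,
                            backend = c("oracle", "network"),
                            model_path = NULL, oracle_flip_rate = 0,
                            tile = NULL, overlap = 32, seed = 1) {
  backend <- match.arg(backend)
  stopifnot(pixel_size_um > 0, prob_threshold > 0, prob_threshold < 1,
            cavity_px >= 0, oracle_flip_rate >= 0, oracle_flip_rate < 0.5)
  fill_direction <- match.arg(fill_direction, c("larger", "smaller"))
  structure(list(
    pixel_size_um = pixel_size_um, prob_threshold = prob_threshold,
    cavity_px = cavity_px, fill_direction = fill_direction,
    max_eccentricity = max_eccentricity, min_solidity = min_solidity,
    min_area_px = min_area_px, exclude_border = exclude_border,
    backend = backend, model_path = model_path,
    oracle_flip_rate = oracle_flip_rate, tile = tile, overlap = overlap,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Run the full morphometry pipeline
#'
#' image -> probability maps -> thresholded and cavity-filled label mask ->
#' fiber extraction -> quality selection -> per-fiber morphometrics ->
#' summary. With an output directory all artifacts are written: `mask.png`,
#' `instances.tif` (2-channel 16-bit: axon ids, myelin ids), `fibers.csv`,
#' `morphometrics.csv`, `summary.json`, `config.yaml` and `log.txt` (one line
#' per excluded fiber with its reasons). Runs are deterministic given the
#' config seed; rerunning with the same inputs reproduces the CSVs
#' byte-identically.
#'
#' @param input a `phantom_scene`, or a path to a PNG/TIFF image.
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param truth_mask optional [label_mask()] (or mask PNG path) used by the
#'   oracle backend and for evaluation; taken from the scene when `input` is
#'   a phantom.
#' @return Invisibly, a `pipeline_run`: list with `mask`, `fiber_set`,
#'   `morphometrics` (tibble), `summary` (list), `evaluation` (tibble or
#'   NULL), `log` (character), `out_dir`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         truth_mask = NULL) {
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  if (inherits(input, "phantom_scene")) {
    image <- input$image
    if (is.null(truth_mask)) truth_mask <- input$mask
    config$pixel_size_um <- input$pixel_size_um
    say("input: phantom scene %dx%d, %d designed fibers, seed %d",
        nrow(image), ncol(image), nrow(input$fibers), input$seed)
  } else if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input)) stop("input image not found: ", input)
    image <- read_image(input)
    say("input: image %s (%dx%d)", input, nrow(image), ncol(image))
  } else if (is.matrix(input)) {
    image <- input
    say("input: in-memory image %dx%d", nrow(image), ncol(image))
  } else {
    stop("input must be a phantom_scene, a matrix, or an image path")
  }
  if (is.character(truth_mask)) {
    truth_mask <- read_mask_png(truth_mask, pixel_size_um = config$pixel_size_um)
  }

  prob <- switch(config$backend,
    oracle = {
      if (is.null(truth_mask)) {
        stop("oracle backend needs a ground-truth mask (phantom scene or truth_mask=)")
      }
      say("backend: oracle, flip rate %.3f", config$oracle_flip_rate)
      oracle_predict(truth_mask, flip_rate = config$oracle_flip_rate,
                     seed = config$seed)
    },
    network = {
      if (is.null(config$model_path)) stop("network backend needs config$model_path")
      model <- load_segmenter(config$model_path)
      say("backend: network checkpoint %s", config$model_path)
      predict_probabilities(image, model, tile = config$tile,
                            overlap = config$overlap)
    }
  )

  mask <- threshold_probabilities(prob, threshold = config$prob_threshold,
                                  pixel_size_um = config$pixel_size_um)
  mask <- fill_cavities(mask, min_cavity_px = config$cavity_px,
                        fill_direction = config$fill_direction)
  say("mask: %d axon px, %d myelin px",
      sum(mask == CLASS_AXON), sum(mask == CLASS_MYELIN))

  criteria <- selection_criteria(config$max_eccentricity, config$min_solidity,
                                 config$min_area_px)
  fs <- extract_fibers(mask) |>
    select_fibers(criteria, exclude_border = config$exclude_border)
  excluded <- dplyr::filter(fs$fibers, !.data$selected)
  say("fibers: %d found, %d selected, %d excluded",
      nrow(fs$fibers), sum(fs$fibers$selected), nrow(excluded))
  for (i in seq_len(nrow(excluded))) {
    say("excluded fiber %d: %s (ecc %.3f, solidity %.3f, area %d px)",
        excluded$fiber_id[i], excluded$exclusion[i], excluded$eccentricity[i],
        excluded$solidity[i], excluded$axon_area_px[i])
  }

  morpho <- withCallingHandlers(
    compute_morphometrics(fs),
    warning = function(w) {
      say("note: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  selected_morpho <- dplyr::filter(morpho, .data$selected)
  agg <- if (nrow(selected_morpho) > 0) aggregate_morphometrics(selected_morpho) else NULL

  evaluation <- NULL
  if (!is.null(truth_mask) && any(fs$fibers$selected)) {
    evaluation <- evaluate_selected(mask, truth_mask, fs)
  }

  reason_counts <- table(unlist(fs$fibers$exclusion_reasons))
  summary <- list(
    n_fibers = nrow(fs$fibers),
    n_selected = sum(fs$fibers$selected),
    n_excluded = sum(!fs$fibers$selected),
    exclusion_counts = as.list(reason_counts),
    unassigned_myelin_px = fs$n_unassigned_myelin_px,
    pixel_size_um = config$pixel_size_um
  )
  summary$morphometrics <- if (is.null(agg)) NULL else
    stats::setNames(
      purrr::map(seq_len(nrow(agg)), function(i)
        list(mean = agg$mean[i], sd = agg$sd[i], n = agg$n[i])),
      agg$metric
    )
  if (!is.null(evaluation)) {
    summary$evaluation <- purrr::map(
      split(evaluation, paste(evaluation$class, evaluation$scope, sep = "_")),
      function(df) list(dice = df$dice[1], pixel_accuracy = df$pixel_accuracy[1])
    )
  }
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(
    list(mask = mask, fiber_set = fs, morphometrics = morpho,
         summary = summary, evaluation = evaluation, log = log,
         config = config, out_dir = out_dir),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d fibers, %d selected\n",
              x$summary$n_fibers, x$summary$n_selected))
  if (!is.null(x$summary$morphometrics$g_ratio)) {
    g <- x$summary$morphometrics$g_ratio
    cat(sprintf("mean g-ratio %.3f +/- %.3f (n = %d)\n", g$mean, g$sd, g$n))
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mask_png(run$mask, file.path(out_dir, "mask.png"))
  inst <- array(0, dim = c(nrow(run$mask), ncol(run$mask), 2L))
  inst[, , 1] <- run$fiber_set$axon_labels / 65535
  inst[, , 2] <- run$fiber_set$myelin_labels / 65535
  tiff::writeTIFF(inst, file.path(out_dir, "instances.tif"), bits.per.sample = 16L)
  fib <- run$fiber_set$fibers
  fib$exclusion_reasons <- NULL          # list-column: the collapsed string stays
  write.csv(fib, file.path(out_dir, "fibers.csv"), row.names = FALSE)
  write.csv(run$morphometrics, file.path(out_dir, "morphometrics.csv"),
            row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_pipeline_config(run$config, file.path(out_dir, "config.yaml"))
  writeLines(run$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Compare morphometrics across runs
#'
#' Given two or more completed runs (output directories or morphometric
#' tibbles), compares each metric across groups on the selected fibers:
#' group means and SDs, plus a normality-gated test — with two groups a
#' Shapiro–Wilk gate chooses between Wilcoxon rank-sum and Welch t; with
#' three or more groups a one-way ANOVA is used.
#'
#' @param ... run directories (each containing `morphometrics.csv`) or
#'   tibbles from [compute_morphometrics()]; at least 2.
#' @param metrics metric columns to compare.
#' @param alpha normality-gate level.
#' @return A tibble: one row per metric with `test`, `statistic`, `p_value`
#'   and per-group `mean_<i>` / `sd_<i>` / `n_<i>` columns.
#' @export
compare_groups <- function(..., metrics = c("g_ratio", "myelin_thickness_um",
                                            "axon_diameter_um"),
                           alpha = 0.05) {
  groups <- purrr::map(list(...), function(g) {
    if (is.character(g)) {
      g <- read.csv(file.path(g, "morphometrics.csv"))
    } else if (inherits(g, "pipeline_run")) {
      g <- g$morphometrics
    }
    stopifnot(is.data.frame(g))
    if ("selected" %in% names(g)) g <- g[g$selected, , drop = FALSE]
    g
  })
  if (length(groups) < 2L) stop("need at least 2 runs to compare")

  purrr::map_dfr(metrics, function(m) {
    vals <- purrr::map(groups, function(g) g[[m]])
    row <- tibble::tibble(metric = m)
    for (i in seq_along(vals)) {
      row[[paste0("mean_", i)]] <- mean(vals[[i]])
      row[[paste0("sd_", i)]] <- stats::sd(vals[[i]])
      row[[paste0("n_", i)]] <- length(vals[[i]])
    }
    if (length(vals) >= 3L) {
      a <- parallel_sections_anova(vals)
      row$test <- "anova"
      row$statistic <- a$f_stat
      row$p_value <- a$p_value
    } else {
      normal <- all(vapply(vals, function(v) {
        v <- subsample_for_shapiro(v)
        length(unique(v)) > 2 && stats::shapiro.test(v)$p.value >= alpha
      }, logical(1)))
      if (normal) {
        tt <- stats::t.test(vals[[1]], vals[[2]])
        row$test <- "welch_t"
        row$statistic <- unname(tt$statistic)
        row$p_value <- tt$p.value
      } else {
        wt <- suppressWarnings(stats::wilcox.test(vals[[1]], vals[[2]]))
        row$test <- "wilcoxon_rank_sum"
        row$statistic <- unname(wt$statistic)
        row$p_value <- wt$p.value
      }
    }
    row
  })
}

# Shapiro-Wilk accepts 3..5000 values; take a deterministic evenly-spaced
# subset above that.
subsample_for_shapiro <- function(v, cap = 5000L) {
  if (length(v) <= cap) return(v)
  v[round(seq(1L, length(v), length.out = cap))]
}
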