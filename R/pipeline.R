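#' Study configuration
#'
#' Describes an end-to-end in-silico study: per-condition phantom
#' populations (e.g. three cell lines by two treatments), the comparisons
#' to report, analysis parameters, and optional dose-response and FISH
#' arms. All randomness derives from the single `seed`.
#'
#' @param conditions named list of [population_params()], one per condition.
#' @param n_cells cells generated per condition.
#' @param pairs list of 2-vectors `c(treated, control)` of condition names
#'   to compare.
#' @param segmentation a [segmentation_params()].
#' @param k_sigma,min_clump_volume_um3 clump detection settings.
#' @param dose_response optional list with `lines` (named list of lists with
#'   `top`, `bottom`, `logic50`, `hill`), `n_reps`, `noise_sd`.
#' @param fish optional list with `n_cells`, and `conditions`: named list of
#'   lists with `rrd_mean`, `rrd_sd`, `coloc_rho`.
#' @param seed master RNG seed (explicit; no default randomness).
#' @return A list of class `study_config`.
#' @export
study_config <- function(conditions,
                         n_cells = 200L,
                         pairs = list(),
                         segmentation = segmentation_params(),
                         k_sigma = 2,
                         min_clump_volume_um3 = 0.5,
                         dose_response = NULL,
                         fish = NULL,
                         seed = 1L) {
  cfg <- structure(list(
    conditions = conditions, n_cells = as.integer(n_cells), pairs = pairs,
    segmentation = segmentation, k_sigma = k_sigma,
    min_clump_volume_um3 = min_clump_volume_um3,
    dose_response = dose_response, fish = fish, seed = seed
  ), class = "study_config")
  problems <- validate_config(cfg)
  if (length(problems) > 0) {
    abort(paste0("invalid study config:\n", paste("-", problems, collapse = "\n")),
          class = "nucmorph_config_error")
  }
  cfg
}

#' Validate a study configuration
#'
#' Schema and cross-reference checks; returns a character vector of named
#' problems (empty when the configuration is valid). [study_config()] calls
#' this and refuses to construct an invalid object; use it directly on
#' configurations assembled by hand or read from YAML.
#'
#' @param config a `study_config`-shaped list.
#' @return Character vector of problems; `character(0)` means ok.
#' @export
validate_config <- function(config) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  known <- c("conditions", "n_cells", "pairs", "segmentation", "k_sigma",
             "min_clump_volume_um3", "dose_response", "fish", "seed")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) note(paste0("unknown keys: ", paste(extra, collapse = ", ")))
  if (is.null(config$seed) || !is.numeric(config$seed) || !is.finite(config$seed)) {
    note("missing or non-numeric seed")
  }
  if (is.null(config$conditions) || length(config$conditions) == 0 ||
      is.null(names(config$conditions)) || any(names(config$conditions) == "")) {
    note("conditions must be a non-empty named list")
  } else {
    for (nm in names(config$conditions)) {
      pop <- config$conditions[[nm]]
      if (!inherits(pop, "population_params")) {
        note(paste0("condition `", nm, "` is not a population_params object"))
        next
      }
      if (any(check_voxel_size_quiet(pop$voxel_size_um))) {
        note(paste0("condition `", nm, "` has a non-positive voxel size"))
      }
    }
    for (p in config$pairs) {
      if (length(p) != 2 || !all(p %in% names(config$conditions))) {
        note(paste0("pair (", paste(p, collapse = ", "),
                    ") references unknown conditions"))
      }
    }
  }
  if (!is.null(config$n_cells) && (!is.numeric(config$n_cells) || config$n_cells < 1)) {
    note("n_cells must be >= 1")
  }
  problems
}

check_voxel_size_quiet <- function(vs) {
  vs <- tryCatch(check_voxel_size(vs), error = function(e) NULL)
  is.null(vs)
}

#' Run an end-to-end in-silico study
#'
#' For every condition, streams `n_cells` phantoms through segmentation and
#' morphometry (volumes never accumulate in memory), collects the measured
#' feature table alongside the generator ground truth, compares the
#' configured condition pairs with Mann-Whitney and KS tests
#' (Bonferroni-adjusted within each pair's feature family), and runs the
#' optional dose-response and FISH arms. Fully deterministic under the
#' config seed; per-cell failures are collected, reported in the returned
#' `errors` table and counted, never dropped.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, all result tables are
#'   written there as CSV and a `manifest.json` records parameters and
#'   per-stage provenance.
#' @return List with tibbles: `features`, `truth`, `recovery` (per-condition
#'   mean measured-minus-true deltas), `summaries`, `comparisons`,
#'   `dose_response`, `fish_spots`, `errors`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  problems <- validate_config(config)
  if (length(problems) > 0) {
    abort(paste0("invalid study config:\n", paste("-", problems, collapse = "\n")),
          class = "nucmorph_config_error")
  }
  set.seed(config$seed)
  cond_names <- names(config$conditions)
  cond_seeds <- sample.int(.Machine$integer.max, length(cond_names))
  ddr_seed <- sample.int(.Machine$integer.max, 1)
  fish_seed <- sample.int(.Machine$integer.max, 1)

  features <- list()
  truths <- list()
  errors <- list()
  for (i in seq_along(cond_names)) {
    nm <- cond_names[i]
    records <- list()
    co <- make_cohort(
      n_cells = config$n_cells,
      pop = config$conditions[[nm]],
      condition = nm,
      seed = cond_seeds[i],
      per_cell = function(ph, cell_id) {
        res <- tryCatch({
          seg <- segment_cell_nucleus(ph$volume, config$segmentation)
          morphometry_record(ph$volume, seg$cell, seg$nucleus, cell_id,
                             config$k_sigma, config$min_clump_volume_um3)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          errors[[length(errors) + 1L]] <<- tibble::tibble(
            condition = nm, cell_id = cell_id, stage = "segmentation/morphometry",
            message = conditionMessage(res))
        } else {
          records[[length(records) + 1L]] <<- res
        }
      }
    )
    truths[[nm]] <- co$truth
    if (length(records) > 0) {
      features[[nm]] <- records_to_feature_table(dplyr::bind_rows(records), nm)
    }
  }
  features <- dplyr::bind_rows(features)
  truth <- dplyr::bind_rows(truths)
  errors <- if (length(errors) > 0) dplyr::bind_rows(errors) else
    tibble::tibble(condition = character(), cell_id = character(),
                   stage = character(), message = character())

  recovery <- dplyr::inner_join(
    features, truth,
    by = c("cell_id", "condition", "feature"),
    suffix = c("_measured", "_true")
  ) |>
    dplyr::group_by(.data$condition, .data$feature) |>
    dplyr::summarise(
      mean_measured = mean(.data$value_measured),
      mean_true = mean(.data$value_true),
      mean_delta = mean(.data$value_measured - .data$value_true),
      n = dplyr::n(),
      .groups = "drop"
    )

  summaries <- summarize_features(features)
  comparisons <- purrr::map(config$pairs, function(p) {
    dplyr::bind_rows(
      compare_conditions(features, p[1], p[2], "mann-whitney"),
      compare_conditions(features, p[1], p[2], "ks")
    )
  }) |> dplyr::bind_rows()

  ddr <- tibble::tibble()
  if (!is.null(config$dose_response)) {
    dr <- config$dose_response
    set.seed(ddr_seed)
    line_seeds <- sample.int(.Machine$integer.max, length(dr$lines))
    ddr <- purrr::imap(dr$lines, function(par, nm) {
      tab <- make_viability_table(
        top = par$top %||% 100, bottom = par$bottom %||% 0,
        logic50 = par$logic50, hill = par$hill %||% -1,
        n_reps = dr$n_reps %||% 6L, noise_sd = dr$noise_sd %||% 3,
        seed = line_seeds[[which(names(dr$lines) == nm)]]
      )
      fit <- fit_4pl(tab$dose_um, tab$response)
      glance(fit) |>
        dplyr::mutate(line = nm, true_ic50 = 10^par$logic50, .before = 1)
    }) |> dplyr::bind_rows()
  }

  fish_spots <- tibble::tibble()
  if (!is.null(config$fish)) {
    set.seed(fish_seed)
    fc <- config$fish
    rows <- list()
    for (nm in names(fc$conditions)) {
      par <- fc$conditions[[nm]]
      for (j in seq_len(fc$n_cells %||% 20L)) {
        rr <- pmin(pmax(rnorm(2, par$rrd_mean, par$rrd_sd %||% 0.15), 0.02), 0.98)
        ph <- make_fish_phantom(
          spot_rrds = rr, coloc_rho = par$coloc_rho %||% 0.5,
          seed = sample.int(.Machine$integer.max, 1)
        )
        nmask <- segment_nucleus_fluorescence(ph$dapi)
        sp <- measure_spot_positions(ph$fish, nmask,
                                     cell_id = sprintf("%s_cell%03d", nm, j))
        co <- pearson_colocalization(ph$fish, ph$marker, nmask,
                                     cell_id = sprintf("%s_cell%03d", nm, j))
        if (nrow(sp) > 0) {
          rows[[length(rows) + 1L]] <- dplyr::mutate(
            sp, condition = nm, pearson_r = co$pearson_r)
        }
      }
    }
    if (length(rows) > 0) fish_spots <- dplyr::bind_rows(rows)
  }

  result <- list(features = features, truth = truth, recovery = recovery,
                 summaries = summaries, comparisons = comparisons,
                 dose_response = ddr, fish_spots = fish_spots, errors = errors)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(truth, file.path(out_dir, "ground_truth.csv"))
    readr::write_csv(recovery, file.path(out_dir, "recovery.csv"))
    readr::write_csv(summaries, file.path(out_dir, "summaries.csv"))
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    if (nrow(ddr) > 0) readr::write_csv(ddr, file.path(out_dir, "dose_response.csv"))
    if (nrow(fish_spots) > 0) readr::write_csv(fish_spots, file.path(out_dir, "fish_spots.csv"))
    readr::write_csv(errors, file.path(out_dir, "errors.csv"))
    manifest <- list(
      seed = config$seed,
      n_cells = config$n_cells,
      conditions = lapply(config$conditions, function(p) p[
        c("mean_nuclear_volume_um3", "sd_nuclear_volume_um3", "nc_target",
          "clump_mean", "n_invaginations", "invagination_radius_frac",
          "noise_sd", "voxel_size_um", "grid_dim")]),
      pairs = config$pairs,
      segmentation = unclass(config$segmentation),
      k_sigma = config$k_sigma,
      min_clump_volume_um3 = config$min_clump_volume_um3,
      n_failed_cells = nrow(errors)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Read a study configuration from YAML
#'
#' Thin YAML front end over [study_config()]: condition blocks become
#' [population_params()], a `segmentation` block becomes
#' [segmentation_params()], everything else passes through.
#'
#' @param path YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  conds <- lapply(raw$conditions, function(p) do.call(population_params, p))
  seg <- if (!is.null(raw$segmentation)) {
    do.call(segmentation_params, raw$segmentation)
  } else {
    segmentation_params()
  }
  study_config(
    conditions = conds,
    n_cells = raw$n_cells %||% 200L,
    pairs = lapply(raw$pairs, unlist),
    segmentation = seg,
    k_sigma = raw$k_sigma %||% 2,
    min_clump_volume_um3 = raw$min_clump_volume_um3 %||% 0.5,
    dose_response = raw$dose_response,
    fish = raw$fish,
    seed = raw$seed %||% abort("config must set an explicit seed",
                               class = "nucmorph_config_error")
  )
}
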