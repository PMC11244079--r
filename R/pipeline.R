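#' Balance a reference set across status classes
#'
#' Subsamples the reference feature table, without replacement, to exactly
#' `n_per_class` rows for each status class. A deliberately balanced
#' reference avoids prior-driven bias in the wild/domestic discrimination.
#'
#' @param ref data frame with a `status` column (`"wild"`/`"domestic"`) and
#'   feature columns.
#' @param n_per_class rows retained per status class.
#' @param seed integer seed; the subsample is reproducible from it.
#' @return A tibble with `2 * n_per_class` rows.
#' @export
balance_reference <- function(ref, n_per_class, seed = 1L) {
  if (!is.data.frame(ref) || !"status" %in% names(ref)) {
    abort("`ref` must be a data frame with a `status` column")
  }
  n_per_class <- assert_scalar_count(n_per_class, "n_per_class")
  counts <- table(ref$status)
  short <- counts < n_per_class
  if (any(short)) {
    abort(sprintf("insufficient samples for n_per_class = %d: %s",
                  n_per_class,
                  paste(sprintf("%s has %d", names(counts)[short],
                                counts[short]), collapse = ", ")))
  }
  set.seed(as.integer(seed))
  ref |>
    dplyr::group_by(.data$status) |>
    dplyr::slice_sample(n = n_per_class) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id)
}

#' Stage 1: wild/domestic discrimination
#'
#' Runs stepwise feature selection and linear discriminant analysis on the
#' (balanced) reference with status labels, reports both the resubstitution
#' and the leave-one-out cross-validated accuracy of the reference
#' discrimination, and assigns every unknown pip a wild or domestic status.
#'
#' @param ref reference feature table with `sample_id`, `status` and the 24
#'   coefficient columns.
#' @param unknowns unknown feature table with `sample_id`, optionally
#'   `site`, and the coefficient columns.
#' @param f_enter,f_remove,tolerance_min stepwise thresholds (see
#'   [stepwise_select()]).
#' @param priors passed to [fit_lda()].
#' @return An object of class `pip_stage1`: list with `assignments`
#'   (tibble: `sample_id`, `site`, `status`, `posterior`), `model`,
#'   `selection`, `loocv` and `resubstitution_accuracy`.
#' @export
stage1_wild_domestic <- function(ref, unknowns, f_enter = 3.84,
                                 f_remove = 2.71, tolerance_min = 0.001,
                                 priors = "equal") {
  if (!is.data.frame(unknowns) || nrow(unknowns) == 0L) {
    abort("`unknowns` must be a non-empty data frame")
  }
  feats <- intersect(feature_names(), names(ref))
  if (length(feats) == 0L) abort("`ref` has no coefficient columns")
  sel <- stepwise_select(ref, "status", feats, f_enter = f_enter,
                         f_remove = f_remove, tolerance_min = tolerance_min)
  if (length(sel$selected) == 0L) {
    abort("stepwise selection retained no features; classes are inseparable")
  }
  model <- fit_lda(ref, "status", sel$selected, priors = priors)
  cv <- loocv(ref, "status", sel$selected, priors = priors)
  resub <- mean(as.character(classify(model, ref)$.class) == ref$status)
  pred <- classify(model, unknowns)
  assignments <- tibble(
    sample_id = unknowns$sample_id,
    site = if ("site" %in% names(unknowns)) unknowns$site else NA_character_,
    status = as.character(pred$.class),
    posterior = pred$.posterior
  )
  structure(
    list(assignments = assignments, model = model, selection = sel,
         loocv = cv, resubstitution_accuracy = resub),
    class = "pip_stage1"
  )
}

#' @export
print.pip_stage1 <- function(x, ...) {
  cat(sprintf("<pip_stage1> LOOCV accuracy %.3f (resubstitution %.3f); %d unknowns assigned\n",
              x$loocv$accuracy, x$resubstitution_accuracy,
              nrow(x$assignments)))
  invisible(x)
}

#' Stage 2: assignment of domestic pips to cultivars
#'
#' Fits one multi-class discriminant model over the domestic reference with
#' cultivar identity as the group label (equal priors, since archaeological
#' material carries no prior abundance information) and assigns every
#' domestic-classified unknown to exactly one cultivar. Cultivars with fewer
#' than `min_per_cultivar` reference pips are dropped with a warning.
#'
#' @param ref domestic reference feature table with `sample_id`,
#'   `cultivar_id` and coefficient columns.
#' @param domestic_unknowns feature table of the unknowns classified as
#'   domestic in stage 1.
#' @param min_per_cultivar minimum reference pips per cultivar (default 3).
#' @param stepwise if `TRUE` (default) run stepwise selection on the
#'   cultivar labels; otherwise use all coefficient columns.
#' @param f_enter,f_remove,tolerance_min stepwise thresholds.
#' @return An object of class `pip_stage2`: list with `assignments`
#'   (tibble: `sample_id`, `site`, `cultivar_id`, `posterior`), `model`,
#'   `selection` and `dropped_cultivars`.
#' @export
stage2_cultivar_assignment <- function(ref, domestic_unknowns,
                                       min_per_cultivar = 3L,
                                       stepwise = TRUE, f_enter = 3.84,
                                       f_remove = 2.71,
                                       tolerance_min = 0.001) {
  if (!is.data.frame(ref) || !"cultivar_id" %in% names(ref)) {
    abort("`ref` must be a data frame with a `cultivar_id` column")
  }
  if (!is.data.frame(domestic_unknowns) || nrow(domestic_unknowns) == 0L) {
    abort("`domestic_unknowns` must be a non-empty data frame")
  }
  counts <- table(ref$cultivar_id)
  dropped <- names(counts)[counts < min_per_cultivar]
  if (length(dropped) > 0L) {
    warn(sprintf("dropping %d cultivar(s) with fewer than %d reference pips: %s",
                 length(dropped), as.integer(min_per_cultivar),
                 paste(head(dropped, 5L), collapse = ", ")))
    ref <- ref[!ref$cultivar_id %in% dropped, , drop = FALSE]
  }
  feats <- intersect(feature_names(), names(ref))
  g <- length(unique(ref$cultivar_id))
  if (g < 2L) abort("need at least two cultivars after filtering")
  sel_feats <- feats
  sel <- NULL
  if (isTRUE(stepwise)) {
    sel <- stepwise_select(ref, "cultivar_id", feats, f_enter = f_enter,
                           f_remove = f_remove, tolerance_min = tolerance_min)
    if (length(sel$selected) > 0L) sel_feats <- sel$selected
  }
  if (nrow(ref) - g <= length(sel_feats)) {
    abort(sprintf("insufficient reference degrees of freedom: n - g = %d <= p = %d",
                  nrow(ref) - g, length(sel_feats)))
  }
  model <- fit_lda(ref, "cultivar_id", sel_feats, priors = "equal")
  pred <- classify(model, domestic_unknowns)
  assignments <- tibble(
    sample_id = domestic_unknowns$sample_id,
    site = if ("site" %in% names(domestic_unknowns)) domestic_unknowns$site
           else NA_character_,
    cultivar_id = as.character(pred$.class),
    posterior = pred$.posterior
  )
  structure(
    list(assignments = assignments, model = model, selection = sel,
         dropped_cultivars = dropped),
    class = "pip_stage2"
  )
}

#' @export
print.pip_stage2 <- function(x, ...) {
  cat(sprintf("<pip_stage2> %d pips assigned to %d cultivars\n",
              nrow(x$assignments), length(x$model$groups)))
  invisible(x)
}

## merge stage-1 and stage-2 outputs into one assignment table
combine_assignments <- function(stage1, stage2) {
  s1 <- stage1$assignments
  s2 <- stage2$assignments[c("sample_id", "cultivar_id")]
  dplyr::left_join(s1, s2, by = "sample_id")
}

#' Percentage-allocation report
#'
#' Aggregates per-sample assignments into the headline tables: per-site
#' wild/domestic counts with integer percentages (rounded half away from
#' zero), a per-cultivar count table across sites (full, and filtered to
#' cultivars with at least `min_count` assigned pips in total), and berry
#' colour and origin-region percentage breakdowns. Colour and region
#' percentages are shares of assigned pips (not of distinct cultivars),
#' computed per site over the pips that received a cultivar assignment.
#'
#' @param assignments data frame with columns `sample_id`, `site`, `status`
#'   and `cultivar_id` (`NA` for wild-classified pips).
#' @param metadata cultivar metadata with `cultivar_id`, `colour`,
#'   `origin_region` (see [generate_cultivar_metadata()]).
#' @param min_count minimum total pips for a cultivar to enter the filtered
#'   table (default 10).
#' @return An object of class `allocation_report`: list of tibbles `status`,
#'   `cultivar_counts`, `cultivar_table` (filtered), `colour`, `region`,
#'   plus `min_count` and the rounding rule in `rounding`.
#' @export
allocation_report <- function(assignments, metadata, min_count = 10L) {
  need <- c("sample_id", "site", "status", "cultivar_id")
  if (!is.data.frame(assignments) || !all(need %in% names(assignments))) {
    abort(sprintf("`assignments` must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  assigned <- assignments[!is.na(assignments$cultivar_id), , drop = FALSE]
  unknown_cv <- setdiff(assigned$cultivar_id, metadata$cultivar_id)
  if (length(unknown_cv) > 0L) {
    abort(sprintf("cultivar(s) missing from metadata: %s",
                  paste(head(unknown_cv, 5L), collapse = ", ")))
  }
  status <- assignments |>
    dplyr::count(.data$site, .data$status, name = "n") |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(pct = round_half_away(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup()
  cultivar_counts <- assigned |>
    dplyr::count(.data$cultivar_id, .data$site, name = "n") |>
    tidyr::pivot_wider(names_from = "site", values_from = "n",
                       values_fill = 0L)
  site_cols <- setdiff(names(cultivar_counts), "cultivar_id")
  cultivar_counts$total <- as.integer(rowSums(cultivar_counts[site_cols]))
  cultivar_counts <- dplyr::arrange(cultivar_counts, dplyr::desc(.data$total))
  cultivar_table <- cultivar_counts |>
    dplyr::filter(.data$total >= min_count) |>
    dplyr::left_join(metadata, by = "cultivar_id") |>
    dplyr::relocate(dplyr::any_of(c("cultivar_id", "name", "colour",
                                    "origin_region", "use")))
  meta_join <- metadata[c("cultivar_id", "colour", "origin_region")]
  by_meta <- dplyr::left_join(assigned, meta_join, by = "cultivar_id")
  colour <- by_meta |>
    dplyr::count(.data$site, .data$colour, name = "n") |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(pct = round_half_away(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup()
  region <- by_meta |>
    dplyr::count(.data$site, .data$origin_region, name = "n") |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(pct = round_half_away(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup()
  structure(
    list(status = status, cultivar_counts = cultivar_counts,
         cultivar_table = cultivar_table, colour = colour, region = region,
         min_count = as.integer(min_count),
         rounding = "half away from zero"),
    class = "allocation_report"
  )
}

#' @export
print.allocation_report <- function(x, ...) {
  cat("<allocation_report>\n\nStatus by site:\n")
  print(x$status, n = Inf)
  cat(sprintf("\nCultivars with >= %d assigned pips: %d (of %d)\n",
              x$min_count, nrow(x$cultivar_table), nrow(x$cultivar_counts)))
  invisible(x)
}

#' @rdname allocation_report
#' @param x an `allocation_report` object.
#' @param ... unused.
#' @export
tidy.allocation_report <- function(x, ...) x$status

## ---- end-to-end orchestration ----------------------------------------

## reference + site populations from a config; all randomness flows from
## `seed` through one generator stream
build_population_specs <- function(config, seed) {
  set.seed(as.integer(seed))
  gen <- config$generator
  refc <- config$reference
  base <- pip_class_specs(n_wild = 1L, n_domestic = 1L, config = config)
  sds <- coefficient_sds(config)
  lp <- config$image$length_px
  meta <- generate_cultivar_metadata(refc$n_cultivars,
                                     seed = sample.int(2^31 - 1L, 1L))
  ## sub-means: cultivars scatter around the domestic mean, accessions
  ## around the wild mean
  cult_means <- lapply(seq_len(refc$n_cultivars), function(i)
    base$domestic$mean_coefficients +
      rnorm(24L, 0, gen$between_cultivar_ratio * sds))
  acc_means <- lapply(seq_len(refc$wild_accessions), function(i)
    base$wild$mean_coefficients +
      rnorm(24L, 0, gen$between_accession_ratio * sds))
  ref_specs <- c(
    purrr::imap(cult_means, function(mu, i)
      shape_class_spec(meta$cultivar_id[i], mu, sds, refc$pips_per_cultivar,
                       length_px = lp, status = "domestic",
                       cultivar_id = meta$cultivar_id[i])),
    purrr::imap(acc_means, function(mu, i)
      shape_class_spec(sprintf("wild_acc%02d", i), mu, sds,
                       refc$pips_per_accession,
                       length_px = lp * gen$wild_length_ratio,
                       status = "wild"))
  )
  ## unknown assemblages: per-site mixtures of the same sub-classes
  site_specs <- purrr::map(config$sites, function(site) {
    n_dom <- round_half_away(site$n_pips * site$domestic_fraction)
    n_wild <- site$n_pips - n_dom
    cv_draw <- table(sample.int(refc$n_cultivars, n_dom, replace = TRUE))
    acc_draw <- table(sample.int(refc$wild_accessions, n_wild, replace = TRUE))
    c(
      purrr::map(names(cv_draw), function(i) {
        i <- as.integer(i)
        shape_class_spec(paste0("unk_", meta$cultivar_id[i]), cult_means[[i]],
                         sds, as.integer(cv_draw[as.character(i)]),
                         length_px = lp, status = "domestic",
                         cultivar_id = meta$cultivar_id[i])
      }),
      purrr::map(names(acc_draw), function(i) {
        i <- as.integer(i)
        shape_class_spec(sprintf("unk_wild%02d", i), acc_means[[i]], sds,
                         as.integer(acc_draw[as.character(i)]),
                         length_px = lp * gen$wild_length_ratio,
                         status = "wild")
      })
    )
  })
  names(site_specs) <- purrr::map_chr(config$sites, "name")
  list(metadata = meta, ref_specs = ref_specs, site_specs = site_specs,
       pop_seeds = sample.int(2^31 - 1L, 2L + length(site_specs)))
}

## generate + extract features one class at a time so that silhouette
## rasters (1 MB each) are never all held in memory at once; sample ids are
## prefixed per class chunk to stay globally unique
features_for_specs <- function(specs, config, seed) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2^31 - 1L, length(specs))
  n_points <- config$outline$n_points %||% 360L
  nh <- config$efd$n_harmonics %||% 6L
  purrr::imap(specs, function(sp, i) {
    pop <- generate_population(list(sp), image_size = config$image$size,
                               seed = seeds[i], n_points = n_points)
    f <- extract_features(pop, n_points = n_points, n_harmonics = nh,
                          min_size = config$outline$min_size %||% 32L)
    f$sample_id <- sprintf("c%03d_%s", i, f$sample_id)
    f$status <- pop$truth$class
    f$cultivar_id <- pop$truth$cultivar_id
    f
  }) |> dplyr::bind_rows()
}

#' Run the full two-stage analysis pipeline
#'
#' Executes simulate -> extract -> features -> stage 1 -> stage 2 -> report
#' on populations generated from the configuration: a cultivar-structured
#' reference collection, and one unknown assemblage per site. When
#' `out_dir` is given, features, assignments, allocation tables, the fitted
#' models and a run manifest are written there as CSV/JSON.
#'
#' @param config configuration list (see [read_pip_config()]); defaults to
#'   the packaged demo configuration.
#' @param seed integer seed overriding `config$seed`.
#' @param out_dir optional output directory.
#' @param verbose print stage progress.
#' @return An object of class `pip_run`: list with `reference_features`,
#'   `unknown_features`, `stage1`, `stage2`, `assignments`, `report`,
#'   `metadata`, `config` and `seed`.
#' @export
run_pipeline <- function(config = demo_config(), seed = NULL, out_dir = NULL,
                         verbose = FALSE) {
  seed <- as.integer(seed %||% config$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_ctx <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)))
    })
  }
  plan <- stage_ctx("simulate", build_population_specs(config, seed))
  say("generating and extracting reference features (%d classes)",
      length(plan$ref_specs))
  ref_feat <- stage_ctx("extract", features_for_specs(
    plan$ref_specs, config, plan$pop_seeds[1L]))
  unk_feat <- purrr::imap(plan$site_specs, function(specs, site) {
    say("site %s: generating and extracting %d unknowns", site,
        sum(purrr::map_int(specs, "n_samples")))
    f <- stage_ctx("extract", features_for_specs(
      specs, config,
      plan$pop_seeds[1L + which(names(plan$site_specs) == site)]))
    f$sample_id <- paste0(site, "_", f$sample_id)
    f$site <- site
    dplyr::rename(f, true_status = "status",
                  true_cultivar_id = "cultivar_id")
  }) |> dplyr::bind_rows()
  say("balancing reference to %d per class", config$reference$n_per_class)
  balanced <- stage_ctx("balance", balance_reference(
    ref_feat, config$reference$n_per_class,
    seed = plan$pop_seeds[length(plan$pop_seeds)]))
  ldac <- config$lda
  say("stage 1: wild/domestic discrimination")
  s1 <- stage_ctx("stage1", stage1_wild_domestic(
    balanced, unk_feat, f_enter = ldac$f_enter, f_remove = ldac$f_remove,
    tolerance_min = ldac$tolerance_min, priors = ldac$priors %||% "equal"))
  dom_ids <- s1$assignments$sample_id[s1$assignments$status == "domestic"]
  dom_unknowns <- unk_feat[unk_feat$sample_id %in% dom_ids, , drop = FALSE]
  say("stage 2: cultivar assignment of %d domestic pips", nrow(dom_unknowns))
  dom_ref <- ref_feat[ref_feat$status == "domestic", , drop = FALSE]
  s2 <- stage_ctx("stage2", stage2_cultivar_assignment(
    dom_ref, dom_unknowns,
    min_per_cultivar = config$reference$min_per_cultivar %||% 3L,
    f_enter = ldac$f_enter, f_remove = ldac$f_remove,
    tolerance_min = ldac$tolerance_min))
  assignments <- combine_assignments(s1, s2)
  say("report")
  report <- stage_ctx("report", allocation_report(
    assignments, plan$metadata,
    min_count = config$report$min_count %||% 10L))
  run <- structure(
    list(reference_features = ref_feat, unknown_features = unk_feat,
         stage1 = s1, stage2 = s2, assignments = assignments,
         report = report, metadata = plan$metadata, config = config,
         seed = seed),
    class = "pip_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pip_run <- function(x, ...) {
  cat(sprintf("<pip_run> seed %d: %d reference + %d unknown pips, stage-1 LOOCV %.3f\n",
              x$seed, nrow(x$reference_features), nrow(x$unknown_features),
              x$stage1$loocv$accuracy))
  print(x$report)
  invisible(x)
}
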