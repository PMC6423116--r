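# End-to-end orchestration: simulate -> quantify -> fit -> pls/predict ->
# classify, with a reproducible run manifest.

PIPELINE_STAGES <- c("simulate", "quantify", "classify", "simulate_curves",
                     "fit_rheology", "pls", "predict")

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline. Defaults equal the measurement
#' protocol the analysis assumes: 250 Pa creep stress, 180 s creep,
#' 360 s recovery, 0.1-50 Hz sweep at 0.1% strain, 215/1024 um/px image
#' calibration, gliding boxes 8-128 px.
#'
#' @param pixel_size_um image calibration, um/px.
#' @param box_sizes lacunarity box sizes, px.
#' @param size_px synthetic image edge length, px.
#' @param protocol a [rheology_protocol()].
#' @param standard standard-dough attributes for direction comparisons.
#' @param tol classifier direction dead-band.
#' @param noise_cv synthetic noise level (attribute CV / image parameter
#'   jitter / curve noise).
#' @param n_per_type synthetic samples (or seeds) per network type.
#' @param seed master seed; all stage seeds derive from it.
#' @param simulate_images if TRUE the simulate stage draws micrographs
#'   (for the quantify stage); if FALSE it draws attribute tables.
#' @return List of class `run_config`.
#' @export
run_config <- function(pixel_size_um = DEFAULT_PIXEL_SIZE_UM,
                       box_sizes = DEFAULT_BOX_SIZES,
                       size_px = 512,
                       protocol = rheology_protocol(),
                       standard = standard_dough_attributes(),
                       tol = 0.10, noise_cv = 0.1, n_per_type = 5,
                       seed = 1, simulate_images = TRUE) {
  structure(list(pixel_size_um = pixel_size_um, box_sizes = box_sizes,
                 size_px = size_px, protocol = protocol,
                 standard = standard, tol = tol, noise_cv = noise_cv,
                 n_per_type = n_per_type, seed = seed,
                 simulate_images = simulate_images),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, carrying intermediate results
#' in memory and (when `out_dir` is given) writing every intermediate as
#' CSV/PNG/JSON plus a run manifest recording the configuration, package
#' version and MD5 hashes of all written files. Stage names are
#' validated before anything executes. Identical configurations and
#' seeds reproduce outputs bit-identically.
#'
#' Supported stages: `simulate` (archetype micrographs or attribute
#' tables), `quantify` (micrographs to attributes; the classification
#' standard becomes the quantified zero-jitter spread archetype),
#' `classify`, `simulate_curves`, `fit_rheology`, `predict` (frozen
#' equations applied to the current attribute table), `pls` (refit on a
#' linked dataset).
#'
#' @param config a [run_config()].
#' @param stages character vector of stage names, executed in the given
#'   order.
#' @param out_dir optional output directory.
#' @return List of class `run_manifest`: `config`, `stages`, per-stage
#'   `outputs`, `files` (paths and MD5 hashes), `package_version`.
#' @examples
#' \donttest{
#' man <- run_pipeline(run_config(n_per_type = 1, size_px = 256),
#'                     c("simulate", "quantify", "classify"))
#' man$outputs$classify$assigned
#' }
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "quantify", "classify"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         " (supported: ", paste(PIPELINE_STAGES, collapse = ", "), ")")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  state <- list()
  outputs <- list()
  files <- character()
  emit <- function(name, writer) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, name)
      writer(path)
      files[[name]] <<- unname(md5sum(path))
    }
  }

  for (stage in stages) {
    message("[doughnet] stage ", stage)
    if (stage == "simulate" && config$simulate_images) {
      samples <- list(); labels <- character(); k <- 0L
      for (type in NETWORK_TYPES) {
        for (s in seq_len(config$n_per_type)) {
          k <- k + 1L
          samples[[k]] <- generate_network_image(
            type, size_px = config$size_px,
            pixel_size_um = config$pixel_size_um,
            seed = config$seed * 1000L + k, jitter = config$noise_cv)
          labels[k] <- type
        }
      }
      state$images <- samples
      state$truth <- labels
      outputs$simulate <- data.frame(index = seq_len(k), label = labels)
      emit("simulate_truth.csv", function(p)
        write.csv(outputs$simulate, p, row.names = FALSE))
      if (!is.null(out_dir)) {
        for (i in seq_len(k)) {
          emit(sprintf("image_%03d_%s.png", i, labels[i]), function(p)
            write_micrograph(samples[[i]], p))
        }
      }
    } else if (stage == "simulate") {
      tabs <- lapply(seq_along(NETWORK_TYPES), function(i) {
        generate_attribute_table(NETWORK_TYPES[i], config$standard,
                                 n = config$n_per_type,
                                 noise_cv = config$noise_cv,
                                 seed = config$seed * 1000L + i)
      })
      state$attributes <- do.call(rbind, tabs)
      state$truth <- state$attributes$label
      outputs$simulate <- state$attributes
      emit("attributes.csv", function(p)
        write_attribute_table(state$attributes, p))
    } else if (stage == "quantify") {
      if (is.null(state$images))
        stop("quantify needs images from a simulate stage")
      rows <- lapply(state$images, function(img) {
        as.data.frame(as.list(unclass(
          quantify_micrograph(img, box_sizes = config$box_sizes))))
      })
      state$attributes <- do.call(rbind, rows)
      state$attributes$label <- state$truth
      # quantified zero-jitter spread mesh = in-image standard dough
      state$image_standard <- quantify_micrograph(
        generate_network_image("spread", size_px = config$size_px,
                               pixel_size_um = config$pixel_size_um,
                               seed = config$seed, jitter = 0),
        box_sizes = config$box_sizes)
      outputs$quantify <- state$attributes
      emit("quantified.csv", function(p)
        write_attribute_table(state$attributes, p))
    } else if (stage == "classify") {
      if (is.null(state$attributes))
        stop("classify needs an attribute table from an upstream stage")
      standard <- if (!is.null(state$image_standard)) state$image_standard
                  else config$standard
      res <- classify_table(state$attributes, standard, tol = config$tol)
      if (!is.null(state$truth)) {
        res$truth <- state$truth
        attr(res, "accuracy") <- mean(res$assigned == res$truth)
      }
      outputs$classify <- res
      emit("classified.csv", function(p) write.csv(res, p, row.names = FALSE))
    } else if (stage == "simulate_curves") {
      pars <- list(
        power_law = list(a_f = 12000, z = 4),
        creep = list(j0 = 1e-4, j1 = 2e-4, lambda = 10, eta0 = 1e5),
        recovery = list(j0 = 1e-4, j1 = 1.2e-4, j2 = 6e-5,
                        lambda1 = 5, lambda2 = 60))
      state$curve_truth <- pars
      state$curves <- generate_rheology_curves(
        pars$power_law, pars$creep, pars$recovery,
        protocol = config$protocol, noise_cv = config$noise_cv,
        seed = config$seed)
      outputs$simulate_curves <- pars
      emit("sweep.csv", function(p) write_sweep_csv(state$curves$sweep, p))
      emit("creep.csv", function(p) write_creep_csv(state$curves$curve, p))
    } else if (stage == "fit_rheology") {
      if (is.null(state$curves))
        stop("fit_rheology needs curves from simulate_curves")
      state$fits <- fit_rheology(state$curves$sweep, state$curves$curve)
      outputs$fit_rheology <- state$fits
      emit("fits.json", function(p) write_json(
        list(power_law = unclass(state$fits$power_law),
             creep = unclass(state$fits$creep),
             recovery = unclass(state$fits$recovery),
             attributes = as.list(unclass(state$fits$attributes))),
        p, auto_unbox = TRUE, digits = NA))
    } else if (stage == "predict") {
      if (is.null(state$attributes))
        stop("predict needs an attribute table from an upstream stage")
      preds <- do.call(rbind, lapply(seq_len(nrow(state$attributes)),
        function(i) {
          pr <- predict_all_rheology(
            as_micro_attributes(state$attributes[i, ]))
          as.data.frame(lapply(pr, `[[`, "natural"))
        }))
      outputs$predict <- cbind(state$attributes[MICRO_NAMES], preds)
      emit("predictions.csv", function(p)
        write.csv(outputs$predict, p, row.names = FALSE))
    } else if (stage == "pls") {
      data <- generate_linked_dataset(config$standard,
                                      n_per_type = max(config$n_per_type, 2),
                                      noise_cv = config$noise_cv,
                                      seed = config$seed)
      models <- fit_all_pls(data)
      outputs$pls <- models
      emit("pls_models.json", function(p) write_json(
        lapply(models, function(m) list(
          n_factors = m$n_factors,
          coefficients = as.list(m$coefficients),
          intercept = m$intercept, r2y = m$r2y,
          vip = as.list(unclass(m$vip)),
          root_mean_press = m$root_mean_press)),
        p, auto_unbox = TRUE, digits = NA))
    }
  }

  manifest <- structure(list(
    config = config, stages = stages, outputs = outputs, files = files,
    package_version = as.character(packageVersion("doughnet"))
  ), class = "run_manifest")
  if (!is.null(out_dir)) {
    write_json(list(stages = stages,
                    config = .config_snapshot(config),
                    files = as.list(files),
                    package_version = manifest$package_version),
               file.path(out_dir, "manifest.json"),
               auto_unbox = TRUE, digits = NA)
  }
  manifest
}

.config_snapshot <- function(config) {
  list(pixel_size_um = config$pixel_size_um,
       box_sizes = config$box_sizes, size_px = config$size_px,
       protocol = unclass(config$protocol),
       standard = as.list(unclass(config$standard)),
       tol = config$tol, noise_cv = config$noise_cv,
       n_per_type = config$n_per_type, seed = config$seed,
       simulate_images = config$simulate_images)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<pipeline run> stages:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(attr(x$outputs$classify, "accuracy")))
    cat(sprintf("label recovery: %.1f%%\n",
                100 * attr(x$outputs$classify, "accuracy")))
  invisible(x)
}
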