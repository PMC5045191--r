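#' Config-driven experiment runner
#'
#' Reproduces the package's standard experiment shapes from a declarative
#' config (a list, or a YAML/JSON file path): selectivity suites over sets of
#' nonlinearities, single-neuron and network receptive-field learning,
#' objective maps over Gabor grids, Gabor fitting of stored weights, and
#' synthetic-data generation. Every run writes its outputs plus a
#' `manifest.json` capturing the resolved config, package version and all
#' stage seeds; reruns of a config are bit-identical for deterministic
#' stages.
#'
#' Config keys: `kind` (one of `"selectivity"`, `"learn"`, `"network"`,
#' `"objective_map"`, `"fit_gabors"`, `"synth_data"`), `seed`, `output_dir`,
#' `data` (a data-source block, see [build_experiment_data()]),
#' `nonlinearity`/`nonlinearities` (blocks for [nl_from_config()]), `K`,
#' `n_epochs`, `learn` (overrides for [learn_config()]), and per-kind extras
#' (`map`: `sigma_x`/`sigma_y` grids, `frequencies`; `weights_csv`).
#'
#' @param config list or path to a YAML/JSON config file.
#' @param out_dir output directory (overrides `config$output_dir`).
#' @return (invisibly) the manifest list, with `outputs` naming written files.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config <- validate_experiment_config(config)
  if (!is.null(out_dir)) config$output_dir <- out_dir
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  outputs <- character(0)
  out <- function(name) file.path(config$output_dir, name)

  nls_cfg <- if (!is.null(config$nonlinearities)) config$nonlinearities
             else if (!is.null(config$nonlinearity)) list(config$nonlinearity)
             else NULL
  nls <- if (is.null(nls_cfg)) NULL else lapply(nls_cfg, nl_from_config)

  if (config$kind == "selectivity") {
    method <- config$method %||% "quadrature"
    tab <- do.call(rbind, lapply(seq_along(nls), function(i) {
      r <- selectivity_index(nls[[i]], method = method,
                             n_samples = config$n_samples %||% 1e6,
                             seed = spawn_seed(seed, paste0("si", i)))
      data.frame(label = nls[[i]]$label, si = r$si, numerator = r$numerator,
                 sigma_l = r$sigma_l, sigma_g = r$sigma_g, method = r$method,
                 se = r$se)
    }))
    utils::write.csv(tab, out("si_table.csv"), row.names = FALSE)
    outputs <- c(outputs, "si_table.csv")
  } else if (config$kind %in% c("learn", "network")) {
    ens <- build_experiment_data(config$data, seed)
    lc <- do.call(learn_config, c(
      config$learn %||% list(),
      list(seed = spawn_seed(seed, "learn"),
           g = if (!is.null(config$g)) nl_from_config(config$g) else nl_linear(),
           h = if (!is.null(config$h)) nl_from_config(config$h) else NULL)))
    if (config$kind == "learn") {
      f <- nls[[1]]
      res <- learn_single_neuron(ens, f, lc, n_epochs = config$n_epochs %||% 1L)
      utils::write.table(matrix(res$w, nrow = 1), out("weights.csv"), sep = ",",
                         row.names = FALSE, col.names = FALSE)
      fit <- fit_gabor(res$w, ensemble_geometry(ens)[1:2],
                       seed = spawn_seed(seed, "gaborfit"))
      utils::write.csv(as.data.frame(fit), out("gabor_fit.csv"), row.names = FALSE)
      outputs <- c(outputs, "weights.csv", "gabor_fit.csv")
    } else {
      st <- network_learning(ens, lc, K = config$K %||% 10L,
                             n_epochs = config$n_epochs %||% 1L)
      write_network_state(st, out("state"))
      outputs <- c(outputs, "state_W.csv", "state_V.csv", "state_ymean.csv")
    }
  } else if (config$kind == "objective_map") {
    ens <- build_experiment_data(config$data, seed)
    map <- config$map %||% list()
    cells <- expand.grid(sigma_x = map$sigma_x %||% c(1, 1.5, 2, 3),
                         sigma_y = map$sigma_y %||% c(1.5, 2, 3, 4))
    res <- objective_map(nls[[1]], ens, cells,
                         frequencies = map$frequencies %||% c(0.1, 0.15, 0.2, 0.3))
    utils::write.csv(res, out("objective_map.csv"), row.names = FALSE)
    render_heatmap(res, "sigma_x", "sigma_y", "R_star", out("objective_map.png"))
    outputs <- c(outputs, "objective_map.csv", "objective_map.png")
  } else if (config$kind == "fit_gabors") {
    W <- as.matrix(utils::read.table(config$weights_csv, sep = ","))
    ps <- config$patch_size %||% c(16, 16)
    fits <- do.call(rbind, lapply(seq_len(nrow(W)), function(i) {
      as.data.frame(fit_gabor(as.numeric(W[i, ]), ps,
                              seed = spawn_seed(seed, paste0("fit", i))))
    }))
    utils::write.csv(fits, out("gabor_fits.csv"), row.names = FALSE)
    outputs <- c(outputs, "gabor_fits.csv")
  } else if (config$kind == "synth_data") {
    ens <- build_experiment_data(config$data, seed)
    write_ensemble(ens, out("ensemble.csv"))
    outputs <- c(outputs, "ensemble.csv", "ensemble.csv.meta.json")
  }

  manifest <- list(package = "nlhebb",
                   version = as.character(utils::packageVersion("nlhebb")),
                   config = config, outputs = outputs)
  manifest$hash <- manifest_hash(manifest)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an experiment config
#'
#' Checks the `kind` tag and the keys it requires; unknown kinds and missing
#' keys raise a configuration error naming the offending keys.
#'
#' @param config experiment config list.
#' @return the config with defaults filled in.
#' @export
validate_experiment_config <- function(config) {
  kinds <- c("selectivity", "learn", "network", "objective_map", "fit_gabors",
             "synth_data")
  if (is.null(config$kind) || !config$kind %in% kinds) {
    nlh_stop(paste0("config$kind must be one of: ", paste(kinds, collapse = ", ")),
             "nlhebb_configuration_error")
  }
  required <- switch(config$kind,
    selectivity = "nonlinearities|nonlinearity",
    learn = c("data", "nonlinearities|nonlinearity"),
    network = c("data", "g"),
    objective_map = c("data", "nonlinearities|nonlinearity"),
    fit_gabors = "weights_csv",
    synth_data = "data")
  missing <- Filter(function(k) {
    alts <- strsplit(k, "|", fixed = TRUE)[[1]]
    !any(vapply(alts, function(a) !is.null(config[[a]]), logical(1)))
  }, required)
  if (length(missing)) {
    nlh_stop(paste0("config for kind '", config$kind, "' is missing: ",
                    paste(unlist(missing), collapse = ", ")),
             "nlhebb_configuration_error")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "nlhebb_run"
  config
}

#' Build an ensemble from a data-source block
#'
#' Supported sources: `source = "generative"` (Gabor dictionary + heavy-tailed
#' latents; keys `n`, `m`, `patch_size`, `latent_law`, `noise_sd`),
#' `"stationary"` (patches from a [synthetic_image_stack()]; keys `n`,
#' `patch_size`, `image_size`, `stack_kind`), `"spectrogram"` (synthetic
#' audio; key `n`), `"ensemble_csv"` (key `path`). `whiten = TRUE` applies
#' exact whitening after generation.
#'
#' @param data data-source block (list).
#' @param seed global seed; stage seeds are spawned from it.
#' @export
build_experiment_data <- function(data, seed = 1L) {
  if (is.null(data$source)) {
    nlh_stop("data block needs a 'source'", "nlhebb_configuration_error")
  }
  ens <- switch(data$source,
    generative = {
      ps <- data$patch_size %||% c(16, 16)
      D <- gabor_dictionary(ps, m = data$m %||% 64,
                            seed = spawn_seed(seed, "dict"))
      gm <- generative_model(D, latent_law = data$latent_law %||% "laplacian",
                             noise_sd = data$noise_sd %||% 0.1,
                             geometry = c(ps, 1L),
                             seed = spawn_seed(seed, "latents"))
      generate_patch_ensemble(gm, n = data$n %||% 10000)
    },
    stationary = {
      stack <- synthetic_image_stack(n_images = data$n_images %||% 8,
                                     size = data$image_size %||% 64,
                                     kind = data$stack_kind %||% "kurtotic",
                                     seed = spawn_seed(seed, "stack"))
      sample_patches(stack, data$patch_size %||% c(16, 16), n = data$n %||% 10000,
                     rotate_augment = isTRUE(data$rotate_augment),
                     seed = spawn_seed(seed, "patches"), wrap = TRUE)
    },
    spectrogram = spectrogram_segments(n_segments = data$n %||% 1000,
                                       seed = spawn_seed(seed, "audio")),
    ensemble_csv = read_ensemble(data$path),
    nlh_stop(paste0("unknown data source: ", data$source),
             "nlhebb_configuration_error"))
  if (isTRUE(data$whiten)) {
    ens <- apply_whitening(suppressWarnings(fit_whitening(ens)), ens)
  }
  ens
}

# Deterministic content hash of the manifest (timestamps and output paths
# excluded) so rerun identity is checkable across output directories.
manifest_hash <- function(manifest) {
  manifest$hash <- NULL
  manifest$config$output_dir <- NULL
  s <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- (h * 16777619 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

render_heatmap <- function(df, xcol, ycol, vcol, path) {
  xs <- sort(unique(df[[xcol]])); ys <- sort(unique(df[[ycol]]))
  z <- matrix(NA_real_, length(xs), length(ys))
  for (i in seq_len(nrow(df))) {
    z[match(df[[xcol]][i], xs), match(df[[ycol]][i], ys)] <- df[[vcol]][i]
  }
  grDevices::png(path, width = 480, height = 420)
  on.exit(grDevices::dev.off())
  graphics::image(xs, ys, z, col = grDevices::gray.colors(64, 0, 1),
                  xlab = xcol, ylab = ycol, main = vcol)
  invisible(path)
}
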