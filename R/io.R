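#' Read an interaction matrix from CSV
#'
#' Expects a dense N x N numeric CSV, optionally with a single header row of
#' strain labels. Rows are the colonizer/resident strain, columns the
#' incoming co-colonizer. Values round-trip with
#' [write_interaction_matrix()] at full double precision.
#'
#' @param path Path to the CSV file.
#' @return An N x N numeric interaction matrix, with labels if present.
#' @export
read_interaction_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  fields <- utils::count.fields(path, sep = ",")
  if (length(unique(fields)) != 1L) {
    bad <- which(fields != fields[1L])[1L]
    stop(sprintf("Ragged CSV: row %d has %d fields, expected %d.",
                 bad, fields[bad], fields[1L]), call. = FALSE)
  }
  first <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.csv(path, header = has_header, check.names = FALSE)
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (any(is.na(v) & !is.na(df[[j]])) || any(is.na(v)))
      stop(sprintf("Non-numeric cell in column %d (row %d of the data).",
                   j, which(is.na(v))[1L]), call. = FALSE)
    df[[j]] <- v
  }
  K <- as.matrix(df)
  if (nrow(K) != ncol(K))
    stop(sprintf("Interaction matrix must be square; file has %d rows x %d columns.",
                 nrow(K), ncol(K)), call. = FALSE)
  if (has_header) dimnames(K) <- list(colnames(K), colnames(K))
  else dimnames(K) <- NULL
  validate_interaction_matrix(K)
}

#' Write an interaction matrix to CSV
#'
#' Writes a dense CSV with a header row of strain labels (row = colonizer,
#' column = co-colonizer), preserving full double precision.
#'
#' @param K Interaction matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(K, path) {
  validate_interaction_matrix(K)
  labels <- colnames(K) %||% paste0("strain_", seq_len(ncol(K)))
  df <- as.data.frame(K)
  names(df) <- labels
  readr::write_csv(df, path)
  invisible(path)
}

# Collect all config validation problems in one pass.
validate_config <- function(config) {
  problems <- character()
  need_num <- function(field, positive = TRUE) {
    v <- config[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      problems <<- c(problems, sprintf("`%s` must be a single finite number.", field))
    else if (positive && v <= 0)
      problems <<- c(problems, sprintf("`%s` must be positive.", field))
  }
  modes <- c("generate", "decompose", "neutral", "full", "replicator",
             "validate", "ensemble", "network")
  if (is.null(config$mode) || !config$mode %in% modes)
    problems <- c(problems, sprintf("`mode` must be one of: %s.",
                                    paste(modes, collapse = ", ")))
  need_num("beta"); need_num("gamma"); need_num("r")
  if (is.null(config$N) || config$N < 1)
    problems <- c(problems, "`N` must be an integer >= 1.")
  has_file <- !is.null(config$matrix_file)
  has_gen <- !is.null(config$k)
  if (!has_file && !has_gen)
    problems <- c(problems, "Exactly one matrix source required: `matrix_file` or generator fields (`k`, `epsilon`, optional `structure`, `seed`).")
  if (has_file && has_gen)
    problems <- c(problems, "Supply either `matrix_file` or generator fields, not both.")
  if (length(problems)) stop(paste(c("Invalid configuration:", problems), collapse = "\n  "),
                             call. = FALSE)
  invisible(config)
}

config_matrix <- function(config) {
  if (!is.null(config$matrix_file)) {
    read_interaction_matrix(config$matrix_file)
  } else if ((config$epsilon %||% 0.1) == 0 || config$N == 1) {
    # neutral (constant) matrix; also the only valid single-strain source
    matrix(config$k, config$N, config$N)
  } else if (!is.null(config$structure)) {
    structured_interaction_matrix(config$N, structure = config$structure,
                                  k = config$k,
                                  epsilon = config$epsilon %||% 0.1,
                                  seed = config$seed)
  } else {
    random_interaction_matrix(config$N, k = config$k,
                              epsilon = config$epsilon %||% 0.1,
                              seed = config$seed)
  }
}

#' Run a complete analysis from a configuration
#'
#' Drives the package from a flat configuration (a named list or a path to a
#' JSON file) and writes all artifacts under `out_dir`: trajectory CSVs,
#' JSON reports, and a `provenance.json` echoing the config, its hash, the
#' seed and the package version, so every run can be regenerated exactly.
#'
#' Config fields: `mode` (one of `generate`, `decompose`, `neutral`, `full`,
#' `replicator`, `validate`, `ensemble`, `network`), `beta`, `gamma`, `r`,
#' `N`, a matrix source (`matrix_file` or `k` + `epsilon` + optional
#' `structure` + `seed`), optional `z0`, `t_max`, `tau_max`, `n_out`,
#' `ensemble_class`, `reps`.
#'
#' @param config Named list or path to a JSON config file.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_from_config <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- epi_params(config$beta, config$gamma, config$r, config$N)
  K <- config_matrix(config)
  d <- decompose_interactions(K)
  n_out <- config$n_out %||% 201
  results <- list(params = params, K = K, decomposition = d)

  write_interaction_matrix(K, file.path(out_dir, "K.csv"))

  if (config$mode %in% c("decompose", "generate")) {
    jsonlite::write_json(as.list(glance(d)), file.path(out_dir, "decomposition.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (config$mode == "neutral") {
    eq <- neutral_equilibrium(params, d$k)
    results$equilibrium <- eq
    jsonlite::write_json(
      list(S_star = eq$S_star, T_star = eq$T_star, I_star = eq$I_star,
           D_star = eq$D_star, mu = eq$mu, Theta = eq$Theta, xi = eq$xi),
      file.path(out_dir, "neutral_equilibrium.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (config$mode == "full") {
    eq <- neutral_equilibrium(params, d$k)
    z0 <- config$z0 %||% rep(1 / params$N, params$N)
    times <- seq(0, config$t_max %||% 100, length.out = n_out)
    traj <- simulate_full(initial_state(z0, eq), params, K, times)
    results$trajectory <- traj
    readr::write_csv(tidy(traj), file.path(out_dir, "full_trajectory.csv"))
  }
  if (config$mode == "replicator") {
    eq <- neutral_equilibrium(params, d$k)
    Lambda <- invasion_fitness_matrix(d$A, eq$mu)
    z0 <- config$z0 %||% rep(1 / params$N, params$N)
    taus <- seq(0, config$tau_max %||% 50, length.out = n_out)
    theta <- config$theta %||% eq$Theta
    traj <- simulate_replicator(z0, Lambda, Theta = theta, taus = taus)
    results$trajectory <- traj
    readr::write_csv(tidy(traj), file.path(out_dir, "replicator_trajectory.csv"))
  }
  if (config$mode == "network") {
    eq <- neutral_equilibrium(params, d$k)
    Lambda <- invasion_fitness_matrix(d$A, eq$mu)
    net <- invasion_network(Lambda, labels = d$labels)
    results$network <- net
    readr::write_csv(net, file.path(out_dir, "invasion_network.csv"))
    jsonlite::write_json(classify_structure(Lambda)["label"],
                         file.path(out_dir, "structure_class.json"),
                         auto_unbox = TRUE)
  }
  if (config$mode == "validate") {
    z0 <- config$z0 %||% rep(1 / params$N, params$N)
    errs <- approximation_error(params, d$A, d$k, z0,
                                epsilons = config$epsilons %||% c(0.2, 0.1, 0.05),
                                tau_max = config$tau_max %||% 5)
    results$errors <- errs
    readr::write_csv(errs, file.path(out_dir, "approximation_error.csv"))
    jsonlite::write_json(purrr::transpose(errs), file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (config$mode == "ensemble") {
    ens <- run_canonical_ensemble(config$ensemble_class %||% "random",
                                  N = params$N,
                                  reps = config$reps %||% 30,
                                  seed = config$seed)
    results$ensemble <- ens
    readr::write_csv(ens$summary, file.path(out_dir, "ensemble_summary.csv"))
  }

  provenance <- list(
    config = config,
    config_hash = rlang::hash(config),
    seed = config$seed %||% NA,
    package_version = as.character(utils::packageVersion("cocodyn")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(results)
}
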