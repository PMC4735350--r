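#' Recommend a group PCA solver for a problem size
#'
#' Encodes the selection heuristic used throughout the package: exact EVD
#' when either data dimension is small (`v <= 10000` or `Mp <= 10000`,
#' where the covariance is cheap to form); otherwise a stacked iterative
#' solver (MPOWIT or Large PCA) when the concatenated data fits in memory;
#' otherwise un-stacked MPOWIT initialized from an STP subspace, which
#' keeps memory independent of the number of subjects and the dataload
#' count near its floor.
#'
#' @param v Number of voxels.
#' @param M Number of subjects.
#' @param p Components per subject after the first PCA stage.
#' @param stacked_fits Can `Y` (8 * v * M * p bytes plus the solver working
#'   set) be held in memory? See [stacked_fits()].
#' @return List with `method` (`"evd"`, `"mpowit"`), `mode`
#'   (`"stacked"`/`"unstacked"`), and `init` (`"random"` or `"stp"`).
#' @export
select_method <- function(v, M, p, stacked_fits = TRUE) {
  stopifnot(v > 0, M > 0, p > 0)
  mp <- M * p
  if (v <= 10000 || mp <= 10000) {
    return(list(method = "evd", mode = if (stacked_fits) "stacked" else "unstacked",
                init = NULL))
  }
  if (stacked_fits) {
    return(list(method = "mpowit", mode = "stacked", init = "random"))
  }
  list(method = "mpowit", mode = "unstacked", init = "stp")
}

#' Does the stacked group matrix fit in a RAM budget?
#'
#' Size arithmetic stand-in for hardware-specific guidance: the stacked
#' data needs `8 * v * M * p` bytes, and the solver working set is
#' approximated as `working_factor` times that of the data's larger
#' iterate blocks.
#'
#' @param v,M,p Problem dimensions.
#' @param ram_gb RAM budget in GiB (default 4).
#' @param working_factor Multiplier for solver working memory (default 1.5).
#' @return Logical.
#' @export
stacked_fits <- function(v, M, p, ram_gb = 4, working_factor = 1.5) {
  bytes <- 8 * v * M * p * working_factor
  bytes <= ram_gb * 1024^3
}

#' Run a configured two-stage group PCA
#'
#' Executes the full pipeline from a run configuration: optional
#' first-stage subject reduction of raw matrices, then the chosen (or
#' automatically selected) group-level solver, writing the PCA result plus
#' a JSON run manifest (seed, parameters, package version, dataload
#' counts) to the output directory.
#'
#' @param config A list, or path to a YAML file, with fields:
#'   `sources` (list of matrices or file paths) or `fixture` (a
#'   [default_fixture()] profile name), `p` (stage-1 order; omit if inputs
#'   are already reduced), `k`, `method` (`"auto"`, `"evd"`, `"svp"`,
#'   `"stp"`, `"large_pca"`, `"mpowit"`, `"em_pca"`), `mode`, `init`
#'   (`"random"`, `"svp"`, `"stp"`), `seed`, `params` (solver-specific
#'   extras), `output_dir` (omit to skip writing).
#' @return List with `result` (a [pca_result()]), `manifest`, and the
#'   `provider` used.
#' @export
run_group_pca <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  k <- as.integer(config[["k"]] %||% stop("config$k is required"))
  seed <- as.integer(config[["seed"]] %||% 0L)
  mode <- config[["mode"]] %||% "stacked"
  params <- config[["params"]] %||% list()

  if (!is.null(config[["fixture"]])) {
    fx <- default_fixture(config[["fixture"]], mode = mode, seed = seed)
    provider <- fx$provider
  } else if (!is.null(config[["sources"]])) {
    sources <- config[["sources"]]
    if (!is.null(config[["p"]])) {
      sources <- lapply(sources, function(src) {
        m <- if (is.character(src)) readRDS(src) else as.matrix(src)
        reduce_subject(center_columns(as.matrix(m)), p = config[["p"]],
                       whiten = isTRUE(config[["whiten"]]))$scores
      })
    }
    provider <- group_provider(sources, mode = mode)
  } else {
    stop("config must name either sources or a fixture profile")
  }
  if (k > min(provider$v, provider$M * provider$p)) {
    stop("k exceeds the rank bound min(v, Mp); nothing was computed")
  }

  method <- config[["method"]] %||% "auto"
  init_name <- config[["init"]] %||% "random"
  if (method == "auto") {
    sel <- select_method(provider$v, provider$M, provider$p,
                         stacked_fits = mode == "stacked")
    method <- sel$method
    init_name <- sel$init %||% init_name
  }
  init <- switch(init_name %||% "random",
    random = NULL,
    svp = svp(provider, k = min(5L * k, provider$M * provider$p),
              k_intermediate = params$k_intermediate),
    stp = stp(provider, k = min(5L * k, provider$M * provider$p),
              k_intermediate = params$k_intermediate,
              g = params$g %||% 20L),
    NULL)

  result <- switch(method,
    evd = evd_group_pca(provider, k),
    svp = svp(provider, k, k_intermediate = params$k_intermediate),
    stp = stp(provider, k, k_intermediate = params$k_intermediate,
              g = params$g %||% 20L),
    large_pca = large_pca(provider, k, b = params$b %||% 170L,
                          j0 = params$j0, tol = params$tol %||% 1e-6,
                          init = init, seed = seed),
    mpowit = mpowit(provider, k, l = params$l %||% 5L,
                    tol = params$tol %||% 1e-6,
                    max_iter = params$max_iter %||% 1000L,
                    init = init, seed = seed),
    em_pca = em_pca(provider, k, tol = params$tol %||% 1e-6,
                    max_iter = params$max_iter %||% 1000L,
                    init = init, seed = seed),
    stop(sprintf("unknown method '%s'", method))
  )

  manifest <- list(
    package = "grouppca",
    version = as.character(utils::packageVersion("grouppca")),
    method = method,
    init = init_name,
    mode = mode,
    k = k,
    seed = seed,
    v = provider$v, M = provider$M, p = provider$p,
    params = params,
    dataloads = result$dataloads,
    eigenvalues = result$eigenvalues
  )
  if (!is.null(config[["output_dir"]])) {
    dir.create(config[["output_dir"]], recursive = TRUE, showWarnings = FALSE)
    write_pca_result(result, file.path(config[["output_dir"]], "pca_result.rds"))
    jsonlite::write_json(manifest,
                         file.path(config[["output_dir"]], "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(result = result, manifest = manifest, provider = provider)
}
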