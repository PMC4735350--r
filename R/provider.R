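#' Column-center a data matrix
#'
#' Removes each column's mean (each time point is mean-centered on zero).
#' Idempotent; the `centered` attribute records that the step has run so
#' downstream code never silently re-centers.
#'
#' @param m Numeric matrix with at least 2 rows, no NaN/Inf.
#' @param subject_id Optional identifier carried along as an attribute.
#' @return The centered matrix with attributes `centered = TRUE` and
#'   `subject_id`.
#' @export
center_columns <- function(m, subject_id = attr(m, "subject_id")) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows to center columns")
  assert_finite(m, "data matrix")
  m <- sweep(m, 2L, colMeans(m), `-`)
  attr(m, "centered") <- TRUE
  attr(m, "subject_id") <- subject_id
  m
}

#' @noRd
check_centered <- function(m, what = "matrix") {
  if (isTRUE(attr(m, "centered"))) return(invisible(TRUE))
  if (!is_col_centered(m)) {
    stop(sprintf("%s is not column-centered; run center_columns() first", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Group data provider
#'
#' Presents the temporally concatenated group matrix `Y = [Y_1 ... Y_M]`
#' (`v` rows, `M * p` columns) through a uniform interface. In `"stacked"`
#' mode all subjects are materialized in memory once; in `"unstacked"` mode
#' subjects are loaded one at a time per pass and every load increments a
#' dataload counter, the unit of I/O cost for the out-of-core solvers.
#'
#' Sources may be in-memory matrices or file paths produced by
#' [write_reduced_subject()] (or `saveRDS()` of a plain matrix). All subjects
#' must share the row count `v` and column count `p`, and must already be
#' column-centered (providers never re-center).
#'
#' @param sources List of numeric matrices and/or file paths.
#' @param mode `"stacked"` or `"unstacked"`.
#' @param subject_ids Optional character vector of subject names.
#' @return An object of class `group_provider` with fields `v`, `p`, `M`,
#'   `mode`, `subject_ids`.
#' @export
group_provider <- function(sources, mode = c("stacked", "unstacked"),
                           subject_ids = NULL) {
  mode <- match.arg(mode)
  if (!is.list(sources) || length(sources) < 1L) {
    stop("sources must be a non-empty list of matrices or file paths")
  }
  M <- length(sources)
  subject_ids <- subject_ids %||% paste0("subject", seq_len(M))
  load_one <- function(i) {
    src <- sources[[i]]
    if (is.character(src)) {
      if (!file.exists(src)) {
        stop(sprintf("cannot read source for %s: %s", subject_ids[i], src))
      }
      obj <- readRDS(src)
      m <- if (is.list(obj) && !is.null(obj$scores)) obj$scores else as.matrix(obj)
    } else {
      m <- as.matrix(src)
    }
    assert_finite(m, sprintf("subject %s", subject_ids[i]))
    m
  }
  # validate once at construction
  first <- load_one(1L)
  v <- nrow(first)
  p <- ncol(first)
  check_centered(first, sprintf("subject %s", subject_ids[1L]))
  env <- new.env(parent = emptyenv())
  env$loads <- 0L
  stacked <- NULL
  if (mode == "stacked") {
    mats <- vector("list", M)
    mats[[1L]] <- first
    for (i in seq_len(M)[-1L]) {
      m <- load_one(i)
      if (nrow(m) != v) stop(sprintf("subject %s has %d rows; expected %d",
                                     subject_ids[i], nrow(m), v))
      if (ncol(m) != p) stop(sprintf("subject %s has %d columns; expected %d",
                                     subject_ids[i], ncol(m), p))
      check_centered(m, sprintf("subject %s", subject_ids[i]))
      mats[[i]] <- m
    }
    stacked <- do.call(cbind, mats)
    env$loads <- M
  } else {
    for (i in seq_len(M)[-1L]) {
      m <- load_one(i)
      if (nrow(m) != v) stop(sprintf("subject %s has %d rows; expected %d",
                                     subject_ids[i], nrow(m), v))
      if (ncol(m) != p) stop(sprintf("subject %s has %d columns; expected %d",
                                     subject_ids[i], ncol(m), p))
      check_centered(m, sprintf("subject %s", subject_ids[i]))
    }
  }
  structure(
    list(v = v, p = p, M = M, mode = mode, subject_ids = subject_ids,
         sources = sources, stacked = stacked, load_one = load_one, env = env),
    class = "group_provider"
  )
}

#' @export
print.group_provider <- function(x, ...) {
  cat(sprintf("Group provider (%s): M=%d subjects, v=%d rows, p=%d columns each (Mp=%d)\n",
              x$mode, x$M, x$v, x$p, x$M * x$p))
  cat(sprintf("  dataloads so far: %d\n", dataloads(x)))
  invisible(x)
}

#' Access one subject's matrix
#'
#' In unstacked mode this counts as one dataload.
#'
#' @param provider A [group_provider()].
#' @param i Subject index in 1..M.
#' @return The subject's v x p matrix.
#' @export
subject_matrix <- function(provider, i) {
  stopifnot(inherits(provider, "group_provider"))
  i <- as.integer(i)
  if (i < 1L || i > provider$M) stop("subject index out of range")
  if (provider$mode == "stacked") {
    cols <- ((i - 1L) * provider$p + 1L):(i * provider$p)
    provider$stacked[, cols, drop = FALSE]
  } else {
    provider$env$loads <- provider$env$loads + 1L
    provider$load_one(i)
  }
}

#' Dataload counter
#'
#' Number of subject reads performed so far. A stacked provider counts only
#' the `M` loads done at materialization; an unstacked provider increments
#' by one per subject access, so one full pass adds exactly `M`.
#'
#' @param provider A [group_provider()].
#' @return Integer count.
#' @export
dataloads <- function(provider) provider$env$loads

#' @rdname dataloads
#' @export
reset_dataloads <- function(provider) {
  provider$env$loads <- if (provider$mode == "stacked") provider$M else 0L
  invisible(provider)
}

#' @noRd
#' The materialized v x Mp matrix (stacked mode only, no load counted).
stacked_matrix <- function(provider) {
  if (provider$mode != "stacked") {
    stop("stacked_matrix() requires a stacked provider")
  }
  provider$stacked
}

# ---- one-pass linear-algebra primitives over the provider ----------------
# Both modes iterate subject-by-subject so stacked and unstacked runs are
# arithmetically identical; unstacked additionally pays one dataload per
# subject per pass.

#' @noRd
#' Y %*% t(t(X) %*% Y) = (Y Y^T) X as a sum of per-subject terms, one pass.
cov_apply <- function(provider, x) {
  acc <- matrix(0, nrow = provider$v, ncol = ncol(x))
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    acc <- acc + yi %*% crossprod(yi, x)
  }
  acc
}

#' @noRd
#' t(Y) %*% X, stacking per-subject row blocks, one pass.
project_time <- function(provider, x) {
  out <- matrix(0, nrow = provider$M * provider$p, ncol = ncol(x))
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    rows <- ((i - 1L) * provider$p + 1L):(i * provider$p)
    out[rows, ] <- crossprod(yi, x)
  }
  out
}

#' @noRd
#' One pass computing both (Y Y^T) X and t(Y) %*% X from the same subject
#' products, so callers that need both pay a single dataload per subject.
cov_apply_tracked <- function(provider, x) {
  chi <- matrix(0, nrow = provider$v, ncol = ncol(x))
  proj <- matrix(0, nrow = provider$M * provider$p, ncol = ncol(x))
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    fi <- crossprod(yi, x)
    rows <- ((i - 1L) * provider$p + 1L):(i * provider$p)
    proj[rows, ] <- fi
    chi <- chi + yi %*% fi
  }
  list(chi = chi, proj = proj)
}

#' @noRd
#' Y %*% F for an (Mp x c) matrix F, one pass.
expand_time <- function(provider, f) {
  acc <- matrix(0, nrow = provider$v, ncol = ncol(f))
  for (i in seq_len(provider$M)) {
    yi <- subject_matrix(provider, i)
    rows <- ((i - 1L) * provider$p + 1L):(i * provider$p)
    acc <- acc + yi %*% f[rows, , drop = FALSE]
  }
  acc
}
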