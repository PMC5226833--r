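#' Read a single-molecule trace file
#'
#' Accepts comma-, tab- or whitespace-delimited text with a header. Two
#' columns are interpreted as `(time_s, fret)`; three columns as
#' `(time_s, donor, acceptor)`, from which the FRET efficiency is computed
#' with [compute_fret()] (zero-intensity frames become `NA`). Timestamps must
#' be uniformly spaced.
#'
#' @param path file path.
#' @return List of class `"observable_trace"`: `time_s`, `fret`, `dt`, and
#'   (for 3-column input) `donor`/`acceptor`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  df <- read.csv(path, sep = sep, header = TRUE,
                 strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(df) < 2 || ncol(df) > 3)
    stop("expected 2 columns (time_s, fret) or 3 (time_s, donor, acceptor)",
         call. = FALSE)
  for (j in seq_len(ncol(df))) {
    if (!is.numeric(df[[j]]))
      stop(sprintf("non-numeric values in column '%s'", names(df)[j]),
           call. = FALSE)
  }
  time_s <- df[[1]]
  if (any(diff(time_s) <= 0))
    stop(sprintf("non-monotone time at row %d",
                 which(diff(time_s) <= 0)[1] + 1L), call. = FALSE)
  dts <- diff(time_s)
  bad <- which(abs(dts - dts[1]) > 1e-6 * max(abs(dts[1]), 1e-12))
  if (length(bad))
    stop(sprintf("non-uniform sampling interval at row %d", bad[1] + 2L),
         call. = FALSE)
  out <- list(time_s = time_s, dt = dts[1])
  if (ncol(df) == 2) {
    out$fret <- df[[2]]
  } else {
    out$donor <- df[[2]]
    out$acceptor <- df[[3]]
    out$fret <- compute_fret(df[[2]], df[[3]])
  }
  structure(out, class = "observable_trace")
}

#' @export
print.observable_trace <- function(x, ...) {
  cat(sprintf("Observable trace: %d frames at dt = %g s (%d missing)\n",
              length(x$fret), x$dt, sum(is.na(x$fret))))
  invisible(x)
}

#' Write a trace to CSV
#'
#' Writes `(time_s, fret)` columns; round-trips through [read_trace()].
#'
#' @param trace an `"observable_trace"`, a `"dcmm_trace"` from the simulator,
#'   or a list with `time_s` and `fret`/`o_n`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  fret <- if (!is.null(trace$fret)) trace$fret else trace$o_n
  df <- data.frame(time_s = trace$time_s, fret = fret)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulated ground truth to CSV
#'
#' Companion to [write_trace()] for simulated traces: writes
#' `(time_s, o, x)` with the internal path padded with `NA` at the final
#' frame (the path is one shorter than the observable trace).
#'
#' @param trace a `"dcmm_trace"`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(trace, path) {
  stopifnot(inherits(trace, "dcmm_trace"))
  df <- data.frame(time_s = trace$time_s, o = trace$o,
                   x = c(trace$x, NA))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full decoding pipeline on an ensemble of traces
#'
#' Orchestrates the three analysis stages on each trace — (i) noise filtering
#' with a Gaussian HMM, (ii) internal-state decoding with the variational
#' double-chain fit and model selection, (iii) decomposition into homogeneous
#' components — then pools components across traces, builds kinetic arrows,
#' and (when enough arrows exist) scans cluster counts for the landscape
#' connectivity. When simulated traces with ground truth are supplied, the
#' decoded paths are scored against the truth.
#'
#' Per-trace failures are caught and recorded; the pipeline continues.
#'
#' @param traces list of inputs: numeric signal vectors, `"dcmm_trace"`
#'   simulator outputs, `"observable_trace"` objects, or file paths.
#' @param N number of observable states.
#' @param K_max largest internal-state count scanned per trace.
#' @param priors a [dcmm_priors()] object.
#' @param n_restarts restarts per model fit.
#' @param min_dwell minimum component length, see [decompose_trace()].
#' @param cluster_K_range,min_cluster_size,n_init clustering settings, see
#'   [select_clusters()].
#' @param seed root integer seed.
#' @param skip_filter set `TRUE` when traces are already discrete observable
#'   sequences (skips the Gaussian-HMM stage).
#' @return List of class `"dcmm_pipeline"`: per-trace `results` (scan,
#'   decoded path, components, chi when truth is known), pooled `components`,
#'   `arrows`, `cluster_scan` (or `NULL`), `failures`, and the `seed`.
#' @export
run_pipeline <- function(traces, N = 2, K_max = 3, priors = dcmm_priors(),
                         n_restarts = 5, min_dwell = 10,
                         cluster_K_range = seq(2, 14, 2),
                         min_cluster_size = 10, n_init = 200, seed = 1,
                         skip_filter = FALSE) {
  results <- vector("list", length(traces))
  failures <- vector("list", length(traces))
  all_components <- list()
  for (i in seq_along(traces)) {
    res <- tryCatch({
      tr <- traces[[i]]
      truth <- NULL
      if (is.character(tr)) tr <- read_trace(tr)
      if (inherits(tr, "dcmm_trace")) {
        truth <- tr
        o_n <- tr$o_n
      } else if (inherits(tr, "observable_trace")) {
        o_n <- tr$fret
      } else {
        o_n <- as.numeric(tr)
      }
      if (skip_filter) {
        o <- as.integer(o_n)
        hmm <- NULL
      } else {
        ideal <- idealize_trace(o_n, N = N, seed = seed + 7L * i)
        o <- ideal$o
        hmm <- ideal$hmm
      }
      scan <- select_model(o, K_max = K_max, priors = priors,
                           n_restarts = n_restarts, seed = seed + 13L * i)
      x_hat <- scan$paths[[scan$K_star]]
      comps <- decompose_trace(o, x_hat, min_dwell = min_dwell, trace_id = i)
      chi <- NULL
      if (!is.null(truth) && length(truth$x) == length(x_hat)) {
        fit <- scan$fits[[scan$K_star]]
        chi <- if (fit$K == truth$config$K) {
          perm <- match_labels(fit$model$B, truth$config$B)
          overlap_chi(truth$x, x_hat, perm)
        } else overlap_chi(truth$x, x_hat)
      }
      list(hmm = hmm, scan = scan, K_star = scan$K_star, x_hat = x_hat,
           components = comps, chi = chi)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[i]] <- conditionMessage(res)
    } else {
      results[[i]] <- res
      all_components[[length(all_components) + 1L]] <- res$components
    }
  }
  arrows <- if (length(all_components)) kinetic_arrows(all_components) else NULL
  cluster_scan <- NULL
  if (!is.null(arrows) && nrow(arrows) >= min(cluster_K_range)) {
    cluster_scan <- tryCatch(
      select_clusters(arrows, K_range = cluster_K_range,
                      min_cluster_size = min_cluster_size, n_init = n_init,
                      seed = seed),
      error = function(e) NULL)
  }
  structure(list(results = results, failures = failures,
                 components = all_components, arrows = arrows,
                 cluster_scan = cluster_scan, seed = seed),
            class = "dcmm_pipeline")
}

#' @export
print.dcmm_pipeline <- function(x, ...) {
  ok <- sum(!vapply(x$results, is.null, logical(1)))
  cat(sprintf("Pipeline run: %d/%d traces decoded (seed %d)\n",
              ok, length(x$results), x$seed))
  ks <- vapply(x$results, function(r) if (is.null(r)) NA_integer_ else
    as.integer(r$K_star), integer(1))
  if (ok) cat("  K* per trace:", paste(ks, collapse = " "), "\n")
  chis <- unlist(lapply(x$results, `[[`, "chi"))
  if (length(chis))
    cat(sprintf("  mean overlap with truth: %.3f\n", mean(chis)))
  if (!is.null(x$arrows))
    cat(sprintf("  kinetic arrows pooled: %d\n", nrow(x$arrows)))
  if (!is.null(x$cluster_scan))
    cat(sprintf("  cluster scan K* = %s\n", x$cluster_scan$K_star))
  invisible(x)
}
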