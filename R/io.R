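# Shared I/O: trajectory CSV reading/writing and plain-text reports.

#' Read trajectories from CSV
#'
#' Reads relocation data from a CSV file with header columns `id, t, x, y`
#' (`y` optional) and returns a validated [trajectory_set()]. Rows with
#' non-numeric fields and duplicate `(id, t)` records are rejected with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "t", "x")
  if (!all(need %in% names(raw)))
    stop("trajectory CSV must have header columns id,t,x[,y]; found: ",
         paste(names(raw), collapse = ","))
  has_y <- "y" %in% names(raw)
  cols <- c("t", "x", if (has_y) "y")
  bad <- rep(FALSE, nrow(raw))
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- bad | is.na(v)
    raw[[cl]] <- v
  }
  if (any(bad))
    stop("malformed rows (non-numeric fields) at line(s): ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "))
  key <- paste(raw$id, raw$t, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (id, t) records at line(s): ",
         paste(utils::head(which(dup) + 1L, 10), collapse = ", "))
  trajectory_set(raw[c("id", "t", "x", if (has_y) "y")])
}

#' Write trajectories to CSV
#'
#' @param traj a [trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a plain-text analysis report
#'
#' Writes a human-readable header followed by a machine-readable
#' `key = value` section at full numeric precision. Values are flattened
#' from (possibly nested) named lists and classed results (anything with a
#' [coef()] method contributes its coefficients). Re-running with the same
#' inputs produces a byte-identical machine-readable section.
#'
#' @param results named list of results, or a single classed result object.
#' @param path output file path.
#' @param title report title line.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, title = "territoria report") {
  kv <- .flatten_results(results)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste("#", title),
               paste("# fields:", length(kv)),
               "# --- machine-readable ---"), con)
  if (length(kv))
    writeLines(paste0(names(kv), " = ",
                      vapply(kv, function(v)
                        format(v, digits = 17, scientific = FALSE,
                               trim = TRUE), character(1))), con)
  invisible(path)
}

.flatten_results <- function(x, prefix = "") {
  if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
  if (!is.list(x) || inherits(x, "data.frame")) {
    if (inherits(x, "data.frame")) {
      out <- list()
      for (cl in names(x)) if (is.numeric(x[[cl]]))
        out[[cl]] <- stats::setNames(x[[cl]],
                                     paste0(prefix, cl, ".", seq_len(nrow(x))))
      v <- unlist(out, use.names = TRUE)
      names(v) <- sub("^[^.]*\\.", "", names(v))
      if (length(out)) names(v) <- unlist(lapply(out, names))
      return(v)
    }
    v <- suppressWarnings(as.numeric(x))
    v <- v[!is.na(v)]
    if (!length(v)) return(stats::setNames(numeric(0), character(0)))
    nm <- if (length(v) == 1L) prefix else paste0(prefix, ".", seq_along(v))
    return(stats::setNames(v, nm))
  }
  # classed objects with coefficients contribute those
  if (!is.null(attr(class(x), "package")) ||
      inherits(x, c("homerange_estimate", "likelihood_fit", "ss_fit",
                    "hurst_estimate"))) {
    cf <- tryCatch(stats::coef(x), error = function(e) NULL)
    if (!is.null(cf))
      return(stats::setNames(as.numeric(cf),
                             paste0(prefix, if (nzchar(prefix)) ".", names(cf))))
  }
  out <- numeric(0)
  nms <- names(x)
  if (is.null(nms)) nms <- as.character(seq_along(x))
  for (k in seq_along(x)) {
    p2 <- if (nzchar(prefix)) paste0(prefix, ".", nms[k]) else nms[k]
    out <- c(out, .flatten_results(x[[k]], p2))
  }
  out
}
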