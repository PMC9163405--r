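#' Read and write network time courses as TSV
#'
#' Time courses are stored one subject per file: a header row of network
#' labels, one row per timepoint, tab-separated, UTF-8, '.' decimal.
#' `read_timecourses` checks for ragged rows, non-numeric cells and (when
#' `expected_labels` is given) label mismatches; it never reorders
#' columns silently.
#'
#' @param tc a [timecourse()].
#' @param path file path.
#' @export
write_timecourses <- function(tc, path) {
  write.table(tc$data, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_timecourses
#' @param tr repetition time in seconds to attach.
#' @param subject_id subject id to attach (default: file stem).
#' @param expected_labels optional label vector that the header must equal
#'   in the same order.
#' @export
read_timecourses <- function(path, tr = 2, subject_id = NULL,
                             expected_labels = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  mat <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw))))
  if (any(is.na(mat))) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop_dynfc("%s: non-numeric or missing cell at row %d, column '%s'",
               path, bad[1], colnames(raw)[bad[2]])
  }
  if (!is.null(expected_labels) &&
      !identical(colnames(raw), expected_labels))
    stop_dynfc("%s: network labels (%s) do not match expected order (%s)",
               path, paste(colnames(raw), collapse = ","),
               paste(expected_labels, collapse = ","))
  timecourse(mat, colnames(raw), tr = tr, subject_id = subject_id)
}

#' Read and write the per-subject covariate table as CSV
#' @param covariates data frame with one row per subject.
#' @param path file path.
#' @export
write_covariates <- function(covariates, path) {
  write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read simulation ground truth as JSON
#'
#' Stores, per subject, the per-timepoint hidden-state sequence, the
#' switch count, the occupancy vector and the group label.
#'
#' @param truths list of ground-truth lists from [simulate_cohort()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truths, path) {
  out <- lapply(truths, function(tr)
    list(group = tr$group, state_sequence = tr$state_sequence,
         n_switches = tr$n_switches, occupancy = tr$occupancy))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Build a generator spec from a scenario file
#'
#' Reads a flat YAML scenario (scalar fields of [synth_spec()]:
#' `n_networks`, `n_timepoints`, `tr`, `k_states`, `noise_sd`,
#' `ar_coeff`, `seed`, and optionally `weights`, the base occupancy
#' weights of the default transition matrices). Unknown keys are
#' rejected. Fields not present keep the package defaults.
#'
#' @param path YAML file path.
#' @return a [synth_spec()].
#' @export
synth_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_networks", "n_timepoints", "tr", "k_states", "noise_sd",
             "ar_coeff", "seed", "weights")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_dynfc("scenario %s: unknown key(s): %s", path,
               paste(unknown, collapse = ", "))
  args <- cfg[setdiff(names(cfg), "weights")]
  if (!is.null(cfg$weights)) {
    args$transition_matrix_per_group <-
      default_transition_matrices(length(cfg$weights), cfg$weights)
    args$initial_distribution <- cfg$weights
  }
  do.call(synth_spec, args)
}

#' Write a windowed FC stack as TSV plus a JSON sidecar
#'
#' The TSV holds the windows x edges z-values with "label_label" headers;
#' the sidecar records the subject, window centers, selected penalty and
#' the edge-index map.
#'
#' @param stack an `fc_stack`.
#' @param path TSV path (the sidecar is `path` with `.json` appended).
#' @export
write_fc_stack <- function(stack, path) {
  write.table(stack$edge_values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  side <- list(subject_id = stack$subject_id,
               n_windows = stack$n_windows,
               window_centers = stack$window_centers,
               penalty = stack$penalty,
               network_labels = stack$network_labels,
               edge_i = stack$edge_index[, 1],
               edge_j = stack$edge_index[, 2])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fc_stack
#' @export
read_fc_stack <- function(path) {
  Z <- as.matrix(read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(subject_id = side$subject_id, edge_values = Z,
                 edge_index = cbind(i = side$edge_i, j = side$edge_j),
                 window_centers = side$window_centers,
                 n_windows = side$n_windows, penalty = side$penalty,
                 network_labels = side$network_labels),
            class = "fc_stack")
}

#' Write state-model outputs
#'
#' Centroids as k x E TSV, assignments as (subject, window, state) TSV,
#' and per-subject temporal metrics as CSV.
#'
#' @param model a `state_model`.
#' @param subject_ids subject id per window (same length as assignments).
#' @param dir output directory.
#' @export
write_state_model <- function(model, subject_ids, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(model$centroids, file.path(dir, "centroids.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  windows <- unlist(lapply(rle(subject_ids)$lengths, seq_len))
  write.table(data.frame(subject = subject_ids, window = windows,
                         state = model$assignments),
              file.path(dir, "assignments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(k = model$k, objective = model$objective,
                            replicate_seeds = model$replicate_seeds),
                       file.path(dir, "state_model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write per-subject temporal metrics as CSV
#' @param metrics list of [temporal_metrics()] per subject.
#' @param subject_ids subject identifiers.
#' @param path CSV path.
#' @export
write_temporal_metrics <- function(metrics, subject_ids, path) {
  k <- length(metrics[[1]]$fractional_windows)
  rows <- lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    row <- c(list(subject = subject_ids[i]),
             setNames(as.list(m$fractional_windows),
                      paste0("frac_state", seq_len(k))),
             setNames(as.list(m$mean_dwell),
                      paste0("dwell_state", seq_len(k))),
             list(n_transitions = m$n_transitions))
    as.data.frame(row)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
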