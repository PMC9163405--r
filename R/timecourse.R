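#' Network time-course container
#'
#' One subject's (post-ICA) network signals: a timepoints x networks matrix
#' with network labels and the repetition time. This is the unit every
#' preprocessing and windowed-FC operation works on.
#'
#' @param data numeric matrix, timepoints x networks.
#' @param network_labels character vector, one label per column.
#' @param tr repetition time in seconds.
#' @param subject_id subject identifier.
#' @return an object of class `timecourse`.
#' @export
timecourse <- function(data, network_labels = colnames(data), tr = 2,
                       subject_id = "subj") {
  data <- as.matrix(data)
  if (is.null(network_labels))
    network_labels <- paste0("N", seq_len(ncol(data)))
  if (length(network_labels) != ncol(data))
    stop_dynfc("timecourse: %d labels for %d columns",
               length(network_labels), ncol(data))
  if (nrow(data) < 2) stop_dynfc("timecourse: need at least 2 timepoints")
  if (!all(is.finite(data))) stop_dynfc("timecourse: non-finite values")
  if (!is.numeric(tr) || tr <= 0) stop_dynfc("timecourse: bad tr")
  colnames(data) <- network_labels
  structure(list(subject_id = subject_id,
                 network_labels = network_labels,
                 data = data, tr = tr),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %s: %d timepoints x %d networks, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' @export
dim.timecourse <- function(x) dim(x$data)

# rebuild a timecourse with new data, keeping metadata
tc_replace <- function(tc, data) {
  tc$data <- data
  colnames(tc$data) <- tc$network_labels
  tc
}
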