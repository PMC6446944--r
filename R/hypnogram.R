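#' Hypnogram: per-epoch sleep stage labels
#'
#' Stage labels in 30-s (or other fixed-length) epochs, optionally carrying
#' the classifier's per-class probability matrix. Labels come from the
#' five-stage vocabulary W/N1/N2/N3/REM, or from \{W, S\} for collapsed
#' sleep-wake scoring.
#'
#' @param labels Character vector of stage labels.
#' @param epoch_s Epoch length in seconds (default 30).
#' @param probabilities Optional epochs x classes matrix; rows must sum
#'   to 1 and columns must be named with the stage vocabulary.
#' @param forced_wake Optional logical vector flagging epochs scored W
#'   because every feature was missing (fully rejected epochs).
#' @return An object of class `"hypnogram"`.
#' @examples
#' h <- hypnogram(c("W", "W", "N2", "N2", "REM"))
#' table(h$labels)
#' @export
hypnogram <- function(labels, epoch_s = 30, probabilities = NULL,
                      forced_wake = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stopf("hypnogram must have at least one epoch")
  vocab <- union(sleep_stages(), "S")
  bad <- setdiff(unique(labels), vocab)
  if (length(bad))
    stopf("unknown stage label(s): %s", paste(bad, collapse = ", "))
  if (!is.null(probabilities)) {
    probabilities <- as.matrix(probabilities)
    if (nrow(probabilities) != length(labels))
      stopf("probability matrix must have one row per epoch")
    if (is.null(colnames(probabilities)))
      stopf("probability matrix needs stage column names")
    rs <- rowSums(probabilities)
    if (any(abs(rs - 1) > 1e-8))
      stopf("probability rows must sum to 1")
  }
  if (!is.null(forced_wake) && length(forced_wake) != length(labels))
    stopf("forced_wake must have one flag per epoch")
  structure(list(labels = labels, epoch_s = epoch_s,
                 probabilities = probabilities,
                 forced_wake = forced_wake %||% rep(FALSE, length(labels))),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<hypnogram> %d epochs x %gs (%.1f min)\n", n, x$epoch_s,
              n * x$epoch_s / 60))
  tab <- table(factor(x$labels, levels = intersect(
    union(sleep_stages(), "S"), unique(x$labels))))
  cat(" ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  if (!is.null(x$probabilities)) cat("  with class probabilities\n")
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Collapse a five-stage hypnogram to sleep-wake
#'
#' All non-W stages map to "S"; used for two-stage agreement metrics and
#' for comparison against actigraphy.
#' @param h A `hypnogram`.
#' @return A `hypnogram` over \{W, S\}.
#' @export
collapse_sleep_wake <- function(h) {
  hypnogram(ifelse(h$labels == "W", "W", "S"), epoch_s = h$epoch_s,
            forced_wake = h$forced_wake)
}

is_sleep <- function(labels) labels != "W"

#' Read / write hypnogram CSV
#'
#' Plain two-column CSV `epoch_index,stage` (1-based epoch index).
#' @param h A `hypnogram`.
#' @param path File path.
#' @param epoch_s Epoch length in seconds when reading.
#' @return `read_hypnogram` returns a `hypnogram`; `write_hypnogram`
#'   returns `path` invisibly.
#' @export
write_hypnogram <- function(h, path) {
  utils::write.csv(data.frame(epoch_index = seq_along(h$labels),
                              stage = h$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, epoch_s = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df)))
    stopf("hypnogram CSV needs columns epoch_index,stage")
  hypnogram(df$stage[order(df$epoch_index)], epoch_s = epoch_s)
}
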