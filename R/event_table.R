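#' Per-sample flow-cytometry event table
#'
#' Container for the events acquired on one sample: a data frame of
#' per-event fluorescence intensities (one column per channel, arbitrary
#' units, nonnegative) plus the sample metadata the downstream analysis
#' needs (group, tissue, mouse, tissue mass, control role).
#'
#' @param channels data frame or named list of equal-length numeric vectors
#'   of per-event intensities (e.g. `GFP`, `Ki67`, `aCasp3`, `PI`).
#' @param sample_id character scalar identifying the sample.
#' @param tissue one of `"lung"`, `"implant"`, `"primary-tumor"`, `"control"`.
#' @param group group label (treatment arm), or `NA`.
#' @param role one of `"experimental"`, `"FMO-control"`, `"biological-control"`.
#' @param mass tissue mass in mg, or `NA` when not recorded.
#'
#' @return An object of class `event_table`: a list with elements
#'   `channels` (data frame), `sample_id`, `tissue`, `group`, `role`, `mass`.
#' @examples
#' et <- event_table(data.frame(GFP = rlnorm(100)), "s1")
#' n_events(et)
#' @export
event_table <- function(channels, sample_id,
                        tissue = c("lung", "implant", "primary-tumor", "control"),
                        group = NA_character_,
                        role = c("experimental", "FMO-control", "biological-control"),
                        mass = NA_real_) {
  tissue <- match.arg(tissue)
  role <- match.arg(role)
  channels <- as.data.frame(channels)
  if (ncol(channels) < 1L || nrow(channels) < 1L)
    stop("event_table: 'channels' must contain at least one channel and one event")
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("event_table: channel '", ch, "' must be finite numeric")
  }
  structure(
    list(channels = channels, sample_id = as.character(sample_id),
         tissue = tissue, group = group, role = role, mass = mass),
    class = "event_table"
  )
}

#' @rdname event_table
#' @param x an `event_table`.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_table"))
  nrow(x$channels)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %s  [%s, %s, %s]  %d events, channels: %s\n",
              x$sample_id, x$group, x$tissue, x$role, n_events(x),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

channel_values <- function(x, channel) {
  stopifnot(inherits(x, "event_table"))
  if (!channel %in% names(x$channels))
    stop("channel '", channel, "' not present in sample '", x$sample_id, "'")
  x$channels[[channel]]
}

#' Write / read event tables as CSV
#'
#' One row per event, one column per channel; metadata carried in a
#' commented header so a round trip preserves the object.
#'
#' @param x an `event_table`.
#' @param path file path.
#' @return `read_event_csv` returns an `event_table`; `write_event_csv`
#'   returns `path` invisibly.
#' @export
write_event_csv <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s tissue=%s group=%s role=%s mass=%s",
                     x$sample_id, x$tissue, x$group, x$role,
                     format(x$mass)), con)
  utils::write.csv(x$channels, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- c(sample_id = "sample", tissue = "control", group = NA_character_,
            role = "experimental", mass = NA_character_)
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[^ ]+", hdr))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      meta[parts[1]] <- parts[2]
    }
  }
  channels <- utils::read.csv(path, comment.char = "#")
  event_table(channels,
              sample_id = meta[["sample_id"]],
              tissue = meta[["tissue"]],
              group = if (identical(meta[["group"]], "NA")) NA_character_ else meta[["group"]],
              role = meta[["role"]],
              mass = suppressWarnings(as.numeric(meta[["mass"]])))
}
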