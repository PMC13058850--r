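#' Write a trajectory's events to a BIDS-style TSV
#'
#' Tab-separated, header row, `onset` and `duration` in seconds with a "."
#' decimal separator. The mandatory columns `onset`, `duration`,
#' `trial_type`, `direction` come first; any further columns (e.g. the
#' positions recorded by [generate_trajectory()]) are written after them and
#' survive a round trip through [read_events()].
#'
#' @param trajectory a `trajectory` object or an events data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(trajectory, path) {
  ev <- if (inherits(trajectory, "trajectory")) trajectory$events else trajectory
  required <- c("onset", "duration", "trial_type", "direction")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("events table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  ev <- ev[, c(required, setdiff(names(ev), required)), drop = FALSE]
  num <- vapply(ev, is.numeric, logical(1))
  ev[num] <- lapply(ev[num], function(x) {
    ifelse(is.na(x), "n/a", formatC(x, format = "g", digits = 17))
  })
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' Tolerant reader: mandatory columns are validated, unknown columns are
#' preserved untouched. `n/a` encodes missing values.
#'
#' @param path TSV file path.
#' @return events data frame with `onset`, `duration`, `trial_type`,
#'   `direction` plus any extra columns in file order.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("onset", "duration", "trial_type", "direction")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("events file ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("onset", "duration", "direction"))
    ev[[col]] <- as.numeric(ev[[col]])
  if (is.unsorted(ev$onset))
    stop("non-monotone onsets in ", path, ": first offending row ",
         which(diff(ev$onset) < 0)[1] + 1L)
  bad <- which(ev$trial_type == "translation" & !is.finite(ev$direction))
  if (length(bad))
    stop("translation row(s) missing direction in ", path, ": row ",
         paste(bad, collapse = ", "))
  ev
}
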