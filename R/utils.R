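# internal validation helpers

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, min = -Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x)))
    stop_param(sprintf("'%s' must be a single numeric value", name))
  if (!is.na(x) && x < min)
    stop_param(sprintf("'%s' must be >= %g (got %g)", name, min, x))
  invisible(x)
}

#' Normalise exclusion intervals
#'
#' Sorts half-open `[start, end)` intervals and merges overlaps, so that
#' downstream masking logic can assume pairwise-disjoint, ordered intervals.
#'
#' @param exclusions a two-column matrix or data frame of `start`, `end`
#'   times in seconds, or `NULL` for none.
#' @return a matrix with columns `start`, `end` (possibly zero rows).
#' @keywords internal
normalize_exclusions <- function(exclusions) {
  if (is.null(exclusions) || NROW(exclusions) == 0L)
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  m <- as.matrix(exclusions)[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop_param("exclusion intervals must be finite")
  if (any(m[, 2L] <= m[, 1L]))
    stop_param("exclusion intervals must have end > start")
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1L] <= out[k, 2L]) {
        out[k, 2L] <- max(out[k, 2L], m[i, 2L])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

# TRUE for points falling inside any [start, end) interval
in_exclusion <- function(t, excl) {
  if (nrow(excl) == 0L) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (i in seq_len(nrow(excl)))
    hit <- hit | (t >= excl[i, 1L] & t < excl[i, 2L])
  hit
}

# TRUE when the open span (a, b) intersects any exclusion interval
span_intersects <- function(a, b, excl) {
  if (nrow(excl) == 0L) return(rep(FALSE, length(a)))
  hit <- rep(FALSE, length(a))
  for (i in seq_len(nrow(excl)))
    hit <- hit | (a < excl[i, 2L] & b > excl[i, 1L])
  hit
}

#' Read an exclusion-interval CSV
#'
#' Expects a header `start_s,end_s`; intervals mark periods (valve motion,
#' waste excretion, compromised detection) to drop from beat and IBI
#' analysis.
#'
#' @param path path to a CSV file.
#' @return normalised interval matrix (see [normalize_exclusions()]).
#' @export
load_exclusions <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(df)))
    stop_param("exclusions CSV must have columns 'start_s' and 'end_s'")
  normalize_exclusions(df[, c("start_s", "end_s")])
}
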