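#' Nested metric template
#'
#' A metric template is a set of nested isochronous pulses laid over a cyclic
#' grid of events. Each pulse is given by its period in events (e.g. periods
#' 2, 4 and 12 on a 12-event grid describe a meter with pulses every 400 ms,
#' 800 ms and 2.4 s at a 5 Hz event rate). The template induces one integer
#' weight per grid position: position 0 (shared by all pulses) has the maximal
#' weight 0, and every position is penalised by one unit for each pulse level
#' (counted from the slowest) whose grid does not contain it. For periods
#' \{2, 4, 12\} the weights are
#' `0 -3 -2 -3 -1 -3 -2 -3 -1 -3 -2 -3`.
#'
#' @param periods integer vector of pulse periods in events. Periods must be
#'   strictly nested: sorted ascending, each must divide the next, and the
#'   largest must divide `cycle`.
#' @param cycle length of the cyclic grid in events. Defaults to the least
#'   common multiple requirement, i.e. the largest period.
#' @return an object of class `metric_template` with fields `periods`,
#'   `cycle` and `weights` (length-`cycle` integer vector).
#' @examples
#' metric_template(c(2, 4, 12))
#' metric_template(c(2, 4), cycle = 4)
#' @export
metric_template <- function(periods, cycle = max(periods)) {
  periods <- sort(as.integer(periods))
  if (length(periods) < 1L) stop("at least one pulse period is required")
  if (any(periods < 1L)) stop("pulse periods must be positive")
  cycle <- as.integer(cycle)
  if (cycle %% periods[length(periods)] != 0L)
    stop("every period must divide the cycle")
  if (length(periods) > 1L) {
    ratio <- periods[-1L] %% periods[-length(periods)]
    if (any(ratio != 0L))
      stop("periods must be strictly nested (each must divide the next)")
  }
  pos <- seq_len(cycle) - 1L
  # one penalty unit per pulse level (slowest first) missing the position
  weights <- -vapply(pos, function(p) sum(p %% periods != 0L), integer(1))
  structure(
    list(periods = periods, cycle = cycle, weights = weights),
    class = "metric_template"
  )
}

#' @export
print.metric_template <- function(x, ...) {
  cat("Metric template: pulses every {", paste(x$periods, collapse = ", "),
      "} events on a ", x$cycle, "-event cycle\n", sep = "")
  cat("Weights:", x$weights, "\n")
  invisible(x)
}

#' Template label such as "{2,4}"
#' @param template a [metric_template()]
#' @return character scalar
#' @export
template_label <- function(template) {
  paste0("{", paste(template$periods, collapse = ","), "}")
}
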