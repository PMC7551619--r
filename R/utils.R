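#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats lm coef qt plogis rbinom rnorm runif sd t.test uniroot vcov setNames
NULL

# geometric mean via mean of base-10 logs; all thresholds in this package live
# on the log10(ng/L) scale
geomean <- function(x) 10^mean(log10(x))

stop_domain <- function(msg, ...) {
  abort(msg, class = "threshpanel_domain_error", ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = "threshpanel_schema_error", ...)
}

stop_integrity <- function(msg, ...) {
  abort(msg, class = "threshpanel_integrity_error", ...)
}

stop_insufficient <- function(msg, ...) {
  abort(msg, class = "threshpanel_insufficient_data_error", ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
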