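#' End-to-end detection-threshold analysis for a two-condition study
#'
#' Runs the full detection-threshold chain on two discrimination
#' datasets (e.g. orthonasal and retronasal delivery): per-panelist BETs
#' under the modified ASTM rule, group geometric-mean summaries, the
#' graphical group threshold fitted on the responder subset of each
#' condition, and the pooled t-test comparing the two conditions on
#' logged responder BETs.
#'
#' @param data_a,data_b Discrimination datasets for the two conditions.
#' @param conditions Length-2 character vector of condition labels.
#' @param chance Guessing rate of the task (1/3 triangle).
#' @param criterion Proportion-correct criterion for the graphical fits;
#'   defaults to [criterion_for()] of `chance`.
#' @param conf_level Confidence level for graphical bounds.
#' @return An object of class `study_report`: per-condition `bets`,
#'   `summary` and `graphical` blocks, the `comparison` row, and a
#'   `provenance` block (input hashes, parameters, package version).
#' @export
run_study1 <- function(data_a, data_b,
                       conditions = c("orthonasal", "retronasal"),
                       chance = 1 / 3,
                       criterion = criterion_for(chance),
                       conf_level = 0.95) {
  stopifnot(length(conditions) == 2)
  run_condition <- function(data, label) {
    data <- as_discrimination_data(data, series = attr(data, "series"))
    bets <- withCallingHandlers(
      estimate_bets(data),
      error = function(e) abort(paste0("condition '", label, "': ",
                                       conditionMessage(e)), parent = e)
    )
    responders <- bets$panelist[bets$responder]
    fit <- if (length(responders) > 0) {
      fit_graphical(data, include = responders, criterion = criterion,
                    chance = chance, conf_level = conf_level)
    } else {
      NULL
    }
    list(condition = label, bets = bets, summary = summarize_bets(bets),
         graphical = fit, input_hash = rlang::hash(as.data.frame(data)))
  }
  a <- run_condition(data_a, conditions[1])
  b <- run_condition(data_b, conditions[2])
  comparison <- tryCatch(
    compare_log_bets(a$bets, b$bets),
    threshpanel_insufficient_data_error = function(e) NULL
  )
  structure(
    list(
      conditions = stats::setNames(list(a, b), conditions),
      comparison = comparison,
      provenance = list(
        input_hashes = stats::setNames(c(a$input_hash, b$input_hash), conditions),
        chance = chance, criterion = criterion, conf_level = conf_level,
        package_version = as.character(utils::packageVersion("threshpanel"))
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in names(x$conditions)) {
    cond <- x$conditions[[nm]]
    cat("\n== condition:", nm, "==\n")
    print(cond$summary)
    if (!is.null(cond$graphical)) print(cond$graphical)
  }
  if (!is.null(x$comparison)) {
    cat("\n== comparison on logged responder BETs ==\n")
    print(x$comparison)
  }
  invisible(x)
}

#' Histogram bins of attainable BET values
#'
#' Under the ladder-based decision rules a BET can only take a small set
#' of values: the geometric-mean midpoints of adjacent ladder levels
#' (shared by the standard and adaptation branches), the below-range
#' midpoint (lowest level and the hypothetical level below), and the
#' imputed non-responder value (top level and the theoretical level
#' above). `bet_histogram()` bins a set of BETs over exactly these
#' attainable values; counts always sum to the panel size. Imputed BETs
#' appear here for display even though they are excluded from all
#' summary statistics.
#'
#' @param bets BET tibble from [estimate_bets()].
#' @param series The [concentration_series()] the BETs were computed on.
#' @return A tibble: `bet_value` (ng/L, ascending), `kind`
#'   (`below-range`, `midpoint`, `imputed`), `count`.
#' @export
bet_histogram <- function(bets, series) {
  if (nrow(bets) == 0) stop_insufficient("no BETs to bin")
  series <- as_concentration_series(series)
  lv <- as.numeric(series)
  n <- length(lv)
  values <- c(
    geomean(c(extend_series(series, "below"), lv[1])),
    sqrt(lv[-n] * lv[-1]),
    geomean(c(lv[n], extend_series(series, "above")))
  )
  bins <- tibble(
    bet_value = values,
    kind = c("below-range", rep("midpoint", n - 1), "imputed")
  )
  idx <- vapply(bets$bet, function(b) {
    hit <- which(abs(log10(b) - log10(bins$bet_value)) < 1e-8)
    if (length(hit) != 1) {
      stop_integrity(paste0("BET ", b, " ng/L is not an attainable value on ",
                            "this ladder"))
    }
    hit
  }, integer(1))
  bins$count <- tabulate(idx, nbins = nrow(bins))
  bins
}

#' Write a study report as stable JSON
#'
#' Serialises a `study_report` (or any report-shaped list) to JSON with
#' fixed key order and full floating-point precision, so regenerating the
#' report from identical inputs produces a byte-identical file.
#'
#' @param report A `study_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  cond_block <- function(cond) {
    list(
      condition = cond$condition,
      summary = as.list(cond$summary),
      graphical = if (!is.null(cond$graphical))
        as.list(glance(cond$graphical)) else NULL,
      bets = cond$bets
    )
  }
  payload <- list(
    conditions = lapply(report$conditions, cond_block),
    comparison = if (!is.null(report$comparison))
      as.list(report$comparison) else NULL,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
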