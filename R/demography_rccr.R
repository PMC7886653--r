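#' Relative cross-coalescence rate series
#'
#' Ordered time segments with left/right boundaries (scaled coalescent units
#' or generations) and an RCCR value per segment. RCCR near 1 means the two
#' populations coalesce freely (one population); a decline toward 0 marks
#' their separation.
#'
#' @param segments tibble with `left_time_boundary`, `right_time_boundary`,
#'   `rccr` and optionally `index`.
#' @param units `"generations"` or `"scaled"` (coalescent units; see
#'   [scale_times()]).
#' @param orientation `"past_to_present"` (required by the decision rule) or
#'   `"present_to_past"`.
#' @return An `rccr_series` tibble.
#' @export
rccr_series <- function(segments, units = c("generations", "scaled"),
                        orientation = c("past_to_present", "present_to_past")) {
  segments <- tibble::as_tibble(segments)
  need <- c("left_time_boundary", "right_time_boundary", "rccr")
  if (!all(need %in% names(segments))) abort_input("missing RCCR segment columns")
  if (any(!is.finite(segments$rccr))) abort_input("rccr values must be finite")
  if (!"index" %in% names(segments)) segments$index <- seq_len(nrow(segments)) - 1L
  attr(segments, "units") <- match.arg(units)
  attr(segments, "orientation") <- match.arg(orientation)
  class(segments) <- c("rccr_series", class(segments))
  segments
}

#' Detect population-separation onset in an RCCR series
#'
#' Walking past to present, a separation candidate is a qualifying decline -
#' a single step, a run of contiguous declining steps, or two declining steps
#' separated by one other step - whose summed decline exceeds `decline_min`,
#' with every following step difference at most `near_zero_max` until the
#' series end or the next candidate. When another qualifying decline begins
#' within `lookahead` segments of a candidate, the later one is taken as the
#' separation start.
#'
#' @param series an [rccr_series()] oriented past to present, in generations.
#' @param decline_min minimum summed decline of a candidate.
#' @param near_zero_max plateau tolerance on subsequent step differences.
#' @param lookahead segments within which a later decline supersedes.
#' @param smooth optional odd window for a running-mean smooth (default 1 =
#'   raw values).
#' @return One-row tibble (`segment`, `index`, `generation`, `decline`) or a
#'   zero-row tibble when no separation is detected.
#' @export
detect_separation <- function(series, decline_min = 0.01, near_zero_max = 0.009,
                              lookahead = 5L, smooth = 1L) {
  stopifnot(inherits(series, "rccr_series"))
  if (attr(series, "orientation") != "past_to_present")
    rlang::abort("series must be oriented past to present", class = "polyadapt_orientation_error")
  n <- nrow(series)
  if (n < 3) abort_input("need >= 3 segments")
  r <- series$rccr
  if (smooth > 1L) r <- stats::filter(r, rep(1 / smooth, smooth), sides = 2) |>
      as.numeric() |> (\(x) ifelse(is.na(x), series$rccr, x))()
  dec <- r[-n] - r[-1L]                 # decline at step into segment j+1
  active <- dec > near_zero_max
  # group actives: contiguous, or separated by exactly one inactive step
  grp <- integer(n - 1L); cur <- 0L; last_active <- -10L
  for (j in seq_len(n - 1L)) {
    if (active[j]) {
      if (j - last_active > 2L) cur <- cur + 1L
      grp[j] <- cur; last_active <- j
    }
  }
  cands <- NULL
  if (cur > 0L) {
    cands <- purrr::map_dfr(seq_len(cur), function(g) {
      js <- which(grp == g)
      tibble::tibble(start_step = js[1L], end_step = js[length(js)],
                     decline = sum(dec[js]))
    }) |> dplyr::filter(.data$decline > decline_min)
  }
  if (is.null(cands) || nrow(cands) == 0)
    return(tibble::tibble(segment = integer(), index = integer(),
                          generation = numeric(), decline = numeric()))
  # plateau: after a candidate, steps stay <= near_zero_max until next candidate
  plateau_ok <- vapply(seq_len(nrow(cands)), function(i) {
    from <- cands$end_step[i] + 1L
    to <- if (i < nrow(cands)) cands$start_step[i + 1L] - 1L else n - 1L
    if (from > to) TRUE else all(dec[from:to] <= near_zero_max)
  }, logical(1))
  cands <- cands[plateau_ok, ]
  if (nrow(cands) == 0)
    return(tibble::tibble(segment = integer(), index = integer(),
                          generation = numeric(), decline = numeric()))
  # later-decline override within the lookahead window
  pick <- 1L
  while (pick < nrow(cands) &&
         cands$start_step[pick + 1L] - cands$start_step[pick] <= lookahead)
    pick <- pick + 1L
  seg <- cands$start_step[pick] + 1L     # present-side segment of the step
  tibble::tibble(segment = seg, index = series$index[seg],
                 generation = series$left_time_boundary[seg],
                 decline = cands$decline[pick])
}

#' Convert generations to calendar time
#'
#' @param g generations (vectorized).
#' @param gen_time generation time in years.
#' @return tibble `generations`, `gen_time`, `years`, `ma` (rounded to one
#'   decimal), `ka` (nearest integer).
#' @export
generations_to_years <- function(g, gen_time) {
  if (any(g < 0) || any(gen_time <= 0)) abort_param("g >= 0 and gen_time > 0 required")
  years <- g * gen_time
  tibble::tibble(generations = g, gen_time = gen_time, years = years,
                 ma = round(years / 1e6, 1), ka = round(years / 1e3))
}

#' Rescale an RCCR series from coalescent units to generations
#'
#' Standard MSMC scaling: `t_generations = t_scaled / mu`. A series already
#' in generations is returned unchanged.
#'
#' @param series an [rccr_series()].
#' @param mu per-site per-generation mutation rate (default 6.5e-8).
#' @return The series in generations.
#' @export
scale_times <- function(series, mu = 6.5e-8) {
  stopifnot(inherits(series, "rccr_series"))
  if (mu <= 0) abort_param("mu must be > 0")
  if (attr(series, "units") == "generations") return(series)
  series$left_time_boundary <- series$left_time_boundary / mu
  series$right_time_boundary <- series$right_time_boundary / mu
  attr(series, "units") <- "generations"
  series
}

#' Read MSMC-style combined cross-coalescence output
#'
#' Expects the columns `time_index`, `left_time_boundary`,
#' `right_time_boundary`, `lambda_00`, `lambda_01`, `lambda_11`; computes
#' `rccr = 2 lambda_01 / (lambda_00 + lambda_11)`. MSMC rows run present to
#' past; the returned series is reordered past to present.
#'
#' @param path TSV file path.
#' @param units time units of the file (default scaled coalescent units).
#' @return An [rccr_series()].
#' @export
read_rccr_msmc <- function(path, units = "scaled") {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("time_index", "left_time_boundary", "right_time_boundary",
            "lambda_00", "lambda_01", "lambda_11")
  if (!all(need %in% names(d))) abort_input("not an MSMC-style combined file")
  d$rccr <- 2 * d$lambda_01 / (d$lambda_00 + d$lambda_11)
  d <- d[order(-d$left_time_boundary), ]
  rccr_series(tibble::tibble(index = d$time_index,
                             left_time_boundary = d$left_time_boundary,
                             right_time_boundary = d$right_time_boundary,
                             rccr = d$rccr),
              units = units, orientation = "past_to_present")
}
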