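#' Analytical eco-scale score
#'
#' The eco-scale starts at 100 points and subtracts penalty points for
#' reagents, instrument energy, occupational hazard and waste.  Ratings:
#' 100 is ideal; above 75 excellent; 50 to 75 acceptable; below 50
#' inadequate.
#'
#' @param items Penalty ledger: a data frame with columns `label`,
#'   `category` (one of reagent, instrument_energy, occupational_hazard,
#'   waste) and `penalty_points` (non-negative), or a list of such
#'   records.
#' @return Object of class `eco_scale`: `items`, `total_pp`, `score`,
#'   `rating`.
#' @export
#' @examples
#' eco_scale(data.frame(label = c("methanol", "waste"),
#'                      category = c("reagent", "waste"),
#'                      penalty_points = c(6, 1)))
eco_scale <- function(items = NULL) {
  categories <- c("reagent", "instrument_energy", "occupational_hazard", "waste")
  if (is.null(items)) {
    items <- data.frame(label = character(), category = character(),
                        penalty_points = numeric())
  }
  if (!is.data.frame(items)) {
    items <- do.call(rbind, lapply(items, function(it)
      data.frame(label = it$label, category = it$category,
                 penalty_points = it$penalty_points)))
    if (is.null(items))
      items <- data.frame(label = character(), category = character(),
                          penalty_points = numeric())
  }
  if (nrow(items)) {
    if (any(!items$category %in% categories))
      stop("category must be one of: ", paste(categories, collapse = ", "))
    if (any(items$penalty_points < 0)) stop("penalty points must be non-negative")
  }
  total <- sum(items$penalty_points)
  if (total > 100) stop("total penalty points exceed 100")
  score <- 100 - total
  rating <- if (score == 100) "ideal"
            else if (score > 75) "excellent"
            else if (score >= 50) "acceptable"
            else "inadequate"
  structure(list(items = items, total_pp = total, score = score,
                 rating = rating),
            class = "eco_scale")
}

#' @export
print.eco_scale <- function(x, ...) {
  cat(sprintf("Analytical eco-scale: %g penalty points, score %g (%s)\n",
              x$total_pp, x$score, x$rating))
  invisible(x)
}

#' Built-in eco-scale penalty ledgers
#'
#' Itemised penalty points for the chemometric UV method (methanol 6,
#' waste 1: total 7, score 93) and for the reference HPLC method
#' (methanol 6, water 0, instrument energy 1, waste 5: total 12, score
#' 88).  Both rate as excellent green analyses.
#'
#' @param method `"chemometric"` or `"hplc"`.
#' @return A penalty-item data frame suitable for [eco_scale()].
#' @export
ecoscale_ledger <- function(method = c("chemometric", "hplc")) {
  method <- match.arg(method)
  if (method == "chemometric") {
    data.frame(
      label = c("methanol", "instrument energy", "occupational hazard", "waste"),
      category = c("reagent", "instrument_energy", "occupational_hazard", "waste"),
      penalty_points = c(6, 0, 0, 1))
  } else {
    data.frame(
      label = c("methanol", "water", "instrument energy",
                "occupational hazard", "waste"),
      category = c("reagent", "reagent", "instrument_energy",
                   "occupational_hazard", "waste"),
      penalty_points = c(6, 0, 1, 0, 5))
  }
}

#' AGREE greenness score
#'
#' Weighted arithmetic mean of twelve segment scores in [0, 1]; the
#' overall score is invariant to uniform weight rescaling and bounded by
#' the extreme segment scores.  Segment colour classes use configurable
#' thresholds (default: red below 1/3, yellow below 2/3, else green).
#'
#' @param scores Twelve segment scores in [0, 1].
#' @param weights Twelve positive weights (default equal).
#' @param breaks Two increasing colour-class thresholds.
#' @return List with `overall`, `segment_scores`, `weights`,
#'   `segment_colors`, `overall_color`.
#' @export
#' @examples
#' agree_score(rep(0.5, 12))$overall
agree_score <- function(scores, weights = rep(1, 12), breaks = c(1/3, 2/3)) {
  if (length(scores) != 12) stop("exactly 12 segment scores are required")
  if (length(weights) != 12) stop("exactly 12 weights are required")
  if (any(weights <= 0)) stop("weights must be positive")
  if (any(scores < 0 | scores > 1)) stop("segment scores must lie in [0, 1]")
  overall <- sum(weights * scores) / sum(weights)
  color_of <- function(s) if (s < breaks[1]) "red"
                          else if (s < breaks[2]) "yellow" else "green"
  list(overall = overall, segment_scores = scores, weights = weights,
       segment_colors = vapply(scores, color_of, ""),
       overall_color = color_of(overall))
}

#' GAPI categorical greenness profile
#'
#' A GAPI assessment is fifteen pentagram fields, each coloured green
#' (high ecological tolerance), yellow or red (significant environmental
#' risk).  `gapi_profile` validates the data entry; `gapi_compare` counts
#' colours and declares the profile with fewer red fields the greener one
#' (equal red counts give a tie).
#'
#' @param fields Character vector of 15 values in green/yellow/red.
#' @return `gapi_profile`: the validated profile.  `gapi_compare`: list
#'   with `counts_a`, `counts_b` (named green/yellow/red counts) and
#'   `verdict` (`"a"`, `"b"` or `"tie"`).
#' @export
#' @examples
#' a <- gapi_profile(c(rep("green", 12), rep("yellow", 2), "red"))
#' b <- gapi_profile(c(rep("green", 10), rep("yellow", 2), rep("red", 3)))
#' gapi_compare(a, b)$verdict
gapi_profile <- function(fields) {
  if (length(fields) != 15) stop("a GAPI profile has exactly 15 fields")
  if (any(!fields %in% c("green", "yellow", "red")))
    stop("fields must be 'green', 'yellow' or 'red'")
  structure(fields, class = "gapi_profile")
}

#' @rdname gapi_profile
#' @param a,b `gapi_profile` objects.
#' @export
gapi_compare <- function(a, b) {
  count <- function(p) {
    vapply(c(green = "green", yellow = "yellow", red = "red"),
           function(cl) sum(unclass(p) == cl), 0L)
  }
  ca <- count(a); cb <- count(b)
  verdict <- if (ca["red"] < cb["red"]) "a"
             else if (cb["red"] < ca["red"]) "b"
             else "tie"
  list(counts_a = ca, counts_b = cb, verdict = verdict)
}

#' Read a greenness configuration file
#'
#' YAML layout:
#' ```
#' ecoscale:
#'   items:
#'     - {label: methanol, category: reagent, pp: 6}
#' agree:
#'   scores: [1, 0.8, ...]   # 12 values
#'   weights: [1, 1, ...]    # optional
#' gapi:
#'   fields: [green, green, ...]  # 15 values
#' ```
#'
#' @param path YAML file path.
#' @return List with any of `ecoscale` ([eco_scale()] result), `agree`
#'   ([agree_score()] result), `gapi` ([gapi_profile()]).
#' @export
read_greenness_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$ecoscale)) {
    items <- do.call(rbind, lapply(cfg$ecoscale$items, function(it)
      data.frame(label = it$label, category = it$category,
                 penalty_points = it$pp)))
    out$ecoscale <- eco_scale(items)
  }
  if (!is.null(cfg$agree)) {
    w <- cfg$agree$weights
    if (is.null(w)) w <- rep(1, 12)
    out$agree <- agree_score(as.numeric(cfg$agree$scores), as.numeric(w))
  }
  if (!is.null(cfg$gapi)) {
    out$gapi <- gapi_profile(unlist(cfg$gapi$fields))
  }
  out
}
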