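# Interaction-strength scaling: standardization to 100%, log2 ordinal
# binning, seasonal averaging, case-study floor, winter extrapolation.

# Round half away from zero; base round() is banker's rounding.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Standardize raw interaction values to percentage shares
#'
#' Literature diet metrics (frequency of occurrence, relative biomass, caloric
#' fraction, ...) are incommensurable across studies. Within each
#' study-consumer group the raw values are rescaled so they sum to 100%,
#' which removes the metric's native scale. Metric types must be uniform
#' within a group (no conversion between metrics is attempted) and at least
#' one raw value must be positive.
#'
#' @param records quantitative interaction records (validated); may span many
#'   study-consumer groups.
#' @return The records with a `share` column in percent; within each
#'   `(study_id, consumer)` group the shares sum to 100 (tolerance 1e-9).
#' @export
standardize_shares <- function(records) {
  if (nrow(records) == 0L) {
    records$share <- numeric(0)
    return(records)
  }
  if (any(records$study_type != "quantitative"))
    stop("standardize_shares expects quantitative records only")
  if (anyNA(records$raw_value))
    stop("quantitative record with missing raw_value")
  key <- interaction(records$study_id, records$consumer, drop = TRUE)
  share <- numeric(nrow(records))
  for (idx in split(seq_len(nrow(records)), key)) {
    grp <- records[idx, ]
    if (length(unique(grp$metric_type)) > 1L)
      stop("mixed metric_type within study-consumer group ",
           grp$study_id[1], " x ", grp$consumer[1], ": ",
           paste(unique(grp$metric_type), collapse = ", "))
    tot <- sum(grp$raw_value)
    if (tot <= 0)
      stop("all-zero raw values in study-consumer group ",
           grp$study_id[1], " x ", grp$consumer[1])
    share[idx] <- 100 * grp$raw_value / tot
  }
  records$share <- share
  records
}

#' Map a standardized share to its log2 ordinal strength score
#'
#' The ordinal scale reflects the nonlinear increase in relative interaction
#' importance: 0 absence (0%), 1 marginal (0-5%], 2 auxiliary (5-20%],
#' 4 primary (20-67%], 8 keystone (over 67%, when one interaction is about
#' twice as strong as any other). Intervals are upper-inclusive: a share of
#' exactly 67% is primary because the keystone class starts strictly above
#' 67%.
#'
#' @param share numeric vector of percentages in `[0, 100]`.
#' @return Integer vector with values in `{0, 1, 2, 4, 8}`.
#' @examples
#' scale_share(c(0, 3, 10, 50, 80))  # 0 1 2 4 8
#' @export
scale_share <- function(share) {
  if (!is.numeric(share) || anyNA(share))
    stop("share must be numeric and non-missing")
  if (any(share < 0 | share > 100))
    stop("share outside [0, 100]: ",
         paste(share[share < 0 | share > 100], collapse = ", "))
  score <- integer(length(share))
  score[share > 0]  <- 1L
  score[share > 5]  <- 2L
  score[share > 20] <- 4L
  score[share > 67] <- 8L
  score
}

#' Average per-study ordinal scores for one link-season
#'
#' When several studies cover the same consumer-resource-layer-season link,
#' the per-study scores are averaged with equal weight (no weighting by
#' sample size or metric) and rounded to one decimal, so intermediate values
#' between the ordinal categories can occur.
#'
#' @param scores numeric vector of per-study ordinal scores.
#' @param rounding_decimals decimals kept (default 1).
#' @return The averaged strength.
#' @export
average_scores <- function(scores, rounding_decimals = 1L) {
  if (length(scores) == 0L) stop("no scores to average")
  round_half_up(mean(scores), rounding_decimals)
}

#' Floor case-study-only links at a minimal averaged score
#'
#' Anecdotal case reports establish that a link exists without quantifying
#' it. Links covered only by case studies for a season are assigned a
#' constant minimal averaged score (default 0.1) regardless of how many case
#' reports exist; where quantitative measurements exist the case reports are
#' ignored.
#'
#' @param measured scaled-link `data.frame` from quantitative studies
#'   (columns consumer, resource, layer, season, strength, n_studies,
#'   provenance).
#' @param case_candidates `data.frame` of case-only candidates with columns
#'   consumer, resource, layer, season, n_studies.
#' @param case_floor the constant floor strength (default 0.1).
#' @return Combined scaled-link `data.frame`; floored rows have
#'   `provenance == "case_only"`.
#' @export
apply_case_study_floor <- function(measured, case_candidates,
                                   case_floor = 0.1) {
  if (is.null(case_candidates) || nrow(case_candidates) == 0L)
    return(measured)
  link_key <- function(d) paste(d$consumer, d$resource, d$layer, d$season,
                                sep = "\r")
  keep <- !link_key(case_candidates) %in% link_key(measured)
  cand <- case_candidates[keep, , drop = FALSE]
  if (nrow(cand)) {
    cand$strength <- case_floor
    cand$provenance <- "case_only"
    measured <- rbind(measured,
                      cand[, c("consumer", "resource", "layer", "season",
                               "strength", "n_studies", "provenance")])
  }
  measured
}

#' Extrapolate summer link strengths to winter
#'
#' Winter literature is scarce; for an explicit, config-supplied list of
#' links the summer strength is copied to winter with provenance
#' `"extrapolated"`. Extrapolation is opt-in only and refuses to overwrite a
#' measured winter strength; an existing case-only winter floor is replaced.
#'
#' @param links scaled-link `data.frame` (as from [scale_strengths()]).
#' @param extrapolate links to extrapolate: a `data.frame` with columns
#'   consumer, resource, layer, or a list of length-3 vectors/lists.
#' @return The links with the extrapolated winter rows appended
#'   (`n_studies = 0`).
#' @export
extrapolate_winter <- function(links, extrapolate) {
  ex <- normalize_extrapolation(extrapolate)
  if (is.null(ex) || nrow(ex) == 0L) return(links)
  for (i in seq_len(nrow(ex))) {
    sel <- links$consumer == ex$consumer[i] & links$resource == ex$resource[i] &
      links$layer == ex$layer[i]
    wi <- sel & links$season == "winter"
    if (any(wi & links$provenance == "measured"))
      stop("refusing to extrapolate ", ex$consumer[i], " <- ", ex$resource[i],
           " (", ex$layer[i], "): measured winter strength already present")
    su <- which(sel & links$season == "summer")
    if (!length(su))
      stop("cannot extrapolate ", ex$consumer[i], " <- ", ex$resource[i],
           " (", ex$layer[i], "): no summer strength available")
    links <- links[!(seq_len(nrow(links)) %in% which(wi)), , drop = FALSE]
    new <- links[su[1], , drop = FALSE]
    new$season <- "winter"
    new$n_studies <- 0L
    new$provenance <- "extrapolated"
    links <- rbind(links, new)
  }
  rownames(links) <- NULL
  links
}

normalize_extrapolation <- function(extrapolate) {
  if (is.null(extrapolate)) return(NULL)
  if (is.data.frame(extrapolate)) {
    stopifnot(all(c("consumer", "resource", "layer") %in% names(extrapolate)))
    return(extrapolate)
  }
  do.call(rbind, lapply(extrapolate, function(e) {
    e <- unlist(e, use.names = TRUE)
    if (is.null(names(e)) || !all(c("consumer", "resource", "layer") %in% names(e)))
      names(e) <- c("consumer", "resource", "layer")[seq_along(e)]
    data.frame(consumer = e[["consumer"]], resource = e[["resource"]],
               layer = e[["layer"]], stringsAsFactors = FALSE)
  }))
}

#' Run the full interaction-strength scaling stage
#'
#' Converts validated literature records into seasonal scaled links:
#' 1. records from excluded reviews are dropped;
#' 2. each study is classified as a summer or winter study by the majority of
#'    its covered months (unclassifiable quantitative studies are dropped
#'    with a warning);
#' 3. within each study-consumer group raw values are standardized to 100%
#'    and binned on the log2 ordinal scale;
#' 4. per-study scores are averaged per consumer-resource-layer-season link
#'    and rounded to one decimal;
#' 5. link-seasons covered only by case studies receive the constant case
#'    floor (a case report without a classifiable season is taken as
#'    season-agnostic and floors both seasons);
#' 6. listed links are extrapolated from summer to winter.
#'
#' @param records validated record `data.frame` (see [read_records()]).
#' @param case_floor minimal averaged score for case-only links.
#' @param extrapolate optional link list for [extrapolate_winter()].
#' @param rounding_decimals decimals kept after averaging.
#' @return A scaled-link `data.frame` with columns consumer, resource, layer,
#'   season, strength, n_studies, provenance.
#' @export
scale_strengths <- function(records, case_floor = 0.1, extrapolate = NULL,
                            rounding_decimals = 1L) {
  records <- records[!isTRUE_vec(records$excluded_review), , drop = FALSE]
  if (is.null(records$season))
    records$season <- classify_season_vec(records$study_months)

  quant <- records[records$study_type == "quantitative", , drop = FALSE]
  n_uncl <- sum(quant$season == "unclassified")
  if (n_uncl > 0) {
    warning(n_uncl, " quantitative record(s) with unclassifiable season ",
            "excluded from seasonal averaging")
    quant <- quant[quant$season != "unclassified", , drop = FALSE]
  }

  measured <- empty_links()
  if (nrow(quant)) {
    quant <- standardize_shares(quant)
    # one score per study and link: shares of duplicate rows within a study
    # for the same link are pooled before binning
    agg <- stats::aggregate(share ~ study_id + consumer + resource + layer +
                              season, data = quant, FUN = sum)
    agg$score <- scale_share(agg$share)
    grp <- split(agg, paste(agg$consumer, agg$resource, agg$layer, agg$season,
                            sep = "\r"))
    measured <- do.call(rbind, lapply(grp, function(g) data.frame(
      consumer = g$consumer[1], resource = g$resource[1], layer = g$layer[1],
      season = g$season[1],
      strength = average_scores(g$score, rounding_decimals),
      n_studies = length(unique(g$study_id)),
      provenance = "measured", stringsAsFactors = FALSE)))
    rownames(measured) <- NULL
  }

  cases <- records[records$study_type == "case_study", , drop = FALSE]
  cand <- NULL
  if (nrow(cases)) {
    # season-agnostic case reports floor both seasons
    expand <- lapply(seq_len(nrow(cases)), function(i) {
      s <- cases$season[i]
      seasons <- if (s == "unclassified") c("summer", "winter") else s
      data.frame(consumer = cases$consumer[i], resource = cases$resource[i],
                 layer = cases$layer[i], season = seasons,
                 study_id = cases$study_id[i], stringsAsFactors = FALSE)
    })
    expand <- do.call(rbind, expand)
    cand <- stats::aggregate(study_id ~ consumer + resource + layer + season,
                             data = expand,
                             FUN = function(s) length(unique(s)))
    names(cand)[names(cand) == "study_id"] <- "n_studies"
  }
  links <- apply_case_study_floor(measured, cand, case_floor)
  links <- extrapolate_winter(links, extrapolate)
  links <- links[order(links$consumer, links$resource, links$layer,
                       links$season), , drop = FALSE]
  rownames(links) <- NULL
  links
}

empty_links <- function() {
  data.frame(consumer = character(0), resource = character(0),
             layer = character(0), season = character(0),
             strength = numeric(0), n_studies = integer(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & x
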