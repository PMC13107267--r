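# Literature knowledge-bias scores: per-node publication-species knowledge
# and knowledge-accumulation curves.

#' Per-node literature knowledge scores
#'
#' Quantifies how well each node's interactions are studied, and thereby the
#' taxonomic bias of the recovered network. Each (paper, species) pair
#' contributes 1 when the paper measured interaction strength for that
#' species and 0.25 when it is only a case study (no strength measured); a
#' paper that both measures and anecdotally mentions the same species counts
#' once as measured. Contributions are summed per node, and the weighted
#' score divides the sum by the number of species aggregated in the node, so
#' a species-rich node is not credited for knowledge concentrated on one of
#' its members. Records flagged `excluded_review` (e.g. syntheses that would
#' double-count their sources) are removed first.
#'
#' Species granularity comes from the optional `species` column of the record
#' table; without it, each (paper, consumer-node) pair counts as one studied
#' species.
#'
#' @param records validated record `data.frame`.
#' @param nodes validated node table.
#' @return A `data.frame` with one row per node: `node_id`, `knowledge_sum`,
#'   `n_species`, `weighted` (sum / n_species, rounded to two decimals).
#' @examples
#' # three papers on a 3-species node: strength measured for species A;
#' # strength measured for A and B; a case study on C
#' fx <- reference_fixtures()$knowledge
#' knowledge_score(fx$records, fx$nodes)  # FOCAL: sum 3.25, weighted 1.08
#' @export
knowledge_score <- function(records, nodes) {
  nodes <- validate_nodes(nodes)
  if (any(nodes$n_species < 1L)) stop("n_species must be >= 1")
  records <- records[!isTRUE_vec(records$excluded_review), , drop = FALSE]
  species <- if ("species" %in% names(records)) records$species
             else records$consumer
  out <- data.frame(node_id = nodes$node_id, knowledge_sum = 0,
                    n_species = nodes$n_species, stringsAsFactors = FALSE)
  if (nrow(records)) {
    pair <- paste(records$study_id, species, sep = "\r")
    # "measured" dominates within a (paper, species) pair
    measured <- tapply(records$study_type == "quantitative", pair, any)
    pair_node <- tapply(records$consumer, pair, function(n) {
      u <- unique(n)
      if (length(u) > 1L)
        stop("species assigned to multiple nodes within one paper: ",
             paste(u, collapse = ", "))
      u
    })
    contrib <- ifelse(measured, 1, 0.25)
    sums <- tapply(contrib, unlist(pair_node), sum)
    idx <- match(names(sums), out$node_id)
    out$knowledge_sum[idx] <- as.numeric(sums)
  }
  out$weighted <- round_half_up(out$knowledge_sum / out$n_species, 2L)
  out
}

#' Literature accumulation curve
#'
#' Cumulative number of distinct interaction studies by publication year —
#' the growth of the evidence base over time.
#'
#' @param records validated record `data.frame`.
#' @return A `data.frame` with columns `year`, `n_new`, `cumulative`;
#'   `cumulative` is non-decreasing. Empty input gives an empty curve.
#' @export
accumulation_curve <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(year = integer(0), n_new = integer(0),
                      cumulative = integer(0)))
  yr <- tapply(records$pub_year, records$study_id, function(y) {
    u <- unique(y)
    if (length(u) > 1L)
      stop("study with inconsistent pub_year: ",
           paste(u, collapse = ", "))
    u
  })
  tab <- table(as.integer(yr))
  data.frame(year = as.integer(names(tab)),
             n_new = as.integer(tab),
             cumulative = cumsum(as.integer(tab)))
}
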