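# Multilayer seasonal metaweb: assembly, sparse-layer exclusion, subwebs,
# realm-crossover profiles, summaries, exports.

#' Assemble a directed multilayer seasonal metaweb
#'
#' Builds the regional pool of potential interactions (a metaweb, not
#' co-occurrence-filtered) from scaled links and a node table. Edges run in
#' the energy-flow direction, resource to consumer, weighted by the scaled
#' strength; the interaction layer (Pr, Sc, He, Po, Kl, Co, De) is kept as a
#' parallel edge attribute. Pollination edges are retained in the same
#' unipartite graph as energy transfer via nectar/pollen; kleptoparasitic
#' edges book-keep the robbed victim as the resource. Links with strength 0
#' (measured absences) are dropped.
#'
#' @param links scaled-link `data.frame` from [scale_strengths()].
#' @param nodes validated node table ([read_nodes()]).
#' @param season `"summer"`, `"winter"` or `"both"`.
#' @return An object of class `"metaweb"`: a list with `nodes`, `edges`,
#'   `layers` and `season`.
#' @export
metaweb <- function(links, nodes, season = c("both", "summer", "winter")) {
  season <- match.arg(season)
  nodes <- validate_nodes(nodes)
  req <- c("consumer", "resource", "layer", "season", "strength",
           "n_studies", "provenance")
  missing <- setdiff(req, names(links))
  if (length(missing))
    stop("links are missing column(s): ", paste(missing, collapse = ", "))
  if (season != "both")
    links <- links[links$season == season, , drop = FALSE]
  links <- links[links$season %in% c("summer", "winter"), , drop = FALSE]
  bad <- unique(c(setdiff(links$consumer, nodes$node_id),
                  setdiff(links$resource, nodes$node_id)))
  if (length(bad))
    stop("link endpoint(s) missing from node table: ",
         paste(bad, collapse = ", "))
  key <- paste(links$consumer, links$resource, links$layer, links$season,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate link key(s) (consumer, resource, layer, season): ",
         paste(unique(gsub("\r", " / ", key[duplicated(key)])), collapse = "; "))
  links <- links[links$strength > 0, , drop = FALSE]
  rownames(links) <- NULL
  structure(list(nodes = nodes, edges = links,
                 layers = sort(unique(links$layer)), season = season),
            class = "metaweb")
}

#' @export
print.metaweb <- function(x, ...) {
  cat("Multilayer metaweb (", x$season, " season)\n", sep = "")
  cat("  nodes: ", nrow(x$nodes), " (",
      paste(names(table(x$nodes$realm)), table(x$nodes$realm),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  cat("  links: ", nrow(x$edges), " across layer(s) ",
      paste(x$layers, collapse = ", "), "\n", sep = "")
  if (!is.null(attr(x, "exclusion_report"))) {
    rep <- attr(x, "exclusion_report")
    dropped <- rep[rep$dropped, , drop = FALSE]
    if (nrow(dropped))
      cat("  excluded sparse layer(s): ",
          paste0(dropped$layer, " (", dropped$n_measured, " measured link(s))",
                 collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Summarise a metaweb by layer and season
#'
#' Tabulates node and link counts per layer and season and the distribution
#' of scaled strengths — the numbers behind statements such as "the
#' summer-time network has more nodes and links than the winter one".
#'
#' @param web a `metaweb`.
#' @return A list of class `"metaweb_summary"` with elements
#'   `layer_season_counts`, `season_counts` (nodes/links per season) and
#'   `strength_summary`.
#' @export
network_summary <- function(web) {
  e <- web$edges
  ls_counts <- if (nrow(e)) as.data.frame(table(layer = e$layer,
                                                season = e$season),
                                          stringsAsFactors = FALSE)
               else data.frame(layer = character(0), season = character(0),
                               Freq = integer(0))
  names(ls_counts)[names(ls_counts) == "Freq"] <- "n_links"
  ls_counts <- ls_counts[ls_counts$n_links > 0 |
                           ls_counts$layer %in% web$layers, , drop = FALSE]
  seas <- unique(e$season)
  season_counts <- do.call(rbind, lapply(seas, function(s) {
    es <- e[e$season == s, , drop = FALSE]
    data.frame(season = s, n_links = nrow(es),
               n_nodes = length(unique(c(es$consumer, es$resource))),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    layer_season_counts = ls_counts,
    season_counts = season_counts,
    strength_summary = if (nrow(e)) summary(e$strength) else NULL),
    class = "metaweb_summary")
}

#' @export
print.metaweb_summary <- function(x, ...) {
  cat("Links per layer and season:\n")
  print(x$layer_season_counts, row.names = FALSE)
  if (!is.null(x$season_counts)) {
    cat("Nodes and links per season:\n")
    print(x$season_counts, row.names = FALSE)
  }
  if (!is.null(x$strength_summary)) {
    cat("Scaled strength distribution:\n")
    print(x$strength_summary)
  }
  invisible(x)
}

#' @export
summary.metaweb <- function(object, ...) network_summary(object)

#' Drop interaction layers too sparse to resolve
#'
#' Layers supported by fewer than `min_links` measured (non-case-only) links
#' cannot be resolved reliably and are removed — in regional Arctic
#' syntheses this typically eliminates coprophagy and detritus flow. The
#' decision counts only measured links, so a layer cannot be retained on
#' anecdotes alone.
#'
#' @param web a `metaweb`.
#' @param min_links minimum number of measured links a layer needs (>= 1).
#' @return The pruned `metaweb`; the exclusion report (layer, measured link
#'   count, dropped flag) is attached as attribute `"exclusion_report"`.
#' @export
exclude_sparse_layers <- function(web, min_links = 3L) {
  stopifnot(min_links >= 1L)
  e <- web$edges
  report <- do.call(rbind, lapply(web$layers, function(l) {
    n_meas <- sum(e$layer == l & e$provenance != "case_only")
    data.frame(layer = l, n_measured = n_meas, dropped = n_meas < min_links,
               stringsAsFactors = FALSE)
  }))
  if (is.null(report))
    report <- data.frame(layer = character(0), n_measured = integer(0),
                         dropped = logical(0))
  keep <- report$layer[!report$dropped]
  web$edges <- e[e$layer %in% keep, , drop = FALSE]
  rownames(web$edges) <- NULL
  web$layers <- keep
  attr(web, "exclusion_report") <- report
  web
}

#' Extract an induced subweb
#'
#' Restricts the metaweb to edges flowing from a named resource set to a
#' named consumer set within the named layers — e.g., terrestrial plants to
#' pollinators in the pollination layer.
#'
#' @param web a `metaweb`.
#' @param consumers,resources character vectors of node ids.
#' @param layers layers to keep (default: all layers in the web).
#' @return A `metaweb` containing only the matching edges and the nodes they
#'   touch.
#' @export
extract_subweb <- function(web, consumers, resources, layers = web$layers) {
  unknown <- setdiff(c(consumers, resources), web$nodes$node_id)
  if (length(unknown))
    stop("unknown node id(s): ", paste(unknown, collapse = ", "))
  e <- web$edges
  keep <- e$consumer %in% consumers & e$resource %in% resources &
    e$layer %in% layers
  web$edges <- e[keep, , drop = FALSE]
  rownames(web$edges) <- NULL
  used <- unique(c(web$edges$consumer, web$edges$resource))
  web$nodes <- web$nodes[web$nodes$node_id %in% used, , drop = FALSE]
  web$layers <- sort(unique(web$edges$layer))
  attr(web, "exclusion_report") <- NULL
  web
}

#' Marine-terrestrial energy-crossover profile of one consumer
#'
#' Sums the scaled strengths of a consumer's incoming energy links into
#' realm buckets (marine / terrestrial / coastal, by the realm of each
#' resource) and reports the fractions — the quantity behind statements that
#' a top predator draws energy from both marine and inland ecosystems.
#'
#' @param web a `metaweb`.
#' @param consumer node id of the consumer.
#' @return An object of class `"consumer_profile"`: `entries` lists
#'   (resource, layer, season, strength, realm); `realm_split` gives, per
#'   season, the summed strength and realm fractions. Seasons with no
#'   incoming energy are flagged `defined = FALSE` with `NA` fractions.
#' @export
crossover_summary <- function(web, consumer) {
  if (!consumer %in% web$nodes$node_id)
    stop("unknown consumer: ", consumer)
  e <- web$edges[web$edges$consumer == consumer, , drop = FALSE]
  e$realm <- web$nodes$realm[match(e$resource, web$nodes$node_id)]
  seasons <- unique(e$season)
  if (!length(seasons)) seasons <- character(0)
  split_rows <- lapply(seasons, function(s) {
    es <- e[e$season == s, , drop = FALSE]
    tot <- sum(es$strength)
    fr <- vapply(realm_codes(), function(r)
      if (tot > 0) sum(es$strength[es$realm == r]) / tot else NA_real_,
      numeric(1))
    data.frame(season = s, total_strength = tot,
               marine = fr[["marine"]], terrestrial = fr[["terrestrial"]],
               coastal = fr[["coastal"]], defined = tot > 0,
               stringsAsFactors = FALSE)
  })
  realm_split <- if (length(split_rows)) do.call(rbind, split_rows)
                 else data.frame(season = character(0),
                                 total_strength = numeric(0),
                                 marine = numeric(0), terrestrial = numeric(0),
                                 coastal = numeric(0), defined = logical(0))
  structure(list(consumer = consumer,
                 entries = e[, c("resource", "layer", "season", "strength",
                                 "realm")],
                 realm_split = realm_split),
            class = "consumer_profile")
}

#' @export
print.consumer_profile <- function(x, ...) {
  cat("Seasonal resource profile of ", x$consumer, "\n", sep = "")
  if (nrow(x$entries)) print(x$entries, row.names = FALSE)
  else cat("  no incoming energy links\n")
  cat("Realm split of incoming strength:\n")
  print(x$realm_split, row.names = FALSE)
  invisible(x)
}

#' Convert a metaweb to an igraph graph
#'
#' Edges point from resource to consumer (energy flow); layer, season,
#' strength (as `weight`), study count and provenance become edge
#' attributes; guild, realm, species count and flagship status become vertex
#' attributes.
#'
#' @param web a `metaweb`.
#' @return An `igraph` directed graph.
#' @export
metaweb_graph <- function(web) {
  ed <- data.frame(from = web$edges$resource, to = web$edges$consumer,
                   weight = web$edges$strength, layer = web$edges$layer,
                   season = web$edges$season,
                   n_studies = web$edges$n_studies,
                   provenance = web$edges$provenance,
                   stringsAsFactors = FALSE)
  vx <- data.frame(name = web$nodes$node_id, label = web$nodes$label,
                   guild = web$nodes$guild, realm = web$nodes$realm,
                   n_species = web$nodes$n_species,
                   flagship = web$nodes$flagship, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = vx)
}

#' Export a metaweb
#'
#' `write_metaweb_csv()` writes the edge list (consumer, resource, layer,
#' season, strength, n_studies, provenance); `write_metaweb_graphml()`
#' writes GraphML with full node and edge attributes via igraph.
#' `read_metaweb_csv()` reads an edge list back; together with the node
#' table this round-trips edge weights exactly (weights are serialized as
#' decimal strings).
#'
#' @param web a `metaweb`.
#' @param path output file path.
#' @export
write_metaweb_csv <- function(web, path) {
  utils::write.csv(web$edges, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_metaweb_csv
#' @export
read_metaweb_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = c(strength = "numeric"))
}

#' @rdname write_metaweb_csv
#' @export
write_metaweb_graphml <- function(web, path) {
  igraph::write_graph(metaweb_graph(web), path, format = "graphml")
  invisible(path)
}

#' Plot a metaweb
#'
#' A simple layered plot: arrow width proportional to scaled strength,
#' colour by interaction layer, vertex colour by realm. Intended as a quick
#' look, not a publication figure.
#'
#' @param x a `metaweb`.
#' @param seed layout seed for reproducible node placement.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.metaweb <- function(x, seed = 42L, ...) {
  if (!nrow(x$edges)) {
    graphics::plot.new()
    graphics::title("empty metaweb")
    return(invisible(x))
  }
  g <- metaweb_graph(x)
  layer_cols <- stats::setNames(
    grDevices::hcl.colors(length(layer_codes()), "Dark 3"), layer_codes())
  realm_cols <- c(marine = "#4477AA", terrestrial = "#228833",
                  coastal = "#CCBB44")
  old_seed <- withr_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  lay <- igraph::layout_with_fr(g)
  igraph::plot.igraph(
    g, layout = lay,
    edge.width = 0.5 + igraph::E(g)$weight,
    edge.color = layer_cols[igraph::E(g)$layer],
    edge.arrow.size = 0.4,
    vertex.color = realm_cols[igraph::V(g)$realm],
    vertex.label = igraph::V(g)$label, vertex.label.cex = 0.7,
    vertex.size = 8, ...)
  invisible(x)
}

withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
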