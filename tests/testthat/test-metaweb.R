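mini <- reference_fixtures()$mini_metaweb

test_that("metaweb assembly keeps layers, drops zero links, checks keys", {
  web <- metaweb(mini$links, mini$nodes)
  expect_s3_class(web, "metaweb")
  expect_equal(nrow(web$edges), nrow(mini$links))
  expect_setequal(web$layers, c("Pr", "Sc", "He", "Po", "Kl", "Co"))

  # empty link set -> empty metaweb, no error
  empty <- metaweb(mini$links[0, ], mini$nodes)
  expect_equal(nrow(empty$edges), 0L)

  # measured absences (strength 0) are not edges
  withzero <- rbind(mini$links,
                    transform(mini$links[1, ], resource = "MIDGE",
                              strength = 0))
  expect_equal(nrow(metaweb(withzero, mini$nodes)$edges), nrow(mini$links))

  dup <- rbind(mini$links, mini$links[1, ])
  expect_error(metaweb(dup, mini$nodes), "duplicate link key")

  orphan <- transform(mini$links, consumer = replace(consumer, 1, "YETI"))
  expect_error(metaweb(orphan, mini$nodes), "missing from node table")
})

test_that("sparse layers are excluded by measured-link count", {
  web <- metaweb(mini$links, mini$nodes)
  pruned <- exclude_sparse_layers(web, min_links = 3L)
  report <- attr(pruned, "exclusion_report")

  expect_false("Co" %in% pruned$layers)
  expect_setequal(pruned$layers, c("Pr", "Sc", "He", "Po", "Kl"))
  expect_true(report$dropped[report$layer == "Co"])
  expect_equal(report$n_measured[report$layer == "Co"], 1L)
  expect_false(any(report$dropped[report$layer != "Co"]))

  # lower bound: min_links = 1 keeps every layer with a measured link
  expect_setequal(exclude_sparse_layers(web, min_links = 1L)$layers,
                  web$layers)
  # case-only links do not count toward retention
  expect_equal(sum(pruned$edges$layer == "Co"), 0L)
})

test_that("subweb extraction induces resource -> consumer edges only", {
  web <- metaweb(mini$links, mini$nodes)
  pol <- extract_subweb(web, consumers = c("FLY", "MIDGE"),
                        resources = c("PLANT", "DRYAS"), layers = "Po")
  expect_equal(nrow(pol$edges), 3L)
  expect_setequal(pol$edges$layer, "Po")
  expect_true(all(pol$edges$consumer %in% c("FLY", "MIDGE")))
  expect_true(all(pol$edges$resource %in% c("PLANT", "DRYAS")))

  expect_equal(nrow(extract_subweb(web, character(0), "PLANT")$edges), 0L)
  expect_error(extract_subweb(web, "YETI", "PLANT"), "unknown node")

  # monotonicity and commutation with layer exclusion
  set.seed(5)
  for (i in 1:10) {
    cons <- sample(mini$nodes$node_id, 4)
    res <- sample(mini$nodes$node_id, 4)
    sub <- extract_subweb(web, cons, res)
    expect_lte(nrow(sub$edges), nrow(web$edges))
    a <- extract_subweb(exclude_sparse_layers(web, 3L), cons, res)
    b <- extract_subweb(web, cons, res,
                        layers = exclude_sparse_layers(web, 3L)$layers)
    expect_equal(a$edges[order(a$edges$consumer, a$edges$resource,
                               a$edges$layer), ],
                 b$edges[order(b$edges$consumer, b$edges$resource,
                               b$edges$layer), ],
                 ignore_attr = TRUE)
  }
})

test_that("crossover profiles split incoming strength by resource realm", {
  web <- metaweb(mini$links, mini$nodes)
  fox <- crossover_summary(web, "FOX")
  rs <- fox$realm_split
  expect_true(all(abs(rowSums(rs[, c("marine", "terrestrial", "coastal")]) - 1)
                  < 1e-9))
  # fox: marine intake SEAL 2 + BEAR 1; terrestrial GOOSE 4 + REIN 4 + MIDGE 0.1
  expect_equal(rs$marine, 3 / 11.1)
  expect_equal(rs$terrestrial, 8.1 / 11.1)

  # all resources marine -> marine fraction 1
  bear <- crossover_summary(web, "BEAR")
  expect_equal(bear$realm_split$marine[1],
               8 / 9 + 0)  # SEAL 8 marine, REIN 1 terrestrial
  seal_only <- extract_subweb(web, "BEAR", "SEAL")
  expect_equal(crossover_summary(seal_only, "BEAR")$realm_split$marine, 1)

  # consumer with no incoming energy is flagged undefined
  plant <- crossover_summary(web, "PLANT")
  expect_equal(nrow(plant$entries), 0L)
  expect_true(all(!plant$realm_split$defined))
  expect_error(crossover_summary(web, "YETI"), "unknown consumer")
})

test_that("network summaries tabulate layers, seasons and strengths", {
  web <- metaweb(mini$links, mini$nodes)
  ns <- network_summary(web)
  counts <- ns$layer_season_counts
  expect_equal(counts$n_links[counts$layer == "Pr" &
                                counts$season == "summer"], 5L)
  expect_equal(counts$n_links[counts$layer == "He" &
                                counts$season == "summer"], 3L)
  expect_equal(sum(counts$n_links), nrow(web$edges))
  expect_true(all(web$edges$strength >= 0 & web$edges$strength <= 8))

  # a winter subset never outcounts the summer web it came from
  wlinks <- transform(mini$links[1:4, ], season = "winter")
  both <- metaweb(rbind(mini$links, wlinks), mini$nodes)
  sc <- network_summary(both)$season_counts
  expect_gte(sc$n_links[sc$season == "summer"],
             sc$n_links[sc$season == "winter"])
  expect_gte(sc$n_nodes[sc$season == "summer"],
             sc$n_nodes[sc$season == "winter"])
})

test_that("exports round-trip edges and node attributes", {
  web <- metaweb(mini$links, mini$nodes)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metaweb_csv(web, csv)
  back <- read_metaweb_csv(csv)
  expect_identical(back$strength, web$edges$strength)
  expect_equal(back, web$edges, ignore_attr = TRUE)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_metaweb_graphml(web, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(mini$nodes))
  expect_equal(igraph::gsize(g), nrow(web$edges))
  expect_identical(sort(igraph::E(g)$weight), sort(web$edges$strength))
  v <- match(web$nodes$node_id, igraph::V(g)$name)
  expect_identical(igraph::V(g)$realm[v], web$nodes$realm)
  expect_identical(as.integer(igraph::V(g)$n_species[v]),
                   web$nodes$n_species)
})

test_that("season filtering and plotting behave", {
  wlinks <- transform(mini$links[1:4, ], season = "winter")
  all_links <- rbind(mini$links, wlinks)
  su <- metaweb(all_links, mini$nodes, season = "summer")
  expect_setequal(su$edges$season, "summer")
  wi <- metaweb(all_links, mini$nodes, season = "winter")
  expect_equal(nrow(wi$edges), 4L)

  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(su))
})
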