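# Small in-code fixtures shared across test files.

tiny_nodes <- function() {
  data.frame(
    node_id = c("FOX", "GOOSE", "SEAL", "PLANT"),
    label = c("Fox", "Goose", "Seal", "Plants"),
    guild = c("fox", "goose", "pinniped", "vascular plant"),
    realm = c("terrestrial", "terrestrial", "marine", "terrestrial"),
    n_species = c(1L, 3L, 5L, 40L),
    flagship = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# one quantitative summer study of the fox diet plus a winter case report
tiny_records <- function() {
  data.frame(
    study_id = c("S1", "S1", "S2"),
    pub_year = c(2001L, 2001L, 2015L),
    consumer = "FOX",
    resource = c("GOOSE", "SEAL", "PLANT"),
    layer = c("Pr", "Sc", "He"),
    metric_type = c("freq_occurrence", "freq_occurrence", "anecdotal"),
    raw_value = c(60, 40, NA),
    study_months = c("Jun;Jul", "Jun;Jul", "Dec;Jan"),
    study_type = c("quantitative", "quantitative", "case_study"),
    excluded_review = FALSE,
    stringsAsFactors = FALSE)
}

# quantitative record rows for one study-consumer group
quant_rows <- function(study = "S1", consumer = "FOX",
                       resources = c("GOOSE", "SEAL"),
                       raw = c(60, 40), metric = "freq_occurrence",
                       months = "Jun;Jul", layer = "Pr", year = 2000L) {
  data.frame(study_id = study, pub_year = year, consumer = consumer,
             resource = resources, layer = layer, metric_type = metric,
             raw_value = raw, study_months = months,
             study_type = "quantitative", excluded_review = FALSE,
             stringsAsFactors = FALSE)
}
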