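#' @title Bundled synthetic toy lexicon
#' @description
#' A deterministic, fully synthetic stand-in for the WordNet noun hierarchy
#' and a pretrained embedding table, shipped in code so that every
#' lexico-semantic feature is testable offline. The hypernym graph has about
#' 110 nodes rooted at `entity`, including the canonical specificity chain
#' entity -> animal -> dog -> bulldog (depths 1, 2, 3), with nouns at depths
#' 1 through 10 so all granularity bins are populated. The embedding table
#' covers every lexicon word plus verbs, adjectives, adverbs, stop words and
#' fillers, organized into a handful of clusters so that adjacent-word
#' distance series have controllable variance. It emulates none of the
#' distributional semantics of a real pretrained table.
#' @name toy_lexicon
NULL

# child -> parent edges of the synthetic noun taxonomy (depths shown for the
# reviewer's orientation only; depth = hypernym hops to "entity").
toy_taxonomy_edges <- function() {
  e <- c(
    # depth 1
    "animal", "entity", "person", "entity", "object", "entity",
    "substance", "entity", "event", "entity",
    # depth 2
    "dog", "animal", "cat", "animal", "bird", "animal", "horse", "animal",
    "child", "person", "adult", "person", "worker", "person",
    "artifact", "object", "rock", "object",
    "food", "substance", "liquid", "substance",
    "action", "event",
    # depth 3
    "bulldog", "dog", "poodle", "dog", "terrier", "dog",
    "tabby", "cat", "siamese", "cat",
    "sparrow", "bird", "penguin", "bird", "hawk", "bird",
    "pony", "horse",
    "boy", "child", "girl", "child", "toddler", "child",
    "mother", "adult", "father", "adult", "neighbor", "adult",
    "baker", "worker", "plumber", "worker",
    "instrumentality", "artifact", "furniture", "artifact",
    "structure", "artifact", "fabric", "artifact",
    "pebble", "rock",
    "cookie", "food", "cake", "food", "bread", "food", "fruit", "food",
    "water", "liquid", "milk", "liquid", "juice", "liquid",
    "theft", "action", "mishap", "action",
    # depth 4
    "utensil", "instrumentality", "container", "instrumentality",
    "device", "instrumentality",
    "stool", "furniture", "chair", "furniture", "table", "furniture",
    "cupboard", "furniture",
    "window", "structure", "curtain", "structure", "sink", "structure",
    "floor", "structure", "wall", "structure",
    "apron", "fabric", "towel", "fabric",
    "macaroon", "cookie", "shortbread", "cookie",
    "crumb", "bread", "apple", "fruit", "droplet", "water",
    "overflow", "mishap",
    # depth 5
    "spoon", "utensil", "knife", "utensil", "whisk", "utensil",
    "vessel", "container", "basket", "container",
    "machine", "device", "gadget", "device",
    "sash", "window", "pane", "window",
    "faucet", "sink", "drain", "sink",
    "shelf", "cupboard", "countertop", "table",
    # depth 6
    "cup", "vessel", "jar", "vessel", "bottle", "vessel",
    "appliance", "machine", "timer", "gadget",
    "spout", "faucet", "teaspoon", "spoon", "paring_knife", "knife",
    # depth 7
    "cookie_jar", "jar", "mason_jar", "jar", "flask", "bottle",
    "oven", "appliance", "mixer", "appliance",
    "teacup", "cup", "demitasse_spoon", "teaspoon",
    # depth 8
    "vial", "flask", "toaster_oven", "oven", "convection_oven", "oven",
    "stand_mixer", "mixer", "ceramic_jar", "cookie_jar",
    "espresso_cup", "teacup",
    # depth 9
    "ampoule", "vial", "mini_toaster", "toaster_oven",
    "dough_mixer", "stand_mixer", "glazed_jar", "ceramic_jar",
    # depth 10
    "micro_ampoule", "ampoule", "travel_toaster", "mini_toaster",
    "heirloom_jar", "glazed_jar"
  )
  m <- matrix(e, ncol = 2L, byrow = TRUE)
  data.frame(child = m[, 1], parent = m[, 2], stringsAsFactors = FALSE)
}

toy_word_lists <- function() {
  list(
    verb = c("run", "fall", "wash", "steal", "reach", "dry_off", "stand",
             "take", "give", "climb", "spill", "laugh", "ask", "see",
             "describe"),
    adjective = c("small", "tall", "wet", "sunny", "open", "full", "empty",
                  "happy", "busy", "quiet"),
    adverb = c("quickly", "slowly", "quietly", "carefully", "almost",
               "very", "outside", "nearby", "often", "again"),
    stop = c("the", "a", "an", "is", "was", "of", "in", "on", "and", "to",
             "it", "he", "she", "they", "that", "this", "with", "for",
             "at", "by"),
    filler = c("um", "uh", "well", "oh", "so", "like")
  )
}

#' Bundled toy hypernym graph and embedding table
#'
#' Deterministic: two calls with the same `language` return identical
#' objects. The `"es"` variant is a *synthetic second language*: the same
#' taxonomy shape and word lists with a `_es` suffix and an independently
#' generated (disjoint) embedding table, used by the transfer experiments.
#'
#' @param language `"en"` (default) or `"es"`.
#' @param dim embedding dimension (default 12).
#' @param n_clusters embedding cluster count (default 6).
#' @return list with `graph` (a [hypernym_graph()]), `embeddings`
#'   (an [embedding_table()]), `words` (POS word lists),
#'   `nouns_by_depth` (list: depth as character -> noun vector), and
#'   `clusters` (named cluster assignment used by the generator).
#' @export
bundled_toy_lexicon <- function(language = c("en", "es"), dim = 12L,
                                n_clusters = 6L) {
  language <- match.arg(language)
  edges <- toy_taxonomy_edges()
  words <- toy_word_lists()
  suffix <- if (language == "es") "_es" else ""
  if (nzchar(suffix)) {
    edges$child <- paste0(edges$child, suffix)
    edges$parent <- ifelse(edges$parent == "entity", "entity",
                           paste0(edges$parent, suffix))
    words <- lapply(words, function(w) paste0(w, suffix))
  }
  graph <- hypernym_graph(edges, root = "entity")
  nouns <- setdiff(graph$nodes, "entity")
  depths <- graph$depths[nouns]
  nouns_by_depth <- split(nouns, depths)

  vocab <- c("entity", nouns, unlist(words, use.names = FALSE))
  # deterministic cluster assignment and jittered cluster-centre vectors
  seed <- 20251015L + if (language == "es") 7919L else 0L
  vecs <- with_local_seed(seed, {
    cl <- sample(rep_len(seq_len(n_clusters), length(vocab)))
    centers <- matrix(0, n_clusters, dim)
    for (c_i in seq_len(n_clusters)) {
      centers[c_i, (2 * c_i - 1):(2 * c_i)] <- 1
    }
    v <- centers[cl, , drop = FALSE] +
      matrix(stats::rnorm(length(vocab) * dim, sd = 0.15),
             length(vocab), dim)
    rownames(v) <- vocab
    attr(v, "clusters") <- stats::setNames(cl, vocab)
    v
  })
  list(graph = graph,
       embeddings = embedding_table(vecs, language),
       words = words,
       nouns_by_depth = nouns_by_depth,
       clusters = attr(vecs, "clusters"))
}
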