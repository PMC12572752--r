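#' @title Lexico-semantic features
#' @description
#' Three families of vocabulary-selection features: word-class ratios (the
#' proportion of nouns, verbs, adjectives and adverbs, relative both to all
#' words and to content words only); semantic granularity (the minimum
#' hypernym-path length from a word's concept node to the root "entity" of a
#' noun hierarchy — more hops, more specific); and semantic variability (the
#' variance of the series of cosine distances between embedding vectors of
#' successive words). Feature names carry the modality prefix `lexsem__`.
#' @name lexsem_features
NULL

#' Construct a hypernym graph
#'
#' A directed acyclic graph of concept nodes whose edges point from a concept
#' to its hypernym(s), converging on a single root (conventionally
#' `"entity"`). Words may map to several nodes (senses).
#'
#' @param edges data.frame with columns `child`, `parent` (concept ids).
#' @param word_map optional data.frame with columns `word`, `node`; defaults
#'   to the identity map over all node ids.
#' @param root root node id (default `"entity"`).
#' @return object of class `hypernym_graph`.
#' @export
hypernym_graph <- function(edges, word_map = NULL, root = "entity") {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  nodes <- unique(c(edges$child, edges$parent, root))
  parents <- split(edges$parent, edges$child)
  if (is.null(word_map)) {
    word_map <- data.frame(word = nodes, node = nodes,
                           stringsAsFactors = FALSE)
  }
  word2nodes <- split(as.character(word_map$node), as.character(word_map$word))
  g <- structure(list(nodes = nodes, parents = parents,
                      word2nodes = word2nodes, root = root),
                 class = "hypernym_graph")
  depths <- node_depths(g)
  if (anyNA(depths)) {
    stop("root not reachable from node(s): ",
         paste(utils::head(names(depths)[is.na(depths)], 5L), collapse = ", "))
  }
  g$depths <- depths
  g
}

# BFS upward from every node; returns named vector of minimum edge counts to
# the root (NA when unreachable). Also serves as the acyclicity guard: a
# cycle disconnected from the root shows up as unreachable.
node_depths <- function(g) {
  depths <- stats::setNames(rep(NA_real_, length(g$nodes)), g$nodes)
  depths[g$root] <- 0
  frontier <- g$root
  children_of <- split(rep(names(g$parents), lengths(g$parents)),
                       unlist(g$parents, use.names = FALSE))
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt) & is.na(depths[nxt])]
    depths[nxt] <- d
    frontier <- nxt
  }
  depths
}

#' Load a hypernym graph from an edge-list TSV
#'
#' @param path TSV with header columns `child`, `parent` and optionally a
#'   second file-free `word_map` is not supported here; words default to node
#'   ids.
#' @param root root node id.
#' @return a [hypernym_graph()].
#' @export
read_hypernym_graph <- function(path, root = "entity") {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  hypernym_graph(edges, root = root)
}

#' Semantic granularity of a word
#'
#' Minimum number of hypernym edges between any of the word's concept nodes
#' and the root. The root itself has granularity 0; deeper (more specific)
#' concepts have larger values. Out-of-vocabulary words return `NA`.
#'
#' @param word character scalar.
#' @param graph a [hypernym_graph()].
#' @return non-negative integer depth, or `NA` for out-of-vocabulary words.
#' @export
granularity <- function(word, graph) {
  stopifnot(inherits(graph, "hypernym_graph"))
  nodes <- graph$word2nodes[[word]]
  if (is.null(nodes)) return(NA_real_)
  min(graph$depths[nodes])
}

#' Word-class ratios
#'
#' Proportion of each content-word class (noun, verb, adjective, adverb)
#' relative to the total word count and to the content-word count. With zero
#' content words the content-relative ratios are `NA` markers.
#'
#' @param transcript an [aligned_transcript()].
#' @return named numeric vector `lexsem__<pos>_ratio__{all,content}`.
#' @export
word_class_ratios <- function(transcript) {
  stopifnot(inherits(transcript, "aligned_transcript"))
  tok <- transcript$tokens
  if (nrow(tok) == 0L) stop("empty transcript")
  n_all <- nrow(tok)
  n_content <- sum(tok$is_content)
  out <- numeric(0)
  for (pos in CONTENT_POS) {
    cnt <- sum(tok$pos == pos)
    out[paste0("lexsem__", pos, "_ratio__all")] <- cnt / n_all
    out[paste0("lexsem__", pos, "_ratio__content")] <-
      if (n_content > 0L) cnt / n_content else NA_real_
  }
  out
}

#' Granularity features
#'
#' Six-moment summary of per-word granularity over in-vocabulary words, plus
#' the proportions of words with low, intermediate and high granularity
#' relative to the *total* word count (so the three proportions sum to the
#' in-vocabulary fraction). Out-of-vocabulary words are excluded from the
#' statistics, never zero-imputed.
#'
#' @param transcript an [aligned_transcript()].
#' @param graph a [hypernym_graph()].
#' @param bins length-2 numeric `(low_max, high_min)`: depths `<= low_max`
#'   are low, `>= high_min` high, the rest intermediate. Default `c(4, 8)`.
#' @param words which tokens to score: `"all"` (default) or `"content"`.
#' @return named numeric vector of `lexsem__granularity*` features.
#' @export
granularity_features <- function(transcript, graph, bins = c(4, 8),
                                 words = c("all", "content")) {
  words <- match.arg(words)
  stopifnot(inherits(transcript, "aligned_transcript"),
            length(bins) == 2L, bins[1] < bins[2])
  tok <- transcript$tokens
  if (words == "content") tok <- tok[tok$is_content, , drop = FALSE]
  n_total <- nrow(tok)
  depths <- vapply(tok$token, granularity, numeric(1), graph = graph,
                   USE.NAMES = FALSE)
  iv <- depths[!is.na(depths)]
  na6 <- c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
           kurtosis = NA_real_, min = NA_real_, max = NA_real_)
  st <- if (length(iv)) summary_stats(iv) else na6
  props <- if (n_total > 0L && length(iv)) {
    c(low = sum(iv <= bins[1]) / n_total,
      intermediate = sum(iv > bins[1] & iv < bins[2]) / n_total,
      high = sum(iv >= bins[2]) / n_total)
  } else c(low = NA_real_, intermediate = NA_real_, high = NA_real_)
  c(stats::setNames(st, paste0("lexsem__granularity__", names(st))),
    stats::setNames(props, paste0("lexsem__granularity_prop_", names(props))))
}

#' Construct an embedding table
#'
#' @param vectors numeric matrix, one row per word, rownames = words; all
#'   rows must have nonzero norm.
#' @param language language tag.
#' @return object of class `embedding_table`.
#' @export
embedding_table <- function(vectors, language = "und") {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("zero-norm embedding vector(s)")
  structure(list(vectors = vectors, dim = ncol(vectors), language = language),
            class = "embedding_table")
}

#' Read a word2vec-style text embedding table
#'
#' Format: optional first line `n d`, then one word followed by `d`
#' whitespace-separated floats per line.
#'
#' @param path file path.
#' @param language language tag.
#' @return an [embedding_table()].
#' @export
read_embedding_table <- function(path, language = "und") {
  lines <- readLines(path, encoding = "UTF-8")
  if (grepl("^\\s*\\d+\\s+\\d+\\s*$", lines[1])) lines <- lines[-1]
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(parts[[1]]) - 1L)))
  rownames(vecs) <- words
  embedding_table(vecs, language)
}

cosine_distance <- function(a, b) {
  1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Semantic variability
#'
#' Filters the token sequence per `variant`, maps words to embedding vectors,
#' computes the cosine (default) distance between each adjacent vector pair,
#' and returns the sample variance of that distance series. Variants:
#' `"content"` keeps content words; `"nonrep_all"` keeps all words but
#' collapses runs of identical adjacent word forms; `"nonrep_content"` keeps
#' content words then collapses runs. Out-of-vocabulary words are dropped
#' (with the filtering applied afterwards on the surviving sequence). Fewer
#' than two distances yields `NA`.
#'
#' @param transcript an [aligned_transcript()].
#' @param table an [embedding_table()].
#' @param variant one of `"content"`, `"nonrep_all"`, `"nonrep_content"`.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return scalar variance (>= 0) or `NA`.
#' @export
semantic_variability <- function(transcript, table,
                                 variant = c("content", "nonrep_all",
                                             "nonrep_content"),
                                 metric = c("cosine", "euclidean")) {
  variant <- match.arg(variant)
  metric <- match.arg(metric)
  stopifnot(inherits(transcript, "aligned_transcript"),
            inherits(table, "embedding_table"))
  tok <- transcript$tokens
  tok <- tok[tok$token %in% rownames(table$vectors), , drop = FALSE]
  if (variant %in% c("content", "nonrep_content")) {
    tok <- tok[tok$is_content, , drop = FALSE]
  }
  words <- tok$token
  if (variant %in% c("nonrep_all", "nonrep_content") && length(words) > 1L) {
    words <- words[c(TRUE, words[-1L] != words[-length(words)])]
  }
  if (length(words) < 3L) return(NA_real_)
  v <- table$vectors[words, , drop = FALSE]
  d <- vapply(seq_len(nrow(v) - 1L), function(i) {
    if (metric == "cosine") cosine_distance(v[i, ], v[i + 1L, ])
    else sqrt(sum((v[i, ] - v[i + 1L, ])^2))
  }, numeric(1))
  stats::var(d)
}

#' All lexico-semantic features for one transcript
#'
#' @param transcript an [aligned_transcript()].
#' @param graph a [hypernym_graph()].
#' @param table an [embedding_table()].
#' @param bins granularity bin boundaries, see [granularity_features()].
#' @return named numeric feature vector (modality prefix `lexsem__`).
#' @export
lexsem_features <- function(transcript, graph, table, bins = c(4, 8)) {
  sv <- vapply(c("content", "nonrep_all", "nonrep_content"),
               function(v) semantic_variability(transcript, table, v),
               numeric(1))
  c(word_class_ratios(transcript),
    granularity_features(transcript, graph, bins),
    stats::setNames(sv, paste0("lexsem__semantic_variability__", names(sv))))
}
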